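#' Poisson likelihood Hamiltonian
#'
#' Negative log-likelihood of photon counts under independent per-pixel
#' Poisson statistics with rate image `mu`:
#' `sum(mu - d * log(mu))`, dropping the data-only `log(d!)` term
#' (constant in `mu`). The per-pixel gradient `1 - d/mu` vanishes at
#' `mu = d`.
#'
#' @param d non-negative integer counts (vector or image).
#' @param mu positive rate image of the same shape.
#' @return Scalar Hamiltonian value.
#' @export
poisson_hamiltonian <- function(d, mu) {
  d <- as.numeric(d); mu <- as.numeric(mu)
  if (length(d) != length(mu)) stop("counts and rates must share shape")
  if (any(d < 0) || any(d != round(d))) stop("counts must be non-negative integers")
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("rates must be positive (clip before evaluating)")
  sum(mu - d * log(mu))
}

#' Inverse-gamma point-source prior
#'
#' Configuration of the brightness prior used in the imaging step: an
#' inverse-gamma distribution with shape `alpha` and scale `q`
#' (density proportional to `x^(-alpha-1) exp(-q/x)`), heavy-tailed so that
#' a few bright point sources over a faint background are a priori
#' plausible. `clip_floor` is the positivity clip applied to the predicted
#' signal response (the Poisson rates), not to the signal itself.
#'
#' @param alpha shape (> 0), default 1.
#' @param q scale (> 0, brightness units), default 1.
#' @param clip_floor minimum predicted rate (> 0), default 1e-8.
#' @return An object of class `bf_prior_config`.
#' @export
prior_config <- function(alpha = 1, q = 1, clip_floor = 1e-8) {
  stopifnot(alpha > 0, q > 0, clip_floor > 0)
  structure(list(alpha = alpha, q = q, clip_floor = clip_floor),
            class = "bf_prior_config")
}

#' Standardized inverse-gamma generative transform
#'
#' Maps standard-normal latent values through the inverse-gamma quantile
#' function, so a unit Gaussian prior on the latent field corresponds to an
#' inverse-gamma prior on the (strictly positive) signal. Monotone
#' increasing in the latent; `xi = 0` maps to the prior median
#' (`1/log(2) = 1.4427` for `alpha = q = 1`).
#'
#' @param xi latent values (standard-normal scale); vector or image.
#' @param cfg a [prior_config()].
#' @return Positive values in the shape of `xi`.
#' @export
inverse_gamma_transform <- function(xi, cfg = prior_config()) {
  if (any(!is.finite(xi))) stop("latent values must be finite")
  # X ~ InvGamma(alpha, q)  <=>  1/X ~ Gamma(alpha, rate = q);
  # quantile at p: 1 / qgamma(1 - p, alpha, rate = q), evaluated through
  # log upper-tail probabilities for stability in both tails.
  lp <- stats::pnorm(as.vector(xi), log.p = TRUE)
  out <- 1 / stats::qgamma(lp, shape = cfg$alpha, rate = cfg$q,
                           lower.tail = FALSE, log.p = TRUE)
  if (!is.null(dim(xi))) dim(out) <- dim(xi)
  out
}

# d(signal)/d(latent) of the quantile transform, via the density ratio
# dnorm(xi) / f_invgamma(s), computed in logs.
inverse_gamma_transform_deriv <- function(xi, s, cfg) {
  logf <- cfg$alpha * log(cfg$q) - lgamma(cfg$alpha) -
    (cfg$alpha + 1) * log(s) - cfg$q / s
  exp(stats::dnorm(xi, log = TRUE) - logf)
}

#' MAP image reconstruction with a trained butterfly response
#'
#' Bayesian point-source imaging: given Poisson photon counts and a trained
#' butterfly network standing in for the instrument response, the signal is
#' estimated by minimizing the joint Hamiltonian
#' `sum(mu - d log mu) + 0.5 * ||xi||^2` over a standard-normal latent
#' field `xi`, where the positive signal is `s = T(xi)` (the inverse-gamma
#' quantile transform of [inverse_gamma_transform()]) and the rates are the
#' signal response clipped from below, `mu = max(R s, clip_floor)`.
#' Minimization uses the same Newton-CG scheme as [train_map()] with a
#' Gauss-Newton curvature (`d/mu^2` weights on the response Jacobian, plus
#' the latent prior identity).
#'
#' @param counts non-negative integer count image (matrix or flattened
#'   vector).
#' @param response the trained response: a [bf_fit()] result, or a list of
#'   [bf_bco()] with attribute/argument `composition`.
#' @param prior a [prior_config()].
#' @param max_steps Newton step budget (default 100).
#' @param cg_tol,cg_max_iter CG controls as in [train_map()].
#' @param composition used when `response` is a plain BCO list.
#' @param laplace_sd if `TRUE`, also return a diagonal-curvature (Laplace)
#'   approximation of the posterior standard deviation of the signal — a
#'   labelled approximation, not a sampled posterior.
#' @return An object of class `butterfly_map`: `signal` (positive MAP
#'   estimate, image), `rates` (predicted signal response), `residuals`
#'   (absolute difference between counts and rates), `latent`, `trace`
#'   (non-increasing joint Hamiltonian), `status`, and optionally
#'   `signal_sd`.
#' @export
reconstruct_map <- function(counts, response, prior = prior_config(),
                            max_steps = 100, cg_tol = 1e-5,
                            cg_max_iter = 50,
                            composition = c("serial", "parallel"),
                            laplace_sd = FALSE) {
  if (inherits(response, "butterfly_fit")) {
    net <- response$network
    composition <- response$composition
    grid <- response$config$grid
  } else {
    net <- response
    if (inherits(net, "bf_bco")) net <- list(net)
    composition <- attr(net, "composition") %||% match.arg(composition)
    grid <- net[[1]]$grid
  }
  d_img <- counts
  d <- as.numeric(counts)
  if (length(d) != grid$n) stop("counts and response grids disagree")
  if (any(d < 0) || any(d != round(d)))
    stop("counts must be non-negative integers")
  eng <- compile_bcos(net, composition)
  ce <- compile_engine(eng)
  pl <- unname(eng$pars)
  floor_ <- prior$clip_floor

  resp_fwd <- function(s) {
    V <- as_cplx_mat(s, grid$n)
    Re(drop(Reduce(`+`, lapply(ce$progs, function(p) eng_fwd(p, pl, V)))))
  }
  resp_adj <- function(w) {
    W <- as_cplx_mat(w, grid$n)
    Re(drop(Reduce(`+`, lapply(ce$progs, function(p) eng_adjoint(p, pl, W)))))
  }

  state <- function(xi) {
    s <- inverse_gamma_transform(xi, prior)
    pre <- resp_fwd(s)
    mu <- pmax(pre, floor_)
    list(s = s, mu = mu, mask = as.numeric(pre > floor_),
         ds = inverse_gamma_transform_deriv(xi, s, prior))
  }

  obj <- list(
    x0 = numeric(grid$n),
    # +Inf (not an error) outside the representable range, so the line
    # search backs off from overflowing latent excursions
    value = function(xi) {
      st <- state(xi)
      if (any(!is.finite(st$mu))) return(Inf)
      poisson_hamiltonian(d, st$mu) + 0.5 * sum(xi^2)
    },
    value_grad = function(xi) {
      st <- state(xi)
      val <- poisson_hamiltonian(d, st$mu) + 0.5 * sum(xi^2)
      g <- resp_adj((1 - d / st$mu) * st$mask) * st$ds + xi
      list(value = val, grad = g, ctx = st)
    },
    hvp = function(st, v) {
      jv <- resp_fwd(st$ds * v) * st$mask
      resp_adj((d / st$mu^2) * jv * st$mask) * st$ds + v
    })

  res <- newton_cg(obj, max_steps, cg_tol, cg_max_iter)
  st <- state(res$x)
  shape_as <- function(v) if (!is.null(dim(d_img))) {
    dim(v) <- dim(d_img); v
  } else v
  out <- list(signal = shape_as(st$s), rates = shape_as(st$mu),
              residuals = shape_as(abs(d - st$mu)),
              latent = shape_as(res$x), counts = d_img,
              hamiltonian = res$value, trace = res$trace,
              status = res$status, steps = res$steps, grid = grid,
              prior = prior)
  if (laplace_sd) {
    hdiag <- vapply(seq_len(grid$n), function(i) {
      e <- numeric(grid$n); e[i] <- 1
      obj$hvp(st, e)[i]
    }, numeric(1))
    # latent-space curvature mapped to signal scale
    out$signal_sd <- shape_as(st$ds / sqrt(pmax(hdiag, .Machine$double.eps)))
  }
  structure(out, class = "butterfly_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.butterfly_map <- function(x, ...) {
  cat("<butterfly_map> MAP reconstruction on ", x$grid$rows, "x",
      x$grid$cols, "\n", sep = "")
  cat("  joint Hamiltonian: ", format(x$hamiltonian, digits = 6),
      " after ", x$steps, " accepted steps (", x$status, ")\n", sep = "")
  cat("  signal total: ", format(sum(x$signal), digits = 6),
      ", counts total: ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' Local maxima of an image on the pixel torus
#'
#' A pixel is a local maximum if its value is strictly greater than all
#' eight periodic neighbours. Used to match reconstructed point sources to
#' ground-truth positions.
#'
#' @param img matrix.
#' @return 0-based `n x 2` matrix of (row, col) positions.
#' @export
local_maxima <- function(img) {
  m <- nrow(img); l <- ncol(img)
  ri <- seq_len(m); ci <- seq_len(l)
  ok <- matrix(TRUE, m, l)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- img[((ri + dr - 1L) %% m) + 1L, ((ci + dc - 1L) %% l) + 1L]
    ok <- ok & (img > nb)
  }
  w <- which(ok, arr.ind = TRUE)
  cbind(row = w[, 1] - 1L, col = w[, 2] - 1L)
}
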