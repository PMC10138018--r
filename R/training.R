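#' Gaussian likelihood Hamiltonian
#'
#' Negative log-likelihood of the signal-response training data under
#' independent Gaussian noise with diagonal covariance:
#' `0.5 * sum((d - R(s))^2) / noise_variance`, dropping the constant
#' log-determinant term (irrelevant for MAP).
#'
#' @param targets observed/simulated responses (any numeric array).
#' @param predictions network predictions of the same shape.
#' @param noise_variance positive noise variance per data pixel.
#' @return Scalar Hamiltonian value.
#' @export
gaussian_likelihood_hamiltonian <- function(targets, predictions,
                                            noise_variance) {
  if (noise_variance <= 0) stop("noise_variance must be positive")
  if (length(targets) != length(predictions))
    stop("targets and predictions must have equal shape")
  0.5 * sum((as.numeric(targets) - as.numeric(predictions))^2) / noise_variance
}

#' Gaussian prior Hamiltonian on network parameters
#'
#' Independent Gaussian priors centred at the delta-peak initialization:
#' `0.5 * sum(((params - init_means) / prior_std)^2)`. Additive over
#' parameters.
#'
#' @param params flattened parameter vector.
#' @param init_means prior means (the initialization values).
#' @param prior_std prior standard deviation (default 1: unit variance).
#' @return Scalar Hamiltonian value.
#' @export
prior_hamiltonian <- function(params, init_means, prior_std = 1) {
  if (length(params) != length(init_means))
    stop("params and init_means must have equal length")
  0.5 * sum(((params - init_means) / prior_std)^2)
}

# fixed-order flatten/unflatten between the engine's named parameter list
# and the optimizer vector
par_layout <- function(pars) {
  lens <- lengths(pars)
  ends <- cumsum(lens)
  list(names = names(pars), lens = lens,
       starts = ends - lens + 1L, ends = ends, total = sum(lens))
}

flatten_pars <- function(pars) unlist(pars, use.names = FALSE)

unflatten_pars <- function(x, layout) {
  out <- vector("list", length(layout$names))
  names(out) <- layout$names
  for (i in seq_along(out))
    out[[i]] <- x[layout$starts[i]:layout$ends[i]]
  out
}

#' MAP objective for butterfly-network training
#'
#' Builds the joint Hamiltonian (Gaussian likelihood plus Gaussian priors
#' around the initialization) over the flattened network parameter vector,
#' with exact reverse-mode gradients and Gauss-Newton Hessian-vector
#' products derived from the operator algebra. Mainly of interest for
#' testing and custom optimizers; [train_map()] drives it.
#'
#' @param net list of [bf_bco()] (the initialization; also the prior means).
#' @param signals `N x P` matrix of training signals (columns are flattened
#'   images).
#' @param targets `N x P` matrix of corresponding responses.
#' @param noise_variance Gaussian noise variance per data pixel.
#' @param prior_std prior standard deviation around the initialization.
#' @param composition `"serial"` or `"parallel"`.
#' @param use_compiled use the compiled engine passes (default); `FALSE`
#'   selects the plain-R reference implementation of the same passes.
#' @return List of closures: `value(x)`, `value_grad(x)` (returns
#'   `list(value, grad, ctx)`), `hvp(ctx, v)` (Gauss-Newton product),
#'   plus `x0` (initial vector), `layout`, and `to_network(x)`.
#' @export
map_objective <- function(net, signals, targets, noise_variance,
                          prior_std = 1,
                          composition = c("serial", "parallel"),
                          use_compiled = TRUE) {
  composition <- match.arg(composition)
  if (noise_variance <= 0) stop("noise_variance must be positive")
  eng <- compile_bcos(net, composition)
  n <- eng$grid$n
  S <- as_cplx_mat(signals, n)
  D <- targets
  if (is.null(dim(D))) D <- matrix(D, nrow = n)
  if (!all(dim(D) == dim(S))) stop("signals and targets must share shape")
  layout <- par_layout(eng$pars)
  x0 <- flatten_pars(eng$pars)
  pv <- prior_std^2

  if (use_compiled) {
    ce <- compile_engine(eng)
    # one reusable tape per branch: a value_grad call overwrites it, and
    # hvp calls refer to the most recent value_grad point (which is how
    # newton_cg uses the closures)
    tapes <- lapply(ce$progs, function(p) eng_new_tape())
    sum_grads <- function(ctx, W) {
      gl <- NULL
      for (i in seq_along(ce$progs)) {
        r <- eng_vjp(ce$progs[[i]], ctx$pl, tapes[[i]], W)
        gl <- if (is.null(gl)) r$grads
              else mapply(`+`, gl, r$grads, SIMPLIFY = FALSE)
      }
      unlist(gl, use.names = FALSE)
    }
    value <- function(x) {
      pl <- unname(unflatten_pars(x, layout))
      y <- Re(Reduce(`+`, lapply(ce$progs, function(p) eng_fwd(p, pl, S))))
      0.5 * sum((y - D)^2) / noise_variance + 0.5 * sum((x - x0)^2) / pv
    }
    value_grad <- function(x) {
      pl <- unname(unflatten_pars(x, layout))
      y <- Re(Reduce(`+`, lapply(seq_along(ce$progs), function(i)
        eng_fwd_tape(ce$progs[[i]], pl, S, tapes[[i]]))))
      res <- y - D
      val <- 0.5 * sum(res^2) / noise_variance + 0.5 * sum((x - x0)^2) / pv
      W <- res / noise_variance
      storage.mode(W) <- "complex"
      ctx <- list(pl = pl)
      g <- sum_grads(ctx, W) + (x - x0) / pv
      list(value = val, grad = g, ctx = ctx)
    }
    hvp <- function(ctx, v) {
      dpl <- unname(unflatten_pars(v, layout))
      zero <- matrix(0+0i, nrow(S), ncol(S))
      dy <- Re(Reduce(`+`, lapply(seq_along(ce$progs), function(i)
        eng_jvp(ce$progs[[i]], ctx$pl, tapes[[i]], dpl, zero))))
      W <- dy / noise_variance
      storage.mode(W) <- "complex"
      sum_grads(ctx, W) + v / pv
    }
  } else {
    value <- function(x) {
      pars <- unflatten_pars(x, layout)
      out <- NULL
      for (br in eng$branches) {
        y <- run_fwd(br, pars, S)
        out <- if (is.null(out)) y else out + y
      }
      0.5 * sum((Re(out) - D)^2) / noise_variance +
        0.5 * sum((x - x0)^2) / pv
    }
    value_grad <- function(x) {
      pars <- unflatten_pars(x, layout)
      tapes <- lapply(eng$branches, function(br)
        run_fwd(br, pars, S, tape = TRUE))
      y <- Re(Reduce(`+`, lapply(tapes, `[[`, "out")))
      res <- y - D
      val <- 0.5 * sum(res^2) / noise_variance + 0.5 * sum((x - x0)^2) / pv
      W <- res / noise_variance
      storage.mode(W) <- "complex"
      acc <- new_grad_env(eng$pars)
      for (i in seq_along(eng$branches))
        run_vjp(eng$branches[[i]], pars, tapes[[i]], W, acc)
      g <- flatten_pars(grad_env_to_list(acc, eng$pars)) + (x - x0) / pv
      list(value = val, grad = g, ctx = list(pars = pars, tapes = tapes))
    }
    hvp <- function(ctx, v) {
      dpars <- unflatten_pars(v, layout)
      zero <- matrix(0+0i, nrow(S), ncol(S))
      dy <- NULL
      for (i in seq_along(eng$branches)) {
        d <- run_jvp(eng$branches[[i]], ctx$pars, ctx$tapes[[i]], dpars, zero)
        dy <- if (is.null(dy)) d else dy + d
      }
      W <- Re(dy) / noise_variance
      storage.mode(W) <- "complex"
      acc <- new_grad_env(eng$pars)
      for (i in seq_along(eng$branches))
        run_vjp(eng$branches[[i]], ctx$pars, ctx$tapes[[i]], W, acc)
      flatten_pars(grad_env_to_list(acc, eng$pars)) + v / pv
    }
  }

  to_network <- function(x)
    pars_to_bcos(unflatten_pars(x, layout), net)

  list(value = value, value_grad = value_grad, hvp = hvp,
       x0 = x0, layout = layout, to_network = to_network)
}

# Truncated conjugate gradient for the (positive definite) Gauss-Newton
# system H p = b.
cg_solve <- function(hvp_fun, b, tol, maxit) {
  x <- numeric(length(b))
  r <- b; d <- r
  rs <- sum(r^2)
  if (sqrt(rs) <= tol) return(x)
  for (i in seq_len(maxit)) {
    hd <- hvp_fun(d)
    dhd <- sum(d * hd)
    if (!is.finite(dhd) || dhd <= 0) break
    alpha <- rs / dhd
    x <- x + alpha * d
    r <- r - alpha * hd
    rs_new <- sum(r^2)
    if (sqrt(rs_new) <= tol) break
    d <- r + (rs_new / rs) * d
    rs <- rs_new
  }
  x
}

# Newton-CG driver with backtracking line search. `obj` is a map_objective.
newton_cg <- function(obj, max_steps, cg_tol = 1e-5, cg_max_iter = 100,
                      grad_tol = 0, verbose = FALSE) {
  x <- obj$x0
  trace <- numeric(0)
  status <- "max_steps"
  fg <- obj$value_grad(x)
  for (step in seq_len(max_steps)) {
    if (!is.finite(fg$value))
      stop("non-finite loss at step ", step, "; aborting")
    gnorm <- sqrt(sum(fg$grad^2))
    if (gnorm <= grad_tol) { status <- "gradient_converged"; break }
    p <- cg_solve(function(v) obj$hvp(fg$ctx, v), -fg$grad,
                  tol = cg_tol * gnorm, maxit = cg_max_iter)
    slope <- sum(fg$grad * p)
    if (!is.finite(slope) || slope >= 0) { # fall back to steepest descent
      p <- -fg$grad / gnorm
      slope <- -gnorm
    }
    alpha <- 1
    accepted <- FALSE
    for (ls in 1:40) {
      xn <- x + alpha * p
      vn <- obj$value(xn)
      if (is.finite(vn) && vn <= fg$value + 1e-4 * alpha * slope) {
        accepted <- TRUE; break
      }
      alpha <- alpha / 2
    }
    if (!accepted) { status <- "line_search_failed"; break }
    x <- xn
    fg <- obj$value_grad(x)
    trace <- c(trace, fg$value)
    if (verbose)
      message(sprintf("step %4d  loss %.6e  |grad| %.3e  alpha %.2e",
                      step, fg$value, sqrt(sum(fg$grad^2)), alpha))
  }
  list(x = x, value = fg$value, grad_norm = sqrt(sum(fg$grad^2)),
       trace = trace, status = status, steps = length(trace))
}

#' Per-pixel point-source training set
#'
#' The standard training data for approximating the synthetic response: one
#' signal-response pair per grid pixel, with the signal a point source of
#' fixed brightness at that pixel and the target the simulated response.
#'
#' @param model an [svpsf_model()], or a precomputed `response_stack`.
#' @param brightness point-source brightness (default 40).
#' @return List with `signals` and `targets` (`N x N` matrices, one column
#'   per source pixel) and the grid.
#' @export
training_pairs <- function(model, brightness = 40) {
  if (inherits(model, "svpsf_model")) {
    stack <- build_response_stack(model)
    grid <- model$grid
  } else if (inherits(model, "response_stack")) {
    stack <- model
    grid <- attr(model, "grid")
  } else stop("model must be an svpsf_model or a response_stack")
  n <- nrow(stack)
  list(signals = diag(brightness, n), targets = brightness * unclass(stack),
       grid = grid)
}

#' MAP training of a butterfly network
#'
#' Fits the network parameters (angles, phases, log-amplitudes and
#' spectra of every BCO) to signal-response pairs by minimizing the joint
#' Hamiltonian: Gaussian likelihood with diagonal noise covariance plus
#' independent Gaussian priors centred at the delta-peak initialization.
#' Minimization uses Newton-CG: truncated conjugate gradients on the
#' Gauss-Newton curvature (likelihood curvature plus prior identity, so the
#' CG system is positive definite) with a backtracking line search.
#' The procedure is deterministic: full-batch data, fixed initialization.
#'
#' @param config a [network_config()] (or preset) defining the architecture.
#' @param data list with `signals` and `targets` (`N x P` column-major
#'   matrices) and optionally `noise_variance`; see [training_pairs()].
#' @param noise_variance Gaussian noise variance per data pixel
#'   (default 1e-6, overridden by `data$noise_variance` if present).
#' @param prior_std prior standard deviation (default 1: unit variance).
#' @param max_steps maximum number of Newton steps (default 300).
#' @param cg_tol relative CG tolerance (times the gradient norm).
#' @param cg_max_iter CG iteration cap per Newton step.
#' @param optimizer `"newton_cg"` (default) or `"lbfgs"` (quasi-Newton
#'   fallback via [stats::optim()]).
#' @param verbose print per-step loss and gradient norm.
#' @return List with `network` (fitted [bf_bco()] list), `composition`,
#'   `trace` (loss per accepted step, non-increasing), `status`, `steps`,
#'   `value`, `grad_norm` and the initialization `network_init`.
#' @export
train_map <- function(config, data, noise_variance = 1e-6, prior_std = 1,
                      max_steps = 300, cg_tol = 1e-5, cg_max_iter = 100,
                      optimizer = c("newton_cg", "lbfgs"), verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  if (!is.null(data$noise_variance)) noise_variance <- data$noise_variance
  stopifnot(max_steps >= 1)
  net0 <- network_init(config)
  obj <- map_objective(net0, data$signals, data$targets, noise_variance,
                       prior_std, config$composition)
  if (optimizer == "newton_cg") {
    res <- newton_cg(obj, max_steps, cg_tol, cg_max_iter, verbose = verbose)
  } else {
    opt <- stats::optim(obj$x0,
                        fn = function(x) obj$value(x),
                        gr = function(x) obj$value_grad(x)$grad,
                        method = "L-BFGS-B",
                        control = list(maxit = max_steps))
    res <- list(x = opt$par, value = opt$value, grad_norm = NA_real_,
                trace = opt$value, status = "lbfgs", steps = opt$counts[1])
  }
  list(network = obj$to_network(res$x), composition = config$composition,
       trace = res$trace, status = res$status, steps = res$steps,
       value = res$value, grad_norm = res$grad_norm, network_init = net0)
}

#' Fit a butterfly response representation
#'
#' The top-level model-fitting interface: trains a butterfly convolution
#' network to reproduce a (simulated) spatially variant instrument response
#' from per-pixel point-source signal-response pairs by MAP, then evaluates
#' the approximation quality against the full response stack.
#'
#' @param model an [svpsf_model()] (ground truth generator) or a
#'   precomputed `response_stack`.
#' @param config a [network_config()] or a preset name (`"net1"` ...
#'   `"net7"`, resolved on the model's grid).
#' @param brightness training point-source brightness (default 40).
#' @param noise_variance Gaussian noise variance (default 1e-6).
#' @param prior_std prior standard deviation (default 1).
#' @param max_steps Newton step budget (default 300).
#' @param ... further arguments passed to [train_map()].
#' @return An object of class `butterfly_fit` with methods [print()],
#'   [summary()], [coef()], [predict()], [fitted()], [residuals()] and
#'   [plot()]. Elements include `network` (fitted BCOs), `error_map`,
#'   `zeta`, `trace` and the training configuration.
#' @examples
#' \donttest{
#' mod <- svpsf_model(bf_grid(8))
#' fit <- bf_fit(mod, network_preset("net1", bf_grid(8)), max_steps = 25)
#' summary(fit)
#' }
#' @export
bf_fit <- function(model, config, brightness = 40, noise_variance = 1e-6,
                   prior_std = 1, max_steps = 300, ...) {
  if (is.character(config)) {
    grid <- if (inherits(model, "svpsf_model")) model$grid
            else attr(model, "grid")
    config <- network_preset(config, grid)
  }
  stopifnot(inherits(config, "bf_network_config"))
  data <- training_pairs(model, brightness)
  if (!identical(data$grid$n, config$grid$n))
    stop("model and network grids disagree")
  res <- train_map(config, data, noise_variance = noise_variance,
                   prior_std = prior_std, max_steps = max_steps, ...)
  sim <- structure(data$targets / brightness, grid = data$grid,
                   class = c("response_stack", "matrix"))
  but <- network_response_stack(res$network, config$composition)
  em <- error_map(sim, but)
  structure(list(network = res$network, composition = config$composition,
                 config = config, model = model,
                 sim_stack = sim, but_stack = but,
                 error_map = em, zeta = em$zeta,
                 trace = res$trace, status = res$status, steps = res$steps,
                 loss = res$value, grad_norm = res$grad_norm,
                 brightness = brightness, noise_variance = noise_variance,
                 prior_std = prior_std),
            class = "butterfly_fit")
}

#' @export
print.butterfly_fit <- function(x, ...) {
  cat("Butterfly response fit\n")
  print(x$config)
  cat("  ", x$steps, " accepted Newton steps (", x$status, ")\n", sep = "")
  cat("  final joint Hamiltonian: ", format(x$loss, digits = 6), "\n", sep = "")
  cat("  total approximation error zeta: ",
      format(100 * x$zeta, digits = 4), "%\n", sep = "")
  invisible(x)
}

#' @export
summary.butterfly_fit <- function(object, ...) {
  eps <- as.vector(object$error_map$epsilon)
  structure(list(config = object$config,
                 n_parameters = count_parameters(object$config),
                 density = network_density(object$config),
                 zeta = object$zeta,
                 epsilon = c(min = min(eps), mean = mean(eps),
                             max = max(eps)),
                 steps = object$steps, status = object$status,
                 loss = object$loss),
            class = "summary.butterfly_fit")
}

#' @export
print.summary.butterfly_fit <- function(x, ...) {
  print(x$config)
  cat("  parameters: ", x$n_parameters, "  (density ",
      format(x$density, digits = 4), "%)\n", sep = "")
  cat("  zeta: ", format(100 * x$zeta, digits = 4), "%\n", sep = "")
  cat("  epsilon: min ", format(x$epsilon["min"], digits = 3),
      ", mean ", format(x$epsilon["mean"], digits = 3),
      ", max ", format(x$epsilon["max"], digits = 3), "\n", sep = "")
  cat("  ", x$steps, " accepted steps (", x$status, "), final loss ",
      format(x$loss, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
coef.butterfly_fit <- function(object, ...) {
  eng <- compile_bcos(object$network, object$composition)
  unlist(eng$pars)
}

#' @export
fitted.butterfly_fit <- function(object, ...) object$but_stack

#' @export
residuals.butterfly_fit <- function(object, ...)
  approximation_error(unclass(object$sim_stack), unclass(object$but_stack))

#' Predict responses with a fitted butterfly network
#'
#' Applies the fitted operator to new signals.
#'
#' @param object a [bf_fit()] result.
#' @param newdata signal image (matrix), flattened vector, or `N x k`
#'   matrix of flattened signals.
#' @param ... unused.
#' @return Predicted response in the shape of `newdata`.
#' @export
predict.butterfly_fit <- function(object, newdata, ...) {
  grid <- object$config$grid
  is_image <- is.matrix(newdata) && nrow(newdata) == grid$rows &&
    ncol(newdata) == grid$cols && nrow(newdata) != grid$n
  if (is_image) {
    out <- network_apply(object$network, as.vector(newdata),
                         object$composition)
    return(matrix(out, grid$rows, grid$cols))
  }
  network_apply(object$network, newdata, object$composition)
}
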