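#' Spatially variant Gaussian PSF model
#'
#' The synthetic ground-truth instrument response: every point source at
#' pixel `z` is blurred with a rotationally symmetric, zero-centred Gaussian
#' whose variance grows quadratically with the source's relative distance
#' from the image centre,
#' \deqn{\sigma^2(\hat r) = \beta \hat r^2 + \eta, \qquad
#'       \hat r = \|c - z\|_2 / r_{max} \in [0, 1],}
#' so central sources stay sharp while sources near the border are blurred
#' broadly. Kernels are evaluated with periodic boundaries (minimal-image
#' wrap on the pixel torus).
#'
#' Units: `beta` and `eta` are variances in image-normalized length units
#' (the longer image side has length 1), which keeps them
#' resolution-independent; kernels are evaluated in pixel units with
#' `sigma2_pix = sigma2 * max(rows, cols)^2`. Pixel coordinates are 0-based
#' and pixel-centred; the image centre `c = ((rows-1)/2, (cols-1)/2)` lies
#' between pixels for even sizes, and `r_max` is the distance from `c` to
#' the farthest pixel centre.
#'
#' @param grid a [bf_grid()].
#' @param beta variance slope (default 0.01).
#' @param eta variance floor (default 1e-5); must be positive.
#' @param renormalize if `TRUE`, divide each discrete kernel by its pixel
#'   sum. The default keeps the continuous prefactor `1/(2 pi sigma2)`
#'   without renormalization, so near-singular central kernels concentrate
#'   their mass in one pixel at the model's native brightness scale.
#' @return An object of class `svpsf_model`.
#' @examples
#' mod <- svpsf_model(bf_grid(16))
#' variance_profile(mod, c(7.5, 7.5))  # eta at the centre
#' @export
svpsf_model <- function(grid, beta = 0.01, eta = 1e-5, renormalize = FALSE) {
  stopifnot(inherits(grid, "bf_grid"), beta >= 0, eta > 0)
  m <- grid$rows; l <- grid$cols
  centre <- c((m - 1) / 2, (l - 1) / 2)
  rows <- rep(0:(m - 1L), times = l); cols <- rep(0:(l - 1L), each = m)
  rmax <- sqrt(max((rows - centre[1])^2 + (cols - centre[2])^2))
  structure(list(grid = grid, beta = beta, eta = eta, centre = centre,
                 rmax = rmax, scale = max(m, l),
                 renormalize = isTRUE(renormalize)),
            class = "svpsf_model")
}

#' @export
print.svpsf_model <- function(x, ...) {
  cat("<svpsf_model> ", x$grid$rows, "x", x$grid$cols,
      ", beta = ", x$beta, ", eta = ", x$eta, "\n", sep = "")
  invisible(x)
}

check_on_grid <- function(model, z) {
  z <- as.numeric(z)
  if (length(z) != 2 || any(!is.finite(z)) ||
      z[1] < 0 || z[1] > model$grid$rows - 1 ||
      z[2] < 0 || z[2] > model$grid$cols - 1)
    stop("source position must be a (row, col) pixel coordinate on the grid")
  z
}

#' Position-dependent PSF variance
#'
#' Relative distance of the source from the image centre,
#' `rhat = ||c - z|| / r_max`, mapped to the Gaussian variance
#' `beta * rhat^2 + eta` (image-normalized units).
#'
#' @param model an [svpsf_model()].
#' @param z source pixel coordinate `c(row, col)`, 0-based.
#' @return The variance `sigma2(rhat)`.
#' @export
variance_profile <- function(model, z) {
  z <- check_on_grid(model, z)
  rhat <- sqrt(sum((z - model$centre)^2)) / model$rmax
  model$beta * rhat^2 + model$eta
}

# squared periodic pixel distance of every pixel from pixel (0, 0)
periodic_rho2 <- function(grid) {
  m <- grid$rows; l <- grid$cols
  dr <- pmin(0:(m - 1L), m - 0:(m - 1L))
  dc <- pmin(0:(l - 1L), l - 0:(l - 1L))
  outer(dr^2, dc^2, "+")
}

#' Gaussian PSF kernel for one source position
#'
#' The zero-centred blur kernel a point source at `z` is convolved with:
#' `exp(-rho^2 / (2 sigma2_pix)) / (2 pi sigma2_pix)` where `rho` is the
#' periodic (minimal-image) pixel distance from the origin pixel and
#' `sigma2_pix` the variance of [variance_profile()] converted to pixel
#' units. Returned centred at pixel (0, 0); [apply_synthetic_response()]
#' translates it to the source position.
#'
#' @inheritParams variance_profile
#' @return `rows x cols` matrix.
#' @export
psf_kernel <- function(model, z) {
  s2p <- variance_profile(model, z) * model$scale^2
  k <- exp(-periodic_rho2(model$grid) / (2 * s2p)) / (2 * pi * s2p)
  if (model$renormalize) k <- k / sum(k)
  k
}

#' Apply the spatially variant synthetic response
#'
#' Discrete version of the response integral: the output at pixel `y` is
#' the sum over source pixels `x` of `PSF(y - x, x) * s(x)` with periodic
#' wrap, i.e. every source pixel contributes its own position-dependent
#' kernel, translated to its location. Linear in `s`.
#'
#' @param model an [svpsf_model()].
#' @param s signal image: `rows x cols` matrix or column-major flattened
#'   vector of length `N`.
#' @return Response image in the same shape as `s`.
#' @export
apply_synthetic_response <- function(model, s) {
  m <- model$grid$rows; l <- model$grid$cols
  was_vec <- is.null(dim(s))
  if (was_vec) {
    if (length(s) != model$grid$n) stop("signal length must be N = ", model$grid$n)
    s <- matrix(s, m, l)
  } else if (!all(dim(s) == c(m, l))) {
    stop("signal must be a ", m, "x", l, " image")
  }
  out <- matrix(0, m, l)
  nz <- which(s != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(nz))) {
    r0 <- nz[i, 1] - 1L; c0 <- nz[i, 2] - 1L
    k <- psf_kernel(model, c(r0, c0))
    # translate kernel to the source position (periodic)
    ridx <- ((0:(m - 1L) - r0) %% m) + 1L
    cidx <- ((0:(l - 1L) - c0) %% l) + 1L
    out <- out + s[nz[i, 1], nz[i, 2]] * k[ridx, cidx]
  }
  if (was_vec) as.vector(out) else out
}

#' Full response stack of the synthetic model
#'
#' One response image per source pixel: column `z` (column-major pixel
#' order) holds the flattened response to a unit point source at `z`. The
#' stack is the dense matrix representation of the synthetic response
#' operator; a 16x16 grid yields 256 responses of 256 pixels.
#'
#' @param model an [svpsf_model()].
#' @return `N x N` matrix of class `response_stack` with the grid attached
#'   as attribute `grid`.
#' @export
build_response_stack <- function(model) {
  m <- model$grid$rows; l <- model$grid$cols; n <- model$grid$n
  stack <- matrix(0, n, n)
  for (z in seq_len(n)) {
    r0 <- (z - 1L) %% m; c0 <- (z - 1L) %/% m
    k <- psf_kernel(model, c(r0, c0))
    ridx <- ((0:(m - 1L) - r0) %% m) + 1L
    cidx <- ((0:(l - 1L) - c0) %% l) + 1L
    stack[, z] <- as.vector(k[ridx, cidx])
  }
  structure(stack, grid = model$grid, class = c("response_stack", "matrix"))
}

#' Response stack realized by a butterfly network
#'
#' Evaluates the network on every unit point source, giving the stack that
#' can be compared against [build_response_stack()] with [error_map()] and
#' [total_error()].
#'
#' @inheritParams network_apply
#' @return `N x N` matrix of class `response_stack`.
#' @export
network_response_stack <- function(net, composition = c("serial", "parallel")) {
  if (inherits(net, "bf_bco")) net <- list(net)
  M <- materialize_matrix(net, match.arg(composition), cap = Inf)
  structure(M, grid = net[[1]]$grid, class = c("response_stack", "matrix"))
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
  }
  force(expr)
}

#' Simulate a point-source scene
#'
#' Draws point sources at uniformly random distinct pixels with
#' uniformly distributed brightness values; the reference configuration is
#' 15 sources with brightness between 900 and 1000.
#'
#' @param grid a [bf_grid()].
#' @param n_sources number of point sources (at most `N`).
#' @param brightness_range length-2 interval for uniform brightness draws.
#' @param seed integer seed making the scene reproducible.
#' @return An object of class `bf_scene`: positions (0-based `n x 2` matrix
#'   of row/col), brightness vector, grid and seed. [scene_image()] rasters
#'   it.
#' @export
simulate_scene <- function(grid, n_sources = 15,
                           brightness_range = c(900, 1000), seed = 1) {
  stopifnot(inherits(grid, "bf_grid"))
  if (n_sources > grid$n)
    stop("cannot place ", n_sources, " sources on ", grid$n, " pixels")
  with_seed(seed, {
    pix <- sample.int(grid$n, n_sources) - 1L
    bright <- stats::runif(n_sources, brightness_range[1], brightness_range[2])
    structure(list(positions = cbind(row = pix %% grid$rows,
                                     col = pix %/% grid$rows),
                   brightness = bright, grid = grid, seed = seed),
              class = "bf_scene")
  })
}

#' @export
print.bf_scene <- function(x, ...) {
  cat("<bf_scene> ", nrow(x$positions), " sources on ", x$grid$rows, "x",
      x$grid$cols, ", brightness [", round(min(x$brightness), 1), ", ",
      round(max(x$brightness), 1), "]\n", sep = "")
  invisible(x)
}

#' @rdname simulate_scene
#' @param scene a `bf_scene`.
#' @export
scene_image <- function(scene) {
  img <- matrix(0, scene$grid$rows, scene$grid$cols)
  img[cbind(scene$positions[, 1] + 1L, scene$positions[, 2] + 1L)] <-
    scene$brightness
  img
}

#' Poisson observation of a rate image
#'
#' Independent Poisson draws per pixel. Negative rates are clipped to zero
#' with a warning (they can arise from approximation error in a learned
#' response).
#'
#' @param rates non-negative rate image (matrix or vector).
#' @param seed integer seed.
#' @return Integer counts in the shape of `rates`.
#' @export
poisson_observe <- function(rates, seed = 1) {
  if (any(!is.finite(rates))) stop("rates must be finite")
  if (any(rates < 0)) {
    warning("negative rates clipped to zero")
    rates[rates < 0] <- 0
  }
  counts <- with_seed(seed, stats::rpois(length(rates), as.vector(rates)))
  if (!is.null(dim(rates))) dim(counts) <- dim(rates)
  counts
}
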