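#' Butterfly convolution operator (BCO)
#'
#' A convolution-like operator built from butterfly transforms and a complex
#' diagonal spectrum: mirrored `O = B' L B` (shared parameters between
#' analysis and synthesis, `B'` the conjugate transpose of the full,
#' possibly non-unitary `B`) or non-mirrored `O = B1' L B2` with independent
#' transforms. The diagonal `L = diag(exp(lambda))` plays the role of the
#' Fourier-transformed point spread function; for a spatially invariant PSF
#' and FFT-configured transforms the operator is exactly a circular
#' convolution.
#'
#' @param b1 a [butterfly_params()]: the synthesis transform (applied as its
#'   adjoint). In the mirrored architecture it is also the analysis transform.
#' @param lambda complex vector of length `N`: the log-spectrum
#'   \eqn{\lambda}; the operator multiplies by `exp(lambda)` in transform
#'   space. `lambda = 0` with FFT-initialized transforms gives the identity
#'   (convolution with a unit delta peak).
#' @param b2 analysis transform for the non-mirrored architecture, or
#'   `NULL` (mirrored).
#' @return An object of class `bf_bco`.
#' @examples
#' g <- bf_grid(4, 4)
#' op <- bf_bco(fft_initialization(g, "flat"), lambda = rep(0+0i, g$n))
#' v <- rnorm(g$n)
#' max(abs(bco_apply(op, v) - v))  # delta initialization: identity
#' @export
bf_bco <- function(b1, lambda, b2 = NULL) {
  stopifnot(inherits(b1, "butterfly_params"))
  if (!is.null(b2)) {
    stopifnot(inherits(b2, "butterfly_params"))
    if (!identical(b2$grid, b1$grid) || !identical(b2$design, b1$design))
      stop("b1 and b2 must share grid and design")
  }
  lambda <- as.complex(lambda)
  if (length(lambda) != b1$grid$n)
    stop("lambda must have length N = ", b1$grid$n)
  if (!all(is.finite(Re(lambda)) & is.finite(Im(lambda))))
    stop("lambda entries must be finite")
  structure(list(mirrored = is.null(b2), design = b1$design,
                 grid = b1$grid, b1 = b1, b2 = b2, lambda = lambda),
            class = "bf_bco")
}

#' @export
print.bf_bco <- function(x, ...) {
  cat("<bf_bco> ", if (x$mirrored) "mirrored" else "non-mirrored", ", ",
      x$design, " design on ", x$grid$rows, "x", x$grid$cols, "\n", sep = "")
  invisible(x)
}

#' Delta-peak initialized BCO
#'
#' A BCO whose transforms are FFT-initialized and whose spectrum is
#' `exp(lambda) = 1` (`lambda = 0`), so the operator is exactly the
#' identity: a convolution with a unit delta peak. This is the starting
#' point of MAP training.
#'
#' @param grid a [bf_grid()].
#' @param design `"flat"` or `"two_d"`.
#' @param mirrored logical; share parameters between analysis and synthesis?
#' @return A `bf_bco`.
#' @export
bco_delta_init <- function(grid, design = c("flat", "two_d"),
                           mirrored = TRUE) {
  design <- match.arg(design)
  b1 <- fft_initialization(grid, design)
  bf_bco(b1, lambda = complex(real = numeric(grid$n)),
         b2 = if (!mirrored) fft_initialization(grid, design))
}

#' Apply a complex log-spectrum diagonal
#'
#' Entrywise multiplication by `exp(lambda)`, the diagonal operator
#' standing between analysis and synthesis transforms of a BCO.
#'
#' @param lambda complex vector.
#' @param v complex (or real) vector of the same length.
#' @return Complex vector.
#' @export
lambda_apply <- function(lambda, v) {
  if (length(lambda) != length(v))
    stop("lambda and v must have equal length")
  exp(as.complex(lambda)) * as.complex(v)
}

# Compile a list of BCOs into engine programs + a flat parameter list.
# Serial composition R = O1 ... On applies On first, so programs are
# concatenated in reverse BCO order into a single branch; parallel
# composition keeps one branch per BCO and sums the outputs.
compile_bcos <- function(bcos, composition = c("serial", "parallel")) {
  composition <- match.arg(composition)
  stopifnot(length(bcos) >= 1)
  grid <- bcos[[1]]$grid
  pars <- list()
  progs <- vector("list", length(bcos))
  for (i in seq_along(bcos)) {
    op <- bcos[[i]]
    if (!identical(op$grid, grid)) stop("all BCOs must share one grid")
    plan <- bf_plan(grid, op$design)
    pre <- paste0("o", i)
    p1 <- paste0(pre, ".b1")
    pars <- c(pars, params_to_pars(op$b1, p1))
    ana <- p1
    if (!op$mirrored) {
      ana <- paste0(pre, ".b2")
      pars <- c(pars, params_to_pars(op$b2, ana))
    }
    lre <- paste0(pre, ".la.re"); lim <- paste0(pre, ".la.im")
    pars[[lre]] <- Re(op$lambda); pars[[lim]] <- Im(op$lambda)
    progs[[i]] <- c(prog_butterfly(plan, ana),
                    list(op_lam(lre, lim)),
                    prog_butterfly_adjoint(plan, p1))
  }
  branches <- if (composition == "serial")
    list(do.call(c, rev(progs))) else progs
  list(branches = branches, pars = pars, grid = grid,
       composition = composition)
}

# Rebuild bf_bco objects from an engine parameter list.
pars_to_bcos <- function(pars, bcos_template) {
  out <- bcos_template
  for (i in seq_along(out)) {
    pre <- paste0("o", i)
    op <- out[[i]]
    b1 <- pars_to_params(pars, paste0(pre, ".b1"), op$grid, op$design)
    b2 <- if (!op$mirrored)
      pars_to_params(pars, paste0(pre, ".b2"), op$grid, op$design)
    lambda <- complex(real = pars[[paste0(pre, ".la.re")]],
                      imaginary = pars[[paste0(pre, ".la.im")]])
    out[[i]] <- bf_bco(b1, lambda, b2)
  }
  out
}

run_network <- function(eng, V) {
  out <- NULL
  for (br in eng$branches) {
    y <- run_fwd(br, eng$pars, V)
    out <- if (is.null(out)) y else out + y
  }
  out
}

#' Apply a butterfly convolution operator
#'
#' Computes `B1' (exp(lambda) * (B2 v))` (non-mirrored) or the mirrored
#' variant with shared parameters. Linear in `v`; output is complex.
#'
#' @param op a [bf_bco()].
#' @param v complex or real vector of length `N`, or an `N x k` matrix.
#' @return Complex vector/matrix of the same shape.
#' @export
bco_apply <- function(op, v) {
  stopifnot(inherits(op, "bf_bco"))
  eng <- compile_bcos(list(op))
  vec <- is.null(dim(v))
  out <- run_network(eng, as_cplx_mat(v, op$grid$n))
  if (vec) drop(out) else out
}

#' Apply a butterfly network
#'
#' Serial composition applies the operators sequentially
#' (`R s = O1 ... On s`, the last listed operator acting first); parallel
#' composition sums the individual operator outputs
#' (`R s = (O1 + ... + On) s`, a plain unweighted sum). The instrument
#' responses being modelled are real images, so the real part of the final
#' complex vector is returned.
#'
#' @param net list of [bf_bco()] objects sharing one grid.
#' @param v real or complex vector of length `N` (column-major flattened
#'   image), or an `N x k` matrix of signals.
#' @param composition `"serial"` or `"parallel"`.
#' @return Real vector/matrix of the same shape as `v`.
#' @export
network_apply <- function(net, v, composition = c("serial", "parallel")) {
  if (inherits(net, "bf_bco")) net <- list(net)
  if (length(net) == 0) stop("empty network")
  eng <- compile_bcos(net, match.arg(composition))
  vec <- is.null(dim(v))
  out <- Re(run_network(eng, as_cplx_mat(v, eng$grid$n)))
  if (vec) drop(out) else out
}

#' Network architecture configuration
#'
#' Describes a butterfly network: how many BCOs, mirrored or not, flat or
#' 2D design, serial or parallel composition, on which grid. The named
#' presets `"net1"` to `"net7"` are the seven architectures compared in the
#' package's reference experiment: 1/2/3 mirrored flat serial BCOs
#' (net1-net3), 3 non-mirrored flat serial (net4), 3 mirrored 2D serial
#' (net5), 3 non-mirrored 2D serial (net6) and 3 non-mirrored flat parallel
#' (net7).
#'
#' @param grid a [bf_grid()].
#' @param n_bcos number of butterfly convolution operators.
#' @param mirrored logical.
#' @param design `"flat"` or `"two_d"`.
#' @param composition `"serial"` or `"parallel"`.
#' @return An object of class `bf_network_config`.
#' @export
network_config <- function(grid, n_bcos = 1, mirrored = TRUE,
                           design = c("flat", "two_d"),
                           composition = c("serial", "parallel")) {
  stopifnot(inherits(grid, "bf_grid"), n_bcos >= 1)
  structure(list(grid = grid, n_bcos = as.integer(n_bcos),
                 mirrored = isTRUE(mirrored), design = match.arg(design),
                 composition = match.arg(composition)),
            class = "bf_network_config")
}

#' @rdname network_config
#' @param preset one of `"net1"` ... `"net7"`.
#' @export
network_preset <- function(preset, grid) {
  spec <- switch(preset,
    net1 = list(1, TRUE,  "flat",  "serial"),
    net2 = list(2, TRUE,  "flat",  "serial"),
    net3 = list(3, TRUE,  "flat",  "serial"),
    net4 = list(3, FALSE, "flat",  "serial"),
    net5 = list(3, TRUE,  "two_d", "serial"),
    net6 = list(3, FALSE, "two_d", "serial"),
    net7 = list(3, FALSE, "flat",  "parallel"),
    stop("unknown preset: ", preset))
  network_config(grid, spec[[1]], spec[[2]], spec[[3]], spec[[4]])
}

#' @export
print.bf_network_config <- function(x, ...) {
  cat("<bf_network_config> ", x$n_bcos, " ",
      if (x$mirrored) "mirrored" else "non-mirrored", " ", x$design,
      " BCO(s), ", x$composition, " on ", x$grid$rows, "x", x$grid$cols,
      " (", count_parameters(x), " parameters)\n", sep = "")
  invisible(x)
}

#' Instantiate a network at the delta-peak initialization
#'
#' @param config a [network_config()] or preset name with `grid`.
#' @return List of [bf_bco()] objects (the network), with the composition
#'   mode attached as attribute `composition`.
#' @export
network_init <- function(config) {
  stopifnot(inherits(config, "bf_network_config"))
  net <- lapply(seq_len(config$n_bcos), function(i)
    bco_delta_init(config$grid, config$design, config$mirrored))
  attr(net, "composition") <- config$composition
  net
}

# real parameters of one butterfly transform
count_butterfly_params <- function(grid, design) {
  m <- grid$rows; l <- grid$cols; N <- grid$n
  if (design == "flat") {
    (N %/% 2L) * log2int(N) + 2L * N * log2int(N)
  } else {
    (m %/% 2L) * log2int(m) + (l %/% 2L) * log2int(l) +
      2L * N * log2int(max(m, l))
  }
}

#' Count real network parameters
#'
#' Total number of real scalar degrees of freedom of a butterfly network:
#' per transform the angle, phase and log-amplitude counts (flat design on
#' `N` pixels: `N/2*log2(N)` angles and `N*log2(N)` each of phases and
#' log-amplitudes; 2D design on `m x l`: `m/2*log2(m) + l/2*log2(l)` angles
#' and `m*l*log2(max(m,l))` each of phases and log-amplitudes), per BCO one
#' transform (mirrored) or two (non-mirrored) plus `2N` reals for the
#' complex spectrum. The composition mode does not change the count.
#'
#' @param net a [network_config()] or a list of [bf_bco()] objects.
#' @return Integer parameter count.
#' @examples
#' count_parameters(network_preset("net1", bf_grid(16)))  # 5632
#' @export
count_parameters <- function(net) {
  if (inherits(net, "bf_network_config")) {
    b <- count_butterfly_params(net$grid, net$design)
    per <- (if (net$mirrored) 1L else 2L) * b + 2L * net$grid$n
    return(net$n_bcos * per)
  }
  if (inherits(net, "bf_bco")) net <- list(net)
  sum(vapply(net, function(op) {
    b <- count_butterfly_params(op$grid, op$design)
    (if (op$mirrored) 1L else 2L) * b + 2L * op$grid$n
  }, numeric(1)))
}

#' Network density
#'
#' Ratio of the number of network parameters to the entry count `N^2` of an
#' equivalent dense matrix representation, in percent.
#'
#' @inheritParams count_parameters
#' @param grid the grid (taken from `net` if omitted).
#' @return Density in percent.
#' @export
network_density <- function(net, grid = NULL) {
  if (is.null(grid))
    grid <- if (inherits(net, "bf_network_config")) net$grid else net[[1]]$grid
  100 * count_parameters(net) / as.numeric(grid$n)^2
}

#' Materialize a network as a dense matrix
#'
#' Column `j` is the network applied to the `j`-th standard basis vector.
#' Intended for oracles and error evaluation on small grids.
#'
#' @inheritParams network_apply
#' @param cap refuse to materialize above this `N` (memory guard).
#' @return Real `N x N` matrix.
#' @export
materialize_matrix <- function(net, composition = c("serial", "parallel"),
                               cap = 4096) {
  if (inherits(net, "bf_bco")) net <- list(net)
  eng <- compile_bcos(net, match.arg(composition))
  n <- eng$grid$n
  if (n > cap) stop("N = ", n, " exceeds materialization cap ", cap)
  Re(run_network(eng, diag(1 + 0i, n)))
}
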