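#' Butterfly transform parameters
#'
#' Container for the per-layer parameters of one butterfly transform
#' \eqn{B = \Gamma_0\Phi_0\Theta_0 \cdots \Gamma_{n-1}\Phi_{n-1}\Theta_{n-1}}:
#' mixing angles \eqn{\theta} (radians, one per connected pair), phases
#' \eqn{\phi} (radians, one per entry) and log-amplitudes \eqn{\gamma}
#' (one per entry; \eqn{\gamma \neq 0} breaks unitarity).
#'
#' The flat design applies one transform of `log2(N)` layers to the
#' column-major flattened image (each layer: N/2 angles, N phases, N
#' log-amplitudes). The 2D design mixes each axis separately with shared
#' angles (m/2 per row stage, l/2 per column stage) while phases and
#' amplitudes remain full `m*l` diagonals, one pair per stage.
#'
#' @param grid a [bf_grid()].
#' @param design `"flat"` or `"two_d"`.
#' @param theta,phi,gamma nested lists of numeric vectors, shaped as
#'   produced by [fft_initialization()]; `NULL` gives zero entries
#'   (`theta = 0` too, i.e. *not* the FFT configuration).
#' @return An object of class `butterfly_params`.
#' @seealso [fft_initialization()], [butterfly_forward()]
#' @export
butterfly_params <- function(grid, design = c("flat", "two_d"),
                             theta = NULL, phi = NULL, gamma = NULL) {
  design <- match.arg(design)
  plan <- bf_plan(grid, design)
  shape_theta <- lapply(plan$stages, function(st)
    lapply(st$mixes, function(mx) numeric(mx$K)))
  shape_diag <- lapply(plan$stages, function(st) numeric(grid$n))
  p <- structure(list(grid = grid, design = design,
                      theta = if (is.null(theta)) shape_theta else theta,
                      phi = if (is.null(phi)) shape_diag else phi,
                      gamma = if (is.null(gamma)) shape_diag else gamma),
                 class = "butterfly_params")
  validate_butterfly_params(p, plan)
  p
}

validate_butterfly_params <- function(p, plan = bf_plan(p$grid, p$design)) {
  ns <- plan$n_stages
  if (length(p$theta) != ns || length(p$phi) != ns || length(p$gamma) != ns)
    stop("parameter lists must have one entry per layer (", ns, ")")
  for (s in seq_len(ns)) {
    mixes <- plan$stages[[s]]$mixes
    if (length(p$theta[[s]]) != length(mixes))
      stop("layer ", s, ": expected ", length(mixes), " angle block(s)")
    for (t in seq_along(mixes))
      if (length(p$theta[[s]][[t]]) != mixes[[t]]$K)
        stop("layer ", s, ": angle block ", t, " must hold ",
             mixes[[t]]$K, " angles")
    if (length(p$phi[[s]]) != p$grid$n || length(p$gamma[[s]]) != p$grid$n)
      stop("layer ", s, ": phi and gamma must hold ", p$grid$n, " entries")
  }
  vals <- c(unlist(p$theta), unlist(p$phi), unlist(p$gamma))
  if (!all(is.finite(vals))) stop("butterfly parameters must be finite")
  invisible(p)
}

#' @export
print.butterfly_params <- function(x, ...) {
  cat("<butterfly_params> ", x$design, " design on ", x$grid$rows, "x",
      x$grid$cols, ", ", length(x$phi), " layers, ",
      count_butterfly_params(x$grid, x$design), " parameters\n", sep = "")
  invisible(x)
}

# Flat named parameter list for the engine, prefix `pre`.
params_to_pars <- function(p, pre) {
  pars <- list()
  for (s in seq_along(p$phi)) {
    for (t in seq_along(p$theta[[s]]))
      pars[[ref_theta(pre, s, t)]] <- p$theta[[s]][[t]]
    pars[[ref_phi(pre, s)]] <- p$phi[[s]]
    pars[[ref_gamma(pre, s)]] <- p$gamma[[s]]
  }
  pars
}

pars_to_params <- function(pars, pre, grid, design) {
  plan <- bf_plan(grid, design)
  theta <- lapply(seq_len(plan$n_stages), function(s)
    lapply(seq_along(plan$stages[[s]]$mixes), function(t)
      pars[[ref_theta(pre, s, t)]]))
  phi <- lapply(seq_len(plan$n_stages), function(s) pars[[ref_phi(pre, s)]])
  gamma <- lapply(seq_len(plan$n_stages), function(s) pars[[ref_gamma(pre, s)]])
  butterfly_params(grid, design, theta, phi, gamma)
}

#' FFT initialization of a butterfly transform
#'
#' Returns the parameter configuration at which the butterfly transform
#' equals the *unitary* discrete Fourier transform: all angles
#' \eqn{\theta = \pi/4}, all log-amplitudes \eqn{\gamma = 0}, and phases
#' \eqn{\phi} set to the Cooley-Tukey twiddle factors (powers of
#' \eqn{\omega_N = e^{-2\pi i/N}}). For the 2D design the realized operator
#' is the separable unitary 2D DFT.
#'
#' The twiddle diagonal needed in front of the stride-`2L` mixing stage is
#' carried by the phase layer of the preceding stage (the stride-1 stage
#' needs no twiddles), so the per-layer order Theta, Phi, Gamma realizes the
#' standard decimation-in-time factorization.
#'
#' @inheritParams butterfly_params
#' @return A `butterfly_params` object.
#' @examples
#' p <- fft_initialization(bf_grid(2, 1))
#' # the realized 2x2 operator is (1/sqrt(2)) * [[1, 1], [1, -1]]
#' Re(cbind(butterfly_forward(p, c(1, 0)), butterfly_forward(p, c(0, 1))))
#' @export
fft_initialization <- function(grid, design = c("flat", "two_d")) {
  design <- match.arg(design)
  plan <- bf_plan(grid, design)
  m <- grid$rows; l <- grid$cols; N <- grid$n
  theta <- lapply(plan$stages, function(st)
    lapply(st$mixes, function(mx) rep(pi / 4, mx$K)))
  gamma <- lapply(plan$stages, function(st) numeric(N))
  twiddle <- function(idx, s) {
    # phases of diag(I_L, W_L) ahead of the stride-2L stage, L = 2^s
    L <- bitwShiftL(1L, s)
    r <- idx %% (2L * L)
    ifelse(r >= L, -2 * pi * (r - L) / (2 * L), 0)
  }
  if (design == "flat") {
    nb <- plan$n_stages
    idx <- 0:(N - 1L)
    phi <- lapply(seq_len(nb), function(s)
      if (s < nb) twiddle(idx, s) else numeric(N))
  } else {
    nr <- log2int(m); nc <- log2int(l)
    rowidx <- rep(0:(m - 1L), times = l)
    colidx <- rep(0:(l - 1L), each = m)
    phi <- lapply(seq_len(plan$n_stages), function(s) {
      ph <- numeric(N)
      if (s + 1L <= nr) ph <- ph + twiddle(rowidx, s)
      if (s + 1L <= nc) ph <- ph + twiddle(colidx, s)
      ph
    })
  }
  butterfly_params(grid, design, theta, phi, gamma)
}

#' Apply a butterfly transform or its adjoint
#'
#' `butterfly_forward` applies the layered operator
#' \eqn{B = \prod_j \Gamma_j\Phi_j\Theta_j} to a complex vector (or to each
#' column of a matrix): the input bit-reversal permutation first, then per
#' layer the pairwise mixing \eqn{\Theta}, the phase diagonal \eqn{\Phi} and
#' the amplitude diagonal \eqn{\Gamma}, with layer strides increasing by a
#' factor two. `butterfly_adjoint` applies the conjugate transpose
#' \eqn{B^\dagger}, so that `sum(Conj(butterfly_forward(p, x)) * y)` equals
#' `sum(Conj(x) * butterfly_adjoint(p, y))` up to round-off. With all
#' \eqn{\gamma = 0} the transform is unitary and the adjoint inverts it.
#'
#' @param p a [butterfly_params()] object.
#' @param v complex (or real, promoted) vector of length `N = rows * cols`
#'   holding the column-major flattened image, or an `N x k` matrix of such
#'   vectors.
#' @return Complex vector or matrix of the same shape as `v`.
#' @examples
#' p <- fft_initialization(bf_grid(4, 1))
#' butterfly_forward(p, c(1, 0, 0, 0))  # constant 1/2 vector: unitary DFT
#' @export
butterfly_forward <- function(p, v) {
  validate_butterfly_params(p)
  vec <- is.null(dim(v))
  V <- as_cplx_mat(v, p$grid$n)
  out <- run_fwd(prog_butterfly(bf_plan(p$grid, p$design), "b"),
                 params_to_pars(p, "b"), V)
  if (vec) drop(out) else out
}

#' @rdname butterfly_forward
#' @export
butterfly_adjoint <- function(p, v) {
  validate_butterfly_params(p)
  vec <- is.null(dim(v))
  V <- as_cplx_mat(v, p$grid$n)
  out <- run_fwd(prog_butterfly_adjoint(bf_plan(p$grid, p$design), "b"),
                 params_to_pars(p, "b"), V)
  if (vec) drop(out) else out
}

#' Elementary butterfly layer operations
#'
#' The three building blocks of one butterfly layer, exposed for testing
#' and for building custom operators. `theta_apply` mixes connected pairs
#' `(a, b)` into `(a cos(t) + b sin(t), a sin(t) - b cos(t))` (real
#' orthogonal per pair), `phi_apply` multiplies entries by `exp(1i * phi)`
#' and `gamma_apply` by `exp(gamma)`.
#'
#' @param angles numeric vector, one angle per pair.
#' @param pairing a [layer_pairing()] (or any list with 1-based integer
#'   index vectors `idxA`, `idxB` covering every entry exactly once).
#' @param phases,log_amplitudes numeric vectors, one entry per element of `v`.
#' @param v complex (or real) vector.
#' @return Complex vector of the same length as `v`.
#' @examples
#' theta_apply(pi / 4, layer_pairing(2, 1), c(1, 0))  # (1, 1)/sqrt(2)
#' @export
theta_apply <- function(angles, pairing, v) {
  if (length(angles) != length(pairing$idxA))
    stop("need one angle per pair: ", length(pairing$idxA), " pairs, got ",
         length(angles), " angles")
  v <- as.complex(v)
  a <- v[pairing$idxA]; b <- v[pairing$idxB]
  cs <- cos(angles); sn <- sin(angles)
  v[pairing$idxA] <- cs * a + sn * b
  v[pairing$idxB] <- sn * a - cs * b
  v
}

#' @rdname theta_apply
#' @export
phi_apply <- function(phases, v) {
  if (length(phases) != length(v))
    stop("need one phase per entry, got ", length(phases), " for ", length(v))
  exp(1i * phases) * as.complex(v)
}

#' @rdname theta_apply
#' @export
gamma_apply <- function(log_amplitudes, v) {
  if (length(log_amplitudes) != length(v))
    stop("need one log-amplitude per entry, got ", length(log_amplitudes),
         " for ", length(v))
  exp(log_amplitudes) * as.complex(v)
}

#' Radix-2 layer pairing
#'
#' The index pairs `(k, k + stride)` connected by the mixing operator of one
#' butterfly layer (decimation-in-time ordering, applied after the input
#' bit-reversal permutation). Every index appears in exactly one pair.
#'
#' @param n vector length (power of two).
#' @param stride pair distance, a power of two below `n`.
#' @return List with 1-based integer vectors `idxA`, `idxB` of length `n/2`.
#' @export
layer_pairing <- function(n, stride = 1L) {
  if (!is_pow2(n) || !is_pow2(stride) || stride >= n)
    stop("n and stride must be powers of two with stride < n")
  idx <- 0:(n - 1L)
  a <- idx[bitwAnd(idx, as.integer(stride)) == 0L]
  list(idxA = a + 1L, idxB = a + as.integer(stride) + 1L)
}
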