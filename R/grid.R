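#' Power-of-two image grid
#'
#' Defines the pixel grid a butterfly transform operates on. Both axis sizes
#' must be powers of two; images are flattened column-major (all column
#' vectors concatenated) when handed to a flat-design transform.
#'
#' @param rows number of rows \eqn{m} (power of two).
#' @param cols number of columns \eqn{l} (power of two), default `rows`.
#' @return An object of class `bf_grid` with elements `rows`, `cols`, `n`.
#' @examples
#' g <- bf_grid(16)
#' g$n
#' @export
bf_grid <- function(rows, cols = rows) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (!is_pow2(rows) || !is_pow2(cols))
    stop("grid sizes must be powers of two, got ", rows, "x", cols)
  structure(list(rows = rows, cols = cols, n = rows * cols),
            class = "bf_grid")
}

#' @export
print.bf_grid <- function(x, ...) {
  cat("<bf_grid> ", x$rows, "x", x$cols, " (N = ", x$n, ")\n", sep = "")
  invisible(x)
}

is_pow2 <- function(n) {
  n <- as.integer(n)
  length(n) == 1L && !is.na(n) && n >= 1L && bitwAnd(n, n - 1L) == 0L
}

log2int <- function(n) as.integer(round(log2(n)))

#' Bit-reversal permutation
#'
#' The index reordering of the radix-2 decimation-in-time FFT: index `i`
#' maps to the integer whose `log2(n)`-bit binary representation is read
#' backwards. The permutation is self-inverse.
#'
#' @param n vector length, a power of two.
#' @return Integer vector of length `n`: the 1-based permutation, i.e.
#'   `v[bit_reversal_permutation(n)]` reorders `v` into bit-reversed order.
#' @examples
#' bit_reversal_permutation(8) - 1L  # 0 4 2 6 1 5 3 7
#' @export
bit_reversal_permutation <- function(n) {
  if (!is_pow2(n)) stop("n must be a power of two, got ", n)
  n <- as.integer(n)
  bits <- log2int(n)
  if (bits == 0L) return(1L)
  idx <- 0:(n - 1L)
  rev <- integer(n)
  for (b in seq_len(bits) - 1L) {
    bit <- bitwAnd(bitwShiftR(idx, b), 1L)
    rev <- bitwOr(rev, bitwShiftL(bit, bits - 1L - b))
  }
  rev + 1L
}

# Wiring plan for one butterfly transform: the input permutation and, per
# stage, the pairings (mix specs) for the Theta operators. Fixed structure,
# not learnable.
#
# A mix spec holds 1-based index vectors idxA/idxB covering every entry once,
# the raw theta length K, and how a raw theta vector expands to the pair list
# ("none", "times" = rep(theta, times = n), "each" = rep(theta, each = n)).
bf_plan <- function(grid, design = c("flat", "two_d")) {
  design <- match.arg(design)
  m <- grid$rows; l <- grid$cols; N <- grid$n
  if (design == "flat") {
    nb <- log2int(N)
    if (nb == 0L) stop("flat design needs at least 2 pixels")
    perm <- bit_reversal_permutation(N)
    stages <- vector("list", nb)
    idx <- 0:(N - 1L)
    for (s in seq_len(nb)) {
      stride <- bitwShiftL(1L, s - 1L)
      a <- idx[bitwAnd(idx, stride) == 0L]
      stages[[s]] <- list(mixes = list(list(
        idxA = a + 1L, idxB = a + stride + 1L,
        K = N %/% 2L, expand = "none", expand_n = 1L)))
    }
  } else {
    nr <- log2int(m); nc <- log2int(l)
    ns <- max(nr, nc)
    if (ns == 0L) stop("two_d design needs at least 2 pixels")
    rrev <- bit_reversal_permutation(m) - 1L
    crev <- bit_reversal_permutation(l) - 1L
    perm <- as.vector(outer(rrev, m * crev, "+")) + 1L
    rows <- 0:(m - 1L); cols <- 0:(l - 1L)
    stages <- vector("list", ns)
    for (s in seq_len(ns)) {
      mixes <- list()
      if (s <= nr) {
        stride <- bitwShiftL(1L, s - 1L)
        ra <- rows[bitwAnd(rows, stride) == 0L]
        mixes[[length(mixes) + 1L]] <- list(
          idxA = as.vector(outer(ra, m * cols, "+")) + 1L,
          idxB = as.vector(outer(ra + stride, m * cols, "+")) + 1L,
          K = m %/% 2L, expand = "times", expand_n = l)
      }
      if (s <= nc) {
        stride <- bitwShiftL(1L, s - 1L)
        ca <- cols[bitwAnd(cols, stride) == 0L]
        mixes[[length(mixes) + 1L]] <- list(
          idxA = as.vector(outer(rows, m * ca, "+")) + 1L,
          idxB = as.vector(outer(rows, m * (ca + stride), "+")) + 1L,
          K = l %/% 2L, expand = "each", expand_n = m)
      }
      stages[[s]] <- list(mixes = mixes)
    }
  }
  stages <- lapply(stages, function(st) {
    st$mixes <- lapply(st$mixes, finalize_mix, n = N)
    st
  })
  list(design = design, grid = grid, perm = perm, stages = stages,
       n_stages = length(stages))
}

expand_theta <- function(theta, mix) {
  switch(mix$expand,
         none  = theta,
         times = rep(theta, times = mix$expand_n),
         each  = rep(theta, each = mix$expand_n))
}

# Augment a mix spec with the full-vector form used by the engine:
# out = sgn*cos(th)*v + sin(th)*v[partner], with `partner` the pair
# involution, `sgn` +1 on first and -1 on second pair members, and `map`
# scattering the raw angle vector to all N positions.
finalize_mix <- function(mix, n) {
  partner <- integer(n); sgn <- numeric(n); map <- integer(n)
  partner[mix$idxA] <- mix$idxB; partner[mix$idxB] <- mix$idxA
  sgn[mix$idxA] <- 1; sgn[mix$idxB] <- -1
  raw <- switch(mix$expand,
                none  = seq_len(mix$K),
                times = rep(seq_len(mix$K), times = mix$expand_n),
                each  = rep(seq_len(mix$K), each = mix$expand_n))
  map[mix$idxA] <- raw; map[mix$idxB] <- raw
  c(mix, list(partner = partner, sgn = sgn, map = map))
}
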