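#' Response approximation error image
#'
#' Elementwise difference `E(s) = R_sim(s) - R_but(s)` between the
#' simulated (ground-truth) and the learned butterfly signal response.
#'
#' @param r_sim,r_but response images of equal shape.
#' @return Difference image.
#' @export
approximation_error <- function(r_sim, r_but) {
  if (!identical(dim(r_sim), dim(r_but)) || length(r_sim) != length(r_but))
    stop("response images must have identical shape")
  r_sim - r_but
}

norm2 <- function(x) sqrt(sum(as.numeric(x)^2))

check_stacks <- function(sim, but) {
  if (!identical(dim(sim), dim(but)))
    stop("response stacks must have identical shape")
  if (is.complex(but)) but <- Re(but)
  if (is.complex(sim)) sim <- Re(sim)
  list(sim = sim, but = but)
}

#' Per-position relative error map
#'
#' For every source position `z`, the 2-norm of the difference between the
#' simulated and the butterfly response to a unit point source at `z`,
#' normalized by the 2-norm of the simulated response:
#' \deqn{\hat\epsilon_z = \|E[\delta_z]\|_2 / \|R_{sim}[\delta_z]\|_2.}
#' Complex-valued butterfly outputs are reduced to their real part first.
#'
#' @param sim,but `N x N` response stacks (columns indexed by source pixel),
#'   e.g. from [build_response_stack()] and [network_response_stack()].
#' @return An object of class `bf_error_map`: list with `epsilon` (the
#'   relative error per source pixel, as a `rows x cols` image when a grid
#'   is attached to `sim`), `zeta` (the total error, see [total_error()])
#'   and the grid.
#' @export
error_map <- function(sim, but) {
  st <- check_stacks(sim, but)
  nsim <- sqrt(colSums(st$sim^2))
  if (any(nsim == 0))
    stop("simulated response stack has zero-norm column(s); relative error undefined")
  eps <- sqrt(colSums((st$sim - st$but)^2)) / nsim
  grid <- attr(sim, "grid")
  if (!is.null(grid)) dim(eps) <- c(grid$rows, grid$cols)
  structure(list(epsilon = eps, zeta = total_error(st$sim, st$but),
                 grid = grid),
            class = "bf_error_map")
}

#' @export
print.bf_error_map <- function(x, ...) {
  cat("<bf_error_map> zeta = ", format(x$zeta, digits = 4),
      " (", format(100 * x$zeta, digits = 4), "%), epsilon in [",
      format(min(x$epsilon), digits = 3), ", ",
      format(max(x$epsilon), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Total response approximation error
#'
#' The scalar summary
#' \deqn{\hat\zeta = \|E\|_2 / \|R_{sim}\|_2,}
#' the Euclidean 2-norm of the full 4D difference stack (all error images
#' for all source positions) over the 2-norm of the full simulated stack.
#' A perfect representation gives 0; the zero map gives 1. Invariant under
#' joint rescaling of both stacks.
#'
#' @inheritParams error_map
#' @return Scalar total error.
#' @export
total_error <- function(sim, but) {
  st <- check_stacks(sim, but)
  ns <- norm2(st$sim)
  if (ns == 0) stop("simulated response stack has zero norm")
  norm2(st$sim - st$but) / ns
}

#' Relative distance versus relative error table
#'
#' Pairs each source pixel's relative centre distance `rhat` with its
#' relative approximation error `epsilon`, the raw material of the radial
#' error histogram.
#'
#' @param map a [error_map()] result.
#' @param model the [svpsf_model()] providing the centre geometry.
#' @return `data.frame` with columns `row`, `col`, `rhat`, `epsilon`
#'   (one row per source pixel).
#' @export
radial_error_histogram <- function(map, model) {
  grid <- model$grid
  eps <- as.vector(map$epsilon)
  if (length(eps) != grid$n)
    stop("error map and model grid disagree")
  rows <- rep(0:(grid$rows - 1L), times = grid$cols)
  cols <- rep(0:(grid$cols - 1L), each = grid$rows)
  rhat <- sqrt((rows - model$centre[1])^2 +
               (cols - model$centre[2])^2) / model$rmax
  data.frame(row = rows, col = cols, rhat = rhat, epsilon = eps)
}
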