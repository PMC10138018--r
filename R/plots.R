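# Figure export. All panel writers draw with base graphics into a PNG
# device and return the file path invisibly.

open_png <- function(path, width, height) {
  grDevices::png(path, width = width, height = height, res = 110)
}

img_panel <- function(img, main = "", zlim = NULL, log_scale = FALSE,
                      col = grDevices::hcl.colors(64, "viridis")) {
  if (log_scale) {
    img <- log10(pmax(img, 1e-12))
    if (!is.null(zlim)) zlim <- log10(pmax(zlim, 1e-12))
  }
  if (is.null(zlim)) zlim <- range(img)
  if (zlim[1] == zlim[2]) zlim <- zlim + c(-0.5, 0.5)
  graphics::image(t(img)[, nrow(img):1, drop = FALSE], zlim = zlim,
                  col = col, axes = FALSE, main = main, cex.main = 0.8)
  graphics::box()
}

# 5x5 lattice of source positions spread over the grid
panel_lattice <- function(grid, k = 5) {
  r <- round(seq(0, grid$rows - 1, length.out = k))
  c <- round(seq(0, grid$cols - 1, length.out = k))
  as.matrix(expand.grid(row = r, col = c))
}

#' Signal-response panel figures
#'
#' `plot_response_panels` writes a figure of the responses to point
#' sources on a 5x5 position lattice (25 panels), e.g. of the simulated
#' truth or of a butterfly approximation; panels share one colour scale so
#' truth and approximation figures are directly comparable via `zlim`.
#' `plot_error_panels` writes the 25 corresponding difference images.
#' `plot_error_map` writes the relative error map next to the relative
#' distance versus error scatter. `plot_imaging_summary` writes the
#' six-panel imaging overview (truth, observed event density, counts,
#' reconstruction, predicted rates, data residuals).
#'
#' @param stack `N x N` response stack ([build_response_stack()] /
#'   [network_response_stack()]).
#' @param grid the [bf_grid()] (taken from the stack attribute if absent).
#' @param path output PNG path.
#' @param zlim shared colour range; defaults to the range of the drawn
#'   panels. Returned as attribute `zlim` for reuse.
#' @param log_scale draw log10 brightness.
#' @return The path, invisibly (with attribute `zlim` where applicable).
#' @export
plot_response_panels <- function(stack, path, grid = attr(stack, "grid"),
                                 zlim = NULL, log_scale = FALSE) {
  stopifnot(!is.null(grid))
  pos <- panel_lattice(grid)
  imgs <- lapply(seq_len(nrow(pos)), function(i) {
    z <- pos[i, 1] + grid$rows * pos[i, 2] + 1L
    matrix(Re(stack[, z]), grid$rows, grid$cols)
  })
  if (is.null(zlim)) zlim <- range(unlist(imgs))
  open_png(path, 900, 900)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(5, 5), mar = c(0.4, 0.4, 1.2, 0.4))
  for (i in seq_along(imgs))
    img_panel(imgs[[i]], main = paste0("z=(", pos[i, 1], ",", pos[i, 2], ")"),
              zlim = zlim, log_scale = log_scale)
  invisible(structure(path, zlim = zlim))
}

#' @rdname plot_response_panels
#' @param sim,but aligned response stacks (truth and approximation).
#' @export
plot_error_panels <- function(sim, but, path, grid = attr(sim, "grid")) {
  stopifnot(!is.null(grid))
  diff <- unclass(sim) - Re(unclass(but))
  plot_response_panels(structure(diff, grid = grid), path, grid)
}

#' @rdname plot_response_panels
#' @param map a [error_map()] result.
#' @param model the [svpsf_model()] (for the radial histogram geometry).
#' @export
plot_error_map <- function(map, model, path) {
  tab <- radial_error_histogram(map, model)
  open_png(path, 1000, 480)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  img_panel(as.matrix(map$epsilon), main = "relative error map")
  graphics::plot(tab$rhat, tab$epsilon, pch = 16, cex = 0.6,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "relative centre distance", ylab = "relative error",
                 main = "error vs. distance")
  invisible(path)
}

#' @rdname plot_response_panels
#' @param recon a [reconstruct_map()] result.
#' @param truth ground-truth signal image (e.g. [scene_image()]), optional.
#' @param observed noiseless observed event density image, optional.
#' @export
plot_imaging_summary <- function(recon, path, truth = NULL, observed = NULL) {
  open_png(path, 1100, 760)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 3), mar = c(0.5, 0.5, 2, 0.5))
  if (!is.null(truth)) img_panel(truth, "ground truth")
  else graphics::plot.new()
  if (!is.null(observed)) img_panel(observed, "observed event density")
  else graphics::plot.new()
  img_panel(matrix(as.vector(recon$counts), recon$grid$rows), "counts")
  img_panel(matrix(as.vector(recon$signal), recon$grid$rows), "MAP signal")
  img_panel(matrix(as.vector(recon$rates), recon$grid$rows), "predicted rates")
  img_panel(matrix(as.vector(recon$residuals), recon$grid$rows),
            "data residuals |d - mu|")
  invisible(path)
}

#' @export
plot.butterfly_fit <- function(x, ...) {
  graphics::par(mar = c(1, 1, 3, 1))
  img_panel(as.matrix(x$error_map$epsilon),
            main = sprintf("relative error map (zeta = %.2f%%)",
                           100 * x$zeta))
  invisible(x)
}

#' @export
plot.butterfly_map <- function(x, ...) {
  graphics::par(mfrow = c(2, 2), mar = c(0.5, 0.5, 2, 0.5))
  img_panel(matrix(as.vector(x$counts), x$grid$rows), "counts")
  img_panel(matrix(as.vector(x$signal), x$grid$rows), "MAP signal")
  img_panel(matrix(as.vector(x$rates), x$grid$rows), "predicted rates")
  img_panel(matrix(as.vector(x$residuals), x$grid$rows), "data residuals")
  invisible(x)
}
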