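ARCHIVE_VERSION <- "1.0"

fmt_num <- function(x) sprintf("%.17g", x)          # bit-exact double round trip
parse_num <- function(x) {
  v <- as.numeric(x)
  if (any(is.na(v))) stop("corrupted archive: non-numeric parameter entries")
  v
}

serialize_butterfly <- function(p) {
  list(theta = lapply(p$theta, function(st) lapply(st, fmt_num)),
       phi = lapply(p$phi, fmt_num),
       gamma = lapply(p$gamma, fmt_num))
}

deserialize_butterfly <- function(obj, grid, design) {
  butterfly_params(grid, design,
                   theta = lapply(obj$theta, function(st) lapply(st, parse_num)),
                   phi = lapply(obj$phi, parse_num),
                   gamma = lapply(obj$gamma, parse_num))
}

#' Save and load butterfly networks
#'
#' Networks are stored as JSON text archives: per BCO the nested
#' theta/phi/gamma arrays of each transform (`b1`, and `b2` unless
#' mirrored) and the real/imaginary parts of the spectrum, plus design,
#' grid shape, mirrored flag, composition and a format version. All doubles
#' are written with 17 significant digits, so a save/load round trip is
#' bit-exact.
#'
#' @param net list of [bf_bco()] (or a [bf_fit()] result, whose fitted
#'   network is stored).
#' @param path file path of the archive.
#' @param composition stored alongside the parameters; taken from `net`'s
#'   attribute or a `butterfly_fit` when available.
#' @return `save_network` invisibly returns `path`; `load_network` returns
#'   the list of `bf_bco` with attribute `composition`.
#' @export
save_network <- function(net, path, composition = NULL) {
  if (inherits(net, "butterfly_fit")) {
    composition <- composition %||% net$composition
    net <- net$network
  }
  if (inherits(net, "bf_bco")) net <- list(net)
  composition <- composition %||% attr(net, "composition") %||% "serial"
  grid <- net[[1]]$grid
  arch <- list(
    format_version = ARCHIVE_VERSION,
    package = "butterflypsf",
    grid = c(grid$rows, grid$cols),
    composition = composition,
    bcos = lapply(net, function(op) {
      b <- list(mirrored = op$mirrored, design = op$design,
                b1 = serialize_butterfly(op$b1),
                lambda_re = fmt_num(Re(op$lambda)),
                lambda_im = fmt_num(Im(op$lambda)))
      if (!op$mirrored) b$b2 <- serialize_butterfly(op$b2)
      b
    }))
  jsonlite::write_json(arch, path, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  arch <- tryCatch(jsonlite::read_json(path),
                   error = function(e) stop("corrupted archive: ",
                                            conditionMessage(e)))
  for (field in c("format_version", "grid", "composition", "bcos"))
    if (is.null(arch[[field]]))
      stop("corrupted archive: missing field '", field, "'")
  if (!identical(arch$format_version, ARCHIVE_VERSION))
    stop("archive format version ", arch$format_version,
         " not supported (expected ", ARCHIVE_VERSION, ")")
  grid <- bf_grid(arch$grid[[1]], arch$grid[[2]])
  net <- lapply(arch$bcos, function(b) {
    b1 <- deserialize_butterfly(b$b1, grid, b$design)
    b2 <- if (!isTRUE(b$mirrored)) deserialize_butterfly(b$b2, grid, b$design)
    bf_bco(b1, complex(real = parse_num(b$lambda_re),
                       imaginary = parse_num(b$lambda_im)), b2)
  })
  attr(net, "composition") <- arch$composition
  net
}

#' Forward-pass runtime benchmark
#'
#' Times the butterfly network forward pass against a dense matrix-vector
#' product with the materialized operator (when `N` is at or below
#' `dense_cap`; above it the dense branch is skipped with a warning, as the
#' dense matrix would not fit in memory). Informational only — results
#' depend on hardware.
#'
#' @inheritParams network_apply
#' @param repeats number of timed repetitions.
#' @param dense_cap largest `N` for which the dense comparison is run.
#' @return `data.frame` with columns `method`, `median_s`, `min_s`,
#'   `max_s`, `repeats`.
#' @export
benchmark_forward <- function(net, repeats = 11,
                              composition = c("serial", "parallel"),
                              dense_cap = 4096) {
  if (inherits(net, "bf_bco")) net <- list(net)
  composition <- match.arg(composition)
  n <- net[[1]]$grid$n
  v <- stats::rnorm(n)
  time_one <- function(f) vapply(seq_len(repeats), function(i)
    system.time(f())[["elapsed"]], numeric(1))
  tb <- time_one(function() network_apply(net, v, composition))
  out <- data.frame(method = "butterfly", median_s = stats::median(tb),
                    min_s = min(tb), max_s = max(tb), repeats = repeats)
  if (n <= dense_cap) {
    M <- materialize_matrix(net, composition, cap = dense_cap)
    td <- time_one(function() M %*% v)
    out <- rbind(out, data.frame(method = "dense", median_s = stats::median(td),
                                 min_s = min(td), max_s = max(td),
                                 repeats = repeats))
  } else {
    warning("N = ", n, " exceeds dense_cap; dense comparison skipped")
  }
  out
}
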