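#' Microtubule path
#'
#' A filament represented as a 2D polyline in nanometer coordinates. Arc
#' length along the polyline is the coordinate that kymographs and run
#' detection work in; vertex order defines the direction of increasing arc
#' length (for dynein-driven runs, landings move toward the microtubule
#' minus end, which the simulator places at arc = L by convention).
#'
#' @param vertices numeric matrix (>= 2 rows) of x/y vertex coordinates, nm.
#' @param id path identifier (integer or character).
#' @return an object of class `mt_path` with fields `vertices`, `id`,
#'   `seg_len` (per-segment lengths, nm), `cum_len` (cumulative arc at each
#'   vertex, nm) and `length_nm`.
#' @examples
#' p <- mt_path(rbind(c(0, 0), c(15000, 0)), id = 1)
#' path_length_um(p)
#' @export
mt_path <- function(vertices, id = 1L) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 2L)
    stopf("'vertices' must be a numeric matrix with 2 columns and >= 2 rows")
  if (any(!is.finite(vertices))) stopf("path vertices must be finite")
  d <- diff(vertices)
  seg_len <- sqrt(rowSums(d^2))
  if (any(seg_len == 0)) stopf("consecutive path vertices must be distinct")
  structure(list(vertices = unname(vertices), id = id, seg_len = seg_len,
                 cum_len = c(0, cumsum(seg_len)),
                 length_nm = sum(seg_len)),
            class = "mt_path")
}

#' @export
print.mt_path <- function(x, ...) {
  cat(sprintf("microtubule path %s: %d vertices, L = %.2f um\n",
              format(x$id), nrow(x$vertices), x$length_nm / 1000))
  invisible(x)
}

#' Arc length of a path in micrometers
#' @param path an [mt_path()].
#' @return length in micrometers.
#' @export
path_length_um <- function(path) {
  stopifnot(inherits(path, "mt_path"))
  path$length_nm / 1000
}

#' Interpolate positions along a path
#'
#' Maps arc-length coordinates (nm, clamped to `[0, L]`) to x/y positions on
#' the polyline.
#'
#' @param path an [mt_path()].
#' @param arc_nm numeric vector of arc-length positions, nm.
#' @return matrix with columns `x`, `y` (nm).
#' @export
path_point <- function(path, arc_nm) {
  stopifnot(inherits(path, "mt_path"))
  s <- pmin(pmax(arc_nm, 0), path$length_nm)
  seg <- findInterval(s, path$cum_len, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), length(path$seg_len))
  frac <- (s - path$cum_len[seg]) / path$seg_len[seg]
  v0 <- path$vertices[seg, , drop = FALSE]
  v1 <- path$vertices[seg + 1L, , drop = FALSE]
  out <- v0 + frac * (v1 - v0)
  colnames(out) <- c("x", "y")
  out
}

#' Unit tangent and normal along a path
#' @param path an [mt_path()].
#' @param arc_nm arc positions, nm.
#' @return list of matrices `tangent` and `normal` (unit vectors).
#' @export
path_frame <- function(path, arc_nm) {
  stopifnot(inherits(path, "mt_path"))
  s <- pmin(pmax(arc_nm, 0), path$length_nm)
  seg <- findInterval(s, path$cum_len, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), length(path$seg_len))
  d <- (path$vertices[seg + 1L, , drop = FALSE] -
          path$vertices[seg, , drop = FALSE]) / path$seg_len[seg]
  list(tangent = d, normal = cbind(-d[, 2], d[, 1]))
}

#' Project points onto a path
#'
#' Finds, for each x/y point, the closest point on the polyline; returns its
#' arc-length coordinate and the perpendicular distance.
#'
#' @param path an [mt_path()].
#' @param xy numeric matrix of points (columns x, y), nm.
#' @return data.frame with columns `arc_nm` and `dist_nm`.
#' @export
project_onto_path <- function(path, xy) {
  stopifnot(inherits(path, "mt_path"))
  xy <- matrix(as.numeric(xy), ncol = 2L)
  n_seg <- length(path$seg_len)
  best_d2 <- rep(Inf, nrow(xy))
  best_arc <- numeric(nrow(xy))
  for (k in seq_len(n_seg)) {
    a <- path$vertices[k, ]
    b <- path$vertices[k + 1L, ]
    ab <- b - a
    t <- ((xy[, 1] - a[1]) * ab[1] + (xy[, 2] - a[2]) * ab[2]) /
      path$seg_len[k]^2
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * ab[1]
    py <- a[2] + t * ab[2]
    d2 <- (xy[, 1] - px)^2 + (xy[, 2] - py)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- path$cum_len[k] + t[upd] * path$seg_len[k]
  }
  data.frame(arc_nm = best_arc, dist_nm = sqrt(best_d2))
}

#' Keep microtubules above the analysis length cutoff
#'
#' Only microtubules at least `min_length_um` long enter run-frequency
#' analysis (the boundary is inclusive: a 10 um filament is retained under
#' the default cutoff).
#'
#' @param paths list of [mt_path()] objects.
#' @param min_length_um length cutoff in micrometers (default 10).
#' @return the retained subset (possibly empty, with a warning if all paths
#'   were discarded from a non-empty input).
#' @export
filter_microtubules <- function(paths, min_length_um = 10) {
  if (inherits(paths, "mt_path")) paths <- list(paths)
  assert_scalar_num(min_length_um, "min_length_um", nonneg = TRUE)
  keep <- vapply(paths, path_length_um, numeric(1)) >= min_length_um
  out <- paths[keep]
  if (length(paths) > 0L && length(out) == 0L)
    warnf("all %d microtubules are shorter than %g um; none retained",
          length(paths), min_length_um)
  out
}

#' Read / write microtubule paths as CSV
#'
#' The CSV has columns `path_id`, `vertex`, `x_nm`, `y_nm`, one row per
#' polyline vertex.
#'
#' @param paths list of [mt_path()] objects.
#' @param file CSV path.
#' @return `write_paths_csv` returns `file` invisibly; `read_paths_csv`
#'   returns a list of `mt_path` objects.
#' @export
write_paths_csv <- function(paths, file) {
  if (inherits(paths, "mt_path")) paths <- list(paths)
  rows <- do.call(rbind, lapply(paths, function(p) {
    data.frame(path_id = p$id, vertex = seq_len(nrow(p$vertices)),
               x_nm = p$vertices[, 1], y_nm = p$vertices[, 2])
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_paths_csv
#' @export
read_paths_csv <- function(file) {
  df <- utils::read.csv(file)
  lapply(split(df, df$path_id), function(g) {
    g <- g[order(g$vertex), ]
    mt_path(cbind(g$x_nm, g$y_nm), id = g$path_id[1])
  })
}
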