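#' Construct a toy raster grid
#'
#' A minimal in-memory raster: a rectangular matrix of values anchored at a
#' lon/lat origin (lower-left corner) with square cells of `cell_size_m`
#' metres. Row 1 is the southernmost row. Values are either impervious
#' surface fractions in `[0, 1]` or integer land-cover class codes.
#'
#' @param values numeric matrix of cell values.
#' @param origin_lon,origin_lat coordinates of the lower-left grid corner.
#' @param cell_size_m cell edge length in metres (> 0).
#' @return an object of class `toy_raster`.
#' @export
toy_raster <- function(values, origin_lon, origin_lat, cell_size_m) {
  stopifnot(is.matrix(values), cell_size_m > 0)
  structure(list(values = values, origin_lon = origin_lon,
                 origin_lat = origin_lat, cell_size_m = cell_size_m),
            class = "toy_raster")
}

#' @export
print.toy_raster <- function(x, ...) {
  cat(sprintf("toy_raster: %d x %d cells of %.0f m, origin (%.4f, %.4f)\n",
              nrow(x$values), ncol(x$values), x$cell_size_m,
              x$origin_lon, x$origin_lat))
  invisible(x)
}

#' Write / read a toy raster as a plain-text grid
#'
#' Self-describing text format: three header lines (`origin`, `cell_size_m`,
#' `dim`) followed by the value matrix, one row per line, southernmost row
#' first.
#'
#' @param raster a [toy_raster()].
#' @param path file path.
#' @return `write_toy_raster` returns `path` invisibly; `read_toy_raster`
#'   returns the reconstructed `toy_raster`.
#' @export
write_toy_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("origin %.10f %.10f", raster$origin_lon, raster$origin_lat),
               sprintf("cell_size_m %.6f", raster$cell_size_m),
               sprintf("dim %d %d", nrow(raster$values), ncol(raster$values))),
             con)
  utils::write.table(format(raster$values, digits = 15, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_toy_raster
#' @export
read_toy_raster <- function(path) {
  lines <- readLines(path)
  org <- as.numeric(strsplit(lines[1], " ")[[1]][2:3])
  cs <- as.numeric(strsplit(lines[2], " ")[[1]][2])
  dm <- as.integer(strsplit(lines[3], " ")[[1]][2:3])
  vals <- matrix(scan(text = lines[-(1:3)], quiet = TRUE),
                 nrow = dm[1], ncol = dm[2], byrow = TRUE)
  toy_raster(vals, org[1], org[2], cs)
}

#' Impervious-surface proportion within a circular buffer
#'
#' Mean value of the raster cells whose centres fall within `radius_m` of
#' the query point (cell-centre inclusion rule). Padding the raster outside
#' the buffer cannot change the result.
#'
#' @param raster a [toy_raster()] of ISA fractions.
#' @param lon,lat buffer centre.
#' @param radius_m buffer radius in metres.
#' @return proportion in `[0, 1]`.
#' @export
isa_proportion <- function(raster, lon, lat, radius_m) {
  v <- uv_cells_in_buffer(raster, lon, lat, radius_m)
  if (!length(v))
    stop("no raster cell centre falls inside the buffer; use a larger ",
         "radius or a finer raster")
  mean(v)
}

#' Shannon diversity of land-cover class counts
#'
#' `H = -sum(p_i * log(p_i))` in nats over classes with positive counts.
#' Zero iff a single class is present; maximal at `log(K)` for `K` equally
#' common classes; invariant to class relabelling.
#'
#' @param class_counts numeric vector of non-negative counts (optionally
#'   named by class).
#' @return diversity in nats (>= 0).
#' @export
shannon_diversity <- function(class_counts) {
  if (any(class_counts < 0)) stop("class counts must be non-negative")
  tot <- sum(class_counts)
  if (tot <= 0) stop("total class count must be positive")
  p <- class_counts[class_counts > 0] / tot
  -sum(p * log(p))
}

#' Shannon diversity of land cover within a buffer
#'
#' @param raster a [toy_raster()] of integer land-cover classes.
#' @inheritParams isa_proportion
#' @return Shannon diversity (nats) of the class counts among cells whose
#'   centres fall inside the buffer.
#' @export
landcover_shannon <- function(raster, lon, lat, radius_m) {
  v <- uv_cells_in_buffer(raster, lon, lat, radius_m)
  if (!length(v))
    stop("no raster cell centre falls inside the buffer; use a larger ",
         "radius or a finer raster")
  shannon_diversity(as.numeric(table(v)))
}

#' Attach environmental metrics to clusters
#'
#' Adds `isa_100`, `isa_1000` (impervious surface proportion in 100 m and
#' 1000 m buffers around the cluster centroid) and `shannon_h` (land-cover
#' Shannon diversity within the 1000 m buffer) to a cluster table.
#'
#' @param cluster_set a [build_clusters()] result (or its `clusters` data
#'   frame with `centroid_lon`/`centroid_lat`).
#' @param isa_raster toy raster of impervious-surface fractions.
#' @param landcover_raster toy raster of integer land-cover classes.
#' @return the cluster set (or data frame) with the three metric columns
#'   added.
#' @export
attach_env <- function(cluster_set, isa_raster, landcover_raster) {
  cl <- if (inherits(cluster_set, "cluster_set")) cluster_set$clusters else
    cluster_set
  cl$isa_100 <- mapply(function(lo, la)
    isa_proportion(isa_raster, lo, la, 100), cl$centroid_lon, cl$centroid_lat)
  cl$isa_1000 <- mapply(function(lo, la)
    isa_proportion(isa_raster, lo, la, 1000), cl$centroid_lon, cl$centroid_lat)
  cl$shannon_h <- mapply(function(lo, la)
    landcover_shannon(landcover_raster, lo, la, 1000),
    cl$centroid_lon, cl$centroid_lat)
  if (inherits(cluster_set, "cluster_set")) {
    cluster_set$clusters <- cl
    cluster_set
  } else cl
}

# values of cells whose centres lie within radius_m of (lon, lat), using a
# local equirectangular plane anchored at the raster origin
uv_cells_in_buffer <- function(raster, lon, lat, radius_m) {
  R <- 6371008.8
  k <- pi / 180 * R
  x0 <- (lon - raster$origin_lon) * k * cos(raster$origin_lat * pi / 180)
  y0 <- (lat - raster$origin_lat) * k
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  cs <- raster$cell_size_m
  xc <- (seq_len(nc) - 0.5) * cs
  yc <- (seq_len(nr) - 0.5) * cs
  dx2 <- outer(rep(1, nr), (xc - x0)^2)
  dy2 <- outer((yc - y0)^2, rep(1, nc))
  raster$values[dx2 + dy2 <= radius_m^2]
}
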