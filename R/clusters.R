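#' Group nest boxes into subpopulation clusters
#'
#' Clusters are the connected components of the graph joining boxes whose
#' geodesic (WGS84) distance is at most `max_link_m`; components with fewer
#' than `min_size` members are discarded and their boxes reported as
#' unassigned. This single-linkage chaining rule keeps transect-shaped box
#' lines together. Boxes are clustered within each study system. The result
#' is independent of input row order: cluster ids are assigned by sorting on
#' each component's smallest member `box_id`.
#'
#' @param boxes nest-box data frame as returned by [read_nest_boxes()].
#' @param max_link_m linkage distance in metres (default 300).
#' @param min_size minimum number of boxes per cluster (default 5).
#' @param buffer_m buffer radius in metres used for cluster area
#'   (default 150, half the linkage distance).
#' @return a list of class `cluster_set` with elements
#'   \describe{
#'     \item{clusters}{data frame: `cluster_id`, `system_id`, `habitat`,
#'       `n_boxes`, `area_km2`, `mean_lat`, `centroid_lon`, `centroid_lat`,
#'       `mixed`, `minority_frac`;}
#'     \item{membership}{data frame `box_id` -> `cluster_id`;}
#'     \item{unassigned}{character vector of box ids in undersized
#'       components.}
#'   }
#' @export
build_clusters <- function(boxes, max_link_m = 300, min_size = 5,
                           buffer_m = 150) {
  stopifnot(is.data.frame(boxes))
  if (any(duplicated(paste(boxes$system_id, boxes$box_id))))
    stop("duplicate box_id within system")
  if (any(!is.finite(boxes$lon)) || any(!is.finite(boxes$lat)))
    stop("non-finite coordinates")

  clusters <- list(); membership <- list(); unassigned <- character(0)
  for (sys in sort(unique(boxes$system_id))) {
    b <- boxes[boxes$system_id == sys, , drop = FALSE]
    if (nrow(b) < min_size) {
      warning("system ", sys, " has fewer than ", min_size,
              " boxes; none assigned")
      unassigned <- c(unassigned, b$box_id)
      next
    }
    comp <- uv_components(b$lon, b$lat, max_link_m)
    sizes <- tabulate(comp)
    keep <- which(sizes >= min_size)
    unassigned <- c(unassigned, b$box_id[!comp %in% keep])
    if (!length(keep)) next
    # order components by their smallest member box_id for stable labels
    min_id <- vapply(keep, function(k) min(b$box_id[comp == k]), character(1))
    keep <- keep[order(min_id)]
    for (j in seq_along(keep)) {
      m <- b[comp == keep[j], , drop = FALSE]
      cid <- sprintf("%s_c%02d", sys, j)
      hab <- assign_habitat(m$habitat)
      geo <- cluster_geometry(m$lon, m$lat, buffer_m)
      if (hab$mixed)
        uv_log("cluster %s is habitat-mixed (minority fraction %.2f)",
               cid, hab$minority_frac)
      clusters[[cid]] <- data.frame(
        cluster_id = cid, system_id = sys, habitat = hab$habitat,
        n_boxes = nrow(m), area_km2 = geo$area_km2, mean_lat = geo$mean_lat,
        centroid_lon = mean(m$lon), centroid_lat = mean(m$lat),
        mixed = hab$mixed, minority_frac = hab$minority_frac,
        stringsAsFactors = FALSE)
      membership[[cid]] <- data.frame(box_id = m$box_id, cluster_id = cid,
                                      stringsAsFactors = FALSE)
    }
  }
  if (!length(clusters))
    warning("no cluster reached the minimum size; all boxes unassigned")
  out <- list(
    clusters = if (length(clusters)) do.call(rbind, unname(clusters)) else
      data.frame(cluster_id = character(0)),
    membership = if (length(membership)) do.call(rbind, unname(membership)) else
      data.frame(box_id = character(0), cluster_id = character(0)),
    unassigned = sort(unassigned))
  rownames(out$clusters) <- NULL
  rownames(out$membership) <- NULL
  class(out) <- "cluster_set"
  out
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("Nest-box cluster set:", nrow(x$clusters), "cluster(s),",
      nrow(x$membership), "assigned box(es),",
      length(x$unassigned), "unassigned\n")
  if (nrow(x$clusters)) {
    tab <- table(x$clusters$habitat)
    cat("  habitats:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Majority habitat of a cluster
#'
#' Returns the majority habitat label of the member boxes; clusters mixing
#' habitats are flagged with the minority fraction. An exact tie is an error
#' requiring a manual habitat assignment in the run configuration.
#'
#' @param labels character vector of member habitat labels
#'   (`forest`/`urban`).
#' @return list with `habitat`, `mixed` (logical) and `minority_frac`.
#' @export
assign_habitat <- function(labels) {
  if (any(is.na(labels))) stop("member boxes must all carry a habitat label")
  tab <- table(factor(labels, levels = .uv_habitats))
  if (tab["forest"] == tab["urban"])
    stop("habitat tie in cluster; set a manual habitat assignment in the ",
         "run configuration")
  hab <- names(tab)[which.max(tab)]
  list(habitat = hab, mixed = min(tab) > 0,
       minority_frac = as.numeric(min(tab) / sum(tab)))
}

#' Cluster area and mean latitude
#'
#' Area is the convex hull of the member boxes buffered by `buffer_m`,
#' computed in a local azimuthal plane centred on the cluster. For a convex
#' hull the buffered (Minkowski) area has the closed form
#' `A + P * r + pi * r^2` with hull area `A`, hull perimeter `P` and buffer
#' radius `r`, which degrades gracefully for collinear (A = 0) and
#' coincident (A = P = 0) members, so the area is always positive.
#'
#' @param lon,lat member box coordinates (degrees, WGS84).
#' @param buffer_m buffer radius in metres.
#' @return list with `area_km2` and `mean_lat`.
#' @export
cluster_geometry <- function(lon, lat, buffer_m = 150) {
  stopifnot(length(lon) == length(lat), length(lon) >= 1)
  lat0 <- mean(lat)
  R <- 6371008.8
  x <- (lon - mean(lon)) * pi / 180 * R * cos(lat0 * pi / 180)
  y <- (lat - lat0) * pi / 180 * R
  pts <- unique(cbind(x, y))
  if (nrow(pts) == 1) {
    A <- 0; P <- 0
  } else {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    hx <- pts[h, 1]; hy <- pts[h, 2]
    nh <- length(h)
    nxt <- c(seq_len(nh)[-1], 1L)
    A <- abs(sum(hx * hy[nxt] - hx[nxt] * hy)) / 2
    # closed traversal; for a degenerate 2-point hull this is the
    # out-and-back length 2*d, exactly the Minkowski perimeter of a segment
    P <- sum(sqrt((hx[nxt] - hx)^2 + (hy[nxt] - hy)^2))
  }
  area_m2 <- A + P * buffer_m + pi * buffer_m^2
  list(area_km2 = area_m2 / 1e6, mean_lat = mean(lat))
}

#' Number of distinct study years per cluster
#'
#' @param membership box -> cluster map from [build_clusters()].
#' @param obs observation data frame with `box_id` and `year`.
#' @return named integer vector of distinct-year counts per cluster id.
#' @export
cluster_years <- function(membership, obs) {
  cl <- membership$cluster_id[match(obs$box_id, membership$box_id)]
  keep <- !is.na(cl)
  tapply(obs$year[keep], cl[keep], function(y) length(unique(y)))
}

# connected components of the <= max_link_m geodesic adjacency graph
uv_components <- function(lon, lat, max_link_m) {
  n <- length(lon)
  if (n == 1) return(1L)
  d <- geosphere::distm(cbind(lon, lat), fun = geosphere::distGeo)
  adj <- d <= max_link_m
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}
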