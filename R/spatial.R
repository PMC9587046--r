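#' Form animal groups from sightings by 50-m chaining
#'
#' Two sightings from the same survey occasion are linked when they lie
#' within `radius` metres of one another; groups are the connected components
#' of that link graph (single-linkage chaining). A group is a mixed-species
#' group (MSG) when it contains two or more distinct species. The group
#' habitat is the modal habitat of its member sightings, ties broken by the
#' canonical habitat order; the group location is the unweighted centroid of
#' the member sighting locations.
#'
#' @param sightings Validated sightings data frame; partitioned internally by
#'   `date` so that chains never span survey occasions.
#' @param radius Linking distance in metres (default 50).
#' @param rule `"chain"` (single-linkage, default) or `"clique"` (complete
#'   linkage: every pair of members within `radius`).
#' @return Groups data frame with `group_id, species_list, counts, habitat,
#'   x, y, date, is_msg`.
#' @export
form_groups <- function(sightings, radius = 50, rule = c("chain", "clique")) {
  rule <- match.arg(rule)
  if (!is.numeric(radius) || radius < 0) stop("radius must be >= 0", call. = FALSE)
  sightings <- validate_sightings(sightings)
  if (nrow(sightings) == 0L) {
    return(validate_groups(data.frame(group_id = character(0),
                                      species_list = character(0),
                                      habitat = character(0))[0, ]))
  }
  method <- if (rule == "chain") "single" else "complete"
  out <- list()
  gi <- 0L
  for (d in split(seq_len(nrow(sightings)), as.character(sightings$date))) {
    s <- sightings[d, , drop = FALSE]
    if (nrow(s) == 1L) {
      comp <- 1L
    } else {
      hc <- stats::hclust(stats::dist(cbind(s$x, s$y)), method = method)
      comp <- stats::cutree(hc, h = radius)
    }
    for (cid in sort(unique(comp))) {
      gi <- gi + 1L
      mem <- s[comp == cid, , drop = FALSE]
      agg <- tapply(mem$count, mem$species, sum)
      hab_counts <- table(factor(mem$habitat, levels = msg_habitats()))
      habitat <- names(hab_counts)[which.max(hab_counts)]  # ties -> first level
      out[[gi]] <- data.frame(
        group_id = sprintf("g%05d", gi),
        species_list = paste(names(agg), collapse = ";"),
        counts = paste(as.integer(agg), collapse = ";"),
        habitat = habitat,
        x = mean(mem$x), y = mean(mem$y),
        date = mem$date[1L],
        stringsAsFactors = FALSE
      )
    }
  }
  validate_groups(do.call(rbind, out))
}

#' Minimum convex polygon home range with isopleth peeling
#'
#' Removes the `ceiling((1 - isopleth) * n)` points farthest from the
#' arithmetic mean centre (ties broken by input order), then returns the
#' convex hull of the remainder. With `isopleth = 1` this is the plain
#' convex hull.
#'
#' @param points Two-column matrix or data frame of x/y coordinates (metres).
#' @param isopleth Fraction of points the polygon must contain, in (0, 1].
#'   Default 0.85.
#' @return Object of class `home_range`: list with `vertices`
#'   (counter-clockwise open ring), `isopleth`, `source_points`, `area` (m^2).
#' @export
mcp_home_range <- function(points, isopleth = 0.85) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (!is.numeric(isopleth) || isopleth <= 0 || isopleth > 1) {
    stop("isopleth must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(pts)
  if (n < 3L) stop("home range needs at least 3 points", call. = FALSE)
  centre <- colMeans(pts)
  d <- sqrt((pts[, 1] - centre[1])^2 + (pts[, 2] - centre[2])^2)
  # round at 9 decimals so binary noise in (1 - isopleth) cannot push an
  # exact multiple over the next integer
  n_drop <- ceiling(round((1 - isopleth) * n, 9))
  keep <- seq_len(n)
  if (n_drop > 0L) {
    drop_idx <- order(-d, seq_len(n))[seq_len(n_drop)]
    keep <- setdiff(keep, drop_idx)
  }
  if (length(keep) < 3L) stop("fewer than 3 points survive peeling", call. = FALSE)
  kept <- pts[keep, , drop = FALSE]
  hull <- grDevices::chull(kept)
  if (length(hull) < 3L) stop("retained points are collinear; hull degenerate",
                              call. = FALSE)
  verts <- kept[rev(hull), , drop = FALSE]  # chull is clockwise; reverse to CCW
  colnames(verts) <- c("x", "y")
  structure(list(vertices = verts, isopleth = isopleth,
                 source_points = n, area = polygon_area(verts)),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("Minimum convex polygon home range: %d vertices, %.0f%% isopleth of %d points, area %.2f km^2\n",
              nrow(x$vertices), 100 * x$isopleth, x$source_points, x$area / 1e6))
  invisible(x)
}

# Shoelace area of a simple polygon given as an open ring.
polygon_area <- function(verts) {
  x <- verts[, 1]; y <- verts[, 2]
  j <- c(seq_len(nrow(verts))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Test points against a convex polygon (boundary counts as inside)
#'
#' Orientation is determined once from the polygon's signed area; a point is
#' inside when every edge cross product lies on that side (within `tol`), so
#' boundary points count as inside by convention.
#'
#' @param x,y Numeric coordinate vectors.
#' @param polygon Two-column vertex matrix (open ring, either orientation) or
#'   a `home_range` object.
#' @param tol Numeric slack for the boundary test, in metres.
#' @return Logical vector.
#' @export
point_in_convex <- function(x, y, polygon, tol = 1e-9) {
  if (inherits(polygon, "home_range")) polygon <- polygon$vertices
  v <- as.matrix(polygon)[, 1:2, drop = FALSE]
  nv <- nrow(v)
  j <- c(seq_len(nv)[-1], 1L)
  signed <- sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
  orient <- if (signed >= 0) 1 else -1
  inside <- rep(TRUE, length(x))
  for (k in seq_len(nv)) {
    ex <- v[j[k], 1] - v[k, 1]
    ey <- v[j[k], 2] - v[k, 2]
    scale <- sqrt(ex^2 + ey^2)
    if (scale == 0) next
    cr <- (ex * (y - v[k, 2]) - ey * (x - v[k, 1])) / scale
    inside <- inside & (orient * cr >= -tol)
  }
  inside
}

#' Flag groups inside a predator home range
#'
#' Sets `in_lhr` by point-in-convex-polygon membership of each group
#' centroid; points on the polygon boundary count as inside.
#'
#' @param groups Groups data frame with `x`, `y` columns.
#' @param hr `home_range` object (or vertex matrix).
#' @return `groups` with a logical `in_lhr` column.
#' @export
classify_lhr <- function(groups, hr) {
  require_columns(groups, c("x", "y"), "groups table")
  groups$in_lhr <- point_in_convex(groups$x, groups$y, hr)
  groups
}

#' Bin group NDVI values into empirical tertiles
#'
#' Class boundaries are the 33rd and 67th percentiles of the group-level
#' NDVI values, computed as exact tertile boundaries (probabilities 1/3 and
#' 2/3, type-7 linear interpolation) so the three classes are equal-sized;
#' values exactly at a boundary fall to the lower class.
#'
#' @param groups Groups data frame with `ndvi_value` set on every row.
#' @return `groups` with an `ndvi_class` column in
#'   `c("small", "medium", "large")`.
#' @export
bin_ndvi <- function(groups) {
  require_columns(groups, "ndvi_value", "groups table")
  miss <- is.na(groups$ndvi_value)
  if (any(miss)) {
    stop(sprintf("ndvi_value unset for group(s): %s",
                 paste(utils::head(groups$group_id[miss], 10L), collapse = ", ")),
         call. = FALSE)
  }
  q <- stats::quantile(groups$ndvi_value, c(1, 2) / 3, type = 7, names = FALSE)
  if (q[1] == q[2]) {
    stop(sprintf("degenerate NDVI quantiles (0.33 and 0.67 percentiles both %.4f); cannot form tertiles", q[1]),
         call. = FALSE)
  }
  cls <- ifelse(groups$ndvi_value <= q[1], "small",
                ifelse(groups$ndvi_value <= q[2], "medium", "large"))
  groups$ndvi_class <- cls
  attr(groups, "ndvi_breaks") <- q
  groups
}

# Minimum distance from points to a closed polyline (polygon boundary).
dist_to_boundary <- function(x, y, polygon) {
  v <- as.matrix(polygon)[, 1:2, drop = FALSE]
  nv <- nrow(v)
  j <- c(seq_len(nv)[-1], 1L)
  dmin <- rep(Inf, length(x))
  for (k in seq_len(nv)) {
    ax <- v[k, 1]; ay <- v[k, 2]
    bx <- v[j[k], 1]; by <- v[j[k], 2]
    ex <- bx - ax; ey <- by - ay
    len2 <- ex^2 + ey^2
    t <- if (len2 == 0) rep(0, length(x)) else ((x - ax) * ex + (y - ay) * ey) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- x - (ax + t * ex); dy <- y - (ay + t * ey)
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

#' Classify groups into core and edge zones
#'
#' A group lies in the `core` zone when its centroid is more than `buffer`
#' metres from the outer boundary polyline, otherwise in the `edge` zone
#' (the higher human-activity band where livestock grazing is permitted).
#'
#' @param groups Groups data frame with `x`, `y`.
#' @param boundary_polygon Two-column vertex matrix of the area boundary.
#' @param buffer Buffer width in metres (default 2000).
#' @return `groups` with a `zone` column.
#' @export
classify_zone <- function(groups, boundary_polygon, buffer = 2000) {
  require_columns(groups, c("x", "y"), "groups table")
  d <- dist_to_boundary(groups$x, groups$y, boundary_polygon)
  groups$zone <- ifelse(d > buffer, "core", "edge")
  groups
}
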