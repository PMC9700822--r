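# Reference grid and range geometry. All geometry is planar, in km, on a
# projected system supplied by the user (the synthetic generator uses an
# abstract plane); cell membership is half-open, [x0, x0 + w) x [y0, y0 + w),
# and all tie-breaks are by lowest id so assignment is order-independent.

#' Build a square reference grid over a projected extent
#'
#' Tiles the extent with square cells of side `cell_size_km` (default 111 km,
#' roughly 1 degree near the equator), ceil-covering: the grid extends past
#' the extent's upper edges if the side lengths are not exact multiples of
#' the cell size. Cell ids run row-major from the lower-left cell.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in km.
#' @param cell_size_km Cell side length in km; must be positive.
#' @return A data frame of class `"abund_grid"` with columns `cell_id`, `x`,
#'   `y` (centroid, km), `col`, `row`, and attributes `xmin`, `ymin`,
#'   `cell_size`, `n_col`, `n_row`.
#' @examples
#' g <- build_grid(c(0, 333, 0, 333))  # 3 x 3 = 9 cells
#' nrow(g)
#' @export
build_grid <- function(extent, cell_size_km = 111) {
  stopifnot(length(extent) == 4)
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  if (w <= 0 || h <= 0) stop("extent side lengths must be positive")
  if (cell_size_km <= 0) stop("cell_size_km must be positive")
  nc <- ceiling(w / cell_size_km); nr <- ceiling(h / cell_size_km)
  col <- rep(seq_len(nc), times = nr); row <- rep(seq_len(nr), each = nc)
  g <- data.frame(
    cell_id = seq_len(nc * nr),
    x = extent[1] + (col - 0.5) * cell_size_km,
    y = extent[3] + (row - 0.5) * cell_size_km,
    col = col, row = row)
  attr(g, "xmin") <- extent[1]; attr(g, "ymin") <- extent[3]
  attr(g, "cell_size") <- cell_size_km
  attr(g, "n_col") <- nc; attr(g, "n_row") <- nr
  class(g) <- c("abund_grid", "data.frame")
  g
}

#' Assign points to grid cells
#'
#' Half-open membership: a point on a cell's lower or left edge belongs to
#' that cell; a point on the shared upper edge of two cells belongs to the
#' cell above. Points outside the grid are returned as `NA` (unassigned is a
#' value, not an error).
#'
#' @param x,y Point coordinates (km), same projection as the grid.
#' @param grid An `"abund_grid"` from [build_grid()].
#' @return Integer vector of cell ids (`NA` = outside the grid).
#' @export
assign_cells <- function(x, y, grid) {
  s <- attr(grid, "cell_size")
  nc <- attr(grid, "n_col"); nr <- attr(grid, "n_row")
  ci <- floor((x - attr(grid, "xmin")) / s)
  ri <- floor((y - attr(grid, "ymin")) / s)
  id <- ri * nc + ci + 1L
  id[ci < 0 | ci >= nc | ri < 0 | ri >= nr] <- NA_integer_
  as.integer(id)
}

# Point-in-polygon by ray casting, with an explicit on-boundary test so that
# centroids lying exactly on a shared region boundary are "inside" every
# region they touch (the lowest region id then wins).
.point_in_ring <- function(px, py, ring, tol = 1e-9) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  j <- c(n, seq_len(n - 1))
  # boundary test: point within tol of any edge segment
  for (i in seq_len(n)) {
    if (.point_seg_dist(px, py, xs[j[i]], ys[j[i]], xs[i], ys[i]) <= tol)
      return(TRUE)
  }
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- xs[j[i]]; y1 <- ys[j[i]]; x2 <- xs[i]; y2 <- ys[i]
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

.point_seg_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  # degenerate segments have dx = dy = 0, so the clamp gives t = 0
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / pmax(L2, 1e-300)))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Normalize a region specification to list(list(id =, rings = list(matrix))).
.normalize_regions <- function(regions) {
  if (is.character(regions) && length(regions) == 1)
    regions <- read_regions_geojson(regions)
  if (is.data.frame(regions)) return(regions)  # explicit cell -> bcr map
  out <- lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    id <- if (!is.null(names(regions)) && nzchar(names(regions)[i]))
      as.integer(names(regions)[i]) else i
    if (is.matrix(r)) list(id = id, rings = list(r))
    else if (is.list(r) && !is.null(r$rings)) r
    else list(id = id, rings = r)
  })
  out[order(vapply(out, `[[`, integer(1), "id"))]
}

#' Read region polygons from a GeoJSON file
#'
#' Accepts a FeatureCollection of Polygon or MultiPolygon features; the
#' region id is taken from a `bcr` (or `bcr_id` or `id`) property, falling
#' back to the feature's position. Only outer rings are used.
#'
#' @param path Path to a GeoJSON file.
#' @return A list of regions, each `list(id =, rings = list of 2-column
#'   coordinate matrices)`, sorted by id.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (!is.null(gj$features)) gj$features else list(gj)
  regs <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    pr <- f$properties
    id <- as.integer(pr$bcr %||% pr$bcr_id %||% pr$id %||% i)
    geom <- f$geometry %||% f
    ring_of <- function(poly) {
      m <- do.call(rbind, lapply(poly[[1]], function(p) c(p[[1]], p[[2]])))
      m
    }
    rings <- if (geom$type == "Polygon") list(ring_of(geom$coordinates))
      else lapply(geom$coordinates, ring_of)
    list(id = id, rings = rings)
  })
  regs[order(vapply(regs, `[[`, integer(1), "id"))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign grid cells to regions (BCRs)
#'
#' Assignment is by cell centroid. Regions may be supplied as polygons (a
#' list of 2-column coordinate matrices, optionally named with integer ids;
#' or a GeoJSON file path), in which case a centroid lying on a shared
#' boundary is assigned to the lowest region id; or as an explicit two-column
#' `cell_id`/`bcr_id` data frame, returned verbatim. Centroids in no region
#' are `NA`.
#'
#' @param grid An `"abund_grid"`.
#' @param regions Polygon list, GeoJSON path, or `data.frame(cell_id, bcr_id)`.
#' @return The grid with a `bcr_id` column.
#' @export
assign_bcr <- function(grid, regions) {
  regions <- .normalize_regions(regions)
  if (is.data.frame(regions)) {
    m <- regions$bcr_id[match(grid$cell_id, regions$cell_id)]
    grid$bcr_id <- as.integer(m)
    return(grid)
  }
  bcr <- rep(NA_integer_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    for (r in regions) {  # regions sorted by id: first hit = lowest id
      hit <- any(vapply(r$rings, function(rg)
        .point_in_ring(grid$x[i], grid$y[i], rg), logical(1)))
      if (hit) { bcr[i] <- r$id; break }
    }
  }
  grid$bcr_id <- bcr
  grid
}

#' Define a species range from detection cells
#'
#' The range is the union of whole regions (BCRs): every cell of every BCR
#' that contains at least one detection cell is in-range, including cells of
#' those BCRs with no detections. Detections should already have had likely
#' vagrants removed upstream (supply an exclusion list before calling; the
#' package never guesses a vagrant rule).
#'
#' @param grid An `"abund_grid"` with a `bcr_id` column (see [assign_bcr()]).
#' @param detection_cells Integer cell ids with at least one detection in
#'   any dataset.
#' @return The grid with a logical `in_range` column.
#' @export
define_range <- function(grid, detection_cells) {
  if (is.null(grid$bcr_id)) stop("assign_bcr() must be run first")
  range_bcrs <- sort(unique(grid$bcr_id[match(detection_cells, grid$cell_id)]))
  range_bcrs <- range_bcrs[!is.na(range_bcrs)]
  if (length(range_bcrs) == 0) {
    if (length(detection_cells) == 0) warning("no detections: empty range")
    grid$in_range <- rep(FALSE, nrow(grid))
    return(grid)
  }
  grid$in_range <- grid$bcr_id %in% range_bcrs
  grid
}

#' Distance from cell centroids to the range edge
#'
#' Euclidean distance (km) from each in-range cell's centroid to the nearest
#' point of the range boundary. By default the boundary is that of the union
#' of in-range cell squares (the range is a union of whole BCRs, i.e. a
#' polygon union); alternatively supply explicit range polygons.
#'
#' @param grid An `"abund_grid"` with an `in_range` column.
#' @param range_polygons Optional list of 2-column boundary coordinate
#'   matrices to measure against instead of the cell-union boundary.
#' @param cells Optional cell ids to compute for; any out-of-range id is an
#'   error. Default: all cells (out-of-range cells get `NA`).
#' @return Numeric vector of distances (km), aligned with `cells` (or with
#'   the grid rows when `cells` is `NULL`, `NA` for out-of-range cells).
#' @export
distance_to_edge <- function(grid, range_polygons = NULL, cells = NULL) {
  if (is.null(grid$in_range)) stop("define_range() must be run first")
  idx <- if (is.null(cells)) seq_len(nrow(grid)) else match(cells, grid$cell_id)
  if (!is.null(cells) && !all(grid$in_range[idx]))
    stop("distance_to_edge requested for out-of-range cell(s)")
  segs <- if (is.null(range_polygons)) .range_boundary_segments(grid)
    else do.call(rbind, lapply(range_polygons, function(m) {
      n <- nrow(m); j <- c(n, seq_len(n - 1))
      cbind(m[j, 1], m[j, 2], m[, 1], m[, 2])
    }))
  out <- rep(NA_real_, length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]
    if (!grid$in_range[i]) next
    out[q] <- min(.point_seg_dist(grid$x[i], grid$y[i],
                                  segs[, 1], segs[, 2], segs[, 3], segs[, 4]))
  }
  out
}

# Boundary of the union of in-range cell squares: every cell edge whose
# neighbouring cell (by row/col offset) is out of range or off the grid.
.range_boundary_segments <- function(grid) {
  s <- attr(grid, "cell_size")
  xmin <- attr(grid, "xmin"); ymin <- attr(grid, "ymin")
  nc <- attr(grid, "n_col"); nr <- attr(grid, "n_row")
  inr <- matrix(FALSE, nr, nc)
  inr[cbind(grid$row, grid$col)] <- grid$in_range
  segs <- list()
  for (i in which(grid$in_range)) {
    r <- grid$row[i]; cc <- grid$col[i]
    x0 <- xmin + (cc - 1) * s; y0 <- ymin + (r - 1) * s
    if (r == 1 || !inr[r - 1, cc])          # bottom edge
      segs[[length(segs) + 1]] <- c(x0, y0, x0 + s, y0)
    if (r == nr || !inr[r + 1, cc])         # top edge
      segs[[length(segs) + 1]] <- c(x0, y0 + s, x0 + s, y0 + s)
    if (cc == 1 || !inr[r, cc - 1])         # left edge
      segs[[length(segs) + 1]] <- c(x0, y0, x0, y0 + s)
    if (cc == nc || !inr[r, cc + 1])        # right edge
      segs[[length(segs) + 1]] <- c(x0 + s, y0, x0 + s, y0 + s)
  }
  if (length(segs) == 0) stop("no in-range cells")
  do.call(rbind, segs)
}

#' Export a grid as delimited text
#'
#' Writes `cell_id, x, y, bcr_id, in_range, dist_edge_km` (columns present
#' only if computed) as CSV.
#'
#' @param grid An `"abund_grid"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  keep <- intersect(c("cell_id", "x", "y", "bcr_id", "in_range",
                      "dist_edge_km"), names(grid))
  utils::write.csv(as.data.frame(grid)[keep], path, row.names = FALSE)
  invisible(path)
}
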