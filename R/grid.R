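#' Define a regular latitude-longitude grid
#'
#' A `grid_spec` describes a regular geographic grid referenced to its
#' north-west corner. Rasters on the grid are plain R matrices, row-major
#' from the north-west: row 1 is the northernmost row, column 1 the
#' westernmost column. Cell (i, j) has its centre at
#' `lon = origin_lon + (j - 0.5) * cellsize` and
#' `lat = origin_lat - (i - 0.5) * cellsize`.
#'
#' @param rows,cols grid dimensions (positive integers).
#' @param origin_lat,origin_lon latitude/longitude of the north-west
#'   *corner* of the grid, decimal degrees.
#' @param cellsize cell edge length in decimal degrees (> 0).
#' @param datum datum label, informational only. Plain geographic
#'   coordinates are assumed; the GDA94 vs WGS84 offset (< 2 m) is
#'   sub-pixel at the resolutions used here and is ignored.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(rows, cols, origin_lat = 0, origin_lon = 0,
                      cellsize = 0.01, datum = "GDA94") {
  stopifnot(is.numeric(rows), is.numeric(cols), rows >= 1, cols >= 1,
            rows == round(rows), cols == round(cols))
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("cellsize must be a single positive number")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 origin_lat = origin_lat, origin_lon = origin_lon,
                 cellsize = cellsize, datum = datum),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g deg, NW corner (%g, %g), %s\n",
              x$rows, x$cols, x$cellsize, x$origin_lat, x$origin_lon,
              x$datum))
  invisible(x)
}

#' @rdname grid_spec
#' @param x object to test.
#' @export
is_grid_spec <- function(x) inherits(x, "grid_spec")

grid_lat_centres <- function(grid) {
  grid$origin_lat - (seq_len(grid$rows) - 0.5) * grid$cellsize
}

grid_lon_centres <- function(grid) {
  grid$origin_lon + (seq_len(grid$cols) - 0.5) * grid$cellsize
}

same_grid <- function(a, b, tol = 1e-9) {
  a$rows == b$rows && a$cols == b$cols &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Spherical cell areas for a regular lat-lon grid
#'
#' Area of each grid cell on a sphere of radius 6371 km:
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))` with `dlambda` the
#' cell width in radians. A 0.01 degree cell at the equator is about
#' 1.2364 km^2 (the nominal "1.1 km x 1.1 km" AVHRR-class pixel).
#'
#' @param grid a [grid_spec()].
#' @return Matrix (rows x cols) of cell areas in km^2.
#' @export
cell_area_km2 <- function(grid) {
  stopifnot(is_grid_spec(grid))
  R <- 6371.0
  d2r <- pi / 180
  lat_top <- grid$origin_lat - (seq_len(grid$rows) - 1) * grid$cellsize
  lat_bot <- lat_top - grid$cellsize
  band <- R^2 * (grid$cellsize * d2r) *
    (sin(lat_top * d2r) - sin(lat_bot * d2r))
  matrix(rep(band, grid$cols), nrow = grid$rows, ncol = grid$cols)
}

#' Majority-resample a boolean mask to a coarser grid
#'
#' Aggregates `factor x factor` blocks of a fine-resolution forest mask to
#' one coarse cell. The coarse cell is forest iff strictly more than half
#' of its constituent fine cells are forest; an exact 50% tie resolves to
#' non-forest (conservative mask).
#'
#' @param mask logical matrix (fine resolution).
#' @param factor integer block size; must divide both dimensions.
#' @param grid optional [grid_spec()] of `mask`; if supplied, the matching
#'   coarse `grid_spec` is attached as attribute `"grid"`.
#' @return Logical matrix with dimensions `dim(mask) / factor`.
#' @export
majority_resample <- function(mask, factor, grid = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  if (nrow(mask) %% factor != 0L || ncol(mask) %% factor != 0L)
    stop("factor must divide both grid dimensions")
  nr <- nrow(mask) %/% factor
  nc <- ncol(mask) %/% factor
  # block sums via row-group then column-group aggregation
  ri <- rep(seq_len(nr), each = factor)
  ci <- rep(seq_len(nc), each = factor)
  counts <- rowsum(mask + 0, ri)           # nr x (nc*factor)
  counts <- t(rowsum(t(counts), ci))       # nr x nc
  out <- counts > (factor^2) / 2
  if (!is.null(grid)) {
    attr(out, "grid") <- grid_spec(nr, nc, grid$origin_lat, grid$origin_lon,
                                   grid$cellsize * factor, grid$datum)
  }
  out
}

#' Nearest-neighbour resampling between regular grids
#'
#' Assigns to each target cell the value of the source cell whose centre is
#' nearest to the target cell centre. Values pass through unchanged (no
#' interpolation), so resampling onto the source grid itself is the
#' identity.
#'
#' @param raster matrix on `source` grid.
#' @param source,target [grid_spec()] objects.
#' @return Matrix on the target grid.
#' @export
nearest_neighbour_resample <- function(raster, source, target) {
  stopifnot(is.matrix(raster), is_grid_spec(source), is_grid_spec(target),
            nrow(raster) == source$rows, ncol(raster) == source$cols)
  tg_lat <- grid_lat_centres(target)
  tg_lon <- grid_lon_centres(target)
  # nearest source row/col index for each target centre
  src_i <- round((source$origin_lat - tg_lat) / source$cellsize + 0.5)
  src_j <- round((tg_lon - source$origin_lon) / source$cellsize + 0.5)
  if (all(src_i < 1 | src_i > source$rows) ||
      all(src_j < 1 | src_j > source$cols))
    stop("target grid does not overlap the source grid")
  src_i <- pmin(pmax(src_i, 1L), source$rows)
  src_j <- pmin(pmax(src_j, 1L), source$cols)
  raster[src_i, src_j, drop = FALSE]
}

# Even-odd point-in-polygon with boundary points counted inside.
# px, py: point coordinates (vectors); vx, vy: polygon vertices (closed or
# open ring). Returns logical vector.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  if (n != length(vy) || n < 3L) stop("polygon needs >= 3 vertices")
  # drop duplicated closing vertex
  if (vx[1] == vx[n] && vy[1] == vy[n]) { vx <- vx[-n]; vy <- vy[-n]; n <- n - 1L }
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary test: point collinear with and within the segment bbox
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on_seg <- abs(cross) < 1e-12 &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | on_seg
    # even-odd ray cast (horizontal ray towards +x)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Rasterize fire perimeters onto annual occurrence rasters
#'
#' Marks a grid cell burned in a given year/cause if the cell centre falls
#' inside (or exactly on the boundary of) any perimeter polygon carrying
#' that year and cause. Overlapping polygons of the same year burn a cell
#' once (boolean occurrence). Polygons wholly outside the grid are skipped
#' with a warning.
#'
#' @param perimeters data frame of polygon vertices with columns
#'   `poly_id`, `lon`, `lat` (vertices in ring order per polygon).
#' @param attrs data frame with one row per `poly_id` and columns
#'   `poly_id`, `year`, `cause` (`"wildfire"` or `"prescribed"`).
#' @param grid a [grid_spec()].
#' @return Named list: one logical `rows x cols` matrix per `"year.cause"`
#'   combination present, plus attribute `"grid"`.
#' @export
rasterize_perimeters <- function(perimeters, attrs, grid) {
  stopifnot(is.data.frame(perimeters),
            all(c("poly_id", "lon", "lat") %in% names(perimeters)),
            is.data.frame(attrs),
            all(c("poly_id", "year") %in% names(attrs)),
            is_grid_spec(grid))
  if (is.null(attrs$cause)) attrs$cause <- "wildfire"
  if (anyNA(attrs$year)) stop("every polygon needs a year attribute")
  lat <- grid_lat_centres(grid)
  lon <- grid_lon_centres(grid)
  px <- rep(lon, each = grid$rows)
  py <- rep(lat, times = grid$cols)
  out <- list()
  for (k in seq_len(nrow(attrs))) {
    id <- attrs$poly_id[k]
    ring <- perimeters[perimeters$poly_id == id, , drop = FALSE]
    if (nrow(ring) < 3L) stop(sprintf("polygon %s has < 3 vertices", id))
    if (max(ring$lon) < grid$origin_lon ||
        min(ring$lon) > grid$origin_lon + grid$cols * grid$cellsize ||
        max(ring$lat) < grid$origin_lat - grid$rows * grid$cellsize ||
        min(ring$lat) > grid$origin_lat) {
      warning(sprintf("polygon %s lies outside the grid extent; skipped", id))
      next
    }
    key <- paste(attrs$year[k], attrs$cause[k], sep = ".")
    hit <- point_in_polygon(px, py, ring$lon, ring$lat)
    m <- matrix(hit, nrow = grid$rows, ncol = grid$cols)
    out[[key]] <- if (is.null(out[[key]])) m else (out[[key]] | m)
  }
  attr(out, "grid") <- grid
  out
}

#' Read/write a raster as tab-separated text
#'
#' Plain-text raster exchange: a header line with the [grid_spec()] fields
#' followed by the matrix rows (north to south). Values round-trip
#' losslessly for logical and full-precision numeric rasters.
#'
#' @param raster matrix to write.
#' @param grid the raster's [grid_spec()].
#' @param path file path.
#' @return `write_raster_tsv` returns `path` invisibly; `read_raster_tsv`
#'   returns the matrix with the `grid_spec` attached as attribute
#'   `"grid"`.
#' @export
write_raster_tsv <- function(raster, grid, path) {
  stopifnot(is.matrix(raster), is_grid_spec(grid))
  hdr <- sprintf("# grid rows=%d cols=%d origin_lat=%.10g origin_lon=%.10g cellsize=%.10g datum=%s",
                 grid$rows, grid$cols, grid$origin_lat, grid$origin_lon,
                 grid$cellsize, grid$datum)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(raster, digits = 17, trim = TRUE), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_raster_tsv
#' @export
read_raster_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  fields <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(fields, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  grid <- grid_spec(as.integer(vals["rows"]), as.integer(vals["cols"]),
                    as.numeric(vals["origin_lat"]),
                    as.numeric(vals["origin_lon"]),
                    as.numeric(vals["cellsize"]), vals[["datum"]])
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L,
                                   colClasses = "character"))
  if (all(m %in% c("TRUE", "FALSE"))) {
    m <- matrix(m == "TRUE", nrow = grid$rows)
  } else {
    m <- matrix(as.numeric(m), nrow = grid$rows)
  }
  dimnames(m) <- NULL
  attr(m, "grid") <- grid
  m
}
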