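#' @useDynLib demicabc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx coef density dnorm dunif ks.test lm lm.fit
#'   optimize pnorm predict quantile rbinom rgamma rnorm rpois runif sd
#'   setNames var
#' @importFrom utils read.csv write.csv head combn
NULL

#' Meters per degree in the WGS84 Plate Carree (equirectangular) projection
#'
#' Equatorial radius 6,378,137 m times pi/180, i.e. ~111,319.49 m/degree.
#' All grid georeferencing uses this single constant; the projection treats
#' degrees of latitude and longitude as equal-length.
#' @export
PC_METERS_PER_DEGREE <- (pi / 180) * 6378137

#' Convert longitude/latitude to Plate Carree meters
#'
#' Equirectangular projection: `x = lon * k`, `y = lat * k` with
#' `k = (pi/180) * 6378137`. The inverse is [lonlat_from_platecarree()];
#' the pair round-trips exactly up to floating point.
#'
#' @param lon,lat numeric vectors, degrees. `|lat|` must not exceed 90.
#' @return data.frame with columns `x`, `y` (meters).
#' @export
platecarree_from_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates")
  if (any(abs(lat) > 90)) stop("invalid coordinate: |latitude| > 90")
  data.frame(x = lon * PC_METERS_PER_DEGREE, y = lat * PC_METERS_PER_DEGREE)
}

#' Inverse Plate Carree conversion (meters to degrees)
#' @param x,y numeric vectors, Plate Carree meters.
#' @return data.frame with columns `lon`, `lat` (degrees).
#' @export
lonlat_from_platecarree <- function(x, y) {
  lat <- y / PC_METERS_PER_DEGREE
  if (any(abs(lat) > 90 + 1e-9)) stop("invalid coordinate: |latitude| > 90")
  data.frame(lon = x / PC_METERS_PER_DEGREE, lat = lat)
}

#' Georeferenced simulation lattice
#'
#' A lattice of square cells in Plate Carree meters. Each cell holds one
#' deme per population layer. The default dimensions (75 columns x 47 rows
#' of 100 x 100 km) cover western Eurasia and North Africa starting at
#' 10 degrees W / 30 degrees N; the packaged default mask is all land
#' (synthetic: no coastline data are shipped). Cells are half-open
#' intervals `[edge, edge + cell_size)` so that every point maps to exactly
#' one cell. Demes are indexed `1..n_cols*n_rows`, row-major with row 1 the
#' southernmost row.
#'
#' @param n_cols,n_rows lattice dimensions.
#' @param cell_size cell edge length in meters (default 100 km).
#' @param origin numeric length-2, Plate Carree x/y of the lower-left grid
#'   corner in meters. Default corresponds to 10W, 30N.
#' @param land_mask logical matrix `n_rows x n_cols` (row 1 = southernmost)
#'   or `NULL` for all land.
#' @param zone_boundary_lat latitude (degrees) splitting the southern and
#'   northern competition/admixture zones (default 43.2).
#' @return object of class `world_grid`.
#' @export
world_grid <- function(n_cols = 75, n_rows = 47, cell_size = 1e5,
                       origin = c(x = -10 * PC_METERS_PER_DEGREE,
                                  y = 30 * PC_METERS_PER_DEGREE),
                       land_mask = NULL, zone_boundary_lat = 43.2) {
  stopifnot(n_cols >= 1, n_rows >= 1, cell_size > 0)
  if (is.null(land_mask)) {
    land_mask <- matrix(TRUE, nrow = n_rows, ncol = n_cols)
  }
  stopifnot(is.matrix(land_mask), nrow(land_mask) == n_rows,
            ncol(land_mask) == n_cols)
  w <- list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
            cell_size = cell_size,
            origin = c(x = unname(origin[1]), y = unname(origin[2])),
            land_mask = land_mask,
            zone_boundary_lat = zone_boundary_lat)
  class(w) <- "world_grid"
  w
}

#' @export
print.world_grid <- function(x, ...) {
  cat(sprintf("world_grid: %d x %d cells of %.0f km, %d land cells\n",
              x$n_cols, x$n_rows, x$cell_size / 1000, sum(x$land_mask)))
  invisible(x)
}

n_demes <- function(world) world$n_cols * world$n_rows

deme_id <- function(world, row, col) (row - 1L) * world$n_cols + col

deme_rowcol <- function(world, deme) {
  deme <- as.integer(deme)
  if (any(deme < 1L | deme > n_demes(world))) stop("deme id out of range")
  list(row = (deme - 1L) %/% world$n_cols + 1L,
       col = (deme - 1L) %% world$n_cols + 1L)
}

#' Locate the cell containing a point
#'
#' Cells are half-open `[edge, edge + cell_size)`: a point exactly on a
#' shared edge belongs to the lower-index cell.
#'
#' @param world a [world_grid()].
#' @param x,y Plate Carree meters (vectors).
#' @return integer deme ids with attribute `land` (logical vector) marking
#'   whether each cell is land.
#' @export
deme_of <- function(world, x, y) {
  col <- floor((x - world$origin["x"]) / world$cell_size) + 1
  row <- floor((y - world$origin["y"]) / world$cell_size) + 1
  if (any(col < 1 | col > world$n_cols | row < 1 | row > world$n_rows))
    stop("coordinates outside grid bounds")
  id <- deme_id(world, as.integer(row), as.integer(col))
  attr(id, "land") <- is_land(world, id)
  id
}

#' @rdname deme_of
#' @param deme integer deme ids.
#' @export
is_land <- function(world, deme) {
  rc <- deme_rowcol(world, deme)
  world$land_mask[cbind(rc$row, rc$col)]
}

#' Cell-center coordinates of demes
#' @inheritParams is_land
#' @return data.frame with `x`, `y` (meters) of cell centers.
#' @export
deme_center <- function(world, deme) {
  rc <- deme_rowcol(world, deme)
  data.frame(x = world$origin["x"] + (rc$col - 0.5) * world$cell_size,
             y = world$origin["y"] + (rc$row - 0.5) * world$cell_size,
             row.names = NULL)
}

#' Competition/admixture zone of a deme
#'
#' A deme is in the northern zone iff its cell-center latitude is strictly
#' greater than the boundary latitude (default 43.2 degrees); a center
#' exactly on the boundary is southern.
#'
#' @inheritParams is_land
#' @return character vector, `"north"` or `"south"`.
#' @export
zone_of <- function(world, deme) {
  ctr <- deme_center(world, deme)
  lat <- lonlat_from_platecarree(ctr$x, ctr$y)$lat
  ifelse(lat > world$zone_boundary_lat, "north", "south")
}

#' Map a mean age to a simulation generation index
#'
#' Generations run forward from the simulation start: generation 0 is
#' `start_BP` years before present and one generation spans `gen_years`
#' years. Rounding is half-up for reproducibility.
#'
#' @param age_BP age in years before present (0 <= age_BP <= start_BP).
#' @param start_BP simulation start, years B.P. (default 40,000).
#' @param gen_years generation interval in years (default 25).
#' @return integer generation index.
#' @export
generation_from_age <- function(age_BP, start_BP = 40000, gen_years = 25) {
  if (any(age_BP < 0)) stop("invalid age: negative")
  if (any(age_BP > start_BP)) stop("invalid age: older than simulation start")
  as.integer(floor((start_BP - age_BP) / gen_years + 0.5))
}

#' Read a world from an Esri ASCII grid
#'
#' Header keys `ncols`, `nrows`, `cellsize` and either `xllcorner`/
#' `yllcorner` are required; `NODATA_value` defaults to -9999. Cell values
#' equal to the NODATA sentinel or 0 are water, anything else is land.
#' Esri ASCII rows are stored north-to-south; they are flipped so that
#' internal row 1 is the southernmost.
#'
#' @param path path to a `.asc` file.
#' @param zone_boundary_lat see [world_grid()].
#' @return a [world_grid()].
#' @export
load_world <- function(path, zone_boundary_lat = 43.2) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize", "xllcorner", "yllcorner")
  if (!all(need %in% names(hdr)))
    stop("malformed Esri ASCII header: need ", paste(need, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("malformed raster: expected ", hdr$ncols * hdr$nrows, " values")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # row 1 = south
  world_grid(n_cols = hdr$ncols, n_rows = hdr$nrows, cell_size = hdr$cellsize,
             origin = c(x = hdr$xllcorner, y = hdr$yllcorner),
             land_mask = (m != nodata) & (m != 0),
             zone_boundary_lat = zone_boundary_lat)
}

#' Write a world as an Esri ASCII grid (land = 1, water = NODATA)
#' @param world a [world_grid()].
#' @param path output path.
#' @export
write_world <- function(world, path) {
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.6f\nyllcorner %.6f\ncellsize %.6f\nNODATA_value -9999",
    world$n_cols, world$n_rows, world$origin["x"], world$origin["y"],
    world$cell_size)
  m <- ifelse(world$land_mask, 1, -9999)
  rows <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1, paste,
                collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Sampling scheme: serially sampled population samples
#'
#' A table of "population samples": groups of individuals sampled from one
#' deme, one population layer (HG or FA) and one mean age. Ages are mapped
#' to simulation generations with [generation_from_age()].
#'
#' @param samples data.frame with columns `label`, `layer` (`"HG"`/`"FA"`),
#'   `x`, `y` (Plate Carree meters), `n` (individuals, >= 1), `mean_age`
#'   (yr B.P.).
#' @param start_BP,generations_total simulation time frame; every sample's
#'   generation must be `< generations_total`.
#' @param gen_years years per generation.
#' @return object of class `sampling_scheme` (the validated data.frame with
#'   a `generation` column and metadata attributes).
#' @export
sampling_scheme <- function(samples, start_BP = 40000,
                            generations_total = 1600, gen_years = 25) {
  need <- c("label", "layer", "x", "y", "n", "mean_age")
  if (!all(need %in% names(samples)))
    stop("scheme table must have columns ", paste(need, collapse = ", "))
  samples <- as.data.frame(samples)[, need]
  if (nrow(samples) > 0) {
    if (anyDuplicated(samples$label)) stop("duplicate sample labels")
    if (!all(samples$layer %in% c("HG", "FA")))
      stop("layer must be HG or FA")
    if (any(samples$n < 1)) stop("sample sizes must be >= 1")
    samples$generation <- generation_from_age(samples$mean_age, start_BP,
                                              gen_years)
    if (any(samples$generation >= generations_total))
      stop("sample generation beyond the simulated time frame")
  } else {
    samples$generation <- integer(0)
  }
  structure(samples, class = c("sampling_scheme", "data.frame"),
            start_BP = start_BP, generations_total = generations_total,
            gen_years = gen_years)
}

#' Read a sampling scheme from CSV
#' @param path CSV file with a header row and the columns documented in
#'   [sampling_scheme()].
#' @inheritParams sampling_scheme
#' @export
load_sampling_scheme <- function(path, start_BP = 40000,
                                 generations_total = 1600, gen_years = 25) {
  sampling_scheme(read.csv(path, stringsAsFactors = FALSE), start_BP,
                  generations_total, gen_years)
}

#' Resolve scheme demes on a world
#'
#' Maps each sample's coordinates to its deme and errors if any sample
#' falls on water or outside the grid.
#'
#' @param world a [world_grid()].
#' @param scheme a [sampling_scheme()].
#' @return integer vector of deme ids, one per sample.
#' @export
scheme_demes <- function(world, scheme) {
  if (nrow(scheme) == 0) return(integer(0))
  id <- deme_of(world, scheme$x, scheme$y)
  if (!all(attr(id, "land")))
    stop("sample deme(s) on water: ",
         paste(scheme$label[!attr(id, "land")], collapse = ", "))
  as.integer(id)
}
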