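#' Construct a fluorescence image
#'
#' A `fluor_image` couples a 2-D intensity array in arbitrary units (a.u.)
#' with the physical pixel size in millimeters. The default geometry mirrors
#' a closed-box specimen imager: 1300 x 964 pixels at 85 um resolution.
#' Pixel values are stored as a numeric matrix with rows running down the
#' image (y) and columns across (x).
#'
#' @param pixels numeric matrix of non-negative, finite intensities (a.u.).
#' @param pixel_size_mm positive physical edge length of one pixel, in mm.
#'   Default 0.085 (85 um).
#' @return An object of class `fluor_image` with elements `pixels`,
#'   `pixel_size_mm`, `width` (columns) and `height` (rows).
#' @examples
#' img <- fluor_image(matrix(0.2, 50, 80))
#' img$width   # 80
#' img$height  # 50
#' @export
fluor_image <- function(pixels, pixel_size_mm = 0.085) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("intensities must be finite")
  if (any(pixels < 0))
    stop("intensities must be non-negative")
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      !is.finite(pixel_size_mm) || pixel_size_mm <= 0)
    stop("'pixel_size_mm' must be a single positive number")
  structure(
    list(pixels = pixels, pixel_size_mm = as.numeric(pixel_size_mm),
         width = ncol(pixels), height = nrow(pixels)),
    class = "fluor_image"
  )
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf("<fluor_image> %d x %d px @ %.3f mm/px, range [%.4g, %.4g] a.u.\n",
              x$width, x$height, x$pixel_size_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Parse PhysicalSizeX (um unless another unit is declared) out of an OME-XML
# image description. Returns the pixel size in mm, or NA if absent.
ome_pixel_size_mm <- function(description) {
  if (is.null(description) || !nzchar(description)) return(NA_real_)
  m <- regmatches(description,
                  regexec('PhysicalSizeX="([0-9.eE+-]+)"', description))[[1]]
  if (length(m) < 2L) return(NA_real_)
  val <- as.numeric(m[2])
  unit <- regmatches(description,
                     regexec('PhysicalSizeXUnit="([^"]+)"', description))[[1]]
  unit <- if (length(unit) >= 2L) unit[2] else "µm"
  scale <- switch(unit,
                  "mm" = 1, "µm" = 1e-3, "um" = 1e-3, "nm" = 1e-6,
                  NA_real_)
  val * scale
}

read_tiff_matrix <- function(path) {
  x <- tiff::readTIFF(path, info = TRUE)
  if (length(dim(x)) == 3L) x <- x[, , 1L]  # first channel of multi-channel
  x
}

#' Read a paired white-light and fluorescence image
#'
#' Both images must be TIFF/OME-TIFF on a common pixel grid; a shape mismatch
#' is rejected as an unpaired acquisition. The pixel size is taken from the
#' OME-XML `PhysicalSizeX` attribute of the fluorescence image when present;
#' otherwise the supplied `pixel_size_mm` is used, defaulting to 0.085 mm
#' with a warning when no metadata is available and no override is given.
#'
#' @param white_path path to the white-light TIFF.
#' @param fluor_path path to the fluorescence TIFF.
#' @param pixel_size_mm optional override for the physical pixel size in mm;
#'   takes precedence over the metadata fallback warning (but embedded
#'   metadata, when readable, wins).
#' @return A list with elements `white` and `fluor`, both `fluor_image`
#'   objects on the same grid.
#' @export
read_image_pair <- function(white_path, fluor_path, pixel_size_mm = NULL) {
  for (p in c(white_path, fluor_path))
    if (!file.exists(p)) stop("file not found: ", p)
  white <- read_tiff_matrix(white_path)
  fluor <- read_tiff_matrix(fluor_path)
  if (!identical(dim(white), dim(fluor)))
    stop("unpaired images: white is ", paste(dim(white), collapse = "x"),
         " but fluorescence is ", paste(dim(fluor), collapse = "x"))
  meta_mm <- ome_pixel_size_mm(attr(fluor, "description"))
  px <- if (is.finite(meta_mm) && meta_mm > 0) {
    meta_mm
  } else if (!is.null(pixel_size_mm)) {
    pixel_size_mm
  } else {
    warning("no pixel-size metadata found; assuming 0.085 mm/px")
    0.085
  }
  list(white = fluor_image(unclass(white), px),
       fluor = fluor_image(unclass(fluor), px))
}

#' Write a fluorescence image to TIFF
#'
#' Intensities are stored as 32-bit integer samples; values must lie in
#' \[0, 1\] a.u. The round trip quantizes to multiples of 1/(2^32 - 1), i.e.
#' an absolute error below 2.4e-10; values already on that lattice survive
#' bit-exactly.
#'
#' @param image a `fluor_image` or numeric matrix with values in \[0, 1\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "fluor_image")) image$pixels else image
  if (any(px < 0) || any(px > 1))
    stop("TIFF storage requires intensities in [0, 1] a.u.")
  tiff::writeTIFF(px, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' Read a binary mask from a TIFF label image
#'
#' Any strictly positive pixel is foreground.
#'
#' @param path TIFF file path.
#' @return A logical matrix.
#' @export
read_mask_tiff <- function(path) {
  x <- read_tiff_matrix(path)
  unclass(x) > 0
}

# -- polygons -----------------------------------------------------------------

# Polygon representation: a list of rings; each ring a 2-column numeric matrix
# of (x, y) vertices in pixel coordinates. Coordinates are 0-based with the
# origin at the top-left pixel center: pixel [i, j] (1-based R indices) has
# its center at (x = j - 1, y = i - 1), x increasing rightwards (columns),
# y downwards (rows). Multiple rings combine under the even-odd rule, so
# interior rings cut holes.

as_rings <- function(roi) {
  if (is.matrix(roi)) roi <- list(roi)
  lapply(roi, function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    if (ncol(r) != 2L || nrow(r) < 3L)
      stop("each ring needs >= 3 (x, y) vertices")
    # drop an explicit closing vertex
    if (all(r[1L, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3L) stop("each ring needs >= 3 distinct vertices")
    r
  })
}

# Even-odd crossing count for points (px, py) against one ring.
ring_crossings <- function(px, py, ring) {
  n <- nrow(ring)
  x1 <- ring[, 1L]; y1 <- ring[, 2L]
  x2 <- ring[c(2:n, 1L), 1L]; y2 <- ring[c(2:n, 1L), 2L]
  cross <- integer(length(px))
  for (e in seq_len(n)) {
    if (y1[e] == y2[e]) next  # horizontal edge: no upward/downward crossing
    straddles <- (y1[e] > py) != (y2[e] > py)
    if (!any(straddles)) next
    xint <- x1[e] + (py[straddles] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
    hit <- px[straddles] < xint
    cross[straddles] <- cross[straddles] + as.integer(hit)
  }
  cross
}

ring_area <- function(ring) {
  n <- nrow(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- x[c(2:n, 1L)]; yn <- y[c(2:n, 1L)]
  abs(sum(x * yn - xn * y)) / 2
}

#' Rasterize a polygon ROI onto an image grid
#'
#' A pixel belongs to the mask iff its center lies inside the polygon under
#' the even-odd rule. Coordinates are 0-based pixel-center coordinates with
#' the origin at the top-left, x rightwards and y downwards (the convention
#' used by common viewers' polygon exports). The polygon is clipped to the
#' image; an ROI that covers no pixel center raises an error.
#'
#' @param roi a single ring (2-column matrix of x, y vertices) or a list of
#'   rings (holes under even-odd).
#' @param grid a `fluor_image`, a matrix, or an integer vector
#'   `c(nrow, ncol)` defining the target grid.
#' @return A logical matrix (the `BinaryMask`) of the grid's dimensions.
#' @examples
#' rect <- cbind(c(9.5, 19.5, 19.5, 9.5), c(9.5, 9.5, 19.5, 19.5))
#' m <- rasterize_roi(rect, c(30, 30))
#' sum(m)  # 100 pixel centers inside
#' @export
rasterize_roi <- function(roi, grid) {
  dims <- if (inherits(grid, "fluor_image")) dim(grid$pixels)
          else if (is.matrix(grid)) dim(grid)
          else as.integer(grid)
  nr <- dims[1L]; nc <- dims[2L]
  rings <- as_rings(roi)
  if (sum(vapply(rings, ring_area, numeric(1))) == 0)
    stop("empty ROI: polygon has zero area")
  allv <- do.call(rbind, rings)
  # candidate pixels: bounding box clipped to the grid
  c0 <- max(1L, floor(min(allv[, 1L])) + 1L)
  c1 <- min(nc, ceiling(max(allv[, 1L])) + 1L)
  r0 <- max(1L, floor(min(allv[, 2L])) + 1L)
  r1 <- min(nr, ceiling(max(allv[, 2L])) + 1L)
  mask <- matrix(FALSE, nr, nc)
  if (c0 > c1 || r0 > r1) stop("empty ROI: polygon lies outside the image")
  rows <- r0:r1; cols <- c0:c1
  px <- rep(cols - 1, each = length(rows))   # x = column index, 0-based
  py <- rep(rows - 1, times = length(cols))  # y = row index, 0-based
  cross <- integer(length(px))
  for (ring in rings) cross <- cross + ring_crossings(px, py, ring)
  inside <- matrix(cross %% 2L == 1L, nrow = length(rows))
  mask[rows, cols] <- inside
  if (!any(mask)) stop("empty ROI: no pixel center falls inside the polygon")
  mask
}

#' Convert an axis-aligned mask boundary to a polygon ring
#'
#' Helper for round-trip checks and for exporting rectangular masks: returns
#' the half-pixel-outset bounding rectangle of a rectangular mask, which
#' rasterizes back to the mask exactly.
#'
#' @param mask logical matrix filled within one axis-aligned rectangle.
#' @return A 4-vertex ring (matrix of x, y).
#' @export
mask_bbox_polygon <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  x0 <- min(idx[, 2L]) - 1; x1 <- max(idx[, 2L]) - 1
  y0 <- min(idx[, 1L]) - 1; y1 <- max(idx[, 1L]) - 1
  cbind(x = c(x0 - 0.5, x1 + 0.5, x1 + 0.5, x0 - 0.5),
        y = c(y0 - 0.5, y0 - 0.5, y1 + 0.5, y1 + 0.5))
}

# -- GeoJSON ------------------------------------------------------------------

geometry_to_rings <- function(geom) {
  type <- geom$type
  coords <- geom$coordinates
  ring_mat <- function(rng) {
    m <- do.call(rbind, lapply(rng, function(v)
      c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
    colnames(m) <- c("x", "y")
    m
  }
  if (identical(type, "Polygon")) {
    lapply(coords, ring_mat)
  } else if (identical(type, "MultiPolygon")) {
    unlist(lapply(coords, function(poly) lapply(poly, ring_mat)),
           recursive = FALSE)
  } else {
    stop("unsupported GeoJSON geometry type: ", type)
  }
}

#' Read polygon ROIs from a GeoJSON file
#'
#' Accepts a Feature, FeatureCollection, or bare geometry whose coordinates
#' are in 0-based pixel units (the pixel-center convention of
#' [rasterize_roi()]). Feature `properties$name` (or
#' `properties$classification$name`) labels each ROI.
#'
#' @param path GeoJSON file path.
#' @return A named list of polygons (each a list of rings).
#' @export
read_geojson_roi <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- switch(g$type,
                  FeatureCollection = g$features,
                  Feature = list(g),
                  list(list(geometry = g, properties = NULL)))
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    nm <- f$properties$name
    if (is.null(nm)) nm <- f$properties$classification$name
    if (is.null(nm)) nm <- paste0("roi_", i)
    out[[nm]] <- geometry_to_rings(f$geometry)
  }
  out
}

rings_to_geojson_feature <- function(rings, name) {
  coords <- lapply(rings, function(r) {
    r <- rbind(r, r[1L, , drop = FALSE])  # close the ring
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L]))
  })
  list(type = "Feature",
       properties = list(name = name),
       geometry = list(type = "Polygon", coordinates = coords))
}

#' Write named polygon ROIs to GeoJSON
#'
#' @param rois named list of polygons (each a ring matrix or list of rings),
#'   pixel coordinates.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geojson_roi <- function(rois, path) {
  feats <- lapply(names(rois), function(nm)
    rings_to_geojson_feature(as_rings(rois[[nm]]), nm))
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# -- delineation sets ---------------------------------------------------------

#' Bundle one observer/session's tumor and bread-loaf ROIs
#'
#' Normalizes polygon or mask input to binary masks on a common grid. The
#' tumor mask is intersected with the bread-loaf mask at load time (both
#' quantification pipelines assume tumor within loaf); any clipped area is
#' reported via a message. Both ROIs must be non-empty after rasterization.
#'
#' @param tumor,loaf polygon (ring matrix or list of rings) or logical mask.
#' @param grid grid spec for rasterization (see [rasterize_roi()]); may be
#'   omitted when both ROIs are masks.
#' @param observer_id,session_id provenance strings.
#' @param method `"automatic"` or `"manual"`.
#' @return A `delineation_set` with elements `tumor` and `loaf` (logical
#'   masks) plus provenance fields.
#' @export
delineation_set <- function(tumor, loaf, grid = NULL,
                            observer_id = "obs1", session_id = "s1",
                            method = c("automatic", "manual")) {
  method <- match.arg(method)
  to_mask <- function(x, what) {
    if (is.logical(x) && is.matrix(x)) return(x)
    if (is.null(grid)) stop("'grid' is required to rasterize the ", what, " polygon")
    rasterize_roi(x, grid)
  }
  loaf_m <- to_mask(loaf, "loaf")
  tumor_m <- to_mask(tumor, "tumor")
  if (!identical(dim(tumor_m), dim(loaf_m)))
    stop("tumor and loaf masks are on different grids")
  clipped <- sum(tumor_m & !loaf_m)
  if (clipped > 0) {
    message(sprintf("delineation %s/%s: clipped %d tumor px outside the bread loaf",
                    observer_id, session_id, clipped))
    tumor_m <- tumor_m & loaf_m
  }
  if (!any(tumor_m)) stop("empty tumor ROI after rasterization")
  if (!any(loaf_m)) stop("empty bread-loaf ROI after rasterization")
  structure(
    list(tumor = tumor_m, loaf = loaf_m, observer_id = observer_id,
         session_id = session_id, method = method),
    class = "delineation_set"
  )
}

#' Load a delineation GeoJSON into a `delineation_set`
#'
#' The file must contain features named `"tumor"` and `"loaf"`.
#'
#' @param path GeoJSON path.
#' @param grid grid spec (see [rasterize_roi()]).
#' @inheritParams delineation_set
#' @return A `delineation_set`.
#' @export
load_delineation <- function(path, grid, observer_id = "obs1",
                             session_id = "s1",
                             method = c("automatic", "manual")) {
  rois <- read_geojson_roi(path)
  if (is.null(rois$tumor) || is.null(rois$loaf))
    stop("delineation file must contain 'tumor' and 'loaf' features: ", path)
  delineation_set(rois$tumor, rois$loaf, grid = grid,
                  observer_id = observer_id, session_id = session_id,
                  method = match.arg(method))
}

# -- results CSV --------------------------------------------------------------

quant_csv_columns <- c(
  "loaf_id", "lesion_id", "observer", "session", "method", "pipeline",
  "signal_mfi", "background_mfi", "ratio", "signal_area_px",
  "background_area_px", "signal_halo_mm", "background_margin_mm")

#' Write quantification records to CSV
#'
#' One row per record, fixed column order, UTF-8 with a header row; the file
#' round-trips through [read_quantification_csv()].
#'
#' @param results a data.frame of quantification records or a list of
#'   `quant_result` objects carrying provenance (see [as_quant_record()]).
#' @param path output CSV path.
#' @return The data.frame written, invisibly.
#' @export
write_quantification_csv <- function(results, path) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, as.data.frame))
  if (is.null(results) || nrow(results) == 0L) {
    warning("no quantification records; writing header-only CSV")
    results <- as.data.frame(
      setNames(rep(list(character(0)), length(quant_csv_columns)),
               quant_csv_columns))
  }
  missing_cols <- setdiff(quant_csv_columns, names(results))
  if (length(missing_cols))
    stop("records lack required columns: ", paste(missing_cols, collapse = ", "))
  results <- results[, quant_csv_columns]
  write.csv(results, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(results)
}

#' Read a quantification CSV written by [write_quantification_csv()]
#'
#' @param path CSV path.
#' @return A data.frame with the standard quantification columns.
#' @export
read_quantification_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
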