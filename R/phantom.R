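# Synthetic bread-loaf phantoms: specimen-like white-light/fluorescence image
# pairs with known geometry and an analytically integrated ground-truth
# SBR/TBR, plus simulated observers. All randomness is derived from explicit
# seeds; the global RNG state is restored on exit.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

derive_seed <- function(seed, ...) {
  s <- as.numeric(seed)
  for (x in c(...)) s <- (s * 7919 + as.numeric(x) * 104729 + 12345) %% 2147483629
  as.integer(s)
}

#' Specify a synthetic specimen phantom
#'
#' The phantom emulates a bread loaf imaged in a closed-box system: an
#' elliptical loaf on a black field, a circular (optionally lobed) tumor,
#' and one of two dye patterns -- `"rim"`, where fluorescence accumulates in
#' a peritumoral rim decaying exponentially with distance from the tumor
#' boundary (ICG-like), or `"filled"`, where the tumor interior fluoresces
#' uniformly (SGM-101-like). A smooth low-frequency heterogeneity field
#' modulates the background, and additive Gaussian noise (clipped at zero)
#' is applied last. All intensities are in arbitrary units within \[0, 1\].
#'
#' Default intensity levels are chosen so that the resulting ratios sit in
#' the range reported for clinical colorectal specimens: the rim defaults
#' give an SBR around 6, the filled defaults a TBR around 3.
#'
#' @param width,height image size in px. Defaults 1300 x 964.
#' @param pixel_size_mm physical pixel size, default 0.085.
#' @param loaf ellipse `list(cx, cy, rx, ry)` in px (0-based center coords).
#' @param tumor `list(cx, cy, r, lobes, lobe_amp, phase)` in px; `lobes > 0`
#'   modulates the radius `r * (1 + lobe_amp * cos(lobes * theta + phase))`
#'   for an irregular, star-shaped tumor.
#' @param pattern `"rim"` or `"filled"`.
#' @param background_level background fluorescence level b (a.u.).
#' @param tumor_level intratumoral level t (a.u., filled pattern).
#' @param rim_amplitude peak rim amplitude a at the tumor boundary (a.u.,
#'   rim pattern).
#' @param rim_decay_mm rim decay length d in mm (rim pattern).
#' @param heterogeneity relative amplitude of the smooth background
#'   heterogeneity field (fraction of `background_level`). Default 0.10.
#' @param noise_sd additive Gaussian noise SD in a.u.
#' @param seed integer seed; fixes the heterogeneity field and the noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width = 1300, height = 964, pixel_size_mm = 0.085,
                         loaf = list(cx = (width - 1) / 2,
                                     cy = (height - 1) / 2,
                                     rx = 0.40 * width, ry = 0.36 * height),
                         tumor = list(cx = (width - 1) / 2,
                                      cy = (height - 1) / 2,
                                      r = 0.125 * height,
                                      lobes = 0, lobe_amp = 0, phase = 0),
                         pattern = c("rim", "filled"),
                         background_level = if (match.arg(pattern) == "rim")
                           0.06 else 0.04,
                         tumor_level = 0.13,
                         rim_amplitude = 0.65,
                         rim_decay_mm = 1.5,
                         heterogeneity = 0.10,
                         noise_sd = 0.005,
                         seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(width >= 16, height >= 16, pixel_size_mm > 0,
            background_level >= 0, tumor_level >= 0, rim_amplitude >= 0,
            rim_decay_mm > 0, heterogeneity >= 0, noise_sd >= 0)
  tumor <- utils::modifyList(
    list(lobes = 0, lobe_amp = 0, phase = 0), tumor)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         pixel_size_mm = pixel_size_mm, loaf = loaf, tumor = tumor,
         pattern = pattern, background_level = background_level,
         tumor_level = tumor_level, rim_amplitude = rim_amplitude,
         rim_decay_mm = rim_decay_mm, heterogeneity = heterogeneity,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

tumor_radius_at <- function(tm, theta) {
  tm$r * (1 + tm$lobe_amp * cos(tm$lobes * theta + tm$phase))
}

#' Tumor boundary polygon of a phantom
#'
#' @param spec a `phantom_spec`.
#' @param n_vertices number of boundary vertices.
#' @return A ring matrix of (x, y) pixel coordinates.
#' @export
phantom_tumor_polygon <- function(spec, n_vertices = 180L) {
  tm <- spec$tumor
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- tumor_radius_at(tm, theta)
  cbind(x = tm$cx + r * cos(theta), y = tm$cy + r * sin(theta))
}

# Vectorized point functions in 0-based pixel coordinates.
phantom_geometry <- function(spec) {
  lf <- spec$loaf; tm <- spec$tumor
  inside_loaf <- function(x, y)
    ((x - lf$cx) / lf$rx)^2 + ((y - lf$cy) / lf$ry)^2 <= 1
  inside_tumor <- function(x, y) {
    dx <- x - tm$cx; dy <- y - tm$cy
    rho <- sqrt(dx^2 + dy^2)
    if (tm$lobes == 0 || tm$lobe_amp == 0) rho <= tm$r
    else rho <= tumor_radius_at(tm, atan2(dy, dx))
  }
  # Euclidean distance (px) from a point to the tumor boundary curve.
  dist_tumor_boundary <- function(x, y) {
    dx <- x - tm$cx; dy <- y - tm$cy
    rho <- sqrt(dx^2 + dy^2)
    if (tm$lobes == 0 || tm$lobe_amp == 0) return(abs(rho - tm$r))
    poly <- phantom_tumor_polygon(spec, 360L)
    n <- nrow(poly)
    ax <- poly[, 1L]; ay <- poly[, 2L]
    bx <- poly[c(2:n, 1L), 1L]; by <- poly[c(2:n, 1L), 2L]
    best <- rep(Inf, length(x))
    for (e in seq_len(n)) {
      ex <- bx[e] - ax[e]; ey <- by[e] - ay[e]
      len2 <- ex^2 + ey^2
      t <- pmin(1, pmax(0, ((x - ax[e]) * ex + (y - ay[e]) * ey) / len2))
      d2 <- (x - (ax[e] + t * ex))^2 + (y - (ay[e] + t * ey))^2
      best <- pmin(best, d2)
    }
    sqrt(best)
  }
  list(inside_loaf = inside_loaf, inside_tumor = inside_tumor,
       dist_tumor_boundary = dist_tumor_boundary)
}

# Smooth heterogeneity field: three fixed-seed sinusoids with wavelengths of
# 8-20 mm, normalized to unit peak amplitude before scaling.
phantom_heterogeneity <- function(spec) {
  pars <- with_seed(derive_seed(spec$seed, 101L), list(
    lambda = runif(3, 8, 20), phase = runif(3, 0, 2 * pi),
    angle = runif(3, 0, pi)))
  amp <- spec$heterogeneity
  px <- spec$pixel_size_mm
  function(x, y) {
    s <- 0
    for (i in 1:3) {
      u <- (x * cos(pars$angle[i]) + y * sin(pars$angle[i])) * px
      s <- s + sin(2 * pi * u / pars$lambda[i] + pars$phase[i])
    }
    amp * s / 3
  }
}

# Deterministic (noiseless) fluorescence profile at arbitrary coordinates.
phantom_profile <- function(spec) {
  geom <- phantom_geometry(spec)
  het <- phantom_heterogeneity(spec)
  b <- spec$background_level
  function(x, y) {
    inl <- geom$inside_loaf(x, y)
    int <- geom$inside_tumor(x, y)
    val <- numeric(length(x))
    base <- b * (1 + het(x, y))
    val[inl] <- base[inl]
    if (spec$pattern == "rim") {
      sel <- inl & !int
      if (any(sel)) {
        d_mm <- geom$dist_tumor_boundary(x[sel], y[sel]) * spec$pixel_size_mm
        val[sel] <- val[sel] +
          spec$rim_amplitude * exp(-d_mm / spec$rim_decay_mm)
      }
    } else {
      val[int & inl] <- spec$tumor_level
    }
    val
  }
}

# Ground-truth signal/background means: the noiseless profile integrated
# over the CONTINUOUS geometric counterparts of the pipeline regions (loaf
# ellipse, tumor disk/blob, mm halos around the true tumor boundary), on a
# subpixel midpoint grid. This is the module's independent route to the
# ground-truth ratio: it never touches the rasterized masks or the
# histogram MFI code path, so boundary pixels cannot bias it.
analytic_region_means <- function(spec, params, subdiv = 3L) {
  geom <- phantom_geometry(spec)
  profile <- phantom_profile(spec)
  lf <- spec$loaf
  # subpixel sample points covering the loaf's bounding box
  xs <- seq(max(0, lf$cx - lf$rx - 1), min(spec$width - 1, lf$cx + lf$rx + 1),
            by = 1 / subdiv)
  ys <- seq(max(0, lf$cy - lf$ry - 1), min(spec$height - 1, lf$cy + lf$ry + 1),
            by = 1 / subdiv)
  x <- rep(xs, times = length(ys))
  y <- rep(ys, each = length(xs))
  inl <- geom$inside_loaf(x, y)
  x <- x[inl]; y <- y[inl]
  int <- geom$inside_tumor(x, y)
  d_mm <- geom$dist_tumor_boundary(x, y) * spec$pixel_size_mm
  val <- profile(x, y)
  if (spec$pattern == "rim") {
    sig <- !int & d_mm <= params$signal_halo_mm
    bg <- !int & d_mm > params$background_margin_mm
  } else {
    sig <- int
    bg <- !int & d_mm <= params$background_margin_mm
  }
  if (!any(sig) || !any(bg))
    stop("degenerate phantom geometry: empty ground-truth region")
  c(signal = mean(val[sig]), background = mean(val[bg]))
}

#' Generate a synthetic specimen phantom
#'
#' Renders the white-light and fluorescence images of the phantom described
#' by `spec` and returns them together with the ground truth: the exact
#' tumor and loaf masks and the analytic ratio (SBR for the rim pattern,
#' TBR for the filled pattern) obtained by numerically integrating the
#' noiseless intensity profile over the continuous geometric counterparts
#' of the pipeline regions on a subpixel grid, independently of the
#' rasterized masks and the histogram MFI code path.
#'
#' Identical specs (including the seed) produce bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param params [halo_params()] used for the ground-truth region
#'   construction.
#' @return A list with `white` and `fluor` (`fluor_image`s) and `truth`, a
#'   `phantom_truth` list carrying `tumor_mask`, `loaf_mask`,
#'   `analytic_ratio`, `signal_mean`, `background_mean` and the generating
#'   `phantom_spec`.
#' @export
generate_phantom <- function(spec, params = halo_params()) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry(spec)
  nr <- spec$height; nc <- spec$width
  x <- matrix(rep(0:(nc - 1), each = nr), nr, nc)   # column coord
  y <- matrix(rep(0:(nr - 1), times = nc), nr, nc)  # row coord
  loaf_mask <- geom$inside_loaf(x, y)
  tumor_mask <- geom$inside_tumor(x, y)
  dim(loaf_mask) <- dim(tumor_mask) <- c(nr, nc)
  if (any(tumor_mask & !loaf_mask))
    stop("tumor is not inside the bread loaf")
  if (!any(tumor_mask)) stop("tumor covers no pixel")

  profile <- phantom_profile(spec)
  fl <- profile(as.vector(x), as.vector(y))
  dim(fl) <- c(nr, nc)
  if (spec$noise_sd > 0) {
    # detector noise applies to tissue; the field stays dark off the loaf
    noise <- with_seed(derive_seed(spec$seed, 202L),
                       rnorm(length(fl), 0, spec$noise_sd))
    dim(noise) <- c(nr, nc)
    fl[loaf_mask] <- fl[loaf_mask] + noise[loaf_mask]
    fl[fl < 0] <- 0
  }
  if (max(fl) > 1) {
    warning("intensities clipped at 1 a.u. for storage")
    fl[fl > 1] <- 1
  }

  white <- matrix(0, nr, nc)
  white[loaf_mask] <- 0.55
  white[tumor_mask] <- 0.40

  means <- analytic_region_means(spec, params)
  s_mean <- means[["signal"]]
  b_mean <- means[["background"]]

  truth <- structure(
    list(tumor_mask = tumor_mask, loaf_mask = loaf_mask,
         analytic_ratio = s_mean / b_mean,
         signal_mean = s_mean, background_mean = b_mean,
         ratio_kind = if (spec$pattern == "rim") "SBR" else "TBR",
         halo_params = params, spec = spec),
    class = "phantom_truth")

  list(white = fluor_image(white, spec$pixel_size_mm),
       fluor = fluor_image(fl, spec$pixel_size_mm),
       truth = truth)
}

# -- simulated observers ------------------------------------------------------

# Longest iso-0.5 contour of a mask, as a closed (x, y) polygon in 0-based
# pixel coordinates. contourLines' x axis runs along matrix rows (our y).
mask_contour <- function(mask) {
  z <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  cl <- contourLines(x = 0:(nrow(z) - 1), y = 0:(ncol(z) - 1), z = z,
                     levels = 0.5)
  if (!length(cl)) stop("mask has no contour")
  len <- vapply(cl, function(cc) length(cc$x), numeric(1))
  cc <- cl[[which.max(len)]]
  cbind(x = cc$y, y = cc$x)
}

resample_closed <- function(poly, n) {
  p <- rbind(poly, poly[1L, , drop = FALSE])
  seglen <- sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2)
  s <- c(0, cumsum(seglen))
  keep <- c(TRUE, diff(s) > 0)
  p <- p[keep, , drop = FALSE]; s <- s[keep]
  target <- seq(0, s[length(s)], length.out = n + 1L)[seq_len(n)]
  cbind(x = stats::approx(s, p[, 1L], xout = target)$y,
        y = stats::approx(s, p[, 2L], xout = target)$y)
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  a <- poly; b <- poly[c(2:n, 1L), , drop = FALSE]
  seg_int <- function(i, j) {
    p1 <- a[i, ]; p2 <- b[i, ]; p3 <- a[j, ]; p4 <- b[j, ]
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) if (seg_int(i, j)) return(TRUE)
  }
  FALSE
}

#' Simulate an observer's delineation of a true region
#'
#' Extracts the boundary contour of the truth mask, resamples it to
#' `n_vertices` equally spaced vertices, and perturbs each vertex radially
#' (about the polygon centroid) by `bias_px` plus Gaussian jitter of SD
#' `jitter_sd_px`. A positive bias emulates systematic over-delineation.
#' With zero bias and jitter, the rasterized polygon reproduces the truth
#' mask to DSC >= 0.99. Draws that produce a self-intersecting polygon are
#' retried with fresh seed-derived jitter up to `max_attempts` times.
#'
#' @param truth_mask simply connected logical mask.
#' @param jitter_sd_px radial jitter SD in px (>= 0).
#' @param bias_px systematic radial offset in px.
#' @param seed integer seed.
#' @param n_vertices polygon resolution. Default 64.
#' @param max_attempts retry budget for self-intersecting draws.
#' @return A ring matrix of (x, y) pixel coordinates.
#' @export
simulate_observer <- function(truth_mask, jitter_sd_px = 0, bias_px = 0,
                              seed = 1L, n_vertices = 64L,
                              max_attempts = 25L) {
  stopifnot(jitter_sd_px >= 0)
  base <- resample_closed(mask_contour(truth_mask), n_vertices)
  cx <- mean(base[, 1L]); cy <- mean(base[, 2L])
  rad <- sqrt((base[, 1L] - cx)^2 + (base[, 2L] - cy)^2)
  ux <- (base[, 1L] - cx) / rad; uy <- (base[, 2L] - cy) / rad
  for (attempt in seq_len(max_attempts)) {
    jit <- if (jitter_sd_px > 0)
      with_seed(derive_seed(seed, 303L, attempt),
                rnorm(n_vertices, 0, jitter_sd_px))
    else rep(0, n_vertices)
    r2 <- pmax(0.05 * rad, rad + bias_px + jit)
    poly <- cbind(x = cx + ux * r2, y = cy + uy * r2)
    if (!polygon_self_intersects(poly)) return(poly)
  }
  stop("could not draw a simple polygon in ", max_attempts, " attempts")
}

# -- evaluation datasets ------------------------------------------------------

default_observers <- function() {
  list(obs1 = list(bias_px = 0,   jitter_sd_px = 2),
       obs2 = list(bias_px = 1.5, jitter_sd_px = 2),
       obs3 = list(bias_px = -1.5, jitter_sd_px = 2))
}

#' Generate an on-disk observer-evaluation dataset
#'
#' Emulates the evaluation design of the clinical study: `n_loaves` bread
#' loaves, each delineated by three observers in two sessions. Per loaf, the
#' tumor size/position and dye levels are drawn around the base spec so
#' that the ratios vary between loaves, and each observer/session
#' delineation of both the tumor and the loaf is produced by
#' [simulate_observer()] with per-observer bias and jitter. Everything is
#' reproducible from `seed`: the same seed yields byte-identical manifests.
#'
#' Layout: `<dir>/manifest.json`, and per loaf `loaf_NN/white.tif`,
#' `loaf_NN/fluor.tif`, `loaf_NN/truth.json`, `loaf_NN/truth.geojson`
#' (exact contours) and `loaf_NN/delineations/<observer>_<session>.geojson`.
#'
#' @param dir output directory (created if needed).
#' @param n_loaves number of loaves (>= 2). Default 10.
#' @param pattern `"rim"` or `"filled"`.
#' @param observers named list of per-observer settings
#'   (`bias_px`, `jitter_sd_px`); exactly 3 for the standard design.
#' @param n_sessions delineation sessions per observer. Default 2.
#' @param seed integer master seed.
#' @param base_spec a [phantom_spec()] giving the base geometry and levels;
#'   its own seed is ignored (per-loaf seeds are derived from `seed`).
#' @return Invisibly, the manifest list.
#' @export
generate_evaluation_dataset <- function(dir, n_loaves = 10,
                                        pattern = c("rim", "filled"),
                                        observers = default_observers(),
                                        n_sessions = 2L, seed = 1L,
                                        base_spec = phantom_spec(
                                          pattern = pattern)) {
  pattern <- match.arg(pattern)
  if (n_loaves < 2) stop("need at least 2 loaves")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loaf_entries <- list()
  for (i in seq_len(n_loaves)) {
    loaf_seed <- derive_seed(seed, i)
    draws <- with_seed(loaf_seed, list(
      r_scale = runif(1, 0.75, 1.30),
      cx_off = runif(1, -0.05, 0.05), cy_off = runif(1, -0.05, 0.05),
      level_scale = runif(1, 0.70, 1.30),
      bg_scale = runif(1, 0.85, 1.15)))
    spec <- base_spec
    spec$seed <- loaf_seed
    spec$tumor$r <- base_spec$tumor$r * draws$r_scale
    spec$tumor$cx <- base_spec$tumor$cx + draws$cx_off * base_spec$width
    spec$tumor$cy <- base_spec$tumor$cy + draws$cy_off * base_spec$height
    spec$background_level <- base_spec$background_level * draws$bg_scale
    if (pattern == "rim")
      spec$rim_amplitude <- base_spec$rim_amplitude * draws$level_scale
    else
      spec$tumor_level <- base_spec$tumor_level * draws$level_scale

    ph <- generate_phantom(spec)
    loaf_id <- sprintf("loaf_%02d", i)
    ldir <- file.path(dir, loaf_id)
    dir.create(file.path(ldir, "delineations"), recursive = TRUE,
               showWarnings = FALSE)
    write_image(ph$white, file.path(ldir, "white.tif"))
    write_image(ph$fluor, file.path(ldir, "fluor.tif"))
    write_geojson_roi(
      list(tumor = mask_contour(ph$truth$tumor_mask),
           loaf = mask_contour(ph$truth$loaf_mask)),
      file.path(ldir, "truth.geojson"))
    jsonlite::write_json(
      list(loaf_id = loaf_id, pattern = pattern,
           analytic_ratio = ph$truth$analytic_ratio,
           ratio_kind = ph$truth$ratio_kind,
           signal_mean = ph$truth$signal_mean,
           background_mean = ph$truth$background_mean,
           tumor_area_px = sum(ph$truth$tumor_mask),
           loaf_area_px = sum(ph$truth$loaf_mask),
           spec = unclass(spec)),
      file.path(ldir, "truth.json"), auto_unbox = TRUE, digits = NA)

    for (oi in seq_along(observers)) {
      oname <- names(observers)[oi]
      oset <- observers[[oi]]
      for (s in seq_len(n_sessions)) {
        sname <- sprintf("s%d", s)
        obs_seed <- derive_seed(loaf_seed, oi, s)
        tumor_poly <- simulate_observer(
          ph$truth$tumor_mask, oset$jitter_sd_px, oset$bias_px,
          seed = obs_seed)
        loaf_poly <- simulate_observer(
          ph$truth$loaf_mask, oset$jitter_sd_px, oset$bias_px,
          seed = derive_seed(obs_seed, 99L))
        write_geojson_roi(
          list(tumor = tumor_poly, loaf = loaf_poly),
          file.path(ldir, "delineations",
                    sprintf("%s_%s.geojson", oname, sname)))
      }
    }
    loaf_entries[[loaf_id]] <- list(
      seed = loaf_seed, tumor_r_px = spec$tumor$r,
      analytic_ratio = ph$truth$analytic_ratio)
  }
  manifest <- list(
    seed = seed, n_loaves = n_loaves, pattern = pattern,
    n_sessions = n_sessions, observers = observers,
    pixel_size_mm = base_spec$pixel_size_mm,
    width = base_spec$width, height = base_spec$height,
    base_spec = unclass(base_spec), loaves = loaf_entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
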