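#' Halo parameters for region construction
#'
#' The non-targeted pipeline takes its signal from the first
#' `signal_halo_mm` of tissue around the tumor (default 3 mm, the zone
#' informative about the delineation) and its background from loaf tissue
#' beyond `background_margin_mm` of the tumor (default 5 mm, far enough that
#' heterogeneous peritumoral uptake does not contaminate the estimate).
#' The targeted pipeline uses only `background_margin_mm`: its background is
#' the 0-5 mm halo itself, the clinically relevant margin zone. The margin
#' may be widened (e.g. 10 or 15 mm) for other tissue types or dyes.
#'
#' @param signal_halo_mm positive signal halo width in mm (non-targeted
#'   pipeline only). Default 3.
#' @param background_margin_mm positive background dilation distance in mm.
#'   Default 5. Must be >= `signal_halo_mm`, otherwise the non-targeted
#'   signal and background regions would overlap.
#' @return A `halo_params` list.
#' @export
halo_params <- function(signal_halo_mm = 3, background_margin_mm = 5) {
  if (signal_halo_mm <= 0 || background_margin_mm <= 0)
    stop("halo distances must be strictly positive")
  if (signal_halo_mm > background_margin_mm)
    stop("signal_halo_mm (", signal_halo_mm,
         ") must not exceed background_margin_mm (", background_margin_mm,
         "): the signal and background regions would overlap")
  structure(list(signal_halo_mm = signal_halo_mm,
                 background_margin_mm = background_margin_mm),
            class = "halo_params")
}

#' Dilate a binary mask by a physical distance
#'
#' Thresholds the exact Euclidean distance transform of the mask's
#' complement at `distance_mm / pixel_size_mm` pixels: a pixel belongs to
#' the output iff its center lies within that Euclidean distance of some
#' mask pixel center. The radius is kept real-valued (3 mm at 0.085 mm/px
#' is 35.294... px) and compared with `<=`; no structuring-element
#' approximation or integer rounding is applied, so the result is exact up
#' to pixel-center discretization and independent of the implementation.
#'
#' @param mask non-empty logical matrix.
#' @param distance_mm dilation distance in mm (>= 0; 0 returns the input).
#' @param pixel_size_mm physical pixel size in mm.
#' @return A logical matrix containing the input mask.
#' @export
dilate_mm <- function(mask, distance_mm, pixel_size_mm = 0.085) {
  if (!is.logical(mask) || !is.matrix(mask)) stop("'mask' must be a logical matrix")
  if (!any(mask)) stop("cannot dilate empty mask")
  if (distance_mm < 0) stop("'distance_mm' must be >= 0")
  if (pixel_size_mm <= 0) stop("'pixel_size_mm' must be > 0")
  if (distance_mm == 0 || all(mask)) return(mask)
  r_px <- distance_mm / pixel_size_mm
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(!mask)))
  # distmap returns sqrt of an integer squared distance; recover the integer
  # to make the threshold comparison exact.
  sq <- round(dm * dm)
  mask | (sq <= r_px * r_px)
}

check_tumor_in_loaf <- function(tumor, loaf) {
  if (!identical(dim(tumor), dim(loaf)))
    stop("tumor and loaf masks are on different grids")
  if (!any(tumor)) stop("empty tumor mask")
  if (any(tumor & !loaf))
    stop("tumor mask extends outside the bread loaf; ",
         "intersect it with the loaf first (see delineation_set)")
}

#' Signal region for the non-targeted (SBR) pipeline
#'
#' The halo of the tumor dilated by `signal_halo_mm`, with the tumor itself
#' removed, restricted to the bread loaf: `(dilate(tumor) \ tumor) & loaf`.
#' Restricting to the loaf prevents zero-intensity pixels outside the
#' specimen from deflating the signal estimate.
#'
#' @param tumor,loaf logical masks on a common grid, tumor within loaf.
#' @param params a [halo_params()] object.
#' @param pixel_size_mm physical pixel size in mm.
#' @return A logical mask.
#' @export
signal_region_nontargeted <- function(tumor, loaf, params = halo_params(),
                                      pixel_size_mm = 0.085) {
  check_tumor_in_loaf(tumor, loaf)
  halo <- dilate_mm(tumor, params$signal_halo_mm, pixel_size_mm) & !tumor & loaf
  if (!any(halo))
    stop("no signal region: the tumor fills the bread loaf within ",
         params$signal_halo_mm, " mm")
  halo
}

#' Background region for the non-targeted (SBR) pipeline
#'
#' Loaf tissue beyond `background_margin_mm` of the tumor:
#' `loaf \ dilate(tumor, background_margin_mm)`.
#'
#' @inheritParams signal_region_nontargeted
#' @return A logical mask.
#' @export
background_region_nontargeted <- function(tumor, loaf, params = halo_params(),
                                          pixel_size_mm = 0.085) {
  check_tumor_in_loaf(tumor, loaf)
  bg <- loaf & !dilate_mm(tumor, params$background_margin_mm, pixel_size_mm)
  if (!any(bg))
    stop("no background region: the whole bread loaf lies within ",
         params$background_margin_mm,
         " mm of the tumor (small resection margin); consider a smaller ",
         "background_margin_mm")
  bg
}

#' Background region for the tumor-targeted (TBR) pipeline
#'
#' The 0 to `background_margin_mm` halo around the tumor, restricted to the
#' loaf: `(dilate(tumor, background_margin_mm) \ tumor) & loaf`. This is the
#' margin zone against which intratumoral fluorescence is compared.
#'
#' @inheritParams signal_region_nontargeted
#' @return A logical mask.
#' @export
background_region_targeted <- function(tumor, loaf, params = halo_params(),
                                       pixel_size_mm = 0.085) {
  check_tumor_in_loaf(tumor, loaf)
  bg <- dilate_mm(tumor, params$background_margin_mm, pixel_size_mm) &
    !tumor & loaf
  if (!any(bg))
    stop("no background region: the tumor fills the bread loaf within ",
         params$background_margin_mm, " mm")
  bg
}
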