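#' Dice similarity coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 means perfect overlap, 0 disjoint.
#'
#' @param a,b logical masks on the same grid, not both empty.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks are on different grids")
  denom <- sum(a) + sum(b)
  if (denom == 0L) stop("undefined DSC: both masks are empty")
  2 * sum(a & b) / denom
}

check_schedule <- function(masks, n_observers = 3L, n_sessions = 2L) {
  obs <- names(masks)
  missing <- character(0)
  if (length(obs) != n_observers)
    stop("expected exactly ", n_observers, " observers, got ", length(obs),
         " (", paste(obs, collapse = ", "), ")")
  for (o in obs) {
    ses <- names(masks[[o]])
    if (length(ses) != n_sessions)
      missing <- c(missing, paste0(o, ": ", length(ses), " session(s)"))
  }
  if (length(missing))
    stop("incomplete observer/session design: ", paste(missing, collapse = "; "))
  invisible(masks)
}

#' Interobserver DSC schedule for one bread loaf and ROI kind
#'
#' For each of the three observer pairs (I vs II, II vs III, I vs III) the
#' DSC is computed for all four session combinations (I-I, I-II, II-I,
#' II-II), giving 12 records per loaf per ROI kind.
#'
#' @param masks nested list `masks[[observer]][[session]]` of logical masks;
#'   exactly 3 observers with 2 sessions each.
#' @param loaf_id,roi_kind identifiers copied into the records
#'   (`roi_kind` is typically `"tumor"` or `"background"`).
#' @return A data.frame with columns `loaf_id`, `roi_kind`, `comparison`,
#'   `observer_a`, `observer_b`, `session_a`, `session_b`, `dsc` (12 rows).
#' @export
interobserver_dsc_schedule <- function(masks, loaf_id = "loaf1",
                                       roi_kind = "tumor") {
  check_schedule(masks)
  obs <- names(masks)
  pairs <- utils::combn(obs, 2L)
  out <- list()
  for (p in seq_len(ncol(pairs))) {
    oa <- pairs[1L, p]; ob <- pairs[2L, p]
    sa_names <- names(masks[[oa]]); sb_names <- names(masks[[ob]])
    for (sa in sa_names) for (sb in sb_names) {
      out[[length(out) + 1L]] <- data.frame(
        loaf_id = loaf_id, roi_kind = roi_kind,
        comparison = "interobserver",
        observer_a = oa, observer_b = ob, session_a = sa, session_b = sb,
        dsc = dice(masks[[oa]][[sa]], masks[[ob]][[sb]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Intraobserver DSC schedule for one bread loaf and ROI kind
#'
#' One DSC per observer, comparing that observer's first and second
#' delineation sessions.
#'
#' @inheritParams interobserver_dsc_schedule
#' @return A data.frame with one row per observer (3 rows).
#' @export
intraobserver_dsc_schedule <- function(masks, loaf_id = "loaf1",
                                       roi_kind = "tumor") {
  check_schedule(masks)
  out <- lapply(names(masks), function(o) {
    ses <- names(masks[[o]])
    data.frame(
      loaf_id = loaf_id, roi_kind = roi_kind, comparison = "intraobserver",
      observer_a = o, observer_b = o,
      session_a = ses[1L], session_b = ses[2L],
      dsc = dice(masks[[o]][[ses[1L]]], masks[[o]][[ses[2L]]]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# -- ICC ----------------------------------------------------------------------

#' Qualitative rating of an ICC value
#'
#' Bands: poor (< 0.5), moderate (0.5 to 0.75), good (0.75 to 0.9),
#' excellent (> 0.9). The printed bands are ambiguous at the interior
#' boundaries; this implementation assigns 0.75 to moderate and 0.9 to
#' good, consistent with the strict inequalities at the outer boundaries.
#'
#' @param value numeric ICC value(s), each <= 1.
#' @return Character vector: `"poor"`, `"moderate"`, `"good"` or
#'   `"excellent"`.
#' @export
rate_icc <- function(value) {
  if (any(value > 1 + 1e-12)) stop("ICC values cannot exceed 1")
  ifelse(value < 0.5, "poor",
         ifelse(value <= 0.75, "moderate",
                ifelse(value <= 0.9, "good", "excellent")))
}

#' Two-way absolute-agreement mean-rating ICC with confidence interval
#'
#' Computes the intraclass correlation for a two-way (subjects x raters)
#' layout under absolute agreement, reliability of the mean of the k
#' raters -- McGraw & Wong's ICC(A,k), the estimand of a "two-way
#' mixed-effects, absolute-agreement, mean-rating" model. The point
#' estimate is
#' \deqn{\widehat{ICC}(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the two-way ANOVA mean
#' squares for subjects (rows), raters (columns) and residual. The
#' `1 - alpha` confidence interval is the F-based interval for the
#' single-rater form with Satterthwaite-approximated denominator degrees of
#' freedom, transformed to the mean-rating scale by the Spearman-Brown
#' step-up.
#'
#' Negative estimates (possible when rater disagreement exceeds subject
#' variance) are returned as computed and flagged, never truncated to zero.
#'
#' @param values numeric n x k matrix, subjects in rows, raters in columns;
#'   complete (no missing cells), n >= 2, k >= 2.
#' @param alpha two-sided significance level for the CI. Default 0.05.
#' @return An `icc_result` with `estimate`, `ci_low`, `ci_high`, `alpha`,
#'   `n`, `k`, `rating_point`, `rating_range` (ratings of the CI ends) and
#'   `flag_negative`.
#' @export
icc_absolute_agreement <- function(values, alpha = 0.05) {
  x <- as.matrix(values)
  if (anyNA(x)) stop("incomplete rater matrix: missing cells are not supported")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  gm <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  MSR <- k * sum((rm_ - gm)^2) / (n - 1)
  MSC <- n * sum((cm - gm)^2) / (k - 1)
  MSE <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2) /
    ((n - 1) * (k - 1))
  scale <- mean(x^2) + 1  # guards the degeneracy test against unit changes
  if ((MSR + MSC + MSE) / scale < 1e-14)
    stop("degenerate matrix: no variance in subjects, raters or residuals")
  est <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
  r1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  if (1 - r1 < 1e-12) {
    # perfect agreement: all raters identical, subjects differ
    ci <- c(1, 1)
  } else {
    a <- k * r1 / (n * (1 - r1))
    b <- 1 + k * r1 * (n - 1) / (n * (1 - r1))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, df1 = n - 1, df2 = v)
    FU <- qf(1 - alpha / 2, df1 = v, df2 = n - 1)
    L1 <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    U1 <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(L1 * k / (1 + (k - 1) * L1), U1 * k / (1 + (k - 1) * U1))
  }
  ci[1L] <- min(ci[1L], est)
  ci[2L] <- max(ci[2L], est)
  structure(
    list(estimate = est, ci_low = ci[1L], ci_high = ci[2L], alpha = alpha,
         n = n, k = k,
         rating_point = rate_icc(min(est, 1)),
         rating_range = c(rate_icc(min(ci[1L], 1)), rate_icc(min(ci[2L], 1))),
         flag_negative = est < 0,
         mean_squares = c(MSR = MSR, MSC = MSC, MSE = MSE)),
    class = "icc_result"
  )
}

#' Assemble an ICC result from an externally reported estimate and CI
#'
#' Useful for applying the rating bands and CI-overlap rule to published
#' values.
#'
#' @param estimate,ci_low,ci_high numeric.
#' @param alpha significance level the CI was computed at.
#' @return An `icc_result`.
#' @export
icc_result <- function(estimate, ci_low, ci_high, alpha = 0.05) {
  stopifnot(ci_low <= estimate, estimate <= ci_high)
  structure(
    list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
         alpha = alpha, n = NA_integer_, k = NA_integer_,
         rating_point = rate_icc(estimate),
         rating_range = c(rate_icc(ci_low), rate_icc(ci_high)),
         flag_negative = estimate < 0, mean_squares = NULL),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  rng <- if (x$rating_range[1L] == x$rating_range[2L]) x$rating_range[1L]
         else paste(x$rating_range[1L], "to", x$rating_range[2L])
  cat(sprintf("<icc_result> ICC(A,k) = %.3f [%.3f, %.3f] (%d%% CI), rated %s (%s)%s\n",
              x$estimate, x$ci_low, x$ci_high,
              round(100 * (1 - x$alpha)), x$rating_point, rng,
              if (isTRUE(x$flag_negative)) " [negative estimate]" else ""))
  invisible(x)
}

#' Compare two ICC results by confidence-interval overlap
#'
#' The difference is called statistically significant iff the two CIs do
#' not overlap.
#'
#' @param a,b `icc_result` objects with finite CIs.
#' @return `"significant"` or `"not_significant"`.
#' @export
compare_by_ci_overlap <- function(a, b) {
  stopifnot(inherits(a, "icc_result"), inherits(b, "icc_result"),
            is.finite(a$ci_low), is.finite(a$ci_high),
            is.finite(b$ci_low), is.finite(b$ci_high))
  if (a$ci_high < b$ci_low || b$ci_high < a$ci_low) "significant"
  else "not_significant"
}

# -- rater matrices from quantification records -------------------------------

pivot_complete <- function(df, subject_cols, rater_col, value_col = "ratio") {
  subj <- interaction(df[subject_cols], drop = TRUE, lex.order = TRUE)
  raters <- sort(unique(df[[rater_col]]))
  subjects <- levels(subj)
  m <- matrix(NA_real_, length(subjects), length(raters),
              dimnames = list(subjects, raters))
  m[cbind(match(subj, subjects), match(df[[rater_col]], raters))] <-
    df[[value_col]]
  if (anyNA(m)) {
    gaps <- which(is.na(m), arr.ind = TRUE)
    stop("incomplete design; missing cells: ",
         paste(sprintf("%s x %s", rownames(m)[gaps[, 1L]],
                       colnames(m)[gaps[, 2L]]), collapse = ", "))
  }
  m
}

#' Rater matrix for interobserver reliability of SBR/TBR
#'
#' Ratings from both delineation sessions enter one analysis: the subjects
#' are the loaf-by-session combinations (n = 2 x number of loaves) and the
#' raters are the observers (k = 3 in the standard design).
#'
#' @param records data.frame with columns `loaf_id`, `observer`, `session`
#'   and the value column.
#' @param value_col measurement column. Default `"ratio"`.
#' @return A complete numeric subjects x observers matrix.
#' @export
interobserver_rater_matrix <- function(records, value_col = "ratio") {
  pivot_complete(records, c("loaf_id", "session"), "observer", value_col)
}

#' Rater matrix for intraobserver reliability of SBR/TBR
#'
#' All measurements enter one analysis: the subjects are the
#' loaf-by-observer combinations and the raters are the two delineation
#' sessions (k = 2).
#'
#' @inheritParams interobserver_rater_matrix
#' @return A complete numeric subjects x sessions matrix.
#' @export
intraobserver_rater_matrix <- function(records, value_col = "ratio") {
  pivot_complete(records, c("loaf_id", "observer"), "session", value_col)
}
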