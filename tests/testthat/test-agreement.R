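test_that("dice is symmetric, bounded, 1 on identity and 0 on disjoint", {
  set.seed(31)
  for (i in 1:10) {
    a <- random_mask(40, 40, 0.1); b <- random_mask(40, 40, 0.1)
    expect_identical(dice(a, b), dice(b, a))
    expect_gte(dice(a, b), 0); expect_lte(dice(a, b), 1)
    expect_identical(dice(a, a), 1)
  }
  sq1 <- rect_mask(40, 40, 1, 10, 1, 10)
  sq2 <- rect_mask(40, 40, 1, 10, 6, 15)   # 100 px each, 50 px overlap
  expect_equal(dice(sq1, sq2), 0.5)
  expect_equal(dice(sq1, rect_mask(40, 40, 30, 39, 30, 39)), 0)
  expect_error(dice(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), "undefined")
})

make_mask_sets <- function(jitter = 0, seed = 1) {
  base <- disk_mask(80, 80, 39.5, 39.5, 20)
  set.seed(seed)
  out <- list()
  for (o in c("obs1", "obs2", "obs3")) for (s in c("s1", "s2")) {
    m <- base
    if (jitter > 0) {
      shift <- sample(-jitter:jitter, 2, replace = TRUE)
      m <- disk_mask(80, 80, 39.5 + shift[1], 39.5 + shift[2], 20)
    }
    out[[o]][[s]] <- m
  }
  out
}

test_that("interobserver schedule emits 3 pairs x 4 session combinations", {
  masks <- make_mask_sets(jitter = 2, seed = 2)
  rec <- interobserver_dsc_schedule(masks, "loaf_01", "tumor")
  expect_equal(nrow(rec), 12)
  expect_setequal(unique(paste(rec$observer_a, rec$observer_b)),
                  c("obs1 obs2", "obs2 obs3", "obs1 obs3"))
  expect_equal(sum(rec$observer_a == "obs1" & rec$observer_b == "obs2"), 4)
  expect_true(all(rec$comparison == "interobserver"))
  # identical delineations give DSC 1 everywhere
  rec1 <- interobserver_dsc_schedule(make_mask_sets(0), "loaf_01", "tumor")
  expect_true(all(rec1$dsc == 1))
})

test_that("intraobserver schedule emits one record per observer", {
  masks <- make_mask_sets(jitter = 2, seed = 3)
  rec <- intraobserver_dsc_schedule(masks, "loaf_01", "background")
  expect_equal(nrow(rec), 3)
  expect_setequal(rec$observer_a, c("obs1", "obs2", "obs3"))
  expect_true(all(rec$session_a == "s1" & rec$session_b == "s2"))
  expect_true(all(intraobserver_dsc_schedule(make_mask_sets(0))$dsc == 1))
})

test_that("incomplete observer/session designs are rejected with specifics", {
  masks <- make_mask_sets()
  expect_error(interobserver_dsc_schedule(masks[1:2]), "3 observers")
  masks$obs2$s2 <- NULL
  expect_error(interobserver_dsc_schedule(masks), "obs2")
  expect_error(intraobserver_dsc_schedule(masks), "obs2")
})

test_that("ICC(A,k) reproduces the published worked-example matrix", {
  # 6 subjects x 4 raters reliability data (Shrout & Fleiss);
  # reference values computed independently from the two-way ANOVA
  # mean squares and the F-based interval with Satterthwaite df.
  x <- matrix(c(9, 6, 8, 7, 10, 6,
                2, 1, 4, 1, 5, 2,
                5, 3, 6, 2, 6, 4,
                8, 2, 8, 6, 9, 7), 6, 4)
  r <- icc_absolute_agreement(x)
  expect_equal(r$estimate, 0.6200505475989891, tolerance = 1e-12)
  expect_equal(r$ci_low, 0.07113681530250336, tolerance = 1e-9)
  expect_equal(r$ci_high, 0.9272320401677219, tolerance = 1e-9)
  expect_equal(r$rating_point, "moderate")
  expect_equal(r$rating_range, c("poor", "excellent"))
})

test_that("ICC(A,k) equals the aov-based oracle on random matrices", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(3:12, 1); k <- sample(2:4, 1)
    x <- simulate_rater_matrix(n, k, runif(1, 0.5, 2), runif(1, 0, 0.5),
                               runif(1, 0.05, 1))
    r <- icc_absolute_agreement(x)
    expect_equal(r$estimate, icc_aov_oracle(x), tolerance = 1e-10)
    expect_lte(r$ci_low, r$estimate)
    expect_gte(r$ci_high, r$estimate)
  }
})

test_that("perfect agreement gives ICC 1 and degenerate input errors", {
  x <- matrix(rep(c(1, 5, 9, 13), 3), 4, 3)
  r <- icc_absolute_agreement(x)
  expect_equal(r$estimate, 1)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  expect_error(icc_absolute_agreement(matrix(2, 4, 3)), "degenerate")
  expect_error(icc_absolute_agreement(matrix(1:4, 1, 4)), "at least 2")
  expect_error(icc_absolute_agreement(matrix(c(1, NA, 2, 3), 2, 2)),
               "incomplete")
})

test_that("pure rater bias strictly lowers absolute-agreement ICC", {
  set.seed(43)
  for (i in 1:10) {
    x <- simulate_rater_matrix(10, 3, 1, 0, 0.2)
    base <- icc_absolute_agreement(x)$estimate
    xb <- x; xb[, 2] <- xb[, 2] + 1.5
    expect_lt(icc_absolute_agreement(xb)$estimate, base)
  }
})

test_that("negative estimates are returned as computed and flagged", {
  set.seed(44)
  # rater disagreement dwarfs subject variance
  x <- simulate_rater_matrix(6, 3, 0.01, 3, 0.5)
  r <- icc_absolute_agreement(x)
  expect_lt(r$estimate, 0)
  expect_true(r$flag_negative)
  expect_equal(r$estimate, icc_aov_oracle(x), tolerance = 1e-10)
})

test_that("rating bands follow the poor/moderate/good/excellent cutpoints", {
  expect_equal(rate_icc(c(0.49, 0.5, 0.75, 0.76, 0.9, 0.91, 0.98, -0.2)),
               c("poor", "moderate", "moderate", "good", "good",
                 "excellent", "excellent", "poor"))
  expect_error(rate_icc(1.2), "exceed")
  r <- icc_result(0.66, 0.24, 0.86)
  expect_equal(r$rating_point, "moderate")
  expect_equal(r$rating_range, c("poor", "good"))
  r2 <- icc_result(0.80, 0.57, 0.91)
  expect_equal(r2$rating_range, c("moderate", "excellent"))
})

test_that("CI-overlap comparison flags only disjoint intervals", {
  a <- icc_result(0.98, 0.95, 0.99)
  b <- icc_result(0.66, 0.24, 0.86)
  expect_equal(compare_by_ci_overlap(a, b), "significant")
  expect_equal(compare_by_ci_overlap(b, a), "significant")
  c1 <- icc_result(0.93, 0.60, 0.98)
  c2 <- icc_result(0.96, 0.92, 0.98)
  expect_equal(compare_by_ci_overlap(c1, c2), "not_significant")
  expect_equal(compare_by_ci_overlap(a, a), "not_significant")
})

test_that("rater-matrix builders stack the design as declared", {
  recs <- expand.grid(loaf_id = sprintf("loaf_%02d", 1:4),
                      observer = c("obs1", "obs2", "obs3"),
                      session = c("s1", "s2"), stringsAsFactors = FALSE)
  recs$ratio <- seq_len(nrow(recs)) / 10
  inter <- interobserver_rater_matrix(recs)
  expect_equal(dim(inter), c(8, 3))   # loaf x session subjects, observer raters
  intra <- intraobserver_rater_matrix(recs)
  expect_equal(dim(intra), c(12, 2))  # loaf x observer subjects, session raters
  # a named cell lands where it should
  v <- recs$ratio[recs$loaf_id == "loaf_02" & recs$observer == "obs3" &
                    recs$session == "s2"]
  expect_equal(inter["loaf_02.s2", "obs3"], v)
  expect_equal(intra["loaf_02.obs3", "s2"], v)
  expect_error(interobserver_rater_matrix(recs[-1, ]), "missing cells")
})
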