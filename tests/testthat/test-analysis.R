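# Tissue statistics, lesion classification, pipeline comparison, reporting.

test_that("classifier cutoffs derive from the WM reference and margin", {
  cfg <- classifier_config()
  expect_equal(cfg$wm_reference + cfg$margin, 0.3)
  expect_equal(cfg$wm_reference - cfg$margin, -1.7)
  expect_equal(classify_lesion(c(1.5, -0.4, -3.6)),
               c("hyperintense", "isointense", "hypointense"))
  # strict inequalities: both boundary values are isointense
  expect_equal(classify_lesion(0.3), "isointense")
  expect_equal(classify_lesion(-1.7), "isointense")
  expect_equal(classify_lesion(0.3 + 1e-9), "hyperintense")
  expect_equal(classify_lesion(-1.7 - 1e-9), "hypointense")
  expect_error(classifier_config(margin = 0), "margin")
  expect_error(classify_lesion(NaN), "finite")
})

test_that("classification is monotone in mean susceptibility", {
  x <- sort(stats::runif(200, -6, 4))
  cats <- classify_lesion(x)
  ord <- match(cats, c("hypointense", "isointense", "hyperintense"))
  expect_true(all(diff(ord) >= 0))
})

test_that("region statistics report mean, SD and voxel counts per tissue", {
  d <- c(8L, 8L, 2L)
  v <- array(0, d)
  gm <- array(FALSE, d); gm[1:3, 1:3, ] <- TRUE
  wm <- array(FALSE, d); wm[5:8, 5:8, ] <- TRUE
  v[gm] <- 3.1
  st <- region_stats(v, list(GM = gm, WM = wm))
  expect_equal(st$mean[st$tissue == "GM"], 3.1)
  expect_equal(st$sd[st$tissue == "GM"], 0)
  expect_equal(st$n_voxels, c(sum(gm), sum(wm)))
  # moving one voxel between masks changes both counts by one
  gm2 <- gm; wm2 <- wm
  gm2[5, 5, 1] <- TRUE; wm2[5, 5, 1] <- FALSE
  st2 <- region_stats(v, list(GM = gm2, WM = wm2))
  expect_equal(st2$n_voxels - st$n_voxels, c(1L, -1L))
  expect_warning(st3 <- region_stats(v, list(GM = gm, empty = array(FALSE, d))),
                 "empty mask")
  expect_equal(nrow(st3), 1L)
})

test_that("lesion records carry id, size, mean and category", {
  d <- c(8L, 8L, 2L)
  v <- array(-0.5, d)
  l1 <- array(FALSE, d); l1[1:2, 1:2, 1] <- TRUE
  l2 <- array(FALSE, d); l2[5:6, 5:6, 1] <- TRUE
  v[l1] <- 1.5; v[l2] <- -3.6
  rec <- lesion_records(v, list(a = l1, b = l2))
  expect_equal(rec$category, c("hyperintense", "hypointense"))
  expect_equal(rec$n_voxels, c(4L, 4L))
  expect_equal(rec$mean_chi, c(1.5, -3.6))
  expect_warning(r0 <- lesion_records(v, list(none = array(FALSE, d))),
                 "empty lesion mask")
  expect_equal(nrow(r0), 0L)
})

test_that("pipeline comparison reproduces a closed-form regression", {
  d <- c(10L, 1L, 1L)
  xa <- array(c(0.5, 1.2, -0.3, 2.1, 0.9, -1.4, 0.2, 1.8, -0.7, 0.4), d)
  xb <- array(0.78 * as.vector(xa) + 0.05, d)
  mask <- array(TRUE, d)
  rep <- suppressWarnings(
    compare_pipelines(xa, xb, list(all = mask)))
  # closed-form least squares oracle
  x <- as.vector(xa); y <- as.vector(xb)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(rep$regression$slope, slope, tolerance = 1e-12)
  expect_equal(rep$regression$intercept, intercept, tolerance = 1e-12)
  expect_equal(rep$regression$r_squared, 1, tolerance = 1e-12)
})

test_that("identical maps give slope one and R-squared one", {
  d <- c(6L, 6L, 2L)
  set.seed(12)
  v <- array(stats::rnorm(prod(d)), d)
  mask <- array(TRUE, d)
  rep <- suppressWarnings(compare_pipelines(v, v, list(all = mask)))
  expect_equal(rep$regression$slope, 1, tolerance = 1e-12)
  expect_equal(rep$regression$intercept, 0, tolerance = 1e-10)
  expect_equal(rep$regression$r_squared, 1)
})

test_that("a known attenuation is recovered across noisy replicates", {
  set.seed(31)
  d <- c(12L, 12L, 4L)
  mask <- array(FALSE, d); mask[3:10, 3:10, ] <- TRUE
  la <- list(); lb <- list()
  for (i in 1:6) {
    a <- array(stats::rnorm(prod(d), sd = 2), d)
    la[[i]] <- a
    lb[[i]] <- 0.78 * a + array(stats::rnorm(prod(d), sd = 0.05), d)
  }
  rep <- compare_pipelines(la, lb, list(GM = mask))
  expect_equal(rep$regression$slope, 0.78, tolerance = 0.02)
  expect_false(is.null(rep$tests$GM$paired_t))
  # hand-rolled paired t oracle on the per-replicate means
  diffs <- vapply(1:6, function(i) mean(lb[[i]][mask]) - mean(la[[i]][mask]),
                  numeric(1))
  tstat <- mean(diffs) / (stats::sd(diffs) / sqrt(6))
  pval <- 2 * stats::pt(-abs(tstat), df = 5)
  expect_equal(rep$tests$GM$paired_t$statistic, tstat, tolerance = 1e-10)
  expect_equal(rep$tests$GM$paired_t$p, pval, tolerance = 1e-10)
  expect_equal(rep$tests$GM$shapiro$statistic,
               unname(stats::shapiro.test(diffs)$statistic))
})

test_that("degenerate comparisons are reported without NaNs", {
  d <- c(4L, 4L, 1L)
  mask <- array(TRUE, d)
  maps <- lapply(1:4, function(i) array(i * 0.1, d))
  rep <- compare_pipelines(maps, maps, list(t = mask))
  expect_equal(rep$tests$t$paired_t$statistic, 0)
  expect_equal(rep$tests$t$paired_t$p, 1)
  expect_match(rep$tests$t$note, "no difference")
  expect_warning(
    r2 <- compare_pipelines(maps[1:2], maps[1:2], list(t = mask)),
    "fewer than 3")
  expect_equal(r2$tests$t$note, "skipped")
})

test_that("the report aggregates categories with rounded percentages", {
  set.seed(2)
  recs <- data.frame(
    id = as.character(1:28),
    mean_chi = c(stats::rnorm(2, -3.6, 0.1), stats::rnorm(12, -0.4, 0.1),
                 stats::rnorm(14, 1.5, 0.1)),
    n_voxels = rep(5L, 28))
  recs$category <- classify_lesion(recs$mean_chi)
  rep <- build_report(recs)
  s <- rep$lesion_summary
  expect_equal(s$n, c(2L, 12L, 14L))
  expect_equal(s$percent, c(7, 43, 50))
  expect_lte(abs(sum(s$percent) - 100), 1)  # rounding only
  # empty input: empty tables, no failure
  empty <- build_report(NULL)
  expect_equal(nrow(empty$lesion_summary), 0L)
  # files written when out_dir given
  out <- tempfile()
  build_report(recs, out_dir = out)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "lesions.csv")))
})
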