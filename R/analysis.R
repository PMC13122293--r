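# Quantitative outputs: tissue statistics, agreement between the two field-
# fitting pipelines, and susceptibility-based MS-lesion classification.

#' Lesion classifier configuration
#'
#' Lesions are called hyperintense when their mean susceptibility exceeds the
#' healthy white-matter reference by more than the margin, hypointense when
#' below it by more than the margin, isointense otherwise. With the defaults
#' (-0.7 ppb reference, 1 ppb margin) the cutoffs are > 0.3 ppb and
#' < -1.7 ppb; both inequalities are strict, so the boundary values
#' themselves are isointense. The reference should be re-derived for any new
#' dataset.
#'
#' @param wm_reference healthy-WM mean susceptibility, ppb.
#' @param margin classification margin, ppb (> 0).
#' @return a `classifier_config` object.
#' @export
classifier_config <- function(wm_reference = -0.7, margin = 1.0) {
  if (margin <= 0) stop("margin must be positive")
  structure(list(wm_reference = wm_reference, margin = margin),
            class = "classifier_config")
}

#' Classify a lesion by its mean susceptibility
#'
#' @param mean_chi lesion mean susceptibility, ppb (finite; vectorised).
#' @param config a [classifier_config()].
#' @return character vector: "hypointense", "isointense" or "hyperintense".
#' @export
#' @examples
#' classify_lesion(c(1.5, -0.4, -3.6))  # hyper, iso, hypo
classify_lesion <- function(mean_chi, config = classifier_config()) {
  if (any(!is.finite(mean_chi))) stop("mean_chi must be finite")
  hi <- config$wm_reference + config$margin
  lo <- config$wm_reference - config$margin
  ifelse(mean_chi > hi, "hyperintense",
         ifelse(mean_chi < lo, "hypointense", "isointense"))
}

#' Per-tissue susceptibility statistics
#'
#' @param chi a `susceptibility_map` (or plain ppb volume).
#' @param masks named list of logical volumes (e.g. GM, WM, cord). Empty
#'   masks are omitted with a warning.
#' @return data frame with columns `tissue`, `mean`, `sd`, `n_voxels`.
#' @export
region_stats <- function(chi, masks) {
  v <- if (inherits(chi, "susceptibility_map")) chi$value else chi
  masks <- masks[vapply(masks, is.logical, logical(1))]
  rows <- lapply(names(masks), function(t) {
    m <- masks[[t]]
    if (sum(m) == 0) {
      warning("empty mask '", t, "' omitted")
      return(NULL)
    }
    x <- v[m]
    data.frame(tissue = t, mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               n_voxels = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Per-lesion records on a susceptibility map
#'
#' @param chi a `susceptibility_map` or ppb volume.
#' @param lesion_masks named list (or plain list) of logical lesion volumes.
#' @param config a [classifier_config()].
#' @return data frame with `id`, `mean_chi`, `n_voxels`, `category`.
#' @export
lesion_records <- function(chi, lesion_masks, config = classifier_config()) {
  v <- if (inherits(chi, "susceptibility_map")) chi$value else chi
  ids <- names(lesion_masks)
  if (is.null(ids)) ids <- as.character(seq_along(lesion_masks))
  rows <- lapply(seq_along(lesion_masks), function(i) {
    m <- lesion_masks[[i]]
    if (sum(m) == 0) {
      warning("empty lesion mask '", ids[i], "' omitted")
      return(NULL)
    }
    mu <- mean(v[m])
    data.frame(id = ids[i], mean_chi = mu, n_voxels = sum(m),
               category = classify_lesion(mu, config),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(id = character(0), mean_chi = numeric(0),
                      n_voxels = integer(0), category = character(0)))
  do.call(rbind, rows)
}

#' Compare two susceptibility maps tissue by tissue
#'
#' For each tissue, ordinary least squares of the second map on the first
#' over concatenated in-mask voxels (pooling replicates when lists of maps
#' are given), plus a Shapiro-Wilk normality test and a paired t-test on the
#' per-replicate tissue means. Tests require at least 3 replicates and are
#' otherwise skipped with a warning; identical means are reported as "no
#' difference" (t = 0, p = 1) rather than NaN.
#'
#' @param chi_a,chi_b `susceptibility_map`s, ppb volumes, or lists of these
#'   (replicates).
#' @param masks named list of tissue masks (typically GM and WM).
#' @param voxelwise_tests run the paired test on voxels instead of
#'   per-replicate means.
#' @param alpha significance level for the `significant` flag.
#' @return a `comparison_report`: per-tissue data frame `regression`
#'   (slope, intercept, r_squared) and per-tissue test list `tests`.
#' @export
compare_pipelines <- function(chi_a, chi_b, masks, voxelwise_tests = FALSE,
                              alpha = 0.05) {
  as_list <- function(x) {
    if (inherits(x, "susceptibility_map") || is.array(x)) list(x) else x
  }
  val <- function(x) if (inherits(x, "susceptibility_map")) x$value else x
  la <- lapply(as_list(chi_a), val)
  lb <- lapply(as_list(chi_b), val)
  stopifnot(length(la) == length(lb))
  nrep <- length(la)

  reg_rows <- list(); tests <- list()
  for (t in names(masks)) {
    m <- masks[[t]]
    xa <- unlist(lapply(la, function(v) v[m]))
    xb <- unlist(lapply(lb, function(v) v[m]))
    fit <- stats::lm(xb ~ xa)
    r2 <- stats::cor(xa, xb)^2
    reg_rows[[t]] <- data.frame(
      tissue = t, slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]), r_squared = r2,
      mean_a = mean(xa), sd_a = stats::sd(xa),
      mean_b = mean(xb), sd_b = stats::sd(xb),
      n_voxels = length(xa), stringsAsFactors = FALSE)

    if (voxelwise_tests) {
      diffs <- xb - xa
    } else {
      diffs <- vapply(seq_len(nrep), function(i)
        mean(lb[[i]][m]) - mean(la[[i]][m]), numeric(1))
    }
    if (length(diffs) < 3) {
      warning("fewer than 3 pairs for tissue '", t, "'; tests skipped")
      tests[[t]] <- list(shapiro = NULL, paired_t = NULL, note = "skipped")
    } else if (stats::sd(diffs) == 0) {
      tests[[t]] <- list(
        shapiro = list(statistic = NA_real_, p = NA_real_),
        paired_t = list(statistic = 0, p = 1, significant = FALSE),
        note = "no difference (zero-variance paired differences)")
    } else {
      sw <- stats::shapiro.test(diffs)
      tt <- stats::t.test(diffs)
      tests[[t]] <- list(
        shapiro = list(statistic = unname(sw$statistic), p = sw$p.value),
        paired_t = list(statistic = unname(tt$statistic), p = tt$p.value,
                        significant = tt$p.value < alpha),
        note = "")
    }
  }
  structure(list(regression = do.call(rbind, reg_rows), tests = tests,
                 n_replicates = nrep, alpha = alpha),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$n_replicates, " replicate(s)\n", sep = "")
  print(x$regression, row.names = FALSE)
  for (t in names(x$tests)) {
    tt <- x$tests[[t]]$paired_t
    if (!is.null(tt))
      cat(sprintf("  %s paired t: t = %.3g, p = %.3g\n", t, tt$statistic,
                  tt$p))
  }
  invisible(x)
}

#' Assemble the summary report
#'
#' Aggregates lesion records into category percentages and per-category mean
#' +/- SD, alongside tissue statistics and the pipeline comparison; writes
#' machine-readable (JSON, CSV) and human-readable output when `out_dir` is
#' given.
#'
#' @param records data frame from [lesion_records()] (may have zero rows).
#' @param stats optional data frame from [region_stats()].
#' @param comparison optional `comparison_report`.
#' @param out_dir optional output directory for report.json, lesions.csv,
#'   tissue_stats.csv and report.txt.
#' @return a `qsm_report` list with `lesion_summary` (category, n, percent,
#'   mean, sd), `records`, `tissue_stats`, `comparison`.
#' @export
build_report <- function(records = NULL, stats = NULL, comparison = NULL,
                         out_dir = NULL) {
  cats <- c("hypointense", "isointense", "hyperintense")
  if (!is.null(records) && nrow(records) > 0) {
    n_tot <- nrow(records)
    summ <- do.call(rbind, lapply(cats, function(cg) {
      x <- records$mean_chi[records$category == cg]
      data.frame(category = cg, n = length(x),
                 percent = round(100 * length(x) / n_tot),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) > 1) stats::sd(x) else
                   if (length(x) == 1) 0 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  } else {
    summ <- data.frame(category = character(0), n = integer(0),
                       percent = numeric(0), mean = numeric(0),
                       sd = numeric(0))
    records <- data.frame(id = character(0), mean_chi = numeric(0),
                          n_voxels = integer(0), category = character(0))
  }
  rep <- structure(list(lesion_summary = summ, records = records,
                        tissue_stats = stats, comparison = comparison),
                   class = "qsm_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(records, file.path(out_dir, "lesions.csv"),
                     row.names = FALSE)
    if (!is.null(stats))
      utils::write.csv(stats, file.path(out_dir, "tissue_stats.csv"),
                       row.names = FALSE)
    json <- list(lesion_summary = summ,
                 tissue_stats = stats,
                 comparison = if (!is.null(comparison))
                   list(regression = comparison$regression,
                        tests = comparison$tests) else NULL)
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, null = "null")
    txt <- utils::capture.output(print(rep))
    writeLines(txt, file.path(out_dir, "report.txt"))
  }
  rep
}

#' @export
print.qsm_report <- function(x, ...) {
  cat("Lesion categories:\n")
  print(x$lesion_summary, row.names = FALSE)
  if (!is.null(x$tissue_stats)) {
    cat("Tissue statistics (ppb):\n")
    print(x$tissue_stats, row.names = FALSE)
  }
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
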