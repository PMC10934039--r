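# Subject- and study-level orchestration: raw recording -> trend -> state
# features -> discriminant reports.

#' Run the full single-subject analysis chain
#'
#' From an ECG record or R-R series: artifact cleaning, tachogram
#' resampling at the mean heart rate, sliding maximum-entropy LF/HF trend,
#' Rest/Task/After averaging with the 30-s settling skip, responsiveness
#' ratios, the 12-entry feature vector, and (when digits are supplied) the
#' RNG task index.
#'
#' @param input an [ecg_record()], an [rr_series()], or a path to an R-R
#'   CSV (`onset_s`, `rr_ms`).
#' @param plan a [state_plan()]; when `NULL`, annotations attached to an
#'   ECG input are used, otherwise the default 60/100/60 s plan.
#' @param digits optional RNG-task digit sequence (vector, string or file
#'   path).
#' @param order Burg AR order for the spectral trend.
#' @param out_dir optional directory; when given, writes `rr_clean.csv`,
#'   `trend.csv` and `features.csv` there.
#' @param id subject identifier used in the feature row.
#' @return object of class `hrv_subject`: list with `features`, `averages`,
#'   `ratios`, `trend`, `rr`, `rng_index` (NA without digits), `plan`, `id`.
#' @export
run_subject <- function(input, plan = NULL, digits = NULL, order = 16L,
                        out_dir = NULL, id = "subject") {
  rr <- NULL
  if (is.character(input)) {
    rr <- read_rr(input)
  } else if (inherits(input, "ecg_record")) {
    if (is.null(plan) && !is.null(input$annotations)) {
      plan <- plan_from_annotations(input$annotations)
    }
    rr <- rr_from_peaks(detect_r_peaks(input))
  } else if (inherits(input, "rr_series")) {
    rr <- input
  } else {
    stop("config error: input must be an ECG record, an R-R series or a CSV path",
         call. = FALSE)
  }
  if (is.null(plan)) plan <- state_plan(start = rr$onsets[1])
  rr <- clean_rr(rr)
  tach <- resample_tachogram(rr)
  trend <- sliding_trend(tach, order = order)
  avg <- state_averages(trend, plan)
  ratios <- response_ratios(avg)
  features <- build_features(avg, ratios)
  rng <- NA_real_
  if (!is.null(digits)) {
    if (is.character(digits) && length(digits) == 1L && file.exists(digits)) {
      digits <- read_digits(digits)
    }
    rng <- rng_index(digits)
  }
  out <- structure(list(id = id, features = features, averages = avg,
                        ratios = ratios, trend = trend, rr = rr,
                        rng_index = rng, plan = plan),
                   class = "hrv_subject")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_rr(rr, file.path(out_dir, "rr_clean.csv"))
    write_trend(trend, file.path(out_dir, "trend.csv"))
    row <- data.frame(id = id, t(features), rng_index = rng, check.names = FALSE)
    utils::write.csv(row, file.path(out_dir, "features.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  out
}

#' @export
print.hrv_subject <- function(x, ...) {
  cat(sprintf("<hrv_subject> %s  (RNG index %s)\n", x$id,
              if (is.na(x$rng_index)) "n/a" else sprintf("%.3f", x$rng_index)))
  print(round(x$features, 3))
  invisible(x)
}

#' Feature table of a simulated cohort
#'
#' Runs [run_subject()] on every subject of an [simulate_cohort()] result.
#'
#' @param cohort an `hrv_cohort`.
#' @param order Burg AR order.
#' @return `data.frame` with `id`, `group`, `epds`, `rng_index` and the 12
#'   feature columns.
#' @export
cohort_features <- function(cohort, order = 16L) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    subj <- run_subject(s$rr, plan = cohort$config$plan, digits = s$digits,
                        order = order, id = s$id)
    data.frame(id = s$id, group = s$group, epds = s$epds,
               rng_index = subj$rng_index, t(subj$features),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit the pairwise discriminants for a labeled feature table
#'
#' Fits the available two-group models (by default PPD vs control, PPD vs
#' AJD and AJD vs control; pairs whose groups have fewer than 2 subjects
#' are skipped with a warning) and assembles a confusion/performance
#' report.
#'
#' @param features `data.frame` with a `group` column and the 12 feature
#'   columns (see [cohort_features()]), or a path to such a CSV.
#' @param pairs list of character pairs `(former, latter)`.
#' @param ridge ridge weight passed to [fit_lda()].
#' @param out_dir optional directory for `model_<former>_vs_<latter>.json`
#'   files, per-subject `d_scores.csv` and `report.csv`.
#' @return object of class `hrv_study`: list with `models` (named list of
#'   [hrv_lda()] fits) and `report` (`data.frame` of counts, sensitivity,
#'   specificity, Mahalanobis distance and p per pair).
#' @export
run_study <- function(features,
                      pairs = list(c("PPD", "control"), c("PPD", "AJD"),
                                   c("AJD", "control")),
                      ridge = NULL, out_dir = NULL) {
  if (is.character(features)) features <- utils::read.csv(features, check.names = FALSE)
  if (!"group" %in% names(features)) stop("feature table needs a 'group' column", call. = FALSE)
  counts <- table(features$group)
  if (sum(counts >= 2) < 2) stop("need at least 2 labeled groups with n >= 2", call. = FALSE)
  models <- list()
  rows <- list()
  scores <- list()
  for (pr in pairs) {
    if (any(!pr %in% names(counts)) || any(counts[pr] < 2)) {
      warning("skipping pair ", pr[1], " vs ", pr[2], ": a group has n < 2")
      next
    }
    fit <- hrv_lda(stats::as.formula("group ~ ."), data = features, pair = pr,
                   ridge = ridge)
    key <- paste0(pr[1], "_vs_", pr[2])
    models[[key]] <- fit
    ct <- fit$confusion
    rows[[key]] <- data.frame(
      pair = key, n_former = fit$fit$n[["former"]], n_latter = fit$fit$n[["latter"]],
      tp = ct$tp, fn = ct$fn, fp = ct$fp, tn = ct$tn,
      sensitivity = fit$performance$sensitivity,
      specificity = fit$performance$specificity,
      md = fit$separation$md, p = fit$separation$p)
    sel <- features$group %in% pr
    scores[[key]] <- data.frame(pair = key,
                                id = if ("id" %in% names(features)) features$id[sel]
                                     else which(sel),
                                group = features$group[sel], d = fit$scores)
  }
  if (!length(models)) stop("no group pair could be fitted", call. = FALSE)
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  out <- structure(list(models = models, report = report), class = "hrv_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(models)) {
      write_model(models[[key]], file.path(out_dir, paste0("model_", key, ".json")))
    }
    utils::write.csv(do.call(rbind, scores), file.path(out_dir, "d_scores.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  out
}

#' @export
print.hrv_study <- function(x, ...) {
  cat("<hrv_study> pairwise discriminants (D > 0 supports the former group)\n\n")
  rep <- x$report
  for (i in seq_len(nrow(rep))) {
    r <- rep[i, ]
    cat(sprintf("  %-18s  D>0/D<0: %d/%d vs %d/%d  sens %.1f%%  spec %.1f%%  Md %.2f (p %.2g)\n",
                r$pair, r$tp, r$fn, r$fp, r$tn, r$sensitivity, r$specificity,
                r$md, r$p))
  }
  invisible(x)
}
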