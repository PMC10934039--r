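# Rest/Task/After segmentation of the HRV trend, 30-s settling skip
# averaging, responsiveness ratios and the 12-entry discriminant feature
# vector, plus subject-level screening bookkeeping.

#' Canonical order of the 12 discriminant features
#'
#' HF triplet, LF triplet, LF/HF triplet, HR triplet; within each triplet
#' the Rest level, the Task/Rest ratio and the After/Rest ratio.
#' @export
FEATURE_NAMES <- c("hf_rest", "hf_task_rest", "hf_after_rest",
                   "lf_rest", "lf_task_rest", "lf_after_rest",
                   "lfhf_rest", "lfhf_task_rest", "lfhf_after_rest",
                   "hr_rest", "hr_task_rest", "hr_after_rest")

#' Behavioral-state plan for the three-state paradigm
#'
#' Contiguous Rest -> Task -> After intervals. Defaults follow the
#' standard protocol: about 60 s of quiet rest, 100 s of the random number
#' generation task, and 60 s of rest after the task. Every state must
#' exceed 30 s, because the first 30 s of each state are skipped when
#' averaging.
#'
#' @param rest_dur,task_dur,after_dur state durations in s.
#' @param start time of Rest onset in s (default 0).
#' @return object of class `state_plan` with elements `rest_start`,
#'   `task_start`, `after_start`, `end`.
#' @export
state_plan <- function(rest_dur = 60, task_dur = 100, after_dur = 60, start = 0) {
  if (any(c(rest_dur, task_dur, after_dur) <= 30)) {
    stop("every state must last longer than 30 s (the settling skip)", call. = FALSE)
  }
  structure(list(rest_start = start,
                 task_start = start + rest_dur,
                 after_start = start + rest_dur + task_dur,
                 end = start + rest_dur + task_dur + after_dur),
            class = "state_plan")
}

#' Build a state plan from annotation marks
#'
#' @param annotations `data.frame` with columns `label` (`rest_start`,
#'   `task_start`, `after_start`, `end`) and `time_s`.
#' @return a [state_plan()].
#' @export
plan_from_annotations <- function(annotations) {
  need <- c("rest_start", "task_start", "after_start", "end")
  tm <- annotations$time_s[match(need, annotations$label)]
  if (any(is.na(tm))) {
    stop("annotations must mark ", paste(need, collapse = ", "), call. = FALSE)
  }
  state_plan(rest_dur = tm[2] - tm[1], task_dur = tm[3] - tm[2],
             after_dur = tm[4] - tm[3], start = tm[1])
}

#' @export
print.state_plan <- function(x, ...) {
  cat(sprintf("<state_plan> Rest [%g, %g) Task [%g, %g) After [%g, %g] s\n",
              x$rest_start, x$task_start, x$task_start, x$after_start,
              x$after_start, x$end))
  invisible(x)
}

# A recording that stops at the nominal protocol end yields its last trend
# frame up to one trend step plus one beat earlier; allow that much slack
# when checking that a trend covers a plan.
.coverage_slack <- 3

.state_bounds <- function(plan) {
  list(Rest = c(plan$rest_start, plan$task_start),
       Task = c(plan$task_start, plan$after_start),
       After = c(plan$after_start, plan$end))
}

#' Split an HRV trend into Rest/Task/After slices
#'
#' Intervals are half-open on the right except the final one, so a frame
#' stamped exactly at a state boundary belongs to the later state.
#'
#' @param trend an [sliding_trend()] result.
#' @param plan a [state_plan()].
#' @return named list of three `data.frame` slices (`Rest`, `Task`, `After`).
#' @export
segment_states <- function(trend, plan) {
  stopifnot(inherits(trend, "hrv_trend"), inherits(plan, "state_plan"))
  if (max(trend$t) < plan$end - .coverage_slack) {
    stop("coverage error: trend ends at ", max(trend$t), " s but the plan needs ",
         plan$end, " s", call. = FALSE)
  }
  b <- .state_bounds(plan)
  lapply(seq_along(b), function(i) {
    lo <- b[[i]][1]; hi <- b[[i]][2]
    sel <- if (i < 3L) trend$t >= lo - .t_eps & trend$t < hi - .t_eps
           else trend$t >= lo - .t_eps & trend$t <= hi + .t_eps
    as.data.frame(trend)[sel, , drop = FALSE]
  }) |> stats::setNames(names(b))
}

#' Average HRV indices over a state, skipping the first 30 s
#'
#' Frames are stamped with their window end time, so a frame at `t` uses
#' only data from `(t - 30, t]`; restricting to `t > state_start + 30`
#' guarantees the average contains no data recorded before the state began.
#'
#' @param trend an [sliding_trend()] result (or a slice of one).
#' @param state_start,state_end state boundaries in s.
#' @param skip_s settling time discarded at the head of the state (default 30).
#' @return named list `lf`, `hf`, `lfhf`, `hr`; `lfhf` averages only frames
#'   where it is defined (NA when none are).
#' @export
state_average <- function(trend, state_start, state_end, skip_s = 30) {
  if (state_end - state_start <= skip_s) {
    stop("state duration must exceed the ", skip_s, " s settling skip", call. = FALSE)
  }
  sel <- trend$t > state_start + skip_s + .t_eps & trend$t <= state_end + .t_eps
  if (!any(sel)) {
    stop("insufficient data: no trend frames in (", state_start + skip_s, ", ",
         state_end, "] s", call. = FALSE)
  }
  lfhf <- trend$lfhf[sel]
  list(lf = mean(trend$lf[sel]),
       hf = mean(trend$hf[sel]),
       lfhf = if (all(is.na(lfhf))) NA_real_ else mean(lfhf, na.rm = TRUE),
       hr = mean(trend$hr[sel]))
}

#' Per-state HRV averages for a whole plan
#'
#' @param trend an [sliding_trend()] result.
#' @param plan a [state_plan()].
#' @param skip_s settling skip in s.
#' @return object of class `state_averages`: named list of
#'   [state_average()] results for `Rest`, `Task` and `After`.
#' @export
state_averages <- function(trend, plan, skip_s = 30) {
  stopifnot(inherits(plan, "state_plan"))
  if (max(trend$t) < plan$end - .coverage_slack) {
    stop("coverage error: trend ends before the plan does", call. = FALSE)
  }
  b <- .state_bounds(plan)
  structure(lapply(b, function(bd) state_average(trend, bd[1], bd[2], skip_s)),
            class = "state_averages")
}

#' @export
print.state_averages <- function(x, ...) {
  m <- do.call(rbind, lapply(x, function(s) unlist(s)))
  cat("<state_averages>\n")
  print(round(m, 3))
  invisible(x)
}

#' Task/Rest and After/Rest responsiveness ratios
#'
#' @param avg a [state_averages()] object.
#' @return list with elements `task_rest` and `after_rest`, each a named
#'   list over `lf`, `hf`, `lfhf`, `hr`.
#' @export
response_ratios <- function(avg) {
  stopifnot(inherits(avg, "state_averages"))
  idx <- c("lf", "hf", "lfhf", "hr")
  for (k in idx) {
    v <- avg$Rest[[k]]
    if (is.na(v) || v == 0) {
      stop("division guard: Rest average of '", k, "' is ",
           if (is.na(v)) "undefined" else "zero", call. = FALSE)
    }
  }
  ratio <- function(state) stats::setNames(
    lapply(idx, function(k) avg[[state]][[k]] / avg$Rest[[k]]), idx)
  list(task_rest = ratio("Task"), after_rest = ratio("After"))
}

#' Assemble the 12-entry discriminant feature vector
#'
#' Fixed ordering (see [FEATURE_NAMES]): the HF triplet (Rest level,
#' Task/Rest, After/Rest), then the LF, LF/HF and HR triplets.
#'
#' @param avg a [state_averages()] object.
#' @param ratios a [response_ratios()] result (computed from `avg` when
#'   omitted).
#' @return named numeric vector of length 12.
#' @export
build_features <- function(avg, ratios = NULL) {
  stopifnot(inherits(avg, "state_averages"))
  if (is.null(ratios)) ratios <- response_ratios(avg)
  v <- c(avg$Rest$hf, ratios$task_rest$hf, ratios$after_rest$hf,
         avg$Rest$lf, ratios$task_rest$lf, ratios$after_rest$lf,
         avg$Rest$lfhf, ratios$task_rest$lfhf, ratios$after_rest$lfhf,
         avg$Rest$hr, ratios$task_rest$hr, ratios$after_rest$hr)
  names(v) <- FEATURE_NAMES
  if (any(is.na(v))) {
    stop("missing feature component(s): ", paste(names(v)[is.na(v)], collapse = ", "),
         call. = FALSE)
  }
  v
}

#' Check that the breathing rate lies in the HF band
#'
#' HF power indexes respiratory parasympathetic activity only while the
#' subject breathes at 9-24 cycles/min (0.15-0.4 Hz); outside that range
#' the respiratory peak leaves the HF band and the measurement should be
#' repeated.
#'
#' @param rate breathing rate in cycles/min (> 0).
#' @return `"valid"` or `"out_of_band"` (the latter with a warning).
#' @export
check_respiration <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("breathing rate must be a single positive number", call. = FALSE)
  }
  if (rate >= 9 && rate <= 24) {
    "valid"
  } else {
    warning("breathing rate ", rate, "/min is outside 9-24/min; ",
            "HF may not reflect respiratory parasympathetic power")
    "out_of_band"
  }
}

#' Edinburgh Postnatal Depression Scale screening decision
#'
#' @param score integer EPDS total, 0-30.
#' @param cutoff positivity cutoff (default 9; scores at or above it are
#'   positive).
#' @return `"positive"` or `"negative"`.
#' @export
epds_screen <- function(score, cutoff = 9) {
  if (!is.numeric(score) || length(score) != 1L || is.na(score) ||
      score != round(score) || score < 0 || score > 30) {
    stop("EPDS score must be an integer in [0, 30]", call. = FALSE)
  }
  if (score >= cutoff) "positive" else "negative"
}

#' Cohort accounting and Table-style summary
#'
#' Counts subjects per diagnostic group, expresses each labeled group as a
#' percentage of the screen-positive sample (and the whole sample as a
#' percentage of the screened population when `n_screened` is given), and
#' tabulates mean and s.d. of any feature columns per group. Percentages
#' are rounded half-up to one decimal.
#'
#' @param subjects `data.frame` with a `group` column
#'   (`control`/`PPD`/`AJD`/`unlabeled`) and optionally feature columns
#'   (see [FEATURE_NAMES]) and `epds`.
#' @param n_screened optional size of the screened population from which
#'   the cohort was enrolled.
#' @return object of class `cohort_summary`: list with `counts`
#'   (`data.frame`: group, n, pct_of_cohort), `enrolled_pct` (or NA) and
#'   `features` (list per group of mean/sd `data.frame`s, NULL when no
#'   feature columns are present).
#' @export
cohort_summary <- function(subjects, n_screened = NULL) {
  stopifnot(is.data.frame(subjects), nrow(subjects) > 0)
  if (!"group" %in% names(subjects)) stop("subjects need a 'group' column", call. = FALSE)
  known <- c("control", "PPD", "AJD", "unlabeled")
  bad <- setdiff(unique(subjects$group), known)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n_total <- nrow(subjects)
  groups <- intersect(known, unique(subjects$group))
  counts <- data.frame(group = groups,
                       n = vapply(groups, function(g) sum(subjects$group == g), numeric(1)))
  counts$pct_of_cohort <- round_half_up(100 * counts$n / n_total, 1)
  enrolled_pct <- if (is.null(n_screened)) NA_real_ else
    round_half_up(100 * n_total / n_screened, 1)
  feat_cols <- intersect(FEATURE_NAMES, names(subjects))
  feats <- NULL
  if (length(feat_cols)) {
    feats <- lapply(stats::setNames(groups, groups), function(g) {
      sub <- subjects[subjects$group == g, feat_cols, drop = FALSE]
      data.frame(feature = feat_cols,
                 mean = vapply(sub, mean, numeric(1)),
                 sd = vapply(sub, stats::sd, numeric(1)),
                 row.names = NULL)
    })
  }
  structure(list(counts = counts, enrolled_pct = enrolled_pct,
                 n_screened = n_screened, features = feats),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  if (!is.na(x$enrolled_pct)) {
    cat(sprintf("  enrolled: %d of %d screened (%.1f%%)\n",
                sum(x$counts$n), x$n_screened, x$enrolled_pct))
  }
  print(x$counts, row.names = FALSE)
  if (!is.null(x$features)) {
    for (g in names(x$features)) {
      cat("\n ", g, "(mean +/- s.d.):\n")
      f <- x$features[[g]]
      cat(paste(sprintf("   %-16s %8.2f +/- %.2f", f$feature, f$mean, f$sd),
                collapse = "\n"), "\n")
    }
  }
  invisible(x)
}
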