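# ECG / R-R ingestion: reading recordings, QRS detection, interval cleaning,
# and resampling of the tachogram onto a uniform grid at the mean heart rate.

#' ECG record constructor
#'
#' A single-lead ECG trace sampled uniformly at `fs` Hz, optionally carrying
#' behavioral-state annotations (label + time).
#'
#' @param samples numeric voltage series (arbitrary units).
#' @param fs sampling rate in Hz (> 0).
#' @param t0 recording start time in seconds.
#' @param annotations optional `data.frame` with columns `label`, `time_s`.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, t0 = 0, annotations = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("ECG record has no samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  dur <- length(samples) / fs
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations),
              all(c("label", "time_s") %in% names(annotations)))
    if (any(annotations$time_s < t0 - .t_eps | annotations$time_s > t0 + dur + .t_eps)) {
      stop("annotation times fall outside the recording", call. = FALSE)
    }
  }
  structure(list(samples = samples, fs = fs, t0 = t0, annotations = annotations),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %.6g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  if (!is.null(x$annotations)) {
    cat("  annotations:", paste(x$annotations$label, collapse = ", "), "\n")
  }
  invisible(x)
}

#' R-R interval series constructor
#'
#' Beat-to-beat intervals in ms with the onset time (s) of each interval's
#' starting beat and a per-interval quality flag.
#'
#' @param intervals R-R durations in ms (> 0).
#' @param onsets strictly increasing onset times in s, one per interval.
#' @param flags character flags, each one of `"accepted"` or `"replaced"`.
#' @return an object of class `rr_series`.
#' @export
rr_series <- function(intervals, onsets, flags = rep("accepted", length(intervals))) {
  intervals <- as.numeric(intervals)
  onsets <- as.numeric(onsets)
  if (length(intervals) != length(onsets) || length(intervals) != length(flags)) {
    stop("intervals, onsets and flags must have equal length", call. = FALSE)
  }
  if (any(intervals <= 0)) stop("R-R intervals must be positive", call. = FALSE)
  if (length(onsets) > 1L && any(diff(onsets) <= 0)) {
    stop("onsets must be strictly increasing", call. = FALSE)
  }
  if (!all(flags %in% c("accepted", "replaced"))) {
    stop("flags must be 'accepted' or 'replaced'", call. = FALSE)
  }
  structure(list(intervals = intervals, onsets = onsets, flags = flags),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals, mean %.1f ms (%d replaced)\n",
              length(x$intervals), mean(x$intervals), sum(x$flags == "replaced")))
  ex <- attr(x, "excluded")
  if (!is.null(ex) && nrow(ex)) cat(sprintf("  %d boundary interval(s) excluded\n", nrow(ex)))
  invisible(x)
}

#' Read a single-lead ECG recording
#'
#' CSV input must have header columns `time_s` and `voltage`; the sampling
#' rate is inferred from the median sample spacing and the grid must be
#' uniform to within 1% jitter. The `"wfdb"` format reads a plain-text
#' record directory containing `header.txt` (lines `fs: <Hz>` and
#' `t0: <s>`) and `signal.csv` (column `voltage`); this is a simplified
#' text rendering of the classic record-directory layout, not a binary
#' WFDB reader.
#'
#' @param path file path (CSV) or record directory (`"wfdb"`).
#' @param format `"csv"` or `"wfdb"`.
#' @param annotations optional path to a sidecar CSV with columns
#'   `label` (e.g. `rest_start`, `task_start`, `after_start`, `end`) and
#'   `time_s`.
#' @return an [ecg_record()].
#' @export
read_ecg <- function(path, format = c("csv", "wfdb"), annotations = NULL) {
  format <- match.arg(format)
  ann <- NULL
  if (!is.null(annotations)) {
    if (!file.exists(annotations)) stop("annotation file not found: ", annotations, call. = FALSE)
    ann <- utils::read.csv(annotations, stringsAsFactors = FALSE)
    if (!all(c("label", "time_s") %in% names(ann))) {
      stop("annotation file must have columns 'label' and 'time_s'", call. = FALSE)
    }
  }
  if (format == "csv") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    dat <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                    error = function(e) stop("parse error in ", path, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (nrow(dat) == 0L) stop("parse error: ", path, " contains no data rows", call. = FALSE)
    if (!all(c("time_s", "voltage") %in% names(dat))) {
      stop("parse error: header must declare columns 'time_s' and 'voltage' (line 1)",
           call. = FALSE)
    }
    bad <- which(!is.finite(dat$time_s) | !is.finite(dat$voltage))
    if (length(bad)) {
      stop("parse error: non-numeric value at line ", bad[1] + 1L, call. = FALSE)
    }
    if (nrow(dat) < 2L) stop("parse error: need at least 2 samples", call. = FALSE)
    d <- diff(dat$time_s)
    if (any(d <= 0)) {
      stop("format error: duplicated or non-increasing timestamps at line ",
           which(d <= 0)[1] + 2L, call. = FALSE)
    }
    med <- stats::median(d)
    if (max(abs(d - med)) / med > 0.01) {
      stop("format error: non-uniform sampling (jitter beyond 1% of the median spacing)",
           call. = FALSE)
    }
    ecg_record(dat$voltage, fs = 1 / med, t0 = dat$time_s[1], annotations = ann)
  } else {
    hdr_path <- file.path(path, "header.txt")
    sig_path <- file.path(path, "signal.csv")
    if (!file.exists(hdr_path) || !file.exists(sig_path)) {
      stop("wfdb-style record directory must contain header.txt and signal.csv",
           call. = FALSE)
    }
    hdr <- tryCatch(yaml::read_yaml(hdr_path),
                    error = function(e) stop("parse error in header.txt: ",
                                             conditionMessage(e), call. = FALSE))
    if (is.null(hdr$fs)) stop("parse error: header.txt lacks an 'fs' entry", call. = FALSE)
    sig <- utils::read.csv(sig_path, stringsAsFactors = FALSE)
    if (!"voltage" %in% names(sig)) {
      stop("parse error: signal.csv must have a 'voltage' column", call. = FALSE)
    }
    ecg_record(sig$voltage, fs = as.numeric(hdr$fs), t0 = as.numeric(hdr$t0 %||% 0),
               annotations = ann)
  }
}

#' Detect R peaks in a single-lead ECG
#'
#' Pan-Tompkins-style detector: 5-25 Hz band-pass, squared derivative,
#' 150 ms moving-window integration, adaptive threshold, and a 250 ms
#' refractory period. Peak times are refined to the local maximum of the
#' band-passed signal.
#'
#' @param ecg an [ecg_record()] of at least 10 s, sampled at >= 100 Hz.
#' @param refractory_s minimum allowed peak separation in seconds.
#' @return object of class `r_peak_train`: list with strictly increasing
#'   `times` (s).
#' @export
detect_r_peaks <- function(ecg, refractory_s = 0.25) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- ecg$fs
  x <- ecg$samples
  if (length(x) / fs < 10) stop("recording shorter than 10 s", call. = FALSE)
  if (fs < 100) stop("sampling rate below 100 Hz", call. = FALSE)
  if (stats::var(x) == 0) stop("detection error: flat-line input", call. = FALSE)

  bp <- signal::filtfilt(signal::butter(2, c(5, 25) / (fs / 2), type = "pass"), x)
  d <- c(0, diff(bp)) * fs
  sq <- d^2
  win <- max(3L, as.integer(round(0.15 * fs)))
  env <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 2))
  env[is.na(env)] <- 0

  thr <- 0.3 * stats::quantile(env, 0.99, names = FALSE)
  n <- length(env)
  is_max <- c(FALSE, env[2:(n - 1)] >= env[1:(n - 2)] & env[2:(n - 1)] > env[3:n], FALSE)
  cand <- which(is_max & env > thr)
  if (!length(cand)) stop("detection error: no QRS candidates found", call. = FALSE)

  # refractory pass on the integrated envelope: keep the larger of two close peaks
  keep <- integer(0)
  ref_n <- refractory_s * fs
  for (i in cand) {
    if (length(keep) && (i - keep[length(keep)]) < ref_n) {
      if (env[i] > env[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }

  # refine each detection to the band-passed R-wave apex within +/- 100 ms
  half <- as.integer(round(0.1 * fs))
  idx <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(length(bp), i + half)
    lo + which.max(bp[lo:hi]) - 1L
  }, integer(1))
  idx <- sort(unique(idx))
  # refinement can re-merge neighbours; enforce the refractory once more
  if (length(idx) > 1L) {
    ok <- c(TRUE, diff(idx) >= ref_n)
    idx <- idx[ok]
  }
  structure(list(times = ecg$t0 + (idx - 1L) / fs), class = "r_peak_train")
}

#' @export
print.r_peak_train <- function(x, ...) {
  cat(sprintf("<r_peak_train> %d peaks over %.1f s\n", length(x$times),
              diff(range(x$times))))
  invisible(x)
}

#' R-R intervals from an R-peak train
#'
#' @param peaks an `r_peak_train` (or numeric vector of peak times in s)
#'   with at least two peaks.
#' @return an [rr_series()] with all intervals flagged `accepted`.
#' @export
rr_from_peaks <- function(peaks) {
  times <- if (inherits(peaks, "r_peak_train")) peaks$times else as.numeric(peaks)
  if (length(times) < 2L) stop("insufficient data: need at least 2 R peaks", call. = FALSE)
  if (any(diff(times) <= 0)) stop("peak times must be strictly increasing", call. = FALSE)
  rr_series(intervals = diff(times) * 1000,
            onsets = times[-length(times)])
}

#' Exclude paroxysmal beats from an R-R series
#'
#' Intervals outside `[lo, hi]` ms are treated as artifacts: an isolated
#' out-of-range interval is replaced by the mean of its two neighbouring
#' intervals and flagged `replaced`; an out-of-range interval at either end
#' of the series (lacking two neighbours) is dropped and recorded in the
#' `excluded` attribute. Two or more consecutive out-of-range intervals
#' are rejected outright, because neighbour averaging is then meaningless.
#'
#' @param rr an [rr_series()].
#' @param lo,hi acceptance window in ms (defaults 273 and 1500).
#' @return a cleaned [rr_series()]; attribute `excluded` is a `data.frame`
#'   (`onset_s`, `rr_ms`) of dropped edge intervals.
#' @export
clean_rr <- function(rr, lo = 273, hi = 1500) {
  stopifnot(inherits(rr, "rr_series"))
  n <- length(rr$intervals)
  if (n == 0L) stop("empty R-R series", call. = FALSE)
  out <- which(rr$intervals < lo | rr$intervals > hi)
  excluded <- data.frame(onset_s = numeric(0), rr_ms = numeric(0))
  if (length(out)) {
    if (any(diff(out) == 1L)) {
      stop("rejection error: two or more consecutive intervals outside [",
           lo, ", ", hi, "] ms", call. = FALSE)
    }
    intervals <- rr$intervals
    flags <- rr$flags
    drop <- out[out == 1L | out == n]
    for (i in setdiff(out, drop)) {
      intervals[i] <- (intervals[i - 1L] + intervals[i + 1L]) / 2
      flags[i] <- "replaced"
    }
    keep <- setdiff(seq_len(n), drop)
    if (!length(keep)) stop("rejection error: no intervals survive cleaning", call. = FALSE)
    excluded <- data.frame(onset_s = rr$onsets[drop], rr_ms = rr$intervals[drop])
    rr <- rr_series(intervals[keep], rr$onsets[keep], flags[keep])
  }
  attr(rr, "excluded") <- excluded
  rr
}

#' Resample the R-R tachogram on a uniform grid at the mean heart rate
#'
#' The interval-versus-onset-time curve is interpolated (natural cubic
#' spline; linear for fewer than 4 beats) on a uniform grid whose rate is
#' the mean heart rate in beats/s, `1000 / mean(intervals)`.
#'
#' @param rr a cleaned [rr_series()] spanning at least `min_span_s` seconds.
#' @param min_span_s minimum recording span in s (default 30, one analysis
#'   window).
#' @return object of class `tachogram`: list with `values` (ms), `rate`
#'   (Hz) and `t_start` (s).
#' @export
resample_tachogram <- function(rr, min_span_s = 30) {
  stopifnot(inherits(rr, "rr_series"))
  n <- length(rr$intervals)
  span <- rr$onsets[n] + rr$intervals[n] / 1000 - rr$onsets[1]
  if (span < min_span_s) {
    stop("insufficient data: recording spans ", round(span, 1), " s < ",
         min_span_s, " s", call. = FALSE)
  }
  rate <- 1000 / mean(rr$intervals)
  nout <- floor(span * rate + .t_eps)
  tt <- rr$onsets[1] + (seq_len(nout) - 1L) / rate
  if (n >= 4L) {
    f <- stats::splinefun(rr$onsets, rr$intervals, method = "natural")
  } else {
    f <- stats::approxfun(rr$onsets, rr$intervals, rule = 2)
  }
  values <- f(tt)
  if (any(values <= 0)) {
    stop("interpolation produced non-positive R-R values", call. = FALSE)
  }
  structure(list(values = values, rate = rate, t_start = rr$onsets[1]),
            class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram> %d samples @ %.4g Hz from t = %.2f s\n",
              length(x$values), x$rate, x$t_start))
  invisible(x)
}

#' Read an R-R interval series from CSV
#'
#' Bypass for devices that export beat annotations directly: columns
#' `onset_s` and `rr_ms` (an optional `flag` column is honoured).
#'
#' @param path CSV file path.
#' @return an [rr_series()].
#' @export
read_rr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "rr_ms") %in% names(dat))) {
    stop("parse error: R-R CSV must have columns 'onset_s' and 'rr_ms'", call. = FALSE)
  }
  flags <- if ("flag" %in% names(dat)) dat$flag else rep("accepted", nrow(dat))
  rr_series(dat$rr_ms, dat$onset_s, flags)
}

#' Write a (cleaned) R-R series to CSV with its quality flags
#'
#' @param rr an [rr_series()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  dat <- data.frame(onset_s = sprintf("%.6f", rr$onsets),
                    rr_ms = sprintf("%.6f", rr$intervals),
                    flag = rr$flags)
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
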