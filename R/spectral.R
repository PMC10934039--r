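# Maximum-entropy (Burg autoregressive) spectral estimation. The Burg
# lattice recursion is implemented directly; stats::ar.burg is used only as
# an independent cross-check in the test suite.

#' Fit an autoregressive model by the Burg (maximum entropy) recursion
#'
#' The segment mean is subtracted before fitting. The model convention is
#' `x_t = sum_k phi_k x_(t-k) + e_t` with innovation variance `noise_var`.
#' Burg's reflection coefficients lie in (-1, 1), which guarantees a stable
#' model; a (numerically) unstable fit is flagged rather than silently used.
#'
#' @param segment numeric series on a uniform grid (values in ms for R-R
#'   work, but any unit is accepted).
#' @param order AR model order (< length(segment); order 0 models white
#'   noise).
#' @return object of class `ar_model`: list with `order`, `phi` (AR
#'   coefficients), `noise_var`, `reflection` (per-stage coefficients),
#'   `stable` (logical) and `mean` (the subtracted level).
#' @export
burg_ar <- function(segment, order = 16L) {
  x <- as.numeric(segment)
  n <- length(x)
  order <- as.integer(order)
  if (order < 0L) stop("order must be >= 0", call. = FALSE)
  if (n <= order) {
    stop("segment length (", n, ") must exceed the AR order (", order, ")",
         call. = FALSE)
  }
  mu <- mean(x)
  x <- x - mu
  e <- sum(x^2) / n
  if (e == 0) {
    return(structure(list(order = order, phi = numeric(order), noise_var = 0,
                          reflection = numeric(order), stable = TRUE, mean = mu),
                     class = "ar_model"))
  }
  f <- x
  b <- x
  a <- numeric(0)
  k_all <- numeric(order)
  len <- n
  e0 <- e
  for (m in seq_len(order)) {
    # an exactly predictable segment (noise-free sinusoid) collapses the
    # prediction error to round-off before the requested order is reached;
    # fitting further stages to that noise floor stacks spurious poles, so
    # stop and leave the remaining reflection coefficients at zero
    if (e <= 1e-12 * e0) {
      a <- c(a, numeric(order - m + 1L))
      break
    }
    ff <- f[2:len]
    bb <- b[1:(len - 1L)]
    den <- sum(ff^2) + sum(bb^2)
    k <- if (den > 0) -2 * sum(ff * bb) / den else 0
    # |k| <= 1 by Cauchy-Schwarz. Exactly predictable segments (pure
    # sinusoids) drive |k| -> 1, putting spectral poles so close to the
    # unit circle that |A(e^{-iw})|^2 is lost to cancellation; the cap
    # keeps peak widths representable in double precision while leaving
    # any realistic (noisy) fit untouched. Band power is insensitive to
    # the cap because a resonance's area, not its width, carries it.
    k <- max(min(k, 1 - 1e-5), -(1 - 1e-5))
    k_all[m] <- k
    a <- c(a + k * rev(a), k)
    f <- ff + k * bb
    b <- bb + k * ff
    len <- len - 1L
    e <- e * (1 - k^2)
  }
  structure(list(order = order, phi = -a, noise_var = max(e, 0),
                 reflection = k_all, stable = all(abs(k_all) < 1), mean = mu),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> Burg AR(%d), innovation variance %.4g%s\n",
              x$order, x$noise_var, if (x$stable) "" else " [UNSTABLE]"))
  invisible(x)
}

# PSD values on a frequency grid given phi, noise_var, sampling step dt and a
# precomputed complex matrix E = exp(-2i*pi*dt*outer(freqs, 1:order)).
.ar_psd_values <- function(phi, noise_var, dt, E) {
  if (noise_var == 0) return(numeric(nrow(E)))
  den <- 1 - as.vector(E %*% phi)
  2 * noise_var * dt / (Mod(den)^2)
}

.psd_on <- function(phi, noise_var, dt, freqs) {
  E <- exp(-2i * pi * dt * outer(freqs, seq_along(phi)))
  .ar_psd_values(phi, noise_var, dt, E)
}

# Inverse Levinson (step-down) recursion: reflection coefficients from AR
# coefficients. Returns NULL when the polynomial is not minimum-phase.
.stepdown_k <- function(phi) {
  cc <- -phi
  p <- length(cc)
  ks <- numeric(p)
  for (m in p:1) {
    k <- cc[m]
    ks[m] <- k
    if (abs(k) >= 1) return(NULL)
    if (m > 1) cc <- (cc[1:(m - 1)] - k * rev(cc[1:(m - 1)])) / (1 - k^2)
  }
  ks
}

# An exactly predictable segment can leave spectral poles within ~1e-10 of
# the unit circle, where |A(e^{-iw})|^2 is pure cancellation noise and no
# quadrature can recover the line's area. Pull such poles radially out to a
# width representable in double precision and rescale the innovation
# variance so the model's implied total power (which the lattice identity
# fixes at the fitted segment's variance) is unchanged: line areas are
# preserved, line widths are floored at ~delta in angular frequency.
.condition_model <- function(model, delta = 1e-8) {
  phi <- model$phi
  if (model$noise_var == 0 || !length(phi) || all(phi == 0)) return(model)
  rts <- tryCatch(polyroot(c(1, -phi)), error = function(e) NULL)
  if (is.null(rts)) return(model)
  rho <- Mod(rts)
  if (all(rho >= 1 + delta)) return(model)
  implied_var <- model$noise_var / prod(1 - model$reflection^2)
  rts <- rts * ifelse(rho < 1 + delta, (1 + delta) / rho, 1)
  co <- 1
  for (x0 in rts) co <- c(co, 0) - c(0, co) / x0
  # polyroot drops trailing zero coefficients; restore the nominal order
  phi_adj <- c(-Re(co[-1]), numeric(length(phi) - (length(co) - 1L)))
  ks <- .stepdown_k(phi_adj)
  if (is.null(ks)) return(model)
  model$phi <- phi_adj
  model$noise_var <- implied_var * prod(1 - ks^2)
  model$reflection <- ks
  model
}

# Spectral peaks of a near-singular AR model can be orders of magnitude
# narrower than any fixed frequency grid (a noise-free sinusoid puts the
# pole essentially on the unit circle). For every sharp pole this returns
# extra grid points tangent-spaced across the peak so that trapezoidal
# integration captures its full (finite) area.
.refine_freqs <- function(model, rate, base_df, npts = 401L) {
  phi <- model$phi
  if (model$noise_var == 0 || all(phi == 0)) return(numeric(0))
  roots <- tryCatch(polyroot(c(1, -phi)), error = function(e) complex(0))
  extra <- numeric(0)
  for (x in roots) {
    f_peak <- abs(Arg(x)) * rate / (2 * pi)   # 0 (DC drift) and Nyquist included
    w <- max(Mod(x) - 1, 1e-13) * rate / (2 * pi)   # half-width in Hz
    if (w < 5 * base_df) {
      loc <- f_peak + w * tan(seq(-pi / 2 + 1e-3, pi / 2 - 1e-3, length.out = npts))
      extra <- c(extra, loc[loc > 0 & loc < rate / 2])
    }
  }
  extra
}

#' One-sided power spectral density of a fitted AR model
#'
#' `psd(f) = 2 * noise_var * dt / |1 - sum_k phi_k exp(-2i pi f k dt)|^2`
#' with `dt = 1/rate`. The factor 2 makes the one-sided convention hold:
#' the integral of the PSD over `[0, rate/2]` equals the process variance.
#'
#' @param model an [burg_ar()] fit.
#' @param rate sampling rate of the underlying series in Hz.
#' @param freqs frequency grid in Hz; default 1024 points on `[0, rate/2]`.
#' @return object of class `spectral_frame`: list with `freqs` (Hz), `psd`
#'   (ms^2/Hz) and `rate`.
#' @export
ar_psd <- function(model, rate, freqs = NULL) {
  stopifnot(inherits(model, "ar_model"))
  if (!model$stable) {
    stop("unstable AR model (reflection coefficients: ",
         paste(signif(model$reflection, 3), collapse = ", "), ")", call. = FALSE)
  }
  model <- .condition_model(model)
  if (is.null(freqs)) {
    freqs <- seq(0, rate / 2, length.out = 1024L)
    freqs <- sort(c(freqs, .refine_freqs(model, rate, freqs[2] - freqs[1])))
    freqs <- freqs[c(TRUE, diff(freqs) > 0)]
  }
  if (any(freqs < 0) || any(freqs > rate / 2 + .t_eps)) {
    stop("frequencies must lie within [0, rate/2]", call. = FALSE)
  }
  structure(list(freqs = freqs,
                 psd = .psd_on(model$phi, model$noise_var, 1 / rate, freqs),
                 rate = rate, t_end = NA_real_),
            class = "spectral_frame")
}

#' @export
print.spectral_frame <- function(x, ...) {
  cat(sprintf("<spectral_frame> %d frequencies on [0, %.4g] Hz\n",
              length(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Integrate spectral power over a frequency band
#'
#' Trapezoidal integral of the PSD over `[f_lo, f_hi]`, with the PSD
#' linearly interpolated at the band edges so the result does not depend on
#' whether an edge falls on a grid point. Adjacent bands that share an edge
#' (such as LF ending and HF beginning at 0.15 Hz) therefore partition the
#' spectrum without double counting.
#'
#' @param frame a `spectral_frame` from [ar_psd()].
#' @param band numeric length-2, `c(f_lo, f_hi)` in Hz with `f_lo < f_hi`.
#' @return band power in ms^2.
#' @export
band_power <- function(frame, band) {
  stopifnot(inherits(frame, "spectral_frame"))
  if (length(band) != 2L || band[1] >= band[2]) {
    stop("band must be c(f_lo, f_hi) with f_lo < f_hi", call. = FALSE)
  }
  f <- frame$freqs
  p <- frame$psd
  if (band[1] < min(f) - .t_eps || band[2] > max(f) + .t_eps) {
    stop("band must lie within the spectral frame's frequency range", call. = FALSE)
  }
  lo <- max(band[1], min(f))
  hi <- min(band[2], max(f))
  inside <- f > lo & f < hi
  fi <- c(lo, f[inside], hi)
  pi_ <- c(stats::approx(f, p, xout = lo)$y, p[inside], stats::approx(f, p, xout = hi)$y)
  sum(diff(fi) * (pi_[-length(pi_)] + pi_[-1]) / 2)
}

#' LF/HF spectral trend from a sliding maximum-entropy analysis
#'
#' Every `step_s` seconds, the preceding `window_s` seconds of the uniform
#' tachogram are mean-subtracted, fitted with [burg_ar()], and the one-sided
#' AR spectrum is integrated over the LF and HF bands. Heart rate is the
#' window-mean R-R converted to beats/min. The first frame is emitted
#' `window_s` seconds after the tachogram starts; frames are stamped with
#' their window END time, so the frame at `t` summarises `(t - window_s, t]`.
#'
#' @param tach a [resample_tachogram()] result.
#' @param window_s analysis window length in s (default 30).
#' @param step_s trend step in s (default 2).
#' @param order Burg AR order (default 16).
#' @param lf_band,hf_band integration bands in Hz (defaults 0.04-0.15 and
#'   0.15-0.4).
#' @param nfreq PSD grid resolution (default 1024 points on `[0, rate/2]`).
#' @return object of class `hrv_trend`: a `data.frame` with columns `t`
#'   (s), `lf` (ms^2), `hf` (ms^2), `lfhf` (NA where HF power is 0) and
#'   `hr` (beats/min).
#' @export
sliding_trend <- function(tach, window_s = 30, step_s = 2, order = 16L,
                          lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                          nfreq = 1024L) {
  stopifnot(inherits(tach, "tachogram"))
  rate <- tach$rate
  nv <- length(tach$values)
  span <- nv / rate
  if (span < window_s) {
    stop("tachogram spans ", round(span, 1), " s < window of ", window_s, " s",
         call. = FALSE)
  }
  if (hf_band[2] > rate / 2 + .t_eps) {
    stop("HF band extends beyond the tachogram Nyquist frequency (",
         signif(rate / 2, 4), " Hz)", call. = FALSE)
  }
  tt <- tach$t_start + (seq_len(nv) - 1L) / rate
  t_ends <- seq(tach$t_start + window_s, tach$t_start + span + .t_eps, by = step_s)
  freqs <- seq(0, rate / 2, length.out = nfreq)
  dt <- 1 / rate
  E <- exp(-2i * pi * dt * outer(freqs, seq_len(order)))
  frame <- structure(list(freqs = freqs, psd = NULL, rate = rate, t_end = NA_real_),
                     class = "spectral_frame")
  res <- matrix(NA_real_, length(t_ends), 4L,
                dimnames = list(NULL, c("lf", "hf", "lfhf", "hr")))
  zero_hf <- FALSE
  base_df <- freqs[2] - freqs[1]
  for (i in seq_along(t_ends)) {
    te <- t_ends[i]
    w <- tach$values[tt > te - window_s - .t_eps & tt <= te + .t_eps]
    fit <- .condition_model(burg_ar(w, order = order))
    psd <- .ar_psd_values(fit$phi, fit$noise_var, dt, E)
    extra <- .refine_freqs(fit, rate, base_df)
    if (length(extra)) {
      fa <- c(freqs, extra)
      pa <- c(psd, .psd_on(fit$phi, fit$noise_var, dt, extra))
      ord <- order(fa)
      fa <- fa[ord]; pa <- pa[ord]
      keep <- c(TRUE, diff(fa) > 0)
      frame$freqs <- fa[keep]
      frame$psd <- pa[keep]
    } else {
      frame$freqs <- freqs
      frame$psd <- psd
    }
    lf <- band_power(frame, lf_band)
    hf <- band_power(frame, hf_band)
    res[i, "lf"] <- lf
    res[i, "hf"] <- hf
    if (hf > 0) res[i, "lfhf"] <- lf / hf else zero_hf <- TRUE
    res[i, "hr"] <- 60000 / mean(w)
  }
  if (zero_hf) warning("HF power is 0 in some frames; LF/HF recorded as missing there")
  out <- data.frame(t = t_ends, res)
  structure(out, class = c("hrv_trend", "data.frame"),
            window_s = window_s, step_s = step_s, order = order,
            lf_band = lf_band, hf_band = hf_band, rate = rate)
}

#' @export
print.hrv_trend <- function(x, ...) {
  cat(sprintf("<hrv_trend> %d frames, t = %.0f..%.0f s (window %g s, step %g s, AR order %d)\n",
              nrow(x), min(x$t), max(x$t), attr(x, "window_s"), attr(x, "step_s"),
              attr(x, "order")))
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE)
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
plot.hrv_trend <- function(x, ...) {
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$lf, type = "l", xlab = "", ylab = "LF (ms²)", ...)
  graphics::plot(x$t, x$hf, type = "l", xlab = "", ylab = "HF (ms²)", ...)
  graphics::plot(x$t, x$lfhf, type = "l", xlab = "", ylab = "LF/HF", ...)
  graphics::plot(x$t, x$hr, type = "l", xlab = "time (s)", ylab = "HR (/min)", ...)
  invisible(x)
}

#' Write an HRV trend to CSV
#'
#' Columns `t_s, lf_ms2, hf_ms2, lf_hf, hr_bpm`; missing LF/HF is written
#' as an empty cell.
#'
#' @param trend an `hrv_trend`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trend <- function(trend, path) {
  stopifnot(inherits(trend, "hrv_trend"))
  dat <- data.frame(t_s = sprintf("%.2f", trend$t),
                    lf_ms2 = sprintf("%.6f", trend$lf),
                    hf_ms2 = sprintf("%.6f", trend$hf),
                    lf_hf = ifelse(is.na(trend$lfhf), "", sprintf("%.6f", trend$lfhf)),
                    hr_bpm = sprintf("%.6f", trend$hr))
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
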