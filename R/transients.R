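#' Segment a cell-shortening trace into beats
#'
#' Detects contraction onsets in a cell-length trace recorded under
#' continuous field stimulation (1 Hz by default) and returns one window
#' per detected beat. Onset is the crossing of 10 percent of the beat
#' amplitude on the falling (shortening) phase, after smoothing with a
#' 5-sample moving average; both conventions are arguments. Windows run
#' from one onset (minus a small pre-onset margin for the baseline
#' estimate) to the next onset.
#'
#' @param trace Data frame with columns `time_s` (strictly increasing,
#'   uniformly sampled within 1 percent) and `length_um`.
#' @param stimulus_rate Stimulation rate in Hz (default 1).
#' @param onset_frac Fraction of beat amplitude defining onset (0.10).
#' @param smooth Moving-average window in samples (5).
#' @return Tibble with one row per beat: `beat`, `onset_time`,
#'   `start_time`, `end_time`. Warns when fewer beats than stimulus
#'   periods are found (missed beats) or when onset spacing is
#'   arrhythmic (CV > 20 percent).
#' @export
segment_beats <- function(trace, stimulus_rate = 1, onset_frac = 0.10,
                          smooth = 5L) {
  t <- trace$time_s
  y <- trace$length_um
  if (is.unsorted(t, strictly = TRUE)) {
    abort("Trace time must be strictly increasing.")
  }
  dt <- diff(t)
  if (max(dt) / min(dt) > 1.02) {
    warn("Trace sampling is non-uniform beyond 1%; results may be biased.")
  }
  ys <- moving_average(y, smooth)
  base <- quantile(ys, 0.9, names = FALSE)   # resting length
  floor_ <- quantile(ys, 0.02, names = FALSE)  # typical peak shortening
  amp <- base - floor_
  if (amp <= max(6 * sd(diff(ys)), 1e-6)) {
    abort("No detectable beats: trace is flat relative to its noise.")
  }
  thr <- base - onset_frac * amp
  arm_level <- base - 0.3 * onset_frac * amp
  below <- ys < thr
  crossings <- which(!below[-length(below)] & below[-1]) + 1L
  # hysteresis: a crossing only counts after the trace has re-armed near
  # baseline, so noise wiggles on the relaxation limb are ignored; also
  # enforce refractory spacing of half a stimulus period
  period <- 1 / stimulus_rate
  onsets <- integer(0)
  last_t <- -Inf
  last_i <- 1L
  for (i in crossings) {
    armed <- any(ys[last_i:i] > arm_level)
    if (armed && t[i] - last_t >= 0.5 * period) {
      onsets <- c(onsets, i)
      last_t <- t[i]
      last_i <- i
    }
  }
  if (length(onsets) < 3L) {
    abort("Fewer than 3 beats detected; cannot analyse this trace.")
  }
  expected <- round((max(t) - min(t)) / period)
  if (length(onsets) < expected) {
    warn(paste0("Detected ", length(onsets), " beats where ~", expected,
                " stimulus periods elapsed; possible missed beats."))
  }
  gaps <- diff(t[onsets])
  if (length(gaps) >= 2 && sd(gaps) / mean(gaps) > 0.2) {
    warn("Arrhythmic beat spacing: CV of onset intervals exceeds 20%.")
  }
  onset_time <- t[onsets]
  margin <- 0.15 * period
  tibble(
    beat = seq_along(onsets),
    onset_time = onset_time,
    start_time = pmax(min(t), onset_time - margin),
    end_time = c(onset_time[-1] - margin, max(t))
  )
}

moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) |>
    (\(z) { z[is.na(z)] <- x[is.na(z)]; z })()
}

#' Contractility features of one beat
#'
#' From a single beat window: resting length `L0` (median of pre-onset
#' samples), shortening amplitude as percent of `L0`, time from onset to
#' 90 percent of peak shortening (`ttp90`) and time from the peak to
#' recovery of 90 percent of the shortening amplitude back toward
#' baseline (`ttb90`); crossing times are linearly interpolated between
#' samples.
#'
#' @param trace Trace data frame (`time_s`, `length_um`).
#' @param onset_time,start_time,end_time One beat window as produced by
#'   [segment_beats()].
#' @param smooth Moving-average window (samples) applied to the beat
#'   before measuring (3 by default; kept narrow so the asymmetric
#'   rise/decay around the peak is not skewed).
#' @return One-row tibble: `L0`, `amplitude_pct`, `ttp90`, `ttb90`
#'   (seconds; `NA` when the beat does not recover within its window).
#' @export
beat_features <- function(trace, onset_time, start_time, end_time,
                          smooth = 3L) {
  w <- trace[trace$time_s >= start_time & trace$time_s <= end_time, ]
  w$length_um <- moving_average(w$length_um, smooth)
  pre <- w$length_um[w$time_s < onset_time]
  if (length(pre) < 2L) abort("Beat window has no pre-onset baseline.")
  L0 <- median(pre)
  post <- w[w$time_s >= onset_time, ]
  ipk <- which.min(post$length_um)
  peak_len <- post$length_um[ipk]
  peak_time <- post$time_s[ipk]
  if (ipk > 1L && ipk < nrow(post)) {
    # parabolic vertex through the three samples around the minimum
    # removes the sampling-grid quantisation of the peak time
    y0 <- post$length_um[ipk - 1L]; y1 <- peak_len
    y2 <- post$length_um[ipk + 1L]
    den <- y0 - 2 * y1 + y2
    if (den > 0) {
      delta <- 0.5 * (y0 - y2) / den
      dt <- post$time_s[ipk + 1L] - post$time_s[ipk]
      peak_time <- peak_time + delta * dt
      peak_len <- y1 - 0.25 * (y0 - y2) * delta
    }
  }
  amp <- L0 - peak_len
  if (amp <= 0) abort("Beat has no shortening below baseline.")
  # ttp90: first crossing of 90% of peak shortening on the falling phase
  target_p <- L0 - 0.9 * amp
  fall <- post[seq_len(ipk), ]
  t90p <- first_crossing(fall$time_s, fall$length_um, target_p,
                         direction = "down")
  ttp90 <- t90p - onset_time
  # ttb90: from peak, recovery of 90% of the amplitude toward L0
  target_b <- peak_len + 0.9 * amp
  rise <- post[ipk:nrow(post), ]
  t90b <- first_crossing(rise$time_s, rise$length_um, target_b,
                         direction = "up")
  ttb90 <- if (is.na(t90b)) NA_real_ else t90b - peak_time
  tibble(L0 = L0, amplitude_pct = 100 * amp / L0,
         ttp90 = ttp90, ttb90 = ttb90)
}

first_crossing <- function(t, y, target, direction = c("down", "up")) {
  direction <- match.arg(direction)
  hit <- if (direction == "down") y <= target else y >= target
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t[1])
  # linear interpolation between samples i-1 and i
  t[i - 1L] + (target - y[i - 1L]) * (t[i] - t[i - 1L]) / (y[i] - y[i - 1L])
}

#' Per-cell contractility features
#'
#' Segments a trace and reduces the accepted beats to one row per cell:
#' the median over beats of `L0`, `amplitude_pct`, `ttp90` and `ttb90`
#' (robust to one aberrant beat in a 10-s record).
#'
#' @inheritParams segment_beats
#' @return One-row tibble of median features plus `n_beats`.
#' @export
transient_features <- function(trace, stimulus_rate = 1, onset_frac = 0.10,
                               smooth = 5L) {
  beats <- segment_beats(trace, stimulus_rate = stimulus_rate,
                         onset_frac = onset_frac, smooth = smooth)
  feats <- purrr::pmap_dfr(
    beats[, c("onset_time", "start_time", "end_time")],
    function(onset_time, start_time, end_time) {
      tryCatch(
        beat_features(trace, onset_time, start_time, end_time),
        error = function(e) tibble(L0 = NA_real_, amplitude_pct = NA_real_,
                                   ttp90 = NA_real_, ttb90 = NA_real_)
      )
    }
  )
  feats |>
    summarise(across(c("L0", "amplitude_pct", "ttp90", "ttb90"),
                     ~ median(.x, na.rm = TRUE))) |>
    mutate(n_beats = nrow(beats))
}

#' Lusitropy statistic
#'
#' Fractional shortening of the relaxation time due to dobutamine:
#' `1 - ttb90(dobutamine) / ttb90(baseline)`. Positive values mean faster
#' relaxation (lusitropy present); values near zero or negative mean the
#' lusitropic response is absent.
#'
#' @param ttb90_pre,ttb90_dob Relaxation times (s) before and during
#'   dobutamine; both must be positive. Vectorised.
#' @return Numeric lusitropy value(s), always < 1.
#' @examples
#' lusitropy(0.50, 0.395)  # 0.21: a 21% faster relaxation
#' @export
lusitropy <- function(ttb90_pre, ttb90_dob) {
  if (any(ttb90_pre <= 0) || any(ttb90_dob <= 0)) {
    abort("ttb90 values must be positive.")
  }
  1 - ttb90_dob / ttb90_pre
}

#' Paired dobutamine response over cells
#'
#' Per-cell deltas (dobutamine minus baseline) of amplitude, ttp90 and
#' ttb90 plus the per-cell lusitropy, summarised as mean, SEM and a
#' two-tailed paired t-test with two-level star coding (* p < 0.05,
#' ** p < 0.01).
#'
#' @param data Data frame with one row per cell x treatment: columns
#'   `cell_id`, `treatment` (`"baseline"` / `"dobutamine"`),
#'   `amplitude_pct`, `ttp90`, `ttb90`.
#' @return Tibble with one row per measure (`amplitude_pct`, `ttp90`,
#'   `ttb90`, `lusitropy`): `n`, `mean`, `sem`, `p_value`, `stars`.
#' @export
paired_response <- function(data) {
  wide <- data |>
    select(dplyr::all_of(c("cell_id", "treatment", "amplitude_pct",
                           "ttp90", "ttb90"))) |>
    tidyr::pivot_wider(names_from = "treatment",
                       values_from = c("amplitude_pct", "ttp90", "ttb90"))
  need <- c("amplitude_pct_baseline", "amplitude_pct_dobutamine",
            "ttp90_baseline", "ttp90_dobutamine",
            "ttb90_baseline", "ttb90_dobutamine")
  miss <- setdiff(need, names(wide))
  if (length(miss)) {
    abort(paste0("Missing paired measurements: ",
                 paste(miss, collapse = ", ")))
  }
  unpaired <- wide$cell_id[!complete.cases(wide[, need])]
  if (length(unpaired)) {
    abort(paste0("Cells without both treatments: ",
                 paste(unpaired, collapse = ", ")))
  }
  if (nrow(wide) < 3L) abort("Paired analysis needs at least 3 cells.")
  one <- function(post, pre, label, values) {
    if (missing(values)) values <- post - pre
    pv <- if (sd(values) == 0) {
      if (mean(values) == 0) 1 else 0
    } else {
      t.test(post, pre, paired = TRUE)$p.value
    }
    tibble(measure = label, n = length(values), mean = mean(values),
           sem = sd(values) / sqrt(length(values)), p_value = pv,
           stars = stars2(pv))
  }
  lus <- lusitropy(wide$ttb90_baseline, wide$ttb90_dobutamine)
  bind_rows(
    one(wide$amplitude_pct_dobutamine, wide$amplitude_pct_baseline,
        "amplitude_pct"),
    one(wide$ttp90_dobutamine, wide$ttp90_baseline, "ttp90"),
    one(wide$ttb90_dobutamine, wide$ttb90_baseline, "ttb90"),
    one(lus, rep(0, length(lus)), "lusitropy", values = lus)
  )
}

stars2 <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Plot a shortening trace with detected beats
#'
#' @param trace Trace data frame (`time_s`, `length_um`).
#' @param beats Optional [segment_beats()] output; computed when NULL.
#' @param ... Passed to [segment_beats()].
#' @return A ggplot object.
#' @export
plot_transient <- function(trace, beats = NULL, ...) {
  if (is.null(beats)) beats <- segment_beats(trace, ...)
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s,
                                      y = .data$length_um)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = beats,
                        ggplot2::aes(xintercept = .data$onset_time),
                        colour = "firebrick", linetype = 3) +
    ggplot2::labs(x = "Time (s)", y = "Cell length (um)") +
    ggplot2::theme_minimal()
}
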