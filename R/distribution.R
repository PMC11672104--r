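#' Distribution summary of a metric series
#'
#' Reduces pooled per-frame metric samples to the summary used in the
#' trajectory-metric tables: sample mean and standard deviation, full
#' width at half maximum (FWHM) of a kernel density estimate, and the
#' percentage of samples strictly above a threshold (e.g. the 110-degree
#' open-state boundary of the helix A/B angle).
#'
#' FWHM uses a Gaussian-kernel density with Scott bandwidth on a
#' 1024-point grid spanning `[min - 3h, max + 3h]`; only the half-height
#' crossings flanking the global-maximum peak are used (main-peak
#' convention, needed for multimodal distributions), located by linear
#' interpolation. The percentage above threshold is computed on the raw
#' samples, not on the density, so it is estimator-free.
#'
#' @param data Data frame of samples (or a bare numeric vector).
#' @param value Column holding the samples (tidy-eval); default `value`.
#' @param threshold Optional threshold for `pct_above` (same units as the
#'   samples); `NA` skips it.
#' @return One-row tibble: `n`, `mean`, `sd`, `fwhm`, `pct_above`
#'   (percent, 0-100 or `NA`), `threshold`. The KDE grid is attached as
#'   attribute `"density"` (tibble `x`, `y`) for plotting.
#' @examples
#' set.seed(1)
#' summarize_distribution(tibble::tibble(value = rnorm(5000, 101.8, 9.15)),
#'                        threshold = 110)
#' @export
summarize_distribution <- function(data, value = value, threshold = NA) {
  if (is.numeric(data)) {
    x <- data
  } else {
    x <- dplyr::pull(data, {{ value }})
  }
  x <- x[is.finite(x)]
  if (length(x) < 10L) {
    abort("summarize_distribution() needs at least 10 finite samples.")
  }
  if (sd(x) == 0) {
    abort("All samples identical: density (and FWHM) are degenerate.")
  }
  h <- stats::bw.nrd(x)  # Scott's rule
  den <- density(x, bw = h, n = 1024L, from = min(x) - 3 * h,
                 to = max(x) + 3 * h)
  out <- tibble(
    n = length(x),
    mean = mean(x),
    sd = sd(x),
    fwhm = kde_fwhm(den$x, den$y),
    pct_above = if (is.na(threshold)) NA_real_ else 100 * mean(x > threshold),
    threshold = as.numeric(threshold)
  )
  attr(out, "density") <- tibble(x = den$x, y = den$y)
  out
}

# width at half of the global-maximum peak height, linear interpolation
kde_fwhm <- function(x, y) {
  ipk <- which.max(y)
  half <- y[ipk] / 2
  cross <- function(side) {
    idx <- if (side == "left") seq(ipk, 1L) else seq(ipk, length(y))
    below <- which(y[idx] < half)
    if (length(below) == 0L) return(x[idx[length(idx)]])
    j <- below[1]
    i1 <- idx[j - 1L]; i2 <- idx[j]
    x[i1] + (half - y[i1]) * (x[i2] - x[i1]) / (y[i2] - y[i1])
  }
  abs(cross("right") - cross("left"))
}

#' Phosphorylation delta between two distribution summaries
#'
#' Differences phosphorylated minus unphosphorylated (the fixed sign
#' convention of the metric tables) for mean, FWHM and percent-above.
#'
#' @param unp,p One-row summaries from [summarize_distribution()] for the
#'   unphosphorylated and phosphorylated states of the same metric (same
#'   units; the thresholds, when present, must agree).
#' @return One-row tibble: `delta_mean`, `delta_fwhm`, `delta_pct_above`,
#'   plus the component means for reporting.
#' @export
phospho_delta <- function(unp, p) {
  if (!identical(is.na(unp$threshold), is.na(p$threshold)) ||
      (!is.na(unp$threshold) && unp$threshold != p$threshold)) {
    abort("Summaries use different thresholds; not comparable.")
  }
  tibble(
    mean_unp = unp$mean, mean_p = p$mean,
    delta_mean = p$mean - unp$mean,
    delta_fwhm = p$fwhm - unp$fwhm,
    delta_pct_above = p$pct_above - unp$pct_above
  )
}

#' Recoupling call from wild-type and candidate phosphorylation deltas
#'
#' A candidate condition "restores" the wild-type phosphorylation
#' response when its delta has the same sign as the wild-type delta and
#' exceeds a dead-band in magnitude. The dead-band guards against calling
#' near-zero changes restored; defaults are 0.5 degrees for angles,
#' 0.25 Angstrom for distances and 1 percentage point for percent-above.
#'
#' @param wt_delta,candidate_delta Scalar deltas (same metric, same sign
#'   convention: phosphorylated minus unphosphorylated).
#' @param dead_band Non-negative magnitude below which a candidate delta
#'   is treated as no change.
#' @return One-row tibble: `wt_delta`, `candidate_delta`, `wt_sign`,
#'   `candidate_sign`, `restored` (logical).
#' @export
classify_recoupling <- function(wt_delta, candidate_delta, dead_band = 0.5) {
  if (dead_band < 0) abort("dead_band must be non-negative.")
  restored <- sign(candidate_delta) == sign(wt_delta) &
    abs(candidate_delta) > dead_band
  tibble(
    wt_delta = wt_delta,
    candidate_delta = candidate_delta,
    wt_sign = sign(wt_delta),
    candidate_sign = sign(candidate_delta),
    restored = restored
  )
}

#' Summarize a long metric table into table-shaped rows
#'
#' Convenience wrapper: takes a long tibble of pooled per-frame values
#' for several conditions x phosphorylation states, summarizes each cell,
#' computes phosphorylation deltas and recoupling calls against the
#' wild-type row.
#'
#' @param data Long tibble with columns `condition` (e.g. troponin x
#'   ligand label), `phospho` (`"uP"` or `"P"`), `value`.
#' @param threshold Optional percent-above threshold passed to
#'   [summarize_distribution()].
#' @param wt Condition label to use as the wild-type reference.
#' @param dead_band Dead-band for [classify_recoupling()].
#' @return Tibble with one row per condition: uP and P mean (sd), deltas,
#'   FWHM triplet, percent-above triplet and `restored` flag (NA for the
#'   wild-type reference row).
#' @export
metric_table <- function(data, threshold = NA, wt = "WT apo",
                         dead_band = 0.5) {
  cells <- data |>
    group_by(.data$condition, .data$phospho) |>
    dplyr::group_modify(~ summarize_distribution(.x, threshold = threshold)) |>
    ungroup()
  wide <- cells |>
    tidyr::pivot_wider(names_from = "phospho",
                       values_from = c("n", "mean", "sd", "fwhm", "pct_above"),
                       id_cols = "condition")
  if (!wt %in% wide$condition) {
    abort(paste0("Wild-type reference condition '", wt, "' not present."))
  }
  wide <- wide |>
    mutate(
      delta_mean = .data$mean_P - .data$mean_uP,
      delta_fwhm = .data$fwhm_P - .data$fwhm_uP,
      delta_pct_above = .data$pct_above_P - .data$pct_above_uP
    )
  wt_delta <- wide$delta_mean[wide$condition == wt]
  wide |>
    mutate(
      restored = ifelse(
        .data$condition == wt, NA,
        classify_recoupling(wt_delta, .data$delta_mean,
                            dead_band = dead_band)$restored
      ),
      threshold = as.numeric(threshold)
    )
}
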