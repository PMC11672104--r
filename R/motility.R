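#' Fit a four-parameter Hill activation curve
#'
#' Least-squares fit of the Hill model
#' \deqn{f = f_{min} + (f_{max} - f_{min}) / (1 + (EC_{50}/[Ca])^{n_H})}
#' to fraction-motile versus calcium-concentration data, parameterised on
#' log-EC50 and fitted on log-concentration (Levenberg-Marquardt via
#' minpack.lm). EC50 is reported in the concentration units of the input
#' (micromolar throughout this package).
#'
#' @param data Data frame of one activation curve.
#' @param ca,response Columns (tidy-eval) holding calcium concentration
#'   (> 0, in uM) and fraction motile; defaults `ca_um`,
#'   `fraction_motile`.
#' @param ca_units Unit label recorded on the fit (used to refuse
#'   ratios across mismatched units); default `"uM"`.
#' @return An object of class `hill_fit` with elements `ec50`, `n_h`,
#'   `f_min`, `f_max`, `rss`, `se` (named standard errors), `fit` (the
#'   nls object), `data`, `ca_units`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @details At least 5 distinct concentrations are required. A curve
#'   whose span does not bracket the fitted EC50 triggers a warning (the
#'   fit is extrapolating); a flat curve (no resolvable amplitude) is a
#'   non-convergence error.
#' @examples
#' curves <- simulate_activation_curves(ec50_unp = 0.059, ratio = 2.24,
#'                                      noise_sd = 0, seed = 1)
#' fit <- fit_hill(dplyr::filter(curves, phospho == "uP"))
#' glance(fit)
#' @export
fit_hill <- function(data, ca = ca_um, response = fraction_motile,
                     ca_units = "uM") {
  df <- tibble(
    ca = dplyr::pull(data, {{ ca }}),
    f = dplyr::pull(data, {{ response }})
  )
  df <- df[complete.cases(df), ]
  if (any(df$ca <= 0)) abort("Calcium concentrations must be positive.")
  if (length(unique(df$ca)) < 5L) {
    abort("Hill fitting needs at least 5 distinct concentrations.")
  }
  span <- diff(range(df$f))
  if (span < 1e-3) {
    abort("Hill fit did not converge: flat curve (no activation range).")
  }
  lca <- log(df$ca)
  # starting values: plateaus from the data, EC50 at half-range crossing
  f0 <- min(df$f); f1 <- max(df$f)
  half <- (f0 + f1) / 2
  ord <- order(lca)
  start_lec50 <- approx(df$f[ord], lca[ord], xout = half, ties = mean)$y
  if (!is.finite(start_lec50)) start_lec50 <- median(lca)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ fmin + (fmax - fmin) / (1 + exp(nh * (lec50 - lca))),
      data = data.frame(f = df$f, lca = lca),
      start = list(fmin = f0, fmax = f1, lec50 = start_lec50, nh = 1.5),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort(paste0("Hill fit did not converge: ",
                                     conditionMessage(e)))
  )
  cf <- coef(fit)
  ec50 <- exp(cf[["lec50"]])
  if (!is.finite(ec50) || ec50 <= 0) {
    abort("Hill fit did not converge: non-positive fitted EC50.")
  }
  if (ec50 < min(df$ca) || ec50 > max(df$ca)) {
    warn(paste0("Fitted EC50 (", signif(ec50, 3),
                " ", ca_units, ") lies outside the measured ",
                "concentration span; the fit extrapolates."))
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   setNames(rep(NA_real_, 4),
                            c("fmin", "fmax", "lec50", "nh")))
  structure(
    list(
      ec50 = ec50,
      n_h = cf[["nh"]],
      f_min = cf[["fmin"]],
      f_max = cf[["fmax"]],
      rss = sum(resid(fit)^2),
      se = se,
      fit = fit,
      data = df,
      ca_units = ca_units
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit> EC50 = ", signif(x$ec50, 4), " ", x$ca_units,
      ", n_H = ", signif(x$n_h, 3),
      ", f = [", signif(x$f_min, 3), ", ", signif(x$f_max, 3), "]\n",
      sep = "")
  invisible(x)
}

#' @rdname fit_hill
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  est <- c(ec50 = x$ec50, n_h = x$n_h, f_min = x$f_min, f_max = x$f_max)
  se <- c(x$se[["lec50"]] * x$ec50,  # delta method for exp(lec50)
          x$se[["nh"]], x$se[["fmin"]], x$se[["fmax"]])
  tibble(term = names(est), estimate = unname(est), std.error = unname(se))
}

#' @rdname fit_hill
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(ec50 = x$ec50, n_h = x$n_h, f_min = x$f_min, f_max = x$f_max,
         rss = x$rss, n = nrow(x$data), ca_units = x$ca_units)
}

#' EC50 phosphorylation ratio of two Hill fits
#'
#' Ratio EC50(phosphorylated) / EC50(unphosphorylated); the coupling
#' metric of the in vitro motility assay. Both fits must share
#' concentration units.
#'
#' @param fit_p,fit_unp `hill_fit` objects for the phosphorylated and
#'   unphosphorylated curves.
#' @return Scalar ratio (full precision; round for display).
#' @export
coupling_ratio <- function(fit_p, fit_unp) {
  stopifnot(inherits(fit_p, "hill_fit"), inherits(fit_unp, "hill_fit"))
  if (!identical(fit_p$ca_units, fit_unp$ca_units)) {
    abort("EC50 ratio across different concentration units is undefined.")
  }
  fit_p$ec50 / fit_unp$ec50
}

#' Coupling call over replicate P/unP EC50 pairs
#'
#' Per-replicate ratios EC50(P)/EC50(unP), their mean and SEM (mean of
#' ratios, matching how single-replicate table rows are exact
#' divisions), a paired two-tailed t-test on log-EC50 when n >= 3, and
#' the coupling call: coupled when the mean ratio exceeds the threshold
#' (default 1.5, which separates coupled from uncoupled rows in the
#' motility data) and, when testable, p < 0.05.
#'
#' @param data Data frame with one row per replicate pair, columns
#'   `ec50_p` and `ec50_unp` (uM). Alternatively pass two numeric
#'   vectors via `ec50_p`/`ec50_unp` with `data` omitted.
#' @param ec50_p,ec50_unp Columns (tidy-eval) or numeric vectors.
#' @param threshold Mean-ratio threshold for the call.
#' @return One-row tibble: `n`, `mean_ratio`, `sem_ratio` (NA for n < 2),
#'   `p_value` (NA when untestable), `coupled`, `significance_tested`.
#'   Per-pair ratios are attached as attribute `"ratios"`.
#' @export
coupling_call <- function(data = NULL, ec50_p = ec50_p, ec50_unp = ec50_unp,
                          threshold = 1.5) {
  if (is.null(data)) {
    p <- ec50_p; u <- ec50_unp
  } else {
    p <- dplyr::pull(data, {{ ec50_p }})
    u <- dplyr::pull(data, {{ ec50_unp }})
  }
  if (length(p) != length(u)) abort("Unequal numbers of P and unP EC50s.")
  if (length(p) == 0L) abort("At least one replicate pair is required.")
  if (any(p <= 0 | u <= 0)) abort("EC50 values must be positive.")
  ratios <- p / u
  n <- length(ratios)
  mean_ratio <- mean(ratios)
  sem_ratio <- if (n >= 2) sd(ratios) / sqrt(n) else NA_real_
  testable <- n >= 3
  ld <- log(p) - log(u)
  p_value <- if (!testable) {
    NA_real_
  } else if (sd(ld) <= 1e-10 * max(abs(mean(ld)), 1)) {
    # degenerate: every replicate shifted by the same factor
    if (abs(mean(ld)) <= 1e-12) 1 else 0
  } else {
    t.test(log(p), log(u), paired = TRUE)$p.value
  }
  coupled <- mean_ratio > threshold && (!testable || p_value < 0.05)
  out <- tibble(
    n = n, mean_ratio = mean_ratio, sem_ratio = sem_ratio,
    p_value = p_value, coupled = coupled,
    significance_tested = testable
  )
  attr(out, "ratios") <- ratios
  out
}

#' Single-concentration rapid coupling screen
#'
#' Paired fraction-motile measurements at one calcium concentration,
#' phosphorylated versus unphosphorylated. The screen is positive
#' (coupling present) when the phosphorylated mean is lower than the
#' unphosphorylated mean with p < 0.05 in a paired two-tailed t-test.
#'
#' @param p,unp Paired numeric vectors of fraction motile (same length,
#'   n >= 3).
#' @param ca_um The fixed calcium concentration used (uM; recorded in the
#'   output, not hard-coded anywhere).
#' @return One-row tibble: `n`, `ca_um`, `mean_p`, `mean_unp`,
#'   `p_value`, `positive`.
#' @export
fixed_ca_screen <- function(p, unp, ca_um = NA_real_) {
  if (length(p) != length(unp)) {
    abort("Screen requires equal numbers of paired P and unP measurements.")
  }
  if (length(p) < 3L) abort("Screen requires at least 3 paired measurements.")
  if (all(p == unp)) {
    p_value <- 1
  } else {
    p_value <- t.test(p, unp, paired = TRUE)$p.value
  }
  tibble(
    n = length(p), ca_um = ca_um,
    mean_p = mean(p), mean_unp = mean(unp),
    p_value = p_value,
    positive = mean(p) < mean(unp) && p_value < 0.05
  )
}

#' @rdname fit_hill
#' @param object A `hill_fit`.
#' @export
autoplot.hill_fit <- function(object, ...) {
  grid <- tibble(
    ca = exp(seq(log(min(object$data$ca)), log(max(object$data$ca)),
                 length.out = 200))
  )
  grid$f <- object$f_min + (object$f_max - object$f_min) /
    (1 + (object$ec50 / grid$ca)^object$n_h)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ca, y = .data$f)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$ec50, linetype = 2,
                        colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0("[Ca2+] (", object$ca_units, ")"),
                  y = "Fraction motile",
                  title = paste0("Hill fit: EC50 = ",
                                 signif(object$ec50, 3), " ",
                                 object$ca_units)) +
    ggplot2::theme_minimal()
}
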