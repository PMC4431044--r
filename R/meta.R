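# Random-effects meta-analysis of log odds ratios with heterogeneity
# statistics, plus the quality-stratified sensitivity analysis: pool all
# studies, exclude those classified low quality, re-pool, and compare
# heterogeneity and precision.

#' Log odds ratio and standard error from a 2x2 table
#'
#' Woolf method: `OR = ad / bc`, `SE(log OR) = sqrt(1/a + 1/b + 1/c + 1/d)`.
#' If any cell is zero, 0.5 is added to every cell (Haldane continuity
#' correction) before both computations; tables with two or more zero
#' cells are rejected.
#'
#' @param a,b,c,d Nonnegative integer cell counts of the genotype-by-status
#'   table (a, b = exposed/unexposed cases; c, d = exposed/unexposed
#'   controls).
#' @return List with `log_or`, `se`, and `corrected` (whether the 0.5
#'   correction was applied).
#' @examples
#' effect_from_2x2(20, 10, 10, 20)  # log OR = log 4, SE = sqrt(0.3)
#' @export
effect_from_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  nzero <- sum(cells == 0)
  if (nzero >= 2) {
    stop("two or more zero cells: odds ratio not estimable", call. = FALSE)
  }
  corrected <- nzero == 1
  if (corrected) cells <- cells + 0.5
  list(log_or = log(cells[["a"]] * cells[["d"]] / (cells[["b"]] * cells[["c"]])),
       se = sqrt(sum(1 / cells)),
       corrected = corrected)
}

#' I-squared heterogeneity statistic
#'
#' Percentage of total variation across studies attributable to
#' heterogeneity rather than chance:
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100}.
#'
#' @param Q Cochran's Q statistic (>= 0).
#' @param df Degrees of freedom (number of studies minus 1, >= 1).
#' @return I-squared, percent in \[0, 100\].
#' @examples
#' i_squared(21.1, 6)  # 71.6, reported as 72
#' i_squared(3.04, 5)  # 0
#' @export
i_squared <- function(Q, df) {
  stopifnot(Q >= 0, df >= 1)
  if (Q == 0) return(0)
  max(0, (Q - df) / Q) * 100
}

#' Test-based confidence interval for I-squared
#'
#' Higgins-Thompson interval built on \eqn{H = \sqrt{Q/df}} (truncated at
#' 1): a normal interval for \eqn{\ln H} with
#' \eqn{SE(\ln H) = (\ln Q - \ln df) / (2(\sqrt{2Q} - \sqrt{2 df - 1}))}
#' when Q exceeds df and
#' \eqn{\sqrt{(1/(2(df-1))) (1 - 1/(3(df-1)^2))}} otherwise, transformed
#' to the I-squared scale by \eqn{I^2 = (H^2 - 1)/H^2} and truncated to
#' \[0, 100\].
#'
#' @inheritParams i_squared
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)`, percents.
#' @examples
#' round(i_squared_ci(21.1, 6))  # 38 87
#' round(i_squared_ci(3.04, 5))  # 0 75
#' @export
i_squared_ci <- function(Q, df, level = 0.95) {
  stopifnot(Q >= 0, level > 0, level < 1)
  if (df < 2) stop("df must be at least 2 for the test-based interval",
                   call. = FALSE)
  ln_h <- log(max(1, sqrt(Q / df)))
  se <- if (Q > df) {
    (log(Q) - log(df)) / (2 * (sqrt(2 * Q) - sqrt(2 * df - 1)))
  } else {
    sqrt(1 / (2 * (df - 1)) * (1 - 1 / (3 * (df - 1)^2)))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  h_bounds <- exp(ln_h + c(-1, 1) * z * se)
  i2 <- pmax(0, (h_bounds^2 - 1) / h_bounds^2) * 100
  pmin(pmax(i2, 0), 100)
}

#' Heterogeneity summary from a reported Q statistic
#'
#' Convenience wrapper for re-deriving the heterogeneity numbers a
#' meta-analysis reports from its Cochran Q and degrees of freedom alone:
#' the chi-square p-value, I-squared, and (when `df >= 2`) its test-based
#' confidence interval.
#'
#' @inheritParams i_squared
#' @param level Confidence level for the I-squared interval.
#' @return List with `Q`, `df`, `p_value`, `i2_percent`, `i2_ci_low`,
#'   `i2_ci_high`.
#' @examples
#' heterogeneity_from_q(21.1, 6)  # I2 72% (38-87), p < 0.01
#' heterogeneity_from_q(3.04, 5)  # I2 0% (0-75), p = 0.69
#' @export
heterogeneity_from_q <- function(Q, df, level = 0.95) {
  stopifnot(Q >= 0, df >= 1)
  ci <- if (df >= 2) i_squared_ci(Q, df, level) else c(NA_real_, NA_real_)
  list(Q = Q, df = df,
       p_value = stats::pchisq(Q, df, lower.tail = FALSE),
       i2_percent = i_squared(Q, df),
       i2_ci_low = ci[1], i2_ci_high = ci[2])
}

#' Pool study effects (fixed effect or DerSimonian-Laird random effects)
#'
#' Inverse-variance pooling of log odds ratios. Under the random-effects
#' model, the DerSimonian-Laird moment estimator
#' \eqn{\hat\tau^2 = \max(0, (Q - df) / (\sum w - \sum w^2 / \sum w))}
#' (with fixed-effect weights \eqn{w_i = 1/se_i^2}) is added to every
#' study variance before re-weighting. Heterogeneity (Q, its p-value,
#' I-squared and its test-based CI) is always computed from the
#' fixed-effect weights.
#'
#' @param effects Data frame with columns `log_or` and `se` (one row per
#'   study; `se > 0`), optionally `study_id` and `quality`.
#' @param model `"dersimonian_laird"` (default) or `"fixed"`.
#' @param level Confidence level for the pooled estimate.
#' @return Object of class `meta_result`: list with `pooled_or`, `ci_low`,
#'   `ci_high`, `log_or`, `se`, `tau2`, `k`, `model`, `heterogeneity`
#'   (list: `Q`, `df`, `p_value`, `i2_percent`, `i2_ci_low`, `i2_ci_high`;
#'   `NULL` when k = 1), and per-study `weights` (normalized).
#' @examples
#' eff <- data.frame(log_or = c(0, 1), se = c(1, 1))
#' pool(eff)  # pooled log OR 0.5, Q = 0.5, tau2 = 0
#' @export
pool <- function(effects, model = c("dersimonian_laird", "fixed"),
                 level = 0.95) {
  model <- match.arg(model)
  stopifnot(is.data.frame(effects),
            all(c("log_or", "se") %in% names(effects)))
  k <- nrow(effects)
  if (k < 1L) stop("no studies to pool", call. = FALSE)
  if (any(!is.finite(effects$log_or)) || any(!is.finite(effects$se)) ||
      any(effects$se <= 0)) {
    stop("every study needs a finite log_or and a positive se", call. = FALSE)
  }
  y <- effects$log_or
  w_fe <- 1 / effects$se^2
  mu_fe <- sum(w_fe * y) / sum(w_fe)
  Q <- sum(w_fe * (y - mu_fe)^2)
  df <- k - 1

  tau2 <- 0
  if (model == "dersimonian_laird" && k >= 2) {
    denom <- sum(w_fe) - sum(w_fe^2) / sum(w_fe)
    if (denom > 0) tau2 <- max(0, (Q - df) / denom)
  }
  w <- if (model == "fixed") w_fe else 1 / (effects$se^2 + tau2)
  mu <- sum(w * y) / sum(w)
  se_mu <- sqrt(1 / sum(w))
  z <- stats::qnorm(1 - (1 - level) / 2)

  het <- NULL
  if (k >= 2) {
    het <- list(Q = Q, df = df,
                p_value = stats::pchisq(Q, df, lower.tail = FALSE),
                i2_percent = i_squared(Q, df),
                i2_ci_low = NA_real_, i2_ci_high = NA_real_)
    if (df >= 2) {
      ci <- i_squared_ci(Q, df, level = level)
      het$i2_ci_low <- ci[1]; het$i2_ci_high <- ci[2]
    }
  }
  out <- list(pooled_or = exp(mu),
              ci_low = exp(mu - z * se_mu),
              ci_high = exp(mu + z * se_mu),
              log_or = mu, se = se_mu, tau2 = tau2, k = k,
              model = model, level = level, heterogeneity = het,
              weights = w / sum(w))
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, digits = 2, ...) {
  cat(sprintf("%s meta-analysis of %d studies\n",
              if (x$model == "fixed") "Fixed-effect" else
                "DerSimonian-Laird random-effects", x$k))
  cat(sprintf("Pooled OR %.2f (%.0f%% CI %.2f-%.2f), tau^2 = %.4f\n",
              x$pooled_or, 100 * x$level, x$ci_low, x$ci_high, x$tau2))
  if (!is.null(x$heterogeneity)) {
    h <- x$heterogeneity
    ci_txt <- if (is.na(h$i2_ci_low)) "" else
      sprintf(" (%.0f%% CI %.0f%%-%.0f%%)", 100 * x$level,
              h$i2_ci_low, h$i2_ci_high)
    cat(sprintf("Heterogeneity: Q = %.2f (%d d.f., p = %.2g), I^2 = %.0f%%%s\n",
                h$Q, h$df, h$p_value, h$i2_percent, ci_txt))
  }
  invisible(x)
}

#' Quality-stratified sensitivity analysis
#'
#' Pools all studies, then re-pools after excluding those classified as
#' low quality, and reports the change in heterogeneity and precision
#' together with a forest-plot-ready per-study table. The expectation
#' under the instrument's rationale: if low-quality studies drive
#' heterogeneity, the restricted pooled estimate is less heterogeneous and
#' more precise.
#'
#' @param effects Data frame with `log_or`, `se`, a `quality` column
#'   (values `low` / `moderate` / `high`), and optionally `study_id`.
#' @param model,level Passed to [pool()].
#' @return Object of class `meta_sensitivity`: list with `all` and
#'   `excluding_low` (both `meta_result`), `n_excluded`, `delta` (data
#'   frame of Q, I-squared, CI-width changes), and `forest` (per-study
#'   table with OR, CI, weight, quality, and an included flag).
#' @export
sensitivity_by_quality <- function(effects,
                                   model = c("dersimonian_laird", "fixed"),
                                   level = 0.95) {
  model <- match.arg(model)
  stopifnot(is.data.frame(effects), "quality" %in% names(effects))
  qual <- as.character(effects$quality)
  if (!all(qual %in% c("low", "moderate", "high"))) {
    stop("quality must be one of low/moderate/high for every study",
         call. = FALSE)
  }
  keep <- qual != "low"
  if (!any(keep)) {
    stop("all studies are low quality: nothing left to pool", call. = FALSE)
  }
  res_all <- pool(effects, model = model, level = level)
  res_ex <- pool(effects[keep, , drop = FALSE], model = model, level = level)

  h_num <- function(res, field) {
    if (is.null(res$heterogeneity)) NA_real_ else res$heterogeneity[[field]]
  }
  width <- function(res) res$ci_high - res$ci_low
  delta <- data.frame(
    measure = c("Q", "i2_percent", "ci_width", "tau2"),
    all_studies = c(h_num(res_all, "Q"), h_num(res_all, "i2_percent"),
                    width(res_all), res_all$tau2),
    excluding_low = c(h_num(res_ex, "Q"), h_num(res_ex, "i2_percent"),
                      width(res_ex), res_ex$tau2)
  )
  delta$change <- delta$excluding_low - delta$all_studies

  z <- stats::qnorm(1 - (1 - level) / 2)
  ids <- if ("study_id" %in% names(effects)) as.character(effects$study_id)
         else paste0("study_", seq_len(nrow(effects)))
  forest <- data.frame(
    study_id = ids,
    or = exp(effects$log_or),
    ci_low = exp(effects$log_or - z * effects$se),
    ci_high = exp(effects$log_or + z * effects$se),
    weight_all = res_all$weights,
    quality = qual,
    included_after_exclusion = keep,
    stringsAsFactors = FALSE
  )
  forest$weight_excluding_low <- NA_real_
  forest$weight_excluding_low[keep] <- res_ex$weights

  out <- list(all = res_all, excluding_low = res_ex,
              n_excluded = sum(!keep), delta = delta, forest = forest)
  class(out) <- "meta_sensitivity"
  out
}

#' @export
print.meta_sensitivity <- function(x, ...) {
  cat("All studies:\n"); print(x$all)
  cat(sprintf("\nExcluding %d low-quality:\n", x$n_excluded))
  print(x$excluding_low)
  invisible(x)
}
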