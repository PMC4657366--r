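#' @importFrom nlme lme lmeControl VarCorr
NULL

mixed_model_result <- function(fixed_intercept, fixed_slope, slope_se, slope_p,
                               random_intercept_sd, residual_sd, residuals,
                               keys, n_obs, n_groups, fallback = FALSE,
                               term = "slope") {
  structure(list(fixed_intercept = fixed_intercept, fixed_slope = fixed_slope,
                 slope_se = slope_se, slope_p = slope_p,
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd, residuals = residuals,
                 keys = keys, n_obs = n_obs, n_groups = n_groups,
                 fallback = fallback, term = term),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf(paste0("<mixed_model_result: intercept %.4f, %s %.5f ",
                     "(SE %.5f, p %.4g); sd_b %.4f, sd_e %.4f; %d obs / %d groups%s>\n"),
              x$fixed_intercept, x$term, x$fixed_slope, x$slope_se, x$slope_p,
              x$random_intercept_sd, x$residual_sd, x$n_obs, x$n_groups,
              if (x$fallback) "; fixed-intercept fallback" else ""))
  invisible(x)
}

# Random-intercept fit of value ~ x with subject grouping, by REML through
# nlme (p-values use nlme's within-group denominator df). With very few
# groups the random-intercept variance can sit at the boundary and the
# REML fit can fail to converge (including the exactly noise-free case);
# the fit then degrades to a fixed-intercept linear model with a warning.
.fit_random_intercept <- function(df, xvar, term_label) {
  df <- df[stats::complete.cases(df[, c("subject", xvar, "value")]), ]
  n_groups <- length(unique(df$subject))
  keys <- df[, intersect(c("subject", "day"), names(df)), drop = FALSE]
  fml <- stats::as.formula(paste("value ~", xvar))
  fit <- tryCatch(
    nlme::lme(fml, random = ~ 1 | subject, data = df, method = "REML",
              control = nlme::lmeControl(returnObject = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    tt <- summary(fit)$tTable
    vc <- as.numeric(nlme::VarCorr(fit)[, "StdDev"])
    res <- stats::resid(fit)  # conditional on the subject intercepts
    return(mixed_model_result(tt[1, "Value"], tt[2, "Value"],
                              tt[2, "Std.Error"], tt[2, "p-value"],
                              vc[1], vc[2], as.numeric(res),
                              keys, nrow(df), n_groups, FALSE, term_label))
  }
  warning("random-intercept fit failed (variance at boundary); ",
          "falling back to a fixed-intercept model", call. = FALSE)
  lm_fit <- stats::lm(fml, data = df)
  sm <- summary(lm_fit)$coefficients
  se <- if (nrow(sm) > 1) sm[2, 2] else NA_real_
  p <- if (nrow(sm) > 1) sm[2, 4] else NA_real_
  mixed_model_result(sm[1, 1], sm[2, 1], se, p, 0,
                     stats::sd(stats::resid(lm_fit)),
                     as.numeric(stats::resid(lm_fit)),
                     keys, nrow(df), n_groups, TRUE, term_label)
}

#' Paired-comparison mixed-effects model
#'
#' Fits `T = T_avg + b_i + gamma * reg + eps`, the random-intercept model
#' used to compare precision/recall with vs. without registration (or
#' between the two algorithms): `reg` is a binary indicator, `b_i` a
#' per-subject random intercept, and the fixed slope `gamma` measures the
#' paired difference; its p-value tests whether the two conditions differ.
#'
#' @param table data frame with columns `subject`, `value`, `reg` (0/1).
#'   Rows with missing `value` (undefined precision/recall) are dropped.
#' @return a `mixed_model_result` (the `fixed_slope` is gamma).
#' @export
fit_comparison_model <- function(table) {
  stopifnot(all(c("subject", "value", "reg") %in% names(table)))
  tab <- table[!is.na(table$value), ]
  if (length(unique(tab$reg)) < 2L) {
    stop_octlongreg("`reg` must contain both levels",
                    "octlongreg_degenerate_input")
  }
  tab$reg <- as.numeric(tab$reg)
  .fit_random_intercept(tab, "reg", "gamma")
}

#' Longitudinal trend mixed-effects model
#'
#' Fits `RNFLT = (a1 + b_i) + a2 * day + xi`: per-subject random
#' intercepts, a common fixed slope over days since baseline. The slope
#' p-value is the test for longitudinal change; slopes are in the units of
#' `value` per day (micrometres per day for thickness features).
#'
#' @param table data frame with columns `subject`, `day`, `value`.
#' @return a `mixed_model_result` (the `fixed_slope` is a2).
#' @export
fit_trend_model <- function(table) {
  stopifnot(all(c("subject", "day", "value") %in% names(table)))
  tab <- table[!is.na(table$value), ]
  if (length(unique(tab$day)) < 2L) {
    stop_octlongreg("`day` must vary to fit a trend",
                    "octlongreg_degenerate_input")
  }
  .fit_random_intercept(tab, "day", "slope")
}

#' Compare residual magnitudes before vs. after registration
#'
#' Takes the per-observation residuals of two trend-model fits on the same
#' (subject, day) keys, and fits the paired-comparison model to their
#' absolute values (`reg = 0` before, `reg = 1` after). A significantly
#' negative slope means registration reduced the unexplained measurement
#' variation.
#'
#' @param before,after `mixed_model_result`s from [fit_trend_model()] on
#'   the same sessions.
#' @return a `mixed_model_result` for the |residual| response.
#' @export
compare_residual_magnitudes <- function(before, after) {
  kb <- before$keys; ka <- after$keys
  if (nrow(kb) != nrow(ka) ||
      !identical(kb[order(kb$subject, kb$day), c("subject", "day")],
                 ka[order(ka$subject, ka$day), c("subject", "day")])) {
    stop_octlongreg("before/after fits must share the same (subject, day) keys",
                    "octlongreg_degenerate_input")
  }
  tab <- rbind(data.frame(subject = kb$subject, value = abs(before$residuals),
                          reg = 0),
               data.frame(subject = ka$subject, value = abs(after$residuals),
                          reg = 1))
  fit_comparison_model(tab)
}

#' Per-feature longitudinal trend report
#'
#' Runs [fit_trend_model()] for each of the 17 RNFLT features in both the
#' unregistered and registered conditions and flags slopes with p < 0.05.
#' No multiple-testing correction is applied by default (matching common
#' reporting practice for these 17 features); `p_adjust = "holm"` enables a
#' Holm correction within each condition.
#'
#' @param features long-format feature table from [feature_series()]
#'   (columns `subject`, `day`, `feature`, `value`, `registered`).
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return data frame with one row per feature x condition: `feature`,
#'   `registered`, `intercept`, `slope`, `slope_se`, `slope_p`,
#'   `significant`.
#' @export
trend_report <- function(features, p_adjust = "none") {
  conds <- sort(unique(features$registered))
  rows <- list()
  for (reg in conds) {
    sub <- features[features$registered == reg, ]
    for (f in unique(sub$feature)) {
      ft <- sub[sub$feature == f, ]
      fit <- fit_trend_model(data.frame(subject = ft$subject, day = ft$day,
                                        value = ft$value))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, registered = reg, intercept = fit$fixed_intercept,
        slope = fit$fixed_slope, slope_se = fit$slope_se,
        slope_p = fit$slope_p)
    }
  }
  out <- do.call(rbind, rows)
  for (reg in conds) {
    i <- out$registered == reg
    out$slope_p_adj[i] <- stats::p.adjust(out$slope_p[i], method = p_adjust)
  }
  out$significant <- out$slope_p_adj < 0.05
  rownames(out) <- NULL
  out
}
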