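# Verification suite: autocorrelation-corrected correlation significance,
# contingency-table metrics (accuracy, hit rate, false alarm rate, SEDI),
# the random-forecast accuracy baseline, and bootstrap significance.

# Sample autocorrelation at lags 0..N-1 with the biased (1/N)
# normalization, as used by the effective-sample-size correction.
acf_full <- function(x) {
  as.numeric(acf(x, lag.max = length(x) - 1, plot = FALSE, demean = TRUE)$acf)
}

#' Effective sample size under autocorrelation
#'
#' Two autocorrelated series carry fewer independent samples than their
#' length. The effective sample size used to assess correlation
#' significance divides N by the triangular-weighted sum of lagged
#' autocorrelation cross-products over symmetric lags,
#' `N_eff = N / (1 + 2 * sum_{t=1}^{N-1} (1 - t/N) * r_t^F * r_t^O)`,
#' where `r_t^F`, `r_t^O` are the sample autocorrelations of the forecast
#' and observed series at lag t (`r_0 = 1`; negative and positive lags
#' contribute equally, hence the factor 2). For white noise the
#' denominator is ~1 and `N_eff ~ N`; for a pair of AR(1) series with
#' coefficient rho it approaches `N * (1 - rho^2) / (1 + rho^2)`.
#'
#' @param forecast,observed Equal-length numeric series (N >= 4 after
#'   dropping incomplete pairs).
#' @return `N_eff`, clamped to (0, N]. Attributes: `n` (pairs used) and
#'   `degenerate` (`TRUE` when the denominator was non-positive, in which
#'   case `N_eff = N` is returned but significance should not be
#'   assessed).
#' @examples
#' set.seed(1)
#' effective_n(rnorm(100), rnorm(100))  # close to 100
#' @export
effective_n <- function(forecast, observed) {
  ok <- stats::complete.cases(forecast, observed)
  f <- forecast[ok]
  o <- observed[ok]
  n <- length(f)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (sd(f) == 0 || sd(o) == 0) {
    stop("series is constant; autocorrelation undefined", call. = FALSE)
  }
  t <- 0:(n - 1)
  w <- ifelse(t == 0, 1, 2)  # symmetric lags: -t and +t contribute equally
  denom <- sum(w * (1 - t / n) * acf_full(f) * acf_full(o))
  degenerate <- denom <= 0
  n_eff <- if (degenerate) n else min(n / denom, n)
  structure(n_eff, n = n, degenerate = degenerate)
}

#' Correlation with autocorrelation-corrected confidence interval
#'
#' Pearson correlation between forecast and observed series with a
#' two-sided confidence interval from the Fisher Z transformation, using
#' the effective sample size: `SE = 1 / sqrt(N_eff - 3)`. Skill is
#' significant when the lower bound exceeds zero.
#'
#' @inheritParams effective_n
#' @param conf Confidence level (default 0.95).
#' @return An object of class `cor_ci`: `r`, `n`, `n_eff`, `ci_low`,
#'   `ci_high`, `significant`, `degenerate`. When `N_eff <= 3` (or the
#'   effective-N denominator is degenerate) the interval is `NA` and the
#'   result is not significant.
#' @export
correlation_with_ci <- function(forecast, observed, conf = 0.95) {
  ok <- stats::complete.cases(forecast, observed)
  f <- forecast[ok]
  o <- observed[ok]
  ne <- effective_n(f, o)
  r <- cor(f, o)
  degenerate <- attr(ne, "degenerate")
  out <- list(r = r, n = attr(ne, "n"), n_eff = as.numeric(ne),
              conf = conf, degenerate = degenerate)
  if (degenerate || as.numeric(ne) <= 3) {
    out$ci_low <- NA_real_
    out$ci_high <- NA_real_
    out$significant <- FALSE
  } else {
    z <- atanh(r)
    se <- 1 / sqrt(as.numeric(ne) - 3)
    q <- qnorm(1 - (1 - conf) / 2)
    out$ci_low <- tanh(z - q * se)
    out$ci_high <- tanh(z + q * se)
    out$significant <- out$ci_low > 0
  }
  structure(out, class = "cor_ci")
}

#' @export
print.cor_ci <- function(x, ...) {
  cat(sprintf(
    "<cor_ci> r = %.3f (N = %d, N_eff = %.1f), %g%% CI [%.3f, %.3f]%s%s\n",
    x$r, x$n, x$n_eff, 100 * x$conf, x$ci_low, x$ci_high,
    if (isTRUE(x$significant)) ", significant" else "",
    if (x$degenerate) " [degenerate N_eff]" else ""
  ))
  invisible(x)
}

#' Contingency table of binary events
#'
#' Cross-classifies observed and forecast event indicators; pairs with a
#' missing value are dropped.
#'
#' @param observed,forecast Logical (or 0/1) vectors.
#' @return An object of class `contingency` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
contingency_table <- function(observed, forecast) {
  observed <- as.logical(observed)
  forecast <- as.logical(forecast)
  ok <- !is.na(observed) & !is.na(forecast)
  o <- observed[ok]
  f <- forecast[ok]
  if (length(o) < 1) stop("no complete event pairs", call. = FALSE)
  structure(
    list(tp = sum(f & o), fp = sum(f & !o),
         fn = sum(!f & o), tn = sum(!f & !o)),
    class = "contingency"
  )
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("<contingency> tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

as_contingency <- function(x, forecast = NULL) {
  if (inherits(x, "contingency")) x else contingency_table(x, forecast)
}

#' Forecast accuracy
#'
#' Fraction of correct forecasts: (tp + tn) / total.
#'
#' @param x A [contingency_table()], or an observed event vector.
#' @param forecast Forecast event vector when `x` is observed events.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(x, forecast = NULL) {
  ct <- as_contingency(x, forecast)
  (ct$tp + ct$tn) / (ct$tp + ct$fp + ct$fn + ct$tn)
}

#' Hit rate (probability of detection)
#' @inheritParams accuracy
#' @return tp / (tp + fn), or `NA` when no events were observed.
#' @export
hit_rate <- function(x, forecast = NULL) {
  ct <- as_contingency(x, forecast)
  if (ct$tp + ct$fn == 0) return(NA_real_)
  ct$tp / (ct$tp + ct$fn)
}

#' False alarm rate
#' @inheritParams accuracy
#' @return fp / (fp + tn), or `NA` when no non-events were observed.
#' @export
false_alarm_rate <- function(x, forecast = NULL) {
  ct <- as_contingency(x, forecast)
  if (ct$fp + ct$tn == 0) return(NA_real_)
  ct$fp / (ct$fp + ct$tn)
}

#' Expected accuracy of a random forecast
#'
#' A forecast issued at random with the event's own frequency `f` is
#' correct with probability `f^2 + (1 - f)^2`; accuracy above this
#' baseline indicates skill beyond chance. At `f = 0.5` the baseline is
#' 0.5; rarer events push it towards 1, which is why accuracy alone
#' flatters rare-event forecasts.
#'
#' @param f Event frequency in \[0, 1\].
#' @return Baseline accuracy in \[0.5, 1\].
#' @examples
#' random_accuracy(0.5)   # 0.5
#' random_accuracy(0.26)  # 0.6152
#' @export
random_accuracy <- function(f) {
  stopifnot(all(f >= 0 & f <= 1))
  f^2 + (1 - f)^2
}

#' Conservative printed bound for the random-accuracy baseline
#'
#' The smallest value on a 0.01 grid strictly above the raw baseline --
#' the conservative two-decimal form in which such bounds are reported
#' (e.g. 0.6152 becomes 0.62, 0.7048 becomes 0.71).
#'
#' @inheritParams random_accuracy
#' @param step Grid step (default 0.01).
#' @return The ceiling of [random_accuracy()] on the grid, strictly above
#'   the raw value.
#' @export
accuracy_bound <- function(f, step = 0.01) {
  raw <- random_accuracy(f)
  b <- ceiling(round(raw / step, 9)) * step
  ifelse(abs(b - raw) < 1e-12, b + step, b)
}

#' Symmetric Extremal Dependence Index
#'
#' `SEDI = (log F - log H - log(1-F) + log(1-H)) /
#'         (log F + log H + log(1-F) + log(1-H))`
#' with hit rate H and false alarm rate F. SEDI is base-rate robust and
#' equitable: random forecasts score 0 in expectation and a perfect
#' forecast scores 1. It is undefined (returned as `NA`, never silently
#' zero) whenever H or F is exactly 0 or 1 -- e.g. months with no false
#' positives.
#'
#' @inheritParams accuracy
#' @return SEDI in \[-1, 1\], or `NA` when undefined.
#' @export
sedi <- function(x, forecast = NULL) {
  ct <- as_contingency(x, forecast)
  H <- hit_rate(ct)
  F_ <- false_alarm_rate(ct)
  sedi_hf(H, F_)
}

# SEDI directly from hit and false-alarm rates (vectorized).
sedi_hf <- function(H, F_) {
  out <- rep(NA_real_, length(H))
  ok <- !is.na(H) & !is.na(F_) & H > 0 & H < 1 & F_ > 0 & F_ < 1
  h <- H[ok]
  f <- F_[ok]
  out[ok] <- (log(f) - log(h) - log(1 - f) + log(1 - h)) /
    (log(f) + log(h) + log(1 - f) + log(1 - h))
  out
}

#' Bootstrap significance of a categorical skill score
#'
#' Builds the null distribution of a metric by issuing random forecasts
#' drawn from the observed event labels (resampling with replacement,
#' equivalent to Bernoulli draws at the observed frequency; a permutation
#' variant is available) and scoring them against the fixed observed
#' events. The metric is significant when it exceeds the 97.5th
#' percentile of the null distribution.
#'
#' @param observed_events Logical vector of observed events (length >= 2).
#' @param forecast_events Logical vector of forecast events; alternatively
#'   supply `metric_value` directly.
#' @param metric `"accuracy"` or `"sedi"`.
#' @param metric_value Precomputed value of the metric (optional).
#' @param n_boot Number of random forecasts (>= 100; 1000 by default).
#' @param method `"resample"` (with replacement) or `"permutation"`.
#' @param seed Optional seed; fixed seeds give identical null percentiles.
#' @return An object of class `boot_sig`: `metric`, `value`, `null_q975`,
#'   `null_ci` (2.5/97.5 null percentiles), `significant`,
#'   `prop_undefined`, `assessed` (`FALSE`, with `significant = NA`, when
#'   the metric was undefined in more than half the null draws), `n_boot`.
#' @export
bootstrap_significance <- function(observed_events, forecast_events = NULL,
                                   metric = c("accuracy", "sedi"),
                                   metric_value = NULL, n_boot = 1000,
                                   method = c("resample", "permutation"),
                                   seed = NULL) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  obs <- as.logical(observed_events)
  obs <- obs[!is.na(obs)]
  n <- length(obs)
  if (n < 2) stop("need at least 2 observed events", call. = FALSE)
  if (n_boot < 100) stop("`n_boot` must be at least 100", call. = FALSE)
  if (is.null(metric_value)) {
    if (is.null(forecast_events)) {
      stop("supply `forecast_events` or `metric_value`", call. = FALSE)
    }
    ct <- contingency_table(obs, forecast_events)
    metric_value <- if (metric == "accuracy") accuracy(ct) else sedi(ct)
  }

  null_vals <- with_seed_if(seed, {
    draws <- if (method == "resample") {
      matrix(sample(obs, n * n_boot, replace = TRUE), n, n_boot)
    } else {
      vapply(seq_len(n_boot), function(i) sample(obs), logical(n))
    }
    if (metric == "accuracy") {
      colMeans(draws == obs)
    } else {
      tp <- colSums(draws & obs)
      fp <- colSums(draws & !obs)
      n_ev <- sum(obs)
      n_non <- n - n_ev
      H <- if (n_ev > 0) tp / n_ev else rep(NA_real_, n_boot)
      F_ <- if (n_non > 0) fp / n_non else rep(NA_real_, n_boot)
      sedi_hf(H, F_)
    }
  })

  prop_undef <- mean(is.na(null_vals))
  assessed <- prop_undef <= 0.5 && !is.na(metric_value)
  valid <- null_vals[!is.na(null_vals)]
  q975 <- if (length(valid) > 0) {
    quantile(valid, 0.975, names = FALSE, type = 7)
  } else {
    NA_real_
  }
  structure(
    list(metric = metric, value = metric_value, null_q975 = q975,
         null_ci = if (length(valid) > 0) {
           quantile(valid, c(0.025, 0.975), names = FALSE, type = 7)
         } else {
           c(NA_real_, NA_real_)
         },
         significant = if (assessed) metric_value > q975 else NA,
         prop_undefined = prop_undef, assessed = assessed, n_boot = n_boot),
    class = "boot_sig"
  )
}

#' @export
print.boot_sig <- function(x, ...) {
  cat(sprintf(
    "<boot_sig> %s = %s vs null 97.5th pct %.3f: %s (%.0f%% of %d null draws undefined)\n",
    x$metric, format(round(x$value, 3)), x$null_q975,
    if (!x$assessed) "not assessed" else if (x$significant) "significant" else "not significant",
    100 * x$prop_undefined, x$n_boot
  ))
  invisible(x)
}

#' Per-group skill report
#'
#' Evaluates the full verification suite on a joined observed/forecast
#' table: for every group (by default target month x lead) it computes
#' the Pearson correlation with effective-sample-size corrected Fisher-Z
#' interval, event accuracy, the random-forecast baseline at the observed
#' event frequency, SEDI, and (optionally) bootstrap significance flags
#' for the categorical scores.
#'
#' @param data A tibble with one row per (group, time point), carrying
#'   observed and forecast values and event indicators.
#' @param obs,fcst Unquoted columns of observed and forecast values.
#' @param obs_event,fcst_event Unquoted columns of event indicators
#'   (optional; categorical metrics are skipped when absent).
#' @param by Character vector of grouping columns (default
#'   `c("target_month", "lead")`).
#' @param time Column ordering observations within a group (default
#'   `"target_year"`).
#' @param n_boot Bootstrap draws for significance flags (0 to skip).
#' @param conf Confidence level for the correlation interval.
#' @param seed Optional seed for the bootstrap (offset per group so each
#'   group has its own reproducible null).
#' @return A tibble with one row per group: `n`, `r`, `n_eff`, `ci_low`,
#'   `ci_high`, `sig_corr`, `f_obs`, `accuracy`, `fa_rand`, `sedi`,
#'   `sig_accuracy`, `sig_sedi`.
#' @export
skill_report <- function(data, obs, fcst, obs_event = NULL, fcst_event = NULL,
                         by = c("target_month", "lead"),
                         time = "target_year", n_boot = 1000, conf = 0.95,
                         seed = NULL) {
  obs_q <- enquo(obs)
  fc_q <- enquo(fcst)
  oe_q <- enquo(obs_event)
  fe_q <- enquo(fcst_event)
  has_events <- !rlang::quo_is_null(oe_q) && !rlang::quo_is_null(fe_q)
  by <- intersect(by, names(data))

  gid <- 0L
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(g, key) {
      gid <<- gid + 1L
      g <- dplyr::arrange(g, .data[[time]])
      o <- dplyr::pull(g, !!obs_q)
      f <- dplyr::pull(g, !!fc_q)
      cc <- correlation_with_ci(f, o, conf = conf)
      row <- tibble::tibble(
        n = cc$n, r = cc$r, n_eff = cc$n_eff,
        ci_low = cc$ci_low, ci_high = cc$ci_high,
        sig_corr = cc$significant
      )
      if (has_events) {
        oe <- dplyr::pull(g, !!oe_q)
        fe <- dplyr::pull(g, !!fe_q)
        ct <- contingency_table(oe, fe)
        f_obs <- mean(oe, na.rm = TRUE)
        row$f_obs <- f_obs
        row$accuracy <- accuracy(ct)
        row$fa_rand <- random_accuracy(f_obs)
        row$sedi <- sedi(ct)
        if (n_boot > 0) {
          seed_g <- if (is.null(seed)) NULL else (as.integer(seed) + gid) %% .Machine$integer.max
          ba <- bootstrap_significance(oe, metric = "accuracy",
                                       metric_value = row$accuracy,
                                       n_boot = n_boot, seed = seed_g)
          bs <- bootstrap_significance(oe, metric = "sedi",
                                       metric_value = row$sedi,
                                       n_boot = n_boot, seed = seed_g)
          row$sig_accuracy <- ba$significant
          row$sig_sedi <- bs$significant
        }
      }
      row
    }) |>
    dplyr::ungroup()
}
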