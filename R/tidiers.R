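# broom-style tidiers for the fitted/verified objects.

#' Tidy a correlation result
#'
#' @param x A [correlation_with_ci()] object.
#' @param ... Unused.
#' @return A one-row tibble with `r`, `n`, `n_eff`, `ci_low`, `ci_high`,
#'   `significant`, `degenerate`.
#' @method tidy cor_ci
#' @export
tidy.cor_ci <- function(x, ...) {
  tibble::tibble(
    r = x$r, n = x$n, n_eff = x$n_eff,
    ci_low = x$ci_low, ci_high = x$ci_high,
    conf = x$conf, significant = x$significant, degenerate = x$degenerate
  )
}

#' @rdname tidy.cor_ci
#' @method glance cor_ci
#' @export
glance.cor_ci <- function(x, ...) tidy.cor_ci(x, ...)

#' Tidy a contingency table
#'
#' @param x A [contingency_table()] object.
#' @param ... Unused.
#' @return A one-row tibble with the counts and derived rates.
#' @method tidy contingency
#' @export
tidy.contingency <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
    n = x$tp + x$fp + x$fn + x$tn,
    accuracy = accuracy(x), hit_rate = hit_rate(x),
    false_alarm_rate = false_alarm_rate(x), sedi = sedi(x)
  )
}

#' Tidy a bootstrap significance result
#'
#' @param x A [bootstrap_significance()] object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy boot_sig
#' @export
tidy.boot_sig <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, value = x$value, null_q975 = x$null_q975,
    significant = x$significant, prop_undefined = x$prop_undefined,
    assessed = x$assessed, n_boot = x$n_boot
  )
}

#' Tidy a closure threshold
#'
#' @param x A [closure_threshold()] object.
#' @param ... Unused.
#' @return A one-row tibble with `value`, `percentile`, `n_closures`, `n`.
#' @method tidy closure_threshold
#' @export
tidy.closure_threshold <- function(x, ...) {
  tibble::tibble(
    value = x$value, percentile = x$percentile,
    n_closures = nrow(x$closures), n = x$n
  )
}

#' @rdname tidy.closure_threshold
#' @method glance closure_threshold
#' @export
glance.closure_threshold <- function(x, ...) tidy.closure_threshold(x, ...)
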