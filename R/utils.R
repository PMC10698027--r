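# Calendar-month arithmetic on an integer index (year * 12 + month - 1).
# Keeping time as an integer makes lead/target bookkeeping exact and cheap;
# Dates are attached only at the tibble surface.

ym_index <- function(year, month) as.integer(year) * 12L + (as.integer(month) - 1L)

ym_year <- function(idx) idx %/% 12L

ym_month <- function(idx) idx %% 12L + 1L

ym_date <- function(idx) lubridate::make_date(ym_year(idx), ym_month(idx), 1L)

# Run `code` under a fixed RNG seed when one is supplied, leaving the
# caller's RNG state untouched; otherwise run it against the ambient RNG.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Normalize longitudes to the -180..180 convention.
wrap_lon <- function(lon) ((lon + 180) %% 360) - 180

`%||%` <- function(x, y) if (is.null(x)) y else x
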