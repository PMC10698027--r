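test_that("effective sample size matches a brute-force double loop", {
  withr::with_seed(5, {
    f <- rnorm(40)
    o <- 0.5 * f + rnorm(40)
  })
  ne <- effective_n(f, o)
  # independent oracle: hand-coded biased autocorrelations and the
  # weighted cross-product sum, all via explicit loops
  acov <- function(x, t) {
    n <- length(x)
    xc <- x - mean(x)
    s <- 0
    for (i in 1:(n - t)) s <- s + xc[i] * xc[i + t]
    s / n
  }
  n <- length(f)
  rf <- vapply(0:(n - 1), function(t) acov(f, t) / acov(f, 0), numeric(1))
  ro <- vapply(0:(n - 1), function(t) acov(o, t) / acov(o, 0), numeric(1))
  denom <- 0
  for (t in 0:(n - 1)) {
    # lags -t and +t contribute symmetrically
    denom <- denom + (if (t == 0) 1 else 2) * (1 - t / n) * rf[t + 1] * ro[t + 1]
  }
  expect_equal(as.numeric(ne), min(n / denom, n), tolerance = 1e-12)
  expect_false(attr(ne, "degenerate"))
  # identical series duplicated run through the same oracle
  ne2 <- effective_n(f, f)
  denom2 <- sum(c(1, rep(2, n - 1)) * (1 - (0:(n - 1)) / n) * rf * rf)
  expect_equal(as.numeric(ne2), min(n / denom2, n), tolerance = 1e-12)
})

test_that("white noise keeps nearly all of its samples", {
  withr::with_seed(6, {
    ratios <- replicate(5, {
      n <- 1500
      as.numeric(effective_n(rnorm(n), rnorm(n))) / n
    })
  })
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("paired AR(1) series lose samples at the closed-form rate", {
  rho <- 0.5
  gen <- function(n) as.numeric(stats::arima.sim(list(ar = rho), n))
  withr::with_seed(7, {
    ratios <- replicate(5, {
      n <- 2000
      as.numeric(effective_n(gen(n), gen(n))) / n
    })
  })
  expect_equal(mean(ratios), (1 - rho^2) / (1 + rho^2), tolerance = 0.05)
})

test_that("a perfect forecast is significantly correlated", {
  withr::with_seed(8, x <- rnorm(30))
  cc <- correlation_with_ci(x, x)
  expect_equal(cc$r, 1)
  expect_true(cc$significant)
})

test_that("the Fisher-Z interval matches a textbook computation on a fixture", {
  # frozen 20-point fixture
  f <- c(0.61, -0.52, 1.42, 0.46, -1.05, 1.92, 0.08, -0.42, 1.31, -0.26,
         2.24, 0.21, -0.69, 1.18, 0.37, -1.57, 0.64, 1.04, -0.11, 0.78)
  o <- c(0.45, -0.81, 1.10, 0.73, -0.60, 1.55, -0.12, -0.30, 0.95, 0.04,
         1.80, 0.55, -1.02, 0.87, 0.12, -1.23, 0.33, 1.21, 0.28, 0.49)
  cc <- correlation_with_ci(f, o)
  r <- cor(f, o)
  z <- 0.5 * log((1 + r) / (1 - r))
  se <- 1 / sqrt(cc$n_eff - 3)
  lo <- (exp(2 * (z - 1.959964 * se)) - 1) / (exp(2 * (z - 1.959964 * se)) + 1)
  hi <- (exp(2 * (z + 1.959964 * se)) - 1) / (exp(2 * (z + 1.959964 * se)) + 1)
  expect_equal(cc$ci_low, lo, tolerance = 1e-6)
  expect_equal(cc$ci_high, hi, tolerance = 1e-6)
  expect_true(cc$ci_low <= cc$r && cc$r <= cc$ci_high)
  td <- tidy(cc)
  expect_equal(td$r, cc$r)
  expect_equal(td$n_eff, cc$n_eff)
})

test_that("degenerate or tiny effective sample sizes disable the interval", {
  cc <- correlation_with_ci(c(1, 2, 1, 2, 1, 2), c(2, 1, 2, 1, 2, 1))
  expect_false(cc$significant)
  expect_true(is.na(cc$ci_low))
  expect_error(effective_n(rep(1, 10), rnorm(10)), "constant")
  expect_error(effective_n(rnorm(3), rnorm(3)), "at least 4")
})

test_that("accuracy counts correct forecasts", {
  obs <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  fc <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  ct <- contingency_table(obs, fc)
  expect_equal(ct$tp, 2)
  expect_equal(ct$fp, 1)
  expect_equal(ct$fn, 4)
  expect_equal(ct$tn, 3)
  expect_equal(accuracy(ct), 0.5)
  expect_equal(accuracy(obs, obs), 1)
  expect_equal(accuracy(obs, !obs), 0)
  td <- tidy(ct)
  expect_equal(td$accuracy, 0.5)
})

test_that("the random-forecast baseline and its printed bound behave", {
  expect_identical(random_accuracy(0.5), 0.5)
  expect_identical(random_accuracy(0), 1)
  expect_identical(random_accuracy(1), 1)
  expect_equal(random_accuracy(0.26), 0.6152)
  expect_equal(accuracy_bound(0.26), 0.62)
  expect_equal(accuracy_bound(0.18), 0.71)
  # a baseline already on the grid moves strictly up
  expect_equal(accuracy_bound(0.5), 0.51)
})

test_that("SEDI is zero at H = F, near one for sharp forecasts, NA at the edges", {
  # H = F = 0.25: tp=1 fn=3, fp=1 tn=3
  ct0 <- structure(list(tp = 1, fp = 1, fn = 3, tn = 3), class = "contingency")
  expect_equal(sedi(ct0), 0)
  # H = 0.9, F = 0.1 -> 0.912489 (direct evaluation, frozen)
  ct1 <- structure(list(tp = 9, fp = 1, fn = 1, tn = 9), class = "contingency")
  expect_equal(sedi(ct1), 0.9124889, tolerance = 1e-6)
  # no false positives -> undefined, not zero
  ct2 <- structure(list(tp = 5, fp = 0, fn = 5, tn = 10), class = "contingency")
  expect_true(is.na(sedi(ct2)))
  ct3 <- structure(list(tp = 10, fp = 2, fn = 0, tn = 8), class = "contingency")
  expect_true(is.na(sedi(ct3)))  # perfect hit rate is an edge too
  # approach to the perfect corner
  ct4 <- structure(list(tp = 999, fp = 1, fn = 1, tn = 999),
                   class = "contingency")
  expect_gt(sedi(ct4), 0.99)
})

test_that("event-vector and contingency paths agree on random instances", {
  withr::with_seed(9, {
    for (i in 1:20) {
      n <- sample(10:40, 1)
      obs <- runif(n) < runif(1, 0.2, 0.8)
      fc <- runif(n) < runif(1, 0.2, 0.8)
      ct <- contingency_table(obs, fc)
      expect_equal(accuracy(ct), mean(obs == fc))
      if (any(obs)) expect_equal(hit_rate(ct), sum(fc & obs) / sum(obs))
      if (any(!obs)) {
        expect_equal(false_alarm_rate(ct), sum(fc & !obs) / sum(!obs))
      }
      s <- sedi(ct)
      if (!is.na(s)) {
        H <- sum(fc & obs) / sum(obs)
        F_ <- sum(fc & !obs) / sum(!obs)
        expect_equal(
          s,
          (log(F_) - log(H) - log(1 - F_) + log(1 - H)) /
            (log(F_) + log(H) + log(1 - F_) + log(1 - H))
        )
        expect_true(s >= -1 && s <= 1)
      }
    }
  })
})

test_that("bootstrap significance is deterministic and flags perfect skill", {
  withr::with_seed(10, obs <- runif(40) < 0.5)
  b1 <- bootstrap_significance(obs, forecast_events = obs,
                               metric = "accuracy", n_boot = 500, seed = 123)
  b2 <- bootstrap_significance(obs, forecast_events = obs,
                               metric = "accuracy", n_boot = 500, seed = 123)
  expect_identical(b1$null_q975, b2$null_q975)
  expect_true(b1$significant)
  expect_equal(b1$value, 1)
  # permutation variant runs and is also deterministic
  p1 <- bootstrap_significance(obs, forecast_events = obs,
                               metric = "accuracy", n_boot = 200,
                               method = "permutation", seed = 5)
  expect_true(p1$significant)
})

test_that("mostly-undefined nulls refuse to assess significance", {
  obs <- rep(TRUE, 20)  # no non-events: SEDI never defined
  b <- bootstrap_significance(obs, metric = "sedi", metric_value = 0.5,
                              n_boot = 200, seed = 1)
  expect_false(b$assessed)
  expect_true(is.na(b$significant))
  expect_equal(b$prop_undefined, 1)
})

test_that("skill_report assembles the full metric set per group", {
  withr::with_seed(11, {
    d <- tidyr::expand_grid(target_month = c(1L, 7L), lead = c(0.5, 6.5),
                            target_year = 1981:2010) |>
      dplyr::mutate(
        obs_v = rnorm(dplyr::n()),
        fc_v = obs_v * 0.8 + rnorm(dplyr::n(), sd = 0.5),
        obs_e = obs_v < 0,
        fc_e = fc_v < 0
      )
  })
  rep <- skill_report(d, obs = obs_v, fcst = fc_v, obs_event = obs_e,
                      fcst_event = fc_e, n_boot = 200, seed = 42)
  expect_equal(nrow(rep), 4)
  expect_true(all(c("r", "n_eff", "ci_low", "sig_corr", "accuracy",
                    "fa_rand", "sedi", "sig_accuracy") %in% names(rep)))
  expect_true(all(rep$n == 30))
  expect_true(all(rep$n_eff <= rep$n))
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 1))
  expect_true(all(rep$r > 0.4))  # strongly related by construction
  # reproducible with the same seed
  rep2 <- skill_report(d, obs = obs_v, fcst = fc_v, obs_event = obs_e,
                       fcst_event = fc_e, n_boot = 200, seed = 42)
  expect_identical(rep, rep2)
})
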