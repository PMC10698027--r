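# End-to-end retrospective pipeline: synthetic world -> indices ->
# verification, with CSV/netCDF artifacts on disk. This is what the
# command-line wrapper drives.

#' Default pipeline configuration
#'
#' The defaults describe the study conditions the package emulates: a
#' 1981-2020 monthly record over the California Current domain with a
#' multi-year warm extreme (Mar 2014 - Dec 2016, +2 degC), a 73-member
#' global ensemble initialized monthly, a 3-member higher-skill
#' "downscaled" ensemble initialized in January and July, 1981-2010 and
#' 1981-2020 climatology spans, the 75/150 km HCI bands off 35-40 N and
#' the Southern California Bight box with its three historical closure
#' periods. Any element can be overridden via `...` (nested lists are
#' merged).
#'
#' @param ... Named overrides, e.g. `years = 1981:2000`,
#'   `global = list(n_members = 5)`.
#' @return A nested configuration list of class `run_config`.
#' @examples
#' cfg <- pipeline_config(years = 1981:1995,
#'                        heatwaves = list(heatwave(c(1993, 1), c(1994, 12), 2)),
#'                        global = list(n_members = 3))
#' @export
pipeline_config <- function(...) {
  base <- list(
    lat_range = c(30, 48),
    lon_range = c(-134, -115.5),
    resolution = 1,
    years = 1981:2020,
    clim_years_full = 1981:2020,
    clim_years_comparison = 1981:2010,
    ocean = list(mean_sst = 14, lat_slope = -0.35, seasonal_amp = 3,
                 seasonal_peak = 8, ar1 = 0.8, anomaly_sd = 0.8,
                 cell_noise_sd = 0.3),
    heatwaves = list(heatwave(c(2014, 3), c(2016, 12), amplitude = 2)),
    global = list(n_members = 73, init_months = 1:12,
                  profile = skill_profile(rho0 = 0.85, decay = 0.93,
                                          drift_bias = 0.08)),
    downscaled = list(n_members = 3, init_months = c(1, 7),
                      profile = skill_profile(rho0 = 0.9, decay = 0.95,
                                              drift_bias = 0.02)),
    hci = list(band_km = c(75, 150), lat_min = 35, lat_max = 40,
               comparator = "lte"),
    total = list(box = list(lat_min = 31, lat_max = 34,
                            lon_min = -120, lon_max = -116),
                 closure_months = 6:8,
                 closures = list(c(2014, 8), c(2015, 6), c(2015, 7),
                                 c(2015, 8), c(2016, 6), c(2016, 7),
                                 c(2016, 8))),
    indices = c("hci", "total"),
    n_boot = 1000,
    restrict_cells = TRUE,
    write_netcdf = TRUE,
    write_figures = TRUE,
    seed = 1
  )
  over <- list(...)
  cfg <- modify_list_deep(base, over)
  class(cfg) <- "run_config"
  cfg
}

modify_list_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !inherits(over[[nm]], c("skill_profile", "heatwave")) &&
        !is.null(names(over[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] overrides; skill
#' profiles are given as lists with `rho0`, `decay`, `drift_bias`;
#' heatwaves as lists with `start`, `end` (`[year, month]`) and
#' `amplitude`. A run is reproducible from the configuration plus a seed.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$years) && length(y$years) == 2) {
    y$years <- seq(y$years[1], y$years[2])
  }
  for (span in c("clim_years_full", "clim_years_comparison")) {
    if (!is.null(y[[span]]) && length(y[[span]]) == 2) {
      y[[span]] <- seq(y[[span]][1], y[[span]][2])
    }
  }
  if (!is.null(y$heatwaves)) {
    y$heatwaves <- lapply(y$heatwaves, function(h) {
      heatwave(unlist(h$start), unlist(h$end), h$amplitude)
    })
  }
  for (ens in c("global", "downscaled")) {
    if (!is.null(y[[ens]]$profile)) {
      y[[ens]]$profile <- do.call(skill_profile, y[[ens]]$profile)
    }
  }
  do.call(pipeline_config, y)
}

#' Run the retrospective forecast pipeline
#'
#' Simulates the synthetic world, computes observed and forecast indices,
#' verifies them, and writes artifacts under `outdir`: netCDF for gridded
#' fields, CSV for index and skill tables, PNG figures, and a
#' `run_info.json` with the configuration hash, seed, per-stage timings
#' and record counts. A failure during a later stage leaves earlier
#' artifacts intact and drops a `FAILED` marker naming the stage.
#'
#' @param config A [pipeline_config()] list.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed for every random stage (defaults to
#'   `config$seed`).
#' @param stages Stages to run, in order: `"simulate"`, `"indices"`,
#'   `"skill"`, `"compare"` (the four-configuration comparison is the
#'   most expensive and is off by default).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = "shorecast_run",
                         seed = NULL,
                         stages = c("simulate", "indices", "skill")) {
  stopifnot(inherits(config, "run_config"))
  seed <- as.integer(seed %||% config$seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  info <- list(config_hash = rlang::hash(config), seed = seed,
               stages = stages, timings = list(), counts = list())
  res <- list()
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(code, error = function(e) {
      writeLines(
        sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
        file.path(outdir, "FAILED")
      )
      stop(e)
    })
    info$timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    out
  }
  has_nc <- requireNamespace("ncdf4", quietly = TRUE)

  # ---- simulate ----
  world <- stage("simulate", {
    grid <- make_grid(config$lat_range, config$lon_range, config$resolution)
    band75 <- coastal_band(grid, config$hci$band_km[1], config$hci$lat_min,
                           config$hci$lat_max)
    band150 <- coastal_band(grid, config$hci$band_km[2], config$hci$lat_min,
                            config$hci$lat_max)
    box <- region_box(grid, config$total$box$lat_min, config$total$box$lat_max,
                      config$total$box$lon_min, config$total$box$lon_max)
    obs <- do.call(simulate_observed_sst, c(
      list(grid = grid, years = config$years, heatwaves = config$heatwaves,
           seed = seed),
      config$ocean
    ))
    cells <- if (isTRUE(config$restrict_cells)) {
      union(band150$cell, box$cell)
    } else {
      NULL
    }
    g_fc <- simulate_forecasts(
      obs, grid, config$global$profile, config$global$n_members,
      init_months = config$global$init_months, cells = cells,
      model = "global", seed = seed + 1L
    )
    d_fc <- simulate_forecasts(
      obs, grid, config$downscaled$profile, config$downscaled$n_members,
      init_months = config$downscaled$init_months, cells = cells,
      model = "downscaled", seed = seed + 2L
    )
    if (isTRUE(config$write_netcdf) && has_nc) {
      write_sst_netcdf(obs, grid, file.path(outdir, "observed_sst.nc"))
      write_mask_netcdf(band150, grid, file.path(outdir, "band150.nc"))
      write_mask_netcdf(box, grid, file.path(outdir, "box.nc"))
    }
    list(grid = grid, band75 = band75, band150 = band150, box = box,
         obs = obs, global = g_fc, downscaled = d_fc)
  })
  info$counts$observed_rows <- nrow(world$obs)
  info$counts$global_forecast_rows <- nrow(world$global)
  info$counts$downscaled_forecast_rows <- nrow(world$downscaled)
  res$world <- world

  # ---- indices ----
  if ("indices" %in% stages || "skill" %in% stages || "compare" %in% stages) {
    idx <- stage("indices", {
      out <- list()
      yrs <- config$clim_years_full
      if ("hci" %in% config$indices) {
        thr <- monthly_thresholds(world$obs, world$band75, yrs)
        obs_hci <- hci_series(world$obs, thr, world$band150) |>
          classify_high_compression(clim_years = yrs,
                                    comparator = config$hci$comparator)
        fc_hci <- forecast_hci(world$global, world$band75, world$band150, yrs,
                               comparator = config$hci$comparator)
        readr::write_csv(obs_hci, file.path(outdir, "hci_observed.csv"))
        readr::write_csv(fc_hci, file.path(outdir, "hci_forecast_global.csv"))
        out$thresholds <- thr
        out$obs_hci <- obs_hci
        out$fc_hci <- fc_hci
      }
      if ("total" %in% config$indices) {
        ssta <- box_mean_ssta(world$obs, world$box, yrs)
        rt <- rolling_total(ssta)
        obs_total <- total_series(ssta, config$total$closure_months)
        thr_obs <- closure_threshold(obs_total, config$total$closures,
                                     distribution = rt$total)
        obs_total$closure <- recommend_closure(obs_total$total, thr_obs)
        fc_total <- forecast_total(world$global, world$box, yrs,
                                   config$total$closure_months)
        thr_fc <- forecast_closure_thresholds(fc_total, thr_obs$percentile)
        fc_total <- fc_total |>
          dplyr::left_join(thr_fc, by = "lead") |>
          dplyr::mutate(closure = recommend_closure(total, threshold))
        readr::write_csv(obs_total, file.path(outdir, "total_observed.csv"))
        readr::write_csv(fc_total, file.path(outdir, "total_forecast_global.csv"))
        readr::write_csv(tidy(thr_obs), file.path(outdir, "total_threshold.csv"))
        out$obs_ssta <- ssta
        out$obs_total <- obs_total
        out$total_threshold <- thr_obs
        out$fc_total <- fc_total
      }
      out
    })
    res$indices <- idx
  }

  # ---- skill ----
  if ("skill" %in% stages) {
    skl <- stage("skill", {
      out <- list()
      if ("hci" %in% config$indices) {
        joined <- dplyr::inner_join(
          dplyr::select(idx$obs_hci, year, month, obs_hci = hci,
                        obs_event = event),
          dplyr::select(idx$fc_hci, target_year, target_month, lead,
                        fc_hci = hci, fc_event = event),
          by = c("year" = "target_year", "month" = "target_month")
        )
        out$hci <- skill_report(joined, obs = obs_hci, fcst = fc_hci,
                                obs_event = obs_event, fcst_event = fc_event,
                                by = c("month", "lead"), time = "year",
                                n_boot = config$n_boot, seed = seed + 10L)
        readr::write_csv(out$hci, file.path(outdir, "skill_hci_global.csv"))
      }
      if ("total" %in% config$indices) {
        joined <- dplyr::inner_join(
          dplyr::select(idx$obs_total, year, month, obs_total = total,
                        obs_closure = closure),
          dplyr::select(idx$fc_total, target_year, target_month, lead,
                        fc_total = total, fc_closure = closure),
          by = c("year" = "target_year", "month" = "target_month")
        )
        out$total <- skill_report(joined, obs = obs_total, fcst = fc_total,
                                  obs_event = obs_closure,
                                  fcst_event = fc_closure,
                                  by = c("month", "lead"), time = "year",
                                  n_boot = config$n_boot, seed = seed + 11L)
        readr::write_csv(out$total, file.path(outdir, "skill_total_global.csv"))
      }
      out
    })
    res$skill <- skl
    if (isTRUE(config$write_figures)) {
      stage("figures", {
        if (!is.null(skl$hci)) {
          for (m in c("r", "accuracy", "sedi")) {
            ggplot2::ggsave(
              file.path(outdir, sprintf("skill_hci_%s.png", m)),
              plot_skill_heatmap(skl$hci, m), width = 7, height = 5, dpi = 120
            )
          }
          ggplot2::ggsave(
            file.path(outdir, "hci_series.png"),
            plot_index_series(dplyr::filter(idx$fc_hci, lead %in% c(0.5, 6.5, 11.5)),
                              idx$obs_hci, value = "hci"),
            width = 8, height = 4, dpi = 120
          )
        }
        invisible(NULL)
      })
    }
  }

  # ---- compare (four configurations) ----
  if ("compare" %in% stages) {
    cmp <- stage("compare", {
      configs <- build_configurations(
        world$global, world$downscaled,
        full_years = config$clim_years_full,
        comparison_years = config$clim_years_comparison
      )
      rep <- configuration_skill(configs, world$obs, world$band75,
                                 world$band150, n_boot = 0)
      readr::write_csv(rep, file.path(outdir, "skill_by_configuration.csv"))
      if (isTRUE(config$write_figures)) {
        ggplot2::ggsave(file.path(outdir, "skill_by_configuration.png"),
                        plot_skill_boxplot(rep), width = 8, height = 4,
                        dpi = 120)
      }
      rep
    })
    res$comparison <- cmp
  }

  jsonlite::write_json(info, file.path(outdir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$info <- info
  invisible(res)
}
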