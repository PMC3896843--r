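#' Configuration for an end-to-end run
#'
#' @param out_dir Run directory (created; artifacts and manifest land here).
#' @param seed Mandatory root seed; every stage derives its own substream.
#' @param world_preset `"desk"` (24 countries; default) or `"paper-scale"`
#'   (137 countries; not used by the test suite).
#' @param sim_config Optional [bf_sim_config()] overriding the preset.
#' @param stages Named logical vector toggling stages `estimate`, `quintiles`,
#'   `burden`, `report`.
#' @param pipeline A [bf_pipeline_config()]; its seed is overwritten by `seed`.
#' @return List of class `bf_run_config`.
#' @export
bf_run_config <- function(out_dir, seed,
                          world_preset = c("desk", "paper-scale"),
                          sim_config = NULL,
                          stages = c(estimate = TRUE, quintiles = TRUE,
                                     burden = TRUE, report = TRUE),
                          pipeline = bf_pipeline_config()) {
  if (missing(seed)) abort("seed is mandatory", class = "bf_config_error")
  world_preset <- match.arg(world_preset)
  defaults <- c(estimate = TRUE, quintiles = TRUE, burden = TRUE, report = TRUE)
  defaults[names(stages)] <- stages
  sim <- sim_config %||% bf_sim_config(seed = seed,
                                       paper_scale = world_preset == "paper-scale")
  sim$seed <- as.integer(seed)
  pipeline$seed <- as.integer(seed)
  pipeline$gpr$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 world_preset = world_preset, sim_config = sim,
                 stages = defaults, pipeline = pipeline),
            class = "bf_run_config")
}

write_stage <- function(tbl, dir, name) {
  readr::write_csv(tbl, file.path(dir, name))
  name
}

#' Run the full analysis end to end
#'
#' Simulates the synthetic world, harmonizes and models prevalence, runs the
#' wealth-quintile analysis and the comparative risk assessment, writes all
#' artifacts as plain CSV into the run directory, and finishes with a manifest
#' (package version, seed, per-file MD5 hashes) that makes the run exactly
#' reproducible. Stage failures abort with the stage name; artifacts written
#' before the failure are retained.
#'
#' @param config A [bf_run_config()].
#' @param quiet Suppress per-stage messages.
#' @return List of class `bf_run` with the in-memory results (`world`,
#'   `surveys`, `fit`, `income`, `trends`, `burden`, `manifest`) and the run
#'   directory.
#' @export
bf_run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "bf_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "bf_stage_error")
    })
    say("stage %-10s %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  world <- run_stage("simulate", {
    w <- bf_sim_world(config$sim_config)
    files <- c(files, write_stage(w$trajectories, config$out_dir, "world.csv"),
                write_stage(w$covariates, config$out_dir, "covariates.csv"),
                write_stage(w$geo, config$out_dir, "geo.csv"))
    w
  })
  surveys <- run_stage("surveys", {
    s <- bf_sim_surveys(world)
    files <- c(files, write_stage(s, config$out_dir, "surveys.csv"))
    s
  })

  fit <- NULL
  if (config$stages[["estimate"]]) {
    fit <- run_stage("estimate", {
      f <- bf_estimate_prevalence(surveys, world$covariates, world$geo,
                                  config$pipeline)
      files <- c(files, write_stage(f$estimates, config$out_dir, "estimates.csv"))
      f
    })
  }

  income <- NULL; trends <- NULL
  if (config$stages[["quintiles"]]) {
    qres <- run_stage("quintiles", {
      hh <- bf_sim_households(seed = config$seed)
      sel <- bf_select_assets(hh)
      inc <- bf_estimate_income(sel)
      records <- bf_sim_quintile_records(
        gradient = 0.02, trend_per_year = 0.008, seed = config$seed
      )
      qprev <- bf_quintile_prevalence(records)
      tr <- bf_quintile_trends(qprev)
      files <- c(files,
                  write_stage(inc, config$out_dir, "income.csv"),
                  write_stage(qprev, config$out_dir, "quintile_prevalence.csv"),
                  write_stage(tibble::tibble(verdict = tr$verdict,
                                             f_statistic = tr$f_statistic,
                                             p_value = tr$p_value),
                              config$out_dir, "trend_verdicts.csv"))
      list(income = inc, trends = tr, qprev = qprev)
    })
    income <- qres$income; trends <- qres$trends
  }

  burden <- NULL
  if (config$stages[["burden"]]) {
    if (is.null(fit)) {
      abort("stage 'burden' failed: burden requires the estimate stage",
            class = "bf_stage_error")
    }
    burden <- run_stage("burden", {
      bg <- bf_sim_burden_background(world)
      files <- c(files, write_stage(bg, config$out_dir, "burden_background.csv"))
      b <- bf_burden_cra(fit, bg, seed = config$seed)
      files <- c(files,
                  write_stage(dplyr::select(b, -".draws"), config$out_dir,
                              "attributable.csv"),
                  write_stage(
                    dplyr::select(b, "country_id", "year", "age_group",
                                  "outcome", "metric", "paf_mean",
                                  "paf_lower", "paf_upper"),
                    config$out_dir, "paf.csv"))
      b
    })
  }

  if (config$stages[["report"]] && !is.null(burden)) {
    run_stage("report", {
      rep_files <- bf_make_report(config$out_dir)
      files <- c(files, rep_files)
      invisible(NULL)
    })
  }

  manifest <- list(
    package = "bfequity",
    version = as.character(utils::packageVersion("bfequity")),
    seed = config$seed,
    world_preset = config$world_preset,
    stages = as.list(config$stages),
    files = as.list(tools::md5sum(file.path(config$out_dir, unique(files))))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(world = world, surveys = surveys, fit = fit, income = income,
                 trends = trends, burden = burden, manifest = manifest,
                 out_dir = config$out_dir),
            class = "bf_run")
}

md_table <- function(df) {
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}

#' Build summary report tables from a run directory
#'
#' Produces, as CSV plus one markdown file: the top-k countries by absolute
#' attributable DALYs and by attributable DALYs as a percent of the country's
#' total DALYs (latest year, all ages and outcomes combined), with countries
#' appearing on both lists flagged; a first-versus-last-year prevalence
#' comparison per country and indicator with a percent-change column; and the
#' quintile trend verdicts.
#'
#' @param run_dir Directory written by [bf_run_all()].
#' @param k Table length (default 10).
#' @return Character vector of files written (relative to `run_dir`),
#'   invisibly the same.
#' @export
bf_make_report <- function(run_dir, k = 10) {
  need <- c("attributable.csv", "estimates.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0) {
    abort(paste0("missing artifacts: ", paste(missing, collapse = ", ")),
          class = "bf_report_error")
  }
  att <- readr::read_csv(file.path(run_dir, "attributable.csv"),
                         show_col_types = FALSE)
  est <- readr::read_csv(file.path(run_dir, "estimates.csv"),
                         show_col_types = FALSE)
  files <- character(0)

  yr <- max(att$year)
  dalys <- att |>
    dplyr::filter(.data$metric == "DALYs", .data$year == yr) |>
    dplyr::group_by(.data$country_id) |>
    dplyr::summarise(attributable = sum(.data$attributable_mean),
                     total = sum(.data$background), .groups = "drop") |>
    dplyr::mutate(percent = 100 * .data$attributable / .data$total)
  top_abs <- dalys |>
    dplyr::slice_max(.data$attributable, n = k, with_ties = FALSE) |>
    dplyr::mutate(rank = dplyr::row_number())
  top_pct <- dalys |>
    dplyr::slice_max(.data$percent, n = k, with_ties = FALSE) |>
    dplyr::mutate(rank = dplyr::row_number())
  both <- intersect(top_abs$country_id, top_pct$country_id)
  top_abs$in_both_lists <- top_abs$country_id %in% both
  top_pct$in_both_lists <- top_pct$country_id %in% both
  files <- c(files, write_stage(top_abs, run_dir, "report_top_absolute.csv"),
             write_stage(top_pct, run_dir, "report_top_percent.csv"))

  y0 <- min(est$year); y1 <- max(est$year)
  firstlast <- est |>
    dplyr::filter(.data$year %in% c(y0, y1)) |>
    dplyr::select("country_id", "indicator", "year", "mean", "lower_95",
                  "upper_95") |>
    tidyr::pivot_wider(names_from = "year",
                       values_from = c("mean", "lower_95", "upper_95")) |>
    dplyr::mutate(percent_change =
                    100 * (.data[[paste0("mean_", y1)]] -
                             .data[[paste0("mean_", y0)]]) /
                    .data[[paste0("mean_", y0)]])
  files <- c(files, write_stage(firstlast, run_dir, "report_first_last.csv"))

  md <- c(
    sprintf("# Run report (%d)", yr),
    "",
    sprintf("## Top %d countries, absolute attributable DALYs", k),
    md_table(dplyr::mutate(top_abs, dplyr::across(dplyr::where(is.numeric),
                                                  ~signif(.x, 4)))),
    "",
    sprintf("## Top %d countries, percent of total DALYs attributable", k),
    md_table(dplyr::mutate(top_pct, dplyr::across(dplyr::where(is.numeric),
                                                  ~signif(.x, 4))))
  )
  if (file.exists(file.path(run_dir, "trend_verdicts.csv"))) {
    tv <- readr::read_csv(file.path(run_dir, "trend_verdicts.csv"),
                          show_col_types = FALSE)
    md <- c(md, "", "## Quintile trend verdicts",
            md_table(dplyr::mutate(tv, dplyr::across(dplyr::where(is.numeric),
                                                     ~signif(.x, 4)))))
  }
  writeLines(md, file.path(run_dir, "report.md"))
  files <- c(files, "report.md")
  invisible(files)
}
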