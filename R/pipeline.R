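# End-to-end orchestration: data (synthetic or CSV) -> network -> capacity ->
# stress scenarios -> indicators, with input validation, seeded replicates
# and a run manifest.

#' Validate the three input tables
#'
#' Checks, before any simulation starts: 5-digit municipality IDs with a
#' non-zero state digit, non-negative opening hours, parseable visit dates
#' (inside the configured period if one is given) and referential integrity
#' (every contact's physician exists in the physician table, every
#' municipality in the gazetteer).
#'
#' @param contacts,physicians,municipalities The three input tables.
#' @param period Optional `Date` vector of length 2 bounding the visit dates.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_tables <- function(contacts, physicians, municipalities,
                            period = NULL) {
  check_municipality_ids(municipalities$municipality_id)
  check_municipality_ids(physicians$municipality_id,
                         "physicians$municipality_id")
  check_municipality_ids(contacts$municipality_id,
                         "contacts$municipality_id")
  if (any(is.na(physicians$weekly_opening_hours) |
          physicians$weekly_opening_hours < 0, na.rm = FALSE)) {
    bad <- which(is.na(physicians$weekly_opening_hours) |
                   physicians$weekly_opening_hours < 0)[1]
    abort(sprintf("negative or missing opening hours for physician '%s'",
                  physicians$physician_id[bad]))
  }
  dates <- suppressWarnings(as.Date(contacts$visit_date))
  if (anyNA(dates)) {
    abort(sprintf("unparseable visit_date at contacts row %d",
                  which(is.na(dates))[1]))
  }
  if (!is.null(period)) {
    out <- dates < period[1] | dates > period[2]
    if (any(out)) {
      abort(sprintf("visit_date outside the configured period at contacts row %d",
                    which(out)[1]))
    }
  }
  miss_phys <- setdiff(contacts$physician_id, physicians$physician_id)
  if (length(miss_phys) > 0) {
    abort(sprintf("contact references unknown physician '%s'", miss_phys[1]))
  }
  miss_mun <- setdiff(c(physicians$municipality_id, contacts$municipality_id),
                      as.character(municipalities$municipality_id))
  if (length(miss_mun) > 0) {
    abort(sprintf("unknown municipality '%s'", miss_mun[1]))
  }
  invisible(TRUE)
}

#' Default pipeline configuration
#'
#' @param synth A [synth_config()] (or `NULL` to read CSVs from
#'   `input_dir`).
#' @param input_dir Directory with `contacts.csv`, `physicians.csv`,
#'   `municipalities.csv` when `synth` is `NULL`.
#' @param params A [sim_params()].
#' @param specialties Specialties to process (default: all present).
#' @param scenario `"removal"`, `"shock"` or `"both"`.
#' @param ensemble_removal,ensemble_shock Ensemble sizes (defaults 100 and
#'   10).
#' @param shock_fraction Shock size in percent (default 15).
#' @param window_days Co-visit window half-width (default 91).
#' @param seed Master seed.
#' @return A `care_config` list.
#' @export
care_config <- function(synth = synth_config(), input_dir = NULL,
                        params = sim_params(), specialties = NULL,
                        scenario = c("removal", "shock", "both"),
                        ensemble_removal = 100, ensemble_shock = 10,
                        shock_fraction = 15, window_days = 91, seed = 1) {
  structure(list(
    synth = synth, input_dir = input_dir, params = params,
    specialties = specialties, scenario = match.arg(scenario),
    ensemble_removal = as.integer(ensemble_removal),
    ensemble_shock = as.integer(ensemble_shock),
    shock_fraction = shock_fraction, window_days = window_days,
    seed = as.integer(seed)
  ), class = "care_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may contain blocks `synth` (fields of [synth_config()]), `params`
#' (fields of [sim_params()]) and any top-level field of [care_config()].
#'
#' @param path YAML or JSON configuration file.
#' @return A `care_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  synth <- NULL
  if (!is.null(raw$synth)) synth <- do.call(synth_config, raw$synth)
  params <- do.call(sim_params, if (is.null(raw$params)) list() else raw$params)
  keep <- intersect(names(raw), c("input_dir", "specialties", "scenario",
                                  "ensemble_removal", "ensemble_shock",
                                  "shock_fraction", "window_days", "seed"))
  do.call(care_config, c(list(synth = synth, params = params), raw[keep]))
}

#' Run the full stress-testing pipeline
#'
#' Generates (or reads and validates) the input tables, builds and thresholds
#' the patient-sharing network, estimates capacities, runs the configured
#' stress scenario(s) per specialty and writes network exports, trajectories,
#' resilience curves, critical limits, risk/benefit scores, regional levels,
#' an aggregate JSON summary and a run manifest to `out_dir`.
#'
#' @param config A `care_config` (or path to a YAML/JSON file).
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results (`dataset`,
#'   `networks`, `profiles`, `trajectories`, `curves`, `limits`, `scores`,
#'   `regression`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "care_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  if (!is.null(config$synth)) {
    say("generating synthetic data (seed %d)", config$synth$seed)
    dataset <- generate_dataset(config$synth)
  } else {
    if (is.null(config$input_dir)) abort("config needs `synth` or `input_dir`")
    dataset <- read_dataset(config$input_dir)
  }
  validate_tables(dataset$contacts, dataset$physicians, dataset$municipalities)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_dataset(dataset, file.path(out_dir, "data"))

  say("building patient-sharing network (window %d days)", config$window_days)
  net_all <- build_sharing_network(dataset$contacts, dataset$physicians,
                                   window_days = config$window_days)
  net_all <- threshold_network(net_all, p = config$params$p,
                               d = config$params$d, dataset$municipalities)
  profiles <- build_physician_profiles(dataset$contacts, dataset$physicians)
  profiles <- estimate_capacity(profiles, c = config$params$c)
  readr::write_csv(profiles, file.path(out_dir, "physician_profiles.csv"))

  specs <- config$specialties
  if (is.null(specs)) specs <- sort(unique(stats::na.omit(net_all$nodes$specialty)))

  results <- list(dataset = dataset, profiles = profiles, networks = list(),
                  trajectories = list(), shocks = list(), curves = list(),
                  limits = list(), scores = list())
  all_limits <- list(); all_risk <- list(); all_benefit <- list()
  for (sp in specs) {
    say("specialty %s", sp)
    net <- specialty_layer(net_all, sp)
    results$networks[[sp]] <- net
    write_network(net, file.path(out_dir, sprintf("network_%s.csv", sp)))
    prof_sp <- dplyr::semi_join(profiles, net$nodes, by = "node_id")

    risk <- risk_scores(net, prof_sp)
    benefit <- benefit_scores(prof_sp)
    all_risk[[sp]] <- risk; all_benefit[[sp]] <- benefit

    if (config$scenario %in% c("removal", "both")) {
      traj <- run_iterative_removal(net, prof_sp, dataset$municipalities,
                                    config$params,
                                    ensemble = config$ensemble_removal,
                                    seed = config$seed)
      curves <- resilience_curves(traj)
      limits <- critical_limits(curves)
      limits$specialty <- sp
      results$trajectories[[sp]] <- traj
      results$curves[[sp]] <- curves
      results$limits[[sp]] <- limits
      all_limits[[sp]] <- limits
      readr::write_csv(traj, file.path(out_dir, sprintf("trajectories_%s.csv", sp)))
      readr::write_csv(curves, file.path(out_dir, sprintf("curves_%s.csv", sp)))
    }
    if (config$scenario %in% c("shock", "both")) {
      shock <- run_shock(net, prof_sp, dataset$municipalities, config$params,
                         shock_fraction = config$shock_fraction,
                         ensemble = config$ensemble_shock,
                         seed = config$seed)
      results$shocks[[sp]] <- shock
      readr::write_csv(shock, file.path(out_dir, sprintf("shock_%s.csv", sp)))
    }
  }
  risk_all <- dplyr::bind_rows(all_risk)
  benefit_all <- dplyr::bind_rows(all_benefit)
  results$scores <- list(risk = risk_all, benefit = benefit_all)
  readr::write_csv(risk_all, file.path(out_dir, "risk_scores.csv"))
  readr::write_csv(benefit_all, file.path(out_dir, "benefit_scores.csv"))

  summary_rows <- NULL
  if (length(all_limits) > 0) {
    limits_all <- dplyr::bind_rows(all_limits)
    readr::write_csv(limits_all, file.path(out_dir, "critical_limits.csv"))
    lev_r <- regional_levels(risk_all, "risk")
    lev_b <- regional_levels(benefit_all, "benefit")
    summary_rows <- dplyr::left_join(
      limits_all,
      dplyr::full_join(
        dplyr::rename(lev_r, pct_risk_above = "pct_above_average"),
        dplyr::rename(dplyr::select(lev_b, -"n_physicians"),
                      pct_benefit_above = "pct_above_average"),
        by = c("specialty", "region")),
      by = c("specialty", "region"))
    jsonlite::write_json(summary_rows, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (length(specs) > 1) {
      means <- state_score_means(risk_all, benefit_all)
      results$regression <- tryCatch(
        score_resilience_regression(limits_all, means),
        error = function(e) NULL)
      if (!is.null(results$regression)) {
        readr::write_csv(tidy(results$regression),
                         file.path(out_dir, "regression_coefficients.csv"))
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("carestress")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    replicate_seeds_removal = config$seed + seq_len(config$ensemble_removal) - 1,
    replicate_seeds_shock = config$seed + seq_len(config$ensemble_shock) - 1,
    scenario = config$scenario,
    params = unclass(config$params),
    synth = if (!is.null(config$synth)) {
      s <- unclass(config$synth); s$period_start <- as.character(s$period_start); s
    },
    input_checksums = as.list(tools::md5sum(
      list.files(file.path(out_dir, "data"), full.names = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %s", out_dir)
  invisible(results)
}
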