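# Synthetic claims-like data: municipality gazetteer, physician attributes and
# one year of patient-physician contact records. The generator reproduces the
# statistical structure the downstream modules rely on -- spatially clustered
# states, Zipf-like municipality sizes, heavy-tailed physician loads and
# distance-decaying patient-physician affinity -- without resembling any real
# region.

#' The 13 medical specialty abbreviations
#'
#' @return Character vector of specialty labels (GP, OPH, SRG, DER, OBGYN,
#'   ENT, IM, PED, NEU, ORTH, PSY, RAD, URO).
#' @export
specialty_labels <- function() {
  c("GP", "OPH", "SRG", "DER", "OBGYN", "ENT", "IM", "PED",
    "NEU", "ORTH", "PSY", "RAD", "URO")
}

#' Configuration for the synthetic-data generator
#'
#' @param n_municipalities Number of municipalities.
#' @param n_states Number of federal states (at most 9; the state is encoded
#'   in the first digit of the 5-digit municipality ID).
#' @param n_physicians_per_specialty Physicians generated per specialty.
#' @param specialties Specialty labels; defaults to [specialty_labels()].
#' @param n_patients Number of patients.
#' @param visits_per_patient_mean Mean number of visits per patient over the
#'   period (Poisson). The default, 13, matches the order of magnitude of
#'   annual per-capita physician contacts in European administrative data.
#' @param specialties_per_patient Size of each patient's specialty
#'   repertoire: patients repeatedly visit a small personal set of
#'   specialties rather than all of them, which is what creates
#'   same-specialty co-visits and hence patient-sharing edges.
#' @param period_days Length of the observation period in days.
#' @param period_start First day of the observation period (`Date`).
#' @param locality_scale_km Spatial decay scale (km) of patient-physician
#'   affinity: visit probability decays as `exp(-distance / scale)`.
#' @param opening_hours_range Range (hours/week) from which weekly opening
#'   hours are drawn uniformly.
#' @param attractiveness_sdlog Log-normal sd of the per-physician
#'   attractiveness multiplier; produces heavy-tailed patient loads. Set to 0
#'   for homogeneous physicians.
#' @param zipf_exponent Exponent of the Zipf-like municipality size weights.
#' @param area_scale Linear scale factor for the national bounding box
#'   (default 1, a compact ~300 x 220 km country). Values above ~2 push
#'   neighbouring states beyond typical travel-distance thresholds, giving
#'   loosely coupled regions whose resilience is determined by their own
#'   capacity rather than by country-wide spillover.
#' @param state_weights Optional vector of relative state population weights
#'   (length `n_states`). The default `NULL` gives states comparable
#'   weight; unequal weights create dense and sparse states, i.e. regions
#'   that genuinely differ in physician density and hence resilience.
#' @param patient_state_weights Optional vector (length `n_states`) of
#'   relative patient-population weights. When it differs from
#'   `state_weights`, states get different patients-per-physician ratios —
#'   the structural under-/over-supply that makes regions genuinely more or
#'   less resilient. `NULL` uses the same weights as physicians.
#' @param seed Integer seed; all generators are exactly reproducible.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_municipalities = 45,
                         n_states = 9,
                         n_physicians_per_specialty = 15,
                         specialties = specialty_labels(),
                         n_patients = 2000,
                         visits_per_patient_mean = 13,
                         specialties_per_patient = 2,
                         period_days = 365,
                         period_start = as.Date("2018-01-01"),
                         locality_scale_km = 30,
                         opening_hours_range = c(15, 45),
                         attractiveness_sdlog = 0.75,
                         zipf_exponent = 1,
                         area_scale = 1,
                         state_weights = NULL,
                         patient_state_weights = NULL,
                         seed = 1L) {
  cfg <- list(
    n_municipalities = check_count(n_municipalities, "n_municipalities"),
    n_states = check_count(n_states, "n_states"),
    n_physicians_per_specialty = check_count(n_physicians_per_specialty,
                                             "n_physicians_per_specialty"),
    specialties = as.character(specialties),
    n_patients = check_count(n_patients, "n_patients"),
    visits_per_patient_mean = check_positive(visits_per_patient_mean,
                                             "visits_per_patient_mean"),
    specialties_per_patient = check_count(specialties_per_patient,
                                          "specialties_per_patient"),
    period_days = check_count(period_days, "period_days"),
    period_start = as.Date(period_start),
    locality_scale_km = check_positive(locality_scale_km, "locality_scale_km"),
    opening_hours_range = as.numeric(opening_hours_range),
    attractiveness_sdlog = as.numeric(attractiveness_sdlog),
    zipf_exponent = as.numeric(zipf_exponent),
    area_scale = check_positive(area_scale, "area_scale"),
    state_weights = if (!is.null(state_weights)) as.numeric(state_weights),
    patient_state_weights = if (!is.null(patient_state_weights))
      as.numeric(patient_state_weights),
    seed = check_count(seed, "seed", min = 0)
  )
  for (f in c("state_weights", "patient_state_weights")) {
    if (!is.null(cfg[[f]]) &&
        (length(cfg[[f]]) != cfg$n_states || any(cfg[[f]] <= 0))) {
      abort(sprintf("`%s` must be positive and of length `n_states`", f))
    }
  }
  if (cfg$n_states > 9) abort("`n_states` must be at most 9 (single state digit)")
  if (cfg$n_municipalities < cfg$n_states) {
    abort("need at least one municipality per state")
  }
  if (length(cfg$specialties) < 1 || anyDuplicated(cfg$specialties)) {
    abort("`specialties` must be a non-empty set of unique labels")
  }
  cfg$specialties_per_patient <- min(cfg$specialties_per_patient,
                                     length(cfg$specialties))
  if (length(cfg$opening_hours_range) != 2 ||
      diff(cfg$opening_hours_range) < 0 || cfg$opening_hours_range[1] < 0) {
    abort("`opening_hours_range` must be an increasing pair of non-negative hours")
  }
  if (cfg$attractiveness_sdlog < 0) abort("`attractiveness_sdlog` must be >= 0")
  structure(cfg, class = "synth_config")
}

#' Generate a municipality gazetteer
#'
#' States are laid out as spatially contiguous clusters on a bounded
#' coordinate box; municipalities scatter around their state centre. Each
#' municipality receives a Zipf-like size weight that drives both patient
#' homes and physician locations, producing urban/rural heterogeneity.
#'
#' @param cfg A [synth_config()].
#' @return Tibble with columns `municipality_id` (5-digit string, first digit
#'   = state), `state`, `lat`, `lon`, `size_weight`.
#' @export
generate_municipalities <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  ns <- cfg$n_states
  # state centres on a grid inside a ~ national-scale box
  ncol_grid <- ceiling(sqrt(ns))
  nrow_grid <- ceiling(ns / ncol_grid)
  # a compact national box (~300 x 220 km at area_scale 1) keeps the
  # physician density per km^2 realistic at desk-scale physician counts, so
  # the default distance threshold d = 100 km does not shatter the
  # specialty layers
  lon_range <- 12 + c(-2, 2) * cfg$area_scale
  lat_range <- 47.5 + c(-1, 1) * cfg$area_scale
  cx <- lon_range[1] + (seq_len(ncol_grid) - 0.5) / ncol_grid * diff(lon_range)
  cy <- lat_range[1] + (seq_len(nrow_grid) - 0.5) / nrow_grid * diff(lat_range)
  centres <- expand.grid(lon = cx, lat = cy)[seq_len(ns), ]
  # municipality counts per state: as equal as possible
  per_state <- rep(cfg$n_municipalities %/% ns, ns)
  extra <- cfg$n_municipalities %% ns
  if (extra > 0) per_state[seq_len(extra)] <- per_state[seq_len(extra)] + 1
  sd_lon <- diff(lon_range) / ncol_grid / 5
  sd_lat <- diff(lat_range) / nrow_grid / 5
  rows <- purrr::map(seq_len(ns), function(s) {
    k <- per_state[s]
    tibble::tibble(
      municipality_id = sprintf("%d%04d", s, seq_len(k)),
      state = as.character(s),
      lat = stats::rnorm(k, centres$lat[s], sd_lat),
      lon = stats::rnorm(k, centres$lon[s], sd_lon)
    )
  })
  out <- dplyr::bind_rows(rows)
  # Zipf-like size weights within each state: every state has its own
  # urban hierarchy (capital, towns, villages), so states end up with
  # comparable populations but strong internal heterogeneity
  out$size_weight <- stats::ave(rep(1, nrow(out)), out$state,
                                FUN = function(x) {
                                  r <- sample.int(length(x))
                                  w <- 1 / r^cfg$zipf_exponent
                                  w / sum(w)
                                })
  if (!is.null(cfg$state_weights)) {
    out$size_weight <- out$size_weight *
      cfg$state_weights[as.integer(out$state)]
  }
  out$size_weight <- out$size_weight / sum(out$size_weight)
  out
}

#' Generate physician attributes
#'
#' Physicians of each specialty are placed in municipalities proportionally to
#' the municipality size weight. Weekly opening hours are uniform over
#' `cfg$opening_hours_range`; a log-normal attractiveness multiplier makes
#' patient loads heavy-tailed.
#'
#' @param cfg A [synth_config()].
#' @param municipalities Output of [generate_municipalities()].
#' @return Tibble with columns `physician_id`, `specialty`, `municipality_id`,
#'   `weekly_opening_hours`, `attractiveness`.
#' @export
generate_physicians <- function(cfg, municipalities) {
  stopifnot(inherits(cfg, "synth_config"))
  if (nrow(municipalities) == 0) abort("empty municipality table")
  set.seed(cfg$seed + 2L)
  n_spec <- length(cfg$specialties)
  n_total <- n_spec * cfg$n_physicians_per_specialty
  mun_idx <- sample.int(nrow(municipalities), n_total, replace = TRUE,
                        prob = municipalities$size_weight)
  tibble::tibble(
    physician_id = sprintf("D%05d", seq_len(n_total)),
    specialty = rep(cfg$specialties, each = cfg$n_physicians_per_specialty),
    municipality_id = municipalities$municipality_id[mun_idx],
    weekly_opening_hours = round(runif(n_total, cfg$opening_hours_range[1],
                                       cfg$opening_hours_range[2]), 1),
    attractiveness = rlnorm(n_total, meanlog = 0, sdlog = cfg$attractiveness_sdlog)
  )
}

#' Generate contact records
#'
#' Each patient gets a home municipality (drawn by size weight), a personal
#' repertoire of `specialties_per_patient` specialties, and a Poisson number
#' of visits with dates i.i.d. uniform over the period. For every visit a
#' specialty is drawn uniformly from the patient's repertoire and the
#' physician within the specialty is chosen with probability proportional to
#' `attractiveness * exp(-distance(home, physician) / locality_scale_km)`.
#' If all affinities underflow to zero (vanishing locality scale with no
#' physician in reach) the choice falls back to the nearest physicians of the
#' specialty, weighted by attractiveness.
#'
#' @param cfg A [synth_config()].
#' @param municipalities Output of [generate_municipalities()].
#' @param physicians Output of [generate_physicians()].
#' @return Tibble with columns `patient_id`, `physician_id`, `visit_date`
#'   (Date), `municipality_id` (the physician's).
#' @export
generate_contacts <- function(cfg, municipalities, physicians) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(physicians) || nrow(physicians) == 0) {
    abort("empty physician table: cannot generate contacts")
  }
  set.seed(cfg$seed + 3L)
  dmat <- municipality_distances(municipalities)
  phys_mun <- match(physicians$municipality_id, municipalities$municipality_id)
  if (anyNA(phys_mun)) abort("physician municipality missing from gazetteer")

  home_w <- municipalities$size_weight
  if (!is.null(cfg$patient_state_weights)) {
    # reweight states for patients while keeping the within-state hierarchy
    st <- as.integer(municipalities$state)
    state_tot <- tapply(home_w, st, sum)
    home_w <- home_w / state_tot[as.character(st)] *
      cfg$patient_state_weights[st]
  }
  home_idx <- sample.int(nrow(municipalities), cfg$n_patients, replace = TRUE,
                         prob = home_w)
  n_visits <- rpois(cfg$n_patients, cfg$visits_per_patient_mean)
  visits <- tibble::tibble(
    patient_id = rep(sprintf("P%06d", seq_len(cfg$n_patients)), n_visits),
    home_idx = rep(home_idx, n_visits)
  )
  n_tot <- nrow(visits)
  if (n_tot == 0) {
    return(tibble::tibble(patient_id = character(), physician_id = character(),
                          visit_date = as.Date(character()),
                          municipality_id = character()))
  }
  # per-patient specialty repertoire; visits draw uniformly within it
  k_rep <- cfg$specialties_per_patient
  repertoire <- replicate(cfg$n_patients,
                          sample(cfg$specialties, k_rep), simplify = FALSE)
  pat_idx <- rep(seq_len(cfg$n_patients), n_visits)
  visits$specialty <- vapply(pat_idx, function(p) {
    r <- repertoire[[p]]
    r[sample.int(length(r), 1L)]
  }, character(1))

  # choice probabilities per (home municipality, specialty): shared by all
  # visits in a group, so draw grouped
  spec_rows <- split(seq_len(nrow(physicians)), physicians$specialty)
  visits$phys_row <- NA_integer_
  grp <- paste(visits$home_idx, visits$specialty, sep = "|")
  for (g in unique(grp)) {
    sel <- which(grp == g)
    h <- visits$home_idx[sel[1]]
    rows <- spec_rows[[visits$specialty[sel[1]]]]
    dist_km <- dmat[h, phys_mun[rows]]
    w <- physicians$attractiveness[rows] * exp(-dist_km / cfg$locality_scale_km)
    if (sum(w) <= 0) {
      # vanishing locality scale: restrict to the closest physicians
      nearest <- dist_km <= min(dist_km) + 1e-9
      w <- physicians$attractiveness[rows] * nearest
    }
    visits$phys_row[sel] <- rows[sample.int(length(rows), length(sel),
                                            replace = TRUE, prob = w)]
  }
  visits$visit_date <- cfg$period_start +
    sample.int(cfg$period_days, n_tot, replace = TRUE) - 1L
  out <- tibble::tibble(
    patient_id = visits$patient_id,
    physician_id = physicians$physician_id[visits$phys_row],
    visit_date = visits$visit_date,
    municipality_id = physicians$municipality_id[visits$phys_row]
  )
  dplyr::arrange(out, .data$patient_id, .data$visit_date, .data$physician_id)
}

#' Generate a full synthetic data set
#'
#' @param cfg A [synth_config()].
#' @return List with tibbles `municipalities`, `physicians`, `contacts`.
#' @export
generate_dataset <- function(cfg) {
  municipalities <- generate_municipalities(cfg)
  physicians <- generate_physicians(cfg, municipalities)
  contacts <- generate_contacts(cfg, municipalities, physicians)
  list(municipalities = municipalities, physicians = physicians,
       contacts = contacts)
}

#' Write a synthetic data set to CSV
#'
#' Writes `contacts.csv`, `physicians.csv` and `municipalities.csv` with
#' headers; dates are ISO-8601.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(dataset$contacts, file.path(dir, "contacts.csv"))
  readr::write_csv(dataset$physicians, file.path(dir, "physicians.csv"))
  readr::write_csv(dataset$municipalities, file.path(dir, "municipalities.csv"))
  invisible(dir)
}

#' Read a data set written by [write_dataset()]
#'
#' @param dir Directory holding `contacts.csv`, `physicians.csv`,
#'   `municipalities.csv`.
#' @return List with tibbles `municipalities`, `physicians`, `contacts`.
#' @export
read_dataset <- function(dir) {
  read1 <- function(f, coltypes) {
    path <- file.path(dir, f)
    if (!file.exists(path)) abort(sprintf("missing input file: %s", path))
    readr::read_csv(path, col_types = coltypes, progress = FALSE)
  }
  list(
    municipalities = read1("municipalities.csv",
                           readr::cols(municipality_id = "c", state = "c",
                                       .default = "?")),
    physicians = read1("physicians.csv",
                       readr::cols(physician_id = "c", municipality_id = "c",
                                   .default = "?")),
    contacts = read1("contacts.csv",
                     readr::cols(patient_id = "c", physician_id = "c",
                                 municipality_id = "c", visit_date = "D",
                                 .default = "?"))
  )
}
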