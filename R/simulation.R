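# Agent-based displacement engine. Patients sit at physicians; when a
# physician is removed their patients enter a searching state and try to
# relocate along the patient-sharing network. A searching patient picks a new
# physician proportionally to the shared-patient weight from their most
# recent physician (or uniformly at random with probability alpha), subject
# to a maximum travel distance d from their home municipality; after s
# rejections the patient is lost and leaves the simulation.

#' Simulation parameters
#'
#' Baseline values: `s = 10` rejections before a patient is lost, `c = 10`
#' (top capacity percentile used in [estimate_capacity()]), `d = 100` km
#' maximum travel distance, `p = 2` minimum shared patients for a network
#' edge, `alpha = 0` probability of random re-location. A candidate farther
#' than `d` from the patient's home municipality is redrawn up to
#' `max_distance_retries` times (fixed at 10); after that the last candidate
#' is kept regardless of distance.
#'
#' @param s Maximum rejections before a patient is lost.
#' @param c Capacity percentile (documented here; consumed by
#'   [estimate_capacity()]).
#' @param d Maximum travel distance in km.
#' @param p Minimum shared patients (consumed by [threshold_network()]).
#' @param alpha Probability of choosing a physician uniformly at random,
#'   ignoring network weights.
#' @param max_distance_retries Redraws allowed before the distance rule is
#'   waived.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(s = 10, c = 10, d = 100, p = 2, alpha = 0,
                       max_distance_retries = 10) {
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1]")
  if (s < 1) abort("`s` must be >= 1")
  if (d <= 0) abort("`d` must be > 0")
  if (p < 1) abort("`p` must be >= 1")
  structure(list(s = as.integer(s), c = as.numeric(c), d = as.numeric(d),
                 p = as.numeric(p), alpha = as.numeric(alpha),
                 max_distance_retries = as.integer(max_distance_retries)),
            class = "sim_params")
}

#' Initialise the simulation state
#'
#' Creates `N_i` patient agents at every physician `i` of a single-specialty
#' network. Each patient's home municipality is the municipality of their
#' initial physician. Initially no patient is searching or lost and every
#' physician's free capacity is `C_i - N_i` (non-negative by capacity
#' flooring).
#'
#' @param net A thresholded, single-specialty `sharing_network`.
#' @param profiles Physician profiles with `node_id`, `n_quarterly`,
#'   `capacity` (see [estimate_capacity()]).
#' @param municipalities Gazetteer with coordinates for all node
#'   municipalities.
#' @return A `care_state` object.
#' @export
initialize_state <- function(net, profiles, municipalities) {
  stopifnot(inherits(net, "sharing_network"))
  if (nrow(net$nodes) == 0) abort("empty network: nothing to simulate")
  specs <- unique(net$nodes$specialty)
  if (length(specs) > 1) {
    abort("network spans several specialties; apply specialty_layer() first")
  }
  prof <- dplyr::left_join(net$nodes, profiles, by = "node_id",
                           suffix = c("", ".prof"))
  if (anyNA(prof$n_quarterly) || anyNA(prof$capacity)) {
    abort("profiles must provide n_quarterly and capacity for every node")
  }
  if (any(prof$n_quarterly > prof$capacity)) {
    abort("initial patient count exceeds capacity for at least one physician")
  }
  mun_ids <- as.character(municipalities$municipality_id)
  phys_mun <- match(net$nodes$municipality_id, mun_ids)
  if (anyNA(phys_mun)) {
    abort(sprintf("no coordinates for municipality '%s'",
                  net$nodes$municipality_id[which(is.na(phys_mun))[1]]))
  }
  n <- nrow(net$nodes)
  idx_of <- setNames(seq_len(n), net$nodes$node_id)
  nbr <- rep(list(integer()), n)
  nbrw <- rep(list(numeric()), n)
  if (nrow(net$edges) > 0) {
    ei <- idx_of[net$edges$from]
    ej <- idx_of[net$edges$to]
    w <- net$edges$weight
    both_i <- c(ei, ej)
    both_j <- c(ej, ei)
    both_w <- c(w, w)
    sp <- split(seq_along(both_i), both_i)
    for (k in names(sp)) {
      i <- as.integer(k)
      nbr[[i]] <- both_j[sp[[k]]]
      nbrw[[i]] <- both_w[sp[[k]]]
    }
  }
  npat <- as.integer(prof$n_quarterly)
  cur <- rep(seq_len(n), npat)
  phys_state <- municipality_state(net$nodes$municipality_id)
  regions <- sort(unique(phys_state))
  state <- list(
    node_id = net$nodes$node_id,
    specialty = specs,
    phys_mun = phys_mun,
    phys_state = phys_state,
    regions = regions,
    phys_state_idx = match(phys_state, regions),
    cap = as.integer(prof$capacity),
    load = npat,
    avail = rep(TRUE, n),
    nbr = nbr, nbrw = nbrw,
    mun_ids = mun_ids,
    mun_dist = municipality_distances(municipalities),
    cur = cur,
    last = cur,
    home_mun = phys_mun[cur],
    home_state = phys_state[cur],
    home_state_idx = match(phys_state, regions)[cur],
    rej = integer(length(cur)),
    lost = logical(length(cur)),
    travelled = numeric(length(cur)),
    n_total = length(cur),
    n_removed = 0L
  )
  class(state) <- "care_state"
  state
}

#' @export
print.care_state <- function(x, ...) {
  cat(sprintf(
    "<care_state> %s: %d/%d physicians available; patients: %d located, %d searching, %d lost\n",
    x$specialty, sum(x$avail), length(x$avail),
    sum(x$cur > 0L), sum(x$cur == 0L & !x$lost), sum(x$lost)))
  invisible(x)
}

#' Patient bookkeeping of a simulation state
#'
#' @param state A `care_state`.
#' @return Tibble with one row: `located`, `searching`, `lost`, `total`,
#'   `free_capacity` (over available physicians), `n_removed`.
#' @export
state_summary <- function(state) {
  stopifnot(inherits(state, "care_state"))
  tibble::tibble(
    located = sum(state$cur > 0L),
    searching = sum(state$cur == 0L & !state$lost),
    lost = sum(state$lost),
    total = state$n_total,
    free_capacity = sum((state$cap - state$load)[state$avail]),
    n_removed = state$n_removed
  )
}

#' Remove a physician from the system
#'
#' Flags the physician unavailable for the remainder of the simulation, sets
#' all their patients to the searching state and stops counting their free
#' capacity.
#'
#' @param state A `care_state`.
#' @param physician Node ID (character) or node index of an available
#'   physician.
#' @return The updated `care_state`.
#' @export
remove_physician <- function(state, physician) {
  stopifnot(inherits(state, "care_state"))
  i <- if (is.character(physician)) match(physician, state$node_id) else as.integer(physician)
  if (is.na(i) || i < 1 || i > length(state$avail)) {
    abort(sprintf("unknown physician '%s'", as.character(physician)))
  }
  if (!state$avail[i]) {
    abort(sprintf("physician '%s' was already removed", state$node_id[i]))
  }
  state$avail[i] <- FALSE
  displaced <- state$cur == i
  state$cur[displaced] <- 0L
  state$load[i] <- 0L
  state$n_removed <- state$n_removed + 1L
  state
}

# Draw one candidate physician for a searching patient. With probability
# alpha the draw is uniform over all available physicians; otherwise it is
# proportional to the shared-patient weights from the patient's most recent
# physician, restricted to available neighbours. Candidates farther than d
# from the patient's home municipality are redrawn; after
# max_distance_retries draws the last candidate is kept.
draw_candidate <- function(last_i, home_i, avail, avail_idx, nbr, nbrw,
                           phys_mun, mun_dist, params) {
  nb <- nbr[[last_i]]
  keep <- avail[nb]
  nb_av <- nb[keep]
  w_av <- nbrw[[last_i]][keep]
  cand <- NA_integer_
  for (t in seq_len(params$max_distance_retries)) {
    if (params$alpha > 0 && runif(1) < params$alpha) {
      if (length(avail_idx) == 0) return(NA_integer_)
      cand <- avail_idx[sample.int(length(avail_idx), 1L)]
    } else {
      if (length(nb_av) == 0) return(NA_integer_)
      cand <- nb_av[sample.int(length(nb_av), 1L, prob = w_av)]
    }
    if (mun_dist[home_i, phys_mun[cand]] <= params$d) return(cand)
  }
  cand
}

#' Pick a candidate physician for one searching patient
#'
#' Exposes a single draw of the relocation rule: with probability `alpha` a
#' uniform draw over all available physicians, otherwise a draw proportional
#' to the shared-patient weights from the patient's most recent physician
#' over its available neighbours; the travel-distance rule (`d`, measured
#' from the patient's home municipality) is applied with up to 10 redraws.
#'
#' @param state A `care_state`.
#' @param patient Index of a searching patient.
#' @param params A [sim_params()].
#' @return Node index of the candidate, or `NA` if no candidate exists
#'   (counts as a rejection).
#' @export
pick_new_physician <- function(state, patient, params = sim_params()) {
  stopifnot(inherits(state, "care_state"))
  patient <- as.integer(patient)
  if (state$lost[patient] || state$cur[patient] != 0L) {
    abort("patient is not searching")
  }
  draw_candidate(state$last[patient], state$home_mun[patient],
                 state$avail, which(state$avail), state$nbr, state$nbrw,
                 state$phys_mun, state$mun_dist, params)
}

#' Run one displacement round
#'
#' Every searching patient, in uniformly random order, attempts one
#' placement. Acceptance (free capacity at the candidate) updates the
#' patient's location, resets their rejection counter and decrements the
#' target's free capacity; rejection (full candidate, or no candidate at all)
#' increments the counter. Patients reaching `s` rejections are lost and
#' removed from the simulation.
#'
#' @param state A `care_state`.
#' @param params A [sim_params()].
#' @return The updated `care_state`.
#' @export
displacement_round <- function(state, params = sim_params()) {
  stopifnot(inherits(state, "care_state"))
  searching <- which(state$cur == 0L & !state$lost)
  if (length(searching) == 0) return(state)
  ord <- searching[sample.int(length(searching))]

  cur <- state$cur; last <- state$last; rej <- state$rej
  lost <- state$lost; travelled <- state$travelled
  load <- state$load; cap <- state$cap
  avail <- state$avail; avail_idx <- which(avail)
  phys_mun <- state$phys_mun; mun_dist <- state$mun_dist
  home_mun <- state$home_mun
  s <- params$s; alpha <- params$alpha; R <- params$max_distance_retries

  # Candidate draws are independent of the acceptance outcomes within a
  # round (the draw distribution depends on availability, which only changes
  # between removals), so candidates can be drawn in batch per source
  # physician; acceptance is then applied sequentially in the random order.
  cand <- rep(NA_integer_, length(ord))
  by_last <- split(seq_along(ord), last[ord])
  for (g in names(by_last)) {
    idxs <- by_last[[g]]
    L <- as.integer(g)
    nb <- state$nbr[[L]]
    keep <- avail[nb]
    nb_av <- nb[keep]
    w_av <- state$nbrw[[L]][keep]
    k <- length(idxs)
    res <- rep(NA_integer_, k)
    active <- rep(TRUE, k)
    for (attempt in seq_len(R)) {
      act <- which(active)
      if (length(act) == 0) break
      m <- length(act)
      picks <- rep(NA_integer_, m)
      flips <- if (alpha > 0) runif(m) < alpha else rep(FALSE, m)
      wsel <- which(!flips)
      if (length(wsel) > 0 && length(nb_av) > 0) {
        picks[wsel] <- nb_av[sample.int(length(nb_av), length(wsel),
                                        replace = TRUE, prob = w_av)]
      }
      usel <- which(flips)
      if (length(usel) > 0 && length(avail_idx) > 0) {
        picks[usel] <- avail_idx[sample.int(length(avail_idx), length(usel),
                                            replace = TRUE)]
      }
      res[act] <- picks
      isna <- is.na(picks)
      far <- logical(m)
      if (any(!isna)) {
        pp <- which(!isna)
        far[pp] <- mun_dist[cbind(home_mun[ord[idxs[act[pp]]]],
                                  phys_mun[picks[pp]])] > params$d
      }
      # far candidates are redrawn unless this was the last attempt;
      # no-candidate and near outcomes are final
      active[act] <- far & (attempt < R)
    }
    cand[idxs] <- res
  }

  for (t in seq_along(ord)) {
    pt <- ord[t]
    cd <- cand[t]
    if (!is.na(cd) && load[cd] < cap[cd]) {
      load[cd] <- load[cd] + 1L
      travelled[pt] <- travelled[pt] + mun_dist[phys_mun[last[pt]], phys_mun[cd]]
      cur[pt] <- cd
      last[pt] <- cd
      rej[pt] <- 0L
    } else {
      rej[pt] <- rej[pt] + 1L
      if (rej[pt] >= s) lost[pt] <- TRUE
    }
  }
  state$cur <- cur; state$last <- last; state$rej <- rej
  state$lost <- lost; state$travelled <- travelled; state$load <- load
  state
}

# run displacement rounds until no patient is searching (bounded by s rounds
# per episode: every round each searching patient either places or collects a
# rejection)
run_displacement <- function(state, params) {
  repeat {
    if (!any(state$cur == 0L & !state$lost)) return(state)
    state <- displacement_round(state, params)
  }
}

# per-region snapshot used by both scenarios
region_levels <- function(state) state$regions

record_regions <- function(state, regions) {
  nb <- length(regions)
  fc <- (state$cap - state$load) * state$avail
  fc_by <- as.numeric(rowsum(fc, state$phys_state_idx,
                             reorder = TRUE)[as.character(seq_len(nb)), 1])
  fc_by[is.na(fc_by)] <- 0
  located <- state$cur > 0L
  searching <- state$cur == 0L & !state$lost
  hs <- state$home_state_idx
  list(free_capacity = fc_by,
       located = tabulate(hs[located], nb),
       searching = tabulate(hs[searching], nb),
       lost = tabulate(hs[state$lost], nb))
}

#' Scenario (i): iterative removal of single physicians
#'
#' In each artificial timestep one uniformly random available physician of
#' the specialty is removed country-wide; displaced patients then relocate
#' until no patient is searching (each bounded by `s` rejections). By default
#' this repeats until a single physician remains. After every removal the
#' per-state remaining free capacity, located patients and cumulative lost
#' patients are recorded.
#'
#' @param net Thresholded single-specialty `sharing_network`.
#' @param profiles Physician profiles with capacities.
#' @param municipalities Gazetteer.
#' @param params A [sim_params()].
#' @param ensemble Number of replicate simulations (default 100).
#' @param seed Integer seed; replicate `r` uses `seed + r - 1`.
#' @param until_empty If `TRUE`, continue until every physician is removed
#'   (after which all patients are lost).
#' @return A `removal_trajectories` tibble with columns `replicate`, `step`,
#'   `frac_removed`, `region`, `free_capacity`, `located`, `searching`,
#'   `lost`, plus attributes `n_physicians`, `n_patients`, `params`.
#' @export
run_iterative_removal <- function(net, profiles, municipalities,
                                  params = sim_params(), ensemble = 100,
                                  seed = 1, until_empty = FALSE) {
  out <- vector("list", ensemble)
  for (r in seq_len(ensemble)) {
    set.seed(seed + r - 1)
    state <- initialize_state(net, profiles, municipalities)
    regions <- region_levels(state)
    n <- length(state$avail)
    stop_at <- if (until_empty) 0L else 1L
    n_steps <- n - stop_at
    nr <- length(regions)
    mat <- matrix(0, nrow = (n_steps + 1) * nr, ncol = 4)
    step_col <- integer((n_steps + 1) * nr)
    snap <- record_regions(state, regions)
    mat[seq_len(nr), ] <- cbind(snap$free_capacity, snap$located,
                                snap$searching, snap$lost)
    for (k in seq_len(n_steps)) {
      avail_idx <- which(state$avail)
      victim <- avail_idx[sample.int(length(avail_idx), 1L)]
      state <- remove_physician(state, victim)
      state <- run_displacement(state, params)
      snap <- record_regions(state, regions)
      rows <- k * nr + seq_len(nr)
      mat[rows, ] <- cbind(snap$free_capacity, snap$located,
                           snap$searching, snap$lost)
      step_col[rows] <- k
    }
    out[[r]] <- tibble::tibble(
      replicate = r,
      step = step_col,
      frac_removed = step_col / n,
      region = rep(regions, n_steps + 1),
      free_capacity = mat[, 1], located = mat[, 2],
      searching = mat[, 3], lost = mat[, 4]
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_physicians") <- nrow(net$nodes)
  attr(res, "n_patients") <- sum(dplyr::left_join(
    net$nodes, profiles, by = "node_id", suffix = c("", ".p"))$n_quarterly)
  attr(res, "params") <- params
  class(res) <- c("removal_trajectories", class(res))
  res
}

#' Scenario (ii): a single large shock
#'
#' Removes `floor(shock_fraction/100 * n)` randomly chosen physicians of the
#' specialty simultaneously, then runs exactly `s` displacement rounds,
#' recording after each round the number of patients who currently have an
#' active physician. Patients still searching after round `s` are lost.
#'
#' @param net Thresholded single-specialty `sharing_network`.
#' @param profiles Physician profiles with capacities.
#' @param municipalities Gazetteer.
#' @param params A [sim_params()].
#' @param shock_fraction Percentage of physicians removed at once (0-100,
#'   exclusive; default 15).
#' @param ensemble Number of replicate simulations (default 10).
#' @param seed Integer seed; replicate `r` uses `seed + r - 1`.
#' @return A `shock_trajectories` tibble with columns `replicate`, `step`
#'   (displacement round, 0 = immediately after the shock), `region`,
#'   `located`, `searching`, `lost`, `free_capacity`.
#' @export
run_shock <- function(net, profiles, municipalities, params = sim_params(),
                      shock_fraction = 15, ensemble = 10, seed = 1) {
  if (shock_fraction <= 0 || shock_fraction >= 100) {
    abort("`shock_fraction` must be strictly between 0 and 100 percent")
  }
  out <- vector("list", ensemble)
  for (r in seq_len(ensemble)) {
    set.seed(seed + r - 1)
    state <- initialize_state(net, profiles, municipalities)
    regions <- region_levels(state)
    n <- length(state$avail)
    k <- floor(shock_fraction / 100 * n)
    victims <- sample.int(n, k)
    for (v in victims) state <- remove_physician(state, v)
    rows <- vector("list", params$s + 1)
    snap <- record_regions(state, regions)
    rows[[1]] <- tibble::tibble(replicate = r, step = 0L, region = regions,
                                located = snap$located,
                                searching = snap$searching, lost = snap$lost,
                                free_capacity = snap$free_capacity)
    for (t in seq_len(params$s)) {
      state <- displacement_round(state, params)
      snap <- record_regions(state, regions)
      rows[[t + 1]] <- tibble::tibble(replicate = r, step = t, region = regions,
                                      located = snap$located,
                                      searching = snap$searching,
                                      lost = snap$lost,
                                      free_capacity = snap$free_capacity)
    }
    out[[r]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_physicians") <- nrow(net$nodes)
  attr(res, "params") <- params
  attr(res, "shock_fraction") <- shock_fraction
  class(res) <- c("shock_trajectories", class(res))
  res
}
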