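# Regional resilience indicators: ensemble curves of lost patients and free
# capacity, critical limits L_FC and L_LP, and per-physician risk and benefit
# scores.

#' Ensemble resilience curves per federal state
#'
#' Normalises each replicate's trajectory by its initial per-state free
#' capacity and patient count, then averages over the ensemble: relative
#' remaining free capacity and cumulative lost-patient fraction as functions
#' of the fraction of physicians removed.
#'
#' @param trajectories Output of [run_iterative_removal()].
#' @return A `resilience_curves` tibble with columns `region`, `step`,
#'   `frac_removed`, `free_capacity_mean`, `free_capacity_sd`, `lost_mean`,
#'   `lost_sd`, `n_replicates`.
#' @export
resilience_curves <- function(trajectories) {
  if (is.null(trajectories) || nrow(trajectories) == 0) {
    abort("empty trajectory ensemble")
  }
  base <- dplyr::filter(trajectories, .data$step == 0L)
  base <- dplyr::transmute(base, .data$replicate, .data$region,
                           fc0 = .data$free_capacity,
                           pat0 = .data$located + .data$searching + .data$lost)
  rel <- dplyr::left_join(tibble::as_tibble(trajectories), base,
                          by = c("replicate", "region"))
  rel <- dplyr::mutate(
    rel,
    rel_fc = ifelse(.data$fc0 > 0, .data$free_capacity / .data$fc0,
                    as.numeric(.data$free_capacity == 0)),
    rel_lost = ifelse(.data$pat0 > 0, .data$lost / .data$pat0, 0)
  )
  out <- dplyr::summarise(
    dplyr::group_by(rel, .data$region, .data$step, .data$frac_removed),
    free_capacity_mean = mean(.data$rel_fc),
    free_capacity_sd = sd_or_zero(.data$rel_fc),
    lost_mean = mean(.data$rel_lost),
    lost_sd = sd_or_zero(.data$rel_lost),
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$region, .data$step)
  class(out) <- c("resilience_curves", class(out))
  out
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else sd(x)

#' Critical resilience limits per federal state
#'
#' `L_FC` is the smallest fraction of removed physicians at which the
#' ensemble-mean remaining free capacity drops below `fc_limit` (default
#' 20%); `L_LP` the smallest fraction at which the mean cumulative
#' lost-patient share exceeds `lp_limit` (default 1%). Crossings are
#' interpolated linearly between recorded removal steps. A limit that is
#' never crossed is reported as 1 with a censoring flag.
#'
#' @param curves Output of [resilience_curves()].
#' @param fc_limit Free-capacity threshold as a fraction (default 0.20).
#' @param lp_limit Lost-patient threshold as a fraction (default 0.01).
#' @return Tibble with `region`, `L_FC`, `L_LP`, `fc_censored`,
#'   `lp_censored`.
#' @export
critical_limits <- function(curves, fc_limit = 0.20, lp_limit = 0.01) {
  stopifnot(is.data.frame(curves))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(curves), .data$region),
    L_FC = first_crossing(.data$frac_removed, .data$free_capacity_mean,
                          fc_limit, below = TRUE),
    L_LP = first_crossing(.data$frac_removed, .data$lost_mean,
                          lp_limit, below = FALSE),
    .groups = "drop"
  )
  out$fc_censored <- is.na(out$L_FC)
  out$lp_censored <- is.na(out$L_LP)
  out$L_FC[out$fc_censored] <- 1
  out$L_LP[out$lp_censored] <- 1
  out
}

# first fraction where y < limit (below = TRUE) or y > limit (below = FALSE),
# linearly interpolated between recorded steps; NA when never crossed. When
# the previous point already sits on the threshold (degenerate crossing) the
# recorded fraction itself is returned.
first_crossing <- function(frac, y, limit, below) {
  ord <- order(frac)
  frac <- frac[ord]; y <- y[ord]
  hit <- if (below) y < limit else y > limit
  k <- which(hit)[1]
  if (is.na(k)) return(NA_real_)
  if (k == 1) return(frac[1])
  y0 <- y[k - 1]; y1 <- y[k]
  proper <- if (below) y0 > limit else y0 < limit
  if (!proper || y0 == y1) return(frac[k])
  frac[k - 1] + (y0 - limit) / (y0 - y1) * (frac[k] - frac[k - 1])
}

#' Per-physician risk scores
#'
#' The risk score of physician `i` is the mean clamped extra load their
#' first-degree network neighbours would have to bear if `i` became
#' unavailable: `R_i = mean_j( min((N_j + N_i * w_j) / C_j, 1) )`, where the
#' weights `w_j = a_ij / sum_k a_ik` distribute `i`'s patients over the
#' neighbours proportionally to shared patients. Scores lie in `[0, 1]`.
#' Isolated physicians have no neighbourhood to absorb their patients and
#' get `NA` (excluded from aggregates).
#'
#' @param net Thresholded (typically single-specialty) `sharing_network`.
#' @param profiles Profiles with `node_id`, `n_quarterly`, `capacity`.
#' @return Tibble with `node_id`, `specialty`, `region`, `risk`.
#' @export
risk_scores <- function(net, profiles) {
  stopifnot(inherits(net, "sharing_network"))
  look <- dplyr::select(tibble::as_tibble(profiles), "node_id",
                        "n_quarterly", "capacity")
  nodes <- dplyr::left_join(net$nodes, look, by = "node_id")
  if (anyNA(nodes$n_quarterly) || anyNA(nodes$capacity)) {
    abort("profiles must provide n_quarterly and capacity for every node")
  }
  if (any(nodes$capacity <= 0 & nodes$n_quarterly > 0)) {
    abort("capacity must be positive for physicians with patients")
  }
  N <- setNames(nodes$n_quarterly, nodes$node_id)
  C <- setNames(nodes$capacity, nodes$node_id)
  # both directions of each undirected edge: i -> neighbour j
  dir <- dplyr::bind_rows(
    dplyr::select(net$edges, i = "from", j = "to", "weight"),
    dplyr::select(net$edges, i = "to", j = "from", "weight")
  )
  if (nrow(dir) > 0) {
    dir <- dplyr::mutate(dplyr::group_by(dir, .data$i),
                         w = .data$weight / sum(.data$weight))
    dir <- dplyr::ungroup(dir)
    dir <- dplyr::mutate(
      dir,
      # a fully idle neighbour with zero capacity contributes zero load
      load = ifelse(C[.data$j] > 0,
                    pmin((N[.data$j] + N[.data$i] * .data$w) / C[.data$j], 1),
                    0)
    )
    agg <- dplyr::summarise(dplyr::group_by(dir, .data$i),
                            risk = mean(.data$load), .groups = "drop")
  } else {
    agg <- tibble::tibble(i = character(), risk = numeric())
  }
  out <- dplyr::left_join(net$nodes, agg, by = c(node_id = "i"))
  tibble::tibble(node_id = out$node_id, specialty = out$specialty,
                 region = municipality_state(out$municipality_id),
                 risk = out$risk)
}

#' Per-physician benefit scores
#'
#' The benefit score is the physician's initial free capacity
#' `FC_i = C_i - N_i`, min-max normalised over all physicians of the same
#' specialty so both endpoints 0 and 1 are attained. If every physician of a
#' specialty has identical free capacity the scores are 0 with a degeneracy
#' flag.
#'
#' @param profiles Profiles with `node_id`, `specialty`, `municipality_id`,
#'   `n_quarterly`, `capacity`.
#' @return Tibble with `node_id`, `specialty`, `region`, `free_capacity`,
#'   `benefit`, `degenerate`.
#' @export
benefit_scores <- function(profiles) {
  req <- c("node_id", "specialty", "municipality_id", "n_quarterly", "capacity")
  missing_cols <- setdiff(req, names(profiles))
  if (length(missing_cols) > 0) {
    abort(sprintf("profiles lacks columns: %s", paste(missing_cols, collapse = ", ")))
  }
  out <- dplyr::mutate(tibble::as_tibble(profiles),
                       free_capacity = .data$capacity - .data$n_quarterly)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$specialty),
    degenerate = max(.data$free_capacity) == min(.data$free_capacity),
    benefit = ifelse(
      .data$degenerate, 0,
      (.data$free_capacity - min(.data$free_capacity)) /
        (max(.data$free_capacity) - min(.data$free_capacity)))
  )
  out <- dplyr::ungroup(out)
  tibble::tibble(node_id = out$node_id, specialty = out$specialty,
                 region = municipality_state(out$municipality_id),
                 free_capacity = out$free_capacity,
                 benefit = out$benefit, degenerate = out$degenerate)
}

#' Regional score levels
#'
#' For each (state, specialty): the percentage of physicians whose score is
#' strictly above the nationwide mean of that specialty.
#'
#' @param scores Tibble with `region`, `specialty` and a score column.
#' @param score Name of the score column (default `"risk"`).
#' @return Tibble with `specialty`, `region`, `n_physicians`,
#'   `pct_above_average`.
#' @export
regional_levels <- function(scores, score = "risk") {
  if (!score %in% names(scores)) {
    abort(sprintf("no column '%s' in scores", score))
  }
  x <- tibble::as_tibble(scores)
  x$.score <- x[[score]]
  x <- dplyr::filter(x, !is.na(.data$.score))
  x <- dplyr::mutate(dplyr::group_by(x, .data$specialty),
                     .nat = mean(.data$.score))
  x <- dplyr::ungroup(x)
  dplyr::summarise(
    dplyr::group_by(x, .data$specialty, .data$region),
    n_physicians = dplyr::n(),
    pct_above_average = 100 * mean(.data$.score > .data$.nat),
    .groups = "drop"
  )
}

#' State-level score aggregates
#'
#' Plain means of per-physician risk and benefit scores per (state,
#' specialty), the covariates of [score_resilience_regression()]. Physicians
#' with missing risk (isolates) are excluded.
#'
#' @param risk Output of [risk_scores()].
#' @param benefit Output of [benefit_scores()].
#' @return Tibble with `specialty`, `region`, `risk`, `benefit`.
#' @export
state_score_means <- function(risk, benefit) {
  r <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(risk), .data$specialty, .data$region),
    risk = mean(.data$risk, na.rm = TRUE), .groups = "drop")
  b <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(benefit), .data$specialty, .data$region),
    benefit = mean(.data$benefit), .groups = "drop")
  dplyr::full_join(r, b, by = c("specialty", "region"))
}
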