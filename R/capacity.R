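# Capacity estimation: each physician's maximum patient capacity C is derived
# from weekly opening hours and quarterly patient contacts. Within each
# (specialty, 5-hour opening-hours bin), C is the median quarterly patient
# count of the top share of physicians by volume, assigned to everyone in the
# bin and floored at the physician's own volume so nobody starts over
# capacity.

#' Quarterly patient counts per physician
#'
#' Counts distinct patients per physician and calendar quarter, then averages
#' over the quarters in which the physician has any contact and rounds to the
#' nearest integer.
#'
#' @param contacts Contact records (`patient_id`, `physician_id`,
#'   `visit_date`, `municipality_id`).
#' @return Tibble with `node_id`, `physician_id`, `municipality_id`,
#'   `n_quarterly`.
#' @export
quarterly_patient_counts <- function(contacts) {
  if (is.null(contacts) || nrow(contacts) == 0) abort("contacts table is empty")
  dates <- as.Date(contacts$visit_date)
  quarter <- paste0(format(dates, "%Y"), "Q", (as.integer(format(dates, "%m")) - 1) %/% 3 + 1)
  per_q <- dplyr::distinct(
    dplyr::mutate(contacts, quarter = quarter),
    .data$physician_id, .data$municipality_id, .data$quarter, .data$patient_id
  )
  per_q <- dplyr::count(per_q, .data$physician_id, .data$municipality_id,
                        .data$quarter, name = "patients")
  out <- dplyr::summarise(
    dplyr::group_by(per_q, .data$physician_id, .data$municipality_id),
    n_quarterly = as.integer(round(mean(.data$patients))),
    .groups = "drop"
  )
  out$node_id <- make_node_ids(out)
  dplyr::select(out, "node_id", "physician_id", "municipality_id", "n_quarterly")
}

#' Build physician profiles from contacts and attributes
#'
#' Joins quarterly patient counts with physician attributes into the profile
#' table consumed by [estimate_capacity()] and [initialize_state()]. Only
#' physicians appearing in the contact records become nodes.
#'
#' @param contacts Contact records.
#' @param physicians Physician attribute table (`physician_id`, `specialty`,
#'   `weekly_opening_hours`, ...).
#' @return Tibble with `node_id`, `physician_id`, `specialty`,
#'   `municipality_id`, `weekly_opening_hours`, `n_quarterly`.
#' @export
build_physician_profiles <- function(contacts, physicians) {
  counts <- quarterly_patient_counts(contacts)
  out <- dplyr::left_join(
    counts,
    dplyr::distinct(physicians, .data$physician_id, .data$specialty,
                    .data$weekly_opening_hours),
    by = "physician_id"
  )
  dplyr::select(out, "node_id", "physician_id", "specialty", "municipality_id",
                "weekly_opening_hours", "n_quarterly")
}

#' Estimate maximum patient capacities
#'
#' Physicians of each specialty are divided into half-open weekly
#' opening-hour bins `[0,5), [5,10), ...` of width `bin_hours`. Within each
#' bin the top `c` percent of physicians by quarterly patient count (set size
#' `ceiling(c/100 * bin size)`, at least 1) are identified and their median
#' quarterly count becomes the bin capacity, assigned to every physician in
#' the bin. Each physician's capacity is then floored at their own quarterly
#' count (`C = max(C_bin, N)`) so that initial free capacity is never
#' negative. Physicians without opening-hour information receive the median
#' capacity of their specialty.
#'
#' @param profiles Profile table from [build_physician_profiles()] (needs
#'   `specialty`, `weekly_opening_hours`, `n_quarterly`).
#' @param bin_hours Opening-hours bin width (default 5).
#' @param c Top share in percent used for the bin capacity (default 10).
#' @return `profiles` with an integer `capacity` column.
#' @export
estimate_capacity <- function(profiles, bin_hours = 5, c = 10) {
  req <- c("specialty", "weekly_opening_hours", "n_quarterly")
  missing_cols <- setdiff(req, names(profiles))
  if (length(missing_cols) > 0) {
    abort(sprintf("profiles lacks columns: %s", paste(missing_cols, collapse = ", ")))
  }
  if (c <= 0 || c > 100) abort("`c` must be a percentage in (0, 100]")
  profiles <- dplyr::mutate(
    profiles,
    .bin = ifelse(is.na(.data$weekly_opening_hours), NA_real_,
                  floor(.data$weekly_opening_hours / bin_hours) * bin_hours)
  )
  binned <- dplyr::mutate(
    dplyr::group_by(profiles, .data$specialty, .data$.bin),
    capacity = ifelse(is.na(.data$.bin), NA_real_,
                      bin_capacity(.data$n_quarterly, c))
  )
  binned <- dplyr::ungroup(binned)
  # physicians missing from the opening-hours source: specialty median capacity
  binned <- dplyr::mutate(
    dplyr::group_by(binned, .data$specialty),
    capacity = ifelse(is.na(.data$capacity),
                      median(.data$capacity, na.rm = TRUE), .data$capacity)
  )
  binned <- dplyr::ungroup(binned)
  if (anyNA(binned$capacity)) {
    # an entire specialty without opening hours: fall back to own volume
    binned$capacity[is.na(binned$capacity)] <- binned$n_quarterly[is.na(binned$capacity)]
  }
  binned$capacity <- as.integer(round(pmax(binned$capacity, binned$n_quarterly)))
  dplyr::select(binned, -".bin")
}

# median quarterly count of the top-c% physicians in one bin
bin_capacity <- function(n_quarterly, c) {
  k <- max(1L, ceiling(c / 100 * length(n_quarterly)))
  top <- sort(n_quarterly, decreasing = TRUE)[seq_len(k)]
  median(top)
}
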