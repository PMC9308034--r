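# Shared helpers: municipality IDs, distances, node identity.

#' Federal state of a municipality
#'
#' Municipality identifiers are 5-digit strings whose first digit encodes the
#' federal state (up to 9 states). This extracts that digit.
#'
#' @param municipality_id Character vector of 5-digit municipality IDs.
#' @return Character vector of single-digit state codes.
#' @export
municipality_state <- function(municipality_id) {
  check_municipality_ids(municipality_id)
  substr(as.character(municipality_id), 1L, 1L)
}

check_municipality_ids <- function(ids, what = "municipality_id") {
  ids <- as.character(ids)
  bad <- !grepl("^[1-9][0-9]{4}$", ids)
  if (any(bad)) {
    abort(sprintf(
      "%s must be 5-digit strings with a non-zero leading state digit; offending value: '%s'",
      what, ids[which(bad)[1]]
    ))
  }
  invisible(ids)
}

#' Great-circle distances between municipalities
#'
#' Returns a symmetric matrix of haversine distances in kilometres, with
#' dimnames set to the municipality IDs, for fast lookup during network
#' thresholding and simulation.
#'
#' @param municipalities Data frame with columns `municipality_id`, `lat`,
#'   `lon`.
#' @return Numeric matrix (km), rows/columns named by municipality ID.
#' @export
municipality_distances <- function(municipalities) {
  stopifnot(all(c("municipality_id", "lat", "lon") %in% names(municipalities)))
  coords <- as.matrix(municipalities[, c("lon", "lat")])
  n <- nrow(coords)
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      dd <- geosphere::distHaversine(coords[i, , drop = FALSE], coords[j, , drop = FALSE]) / 1000
      d[i, j] <- dd
      d[j, i] <- dd
    }
  }
  dimnames(d) <- list(municipalities$municipality_id, municipalities$municipality_id)
  d
}

# Node identity: a "physician" in the model is a unique
# (physician, specialty, municipality) combination. When a physician ID maps
# to a single combination the node ID is the physician ID itself; otherwise a
# composite ID keeps the combinations apart.
make_node_ids <- function(df) {
  stopifnot(all(c("physician_id", "municipality_id") %in% names(df)))
  spec <- if ("specialty" %in% names(df)) df$specialty else ""
  combo <- paste(df$physician_id, spec, df$municipality_id, sep = "@")
  n_combo <- tapply(combo, df$physician_id, function(x) length(unique(x)))
  multi <- names(n_combo)[n_combo > 1]
  ifelse(df$physician_id %in% multi, combo, df$physician_id)
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
  as.numeric(x)
}
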