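# Shared fixtures: toy gazetteers, networks and profile tables built in code.

# municipalities on a line of given spacing (km) along a parallel;
# 1 degree of longitude at 47N is ~ 75.9 km
mun_table <- function(ids, spacing_km = 10) {
  deg_per_km <- 1 / (111.32 * cos(47 * pi / 180))
  tibble::tibble(
    municipality_id = ids,
    lat = 47,
    lon = seq_along(ids) * spacing_km * deg_per_km
  )
}

# single-specialty toy network: full control over edges and capacities
toy_setup <- function(weights, N, C, specialty = "GP",
                      municipality_id = NULL, spacing_km = 10) {
  n <- length(N)
  ids <- sprintf("doc%d", seq_len(n))
  if (is.null(municipality_id)) municipality_id <- rep("10001", n)
  mun <- mun_table(sort(unique(municipality_id)), spacing_km)
  nodes <- tibble::tibble(node_id = ids, specialty = specialty,
                          municipality_id = municipality_id)
  edges <- NULL
  if (!is.null(weights) && nrow(weights) > 0) {
    edges <- tibble::tibble(from = ids[weights$i], to = ids[weights$j],
                            weight = weights$w)
  }
  net <- sharing_network(nodes, edges)
  profiles <- tibble::tibble(node_id = ids, specialty = specialty,
                             municipality_id = municipality_id,
                             n_quarterly = as.integer(N),
                             capacity = as.integer(C))
  list(net = net, profiles = profiles, municipalities = mun)
}

edge_df <- function(i, j, w) data.frame(i = i, j = j, w = w)

# small random single-specialty setup for property tests
random_setup <- function(seed, n_phys = NULL) {
  set.seed(seed)
  n <- if (is.null(n_phys)) sample(4:10, 1) else n_phys
  n_mun <- sample(2:4, 1)
  mun_ids <- sprintf("%d000%d", sample(1:9, n_mun), seq_len(n_mun))
  municipality_id <- sample(mun_ids, n, replace = TRUE)
  # connected-ish random graph: a ring plus random chords
  w <- edge_df(seq_len(n - 1), 2:n, sample(1:5, n - 1, replace = TRUE))
  extra <- which(runif(n) < 0.4)
  for (i in extra) {
    j <- sample(setdiff(seq_len(n), i), 1)
    w <- rbind(w, edge_df(min(i, j), max(i, j), sample(1:5, 1)))
  }
  N <- sample(0:8, n, replace = TRUE)
  C <- N + sample(0:6, n, replace = TRUE)
  toy_setup(w, N, C, municipality_id = municipality_id,
            spacing_km = sample(c(5, 30), 1))
}

# fast synthetic config for end-to-end tests
small_synth <- function(seed = 1, ...) {
  synth_config(n_municipalities = 12, n_states = 4,
               n_physicians_per_specialty = 8,
               specialties = c("GP", "DER"), n_patients = 400,
               visits_per_patient_mean = 10, seed = seed, ...)
}
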