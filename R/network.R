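# Patient-sharing network construction. Nodes are unique
# (physician, specialty, municipality) combinations; an edge weight a_ij is
# the number of distinct patients who visited both i and j within a +/- 3
# month co-visit window. The adjacency is symmetric with zero diagonal.

#' Construct a patient-sharing network from contact records
#'
#' For every unordered physician pair, the edge weight counts the distinct
#' patients having at least one visit to each of the two physicians within
#' `window_days` of each other ("3 months" is implemented as 91 days,
#' inclusive at both ends). A patient co-visiting a pair in several separate
#' windows still counts once: the weight is a patient count.
#'
#' @param contacts Data frame with columns `patient_id`, `physician_id`,
#'   `visit_date`, `municipality_id`.
#' @param physicians Optional physician attribute table with `physician_id`
#'   and `specialty`; when given, specialties are attached to the nodes
#'   (required before [specialty_layer()]).
#' @param window_days Half-width of the co-visit window in days (default 91).
#' @return A `sharing_network`: list with tibbles `nodes` (`node_id`,
#'   `physician_id`, `specialty`, `municipality_id`) and `edges` (`from`,
#'   `to`, `weight`), `from < to` lexicographically.
#' @export
build_sharing_network <- function(contacts, physicians = NULL, window_days = 91) {
  if (is.null(contacts) || nrow(contacts) == 0) abort("contacts table is empty")
  req <- c("patient_id", "physician_id", "visit_date", "municipality_id")
  missing_cols <- setdiff(req, names(contacts))
  if (length(missing_cols) > 0) {
    abort(sprintf("contacts lacks columns: %s", paste(missing_cols, collapse = ", ")))
  }
  dates <- suppressWarnings(as.Date(contacts$visit_date))
  if (anyNA(dates)) {
    abort(sprintf("unparseable visit_date at contacts row %d",
                  which(is.na(dates))[1]))
  }
  contacts <- dplyr::mutate(contacts, visit_date = dates)

  nodes <- dplyr::distinct(contacts, .data$physician_id, .data$municipality_id)
  if (!is.null(physicians)) {
    nodes <- dplyr::left_join(
      nodes, dplyr::distinct(physicians, .data$physician_id, .data$specialty),
      by = "physician_id"
    )
  } else {
    nodes$specialty <- NA_character_
  }
  nodes$node_id <- make_node_ids(nodes)
  nodes <- dplyr::select(nodes, "node_id", "physician_id", "specialty",
                         "municipality_id")
  nodes <- dplyr::arrange(nodes, .data$node_id)

  key <- dplyr::left_join(contacts, nodes,
                          by = c("physician_id", "municipality_id"))
  visits <- dplyr::distinct(key, .data$patient_id, .data$node_id,
                            .data$visit_date)
  # all same-patient visit pairs within the window, each distinct patient
  # counted once per unordered node pair
  pairs <- dplyr::inner_join(visits, visits, by = "patient_id",
                             relationship = "many-to-many",
                             suffix = c("_i", "_j"))
  pairs <- dplyr::filter(
    pairs,
    .data$node_id_i < .data$node_id_j,
    abs(as.numeric(.data$visit_date_i - .data$visit_date_j)) <= window_days
  )
  edges <- dplyr::distinct(pairs, .data$patient_id, .data$node_id_i,
                           .data$node_id_j)
  edges <- dplyr::count(edges, from = .data$node_id_i, to = .data$node_id_j,
                        name = "weight")
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  new_sharing_network(nodes, edges)
}

#' Build a sharing network from node and edge tables
#'
#' Constructor for externally assembled networks (e.g. toy examples or edge
#' lists from other tools). Edges are undirected: pairs are normalised so
#' `from < to` and duplicate pairs are summed; self-loops are rejected.
#'
#' @param nodes Data frame with `node_id`, `specialty`, `municipality_id`
#'   (and optionally `physician_id`, defaulting to `node_id`).
#' @param edges Data frame with `from`, `to`, `weight` referring to node IDs.
#' @return A `sharing_network`.
#' @export
sharing_network <- function(nodes, edges = NULL) {
  nodes <- tibble::as_tibble(nodes)
  if (!"node_id" %in% names(nodes)) abort("nodes needs a `node_id` column")
  if (anyDuplicated(nodes$node_id)) abort("duplicate node_id in nodes")
  if (!"physician_id" %in% names(nodes)) nodes$physician_id <- nodes$node_id
  if (!"specialty" %in% names(nodes)) nodes$specialty <- NA_character_
  if (!"municipality_id" %in% names(nodes)) {
    abort("nodes needs a `municipality_id` column")
  }
  nodes <- dplyr::select(nodes, "node_id", "physician_id", "specialty",
                         "municipality_id")
  if (is.null(edges) || nrow(edges) == 0) {
    return(new_sharing_network(nodes, NULL))
  }
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  unknown <- setdiff(c(edges$from, edges$to), nodes$node_id)
  if (length(unknown) > 0) {
    abort(sprintf("edge references unknown node '%s'", unknown[1]))
  }
  if (any(edges$from == edges$to)) abort("self-loops are not allowed")
  if (any(edges$weight < 0)) abort("edge weights must be non-negative")
  norm <- tibble::tibble(
    from = pmin(edges$from, edges$to),
    to = pmax(edges$from, edges$to),
    weight = edges$weight
  )
  norm <- dplyr::summarise(dplyr::group_by(norm, .data$from, .data$to),
                           weight = sum(.data$weight), .groups = "drop")
  norm <- dplyr::filter(norm, .data$weight > 0)
  new_sharing_network(nodes, dplyr::arrange(norm, .data$from, .data$to))
}

new_sharing_network <- function(nodes, edges) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = integer())
  } else {
    edges <- tibble::as_tibble(edges)
  }
  structure(list(nodes = tibble::as_tibble(nodes), edges = edges),
            class = "sharing_network")
}

#' @export
print.sharing_network <- function(x, ...) {
  ns <- unique(x$nodes$specialty)
  cat(sprintf("<sharing_network> %d physicians, %d edges, %d specialt%s\n",
              nrow(x$nodes), nrow(x$edges), length(ns),
              if (length(ns) == 1) "y" else "ies"))
  invisible(x)
}

#' Edge list of a sharing network as a tibble
#' @param x A `sharing_network`.
#' @param ... Unused.
#' @export
as_tibble.sharing_network <- function(x, ...) x$edges

#' Threshold a sharing network by weight and distance
#'
#' Removes edges with fewer than `p` shared patients or whose endpoint
#' municipalities are more than `d` kilometres apart (great-circle distance;
#' the boundary `<= d` is kept). Surviving weights are unchanged.
#'
#' @param net A `sharing_network`.
#' @param p Minimum shared patients for a valid edge (default 2).
#' @param d Maximum distance in km (default 100).
#' @param municipalities Gazetteer with `municipality_id`, `lat`, `lon`.
#' @return The thresholded `sharing_network`.
#' @export
threshold_network <- function(net, p = 2, d = 100, municipalities) {
  stopifnot(inherits(net, "sharing_network"))
  if (p < 1) abort("`p` must be >= 1")
  if (d <= 0) abort("`d` must be > 0")
  miss <- setdiff(unique(net$nodes$municipality_id),
                  as.character(municipalities$municipality_id))
  if (length(miss) > 0) {
    abort(sprintf("no coordinates for municipality '%s'", miss[1]))
  }
  if (nrow(net$edges) == 0) return(net)
  dmat <- municipality_distances(municipalities)
  mun_of <- setNames(net$nodes$municipality_id, net$nodes$node_id)
  dist_km <- dmat[cbind(mun_of[net$edges$from], mun_of[net$edges$to])]
  keep <- net$edges$weight >= p & dist_km <= d
  new_sharing_network(net$nodes, net$edges[keep, ])
}

#' Restrict a sharing network to one specialty layer
#'
#' Keeps only the physicians of the given specialty and the edges among them;
#' all cross-specialty edges are dropped.
#'
#' @param net A `sharing_network` with node specialties attached.
#' @param specialty A single specialty label present in the network.
#' @return The single-specialty `sharing_network`.
#' @export
specialty_layer <- function(net, specialty) {
  stopifnot(inherits(net, "sharing_network"))
  if (length(specialty) != 1 || !specialty %in% net$nodes$specialty) {
    abort(sprintf("unknown specialty '%s'", as.character(specialty)[1]))
  }
  nodes <- dplyr::filter(net$nodes, .data$specialty == !!specialty)
  keep <- net$edges$from %in% nodes$node_id & net$edges$to %in% nodes$node_id
  new_sharing_network(nodes, net$edges[keep, ])
}

#' Flag the giant component of a sharing network
#'
#' Identifies the largest connected component by node count. Physicians
#' outside it (including isolates) remain in the node set: during simulation
#' they stay selectable, but only through random re-location (`alpha > 0`).
#'
#' @param net A `sharing_network`.
#' @return The `nodes` tibble with a logical `in_giant` column.
#' @export
giant_component <- function(net) {
  stopifnot(inherits(net, "sharing_network"))
  nodes <- net$nodes
  if (nrow(nodes) == 0) {
    nodes$in_giant <- logical()
    return(nodes)
  }
  g <- as_igraph(net)
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  flag <- comp$membership[nodes$node_id] == giant
  nodes$in_giant <- unname(flag)
  nodes
}

#' Convert a sharing network to an igraph object
#'
#' @param net A `sharing_network`.
#' @return An undirected weighted `igraph` graph including isolated nodes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "sharing_network"))
  igraph::graph_from_data_frame(
    d = net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes$node_id,
                          specialty = net$nodes$specialty,
                          municipality_id = net$nodes$municipality_id)
  )
}

#' Symmetric adjacency matrix of a sharing network
#'
#' @param net A `sharing_network`.
#' @return Dense numeric matrix with zero diagonal, dimnames = node IDs.
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "sharing_network"))
  ids <- net$nodes$node_id
  a <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges) > 0) {
    a[cbind(net$edges$from, net$edges$to)] <- net$edges$weight
    a[cbind(net$edges$to, net$edges$from)] <- net$edges$weight
  }
  a
}

#' Export a sharing network
#'
#' Writes the weighted edge list (`src_id`, `dst_id`, `weight`) and the node
#' attribute table as CSV, or the full graph as GraphML.
#'
#' @param net A `sharing_network`.
#' @param path Output file path. Format chosen by `format`.
#' @param format `"csv"` (edge list; a sibling `*_nodes.csv` node table is
#'   written alongside) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    edges <- dplyr::rename(net$edges, src_id = "from", dst_id = "to")
    readr::write_csv(edges, path)
    readr::write_csv(net$nodes, sub("\\.csv$", "_nodes.csv", path))
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a sharing network written by [write_network()]
#'
#' @param path Edge-list CSV (with its sibling `*_nodes.csv`) or GraphML file.
#' @param format `"csv"` or `"graphml"`.
#' @return A `sharing_network`.
#' @export
read_network <- function(path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    edges <- readr::read_csv(path, col_types = readr::cols(
      src_id = "c", dst_id = "c", weight = "d"), progress = FALSE)
    nodes <- readr::read_csv(sub("\\.csv$", "_nodes.csv", path),
                             col_types = readr::cols(.default = "c"),
                             progress = FALSE)
    new_sharing_network(nodes, dplyr::rename(edges, from = "src_id",
                                             to = "dst_id"))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble::tibble(
      node_id = igraph::V(g)$name,
      physician_id = igraph::V(g)$name,
      specialty = igraph::V(g)$specialty,
      municipality_id = igraph::V(g)$municipality_id
    )
    e <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble::tibble(
      from = pmin(e$from, e$to), to = pmax(e$from, e$to),
      weight = e$weight
    )
    new_sharing_network(nodes, dplyr::arrange(edges, .data$from, .data$to))
  }
}
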