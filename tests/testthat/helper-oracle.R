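# Independent oracles.
#
# 1. brute_force_pair_counts: O(visits^2) enumeration of co-visit windows,
#    kept deliberately naive (double loop over all visit pairs).
# 2. oracle_expected_lost: exact expected number of lost patients for the
#    iterative-removal scenario on tiny systems, by exhaustive enumeration of
#    the probability tree (removal choices, patient orderings, relocation
#    draws). Patients are grouped into exchangeable classes -- uniformly
#    random orderings over patients are equivalent to sequentially picking a
#    class with probability proportional to its remaining count -- and the
#    distance-redraw subprocess is folded in closed form.

brute_force_pair_counts <- function(contacts, window_days = 91) {
  v <- contacts
  v$date <- as.Date(v$visit_date)
  v$node <- paste(v$physician_id, v$municipality_id, sep = "@")
  seen <- character()
  n <- nrow(v)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      if (v$patient_id[a] != v$patient_id[b]) next
      if (v$node[a] == v$node[b]) next
      if (abs(as.numeric(v$date[a] - v$date[b])) > window_days) next
      pair <- paste(sort(c(v$node[a], v$node[b])), collapse = "|")
      seen <- c(seen, paste(v$patient_id[a], pair))
    }
  }
  seen <- unique(seen)
  if (length(seen) == 0) {
    return(data.frame(pair = character(), weight = integer()))
  }
  pair <- sub("^\\S+ ", "", seen)
  as.data.frame(table(pair = pair), responseName = "weight",
                stringsAsFactors = FALSE)
}

# ---- exact expected lost patients (scenario i) -------------------------------

# candidate distribution for one pick: per-attempt mixture of the alpha
# (uniform over available) and weighted (available neighbours) branches, with
# the up-to-R distance redraw folded analytically. Returns candidates (0
# encodes "no candidate") and probabilities.
oracle_cand_dist <- function(last, home, avail, W, C, mun_of, dkm, params) {
  n <- length(avail)
  m <- numeric(n + 1) # m[n+1] = no-candidate mass
  av <- which(avail)
  nb <- which(W[last, ] > 0 & avail)
  a <- params$alpha
  if (a > 0) {
    if (length(av) == 0) m[n + 1] <- m[n + 1] + a
    else m[av] <- m[av] + a / length(av)
  }
  if (a < 1) {
    if (length(nb) == 0) m[n + 1] <- m[n + 1] + (1 - a)
    else m[nb] <- m[nb] + (1 - a) * W[last, nb] / sum(W[last, nb])
  }
  far <- c(dkm[home, mun_of] > params$d, FALSE)
  R <- params$max_distance_retries
  P_far <- sum(m[far])
  geo <- if (P_far >= 1) R else (1 - P_far^R) / (1 - P_far)
  probs <- ifelse(far, m * P_far^(R - 1), m * geo)
  keep <- probs > 0
  list(cand = c(seq_len(n), 0L)[keep], prob = probs[keep])
}

# classes: matrix with columns status (1 located / 2 searching), phys, rej,
# home, count, rem (patients of the class still to act this round)
oracle_expected_lost <- function(setup, params) {
  W <- adjacency_matrix(setup$net)
  ord <- setup$net$nodes$node_id
  prof <- setup$profiles[match(ord, setup$profiles$node_id), ]
  C <- prof$capacity
  N <- prof$n_quarterly
  dkm <- municipality_distances(setup$municipalities)
  mun_of <- match(setup$net$nodes$municipality_id,
                  setup$municipalities$municipality_id)
  n <- length(C)
  memo <- new.env(parent = emptyenv())

  canon <- function(avail, load, cls) {
    if (nrow(cls) > 0) {
      cls <- cls[cls[, "count"] > 0, , drop = FALSE]
      o <- do.call(order, as.data.frame(cls))
      cls <- cls[o, , drop = FALSE]
    }
    paste(c(avail, load, t(cls)), collapse = ",")
  }

  add_class <- function(cls, status, phys, rej, home, k, rem = 0) {
    hit <- which(cls[, "status"] == status & cls[, "phys"] == phys &
                   cls[, "rej"] == rej & cls[, "home"] == home &
                   cls[, "rem"] == rem)
    if (length(hit) > 0) {
      cls[hit[1], "count"] <- cls[hit[1], "count"] + k
    } else {
      cls <- rbind(cls, c(status, phys, rej, home, k, rem))
    }
    cls
  }

  new_cls <- function() {
    m <- matrix(integer(), ncol = 6)
    colnames(m) <- c("status", "phys", "rej", "home", "count", "rem")
    m
  }

  e_removal <- function(avail, load, cls) {
    if (sum(avail) <= 1) return(0)
    key <- paste("rm", canon(avail, load, cls))
    if (!is.null(memo[[key]])) return(memo[[key]])
    victims <- which(avail)
    total <- 0
    for (v in victims) {
      av2 <- avail; av2[v] <- FALSE
      ld2 <- load; ld2[v] <- 0L
      cls2 <- new_cls()
      for (r in seq_len(nrow(cls))) {
        if (cls[r, "count"] == 0) next
        if (cls[r, "status"] == 1 && cls[r, "phys"] == v) {
          cls2 <- add_class(cls2, 2L, v, 0L, cls[r, "home"], cls[r, "count"])
        } else {
          cls2 <- add_class(cls2, cls[r, "status"], cls[r, "phys"],
                            cls[r, "rej"], cls[r, "home"], cls[r, "count"],
                            cls[r, "rem"])
        }
      }
      total <- total + e_round(av2, ld2, start_round(cls2))
    }
    res <- total / length(victims)
    memo[[key]] <- res
    res
  }

  start_round <- function(cls) {
    for (r in seq_len(nrow(cls))) {
      if (cls[r, "status"] == 2) cls[r, "rem"] <- cls[r, "count"]
    }
    cls
  }

  e_round <- function(avail, load, cls) {
    key <- paste("rd", canon(avail, load, cls))
    if (!is.null(memo[[key]])) return(memo[[key]])
    tot_rem <- if (nrow(cls) == 0) 0 else sum(cls[, "rem"])
    if (tot_rem == 0) {
      searching <- nrow(cls) > 0 && any(cls[, "status"] == 2 & cls[, "count"] > 0)
      res <- if (searching) e_round(avail, load, start_round(cls))
             else e_removal(avail, load, cls)
      memo[[key]] <- res
      return(res)
    }
    total <- 0
    for (r in seq_len(nrow(cls))) {
      if (cls[r, "rem"] == 0) next
      p_c <- cls[r, "rem"] / tot_rem
      dist <- oracle_cand_dist(cls[r, "phys"], cls[r, "home"], avail, W, C,
                               mun_of, dkm, params)
      for (k in seq_along(dist$cand)) {
        cand <- dist$cand[k]
        p_k <- dist$prob[k]
        cls2 <- cls
        cls2[r, "count"] <- cls2[r, "count"] - 1L
        cls2[r, "rem"] <- cls2[r, "rem"] - 1L
        ld2 <- load
        imm <- 0
        if (cand > 0 && load[cand] < C[cand]) {
          ld2[cand] <- ld2[cand] + 1L
          cls2 <- add_class(cls2, 1L, cand, 0L, cls[r, "home"], 1L)
        } else {
          r2 <- cls[r, "rej"] + 1L
          if (r2 >= params$s) {
            imm <- 1
          } else {
            cls2 <- add_class(cls2, 2L, cls[r, "phys"], r2, cls[r, "home"], 1L)
          }
        }
        total <- total + p_c * p_k * (imm + e_round(avail, ld2, cls2))
      }
    }
    memo[[key]] <- total
    total
  }

  cls0 <- new_cls()
  for (i in seq_len(n)) {
    if (N[i] > 0) cls0 <- add_class(cls0, 1L, i, 0L, mun_of[i], N[i])
  }
  e_removal(rep(TRUE, n), as.integer(N), cls0)
}
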