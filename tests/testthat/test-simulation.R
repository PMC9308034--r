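# Displacement engine: initialisation, relocation draws, rounds, removal.

test_that("initialisation places N patients per physician with free capacity C - N", {
  s <- toy_setup(edge_df(1, 2, 1), N = c(3, 0), C = c(5, 4))
  st <- initialize_state(s$net, s$profiles, s$municipalities)
  sm <- state_summary(st)
  expect_equal(sm$located, 3)
  expect_equal(sm$searching, 0)
  expect_equal(sm$lost, 0)
  expect_equal(sm$free_capacity, (5 - 3) + (4 - 0))
  expect_equal(sm$total, sum(s$profiles$n_quarterly))

  bad <- s$profiles
  bad$capacity[1] <- 2L
  expect_error(initialize_state(s$net, bad, s$municipalities),
               "exceeds capacity")
  empty <- sharing_network(s$net$nodes[0, ])
  expect_error(initialize_state(empty, s$profiles, s$municipalities),
               "empty network")
})

test_that("relocation draws follow the shared-patient weights", {
  # neighbours with weights {B: 3, C: 1} -> P(B) = 0.75
  s <- toy_setup(edge_df(c(1, 1), c(2, 3), c(3, 1)), N = c(1, 0, 0),
                 C = c(5, 5, 5))
  st <- initialize_state(s$net, s$profiles, s$municipalities)
  st <- remove_physician(st, "doc1")
  set.seed(1)
  draws <- replicate(10000, pick_new_physician(st, 1, sim_params()))
  counts <- table(factor(draws, levels = 2:3))
  p <- stats::chisq.test(as.vector(counts), p = c(0.75, 0.25))$p.value
  expect_gt(p, 0.01)

  # a single available neighbour is picked with probability 1
  s2 <- toy_setup(edge_df(1, 2, 4), N = c(1, 0), C = c(2, 2))
  st2 <- remove_physician(initialize_state(s2$net, s2$profiles,
                                           s2$municipalities), "doc1")
  set.seed(2)
  expect_true(all(replicate(50, pick_new_physician(st2, 1)) == 2))
})

test_that("alpha = 1 draws uniformly over available physicians, ignoring weights", {
  s <- toy_setup(edge_df(c(1, 1), c(2, 3), c(30, 1)), N = c(1, 0, 0),
                 C = c(5, 5, 5))
  st <- remove_physician(initialize_state(s$net, s$profiles,
                                          s$municipalities), "doc1")
  set.seed(3)
  draws <- replicate(8000, pick_new_physician(st, 1, sim_params(alpha = 1)))
  counts <- table(factor(draws, levels = 2:3))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("distance rule redraws far candidates and waives after 10 attempts", {
  # doc2 near (75 km), doc3 far (150 km), equal weights, d = 100:
  # P(far survives) = 0.5^10
  s <- toy_setup(edge_df(c(1, 1), c(2, 3), c(1, 1)), N = c(1, 0, 0),
                 C = c(5, 5, 5),
                 municipality_id = c("10001", "10002", "10003"),
                 spacing_km = 75)
  st <- remove_physician(initialize_state(s$net, s$profiles,
                                          s$municipalities), "doc1")
  set.seed(4)
  draws <- replicate(3000, pick_new_physician(st, 1, sim_params(d = 100)))
  expect_gt(mean(draws == 2), 0.99)
  # the waiver keeps the run from stalling when only far physicians remain:
  # with doc2 unavailable every draw must return the far doc3
  st2 <- remove_physician(st, "doc2")
  set.seed(5)
  expect_true(all(replicate(30, pick_new_physician(st2, 1,
                                                   sim_params(d = 100))) == 3))
})

test_that("a searching patient with no available neighbours gets no candidate", {
  s <- toy_setup(edge_df(1, 2, 1), N = c(1, 0, 0), C = c(2, 2, 2))
  st <- initialize_state(s$net, s$profiles, s$municipalities)
  st <- remove_physician(st, "doc1")
  st <- remove_physician(st, "doc2")
  expect_true(is.na(pick_new_physician(st, 1, sim_params(alpha = 0))))
  # with alpha > 0 the patient can still reach the unconnected doc3
  set.seed(6)
  expect_equal(pick_new_physician(st, 1, sim_params(alpha = 1)), 3)
})

test_that("rounds place up to free capacity and lose patients after s rejections", {
  # 10 searching patients, one neighbour with free capacity 3, s = 2:
  # 3 placed, 7 lost after two rounds
  s <- toy_setup(edge_df(1, 2, 2), N = c(10, 2), C = c(10, 5))
  st <- initialize_state(s$net, s$profiles, s$municipalities)
  st <- remove_physician(st, "doc1")
  prm <- sim_params(s = 2)
  set.seed(7)
  st <- displacement_round(st, prm)
  sm <- state_summary(st)
  expect_equal(sm$located, 2 + 3)
  expect_equal(sm$searching, 7)
  expect_equal(sm$lost, 0)
  st <- displacement_round(st, prm)
  sm <- state_summary(st)
  expect_equal(sm$located, 5)
  expect_equal(sm$searching, 0)
  expect_equal(sm$lost, 7)

  # fixed point: no searching patients -> state unchanged
  st2 <- displacement_round(st, prm)
  expect_identical(st2, st)
})

test_that("ample capacity places every displaced patient in one round", {
  s <- toy_setup(edge_df(1, 2, 1), N = c(6, 1), C = c(6, 20))
  st <- remove_physician(initialize_state(s$net, s$profiles,
                                          s$municipalities), "doc1")
  set.seed(8)
  st <- displacement_round(st, sim_params())
  expect_equal(state_summary(st)$located, 7)
  expect_equal(state_summary(st)$searching, 0)
})

test_that("removal displaces patients, drops capacity, and is not repeatable", {
  s <- toy_setup(edge_df(1, 2, 1), N = c(4, 0), C = c(6, 3))
  st <- initialize_state(s$net, s$profiles, s$municipalities)

  # removing an empty physician changes capacity but displaces nobody
  st1 <- remove_physician(st, "doc2")
  expect_equal(state_summary(st1)$searching, 0)
  expect_equal(state_summary(st1)$free_capacity,
               state_summary(st)$free_capacity - 3)

  # removing a loaded physician sets its k patients searching
  st2 <- remove_physician(st, "doc1")
  expect_equal(state_summary(st2)$searching, 4)

  expect_error(remove_physician(st1, "doc2"), "already removed")
  expect_error(remove_physician(st, "nope"), "unknown physician")
})

test_that("iterative removal is seed-reproducible and conserves patients", {
  s <- random_setup(101)
  t1 <- run_iterative_removal(s$net, s$profiles, s$municipalities,
                              sim_params(s = 3), ensemble = 2, seed = 9)
  t2 <- run_iterative_removal(s$net, s$profiles, s$municipalities,
                              sim_params(s = 3), ensemble = 2, seed = 9)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- run_iterative_removal(s$net, s$profiles, s$municipalities,
                              sim_params(s = 3), ensemble = 2, seed = 10)
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))

  tot <- sum(s$profiles$n_quarterly)
  per_step <- aggregate(cbind(located, searching, lost) ~ replicate + step,
                        data = as.data.frame(t1), FUN = sum)
  expect_true(all(per_step$located + per_step$searching + per_step$lost == tot))
  # trajectory length: one record per removal plus the initial state
  n <- nrow(s$net$nodes)
  expect_equal(sort(unique(t1$step)), 0:(n - 1))
})

test_that("a full sweep removing every physician loses every patient", {
  s <- random_setup(202)
  tr <- run_iterative_removal(s$net, s$profiles, s$municipalities,
                              sim_params(s = 2), ensemble = 1, seed = 11,
                              until_empty = TRUE)
  fin <- tr[tr$step == max(tr$step), ]
  expect_equal(sum(fin$lost), sum(s$profiles$n_quarterly))
  expect_equal(sum(fin$located) + sum(fin$searching), 0)
  expect_equal(sum(fin$free_capacity), 0)
})

test_that("shock removes the configured share and resolves within s rounds", {
  # 3 nodes fully connected; remove 2, survivor has huge capacity:
  # every patient is placed in round 1
  s <- toy_setup(edge_df(c(1, 1, 2), c(2, 3, 3), c(1, 1, 1)),
                 N = c(4, 4, 2), C = c(100, 100, 100))
  shock <- run_shock(s$net, s$profiles, s$municipalities, sim_params(),
                     shock_fraction = 67, ensemble = 3, seed = 12)
  tot <- aggregate(cbind(located, searching, lost) ~ replicate + step,
                   data = as.data.frame(shock), FUN = sum)
  step0 <- tot[tot$step == 0, ]
  step1 <- tot[tot$step == 1, ]
  # accounting identity at step 0: located = total - patients of the removed
  expect_true(all(step0$located + step0$searching == 10))
  expect_true(all(step0$lost == 0))
  expect_true(all(step1$located == 10))
  fin <- tot[tot$step == max(tot$step), ]
  expect_true(all(fin$searching == 0))

  # a fraction too small to remove anyone keeps the curve constant
  none <- run_shock(s$net, s$profiles, s$municipalities, sim_params(),
                    shock_fraction = 10, ensemble = 1, seed = 13)
  tot0 <- aggregate(located ~ step, data = as.data.frame(none), FUN = sum)
  expect_true(all(tot0$located == 10))

  expect_error(run_shock(s$net, s$profiles, s$municipalities, sim_params(),
                         shock_fraction = 100), "between 0 and 100")
})

test_that("patients never exceed capacity and losses are monotone", {
  for (seed in c(301, 302, 303)) {
    s <- random_setup(seed)
    prm <- sim_params(s = 3)
    set.seed(seed)
    st <- initialize_state(s$net, s$profiles, s$municipalities)
    lost_prev <- 0
    while (sum(st$avail) > 1) {
      avail <- which(st$avail)
      st <- remove_physician(st, avail[sample.int(length(avail), 1)])
      repeat {
        st <- displacement_round(st, prm)
        expect_true(all(st$load <= st$cap))
        sm <- state_summary(st)
        expect_equal(sm$located + sm$searching + sm$lost, sm$total)
        expect_gte(sm$lost, lost_prev)
        lost_prev <- sm$lost
        if (sm$searching == 0) break
      }
    }
  }
})
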