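# Resilience curves, critical limits, risk/benefit scores, regional levels
# and the score-resilience regression.

fake_traj <- function(rows) {
  out <- tibble::as_tibble(rows)
  class(out) <- c("removal_trajectories", class(out))
  out
}

test_that("resilience curves normalise by initial state and average the ensemble", {
  # two identical deterministic replicates -> SD 0, known values
  one <- tibble::tibble(
    replicate = 1L, step = 0:2, frac_removed = c(0, 0.5, 1), region = "1",
    free_capacity = c(10, 4, 0), located = c(20, 16, 0),
    searching = 0, lost = c(0, 4, 20)
  )
  traj <- fake_traj(dplyr::bind_rows(one, dplyr::mutate(one, replicate = 2L)))
  cv <- resilience_curves(traj)
  expect_equal(cv$free_capacity_mean, c(1, 0.4, 0))
  expect_equal(cv$lost_mean, c(0, 0.2, 1))
  expect_true(all(cv$free_capacity_sd == 0))
  expect_true(all(cv$lost_sd == 0))
  expect_equal(cv$n_replicates, rep(2L, 3))

  # step 0 is always (1, 0)
  s <- random_setup(41)
  tr <- run_iterative_removal(s$net, s$profiles, s$municipalities,
                              sim_params(s = 2), ensemble = 3, seed = 14)
  cv <- resilience_curves(tr)
  first <- cv[cv$step == 0, ]
  expect_true(all(first$free_capacity_mean == 1))
  expect_true(all(first$lost_mean == 0))

  expect_error(resilience_curves(tibble::tibble()), "empty")
})

test_that("critical limits interpolate linearly and flag censoring", {
  cv <- tibble::tibble(
    region = "1", step = 0:2, frac_removed = c(0, 0.33, 0.67),
    free_capacity_mean = c(1, 0.5, 0.15), free_capacity_sd = 0,
    lost_mean = c(0, 0, 0.05), lost_sd = 0, n_replicates = 2L
  )
  lim <- critical_limits(cv, fc_limit = 0.20, lp_limit = 0.01)
  expect_equal(lim$L_FC, 0.33 + (0.5 - 0.2) / (0.5 - 0.15) * (0.67 - 0.33),
               tolerance = 1e-12)
  expect_equal(round(lim$L_FC, 2), 0.62)
  expect_equal(lim$L_LP, 0.33 + 0.01 / 0.05 * (0.67 - 0.33), tolerance = 1e-12)
  expect_false(lim$fc_censored || lim$lp_censored)

  # lost patients never exceeding the limit -> censored at 1
  cv2 <- dplyr::mutate(cv, lost_mean = 0)
  lim2 <- critical_limits(cv2)
  expect_equal(lim2$L_LP, 1)
  expect_true(lim2$lp_censored)

  # degenerate threshold: the curve sits on the limit at step 0,
  # so the first recorded removal fraction is the answer
  lim3 <- critical_limits(cv, fc_limit = 1.0)
  expect_equal(lim3$L_FC, 0.33)
})

test_that("critical limits are monotone in their thresholds", {
  set.seed(51)
  for (rep in 1:10) {
    k <- 8
    fc <- c(1, sort(runif(k - 1), decreasing = TRUE), 0)
    lost <- c(0, sort(runif(k - 1)), 1)
    cv <- tibble::tibble(region = "1", step = 0:k,
                         frac_removed = (0:k) / k,
                         free_capacity_mean = fc, free_capacity_sd = 0,
                         lost_mean = lost, lost_sd = 0, n_replicates = 1L)
    fc_lims <- vapply(c(0.1, 0.2, 0.4), function(l)
      critical_limits(cv, fc_limit = l)$L_FC, 0)
    expect_true(all(diff(fc_lims) <= 1e-9)) # higher limit -> reached earlier
    lp_lims <- vapply(c(0.01, 0.05, 0.2), function(l)
      critical_limits(cv, lp_limit = l)$L_LP, 0)
    expect_true(all(diff(lp_lims) >= -1e-9))
  }
})

test_that("risk scores follow the clamped neighbour-load formula", {
  # worked example: N_i = 10; neighbours (N=2, C=10, a=1), (N=4, C=20, a=1)
  s <- toy_setup(edge_df(c(1, 1), c(2, 3), c(1, 1)),
                 N = c(10, 2, 4), C = c(20, 10, 20))
  r <- risk_scores(s$net, s$profiles)
  expect_equal(r$risk[r$node_id == "doc1"], 0.575)

  # all neighbours at full capacity -> clamped at 1
  s2 <- toy_setup(edge_df(c(1, 1), c(2, 3), c(2, 5)),
                  N = c(3, 10, 20), C = c(5, 10, 20))
  r2 <- risk_scores(s2$net, s2$profiles)
  expect_equal(r2$risk[r2$node_id == "doc1"], 1)

  # nobody has patients -> zero risk
  s3 <- toy_setup(edge_df(1, 2, 1), N = c(0, 0), C = c(5, 5))
  expect_equal(risk_scores(s3$net, s3$profiles)$risk, c(0, 0))

  # isolated physicians are missing, not zero
  s4 <- toy_setup(edge_df(1, 2, 1), N = c(1, 1, 1), C = c(2, 2, 2))
  r4 <- risk_scores(s4$net, s4$profiles)
  expect_true(is.na(r4$risk[r4$node_id == "doc3"]))
  expect_false(anyNA(r4$risk[r4$node_id != "doc3"]))
})

test_that("adding a fully loaded neighbour never decreases the risk score", {
  base <- toy_setup(edge_df(c(1, 1), c(2, 3), c(2, 1)),
                    N = c(6, 2, 3), C = c(10, 8, 9))
  with_full <- toy_setup(edge_df(c(1, 1, 1), c(2, 3, 4), c(2, 1, 2)),
                         N = c(6, 2, 3, 12), C = c(10, 8, 9, 12))
  r0 <- risk_scores(base$net, base$profiles)
  r1 <- risk_scores(with_full$net, with_full$profiles)
  expect_gte(r1$risk[r1$node_id == "doc1"], r0$risk[r0$node_id == "doc1"])
})

test_that("benefit scores are min-max normalised within specialty", {
  s <- toy_setup(NULL, N = c(5, 5, 5), C = c(5, 10, 15))
  b <- benefit_scores(s$profiles)
  expect_equal(b$benefit, c(0, 0.5, 1))
  expect_equal(b$benefit[which.max(b$free_capacity)], 1)
  expect_equal(b$benefit[which.min(b$free_capacity)], 0)
  expect_false(any(b$degenerate))

  s2 <- toy_setup(NULL, N = c(5, 5), C = c(8, 8))
  b2 <- benefit_scores(s2$profiles)
  expect_equal(b2$benefit, c(0, 0))
  expect_true(all(b2$degenerate))
})

test_that("regional levels count strict exceedances of the nationwide mean", {
  scores <- tibble::tibble(
    node_id = sprintf("d%d", 1:4), specialty = "GP",
    region = c("1", "1", "2", "2"), risk = c(0.2, 0.4, 0.6, 0.8)
  )
  lev <- regional_levels(scores, "risk") # mean 0.5
  expect_equal(lev$pct_above_average[lev$region == "1"], 0)
  expect_equal(lev$pct_above_average[lev$region == "2"], 100)

  # identical scores: strict inequality -> 0% everywhere
  lev0 <- regional_levels(dplyr::mutate(scores, risk = 0.3), "risk")
  expect_true(all(lev0$pct_above_average == 0))

  # one state holding every above-average physician
  scores$risk <- c(0.9, 0.8, 0.1, 0.2)
  lev1 <- regional_levels(scores, "risk")
  expect_equal(lev1$pct_above_average[lev1$region == "1"], 100)
  expect_equal(lev1$pct_above_average[lev1$region == "2"], 0)
})

test_that("the score-resilience regression recovers planted coefficients", {
  make_inputs <- function(noise_sd = 0, seed = 1) {
    set.seed(seed)
    states <- as.character(1:8)
    risk <- seq(0.1, 0.8, 0.1)
    benefit <- c(0.3, 0.9, 0.1, 0.7, 0.5, 0.2, 0.8, 0.4)
    L <- 2 * risk - 3 * benefit + 1 + rnorm(8, 0, noise_sd)
    list(
      limits = tibble::tibble(specialty = "GP", region = states,
                              L_FC = L, L_LP = L),
      scores = tibble::tibble(specialty = "GP", region = states,
                              risk = risk, benefit = benefit)
    )
  }
  noiseless <- make_inputs()
  fit <- score_resilience_regression(noiseless$limits, noiseless$scores)
  co <- tidy(fit)
  est <- co$estimate[co$outcome == "L_FC"]
  names(est) <- co$term[co$outcome == "L_FC"]
  expect_equal(unname(est[c("risk", "benefit", "(Intercept)")]),
               c(2, -3, 1), tolerance = 1e-10)
  expect_equal(fit$summary$mean[fit$summary$outcome == "L_FC" &
                                  fit$summary$term == "risk"], 2,
               tolerance = 1e-10)

  # duplicated rows leave the OLS solution unchanged
  dup <- score_resilience_regression(
    dplyr::bind_rows(noiseless$limits, noiseless$limits),
    noiseless$scores)
  expect_equal(tidy(dup)$estimate, co$estimate, tolerance = 1e-10)

  # constant benefit -> rank deficiency is flagged
  flat <- noiseless
  flat$scores$benefit <- 0.5
  fit2 <- score_resilience_regression(flat$limits, flat$scores)
  expect_true(all(tidy(fit2)$flag == "rank_deficient"))
  expect_true(all(is.na(tidy(fit2)$estimate)))

  # fewer than four states is refused per specialty
  small <- noiseless
  small$limits <- small$limits[1:3, ]
  fit3 <- score_resilience_regression(small$limits, small$scores)
  expect_true(all(tidy(fit3)$flag == "insufficient_states"))

  gl <- suppressWarnings(glance(fit)) # summary.lm warns on a perfect fit
  expect_s3_class(gl, "tbl_df")
  expect_equal(gl$r.squared, c(1, 1), tolerance = 1e-10)
})

test_that("the regression is unbiased over repeated noisy draws", {
  errs <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    states <- as.character(1:9)
    risk <- runif(9)
    benefit <- runif(9)
    L <- 2 * risk - 3 * benefit + 1 + rnorm(9, 0, 0.3)
    fit <- score_resilience_regression(
      tibble::tibble(specialty = "GP", region = states, L_FC = L, L_LP = L),
      tibble::tibble(specialty = "GP", region = states, risk = risk,
                     benefit = benefit))
    co <- tidy(fit)
    co$estimate[co$outcome == "L_FC" & co$term == "risk"] - 2
  }, 0)
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))
})

test_that("state score means aggregate physicians by plain averaging", {
  risk <- tibble::tibble(node_id = sprintf("d%d", 1:4), specialty = "GP",
                         region = c("1", "1", "2", "2"),
                         risk = c(0.2, 0.4, NA, 0.8))
  benefit <- tibble::tibble(node_id = sprintf("d%d", 1:4), specialty = "GP",
                            region = c("1", "1", "2", "2"),
                            benefit = c(0, 1, 0.5, 0.5))
  m <- state_score_means(risk, benefit)
  expect_equal(m$risk[m$region == "1"], 0.3)
  expect_equal(m$risk[m$region == "2"], 0.8) # NA isolate excluded
  expect_equal(m$benefit[m$region == "1"], 0.5)
})
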