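test_that("branch integrator matches closed-form survival on one branch", {
  # single lineage, no transitions, no extinction: D(t) = e^{-lambda t}
  y <- venomdiv:::sse_branch_cpp(c(0, 0, 1, 0), 3, c(0.1, 0.1), c(0, 0),
                                 matrix(0, 2, 2), 1e-10, 1e-12)
  expect_equal(y[3], exp(-0.3), tolerance = 1e-9)
  expect_equal(y[1], 0)
})

test_that("SSE lnL matches a high-resolution dense integrator", {
  tr <- tree3()
  st <- c(A = 0, B = 1, C = 0)
  Q <- matrix(0, 2, 2); Q[1, 2] <- 0.05; Q[2, 1] <- 0.03
  m <- sse_model(c(0.1, 0.2), c(0.01, 0.02), Q)
  ll <- sse_loglik(tr, st, m)
  oracle <- bisse_oracle_lnL(tr, st, m$lambda, m$mu, Q)
  expect_equal(ll, oracle, tolerance = 1e-4)

  # also on a small simulated tree with a polytomy
  set.seed(40)
  sim <- simulate_sse(m, root_state = 1, T = 25, min_tips = 5,
                      max_tips = 60)
  poly <- ape::di2multi(condition_tree(sim$tree, pad = 0.2), tol = 0.3)
  st2 <- sim$obs_states[poly$tip.label]
  expect_equal(sse_loglik(poly, st2, m),
               bisse_oracle_lnL(poly, st2, m$lambda, m$mu, Q),
               tolerance = 1e-4)
})

test_that("equal-rates SSE factorizes into pure-birth x Markov-trait parts", {
  ds <- fixture_dataset()
  tr <- ds$tree
  st <- stats::setNames(ds$families$venomous, ds$families$family)
  lam <- 0.04; q <- 0.015
  Q <- matrix(0, 2, 2); Q[1, 2] <- q; Q[2, 1] <- q
  m <- sse_model(c(lam, lam), c(0, 0), Q)
  ll <- sse_loglik(tr, st, m, root = "equal", condition_surv = FALSE)
  n <- ape::Ntip(tr)
  ll_yule <- (n - 1) * log(lam) - lam * sum(tr$edge.length)
  ll_mk <- venomdiv:::mk2_loglik(tr, as.integer(st[tr$tip.label]), q, q,
                                 root = "equal")
  expect_equal(ll, ll_yule + ll_mk, tolerance = 1e-6)
})

test_that("lnL is invariant to tip relabelling order and child rotation", {
  ds <- fixture_dataset()
  tr <- ds$tree
  st <- stats::setNames(ds$families$venomous, ds$families$family)
  Q <- matrix(0, 2, 2); Q[1, 2] <- 0.004; Q[2, 1] <- 0.03
  m <- sse_model(c(0.03, 0.06), c(0.005, 0.005), Q)
  ll <- sse_loglik(tr, st, m)
  # permuted state vector (names carry the mapping)
  st_perm <- st[sample(names(st))]
  expect_equal(sse_loglik(tr, st_perm, m), ll, tolerance = 1e-8)
  # rotating children rewrites the edge table but not the likelihood
  tr_rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(sse_loglik(tr_rot, st, m), ll, tolerance = 1e-8)
})

test_that("constrained fits are nested under the unconstrained fit", {
  set.seed(41)
  Q <- matrix(0, 2, 2); Q[1, 2] <- 0.01; Q[2, 1] <- 0.03
  truth <- sse_model(c(0.05, 0.1), c(0.01, 0.01), Q)
  sim <- simulate_sse(truth, root_state = 1, T = 70, min_tips = 60,
                      max_tips = 500)
  ms <- model_set(sim$tree, sim$obs_states,
                  variants = c("full", "equal_all", "equal_div",
                               "equal_lambda", "equal_mu"),
                  n_restarts = 1, seed = 5)
  lnl <- stats::setNames(ms$aic_table$lnL, ms$aic_table$variant)
  expect_true(all(lnl <= lnl["full"] + 1e-6))
  ks <- stats::setNames(ms$aic_table$k, ms$aic_table$variant)
  expect_equal(unname(ks[c("full", "equal_all", "equal_div",
                           "equal_lambda", "equal_mu")]),
               c(6, 3, 4, 5, 5))
})

test_that("simulation obeys degenerate and expectation checks", {
  m0 <- sse_model(0, 0, matrix(0, 1, 1))
  sim <- simulate_sse(m0, root_state = 1, T = 5, reject = FALSE)
  expect_null(sim$tree)
  expect_equal(sim$n_tips, 1)  # no events: the root lineage alone

  # Yule expectation: mean surviving tips ~ e^{lambda T}
  my <- sse_model(0.1, 0, matrix(0, 1, 1))
  set.seed(42)
  tips <- replicate(1000, simulate_sse(my, 1, T = 10, reject = FALSE)$n_tips)
  expect_equal(mean(tips), exp(1), tolerance = 0.1)

  # fast symmetric switching equilibrates tip states near 50/50
  Q <- matrix(0, 2, 2); Q[1, 2] <- 2; Q[2, 1] <- 2
  mq <- sse_model(c(0.15, 0.15), c(0, 0), Q)
  set.seed(43)
  sim <- simulate_sse(mq, 1, T = 40, min_tips = 150, max_tips = 5e4)
  p1 <- mean(sim$obs_states == 1)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / sim$n_tips) + 0.02)
})

test_that("adequacy check brackets data simulated from the model itself", {
  set.seed(44)
  Q <- matrix(0, 2, 2); Q[1, 2] <- 0.02; Q[2, 1] <- 0.02
  truth <- sse_model(c(0.06, 0.06), c(0.01, 0.01), Q)
  sim <- simulate_sse(truth, root_state = 1, T = 60, min_tips = 40,
                      max_tips = 2000)
  fit <- fit_sse(sim$tree, sim$obs_states, "equal_div", n_restarts = 1,
                 seed = 6)
  adq <- adequacy_check(fit, sim$tree, sim$obs_states, n_sims = 100,
                        seed = 7)
  expect_equal(nrow(adq$sims), 100)
  expect_true(adq$quantiles[["prop1"]] > 0.025 &&
              adq$quantiles[["prop1"]] < 0.975)
  one <- adequacy_check(fit, sim$tree, sim$obs_states, n_sims = 1, seed = 8)
  expect_equal(nrow(one$sims), 1)
})
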