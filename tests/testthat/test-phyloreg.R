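test_that("covariance models reduce to BM at neutral parameters", {
  trees <- list(tree3(), {
    set.seed(20); ape::rphylo(40, birth = 0.1, death = 0)
  })
  for (tr in trees) {
    C <- phylo_covariance(tr, "BM")
    expect_lt(max(abs(phylo_covariance(tr, "lambda", 1) - C)), 1e-10)
    expect_lt(max(abs(phylo_covariance(tr, "kappa", 1) - C)), 1e-10)
    expect_lt(max(abs(phylo_covariance(tr, "delta", 1) - C)), 1e-10)
    expect_lt(max(abs(phylo_covariance(tr, "early_burst", 0) - C)), 1e-10)
  }
})

test_that("BM covariance on the 3-tip tree matches hand computation", {
  C <- phylo_covariance(tree3(), "BM")
  expect_equal(unname(C), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  # lambda = 0 keeps only the diagonal
  L0 <- phylo_covariance(tree3(), "lambda", 0)
  expect_equal(unname(L0), diag(c(2, 2, 2)))
  expect_error(phylo_covariance(tree3(), "lambda", 1.2), "range")
  expect_error(phylo_covariance(tree3(), "early_burst", 0.5), "range")
})

test_that("every covariance kind yields a PSD matrix on random trees", {
  kinds <- list(BM = NULL, OU_random_root = 0.05, OU_fixed_root = 0.05,
                lambda = 0.4, kappa = 0.6, delta = 1.8, early_burst = -0.05,
                nonphylo_OLS = NULL)
  set.seed(21)
  for (rep in 1:3) {
    tr <- ape::rphylo(30, birth = 0.1, death = 0)
    for (kind in names(kinds)) {
      V <- phylo_covariance(tr, kind, kinds[[kind]])
      expect_lt(max(abs(V - t(V))), 1e-12)
      expect_gt(min(eigen(V, symmetric = TRUE,
                          only.values = TRUE)$values), -1e-8)
    }
  }
})

test_that("PGLS on a star tree and identity covariance reproduce OLS", {
  star <- ape::read.tree(text = paste0(
    "(", paste0("t", 1:12, ":1", collapse = ","), ");"))
  set.seed(22)
  x <- rnorm(12); y <- 1 + 2 * x + rnorm(12, sd = 0.3)
  X <- cbind(Intercept = 1, x = x)
  ols <- stats::lm(y ~ x)
  for (kind in c("BM", "nonphylo_OLS")) {
    f <- fit_pgls(y, X, star, kind)
    expect_equal(f$coefficients$Coefficient, unname(coef(ols)),
                 tolerance = 1e-8)
    expect_equal(f$coefficients$t,
                 unname(summary(ols)$coefficients[, "t value"]),
                 tolerance = 1e-6)
    expect_equal(f$coefficients$Coefficient / f$coefficients$SE,
                 f$coefficients$t, tolerance = 1e-12)
    expect_equal(f$AIC, 2 * f$k - 2 * f$logLik)
  }
})

test_that("ML lambda fit agrees with the nlme/corPagel implementation", {
  ds <- fixture_dataset()
  tr <- ds$tree
  n <- ape::Ntip(tr)
  set.seed(23)
  sig <- 0.5 * phylo_covariance(tr, "lambda", 0.6)
  y <- 2 + drop(t(chol(sig)) %*% rnorm(n))
  x <- rnorm(n)
  y <- y + 1.5 * x
  f <- fit_pgls(y, cbind(Intercept = 1, x = x), tr, "lambda")
  d <- data.frame(y = y, x = x, sp = tr$tip.label)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corPagel(0.5, tr, form = ~sp),
                 method = "ML")
  expect_equal(unname(f$cov_par), g$modelStruct$corStruct[[1]],
               tolerance = 1e-4)
  expect_equal(f$coefficients$Coefficient, unname(coef(g)),
               tolerance = 1e-6)
  expect_equal(f$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
})

test_that("BM regression coefficients are recovered across replicates", {
  set.seed(24)
  tr <- ape::rphylo(200, birth = 0.1, death = 0)
  Vchol <- t(chol(phylo_covariance(tr, "BM")))
  n <- 200
  est <- replicate(100, {
    x <- rnorm(n)
    y <- 1 + 2 * x + drop(Vchol %*% rnorm(n))
    fit_pgls(y, cbind(Intercept = 1, x = x), tr, "BM")$coefficients$Coefficient
  })
  # slope: tight recovery; intercept: unbiased but with the large sampling
  # variance a Brownian root state implies, so bound by its Monte-Carlo SE
  expect_lt(abs(mean(est[2, ]) - 2), 0.1)
  se1 <- stats::sd(est[1, ]) / sqrt(ncol(est))
  expect_lt(abs(mean(est[1, ]) - 1), 4 * se1)
})

test_that("AIC selection identifies strong lambda structure", {
  set.seed(25)
  tr <- ape::rphylo(150, birth = 0.1, death = 0)
  Lchol <- t(chol(phylo_covariance(tr, "lambda", 0.3)))
  wins <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    y <- drop(Lchol %*% rnorm(150))
    sel <- select_model(y, cbind(Intercept = rep(1, 150)), tr,
                        candidates = c("BM", "lambda"))
    tab <- sel$aic_table
    if (tab$AIC[tab$kind == "BM"] - tab$AIC[tab$kind == "lambda"] > 2)
      wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.8)

  # a single candidate is returned unchanged
  y <- rnorm(150)
  one <- select_model(y, cbind(Intercept = rep(1, 150)), tr,
                      candidates = "BM")
  expect_equal(one$best$model, "BM")
  expect_equal(nrow(one$aic_table), 1)
})

test_that("richness regression recovers a planted rate effect", {
  ds <- fixture_dataset()
  fam <- ds$families
  rates <- rate_table(fam, eps_list = 0.5)
  set.seed(26)
  fam2 <- fam
  r <- rates$rate
  fam2$richness <- pmax(1, round(exp(
    2 + 30 * r + rnorm(nrow(fam), sd = 0.2))))  # offset keeps counts >> 1
  # regress against the ORIGINAL rate table so the planted linear link
  # between log richness and the rate predictor is preserved
  sel <- richness_model(fam2, rates, ds$tree,
                        epsilon = 0.5, candidates = c("BM", "lambda",
                                                      "nonphylo_OLS"))
  co <- sel$best$coefficients
  expect_lt(abs(co["Rate", "Coefficient"] - 30), 5)
  expect_true(all(abs(co["Rate", "t"]) >= abs(co[c("Venom", "Age"), "t"])))
})

test_that("rate regression recovers a planted venom effect and its null", {
  ds <- fixture_dataset()
  fam <- ds$families
  tr <- ds$tree
  set.seed(27)
  n_rep <- 50L
  est <- numeric(n_rep); est0 <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    base <- 0.05 - 0.0005 * fam$stem_age + rnorm(nrow(fam), sd = 0.01)
    rates1 <- data.frame(family = fam$family, venomous = fam$venomous,
                         epsilon = 0.5, rate = base + 0.02 * fam$venomous)
    rates0 <- data.frame(family = fam$family, venomous = fam$venomous,
                         epsilon = 0.5, rate = base)
    est[i] <- divrate_model(fam, rates1, tr, epsilon = 0.5,
                            candidates = "BM")$best$
      coefficients["Venom", "Coefficient"]
    est0[i] <- divrate_model(fam, rates0, tr, epsilon = 0.5,
                             candidates = "BM")$best$
      coefficients["Venom", "Coefficient"]
  }
  expect_gt(mean(est), 0.01)
  expect_lt(mean(est), 0.03)
  expect_lt(abs(mean(est0)), 0.005)  # null effect centred on zero
})
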