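test_that("sister pairs are found, skipped and summed correctly", {
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  st <- c(A = 1, B = 1, C = 0, D = 0)
  ri <- c(A = 10, B = 5, C = 2, D = 1)
  pairs <- find_sister_pairs(tr4, st, ri)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$n1, 15)
  expect_equal(pairs$n0, 3)
  expect_equal(pairs$age, 2)

  expect_warning(find_sister_pairs(tr4, c(A = 0, B = 0, C = 0, D = 0)),
                 "state 1")

  # a mixed-state sister is skipped (with a message); the clean pair stays
  tr5 <- ape::read.tree(text = "((A:1,(B:0.5,C:0.5):0.5):1,D:2);")
  st5 <- c(A = 1, B = 1, C = 0, D = 0)
  expect_message(pr <- find_sister_pairs(tr5, st5), "skipped")
  expect_equal(nrow(pr), 1)
  expect_equal(pr$clade1_tips, "B")
  expect_equal(pr$clade0_tips, "C")
  expect_equal(pr$age, 0.5)
})

test_that("returned pairs are true uniform-state sisters (brute force)", {
  ds <- fixture_dataset()
  tr <- ds$tree
  st <- stats::setNames(ds$families$venomous, ds$families$family)
  ri <- stats::setNames(ds$families$richness, ds$families$family)
  pairs <- suppressMessages(find_sister_pairs(tr, st, ri))
  expect_gt(nrow(pairs), 0)
  used1 <- character()
  for (i in seq_len(nrow(pairs))) {
    t1 <- strsplit(pairs$clade1_tips[i], ",")[[1]]
    t0 <- strsplit(pairs$clade0_tips[i], ",")[[1]]
    expect_true(all(st[t1] == 1))
    expect_true(all(st[t0] == 0))
    expect_equal(pairs$n1[i], sum(ri[t1]))
    expect_equal(pairs$n0[i], sum(ri[t0]))
    # exhaustive check: the union is exactly the clade of its MRCA
    mrca <- ape::getMRCA(tr, c(t1, t0))
    clade <- ape::extract.clade(tr, mrca)$tip.label
    expect_setequal(clade, c(t1, t0))
    expect_false(any(t1 %in% used1))  # pairs disjoint
    used1 <- c(used1, t1)
  }
})

test_that("Yule richness log-likelihood matches its closed form", {
  expect_equal(yule_richness_loglik(1, 7, 0.3), -2.1, tolerance = 1e-12)
  expect_equal(yule_richness_loglik(5, 10, 0.2),
               -2 + 4 * log(1 - exp(-2)), tolerance = 1e-12)
  # normalization: partial sums approach 1 from below
  p_small <- sum(exp(yule_richness_loglik(1:50, 10, 0.2)))
  p_big <- sum(exp(yule_richness_loglik(1:1e6, 10, 0.2)))
  expect_lt(p_small, p_big)
  expect_lte(p_big, 1 + 1e-12)
  expect_gt(p_big, 1 - 1e-6)
  expect_error(yule_richness_loglik(0, 1, 0.1), "richness")
  expect_error(yule_richness_loglik(2, -1, 0.1), "'t'")
  expect_error(yule_richness_loglik(2, 1, 0), "lam")
})

test_that("richness Yule test: symmetry, agreement with ape, and ordering", {
  # mirrored pairs force chi2 = 0
  mirror <- data.frame(n1 = c(5, 20, 3), n0 = c(5, 20, 3),
                       age = c(10, 30, 12))
  res <- richness_yule_test(mirror)
  expect_lt(res$chi2, 1e-6)
  expect_equal(res$df, 1L)

  # exact agreement with the independent ape implementation
  set.seed(31)
  pairs <- draw_pairs(15, lam1 = 0.08, lam0 = 0.04)
  res <- richness_yule_test(pairs)
  ref <- ape::richness.yule.test(data.frame(pairs$n1, pairs$n0), pairs$age)
  expect_equal(res$chi2, ref$chisq, tolerance = 1e-5)
  expect_equal(res$p, ref$P.val, tolerance = 1e-5)

  # common-rate estimate lies between the class estimates
  for (seed in 32:36) {
    set.seed(seed)
    p <- draw_pairs(12, lam1 = 0.1, lam0 = 0.03)
    r <- richness_yule_test(p)
    expect_gte(r$lambda_common,
               min(r$lambda_venom, r$lambda_nonvenom) - 1e-10)
    expect_lte(r$lambda_common,
               max(r$lambda_venom, r$lambda_nonvenom) + 1e-10)
    expect_gte(r$chi2, 0)
  }
})

test_that("test power increases with the rate ratio", {
  set.seed(37)
  reject <- function(ratio, n_rep = 60) {
    mean(replicate(n_rep, {
      p <- draw_pairs(20, lam1 = 0.04 * ratio, lam0 = 0.04)
      richness_yule_test(p)$p < 0.05
    }))
  }
  r_big <- reject(2.0)
  r_small <- reject(1.2)
  expect_gt(r_big, r_small)
  expect_gt(r_big, 0.5)
})

test_that("mean richness ratio is the pair-ratio average and scale-free", {
  expect_equal(richness_ratio(data.frame(n1 = 50, n0 = 10)), 5)
  prs <- data.frame(n1 = c(4, 9), n0 = c(2, 3))
  expect_equal(richness_ratio(prs), 2.5)
  scaled <- data.frame(n1 = prs$n1 * 7, n0 = prs$n0 * 7)
  expect_equal(richness_ratio(scaled), 2.5)
})
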