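test_that("Newick reading preserves topology, lengths and polytomies", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)

  writeLines("((A:1,B:1,C:1):1,D:2);", f)
  tr <- read_newick(f)
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(tr$Nnode, 2)  # trichotomy kept, not resolved

  # round trip of a simulated 100-tip tree
  set.seed(10)
  sim <- ape::rphylo(100, birth = 0.1, death = 0)
  ape::write.tree(sim, f, digits = 17)
  back <- read_newick(f)
  expect_equal(suppressWarnings(ape::dist.topo(sim, back)),
               structure(0, names = "PH85"), ignore_attr = TRUE)
  d1 <- ape::cophenetic.phylo(sim); d2 <- ape::cophenetic.phylo(back)
  expect_lt(max(abs(d1 - d2[rownames(d1), colnames(d1)])), 1e-10)
})

test_that("invalid trees are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2", f)  # unbalanced, unterminated
  expect_error(suppressWarnings(read_newick(f)))
  writeLines("((A,B),C);", f)
  expect_error(read_newick(f), "branch length")
  writeLines("((A:1,a:1):1,C:2);", f)  # duplicate up to case
  expect_error(read_newick(f), "Duplicate")
})

test_that("pruning preserves path lengths among retained tips", {
  tr <- tree3()
  pruned <- prune_tips(tr, "C")
  expect_equal(sort(pruned$tip.label), c("A", "B"))
  expect_equal(ape::cophenetic.phylo(pruned)["A", "B"], 2)

  expect_identical(prune_tips(tr, character(0)), tr)
  expect_error(prune_tips(tr, "Zzz"), "Zzz")

  set.seed(11)
  big <- ape::rphylo(200, birth = 0.1, death = 0)
  drop <- sample(big$tip.label, 50)
  keep <- setdiff(big$tip.label, drop)
  pruned <- prune_tips(big, drop)
  d0 <- ape::cophenetic.phylo(big)[keep, keep]
  d1 <- ape::cophenetic.phylo(pruned)[keep, keep]
  expect_lt(max(abs(d0 - d1)), 1e-10)
})

test_that("force_ultrametric equalizes depths and is idempotent", {
  tr <- tree3()
  expect_identical(force_ultrametric(tr), tr)  # already ultrametric

  jag <- ape::read.tree(text = "((A:1,B:1.2):1,C:2);")
  fixed <- force_ultrametric(jag)
  dep <- ape::node.depth.edgelength(fixed)[1:3]
  expect_lt(diff(range(dep)), 1e-8)

  set.seed(12)
  base <- ape::rphylo(60, birth = 0.1, death = 0)
  jit <- base
  jit$edge.length <- jit$edge.length * stats::runif(length(jit$edge.length),
                                                   0.99, 1.01)
  out <- force_ultrametric(jit)
  v_in <- stats::var(ape::node.depth.edgelength(jit)[1:60])
  v_out <- stats::var(ape::node.depth.edgelength(out)[1:60])
  expect_lt(v_out, v_in)
  out2 <- force_ultrametric(out)
  expect_lt(max(abs(out2$edge.length - out$edge.length)), 1e-10)
})

test_that("conditioning pads short branches and restores ultrametricity", {
  tr <- tree3()
  same <- condition_tree(tr, pad = 0.5)
  expect_lt(max(abs(same$edge.length - tr$edge.length)), 1e-10)

  poly <- ape::read.tree(text = "(((A:1,B:1):0,C:1):0,(D:0.5,E:0.5):0.5);")
  out <- condition_tree(poly, pad = 0.5)
  expect_true(all(out$edge.length > 0))
  dep <- ape::node.depth.edgelength(out)[1:5]
  expect_lt(diff(range(dep)), 1e-8)

  expect_error(condition_tree(tr, pad = -1), "non-negative")

  set.seed(13)
  big <- ape::rphylo(100, birth = 0.1, death = 0)
  short <- big
  short$edge.length[sample(length(short$edge.length), 10)] <- 0
  out <- condition_tree(short, pad = 0.5)
  dep <- ape::node.depth.edgelength(out)[1:100]
  expect_lt(max(abs(dep - mean(dep))), 1e-8)
  expect_true(all(out$edge.length > 0))
})

test_that("stem ages equal parent-node ages", {
  tr <- tree3()
  expect_equal(stem_ages(tr), c(A = 1, B = 1, C = 2))

  # tip subtended directly by the root gets the root age
  expect_equal(stem_ages(tr)[["C"]], 2)

  set.seed(14)
  sim <- ape::rphylo(80, birth = 0.08, death = 0)
  sa <- stem_ages(sim)
  # independent traversal oracle: parent node depths
  dep <- ape::node.depth.edgelength(sim)
  ages <- max(dep[1:80]) - dep
  parent <- sim$edge[match(1:80, sim$edge[, 2]), 1]
  expect_equal(unname(sa[sim$tip.label]), ages[parent], tolerance = 1e-10)

  jag <- ape::read.tree(text = "((A:1,B:1.7):1,C:2);")
  expect_error(stem_ages(jag), "ultrametric")
})

test_that("family tables are read, validated and aligned", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("family,richness,venomous",
               "A,10,1", "B,5,0", "C,3,0"), f)
  fam <- read_family_table(f)
  expect_equal(fam$mixed_state, c(0L, 0L, 0L))

  writeLines(c("family,richness,venomous", "A,0,1"), f)
  expect_error(read_family_table(f), "richness")
  writeLines(c("family,richness,venomous", "A,2,2"), f)
  expect_error(read_family_table(f), "venomous")
  writeLines(c("family,richness", "A,2"), f)
  expect_error(read_family_table(f), "venomous")

  fam <- data.frame(family = c("a", "B", "Extra"),
                    richness = c(4L, 2L, 9L), venomous = c(1L, 0L, 0L))
  ali <- suppressMessages(align_family_data(tree3(), fam))
  # case-insensitive match; unmatched record dropped; stem ages attached
  expect_equal(nrow(ali$families), 2)
  expect_equal(ali$families$stem_age,
               unname(stem_ages(ali$tree)[ali$families$family]))
})
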