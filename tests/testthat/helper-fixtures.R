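# Shared fixtures, built once per test run.

# 3-tip reference tree used by the hand-computed oracles
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# mid-sized synthetic dataset reused across modules
.fixture_env <- new.env()
fixture_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- gen_dataset(synth_config(n_families = 150, seed = 101))
  .fixture_env$ds
}

# independent 2x2 matrix exponential via eigendecomposition (no shared code
# with the package's closed-form transition probabilities)
expm2_eigen <- function(Q, t) {
  e <- eigen(Q)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

# independent dense-integrator BiSSE pruning oracle built on deSolve
bisse_oracle_lnL <- function(tree, states, lambda, mu, Q,
                             root = "fitzjohn", condition = TRUE) {
  rhs <- function(t, y, p) {
    k <- length(p$lam)
    E <- y[1:k]; D <- y[(k + 1):(2 * k)]
    Qo <- p$Q; diag(Qo) <- 0
    s <- rowSums(Qo)
    dE <- p$mu - (p$lam + p$mu + s) * E + p$lam * E^2 + Qo %*% E
    dD <- -(p$lam + p$mu + s) * D + 2 * p$lam * E * D + Qo %*% D
    list(c(dE, dD))
  }
  p <- list(lam = lambda, mu = mu, Q = Q)
  k <- length(lambda)
  integ <- function(y0, t) {
    if (t == 0) return(y0)
    as.numeric(deSolve::ode(y0, c(0, t), rhs, p,
                            rtol = 1e-10, atol = 1e-12)[2, -1])
  }
  ntip <- ape::Ntip(tree)
  st <- as.integer(states[tree$tip.label])
  vals <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip))
    vals[[i]] <- c(rep(0, k), as.numeric(seq_len(k) - 1 == st[i]))
  edge <- tree$edge
  kids <- split(edge[, 2], edge[, 1])
  up <- vector("list", ntip + tree$Nnode)
  for (e in ape::postorder(tree)) {
    ch <- edge[e, 2]
    if (ch > ntip) {
      cs <- kids[[as.character(ch)]]
      D <- up[[cs[1]]][(k + 1):(2 * k)]
      for (j in cs[-1]) D <- D * up[[j]][(k + 1):(2 * k)] * lambda
      vals[[ch]] <- c(up[[cs[1]]][1:k], D)
    }
    up[[ch]] <- integ(vals[[ch]], tree$edge.length[e])
  }
  rootn <- ntip + 1
  cs <- kids[[as.character(rootn)]]
  D <- up[[cs[1]]][(k + 1):(2 * k)]
  for (j in cs[-1]) D <- D * up[[j]][(k + 1):(2 * k)] * lambda
  E <- up[[cs[1]]][1:k]
  w <- switch(root, fitzjohn = D / sum(D), equal = rep(1 / k, k))
  Dc <- if (condition) D / (lambda * (1 - E)^2) else D
  log(sum(w * Dc))
}

# draw a set of synthetic sister pairs under Yule richness with rates
# (lam1 for the trait-bearing clade, lam0 for its sister)
draw_pairs <- function(n_pairs, lam1, lam0, age_range = c(10, 60)) {
  age <- stats::runif(n_pairs, age_range[1], age_range[2])
  rgeo <- function(lam, t) stats::rgeom(length(t), exp(-lam * t)) + 1L
  data.frame(n1 = rgeo(lam1, age), n0 = rgeo(lam0, age), age = age)
}
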