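#' @name sse
#' @title State-dependent speciation-extinction (SSE) models
#' @description Generalized k-state binary-trait speciation-extinction
#'   likelihood (BiSSE; plus a hidden-state variant in the HiSSE spirit),
#'   the five constrained model variants, maximum-likelihood fitting, AIC
#'   model comparison, exact stochastic simulation and simulation-based
#'   adequacy checking.
NULL

#' Construct an SSE model parameterization
#'
#' @param lambda Speciation rate per state (length k), per My.
#' @param mu Extinction rate per state (length k), per My.
#' @param Q k x k transition-rate matrix; off-diagonal entries are the
#'   rates, the diagonal is set to minus the row sum.
#' @param obs_states Observed (0/1) state emitted by each of the k model
#'   states; defaults to \code{0:(k-1)} (no hidden states).
#' @return List of class \code{"sse_model"}.
#' @export
sse_model <- function(lambda, mu, Q, obs_states = NULL) {
  k <- length(lambda)
  Q <- as.matrix(Q)
  if (length(mu) != k || nrow(Q) != k || ncol(Q) != k)
    stop("lambda, mu and Q dimensions must agree")
  if (any(lambda < 0) || any(mu < 0)) stop("Rates must be >= 0")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("Off-diagonal transition rates must be >= 0")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (is.null(obs_states)) obs_states <- seq_len(k) - 1L
  structure(list(lambda = as.numeric(lambda), mu = as.numeric(mu), Q = Q,
                 k = k, obs_states = as.integer(obs_states)),
            class = "sse_model")
}

#' SSE log-likelihood of a tree with binary tip states
#'
#' Evaluates the joint likelihood of the tree and the observed binary tip
#' states under a k-state speciation-extinction model by postorder pruning.
#' Along each branch the per-state extinction probabilities E and data
#' partial likelihoods D are integrated with an adaptive Runge-Kutta scheme
#' (compiled); at internal nodes daughter D vectors are combined as
#' \eqn{D_i \leftarrow D_i^{(1)} D_i^{(2)} \lambda_i}, multifurcations by
#' sequential pairwise combination. D is log-rescaled at every node to
#' prevent underflow. At the root, states are weighted by their relative
#' contribution to the likelihood (FitzJohn weighting) unless another root
#' treatment is chosen, with optional conditioning on survival of both root
#' daughters (division by \eqn{\lambda_i (1 - E_i)^2}).
#'
#' @param tree Ultrametric \code{"phylo"} object with positive branch
#'   lengths.
#' @param states Named binary (0/1) vector over the tips.
#' @param model An \code{"sse_model"}.
#' @param root Root-state treatment: \code{"fitzjohn"} (default),
#'   \code{"equal"}, or \code{"given"} (supply \code{root_p}).
#' @param root_p Root-state probabilities when \code{root = "given"}.
#' @param condition_surv Condition on survival of the two root lineages
#'   (default \code{TRUE}).
#' @param rtol,atol ODE error tolerances.
#' @param details Also return root-state quantities (used by the adequacy
#'   machinery).
#' @return The log-likelihood, or (if \code{details}) a list with
#'   \code{lnL}, \code{root_D}, \code{root_E}, \code{root_weights}.
#' @export
sse_loglik <- function(tree, states, model, root = c("fitzjohn", "equal",
                                                     "given"),
                       root_p = NULL, condition_surv = TRUE,
                       rtol = 1e-8, atol = 1e-10, details = FALSE) {
  root <- match.arg(root)
  k <- model$k
  ntip <- ape::Ntip(tree)
  tips <- tree$tip.label
  if (is.null(names(states)) || !all(tips %in% names(states)))
    stop("'states' must be named and cover every tip")
  st <- as.integer(states[tips])
  if (!all(st %in% model$obs_states))
    stop("Tip states outside the model's observed states")

  tipD <- vapply(st, function(s) as.numeric(model$obs_states == s),
                 numeric(k))
  if (is.null(dim(tipD))) tipD <- matrix(tipD, nrow = k)
  pr <- sse_prune_cpp(tree$edge, tree$edge.length, ape::postorder(tree),
                      tipD, model$lambda, model$mu, model$Q, ntip,
                      rtol, atol)
  Droot <- pr$D
  Eroot <- pr$E
  logcomp <- pr$logcomp
  w <- switch(root,
    fitzjohn = Droot / sum(Droot),
    equal = rep(1 / k, k),
    given = {
      if (is.null(root_p) || length(root_p) != k)
        stop("'root_p' must have length k")
      root_p / sum(root_p)
    })
  Dc <- if (condition_surv) {
    denom <- model$lambda * (1 - Eroot)^2
    if (any(denom <= 0)) stop("Survival conditioning impossible (E = 1)")
    Droot / denom
  } else Droot
  lik <- sum(w * Dc)
  if (!is.finite(lik) || lik <= 0) stop("Non-positive root likelihood")
  lnL <- log(lik) + logcomp
  if (!details) return(lnL)
  list(lnL = lnL, root_D = Droot, root_E = Eroot, root_weights = w)
}

# Express a constrained variant's fitted parameters in a wider variant's
# parameterization (used for warm starts when enforcing likelihood nesting).
expand_sse_par <- function(from, par, to) {
  full <- switch(from,
    full = par[c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")],
    equal_all = c(par[["lambda"]], par[["lambda"]], par[["mu"]],
                  par[["mu"]], par[["q"]], par[["q"]]),
    equal_div = c(par[["lambda"]], par[["lambda"]], par[["mu"]],
                  par[["mu"]], par[["q01"]], par[["q10"]]),
    equal_lambda = c(par[["lambda"]], par[["lambda"]], par[["mu0"]],
                     par[["mu1"]], par[["q01"]], par[["q10"]]),
    equal_mu = c(par[["lambda0"]], par[["lambda1"]], par[["mu"]],
                 par[["mu"]], par[["q01"]], par[["q10"]]),
    stop("Cannot expand from variant '", from, "'"))
  full <- unname(full)
  switch(to,
    full = full,
    # duplicate the observed-state rates across the two hidden classes and
    # start hidden switching slow
    hisse = c(full[1], full[2], full[1], full[2],
              full[3], full[4], full[3], full[4],
              full[5], full[6], 1e-4),
    stop("Cannot expand to variant '", to, "'"))
}

# ---- constrained BiSSE variant set + hidden-state variant ----------------

# Each variant maps a free-parameter vector (natural scale) to an sse_model.
sse_variants <- function() {
  mkQ2 <- function(q01, q10) matrix(c(0, q10, q01, 0), 2, 2, byrow = FALSE)
  list(
    full = list(
      npar = 6L,
      names = c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10"),
      build = function(p) sse_model(p[1:2], p[3:4], mkQ2(p[5], p[6]))),
    equal_all = list(  # fully constrained: equal diversification + transition
      npar = 3L, names = c("lambda", "mu", "q"),
      build = function(p) sse_model(c(p[1], p[1]), c(p[2], p[2]),
                                    mkQ2(p[3], p[3]))),
    equal_div = list(  # equal lambda and mu; transitions free
      npar = 4L, names = c("lambda", "mu", "q01", "q10"),
      build = function(p) sse_model(c(p[1], p[1]), c(p[2], p[2]),
                                    mkQ2(p[3], p[4]))),
    equal_lambda = list(  # speciation constrained
      npar = 5L, names = c("lambda", "mu0", "mu1", "q01", "q10"),
      build = function(p) sse_model(c(p[1], p[1]), p[2:3],
                                    mkQ2(p[4], p[5]))),
    equal_mu = list(  # extinction constrained
      npar = 5L, names = c("lambda0", "lambda1", "mu", "q01", "q10"),
      build = function(p) sse_model(p[1:2], c(p[3], p[3]),
                                    mkQ2(p[4], p[5]))),
    hisse = list(
      # hidden rate class: states (0A, 1A, 0B, 1B); lambda and mu free per
      # state, observed-trait transitions shared across hidden classes,
      # hidden transitions at one shared rate eta; no dual transitions
      npar = 11L,
      names = c("lambda0A", "lambda1A", "lambda0B", "lambda1B",
                "mu0A", "mu1A", "mu0B", "mu1B", "q01", "q10", "eta"),
      build = function(p) {
        Q <- matrix(0, 4, 4)
        q01 <- p[9]; q10 <- p[10]; eta <- p[11]
        Q[1, 2] <- q01; Q[2, 1] <- q10   # 0A <-> 1A
        Q[3, 4] <- q01; Q[4, 3] <- q10   # 0B <-> 1B
        Q[1, 3] <- eta; Q[3, 1] <- eta   # 0A <-> 0B
        Q[2, 4] <- eta; Q[4, 2] <- eta   # 1A <-> 1B
        sse_model(p[1:4], p[5:8], Q, obs_states = c(0L, 1L, 0L, 1L))
      })
  )
}

#' Fit an SSE model variant by maximum likelihood
#'
#' Maximizes \code{\link{sse_loglik}} over the variant's free parameters on
#' the log scale with box constraints (L-BFGS-B), from a heuristic start
#' plus jittered restarts under a fixed seed.
#'
#' @inheritParams sse_loglik
#' @param variant One of \code{"full"}, \code{"equal_all"} (fully
#'   constrained), \code{"equal_div"}, \code{"equal_lambda"} (speciation
#'   constrained), \code{"equal_mu"} (extinction constrained),
#'   \code{"hisse"} (hidden rate class).
#' @param n_restarts Number of jittered restarts after the heuristic start.
#' @param seed Seed for the restart jitter.
#' @param extra_starts Optional list of additional natural-scale starting
#'   parameter vectors (e.g. warm starts expanded from a nested fit).
#' @return Object of class \code{"sse_fit"}: \code{$par} (named,
#'   natural scale), \code{$model} (the fitted \code{"sse_model"}),
#'   \code{$lnL}, \code{$k}, \code{$AIC}, \code{$variant},
#'   \code{$convergence}, \code{$root_weights}.
#' @export
fit_sse <- function(tree, states, variant = "full", n_restarts = 8L,
                    seed = 1L, root = "fitzjohn", condition_surv = TRUE,
                    rtol = 1e-7, atol = 1e-9, extra_starts = list()) {
  specs <- sse_variants()
  if (!variant %in% names(specs)) stop("Unknown SSE variant: ", variant)
  spec <- specs[[variant]]
  ntip <- ape::Ntip(tree)
  T_height <- max(ape::node.depth.edgelength(tree))
  r0 <- max(log(ntip) / T_height, 1e-4)

  negll <- function(lp) {
    m <- tryCatch(spec$build(exp(lp)), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    ll <- tryCatch(sse_loglik(tree, states, m, root = root,
                              condition_surv = condition_surv,
                              rtol = rtol, atol = atol),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  start_for <- function(nm) {
    vapply(nm, function(s) {
      if (grepl("^lambda", s)) 1.5 * r0
      else if (grepl("^mu", s)) 0.5 * r0
      else if (s == "eta") 0.5 / T_height
      else 1 / T_height  # trait transition rates
    }, numeric(1))
  }
  lp0 <- log(start_for(spec$names))
  lower <- rep(log(1e-9), spec$npar)
  upper <- rep(log(10 * max(r0, 1)), spec$npar)

  if (!is.null(seed)) set.seed(seed)
  starts <- c(list(lp0),
              lapply(extra_starts, function(p) log(pmax(p, 1e-9))),
              lapply(seq_len(n_restarts), function(i)
                lp0 + stats::rnorm(spec$npar, sd = 1)))
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower + 0.5), upper - 0.5)
    op <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 500, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(op) || !is.finite(op$value) || op$value >= 1e10) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best))
    stop("SSE fit failed for variant '", variant,
         "' after all restarts")
  par <- stats::setNames(exp(best$par), spec$names)
  model <- spec$build(par)
  det <- sse_loglik(tree, states, model, root = root,
                    condition_surv = condition_surv,
                    rtol = rtol, atol = atol, details = TRUE)
  k <- spec$npar
  structure(list(par = par, model = model, lnL = det$lnL, k = k,
                 AIC = 2 * k - 2 * det$lnL, variant = variant,
                 convergence = best$convergence,
                 root_weights = det$root_weights,
                 root = root, condition_surv = condition_surv),
            class = "sse_fit")
}

#' @export
print.sse_fit <- function(x, ...) {
  cat("SSE fit, variant:", x$variant, "\n")
  cat("  lnL =", round(x$lnL, 3), " k =", x$k,
      " AIC =", round(x$AIC, 3), "\n")
  print(signif(x$par, 4))
  invisible(x)
}

#' Fit the constrained SSE model set and compare by AIC
#'
#' Fits the five constrained BiSSE variants plus the hidden-state variant
#' and tabulates AIC. The best model is the lowest-AIC fit, except that
#' among models within \code{delta_prefer} AIC units of the minimum the one
#' with fewest parameters is preferred (a more complex model must earn its
#' extra parameters).
#'
#' @inheritParams fit_sse
#' @param variants Variant names to fit.
#' @param delta_prefer AIC margin within which the simpler model wins.
#' @return List: \code{$best} (an \code{"sse_fit"}), \code{$aic_table},
#'   \code{$fits}, \code{$failed} (named error messages).
#' @export
model_set <- function(tree, states, variants = c("full", "equal_all",
                                                 "equal_div", "equal_lambda",
                                                 "equal_mu", "hisse"),
                      n_restarts = 8L, seed = 1L, delta_prefer = 2,
                      ...) {
  fits <- list(); failed <- character()
  for (v in variants) {
    f <- tryCatch(fit_sse(tree, states, v, n_restarts = n_restarts,
                          seed = seed, ...),
                  error = function(e) e)
    if (inherits(f, "error")) failed[v] <- conditionMessage(f)
    else fits[[v]] <- f
  }
  if (!length(fits)) stop("All SSE variant fits failed")
  # nesting repair: a model must fit at least as well as any model nested
  # within it; warm-start the wider model from the better nested optimum
  nested_in <- list(
    full = c("equal_all", "equal_div", "equal_lambda", "equal_mu"),
    equal_div = "equal_all", equal_lambda = "equal_all",
    equal_mu = "equal_all", hisse = c("full", "equal_all", "equal_div",
                                      "equal_lambda", "equal_mu"))
  for (wide in intersect(names(nested_in), names(fits))) {
    inner <- intersect(nested_in[[wide]], names(fits))
    if (!length(inner)) next
    lnl_inner <- vapply(fits[inner], `[[`, numeric(1), "lnL")
    if (max(lnl_inner) > fits[[wide]]$lnL + 1e-6) {
      warm <- lapply(fits[inner], function(f)
        expand_sse_par(f$variant, f$par, wide))
      refit <- tryCatch(
        fit_sse(tree, states, wide, n_restarts = 0L, seed = seed,
                extra_starts = warm, ...),
        error = function(e) NULL)
      if (!is.null(refit) && refit$lnL > fits[[wide]]$lnL)
        fits[[wide]] <- refit
    }
  }
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  tab <- data.frame(variant = names(fits),
                    lnL = vapply(fits, `[[`, numeric(1), "lnL"),
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    AIC = aic, dAIC = aic - min(aic), row.names = NULL)
  tab <- tab[order(tab$AIC), ]
  near <- tab[tab$dAIC <= delta_prefer, ]
  best_variant <- near$variant[which.min(near$k)]
  list(best = fits[[best_variant]], aic_table = tab, fits = fits,
       failed = failed)
}

#' Exact stochastic simulation of an SSE process
#'
#' Forward Gillespie simulation of lineages undergoing state-dependent
#' speciation, extinction and state change, from one root lineage to a
#' fixed age \code{T}. Extinct lineages are pruned; by default, runs
#' surviving with fewer than \code{min_tips} extant lineages are rejected
#' and redrawn (with the number of rejections recorded).
#'
#' @param model An \code{"sse_model"}.
#' @param root_state Model state (index 1..k) of the single root lineage.
#' @param T Simulation age, My.
#' @param seed Optional RNG seed.
#' @param max_tips Guard against runaway growth (error if exceeded).
#' @param min_tips Minimum surviving tips (default 2).
#' @param max_tries Redraw attempts before giving up.
#' @param reject Reject-and-redraw runs below \code{min_tips} (default
#'   \code{TRUE}); if \code{FALSE}, return whatever survived (possibly
#'   \code{tree = NULL} with \code{n_tips} < 2).
#' @return List: \code{tree} (\code{"phylo"} or \code{NULL}), \code{states}
#'   (named model-state indices 1..k), \code{obs_states} (named 0/1),
#'   \code{n_tips}, \code{n_rejected}.
#' @export
simulate_sse <- function(model, root_state = 1L, T, seed = NULL,
                         max_tips = 1e5, min_tips = 2L, max_tries = 1000L,
                         reject = TRUE) {
  if (!inherits(model, "sse_model")) stop("'model' must be an sse_model")
  if (T <= 0) stop("'T' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n_rejected <- 0L
  for (try in seq_len(max_tries)) {
    sim <- sse_gillespie(model, root_state, T, max_tips)
    if (!reject || sim$n_tips >= min_tips) {
      sim$n_rejected <- n_rejected
      return(sim)
    }
    n_rejected <- n_rejected + 1L
  }
  stop("simulate_sse: no run with >= ", min_tips, " surviving tips in ",
       max_tries, " attempts")
}

sse_gillespie <- function(model, root_state, T, max_tips) {
  k <- model$k
  lambda <- model$lambda; mu <- model$mu
  Qoff <- model$Q; diag(Qoff) <- 0
  qrow <- rowSums(Qoff)
  per_state_rate <- lambda + mu + qrow

  # lineage bookkeeping
  cap <- 256L
  parent <- integer(cap); t_start <- numeric(cap); t_end <- numeric(cap)
  state <- integer(cap); child1 <- integer(cap); child2 <- integer(cap)
  dead <- logical(cap)
  M <- 1L
  parent[1] <- 0L; t_start[1] <- 0; state[1] <- root_state
  alive <- 1L
  grow <- function() {
    cap2 <- cap * 2L
    length(parent) <<- cap2; length(t_start) <<- cap2
    length(t_end) <<- cap2; length(state) <<- cap2
    length(child1) <<- cap2; length(child2) <<- cap2
    length(dead) <<- cap2
    child1[(cap + 1L):cap2] <<- 0L; child2[(cap + 1L):cap2] <<- 0L
    dead[(cap + 1L):cap2] <<- FALSE
    cap <<- cap2
  }
  child1[1] <- 0L; child2[1] <- 0L; dead[1] <- FALSE
  now <- 0
  repeat {
    if (length(alive) == 0L) break
    if (length(alive) > max_tips)
      stop("simulate_sse: tip cap (", max_tips,
           ") exceeded; use a smaller T or slower rates")
    rates <- per_state_rate[state[alive]]
    tot <- sum(rates)
    if (tot <= 0) break
    now <- now + stats::rexp(1L, tot)
    if (now >= T) break
    i <- alive[sample.int(length(alive), 1L, prob = rates)]
    s <- state[i]
    ev <- sample.int(3L, 1L,
                     prob = c(lambda[s], mu[s], qrow[s]) / per_state_rate[s])
    if (ev == 1L) {          # speciation
      while (M + 2L > cap) grow()
      for (cc in 1:2) {
        M <- M + 1L
        parent[M] <- i; t_start[M] <- now; state[M] <- s
      }
      child1[i] <- M - 1L; child2[i] <- M
      t_end[i] <- now
      alive <- c(setdiff(alive, i), M - 1L, M)
    } else if (ev == 2L) {   # extinction
      t_end[i] <- now; dead[i] <- TRUE
      alive <- setdiff(alive, i)
    } else {                 # state change
      state[i] <- sample.int(k, 1L, prob = Qoff[s, ])
    }
  }
  t_end[alive] <- T
  leaves <- which(seq_len(M) <= M & child1[seq_len(M)] == 0L)
  survivors <- setdiff(leaves, which(dead[seq_len(M)]))
  if (length(survivors) < 2L)
    return(list(tree = NULL,
                states = stats::setNames(state[survivors],
                                         sprintf("t%d", survivors)),
                obs_states = stats::setNames(
                  model$obs_states[state[survivors]],
                  sprintf("t%d", survivors)),
                n_tips = length(survivors)))

  # assemble Newick over all lineages, then prune extinct tips
  blen <- t_end[seq_len(M)] - t_start[seq_len(M)]
  newick_of <- function(i) {
    if (child1[i] == 0L) paste0("t", i, ":", format(blen[i], digits = 17))
    else paste0("(", newick_of(child1[i]), ",", newick_of(child2[i]),
                "):", format(blen[i], digits = 17))
  }
  txt <- paste0(newick_of(1L), ";")
  tr <- ape::read.tree(text = txt)
  extinct <- setdiff(leaves, survivors)
  if (length(extinct))
    tr <- ape::drop.tip(tr, paste0("t", extinct), collapse.singles = TRUE)
  # the root lineage's stem edge may remain as a root edge; drop it
  tr$root.edge <- NULL
  st <- stats::setNames(state[survivors], paste0("t", survivors))
  st <- st[tr$tip.label]
  list(tree = tr, states = st,
       obs_states = stats::setNames(model$obs_states[st], names(st)),
       n_tips = length(survivors))
}

#' Simulation-based adequacy check of a fitted SSE model
#'
#' Simulates trees plus traits to the empirical tree's age under the fitted
#' model (root state drawn from the fit's root-state weights) and compares
#' the observed proportion of venomous tips and the per-state tip counts
#' with their simulated distributions.
#'
#' @param fit An \code{"sse_fit"}.
#' @param tree,states The empirical data the model was fitted to.
#' @param n_sims Number of simulations (default 1000).
#' @param seed RNG seed.
#' @param max_tips Per-simulation tip cap.
#' @return Object of class \code{"sse_adequacy"}: \code{$sims} (one row per
#'   simulation: n_tips, n_state0, n_state1, prop1), \code{$observed},
#'   \code{$quantiles} (position of each observed value in its simulated
#'   distribution), \code{$n_sims}.
#' @export
adequacy_check <- function(fit, tree, states, n_sims = 1000L, seed = 1L,
                           max_tips = 1e5) {
  if (!inherits(fit, "sse_fit")) stop("'fit' must be an sse_fit")
  T_height <- max(ape::node.depth.edgelength(tree))
  if (!is.null(seed)) set.seed(seed)
  k <- fit$model$k
  rows <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    rs <- sample.int(k, 1L, prob = fit$root_weights)
    sim <- simulate_sse(fit$model, root_state = rs, T = T_height,
                        seed = NULL, max_tips = max_tips)
    obs <- sim$obs_states
    rows[[i]] <- data.frame(n_tips = sim$n_tips,
                            n_state0 = sum(obs == 0),
                            n_state1 = sum(obs == 1),
                            prop1 = mean(obs == 1))
  }
  sims <- do.call(rbind, rows)
  st <- states[tree$tip.label]
  observed <- c(n_tips = ape::Ntip(tree), n_state0 = sum(st == 0),
                n_state1 = sum(st == 1), prop1 = mean(st == 1))
  quantiles <- vapply(names(observed), function(v)
    mean(sims[[v]] <= observed[[v]]), numeric(1))
  structure(list(sims = sims, observed = observed, quantiles = quantiles,
                 n_sims = n_sims), class = "sse_adequacy")
}

#' @export
print.sse_adequacy <- function(x, ...) {
  cat("SSE adequacy check over", x$n_sims, "simulations\n")
  for (v in names(x$observed)) {
    qs <- stats::quantile(x$sims[[v]], c(0.025, 0.975))
    cat(sprintf("  %-9s observed %.3f, sim 95%% envelope [%.3f, %.3f], quantile %.3f\n",
                v, x$observed[[v]], qs[1], qs[2], x$quantiles[[v]]))
  }
  invisible(x)
}
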