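#' @name ancstate
#' @title Binary-trait Markov fitting and stochastic character mapping
#' @description Maximum-likelihood fitting of a 2-state all-rates-different
#'   (ARD) continuous-time Markov model of trait gain and loss, and
#'   stochastic mapping of complete character histories conditioned on the
#'   tip data, used to count trait origins/losses, locate gains on
#'   branches, and measure the fraction of evolutionary time spent in the
#'   trait-bearing state.
NULL

# 2-state transition probability matrix over time t for gain rate a (0->1)
# and loss rate b (1->0); closed form, s = a + b.
mk2_pmat <- function(t, a, b) {
  s <- a + b
  if (s == 0) return(diag(2))
  e <- exp(-s * t)
  matrix(c(b + a * e, a - a * e,
           b - b * e, a + b * e) / s, 2, 2, byrow = TRUE)
}

# Pruning-algorithm log-likelihood of binary tip states; root at the chain's
# stationary distribution by default. Returns conditional likelihoods per
# node when details = TRUE (used by the mapping sampler).
mk2_loglik <- function(tree, st, a, b, root = c("stationary", "equal"),
                       details = FALSE) {
  root <- match.arg(root)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  L <- matrix(NA_real_, 2, ntip + nnode)
  L[1, seq_len(ntip)] <- as.numeric(st == 0)
  L[2, seq_len(ntip)] <- as.numeric(st == 1)
  logcomp <- 0
  edge <- tree$edge; el <- tree$edge.length
  po <- ape::postorder(tree)
  upL <- matrix(NA_real_, 2, ntip + nnode)
  kids <- split(edge[, 2L], edge[, 1L])
  combine <- function(v) {
    Lv <- rep(1, 2)
    for (j in kids[[as.character(v)]]) Lv <- Lv * upL[, j]
    s <- sum(Lv)
    if (s <= 0 || !is.finite(s)) return(FALSE)
    logcomp <<- logcomp + log(s)
    L[, v] <<- Lv / s
    TRUE
  }
  for (e in po) {
    ch <- edge[e, 2L]
    if (ch > ntip && !combine(ch)) return(if (details) NULL else -Inf)
    upL[, ch] <- mk2_pmat(el[e], a, b) %*% L[, ch]
  }
  if (!combine(ntip + 1L)) return(if (details) NULL else -Inf)
  pi <- if (root == "stationary" && a + b > 0) c(b, a) / (a + b)
        else c(0.5, 0.5)
  lik <- sum(pi * L[, ntip + 1L])
  lnL <- log(lik) + logcomp
  if (!details) return(lnL)
  list(lnL = lnL, L = L, upL = upL, pi = pi, kids = kids)
}

#' Fit a 2-state all-rates-different Markov model of trait evolution
#'
#' Maximum-likelihood estimation of the gain rate (0 to 1) and loss rate
#' (1 to 0) of a binary trait on an ultrametric tree, by the pruning
#' algorithm with closed-form 2x2 transition probabilities. The root is
#' placed at the stationary distribution of the fitted chain by default.
#'
#' @param tree Ultrametric \code{"phylo"} object.
#' @param states Named binary (0/1) vector over the tips.
#' @param root \code{"stationary"} (default) or \code{"equal"} root prior.
#' @param n_restarts Jittered optimizer restarts.
#' @param seed Seed for the restart jitter.
#' @return Object of class \code{"mk_fit"}: \code{$q_gain}, \code{$q_loss}
#'   (per My), \code{$lnL}, \code{$root_dist}, \code{$root}.
#' @export
fit_mk_ard <- function(tree, states, root = "stationary",
                       n_restarts = 5L, seed = 1L) {
  validate_tree(tree)
  tips <- tree$tip.label
  if (is.null(names(states)) || !all(tips %in% names(states)))
    stop("'states' must be named and cover every tip")
  st <- as.integer(states[tips])
  if (!all(st %in% c(0L, 1L))) stop("States must be binary 0/1")
  if (length(unique(st)) == 1L)
    warning("All tips share one state; the ",
            if (st[1] == 0) "gain" else "loss",
            " rate is estimated at its boundary")
  T_height <- max(ape::node.depth.edgelength(tree))
  negll <- function(lp) {
    ll <- mk2_loglik(tree, st, exp(lp[1]), exp(lp[2]), root = root)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  lp0 <- log(c(max(mean(st == 1), 0.01), max(mean(st == 0), 0.01)) /
               T_height * 2)
  if (!is.null(seed)) set.seed(seed)
  starts <- c(list(lp0), lapply(seq_len(n_restarts), function(i)
    lp0 + stats::rnorm(2, sd = 1)))
  lower <- rep(log(1e-9), 2); upper <- rep(log(1e3 / T_height), 2)
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower + 0.5), upper - 0.5)
    op <- tryCatch(stats::optim(s, negll, method = "L-BFGS-B",
                                lower = lower, upper = upper),
                   error = function(e) NULL)
    if (is.null(op) || !is.finite(op$value)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("Mk ARD fit failed")
  a <- exp(best$par[1]); b <- exp(best$par[2])
  pi <- if (root == "stationary" && a + b > 0) c(b, a) / (a + b)
        else c(0.5, 0.5)
  structure(list(q_gain = a, q_loss = b, lnL = -best$value,
                 root_dist = pi, root = root),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("2-state ARD Markov fit\n")
  cat(sprintf("  q_gain = %.6g  q_loss = %.6g (per My)  lnL = %.3f\n",
              x$q_gain, x$q_loss, x$lnL))
  cat(sprintf("  root (%s): P(0) = %.3f, P(1) = %.3f\n",
              x$root, x$root_dist[1], x$root_dist[2]))
  invisible(x)
}

# Sample a complete endpoint-conditioned 2-state path on one branch by
# uniformization; returns transition times and new states (possibly none).
sample_branch_path <- function(t, s_from, s_to, a, b) {
  Q <- matrix(c(-a, a, b, -b), 2, 2, byrow = TRUE)
  omega <- max(a, b) * 1.05 + 1e-12
  R <- diag(2) + Q / omega
  P <- mk2_pmat(t, a, b)
  p_ab <- P[s_from + 1L, s_to + 1L]
  if (p_ab <= 0) stop("Endpoint conditioning impossible on branch")
  # number of uniformized jumps: P(N = n | endpoints) by inversion sampling
  u <- stats::runif(1) * p_ab
  n <- -1L
  acc <- 0
  Rn <- diag(2)   # R^n
  lp_pois <- -omega * t  # log Pois(0)
  repeat {
    n <- n + 1L
    if (n > 0) {
      Rn <- Rn %*% R
      lp_pois <- lp_pois + log(omega * t) - log(n)
    }
    acc <- acc + exp(lp_pois) * Rn[s_from + 1L, s_to + 1L]
    if (acc >= u || n > 10000L) break
  }
  if (n == 0L) return(NULL)
  # jump states via backward products of R
  Rpow <- vector("list", n + 1L)
  Rpow[[1L]] <- diag(2)
  for (m in seq_len(n)) Rpow[[m + 1L]] <- Rpow[[m]] %*% R
  s <- s_from
  path_states <- integer(n)
  for (m in seq_len(n)) {
    w <- R[s + 1L, ] * Rpow[[n - m + 1L]][, s_to + 1L]
    s <- sample.int(2L, 1L, prob = w) - 1L
    path_states[m] <- s
  }
  times <- sort(stats::runif(n, 0, t))
  keep <- logical(n)
  cur <- s_from
  for (m in seq_len(n)) {
    if (path_states[m] != cur) { keep[m] <- TRUE; cur <- path_states[m] }
  }
  if (!any(keep)) return(NULL)
  data.frame(time = times[keep], to = path_states[keep])
}

#' Stochastic character maps of a binary trait
#'
#' Draws complete character histories consistent with the tip data and the
#' fitted gain/loss rates. Node states are sampled from their joint
#' conditional distribution (pruning up-pass, then root-to-tip sampling);
#' each branch's history is then sampled conditioned on its endpoint states
#' by uniformization (exact, robust on long branches with low rates). Each
#' map records every transition's branch and time, the per-map gain and
#' loss counts, and the fraction of total tree length spent in state 1.
#'
#' @param tree Ultrametric \code{"phylo"} object.
#' @param states Named binary (0/1) tip states.
#' @param fit An \code{"mk_fit"} from \code{\link{fit_mk_ard}}.
#' @param n_maps Number of maps (default 1000).
#' @param seed RNG seed.
#' @return Object of class \code{"map_set"}: \code{$gains}, \code{$losses}
#'   (per-map counts), \code{$frac1} (per-map state-1 time fraction),
#'   \code{$edge_gain}, \code{$edge_loss} (per-edge counts of maps with at
#'   least one such event), \code{$events} (list of per-map transition
#'   tables), \code{$tree}, \code{$n_maps}.
#' @export
stochastic_maps <- function(tree, states, fit, n_maps = 1000L, seed = 1L) {
  if (!inherits(fit, "mk_fit")) stop("'fit' must be an mk_fit")
  tips <- tree$tip.label
  st <- as.integer(states[tips])
  a <- fit$q_gain; b <- fit$q_loss
  det <- mk2_loglik(tree, st, a, b, root = fit$root, details = TRUE)
  if (is.null(det)) stop("Tip data impossible under the fitted rates")
  ntip <- ape::Ntip(tree)
  edge <- tree$edge; el <- tree$edge.length
  nedge <- nrow(edge)
  total_len <- sum(el)
  preorder_edges <- rev(ape::postorder(tree))

  if (!is.null(seed)) set.seed(seed)
  gains <- integer(n_maps); losses <- integer(n_maps)
  frac1 <- numeric(n_maps)
  edge_gain <- integer(nedge); edge_loss <- integer(nedge)
  events <- vector("list", n_maps)

  for (m in seq_len(n_maps)) {
    node_state <- integer(ntip + tree$Nnode)
    node_state[seq_len(ntip)] <- st
    wroot <- det$pi * det$L[, ntip + 1L]
    node_state[ntip + 1L] <- sample.int(2L, 1L, prob = wroot) - 1L
    # sample internal node states root-to-tip, conditioned on parent state
    for (e in preorder_edges) {
      ch <- edge[e, 2L]
      if (ch <= ntip) next
      pa <- edge[e, 1L]
      P <- mk2_pmat(el[e], a, b)
      w <- P[node_state[pa] + 1L, ] * det$L[, ch]
      node_state[ch] <- sample.int(2L, 1L, prob = w) - 1L
    }
    g <- 0L; l <- 0L; time1 <- 0
    evs <- list()
    for (e in seq_len(nedge)) {
      pa <- edge[e, 1L]; ch <- edge[e, 2L]
      s0 <- node_state[pa]; s1 <- node_state[ch]
      path <- sample_branch_path(el[e], s0, s1, a, b)
      if (is.null(path)) {
        if (s1 == 1) time1 <- time1 + el[e]
      } else {
        tprev <- 0; cur <- s0
        for (r in seq_len(nrow(path))) {
          if (cur == 1) time1 <- time1 + path$time[r] - tprev
          if (path$to[r] == 1L) g <- g + 1L else l <- l + 1L
          tprev <- path$time[r]; cur <- path$to[r]
        }
        if (cur == 1) time1 <- time1 + el[e] - tprev
        if (any(path$to == 1L)) edge_gain[e] <- edge_gain[e] + 1L
        if (any(path$to == 0L)) edge_loss[e] <- edge_loss[e] + 1L
        evs[[length(evs) + 1L]] <-
          cbind(edge = e, time = path$time, to = path$to)
      }
    }
    gains[m] <- g; losses[m] <- l
    frac1[m] <- time1 / total_len
    events[[m]] <- if (length(evs)) do.call(rbind, evs)
                   else matrix(numeric(0), 0, 3,
                               dimnames = list(NULL, c("edge", "time", "to")))
  }
  structure(list(gains = gains, losses = losses, frac1 = frac1,
                 edge_gain = edge_gain, edge_loss = edge_loss,
                 events = events, tree = tree, n_maps = n_maps,
                 fit = fit),
            class = "map_set")
}

#' Summarize a collection of stochastic maps
#'
#' @param maps A \code{"map_set"} from \code{\link{stochastic_maps}}.
#' @param threshold Per-branch gain probability above which a gain is
#'   called "strongly supported" on that branch (default 0.2).
#' @return Object of class \code{"map_summary"}: \code{$gain_prob},
#'   \code{$loss_prob} (per edge), \code{$gains}, \code{$losses} (each a
#'   list with median, mode, range, central 95\%), \code{$min_gains},
#'   \code{$supported_edges} (edges with gain probability >= threshold),
#'   \code{$frac1_mean} (mean fraction of tree length in state 1),
#'   \code{$threshold}.
#' @export
summarize_maps <- function(maps, threshold = 0.2) {
  if (!inherits(maps, "map_set")) stop("'maps' must be a map_set")
  summarize_count <- function(x) {
    tab <- table(x)
    list(median = stats::median(x),
         mode = as.integer(names(tab)[which.max(tab)]),
         range = range(x),
         q95 = unname(stats::quantile(x, c(0.025, 0.975))))
  }
  gain_prob <- maps$edge_gain / maps$n_maps
  loss_prob <- maps$edge_loss / maps$n_maps
  structure(list(gain_prob = gain_prob, loss_prob = loss_prob,
                 gains = summarize_count(maps$gains),
                 losses = summarize_count(maps$losses),
                 min_gains = min(maps$gains),
                 supported_edges = which(gain_prob >= threshold),
                 frac1_mean = mean(maps$frac1),
                 threshold = threshold, n_maps = maps$n_maps),
            class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat("Stochastic mapping summary (", x$n_maps, " maps)\n", sep = "")
  cat(sprintf("  gains:  median %s, mode %d, range [%d, %d]\n",
              format(x$gains$median), x$gains$mode,
              x$gains$range[1], x$gains$range[2]))
  cat(sprintf("  losses: median %s, mode %d, range [%d, %d]\n",
              format(x$losses$median), x$losses$mode,
              x$losses$range[1], x$losses$range[2]))
  cat(sprintf("  %d branch(es) with gain probability >= %.2f\n",
              length(x$supported_edges), x$threshold))
  cat(sprintf("  mean fraction of tree length in state 1: %.4f\n",
              x$frac1_mean))
  invisible(x)
}
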