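#' Find sister-clade pairs differing in a binary trait
#'
#' Locates the maximal clades whose tips are uniformly in state 1
#' (venomous), and pairs each with its sister clade when the sister's tips
#' are uniformly state 0. Pairs whose sister mixes states are skipped (with
#' a message). For each pair the total species richness is summed over the
#' families in each clade, and the pair's age is the age of the common
#' parent node (the time at which both daughters originated).
#'
#' @param tree An ultrametric \code{"phylo"} object.
#' @param states Named binary vector (0/1) over all tip labels.
#' @param richness Named species-richness vector over all tip labels; if
#'   \code{NULL}, each tip counts 1.
#' @return \code{data.frame}, one row per pair: \code{clade1_tips},
#'   \code{clade0_tips} (comma-joined labels), \code{n1}, \code{n0} (summed
#'   richness), \code{age} (My).
#' @export
find_sister_pairs <- function(tree, states, richness = NULL) {
  validate_tree(tree)
  ntip <- ape::Ntip(tree)
  tips <- tree$tip.label
  if (is.null(names(states)) || !all(tips %in% names(states)))
    stop("'states' must be named and cover every tip")
  st <- states[tips]
  if (!all(st %in% c(0, 1))) stop("States must be binary 0/1")
  if (is.null(richness)) richness <- stats::setNames(rep(1, ntip), tips)
  if (!all(tips %in% names(richness)))
    stop("'richness' must be named and cover every tip")
  rich <- richness[tips]

  if (!any(st == 1)) {
    warning("No tips in state 1; no sister pairs")
    return(data.frame(clade1_tips = character(), clade0_tips = character(),
                      n1 = numeric(), n0 = numeric(), age = numeric()))
  }

  nnode <- tree$Nnode
  root <- ntip + 1L
  # children lists and postorder uniform-state flags per node
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  # uniform[v]: 0 / 1 if the clade at v is uniformly in that state, NA mixed
  uniform <- rep(NA_real_, ntip + nnode)
  uniform[seq_len(ntip)] <- st
  ord <- unique(tree$edge[ape::postorder(tree), 1L]) # parents, bottom-up
  for (v in ord) {
    u <- uniform[kids[[as.character(v)]]]
    uniform[v] <- if (anyNA(u) || length(unique(u)) > 1L) NA_real_ else u[1L]
  }
  parent_of <- integer(ntip + nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  ages <- node_ages(tree)

  clade_tips <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(kids[[as.character(v)]], clade_tips))
  }

  # maximal uniform-1 clades: node uniform 1 whose parent is not uniform 1
  cand <- which(!is.na(uniform) & uniform == 1)
  cand <- cand[vapply(cand, function(v) {
    v == root || is.na(uniform[parent_of[v]]) || uniform[parent_of[v]] != 1
  }, logical(1))]

  rows <- list()
  skipped <- 0L
  for (v in cand) {
    if (v == root) next  # whole tree uniform: no sister exists
    p <- parent_of[v]
    sibs <- setdiff(kids[[as.character(p)]], v)
    sib_state <- uniform[sibs]
    if (anyNA(sib_state) || any(sib_state != 0)) {
      skipped <- skipped + 1L
      next
    }
    t1 <- clade_tips(v)
    t0 <- unlist(lapply(sibs, clade_tips))
    rows[[length(rows) + 1L]] <- data.frame(
      clade1_tips = paste(tips[t1], collapse = ","),
      clade0_tips = paste(tips[t0], collapse = ","),
      n1 = sum(rich[t1]), n0 = sum(rich[t0]),
      age = ages[p], stringsAsFactors = FALSE)
  }
  if (skipped)
    message(skipped, " candidate pair(s) skipped (mixed-state sister)")
  if (!length(rows)) {
    if (all(st == 0) || all(st == 1)) {
      warning("Trait is uniform across tips; no pairs")
      return(data.frame(clade1_tips = character(), clade0_tips = character(),
                        n1 = numeric(), n0 = numeric(), age = numeric()))
    }
    stop("No valid sister pairs found")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Yule clade-size log-likelihood
#'
#' Log-probability of observing \code{n} extant species in a clade of age
#' \code{t} that began as a single lineage under a pure-birth (Yule) process
#' with rate \code{lam}: the clade size is geometric,
#' \deqn{\log P(N = n \mid t, \lambda) = -\lambda t +
#'       (n - 1)\log(1 - e^{-\lambda t}).}
#'
#' @param n Clade species richness (integer >= 1); vectorized.
#' @param t Clade (stem) age, My (> 0); vectorized.
#' @param lam Yule speciation rate, per My (> 0).
#' @return Log-likelihood value(s).
#' @export
yule_richness_loglik <- function(n, t, lam) {
  if (anyNA(n) || any(n < 1) || any(n != round(n)))
    stop("'n' must be integer richness >= 1")
  if (anyNA(t) || any(t <= 0)) stop("'t' must be > 0")
  if (length(lam) != 1L || is.na(lam) || lam <= 0) stop("'lam' must be > 0")
  -lam * t + (n - 1) * log1p(-exp(-lam * t))
}

# ML of the Yule rate for a set of clades (n_i, t_i); 1-D search on log(lam)
yule_mle <- function(n, t) {
  f <- function(loglam) -sum(yule_richness_loglik(n, t, exp(loglam)))
  # bracket generously around the moment-style estimate
  lam0 <- max(sum(log(n)) / sum(t), 1e-8)
  op <- stats::optimize(f, lower = log(lam0) - 12, upper = log(lam0) + 8,
                        tol = 1e-10)
  list(lam = exp(op$minimum), logLik = -op$objective)
}

#' Richness Yule likelihood-ratio test for trait-dependent diversification
#'
#' Compares, across sister-clade pairs differing in the binary trait, the
#' null model in which one Yule rate generates the richness of every clade
#' against the alternative with separate rates for the venomous and the
#' non-venomous clades. Both clades of a pair share the pair's age. The
#' statistic is \eqn{\chi^2 = 2(\ln L_1 - \ln L_0)} on 1 degree of freedom.
#'
#' @param pairs Pair table from \code{\link{find_sister_pairs}} (columns
#'   \code{n1}, \code{n0}, \code{age}).
#' @return List: \code{chi2}, \code{df} (= 1), \code{p},
#'   \code{lambda_venom}, \code{lambda_nonvenom}, \code{lambda_common},
#'   \code{mean_ratio} (mean of per-pair \code{n1/n0}), \code{n_pairs}.
#' @export
richness_yule_test <- function(pairs) {
  if (!nrow(pairs)) stop("No sister pairs supplied")
  if (nrow(pairs) < 2L)
    warning("Fewer than 2 sister pairs; the test has little power")
  n1 <- pairs$n1; n0 <- pairs$n0; t <- pairs$age
  h1_v <- yule_mle(n1, t)
  h1_n <- yule_mle(n0, t)
  h0 <- yule_mle(c(n1, n0), c(t, t))
  chi2 <- max(0, 2 * (h1_v$logLik + h1_n$logLik - h0$logLik))
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       lambda_venom = h1_v$lam, lambda_nonvenom = h1_n$lam,
       lambda_common = h0$lam,
       mean_ratio = richness_ratio(pairs), n_pairs = nrow(pairs))
}

#' Mean richness ratio across sister pairs
#'
#' Arithmetic mean of the per-pair ratio of venomous-clade richness to its
#' sister's richness.
#'
#' @param pairs Pair table with columns \code{n1}, \code{n0}.
#' @return Mean of \code{n1/n0}.
#' @export
richness_ratio <- function(pairs) {
  if (!nrow(pairs)) stop("No sister pairs supplied")
  mean(pairs$n1 / pairs$n0)
}
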