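#' @name phyloreg
#' @title Phylogenetic regression under selectable trait-evolution models
#' @description Phylogenetic generalized least squares (PGLS) in which the
#'   residual covariance derives from the tree under one of several
#'   trait-evolution models, with the model's parameter estimated by maximum
#'   likelihood and candidate models compared by AIC.
NULL

.cov_kinds <- c("BM", "OU_random_root", "OU_fixed_root", "lambda", "kappa",
                "delta", "early_burst", "trend", "nonphylo_OLS")

# number of covariance-model parameters estimated per kind
.cov_npar <- c(BM = 0L, OU_random_root = 1L, OU_fixed_root = 1L, lambda = 1L,
               kappa = 1L, delta = 1L, early_burst = 1L, trend = 0L,
               nonphylo_OLS = 0L)

#' Phylogenetic residual covariance matrix under a trait-evolution model
#'
#' Builds the n x n expected residual covariance (up to the scalar rate
#' \eqn{\sigma^2}) among tips for a given model:
#' \itemize{
#'   \item \code{BM}: Brownian motion; \eqn{C_{ij}} = shared root-to-MRCA
#'     path length.
#'   \item \code{lambda}: Pagel's lambda; off-diagonals of the BM matrix
#'     multiplied by \eqn{\lambda \in [0,1]}.
#'   \item \code{kappa}: BM matrix recomputed from branch lengths each raised
#'     to \eqn{\kappa \ge 0} (punctuational as \eqn{\kappa \to 0}).
#'   \item \code{delta}: node depths raised to \eqn{\delta > 0}, rescaled to
#'     the original tree height.
#'   \item \code{early_burst}: exponentially time-varying rate \eqn{r \le 0};
#'     a branch segment from \eqn{t_1} to \eqn{t_2} (time from the root)
#'     contributes \eqn{(e^{r t_2} - e^{r t_1})/r}.
#'   \item \code{OU_random_root}: Ornstein-Uhlenbeck, stationary (random)
#'     root: \eqn{V_{ij} = e^{-\alpha d_{ij}} (1 - e^{-2\alpha T})/(2\alpha)}
#'     with \eqn{d_{ij}} the patristic distance and \eqn{T} the tree height.
#'   \item \code{OU_fixed_root}:
#'     \eqn{V_{ij} = e^{-\alpha d_{ij}} (1 - e^{-2\alpha t_{ij}})/(2\alpha)}
#'     with \eqn{t_{ij}} the depth (from the root) of the tips' MRCA.
#'   \item \code{trend}: BM covariance (the drift enters as a tip-height
#'     regressor in \code{\link{fit_pgls}}, and is degenerate on an
#'     ultrametric tree).
#'   \item \code{nonphylo_OLS}: identity (no phylogenetic structure).
#' }
#'
#' @param tree An ultrametric \code{"phylo"} object.
#' @param kind One of the model kinds above.
#' @param par The model's parameter value (ignored for \code{BM},
#'   \code{trend}, \code{nonphylo_OLS}).
#' @return Symmetric positive-semidefinite matrix with tip-label dimnames,
#'   rows/columns in tip order.
#' @export
phylo_covariance <- function(tree, kind = "BM", par = NULL) {
  kind <- match.arg(kind, .cov_kinds)
  C <- ape::vcv(tree)
  T_height <- max(diag(C))
  V <- switch(kind,
    BM = , trend = C,
    nonphylo_OLS = {
      I <- diag(nrow(C)); dimnames(I) <- dimnames(C); I
    },
    lambda = {
      lam <- check_par(par, "lambda", 0, 1)
      Vl <- C * lam
      diag(Vl) <- diag(C)
      Vl
    },
    kappa = {
      kap <- check_par(par, "kappa", 0, Inf)
      tk <- tree
      tk$edge.length <- tree$edge.length^kap
      ape::vcv(tk)
    },
    delta = {
      del <- check_par(par, "delta", 0, Inf, open_lower = TRUE)
      C^del * T_height^(1 - del)
    },
    early_burst = {
      r <- check_par(par, "early-burst rate", -Inf, 0)
      if (r == 0) C else (exp(r * C) - 1) / r
    },
    OU_random_root = {
      alpha <- check_par(par, "alpha", 0, Inf, open_lower = TRUE)
      d <- 2 * (T_height - C)
      exp(-alpha * d) * (1 - exp(-2 * alpha * T_height)) / (2 * alpha)
    },
    OU_fixed_root = {
      alpha <- check_par(par, "alpha", 0, Inf, open_lower = TRUE)
      d <- 2 * (T_height - C)
      exp(-alpha * d) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
    }
  )
  V
}

check_par <- function(par, name, lo, hi, open_lower = FALSE) {
  if (is.null(par) || length(par) != 1L || is.na(par))
    stop("Model parameter '", name, "' must be a single number")
  if (par < lo || par > hi || (open_lower && par <= lo))
    stop("'", name, "' = ", par, " outside admissible range")
  par
}

# Profile log-likelihood machinery: for a fixed covariance matrix V, the ML
# estimates of beta and sigma^2 are closed-form (GLS); returns the profiled
# multivariate-normal log-likelihood and the GLS pieces.
gls_profile <- function(y, X, V) {
  n <- length(y)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Xs <- backsolve(R, X, transpose = TRUE)
  ys <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X)) stop("Singular design matrix")
  beta <- solve(qrX, crossprod(Xs, ys))
  resid <- ys - Xs %*% beta
  rss <- sum(resid^2)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(R)))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdetV + n)
  list(beta = drop(beta), sigma2 = sigma2, logLik = ll,
       XtX_inv = solve(qrX, diag(ncol(X))))
}

cov_par_bounds <- function(kind, T_height) {
  switch(kind,
    lambda = c(0, 1),
    kappa = c(0, 3),
    delta = c(1e-8, 3),
    early_burst = c(-10 / T_height, 0),
    OU_random_root = , OU_fixed_root = c(1e-8 / T_height, 50 / T_height),
    NULL)
}

#' Fit a phylogenetic regression by maximum likelihood
#'
#' Maximizes the multivariate-normal log-likelihood of the response given
#' the design, jointly over the regression coefficients, the rate
#' \eqn{\sigma^2}, and (where the model has one) the covariance-model
#' parameter. Coefficients and \eqn{\sigma^2} are profiled out in closed
#' form; the single covariance parameter is optimized on its admissible
#' interval by a deterministic coarse grid scan followed by golden-section
#' refinement. Standard errors derive from
#' \eqn{\hat\sigma^2 (X^\top V^{-1} X)^{-1}}; p values are two-sided from
#' the t distribution on \eqn{n - p} degrees of freedom.
#'
#' For \code{kind = "trend"}, tip heights are appended to the design as an
#' auxiliary regressor; on an ultrametric tree they are constant, so the
#' column is dropped and the fit reduces to BM (recorded in
#' \code{$trend_degenerate}).
#'
#' @param y Numeric response vector, ordered as the tree's tips.
#' @param X Design matrix (include the intercept column explicitly), rows
#'   ordered as the tree's tips.
#' @param tree An ultrametric \code{"phylo"} object.
#' @param kind Covariance-model kind; see \code{\link{phylo_covariance}}.
#' @param n_grid Grid points for the covariance-parameter scan.
#' @return Object of class \code{"pgls_fit"}: coefficient table
#'   (\code{$coefficients} with Coefficient, SE, t, P), \code{$sigma2},
#'   \code{$cov_par} (named; \code{NA} where the model has none),
#'   \code{$logLik}, \code{$AIC} (with \eqn{k} counting coefficients +
#'   \eqn{\sigma^2} + covariance parameters), \code{$model}, \code{$n}.
#'   For OU kinds, \code{$half_life} = \eqn{\ln 2 / \alpha}.
#' @export
fit_pgls <- function(y, X, tree, kind = "BM", n_grid = 25L) {
  kind <- match.arg(kind, .cov_kinds)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)) - 1L)
  n <- length(y)
  if (nrow(X) != n || n != ape::Ntip(tree))
    stop("y, X and tree tip count must agree")
  if (anyNA(y) || anyNA(X)) stop("Missing values in y or X")

  trend_degenerate <- FALSE
  if (kind == "trend") {
    h <- ape::node.depth.edgelength(tree)[seq_len(n)]
    if (stats::sd(h) > 1e-8 * max(h)) {
      X <- cbind(X, tip_height = h)
    } else trend_degenerate <- TRUE
  }

  T_height <- max(ape::node.depth.edgelength(tree))
  bounds <- cov_par_bounds(kind, T_height)

  if (is.null(bounds)) {
    V <- phylo_covariance(tree, kind)
    prof <- gls_profile(y, X, V)
    if (is.null(prof)) stop("Covariance matrix not positive definite")
    par_hat <- NA_real_
  } else {
    obj <- function(p) {
      prof <- tryCatch(gls_profile(y, X, phylo_covariance(tree, kind, p)),
                       error = function(e) NULL)
      if (is.null(prof) || !is.finite(prof$logLik)) return(1e10)
      -prof$logLik
    }
    grid <- seq(bounds[1], bounds[2], length.out = n_grid)
    vals <- vapply(grid, obj, numeric(1))
    if (all(vals >= 1e10))
      stop("Covariance-parameter optimization failed for model '", kind, "'")
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(n_grid, i + 1L)]
    op <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-10)
    # keep the better of the grid minimum and the refined point
    par_hat <- if (op$objective <= vals[i]) op$minimum else grid[i]
    prof <- gls_profile(y, X, phylo_covariance(tree, kind, par_hat))
  }

  p <- ncol(X)
  # SEs on the unbiased scale (n/(n-p) times the ML sigma2), so a star tree
  # reproduces OLS t statistics exactly
  se <- sqrt(prof$sigma2 * n / (n - p) * diag(prof$XtX_inv))
  tval <- prof$beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  coefs <- data.frame(Coefficient = prof$beta, SE = se, t = tval, P = pval,
                      row.names = colnames(X))
  k <- p + 1L + .cov_npar[[kind]]
  par_name <- switch(kind, lambda = "lambda", kappa = "kappa",
                     delta = "delta", early_burst = "r",
                     OU_random_root = "alpha", OU_fixed_root = "alpha", NA)
  out <- list(coefficients = coefs, sigma2 = prof$sigma2,
              cov_par = stats::setNames(par_hat, par_name),
              logLik = prof$logLik, k = k, AIC = 2 * k - 2 * prof$logLik,
              model = kind, n = n, df_residual = n - p,
              trend_degenerate = trend_degenerate)
  if (kind %in% c("OU_random_root", "OU_fixed_root"))
    out$half_life <- log(2) / par_hat
  class(out) <- "pgls_fit"
  out
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic regression (ML), covariance model:", x$model, "\n")
  if (!is.na(x$cov_par))
    cat("  ", names(x$cov_par), "=", signif(x$cov_par, 4),
        if (!is.null(x$half_life))
          paste0("(phylogenetic half-life ", signif(x$half_life, 4), " My)"),
        "\n")
  cat("  sigma^2 =", signif(x$sigma2, 4),
      " logLik =", round(x$logLik, 3), " AIC =", round(x$AIC, 3),
      " n =", x$n, "\n")
  if (isTRUE(x$trend_degenerate))
    cat("  note: trend regressor degenerate on an ultrametric tree (= BM)\n")
  print(signif(as.matrix(x$coefficients), 5))
  invisible(x)
}

#' Fit candidate covariance models and select by AIC
#'
#' Fits the regression under each candidate trait-evolution model and
#' returns the minimum-AIC fit. Among fits whose AICs are numerically
#' identical (within \code{tie_tol}), the random-root OU model is preferred,
#' then the model with fewer parameters.
#'
#' @inheritParams fit_pgls
#' @param candidates Character vector of covariance kinds (>= 2, unless a
#'   single model is deliberately requested).
#' @param tie_tol AIC difference treated as a tie.
#' @return List with \code{$best} (a \code{"pgls_fit"}), \code{$aic_table}
#'   (kind, logLik, k, AIC, dAIC, converged), \code{$fits} (all successful
#'   fits, named by kind).
#' @export
select_model <- function(y, X, tree, candidates = .cov_kinds,
                         tie_tol = 1e-6) {
  candidates <- match.arg(candidates, .cov_kinds, several.ok = TRUE)
  fits <- list()
  errs <- character()
  for (kind in candidates) {
    f <- tryCatch(fit_pgls(y, X, tree, kind), error = function(e) e)
    if (inherits(f, "error")) errs[kind] <- conditionMessage(f)
    else fits[[kind]] <- f
  }
  if (!length(fits))
    stop("All candidate model fits failed: ",
         paste(names(errs), unname(errs), sep = ": ", collapse = "; "))
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  tab <- data.frame(kind = names(fits),
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    AIC = aic, dAIC = aic - min(aic),
                    row.names = NULL)
  tab <- tab[order(tab$AIC), ]
  tied <- tab$kind[tab$AIC - min(tab$AIC) <= tie_tol]
  best_kind <- if ("OU_random_root" %in% tied) "OU_random_root"
               else tied[which.min(tab$k[match(tied, tab$kind)])]
  list(best = fits[[best_kind]], aic_table = tab, fits = fits,
       failed = errs)
}

#' Species-richness regression: log richness on rate, age and venom
#'
#' Models log(species richness) as a function of net diversification rate,
#' stem age (with a quadratic term for non-linear age effects) and venom
#' state, selecting the residual covariance model by AIC.
#'
#' @param families Aligned family table with \code{stem_age} (see
#'   \code{\link{align_family_data}}).
#' @param rates Rate table from \code{\link{rate_table}}.
#' @param tree The aligned ultrametric tree.
#' @param epsilon Which relative extinction fraction's rates to use.
#' @param candidates Covariance kinds to compare.
#' @param log10 Model \code{log10(richness)} instead of natural log.
#' @return As \code{\link{select_model}}.
#' @export
richness_model <- function(families, rates, tree, epsilon = 0.5,
                           candidates = .cov_kinds, log10 = FALSE) {
  d <- assemble_regression_data(families, rates, tree, epsilon)
  y <- if (log10) log(d$richness, base = 10) else log(d$richness)
  X <- cbind(Intercept = 1, Venom = d$venomous, Rate = d$rate,
             Age = d$stem_age, Age2 = d$stem_age^2)
  select_model(y, X, tree, candidates)
}

#' Diversification-rate regression: rate on venom and age
#'
#' Models the per-family net diversification rate as a function of venom
#' state and stem age (with a quadratic term), selecting the residual
#' covariance model by AIC.
#'
#' @inheritParams richness_model
#' @return As \code{\link{select_model}}.
#' @export
divrate_model <- function(families, rates, tree, epsilon = 0.5,
                          candidates = .cov_kinds) {
  d <- assemble_regression_data(families, rates, tree, epsilon)
  X <- cbind(Intercept = 1, Venom = d$venomous,
             Age = d$stem_age, Age2 = d$stem_age^2)
  select_model(d$rate, X, tree, candidates)
}

assemble_regression_data <- function(families, rates, tree, epsilon) {
  r <- rates[abs(rates$epsilon - epsilon) < 1e-12, , drop = FALSE]
  if (!nrow(r)) stop("No rates at epsilon = ", epsilon)
  d <- families
  d$rate <- r$rate[match(canonical_name(d$family), canonical_name(r$family))]
  if (anyNA(d$rate))
    stop("Rates missing for: ",
         paste(d$family[is.na(d$rate)], collapse = ", "))
  d <- d[match(canonical_name(tree$tip.label), canonical_name(d$family)), ,
         drop = FALSE]
  if (anyNA(d$family)) stop("Family table does not cover all tree tips")
  d
}
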