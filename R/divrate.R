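#' Stem-age method-of-moments net diversification rate
#'
#' Closed-form estimator of a clade's net diversification rate (speciation
#' minus extinction, per My) from its extant species richness \code{n} and
#' stem age \code{t}, given an assumed relative extinction fraction
#' \code{eps} (extinction/speciation):
#' \deqn{\hat r = \frac{1}{t}\,\log\big(n(1-\epsilon) + \epsilon\big).}
#' A monotypic clade (\code{n = 1}) has rate exactly 0 for all \code{eps}.
#'
#' @param n Species richness (integer >= 1); vectorized.
#' @param t Stem age in My (> 0); vectorized.
#' @param eps Relative extinction fraction in [0, 1).
#' @param log10 Use base-10 logarithm instead of the natural logarithm
#'   (default \code{FALSE}; the estimator's standard form is natural-log).
#' @return Net diversification rate(s), per My.
#' @export
mom_stem_rate <- function(n, t, eps = 0.5, log10 = FALSE) {
  if (length(eps) != 1L || is.na(eps) || eps < 0 || eps >= 1)
    stop("'eps' must be a single value in [0, 1)")
  if (anyNA(n) || any(n < 1)) stop("'n' must be species counts >= 1")
  if (anyNA(t) || any(t <= 0)) stop("'t' (stem age, My) must be > 0")
  x <- n * (1 - eps) + eps
  if (log10) log(x, base = 10) / t else log(x) / t
}

#' Per-family diversification-rate table over a grid of relative extinction
#'
#' Applies \code{\link{mom_stem_rate}} to every family at each requested
#' relative extinction fraction.
#'
#' @param families Family table with \code{family}, \code{richness},
#'   \code{venomous} and \code{stem_age} columns (see
#'   \code{\link{align_family_data}}).
#' @param eps_list Relative extinction fractions (default
#'   \code{c(0, 0.5, 0.9)}).
#' @param log10 Passed to \code{\link{mom_stem_rate}}.
#' @return Long-format \code{data.frame}: \code{family}, \code{venomous},
#'   \code{epsilon}, \code{rate}.
#' @seealso \code{\link{rate_medians}} for group medians.
#' @export
rate_table <- function(families, eps_list = c(0, 0.5, 0.9), log10 = FALSE) {
  families <- validate_family_table(families)
  if (is.null(families$stem_age))
    stop("Stem ages missing; run align_family_data() first")
  bad <- families$family[is.na(families$stem_age) | families$stem_age <= 0]
  if (length(bad))
    stop("Missing/invalid stem age for: ", paste(bad, collapse = ", "))
  out <- do.call(rbind, lapply(eps_list, function(eps) {
    data.frame(family = families$family,
               venomous = families$venomous,
               epsilon = eps,
               rate = mom_stem_rate(families$richness, families$stem_age,
                                    eps = eps, log10 = log10),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Median diversification rate by venom state
#'
#' @param rates A rate table from \code{\link{rate_table}}.
#' @return \code{data.frame} with one row per \code{epsilon}: median rate of
#'   venomous and of non-venomous families and their ratio.
#' @export
rate_medians <- function(rates) {
  stopifnot(all(c("epsilon", "venomous", "rate") %in% names(rates)))
  out <- do.call(rbind, lapply(split(rates, rates$epsilon), function(d) {
    m1 <- stats::median(d$rate[d$venomous == 1])
    m0 <- stats::median(d$rate[d$venomous == 0])
    data.frame(epsilon = d$epsilon[1L], median_venomous = m1,
               median_nonvenomous = m0, ratio = m1 / m0)
  }))
  rownames(out) <- NULL
  out
}
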