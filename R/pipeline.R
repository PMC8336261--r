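#' @name pipeline
#' @title Orchestration of the full family-level analysis
NULL

#' Configuration for a full analysis run
#'
#' @param tree Path to a Newick tree, or a \code{"phylo"} object.
#' @param families Path to a family table (CSV/TSV), or a \code{data.frame}.
#' @param epsilon Relative extinction fractions for the rate estimator;
#'   results are keyed on \code{main_epsilon} with the rest as sensitivity
#'   appendices.
#' @param main_epsilon The headline epsilon (default 0.5).
#' @param candidates Candidate PGLS covariance kinds.
#' @param sse_variants SSE variant names to fit.
#' @param n_maps Stochastic maps to draw.
#' @param n_adequacy Adequacy simulations.
#' @param gain_threshold Per-branch gain probability called "strongly
#'   supported" (default 0.2).
#' @param exclude_mixed Also rerun everything on the reduced dataset that
#'   excludes families flagged \code{mixed_state}.
#' @param pad Branch pad (My) for tree conditioning.
#' @param seed Seed governing every stochastic stage.
#' @param sse_restarts,mk_restarts Optimizer restarts for the SSE and Mk
#'   fits.
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(tree, families, epsilon = c(0, 0.5, 0.9),
                       main_epsilon = 0.5,
                       candidates = c("BM", "OU_random_root",
                                      "OU_fixed_root", "lambda", "kappa",
                                      "delta", "early_burst", "trend",
                                      "nonphylo_OLS"),
                       sse_variants = c("full", "equal_all", "equal_div",
                                        "equal_lambda", "equal_mu", "hisse"),
                       n_maps = 1000L, n_adequacy = 1000L,
                       gain_threshold = 0.2, exclude_mixed = FALSE,
                       pad = 0.5, seed = 1L,
                       sse_restarts = 8L, mk_restarts = 5L) {
  if (any(epsilon < 0 | epsilon >= 1)) stop("'epsilon' values must be in [0, 1)")
  if (!main_epsilon %in% epsilon)
    stop("'main_epsilon' must be among 'epsilon'")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full family-level diversification analysis
#'
#' Executes, in order: tree conditioning and stem-age extraction;
#' method-of-moments rate estimation at each epsilon with group medians;
#' the species-richness and diversification-rate phylogenetic regressions
#' (per epsilon, with AIC selection of the covariance model); the
#' sister-clade richness Yule test; the constrained SSE model set with an
#' adequacy check of the best model; and ARD Mk fitting plus stochastic
#' mapping of trait origins. With \code{exclude_mixed}, the whole analysis
#' is repeated on the dataset without mixed-state families and attached as
#' \code{$reduced}.
#'
#' @param config A \code{"run_config"}.
#' @param out_dir Optional directory; when given, TSV/JSON reports are
#'   written under it.
#' @return Nested report list of class \code{"run_report"}; see the
#'   elements \code{tree}, \code{families}, \code{rates}, \code{medians},
#'   \code{richness_pgls}, \code{divrate_pgls}, \code{sisters},
#'   \code{yule_test}, \code{sse}, \code{adequacy}, \code{mk},
#'   \code{maps}, \code{map_summary}, \code{meta}, and (optionally)
#'   \code{reduced}.
#' @export
run_all <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) stop("'config' must be a run_config")
  report <- run_stages(config)
  if (isTRUE(config$exclude_mixed)) {
    fam <- report$families
    mixed <- fam$family[fam$mixed_state == 1]
    if (length(mixed)) {
      cfg2 <- config
      cfg2$tree <- prune_tips(report$tree, mixed)
      cfg2$families <- fam[fam$mixed_state == 0, , drop = FALSE]
      cfg2$exclude_mixed <- FALSE
      report$reduced <- run_stages(cfg2)
    } else {
      message("No mixed-state families; reduced rerun identical to main")
      report$reduced <- report
    }
  }
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

run_stages <- function(config) {
  stage <- "treedata"
  out <- tryCatch({
    tree <- if (inherits(config$tree, "phylo")) config$tree
            else read_newick(config$tree)
    fam <- if (is.data.frame(config$families)) config$families
           else read_family_table(config$families)
    tree <- condition_tree(tree, pad = config$pad)
    ali <- align_family_data(tree, fam)
    tree <- ali$tree; fam <- ali$families

    stage <- "divrate"
    rates <- rate_table(fam, eps_list = config$epsilon)
    medians <- rate_medians(rates)

    stage <- "phyloreg"
    richness_pgls <- lapply(stats::setNames(config$epsilon, config$epsilon),
      function(e) richness_model(fam, rates, tree, epsilon = e,
                                 candidates = config$candidates))
    divrate_pgls <- lapply(stats::setNames(config$epsilon, config$epsilon),
      function(e) divrate_model(fam, rates, tree, epsilon = e,
                                candidates = config$candidates))

    stage <- "sistertest"
    st <- stats::setNames(fam$venomous, fam$family)
    rich <- stats::setNames(fam$richness, fam$family)
    sisters <- find_sister_pairs(tree, st, rich)
    yule_test <- if (nrow(sisters)) richness_yule_test(sisters) else NULL

    stage <- "sse"
    sse <- model_set(tree, st, variants = config$sse_variants,
                     n_restarts = config$sse_restarts, seed = config$seed)
    adequacy <- adequacy_check(sse$best, tree, st,
                               n_sims = config$n_adequacy,
                               seed = config$seed)

    stage <- "ancstate"
    mk <- fit_mk_ard(tree, st, n_restarts = config$mk_restarts,
                     seed = config$seed)
    maps <- stochastic_maps(tree, st, mk, n_maps = config$n_maps,
                            seed = config$seed)
    map_summary <- summarize_maps(maps, threshold = config$gain_threshold)

    list(tree = tree, families = fam, rates = rates, medians = medians,
         richness_pgls = richness_pgls, divrate_pgls = divrate_pgls,
         sisters = sisters, yule_test = yule_test,
         sse = sse, adequacy = adequacy,
         mk = mk, maps = maps, map_summary = map_summary,
         meta = list(seed = config$seed,
                     main_epsilon = config$main_epsilon,
                     package_version =
                       as.character(utils::packageVersion("venomdiv")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  }, error = function(e) {
    stop("Pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(out) <- "run_report"
  out
}

pgls_report_row <- function(sel) {
  b <- sel$best
  data.frame(model = b$model,
             cov_par = unname(b$cov_par), sigma2 = b$sigma2,
             logLik = b$logLik, AIC = b$AIC,
             term = rownames(b$coefficients), b$coefficients,
             row.names = NULL)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(d, file.path(out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  ape::write.tree(report$tree, file.path(out_dir, "conditioned_tree.nwk"))
  wt(data.frame(family = report$families$family,
                stem_age_my = report$families$stem_age), "stem_ages.tsv")
  wt(report$rates, "rates.tsv")
  wt(report$medians, "rate_medians.tsv")
  for (e in names(report$richness_pgls)) {
    wt(pgls_report_row(report$richness_pgls[[e]]),
       paste0("richness_pgls_eps", e, ".tsv"))
    wt(report$richness_pgls[[e]]$aic_table,
       paste0("richness_pgls_aic_eps", e, ".tsv"))
    wt(pgls_report_row(report$divrate_pgls[[e]]),
       paste0("divrate_pgls_eps", e, ".tsv"))
    wt(report$divrate_pgls[[e]]$aic_table,
       paste0("divrate_pgls_aic_eps", e, ".tsv"))
  }
  wt(report$sisters, "sister_pairs.tsv")
  if (!is.null(report$yule_test))
    jsonlite::write_json(report$yule_test,
                         file.path(out_dir, "yule_test.json"),
                         auto_unbox = TRUE, digits = NA)
  wt(report$sse$aic_table, "sse_aic.tsv")
  wt(data.frame(parameter = names(report$sse$best$par),
                estimate = unname(report$sse$best$par)),
     "sse_best_params.tsv")
  wt(report$adequacy$sims, "adequacy_sims.tsv")
  jsonlite::write_json(list(observed = as.list(report$adequacy$observed),
                            quantiles = as.list(report$adequacy$quantiles)),
                       file.path(out_dir, "adequacy_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  edge <- report$tree$edge
  ages <- node_ages(report$tree)
  labs <- c(report$tree$tip.label,
            rep(NA_character_, report$tree$Nnode))
  wt(data.frame(branch_id = seq_len(nrow(edge)),
                parent_age = ages[edge[, 1]],
                child = ifelse(edge[, 2] <= length(report$tree$tip.label),
                               labs[edge[, 2]], paste0("node", edge[, 2])),
                gain_prob = report$map_summary$gain_prob,
                loss_prob = report$map_summary$loss_prob),
     "branch_gain_probs.tsv")
  ms <- report$map_summary
  jsonlite::write_json(
    list(gains = ms$gains, losses = ms$losses, min_gains = ms$min_gains,
         frac_time_venomous = ms$frac1_mean, threshold = ms$threshold,
         n_supported_branches = length(ms$supported_edges),
         q_gain = report$mk$q_gain, q_loss = report$mk$q_loss,
         meta = report$meta),
    file.path(out_dir, "mapping_summary.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  e <- as.character(x$meta$main_epsilon)
  cat("Family-level venom-diversification analysis\n")
  cat("  families:", nrow(x$families),
      sprintf("(%d venomous, %d non-venomous)\n",
              sum(x$families$venomous == 1), sum(x$families$venomous == 0)))
  m <- x$medians[abs(x$medians$epsilon - x$meta$main_epsilon) < 1e-12, ]
  cat(sprintf("  median rate (eps = %s): venomous %.4f, non-venomous %.4f (ratio %.2f)\n",
              e, m$median_venomous, m$median_nonvenomous, m$ratio))
  b <- x$divrate_pgls[[e]]$best
  cat(sprintf("  divrate PGLS [%s]: venom coefficient %.4f (p = %.3g)\n",
              b$model, b$coefficients["Venom", "Coefficient"],
              b$coefficients["Venom", "P"]))
  if (!is.null(x$yule_test))
    cat(sprintf("  richness Yule test: chi2 = %.2f, p = %.3g (%d pairs, mean ratio %.2f)\n",
                x$yule_test$chi2, x$yule_test$p, x$yule_test$n_pairs,
                x$yule_test$mean_ratio))
  cat("  best SSE variant:", x$sse$best$variant,
      sprintf("(AIC %.2f)\n", x$sse$best$AIC))
  cat(sprintf("  mapped gains: median %s (min %d); venomous time fraction %.3f\n",
              format(x$map_summary$gains$median), x$map_summary$min_gains,
              x$map_summary$frac1_mean))
  invisible(x)
}
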