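#' Read a rooted, time-calibrated phylogeny from a Newick file
#'
#' Reads a single Newick tree (branch lengths in million years, My) and
#' validates it for downstream comparative analyses: the tree must be rooted,
#' all tips labelled, branch lengths present, and tip labels unique
#' (case-insensitively, after trimming whitespace). Polytomies are preserved.
#'
#' @param path Path to a Newick file containing one tree.
#' @return An object of class \code{"phylo"} (see \pkg{ape}).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) stop("Malformed Newick in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Malformed Newick in '", path,
                          "': no tree could be parsed")
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L)
      stop("Expected a single tree per file, found ", length(tree))
    tree <- tree[[1L]]
  }
  validate_tree(tree)
  tree
}

#' Validate a phylogeny for family-level comparative analysis
#'
#' @param tree A \code{"phylo"} object.
#' @param require_ultrametric If \code{TRUE}, error unless the tree is
#'   ultrametric (all root-to-tip path lengths equal within tolerance).
#' @param tol Absolute tolerance (My) for the ultrametricity check.
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_tree <- function(tree, require_ultrametric = FALSE, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a \"phylo\" object")
  if (is.null(tree$edge.length))
    stop("Tree has no branch lengths; time-calibrated branch lengths (My) are required")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("Tree has missing or negative branch lengths")
  if (is.null(tree$tip.label) || anyNA(tree$tip.label) || any(tree$tip.label == ""))
    stop("All tips must be labelled with family names")
  key <- canonical_name(tree$tip.label)
  if (anyDuplicated(key)) {
    dup <- unique(tree$tip.label[duplicated(key)])
    stop("Duplicate tip labels (case-insensitive): ",
         paste(dup, collapse = ", "))
  }
  if (!ape::is.rooted(tree)) stop("Tree must be rooted")
  if (require_ultrametric && !ape::is.ultrametric(tree, tol = tol, option = 1))
    stop("Tree is not ultrametric (tolerance ", tol, " My)")
  invisible(tree)
}

# Canonical form used for all family-name matching: trimmed, lower-case.
canonical_name <- function(x) tolower(trimws(x))

#' Prune a set of tips from a phylogeny
#'
#' Removes the named tips, suppressing resulting degree-2 nodes by summing
#' their branch lengths, so that all pairwise path lengths among retained
#' tips are preserved.
#'
#' @param tree A \code{"phylo"} object.
#' @param labels Character vector of tip labels to remove (matched
#'   case-insensitively after trimming). May be empty.
#' @return The pruned \code{"phylo"} object.
#' @export
prune_tips <- function(tree, labels) {
  validate_tree(tree)
  if (length(labels) == 0L) return(tree)
  idx <- match(canonical_name(labels), canonical_name(tree$tip.label))
  if (anyNA(idx))
    stop("Unknown tip label(s): ", paste(labels[is.na(idx)], collapse = ", "))
  if (length(idx) >= ape::Ntip(tree) - 1L)
    stop("Pruning would leave fewer than 2 tips")
  ape::drop.tip(tree, tree$tip.label[idx], collapse.singles = TRUE)
}

#' Force a phylogeny to be ultrametric
#'
#' Adjusts branch lengths so that all tips are contemporaneous. The default
#' \code{"nnls"} method performs a non-negative least-squares adjustment of
#' all branch lengths (minimal total squared change subject to
#' non-negativity); \code{"extend"} lengthens terminal branches only.
#'
#' @param tree A rooted \code{"phylo"} object with branch lengths.
#' @param method One of \code{"nnls"} (default) or \code{"extend"}.
#' @return An ultrametric \code{"phylo"} object.
#' @export
force_ultrametric <- function(tree, method = c("nnls", "extend")) {
  method <- match.arg(method)
  validate_tree(tree)
  if (ape::is.ultrametric(tree, tol = 1e-10, option = 1)) return(tree)
  out <- suppressMessages(phytools::force.ultrametric(tree, method = method,
                                                      message = FALSE))
  out$edge.length[out$edge.length < 0] <- 0
  out
}

#' Condition a phylogeny for comparative analysis
#'
#' Pads very short (e.g. zero-length, polytomy-resolution artifact) branches
#' by adding \code{pad} My to every branch shorter than \code{pad}, then
#' restores ultrametricity with \code{\link{force_ultrametric}}. With
#' \code{pad_all_branches = TRUE} the pad is added to every branch instead.
#'
#' @param tree A rooted \code{"phylo"} object.
#' @param pad Non-negative pad length in My (default 0.5).
#' @param pad_all_branches Add \code{pad} to all branches rather than only
#'   those shorter than \code{pad}.
#' @param method Ultrametric correction method, passed to
#'   \code{\link{force_ultrametric}}.
#' @return A conditioned, ultrametric \code{"phylo"} object with all branch
#'   lengths strictly positive.
#' @export
condition_tree <- function(tree, pad = 0.5, pad_all_branches = FALSE,
                           method = c("nnls", "extend")) {
  if (!is.numeric(pad) || length(pad) != 1L || is.na(pad) || pad < 0)
    stop("'pad' must be a single non-negative number (My)")
  validate_tree(tree)
  el <- tree$edge.length
  if (pad > 0) {
    if (pad_all_branches) el <- el + pad
    else el[el < pad] <- el[el < pad] + pad
  }
  tree$edge.length <- el
  out <- force_ultrametric(tree, method = match.arg(method))
  if (any(out$edge.length <= 0)) {
    # nnls can push a padded branch back to zero; nudge and re-correct once
    out$edge.length[out$edge.length <= 0] <- pad
    out <- force_ultrametric(out, method = match.arg(method))
    out$edge.length[out$edge.length <= 0] <- .Machine$double.eps
  }
  out
}

#' Node ages (time before present) of a phylogeny
#'
#' @param tree A rooted \code{"phylo"} object.
#' @return Numeric vector of ages (My before present) indexed by node number
#'   (tips \code{1..Ntip}, then internal nodes).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Stem ages of the families (tips) of an ultrametric phylogeny
#'
#' The stem age of a family is the age of its parent node: the time at which
#' the family's lineage split from its sister lineage. For contemporaneous
#' tips this equals the terminal branch length.
#'
#' @param tree An ultrametric \code{"phylo"} object.
#' @param tol Ultrametricity tolerance (My).
#' @return Named numeric vector of stem ages (My), one per tip.
#' @export
stem_ages <- function(tree, tol = 1e-6) {
  validate_tree(tree, require_ultrametric = TRUE, tol = tol)
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  parent <- tree$edge[match(seq_len(ntip), tree$edge[, 2L]), 1L]
  out <- ages[parent]
  names(out) <- tree$tip.label
  out
}

#' Read a per-family data table
#'
#' Reads a CSV or TSV table with columns \code{family}, \code{richness}
#' (total species count), \code{venomous} (0/1), and optionally
#' \code{mixed_state} (0/1; families known to contain both venomous and
#' non-venomous species, used in robustness reruns). A missing
#' \code{mixed_state} column defaults to 0.
#'
#' @param path Path to the table; the delimiter is taken from the extension
#'   (\code{.tsv}/\code{.txt} gives tab, otherwise comma).
#' @return A \code{data.frame} with columns \code{family}, \code{richness},
#'   \code{venomous}, \code{mixed_state}.
#' @export
read_family_table <- function(path) {
  if (!file.exists(path)) stop("Family table not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  names(df) <- tolower(names(df))
  required <- c("family", "richness", "venomous")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("Family table missing column(s): ", paste(missing, collapse = ", "))
  if (is.null(df$mixed_state)) df$mixed_state <- 0L
  validate_family_table(df[, c("family", "richness", "venomous", "mixed_state")])
}

#' Validate a per-family data table
#'
#' @param df Data frame with columns \code{family}, \code{richness},
#'   \code{venomous}, and optionally \code{mixed_state} and \code{stem_age}.
#' @return The validated data frame (invisible coercions applied).
#' @export
validate_family_table <- function(df) {
  if (!is.data.frame(df)) stop("Family table must be a data.frame")
  if (is.null(df$mixed_state)) df$mixed_state <- 0L
  if (anyNA(df$family) || any(trimws(df$family) == ""))
    stop("Family names must be non-missing")
  if (anyDuplicated(canonical_name(df$family))) {
    dup <- unique(df$family[duplicated(canonical_name(df$family))])
    stop("Duplicate family names: ", paste(dup, collapse = ", "))
  }
  if (anyNA(df$richness) || any(df$richness < 1) ||
      any(df$richness != round(df$richness)))
    stop("'richness' must be integer species counts >= 1")
  df$richness <- round(df$richness)  # kept numeric: counts can exceed int range
  for (col in c("venomous", "mixed_state")) {
    if (anyNA(df[[col]]) || !all(df[[col]] %in% c(0, 1)))
      stop("'", col, "' must be binary 0/1")
    df[[col]] <- as.integer(df[[col]])
  }
  if (!is.null(df$stem_age) && (anyNA(df$stem_age) || any(df$stem_age <= 0)))
    stop("'stem_age' must be > 0 My for every family")
  df
}

#' Align a family table with a phylogeny and attach stem ages
#'
#' Matches family names to tip labels case-insensitively (after trimming),
#' drops tree tips without data and data rows without tips (with a message),
#' and attaches the stem age of each retained family.
#'
#' @param tree An ultrametric \code{"phylo"} object.
#' @param families A family table (see \code{\link{read_family_table}}).
#' @return List with elements \code{tree} (possibly pruned) and
#'   \code{families} (rows ordered as the tree's tip labels, with a
#'   \code{stem_age} column).
#' @export
align_family_data <- function(tree, families) {
  families <- validate_family_table(families)
  tip_key <- canonical_name(tree$tip.label)
  fam_key <- canonical_name(families$family)
  drop_tips <- tree$tip.label[!(tip_key %in% fam_key)]
  if (length(drop_tips)) {
    message(length(drop_tips), " tip(s) without family data pruned")
    tree <- prune_tips(tree, drop_tips)
    tip_key <- canonical_name(tree$tip.label)
  }
  keep <- fam_key %in% tip_key
  if (any(!keep))
    message(sum(!keep), " family record(s) not in the tree dropped")
  families <- families[keep, , drop = FALSE]
  families <- families[match(tip_key, canonical_name(families$family)), ,
                       drop = FALSE]
  families$family <- tree$tip.label
  sa <- stem_ages(tree)
  families$stem_age <- unname(sa[tree$tip.label])
  rownames(families) <- NULL
  list(tree = tree, families = families)
}
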