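# Fixation-interval dating on a dated species tree.
#
# Model: a derived allele restricted to one clade arose once on the stem
# branch of that clade (single-gain, Dollo-like parsimony with up to
# `max_losses` reversions, no regain).  The allele must then have been
# fixed between the clade's stem age (divergence from its sister lineage)
# and its crown age (deepest split inside the clade).

#' Read a dated tree from newick
#'
#' Branch lengths are interpreted as millions of years.  Node ages are
#' computed as the tree height minus the root-to-node distance; by default
#' the tree must be ultrametric (all tips contemporaneous at age 0) within
#' a relative tolerance.  Non-contemporaneous tips (e.g. fossils) can be
#' declared via `tip_ages`; the computed ages must then agree with the
#' declared ones.
#'
#' @param path Path to a newick file, or a `phylo` object (taken as-is).
#' @param tolerance Relative tolerance for the ultrametricity / tip-age
#'   consistency check (default `1e-6`).
#' @param tip_ages Optional named numeric vector of tip ages in Mya
#'   (missing tips default to 0).
#' @return An object of class `"dated_tree"`: list with `phylo` (the
#'   [ape::read.tree()] tree) and `ages` (numeric, indexed by ape node
#'   number: tips `1..Ntip`, internals `Ntip+1..`).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' read_dated_newick(tf)$ages  # tips 0, internals 1 and 2
read_dated_newick <- function(path, tolerance = 1e-6, tip_ages = NULL) {
  if (inherits(path, "phylo")) {
    tr <- path
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    tr <- tryCatch(ape::read.tree(path),
                   error = function(e)
                     stop("newick format error: ", conditionMessage(e),
                          call. = FALSE))
    if (is.null(tr)) stop("newick format error: no tree in ", path)
  }
  if (is.null(tr$edge.length))
    stop("dating error: tree has no branch lengths")
  if (any(tr$edge.length < 0))
    stop("format error: negative branch length")
  ntip <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)
  tipd <- depth[seq_len(ntip)]
  ta <- rep(0, ntip)
  names(ta) <- tr$tip.label
  if (!is.null(tip_ages)) {
    known <- intersect(names(tip_ages), tr$tip.label)
    ta[known] <- tip_ages[known]
  }
  height <- max(tipd + ta)
  ages <- height - depth
  scale <- max(height, 1)
  if (any(abs(ages[seq_len(ntip)] - ta) > tolerance * scale)) {
    if (is.null(tip_ages))
      stop("dating error: tree is not ultrametric (tip depths differ); ",
           "supply tip_ages for non-contemporaneous tips")
    stop("dating error: branch lengths inconsistent with declared tip ages")
  }
  ages[seq_len(ntip)] <- ta
  ages[ages < 0] <- 0
  structure(list(phylo = tr, ages = ages), class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("<dated_tree> %d tips, root age %.1f Mya\n",
              length(x$phylo$tip.label), max(x$ages)))
  invisible(x)
}

#' Age of named or numbered nodes
#'
#' @param tree A [read_dated_newick()] tree.
#' @param node Internal-node label, tip label, or ape node number.
#' @return Age in Mya.
#' @export
node_age <- function(tree, node) {
  stopifnot(inherits(tree, "dated_tree"))
  tr <- tree$phylo
  if (is.character(node)) {
    idx <- match(node, tr$tip.label)
    if (is.na(idx) && !is.null(tr$node.label)) {
      j <- match(node, tr$node.label)
      if (!is.na(j)) idx <- length(tr$tip.label) + j
    }
    if (is.na(idx)) stop("node not found: ", node)
    node <- idx
  }
  tree$ages[node]
}

normalize_states <- function(tree, states) {
  tips <- tree$phylo$tip.label
  ok <- c("derived", "ancestral", "unknown")
  if (!is.character(states) || is.null(names(states)))
    stop("states must be a named character vector over ",
         paste(ok, collapse = "/"))
  bad <- setdiff(unique(states), ok)
  if (length(bad) > 0)
    stop("invalid state(s): ", paste(bad, collapse = ","))
  extra <- setdiff(names(states), tips)
  if (length(extra) > 0)
    stop("states given for unknown tip(s): ", paste(extra, collapse = ","))
  full <- stats::setNames(rep("unknown", length(tips)), tips)
  full[names(states)] <- states
  full
}

#' Single-gain clade of a derived allele
#'
#' Finds the most recent common ancestor (MRCA) of all derived tips and
#' checks it is compatible with a single gain of the allele on the MRCA's
#' stem branch, tolerating up to `max_losses` reversions: the number of
#' maximal subclades inside the MRCA clade whose resolved tips are all
#' ancestral must not exceed `max_losses`.  Tips with unknown state are
#' compatible with either state and never force a loss.
#'
#' @param tree A [read_dated_newick()] tree.
#' @param states Named character vector tip -> `"derived"`, `"ancestral"`
#'   or `"unknown"`; tips absent from the vector are `"unknown"`.
#' @param max_losses Maximum number of reversions tolerated (default 1).
#' @return List with `gain_node` (ape node number), `gain_label` (tip or
#'   internal-node label, `NA` if unlabeled), `n_losses` and
#'   `derived_tips`.
#' @export
derived_clade <- function(tree, states, max_losses = 1) {
  stopifnot(inherits(tree, "dated_tree"))
  tr <- tree$phylo
  ntip <- length(tr$tip.label)
  states <- normalize_states(tree, states)
  derived <- names(states)[states == "derived"]
  if (length(derived) == 0)
    stop("empty-state error: no derived tips")
  gain <- if (length(derived) == 1) match(derived, tr$tip.label)
          else ape::getMRCA(tr, derived)
  # nodes (tips + internals) strictly inside the gain clade
  inside <- if (gain <= ntip) integer(0)
            else unlist(phangorn::Descendants(tr, gain, type = "all"))
  tipsets <- phangorn::Descendants(tr, c(gain, inside), type = "tips")
  node_ids <- c(gain, inside)
  st <- states[tr$tip.label]
  is_anc_ok <- vapply(tipsets, function(tp) all(st[tp] != "derived"),
                      logical(1))
  has_anc <- vapply(tipsets, function(tp) any(st[tp] == "ancestral"),
                    logical(1))
  ok <- stats::setNames(is_anc_ok & has_anc, node_ids)
  loss_ok <- stats::setNames(is_anc_ok, node_ids)
  parent <- integer(max(tr$edge))
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  # maximal all-ancestral subclades = loss events
  is_loss <- vapply(seq_along(node_ids), function(i) {
    n <- node_ids[i]
    if (!ok[i]) return(FALSE)
    p <- parent[n]
    p == 0 || n == gain || !isTRUE(loss_ok[as.character(p)])
  }, logical(1))
  n_losses <- sum(is_loss)
  if (n_losses > max_losses)
    stop(sprintf(
      "no-single-gain error: %d loss(es) required inside the derived clade but max_losses = %d",
      n_losses, max_losses))
  lab <- if (gain <= ntip) tr$tip.label[gain]
         else if (!is.null(tr$node.label) &&
                  nzchar(tr$node.label[gain - ntip]))
           tr$node.label[gain - ntip]
         else NA_character_
  list(gain_node = gain, gain_label = lab, n_losses = n_losses,
       derived_tips = derived)
}

#' Fixation interval of a derived allele
#'
#' Bounds on when the allele was fixed, in Mya: the oldest bound is the
#' stem age of the gain clade (the age of the gain node's parent; the root
#' age for a gain on the root edge) and the youngest bound is its crown
#' age (the gain node's own age; 0 for a single-tip gain).
#'
#' @inheritParams derived_clade
#' @param label Optional allele label carried into the result.
#' @return Object of class `"fixation_interval"`: list with `oldest_mya`,
#'   `youngest_mya`, `gain_node`, `gain_label`, `n_losses_assumed`,
#'   `label`.
#' @export
fixation_interval <- function(tree, states, max_losses = 1, label = NULL) {
  g <- derived_clade(tree, states, max_losses)
  tr <- tree$phylo
  young <- unname(tree$ages[g$gain_node])
  pe <- tr$edge[tr$edge[, 2] == g$gain_node, 1]
  old <- if (length(pe) == 0) max(tree$ages) else unname(tree$ages[pe])
  structure(list(oldest_mya = old, youngest_mya = young,
                 gain_node = g$gain_node, gain_label = g$gain_label,
                 n_losses_assumed = g$n_losses, label = label),
            class = "fixation_interval")
}

#' @export
print.fixation_interval <- function(x, ...) {
  cat(sprintf("<fixation_interval>%s fixed %.1f-%.1f Mya (gain at %s, %d loss(es) assumed)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$oldest_mya, x$youngest_mya,
              if (is.na(x$gain_label)) paste0("node ", x$gain_node)
              else x$gain_label,
              x$n_losses_assumed))
  invisible(x)
}

#' Minimum temporal gap between two fixation intervals
#'
#' The interval with the larger oldest bound is taken as the earlier
#' fixation; the gap is `max(0, earlier$youngest_mya - later$oldest_mya)`
#' in Myr.  Zero signals possible overlap of the two windows.
#'
#' @param earlier,later [fixation_interval] objects (order-insensitive:
#'   the earlier one is identified by its oldest bound).
#' @return Gap in Myr (non-negative).
#' @export
#' @examples
#' a <- structure(list(oldest_mya = 32, youngest_mya = 18),
#'                class = "fixation_interval")
#' b <- structure(list(oldest_mya = 12, youngest_mya = 8),
#'                class = "fixation_interval")
#' interval_gap(a, b)  # 6
interval_gap <- function(earlier, later) {
  stopifnot(inherits(earlier, "fixation_interval"),
            inherits(later, "fixation_interval"))
  if (earlier$oldest_mya < later$oldest_mya) {
    tmp <- earlier; earlier <- later; later <- tmp
  }
  max(0, earlier$youngest_mya - later$oldest_mya)
}

#' Read tip states from a TSV
#'
#' @param path TSV with columns `tip`, `state`
#'   (`derived`/`ancestral`/`unknown`).
#' @return Named character vector tip -> state.
#' @export
read_states_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tip", "state") %in% names(tb)))
    stop("states table needs columns: tip, state")
  stats::setNames(tb$state, tb$tip)
}
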