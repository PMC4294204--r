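# Fixtures and independent oracles used across the test files.

toy_alignment <- function(seqs, ids = NULL, reference_id = NULL,
                          molecule = "nucleotide", taxonomy = NULL) {
  if (is.null(ids)) ids <- c("Homo_sapiens",
                             sprintf("sp%02d", seq_along(seqs)[-1]))
  if (is.null(reference_id)) reference_id <- ids[1]
  cpd_alignment(ids, seqs, reference_id, molecule, taxonomy)
}

# Brute-force CI: tally the mapped column by hand, excluding the reference.
oracle_ci <- function(seqs, ref_idx, ref_pos) {
  chars <- strsplit(seqs, "")
  ref <- chars[[ref_idx]]
  col <- which(ref != "-")[ref_pos]
  wt <- ref[col]
  obs <- vapply(chars[-ref_idx], `[`, "", col)
  100 * sum(obs == wt) / length(obs)
}

# Textbook pooled-variance two-sample t statistic and two-sided p.
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# Descendant tip sets from the edge matrix alone (no phangorn).
oracle_tipsets <- function(tr) {
  ntip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  res <- vector("list", ntip + tr$Nnode)
  rec <- function(n) {
    if (n <= ntip) return(n)
    s <- sort(unlist(lapply(kids[[as.character(n)]], rec)))
    res[[n]] <<- s
    s
  }
  for (t in seq_len(ntip)) res[[t]] <- t
  rec(ntip + 1L)
  res
}

# Brute-force single-gain reconstruction: enumerate every clade, find the
# smallest one covering all derived tips, then find the minimal number of
# derived-free clades inside it whose union covers the ancestral tips.
oracle_derived_clade <- function(tr, states, max_search = 4) {
  ntip <- length(tr$tip.label)
  st <- states[tr$tip.label]
  st[is.na(st)] <- "unknown"
  derived <- which(st == "derived")
  tipsets <- oracle_tipsets(tr)
  covering <- which(vapply(tipsets, function(s) all(derived %in% s),
                           logical(1)))
  sizes <- lengths(tipsets[covering])
  gain <- covering[which.min(sizes)]
  anc_inside <- intersect(which(st == "ancestral"), tipsets[[gain]])
  if (length(anc_inside) == 0)
    return(list(gain = gain, losses = 0))
  loss_cands <- Filter(function(n)
    length(intersect(tipsets[[n]], derived)) == 0 &&
      all(tipsets[[n]] %in% tipsets[[gain]]),
    seq_along(tipsets))
  for (k in seq_len(max_search)) {
    for (combo in utils::combn(length(loss_cands), k, simplify = FALSE)) {
      covered <- unique(unlist(tipsets[unlist(loss_cands[combo])]))
      if (all(anc_inside %in% covered))
        return(list(gain = gain, losses = k))
    }
  }
  list(gain = gain, losses = Inf)
}

# Brute-force all-pairs minimum distance.
oracle_min_distance <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

random_tip_states <- function(tr, p_derived = 0.4, p_unknown = 0.15) {
  tips <- tr$tip.label
  st <- sample(c("derived", "ancestral", "unknown"), length(tips),
               replace = TRUE,
               prob = c(p_derived, 1 - p_derived - p_unknown, p_unknown))
  if (!any(st == "derived")) st[sample(length(tips), 1)] <- "derived"
  stats::setNames(st, tips)
}
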