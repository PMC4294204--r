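# Conservation-index statistics on alignment columns.
#
# The conservation index (CI) of a reference position is the percentage of
# non-reference sequences that carry the human wild-type state at the
# homologous alignment column.  Denominator convention: the reference row is
# excluded from both counts; gaps and N/X count in the denominator but never
# as matches (a sequence with a gap does not harbor the wild-type variant).
# This makes published fractions such as 544/608 reproducible as plain
# fractions of the species counted.

#' Conservation index of one reference position
#'
#' @param aln A [cpd_alignment].
#' @param ref_pos 1-based ungapped reference position.
#' @return A list with `ref_position`, `column`, `wildtype` (the reference
#'   row's state), `n_match`, `n_total` and `ci` (percent, full precision;
#'   round to 1 decimal for reporting).
#' @export
#' @examples
#' aln <- cpd_alignment(c("hs", "a", "b", "c"),
#'                      c("ACGT", "ACGT", "ACGA", "AC-T"), "hs")
#' conservation_index(aln, 4)$ci  # 1 of 3 matches T -> 33.33...
conservation_index <- function(aln, ref_pos) {
  stopifnot(inherits(aln, "cpd_alignment"))
  col <- map_reference_position(aln, ref_pos)
  ri <- reference_index(aln)
  wt <- unname(aln$mat[ri, col])
  obs <- aln$mat[-ri, col]
  n_total <- length(obs)
  if (n_total == 0)
    stop("degenerate alignment: no non-reference records")
  n_match <- sum(obs == wt)
  list(ref_position = as.integer(ref_pos), column = col, wildtype = wt,
       n_match = n_match, n_total = n_total,
       ci = 100 * n_match / n_total)
}

#' Conservation profile over reference positions
#'
#' @param aln A [cpd_alignment].
#' @param ref_positions Integer vector of 1-based reference positions;
#'   default every ungapped reference position.
#' @return Data frame with columns `ref_position`, `column`, `wildtype`,
#'   `n_match`, `n_total`, `ci` (percent, full precision).
#' @export
conservation_profile <- function(aln, ref_positions = NULL) {
  if (is.null(ref_positions))
    ref_positions <- seq_len(ungapped_reference_length(aln))
  rows <- lapply(ref_positions, function(p)
    as.data.frame(conservation_index(aln, p), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Gene-wide mean conservation index
#'
#' Arithmetic mean of the per-position CI over every ungapped reference
#' position of the gene.
#'
#' @param aln A [cpd_alignment].
#' @return Mean CI in percent (full precision).
#' @export
gene_mean_ci <- function(aln) {
  mean(conservation_profile(aln)$ci)
}

#' Mean conservation index of a position set
#'
#' @param cis Non-empty numeric vector of per-position CIs (percent).
#' @return Arithmetic mean (percent).
#' @export
#' @examples
#' mean_ci_of_set(c(7.1, 90.0, 24.3, 10.0, 24.3, 55.7))  # 35.23...
mean_ci_of_set <- function(cis) {
  if (length(cis) == 0) stop("empty-set error: no CI values supplied")
  stopifnot(is.numeric(cis))
  mean(cis)
}

#' Compare two sets of conservation indices
#'
#' Unpaired two-tailed t-test between two CI sets.  Default is the
#' classical Student (pooled-variance) test; set `var_equal = FALSE` for
#' Welch.  A result is flagged significant at p < 0.05.
#'
#' @param cis_a,cis_b Numeric vectors of per-position CIs, each of length
#'   at least 2.
#' @param var_equal Use the pooled-variance Student test (default `TRUE`).
#' @param alpha Significance level (default 0.05).
#' @return A list with `t`, `df`, `p_value`, `significant`,
#'   `mean_a`, `mean_b`, `method`.
#' @export
compare_ci_sets <- function(cis_a, cis_b, var_equal = TRUE, alpha = 0.05) {
  if (length(cis_a) < 2 || length(cis_b) < 2)
    stop("sample-size error: each CI set needs at least 2 values")
  if (var_equal) {
    pooled <- ((length(cis_a) - 1) * stats::var(cis_a) +
               (length(cis_b) - 1) * stats::var(cis_b)) /
      (length(cis_a) + length(cis_b) - 2)
    if (pooled == 0)
      stop("degenerate-variance error: zero pooled variance")
  } else if (stats::var(cis_a) == 0 && stats::var(cis_b) == 0) {
    stop("degenerate-variance error: both sets constant")
  }
  tt <- stats::t.test(cis_a, cis_b, var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, significant = tt$p.value < alpha,
       mean_a = mean(cis_a), mean_b = mean(cis_b),
       method = if (var_equal) "student" else "welch")
}
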