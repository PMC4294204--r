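# CPD calling: which species carry a human pathogenic allele as their
# wild type, per-clade tallies, and decoding-site Watson-Crick pairing.

#' Define a pathogenic site
#'
#' @param ref_position 1-based reference position (rCRS numbering for
#'   mtDNA sites, e.g. 1494 for m.1494C>T).
#' @param wildtype Human wild-type state at the position.
#' @param pathogenic Pathogenic allele; must differ from `wildtype`.
#' @param label Display label, default e.g. `"m.1494C>T"` for nucleotide.
#' @param molecule `"nucleotide"` or `"protein"`.
#' @return An object of class `"pathogenic_site"`.
#' @export
#' @examples
#' pathogenic_site(1494, "C", "T")
pathogenic_site <- function(ref_position, wildtype, pathogenic,
                            label = NULL,
                            molecule = c("nucleotide", "protein")) {
  molecule <- match.arg(molecule)
  wildtype <- normalize_chars(wildtype, molecule)
  pathogenic <- normalize_chars(pathogenic, molecule)
  if (wildtype == pathogenic)
    stop("wildtype and pathogenic alleles must differ")
  core <- if (molecule == "nucleotide") .NUC_CORE else .AA_CORE
  if (!wildtype %in% core || !pathogenic %in% core)
    stop("alleles must be unambiguous states of the molecule alphabet")
  if (is.null(label))
    label <- if (molecule == "nucleotide")
      sprintf("m.%d%s>%s", as.integer(ref_position), wildtype, pathogenic)
    else
      sprintf("%s%d%s", wildtype, as.integer(ref_position), pathogenic)
  structure(list(ref_position = as.integer(ref_position),
                 wildtype_allele = wildtype,
                 pathogenic_allele = pathogenic,
                 label = label, molecule = molecule),
            class = "pathogenic_site")
}

#' @export
print.pathogenic_site <- function(x, ...) {
  cat(sprintf("<pathogenic_site> %s (position %d, %s>%s)\n", x$label,
              x$ref_position, x$wildtype_allele, x$pathogenic_allele))
  invisible(x)
}

#' Read a table of pathogenic sites
#'
#' @param path TSV with columns `label`, `ref_position`, `wildtype`,
#'   `pathogenic` (label may be empty).
#' @param molecule Molecule type of the sites.
#' @return List of [pathogenic_site] objects.
#' @export
read_site_table <- function(path, molecule = c("nucleotide", "protein")) {
  molecule <- match.arg(molecule)
  # colClasses: a lone "T" allele must stay character, not become logical
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("ref_position", "wildtype", "pathogenic")
  if (!all(need %in% names(tb)))
    stop("site table needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tb)), function(i)
    pathogenic_site(tb$ref_position[i], tb$wildtype[i], tb$pathogenic[i],
                    label = if ("label" %in% names(tb) &&
                                nzchar(tb$label[i])) tb$label[i] else NULL,
                    molecule = molecule))
}

#' Call compensated pathogenic deviations at a site
#'
#' Maps the site's reference position to its alignment column and assigns
#' each non-reference record a verdict by exact state match:
#' `pathogenic_allele` (the species carries the human pathogenic allele as
#' its wild type, i.e. a candidate CPD), `wildtype`, `other`, or
#' `unresolved` for gaps and N/X.  If the reference row's state disagrees
#' with the declared wild-type allele, the declared site definition wins
#' and a warning is issued.
#'
#' @param aln A [cpd_alignment].
#' @param site A [pathogenic_site].
#' @return Data frame (class `"cpd_calls"`) with columns `id`, `family`,
#'   `subfamily`, `tribe`, `observed_state`, `verdict`; the site is
#'   attached as attribute `"site"`.
#' @export
call_cpd <- function(aln, site) {
  stopifnot(inherits(aln, "cpd_alignment"),
            inherits(site, "pathogenic_site"))
  if (aln$molecule != site$molecule)
    stop("alignment and site molecule types differ")
  col <- map_reference_position(aln, site$ref_position)
  ri <- reference_index(aln)
  refstate <- aln$mat[ri, col]
  if (refstate != site$wildtype_allele)
    warning(sprintf(
      "reference state '%s' at position %d differs from declared wildtype '%s'; using the declared site definition",
      refstate, site$ref_position, site$wildtype_allele), call. = FALSE)
  ids <- aln$ids[-ri]
  obs <- aln$mat[-ri, col]
  unresolved_class <- if (aln$molecule == "nucleotide") "N" else "X"
  verdict <- ifelse(obs == site$pathogenic_allele, "pathogenic_allele",
             ifelse(obs == site$wildtype_allele, "wildtype",
             ifelse(obs %in% c("-", unresolved_class), "unresolved",
                    "other")))
  out <- data.frame(id = ids, family = NA_character_,
                    subfamily = NA_character_, tribe = NA_character_,
                    observed_state = unname(obs),
                    verdict = unname(verdict),
                    stringsAsFactors = FALSE)
  if (!is.null(aln$taxonomy)) {
    m <- match(ids, aln$taxonomy$id)
    out$family <- aln$taxonomy$family[m]
    out$subfamily <- aln$taxonomy$subfamily[m]
    out$tribe <- aln$taxonomy$tribe[m]
  }
  attr(out, "site") <- site
  class(out) <- c("cpd_calls", "data.frame")
  out
}

#' Tally CPD calls by clade
#'
#' @param calls Output of [call_cpd()].
#' @param level Taxonomy rank to group by: `"family"`, `"subfamily"` or
#'   `"tribe"`.  Records without a label at that rank fall into an
#'   `"unassigned"` bucket.
#' @return Data frame with columns `clade`, `n_pathogenic`, `n_wildtype`,
#'   `n_other`, `n_unresolved`, `n_total`; counts sum to `nrow(calls)`.
#' @export
tally_by_clade <- function(calls,
                           level = c("family", "subfamily", "tribe")) {
  level <- match.arg(level)
  key <- calls[[level]]
  key[is.na(key) | key == ""] <- "unassigned"
  verdicts <- c("pathogenic_allele", "wildtype", "other", "unresolved")
  tab <- table(factor(key), factor(calls$verdict, levels = verdicts))
  out <- data.frame(clade = rownames(tab),
                    n_pathogenic = as.integer(tab[, "pathogenic_allele"]),
                    n_wildtype = as.integer(tab[, "wildtype"]),
                    n_other = as.integer(tab[, "other"]),
                    n_unresolved = as.integer(tab[, "unresolved"]),
                    stringsAsFactors = FALSE)
  out$n_total <- out$n_pathogenic + out$n_wildtype + out$n_other +
    out$n_unresolved
  rownames(out) <- NULL
  out
}

#' Report clades fixed for the pathogenic allele
#'
#' A clade is reported as fixed when at least `fraction` of its *resolved*
#' members (gaps and N/X excluded) carry the pathogenic allele; the number
#' of resolved exceptions is listed alongside, so a clade like the old
#' world monkeys -- all pathogenic-allele carriers but a single reverted
#' species -- can be recognized at `fraction` slightly below 1 or read off
#' from the exception count at the default strict threshold.
#'
#' @param calls Output of [call_cpd()].
#' @param level Taxonomy rank, as in [tally_by_clade()].
#' @param fraction Minimum fraction of resolved members carrying the
#'   pathogenic allele (default 1, i.e. strict fixation).
#' @return Data frame with columns `clade`, `n_pathogenic`, `n_resolved`,
#'   `fraction_pathogenic`, `n_exceptions`, `fixed`.
#' @export
fixed_clades <- function(calls, level = c("family", "subfamily", "tribe"),
                         fraction = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  tally <- tally_by_clade(calls, level)
  n_res <- tally$n_pathogenic + tally$n_wildtype + tally$n_other
  frac <- ifelse(n_res > 0, tally$n_pathogenic / n_res, NA_real_)
  data.frame(clade = tally$clade,
             n_pathogenic = tally$n_pathogenic,
             n_resolved = n_res,
             fraction_pathogenic = frac,
             n_exceptions = n_res - tally$n_pathogenic,
             fixed = !is.na(frac) & frac >= fraction,
             stringsAsFactors = FALSE)
}

#' Watson-Crick pairing status of two nucleotide states
#'
#' Strict Watson-Crick complementarity (A-T/U, G-C); G.U wobble counts as
#' non-Watson-Crick.  Gap or N states give `"unresolved"`.  In the human
#' 12S rRNA decoding site, positions m.1494 and m.1555 face each other:
#' the wild-type pair C-A lacks the Watson-Crick bond and either
#' pathogenic transition (m.1494C>T or m.1555A>G) rebuilds it, making the
#' site more bacterial-like and aminoglycoside-binding.
#'
#' @param state_a,state_b Single nucleotide characters (vectors recycle
#'   elementwise); `U` is equated with `T`, case-insensitive.
#' @return Character vector over `"watson_crick"`, `"non_watson_crick"`,
#'   `"unresolved"`.
#' @export
#' @examples
#' wc_pair_status("C", "A")  # non_watson_crick (human wild type)
#' wc_pair_status("T", "A")  # watson_crick (m.1494C>T)
wc_pair_status <- function(state_a, state_b) {
  norm <- function(x) {
    x <- toupper(as.character(x))
    x[x == "U"] <- "T"
    x
  }
  a <- norm(state_a)
  b <- norm(state_b)
  pairs <- c(A = "T", T = "A", G = "C", C = "G")
  mapply(function(ai, bi) {
    if (!(ai %in% names(pairs)) || !(bi %in% names(pairs)))
      return("unresolved")
    if (pairs[[ai]] == bi) "watson_crick" else "non_watson_crick"
  }, a, b, USE.NAMES = FALSE)
}

#' Pairing status of two reference positions across an alignment
#'
#' Convenience wrapper: maps two reference positions (e.g. 1494 and 1555)
#' to their columns and reports each record's [wc_pair_status()].
#'
#' @param aln A [cpd_alignment] (nucleotide).
#' @param pos_a,pos_b 1-based reference positions, distinct.
#' @return Data frame with `id`, `state_a`, `state_b`, `status`.
#' @export
site_pair_status <- function(aln, pos_a, pos_b) {
  stopifnot(inherits(aln, "cpd_alignment"),
            aln$molecule == "nucleotide")
  if (pos_a == pos_b) stop("the two positions must differ")
  sa <- column_states(aln, map_reference_position(aln, pos_a))
  sb <- column_states(aln, map_reference_position(aln, pos_b))
  data.frame(id = names(sa), state_a = unname(sa), state_b = unname(sb),
             status = wc_pair_status(sa, sb), stringsAsFactors = FALSE)
}
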