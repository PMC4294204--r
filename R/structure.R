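# Atomic-coordinate handling: PDB parsing (via bio3d), sequence-based
# equivalence between query numbering and structure residue numbering,
# and minimum inter-atomic distances for contact filtering.

#' Construct a structure model from an atom table
#'
#' Low-level constructor; most users will call [read_structure()].
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`,
#'   `elety` (atom name), `element`, `x`, `y`, `z` (coordinates in
#'   Angstrom).  Missing `element` is derived from the first letter of
#'   `elety`.
#' @return Object of class `"structure_model"`.
#' @export
structure_model <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"element" %in% names(atoms) || all(is.na(atoms$element)))
    atoms$element <- NA_character_
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "", atoms$elety), 1, 1))
  atoms$element <- ifelse(is.na(atoms$element) | atoms$element == "",
                          guess, toupper(trimws(atoms$element)))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  structure(list(atoms = atoms), class = "structure_model")
}

#' Read a PDB coordinate file
#'
#' Parses ATOM/HETATM records of one model from a fixed-column PDB file
#' (wwPDB v3.3 layout) through [bio3d::read.pdb()].  Alternate locations
#' are resolved by keeping the highest-occupancy altloc of each
#' (chain, residue, atom name); waters are excluded by default.
#'
#' @param path Path to the PDB file.
#' @param model 1-based model index (for multi-model files; default 1).
#' @param keep_water Keep water residues (HOH/WAT/DOD)?  Default `FALSE`.
#' @return A [structure_model()] with the selected model's atoms; the
#'   number of models is attached as `$n_models`.
#' @export
read_structure <- function(path, model = 1, keep_water = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e)
      stop("PDB parse error in ", path, ": ", conditionMessage(e),
           call. = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0) stop("PDB parse error: no ATOM/HETATM records")
  n_models <- nrow(pdb$xyz)
  model <- as.integer(model)
  if (is.na(model) || model < 1 || model > n_models)
    stop(sprintf("range error: model %s not present (%d model(s))",
                 model, n_models))
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  if (!keep_water)
    at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  # altloc resolution: highest occupancy wins, ties to the first record
  occ <- if ("o" %in% names(at)) ifelse(is.na(at$o), 1, at$o)
         else rep(1, nrow(at))
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -occ)
  at <- at[ord[!duplicated(key[ord])], , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  out <- structure_model(data.frame(
    chain = at$chain, resno = at$resno, resid = at$resid,
    elety = at$elety,
    element = if ("elesy" %in% names(at)) at$elesy else NA_character_,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
  out$n_models <- n_models
  out$model <- model
  out
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d chain(s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain))))
  invisible(x)
}

.NUC_RESID <- c(A = "A", C = "C", G = "G", U = "T", T = "T",
                DA = "A", DC = "C", DG = "G", DT = "T", DU = "T")

#' One-letter sequence of a structure chain
#'
#' Derives the residue sequence of a chain, in order of appearance, with
#' the parallel author residue numbers.  Protein three-letter codes are
#' translated via [bio3d::aa321()]; nucleotide residues (A/C/G/U/T and
#' deoxy forms) map to one-letter codes with U equated to T; anything else
#' becomes `X`.
#'
#' @param model A [structure_model].
#' @param chain Chain identifier.
#' @return List with `seq` (single string), `resno` (integer vector) and
#'   `molecule` (best guess, `"protein"` or `"nucleotide"`).
#' @export
chain_sequence <- function(model, chain) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("selection error: no atoms in chain ", chain)
  first <- !duplicated(at$resno)
  resno <- at$resno[first]
  resid <- toupper(trimws(at$resid[first]))
  letters1 <- ifelse(resid %in% names(.NUC_RESID),
                     unname(.NUC_RESID[resid]),
                     suppressWarnings(bio3d::aa321(resid)))
  letters1[is.na(letters1) | !(letters1 %in% c(.AA_CORE, "X"))] <- "X"
  molecule <- if (mean(resid %in% names(.NUC_RESID)) > 0.5)
    "nucleotide" else "protein"
  list(seq = paste(letters1, collapse = ""), resno = resno,
       molecule = molecule)
}

#' Map query numbering onto structure residue numbers
#'
#' Establishes the equivalence between positions of a query sequence
#' (human 12S rRNA or MRPS12 numbering) and residue numbers of a structure
#' chain, either from a user-supplied table (which overrides alignment
#' entirely) or by global pairwise alignment (match +1, mismatch -1, gap
#' opening 5, gap extension 1) with pairs taken at aligned non-gap columns.
#'
#' @param query_seq Ungapped query sequence (single string).
#' @param struct_seq Structure chain sequence (single string), e.g. from
#'   [chain_sequence()].
#' @param struct_resno Integer vector of residue numbers parallel to
#'   `struct_seq` (default `1..nchar`).
#' @param chain Chain id recorded in the map.
#' @param table Optional data frame `query_pos`, `chain`, `resno`; when
#'   given it is validated and returned as the map.
#' @param min_coverage Minimum fraction of query positions that must be
#'   mapped (default 0.5); below it, a low-confidence error is raised.
#' @return Data frame of class `"equivalence_map"` with columns
#'   `query_pos`, `chain`, `resno`; attribute `"method"` is
#'   `"alignment"` or `"table"`.
#' @export
build_equivalence <- function(query_seq, struct_seq,
                              struct_resno = NULL, chain = NA_character_,
                              table = NULL, min_coverage = 0.5) {
  if (!is.null(table)) {
    table <- as.data.frame(table, stringsAsFactors = FALSE)
    need <- c("query_pos", "chain", "resno")
    if (!all(need %in% names(table)))
      stop("equivalence table needs columns: ",
           paste(need, collapse = ", "))
    if (anyDuplicated(table$query_pos) ||
        anyDuplicated(paste(table$chain, table$resno)))
      stop("equivalence table must be injective")
    out <- table[, need]
    class(out) <- c("equivalence_map", "data.frame")
    attr(out, "method") <- "table"
    return(out)
  }
  stopifnot(is.character(query_seq), length(query_seq) == 1,
            is.character(struct_seq), length(struct_seq) == 1,
            nchar(query_seq) > 0, nchar(struct_seq) > 0)
  if (is.null(struct_resno)) struct_resno <- seq_len(nchar(struct_seq))
  stopifnot(length(struct_resno) == nchar(struct_seq))
  q <- toupper(query_seq)
  s <- toupper(struct_seq)
  alphabet <- sort(unique(strsplit(paste0(q, s), "")[[1]]))
  m <- matrix(-1, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- 1
  pa <- Biostrings::pairwiseAlignment(q, s, substitutionMatrix = m,
                                      gapOpening = 5, gapExtension = 1,
                                      type = "global")
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qi <- 0L; si <- 0L
  qp <- integer(0); sp <- integer(0)
  for (k in seq_along(qa)) {
    if (qa[k] != "-") qi <- qi + 1L
    if (sa[k] != "-") si <- si + 1L
    if (qa[k] != "-" && sa[k] != "-") {
      qp <- c(qp, qi); sp <- c(sp, si)
    }
  }
  coverage <- length(qp) / nchar(q)
  if (coverage < min_coverage)
    stop(sprintf(
      "low-confidence error: alignment covers %.0f%% of the query (< %.0f%%)",
      100 * coverage, 100 * min_coverage))
  out <- data.frame(query_pos = qp, chain = chain,
                    resno = struct_resno[sp], stringsAsFactors = FALSE)
  class(out) <- c("equivalence_map", "data.frame")
  attr(out, "method") <- "alignment"
  out
}

#' Read an equivalence table
#'
#' @param path TSV with columns `query_pos`, `chain`, `resno`.
#' @return An `"equivalence_map"` data frame (method `"table"`).
#' @export
read_equivalence_tsv <- function(path) {
  build_equivalence(table = utils::read.delim(path,
                                              stringsAsFactors = FALSE))
}

select_atoms <- function(model, sel, atom_class) {
  at <- model$atoms
  keep <- at$chain == sel$chain & at$resno %in% sel$resno
  if (atom_class == "heavy")
    keep <- keep & !(at$element %in% c("H", "D"))
  which(keep)
}

#' Minimum inter-atomic distance between two residue selections
#'
#' Minimum Euclidean distance over all atom pairs between two selections,
#' in Angstrom.  The default atom class is `"heavy"` (hydrogens and
#' deuteriums excluded, as in crystal structures without modeled
#' hydrogens).
#'
#' @param model A [structure_model].
#' @param sel_a,sel_b Selections: lists with `chain` (single id) and
#'   `resno` (one or more residue numbers).  The two selections must
#'   differ.
#' @param atom_class `"heavy"` (default) or `"all"`.
#' @return Minimum distance in Angstrom.
#' @export
min_distance <- function(model, sel_a, sel_b,
                         atom_class = c("heavy", "all")) {
  stopifnot(inherits(model, "structure_model"))
  atom_class <- match.arg(atom_class)
  ia <- select_atoms(model, sel_a, atom_class)
  ib <- select_atoms(model, sel_b, atom_class)
  if (length(ia) == 0)
    stop("selection error: sel_a matches no atoms")
  if (length(ib) == 0)
    stop("selection error: sel_b matches no atoms")
  if (setequal(ia, ib))
    stop("selection error: sel_a and sel_b are the same selection")
  A <- as.matrix(model$atoms[ia, c("x", "y", "z")])
  B <- as.matrix(model$atoms[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(min(d2), 0))
}

#' Filter candidate positions by proximity to a target site
#'
#' For each candidate query position, maps it to a structure residue
#' through `map_protein`, computes the minimum heavy-atom distance to the
#' residue that the target nucleotide position maps to through `map_rna`,
#' and reports whether it falls strictly within the threshold.  Candidates
#' missing from the map are reported as `unresolved`, never dropped.
#'
#' @param model A [structure_model].
#' @param candidates Integer vector of candidate query positions (protein
#'   numbering).
#' @param site Query position of the target nucleotide (rRNA numbering).
#' @param map_protein,map_rna [build_equivalence()] maps for the protein
#'   and rRNA chains.
#' @param threshold_A Distance threshold in Angstrom; the verdict is
#'   strict (`min_distance < threshold_A`).  Default 6.
#' @param atom_class `"heavy"` (default) or `"all"`.
#' @return Data frame with `candidate`, `chain`, `resno`,
#'   `min_distance_A`, `threshold_A`, `within_threshold`, `verdict`
#'   (`"within"`, `"outside"` or `"unresolved"`).
#' @export
proximity_filter <- function(model, candidates, site, map_protein,
                             map_rna, threshold_A = 6,
                             atom_class = c("heavy", "all")) {
  atom_class <- match.arg(atom_class)
  stopifnot(threshold_A >= 0)
  srow <- map_rna[map_rna$query_pos == site, , drop = FALSE]
  if (nrow(srow) == 0)
    stop("mapping error: site position ", site,
         " not present in the rRNA equivalence map")
  sel_site <- list(chain = srow$chain[1], resno = srow$resno[1])
  rows <- lapply(candidates, function(cand) {
    prow <- map_protein[map_protein$query_pos == cand, , drop = FALSE]
    if (nrow(prow) == 0)
      return(data.frame(candidate = cand, chain = NA_character_,
                        resno = NA_integer_, min_distance_A = NA_real_,
                        threshold_A = threshold_A,
                        within_threshold = NA, verdict = "unresolved",
                        stringsAsFactors = FALSE))
    d <- min_distance(model,
                      list(chain = prow$chain[1], resno = prow$resno[1]),
                      sel_site, atom_class)
    data.frame(candidate = cand, chain = prow$chain[1],
               resno = prow$resno[1], min_distance_A = d,
               threshold_A = threshold_A,
               within_threshold = d < threshold_A,
               verdict = if (d < threshold_A) "within" else "outside",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
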