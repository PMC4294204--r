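# Aligned-sequence container and reference-coordinate mapping.
#
# Coordinates are 1-based and closed throughout: rCRS position m.1494 means
# the 1494th ungapped base of the human reference row.

.NUC_CORE <- c("A", "C", "G", "T")
.NUC_OK <- c(.NUC_CORE, "N", "-")
.NUC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
.AA_CORE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_OK <- c(.AA_CORE, "X", "-")
.AA_AMBIG <- c("B", "Z", "J", "U", "O")

# Uppercases, equates U with T (nucleotide), collapses ambiguity codes to
# the molecule's single unresolved class (N or X) with one warning.
normalize_chars <- function(chars, molecule) {
  chars <- toupper(chars)
  if (molecule == "nucleotide") {
    chars[chars == "U"] <- "T"
    ambig <- chars %in% .NUC_AMBIG
    unresolved <- "N"
    ok <- .NUC_OK
  } else {
    ambig <- chars %in% .AA_AMBIG
    unresolved <- "X"
    ok <- .AA_OK
  }
  if (any(ambig)) {
    warning(sprintf("replaced %d ambiguity character(s) (%s) with %s",
                    sum(ambig),
                    paste(sort(unique(chars[ambig])), collapse = ","),
                    unresolved), call. = FALSE)
    chars[ambig] <- unresolved
  }
  chars[chars == "."] <- "-"
  bad <- !(chars %in% ok)
  if (any(bad)) {
    stop(sprintf("invalid %s character(s): %s", molecule,
                 paste(sort(unique(chars[bad])), collapse = ",")),
         call. = FALSE)
  }
  chars
}

#' Construct a validated alignment object
#'
#' Low-level constructor for the alignment container used throughout the
#' package.  Most users will call [read_fasta_alignment()]; this constructor
#' is useful for building fixtures in code and is what the synthetic
#' generator ([make_alignment()]) returns through.
#'
#' @param ids Character vector of taxon identifiers, one per record, unique.
#' @param seqs Character vector of gapped sequences (strings), parallel to
#'   `ids`, all of the same length.  `U` is equated with `T` for nucleotide
#'   alignments; ambiguity codes beyond `N`/`X` are collapsed with a warning.
#' @param reference_id Identifier of the human reference row; must occur
#'   exactly once in `ids`.
#' @param molecule `"nucleotide"` or `"protein"`.
#' @param taxonomy Optional data frame with columns `id`, `family`,
#'   `subfamily`, `tribe` carrying free-form clade labels.
#'
#' @return An object of class `"cpd_alignment"`: a list with elements
#'   `ids`, `mat` (character matrix, one row per record), `molecule`,
#'   `reference_id` and `taxonomy`.
#' @export
#' @examples
#' aln <- cpd_alignment(c("Homo_sapiens", "sp1", "sp2"),
#'                      c("AC-GT", "ACAGT", "ACA-T"),
#'                      reference_id = "Homo_sapiens")
#' alignment_length(aln)
cpd_alignment <- function(ids, seqs, reference_id,
                          molecule = c("nucleotide", "protein"),
                          taxonomy = NULL) {
  molecule <- match.arg(molecule)
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (anyDuplicated(ids))
    stop("duplicated taxon identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ","))
  if (length(ids) < 2)
    stop("an alignment needs at least 2 records")
  if (sum(ids == reference_id) != 1)
    stop(sprintf("reference id '%s' must be present exactly once",
                 reference_id))
  n <- nchar(seqs)
  if (length(unique(n)) != 1)
    stop(sprintf("alignment-shape error: ragged record lengths (%s)",
                 paste(sort(unique(n)), collapse = ",")))
  if (n[1] < 1) stop("alignment has zero columns")
  mat <- matrix(normalize_chars(unlist(strsplit(seqs, "", fixed = TRUE)),
                                molecule),
                nrow = length(ids), byrow = TRUE,
                dimnames = list(ids, NULL))
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
    if (!"id" %in% names(taxonomy))
      stop("taxonomy table needs an 'id' column")
    for (col in c("family", "subfamily", "tribe"))
      if (!col %in% names(taxonomy)) taxonomy[[col]] <- NA_character_
    taxonomy <- taxonomy[, c("id", "family", "subfamily", "tribe")]
  }
  structure(list(ids = ids, mat = mat, molecule = molecule,
                 reference_id = reference_id, taxonomy = taxonomy),
            class = "cpd_alignment")
}

#' Read an aligned FASTA file with a designated reference row
#'
#' Parses an aligned (equal-length, gapped) FASTA file.  Sequences are
#' uppercased, `U` is equated with `T` for nucleotide alignments, and
#' ambiguity codes other than `N` (`X` for protein) are collapsed to the
#' unresolved class with a warning.  Clade labels may ride along either in
#' the FASTA headers, pipe-delimited after the identifier
#' (`>Macaca_mulatta|Cercopithecidae|Cercopithecinae|Papionini`), or in a
#' sidecar TSV passed as `taxonomy`.
#'
#' @param path Path to the aligned FASTA file.
#' @param reference_id Identifier of the human reference row.
#' @param molecule `"nucleotide"` or `"protein"`.
#' @param taxonomy Optional path to a TSV with columns
#'   `id`, `family`, `subfamily`, `tribe`, or a data frame of the same
#'   shape.  Header-derived labels are used when no sidecar is given.
#'
#' @return A [cpd_alignment] object.
#' @seealso [write_fasta_alignment()], [map_reference_position()]
#' @export
read_fasta_alignment <- function(path, reference_id,
                                 molecule = c("nucleotide", "protein"),
                                 taxonomy = NULL) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e)
                   stop("FASTA format error in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (length(ss) == 0) stop("FASTA format error: no records in ", path)
  headers <- names(ss)
  fields <- strsplit(headers, "|", fixed = TRUE)
  ids <- trimws(vapply(fields, `[`, "", 1))
  # first whitespace-delimited token is the id when no pipes are used
  ids <- vapply(strsplit(ids, "[ \t]+"), `[`, "", 1)
  tax <- NULL
  if (is.null(taxonomy) && any(lengths(fields) > 1)) {
    lab <- function(i) {
      x <- trimws(vapply(fields, function(f)
        if (length(f) >= i) f[i] else NA_character_, ""))
      x[x == ""] <- NA_character_
      x
    }
    tax <- data.frame(id = ids, family = lab(2), subfamily = lab(3),
                      tribe = lab(4), stringsAsFactors = FALSE)
  } else if (is.character(taxonomy)) {
    tax <- read_taxonomy_tsv(taxonomy)
  } else if (is.data.frame(taxonomy)) {
    tax <- taxonomy
  }
  cpd_alignment(ids, as.character(ss), reference_id, molecule,
                taxonomy = tax)
}

#' Write an alignment back to FASTA
#'
#' Inverse of [read_fasta_alignment()]: re-reading the written file yields
#' an identical alignment (sequences are already normalized).  Clade labels,
#' when present, are written pipe-delimited in the headers.
#'
#' @param aln A [cpd_alignment].
#' @param path Output file path.
#' @param width Sequence line width (default one line per record).
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, width = Inf) {
  stopifnot(inherits(aln, "cpd_alignment"))
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  headers <- aln$ids
  if (!is.null(aln$taxonomy)) {
    tx <- aln$taxonomy[match(aln$ids, aln$taxonomy$id), ]
    lab <- function(x) ifelse(is.na(x), "", x)
    full <- paste(aln$ids, lab(tx$family), lab(tx$subfamily),
                  lab(tx$tribe), sep = "|")
    full <- sub("\\|+$", "", full)
    headers <- full
  }
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", headers[i]), con)
    s <- seqs[i]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
                 con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' @export
print.cpd_alignment <- function(x, ...) {
  cat(sprintf("<cpd_alignment> %d records x %d columns (%s)\n",
              length(x$ids), ncol(x$mat), x$molecule))
  cat(sprintf("  reference: %s (%d ungapped positions)\n",
              x$reference_id, ungapped_reference_length(x)))
  if (!is.null(x$taxonomy)) cat("  taxonomy: attached\n")
  invisible(x)
}

reference_index <- function(aln) match(aln$reference_id, aln$ids)

reference_row <- function(aln) aln$mat[reference_index(aln), ]

#' Alignment dimensions
#'
#' @param aln A [cpd_alignment].
#' @return `alignment_length()`: the number of columns;
#'   `n_records()`: the number of records (including the reference row);
#'   `ungapped_reference_length()`: the number of non-gap characters in the
#'   reference row, i.e. the maximum mappable reference position.
#' @export
alignment_length <- function(aln) ncol(aln$mat)

#' @rdname alignment_length
#' @export
n_records <- function(aln) nrow(aln$mat)

#' @rdname alignment_length
#' @export
ungapped_reference_length <- function(aln) sum(reference_row(aln) != "-")

#' Map reference positions to alignment columns
#'
#' Converts 1-based ungapped positions of the reference row (rCRS numbering
#' for mtDNA, mature/precursor numbering for a protein) to 1-based alignment
#' columns.  The mapping is a strictly increasing bijection between
#' ungapped reference positions and the reference row's non-gap columns.
#'
#' @param aln A [cpd_alignment].
#' @param ref_pos Integer vector of 1-based ungapped reference positions.
#' @return Integer vector of 1-based alignment columns.
#' @export
#' @examples
#' aln <- cpd_alignment(c("hs", "sp"), c("A--C", "ACGC"), "hs")
#' map_reference_position(aln, 2)  # 4
map_reference_position <- function(aln, ref_pos) {
  stopifnot(inherits(aln, "cpd_alignment"))
  ref_pos <- as.integer(ref_pos)
  nz <- which(reference_row(aln) != "-")
  if (any(is.na(ref_pos)) || any(ref_pos < 1) || any(ref_pos > length(nz)))
    stop(sprintf(
      "range error: reference position outside 1..%d (ungapped length)",
      length(nz)))
  nz[ref_pos]
}

#' Character states of one alignment column
#'
#' @param aln A [cpd_alignment].
#' @param column 1-based alignment column.
#' @return Named character vector, one single-character state per record
#'   (gaps as `"-"`), named by taxon id.
#' @export
column_states <- function(aln, column) {
  stopifnot(inherits(aln, "cpd_alignment"))
  column <- as.integer(column)
  if (length(column) != 1 || is.na(column) || column < 1 ||
      column > ncol(aln$mat))
    stop(sprintf("range error: column outside 1..%d", ncol(aln$mat)))
  stats::setNames(aln$mat[, column], aln$ids)
}

#' Read a taxonomy sidecar table
#'
#' @param path TSV with columns `id`, `family`, `subfamily`, `tribe`
#'   (missing rank columns are filled with `NA`).
#' @return Data frame with those four columns.
#' @export
read_taxonomy_tsv <- function(path) {
  tx <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(tx)) stop("taxonomy table needs an 'id' column")
  for (col in c("family", "subfamily", "tribe"))
    if (!col %in% names(tx)) tx[[col]] <- NA_character_
  tx[, c("id", "family", "subfamily", "tribe")]
}
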