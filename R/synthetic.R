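# Generators for synthetic alignments, dated trees with tip states, and
# toy PDB files with exactly specified composition/geometry.  Every
# generator is a bit-reproducible function of (spec, seed) and draws from
# its own seeded stream, leaving the caller's RNG state untouched.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate an alignment with specified per-column composition
#'
#' Builds an alignment of `n_records` non-reference records plus one
#' reference row.  Columns listed in `column_specs` reproduce exactly the
#' requested counts of wild-type matches, non-matching states and gaps;
#' all other columns are drawn i.i.d., each record matching the reference
#' with probability `match_prob`, otherwise carrying a uniformly chosen
#' non-wild-type character.  Deterministic given `seed`.
#'
#' @param spec A list with fields:
#'   \describe{
#'     \item{n_records}{number of non-reference records.}
#'     \item{length}{alignment length (reference is ungapped).}
#'     \item{seed}{integer seed (required).}
#'     \item{reference}{optional reference sequence string; drawn
#'       uniformly from the core alphabet when absent.}
#'     \item{column_specs}{optional data frame with columns
#'       `ref_position`, `wildtype`, `n_match` and optionally `n_other`,
#'       `n_gap` (defaults: `n_gap = 0`,
#'       `n_other = n_records - n_match - n_gap`); per column the three
#'       counts must sum to `n_records`.  The reference is set to
#'       `wildtype` at these positions.}
#'     \item{taxonomy}{optional data frame `family`, `subfamily`, `tribe`,
#'       `n` whose `n` sum to `n_records`; record ids and clade labels are
#'       generated clade-block by clade-block, in order.}
#'     \item{molecule}{`"nucleotide"` (default) or `"protein"`.}
#'     \item{reference_id}{default `"Homo_sapiens"`.}
#'     \item{match_prob}{match probability of unspecified columns
#'       (default 0.9).}
#'     \item{ordered}{if `TRUE`, specified columns assign match/other/gap
#'       in record order (first `n_match` records match, then `n_other`,
#'       then gaps) instead of at random; useful to line counts up with
#'       taxonomy blocks.  Default `FALSE`.}
#'   }
#' @return A [cpd_alignment].
#' @export
#' @examples
#' aln <- make_alignment(list(n_records = 608, length = 20, seed = 1,
#'   column_specs = data.frame(ref_position = 5, wildtype = "C",
#'                             n_match = 544)))
#' round(conservation_index(aln, 5)$ci, 1)  # 89.5
make_alignment <- function(spec) {
  molecule <- if (is.null(spec$molecule)) "nucleotide" else spec$molecule
  core <- if (molecule == "nucleotide") .NUC_CORE else .AA_CORE
  n <- spec$n_records
  len <- spec$length
  if (is.null(n) || is.null(len) || is.null(spec$seed))
    stop("spec error: n_records, length and seed are required")
  if (n < 1 || len < 1) stop("spec error: n_records and length must be >= 1")
  reference_id <- if (is.null(spec$reference_id)) "Homo_sapiens"
                  else spec$reference_id
  match_prob <- if (is.null(spec$match_prob)) 0.9 else spec$match_prob
  ordered <- isTRUE(spec$ordered)
  cs <- spec$column_specs
  if (!is.null(cs)) {
    cs <- as.data.frame(cs, stringsAsFactors = FALSE)
    if (!all(c("ref_position", "wildtype", "n_match") %in% names(cs)))
      stop("spec error: column_specs needs ref_position, wildtype, n_match")
    if (!"n_gap" %in% names(cs)) cs$n_gap <- 0L
    if (!"n_other" %in% names(cs))
      cs$n_other <- n - cs$n_match - cs$n_gap
    if (any(cs$ref_position < 1 | cs$ref_position > len))
      stop("spec error: column position outside the alignment length")
    if (anyDuplicated(cs$ref_position))
      stop("spec error: duplicated column positions")
    if (any(cs$n_match < 0 | cs$n_other < 0 | cs$n_gap < 0) ||
        any(cs$n_match + cs$n_other + cs$n_gap != n))
      stop("spec error: per-column counts must be non-negative and sum to n_records")
  }
  tax <- NULL
  ids <- NULL
  if (!is.null(spec$taxonomy)) {
    tx <- as.data.frame(spec$taxonomy, stringsAsFactors = FALSE)
    if (!all(c("family", "n") %in% names(tx)))
      stop("spec error: taxonomy needs columns family, n")
    if (sum(tx$n) != n)
      stop("spec error: taxonomy record counts must sum to n_records")
    for (col in c("subfamily", "tribe"))
      if (!col %in% names(tx)) tx[[col]] <- NA_character_
    ids <- unlist(lapply(seq_len(nrow(tx)), function(i)
      sprintf("%s_sp%03d", tx$family[i], seq_len(tx$n[i]))))
    tax <- data.frame(id = ids,
                      family = rep(tx$family, tx$n),
                      subfamily = rep(tx$subfamily, tx$n),
                      tribe = rep(tx$tribe, tx$n),
                      stringsAsFactors = FALSE)
  } else {
    ids <- sprintf("sp%04d", seq_len(n))
  }
  with_seed(spec$seed, {
    ref <- if (!is.null(spec$reference)) {
      r <- normalize_chars(strsplit(toupper(spec$reference), "")[[1]],
                           molecule)
      if (length(r) != len)
        stop("spec error: reference length differs from spec length")
      r
    } else {
      sample(core, len, replace = TRUE)
    }
    if (!is.null(cs)) ref[cs$ref_position] <- toupper(cs$wildtype)
    mat <- matrix("", nrow = n, ncol = len)
    spec_cols <- if (is.null(cs)) integer(0) else cs$ref_position
    for (j in seq_len(len)) {
      wt <- ref[j]
      others <- setdiff(core, wt)
      if (j %in% spec_cols) {
        row <- cs[cs$ref_position == j, ]
        status <- rep(c("m", "o", "g"),
                      c(row$n_match, row$n_other, row$n_gap))
        if (!ordered) status <- sample(status)
        col <- character(n)
        col[status == "m"] <- wt
        col[status == "o"] <- sample(others, sum(status == "o"),
                                     replace = TRUE)
        col[status == "g"] <- "-"
        mat[, j] <- col
      } else {
        hit <- stats::runif(n) < match_prob
        col <- rep(wt, n)
        col[!hit] <- sample(others, sum(!hit), replace = TRUE)
        mat[, j] <- col
      }
    }
    seqs <- apply(mat, 1, paste, collapse = "")
    suppressWarnings(
      cpd_alignment(c(reference_id, ids),
                    c(paste(ref, collapse = ""), seqs),
                    reference_id, molecule, taxonomy = tax))
  })
}

# ---- dated trees --------------------------------------------------------

validate_clade_spec <- function(node, parent_age) {
  if (is.character(node)) return(invisible(TRUE))
  if (is.null(node$age) || is.null(node$children) ||
      length(node$children) < 2)
    stop("spec error: internal clade needs an age and >= 2 children")
  if (!is.null(parent_age) && node$age >= parent_age)
    stop(sprintf("spec error: age inversion at clade '%s' (%s >= %s)",
                 if (is.null(node$name)) "?" else node$name,
                 node$age, parent_age))
  for (ch in node$children) validate_clade_spec(ch, node$age)
  invisible(TRUE)
}

clade_newick <- function(node, parent_age, membership, path) {
  if (is.character(node)) {
    membership[[node]] <- path
    return(list(str = sprintf("%s:%.10g", node, parent_age),
                membership = membership))
  }
  path2 <- c(path, node$name)
  parts <- character(0)
  for (ch in node$children) {
    r <- clade_newick(ch, node$age, membership, path2)
    parts <- c(parts, r$str)
    membership <- r$membership
  }
  bl <- if (is.null(parent_age)) ""
        else sprintf(":%.10g", parent_age - node$age)
  nm <- if (is.null(node$name)) "" else node$name
  list(str = sprintf("(%s)%s%s", paste(parts, collapse = ","), nm, bl),
       membership = membership)
}

#' Generate a dated tree with clade-structured tip states
#'
#' Builds an ultrametric tree from a nested clade specification whose
#' named internal nodes carry exactly the requested crown ages (in Mya),
#' then assigns one or more binary characters to the tips by clade rule.
#'
#' @param spec A list with fields:
#'   \describe{
#'     \item{clades}{nested description of the tree: an internal node is
#'       `list(name =, age =, children = list(...))`, a tip is its label
#'       (a character string).}
#'     \item{states}{optional named list of character rules; each rule is
#'       `list(derived =, unknown =, exceptions =)` where `derived` and
#'       `unknown` name clades or tips, `exceptions` names tips whose
#'       state is flipped between derived and ancestral relative to the
#'       clade rule (a reversion), and everything else is ancestral.}
#'   }
#' @return List with `tree` (a `dated_tree`), `states` (named list of
#'   named tip-state vectors, one per character) and `newick` (the
#'   serialized tree string).
#' @export
#' @seealso [primate_tree_spec()] for a ready-made catarrhine example.
make_dated_tree <- function(spec) {
  if (is.null(spec$clades)) stop("spec error: clades field is required")
  validate_clade_spec(spec$clades, NULL)
  r <- clade_newick(spec$clades, NULL, list(), character(0))
  nwk <- paste0(r$str, ";")
  tr <- ape::read.tree(text = nwk)
  tree <- read_dated_newick(tr)
  membership <- r$membership   # tip -> vector of enclosing clade names
  tips <- names(membership)
  in_group <- function(tip, groups)
    tip %in% groups || any(membership[[tip]] %in% groups)
  states <- NULL
  if (!is.null(spec$states)) {
    states <- lapply(spec$states, function(rule) {
      st <- stats::setNames(rep("ancestral", length(tips)), tips)
      if (!is.null(rule$derived))
        st[vapply(tips, in_group, logical(1), groups = rule$derived)] <-
          "derived"
      if (!is.null(rule$unknown))
        st[vapply(tips, in_group, logical(1), groups = rule$unknown)] <-
          "unknown"
      for (ex in rule$exceptions) {
        if (!ex %in% tips) stop("spec error: exception tip not found: ", ex)
        st[ex] <- if (st[ex] == "derived") "ancestral" else "derived"
      }
      st
    })
  }
  list(tree = tree, states = states, newick = nwk)
}

#' Catarrhine tree specification with the published divergence times
#'
#' A ready-made [make_dated_tree()] specification for the hominoid / old
#' world monkey phylogeny used for fixation dating: Hominoidea and
#' Cercopithecoidea split 32 Mya, the Cercopithecidae crown is 18 Mya,
#' Cercopithecini and Papionini split 12 Mya and the Papionini crown is
#' 8 Mya.  Two characters are predefined: `mt1494T` (the 12S rRNA
#' pathogenic allele, derived in all Cercopithecidae with a
#' *Papio ursinus* reversion) and `mrps12_L68` (the candidate
#' compensatory protein allele, derived in Papionini only).
#'
#' @param colobinae_unknown Mark the Colobinae tips unknown for
#'   `mrps12_L68` (unsampled subfamily) instead of ancestral.
#'   Default `FALSE`.
#' @return A spec list for [make_dated_tree()].
#' @export
#' @examples
#' tt <- make_dated_tree(primate_tree_spec())
#' fixation_interval(tt$tree, tt$states$mt1494T, max_losses = 1)
primate_tree_spec <- function(colobinae_unknown = FALSE) {
  spec <- list(
    clades = list(name = "Catarrhini", age = 32, children = list(
      list(name = "Hominoidea", age = 20, children = list(
        "Pongo_pygmaeus",
        list(name = "Homininae", age = 8, children = list(
          "Homo_sapiens", "Pan_troglodytes"))
      )),
      list(name = "Cercopithecidae", age = 18, children = list(
        list(name = "Colobinae", age = 13, children = list(
          "Colobus_guereza", "Trachypithecus_obscurus")),
        list(name = "Cercopithecinae", age = 12, children = list(
          list(name = "Cercopithecini", age = 9, children = list(
            "Chlorocebus_sabaeus", "Erythrocebus_patas")),
          list(name = "Papionini", age = 8, children = list(
            "Papio_ursinus",
            list(name = "Macaca", age = 5, children = list(
              "Macaca_nemestrina", "Macaca_mulatta"))))
        ))
      ))
    )),
    states = list(
      mt1494T = list(derived = "Cercopithecidae",
                     exceptions = "Papio_ursinus"),
      mrps12_L68 = list(derived = "Papionini")
    )
  )
  if (colobinae_unknown)
    spec$states$mrps12_L68$unknown <- "Colobinae"
  spec
}

# ---- toy structures -----------------------------------------------------

format_atom_record <- function(serial, name, resid, chain, resno,
                               x, y, z, element) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resid, chain, resno, x, y, z, 1.00, 0.00, element)
}

#' Generate a toy PDB file with declared minimum distances
#'
#' Emits a PDB-format coordinate file containing a target "site" residue
#' with fixed atom coordinates and a set of candidate residues, each
#' placed so that its minimum inter-atomic distance to the site equals the
#' declared distance (the closest atom sits exactly at that radius, any
#' further atoms strictly beyond it, all along an outward ray so no site
#' atom comes closer).  The file round-trips through [read_structure()].
#'
#' @param spec A list with fields:
#'   \describe{
#'     \item{site}{`list(chain =, resno =, resid =, coords =)` with
#'       `coords` an n x 3 matrix (default a single atom at the origin,
#'       chain `"R"`, resno 1, resid `"C"`).}
#'     \item{candidates}{list of `list(chain =, resno =, resid =,
#'       distance =, n_atoms =)`; `distance` in Angstrom (>= 0),
#'       `n_atoms` defaults to 3.}
#'     \item{seed}{integer seed (required; directions are random).}
#'   }
#' @param path Output file path.
#' @return `path` invisibly, with the per-candidate declared distances
#'   attached as attribute `"distances"`.
#' @export
#' @examples
#' p <- make_structure(list(seed = 7, candidates = list(
#'   list(chain = "P", resno = 68, resid = "LEU", distance = 4))),
#'   tempfile(fileext = ".pdb"))
#' mod <- read_structure(p)
#' min_distance(mod, list(chain = "P", resno = 68),
#'              list(chain = "R", resno = 1))  # 4
make_structure <- function(spec, path) {
  if (is.null(spec$seed)) stop("spec error: seed is required")
  site <- spec$site
  if (is.null(site)) site <- list()
  if (is.null(site$chain)) site$chain <- "R"
  if (is.null(site$resno)) site$resno <- 1L
  if (is.null(site$resid)) site$resid <- "C"
  if (is.null(site$coords)) site$coords <- matrix(0, 1, 3)
  sc <- matrix(as.numeric(site$coords), ncol = 3)
  cands <- spec$candidates
  if (is.null(cands) || length(cands) == 0)
    stop("spec error: at least one candidate is required")
  for (cd in cands) {
    if (is.null(cd$distance) || cd$distance < 0)
      stop("spec error: candidate distances must be >= 0")
    if (!is.null(cd$n_atoms) && cd$n_atoms < 1)
      stop("spec error: infeasible geometry, candidate with zero atoms")
  }
  lines <- character(0)
  serial <- 0L
  with_seed(spec$seed, {
    for (i in seq_len(nrow(sc))) {
      serial <- serial + 1L
      lines <- c(lines, format_atom_record(
        serial, sprintf("C%d", i), site$resid, site$chain,
        as.integer(site$resno), sc[i, 1], sc[i, 2], sc[i, 3], "C"))
    }
    for (cd in cands) {
      n_atoms <- if (is.null(cd$n_atoms)) 3L else as.integer(cd$n_atoms)
      resid <- if (is.null(cd$resid)) "ALA" else cd$resid
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      # extreme site atom in direction u: all other site atoms stay >= d
      base <- sc[which.max(sc %*% u), ]
      offsets <- c(0, sort(stats::runif(n_atoms - 1, 0.5, 3)))
      for (k in seq_len(n_atoms)) {
        p <- base + (cd$distance + offsets[k]) * u
        serial <- serial + 1L
        lines <- c(lines, format_atom_record(
          serial, sprintf("C%d", k), resid, cd$chain,
          as.integer(cd$resno), p[1], p[2], p[3], "C"))
      }
    }
  })
  writeLines(c(lines, "END"), path)
  dist <- vapply(cands, function(cd) cd$distance, numeric(1))
  attr(path, "distances") <- dist
  invisible(path)
}
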