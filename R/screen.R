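# Orchestration of the full screen (scan -> CI -> proximity -> dating)
# from one YAML/list config, with TSV/JSON reports.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

round1 <- function(x) round(x, 1)

#' Run the full compensated-pathogenic-deviation screen
#'
#' Chains the individually invokable stages -- CPD scan, conservation
#' indices, structural proximity, fixation dating -- from one
#' configuration, writing per-stage TSVs plus a top-level JSON summary to
#' the output directory.  The tree and structure stages are optional:
#' when their config blocks are absent they are reported as `"skipped"`.
#' Every threshold used is echoed in the summary, and reported numbers
#' carry both full precision and 1-decimal reporting values.  Runs are
#' deterministic for a fixed config, so re-running produces a
#' byte-identical summary.
#'
#' @param config Path to a YAML file, or an equivalent nested list, with
#'   blocks:
#'   \describe{
#'     \item{alignment}{`nucleotide: {path, reference_id}` and optionally
#'       `protein: {path, reference_id}`; each may carry a `taxonomy`
#'       sidecar TSV path.}
#'     \item{sites}{path to a TSV of pathogenic sites (`label`,
#'       `ref_position`, `wildtype`, `pathogenic`).}
#'     \item{rank}{taxonomy rank for tallies (default `"family"`).}
#'     \item{fixation_fraction}{clade-fixation fraction (default 1).}
#'     \item{pair}{optional `{pos_a, pos_b}` decoding-site pair for
#'       Watson-Crick status (e.g. 1494 and 1555).}
#'     \item{ci_comparison}{optional `{set_a, set_b}` of protein reference
#'       positions; their CIs are compared with the unpaired two-tailed
#'       Student t-test at `alpha` (default 0.05).}
#'     \item{tree}{optional `{path, states: {label: tsv, ...},
#'       max_losses}` for fixation dating; with two or more characters the
#'       pairwise minimum temporal gap is added.}
#'     \item{structure}{optional `{path, model, rna_chain, protein_chain,
#'       site, candidates, threshold, equivalence: {rna: tsv, protein:
#'       tsv}}`; without explicit equivalence tables the maps are built by
#'       pairwise alignment of the reference sequences against the chain
#'       sequences.}
#'     \item{out_dir}{output directory (required).}
#'   }
#' @return The summary list, invisibly; side effect: TSV/JSON files under
#'   `out_dir`, including `summary.json`.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config error: out_dir is required")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  rank <- if (is.null(config$rank)) "family" else config$rank
  frac <- if (is.null(config$fixation_fraction)) 1
          else config$fixation_fraction
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  max_losses <- if (is.null(config$tree$max_losses)) 1
                else config$tree$max_losses
  threshold <- if (is.null(config$structure$threshold)) 6
               else config$structure$threshold
  stopifnot(frac >= 0, frac <= 1, alpha > 0, alpha < 1,
            max_losses >= 0, threshold >= 0)
  summary <- list(
    tool = "cpdscreen",
    thresholds = list(fixation_fraction = frac,
                      proximity_A = threshold,
                      max_losses = max_losses,
                      alpha = alpha,
                      rank = rank),
    stages = list())

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # ---- scan + ci on the nucleotide alignment ----------------------------
  nuc <- NULL
  if (!is.null(config$alignment$nucleotide)) {
    blk <- config$alignment$nucleotide
    nuc <- stage("scan", read_fasta_alignment(
      blk$path, blk$reference_id, "nucleotide", taxonomy = blk$taxonomy))
  }
  if (!is.null(nuc) && !is.null(config$sites)) {
    stage("scan", {
      sites <- read_site_table(config$sites)
      site_summaries <- lapply(sites, function(site) {
        calls <- call_cpd(nuc, site)
        slug <- gsub("[^A-Za-z0-9._-]", "_", site$label)
        write_tsv(calls, file.path(out, paste0("calls_", slug, ".tsv")))
        tally <- tally_by_clade(calls, rank)
        write_tsv(tally, file.path(out, paste0("tally_", slug, ".tsv")))
        fx <- fixed_clades(calls, rank, frac)
        ci <- conservation_index(nuc, site$ref_position)
        list(label = site$label,
             ref_position = site$ref_position,
             n_pathogenic = sum(calls$verdict == "pathogenic_allele"),
             n_wildtype = sum(calls$verdict == "wildtype"),
             n_other = sum(calls$verdict == "other"),
             n_unresolved = sum(calls$verdict == "unresolved"),
             fixed_clades = as.list(fx$clade[fx$fixed]),
             ci = list(n_match = ci$n_match, n_total = ci$n_total,
                       value = ci$ci, reported = round1(ci$ci)))
      })
      summary$stages$scan <- list(status = "ok", rank = rank,
                                   sites = site_summaries)
    })
  } else {
    summary$stages$scan <- "skipped"
  }

  # ---- decoding-site pair ----------------------------------------------
  if (!is.null(nuc) && !is.null(config$pair)) {
    stage("pair", {
      ps <- site_pair_status(nuc, config$pair$pos_a, config$pair$pos_b)
      write_tsv(ps, file.path(out, "pair_status.tsv"))
      ref <- ps[ps$id == nuc$reference_id, ]
      summary$stages$pair <- list(
        status = "ok",
        pos_a = config$pair$pos_a, pos_b = config$pair$pos_b,
        reference_states = paste0(ref$state_a, ref$state_b),
        reference_status = ref$status,
        n_watson_crick = sum(ps$status == "watson_crick"),
        n_non_watson_crick = sum(ps$status == "non_watson_crick"),
        n_unresolved = sum(ps$status == "unresolved"))
    })
  } else {
    summary$stages$pair <- "skipped"
  }

  # ---- protein CI comparison -------------------------------------------
  prot <- NULL
  if (!is.null(config$alignment$protein)) {
    blk <- config$alignment$protein
    prot <- stage("ci", read_fasta_alignment(
      blk$path, blk$reference_id, "protein", taxonomy = blk$taxonomy))
  }
  if (!is.null(prot) && !is.null(config$ci_comparison)) {
    stage("ci", {
      pa <- unlist(config$ci_comparison$set_a)
      pb <- unlist(config$ci_comparison$set_b)
      ca <- conservation_profile(prot, pa)
      cb <- conservation_profile(prot, pb)
      write_tsv(rbind(cbind(set = "a", ca), cbind(set = "b", cb)),
                file.path(out, "ci_sets.tsv"))
      cmp <- compare_ci_sets(ca$ci, cb$ci, alpha = alpha)
      summary$stages$ci <- list(
        status = "ok",
        set_a = list(positions = as.list(pa), cis = as.list(ca$ci),
                     mean = cmp$mean_a, mean_reported = round1(cmp$mean_a)),
        set_b = list(positions = as.list(pb), cis = as.list(cb$ci),
                     mean = cmp$mean_b, mean_reported = round1(cmp$mean_b)),
        t = cmp$t, p_value = cmp$p_value,
        significant = cmp$significant)
    })
  } else {
    summary$stages$ci <- "skipped"
  }

  # ---- structural proximity --------------------------------------------
  if (!is.null(config$structure)) {
    stage("proximity", {
      sb <- config$structure
      model <- read_structure(sb$path,
                              model = if (is.null(sb$model)) 1 else sb$model)
      get_map <- function(tbl_path, query_seq, chain) {
        if (!is.null(tbl_path)) return(read_equivalence_tsv(tbl_path))
        cs <- chain_sequence(model, chain)
        build_equivalence(query_seq, cs$seq, cs$resno, chain = chain)
      }
      ungapped <- function(aln) paste(
        reference_row(aln)[reference_row(aln) != "-"], collapse = "")
      map_rna <- get_map(sb$equivalence$rna,
                         if (!is.null(nuc)) ungapped(nuc) else NULL,
                         sb$rna_chain)
      map_prot <- get_map(sb$equivalence$protein,
                          if (!is.null(prot)) ungapped(prot) else NULL,
                          sb$protein_chain)
      res <- proximity_filter(model, unlist(sb$candidates), sb$site,
                              map_prot, map_rna, threshold_A = threshold)
      write_tsv(res, file.path(out, "proximity.tsv"))
      summary$stages$proximity <- list(
        status = "ok", site = sb$site, threshold_A = threshold,
        candidates = lapply(seq_len(nrow(res)), function(i) list(
          position = res$candidate[i],
          min_distance_A = res$min_distance_A[i],
          verdict = res$verdict[i])))
    })
  } else {
    summary$stages$proximity <- "skipped"
  }

  # ---- fixation dating --------------------------------------------------
  if (!is.null(config$tree)) {
    stage("dating", {
      tree <- read_dated_newick(config$tree$path)
      chars <- config$tree$states
      intervals <- lapply(names(chars), function(lb) {
        st <- read_states_tsv(chars[[lb]])
        fixation_interval(tree, st, max_losses = max_losses, label = lb)
      })
      names(intervals) <- names(chars)
      dating <- list(status = "ok", max_losses = max_losses,
                     alleles = lapply(intervals, function(fi) list(
                       gain_node = fi$gain_node,
                       gain_label = fi$gain_label,
                       oldest_mya = fi$oldest_mya,
                       youngest_mya = fi$youngest_mya,
                       n_losses_assumed = fi$n_losses_assumed)))
      if (length(intervals) >= 2) {
        nm <- names(intervals)
        gaps <- list()
        for (i in seq_len(length(intervals) - 1))
          for (j in seq(i + 1, length(intervals)))
            gaps[[paste(nm[i], nm[j], sep = "_vs_")]] <-
              interval_gap(intervals[[i]], intervals[[j]])
        dating$gap_myr <- gaps
      }
      summary$stages$dating <- dating
    })
  } else {
    summary$stages$dating <- "skipped"
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}

#' Validate a screen summary against the shipped schema
#'
#' Structural validation of a [run_screen()] `summary.json` (or the
#' equivalent list) against the JSON schema shipped at
#' `system.file("extdata", "screen-summary.schema.json",
#' package = "cpdscreen")`.  Supports the subset of JSON Schema the
#' summary uses: `type`, `properties`, `required`, plus the stage
#' convention that a stage is either the string `"skipped"` or an object.
#'
#' @param summary A summary list or a path to a `summary.json`.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_screen_summary <- function(summary) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary)
  schema <- jsonlite::read_json(system.file(
    "extdata", "screen-summary.schema.json", package = "cpdscreen"))
  check <- function(node, sch, where) {
    ty <- sch$type
    if (!is.null(ty)) {
      ok <- switch(ty,
        object = is.list(node),
        array = is.list(node) || is.vector(node),
        string = is.character(node),
        number = is.numeric(node),
        boolean = is.logical(node),
        stage = (is.character(node) && identical(node[[1]], "skipped")) ||
          is.list(node),
        TRUE)
      if (!ok)
        stop(sprintf("summary invalid at %s: expected %s", where, ty),
             call. = FALSE)
    }
    for (req in sch$required)
      if (!req %in% names(node))
        stop(sprintf("summary invalid at %s: missing required '%s'",
                     where, req), call. = FALSE)
    if (!is.null(sch$properties) && is.list(node))
      for (nm in names(sch$properties))
        if (nm %in% names(node))
          check(node[[nm]], sch$properties[[nm]],
                paste0(where, ".", nm))
    invisible(TRUE)
  }
  check(summary, schema, "$")
  invisible(TRUE)
}
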