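# End-to-end orchestration on a fully synthetic bundle.

make_screen_bundle <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # nucleotide alignment: 20 records, pathogenic-style site at position 4
  nuc <- make_alignment(list(
    n_records = 20, length = 12, seed = 5, ordered = TRUE,
    column_specs = data.frame(ref_position = 4, wildtype = "C",
                              n_match = 6, n_other = 14, n_gap = 0),
    taxonomy = data.frame(
      family = c("Cercopithecidae", "Hominidae"),
      subfamily = c("Cercopithecinae", NA), tribe = c(NA, NA),
      n = c(14, 6))))
  nuc_fa <- file.path(dir, "mtrnr1.fa")
  write_fasta_alignment(nuc, nuc_fa)
  sites <- file.path(dir, "sites.tsv")
  writeLines(c("label\tref_position\twildtype\tpathogenic",
               "siteA\t4\tC\tT"), sites)
  # protein alignment with exact per-column CIs
  prot <- make_alignment(list(
    n_records = 70, length = 10, seed = 6, molecule = "protein",
    column_specs = data.frame(
      ref_position = c(2, 3, 4, 6, 7, 8),
      wildtype = c("R", "T", "R", "C", "Q", "I"),
      n_match = c(65, 63, 68, 5, 7, 17))))
  prot_fa <- file.path(dir, "mrps12.fa")
  write_fasta_alignment(prot, prot_fa)
  # dated tree + states
  tt <- make_dated_tree(primate_tree_spec())
  nwk <- file.path(dir, "tree.nwk")
  writeLines(tt$newick, nwk)
  st_paths <- lapply(names(tt$states), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(
      data.frame(tip = names(tt$states[[nm]]),
                 state = unname(tt$states[[nm]])),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  })
  names(st_paths) <- names(tt$states)
  # toy structure + equivalence tables
  pdb <- file.path(dir, "toy.pdb")
  make_structure(list(seed = 12, site = list(chain = "R", resno = 1),
                      candidates = list(
                        list(chain = "P", resno = 68, resid = "LEU",
                             distance = 4),
                        list(chain = "P", resno = 44, resid = "ARG",
                             distance = 9))), pdb)
  eq_p <- file.path(dir, "eq_protein.tsv")
  writeLines(c("query_pos\tchain\tresno", "68\tP\t68", "44\tP\t44"), eq_p)
  eq_r <- file.path(dir, "eq_rna.tsv")
  writeLines(c("query_pos\tchain\tresno", "1494\tR\t1"), eq_r)
  list(
    alignment = list(
      nucleotide = list(path = nuc_fa, reference_id = "Homo_sapiens"),
      protein = list(path = prot_fa, reference_id = "Homo_sapiens")),
    sites = sites,
    rank = "family",
    fixation_fraction = 0.9,
    pair = list(pos_a = 2, pos_b = 9),
    ci_comparison = list(set_a = c(2, 3, 4), set_b = c(6, 7, 8)),
    tree = list(path = nwk, max_losses = 1,
                states = st_paths),
    structure = list(path = pdb, rna_chain = "R", protein_chain = "P",
                     site = 1494, candidates = c(68, 44), threshold = 6,
                     equivalence = list(rna = eq_r, protein = eq_p)))
}

test_that("the orchestrated screen composes all stages into one summary", {
  dir <- tempfile("bundle")
  config <- make_screen_bundle(dir)
  config$out_dir <- file.path(dir, "out")
  cfg_path <- file.path(dir, "screen.yml")
  yaml::write_yaml(config, cfg_path)
  s <- run_screen(cfg_path)
  expect_equal(s$stages$scan$status, "ok")
  site <- s$stages$scan$sites[[1]]
  # ordered generator put the 6 matching (C) records in the first block
  expect_equal(site$n_wildtype, 6)
  expect_equal(site$n_pathogenic + site$n_other, 14)
  expect_equal(site$ci$reported, 30.0)  # 6/20
  # CI comparison stage: means of exact column counts
  ci <- s$stages$ci
  expect_equal(ci$set_a$mean_reported,
               round(mean(100 * c(65, 63, 68) / 70), 1))
  expect_equal(ci$set_b$mean_reported,
               round(mean(100 * c(5, 7, 17) / 70), 1))
  expect_true(ci$significant)
  # proximity stage
  verd <- vapply(s$stages$proximity$candidates, `[[`, "", "verdict")
  expect_equal(verd, c("within", "outside"))
  # dating stage: stem/crown bounds and the minimum gap
  d <- s$stages$dating
  expect_equal(d$alleles$mt1494T$oldest_mya, 32)
  expect_equal(d$alleles$mt1494T$youngest_mya, 18)
  expect_equal(d$alleles$mrps12_L68$oldest_mya, 12)
  expect_equal(d$alleles$mrps12_L68$youngest_mya, 8)
  expect_equal(d$gap_myr$mt1494T_vs_mrps12_L68, 6)
  # stage files exist
  expect_true(file.exists(file.path(config$out_dir, "summary.json")))
  expect_true(file.exists(file.path(config$out_dir, "proximity.tsv")))
  # summary validates against the shipped schema
  expect_true(validate_screen_summary(
    file.path(config$out_dir, "summary.json")))
})

test_that("optional stages are skipped with an explicit marker", {
  dir <- tempfile("bundle2")
  config <- make_screen_bundle(dir)
  config$tree <- NULL
  config$structure <- NULL
  config$out_dir <- file.path(dir, "out")
  s <- run_screen(config)
  expect_identical(s$stages$dating, "skipped")
  expect_identical(s$stages$proximity, "skipped")
  expect_true(validate_screen_summary(s))
})

test_that("re-running the same config gives a byte-identical summary", {
  dir <- tempfile("bundle3")
  config <- make_screen_bundle(dir)
  config$out_dir <- file.path(dir, "out1")
  run_screen(config)
  config$out_dir <- file.path(dir, "out2")
  run_screen(config)
  expect_identical(readLines(file.path(dir, "out1", "summary.json")),
                   readLines(file.path(dir, "out2", "summary.json")))
})

test_that("a failing stage aborts with the stage name", {
  dir <- tempfile("bundle4")
  config <- make_screen_bundle(dir)
  config$tree$path <- file.path(dir, "missing.nwk")
  config$out_dir <- file.path(dir, "out")
  expect_error(run_screen(config), "stage 'dating'")
})
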