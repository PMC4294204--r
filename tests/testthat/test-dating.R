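test_that("newick reading computes node ages and validates dating", {
  tf <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tf)
  tree <- read_dated_newick(tf)
  expect_equal(unname(tree$ages[1:3]), c(0, 0, 0))
  expect_equal(sort(unname(tree$ages[4:5])), c(1, 2))
  writeLines("((A:1,B:-1):1,C:2);", tf)
  expect_error(read_dated_newick(tf), "negative")
  writeLines("((A:1,B:3):1,C:2);", tf)
  expect_error(read_dated_newick(tf), "ultrametric")
  # declared tip ages admit non-contemporaneous tips
  tr <- read_dated_newick(tf, tip_ages = c(A = 2, B = 0, C = 2))
  expect_equal(node_age(tr, "A"), 2)
  expect_equal(max(tr$ages), 4)
  writeLines("((A:1,B:1):1;", tf)
  expect_error(read_dated_newick(tf), "format")
})

test_that("the published catarrhine ages are recovered from the generator", {
  tt <- make_dated_tree(primate_tree_spec())
  # round trip through a newick file preserves ages
  tf <- tempfile(fileext = ".nwk")
  writeLines(tt$newick, tf)
  tree <- read_dated_newick(tf)
  expect_equal(node_age(tree, "Catarrhini"), 32)
  expect_equal(node_age(tree, "Cercopithecidae"), 18)
  expect_equal(node_age(tree, "Cercopithecinae"), 12)
  expect_equal(node_age(tree, "Papionini"), 8)
})

test_that("single-gain reconstruction tolerates the declared reversions", {
  tt <- make_dated_tree(primate_tree_spec())
  tree <- tt$tree
  # all old world monkey tips derived, no exception: clean single gain
  clean <- tt$states$mt1494T
  clean["Papio_ursinus"] <- "derived"
  g0 <- derived_clade(tree, clean, max_losses = 0)
  expect_equal(g0$gain_label, "Cercopithecidae")
  expect_equal(g0$n_losses, 0)
  # the Papio ursinus-like reversion costs one loss
  expect_error(derived_clade(tree, tt$states$mt1494T, max_losses = 0),
               "no-single-gain")
  g1 <- derived_clade(tree, tt$states$mt1494T, max_losses = 1)
  expect_equal(g1$gain_label, "Cercopithecidae")
  expect_equal(g1$n_losses, 1)
  # single derived tip: the gain is that tip, zero losses
  single <- stats::setNames(rep("ancestral", 10), tree$phylo$tip.label)
  single["Macaca_mulatta"] <- "derived"
  gs <- derived_clade(tree, single, max_losses = 0)
  expect_equal(gs$gain_label, "Macaca_mulatta")
  expect_equal(gs$n_losses, 0)
  # unknown tips are free: unsampled leaf-eating monkeys cost nothing
  spec <- primate_tree_spec(colobinae_unknown = TRUE)
  tt2 <- make_dated_tree(spec)
  g2 <- derived_clade(tt2$tree, tt2$states$mrps12_L68, max_losses = 0)
  expect_equal(g2$gain_label, "Papionini")
  expect_error(derived_clade(tree, stats::setNames("ancestral", "Homo_sapiens")),
               "empty-state")
})

test_that("fixation intervals are the stem/crown ages of the gain clade", {
  tt <- make_dated_tree(primate_tree_spec())
  f1 <- fixation_interval(tt$tree, tt$states$mt1494T, max_losses = 1)
  expect_equal(f1$oldest_mya, 32)
  expect_equal(f1$youngest_mya, 18)
  expect_equal(f1$n_losses_assumed, 1)
  f2 <- fixation_interval(tt$tree, tt$states$mrps12_L68, max_losses = 1)
  expect_equal(f2$oldest_mya, 12)
  expect_equal(f2$youngest_mya, 8)
  expect_true(f1$oldest_mya >= f1$youngest_mya)
  # tip gain: (parent age, 0)
  single <- stats::setNames("derived", "Pan_troglodytes")
  ft <- fixation_interval(tt$tree, single)
  expect_equal(ft$oldest_mya, 8)
  expect_equal(ft$youngest_mya, 0)
  # derived everywhere: gain on the root edge, oldest = root age
  all_d <- stats::setNames(rep("derived", 10), tt$tree$phylo$tip.label)
  fr <- fixation_interval(tt$tree, all_d)
  expect_equal(fr$oldest_mya, 32)
  expect_equal(fr$youngest_mya, 32)
})

test_that("interval gap is the distance between fixation windows", {
  fi <- function(old, young)
    structure(list(oldest_mya = old, youngest_mya = young),
              class = "fixation_interval")
  expect_equal(interval_gap(fi(32, 18), fi(12, 8)), 6)
  expect_equal(interval_gap(fi(12, 8), fi(32, 18)), 6)  # order-insensitive
  expect_equal(interval_gap(fi(10, 5), fi(7, 2)), 0)    # overlap
  expect_equal(interval_gap(fi(10, 5), fi(10, 5)), 0)
})

test_that("an outgroup above the root preserves the crown bound", {
  tt <- make_dated_tree(primate_tree_spec())
  f <- fixation_interval(tt$tree, tt$states$mt1494T, max_losses = 1)
  spec2 <- primate_tree_spec()
  spec2$clades <- list(name = "root", age = 60, children = list(
    "Mus_musculus", spec2$clades))
  tt2 <- make_dated_tree(spec2)
  f2 <- fixation_interval(tt2$tree, tt2$states$mt1494T, max_losses = 1)
  expect_equal(f2$youngest_mya, f$youngest_mya)
  expect_gte(f2$oldest_mya, f$oldest_mya)
})

test_that("gain clade and loss count match brute-force enumeration", {
  set.seed(20114)
  n_cases <- 250
  for (case in seq_len(n_cases)) {
    n <- sample(4:12, 1)
    tr <- ape::rcoal(n)
    tree <- read_dated_newick(tr)
    states <- random_tip_states(tr)
    want <- oracle_derived_clade(tr, states)
    if (is.finite(want$losses) && want$losses <= 2) {
      got <- derived_clade(tree, states, max_losses = 2)
      expect_equal(got$gain_node, want$gain)
      expect_equal(got$n_losses, want$losses)
    } else {
      expect_error(derived_clade(tree, states, max_losses = 2),
                   "no-single-gain")
    }
  }
})

test_that("tip states round-trip through TSV", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("tip\tstate", "A\tderived", "B\tancestral", "C\tunknown"),
             tf)
  st <- read_states_tsv(tf)
  expect_equal(unname(st[c("A", "B", "C")]),
               c("derived", "ancestral", "unknown"))
})
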