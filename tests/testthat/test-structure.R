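toy_pdb_lines <- function() c(
  # chain R: one cytosine-like residue at the origin
  "ATOM      1  C1    C R   1       0.000   0.000   0.000  1.00  0.00           C",
  # chain P residue 68: two atoms at 3-4-5 geometry
  "ATOM      2  CA  LEU P  68       3.000   4.000   0.000  1.00  0.00           C",
  "ATOM      3  CB  LEU P  68       6.000   8.000   0.000  1.00  0.00           C",
  # altloc pair on residue 44: A has higher occupancy
  "ATOM      4  CA AARG P  44       9.000   0.000   0.000  0.60  0.00           C",
  "ATOM      5  CA BARG P  44      20.000   0.000   0.000  0.40  0.00           C",
  # a hydrogen close to the site and a water
  "ATOM      6  H1  LEU P  68       0.500   0.000   0.000  1.00  0.00           H",
  "HETATM    7  O   HOH W   1       1.000   1.000   1.000  1.00  0.00           O",
  "END")

test_that("PDB parsing keeps coordinates, resolves altlocs, drops waters", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(), tf)
  mod <- read_structure(tf)
  expect_s3_class(mod, "structure_model")
  expect_false(any(mod$atoms$resid == "HOH"))
  r44 <- mod$atoms[mod$atoms$chain == "P" & mod$atoms$resno == 44, ]
  expect_equal(nrow(r44), 1)
  expect_equal(r44$x, 9)      # occupancy 0.6 altloc won
  c1 <- mod$atoms[mod$atoms$chain == "R", ]
  expect_equal(c(c1$x, c1$y, c1$z), c(0, 0, 0))
  expect_error(read_structure(tf, model = 2), "model")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("multi-model files select the requested model", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       5.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END"), tf)
  m1 <- read_structure(tf, model = 1)
  m2 <- read_structure(tf, model = 2)
  expect_equal(m1$n_models, 2)
  expect_equal(m1$atoms$x, 0)
  expect_equal(m2$atoms$x, 5)
})

test_that("minimum distances are exact on constructed geometry", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(), tf)
  mod <- read_structure(tf)
  sel68 <- list(chain = "P", resno = 68)
  sel44 <- list(chain = "P", resno = 44)
  selR <- list(chain = "R", resno = 1)
  expect_equal(min_distance(mod, sel68, selR), 5)  # 3-4-5 triangle
  expect_equal(min_distance(mod, sel44, selR), 9)
  # symmetry; hydrogens only count in atom_class = "all"
  expect_equal(min_distance(mod, selR, sel68), 5)
  expect_equal(min_distance(mod, sel68, selR, atom_class = "all"), 0.5)
  expect_lte(min_distance(mod, sel68, selR, atom_class = "all"),
             min_distance(mod, sel68, selR, atom_class = "heavy"))
  expect_error(min_distance(mod, sel68, sel68), "same selection")
  expect_error(min_distance(mod, list(chain = "Z", resno = 1), selR),
               "no atoms")
})

test_that("min distance equals a brute-force all-pairs scan", {
  set.seed(5)
  for (case in 1:30) {
    A <- matrix(rnorm(50 * 3, sd = 10), ncol = 3)
    B <- matrix(rnorm(50 * 3, sd = 10), ncol = 3)
    atoms <- data.frame(
      chain = rep(c("A", "B"), each = 50),
      resno = rep(c(1, 2), each = 50),
      resid = "ALA", elety = "CA", element = "C",
      x = c(A[, 1], B[, 1]), y = c(A[, 2], B[, 2]),
      z = c(A[, 3], B[, 3]))
    mod <- structure_model(atoms)
    got <- min_distance(mod, list(chain = "A", resno = 1),
                        list(chain = "B", resno = 2))
    expect_equal(got, oracle_min_distance(A, B))
  }
})

test_that("min distance is rigid-motion invariant", {
  set.seed(11)
  A <- matrix(rnorm(30), ncol = 3)
  B <- matrix(rnorm(30), ncol = 3) + 5
  make_mod <- function(A, B) structure_model(data.frame(
    chain = rep(c("A", "B"), each = 10), resno = rep(1:2, each = 10),
    resid = "ALA", elety = "CA", element = "C",
    x = c(A[, 1], B[, 1]), y = c(A[, 2], B[, 2]), z = c(A[, 3], B[, 3])))
  d0 <- min_distance(make_mod(A, B), list(chain = "A", resno = 1),
                     list(chain = "B", resno = 2))
  # random rotation (QR of a Gaussian matrix) plus translation
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  t <- c(3, -7, 2)
  A2 <- t(Q %*% t(A)) + rep(t, each = 10)
  B2 <- t(Q %*% t(B)) + rep(t, each = 10)
  d1 <- min_distance(make_mod(A2, B2), list(chain = "A", resno = 1),
                     list(chain = "B", resno = 2))
  expect_equal(d1, d0, tolerance = 1e-6)
})

test_that("sequence-based equivalence maps reproduce hand alignments", {
  # identical sequences: identity map
  m <- build_equivalence("MSWRK", "MSWRK", chain = "P")
  expect_equal(m$query_pos, 1:5)
  expect_equal(m$resno, 1:5)
  # one extra leading residue in the query: map shifted by one
  m2 <- build_equivalence("XMSWRK", "MSWRK")
  expect_equal(m2$query_pos, 2:6)
  expect_equal(m2$resno, 1:5)
  # one internal deletion in the structure: positions after it shift
  #   query  ABCDEFGHIJ
  #   struct ABCDFGHIJ   (E missing)
  m3 <- build_equivalence("ABCDEFGHIJ", "ABCDFGHIJ")
  expect_equal(m3$query_pos, c(1:4, 6:10))
  expect_equal(m3$resno, 1:9)
  # structure residue numbers are carried through
  m4 <- build_equivalence("ABC", "ABC", struct_resno = c(10, 11, 15))
  expect_equal(m4$resno, c(10, 11, 15))
  expect_error(build_equivalence("AAAAAAAAAA", "W"),
               "low-confidence")
})

test_that("user tables override alignment and must be injective", {
  tb <- data.frame(query_pos = c(68, 44), chain = "P", resno = c(201, 180))
  m <- build_equivalence(table = tb)
  expect_equal(attr(m, "method"), "table")
  expect_equal(m$resno, c(201, 180))
  bad <- data.frame(query_pos = c(68, 68), chain = "P", resno = c(1, 2))
  expect_error(build_equivalence(table = bad), "injective")
})

test_that("proximity filtering is strict and never drops candidates", {
  tf <- tempfile(fileext = ".pdb")
  p <- make_structure(list(seed = 3, candidates = list(
    list(chain = "P", resno = 68, resid = "LEU", distance = 4),
    list(chain = "P", resno = 44, resid = "ARG", distance = 9))), tf)
  mod <- read_structure(p)
  mp <- build_equivalence(table = data.frame(
    query_pos = c(68, 44), chain = "P", resno = c(68, 44)))
  mr <- build_equivalence(table = data.frame(
    query_pos = 1494, chain = "R", resno = 1))
  res <- proximity_filter(mod, c(68, 44, 101), 1494, mp, mr,
                          threshold_A = 6)
  expect_equal(res$verdict, c("within", "outside", "unresolved"))
  expect_equal(res$min_distance_A[1], 4, tolerance = 1e-3)
  expect_equal(res$min_distance_A[2], 9, tolerance = 1e-3)
  # threshold 0: nothing within
  res0 <- proximity_filter(mod, c(68, 44), 1494, mp, mr, threshold_A = 0)
  expect_true(all(res0$verdict == "outside"))
  # verdicts invariant under candidate order
  res_r <- proximity_filter(mod, c(101, 44, 68), 1494, mp, mr,
                            threshold_A = 6)
  expect_equal(res_r$verdict[match(res$candidate, res_r$candidate)],
               res$verdict)
  expect_error(proximity_filter(mod, 68, 9999, mp, mr), "mapping error")
})
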