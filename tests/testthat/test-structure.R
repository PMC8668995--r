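minimal_pdb_lines <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "END")

test_that("PDB reading returns exact coordinates and flags malformed records", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_lines, f)
  pdb <- read_pdb(f)
  expect_equal(nrow(pdb$atom), 2)
  expect_equal(pdb$atom$x, c(0, 1.458))
  expect_equal(pdb$atom$elety, c("N", "CA"))

  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(minimal_pdb_lines[1], "ATOM      2  CA  ALA A   1       1.458   bad"), bad)
  expect_error(read_pdb(bad), "line 2")
})

test_that("altloc resolution keeps the highest occupancy, ties to A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB AALA A   2       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   2       8.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  pdb <- read_pdb(f)
  expect_equal(nrow(pdb$atom), 2)
  expect_equal(pdb$atom$x, c(0, 1)) # highest occupancy, then tie -> A
})

test_that("structures written by the package read back identically", {
  g <- simulate_gate(8.3, seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(g, f)
  back <- read_pdb(f)
  expect_equal(back$atom$elety, g$atom$elety)
  expect_equal(back$atom$resno, g$atom$resno)
  # PDB format carries 3 decimals
  expect_equal(back$atom$x, g$atom$x, tolerance = 1e-3)
  expect_equal(back$atom$z, g$atom$z, tolerance = 1e-3)
})

test_that("Kabsch superposition is exact on rigid transforms and proper on noise", {
  set.seed(41)
  A <- matrix(rnorm(150), ncol = 3)
  idk <- kabsch_superpose(A, A)
  expect_equal(idk$rotation, diag(3), tolerance = 1e-12)
  expect_equal(idk$translation, rep(0, 3), tolerance = 1e-12)
  expect_equal(idk$rmsd, 0, tolerance = 1e-12)

  R <- random_rotation()
  tr <- c(4, -2, 7)
  B <- A %*% t(R) + matrix(tr, nrow(A), 3, byrow = TRUE)
  k <- kabsch_superpose(A, B)
  expect_equal(k$rotation, R, tolerance = 1e-9)
  expect_equal(k$translation, tr, tolerance = 1e-9)
  expect_lt(k$rmsd, 1e-9)

  # noisy case: the fitted rmsd beats 1000 random rigid placements
  Bn <- B + matrix(rnorm(length(B), sd = 0.5), nrow(B), 3)
  kn <- kabsch_superpose(A, Bn)
  rand_rmsd <- replicate(1000, {
    Rr <- random_rotation()
    fitted <- A %*% t(Rr)
    fitted <- sweep(fitted, 2, colMeans(fitted) - colMeans(Bn))
    sqrt(mean(rowSums((fitted - Bn)^2)))
  })
  expect_true(all(kn$rmsd <= rand_rmsd))

  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("recovered rotations are proper orthonormal even under reflections/noise", {
  set.seed(43)
  for (k in 1:10) {
    A <- matrix(rnorm(60), ncol = 3)
    B <- matrix(rnorm(60), ncol = 3) # unrelated clouds can induce reflections
    s <- kabsch_superpose(A, B)
    expect_equal(t(s$rotation) %*% s$rotation, diag(3), tolerance = 1e-10)
    expect_equal(det(s$rotation), 1, tolerance = 1e-10)
  }
})

test_that("Kabsch rmsd is invariant under a common rigid motion of both inputs", {
  set.seed(47)
  A <- matrix(rnorm(90), ncol = 3)
  B <- A + matrix(rnorm(90, sd = 0.3), ncol = 3)
  r0 <- kabsch_superpose(A, B)$rmsd
  R <- random_rotation()
  shift <- matrix(c(3, 1, -9), nrow(A), 3, byrow = TRUE)
  r1 <- kabsch_superpose(A %*% t(R) + shift, B %*% t(R) + shift)$rmsd
  expect_equal(r0, r1, tolerance = 1e-9)
})

test_that("alignment-based residue pairing drops gaps and missing CA atoms", {
  sp <- simulate_structure_pair(10, rotation = list(axis = c(0, 0, 1), angle_deg = 25),
                                seed = 6)
  seqA <- chain_sequence(sp$A)
  aln <- global_align(seq_record("sA", seqA$residues), seq_record("sB", seqA$residues))
  pairs <- pair_residues(sp$A, sp$B, aln)
  expect_equal(nrow(pairs), 10)
  expect_equal(pairs$resnoA, pairs$resnoB)

  # a gapped alignment column drops that residue
  gapped <- structure(list(a = seq_record("sA", "AAAAA-AAAAA", gapped = TRUE),
                           b = seq_record("sB", "AAAAAAAAAA-", gapped = TRUE)),
                      class = "pairwise_alignment")
  pairs2 <- pair_residues(sp$A, sp$B, gapped)
  expect_equal(nrow(pairs2), 9)

  # a structure missing one CA loses exactly that pair
  A2 <- sp$A
  drop <- which(A2$atom$elety == "CA" & A2$atom$resno == 5)
  A2$atom <- A2$atom[-drop, ]
  pairs3 <- pair_residues(A2, sp$B, aln)
  expect_equal(nrow(pairs3), 9)

  # sequence/structure disagreement beyond the threshold is an error
  wrong <- global_align(seq_record("sA", paste(rep("W", 10), collapse = "")),
                        seq_record("sB", seqA$residues))
  expect_error(pair_residues(sp$A, sp$B, wrong), "mismatch")
})

test_that("residue distances follow geometry and report the achieving atoms", {
  g <- simulate_gate(5, seed = 9)
  m <- residue_distance(g, "A:309", "A:518")
  expect_equal(m$distance, 5, tolerance = 1e-6)
  expect_equal(m$atomA, "OE2")
  expect_equal(m$atomB, "NH1")

  # symmetric in its arguments
  m2 <- residue_distance(g, "A:518", "A:309")
  expect_equal(m2$distance, m$distance, tolerance = 1e-12)

  # same residue against itself
  expect_equal(residue_distance(g, "A:309", "A:309")$distance, 0)

  # min-heavy includes the backbone and can only be closer or equal
  mh <- residue_distance(g, "A:309", "A:518", mode = "min-heavy")
  expect_lte(mh$distance, m$distance + 1e-12)

  # atom-pair mode measures the named atoms
  ap <- residue_distance(g, "A:309", "A:518", mode = "atom-pair",
                         atomA = "CA", atomB = "CA")
  at <- g$atom
  pa <- unlist(at[at$resno == 309 & at$elety == "CA", c("x", "y", "z")])
  pb <- unlist(at[at$resno == 518 & at$elety == "CA", c("x", "y", "z")])
  expect_equal(ap$distance, sqrt(sum((pa - pb)^2)), tolerance = 1e-9)

  expect_error(residue_distance(g, "A:999", "A:518"), "matches no residue")
})

test_that("gate access tables report planted distances per structure", {
  s1 <- simulate_gate(8.0, seed = 1)
  s2 <- simulate_gate(14.0, seed = 2)
  tab <- gate_access_report(list(human = s1, plant = s2),
                            list(c("A:309", "A:518")))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$distance_angstrom, c(8.0, 14.0), tolerance = 1e-6)
  expect_equal(tab$mode, rep("min-side-chain-heavy", 2))

  one <- gate_access_report(list(only = s1), list(c("A:309", "A:518")))
  expect_equal(nrow(one), 1)
  empty <- gate_access_report(list(), list())
  expect_equal(nrow(empty), 0)
})
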