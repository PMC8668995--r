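test_that("zero substitution, no indels, no events reproduces the reference everywhere", {
  ref <- seq_record("ref", random_seq(40))
  fam <- simulate_family(family_spec(ref, n_taxa = 4, subst_prob = 0, seed = 3))
  for (r in fam$records) expect_equal(r$residues, ref$residues)
  for (h in fam$truth$homology) expect_equal(h, 1:40)
})

test_that("simulation is byte-deterministic under a fixed seed", {
  ref <- synthetic_wee1_reference()
  spec <- family_spec(ref, n_taxa = 5, subst_prob = 0.05, indel_rate = 1,
                      protected = builtin_wee1_catalog()$sites$ref_pos, seed = 19)
  f1 <- simulate_family(spec)
  f2 <- simulate_family(spec)
  expect_identical(write_fasta(f1$records), write_fasta(f2$records))
  expect_identical(f1$truth$homology, f2$truth$homology)

  g1 <- simulate_gate(8.3, seed = 4)
  g2 <- simulate_gate(8.3, seed = 4)
  expect_identical(g1$atom, g2$atom)

  s1 <- simulate_structure_pair(20, seed = 5)
  s2 <- simulate_structure_pair(20, seed = 5)
  expect_identical(s1$B$atom, s2$B$atom)
})

test_that("planted events are present and homology maps are monotone", {
  ref <- synthetic_wee1_reference()
  planted <- data.frame(taxon = "t01", ref_pos = 426L, new_residue = "A")
  spec <- family_spec(ref, n_taxa = 4, subst_prob = 0.02, indel_rate = 2,
                      planted = planted,
                      protected = builtin_wee1_catalog()$sites$ref_pos, seed = 23)
  fam <- simulate_family(spec)
  h <- fam$truth$homology[["t01"]]
  pos <- which(h == 426L)
  expect_length(pos, 1)
  expect_equal(substr(fam$records[[match("t01", vapply(fam$records, `[[`, "", "id"))]]$residues,
                      pos, pos), "A")
  for (hm in fam$truth$homology) {
    expect_false(is.unsorted(hm[!is.na(hm)], strictly = TRUE))
  }
})

test_that("a planted event equal to the reference residue is rejected", {
  ref <- seq_record("ref", "MKVD")
  expect_error(family_spec(ref, planted = data.frame(taxon = "t01", ref_pos = 4L,
                                                     new_residue = "D"), seed = 1),
               "not an event")
  expect_error(family_spec(ref, planted = data.frame(taxon = "t01", ref_pos = 9L,
                                                     new_residue = "A"), seed = 1),
               "outside reference")
})

test_that("noiseless structure pairs recover the planted transform exactly", {
  sp <- simulate_structure_pair(30, rotation = list(axis = c(1, 1, 0), angle_deg = 55),
                                translation = c(2, 4, -1), noise_sd = 0, seed = 31)
  A <- as.matrix(sp$A$atom[, c("x", "y", "z")])
  B <- as.matrix(sp$B$atom[, c("x", "y", "z")])
  k <- kabsch_superpose(A, B)
  expect_equal(k$rotation, sp$truth$rotation, tolerance = 1e-9)
  expect_equal(k$translation, sp$truth$translation, tolerance = 1e-9)
  expect_lt(k$rmsd, 1e-9)

  expect_error(simulate_structure_pair(2, seed = 1), "at least 3")
  expect_error(simulate_structure_pair(5, rotation = list(axis = c(0, 0, 0),
                                                          angle_deg = 10), seed = 1),
               "degenerate")
})

test_that("noisy structure pairs recover the rotation within 2 degrees", {
  for (s in 1:20) {
    sp <- simulate_structure_pair(100, rotation = "random", noise_sd = 0.5, seed = s)
    A <- as.matrix(sp$A$atom[, c("x", "y", "z")])
    B <- as.matrix(sp$B$atom[, c("x", "y", "z")])
    k <- kabsch_superpose(A, B)
    expect_lt(rotation_angle_deg(k$rotation, sp$truth$rotation), 2)
  }
})

test_that("gate structures plant the target distance to 1e-6 with decoys farther", {
  for (d in c(0.1, 8.3, 14.0)) {
    g <- simulate_gate(d, seed = 7)
    m <- residue_distance(g, "A:309", "A:518")
    expect_equal(m$distance, d, tolerance = 1e-6)
  }
  expect_error(simulate_gate(0), "> 0")
})

test_that("indels never disturb protected windows", {
  ref <- synthetic_wee1_reference()
  prot <- builtin_wee1_catalog()$sites$ref_pos
  fam <- simulate_family(family_spec(ref, n_taxa = 6, subst_prob = 0,
                                     indel_rate = 3, protected = prot, seed = 37))
  refch <- strsplit(ref$residues, "")[[1]]
  for (k in seq_along(fam$records)) {
    h <- fam$truth$homology[[fam$records[[k]]$id]]
    # every protected position survives in every taxon
    expect_true(all(prot %in% h[!is.na(h)]))
    # and with subst_prob 0 carries the reference residue
    ch <- strsplit(fam$records[[k]]$residues, "")[[1]]
    expect_equal(ch[match(prot, h)], refch[prot])
  }
})

test_that("planted recovery through the full pipeline has recall and precision 1", {
  ref <- synthetic_wee1_reference()
  cat <- builtin_wee1_catalog()
  planted <- data.frame(taxon = c("t01", "t03"), ref_pos = c(463L, 309L),
                        new_residue = c("G", "H"), stringsAsFactors = FALSE)
  fam <- simulate_family(family_spec(ref, n_taxa = 4, subst_prob = 0,
                                     planted = planted,
                                     protected = cat$sites$ref_pos, seed = 41))
  msa <- progressive_align(c(list(ref), fam$records))
  tab <- call_sites(msa, build_column_map(msa, ref$id), cat)
  hits <- tab[tab$status != "conserved", ]
  expect_equal(sort(paste(hits$seq_id, hits$ref_pos)),
               sort(paste(planted$taxon, planted$ref_pos)))
})
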