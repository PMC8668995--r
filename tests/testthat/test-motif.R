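test_that("consensus scanning matches a naive sliding-window oracle", {
  expect_equal(scan_consensus("AAEGDAA", "EGD")$start, 3L)
  expect_equal(scan_consensus("MDLKPENQ", "DLKPxN")$start, 2L)
  expect_equal(nrow(scan_consensus("IVHRDLKPENIL", "IVHxDLKPxNIx")), 1L)
  # strict mode: missing catalytic D kills the match
  expect_equal(nrow(scan_consensus("IVHRGLKPENIL", "IVHxDLKPxNIx")), 0L)

  set.seed(13)
  for (k in 1:30) {
    s <- random_seq(sample(20:200, 1), alphabet = c("A", "E", "G", "D", "L", "I", "V"))
    pat <- sample(c("EGD", "DxG", "AxxE", "IVx", "LA"), 1)
    relaxed <- sample(c(TRUE, FALSE), 1)
    expect_equal(scan_consensus(s, pat, relaxed = relaxed)$start,
                 naive_scan(s, pat, relaxed = relaxed),
                 info = paste(pat, relaxed, s))
  }

  expect_error(scan_consensus("MKV", "E?D"), "invalid pattern")
  expect_error(scan_consensus("MKV", ""), "non-empty")
})

test_that("relaxed mode tolerates hydrophobic-for-hydrophobic substitutions only", {
  # L in place of the pattern's I is accepted when relaxed
  expect_equal(nrow(scan_consensus("LVHRDLKPENIL", "IVHxDLKPxNIx")), 0L)
  expect_equal(scan_consensus("LVHRDLKPENIL", "IVHxDLKPxNIx", relaxed = TRUE)$start, 1L)
  # but a polar residue there is still rejected
  expect_equal(nrow(scan_consensus("SVHRDLKPENIL", "IVHxDLKPxNIx", relaxed = TRUE)), 0L)
})

test_that("physicochemical classes cover all residues once and follow the legend", {
  expect_equal(classify_residue("E"), "acidic")
  expect_equal(classify_residue("W"), "hydrophobic")
  expect_equal(classify_residue("H"), "aromatic") # H sits with aromatics, not basics
  expect_equal(classify_residue("X"), "unknown")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cls <- vapply(aa, classify_residue, "")
  expect_equal(sort(unname(table(cls))),
               sort(c(hydrophobic = 7L, acidic = 2L, basic = 2L, polar = 4L,
                      aromatic = 2L, cysteine = 1L, proline = 1L, glycine = 1L)),
               ignore_attr = TRUE)
  expect_error(classify_residue("B"), "not an amino-acid")
})

test_that("the built-in WEE1 catalog carries the documented sites uniquely", {
  cat <- builtin_wee1_catalog()
  sites <- cat$sites
  expect_equal(sites$expected[sites$name == "catalytic-D"], "D")
  expect_equal(sites$ref_pos[sites$name == "catalytic-D"], 426L)
  expect_equal(sites$expected[sites$name == "gatekeeper"], "N")
  expect_equal(sites$ref_pos[sites$name == "gatekeeper"], 376L)
  expect_equal(sites$expected[sites$name == "dfg-2"], "LF") # DLG in human, DFG in plants
  expect_false(anyDuplicated(sites$ref_pos) > 0)
  expect_false(anyDuplicated(sites$name) > 0)
  expect_true("IVHxDLKPxNIx" %in% cat$patterns$pattern)
})

test_that("catalog JSON round-trips", {
  cat <- builtin_wee1_catalog()
  f <- withr::local_tempfile(fileext = ".json")
  write_catalog_json(cat, f)
  back <- read_catalog_json(f)
  expect_equal(back$sites, cat$sites)
  expect_equal(back$patterns, cat$patterns)
  expect_equal(back$segments, cat$segments)
})

test_that("the reference row is fully conserved and carries no flags", {
  ref <- synthetic_wee1_reference()
  fam <- simulate_family(family_spec(ref, n_taxa = 3, subst_prob = 0, seed = 1))
  msa <- progressive_align(c(list(ref), fam$records))
  cmap <- build_column_map(msa, ref$id)
  tab <- call_sites(msa, cmap)
  expect_true(all(tab$status == "conserved"))
  flags <- assess_function(tab)
  expect_true(all(lengths(flags) == 0))
})

test_that("planted substitutions at catalog sites are recovered exactly", {
  ref <- synthetic_wee1_reference()
  cat <- builtin_wee1_catalog()
  planted <- data.frame(taxon = c("t02", "t04", "t04"),
                        ref_pos = c(426L, 463L, 518L),
                        new_residue = c("A", "G", "E"),
                        stringsAsFactors = FALSE)
  fam <- simulate_family(family_spec(ref, n_taxa = 5, subst_prob = 0,
                                     planted = planted,
                                     protected = cat$sites$ref_pos, seed = 8))
  msa <- progressive_align(c(list(ref), fam$records))
  tab <- call_sites(msa, build_column_map(msa, ref$id), cat)

  hits <- tab[tab$status != "conserved", ]
  got <- sort(paste(hits$seq_id, hits$ref_pos))
  expect_equal(got, sort(paste(planted$taxon, planted$ref_pos)))

  flags <- assess_function(tab)
  expect_equal(flags[["t02"]], "catalytic-dead")
  expect_equal(sort(flags[["t04"]]), sort(c("ATP-binding-compromised", "R518-variant")))
  expect_length(flags[["t01"]], 0)
})

test_that("site status distinguishes conservative from class-changing substitutions", {
  # catalytic D -> E stays acidic (conservative); D -> A changes class
  m <- read_alignment(">ref\nDKR\n>cons\nEKR\n>chg\nAKR\n", "aligned-fasta")
  cmap <- build_column_map(m, "ref")
  cat <- site_catalog(data.frame(name = "cat-D", ref_pos = 1L, expected = "D",
                                 category = "catalytic"))
  tab <- call_sites(m, cmap, cat)
  expect_equal(tab$status[tab$seq_id == "cons"], "conservative")
  expect_equal(tab$status[tab$seq_id == "chg"], "class-change")

  # multi-residue expectation: membership counts as conserved
  cat2 <- site_catalog(data.frame(name = "dfg2", ref_pos = 2L, expected = "LF",
                                  category = "activation"))
  m2 <- read_alignment(">ref\nDLG\n>f\nDFG\n", "aligned-fasta")
  tab2 <- call_sites(m2, build_column_map(m2, "ref"), cat2)
  expect_true(all(tab2$status == "conserved"))
})
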