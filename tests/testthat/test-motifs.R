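# Motif identity/similarity scoring and the 4 A side-chain pocket rule.

test_that("BLOSUM62 worked example: YAD vs FGE", {
  rows <- rbind(ref = c("Y", "A", "D"), tgt = c("F", "G", "E"))
  msa <- tiny_msa(rows)
  motif <- define_motif(msa, msa$columns, name = "toy")
  cmp <- compare_motif(motif, msa, "tgt")
  expect_equal(cmp$identity_pct, 0)
  expect_equal(cmp$similarity_pct, 100 * 2 / 3, tolerance = 1e-9)
  self <- compare_motif(motif, msa, "ref")
  expect_equal(self$identity_pct, 100)
  expect_equal(self$similarity_pct, 100)
})

test_that("gaps count against n_ref in both statistics", {
  rows <- rbind(ref = c("Y", "A", "D", "W"), tgt = c("Y", "-", "D", "W"))
  msa <- tiny_msa(rows)
  motif <- define_motif(msa, msa$columns)
  cmp <- compare_motif(motif, msa, "tgt")
  expect_equal(cmp$identity_pct, 75)
  expect_equal(cmp$similarity_pct, 75)
  # nonstandard residues count as neither identical nor similar
  rows2 <- rbind(ref = c("Y", "A"), tgt = c("X", "A"))
  cmp2 <- compare_motif(define_motif(tiny_msa(rows2), residue_key("A", 1:2)),
                        tiny_msa(rows2), "tgt")
  expect_equal(cmp2$identity_pct, 50)
})

test_that("brute-force recomputation matches on random motifs", {
  b <- blosum62()
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    ref <- sample(aas, n, replace = TRUE)
    tgt <- sample(c(aas, "-"), n, replace = TRUE)
    msa <- tiny_msa(rbind(ref = ref, tgt = tgt))
    cmp <- compare_motif(define_motif(msa, msa$columns), msa, "tgt")
    ident <- simil <- 0
    for (k in seq_len(n)) {
      if (tgt[k] == "-") next
      if (tgt[k] == ref[k]) ident <- ident + 1
      if (b[ref[k], tgt[k]] > 0) simil <- simil + 1
    }
    expect_equal(cmp$identity_pct, 100 * ident / n)
    expect_equal(cmp$similarity_pct, 100 * simil / n)
    expect_lte(cmp$identity_pct, cmp$similarity_pct)
  }
})

test_that("pocket rule is side-chain only with planted ligands", {
  m <- make_synthetic_channel("pk", seed = 9, helix_len = 8)
  key <- "A:3:"
  expect_true(key %in% pocket_residues(plant_ligand(m, key, 3.5), "LIG"))
  expect_false(key %in% pocket_residues(plant_ligand(m, key, 4.5), "LIG"))
  expect_error(pocket_residues(m, "LIG"), "matches no hetero atoms")
})

test_that("the 4.0 A cutoff is inclusive at exactly 4.0", {
  atoms <- data.frame(
    chain = c("A", "A", "A", "A", "A", "X"),
    resno = c(1L, 1L, 1L, 1L, 1L, 9L), insert = "",
    resname = c(rep("ALA", 5), "LIG"),
    elety = c("N", "CA", "C", "O", "CB", "C1"),
    elesy = c("N", "C", "C", "O", "C", "C"),
    x = c(-1.5, 0, 1.5, 2.5, 0, 4),
    y = c(0, 0, 0, 0, 1.5, 1.5),
    z = 0,
    het = c(rep(FALSE, 5), TRUE), o = 1, stringsAsFactors = FALSE)
  m <- structure_model(atoms, pdb_id = "exact")
  # CB at (0, 1.5, 0), ligand at (4, 1.5, 0): side-chain distance exactly 4
  expect_true("A:1:" %in% pocket_residues(m, "LIG", cutoff = 4.0))
  expect_false("A:1:" %in% pocket_residues(m, "LIG", cutoff = 3.999))
})

test_that("glycine never joins a pocket through its backbone", {
  hx <- make_ideal_helix(helix_spec("alpha", n_res = 8), sequence = "AAAGAAAA")
  a <- hx$atoms
  gly_ca <- as.numeric(a[a$resno == 4 & a$elety == "CA", c("x", "y", "z")])
  lig <- data.frame(chain = "X", resno = 999L, insert = "", resname = "LIG",
                    elety = "C1", elesy = "C", x = gly_ca[1] + 2.5,
                    y = gly_ca[2], z = gly_ca[3], het = TRUE, o = 1)
  hx$atoms <- rbind(hx$atoms, lig)
  pocket <- pocket_residues(hx, "LIG", cutoff = 4.0)
  expect_false("A:4:" %in% pocket)
})

test_that("pocket membership is monotone in the cutoff", {
  m <- plant_ligand(make_synthetic_channel("mono", seed = 10, helix_len = 8),
                    "A:3:", 3.8)
  p1 <- pocket_residues(m, "LIG", cutoff = 3.9)
  p2 <- pocket_residues(m, "LIG", cutoff = 5.5)
  expect_true(all(p1 %in% p2))
  expect_gte(length(p2), length(p1))
})

test_that("heatmap equals elementwise comparisons and ignores row order", {
  rows <- rbind(ref = c("Y", "A", "D", "W", "K"),
                t1 = c("Y", "A", "D", "W", "K"),
                t2 = c("F", "A", "E", "W", "R"),
                t3 = c("-", "-", "D", "W", "K"))
  msa <- tiny_msa(rows)
  motif <- define_motif(msa, msa$columns)
  hm <- motif_heatmap(motif, msa)
  for (i in seq_len(nrow(hm))) {
    cmp <- compare_motif(motif, msa, hm$structure_id[i])
    expect_equal(hm$identity_pct[i], cmp$identity_pct)
    expect_equal(hm$similarity_pct[i], cmp$similarity_pct)
  }
  expect_equal(hm$flag, c("R", "", "", ""))
  # row order of the MSA does not change per-structure values
  msa2 <- tiny_msa(rows[c(1, 4, 2, 3), ])
  cmp_a <- compare_motif(define_motif(msa2, msa2$columns), msa2, "t2")
  cmp_b <- compare_motif(motif, msa, "t2")
  expect_equal(cmp_a$identity_pct, cmp_b$identity_pct)
})

test_that("selectivity-filter motifs come from annotated ranges", {
  rows <- rbind(ref = c("G", "M", "G", "D"), tgt = c("G", "I", "G", "E"))
  msa <- tiny_msa(rows)
  motif <- filter_motif(msa, c(2, 3))
  expect_equal(motif$columns, 2:3)
  expect_equal(motif$reference_residues, c("M", "G"))
  expect_error(filter_motif(msa, c(50, 60)), "matches no MSA columns")
})
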