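# Reference-anchored MSA projection.

# three homologs with correspondences known by construction: the reference,
# a copy missing residues 11-15 (deletion), and a copy with a 5-residue
# excursion spliced in after residue 20 (insertion)
make_homolog_set <- function() {
  ref <- make_random_fold(40, seed = 81)
  xyz <- atom_coords(ref)
  seqs <- model_sequence(ref)
  del <- ca_model(xyz[-(11:15), , drop = FALSE], id = "del")
  del$atoms$resname <- ref$atoms$resname[-(11:15)]
  ins_xyz <- rbind(xyz[1:20, ],
                   sweep(matrix(rnorm(15, sd = 1), 5, 3), 2,
                         -(xyz[20, ] + c(25, 0, 0))),
                   xyz[21:40, ])
  ins <- ca_model(ins_xyz, id = "ins")
  ins$atoms$resname <- c(ref$atoms$resname[1:20], rep("GLY", 5),
                         ref$atoms$resname[21:40])
  out <- list(ref, del, ins)
  names(out) <- vapply(out, function(m) m$pdb_id, character(1))
  out
}

test_that("projection reproduces the constructed truth table", {
  models <- make_homolog_set()
  alns <- lapply(models, function(m) fragment_align(m, models$rf0081))
  msa <- project_to_reference(alns, models, "rf0081")
  expect_equal(length(msa$columns), 40)      # width = reference length
  expect_equal(dim(msa$rows), c(3, 40))
  ref_seq <- unname(model_sequence(models$rf0081))
  # reference row: no gaps, its own sequence
  expect_identical(unname(msa$rows["rf0081", ]), ref_seq)
  # deletion row: gaps exactly at reference positions 11-15
  expect_equal(unname(which(msa$rows["del", ] == "-")), 11:15)
  expect_identical(unname(msa$rows["del", -(11:15)]), ref_seq[-(11:15)])
  # insertion row: width unchanged, inserted GLYs absent, rest intact
  expect_identical(unname(msa$rows["ins", ]), ref_seq)
  ins_keys <- msa$provenance["ins", ]
  expect_false(any(ins_keys %in% residue_key("A", 21:25), na.rm = TRUE))
  # provenance of columns 21-40 points at the shifted residues 26-45
  expect_identical(unname(ins_keys[21:40]), residue_key("A", 26:45))
})

test_that("row insertion order does not change the MSA content", {
  models <- make_homolog_set()
  alns <- lapply(models, function(m) fragment_align(m, models$rf0081))
  m1 <- project_to_reference(alns, models, "rf0081")
  m2 <- project_to_reference(rev(alns), models, "rf0081")
  for (id in rownames(m1$rows))
    expect_identical(m1$rows[id, ], m2$rows[id, ])
})

test_that("column_lookup returns provenance and gap sentinels", {
  models <- make_homolog_set()
  alns <- lapply(models, function(m) fragment_align(m, models$rf0081))
  msa <- project_to_reference(alns, models, "rf0081")
  expect_identical(column_lookup(msa, "rf0081", 7), msa$columns[7])
  expect_true(is.na(column_lookup(msa, "del", 12)))
  expect_identical(column_lookup(msa, "del", msa$columns[5]),
                   residue_key("A", 5))
  expect_error(column_lookup(msa, "nope", 1), "not in MSA")
})

test_that("provenance round-trips the reference-touching part of each mapping", {
  models <- make_homolog_set()
  al <- fragment_align(models$del, models$rf0081)
  msa <- project_to_reference(list(al), models, "rf0081")
  prov <- msa$provenance["del", ]
  rebuilt <- cbind(match(prov[!is.na(prov)], al$mobile_keys),
                   which(!is.na(prov)))
  expect_equal(unname(rebuilt), unname(al$mapping), ignore_attr = TRUE)
})

test_that("alignments not involving the reference are rejected", {
  models <- make_homolog_set()
  al <- fragment_align(models$del, models$ins)
  expect_error(project_to_reference(list(al), models, "rf0081"),
               "does not involve the reference")
})

test_that("FASTA export writes one gapped row per structure", {
  models <- make_homolog_set()
  alns <- lapply(models, function(m) fragment_align(m, models$rf0081))
  msa <- project_to_reference(alns, models, "rf0081")
  f <- tempfile(fileext = ".fasta")
  write_msa_fasta(msa, f)
  aa <- Biostrings::readAAStringSet(f)
  expect_equal(length(aa), 3)
  expect_true(all(Biostrings::width(aa) == 40))
})
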