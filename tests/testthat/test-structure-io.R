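# Parsing, filtering and preprocessing of coordinate files.

test_that("synthetic tetramer round-trips through PDB with stable coordinates", {
  m <- make_synthetic_channel("rt", seed = 3, helix_len = 6)
  f1 <- tempfile(fileext = ".pdb")
  write_structure(m, f1)
  m2 <- read_structure(f1)
  expect_equal(length(unique(m2$atoms$chain)), 4)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(atom_coords(m2), atom_coords(m), tolerance = 1e-3,
               ignore_attr = TRUE)
  # second write is byte-stable
  f2 <- tempfile(fileext = ".pdb")
  write_structure(m2, f2)
  m3 <- read_structure(f2)
  expect_identical(atom_coords(m3), atom_coords(m2))
})

test_that("alternate locations resolve to highest occupancy, ties to A", {
  pdb <- c(
    "ATOM      1  N   ALA A   1      11.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1      10.000  10.000  10.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1      20.000  10.000  10.000  0.60  0.00           C",
    "ATOM      4  CB AALA A   1      10.000  11.000  10.000  0.50  0.00           C",
    "ATOM      5  CB BALA A   1      20.000  11.000  10.000  0.50  0.00           C",
    "ATOM      6  C   ALA A   1      12.000  10.000  10.000  1.00  0.00           C",
    "ATOM      7  O   ALA A   1      13.000  10.000  10.000  1.00  0.00           O",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  m <- read_structure(f)
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 20)            # occupancy 0.6 wins
  cb <- m$atoms[m$atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 10)            # 0.5/0.5 tie -> altloc A
})

test_that("resolution filter is inclusive at the cutoff and flags unknowns", {
  mk <- function(res) { m <- ca_model(cbind(1:4 * 3, 0, 0)); m$resolution <- res; m }
  models <- lapply(c(3.2, 5.0, 5.1), mk)
  kept <- filter_by_resolution(models)
  expect_equal(vapply(kept, function(m) m$resolution, numeric(1)), c(3.2, 5.0))
  expect_identical(filter_by_resolution(list()), list())
  expect_warning(kept2 <- filter_by_resolution(c(models, list(mk(NA)))),
                 "unknown resolution")
  expect_length(kept2, 2)
})

test_that("loop truncation triggers strictly above 100 residues and is idempotent", {
  m100 <- loop_model(100)
  out100 <- strip_and_truncate(m100)
  expect_equal(nrow(out100$atoms), nrow(m100$atoms))
  m150 <- loop_model(150)
  out150 <- strip_and_truncate(m150)
  # 2 x 20 segment residues + 10 kept each side of the loop
  expect_equal(nrow(out150$atoms), 40 + 20)
  kept_loop <- out150$atoms$resno[out150$atoms$resno > 20 &
                                  out150$atoms$resno < 171]
  expect_equal(kept_loop, c(21:30, 161:170))
  expect_identical(strip_and_truncate(out150)$atoms, out150$atoms)
})

test_that("HETATM records are stripped", {
  m <- plant_ligand(make_synthetic_channel("ion", seed = 1, helix_len = 6),
                    target_residue = "A:1:", distance = 3.0)
  expect_true(any(m$atoms$het))
  out <- strip_and_truncate(m)
  expect_false(any(out$atoms$het))
})

test_that("domain extraction honours bounds, protomer rule, and idempotence", {
  m <- make_synthetic_channel("dom", seed = 2, helix_len = 8)
  b <- m$annotations$domain_bounds
  pore <- extract_domain(m, "pore")
  expect_setequal(unique(pore$atoms$chain), c("A", "B", "C", "D"))
  expect_true(all(pore$atoms$resno >= b$pore[1] & pore$atoms$resno <= b$pore[2]))
  s14 <- extract_domain(m, "S1S4")
  expect_equal(unique(s14$atoms$chain), "A")
  expect_identical(extract_domain(pore, "pore")$atoms, pore$atoms)
  # residue count by direct range arithmetic (no gaps inside segments 5-6)
  rt <- residue_table(pore)
  per_chain <- sum(m$annotations$tm_segments$end[5:6] -
                   m$annotations$tm_segments$start[5:6] + 1)
  expect_equal(nrow(rt), 4 * per_chain)
  bad <- m
  bad$annotations$domain_bounds$pore <- c(5000, 6000)
  expect_error(extract_domain(bad, "pore"), "5000-6000")
})

test_that("chain reordering is geometric, permutation-invariant, and flips with the normal", {
  mk_tet <- function(chain_ids, az_deg) {
    rows <- do.call(rbind, lapply(seq_along(chain_ids), function(i) {
      th <- az_deg[i] * pi / 180
      data.frame(chain = chain_ids[i], resno = 1:2, insert = "",
                 resname = "ALA", elety = c("N", "CA"), elesy = c("N", "C"),
                 x = 10 * cos(th), y = 10 * sin(th), z = c(0, 1),
                 het = FALSE, o = 1, stringsAsFactors = FALSE)
    }))
    structure_model(rows, pdb_id = "tet",
                    annotations = structure_annotation())
  }
  m <- mk_tet(c("A", "B", "C", "D"), c(0, 90, 180, 270))
  out <- reorder_and_merge_chains(m)
  expect_equal(out$chain_order, c("A", "B", "C", "D"))
  expect_equal(nrow(residue_table(out)), nrow(residue_table(m)))
  # shuffled chain ids, same geometry -> same geometric order
  m2 <- mk_tet(c("C", "A", "D", "B"), c(180, 0, 270, 90))
  out2 <- reorder_and_merge_chains(m2)
  expect_equal(out2$chain_order, c("A", "B", "C", "D"))
  # flipped extracellular side reverses the cycle
  m3 <- m
  m3$annotations$extracellular_sign <- -1
  out3 <- reorder_and_merge_chains(m3)
  expect_equal(out3$chain_order[1], "A")
  expect_equal(out3$chain_order[-1], rev(out$chain_order[-1]))
})
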