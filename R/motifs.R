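# Selectivity-filter and ligand-pocket motifs: extract the reference motif
# (from annotated filter ranges or from residues contacting a bound ligand),
# look up the structurally equivalent residues of every other structure via
# the reference-anchored MSA, and score identity / BLOSUM62 similarity.

.blosum62_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#' @return the standard 20+ letter BLOSUM62 integer matrix.
#' @export
blosum62 <- function() {
  if (is.null(.blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_env$m <- e$BLOSUM62
  }
  .blosum62_env$m
}

#' Residues lining a ligand-binding pocket
#'
#' A residue is part of the pocket when at least one of its side-chain heavy
#' atoms lies within `cutoff` (inclusive) of any ligand atom. Side chain =
#' heavy atoms excluding backbone N, CA, C, O; glycine can therefore never
#' qualify. With multiple ligand copies the union over copies is returned,
#' ordered by sequence.
#'
#' @param model StructureModel retaining its HETATM records.
#' @param ligand HETATM residue name (e.g. `"LIG"`), or `NULL` for all
#'   hetero atoms.
#' @param cutoff distance (A), default 4.0, inclusive.
#' @return character vector of residue keys in sequence order.
#' @export
pocket_residues <- function(model, ligand = NULL, cutoff = 4.0) {
  a <- model$atoms
  lig <- a$het & (if (is.null(ligand)) TRUE else a$resname %in% ligand)
  if (!any(lig)) stop("ligand selector matches no hetero atoms")
  lig <- lig & toupper(a$elesy) != "H"
  sc <- !a$het & !(a$elety %in% c("N", "CA", "C", "O")) & toupper(a$elesy) != "H"
  if (!any(sc)) return(character())
  lx <- atom_coords(model, lig)
  sx <- atom_coords(model, sc)
  keys <- residue_key(a$chain[sc], a$resno[sc], a$insert[sc])
  hit <- rep(FALSE, nrow(sx))
  for (k in seq_len(nrow(lx))) {
    d2 <- (sx[, 1] - lx[k, 1])^2 + (sx[, 2] - lx[k, 2])^2 +
          (sx[, 3] - lx[k, 3])^2
    hit <- hit | d2 <= cutoff^2
  }
  rt <- residue_table(model)
  intersect(rt$key, unique(keys[hit]))  # sequence order, duplicates collapsed
}

#' Define a motif from MSA columns
#'
#' For a selectivity filter, `residues` are the reference's annotated filter
#' residues (keys); for a ligand pocket, the output of [pocket_residues()] on
#' the reference. Columns are the MSA columns holding those reference
#' residues, in increasing column order.
#'
#' @param msa StructuralMSA whose reference is the motif reference.
#' @param residues reference residue keys.
#' @param name motif label.
#' @param role `"selectivity_filter"` or `"ligand_pocket"`.
#' @return object of class `MotifDefinition`: `name`, `reference_id`,
#'   `columns` (indices), `reference_residues` (1-letter codes), `role`.
#' @export
define_motif <- function(msa, residues, name = "motif",
                         role = c("selectivity_filter", "ligand_pocket")) {
  role <- match.arg(role)
  cols <- match(residues, msa$columns)
  if (any(is.na(cols)))
    stop("reference residues outside the MSA: ",
         paste(residues[is.na(cols)], collapse = ", "))
  cols <- sort(cols)
  structure(list(name = name, reference_id = msa$reference_id,
                 columns = cols,
                 reference_residues = unname(msa$rows[msa$reference_id, cols]),
                 role = role),
            class = "MotifDefinition")
}

#' Selectivity-filter motif from an annotated residue-number range
#'
#' @param msa StructuralMSA.
#' @param sf_range `c(start, end)` author residue numbers of the reference's
#'   filter.
#' @param name motif label.
#' @return [define_motif()] result.
#' @export
filter_motif <- function(msa, sf_range, name = "selectivity_filter") {
  resno <- as.integer(sub("^[^:]*:(-?[0-9]+):.*$", "\\1", msa$columns))
  keys <- msa$columns[resno >= sf_range[1] & resno <= sf_range[2]]
  if (!length(keys))
    stop("selectivity-filter range ", sf_range[1], "-", sf_range[2],
         " matches no MSA columns")
  define_motif(msa, keys, name = name, role = "selectivity_filter")
}

#' Compare one structure's motif against the reference
#'
#' `identity_pct = 100 * n_identical / n_ref` and
#' `similarity_pct = 100 * n_similar / n_ref`, where `n_ref` is the motif
#' length, a residue is similar when its BLOSUM62 score against the reference
#' residue is positive (identities included), and gaps or nonstandard
#' residues in the target count as neither.
#'
#' @param motif MotifDefinition.
#' @param msa StructuralMSA.
#' @param target_id accession of the row to compare.
#' @return object of class `MotifComparison`: `structure_id`, `residues`,
#'   `identity_pct`, `similarity_pct`, `n_ref`.
#' @export
compare_motif <- function(motif, msa, target_id) {
  if (!target_id %in% rownames(msa$rows))
    stop("structure ", target_id, " not in MSA")
  ref <- motif$reference_residues
  tgt <- unname(msa$rows[target_id, motif$columns])
  n_ref <- length(ref)
  b <- blosum62()
  valid <- tgt %in% rownames(b) & tgt != "X" & ref %in% rownames(b)
  n_ident <- sum(valid & tgt == ref)
  n_simil <- sum(valid & b[cbind(match(ref, rownames(b)),
                                 match(tgt, colnames(b)))] > 0, na.rm = TRUE)
  structure(list(structure_id = target_id, residues = tgt,
                 identity_pct = 100 * n_ident / n_ref,
                 similarity_pct = 100 * n_simil / n_ref,
                 n_ref = n_ref),
            class = "MotifComparison")
}

#' Motif identity/similarity heatmap matrix
#'
#' One row per structure (by default every MSA row, in the supplied order,
#' e.g. the cluster leaf order), columns `identity_pct` and `similarity_pct`.
#'
#' @param motif MotifDefinition.
#' @param msa StructuralMSA.
#' @param ids row order; default MSA row order.
#' @return data.frame with `structure_id`, `identity_pct`, `similarity_pct`,
#'   `flag` (`"R"` for the reference, `""` otherwise).
#' @export
motif_heatmap <- function(motif, msa, ids = rownames(msa$rows)) {
  rows <- lapply(ids, function(id) {
    cmp <- compare_motif(motif, msa, id)
    data.frame(structure_id = id, identity_pct = cmp$identity_pct,
               similarity_pct = cmp$similarity_pct,
               flag = if (id == motif$reference_id) "R" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
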