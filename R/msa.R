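# Reference-anchored structural MSA: every structure is placed into the
# coordinate system of one reference's residues using its pairwise alignment;
# insertions relative to the reference are omitted, so the alignment width is
# exactly the reference length.

#' Project pairwise alignments onto a reference into a structural MSA
#'
#' Each non-reference row is built from that structure's pairwise alignment
#' with the reference: a mobile residue aligned to reference position `j` is
#' written into column `j`; mobile residues with no reference partner
#' (insertions) are dropped; reference positions with no partner become gaps.
#' The reference row has no gaps.
#'
#' @param alignments list of `AlignmentResult`, each with the reference as the
#'   stationary or mobile member.
#' @param models named list of StructureModel (names = accessions), including
#'   the reference.
#' @param reference_id accession of the reference structure.
#' @return object of class `StructuralMSA`: `reference_id`, `columns`
#'   (reference residue keys), `rows` (character matrix structures x columns,
#'   1-letter codes or `"-"`), `provenance` (same shape, source residue keys
#'   or `NA`).
#' @export
project_to_reference <- function(alignments, models, reference_id) {
  ref <- models[[reference_id]]
  if (is.null(ref)) stop("reference ", reference_id, " not among models")
  ref_keys <- rownames(ca_coords(ref))
  ncol_ <- length(ref_keys)
  ref_seq <- model_sequence(ref)
  ids <- reference_id
  rows <- matrix(ref_seq[ref_keys], nrow = 1)
  prov <- matrix(ref_keys, nrow = 1)
  for (al in alignments) {
    if (al$stationary_id == reference_id) {
      mob_id <- al$mobile_id
      map_ref <- al$mapping[, "stationary"]
      map_mob <- al$mapping[, "mobile"]
      mob_keys <- al$mobile_keys
    } else if (al$mobile_id == reference_id) {
      mob_id <- al$stationary_id
      map_ref <- al$mapping[, "mobile"]
      map_mob <- al$mapping[, "stationary"]
      mob_keys <- al$stationary_keys
    } else {
      stop("alignment ", al$mobile_id, " -> ", al$stationary_id,
           " does not involve the reference ", reference_id)
    }
    if (mob_id == reference_id) next  # self-alignment adds nothing new
    mob <- models[[mob_id]]
    if (is.null(mob)) stop("model ", mob_id, " missing")
    mob_seq <- model_sequence(mob)
    row <- rep("-", ncol_); prv <- rep(NA_character_, ncol_)
    # first occurrence wins if a reference column is hit twice (possible only
    # at merged-chain junctions; mappings are monotone within a chain)
    dup <- duplicated(map_ref)
    if (any(dup)) warning("duplicate reference columns in alignment of ",
                          mob_id, "; first occurrence kept")
    map_ref <- map_ref[!dup]; map_mob <- map_mob[!dup]
    keys <- mob_keys[map_mob]
    row[map_ref] <- unname(mob_seq[keys])
    prv[map_ref] <- keys
    ids <- c(ids, mob_id)
    rows <- rbind(rows, row)
    prov <- rbind(prov, prv)
  }
  dimnames(rows) <- list(ids, ref_keys)
  dimnames(prov) <- list(ids, ref_keys)
  structure(list(reference_id = reference_id, columns = ref_keys,
                 rows = rows, provenance = prov),
            class = "StructuralMSA")
}

#' @export
print.StructuralMSA <- function(x, ...) {
  cat(sprintf("StructuralMSA: %d structures x %d columns (reference %s)\n",
              nrow(x$rows), length(x$columns), x$reference_id))
  invisible(x)
}

#' Source residue behind one MSA cell
#'
#' @param msa StructuralMSA.
#' @param structure_id row accession.
#' @param column column index (1-based) or reference residue key.
#' @return source residue key, or `NA` for a gap.
#' @export
column_lookup <- function(msa, structure_id, column) {
  if (is.character(column)) column <- match(column, msa$columns)
  stopifnot(!is.na(column), column >= 1, column <= length(msa$columns))
  if (!structure_id %in% rownames(msa$rows))
    stop("structure ", structure_id, " not in MSA")
  msa$provenance[structure_id, column]
}

#' Write a StructuralMSA as aligned FASTA (plus optional provenance TSV)
#'
#' @param msa StructuralMSA.
#' @param path FASTA output path.
#' @param provenance_path optional TSV path (structure_id, column, source key).
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path, provenance_path = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  for (id in rownames(msa$rows)) {
    writeLines(paste0(">", id), con)
    writeLines(paste(msa$rows[id, ], collapse = ""), con)
  }
  if (!is.null(provenance_path)) {
    idx <- which(!is.na(msa$provenance), arr.ind = TRUE)
    tab <- data.frame(structure_id = rownames(msa$rows)[idx[, 1]],
                      column = idx[, 2],
                      source = msa$provenance[idx])
    utils::write.table(tab, provenance_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
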