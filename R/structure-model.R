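#' @useDynLib channelstruct, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats hclust dist cor optim rnorm runif setNames as.dendrogram
#' @importFrom utils read.delim write.csv head tail
NULL

# Atom table columns shared by every StructureModel. Coordinates in Angstrom,
# author numbering for resno; `het` marks HETATM records; `o` is occupancy.
.atom_cols <- c("chain", "resno", "insert", "resname", "elety", "elesy",
                "x", "y", "z", "het", "o")

#' Construct a StructureModel
#'
#' A `StructureModel` is the package's container for atomic coordinates: a flat
#' atom table (one row per atom) plus the accession, the reported resolution
#' and an optional annotation list (membrane normal, TM segments, domain
#' bounds). Residues are identified everywhere by the author-numbering key
#' `chain:resno:insert`; no renumbering takes place on chain merging.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resname`,
#'   `elety` (atom name), `elesy` (element), `x`, `y`, `z`, `het` (logical),
#'   `o` (occupancy).
#' @param pdb_id accession label.
#' @param resolution reported resolution in Angstrom (`NA` if unknown).
#' @param annotations optional list, see [structure_annotation()].
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(atoms, pdb_id = "xxxx", resolution = NA_real_,
                            annotations = NULL) {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(.atom_cols, names(atoms))
  if ("o" %in% missing_cols) { atoms$o <- 1; missing_cols <- setdiff(missing_cols, "o") }
  if ("insert" %in% missing_cols) { atoms$insert <- ""; missing_cols <- setdiff(missing_cols, "insert") }
  if ("het" %in% missing_cols) { atoms$het <- FALSE; missing_cols <- setdiff(missing_cols, "het") }
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms$insert[is.na(atoms$insert)] <- ""
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$elesy)))
    stop("empty element symbols in atom table")
  if (nrow(atoms) == 0L || all(atoms$het))
    stop("empty structure: no protein atoms")
  # order residues by (seq_id, icode) within each chain, chains in first-seen order
  chain_order <- unique(atoms$chain)
  ord <- order(match(atoms$chain, chain_order), atoms$resno, atoms$insert)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(pdb_id = pdb_id, atoms = atoms, resolution = resolution,
                 annotations = annotations),
            class = "StructureModel")
}

#' Structure annotations consumed from membrane-positioning output
#'
#' Holds the per-structure metadata the pipeline consumes but never computes:
#' the membrane normal and which side is extracellular (the role played by
#' OPM/PPM output), TM-segment residue ranges, and domain boundaries.
#'
#' @param subfamily,method,environment,ligand_state qualitative labels.
#' @param membrane_normal unit 3-vector.
#' @param extracellular_sign +1 or -1: sign along `membrane_normal` pointing
#'   to the extracellular side.
#' @param tm_segments data.frame with `start`, `end` residue numbers (author
#'   numbering, applies to each chain).
#' @param domain_bounds named list with elements `TM`, `pore`, `S1S4`, each a
#'   length-2 vector `c(start, end)` of residue numbers.
#' @return list of class `StructureAnnotation`.
#' @export
structure_annotation <- function(subfamily = NA_character_, method = NA_character_,
                                 environment = NA_character_,
                                 ligand_state = "apo",
                                 membrane_normal = c(0, 0, 1),
                                 extracellular_sign = 1,
                                 tm_segments = NULL,
                                 domain_bounds = NULL) {
  n <- sqrt(sum(membrane_normal^2))
  if (!isTRUE(all.equal(n, 1, tolerance = 1e-6)))
    membrane_normal <- membrane_normal / n
  if (!is.null(tm_segments)) {
    stopifnot(all(c("start", "end") %in% names(tm_segments)))
    tm_segments <- tm_segments[order(tm_segments$start), , drop = FALSE]
    if (any(tm_segments$end < tm_segments$start))
      stop("tm_segments ranges reversed")
    if (nrow(tm_segments) > 1 &&
        any(tm_segments$start[-1] <= tm_segments$end[-nrow(tm_segments)]))
      stop("tm_segments overlap")
  }
  structure(list(subfamily = subfamily, method = method,
                 environment = environment, ligand_state = ligand_state,
                 membrane_normal = membrane_normal,
                 extracellular_sign = sign(extracellular_sign),
                 tm_segments = tm_segments, domain_bounds = domain_bounds),
            class = "StructureAnnotation")
}

#' @export
print.StructureModel <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("StructureModel %s: %d chains, %d residues, %d atoms (%d hetero)",
              x$pdb_id, length(unique(x$atoms$chain)), nrow(rt),
              nrow(x$atoms), sum(x$atoms$het)), "\n")
  if (!is.na(x$resolution)) cat(sprintf("  resolution: %.2f A\n", x$resolution))
  invisible(x)
}

#' Residue key strings (`chain:resno:insert`)
#' @param chain,resno,insert vectors of equal length.
#' @return character vector of keys.
#' @export
residue_key <- function(chain, resno, insert = "") {
  insert[is.na(insert) | insert == " "] <- ""
  paste(chain, resno, insert, sep = ":")
}

#' Per-residue summary table of a model
#'
#' @param model StructureModel.
#' @param het include hetero residues? Default drops them.
#' @return data.frame with one row per residue in model order: `chain`,
#'   `resno`, `insert`, `resname`, `key`.
#' @export
residue_table <- function(model, het = FALSE) {
  a <- model$atoms
  if (!het) a <- a[!a$het, , drop = FALSE]
  key <- residue_key(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resname = a$resname[first],
             key = key[first], stringsAsFactors = FALSE)
}

#' CA coordinates of the protein residues of a model
#'
#' @param model StructureModel.
#' @return matrix n x 3 with residue keys as rownames, in residue order.
#' @export
ca_coords <- function(model) {
  a <- model$atoms
  sel <- !a$het & a$elety == "CA"
  a <- a[sel, , drop = FALSE]
  key <- residue_key(a$chain, a$resno, a$insert)
  a <- a[!duplicated(key), , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- residue_key(a$chain, a$resno, a$insert)
  m
}

#' One-letter sequence of a model's protein residues
#' @param model StructureModel.
#' @return character vector of 1-letter codes ('X' for nonstandard), named by
#'   residue key.
#' @export
model_sequence <- function(model) {
  rt <- residue_table(model)
  one <- suppressWarnings(bio3d::aa321(rt$resname))
  one[is.na(one) | !one %in% LETTERS] <- "X"
  setNames(one, rt$key)
}

#' Coordinate matrix of all (or selected) atoms
#' @param model StructureModel.
#' @param sel optional logical vector over atom rows.
#' @return numeric matrix n x 3.
#' @export
atom_coords <- function(model, sel = NULL) {
  a <- model$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Apply a rigid transform to all atoms of a model
#' @param model StructureModel.
#' @param rotation 3x3 proper rotation.
#' @param translation length-3 vector.
#' @return transformed StructureModel.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- atom_coords(model)
  xyz <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}
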