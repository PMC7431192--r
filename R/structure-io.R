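# Coordinate file I/O and the preprocessing steps applied to every structure
# before alignment: resolution filtering, HETATM/loop stripping, domain
# extraction, and counterclockwise chain reordering + merging.

#' Read a coordinate file into a StructureModel
#'
#' Parses PDB or mmCIF through bio3d. Only the first model of multi-model
#' files is used. Alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by alphabetical altloc id, so 'A' wins).
#'
#' @param path file path.
#' @param format `"PDB"` or `"mmCIF"`; guessed from the extension by default.
#' @param annotations optional [structure_annotation()] to attach.
#' @return [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "PDB", "mmCIF"),
                           annotations = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmCIF" else "PDB"
  pdb <- tryCatch(
    if (format == "mmCIF") bio3d::read.cif(path, multi = FALSE)
    else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  at <- pdb$atom
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(!nzchar(trimws(elesy))))
    elesy <- substr(trimws(at$elety), 1, 1)
  elesy <- trimws(elesy)
  elesy[!nzchar(elesy)] <- substr(trimws(at$elety[!nzchar(elesy)]), 1, 1)
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resname = at$resid,
                      elety = trimws(at$elety),
                      elesy = elesy,
                      x = at$x, y = at$y, z = at$z,
                      het = at$type == "HETATM",
                      o = ifelse(is.na(at$o), 1, at$o),
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  alt <- if (!is.null(at$alt)) ifelse(is.na(at$alt), "", at$alt) else rep("", nrow(atoms))
  if (any(nzchar(alt))) atoms <- .resolve_altloc(atoms, alt)
  if (!any(!atoms$het)) stop("no protein residues in ", path)
  res <- .parse_resolution(path, format)
  pdb_id <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  structure_model(atoms, pdb_id = pdb_id, resolution = res,
                  annotations = annotations)
}

# keep, per (residue, atom name), the altloc with highest occupancy;
# ties go to the alphabetically first altloc id
.resolve_altloc <- function(atoms, alt) {
  id <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  ord <- order(id, -atoms$o, alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(id[ord]), , drop = FALSE]
}

.parse_resolution <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (format == "PDB") {
    hit <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
    if (length(hit)) {
      v <- suppressWarnings(as.numeric(sub(".*RESOLUTION\\.\\s*([0-9.]+).*", "\\1", hit[1])))
      return(v)
    }
  } else {
    hit <- grep("_em_3d_reconstruction\\.resolution|_refine\\.ls_d_res_high", lines, value = TRUE)
    if (length(hit)) {
      v <- suppressWarnings(as.numeric(sub(".*?([0-9]+\\.?[0-9]*)\\s*$", "\\1", hit[1])))
      return(v)
    }
  }
  NA_real_
}

#' Write a StructureModel as a PDB file
#'
#' Coordinates round-trip exactly at PDB precision (3 decimals).
#'
#' @param model StructureModel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  n <- nrow(a)
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resname,
                   insert = a$insert, chain = a$chain,
                   elety = a$elety, elesy = a$elesy,
                   o = a$o, b = rep(0, n))
  invisible(path)
}

#' Filter structures by resolution
#'
#' Retains structures whose reported resolution is at or below the cutoff
#' (the boundary is inclusive: 5.0 A passes a 5.0 A cutoff). Structures with
#' unknown resolution are excluded with a warning.
#'
#' @param models list of StructureModel.
#' @param cutoff Angstrom, default 5.0.
#' @return filtered list.
#' @export
filter_by_resolution <- function(models, cutoff = 5.0) {
  if (!length(models)) return(models)
  res <- vapply(models, function(m) as.numeric(m$resolution), numeric(1))
  if (any(is.na(res)))
    warning("excluding ", sum(is.na(res)), " model(s) with unknown resolution")
  models[!is.na(res) & res <= cutoff]
}

#' Remove HETATM records and truncate long inter-segment loops
#'
#' Drops all hetero atoms, then reduces any loop between two annotated TM
#' segments that is longer than 100 residues to the 10 residues adjacent to
#' each flanking segment. Loops of 100 residues or fewer are untouched.
#' Idempotent.
#'
#' @param model StructureModel with `tm_segments` annotated.
#' @return stripped StructureModel.
#' @export
strip_and_truncate <- function(model) {
  ann <- model$annotations
  if (is.null(ann) || is.null(ann$tm_segments))
    stop("strip_and_truncate needs tm_segments annotation")
  a <- model$atoms[!model$atoms$het, , drop = FALSE]
  seg <- ann$tm_segments
  keep <- rep(TRUE, nrow(a))
  if (nrow(seg) > 1) {
    for (k in seq_len(nrow(seg) - 1)) {
      lo <- seg$end[k]; hi <- seg$start[k + 1]
      for (ch in unique(a$chain)) {
        in_loop <- a$chain == ch & a$resno > lo & a$resno < hi
        loop_res <- sort(unique(a$resno[in_loop]))
        if (length(loop_res) > 100) {
          keep_res <- c(head(loop_res, 10), tail(loop_res, 10))
          keep[in_loop & !(a$resno %in% keep_res)] <- FALSE
        }
      }
    }
  }
  model$atoms <- a[keep, , drop = FALSE]
  model
}

#' Extract an annotated domain from a model
#'
#' `TM` and `pore` extractions keep all chains; `S1S4` keeps a single
#' protomer (the first chain in current chain order).
#'
#' @param model StructureModel with `domain_bounds` annotated.
#' @param which `"TM"`, `"pore"` or `"S1S4"`.
#' @return domain-restricted StructureModel.
#' @export
extract_domain <- function(model, which = c("TM", "pore", "S1S4")) {
  which <- match.arg(which)
  ann <- model$annotations
  if (is.null(ann) || is.null(ann$domain_bounds) ||
      is.null(ann$domain_bounds[[which]]))
    stop("domain_bounds for ", which, " not annotated")
  b <- ann$domain_bounds[[which]]
  a <- model$atoms
  sel <- !a$het & a$resno >= b[1] & a$resno <= b[2]
  if (which == "S1S4") sel <- sel & a$chain == a$chain[1]
  if (!any(sel))
    stop("domain ", which, " bounds ", b[1], "-", b[2], " match no residues")
  have <- unique(a$resno[sel])
  if (!(b[1] %in% have) || !(b[2] %in% have))
    warning("domain ", which, " bounds ", b[1], "-", b[2],
            " partially absent (have ", min(have), "-", max(have), ")")
  model$atoms <- a[sel, , drop = FALSE]
  model
}

#' Reorder chains counterclockwise and merge into a single traversal
#'
#' Chains are sorted by the azimuthal angle of their centroids in the membrane
#' plane, traversed counterclockwise as viewed from the extracellular side,
#' starting from the chain nearest azimuth 0 (ties by chain id). With
#' `merge = TRUE` the sorted chains are concatenated into one continuous
#' residue traversal (the `merged` flag is set and downstream stages treat the
#' model as single-chain); author chain ids and residue numbers are preserved
#' so residue keys stay authoritative — a synthetic serial index is implied by
#' row order. Residue count is unchanged.
#'
#' @param model StructureModel with `membrane_normal` and `extracellular_sign`
#'   annotated; at least two chains.
#' @param merge flag the result as one merged traversal (default TRUE).
#' @return reordered StructureModel.
#' @export
reorder_and_merge_chains <- function(model, merge = TRUE) {
  ann <- model$annotations
  if (is.null(ann)) stop("annotations with membrane_normal required")
  a <- model$atoms
  chains <- unique(a$chain)
  if (length(chains) < 2) stop("need >= 2 chains to reorder")
  n <- ann$membrane_normal * ann$extracellular_sign  # points extracellular
  # orthonormal in-plane basis (e1, e2) such that (e1, e2, n) is right-handed:
  # viewed from the extracellular side (down -n), increasing azimuth
  # atan2(<c,e2>, <c,e1>) is counterclockwise
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  origin <- colMeans(atom_coords(model, !a$het))
  cent <- t(vapply(chains, function(ch)
    colMeans(atom_coords(model, a$chain == ch)), numeric(3)))
  rel <- sweep(cent, 2, origin)
  u <- rel %*% cbind(e1, e2)
  r2 <- rowSums(u^2)
  if (all(r2 < 1e-6)) {
    warning("degenerate chain geometry; falling back to lexicographic order")
    ord <- order(chains)
  } else {
    az <- atan2(u[, 2], u[, 1]) %% (2 * pi)
    az[az > 2 * pi - 1e-9] <- 0   # numerical wraparound lands on azimuth 0
    ord <- order(az, chains)
  }
  chains_sorted <- chains[ord]
  pieces <- lapply(chains_sorted, function(ch) a[a$chain == ch, , drop = FALSE])
  a2 <- do.call(rbind, pieces)
  rownames(a2) <- NULL
  out <- model
  out$atoms <- a2  # constructor bypassed: merged residue order is geometric
  out$merged <- isTRUE(merge)
  out$chain_order <- chains_sorted
  out
}

#' Read a per-structure annotation table
#'
#' TSV with columns `pdb_id`, `subfamily`, `method`, `environment`,
#' `ligand_state`, `tm_start`, `tm_end`, `pore_start`, `pore_end`,
#' `s1s4_start`, `s1s4_end`, `tm_segments` (semicolon-separated
#' `start-end` pairs), `normal_x`, `normal_y`, `normal_z`,
#' `extracellular_sign`.
#'
#' @param path TSV path.
#' @return named list of [structure_annotation()] keyed by `pdb_id`.
#' @export
read_annotation_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    segs <- do.call(rbind, lapply(strsplit(r$tm_segments, ";")[[1]], function(s) {
      p <- as.integer(strsplit(s, "-")[[1]])
      data.frame(start = p[1], end = p[2])
    }))
    structure_annotation(
      subfamily = r$subfamily, method = r$method, environment = r$environment,
      ligand_state = r$ligand_state,
      membrane_normal = c(r$normal_x, r$normal_y, r$normal_z),
      extracellular_sign = r$extracellular_sign,
      tm_segments = segs,
      domain_bounds = list(TM = c(r$tm_start, r$tm_end),
                           pore = c(r$pore_start, r$pore_end),
                           S1S4 = c(r$s1s4_start, r$s1s4_end)))
  })
  names(out) <- tab$pdb_id
  out
}
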