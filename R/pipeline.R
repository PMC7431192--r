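# End-to-end orchestration: ingest -> preprocess -> bidirectional alignment
# -> clustering -> reference-anchored MSA -> pore profiles -> secondary
# structure -> motif heatmaps, with per-structure failure capture and
# deterministic, manifest-hashed outputs.

#' Run manifest
#'
#' @param entries data.frame with columns `id`, `path` (PDB/mmCIF file) and
#'   the annotation columns of [read_annotation_table()] (or a `annotation`
#'   list-column of [structure_annotation()] objects).
#' @param reference_id accession used as the MSA reference.
#' @param domains domains to align (subset of `TM`, `pore`, `S1S4`).
#' @param out_dir output directory.
#' @param seed integer master seed.
#' @param pore_step profile plane spacing (A).
#' @return list of class `RunManifest`.
#' @export
run_manifest <- function(entries, reference_id, domains = "TM",
                         out_dir = tempfile("channelstruct_"), seed = 1L,
                         pore_step = 0.25) {
  stopifnot(is.data.frame(entries), all(c("id") %in% names(entries)),
            reference_id %in% entries$id)
  structure(list(entries = entries, reference_id = reference_id,
                 domains = domains, out_dir = out_dir, seed = as.integer(seed),
                 pore_step = pore_step),
            class = "RunManifest")
}

.manifest_hash <- function(manifest) {
  tf <- tempfile()
  on.exit(unlink(tf))
  ent <- manifest$entries
  ent$annotation <- NULL
  utils::write.csv(ent[order(ent$id), , drop = FALSE], tf, row.names = FALSE)
  unname(tools::md5sum(tf))
}

#' Execute the full pipeline described by a manifest
#'
#' Stages: read structures (or take prebuilt models), strip/truncate, extract
#' each requested domain, reorder/merge chains, all-vs-all bidirectional
#' alignment per domain, TM-distance single-linkage clustering along the
#' stationary axis, projection of the all-vs-reference alignments into a
#' structural MSA, pore profiling + lining assignment on the pore domain,
#' secondary-structure assignment with S6 pi statistics, gate-state tallies,
#' and (optionally) motif heatmaps. Per-structure stage failures are recorded
#' and the run continues. Deterministic given manifest + seed; every CSV
#' carries the manifest hash in a leading comment.
#'
#' @param manifest [run_manifest()].
#' @param models optional named list of prebuilt StructureModel (bypasses
#'   file reading; keyed by `entries$id`).
#' @param sf_range optional selectivity-filter residue range of the reference
#'   (enables the filter-motif heatmap).
#' @param write_outputs write CSV/FASTA outputs under `out_dir` (default
#'   TRUE).
#' @return run report list: `score` (per domain, ScoreMatrix), `clusters`,
#'   `msa`, `profiles`, `lining`, `secstruct`, `pi_stats`, `gate_tally`,
#'   `motifs`, `failures`, `manifest_hash`, `out_dir`.
#' @export
run_pipeline <- function(manifest, models = NULL, sf_range = NULL,
                         write_outputs = TRUE) {
  ent <- manifest$entries
  ids <- ent$id
  failures <- list()
  note_failure <- function(id, stage, e) {
    failures[[length(failures) + 1]] <<- data.frame(
      id = id, stage = stage, error = conditionMessage(e))
    NULL
  }
  if (is.null(models)) {
    models <- setNames(vector("list", length(ids)), ids)
    for (i in seq_along(ids)) {
      ann <- if (!is.null(ent$annotation)) ent$annotation[[i]] else NULL
      models[[i]] <- tryCatch(read_structure(ent$path[i], annotations = ann),
                              error = function(e) note_failure(ids[i], "read", e))
      if (!is.null(models[[i]])) models[[i]]$pdb_id <- ids[i]
    }
  }
  ok <- !vapply(models, is.null, logical(1))
  models <- models[ok]

  # preprocess per domain
  prep <- function(m, domain) {
    m <- strip_and_truncate(m)
    m <- extract_domain(m, domain)
    if (domain != "S1S4" && length(unique(m$atoms$chain)) > 1)
      m <- reorder_and_merge_chains(m)
    m
  }
  hash <- .manifest_hash(manifest)
  out_dir <- manifest$out_dir
  if (write_outputs) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  comment <- paste0("manifest_md5=", hash, " seed=", manifest$seed)

  report <- list(score = list(), clusters = list(), manifest_hash = hash,
                 out_dir = out_dir)
  domain_models <- list()
  for (domain in manifest$domains) {
    dm <- list()
    for (id in names(models)) {
      m <- tryCatch(prep(models[[id]], domain),
                    error = function(e) note_failure(id, paste0("prep_", domain), e))
      if (!is.null(m)) dm[[id]] <- m
    }
    domain_models[[domain]] <- dm
    sm <- score_matrix_all(dm)
    cl <- cluster_stationary(tm_distance(sm))
    report$score[[domain]] <- sm
    report$clusters[[domain]] <- cl
    if (write_outputs) {
      write_ordered_matrix(cl, file.path(out_dir, paste0("tmscore_", domain, ".csv")),
                           comment = comment)
    }
  }

  # MSA on the first domain (TM in the standard run)
  d1 <- manifest$domains[1]
  dm <- domain_models[[d1]]
  if (manifest$reference_id %in% names(dm)) {
    ref <- dm[[manifest$reference_id]]
    alns <- lapply(dm, function(m) fragment_align(m, ref))
    report$msa <- project_to_reference(alns, dm, manifest$reference_id)
    if (write_outputs)
      write_msa_fasta(report$msa, file.path(out_dir, "structural_msa.fasta"),
                      file.path(out_dir, "structural_msa_provenance.tsv"))
  }

  # pore profiles + lining + secstruct on the pore-domain tetramer
  report$profiles <- list(); report$lining <- list()
  report$secstruct <- list(); pi_records <- list()
  for (id in names(models)) {
    res <- tryCatch({
      pm <- strip_and_truncate(models[[id]])
      pm <- extract_domain(pm, "pore")
      prof <- pore_profile(pm, step = manifest$pore_step, seed = manifest$seed)
      lin <- lining_residues(pm, prof)
      ss <- assign_secstruct(pm)
      bounds <- models[[id]]$annotations$domain_bounds$pore
      s6 <- c(mean(bounds), bounds[2])  # intracellular-facing half by number
      list(prof = prof, lin = lin, ss = ss,
           pi_len = max_consecutive_pi(ss, window = s6),
           s6_min = window_min_radius(lin, window = s6))
    }, error = function(e) note_failure(id, "pore", e))
    if (is.null(res)) next
    report$profiles[[id]] <- res$prof
    report$lining[[id]] <- res$lin
    report$secstruct[[id]] <- res$ss
    pi_records[[id]] <- data.frame(id = id, pi_len = res$pi_len,
                                   min_radius = res$s6_min)
    if (write_outputs) {
      write_profile_csv(res$prof, file.path(out_dir, paste0("pore_", id, ".csv")),
                        comment = comment)
      write_secstruct_tsv(res$ss, file.path(out_dir, paste0("secstruct_", id, ".tsv")),
                          structure_id = id)
    }
  }
  report$pi_stats <- if (length(pi_records)) do.call(rbind, pi_records) else NULL

  # gate-state tally by annotated ligand state
  states <- vapply(names(report$profiles), function(id) {
    ann <- models[[id]]$annotations
    if (is.null(ann)) "unknown" else ann$ligand_state
  }, character(1))
  report$gate_tally <- summarize_gate_states(report$profiles, states)
  if (write_outputs && !is.null(report$gate_tally))
    utils::write.csv(report$gate_tally,
                     file.path(out_dir, "gate_tally.csv"), row.names = FALSE)

  # motif heatmap from the reference's annotated selectivity filter
  if (!is.null(sf_range) && !is.null(report$msa)) {
    motif <- filter_motif(report$msa, sf_range)
    leaf <- report$clusters[[d1]]$leaf_order
    leaf <- leaf[leaf %in% rownames(report$msa$rows)]
    report$motifs <- motif_heatmap(motif, report$msa, ids = leaf)
    if (write_outputs)
      utils::write.csv(report$motifs, file.path(out_dir, "motif_heatmap.csv"),
                       row.names = FALSE)
  }
  report$failures <- if (length(failures)) do.call(rbind, failures) else NULL
  report
}

#' Tally closed-gate structures per ligand-state group
#'
#' A structure counts as multiply constricted when its profile contains at
#' least two maximal runs of consecutive samples with radius at or below
#' `radius_cut`, separated along z by more than `min_separation` (about one
#' helical residue rise).
#'
#' @param profiles named list of PoreProfile.
#' @param states character vector of ligand-state labels, same names/order.
#' @param radius_cut constriction radius (A), default 1.0.
#' @param min_separation minimum z gap between distinct constrictions (A),
#'   default 1.5.
#' @return data.frame: `ligand_state`, `n`, `n_multi_constricted`.
#' @export
summarize_gate_states <- function(profiles, states, radius_cut = 1.0,
                                  min_separation = 1.5) {
  if (!length(profiles)) return(NULL)
  multi <- vapply(profiles, function(p) {
    s <- p$samples
    narrow <- s$radius <= radius_cut
    if (!any(narrow)) return(FALSE)
    r <- rle(narrow)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    runs <- which(r$values)
    if (length(runs) < 2) return(FALSE)
    z_start <- s$z[starts[runs]]; z_end <- s$z[ends[runs]]
    any(z_start[-1] - z_end[-length(z_end)] > min_separation)
  }, logical(1))
  tab <- data.frame(ligand_state = states, multi = multi)
  agg <- stats::aggregate(multi ~ ligand_state, tab,
                   function(v) c(n = length(v), k = sum(v)))
  data.frame(ligand_state = agg$ligand_state,
             n = agg$multi[, "n"], n_multi_constricted = agg$multi[, "k"])
}
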