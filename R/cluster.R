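# TM-distance clustering. The score matrix is asymmetric (stationary-length
# normalization), so items are the stationary structures (columns); each
# item's feature vector is its column of TM-distances from every mobile
# structure, and single linkage runs on Euclidean distances between those
# vectors.

#' Convert a TM-score matrix to TM-distance
#'
#' Elementwise `1 - TM-score`; applying it twice returns the original.
#'
#' @param matrix `ScoreMatrix` (see [score_matrix_all()]) or plain numeric
#'   matrix.
#' @return same type as the input.
#' @export
tm_distance <- function(matrix) {
  if (inherits(matrix, "ScoreMatrix")) {
    matrix$values <- 1 - matrix$values
    matrix
  } else 1 - matrix
}

#' Single-linkage clustering along the stationary axis
#'
#' Clusters the stationary structures (columns) of a TM-distance matrix:
#' item `j`'s feature vector is column `j`, pairwise dissimilarity is the
#' Euclidean distance between columns, and agglomeration is single linkage
#' (nearest point). Rows are reordered to the same leaf order for display.
#'
#' @param dist `ScoreMatrix` of TM-distances, or a numeric matrix
#'   (rows = mobile, columns = stationary).
#' @return list with `hclust` (the tree), `leaf_order` (column ids in
#'   dendrogram order), `ordered` (the input matrix with rows and columns in
#'   leaf order).
#' @export
cluster_stationary <- function(dist) {
  v <- if (inherits(dist, "ScoreMatrix")) dist$values else as.matrix(dist)
  if (any(is.na(v))) {
    bad <- which(is.na(v), arr.ind = TRUE)[1, ]
    stop("NaN distance for pair ", rownames(v)[bad[1]], " -> ",
         colnames(v)[bad[2]], ": pairwise alignment failed")
  }
  d <- stats::dist(t(v), method = "euclidean")
  hc <- stats::hclust(d, method = "single")
  leaf_order <- unname(colnames(v)[hc$order])
  # rows are reordered to the leaf order only for square all-vs-all matrices
  row_order <- if (!is.null(rownames(v)) && setequal(rownames(v), colnames(v)))
    leaf_order else rownames(v)
  structure(list(hclust = hc, leaf_order = leaf_order,
                 ordered = v[row_order, leaf_order, drop = FALSE]),
            class = "ClusterResult")
}

#' Cut the stationary-axis tree into k groups
#' @param cl `ClusterResult` from [cluster_stationary()].
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cluster_groups <- function(cl, k) stats::cutree(cl$hclust, k = k)

#' Write an ordered score/distance matrix as CSV
#'
#' Header row and first column carry the accessions in leaf order, mirroring
#' the clustered-heatmap source-data layout.
#'
#' @param cl `ClusterResult`.
#' @param path output CSV.
#' @param comment optional `# key=value` comment line written first.
#' @return `path`, invisibly.
#' @export
write_ordered_matrix <- function(cl, path, comment = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  m <- cl$ordered
  writeLines(paste(c("", colnames(m)), collapse = ","), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], format(m[i, ], digits = 15)),
                     collapse = ","), con)
  invisible(path)
}
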