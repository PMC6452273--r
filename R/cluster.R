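#' Build the signed association matrix
#'
#' Combines the screening and phylogenetic test outcomes into a cas x system
#' matrix with entries in `{-1, 0, +1}`: `+1` for a pair that is Bonferroni
#' significant, passes the median-LRT rule and has positive phi; `-1`
#' likewise with negative phi; `0` otherwise. Rows and columns with no
#' nonzero entry are dropped (only traits presenting at least one significant
#' association are represented).
#'
#' @param screen a `screen_result` from [screen_associations()].
#' @param phylo data.frame with columns `system`, `cas`, `significant`
#'   (logical), one row per pair on which the phylogenetic test was run;
#'   every Bonferroni-significant pair must be present.
#' @return integer matrix (rows = cas ids, columns = system ids), possibly
#'   0 x 0 when no association survives both tests.
#' @export
signed_matrix <- function(screen, phylo) {
  stopifnot(inherits(screen, "screen_result"), is.data.frame(phylo))
  req <- c("system", "cas", "significant")
  if (!all(req %in% names(phylo))) {
    stop("phylo results need columns: ", paste(req, collapse = ", "))
  }
  rec <- screen$records
  key <- function(s, ca) paste(s, ca, sep = "\r")
  phylo_sig <- setNames(as.logical(phylo$significant),
                        key(phylo$system, phylo$cas))
  need <- rec$bonferroni_significant
  missing <- !(key(rec$system, rec$cas)[need] %in% names(phylo_sig))
  if (any(missing)) {
    bad <- which(need)[missing][1L]
    stop("missing phylogenetic test outcome for pair (",
         rec$system[bad], ", ", rec$cas[bad], ")")
  }
  cas_ids <- unique(rec$cas)
  sys_ids <- unique(rec$system)
  mat <- matrix(0L, nrow = length(cas_ids), ncol = length(sys_ids),
                dimnames = list(cas_ids, sys_ids))
  for (i in which(need)) {
    if (isTRUE(phylo_sig[[key(rec$system[i], rec$cas[i])]]) &&
        !is.na(rec$phi[i]) && rec$phi[i] != 0) {
      mat[rec$cas[i], rec$system[i]] <- if (rec$phi[i] > 0) 1L else -1L
    }
  }
  keep_r <- rowSums(mat != 0L) > 0L
  keep_c <- colSums(mat != 0L) > 0L
  mat[keep_r, keep_c, drop = FALSE]
}

#' Single-linkage clustering of a signed association matrix
#'
#' Clusters rows and columns independently by agglomerative single-linkage
#' (nearest-neighbour) hierarchical clustering on Euclidean distances, the
#' default of the heatmap-clustering routines common in this field. Returns
#' leaf orders and merge tables rather than a rendered figure.
#'
#' @param mat numeric/integer matrix with at least one row and column;
#'   typically the output of [signed_matrix()].
#' @return list with `row_order` and `col_order` (leaf labels in dendrogram
#'   order) and `row_merge`/`col_merge` data.frames (`child1`, `child2`,
#'   `distance`; negative indices are leaves, positive ones earlier merges,
#'   as in [stats::hclust()]).
#' @export
cluster_signed <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 1L || ncol(mat) < 1L) {
    stop("cannot cluster an empty matrix")
  }
  list(row_order = dimension_cluster(mat)$order,
       col_order = dimension_cluster(t(mat))$order,
       row_merge = dimension_cluster(mat)$merge,
       col_merge = dimension_cluster(t(mat))$merge)
}

dimension_cluster <- function(m) {
  labs <- rownames(m) %||% as.character(seq_len(nrow(m)))
  if (nrow(m) == 1L) {
    return(list(order = labs,
                merge = data.frame(child1 = integer(), child2 = integer(),
                                   distance = numeric())))
  }
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "single")
  list(order = labs[hc$order],
       merge = data.frame(child1 = hc$merge[, 1L], child2 = hc$merge[, 2L],
                          distance = hc$height))
}

#' Cophenetic (dendrogram) distances of a single-linkage clustering
#'
#' Helper exposing the merge heights as a distance matrix between leaves;
#' single-linkage cophenetic distances are invariant to tie-breaking and so
#' give a canonical summary of the clustering.
#'
#' @param m matrix whose rows are clustered.
#' @return a `dist` object of cophenetic distances between rows.
#' @export
cophenetic_single <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  stats::cophenetic(stats::hclust(stats::dist(m), method = "single"))
}
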