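#' Correlation distance between feature profiles
#'
#' `d_ij = 1 - r_ij` with r the Pearson correlation between feature rows,
#' so d ranges over [0, 2]. Clustering needs complete distances: rows with
#' missing samples are handled per `missing` — `"error"` (default),
#' `"impute"` (per-feature mean imputation, logged) or `"drop"` (drop
#' incomplete features).
#'
#' @param m [omics_matrix()] or plain numeric matrix (features in rows).
#' @param missing policy for missing cells.
#' @return `dist` object.
#' @export
correlation_distance <- function(m, missing = c("error", "impute", "drop")) {
  missing <- match.arg(missing)
  vals <- if (inherits(m, "omics_matrix")) m$values else m
  if (nrow(vals) < 2L) stop("need at least 2 features")
  if (anyNA(vals)) {
    if (missing == "error")
      stop("matrix has missing values; impute or drop before clustering")
    if (missing == "drop") {
      vals <- vals[stats::complete.cases(vals), , drop = FALSE]
      message("correlation_distance: dropped incomplete features")
    } else {
      rm_ <- rowMeans(vals, na.rm = TRUE)
      idx <- which(is.na(vals), arr.ind = TRUE)
      vals[idx] <- rm_[idx[, 1L]]
      message(sprintf("correlation_distance: mean-imputed %d cells",
                      nrow(idx)))
    }
  }
  r <- stats::cor(t(vals))
  if (anyNA(r)) stop("zero-variance feature(s): correlation undefined")
  d <- 1 - r
  diag(d) <- 0
  stats::as.dist(d)
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise distance; merge heights are therefore nondecreasing,
#' which is asserted on every run.
#'
#' @param d `dist` object (typically from [correlation_distance()]).
#' @return `hclust` object.
#' @export
hca_complete <- function(d) {
  if (any(!is.finite(d))) stop("non-finite distances")
  t <- stats::hclust(d, method = "complete")
  if (is.unsorted(t$height, strictly = FALSE))
    stop("internal error: non-monotone complete-linkage heights")
  t
}

#' Cut a tree at a similarity threshold
#'
#' Cuts at height `1 - min_sim`: leaves joined at or below that height form
#' one cluster, so every within-cluster cophenetic similarity is
#' >= `min_sim`.
#'
#' @param tree `hclust` object.
#' @param min_sim similarity threshold in [-1, 1].
#' @return named integer vector, leaf id -> cluster label.
#' @export
cut_by_similarity <- function(tree, min_sim) {
  stopifnot(min_sim >= -1, min_sim <= 1)
  stats::cutree(tree, h = 1 - min_sim)
}

#' Genes co-clustered with volatile groups in a joint tree
#'
#' Cuts the joint gene+volatile tree at `min_sim`; each resulting cluster
#' that contains at least one volatile defines a volatile group, and the
#' genes sharing its subtree (i.e. joining it at cophenetic similarity
#' >= `min_sim`) carry "HCA evidence" for that group.
#'
#' @param tree joint `hclust` over gene and volatile leaves.
#' @param volatile_ids character vector of volatile leaf ids.
#' @param min_sim similarity threshold (study default 0.6).
#' @return named list, one element per volatile-containing cluster, each a
#'   list with `volatiles` and `genes`.
#' @export
co_clustered_genes <- function(tree, volatile_ids, min_sim) {
  missing_v <- setdiff(volatile_ids, tree$labels)
  if (length(missing_v))
    stop("volatiles absent from tree: ", paste(missing_v, collapse = ", "))
  cl <- cut_by_similarity(tree, min_sim)
  vol_cl <- sort(unique(cl[volatile_ids]))
  out <- lapply(vol_cl, function(k) {
    members <- names(cl)[cl == k]
    list(volatiles = sort(intersect(members, volatile_ids)),
         genes = sort(setdiff(members, volatile_ids)))
  })
  names(out) <- sprintf("VC%d", seq_along(out))
  out
}

#' Export a tree in Newick format
#'
#' Branch lengths carry the merge heights (correlation distances).
#'
#' @param tree `hclust` object.
#' @param path output file path.
#' @export
export_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(NULL)
}
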