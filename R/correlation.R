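#' All-pairs Pearson correlation between genes and volatiles
#'
#' Computes the dense gene-by-volatile Pearson correlation matrix over
#' pairwise-complete samples, plus the volatile-volatile block (needed for
#' the volatile network) and optionally the gene-gene block. Pairs with
#' fewer than `min_n` shared non-missing samples are masked; zero-variance
#' profiles yield masked correlations with a warning, never 0.
#'
#' @param genes,volatiles [omics_matrix()] objects sharing sample columns.
#' @param min_n minimum shared samples per pair (default 3).
#' @param include_gene_gene also compute the (possibly large) gene-gene
#'   block.
#' @return object of class `correlation_set`: list with `gene_vol`,
#'   `vol_vol`, optionally `gene_gene`, and `n_used` (samples per
#'   gene-volatile pair).
#' @export
pearson_all_pairs <- function(genes, volatiles, min_n = 3L,
                              include_gene_gene = FALSE) {
  stopifnot(inherits(genes, "omics_matrix"),
            inherits(volatiles, "omics_matrix"))
  common <- shared_samples(genes, volatiles)
  G <- genes$values[, common, drop = FALSE]
  V <- volatiles$values[, common, drop = FALSE]
  n_used <- (!is.na(G)) %*% t(!is.na(V))
  suppressWarnings({
    gv <- stats::cor(t(G), t(V), use = "pairwise.complete.obs")
    vv <- stats::cor(t(V), use = "pairwise.complete.obs")
  })
  gv[n_used < min_n] <- NA_real_
  if (anyNA(gv[n_used >= min_n]))
    warning("zero-variance profiles produced masked correlations")
  diag(vv) <- 1
  out <- list(gene_vol = gv, vol_vol = vv, n_used = n_used)
  if (include_gene_gene) {
    suppressWarnings(out$gene_gene <- stats::cor(t(G),
                                                 use = "pairwise.complete.obs"))
    diag(out$gene_gene) <- 1
  }
  class(out) <- "correlation_set"
  out
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(sprintf("correlation_set: %d genes x %d volatiles (%d masked pairs)\n",
              nrow(x$gene_vol), ncol(x$gene_vol), sum(is.na(x$gene_vol))))
  invisible(x)
}

#' Range of gene correlations for one volatile
#'
#' @param cs [pearson_all_pairs()] result.
#' @param volatile_id column id.
#' @return named numeric vector `c(min, max)` over unmasked gene
#'   correlations.
#' @export
correlation_range <- function(cs, volatile_id) {
  stopifnot(inherits(cs, "correlation_set"))
  if (!volatile_id %in% colnames(cs$gene_vol))
    stop("unknown volatile: ", volatile_id)
  r <- cs$gene_vol[, volatile_id]
  r <- r[!is.na(r)]
  if (!length(r)) stop("all correlations masked for ", volatile_id)
  c(min = min(r), max = max(r))
}

#' Top-k genes correlated with a volatile
#'
#' Genes ranked by signed r (descending; "highest direct correlation") or
#' by |r|. Ties are broken by lexicographic gene id; masked pairs are
#' skipped.
#'
#' @param cs [pearson_all_pairs()] result.
#' @param volatile_id column id.
#' @param k list length (>= 1); fewer rows if fewer genes are available.
#' @param signed rank by signed r (TRUE, default) or by |r|.
#' @return data.frame(`gene_id`, `r`, `rank`).
#' @export
top_k_correlated <- function(cs, volatile_id, k = 10L, signed = TRUE) {
  stopifnot(inherits(cs, "correlation_set"), k >= 1L)
  if (!volatile_id %in% colnames(cs$gene_vol))
    stop("unknown volatile: ", volatile_id)
  r <- cs$gene_vol[, volatile_id]
  r <- r[!is.na(r)]
  key <- if (signed) r else abs(r)
  ord <- order(-key, names(r))
  take <- ord[seq_len(min(k, length(ord)))]
  data.frame(gene_id = names(r)[take], r = unname(r[take]),
             rank = seq_along(take), stringsAsFactors = FALSE)
}
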