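#' Construct an omics matrix
#'
#' Container for a features-by-samples matrix of log2(sample/reference)
#' values with sample design and feature metadata. Missing values are `NA`
#' in `values`; the missing mask is implicit.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Row names are feature ids, column names sample ids.
#' @param samples data.frame with columns `sample_id`, `genotype`, `stage`,
#'   `replicate`, one row per column of `values` (same order).
#' @param features optional data.frame with columns `feature_id`, `kind`
#'   (`"gene"` or `"volatile"`), `annotation`, `tags` (`;`-separated),
#'   `volatile_cluster`. Defaults are built from the row names.
#' @return An object of class `omics_matrix`: a list with elements
#'   `values`, `samples`, `features`.
#' @export
omics_matrix <- function(values, samples, features = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have feature row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids in matrix")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "genotype", "stage", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample design lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in design")
  if (!all(colnames(values) %in% samples$sample_id))
    stop("matrix columns not described in design: ",
         paste(setdiff(colnames(values), samples$sample_id), collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(features)) {
    features <- data.frame(feature_id = rownames(values),
                           kind = "gene", annotation = "",
                           tags = "", volatile_cluster = NA_character_,
                           stringsAsFactors = FALSE)
  } else {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
    if (!all(rownames(values) %in% features$feature_id))
      stop("matrix rows missing from feature metadata")
    features <- features[match(rownames(values), features$feature_id), ,
                         drop = FALSE]
    rownames(features) <- NULL
  }
  bad <- which(!is.na(values) & !is.finite(values))
  if (length(bad)) stop("non-finite, non-missing values in matrix")
  structure(list(values = values, samples = samples, features = features),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

.na_tokens <- c("na", "nan", "")

#' Read a sample design table
#'
#' Tab-delimited table with columns `sample_id`, `genotype`, `stage`,
#' `replicate`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("sample_id", "genotype", "stage", "replicate")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("design lacks columns: ", paste(miss, collapse = ", "))
  d$replicate <- as.integer(d$replicate)
  if (any(is.na(d$replicate)) || any(d$replicate < 1))
    stop("replicate must be a positive integer")
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in design")
  d
}

#' Read a feature annotation table
#'
#' Tab-delimited table with columns `feature_id`, `kind`, `annotation`,
#' `tags` (`;`-separated), `volatile_cluster`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("feature_id", "kind") %in% names(a)))
    stop("annotation lacks feature_id/kind columns")
  if (!all(a$kind %in% c("gene", "volatile")))
    stop("kind must be 'gene' or 'volatile'")
  if (any(nzchar(a$volatile_cluster[a$kind == "gene"]) &
          !is.na(a$volatile_cluster[a$kind == "gene"])))
    stop("volatile_cluster may only be set for volatiles")
  a
}

#' Read a feature-by-sample matrix
#'
#' First column feature ids, header row sample ids that must all appear in
#' the design. Tab- or comma-delimited (sniffed from the header line).
#' `NA`, `nan` and empty cells (case-insensitive) are treated as missing.
#'
#' @param path file path.
#' @param design sample design data.frame (see [read_design()]).
#' @param features optional feature annotation data.frame.
#' @return [omics_matrix()].
#' @export
read_matrix <- function(path, design, features = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature id in matrix file: ",
         ids[anyDuplicated(ids)][1L])
  sample_ids <- names(tab)[-1L]
  unknown <- setdiff(sample_ids, design$sample_id)
  if (length(unknown))
    stop("samples in header absent from design: ",
         paste(unknown, collapse = ", "))
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  raw[tolower(trimws(raw)) %in% .na_tokens] <- NA
  vals <- matrix(as.numeric(raw), nrow = nrow(raw),
                 dimnames = list(ids, sample_ids))
  message(sprintf("read_matrix: %d features x %d samples, %d missing",
                  nrow(vals), ncol(vals), sum(is.na(vals))))
  omics_matrix(vals, design[match(sample_ids, design$sample_id), ,
                            drop = FALSE], features)
}

#' Write an omics matrix to TSV
#'
#' Deterministic row/column order (as stored); missing cells written as
#' `NA`. Byte-identical output for identical input.
#'
#' @param m [omics_matrix()].
#' @param path output file path.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(m$values)), collapse = "\t"), con)
  body <- apply(m$values, 1L, function(row)
    paste(ifelse(is.na(row), "NA", sprintf("%.15g", row)), collapse = "\t"))
  writeLines(paste(rownames(m$values), body, sep = "\t"), con)
  invisible(NULL)
}

#' Analysis configuration
#'
#' All thresholds used across the pipeline, with the study's defaults:
#' network preselection at |r| > 0.85, a secondary 0.80 cutoff for the
#' weakly-connected volatile clusters, HCA gene-cluster association at
#' similarity 0.6, top-10 per-volatile correlation lists, SAM at FDR 5% /
#' q < 0.05, volatile t-tests at alpha 0.05, qPCR validation at PCC > 0.7,
#' and a 2-fold change cutoff.
#'
#' @param cna_cutoff_primary,cna_cutoff_secondary correlation cutoffs for
#'   network gene preselection (strict `>`).
#' @param hca_cluster_sim similarity threshold for joint-tree co-clustering.
#' @param top_k per-volatile list length.
#' @param sam_fdr target SAM false discovery rate / q-value threshold.
#' @param ttest_alpha volatile t-test significance level.
#' @param qpcr_validation_pcc qPCR/microarray concordance threshold
#'   (strict `>`).
#' @param fold_change_cutoff linear fold-change filter (strict `>`).
#' @param voc_edge_floor minimum |r| for a volatile-volatile edge.
#' @param edge_strong,edge_moderate |r| boundaries of the strong/moderate/
#'   weak edge classes.
#' @param subcluster_sim |r| threshold defining gene sub-clusters.
#' @param hub_percentile degree percentile above which a node is a hub.
#' @param rng_seed integer seed for any stochastic step.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(cna_cutoff_primary = 0.85,
                            cna_cutoff_secondary = 0.80,
                            hca_cluster_sim = 0.60,
                            top_k = 10L,
                            sam_fdr = 0.05,
                            ttest_alpha = 0.05,
                            qpcr_validation_pcc = 0.70,
                            fold_change_cutoff = 2.0,
                            voc_edge_floor = 0.5,
                            edge_strong = 0.95,
                            edge_moderate = 0.70,
                            subcluster_sim = 0.95,
                            hub_percentile = 0.95,
                            rng_seed = 1L) {
  cfg <- list(cna_cutoff_primary = cna_cutoff_primary,
              cna_cutoff_secondary = cna_cutoff_secondary,
              hca_cluster_sim = hca_cluster_sim,
              top_k = as.integer(top_k),
              sam_fdr = sam_fdr,
              ttest_alpha = ttest_alpha,
              qpcr_validation_pcc = qpcr_validation_pcc,
              fold_change_cutoff = fold_change_cutoff,
              voc_edge_floor = voc_edge_floor,
              edge_strong = edge_strong,
              edge_moderate = edge_moderate,
              subcluster_sim = subcluster_sim,
              hub_percentile = hub_percentile,
              rng_seed = as.integer(rng_seed))
  for (nm in c("cna_cutoff_primary", "cna_cutoff_secondary",
               "hca_cluster_sim", "sam_fdr", "ttest_alpha",
               "qpcr_validation_pcc")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop(nm, " must lie in (0, 1]")
  }
  if (cfg$fold_change_cutoff < 1) stop("fold_change_cutoff must be >= 1")
  if (cfg$top_k < 1L) stop("top_k must be >= 1")
  class(cfg) <- "analysis_config"
  cfg
}

# align two omics matrices on their shared samples (same order)
shared_samples <- function(a, b) {
  common <- intersect(colnames(a$values), colnames(b$values))
  if (length(common) < 3L)
    stop("fewer than 3 shared samples between matrices")
  common
}
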