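#' Relative quantification by the delta-delta-Ct method
#'
#' Technical replicates are averaged on the Ct scale. For each gene and
#' sample, `DCt = Ct_gene - Ct_ref`; `DDCt = DCt_sample - DCt_calibrator`;
#' `RQ = 2^(-DDCt)` (amplification efficiency fixed at 2). The calibrator
#' sample has RQ = 1 exactly, and RQ is invariant to adding a constant to
#' all Ct values of a sample. Samples lacking the reference gene are
#' dropped with a warning.
#'
#' @param ct data.frame(`gene_id`, `sample_id`, `Ct`) with one row per
#'   technical replicate; Ct in cycles (> 0).
#' @param reference_gene id of the normalizer gene (must be measured in
#'   every retained sample).
#' @param calibrator_sample id of the calibrator (e.g. the S1 sample).
#' @return matrix of RQ values (genes x samples, reference gene excluded)
#'   of class `relative_quant`, with attributes `reference_gene` and
#'   `calibrator_sample`.
#' @export
ddct <- function(ct, reference_gene, calibrator_sample) {
  stopifnot(all(c("gene_id", "sample_id", "Ct") %in% names(ct)))
  if (any(ct$Ct <= 0)) stop("Ct values must be positive")
  mean_ct <- tapply(ct$Ct, list(ct$gene_id, ct$sample_id), mean)
  if (!reference_gene %in% rownames(mean_ct))
    stop("reference gene not in table: ", reference_gene)
  ref <- mean_ct[reference_gene, ]
  drop <- is.na(ref)
  if (any(drop)) {
    warning("dropping sample(s) without reference Ct: ",
            paste(colnames(mean_ct)[drop], collapse = ", "))
    mean_ct <- mean_ct[, !drop, drop = FALSE]
    ref <- ref[!drop]
  }
  if (!calibrator_sample %in% colnames(mean_ct))
    stop("calibrator sample not present: ", calibrator_sample)
  dct <- sweep(mean_ct, 2L, ref)
  ddct_ <- dct - dct[, calibrator_sample]
  rq <- 2^(-ddct_)
  rq <- rq[setdiff(rownames(rq), reference_gene), , drop = FALSE]
  structure(rq, class = c("relative_quant", class(rq)),
            reference_gene = reference_gene,
            calibrator_sample = calibrator_sample)
}

#' Validate a microarray profile against qPCR
#'
#' Pearson correlation between the log2 qPCR relative quantities and the
#' microarray log2 ratios across matched samples; the profile is validated
#' iff the coefficient strictly exceeds `threshold` (study rule: 0.7).
#'
#' @param rq named numeric vector of RQ values (linear scale) for one gene,
#'   names are sample ids — e.g. one row of a [ddct()] result.
#' @param microarray named numeric vector of log2 ratios for the same gene.
#' @param threshold validation threshold (strict `>`, default 0.7).
#' @return list(`pcc`, `validated`, `n`).
#' @export
validate_gene <- function(rq, microarray, threshold = 0.7) {
  common <- intersect(names(rq), names(microarray))
  common <- common[!is.na(rq[common]) & !is.na(microarray[common])]
  if (length(common) < 3L) stop("fewer than 3 matched samples")
  if (any(rq[common] <= 0)) stop("RQ values must be positive")
  pcc <- stats::cor(log2(rq[common]), microarray[common])
  list(pcc = pcc, validated = is.finite(pcc) && pcc > threshold,
       n = length(common))
}
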