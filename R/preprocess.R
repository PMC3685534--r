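#' Filter spots against the background-intensity rule
#'
#' Keeps a spot iff its background-subtracted intensity exceeds 2x the mean
#' background intensity in at least one channel (strict `>`). The mean
#' background is computed per hybridization and per channel.
#'
#' @param spots data.frame(`feature_id`, `hybridization_id`, `F_cy5`,
#'   `B_cy5`, `F_cy3`, `B_cy3`).
#' @return filtered data.frame with attribute `n_removed`.
#' @export
spot_filter <- function(spots) {
  req <- c("feature_id", "hybridization_id", "F_cy5", "B_cy5",
           "F_cy3", "B_cy3")
  stopifnot(all(req %in% names(spots)))
  mb5 <- stats::ave(spots$B_cy5, spots$hybridization_id)
  mb3 <- stats::ave(spots$B_cy3, spots$hybridization_id)
  keep <- (spots$F_cy5 - spots$B_cy5 > 2 * mb5) |
          (spots$F_cy3 - spots$B_cy3 > 2 * mb3)
  if (!any(keep)) stop("spot_filter removed every spot (degenerate input)")
  out <- spots[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  message(sprintf("spot_filter: removed %d of %d spots",
                  sum(!keep), length(keep)))
  out
}

#' MA-lowess normalization of two-channel log ratios
#'
#' Per hybridization: `M_raw = log2((F_cy5-B_cy5)/(F_cy3-B_cy3))`,
#' `A = 0.5*log2((F_cy5-B_cy5)*(F_cy3-B_cy3))`; the lowess fit of M on A
#' (tricube-weighted local linear regression, `iter` robustness passes) is
#' subtracted: `M = M_raw - fit(A)`. Spots with a non-positive
#' background-subtracted intensity in either channel are marked invalid,
#' not dropped.
#'
#' @param spots filtered spot table (see [spot_filter()]).
#' @param span lowess span in (0, 1].
#' @param iter robustness iterations.
#' @param normalize when FALSE, M is the raw log ratio (no fit subtracted).
#' @return data.frame(`feature_id`, `hybridization_id`, `M`, `M_raw`, `A`,
#'   `valid`).
#' @export
lowess_normalize <- function(spots, span = 0.3, iter = 3L, normalize = TRUE) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  s5 <- spots$F_cy5 - spots$B_cy5
  s3 <- spots$F_cy3 - spots$B_cy3
  valid <- is.finite(s5) & is.finite(s3) & s5 > 0 & s3 > 0
  M_raw <- A <- rep(NA_real_, nrow(spots))
  M_raw[valid] <- log2(s5[valid] / s3[valid])
  A[valid] <- 0.5 * log2(s5[valid] * s3[valid])
  M <- M_raw
  if (normalize) {
    for (h in unique(spots$hybridization_id)) {
      idx <- which(spots$hybridization_id == h & valid)
      if (length(idx) == 0L) next
      if (length(idx) == 1L) { M[idx] <- 0; next }
      fit <- stats::lowess(A[idx], M_raw[idx], f = span, iter = iter)
      trend <- stats::approx(fit$x, fit$y, xout = A[idx], rule = 2,
                             ties = mean)$y
      M[idx] <- M_raw[idx] - trend
    }
  }
  data.frame(feature_id = spots$feature_id,
             hybridization_id = spots$hybridization_id,
             M = M, M_raw = M_raw, A = A, valid = valid,
             stringsAsFactors = FALSE)
}

#' Apply the 2-of-3 replicate validity rule
#'
#' Each hybridization corresponds to one sample of the design; replicates
#' of the same (genotype, stage) condition form a group. A feature is
#' retained for a condition iff it carries a valid normalized ratio in at
#' least `min_valid` of the group's hybridizations; otherwise the whole
#' group is masked for that feature. Individual invalid replicates stay
#' masked. Output is at replicate level (one column per sample);
#' `aggregate = "group_mean"` instead returns per-condition means (with the
#' per-condition standard deviations as attribute `group_sd`).
#'
#' @param ratios output of [lowess_normalize()].
#' @param design sample design data.frame; `sample_id` must match
#'   `hybridization_id`.
#' @param min_valid minimum valid replicates per condition (default 2).
#' @param aggregate `"none"` (replicate-level) or `"group_mean"`.
#' @return [omics_matrix()].
#' @export
replicate_validity_filter <- function(ratios, design, min_valid = 2L,
                                      aggregate = c("none", "group_mean")) {
  aggregate <- match.arg(aggregate)
  unknown <- setdiff(unique(ratios$hybridization_id), design$sample_id)
  if (length(unknown))
    stop("hybridizations absent from design: ",
         paste(unknown, collapse = ", "))
  group <- interaction(design$genotype, design$stage, drop = TRUE)
  if (any(table(group) < 2L))
    stop("every (genotype, stage) condition needs >= 2 replicates")
  feats <- sort(unique(ratios$feature_id))
  vals <- matrix(NA_real_, nrow = length(feats), ncol = nrow(design),
                 dimnames = list(feats, design$sample_id))
  ok <- ratios$valid & is.finite(ratios$M)
  ri <- cbind(match(ratios$feature_id, feats),
              match(ratios$hybridization_id, design$sample_id))
  # mean over (possibly multiple) valid measurements per feature x sample
  lin <- (ri[ok, 2L] - 1L) * length(feats) + ri[ok, 1L]
  agg_sum <- rowsum(ratios$M[ok], lin)
  agg_n <- rowsum(rep(1, sum(ok)), lin)
  vals[as.integer(rownames(agg_sum))] <- agg_sum / agg_n
  # enforce the >= min_valid rule per condition group
  for (g in levels(group)) {
    cols <- which(group == g)
    n_valid <- rowSums(!is.na(vals[, cols, drop = FALSE]))
    vals[n_valid < min_valid, cols] <- NA_real_
  }
  keep <- rowSums(!is.na(vals)) > 0
  vals <- vals[keep, , drop = FALSE]
  if (nrow(vals) == 0L) stop("no feature survived the validity filter")
  message(sprintf("replicate_validity_filter: %d of %d features retained",
                  nrow(vals), length(feats)))
  if (aggregate == "group_mean") {
    gm <- sapply(levels(group), function(g)
      rowMeans(vals[, group == g, drop = FALSE], na.rm = TRUE))
    gs <- sapply(levels(group), function(g)
      apply(vals[, group == g, drop = FALSE], 1L, stats::sd, na.rm = TRUE))
    gm[is.nan(gm)] <- NA_real_
    gdesign <- unique(design[, c("genotype", "stage")])
    gdesign$sample_id <- paste(gdesign$genotype, gdesign$stage, sep = ".")
    gdesign$replicate <- 1L
    gm <- gm[, match(gdesign$sample_id, colnames(gm)), drop = FALSE]
    out <- omics_matrix(gm, gdesign)
    attr(out, "group_sd") <- gs
    return(out)
  }
  omics_matrix(vals, design)
}

#' Center each feature on the reference-pool median
#'
#' Subtracts, per feature, the median log2 value of the reference pool.
#' Features without a reference value are fully masked with a warning.
#'
#' @param m [omics_matrix()].
#' @param reference named numeric vector (per-feature reference median) or
#'   a numeric matrix of reference-pool log2 values (features x pool
#'   hybridizations), whose row medians are used.
#' @return [omics_matrix()].
#' @export
reference_median_center <- function(m, reference) {
  stopifnot(inherits(m, "omics_matrix"))
  if (is.matrix(reference))
    reference <- apply(reference, 1L, stats::median, na.rm = TRUE)
  ref <- reference[rownames(m$values)]
  missing_ref <- is.na(ref)
  if (any(missing_ref))
    warning(sum(missing_ref), " feature(s) lack a reference value; masked")
  vals <- m$values - ref
  vals[missing_ref, ] <- NA_real_
  m$values <- vals
  m
}

#' Full two-channel preprocessing pipeline
#'
#' Spot filter, then log-ratio computation with (by default) MA-lowess
#' normalization, then the 2-of-`n` replicate validity filter, then
#' optional reference-median centering.
#'
#' @param spots raw spot table.
#' @param design sample design.
#' @param span lowess span.
#' @param normalize `"lowess"` or `"none"` (raw log ratios).
#' @param reference optional reference values for
#'   [reference_median_center()].
#' @param min_valid see [replicate_validity_filter()].
#' @return [omics_matrix()].
#' @export
preprocess_two_channel <- function(spots, design, span = 0.3,
                                   normalize = c("lowess", "none"),
                                   reference = NULL, min_valid = 2L) {
  normalize <- match.arg(normalize)
  kept <- spot_filter(spots)
  ratios <- lowess_normalize(kept, span = span,
                             normalize = normalize == "lowess")
  m <- replicate_validity_filter(ratios, design, min_valid = min_valid)
  if (!is.null(reference)) m <- reference_median_center(m, reference)
  m
}
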