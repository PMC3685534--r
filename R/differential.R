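# group means / pooled SE numerators for a set of label assignments.
# x: genes x samples; g2: logical matrix samples x P (TRUE = group 2).
# Returns num (mean2 - mean1) and pooled standard error s, genes x P.
.sam_stats <- function(x, g2) {
  ns <- ncol(x)
  n2 <- sum(g2[, 1L])
  n1 <- ns - n2
  x2 <- x^2
  ind2 <- g2 * 1
  m2 <- (x %*% ind2) / n2
  m1 <- (x %*% (1 - ind2)) / n1
  e2 <- x2 %*% ind2
  rs2 <- rowSums(x2)
  ss2 <- e2 - n2 * m2^2
  ss1 <- (rs2 - e2) - n1 * m1^2
  s <- sqrt(((1 / n1 + 1 / n2) / (n1 + n2 - 2)) * pmax(ss1 + ss2, 0))
  list(num = m2 - m1, s = s, n1 = n1, n2 = n2)
}

# Tusher-style fudge factor: the percentile of the s_i distribution, over
# the grid 0,5,...,100%, that minimizes the coefficient of variation of the
# median absolute deviation of d across windows of s.
.sam_s0 <- function(num, s) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- stats::quantile(s, alphas, names = FALSE, type = 7)
  nwin <- max(2L, min(100L, floor(length(s) / 10)))
  br <- unique(stats::quantile(s, seq(0, 1, length.out = nwin + 1L),
                               names = FALSE))
  win <- cut(s, breaks = br, include.lowest = TRUE)
  cvs <- vapply(cand, function(s0) {
    d <- num / (s + s0)
    v <- tapply(d, win, stats::mad)
    v <- v[!is.na(v)]
    if (length(v) < 2L || mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cvs)]
}

# all (or sampled) two-class label assignments as a logical matrix ns x P
.sam_permutations <- function(ns, n2, n_perm, seed, observed) {
  total <- choose(ns, n2)
  if (total <= n_perm) {
    sets <- utils::combn(ns, n2)
    exhaustive <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    sets <- replicate(n_perm, sort(sample.int(ns, n2)))
    sets[, 1L] <- observed   # keep the observed labelling in the null set
    exhaustive <- FALSE
  }
  g2 <- matrix(FALSE, ns, ncol(sets))
  g2[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = n2))] <- TRUE
  list(g2 = g2, exhaustive = exhaustive, n = ncol(sets))
}

#' SAM-style two-class permutation test
#'
#' Tusher-style moderated statistic `d_i = (mean2 - mean1)/(s_i + s0)` with
#' `s_i` the pooled standard error and `s0` selected on a percentile grid
#' (see details), a permutation null over class labels (exhaustive when the
#' number of distinct assignments does not exceed `n_perm`, e.g. all 20 for
#' 3 vs 3), the smallest threshold `delta` whose estimated FDR is at most
#' `fdr_target`, and per-gene q-values (the minimum estimated FDR at which
#' a gene is called). The estimated FDR at a threshold is the median (or
#' 90th percentile) permutation count of statistics beyond the cutoffs,
#' divided by the observed call count. A gene is called `up`/`down` when it
#' lies beyond the cutoffs at the selected delta *and* its q-value is below
#' `fdr_target` (the two criteria are applied conjunctively).
#'
#' @param m [omics_matrix()] or numeric matrix (genes x samples), log2
#'   scale; rows with missing values are dropped with a message.
#' @param groups factor/character of length `ncol`, two levels; the
#'   contrast is level 2 minus level 1.
#' @param fdr_target target FDR (default 0.05).
#' @param n_perm maximum number of permutations (exhaustive below this).
#' @param seed RNG seed for sampled permutations.
#' @param fdr_stat `"median"` (SAM default) or `"p90"`.
#' @param s0 optional fixed fudge factor (e.g. 0 to recover the ordinary
#'   pooled-SE t statistic); by default selected automatically.
#' @param n_delta size of the delta grid.
#' @return data.frame of class `sam_result` with columns `gene_id`, `d`,
#'   `fold_change` (linear, group2/group1), `q`, `call`; attributes `s0`,
#'   `delta`, `fdr`, `n_perm`, `exhaustive`, `cutup`, `cutlo`.
#' @export
sam_two_class <- function(m, groups, fdr_target = 0.05, n_perm = 1000L,
                          seed = NULL, fdr_stat = c("median", "p90"),
                          s0 = NULL, n_delta = 60L) {
  fdr_stat <- match.arg(fdr_stat)
  x <- if (inherits(m, "omics_matrix")) m$values else m
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (length(groups) != ncol(x)) stop("groups length must match samples")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  ok <- stats::complete.cases(x)
  if (!all(ok)) {
    message(sprintf("sam_two_class: dropping %d gene(s) with missing values",
                    sum(!ok)))
    x <- x[ok, , drop = FALSE]
  }
  ns <- ncol(x)
  obs_idx <- which(groups == levels(groups)[2L])
  g2_obs <- matrix(seq_len(ns) %in% obs_idx, ncol = 1L)
  obs <- .sam_stats(x, g2_obs)
  if (is.null(s0)) s0 <- .sam_s0(obs$num[, 1L], obs$s[, 1L])
  d <- obs$num[, 1L] / (obs$s[, 1L] + s0)
  fold <- 2^(obs$num[, 1L])

  perms <- .sam_permutations(ns, length(obs_idx), n_perm, seed, obs_idx)
  if (perms$n < 10L)
    warning("fewer than 10 distinct permutations: FDR estimate unstable")
  pstats <- .sam_stats(x, perms$g2)
  dperm <- pstats$num / (pstats$s + s0)
  dperm_sorted <- apply(dperm, 2L, sort)
  dbar <- rowMeans(dperm_sorted)
  ds <- sort(d)
  dif <- ds - dbar

  # candidate thresholds: the call set only changes at the |dif| values, and
  # nearly all of the action is in the tails — keep those exactly and thin
  # only the body of the distribution
  deltas <- sort(unique(abs(dif)))
  if (length(deltas) > n_delta) {
    ntail <- min(30L, length(dif))
    tails <- abs(c(utils::head(dif, ntail), utils::tail(dif, ntail)))
    body <- deltas[unique(round(seq(1, length(deltas),
                                    length.out = n_delta)))]
    deltas <- sort(unique(c(body, tails)))
  }
  deltas <- c(deltas, max(deltas) * 1.000001)
  summ <- function(v) if (fdr_stat == "median") stats::median(v)
                      else stats::quantile(v, 0.9, names = FALSE)
  ng <- length(d)
  q <- rep(1, ng)
  table_rows <- lapply(deltas, function(delta) {
    # cutoffs stay in their own tails (origin-outward scan, as in SAM)
    iu <- which(dif >= delta & ds >= 0)
    il <- which(-dif >= delta & ds <= 0)
    cutup <- if (length(iu)) min(ds[iu]) else Inf
    cutlo <- if (length(il)) max(ds[il]) else -Inf
    called <- d >= cutup | d <= cutlo
    n_called <- sum(called)
    false_b <- colSums(dperm >= cutup | dperm <= cutlo)
    fdr <- if (n_called == 0L) 0 else min(1, summ(false_b) / n_called)
    list(delta = delta, cutup = cutup, cutlo = cutlo,
         n_called = n_called, fdr = fdr, called = called)
  })
  for (row in table_rows) q[row$called] <- pmin(q[row$called], row$fdr)
  fdrs <- vapply(table_rows, `[[`, numeric(1), "fdr")
  sel <- which(fdrs <= fdr_target)[1L]
  if (is.na(sel)) sel <- length(table_rows)
  chosen <- table_rows[[sel]]
  call <- rep("ns", ng)
  sig <- chosen$called & q < fdr_target
  call[sig & d >= chosen$cutup] <- "up"
  call[sig & d <= chosen$cutlo] <- "down"

  out <- data.frame(gene_id = rownames(x), d = d, fold_change = fold,
                    q = q, call = call, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "s0") <- s0
  attr(out, "delta") <- chosen$delta
  attr(out, "fdr") <- chosen$fdr
  attr(out, "cutup") <- chosen$cutup
  attr(out, "cutlo") <- chosen$cutlo
  attr(out, "n_perm") <- perms$n
  attr(out, "exhaustive") <- perms$exhaustive
  class(out) <- c("sam_result", "data.frame")
  out
}

#' Volatile-level two-sample t-tests with fold changes
#'
#' Classical equal-variance Student's t-test (Welch behind a flag) on log2
#' values, per feature. Fold change is reported on the linear scale as
#' `2^|Dmean|` with a direction (contrast: level 2 minus level 1). When
#' both groups have zero variance and equal means, p = 1.
#'
#' @param m [omics_matrix()] or matrix (features x samples).
#' @param groups two-level factor over samples.
#' @param alpha significance level (default 0.05).
#' @param var_equal classical pooled-variance test (default TRUE).
#' @param p_adjust method passed to [stats::p.adjust()] (default "none",
#'   matching the raw p < 0.05 reporting convention).
#' @return data.frame(`feature_id`, `t`, `p`, `p_adj`, `fold_change`,
#'   `direction`, `significant`).
#' @export
ttest_volatiles <- function(m, groups, alpha = 0.05, var_equal = TRUE,
                            p_adjust = "none") {
  x <- if (inherits(m, "omics_matrix")) m$values else m
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  i1 <- groups == levels(groups)[1L]
  i2 <- groups == levels(groups)[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(x[, i2, drop = FALSE], 1L, stats::var)
  diffm <- m2 - m1
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- diffm / se
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se == 0
  t[degen] <- ifelse(diffm[degen] == 0, 0, sign(diffm[degen]) * Inf)
  p[degen] <- ifelse(diffm[degen] == 0, 1, 0)
  p_adj <- stats::p.adjust(p, method = p_adjust)
  data.frame(feature_id = rownames(x), t = t, p = p, p_adj = p_adj,
             fold_change = 2^abs(diffm),
             direction = ifelse(diffm > 0, "up",
                                ifelse(diffm < 0, "down", "none")),
             significant = p_adj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Venn partition of two differential-expression results
#'
#' Shared genes are those called in both contrasts *with the same trend*;
#' a gene called up in one and down in the other is reported as discordant,
#' outside the three disjoint sets.
#'
#' @param resA,resB `sam_result` objects over the same gene universe.
#' @return list with `shared`, `a_only`, `b_only`, `discordant` (character
#'   vectors) and `counts`.
#' @export
venn_partition <- function(resA, resB) {
  if (!setequal(resA$gene_id, resB$gene_id) ||
      length(resA$gene_id) != length(resB$gene_id))
    stop("mismatched gene universes")
  b <- resB[match(resA$gene_id, resB$gene_id), ]
  calledA <- resA$call != "ns"
  calledB <- b$call != "ns"
  shared <- calledA & calledB & resA$call == b$call
  discord <- calledA & calledB & resA$call != b$call
  out <- list(shared = resA$gene_id[shared],
              a_only = resA$gene_id[calledA & !calledB],
              b_only = resA$gene_id[!calledA & calledB],
              discordant = resA$gene_id[discord])
  out$counts <- lengths(out[1:4])
  out
}

#' Filter significant genes by linear fold change
#'
#' Keeps called genes whose linear fold change (in either direction)
#' strictly exceeds `cutoff`; a fold change of exactly `cutoff` is excluded.
#'
#' @param res `sam_result`.
#' @param cutoff linear fold-change cutoff (>= 1, default 2).
#' @return character vector of gene ids.
#' @export
fold_change_filter <- function(res, cutoff = 2) {
  if (cutoff < 1) stop("cutoff must be >= 1")
  fc <- pmax(res$fold_change, 1 / res$fold_change)
  res$gene_id[res$call != "ns" & fc > cutoff]
}
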