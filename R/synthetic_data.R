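#' Default volatile archetype set
#'
#' Six trend archetypes over the ripening series S1..S4 plus the shelf-life
#' condition (S4SL), qualitatively mirroring the behaviour of peach aroma
#' volatiles: two lactone/ester-like increasing families (early-plateau and
#' gradual), a late-rising lactone family, a mid-ripening peak family, a
#' decreasing lipid-derived family (negatively correlated with the
#' increasing ones), and a flat family. Stage means are log2 fold changes
#' versus S1, per genotype; the shelf-life response at S4SL is larger for
#' GenotypeB.
#'
#' @return list of archetypes; each has `label`, `trend`,
#'   `genotype_profiles` (genotype x stage matrix of log2 means),
#'   `within_cluster_sd` and `n_volatiles`.
#' @export
default_archetypes <- function() {
  stages <- c("S1", "S2", "S3", "S4", "S4SL")
  prof <- function(a, b) {
    m <- rbind(GenotypeA = a, GenotypeB = b)
    colnames(m) <- stages
    m
  }
  list(
    list(label = "C1", trend = "increase_early_plateau",
         genotype_profiles = prof(c(0, 1.8, 2.6, 3.0, 3.2),
                                  c(0, 1.5, 2.4, 3.0, 4.2)),
         within_cluster_sd = 0.25, n_volatiles = 10L),
    list(label = "C2", trend = "increase_gradual",
         genotype_profiles = prof(c(0, 0.8, 1.8, 2.8, 3.1),
                                  c(0, 0.6, 1.6, 3.0, 4.5)),
         within_cluster_sd = 0.25, n_volatiles = 10L),
    list(label = "C3", trend = "increase_gradual",
         genotype_profiles = prof(c(0, 0.3, 1.2, 2.6, 2.9),
                                  c(0, 0.2, 1.0, 2.8, 4.6)),
         within_cluster_sd = 0.25, n_volatiles = 8L),
    list(label = "C4", trend = "stage_peak",
         genotype_profiles = prof(c(0, 1.6, 2.4, 1.0, 0.4),
                                  c(0, 1.4, 2.6, 1.2, 0.2)),
         within_cluster_sd = 0.25, n_volatiles = 8L),
    list(label = "C5", trend = "decrease",
         genotype_profiles = prof(c(0, -1.0, -2.0, -2.8, -3.0),
                                  c(0, -0.8, -1.8, -3.0, -4.0)),
         within_cluster_sd = 0.25, n_volatiles = 10L),
    list(label = "C6", trend = "flat",
         genotype_profiles = prof(rep(0, 5), rep(0, 5)),
         within_cluster_sd = 0.25, n_volatiles = 6L)
  )
}

#' Specification of a synthetic coupled gene/volatile dataset
#'
#' Describes the study design (2 genotypes x stages S1..S4 + S4SL x 3
#' replicates = 30 samples), the volatile archetypes, the genes planted at
#' controlled correlation to archetypes, the background-gene trend model
#' and the noise levels. All randomness flows from `rng_seed`.
#'
#' @param n_genes,n_volatiles,n_reps design sizes (defaults 4348, 52, 3).
#' @param stages ordered stage labels; the last is the shelf-life condition.
#' @param genotypes genotype labels.
#' @param archetypes list from [default_archetypes()]; volatile counts must
#'   sum to `n_volatiles`.
#' @param planted_links data.frame(`gene_id`, `target_archetype`,
#'   `target_r`) or NULL to plant `n_planted` genes at `planted_r` spread
#'   over the non-flat archetypes.
#' @param n_planted,planted_r defaults for the planted set.
#' @param noise_sd replicate-level gene noise, log2 units.
#' @param trend_sd per-stage sd of the background stage-profile effects.
#' @param shared_trend weight of the genotype-shared component of a
#'   background profile (0..1).
#' @param shelf_life_effect named per-genotype additive log2 shift applied
#'   at the shelf-life stage to responsive background genes.
#' @param responder_fraction fraction of background genes that respond to
#'   shelf life.
#' @param rng_seed integer.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 4348L, n_volatiles = 52L, n_reps = 3L,
                           stages = c("S1", "S2", "S3", "S4", "S4SL"),
                           genotypes = c("GenotypeA", "GenotypeB"),
                           archetypes = default_archetypes(),
                           planted_links = NULL,
                           n_planted = 12L, planted_r = 0.95,
                           noise_sd = 0.4, trend_sd = 0.5,
                           shared_trend = 0.7,
                           shelf_life_effect = c(GenotypeA = 0.3,
                                                 GenotypeB = 1.5),
                           responder_fraction = 0.15,
                           rng_seed = 1L) {
  if (n_reps < 2L) stop("n_reps must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  counts <- vapply(archetypes, function(a) a$n_volatiles, integer(1))
  if (sum(counts) != n_volatiles)
    stop("archetype volatile counts sum to ", sum(counts),
         ", expected ", n_volatiles)
  for (a in archetypes) {
    gp <- a$genotype_profiles
    if (startsWith(a$trend, "increase") &&
        !any(gp[, ncol(gp)] > gp[, 1L]))
      stop("archetype ", a$label,
           ": increasing trend requires last-stage mean above first")
    if (a$trend == "flat" && any(abs(gp) > a$within_cluster_sd))
      stop("archetype ", a$label, ": flat trend means exceed within-sd")
  }
  if (is.null(planted_links)) {
    lab <- vapply(archetypes, `[[`, "", "label")
    nonflat <- lab[vapply(archetypes, function(a) a$trend != "flat",
                          logical(1))]
    planted_links <- data.frame(
      gene_id = sprintf("GENE_P%03d", seq_len(n_planted)),
      target_archetype = rep_len(nonflat, n_planted),
      target_r = planted_r, stringsAsFactors = FALSE)
  }
  if (any(abs(planted_links$target_r) > 1))
    stop("|target_r| must be <= 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_volatiles = as.integer(n_volatiles),
                 n_reps = as.integer(n_reps),
                 stages = stages, genotypes = genotypes,
                 archetypes = archetypes, planted_links = planted_links,
                 noise_sd = noise_sd, trend_sd = trend_sd,
                 shared_trend = shared_trend,
                 shelf_life_effect = shelf_life_effect,
                 responder_fraction = responder_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

# design table for a spec: genotype x stage x replicate
synthetic_design <- function(spec) {
  g <- expand.grid(replicate = seq_len(spec$n_reps),
                   stage = spec$stages, genotype = spec$genotypes,
                   stringsAsFactors = FALSE)
  g <- g[, c("genotype", "stage", "replicate")]
  g$sample_id <- sprintf("%s_%s_R%d",
                         ifelse(g$genotype == spec$genotypes[1], "GA", "GB"),
                         g$stage, g$replicate)
  g[, c("sample_id", "genotype", "stage", "replicate")]
}

# stage-mean signal vector (length n_samples) for one archetype
archetype_signal <- function(arch, design) {
  gp <- arch$genotype_profiles
  gp[cbind(match(design$genotype, rownames(gp)),
           match(design$stage, colnames(gp)))]
}

#' Generate a coupled synthetic gene/volatile dataset
#'
#' Volatiles follow their archetype's genotype/stage mean profile (times a
#' per-volatile scale jitter) plus replicate noise. Planted genes follow
#' `a * signal + N(0, noise_sd)` with `a` calibrated so the population
#' Pearson correlation to the archetype signal equals `target_r`:
#' `a = noise_sd * r / (sd(signal) * sqrt(1 - r^2))`. Background genes get
#' smooth random stage profiles (adjacent stages coupled by a moving-average
#' smoother, partially shared between genotypes), a fraction of which get an
#' extra additive shift at the shelf-life stage (larger in GenotypeB), plus
#' replicate noise. Fully reproducible from `spec$rng_seed`.
#'
#' @param spec [synthetic_spec()].
#' @return list with elements `genes` and `volatiles` ([omics_matrix()])
#'   and `truth` (volatile archetype map, planted-gene table with the
#'   realized signal correlations, background/responder ids, design).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$rng_seed)
  design <- synthetic_design(spec)
  ns <- nrow(design)
  stages <- spec$stages
  sl_stage <- stages[length(stages)]

  # volatiles
  vol_ids <- character(0); vol_arch <- character(0)
  vol_vals <- matrix(NA_real_, nrow = spec$n_volatiles, ncol = ns)
  i <- 0L
  for (arch in spec$archetypes) {
    sig <- archetype_signal(arch, design)
    for (k in seq_len(arch$n_volatiles)) {
      i <- i + 1L
      scale_v <- stats::runif(1, 0.7, 1.3)
      vol_vals[i, ] <- scale_v * sig +
        stats::rnorm(ns, 0, arch$within_cluster_sd)
      vol_ids[i] <- sprintf("VOC_%s_%02d", arch$label, k)
      vol_arch[i] <- arch$label
    }
  }
  rownames(vol_vals) <- vol_ids
  colnames(vol_vals) <- design$sample_id

  # planted genes
  arch_by_label <- stats::setNames(spec$archetypes,
                                   vapply(spec$archetypes, `[[`, "", "label"))
  pl <- spec$planted_links
  n_pl <- nrow(pl)
  planted_vals <- matrix(NA_real_, nrow = n_pl, ncol = ns)
  realized <- numeric(n_pl)
  for (j in seq_len(n_pl)) {
    arch <- arch_by_label[[pl$target_archetype[j]]]
    if (is.null(arch)) stop("unknown archetype: ", pl$target_archetype[j])
    sig <- archetype_signal(arch, design)
    sds <- stats::sd(sig)
    r <- pl$target_r[j]
    if (sds == 0 && r != 0)
      stop("infeasible target_r for flat archetype ", arch$label,
           ": attainable r is 0")
    if (spec$noise_sd == 0) {
      if (abs(r) != 1 && r != 0)
        stop("infeasible target_r=", r, " with noise_sd=0: ",
             "attainable r is exactly -1, 0 or 1")
      planted_vals[j, ] <- sign(r) * sig
    } else {
      if (abs(r) == 1)
        stop("infeasible target_r=", r, " with noise_sd=", spec$noise_sd,
             ": attainable |r| < 1")
      a <- spec$noise_sd * r / (sds * sqrt(1 - r^2))
      planted_vals[j, ] <- a * sig + stats::rnorm(ns, 0, spec$noise_sd)
    }
    realized[j] <- if (sds > 0) stats::cor(planted_vals[j, ], sig) else NA_real_
  }

  # background genes: smooth random stage profiles, partially genotype-
  # shared. Adjacent stages are coupled by a moving-average smoother rather
  # than a cumulative walk: fully cumulative profiles are almost all
  # monotone and would co-correlate with the ripening archetypes far more
  # often than the study's data anchor allows (~2.5% of genes above the
  # 0.85 preselection cutoff, planted biology included).
  n_bg <- spec$n_genes - n_pl
  if (n_bg < 0) stop("more planted genes than n_genes")
  n_stage <- length(stages)
  smooth_profiles <- function(n) {
    e <- matrix(stats::rnorm(n * n_stage, 0, spec$trend_sd),
                nrow = n, ncol = n_stage)
    sm <- e
    if (n > 0L)
      for (j in 2:n_stage)
        sm[, j] <- (e[, j] + 0.5 * e[, j - 1L]) / sqrt(1.25)
    sm
  }
  common <- smooth_profiles(n_bg)
  w <- spec$shared_trend
  prof <- list()
  for (g in spec$genotypes)
    prof[[g]] <- w * common + (1 - w) * smooth_profiles(n_bg)
  responders <- sort(sample.int(n_bg, round(spec$responder_fraction * n_bg)))
  resp_sign <- sample(c(-1, 1), length(responders), replace = TRUE)
  for (g in spec$genotypes)
    prof[[g]][responders, n_stage] <- prof[[g]][responders, n_stage] +
      resp_sign * spec$shelf_life_effect[[g]]
  bg_vals <- matrix(NA_real_, nrow = n_bg, ncol = ns)
  for (s in seq_len(ns)) {
    g <- design$genotype[s]
    st <- match(design$stage[s], stages)
    bg_vals[, s] <- prof[[g]][, st]
  }
  bg_vals <- bg_vals + matrix(stats::rnorm(n_bg * ns, 0, spec$noise_sd),
                              nrow = n_bg, ncol = ns)
  bg_ids <- sprintf("GENE_B%05d", seq_len(n_bg))

  gene_vals <- rbind(planted_vals, bg_vals)
  rownames(gene_vals) <- c(pl$gene_id, bg_ids)
  colnames(gene_vals) <- design$sample_id

  gene_tags <- rep("", spec$n_genes)
  # a sprinkle of ripening-machinery annotations for the exclusion filter
  if (n_bg > 0L) {
    n_tagged <- max(1L, round(0.02 * n_bg))
    tagged <- sample.int(n_bg, n_tagged)
    gene_tags[n_pl + tagged] <- sample(
      c("ethylene biosynthesis", "ethylene signaling",
        "cell wall softening"),
      n_tagged, replace = TRUE)
  }

  gene_meta <- data.frame(
    feature_id = rownames(gene_vals), kind = "gene",
    annotation = c(sprintf("synthetic planted gene (%s, r=%.2f)",
                           pl$target_archetype, pl$target_r),
                   rep("synthetic background gene", n_bg)),
    tags = gene_tags, volatile_cluster = NA_character_,
    stringsAsFactors = FALSE)
  vol_meta <- data.frame(
    feature_id = vol_ids, kind = "volatile",
    annotation = sprintf("synthetic volatile (archetype %s)", vol_arch),
    tags = "", volatile_cluster = vol_arch, stringsAsFactors = FALSE)

  truth <- list(
    volatile_archetype = stats::setNames(vol_arch, vol_ids),
    planted = cbind(pl, realized_signal_r = realized),
    background_ids = bg_ids,
    responder_ids = bg_ids[responders],
    design = design)

  list(genes = omics_matrix(gene_vals, design, gene_meta),
       volatiles = omics_matrix(vol_vals, design, vol_meta),
       truth = truth)
}

#' Emulate raw two-channel spot intensities from a log2-ratio matrix
#'
#' One hybridization per sample. Per spot, a lognormal brightness `T`
#' (deposition x abundance) is split symmetrically across the channels:
#' reference (Cy3) `T x 2^(-value/2)` and sample (Cy5) `T x 2^(+value/2)`,
#' so `log2(Cy5/Cy3)` recovers the value exactly while the mean log
#' intensity A stays independent of it. (Putting the whole ratio on the
#' sample channel instead would couple A with M and build a spurious M~A
#' trend into bias-free data, which lowess would then wrongly remove.)
#' A smooth intensity-dependent dye-bias curve can be injected on the
#' sample channel so MA-lowess is non-trivially exercised. Additive
#' per-channel background is drawn around `background_mean`. A configurable
#' fraction of spots is driven below the 2x-mean-background filter
#' threshold.
#'
#' @param m gene [omics_matrix()] of log2(sample/reference) values.
#' @param dye_bias_amp peak log2 amplitude of the monotone bias curve
#'   (0 disables it).
#' @param background_mean,background_sd additive background level (set
#'   `background_mean = 0` for exact invertibility).
#' @param ref_meanlog,ref_sdlog lognormal parameters of the spot brightness.
#' @param sub_bg_fraction fraction of spots forced below the spot filter.
#' @param seed optional integer; when NULL the current RNG stream is used.
#' @return data.frame(`feature_id`, `hybridization_id`, `F_cy5`, `B_cy5`,
#'   `F_cy3`, `B_cy3`) with attribute `sub_bg` (ids of forced spots).
#' @export
generate_two_channel <- function(m, dye_bias_amp = 0.6,
                                 background_mean = 50, background_sd = 5,
                                 ref_meanlog = log(1000), ref_sdlog = 0.8,
                                 sub_bg_fraction = 0, seed = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  if (sub_bg_fraction < 0 || sub_bg_fraction >= 1)
    stop("sub_bg_fraction must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  vals <- m$values
  n <- length(vals)
  feature_id <- rep(rownames(vals), times = ncol(vals))
  hyb_id <- rep(colnames(vals), each = nrow(vals))
  v <- as.vector(vals)
  bright <- stats::rlnorm(n, ref_meanlog, ref_sdlog)
  B_cy3 <- pmax(stats::rnorm(n, background_mean, background_sd), 0)
  B_cy5 <- pmax(stats::rnorm(n, background_mean, background_sd), 0)
  # bias evaluated on the noise-free A scale; smooth and monotone in A
  A0 <- log2(bright)
  bias <- if (dye_bias_amp == 0) 0 else {
    z <- (A0 - min(A0)) / (max(A0) - min(A0))
    dye_bias_amp * cos(pi * z)
  }
  refsub <- bright * 2^(-v / 2)
  samplesub <- bright * 2^(v / 2 + bias)
  F_cy3 <- refsub + B_cy3
  F_cy5 <- samplesub + B_cy5
  sub_idx <- integer(0)
  if (sub_bg_fraction > 0) {
    sub_idx <- sample.int(n, round(sub_bg_fraction * n))
    F_cy3[sub_idx] <- B_cy3[sub_idx] + 0.5
    F_cy5[sub_idx] <- B_cy5[sub_idx] + 0.5
  }
  out <- data.frame(feature_id = feature_id, hybridization_id = hyb_id,
                    F_cy5 = F_cy5, B_cy5 = B_cy5,
                    F_cy3 = F_cy3, B_cy3 = B_cy3,
                    stringsAsFactors = FALSE)
  attr(out, "sub_bg") <- sub_idx
  out
}
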