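test_that("spot filter applies the strict 2x-mean-background rule", {
  # all backgrounds are 10, so the per-channel mean background is 10 and
  # the threshold is F - B > 20
  base <- data.frame(feature_id = sprintf("g%d", 1:4),
                     hybridization_id = "h1",
                     F_cy5 = c(10 + 20.1, 10 + 20.0, 10 + 5, 10 + 100),
                     B_cy5 = 10,
                     F_cy3 = c(10 + 5, 10 + 20.0, 10 + 5, 10 + 100),
                     B_cy3 = 10, stringsAsFactors = FALSE)
  kept <- suppressMessages(spot_filter(base))
  expect_setequal(kept$feature_id, c("g1", "g4"))  # g2 at exactly 2x: out
  expect_equal(attr(kept, "n_removed"), 2L)
  all_low <- base
  all_low$F_cy5 <- all_low$F_cy3 <- 11
  expect_error(suppressMessages(spot_filter(all_low)), "degenerate")
})

test_that("lowess normalization is near-identity without dye bias", {
  # one array-scale hybridization with no M~A trend by construction; the
  # lowess fit must stay within 0.02 over the interior intensity range
  # (the per-window fit noise scales as sd(M)/sqrt(span * n_spots), so
  # this bound presumes full spot counts)
  # self-vs-self style hybridization: pure technical scatter (sd 0.15)
  set.seed(110)
  n <- 4348L
  bright <- rlnorm(n, log(1000), 0.8)
  m_true <- rnorm(n, 0, 0.15)
  spots <- data.frame(feature_id = sprintf("g%04d", seq_len(n)),
                      hybridization_id = "h1",
                      F_cy5 = bright * 2^(m_true / 2), B_cy5 = 0,
                      F_cy3 = bright * 2^(-m_true / 2), B_cy3 = 0,
                      stringsAsFactors = FALSE)
  norm <- lowess_normalize(spots, span = 0.3)
  interior <- norm$A > stats::quantile(norm$A, 0.1) &
              norm$A < stats::quantile(norm$A, 0.9)
  expect_lt(max(abs(norm$M - norm$M_raw)[interior]), 0.02)
})

test_that("an injected intensity-dependent bias is corrected by lowess", {
  ds <- generate_dataset(small_spec(seed = 12L, n_genes = 1500L))
  spots <- generate_two_channel(ds$genes, dye_bias_amp = 0.6,
                                background_mean = 0, background_sd = 0,
                                seed = 12L)
  truth <- ds$genes$values[cbind(spots$feature_id, spots$hybridization_id)]
  raw <- lowess_normalize(spots, normalize = FALSE)
  expect_gt(sqrt(mean((raw$M - truth)^2)), 0.15)  # bias really is injected
  norm <- lowess_normalize(spots, span = 0.3)
  expect_lt(sqrt(mean((norm$M - truth)^2)), 0.1)
})

test_that("single-spot and negative-intensity edge cases", {
  one <- data.frame(feature_id = "g1", hybridization_id = "h1",
                    F_cy5 = 500, B_cy5 = 10, F_cy3 = 100, B_cy3 = 10)
  expect_equal(lowess_normalize(one)$M, 0)  # fit passes through the point
  neg <- data.frame(feature_id = c("g1", "g2", "g3"),
                    hybridization_id = "h1",
                    F_cy5 = c(500, 5, 400), B_cy5 = 10,
                    F_cy3 = c(100, 200, 300), B_cy3 = 10)
  norm <- lowess_normalize(neg)
  expect_identical(norm$valid, c(TRUE, FALSE, TRUE))  # invalid, not dropped
  expect_true(is.na(norm$M[2L]))
})

test_that("the 2-of-3 replicate validity rule masks sparse conditions", {
  design <- data.frame(sample_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
                       genotype = "GenotypeA",
                       stage = rep(c("S1", "S2"), each = 3L),
                       replicate = rep(1:3, 2L), stringsAsFactors = FALSE)
  ratios <- data.frame(
    feature_id = rep(c("g1", "g2", "g3"), each = 6L),
    hybridization_id = rep(design$sample_id, 3L),
    M = c(1, 2, 3, 4, 5, 6,          # g1: fully valid
          1, 2, NA, 4, 5, 6,         # g2: 2-of-3 in S1
          1, NA, NA, 4, 5, 6),       # g3: 1-of-3 in S1 -> masked there
    A = 10, stringsAsFactors = FALSE)
  ratios$valid <- !is.na(ratios$M)
  m <- suppressMessages(replicate_validity_filter(ratios, design))
  expect_equal(unname(m$values["g1", ]), c(1, 2, 3, 4, 5, 6))
  expect_equal(unname(m$values["g2", ]), c(1, 2, NA, 4, 5, 6))
  expect_true(all(is.na(m$values["g3", c("a1", "a2", "a3")])))
  expect_equal(unname(m$values["g3", c("b1", "b2", "b3")]), c(4, 5, 6))
  # condition-level aggregation returns the mean of the valid replicates
  gm <- suppressMessages(replicate_validity_filter(ratios, design,
                                                   aggregate = "group_mean"))
  expect_equal(unname(gm$values["g2", ]), c(1.5, 5))
  expect_error(suppressMessages(replicate_validity_filter(
    ratios[ratios$hybridization_id %in% c("a1", "b1", "b2"), ],
    design[c(1, 4, 5), ])), ">= 2 replicates")
})

test_that("reference-median centering subtracts per-feature medians", {
  design <- toy_design(4L)
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(c("g1", "g2", "g3"), design$sample_id))
  m <- omics_matrix(vals, design)
  # zero reference medians: identity
  ref0 <- stats::setNames(rep(0, 3), rownames(vals))
  expect_identical(reference_median_center(m, ref0)$values, vals)
  # matrix reference: row medians subtracted, hand-computed
  refmat <- matrix(c(1, 2, 3, 0.5, 2.5, 3.5, 1.5, 1.5, 2.5), 3, 3,
                   dimnames = list(rownames(vals), NULL))
  med <- apply(refmat, 1L, median)
  out <- reference_median_center(m, refmat)
  expect_equal(out$values, vals - med)
  # feature with constant shift equal to its reference median -> zeros
  m2 <- m; m2$values["g1", ] <- 0.75
  out2 <- reference_median_center(m2, stats::setNames(c(0.75, 0, 0),
                                                      rownames(vals)))
  expect_true(all(out2$values["g1", ] == 0))
  # missing reference -> masked with warning
  expect_warning(out3 <- reference_median_center(m, ref0[-1L]),
                 "masked")
  expect_true(all(is.na(out3$values["g1", ])))
})

test_that("bias-free two-channel data round-trips through preprocessing", {
  ds <- generate_dataset(small_spec(seed = 13L, n_genes = 60L))
  spots <- generate_two_channel(ds$genes, dye_bias_amp = 0,
                                background_mean = 0, background_sd = 0,
                                seed = 13L)
  m <- suppressMessages(preprocess_two_channel(spots, ds$genes$samples,
                                               normalize = "none"))
  truth <- ds$genes$values[rownames(m$values), colnames(m$values)]
  expect_lt(max(abs(m$values - truth)), 1e-10)
  # and the pipeline is deterministic: same bytes on re-run
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_matrix(m, p1)
  m2 <- suppressMessages(preprocess_two_channel(spots, ds$genes$samples,
                                                normalize = "none"))
  write_matrix(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
})
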