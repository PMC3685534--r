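test_that("correlation distance has the right fixed points", {
  design <- toy_design(6L)
  x <- rnorm(6)
  vals <- rbind(a = x, b = x, c = -x, d = rnorm(6))
  colnames(vals) <- design$sample_id
  d <- as.matrix(correlation_distance(vals))
  expect_equal(d["a", "b"], 0, tolerance = 1e-12)
  expect_equal(d["a", "c"], 2, tolerance = 1e-12)
  expect_true(all(abs(diag(d)) < 1e-12))
  expect_equal(d, t(d))
  # brute-force oracle on a random instance
  set.seed(30)
  m <- matrix(rnorm(60), 10, 6)
  rownames(m) <- sprintf("f%02d", 1:10)
  colnames(m) <- design$sample_id
  dd <- as.matrix(correlation_distance(m))
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(dd[i, j], 1 - bf_pearson(m[i, ], m[j, ]),
                 tolerance = 1e-12)
  expect_error(correlation_distance(m[1, , drop = FALSE]), "at least 2")
  m_na <- m; m_na[1, 1] <- NA
  expect_error(correlation_distance(m_na), "missing")
  expect_silent(dimp <- suppressMessages(
    correlation_distance(m_na, missing = "impute")))
})

test_that("complete linkage follows the hand-traced merge order", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.8,
                0.9, 0.8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t <- hca_complete(as.dist(d))
  expect_equal(t$height, c(0.1, 0.9))  # (A,B) at 0.1, then C joins at max
  # n identical profiles: all merges at height 0
  design <- toy_design(5L)
  x <- rnorm(5)
  same <- matrix(rep(x, 4), 4, byrow = TRUE,
                 dimnames = list(letters[1:4], design$sample_id))
  t0 <- hca_complete(correlation_distance(same))
  expect_true(all(abs(t0$height) < 1e-12))
  expect_error(hca_complete(stats::as.dist(matrix(c(0, NA, NA, 0), 2))),
               "non-finite")
})

test_that("merge heights match a naive agglomerative oracle", {
  set.seed(31)
  for (rep in 1:10) {
    m <- matrix(rnorm(12 * 8), 12, 8)
    rownames(m) <- sprintf("f%02d", 1:12)
    colnames(m) <- sprintf("s%d", 1:8)
    D <- as.matrix(1 - cor(t(m)))
    diag(D) <- 0
    t <- hca_complete(stats::as.dist(D))
    expect_equal(t$height, naive_complete_linkage(D), tolerance = 1e-10)
    expect_false(is.unsorted(t$height))
  }
})

test_that("similarity cuts behave at the extremes", {
  set.seed(32)
  m <- matrix(rnorm(6 * 8), 6, 8)
  rownames(m) <- letters[1:6]
  t <- hca_complete(correlation_distance(m))
  below_first <- 1 - min(t$height) + 1e-9    # cut below the first merge
  expect_equal(max(cut_by_similarity(t, below_first)), 6L)
  above_root <- 1 - max(t$height) - 1e-9     # cut above the root
  expect_equal(max(cut_by_similarity(t, above_root)), 1L)
})

test_that("cophenetic similarity never exceeds pairwise similarity", {
  set.seed(33)
  for (rep in 1:10) {
    m <- matrix(rnorm(10 * 8), 10, 8)
    rownames(m) <- sprintf("f%02d", 1:10)
    d <- correlation_distance(m)
    t <- hca_complete(d)
    coph <- stats::cophenetic(t)
    # complete linkage: cophenetic distance >= pairwise distance
    expect_true(all(as.vector(coph) - as.vector(d) >= -1e-12))
  }
})

test_that("leaf order does not change heights or partitions", {
  set.seed(34)
  m <- matrix(rnorm(9 * 10), 9, 10)
  rownames(m) <- sprintf("f%02d", 1:9)
  t1 <- hca_complete(correlation_distance(m))
  perm <- sample(nrow(m))
  t2 <- hca_complete(correlation_distance(m[perm, ]))
  expect_equal(sort(t1$height), sort(t2$height), tolerance = 1e-12)
  part <- function(t) {
    cl <- cut_by_similarity(t, 0.5)
    unname(sort(vapply(split(names(cl), cl),
                       function(s) paste(sort(s), collapse = ","), "")))
  }
  expect_identical(part(t1), part(t2))
})

test_that("genes co-clustered with volatiles are recovered from the tree", {
  design <- toy_design(8L)
  set.seed(35)
  v <- rnorm(8)
  vals <- rbind(VOC_1 = v, GENE_same = v, GENE_far = rnorm(8))
  colnames(vals) <- design$sample_id
  t <- hca_complete(correlation_distance(vals))
  cc <- co_clustered_genes(t, "VOC_1", min_sim = 0.9)
  expect_equal(cc[[1L]]$genes, "GENE_same")   # duplicate profile always in
  # min_sim = 1 on noisy data: no gene joins at similarity 1
  cc1 <- co_clustered_genes(t, "VOC_1", min_sim = 1)
  expect_false("GENE_far" %in% unlist(lapply(cc1, `[[`, "genes")))
  expect_error(co_clustered_genes(t, "VOC_none", 0.5), "absent")
})

test_that("archetype volatile clusters are recovered at the 0.6 cut", {
  # three well-separated trend families; mean adjusted Rand index across
  # 100 simulated worlds must reach 0.9
  arch <- default_archetypes()[c(1L, 4L, 5L)]
  for (i in seq_along(arch)) arch[[i]]$n_volatiles <- 12L
  aris <- vapply(seq_len(100L), function(i) {
    spec <- synthetic_spec(n_genes = 2L, n_volatiles = 36L,
                           archetypes = arch, rng_seed = 5000L + i,
                           planted_links = data.frame(
                             gene_id = character(0),
                             target_archetype = character(0),
                             target_r = numeric(0)))
    ds <- generate_dataset(spec)
    t <- hca_complete(correlation_distance(ds$volatiles))
    cl <- cut_by_similarity(t, 0.6)
    adj_rand_index(cl, ds$truth$volatile_archetype[names(cl)])
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("planted genes carry HCA evidence at the 0.6 similarity cut", {
  hits <- vapply(seq_len(50L), function(i) {
    ds <- generate_dataset(small_spec(seed = 5200L + i, n_genes = 150L))
    joint <- rbind(ds$genes$values, ds$volatiles$values)
    t <- hca_complete(correlation_distance(joint))
    cc <- co_clustered_genes(t, rownames(ds$volatiles$values), 0.6)
    found <- unlist(lapply(cc, `[[`, "genes"))
    mean(ds$truth$planted$gene_id %in% found)
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})
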