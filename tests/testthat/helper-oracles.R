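# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (textbook sums, explicit loops) so they cannot share a
# code path with the package implementation.

# Pearson correlation via the textbook sum formula
bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  num / den
}

# all merge heights of naive agglomerative complete linkage
naive_complete_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    k <- length(clusters)
    bestd <- Inf; bi <- bj <- NA
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < bestd) { bestd <- d; bi <- i; bj <- j }
    }
    heights <- c(heights, bestd)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# adjusted Rand index from the contingency table
adj_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  sa <- sum(comb2(rowSums(tab)))
  sb <- sum(comb2(colSums(tab)))
  expected <- sa * sb / comb2(length(a))
  (sij - expected) / ((sa + sb) / 2 - expected)
}

# degree / local clustering / components from an explicit edge list
bf_topology <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$u[i]]] <- c(adj[[edges$u[i]]], edges$v[i])
    adj[[edges$v[i]]] <- c(adj[[edges$v[i]]], edges$u[i])
  }
  deg <- lengths(adj)
  cc <- vapply(nodes, function(v) {
    nb <- adj[[v]]; k <- length(nb)
    if (k < 2L) return(0)
    links <- 0L
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      if (nb[j] %in% adj[[nb[i]]]) links <- links + 1L
    2 * links / (k * (k - 1))
  }, numeric(1))
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (v in nodes) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, adj[[u]])
    }
  }
  list(degree = deg, clustering = cc, component = comp)
}

# small standard design and a hand-rolled correlation_set for edge cases
toy_design <- function(n = 6L) {
  data.frame(sample_id = sprintf("s%d", seq_len(n)),
             genotype = "GenotypeA",
             stage = rep(c("S1", "S2", "S3", "S4", "S4SL"),
                         length.out = n),
             replicate = seq_len(n), stringsAsFactors = FALSE)
}

make_cs <- function(gene_vol, vol_vol = NULL, gene_gene = NULL) {
  if (is.null(vol_vol)) {
    vol_vol <- diag(ncol(gene_vol))
    dimnames(vol_vol) <- list(colnames(gene_vol), colnames(gene_vol))
  }
  structure(list(gene_vol = gene_vol, vol_vol = vol_vol,
                 gene_gene = gene_gene,
                 n_used = matrix(30L, nrow(gene_vol), ncol(gene_vol),
                                 dimnames = dimnames(gene_vol))),
            class = "correlation_set")
}

# scaled-down synthetic world used where full size is not needed
small_spec <- function(seed = 1L, n_genes = 150L, ...) {
  synthetic_spec(n_genes = n_genes, rng_seed = seed, ...)
}
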