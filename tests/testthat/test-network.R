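# symmetric volatile correlation block from an explicit edge spec
vv_from_edges <- function(ids, edges) {
  vv <- diag(length(ids))
  dimnames(vv) <- list(ids, ids)
  for (i in seq_len(nrow(edges))) {
    vv[edges$u[i], edges$v[i]] <- vv[edges$v[i], edges$u[i]] <- edges$r[i]
  }
  vv
}

test_that("gene preselection is strict at the 0.85 boundary", {
  gv <- matrix(c(0.850, 0.8500001, -0.86, 0.2), 4, 1,
               dimnames = list(c("gBoundary", "gJustOver", "gNegStrong",
                                 "gWeak"), "v1"))
  cs <- make_cs(gv)
  expect_setequal(preselect_genes(cs, 0.85), c("gJustOver", "gNegStrong"))
  expect_error(preselect_genes(cs, 1.2), "cutoff")
  expect_error(preselect_genes(cs, 0.85, volatile_ids = "vX"), "unknown")
})

test_that("volatile network edges are classed and floored correctly", {
  ids <- c("v1", "v2", "v3", "v4")
  vv <- vv_from_edges(ids, data.frame(
    u = c("v1", "v1", "v2", "v3"), v = c("v2", "v3", "v3", "v4"),
    r = c(1.0, -0.96, 0.72, 0.3), stringsAsFactors = FALSE))
  cs <- make_cs(matrix(0, 1, 4, dimnames = list("g1", ids)), vol_vol = vv)
  net <- build_voc_network(cs)
  expect_equal(nrow(net$edges), 3L)       # the 0.3 pair is under the floor
  e12 <- net$edges[net$edges$u == "v1" & net$edges$v == "v2", ]
  expect_equal(e12$r, 1)
  expect_equal(e12$strength, "strong")
  e13 <- net$edges[net$edges$u == "v1" & net$edges$v == "v3", ]
  expect_equal(e13$strength, "strong")
  expect_equal(e13$sign, "negative")
  e23 <- net$edges[net$edges$u == "v2" & net$edges$v == "v3", ]
  expect_equal(e23$strength, "moderate")
  # a floor of 1.0 empties the edge set but keeps all nodes
  net_hi <- build_voc_network(cs, floor = 1.0000001)
  expect_equal(nrow(net_hi$edges), 0L)
  expect_equal(nrow(net_hi$nodes), 4L)
})

test_that("merged network node count and VOC-subgraph invariants hold", {
  ds <- generate_dataset(small_spec(seed = 90L, n_genes = 200L))
  cs <- pearson_all_pairs(ds$genes, ds$volatiles)
  pre <- preselect_genes(cs, 0.85)
  voc <- build_voc_network(cs)
  merged <- build_merged_network(cs, ds$genes, cutoff = 0.85,
                                 preselected = pre)
  expect_equal(nrow(merged$nodes), 52L + length(pre))
  # merged edge set is a superset of the VOC edges, identical weights
  key <- function(e) paste(e$u, e$v, signif(e$r, 12))
  expect_true(all(key(voc$edges) %in% key(merged$edges)))
  # degree sums to twice the edge count
  topo <- topology(merged)
  expect_equal(sum(topo$degree), 2L * nrow(merged$edges))
  # no gene passes: merged equals the VOC network
  merged_none <- build_merged_network(cs, ds$genes, cutoff = 0.85,
                                      preselected = character(0))
  expect_equal(nrow(merged_none$nodes), 52L)
  expect_equal(merged_none$edges, voc$edges)
})

test_that("raising cutoffs never adds nodes or edges", {
  ds <- generate_dataset(small_spec(seed = 91L, n_genes = 200L))
  cs <- pearson_all_pairs(ds$genes, ds$volatiles)
  sizes <- t(vapply(c(0.75, 0.80, 0.85, 0.90, 0.95), function(cut) {
    net <- build_merged_network(cs, ds$genes, cutoff = cut)
    c(nodes = nrow(net$nodes), edges = nrow(net$edges))
  }, numeric(2)))
  expect_true(all(diff(sizes[, "nodes"]) <= 0))
  expect_true(all(diff(sizes[, "edges"]) <= 0))
})

test_that("opposite-trend archetypes are joined by strong negative edges", {
  ds <- generate_dataset(small_spec(seed = 92L, n_genes = 20L))
  cs <- pearson_all_pairs(ds$genes, ds$volatiles)
  net <- build_voc_network(cs)
  arch <- ds$truth$volatile_archetype
  across <- net$edges[(arch[net$edges$u] == "C1" & arch[net$edges$v] == "C5") |
                      (arch[net$edges$u] == "C5" & arch[net$edges$v] == "C1"), ]
  expect_gt(nrow(across), 0L)
  expect_true(all(across$r < 0))
  expect_true(any(across$strength %in% c("strong", "moderate")))
})

test_that("topology matches brute-force recomputation", {
  # star on 40 nodes: center degree 39, clustering 0 everywhere
  ids <- sprintf("v%02d", 1:40)
  star <- data.frame(u = ids[1L], v = ids[-1L], r = 0.9,
                     stringsAsFactors = FALSE)
  cs_star <- make_cs(matrix(0, 1, 40, dimnames = list("g1", ids)),
                     vol_vol = vv_from_edges(ids, star))
  topo <- topology(build_voc_network(cs_star))
  expect_equal(topo$degree[topo$node == ids[1L]], 39L)
  expect_true(all(topo$degree[topo$node != ids[1L]] == 1L))
  expect_true(topo$is_hub[topo$node == ids[1L]])
  expect_true(all(topo$clustering == 0))
  # triangle: clustering coefficient 1 for all three nodes
  tri_ids <- c("a", "b", "c")
  tri <- data.frame(u = c("a", "a", "b"), v = c("b", "c", "c"), r = 0.9,
                    stringsAsFactors = FALSE)
  cs_tri <- make_cs(matrix(0, 1, 3, dimnames = list("g1", tri_ids)),
                    vol_vol = vv_from_edges(tri_ids, tri))
  expect_true(all(topology(build_voc_network(cs_tri))$clustering == 1))
  # random graph vs the brute-force oracle
  set.seed(93)
  nid <- sprintf("n%02d", 1:15)
  pairs <- t(combn(nid, 2L))
  take <- runif(nrow(pairs)) < 0.25
  rnd <- data.frame(u = pairs[take, 1L], v = pairs[take, 2L],
                    r = runif(sum(take), 0.6, 1), stringsAsFactors = FALSE)
  cs_rnd <- make_cs(matrix(0, 1, 15, dimnames = list("g1", nid)),
                    vol_vol = vv_from_edges(nid, rnd))
  net <- build_voc_network(cs_rnd)
  topo <- topology(net)
  bf <- bf_topology(net$edges, nid)
  expect_equal(topo$degree, unname(bf$degree[topo$node]))
  expect_equal(topo$clustering, unname(bf$clustering[topo$node]),
               tolerance = 1e-12)
  # component labels agree up to renaming (same co-membership structure)
  expect_identical(outer(topo$component, topo$component, "=="),
                   outer(unname(bf$component[topo$node]),
                         unname(bf$component[topo$node]), "=="))
})

test_that("sub-clusters are |r|-thresholded gene components", {
  ids <- c("v1")
  gv <- matrix(c(0.9, 0.9, 0.9, 0.9, 0.9), 5, 1,
               dimnames = list(sprintf("g%d", 1:5), ids))
  gg <- diag(5)
  dimnames(gg) <- list(rownames(gv), rownames(gv))
  # module 1: g1-g2-g3 tightly linked; module 2: g4-g5; no cross edges
  gg["g1", "g2"] <- gg["g2", "g1"] <- 0.97
  gg["g2", "g3"] <- gg["g3", "g2"] <- 0.96
  gg["g4", "g5"] <- gg["g5", "g4"] <- 0.98
  cs <- make_cs(gv, gene_gene = gg)
  net <- build_merged_network(cs, cutoff = 0.85)
  sc <- subclusters(net, gene_edge_sim = 0.95)
  expect_equal(length(unique(sc)), 2L)
  expect_equal(unname(sc["g1"]), unname(sc["g3"]))
  expect_false(unname(sc["g1"]) == unname(sc["g4"]))
  # threshold above every edge weight: all singletons
  sc_hi <- subclusters(net, gene_edge_sim = 0.999)
  expect_equal(length(unique(sc_hi)), 5L)
})

test_that("SIF and GraphML exports are written and deterministic", {
  ds <- generate_dataset(small_spec(seed = 94L, n_genes = 80L))
  cs <- pearson_all_pairs(ds$genes, ds$volatiles)
  net <- build_merged_network(cs, ds$genes)
  sif1 <- withr::local_tempfile(fileext = ".sif")
  sif2 <- withr::local_tempfile(fileext = ".sif")
  export_sif(net, sif1); export_sif(net, sif2)
  expect_identical(readLines(sif1), readLines(sif2))
  lines <- readLines(sif1)
  expect_equal(length(lines),
               nrow(net$edges) +
                 sum(!net$nodes$name %in% c(net$edges$u, net$edges$v)))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, gml)
  expect_true(any(grepl("graphml", readLines(gml, n = 5L))))
})
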