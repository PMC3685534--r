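# classify edge strength by |r|
.edge_strength <- function(r, strong, moderate) {
  ifelse(abs(r) >= strong, "strong",
         ifelse(abs(r) >= moderate, "moderate", "weak"))
}

# assemble a typed correlation network and check basic invariants
.make_volnet <- function(nodes, edges, thresholds) {
  if (nrow(edges)) {
    if (any(edges$u == edges$v)) stop("self-edges are not allowed")
    o <- order(edges$u, edges$v)
    edges <- edges[o, , drop = FALSE]
    rownames(edges) <- NULL
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else data.frame(u = character(0), v = character(0)),
    directed = FALSE, vertices = nodes)
  deg <- igraph::degree(g)
  stopifnot(sum(deg) == 2L * nrow(edges))
  net <- list(graph = g, nodes = nodes, edges = edges,
              thresholds = thresholds)
  class(net) <- "vol_network"
  net
}

#' @export
print.vol_network <- function(x, ...) {
  cat(sprintf("vol_network: %d nodes (%d VOC, %d gene), %d edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "VOC"),
              sum(x$nodes$kind == "gene"), nrow(x$edges)))
  invisible(x)
}

#' Preselect genes for the correlation network
#'
#' A gene is retained iff its largest |r| with any volatile strictly
#' exceeds `cutoff` (study default 0.85; a gene at exactly 0.85 is
#' excluded). `volatile_ids` restricts the volatiles considered, as in the
#' secondary 0.80-cutoff network for the weakly connected volatile
#' clusters.
#'
#' @param cs [pearson_all_pairs()] result.
#' @param cutoff correlation cutoff in (0, 1).
#' @param volatile_ids optional subset of volatile columns.
#' @return character vector of gene ids (sorted).
#' @export
preselect_genes <- function(cs, cutoff = 0.85, volatile_ids = NULL) {
  stopifnot(inherits(cs, "correlation_set"), cutoff > 0, cutoff < 1)
  r <- cs$gene_vol
  if (!is.null(volatile_ids)) {
    missing_v <- setdiff(volatile_ids, colnames(r))
    if (length(missing_v)) stop("unknown volatiles: ",
                                paste(missing_v, collapse = ", "))
    r <- r[, volatile_ids, drop = FALSE]
  }
  mx <- suppressWarnings(apply(abs(r), 1L, max, na.rm = TRUE))
  sort(names(mx)[is.finite(mx) & mx > cutoff])
}

#' Volatile-only correlation network
#'
#' Every volatile pair with |r| at or above the retention floor becomes an
#' edge, classed by |r| as strong (>= `strong`), moderate (in
#' [`moderate`, `strong`)) or weak (< `moderate`).
#'
#' @param cs [pearson_all_pairs()] result (uses the volatile-volatile
#'   block).
#' @param floor minimum |r| for edge retention (default 0.5).
#' @param strong,moderate strength class boundaries (defaults 0.95, 0.70).
#' @return `vol_network`.
#' @export
build_voc_network <- function(cs, floor = 0.5, strong = 0.95,
                              moderate = 0.70) {
  stopifnot(inherits(cs, "correlation_set"))
  vv <- cs$vol_vol
  ids <- colnames(vv)
  iu <- which(upper.tri(vv) & !is.na(vv) & abs(vv) >= floor, arr.ind = TRUE)
  r <- vv[iu]
  edges <- data.frame(u = ids[iu[, 1L]], v = ids[iu[, 2L]], r = r,
                      sign = ifelse(r >= 0, "positive", "negative"),
                      strength = .edge_strength(r, strong, moderate),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(name = ids, kind = "VOC", stringsAsFactors = FALSE)
  .make_volnet(nodes, edges,
               list(floor = floor, strong = strong, moderate = moderate))
}

#' Merged volatile + gene correlation network
#'
#' Nodes are all volatiles plus the preselected genes. Edges are (i) all
#' volatile-volatile pairs above the retention floor (identical to the
#' volatile-only network) and (ii) gene-volatile and gene-gene pairs with
#' |r| strictly above `cutoff`.
#'
#' @param cs [pearson_all_pairs()] result.
#' @param genes gene [omics_matrix()] (used for the gene-gene correlations
#'   among preselected genes), or NULL if `cs$gene_gene` is present.
#' @param cutoff gene edge cutoff (strict `>`, default 0.85).
#' @param preselected gene ids; computed via [preselect_genes()] when NULL.
#' @param floor,strong,moderate volatile edge parameters, as in
#'   [build_voc_network()].
#' @return `vol_network`.
#' @export
build_merged_network <- function(cs, genes = NULL, cutoff = 0.85,
                                 preselected = NULL, floor = 0.5,
                                 strong = 0.95, moderate = 0.70) {
  stopifnot(inherits(cs, "correlation_set"))
  if (is.null(preselected)) preselected <- preselect_genes(cs, cutoff)
  voc <- build_voc_network(cs, floor, strong, moderate)
  edges <- voc$edges
  if (length(preselected)) {
    gv <- cs$gene_vol[preselected, , drop = FALSE]
    iu <- which(!is.na(gv) & abs(gv) > cutoff, arr.ind = TRUE)
    if (nrow(iu)) {
      r <- gv[iu]
      edges <- rbind(edges, data.frame(
        u = rownames(gv)[iu[, 1L]], v = colnames(gv)[iu[, 2L]], r = r,
        sign = ifelse(r >= 0, "positive", "negative"),
        strength = .edge_strength(r, strong, moderate),
        stringsAsFactors = FALSE))
    }
    gg <- cs$gene_gene
    if (is.null(gg)) {
      if (is.null(genes)) stop("need gene matrix or gene_gene block")
      gm <- genes$values[preselected, , drop = FALSE]
      suppressWarnings(
        gg <- stats::cor(t(gm), use = "pairwise.complete.obs"))
    } else gg <- gg[preselected, preselected, drop = FALSE]
    gg <- gg[preselected, preselected, drop = FALSE]
    iu <- which(upper.tri(gg) & !is.na(gg) & abs(gg) > cutoff,
                arr.ind = TRUE)
    if (nrow(iu)) {
      r <- gg[iu]
      edges <- rbind(edges, data.frame(
        u = rownames(gg)[iu[, 1L]], v = colnames(gg)[iu[, 2L]], r = r,
        sign = ifelse(r >= 0, "positive", "negative"),
        strength = .edge_strength(r, strong, moderate),
        stringsAsFactors = FALSE))
    }
  }
  nodes <- rbind(voc$nodes,
                 data.frame(name = preselected,
                            kind = rep("gene", length(preselected)),
                            stringsAsFactors = FALSE))
  .make_volnet(nodes, edges,
               list(floor = floor, strong = strong, moderate = moderate,
                    cutoff = cutoff))
}

#' Per-node topology metrics
#'
#' Degree, local clustering coefficient (0 for degree < 2, the
#' NetworkAnalyzer convention), connected-component id and hub status
#' (degree at or above the configured degree percentile).
#'
#' @param net `vol_network`.
#' @param hub_percentile degree percentile defining hubs (default 0.95,
#'   i.e. top 5 percent).
#' @return data.frame(`node`, `kind`, `degree`, `clustering`, `component`,
#'   `is_hub`).
#' @export
topology <- function(net, hub_percentile = 0.95) {
  stopifnot(inherits(net, "vol_network"))
  g <- net$graph
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2L] <- 0
  comp <- igraph::components(g)$membership
  thr <- stats::quantile(deg, hub_percentile, names = FALSE)
  data.frame(node = igraph::V(g)$name,
             kind = net$nodes$kind[match(igraph::V(g)$name, net$nodes$name)],
             degree = unname(deg), clustering = unname(cc),
             component = unname(comp),
             is_hub = unname(deg >= thr & deg > 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene sub-clusters of the merged network
#'
#' Gene nodes are partitioned by the connected components of the gene-gene
#' sub-graph restricted to edges with |r| >= `gene_edge_sim` (default 0.95,
#' the "strong" boundary); singleton genes get their own label. Labels
#' (`SC1`, `SC2`, ...) are assigned by decreasing component size, ties by
#' smallest member id.
#'
#' @param net merged `vol_network`.
#' @param gene_edge_sim |r| threshold for sub-cluster membership.
#' @return named character vector, gene id -> sub-cluster label.
#' @export
subclusters <- function(net, gene_edge_sim = 0.95) {
  stopifnot(inherits(net, "vol_network"))
  gene_ids <- net$nodes$name[net$nodes$kind == "gene"]
  if (!length(gene_ids)) return(stats::setNames(character(0), character(0)))
  e <- net$edges
  keep <- e$u %in% gene_ids & e$v %in% gene_ids & abs(e$r) >= gene_edge_sim
  g <- igraph::graph_from_data_frame(e[keep, c("u", "v"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = gene_ids))
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  firsts <- tapply(names(comp), comp, min)
  ord <- order(-as.integer(sizes), firsts)
  relabel <- stats::setNames(sprintf("SC%d", seq_along(ord)),
                             names(sizes)[ord])
  stats::setNames(unname(relabel[as.character(comp)]), names(comp))
}

#' Export a network in SIF format
#'
#' One line per edge: `source <TAB> strength <TAB> target`; isolated nodes
#' are written as single-column lines (Cytoscape convention).
#'
#' @param net `vol_network`.
#' @param path output file path.
#' @export
export_sif <- function(net, path) {
  e <- net$edges
  lines <- if (nrow(e)) paste(e$u, e$strength, e$v, sep = "\t") else character(0)
  isolated <- setdiff(net$nodes$name, c(e$u, e$v))
  writeLines(c(lines, isolated), path)
  invisible(NULL)
}

#' Export a network in GraphML format (Cytoscape-compatible)
#'
#' @param net `vol_network`.
#' @param path output file path.
#' @export
export_graphml <- function(net, path) {
  g <- net$graph
  igraph::V(g)$kind <- net$nodes$kind[match(igraph::V(g)$name,
                                            net$nodes$name)]
  igraph::write_graph(g, path, format = "graphml")
  invisible(NULL)
}
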