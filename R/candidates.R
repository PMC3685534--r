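#' Collect multi-evidence candidate genes
#'
#' Per volatile cluster, takes the union of the genes found by joint
#' hierarchical co-clustering (HCA), per-volatile top-k Pearson correlation
#' lists (PC), and correlation-network adjacency (CNA), recording which
#' sources identified each gene. One row per (gene, volatile cluster).
#'
#' @param hca output of [co_clustered_genes()] (each element has
#'   `volatiles` and `genes`).
#' @param pc named list, volatile id -> data.frame from
#'   [top_k_correlated()] (or a character vector of gene ids).
#' @param cna merged `vol_network`: genes edge-linked to a member volatile
#'   count as CNA evidence.
#' @param volatile_clusters named character vector, volatile id -> cluster
#'   label.
#' @param gene_universe character vector of known gene ids; evidence naming
#'   an unknown gene is an error.
#' @param annotations optional feature metadata data.frame (`feature_id`,
#'   `annotation`, `tags`) used to fill the annotation column.
#' @return data.frame of class `candidate_table`: `gene_id`, `annotation`,
#'   `volatile_cluster`, logical `hca`/`pc`/`cna`, `identified_by`,
#'   `excluded`, `exclusion_reason`.
#' @export
collect_evidence <- function(hca, pc, cna, volatile_clusters, gene_universe,
                             annotations = NULL) {
  cluster_of <- volatile_clusters
  labels <- sort(unique(cluster_of))
  ev <- list()
  add <- function(genes, cluster, source) {
    genes <- unique(genes)
    if (!length(genes)) return()
    unknown <- setdiff(genes, gene_universe)
    if (length(unknown))
      stop(source, " evidence names unknown gene(s): ",
           paste(unknown, collapse = ", "))
    ev[[length(ev) + 1L]] <<- data.frame(
      gene_id = genes, volatile_cluster = cluster, source = source,
      stringsAsFactors = FALSE)
  }
  for (grp in hca) {
    cls <- unique(cluster_of[grp$volatiles])
    cls <- cls[!is.na(cls)]
    for (cl in cls) add(grp$genes, cl, "HCA")
  }
  for (v in names(pc)) {
    cl <- cluster_of[[v]]
    if (is.null(cl) || is.na(cl)) next
    genes <- if (is.data.frame(pc[[v]])) pc[[v]]$gene_id else pc[[v]]
    add(genes, cl, "PC")
  }
  if (!is.null(cna)) {
    stopifnot(inherits(cna, "vol_network"))
    e <- cna$edges
    gene_nodes <- cna$nodes$name[cna$nodes$kind == "gene"]
    for (cl in labels) {
      members <- names(cluster_of)[cluster_of == cl]
      linked <- unique(c(e$u[e$v %in% members], e$v[e$u %in% members]))
      add(intersect(linked, gene_nodes), cl, "CNA")
    }
  }
  if (!length(ev)) {
    out <- data.frame(gene_id = character(0), annotation = character(0),
                      volatile_cluster = character(0),
                      hca = logical(0), pc = logical(0), cna = logical(0),
                      identified_by = character(0), excluded = logical(0),
                      exclusion_reason = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("candidate_table", "data.frame")
    return(out)
  }
  ev <- do.call(rbind, ev)
  key <- paste(ev$gene_id, ev$volatile_cluster, sep = "\r")
  rows <- unique(ev[, c("gene_id", "volatile_cluster")])
  rows <- rows[order(rows$volatile_cluster, rows$gene_id), , drop = FALSE]
  rkey <- paste(rows$gene_id, rows$volatile_cluster, sep = "\r")
  has <- function(src) rkey %in% key[ev$source == src]
  rows$hca <- has("HCA"); rows$pc <- has("PC"); rows$cna <- has("CNA")
  rows$identified_by <- apply(rows[, c("hca", "pc", "cna")], 1L, function(f)
    paste(c("HCA", "PC", "CNA")[f], collapse = ", "))
  rows$annotation <- if (!is.null(annotations))
    annotations$annotation[match(rows$gene_id, annotations$feature_id)]
  else ""
  rows$excluded <- FALSE
  rows$exclusion_reason <- NA_character_
  rows <- rows[, c("gene_id", "annotation", "volatile_cluster",
                   "hca", "pc", "cna", "identified_by",
                   "excluded", "exclusion_reason")]
  rownames(rows) <- NULL
  class(rows) <- c("candidate_table", "data.frame")
  rows
}

#' Mark ripening-general candidates as excluded
#'
#' Genes whose annotation tags intersect the exclusion set (case-
#' insensitive exact set membership) are flagged excluded with the matching
#' tag as reason — they stay in the table for auditability. The default set
#' encodes the expert rule of removing genes whose annotation points at
#' general ripening machinery rather than aroma formation.
#'
#' @param tab `candidate_table`.
#' @param gene_tags named list (gene id -> character vector of tags) or a
#'   feature metadata data.frame with `feature_id` and `;`-separated `tags`.
#' @param exclusion_tags tags that trigger exclusion.
#' @return `candidate_table` with `excluded`/`exclusion_reason` filled.
#' @export
exclusion_filter <- function(tab, gene_tags,
                             exclusion_tags = c("ethylene biosynthesis",
                                                "ethylene signaling",
                                                "cell wall softening")) {
  stopifnot(inherits(tab, "candidate_table"))
  if (is.data.frame(gene_tags)) {
    gene_tags <- stats::setNames(
      lapply(strsplit(gene_tags$tags, ";", fixed = TRUE), trimws),
      gene_tags$feature_id)
  }
  excl <- tolower(trimws(exclusion_tags))
  for (i in seq_len(nrow(tab))) {
    tags <- tolower(trimws(gene_tags[[tab$gene_id[i]]]))
    hit <- intersect(tags, excl)
    if (length(hit)) {
      tab$excluded[i] <- TRUE
      tab$exclusion_reason[i] <- hit[1L]
    }
  }
  tab
}

#' Render a candidate table as Markdown
#'
#' Mirrors the reporting layout: id, annotation, target volatile cluster,
#' "Identified by" string, exclusion status.
#'
#' @param tab `candidate_table`.
#' @param path optional output file.
#' @return character vector of Markdown lines (invisibly when written).
#' @export
candidate_markdown <- function(tab, path = NULL) {
  hdr <- c("| id | annotation | volatile cluster | Identified by | excluded |",
           "|---|---|---|---|---|")
  body <- sprintf("| %s | %s | %s | %s | %s |",
                  tab$gene_id, tab$annotation, tab$volatile_cluster,
                  tab$identified_by,
                  ifelse(tab$excluded, tab$exclusion_reason, ""))
  lines <- c(hdr, body)
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
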