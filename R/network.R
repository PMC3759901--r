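#' Build the miRNA-mRNA target network from filtered features
#'
#' Integrates the two filtering results with an interaction table into a
#' directed bipartite regulatory network. An interaction is retained iff both
#' endpoints were filtered (matching is case-insensitive on the ids) and the
#' pair is either experimentally validated or predicted by at least
#' `min_algorithms` of the 10 prediction algorithms. Filtered features without
#' any retained interaction do not appear as nodes.
#'
#' @param mirnas a [filter_features()] result (or `maid_fit`) for the miRNA
#'   data set.
#' @param genes a [filter_features()] result (or `maid_fit`) for the mRNA
#'   data set.
#' @param interactions an [interaction_table()].
#' @param min_algorithms consensus threshold on the prediction algorithm count
#'   (default 5 of 10).
#' @return An object of class `target_network`: `nodes` (data.frame `id`,
#'   `role` in mirna/gene, `direction` in up/down/conflict) and `edges`
#'   (data.frame `mirna`, `gene`, `evidence` in predicted/validated/both,
#'   `n_algorithms`).
#' @export
build_network <- function(mirnas, genes, interactions, min_algorithms = 5L) {
  direction_of <- function(fr) {
    if (inherits(fr, "maid_fit")) fr <- fr$filter
    stopifnot(inherits(fr, "maid_filter"))
    ids <- union(fr$union_up, fr$union_down)
    dir <- ifelse(ids %in% fr$conflicts, "conflict",
                  ifelse(ids %in% fr$union_up, "up", "down"))
    stats::setNames(dir, ids)
  }
  mdir <- direction_of(mirnas)
  gdir <- direction_of(genes)
  collide <- intersect(tolower(names(mdir)), tolower(names(gdir)))
  if (length(collide) > 0L)
    stop("identifier collision between miRNA and gene ids: ",
         paste(collide, collapse = ", "))
  it <- as.data.frame(interactions, stringsAsFactors = FALSE)
  m_idx <- match(tolower(it$mirna), tolower(names(mdir)))
  g_idx <- match(tolower(it$gene), tolower(names(gdir)))
  predicted <- !is.na(it$n_algorithms) & it$n_algorithms >= min_algorithms
  keep <- !is.na(m_idx) & !is.na(g_idx) & (it$validated | predicted)
  edges <- data.frame(
    mirna = names(mdir)[m_idx[keep]],
    gene = names(gdir)[g_idx[keep]],
    evidence = ifelse(it$validated[keep] & predicted[keep], "both",
                      ifelse(it$validated[keep], "validated", "predicted")),
    n_algorithms = it$n_algorithms[keep],
    stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$mirna, edges$gene, sep = "\r")), ,
                 drop = FALSE]
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  node_ids <- c(sort(unique(edges$mirna)), sort(unique(edges$gene)))
  nodes <- data.frame(
    id = node_ids,
    role = rep(c("mirna", "gene"),
               c(length(unique(edges$mirna)), length(unique(edges$gene)))),
    stringsAsFactors = FALSE)
  nodes$direction <- ifelse(nodes$role == "mirna",
                            mdir[nodes$id], gdir[nodes$id])
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 min_algorithms = min_algorithms),
            class = "target_network")
}

#' @export
print.target_network <- function(x, ...) {
  st <- network_stats(x)
  cat("miRNA-mRNA target network (consensus >= ", x$min_algorithms,
      " of 10 algorithms)\n", sep = "")
  cat(sprintf("  %d miRNAs -> %d genes; %d predicted and %d validated interactions\n",
              st$n_mirnas_connected, st$n_genes_connected,
              st$n_predicted_edges, st$n_validated_edges))
  if (nrow(st$hubs) > 0L)
    cat("  target hubs (in-degree > 5):",
        paste(st$hubs$id, collapse = ", "), "\n")
  invisible(x)
}

#' Summary statistics of a target network
#'
#' @param net a [build_network()] result.
#' @param hub_degree genes targeted by more than this many miRNAs are reported
#'   as miRNA target hubs (default 5).
#' @return List with `n_mirnas_connected`, `n_genes_connected`, `n_edges`,
#'   `n_predicted_edges` (consensus-predicted, including pairs that are also
#'   validated), `n_validated_edges`, `degrees` (data.frame `id`, `role`,
#'   `degree`), `hubs` (the gene rows with degree > `hub_degree`).
#' @export
network_stats <- function(net, hub_degree = 5L) {
  stopifnot(inherits(net, "target_network"))
  e <- net$edges
  deg_part <- function(ids, role) {
    tb <- table(ids)
    data.frame(id = names(tb), role = rep(role, length(tb)),
               degree = as.integer(tb), stringsAsFactors = FALSE)
  }
  deg <- rbind(deg_part(e$mirna, "mirna"), deg_part(e$gene, "gene"))
  rownames(deg) <- NULL
  hubs <- deg[deg$role == "gene" & deg$degree > hub_degree, , drop = FALSE]
  list(n_mirnas_connected = length(unique(e$mirna)),
       n_genes_connected = length(unique(e$gene)),
       n_edges = nrow(e),
       n_predicted_edges = sum(e$evidence %in% c("predicted", "both")),
       n_validated_edges = sum(e$evidence %in% c("validated", "both")),
       degrees = deg, hubs = hubs)
}

#' Convert a target network to an igraph object
#'
#' @param net a [build_network()] result.
#' @return A directed [igraph::graph] with node attributes `role`,
#'   `direction` and edge attributes `evidence`, `n_algorithms`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "target_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("mirna", "gene", "evidence", "n_algorithms")],
    directed = TRUE, vertices = net$nodes)
}

#' Write a target network as a SIF file
#'
#' Simple interaction format: `mirna targets gene`, one edge per line,
#' loadable by standard graph viewers.
#'
#' @param net a [build_network()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "target_network"))
  lines <- sprintf("%s\ttargets\t%s", net$edges$mirna, net$edges$gene)
  writeLines(lines, path)
  invisible(path)
}

#' Write a target network as GraphML
#'
#' @param net a [build_network()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
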