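#' Gene-Act network: interactions induced on differential genes
#'
#' Pools the supplied gene-gene interactions and keeps the edges whose
#' two endpoints are both differentially expressed; nodes carry their
#' regulation (up/down) and degree, and nodes with degree above
#' `hub_threshold` form the hub list.
#'
#' @param interactions an [interaction_table()].
#' @param de gene-level DE table (see [collapse_by_gene()]) with columns
#'   `gene_symbol` and `status`.
#' @param hub_threshold hub rule: degree strictly greater than this
#'   (default 25).
#' @return An undirected `igraph` with vertex attributes `regulation`,
#'   `degree`, `core`, `hub` and edge attribute `relation`; the hub gene
#'   names are in `graph_attr(g, "hubs")`.
#' @export
build_gene_act <- function(interactions, de, hub_threshold = 25) {
  de_genes <- de$gene_symbol[de$status != "ns"]
  keep <- interactions$gene_a %in% de_genes & interactions$gene_b %in% de_genes
  edges <- interactions[keep, , drop = FALSE]
  if (nrow(edges) == 0L) {
    warning("no interactions between differential genes: empty Gene-Act network",
            call. = FALSE)
    return(annotate_graph(igraph::make_empty_graph(directed = FALSE), de,
                          hub_threshold))
  }
  # metrics use unique undirected gene pairs even when relations differ
  uniq <- edges[!duplicated(edges[, c("gene_a", "gene_b")]), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    uniq[, c("gene_a", "gene_b", "relation")], directed = FALSE)
  annotate_graph(g, de, hub_threshold)
}

annotate_graph <- function(g, de, hub_threshold) {
  reg <- stats::setNames(de$status, de$gene_symbol)
  v <- igraph::V(g)$name
  igraph::V(g)$regulation <- ifelse(is.na(reg[v]), "connector",
                                    unname(reg[v]))
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::V(g)$core <- igraph::coreness(g)
  igraph::V(g)$hub <- igraph::V(g)$degree > hub_threshold
  igraph::graph_attr(g, "hub_threshold") <- hub_threshold
  igraph::graph_attr(g, "hubs") <- v[igraph::V(g)$hub]
  g
}

#' Hub genes of a Gene-Act network
#' @param g graph from [build_gene_act()].
#' @return Character vector of genes with degree above the hub threshold.
#' @export
hub_genes <- function(g) igraph::graph_attr(g, "hubs")

#' Pathway-Act network: significant pathways linked by shared genes
#'
#' Nodes are the significant pathways; two pathways are linked iff they
#' share at least `min_shared` differential genes, with the shared count
#' as edge weight.
#'
#' @param enrich an `enrichment_table` (pathway mode); only rows with
#'   `significant == TRUE` become nodes.
#' @param collection the [gene_set_collection()] the table was computed from.
#' @param de_genes character vector of differential genes.
#' @param min_shared minimum shared differential genes for an edge
#'   (default 3).
#' @return An undirected `igraph`; vertex attribute `regulation` is the
#'   pathway's direction, edge attribute `weight` the shared-gene count.
#' @export
build_pathway_act <- function(enrich, collection, de_genes, min_shared = 3L) {
  sig <- enrich[enrich$significant, , drop = FALSE]
  ids <- unique(sig$set_id)
  reg <- stats::setNames(sig$direction, sig$set_id)[ids]
  members <- lapply(collection$sets[ids], intersect, y = de_genes)
  from <- character(0); to <- character(0); w <- integer(0)
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        shared <- length(intersect(members[[i]], members[[j]]))
        if (shared >= min_shared) {
          from <- c(from, ids[i]); to <- c(to, ids[j]); w <- c(w, shared)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(ids, regulation = unname(reg))
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  }
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::V(g)$core <- igraph::coreness(g)
  g
}

#' Group-specific co-expression network
#'
#' Pearson correlation of every probe pair across the samples of one
#' tissue group; an edge joins a pair iff `|r| >= r_threshold` and the
#' correlation-test P (t transform, n - 2 df) is below `p_threshold`.
#' Pairs involving a constant profile have undefined correlation and are
#' skipped; their count is reported via a message and
#' `graph_attr(g, "skipped_pairs")`.
#'
#' @param x a normalized [expression_matrix()].
#' @param group `"tumor"` or `"normal"`.
#' @param probes probe ids to correlate (typically the differential
#'   probes); default all probes.
#' @param r_threshold absolute-correlation threshold (default 0.8).
#' @param p_threshold correlation-test P threshold (default 0.01).
#' @return An undirected `igraph` named by gene symbol, edge attribute
#'   `weight` = r; vertex attributes `degree` and `core`.
#' @export
build_coexpression <- function(x, group = c("tumor", "normal"), probes = NULL,
                               r_threshold = 0.8, p_threshold = 0.01) {
  group <- match.arg(group)
  samp <- group_samples(x, group)
  n <- length(samp)
  if (n < 4L) stop("group '", group, "' has fewer than 4 samples", call. = FALSE)
  if (is.null(probes)) probes <- x$probes$probe_id
  rows <- match(probes, x$probes$probe_id)
  if (anyNA(rows)) stop("unknown probe id(s)", call. = FALSE)
  m <- t(x$values[rows, samp, drop = FALSE])
  labels <- x$probes$gene_symbol[rows]
  const <- apply(m, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- NA
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-tstat, df = n - 2)
  adj <- !is.na(r) & abs(r) >= r_threshold & pval < p_threshold
  adj[const, ] <- FALSE; adj[, const] <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(labels)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(labels[idx[, 1]], labels[idx[, 2]]),
                           weight = r[idx])
  }
  n_skipped <- sum(const) * (length(labels) - 1L) - choose(sum(const), 2)
  if (any(const)) {
    message(sum(const), " constant profile(s): ", n_skipped,
            " correlation pair(s) skipped")
  }
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::V(g)$core <- igraph::coreness(g)
  igraph::graph_attr(g, "skipped_pairs") <- if (any(const)) n_skipped else 0L
  igraph::graph_attr(g, "group") <- group
  g
}

#' Degree centrality (simple undirected degree)
#' @param g an `igraph`.
#' @return Named integer vector, edges incident on each node.
#' @export
degree_centrality <- function(g) igraph::degree(g)

#' k-core decomposition (core numbers)
#'
#' The core number of a node is the largest k such that the node
#' survives iterative deletion of all nodes with degree < k.
#'
#' @param g an `igraph`.
#' @return Named integer vector of core numbers.
#' @export
kcore_decomposition <- function(g) igraph::coreness(g)

#' Rank key genes by degree then core number
#'
#' @param g an `igraph` (vertex attributes `degree`/`core` recomputed here).
#' @param top_n rows to keep (default 20); larger than the node count
#'   returns every node.
#' @return data.frame `gene`, `degree`, `core`, sorted by degree
#'   descending, core descending, then gene name (documented tiebreak).
#' @export
rank_key_genes <- function(g, top_n = 20L) {
  deg <- igraph::degree(g)
  core <- igraph::coreness(g)
  out <- data.frame(gene = igraph::V(g)$name, degree = as.integer(deg),
                    core = as.integer(core), stringsAsFactors = FALSE)
  out <- out[order(-out$degree, -out$core, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
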