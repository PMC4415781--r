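#' Gene set collection
#'
#' @param sets named list of character member vectors (deduplicated,
#'   non-empty).
#' @param meta data.frame with columns `id`, `name`, `category`
#'   (`"GO"` or `"pathway"`); defaults to ids as names, category `"GO"`.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, meta = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be a uniquely named list", call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (is.null(meta)) {
    meta <- data.frame(id = names(sets), name = names(sets),
                       category = "GO", stringsAsFactors = FALSE)
  }
  stopifnot(identical(meta$id, names(sets)))
  structure(list(sets = sets, meta = meta), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets, member counts",
      min(lengths(x$sets)), "-", max(lengths(x$sets)), "\n")
  invisible(x)
}

#' Gene-gene interaction table
#'
#' Undirected interactions with a relation label. Self-loops are removed
#' (with a warning reporting the count), endpoints are put in canonical
#' (lexicographic) order, and exact duplicate rows are dropped.
#'
#' @param df data.frame with columns `gene_a`, `gene_b`, `relation` and
#'   optionally `source`.
#' @return An `interaction_table` data.frame.
#' @export
interaction_table <- function(df) {
  req <- c("gene_a", "gene_b", "relation")
  if (!all(req %in% names(df))) {
    stop("interaction table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$source)) df$source <- NA_character_
  self <- df$gene_a == df$gene_b
  if (any(self)) {
    warning(sum(self), " self-loop row(s) rejected", call. = FALSE)
    df <- df[!self, , drop = FALSE]
  }
  lo <- pmin(df$gene_a, df$gene_b)
  hi <- pmax(df$gene_a, df$gene_b)
  df$gene_a <- lo; df$gene_b <- hi
  df <- df[!duplicated(df[, c("gene_a", "gene_b", "relation")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interaction_table", "data.frame")
  df
}

fmt_num <- function(x, digits = 15L) {
  # deterministic float serialization; %.15g survives a read round-trip
  sprintf(paste0("%.", digits, "g"), x)
}

#' Write / read an expression matrix as TSV plus a design TSV
#'
#' The expression TSV has columns `probe_id`, `gene_symbol`, `biotype`,
#' then one column per sample; the design TSV has `sample_id`,
#' `condition`, `pair_id`. Writers are deterministic (fixed column order,
#' `%.15g` floats), so identical objects give identical bytes and a
#' write-read round-trip reproduces values to full printed precision.
#'
#' @param x an [expression_matrix()].
#' @param path path of the expression TSV.
#' @param design_path path of the design TSV; defaults to
#'   `<path minus extension>.design.tsv`.
#' @return `write_expression_tsv` invisibly returns `path`;
#'   `read_expression_tsv` returns an `expression_matrix`.
#' @export
write_expression_tsv <- function(x, path, design_path = default_design_path(path)) {
  stopifnot(inherits(x, "expression_matrix"))
  body <- cbind(x$probes[, c("probe_id", "gene_symbol", "biotype")],
                as.data.frame(matrix(fmt_num(x$values), nrow = nrow(x$values)),
                              stringsAsFactors = FALSE))
  names(body) <- c("probe_id", "gene_symbol", "biotype", x$design$sample_id)
  utils::write.table(body, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$design[, c("sample_id", "condition", "pair_id")],
                     design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

default_design_path <- function(path) {
  sub("\\.tsv$", "", path) |> paste0(".design.tsv")
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, design_path = default_design_path(path)) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L) {
    stop("ragged expression TSV: rows with ", paste(unique(nf), collapse = "/"),
         " fields in ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 4L) stop("expression TSV needs annotation + >=1 sample column", call. = FALSE)
  probes <- tab[, c("probe_id", "gene_symbol", "biotype")]
  if (anyDuplicated(probes$probe_id)) {
    stop("duplicate probe ids in ", path, ": ",
         paste(utils::head(unique(probes$probe_id[duplicated(probes$probe_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(tab[, -(1:3), drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- colnames(vals)[!apply(vals, 2, function(z) all(!is.na(suppressWarnings(as.numeric(z)))))]
    stop("non-numeric expression cells in column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  if (!setequal(design$sample_id, colnames(vals))) {
    stop("design samples do not match expression columns (unmatched: ",
         paste(c(setdiff(design$sample_id, colnames(vals)),
                 setdiff(colnames(vals), design$sample_id)), collapse = ", "),
         ")", call. = FALSE)
  }
  design <- design[match(colnames(vals), design$sample_id), , drop = FALSE]
  expression_matrix(vals, probes, design)
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' Duplicate members are dropped with a warning; a line with fewer than
#' three fields or an empty member list is an error naming the line.
#'
#' @param path GMT file path.
#' @param category category stamped on every set (`"GO"` or `"pathway"`).
#' @return `read_gmt` returns a [gene_set_collection()].
#' @export
read_gmt <- function(path, category = "GO") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); ids <- character(0); nms <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("GMT line ", i, ": fewer than 3 fields", call. = FALSE)
    }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop("GMT line ", i, ": empty member list", call. = FALSE)
    }
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " ('", f[1], "'): ",
              sum(duplicated(members)), " duplicate member(s) dropped",
              call. = FALSE)
      members <- unique(members)
    }
    sets[[f[1]]] <- members
    ids <- c(ids, f[1]); nms <- c(nms, f[2])
  }
  gene_set_collection(sets, data.frame(id = ids, name = nms,
                                       category = category,
                                       stringsAsFactors = FALSE))
}

#' @rdname read_gmt
#' @param x a [gene_set_collection()].
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(seq_along(x$sets), function(i) {
    paste(c(x$meta$id[i], x$meta$name[i], x$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-gene interaction TSV
#'
#' Expects >=3 tab-separated columns (`gene_a`, `gene_b`, `relation`,
#' optional `source`). Self-loop rows are rejected with their count
#' reported; undirected pairs are canonicalized.
#'
#' @param path TSV path.
#' @return An [interaction_table()].
#' @export
read_interactions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("interaction TSV needs >= 3 columns", call. = FALSE)
  names(tab)[1:3] <- c("gene_a", "gene_b", "relation")
  interaction_table(tab)
}

#' @rdname read_interactions
#' @param x an [interaction_table()].
#' @export
write_interactions <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph as SIF plus a node-attribute TSV
#'
#' SIF lines are `a<TAB>relation<TAB>b`; the attribute table has one row
#' per node with its regulation label, degree and core number.
#'
#' @param graph an `igraph` object with optional vertex attributes
#'   `regulation`, `core` and edge attribute `relation`.
#' @param sif_path output SIF path.
#' @param attr_path output node-attribute TSV path (default alongside).
#' @return Invisibly, `sif_path`.
#' @export
write_graph_sif <- function(graph, sif_path,
                            attr_path = sub("\\.sif$", ".nodes.tsv", sif_path)) {
  el <- igraph::as_edgelist(graph)
  rel <- igraph::edge_attr(graph, "relation")
  if (is.null(rel)) rel <- rep("interacts", nrow(el))
  writeLines(if (nrow(el)) paste(el[, 1], rel, el[, 2], sep = "\t") else character(0),
             sif_path)
  reg <- igraph::vertex_attr(graph, "regulation")
  if (is.null(reg)) reg <- rep(NA_character_, igraph::vcount(graph))
  core <- igraph::vertex_attr(graph, "core")
  if (is.null(core)) core <- igraph::coreness(graph)
  nodes <- data.frame(node = igraph::V(graph)$name, regulation = reg,
                      degree = igraph::degree(graph), core = core,
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  utils::write.table(nodes, attr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sif_path)
}

#' Read a SIF file back into an igraph
#' @param sif_path SIF path written by [write_graph_sif()].
#' @return An undirected `igraph` with edge attribute `relation`.
#' @export
read_graph_sif <- function(sif_path) {
  lines <- readLines(sif_path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(igraph::make_empty_graph(directed = FALSE))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = f[, 1], to = f[, 3], relation = f[, 2],
               stringsAsFactors = FALSE), directed = FALSE)
  g
}

#' Write / read ground truth as JSON
#' @param truth a `ground_truth` list.
#' @param path JSON path.
#' @return `read_ground_truth` returns the `ground_truth` list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(
    de_probes = as.list(truth$de_probes),
    de_genes = as.list(truth$de_genes),
    enriched_sets = truth$enriched_sets,
    modules = lapply(truth$modules, function(m)
      list(probes = m$probes, group = m$group)),
    hub_genes = truth$hub_genes), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(de_probes = unlist(x$de_probes),
                 de_genes = unlist(x$de_genes),
                 enriched_sets = as.character(x$enriched_sets),
                 modules = lapply(x$modules, function(m)
                   list(probes = as.character(m$probes), group = m$group)),
                 hub_genes = as.character(x$hub_genes)),
            class = "ground_truth")
}

#' Read a qPCR Ct table
#'
#' TSV with columns `sample_id`, `condition`, `pair_id`, `gene`,
#' `ct_target`, `ct_reference`; Ct values must lie in (0, 45].
#'
#' @param path TSV path.
#' @return A `qpcr_table` data.frame.
#' @export
read_qpcr_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "pair_id", "gene", "ct_target", "ct_reference")
  if (!all(req %in% names(tab))) {
    stop("qPCR table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  check_ct(tab$ct_target); check_ct(tab$ct_reference)
  class(tab) <- c("qpcr_table", "data.frame")
  tab
}

#' @rdname read_qpcr_table
#' @param x a `qpcr_table`.
#' @export
write_qpcr_table <- function(x, path) {
  out <- x
  out$ct_target <- fmt_num(out$ct_target)
  out$ct_reference <- fmt_num(out$ct_reference)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level DE results to gene level
#'
#' Multi-probe genes are represented by the probe with the smallest DE
#' P-value (ties: smallest FDR, then first probe id). Enrichment and
#' network stages count genes, not probes, so a collapse rule is needed;
#' it is recorded in the returned attribute `collapse_rule`.
#'
#' @param de a DE table from [run_diffexpr()].
#' @return Gene-level DE table (one row per `gene_symbol`).
#' @export
collapse_by_gene <- function(de) {
  o <- order(de$gene_symbol, de$p, de$fdr, de$probe_id)
  d <- de[o, , drop = FALSE]
  d <- d[!duplicated(d$gene_symbol), , drop = FALSE]
  d <- d[order(d$p, d$probe_id), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "collapse_rule") <- "min-P probe per gene symbol"
  d
}
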