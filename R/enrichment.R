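#' Overlap counts for one gene set
#'
#' Counts the 2x2 table behind the over-representation tests: `k`
#' differential genes inside the set, set size `n_set` (after
#' intersection with the universe), `K` differential genes in the
#' universe, and universe size `N_univ`. Genes outside the universe are
#' ignored (their count is attached as attribute `ignored`).
#'
#' @param members character vector of set members.
#' @param de_genes differential genes (must be a subset of `universe`).
#' @param universe all genes eligible for the test (e.g. every symbol on
#'   the array after probe collapse).
#' @return A list of class `overlap_counts`: `k`, `n_set`, `K`, `N_univ`.
#' @export
count_overlap <- function(members, de_genes, universe) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (!all(de_genes %in% universe)) {
    stop("de_genes must be a subset of the universe", call. = FALSE)
  }
  members <- unique(members)
  inside <- members[members %in% universe]
  de_genes <- unique(de_genes)
  out <- structure(list(k = sum(inside %in% de_genes),
                        n_set = length(inside),
                        K = length(de_genes),
                        N_univ = length(unique(universe))),
                   class = "overlap_counts")
  attr(out, "ignored") <- length(members) - length(inside)
  out
}

#' One-sided Fisher (hypergeometric upper-tail) over-representation P
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N_univ, K, n_set)` counts
#' differential genes in a random set of the observed size.
#'
#' @param counts an [count_overlap()] result (or list with the four counts).
#' @return Upper-tail probability.
#' @export
fisher_exact_p <- function(counts) {
  with(counts, {
    stopifnot(k <= min(n_set, K), n_set <= N_univ, K <= N_univ)
    stats::phyper(k - 1, K, N_univ - K, n_set, lower.tail = FALSE)
  })
}

#' Pearson chi-square P for the implied 2x2 table
#'
#' One degree of freedom, no continuity correction. When any expected
#' cell is below 1 the chi-square approximation is unusable and the
#' Fisher P is returned instead, with attribute `substituted = TRUE`.
#'
#' @param counts an [count_overlap()] result.
#' @return Upper-tail probability, possibly substituted.
#' @export
chisq_p <- function(counts) {
  k <- counts$k; n <- counts$n_set; K <- counts$K; N <- counts$N_univ
  obs <- c(k, n - k, K - k, N - K - n + k)
  row_tot <- c(n, n, N - n, N - n)
  col_tot <- c(K, N - K, K, N - K)
  expd <- row_tot * col_tot / N
  if (any(expd < 1)) {
    p <- fisher_exact_p(counts)
    attr(p, "substituted") <- TRUE
    return(p)
  }
  x2 <- sum((obs - expd)^2 / expd)
  p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  attr(p, "substituted") <- FALSE
  p
}

#' Dual-test discordance FDR (1 - Nk/T)
#'
#' Ranks records by Fisher P ascending; at rank `T` (1-based), `Nk`
#' counts the top-`T` records whose Fisher P is strictly below their
#' chi-square P, and the raw estimate is `1 - Nk/T` -- the running
#' fraction of test-discordant categories. Records tied on Fisher P
#' share the value at the largest tied rank, and a running cumulative
#' maximum then makes the estimate non-decreasing in Fisher P. With
#' `method = "bh"`, plain Benjamini-Hochberg on the Fisher P is used
#' instead.
#'
#' @param records data.frame with columns `p_fisher` and `p_chisq`.
#' @param method `"dual"` (default) or `"bh"`.
#' @return Numeric FDR vector in the input row order.
#' @export
fisher_chisq_fdr <- function(records, method = c("dual", "bh")) {
  method <- match.arg(method)
  if (is.null(records$p_fisher)) stop("missing p_fisher", call. = FALSE)
  if (method == "bh") return(bh_adjust(records$p_fisher))
  if (is.null(records$p_chisq) || any(is.na(records$p_chisq))) {
    stop("missing p_chisq", call. = FALSE)
  }
  o <- order(records$p_fisher)
  pf <- records$p_fisher[o]; pc <- records$p_chisq[o]
  T_ <- seq_along(pf)
  Nk <- cumsum(pf < pc)
  raw <- 1 - Nk / T_
  # ties on Fisher P share the largest tied rank's value
  last_of_tie <- rev(!duplicated(rev(pf)))
  shared <- raw
  shared[!last_of_tie] <- NA
  shared <- rev(cummin_na(rev(shared)))  # propagate value at end of tie group
  fdr_sorted <- cummax(shared)
  out <- numeric(length(pf))
  out[o] <- fdr_sorted
  out
}

# backward fill of NA with the next non-NA value (helper for tie groups)
cummin_na <- function(x) {
  last <- NA_real_
  for (i in seq_along(x)) {
    if (is.na(x[i])) x[i] <- last else last <- x[i]
  }
  x
}

#' Enrichment ratio (observed over expected fraction)
#'
#' `(k / n_set) / (K / N_univ)`: the fraction of a category's genes that
#' are differential, relative to the differential fraction of the whole
#' universe. 1 means no enrichment. Undefined (`NA`) when `K = 0`.
#'
#' @param counts an [count_overlap()] result.
#' @return Non-negative ratio, or `NA` if no differential genes exist.
#' @export
enrichment_ratio <- function(counts) {
  with(counts, {
    if (K == 0 || n_set == 0) return(NA_real_)
    (k / n_set) / (K / N_univ)
  })
}

#' Over-representation analysis of a gene-set collection
#'
#' Runs the dual Fisher/chi-square test separately for the up- and
#' down-regulated gene lists, attaches the discordance FDR (per
#' direction) and the enrichment ratio, and flags significance at
#' `p_fisher < p_threshold & fdr < fdr_threshold`.
#'
#' @param collection a [gene_set_collection()].
#' @param de_up,de_down character vectors of up-/down-regulated genes.
#' @param universe all eligible genes (drawn from the array).
#' @param p_threshold,fdr_threshold significance gates (default 0.01).
#' @param fdr_method `"dual"` (the 1 - Nk/T estimator) or `"bh"`.
#' @param min_set_genes sets with fewer in-universe members are skipped.
#' @return data.frame of class `enrichment_table`, sorted by direction
#'   then Fisher P: `set_id`, `name`, `category`, `direction`, `k`,
#'   `n_set`, `K`, `N_univ`, `p_fisher`, `p_chisq`, `chisq_substituted`,
#'   `fdr`, `ratio`, `significant`.
#' @export
run_enrichment <- function(collection, de_up, de_down, universe,
                           p_threshold = 0.01, fdr_threshold = 0.01,
                           fdr_method = c("dual", "bh"),
                           min_set_genes = 1L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  fdr_method <- match.arg(fdr_method)
  one_direction <- function(de_genes, direction) {
    if (length(de_genes) == 0L) {
      warning("empty DE list for direction '", direction, "'", call. = FALSE)
      return(NULL)
    }
    rows <- lapply(seq_along(collection$sets), function(i) {
      cnt <- count_overlap(collection$sets[[i]], de_genes, universe)
      if (cnt$n_set < min_set_genes) return(NULL)
      pf <- fisher_exact_p(cnt)
      pc <- chisq_p(cnt)
      data.frame(set_id = collection$meta$id[i],
                 name = collection$meta$name[i],
                 category = collection$meta$category[i],
                 direction = direction,
                 k = cnt$k, n_set = cnt$n_set, K = cnt$K, N_univ = cnt$N_univ,
                 p_fisher = pf, p_chisq = as.numeric(pc),
                 chisq_substituted = isTRUE(attr(pc, "substituted")),
                 ratio = enrichment_ratio(cnt), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) return(NULL)
    tab$fdr <- fisher_chisq_fdr(tab, method = fdr_method)
    tab[order(tab$p_fisher, tab$set_id), , drop = FALSE]
  }
  out <- rbind(one_direction(de_up, "up"), one_direction(de_down, "down"))
  if (is.null(out)) {
    out <- data.frame(set_id = character(0), name = character(0),
                      category = character(0), direction = character(0),
                      k = integer(0), n_set = integer(0), K = integer(0),
                      N_univ = integer(0), p_fisher = numeric(0),
                      p_chisq = numeric(0), chisq_substituted = logical(0),
                      ratio = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out$significant <- out$p_fisher < p_threshold & out$fdr < fdr_threshold
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Write an enrichment table as TSV
#' @param x an `enrichment_table`.
#' @param path TSV path.
#' @export
write_enrichment_table <- function(x, path) {
  out <- as.data.frame(x)
  for (col in c("p_fisher", "p_chisq", "fdr", "ratio")) {
    out[[col]] <- fmt_num(out[[col]], 6L)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Induce an ontology tree over significant terms
#'
#' Builds the subgraph of the (acyclic) child-to-parent edge table
#' spanned by the significant terms plus the minimal connecting
#' ancestors: non-significant terms that are ancestors of at least two
#' significant terms (marked `regulation = "connector"`). With no edge
#' table the result is the set of isolated significant nodes.
#'
#' @param terms data.frame with columns `set_id` and `direction`
#'   (significant terms, e.g. rows of an `enrichment_table`).
#' @param ontology_edges data.frame with columns `child`, `parent`, or
#'   `NULL`.
#' @return A directed `igraph` (edges child -> parent) whose vertices
#'   carry `regulation` in up/down/connector.
#' @export
build_go_tree <- function(terms, ontology_edges = NULL) {
  sig <- unique(terms$set_id)
  reg <- stats::setNames(terms$direction, terms$set_id)[sig]
  if (is.null(ontology_edges) || nrow(ontology_edges) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE) +
      igraph::vertices(sig, regulation = unname(reg))
    return(g)
  }
  if (any(ontology_edges$child == ontology_edges$parent)) {
    loops <- unique(ontology_edges$child[ontology_edges$child ==
                                           ontology_edges$parent])
    stop("ontology edges contain a cycle through: ",
         paste(loops, collapse = " -> "), call. = FALSE)
  }
  full <- igraph::graph_from_data_frame(
    ontology_edges[, c("child", "parent")], directed = TRUE)
  if (!igraph::is_dag(full)) {
    comp <- igraph::components(full, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1]]
    stop("ontology edges contain a cycle through: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  present <- intersect(sig, igraph::V(full)$name)
  # ancestors (toward parents) of each significant term
  anc <- lapply(present, function(s)
    setdiff(names(igraph::subcomponent(full, s, mode = "out")), s))
  names(anc) <- present
  anc_count <- table(unlist(anc))
  cand <- setdiff(names(anc_count)[anc_count >= 2], sig)
  # minimality: drop a candidate whose significant descendants are all
  # already collected by a candidate lying below it
  sig_desc <- lapply(cand, function(a)
    present[vapply(anc, function(s) a %in% s, logical(1))])
  names(sig_desc) <- cand
  cand_anc <- lapply(cand, function(a)
    setdiff(names(igraph::subcomponent(full, a, mode = "out")), a))
  names(cand_anc) <- cand
  redundant <- vapply(cand, function(a) {
    below <- cand[vapply(cand_anc, function(ba) a %in% ba, logical(1))]
    any(vapply(below, function(b)
      all(sig_desc[[a]] %in% sig_desc[[b]]), logical(1)))
  }, logical(1))
  connectors <- cand[!redundant]
  keep <- union(sig, connectors)
  sub <- igraph::induced_subgraph(full, intersect(keep, igraph::V(full)$name))
  missing <- setdiff(sig, igraph::V(sub)$name)
  if (length(missing)) sub <- sub + igraph::vertices(missing)
  igraph::V(sub)$regulation <- ifelse(
    igraph::V(sub)$name %in% names(reg), reg[igraph::V(sub)$name], "connector")
  sub
}
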