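#' Probe-by-sample expression container for a paired design
#'
#' Bundles a log2 intensity matrix with its probe annotation (probe id,
#' gene symbol, biotype) and sample design (condition, patient pair).
#' Every analysis stage in the package consumes and returns this class.
#'
#' @param values numeric matrix, probes in rows, samples in columns, log2
#'   intensity units. Row/column names are taken from `probes`/`design`.
#' @param probes data.frame with columns `probe_id` (unique), `gene_symbol`
#'   and `biotype` (`"mRNA"` or `"lncRNA"`), one row per matrix row.
#' @param design data.frame with columns `sample_id` (unique), `condition`
#'   (`"tumor"` or `"normal"`) and `pair_id` (patient identifier), one row
#'   per matrix column. Each `pair_id` must contribute exactly one tumor
#'   and one normal sample.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `probes`, `design`.
#' @export
expression_matrix <- function(values, probes, design) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  req_p <- c("probe_id", "gene_symbol", "biotype")
  req_s <- c("sample_id", "condition", "pair_id")
  if (!all(req_p %in% names(probes))) {
    stop("'probes' needs columns: ", paste(req_p, collapse = ", "), call. = FALSE)
  }
  if (!all(req_s %in% names(design))) {
    stop("'design' needs columns: ", paste(req_s, collapse = ", "), call. = FALSE)
  }
  if (nrow(probes) != nrow(values)) {
    stop("probe annotation rows (", nrow(probes), ") != matrix rows (",
         nrow(values), ")", call. = FALSE)
  }
  if (nrow(design) != ncol(values)) {
    stop("design rows (", nrow(design), ") != matrix columns (",
         ncol(values), ")", call. = FALSE)
  }
  if (anyDuplicated(probes$probe_id)) {
    dup <- unique(probes$probe_id[duplicated(probes$probe_id)])
    stop("duplicate probe ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (!all(probes$biotype %in% c("mRNA", "lncRNA"))) {
    stop("biotype must be 'mRNA' or 'lncRNA'", call. = FALSE)
  }
  if (!all(design$condition %in% c("tumor", "normal"))) {
    stop("condition must be 'tumor' or 'normal'", call. = FALSE)
  }
  check_pairing(design)
  dimnames(values) <- list(probes$probe_id, design$sample_id)
  structure(list(values = values, probes = probes, design = design),
            class = "expression_matrix")
}

# Every pair must have exactly one tumor and one normal sample.
check_pairing <- function(design) {
  for (p in unique(design$pair_id)) {
    cond <- design$condition[design$pair_id == p]
    if (sum(cond == "tumor") != 1L || sum(cond == "normal") != 1L) {
      stop("pair '", p, "' must have exactly one tumor and one normal sample",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples (", sum(x$probes$biotype == "mRNA"), "mRNA /",
      sum(x$probes$biotype == "lncRNA"), "lncRNA;",
      length(unique(x$design$pair_id)), "pairs )\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by probe and/or sample
#'
#' @param x an `expression_matrix`.
#' @param probes logical/integer/character index into the probe rows.
#' @param samples logical/integer/character index into the sample columns.
#' @return A new `expression_matrix`. Pairing is re-validated, so sample
#'   subsets must keep pairs complete.
#' @export
subset_expression <- function(x, probes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  pr <- x$probes
  de <- x$design
  if (!is.null(probes)) {
    if (is.character(probes)) probes <- match(probes, pr$probe_id)
    v <- v[probes, , drop = FALSE]
    pr <- pr[probes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, de$sample_id)
    v <- v[, samples, drop = FALSE]
    de <- de[samples, , drop = FALSE]
  }
  expression_matrix(v, pr, de)
}

#' Sample ids belonging to one tissue group
#'
#' @param x an `expression_matrix`.
#' @param group `"tumor"` or `"normal"`.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(x, group = c("tumor", "normal")) {
  group <- match.arg(group)
  x$design$sample_id[x$design$condition == group]
}

#' Pair ids present in the design
#' @param x an `expression_matrix`.
#' @return Character vector of pair (patient) ids, in first-appearance order.
#' @export
pair_ids <- function(x) unique(x$design$pair_id)
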