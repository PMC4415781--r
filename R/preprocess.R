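#' Quantile normalization
#'
#' Forces every sample column to the same reference distribution: the
#' per-rank mean over samples of the sorted columns. Tied values within a
#' column receive the mean of the reference values at their tied ranks,
#' so the map is deterministic and idempotent.
#'
#' @param x an [expression_matrix()] or a plain numeric matrix.
#' @return Same type as the input, with every column holding the identical
#'   multiset of values (the rank means) in the original rank order.
#' @export
quantile_normalize <- function(x) {
  em <- inherits(x, "expression_matrix")
  v <- if (em) x$values else x
  if (!is.matrix(v) || ncol(v) < 2L) {
    stop("quantile normalization needs a matrix with >= 2 samples", call. = FALSE)
  }
  if (any(!is.finite(v))) {
    bad <- which(apply(v, 1, function(r) any(!is.finite(r))))
    lab <- if (em) x$probes$probe_id[bad] else as.character(bad)
    stop("non-finite values in probe(s): ",
         paste(utils::head(lab, 5), collapse = ", "),
         if (length(lab) > 5) " ..." else "", call. = FALSE)
  }
  ref <- rowMeans(apply(v, 2, sort, method = "quick"))
  out <- apply(v, 2, function(col) {
    q <- numeric(length(col))
    q[order(col)] <- ref
    # ties: average the reference values sitting at the tied positions
    stats::ave(q, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(v)
  if (em) { x$values <- out; x } else out
}

#' Flag outlier samples by PCA and record a clustering report
#'
#' Samples are projected onto the first three principal components of
#' their expression profiles; a sample is flagged when its squared
#' Mahalanobis distance in that 3-D score space exceeds the
#' chi-square(3) upper-`alpha` quantile. Average-linkage hierarchical
#' clustering on 1 - Pearson correlation is recorded for the report
#' (whether each sample co-clusters with its partner at a 2-way cut). A
#' pair is dropped iff at least one member is flagged.
#'
#' @param x a normalized [expression_matrix()].
#' @param alpha upper-tail probability of the flagging rule; `alpha = 0`
#'   flags nothing.
#' @return A `qc_report`: list with `samples` (per-sample PC coordinates,
#'   distance, flag, partner co-membership) and `pairs` (keep/drop).
#' @export
qc_flag_samples <- function(x, alpha = 0.001) {
  stopifnot(inherits(x, "expression_matrix"))
  n <- ncol(x$values)
  if (n < 4L) {
    warning("fewer than 4 samples: QC skipped, nothing flagged", call. = FALSE)
    samples <- data.frame(sample_id = x$design$sample_id,
                          pc1 = NA_real_, pc2 = NA_real_, pc3 = NA_real_,
                          mdist2 = NA_real_, flagged = FALSE,
                          with_partner = NA, stringsAsFactors = FALSE)
    pairs <- data.frame(pair_id = pair_ids(x), keep = TRUE,
                        stringsAsFactors = FALSE)
    return(structure(list(samples = samples, pairs = pairs, alpha = alpha),
                     class = "qc_report"))
  }
  k <- min(3L, n - 1L)
  pc <- stats::prcomp(t(x$values), center = TRUE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # PC scores are centered and uncorrelated: Mahalanobis = sum of
  # squared standardized scores
  d2 <- rowSums(sweep(scores, 2, pc$sdev[seq_len(k)], "/")^2)
  flagged <- if (alpha <= 0) rep(FALSE, n) else
    d2 > stats::qchisq(1 - alpha, df = k)

  hc <- stats::hclust(stats::as.dist(1 - stats::cor(x$values)),
                      method = "average")
  cl <- stats::cutree(hc, k = min(2L, n))
  partner <- vapply(seq_len(n), function(i) {
    mate <- which(x$design$pair_id == x$design$pair_id[i] &
                    x$design$sample_id != x$design$sample_id[i])
    if (length(mate) != 1L) NA else cl[i] == cl[mate]
  }, logical(1))

  samples <- data.frame(sample_id = x$design$sample_id,
                        pc1 = scores[, 1],
                        pc2 = if (k >= 2) scores[, 2] else NA_real_,
                        pc3 = if (k >= 3) scores[, 3] else NA_real_,
                        mdist2 = d2, flagged = flagged,
                        with_partner = partner, stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  drop_pairs <- unique(x$design$pair_id[flagged])
  pairs <- data.frame(pair_id = pair_ids(x),
                      keep = !(pair_ids(x) %in% drop_pairs),
                      stringsAsFactors = FALSE)
  structure(list(samples = samples, pairs = pairs, alpha = alpha),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", sum(x$samples$flagged), "flagged sample(s),",
      sum(!x$pairs$keep), "of", nrow(x$pairs), "pairs dropped (alpha =",
      x$alpha, ")\n")
  invisible(x)
}

#' Drop the pairs a QC report marked for exclusion
#'
#' @param x an [expression_matrix()].
#' @param report the [qc_flag_samples()] result for `x`.
#' @return The `expression_matrix` restricted to kept pairs.
#' @export
drop_flagged_pairs <- function(x, report) {
  keep_pairs <- report$pairs$pair_id[report$pairs$keep]
  subset_expression(x, samples = x$design$pair_id %in% keep_pairs)
}

#' Write a QC report as TSV
#' @param report a `qc_report`.
#' @param path output TSV path (per-sample table; keep/drop appended as a
#'   `pair_kept` column).
#' @export
write_qc_report <- function(report, path) {
  out <- report$samples
  out$mdist2 <- fmt_num(out$mdist2, 6L)
  for (p in c("pc1", "pc2", "pc3")) out[[p]] <- fmt_num(out[[p]], 6L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
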