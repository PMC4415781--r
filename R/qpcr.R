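check_ct <- function(ct) {
  if (any(!is.finite(ct)) || any(ct <= 0 | ct > 45)) {
    stop("Ct values must lie in (0, 45]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Delta-Ct: target Ct minus reference-gene Ct
#'
#' @param ct_target,ct_reference cycle-threshold values in (0, 45].
#' @return `ct_target - ct_reference`, cycles.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  check_ct(ct_target); check_ct(ct_reference)
  ct_target - ct_reference
}

#' Delta-delta-Ct fold change
#'
#' `ddct = dct_sample - dct_control`; fold change `fc = 2^(-ddct)`, so
#' `log2(fc) = -ddct` exactly.
#'
#' @param dct_sample,dct_control delta-Ct values (cycles) of the sample
#'   (e.g. tumor) and control (e.g. normal) tissue.
#' @return data.frame with `ddct` and `fc`.
#' @export
ddct_fold_change <- function(dct_sample, dct_control) {
  ddct <- dct_sample - dct_control
  data.frame(ddct = ddct, fc = 2^(-ddct))
}

#' Per-pair and per-gene qPCR fold changes from a Ct table
#'
#' For every gene and patient pair, computes the tumor and normal
#' delta-Ct (target minus reference), their difference (delta-delta-Ct)
#' and the fold change `2^(-ddct)`. The per-gene summary averages the
#' delta-delta-Ct over pairs (a geometric mean on the fold-change scale).
#'
#' @param qpcr a `qpcr_table` (see [read_qpcr_table()]).
#' @return List with `per_pair` (gene, pair_id, ddct, fc) and `per_gene`
#'   (gene, mean_ddct, fc, n_pairs).
#' @export
qpcr_fold_changes <- function(qpcr) {
  dct <- delta_ct(qpcr$ct_target, qpcr$ct_reference)
  key <- paste(qpcr$gene, qpcr$pair_id, sep = "\r")
  tum <- qpcr$condition == "tumor"
  dct_t <- stats::setNames(dct[tum], key[tum])
  dct_n <- stats::setNames(dct[!tum], key[!tum])
  common <- intersect(names(dct_t), names(dct_n))
  if (!length(common)) stop("no complete tumor/normal Ct pairs", call. = FALSE)
  parts <- do.call(rbind, strsplit(common, "\r", fixed = TRUE))
  fcr <- ddct_fold_change(dct_t[common], dct_n[common])
  per_pair <- data.frame(gene = parts[, 1], pair_id = parts[, 2],
                         ddct = fcr$ddct, fc = fcr$fc,
                         row.names = NULL, stringsAsFactors = FALSE)
  mean_ddct <- tapply(per_pair$ddct, per_pair$gene, mean)
  per_gene <- data.frame(gene = names(mean_ddct),
                         mean_ddct = as.numeric(mean_ddct),
                         fc = 2^(-as.numeric(mean_ddct)),
                         n_pairs = as.integer(table(per_pair$gene)[names(mean_ddct)]),
                         row.names = NULL, stringsAsFactors = FALSE)
  list(per_pair = per_pair, per_gene = per_gene)
}

#' Concordance between qPCR fold changes and array log2 fold changes
#'
#' Per-gene direction agreement (qPCR fold change above 1 vs array
#' log2FC above 0), the overall agreement fraction, and the Spearman
#' rank correlation between `log2(qPCR fc)` and the array log2FC.
#'
#' @param qpcr_fc named numeric vector of per-gene qPCR fold changes.
#' @param array_log2fc named numeric vector of array log2 fold changes.
#' @return List of class `concordance_report`: `per_gene` data.frame,
#'   `agreement` fraction in \[0, 1\], `rank_cor`.
#' @export
concordance <- function(qpcr_fc, array_log2fc) {
  genes <- intersect(names(qpcr_fc), names(array_log2fc))
  if (!length(genes)) stop("no genes shared between qPCR and array", call. = FALSE)
  q <- qpcr_fc[genes]; a <- array_log2fc[genes]
  agree <- (q > 1) == (a > 0)
  per_gene <- data.frame(gene = genes, qpcr_fc = unname(q),
                         qpcr_log2fc = unname(log2(q)),
                         array_log2fc = unname(a), agree = unname(agree),
                         stringsAsFactors = FALSE)
  rank_cor <- if (length(genes) >= 3L) {
    stats::cor(log2(q), a, method = "spearman")
  } else NA_real_
  structure(list(per_gene = per_gene, agreement = mean(agree),
                 rank_cor = rank_cor), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report:", nrow(x$per_gene), "genes, agreement",
      sprintf("%.2f", x$agreement), ", Spearman rho",
      sprintf("%.3f", x$rank_cor), "\n")
  invisible(x)
}
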