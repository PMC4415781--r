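#' Within-patient paired differences
#'
#' For each probe and each patient pair, tumor minus normal log2
#' intensity. All paired statistics in the package run on this matrix,
#' which is algebraically equivalent to the paired linear model for a
#' two-condition design.
#'
#' @param x an [expression_matrix()].
#' @return Numeric matrix, probes x pairs, with pair ids as column names.
#' @export
paired_differences <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  pids <- pair_ids(x)
  tum <- nor <- integer(length(pids))
  for (i in seq_along(pids)) {
    rows <- which(x$design$pair_id == pids[i])
    t_i <- rows[x$design$condition[rows] == "tumor"]
    n_i <- rows[x$design$condition[rows] == "normal"]
    if (length(t_i) != 1L || length(n_i) != 1L) {
      stop("incomplete pair '", pids[i], "'", call. = FALSE)
    }
    tum[i] <- t_i; nor[i] <- n_i
  }
  d <- x$values[, tum, drop = FALSE] - x$values[, nor, drop = FALSE]
  colnames(d) <- pids
  d
}

#' Per-probe paired-model fit
#'
#' @param diffs probe x pair difference matrix from [paired_differences()].
#' @return data.frame with per-probe `log2fc` (row mean), `s2` (sample
#'   variance, denominator `n - 1`) and `df` (`n - 1`). Zero-variance
#'   probes are retained; shrinkage handles them downstream.
#' @export
fit_gene_models <- function(diffs) {
  n <- ncol(diffs)
  if (n < 2L) stop("need >= 2 pairs to estimate a variance", call. = FALSE)
  m <- rowMeans(diffs)
  s2 <- rowSums((diffs - m)^2) / (n - 1)
  data.frame(probe_id = rownames(diffs), log2fc = m, s2 = s2, df = n - 1L,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Solve trigamma(y) = x for y > 0 (Newton, monotone decreasing target).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes hyperparameters for the variance prior
#'
#' Fits the scaled inverse-chi-square prior of the moderated-t model by
#' method of moments on `log(s2)`: with `e = log(s2) - digamma(df/2) +
#' log(df/2)`, the excess of `var(e)` over `trigamma(df/2)` identifies
#' the prior degrees of freedom `d0` through a trigamma inversion, and
#' `mean(e)` then identifies the prior variance `s0_sq`. When the
#' empirical variance of `log(s2)` does not exceed the pure sampling
#' value `trigamma(df/2)`, the prior is a point mass (`d0 = Inf`).
#'
#' @param s2 vector of residual variances (>= 10 positive entries).
#' @param df residual degrees of freedom (scalar).
#' @return List of class `eb_hyperparams`: `d0` (possibly `Inf`), `s0_sq`.
#' @export
estimate_eb_hyperparams <- function(s2, df) {
  pos <- s2[s2 > 0]
  if (length(pos) < 10L) {
    stop("need >= 10 probes with positive variance", call. = FALSE)
  }
  if (length(pos) < length(s2)) {
    warning(length(s2) - length(pos),
            " zero-variance probe(s) excluded from the prior fit",
            call. = FALSE)
  }
  z <- log(pos)
  if (stats::sd(z) == 0) {
    return(structure(list(d0 = Inf, s0_sq = pos[1]), class = "eb_hyperparams"))
  }
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar <= 0) {
    return(structure(list(d0 = Inf, s0_sq = exp(mean(e))),
                     class = "eb_hyperparams"))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  structure(list(d0 = d0, s0_sq = s0_sq), class = "eb_hyperparams")
}

#' @export
print.eb_hyperparams <- function(x, ...) {
  cat("eb_hyperparams: d0 =", x$d0, ", s0_sq =", x$s0_sq, "\n")
  invisible(x)
}

#' Moderated t-statistic and two-sided P
#'
#' Shrinks each probe's variance toward the prior,
#' `s2_post = (d0*s0_sq + df*s2) / (d0 + df)`, and refers
#' `t = log2fc / sqrt(s2_post / n_pairs)` to Student t with `d0 + df`
#' degrees of freedom. `d0 = 0` reproduces the classical paired t-test;
#' `d0 = Inf` uses the prior variance for every probe and the standard
#' normal reference (the infinite-df limit of Student t).
#'
#' @param log2fc,s2,df per-probe fits from [fit_gene_models()].
#' @param hyper an `eb_hyperparams` (or list with `d0`, `s0_sq`).
#' @param n_pairs number of pairs the means were taken over.
#' @return data.frame with `t_mod`, `p`, `s2_post`, `df_total`.
#' @export
moderated_t <- function(log2fc, s2, df, hyper, n_pairs) {
  d0 <- hyper$d0; s0 <- hyper$s0_sq
  stopifnot(d0 >= 0, is.finite(s0), s0 > 0 || d0 == 0)
  if (is.infinite(d0)) {
    s2_post <- rep(s0, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (d0 * s0 + df * s2) / (d0 + df)
    df_total <- rep_len(d0 + df, length(s2_post))
  }
  t_mod <- log2fc / sqrt(s2_post / n_pairs)
  inf <- is.infinite(df_total)
  p <- numeric(length(t_mod))
  p[inf] <- 2 * stats::pnorm(-abs(t_mod[inf]))
  p[!inf] <- 2 * stats::pt(-abs(t_mod[!inf]), df = df_total[!inf])
  data.frame(t_mod = t_mod, p = p, s2_post = s2_post,
             df_total = df_total, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of P-values in \[0, 1\].
#' @return FDR-adjusted values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("P-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Triple-threshold differential-expression classification
#'
#' A probe is `up` iff its fold change exceeds `fc_threshold` (i.e.
#' `log2fc > log2(fc_threshold)`), `p < p_threshold` and
#' `fdr < fdr_threshold`; `down` symmetrically with
#' `log2fc < -log2(fc_threshold)`; otherwise `ns`.
#'
#' @param de data.frame with columns `log2fc`, `p`, `fdr`.
#' @param fc_threshold linear-scale fold-change threshold (default 2).
#' @param p_threshold,fdr_threshold significance gates (default 0.01).
#' @return `de` with a `status` factor-free character column added.
#' @export
classify_de <- function(de, fc_threshold = 2, p_threshold = 0.01,
                        fdr_threshold = 0.01) {
  stopifnot(fc_threshold > 0, p_threshold > 0, fdr_threshold > 0)
  lfc <- log2(fc_threshold)
  sig <- de$p < p_threshold & de$fdr < fdr_threshold
  de$status <- ifelse(sig & de$log2fc > lfc, "up",
                      ifelse(sig & de$log2fc < -lfc, "down", "ns"))
  de
}

#' Run the full paired differential-expression chain
#'
#' Differences -> per-probe fits -> EB prior -> moderated t -> BH FDR ->
#' triple-threshold classification.
#'
#' @param x an [expression_matrix()] (normalized).
#' @param d0 `NULL` to estimate the prior from the data (default); `0`
#'   for the classical paired t-test; any fixed positive value (or `Inf`)
#'   to impose a prior df.
#' @param s0_sq prior variance when `d0` is fixed and positive; ignored
#'   when `d0` is `NULL` or `0`.
#' @param fc_threshold,p_threshold,fdr_threshold see [classify_de()].
#' @return A `de_table` data.frame: `probe_id`, `gene_symbol`, `biotype`,
#'   `log2fc`, `s2`, `df`, `t_mod`, `p`, `fdr`, `status`; the fitted
#'   prior is in `attr(x, "hyper")`.
#' @export
run_diffexpr <- function(x, d0 = NULL, s0_sq = NULL, fc_threshold = 2,
                         p_threshold = 0.01, fdr_threshold = 0.01) {
  diffs <- paired_differences(x)
  fits <- fit_gene_models(diffs)
  hyper <- if (is.null(d0)) {
    estimate_eb_hyperparams(fits$s2, fits$df[1])
  } else if (d0 == 0) {
    structure(list(d0 = 0, s0_sq = 1), class = "eb_hyperparams")
  } else {
    stopifnot(!is.null(s0_sq))
    structure(list(d0 = d0, s0_sq = s0_sq), class = "eb_hyperparams")
  }
  mt <- moderated_t(fits$log2fc, fits$s2, fits$df, hyper, ncol(diffs))
  out <- data.frame(probe_id = fits$probe_id,
                    gene_symbol = x$probes$gene_symbol,
                    biotype = x$probes$biotype,
                    log2fc = fits$log2fc, s2 = fits$s2, df = fits$df,
                    t_mod = mt$t_mod, p = mt$p, fdr = bh_adjust(mt$p),
                    stringsAsFactors = FALSE)
  out <- classify_de(out, fc_threshold, p_threshold, fdr_threshold)
  attr(out, "hyper") <- hyper
  attr(out, "n_pairs") <- ncol(diffs)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Up/down counts split by biotype
#'
#' @param de a `de_table`.
#' @return data.frame with one row per (biotype, status) combination.
#' @export
de_summary <- function(de) {
  tab <- as.data.frame(table(biotype = de$biotype, status = de$status),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab[order(tab$biotype, tab$status), ]
}

#' Write a DE table in the published three-column layout
#'
#' Columns: probe id, gene symbol, log2 fold change, P, FDR, status
#' (numbers printed with 6 significant digits, the precision of the
#' published tables).
#'
#' @param de a `de_table`.
#' @param path TSV path.
#' @param only_significant drop `ns` rows first (default TRUE).
#' @export
write_de_table <- function(de, path, only_significant = TRUE) {
  d <- if (only_significant) de[de$status != "ns", , drop = FALSE] else de
  d <- d[order(d$p), , drop = FALSE]
  out <- data.frame(gene_id = d$probe_id, symbol = d$gene_symbol,
                    biotype = d$biotype,
                    log2fc = fmt_num(d$log2fc, 6L),
                    p_value = fmt_num(d$p, 6L),
                    fdr = fmt_num(d$fdr, 6L),
                    status = d$status, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
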