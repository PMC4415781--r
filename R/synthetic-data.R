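#' Configuration for the synthetic paired-cohort generator
#'
#' The generator emulates a paired tumor-normal microarray study: log2
#' intensities for a few thousand mRNA and lncRNA probes over ~26 patient
#' pairs, with known planted structure -- signed differential effects,
#' DE-loaded gene sets, group-specific co-expression modules driven by a
#' latent factor, and interaction hubs. All downstream stages are scored
#' against the returned ground truth.
#'
#' @param n_pairs number of patients (tumor + normal sample each).
#' @param n_probes number of probes on the simulated array.
#' @param frac_lncRNA fraction of probes labelled lncRNA, in \[0, 1\].
#' @param n_de number of probes given a planted differential effect.
#' @param effect_log2fc magnitude of the planted effect on the log2 scale
#'   (sign randomized per probe and recorded).
#' @param noise_sd per-measurement SD on the log2 scale.
#' @param n_sets number of gene sets emitted by [generate_gene_sets()].
#' @param set_size_range integer length-2 vector, inclusive range of set sizes.
#' @param n_enriched_sets number of sets planted to over-sample DE genes.
#' @param n_modules number of planted co-expression modules.
#' @param module_size probes per module (disjoint, drawn from DE probes).
#' @param module_r target within-module correlation in (0, 1); the latent
#'   factor loading is `noise_sd * sqrt(module_r / (1 - module_r))`.
#' @param module_groups group(s) in which modules are active, recycled over
#'   modules; each element `"tumor"` or `"normal"`.
#' @param patient_sd SD of the per-patient effect shared by both members of
#'   a pair (and by all probes of a sample).
#' @param n_hubs number of interaction hubs planted among DE genes.
#' @param hub_degree planted degree of each hub in the interaction table.
#' @param n_background_edges random non-hub interaction edges.
#' @param seed integer RNG seed; the whole fixture bundle is a pure
#'   function of the configuration including this seed.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_pairs = 26L, n_probes = 5000L, frac_lncRNA = 0.1,
                         n_de = 200L, effect_log2fc = 2.0, noise_sd = 0.5,
                         n_sets = 200L, set_size_range = c(15L, 60L),
                         n_enriched_sets = 3L, n_modules = 2L,
                         module_size = 20L, module_r = 0.85,
                         module_groups = c("tumor", "normal"),
                         patient_sd = 0.3, n_hubs = 5L, hub_degree = 30L,
                         n_background_edges = 1500L, seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs), n_probes = as.integer(n_probes),
              frac_lncRNA = frac_lncRNA, n_de = as.integer(n_de),
              effect_log2fc = effect_log2fc, noise_sd = noise_sd,
              n_sets = as.integer(n_sets),
              set_size_range = as.integer(set_size_range),
              n_enriched_sets = as.integer(n_enriched_sets),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size), module_r = module_r,
              module_groups = module_groups, patient_sd = patient_sd,
              n_hubs = as.integer(n_hubs), hub_degree = as.integer(hub_degree),
              n_background_edges = as.integer(n_background_edges),
              seed = as.integer(seed))
  bad <- function(name, why) {
    stop("invalid synth_config parameter '", name, "': ", why, call. = FALSE)
  }
  if (cfg$n_pairs < 2L) bad("n_pairs", "need at least 2 pairs")
  if (cfg$n_probes < 1L) bad("n_probes", "must be positive")
  if (cfg$frac_lncRNA < 0 || cfg$frac_lncRNA > 1) bad("frac_lncRNA", "must lie in [0,1]")
  if (cfg$n_de < 0L || cfg$n_de > cfg$n_probes) bad("n_de", "must lie in [0, n_probes]")
  if (cfg$effect_log2fc < 0) bad("effect_log2fc", "must be non-negative")
  if (cfg$noise_sd <= 0) bad("noise_sd", "must be positive")
  if (length(cfg$set_size_range) != 2L || any(cfg$set_size_range < 1L) ||
      cfg$set_size_range[1] > cfg$set_size_range[2]) {
    bad("set_size_range", "must be an increasing positive pair")
  }
  if (cfg$set_size_range[2] > cfg$n_probes) {
    bad("set_size_range", "set sizes exceed the probe universe")
  }
  if (cfg$n_enriched_sets < 0L || cfg$n_enriched_sets > cfg$n_sets) {
    bad("n_enriched_sets", "must lie in [0, n_sets]")
  }
  if (cfg$module_r <= 0 || cfg$module_r >= 1) bad("module_r", "must lie in (0,1)")
  if (cfg$n_modules > 0L && cfg$n_modules * cfg$module_size > max(cfg$n_de, 0L)) {
    bad("n_modules", "module memberships (disjoint, drawn from DE probes) exceed n_de")
  }
  if (!all(cfg$module_groups %in% c("tumor", "normal"))) {
    bad("module_groups", "elements must be 'tumor' or 'normal'")
  }
  if (cfg$patient_sd < 0) bad("patient_sd", "must be non-negative")
  if (cfg$n_hubs > cfg$n_de && cfg$n_hubs > 0L) bad("n_hubs", "hubs are drawn from DE probes")
  if (cfg$n_hubs > 0L && cfg$hub_degree >= cfg$n_probes) bad("hub_degree", "exceeds universe")
  class(cfg) <- "synth_config"
  cfg
}

# One deterministic child seed per generator component, so each emitting
# operation is reproducible on its own given (config, seed).
child_seeds <- function(seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 5L)
  names(s) <- c("expression", "sets", "interactions", "qpcr", "sets_pathway")
  s
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a paired tumor-normal expression matrix with planted structure
#'
#' Simulates, per probe, a fixed baseline drawn from
#' Normal(mean ~ U\[6,14\], SD ~ U\[0.2,1\]); per sample, a patient effect
#' shared by the two members of a pair; planted differential probes
#' receive a signed `effect_log2fc` shift on tumor samples; each planted
#' module adds a shared latent factor (per sample, within its active
#' group only) with loading calibrated from `module_r`; and i.i.d.
#' Normal(0, `noise_sd`) measurement noise everywhere.
#'
#' @param config a [synth_config()].
#' @return A list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (a `ground_truth` list: `de_probes` named signed effects,
#'   `modules` with members and active group, `hub_genes`, and
#'   `enriched_sets`, the latter filled by [generate_gene_sets()]).
#' @export
generate_paired_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(child_seeds(config$seed)[["expression"]])
  P <- config$n_probes
  n <- config$n_pairs

  probe_id <- sprintf("P%05d", seq_len(P))
  gene_symbol <- sprintf("G%05d", seq_len(P))
  biotype <- rep("mRNA", P)
  n_lnc <- round(config$frac_lncRNA * P)
  if (n_lnc > 0) biotype[sample.int(P, n_lnc)] <- "lncRNA"

  mu <- stats::runif(P, 6, 14)
  baseline_sd <- stats::runif(P, 0.2, 1.0)
  baseline <- stats::rnorm(P, mu, baseline_sd)

  pair <- sprintf("PT%02d", seq_len(n))
  design <- data.frame(
    sample_id = c(paste0(pair, "_T"), paste0(pair, "_N")),
    condition = rep(c("tumor", "normal"), each = n),
    pair_id = c(pair, pair),
    stringsAsFactors = FALSE)

  # planted DE probes, sign randomized
  de_idx <- if (config$n_de > 0) sample.int(P, config$n_de) else integer(0)
  de_sign <- sample(c(-1, 1), length(de_idx), replace = TRUE)
  de_effect <- numeric(P)
  de_effect[de_idx] <- de_sign * config$effect_log2fc

  # disjoint modules drawn from the planted DE probes
  groups <- rep_len(config$module_groups, max(config$n_modules, 0L))
  modules <- list()
  if (config$n_modules > 0L) {
    pool <- sample(de_idx)  # shuffled DE probes
    for (m in seq_len(config$n_modules)) {
      take <- pool[seq_len(config$module_size) + (m - 1L) * config$module_size]
      modules[[sprintf("MOD%02d", m)]] <- list(probes = probe_id[take],
                                               group = groups[m])
    }
  }

  hub_idx <- if (config$n_hubs > 0L) sample(de_idx, config$n_hubs) else integer(0)

  patient <- stats::rnorm(n, 0, config$patient_sd)
  vals <- matrix(stats::rnorm(P * 2L * n, 0, config$noise_sd), P, 2L * n)
  vals <- vals + baseline                       # recycles down columns
  vals <- sweep(vals, 2, c(patient, patient), "+")
  vals[, seq_len(n)] <- vals[, seq_len(n)] + de_effect

  lambda <- config$noise_sd * sqrt(config$module_r / (1 - config$module_r))
  for (m in seq_along(modules)) {
    rows <- match(modules[[m]]$probes, probe_id)
    cols <- if (modules[[m]]$group == "tumor") seq_len(n) else n + seq_len(n)
    f <- stats::rnorm(length(cols))
    vals[rows, cols] <- vals[rows, cols] +
      lambda * matrix(f, length(rows), length(cols), byrow = TRUE)
  }

  probes <- data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                       biotype = biotype, stringsAsFactors = FALSE)
  em <- expression_matrix(vals, probes, design)
  de_probes <- stats::setNames(de_effect[de_idx], probe_id[de_idx])
  truth <- structure(list(de_probes = de_probes,
                          de_genes = stats::setNames(de_effect[de_idx],
                                                     gene_symbol[de_idx]),
                          enriched_sets = character(0),
                          modules = modules,
                          hub_genes = gene_symbol[hub_idx]),
                     class = "ground_truth")
  list(matrix = em, truth = truth)
}

#' Generate gene sets, some planted to over-sample DE genes
#'
#' Planted "enriched" sets (ids `ENRxx`) draw at least 60% of their
#' members from the planted DE genes; background sets (`SETxxx`) sample
#' uniformly from the whole gene universe.
#'
#' @param truth `ground_truth` from [generate_paired_expression()].
#' @param config the same [synth_config()].
#' @param universe character vector of gene symbols (the array universe).
#' @param category `"GO"` or `"pathway"`, stamped on every set.
#' @return A `gene_set_collection` (see [read_gmt()]); the planted set ids
#'   are in `attr(x, "enriched_sets")`.
#' @export
generate_gene_sets <- function(truth, config, universe, category = "GO") {
  stopifnot(inherits(config, "synth_config"))
  stream <- if (category == "GO") "sets" else "sets_pathway"
  set.seed(child_seeds(config$seed)[[stream]])
  rng <- config$set_size_range
  if (rng[2] > length(universe)) {
    stop("set sizes exceed the gene universe (", length(universe), ")",
         call. = FALSE)
  }
  de_genes <- intersect(names(truth$de_genes), universe)
  sets <- list()
  meta_id <- character(0); meta_name <- character(0)
  n_enr <- config$n_enriched_sets
  for (i in seq_len(n_enr)) {
    size <- sample(seq(rng[1], rng[2]), 1L)
    n_from_de <- min(length(de_genes), ceiling(0.6 * size))
    members <- c(sample(de_genes, n_from_de),
                 sample(setdiff(universe, de_genes), size - n_from_de))
    id <- sprintf("ENR%02d", i)
    sets[[id]] <- sort(unique(members))
    meta_id <- c(meta_id, id)
    meta_name <- c(meta_name, sprintf("planted enriched set %d", i))
  }
  for (i in seq_len(config$n_sets - n_enr)) {
    size <- sample(seq(rng[1], rng[2]), 1L)
    id <- sprintf("SET%03d", i)
    sets[[id]] <- sort(unique(sample(universe, size)))
    meta_id <- c(meta_id, id)
    meta_name <- c(meta_name, sprintf("background set %d", i))
  }
  out <- gene_set_collection(sets,
                             data.frame(id = meta_id, name = meta_name,
                                        category = category,
                                        stringsAsFactors = FALSE))
  attr(out, "enriched_sets") <- sprintf("ENR%02d", seq_len(n_enr))
  out
}

#' Generate a gene-gene interaction table with planted hubs
#'
#' Each hub gene receives exactly `hub_degree` distinct neighbors drawn
#' from the DE genes (so the DE-induced subgraph retains the hub);
#' background edges join random gene pairs. No self-loops; undirected
#' duplicates are removed; relations sampled from
#' activation/inhibition/binding.
#'
#' @param truth `ground_truth`.
#' @param config [synth_config()].
#' @param universe gene symbols of the array.
#' @return An `interaction_table` data.frame
#'   (`gene_a`, `gene_b`, `relation`, `source`).
#' @export
generate_interaction_table <- function(truth, config, universe) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(child_seeds(config$seed)[["interactions"]])
  rel <- c("activation", "inhibition", "binding")
  de_genes <- intersect(names(truth$de_genes), universe)
  a <- character(0); b <- character(0)
  for (h in truth$hub_genes) {
    nb <- sample(setdiff(de_genes, h), config$hub_degree)
    a <- c(a, rep(h, length(nb))); b <- c(b, nb)
  }
  if (config$n_background_edges > 0) {
    # background edges avoid the hubs so planted hub degree is exact
    bg_pool <- setdiff(universe, truth$hub_genes)
    i <- sample(bg_pool, config$n_background_edges, replace = TRUE)
    j <- sample(bg_pool, config$n_background_edges, replace = TRUE)
    keep <- i != j
    a <- c(a, i[keep]); b <- c(b, j[keep])
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[keep]; hi <- hi[keep]
  # hub edges (first in the vector) survive dedup, so planted degree is exact
  interaction_table(data.frame(
    gene_a = lo, gene_b = hi,
    relation = sample(rel, length(lo), replace = TRUE),
    source = "synthetic", stringsAsFactors = FALSE))
}

#' Simulate a qPCR Ct table from the planted effects
#'
#' For each requested gene and each patient pair, the normal-tissue
#' delta-Ct is drawn once per gene; the tumor delta-Ct subtracts the
#' planted log2 effect (qPCR fold change 2^(-ddCt) then matches the
#' planted 2^log2fc) plus Normal(0, `ct_noise_sd`) cycle noise on every
#' measurement. Reference-gene Ct is ~18 cycles.
#'
#' @param truth `ground_truth`.
#' @param config [synth_config()].
#' @param genes gene symbols to assay; default picks up to 10 planted DE
#'   genes (alternating up and down).
#' @param ct_noise_sd per-measurement Ct noise, cycles.
#' @return A `qpcr_table` data.frame
#'   (`sample_id`, `condition`, `pair_id`, `gene`, `ct_target`, `ct_reference`).
#' @export
simulate_qpcr <- function(truth, config, genes = NULL, ct_noise_sd = 0.3) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(child_seeds(config$seed)[["qpcr"]])
  if (is.null(genes)) {
    up <- names(truth$de_genes)[truth$de_genes > 0]
    dn <- names(truth$de_genes)[truth$de_genes < 0]
    genes <- c(utils::head(up, 6L), utils::head(dn, 4L))
  }
  stopifnot(all(genes %in% names(truth$de_genes)))
  n <- config$n_pairs
  pair <- sprintf("PT%02d", seq_len(n))
  rows <- expand.grid(pair_id = pair, condition = c("tumor", "normal"),
                      gene = genes, stringsAsFactors = FALSE)
  dct0 <- stats::setNames(stats::runif(length(genes), 2, 10), genes)
  eff <- truth$de_genes[rows$gene]
  dct <- dct0[rows$gene] - ifelse(rows$condition == "tumor", eff, 0) +
    stats::rnorm(nrow(rows), 0, ct_noise_sd)
  ct_ref <- 18 + stats::rnorm(nrow(rows), 0, 0.1)
  out <- data.frame(
    sample_id = paste0(rows$pair_id, ifelse(rows$condition == "tumor", "_T", "_N")),
    condition = rows$condition, pair_id = rows$pair_id, gene = rows$gene,
    ct_target = pmin(pmax(ct_ref + dct, 1), 45),
    ct_reference = pmin(pmax(ct_ref, 1), 45),
    stringsAsFactors = FALSE)
  class(out) <- c("qpcr_table", "data.frame")
  out
}

#' Generate the complete fixture bundle for one configuration
#'
#' Runs every generator component and returns a consistent bundle whose
#' ground truth has `enriched_sets` filled in. With a fixed config the
#' bundle is byte-identical across calls.
#'
#' @param config a [synth_config()].
#' @return List: `matrix`, `truth`, `go_sets`, `pathway_sets`,
#'   `interactions`, `qpcr`.
#' @export
generate_fixture_bundle <- function(config = synth_config()) {
  ge <- generate_paired_expression(config)
  universe <- unique(ge$matrix$probes$gene_symbol)
  go <- generate_gene_sets(ge$truth, config, universe, category = "GO")
  pw <- generate_gene_sets(ge$truth, config, universe, category = "pathway")
  ge$truth$enriched_sets <- attr(go, "enriched_sets")
  ia <- generate_interaction_table(ge$truth, config, universe)
  qp <- if (config$n_de >= 10L) simulate_qpcr(ge$truth, config) else NULL
  list(matrix = ge$matrix, truth = ge$truth, go_sets = go, pathway_sets = pw,
       interactions = ia, qpcr = qp)
}
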