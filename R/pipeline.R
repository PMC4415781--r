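#' Pipeline configuration
#'
#' One object holds every stage parameter, all file paths and the stage
#' toggles. Defaults follow the published analysis: fold change 2,
#' P < 0.01, FDR < 0.01 for DE and enrichment; hub degree > 25;
#' co-expression |r| >= 0.8 with P < 0.01; top 20 key genes.
#'
#' @param out_dir directory for stage outputs (created if missing).
#' @param seed integer seed used by the simulate stage.
#' @param synth list of [synth_config()] arguments for the simulate
#'   stage, or `NULL` to read the inputs from files.
#' @param expression_tsv,design_tsv,go_gmt,pathway_gmt,interactions_tsv,qpcr_tsv
#'   input paths used when `synth` is `NULL` (qPCR optional).
#' @param qc_alpha QC flagging tail probability; `qc` stage toggle below.
#' @param fc_threshold,p_threshold,fdr_threshold DE triple threshold.
#' @param enrich_p,enrich_fdr,fdr_method enrichment gates and FDR flavor:
#'   `"bh"` (default; Benjamini-Hochberg on the Fisher P) or `"dual"`
#'   (the discordance estimator 1 - Nk/T). The pipeline defaults to BH
#'   because the discordance estimator saturates at 1 whenever the
#'   top-ranked category is test-concordant, which extreme enrichments
#'   almost always are; see the methods vignette.
#' @param hub_threshold,min_shared,r_threshold,coexpr_p,top_n network
#'   parameters.
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "normalize", "qc", "de", "enrichment", "networks",
#'   "qpcr")`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("pairedDE_run_"), seed = 1L,
                            synth = list(),
                            expression_tsv = NULL, design_tsv = NULL,
                            go_gmt = NULL, pathway_gmt = NULL,
                            interactions_tsv = NULL, qpcr_tsv = NULL,
                            qc_alpha = 0.001,
                            fc_threshold = 2, p_threshold = 0.01,
                            fdr_threshold = 0.01,
                            enrich_p = 0.01, enrich_fdr = 0.01,
                            fdr_method = "bh",
                            hub_threshold = 25, min_shared = 3L,
                            r_threshold = 0.8, coexpr_p = 0.01, top_n = 20L,
                            stages = c("simulate", "normalize", "qc", "de",
                                       "enrichment", "networks", "qpcr")) {
  all_stages <- c("simulate", "normalize", "qc", "de", "enrichment",
                  "networks", "qpcr")
  if (!all(stages %in% all_stages)) {
    stop("unknown stage(s): ", paste(setdiff(stages, all_stages), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(fc_threshold > 0, p_threshold > 0, fdr_threshold > 0,
            enrich_p > 0, enrich_fdr > 0, qc_alpha >= 0,
            r_threshold > 0, r_threshold <= 1, coexpr_p > 0, top_n >= 1)
  fdr_method <- match.arg(fdr_method, c("dual", "bh"))
  if (is.null(synth)) {
    for (p in c(expression_tsv, design_tsv, go_gmt, pathway_gmt,
                interactions_tsv, qpcr_tsv)) {
      if (!is.null(p) && !file.exists(p)) {
        stop("input path does not exist: ", p, call. = FALSE)
      }
    }
    if (is.null(expression_tsv)) {
      stop("either 'synth' or 'expression_tsv' must be supplied", call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 expression_tsv = expression_tsv, design_tsv = design_tsv,
                 go_gmt = go_gmt, pathway_gmt = pathway_gmt,
                 interactions_tsv = interactions_tsv, qpcr_tsv = qpcr_tsv,
                 qc_alpha = qc_alpha, fc_threshold = fc_threshold,
                 p_threshold = p_threshold, fdr_threshold = fdr_threshold,
                 enrich_p = enrich_p, enrich_fdr = enrich_fdr,
                 fdr_method = fdr_method, hub_threshold = hub_threshold,
                 min_shared = as.integer(min_shared),
                 r_threshold = r_threshold, coexpr_p = coexpr_p,
                 top_n = as.integer(top_n), stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML document
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

stage_log <- function(manifest, stage, ...) {
  message(sprintf("[%s] ", stage), ...)
  invisible(manifest)
}

add_outputs <- function(manifest, stage, paths, counts = list()) {
  manifest$stages[[stage]] <- list(
    outputs = as.character(paths),
    checksums = unname(tools::md5sum(as.character(paths))),
    counts = counts)
  manifest
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order (simulate/ingest -> normalize ->
#' QC -> DE -> enrichment -> networks -> qPCR concordance), persisting
#' each stage's outputs under `config$out_dir` before the next stage
#' starts, and returns a manifest of counts and output checksums. A
#' failure in stage k leaves the outputs of stages < k on disk.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `run_manifest`: `config`, `version`, `stages`
#'   (per-stage outputs, md5 checksums and record counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  manifest <- list(config = config,
                   version = as.character(utils::packageVersion("pairedDE")),
                   stages = list())
  class(manifest) <- "run_manifest"
  on <- function(s) s %in% config$stages
  em <- NULL; truth <- NULL; go <- NULL; pw <- NULL; ia <- NULL; qp <- NULL

  if (on("simulate")) {
    if (is.null(config$synth)) stop("simulate stage enabled but 'synth' is NULL",
                                    call. = FALSE)
    cfg <- do.call(synth_config, utils::modifyList(config$synth,
                                                   list(seed = config$seed)))
    bundle <- generate_fixture_bundle(cfg)
    em <- bundle$matrix; truth <- bundle$truth
    go <- bundle$go_sets; pw <- bundle$pathway_sets
    ia <- bundle$interactions; qp <- bundle$qpcr
    write_expression_tsv(em, out("expression.tsv"), out("design.tsv"))
    write_gmt(go, out("go_sets.gmt"))
    write_gmt(pw, out("pathway_sets.gmt"))
    write_interactions(ia, out("interactions.tsv"))
    write_ground_truth(truth, out("ground_truth.json"))
    if (!is.null(qp)) write_qpcr_table(qp, out("qpcr.tsv"))
    manifest <- add_outputs(manifest, "simulate",
                            c(out("expression.tsv"), out("design.tsv"),
                              out("go_sets.gmt"), out("pathway_sets.gmt"),
                              out("interactions.tsv"), out("ground_truth.json")),
                            list(probes = nrow(em$values),
                                 pairs = length(pair_ids(em))))
    stage_log(manifest, "simulate", nrow(em$values), " probes, ",
              length(pair_ids(em)), " pairs")
  } else if (length(config$stages)) {
    if (is.null(config$expression_tsv)) {
      stop("no simulate stage and no expression_tsv input", call. = FALSE)
    }
    em <- read_expression_tsv(config$expression_tsv,
                              if (is.null(config$design_tsv))
                                default_design_path(config$expression_tsv)
                              else config$design_tsv)
    if (!is.null(config$go_gmt)) go <- read_gmt(config$go_gmt, "GO")
    if (!is.null(config$pathway_gmt)) pw <- read_gmt(config$pathway_gmt, "pathway")
    if (!is.null(config$interactions_tsv)) ia <- read_interactions(config$interactions_tsv)
    if (!is.null(config$qpcr_tsv)) qp <- read_qpcr_table(config$qpcr_tsv)
  }

  if (on("normalize")) {
    em <- quantile_normalize(em)
    write_expression_tsv(em, out("normalized.tsv"), out("design.tsv"))
    manifest <- add_outputs(manifest, "normalize",
                            c(out("normalized.tsv")),
                            list(probes = nrow(em$values),
                                 samples = ncol(em$values)))
    stage_log(manifest, "normalize", "quantile normalization of ",
              ncol(em$values), " samples")
  }

  if (on("qc")) {
    qc <- qc_flag_samples(em, alpha = config$qc_alpha)
    write_qc_report(qc, out("qc_report.tsv"))
    em <- drop_flagged_pairs(em, qc)
    manifest <- add_outputs(manifest, "qc", out("qc_report.tsv"),
                            list(flagged = sum(qc$samples$flagged),
                                 pairs_kept = sum(qc$pairs$keep)))
    stage_log(manifest, "qc", sum(!qc$pairs$keep), " pair(s) dropped")
  }

  de <- NULL; gene_de <- NULL
  if (on("de")) {
    de <- run_diffexpr(em, fc_threshold = config$fc_threshold,
                       p_threshold = config$p_threshold,
                       fdr_threshold = config$fdr_threshold)
    gene_de <- collapse_by_gene(de)
    write_de_table(de, out("de_table.tsv"))
    write_de_table(de, out("de_all.tsv"), only_significant = FALSE)
    cnt <- de_summary(de)
    manifest <- add_outputs(manifest, "de",
                            c(out("de_table.tsv"), out("de_all.tsv")),
                            list(up = sum(de$status == "up"),
                                 down = sum(de$status == "down"),
                                 by_biotype = cnt))
    stage_log(manifest, "de", sum(de$status == "up"), " up / ",
              sum(de$status == "down"), " down")
  }

  enr_pw <- NULL
  if (on("enrichment")) {
    if (is.null(gene_de)) stop("enrichment stage needs the DE table: enable 'de'",
                               call. = FALSE)
    universe <- unique(gene_de$gene_symbol)
    de_up <- gene_de$gene_symbol[gene_de$status == "up"]
    de_down <- gene_de$gene_symbol[gene_de$status == "down"]
    paths <- character(0); counts <- list()
    if (!is.null(go)) {
      enr_go <- run_enrichment(go, de_up, de_down, universe,
                               p_threshold = config$enrich_p,
                               fdr_threshold = config$enrich_fdr,
                               fdr_method = config$fdr_method)
      write_enrichment_table(enr_go, out("enrichment_go.tsv"))
      paths <- c(paths, out("enrichment_go.tsv"))
      counts$go_significant <- sum(enr_go$significant)
    }
    if (!is.null(pw)) {
      enr_pw <- run_enrichment(pw, de_up, de_down, universe,
                               p_threshold = config$enrich_p,
                               fdr_threshold = config$enrich_fdr,
                               fdr_method = config$fdr_method)
      write_enrichment_table(enr_pw, out("enrichment_pathway.tsv"))
      paths <- c(paths, out("enrichment_pathway.tsv"))
      counts$pathway_significant <- sum(enr_pw$significant)
    }
    if (!length(paths)) stop("enrichment stage needs a gene-set collection",
                             call. = FALSE)
    manifest <- add_outputs(manifest, "enrichment", paths, counts)
    stage_log(manifest, "enrichment",
              paste(names(counts), unlist(counts), collapse = ", "))
  }

  if (on("networks")) {
    if (is.null(gene_de)) stop("networks stage needs the DE table: enable 'de'",
                               call. = FALSE)
    paths <- character(0); counts <- list()
    if (!is.null(ia)) {
      ga <- build_gene_act(ia, gene_de, hub_threshold = config$hub_threshold)
      write_graph_sif(ga, out("gene_act.sif"))
      paths <- c(paths, out("gene_act.sif"), out("gene_act.nodes.tsv"))
      counts$gene_act_nodes <- igraph::vcount(ga)
      counts$gene_act_edges <- igraph::ecount(ga)
      counts$hubs <- length(hub_genes(ga))
    }
    if (!is.null(enr_pw) && !is.null(pw)) {
      pa <- build_pathway_act(enr_pw, pw,
                              gene_de$gene_symbol[gene_de$status != "ns"],
                              min_shared = config$min_shared)
      write_graph_sif(pa, out("pathway_act.sif"))
      paths <- c(paths, out("pathway_act.sif"), out("pathway_act.nodes.tsv"))
      counts$pathway_act_nodes <- igraph::vcount(pa)
      counts$pathway_act_edges <- igraph::ecount(pa)
    }
    sig_probes <- gene_de$probe_id[gene_de$status != "ns"]
    for (grp in c("tumor", "normal")) {
      if (length(group_samples(em, grp)) >= 4L && length(sig_probes) >= 2L) {
        cg <- build_coexpression(em, grp, probes = sig_probes,
                                 r_threshold = config$r_threshold,
                                 p_threshold = config$coexpr_p)
        write_graph_sif(cg, out(paste0("coexpr_", grp, ".sif")))
        key <- rank_key_genes(cg, config$top_n)
        utils::write.table(key, out(paste0("key_genes_", grp, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, out(paste0("coexpr_", grp, ".sif")),
                   out(paste0("coexpr_", grp, ".nodes.tsv")),
                   out(paste0("key_genes_", grp, ".tsv")))
        counts[[paste0("coexpr_", grp, "_edges")]] <- igraph::ecount(cg)
      }
    }
    manifest <- add_outputs(manifest, "networks", paths, counts)
    stage_log(manifest, "networks",
              paste(names(counts), unlist(counts), collapse = ", "))
  }

  if (on("qpcr") && !is.null(qp)) {
    if (is.null(gene_de)) stop("qpcr stage needs the DE table: enable 'de'",
                               call. = FALSE)
    fc <- qpcr_fold_changes(qp)
    arr <- stats::setNames(gene_de$log2fc, gene_de$gene_symbol)
    rep_ <- concordance(stats::setNames(fc$per_gene$fc, fc$per_gene$gene), arr)
    utils::write.table(rep_$per_gene, out("qpcr_concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- add_outputs(manifest, "qpcr", out("qpcr_concordance.tsv"),
                            list(genes = nrow(rep_$per_gene),
                                 agreement = rep_$agreement,
                                 rank_cor = rep_$rank_cor))
    stage_log(manifest, "qpcr", "agreement ",
              sprintf("%.2f", rep_$agreement))
  }
  manifest
}

#' Human-readable run summary
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @param top_n excerpt rows per table (default 5).
#' @return Character vector of report lines (also printable via `cat`).
#' @export
summarize_run <- function(manifest, top_n = 5L) {
  if (!length(manifest$stages)) return("no stages run")
  lines <- c(sprintf("pairedDE run (version %s, seed %d)",
                     manifest$version, manifest$config$seed), "")
  for (s in names(manifest$stages)) {
    st <- manifest$stages[[s]]
    cnt <- st$counts
    flat <- cnt[!vapply(cnt, is.data.frame, logical(1))]
    lines <- c(lines, sprintf("stage %-10s %s", s,
                              paste(names(flat), unlist(flat),
                                    sep = "=", collapse = ", ")))
    if (!is.null(cnt$by_biotype)) {
      b <- cnt$by_biotype
      b <- b[b$status != "ns", , drop = FALSE]
      lines <- c(lines, paste0("  ", b$biotype, " ", b$status, ": ", b$count))
    }
  }
  de_path <- file.path(manifest$config$out_dir, "de_table.tsv")
  if (file.exists(de_path)) {
    top <- utils::read.delim(de_path, nrows = top_n)
    lines <- c(lines, "", sprintf("top differential probes (of %d):",
                                  length(readLines(de_path)) - 1L),
               utils::capture.output(print(top)))
  }
  lines
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(summarize_run(x), sep = "\n")
  invisible(x)
}
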