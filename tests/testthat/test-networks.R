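de_frame <- function(genes, status) {
  data.frame(gene_symbol = genes, status = status, stringsAsFactors = FALSE)
}

test_that("Gene-Act network induces on DE genes and finds planted hubs", {
  b <- generate_fixture_bundle(quick_config(seed = 40L))
  de <- collapse_by_gene(run_diffexpr(b$matrix))
  g <- build_gene_act(b$interactions, de)
  de_genes <- de$gene_symbol[de$status != "ns"]
  expect_true(all(igraph::V(g)$name %in% de_genes))
  # planted hubs have degree 27 > 25 within the DE-induced subgraph
  expect_setequal(hub_genes(g), b$truth$hub_genes)
  expect_true(all(igraph::V(g)$regulation %in% c("up", "down")))

  # no DE genes: empty graph with a warning
  expect_warning(
    g0 <- build_gene_act(b$interactions, de_frame("nope", "ns")),
    "empty Gene-Act")
  expect_equal(igraph::vcount(g0), 0)
})

test_that("induced degrees equal a brute-force adjacency-count oracle", {
  set.seed(41)
  genes <- paste0("g", 1:40)
  ga <- sample(genes, 120, replace = TRUE)
  gb <- sample(genes, 120, replace = TRUE)
  keep0 <- ga != gb
  it <- interaction_table(data.frame(
    gene_a = ga[keep0], gene_b = gb[keep0], relation = "binding"))
  de <- de_frame(genes[1:25], sample(c("up", "down"), 25, replace = TRUE))
  g <- build_gene_act(it, de)
  keep <- it[it$gene_a %in% genes[1:25] & it$gene_b %in% genes[1:25], ]
  keep <- keep[!duplicated(keep[, c("gene_a", "gene_b")]), ]
  oracle <- table(c(keep$gene_a, keep$gene_b))
  for (v in igraph::V(g)$name) {
    expect_equal(unname(igraph::degree(g)[v]), as.numeric(oracle[v]))
  }
})

test_that("Pathway-Act links pathways by shared differential genes", {
  col <- gene_set_collection(list(pw1 = paste0("g", 1:10),
                                  pw2 = paste0("g", 6:15),
                                  pw3 = paste0("g", 30:40)))
  enr <- data.frame(set_id = c("pw1", "pw2", "pw3"),
                    direction = c("up", "up", "down"),
                    significant = TRUE, stringsAsFactors = FALSE)
  de_genes <- paste0("g", 1:20)    # pw1 & pw2 share g6..g10 among DE
  g <- build_pathway_act(enr, col, de_genes, min_shared = 3)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 5)
  expect_equal(igraph::vcount(g), 3)

  g2 <- build_pathway_act(enr, col, de_genes, min_shared = 6)
  expect_equal(igraph::ecount(g2), 0)
  # no self edges by construction
  expect_false(igraph::any_loop(g))
})

test_that("co-expression graph needs 4 samples and skips constant profiles", {
  b <- generate_paired_expression(quick_config(n_probes = 120L, n_de = 40L,
                                               n_modules = 1L, module_size = 10L,
                                               module_groups = "tumor",
                                               n_hubs = 0L, seed = 42L))
  em <- b$matrix
  em$values[3, ] <- 5  # constant probe
  expect_message(
    g <- build_coexpression(em, "tumor", r_threshold = 0.8, p_threshold = 0.01),
    "constant profile")
  expect_gt(igraph::graph_attr(g, "skipped_pairs"), 0)
  expect_false(igraph::any_loop(g))

  few <- subset_expression(em, samples = em$design$pair_id %in%
                             unique(em$design$pair_id)[1:3])
  expect_error(build_coexpression(few, "tumor"), "fewer than 4")
})

test_that("a tumor-only module appears in the tumor graph, not the normal graph", {
  b <- generate_paired_expression(quick_config(n_probes = 600L, n_de = 60L,
                                               n_modules = 1L, module_size = 15L,
                                               module_groups = "tumor",
                                               n_hubs = 0L, seed = 43L))
  mod_probes <- b$truth$modules[[1]]$probes
  syms <- b$matrix$probes$gene_symbol[match(mod_probes, b$matrix$probes$probe_id)]
  probes <- names(b$truth$de_probes)
  gt <- build_coexpression(quantile_normalize(b$matrix), "tumor", probes = probes)
  gn <- build_coexpression(quantile_normalize(b$matrix), "normal", probes = probes)
  within <- function(g) {
    sub <- igraph::induced_subgraph(g, intersect(syms, igraph::V(g)$name))
    igraph::ecount(sub)
  }
  n_pairs_mod <- choose(length(mod_probes), 2)
  expect_gt(within(gt) / n_pairs_mod, 0.5)
  expect_lt(within(gn), 0.05 * n_pairs_mod)
})

test_that("degree centrality equals the adjacency row-sum oracle", {
  tri <- igraph::make_full_graph(3)
  expect_true(all(degree_centrality(tri) == 2))
  star <- igraph::make_star(6, mode = "undirected")
  expect_equal(unname(degree_centrality(star)), c(5, 1, 1, 1, 1, 1))
  set.seed(44)
  g <- igraph::sample_gnp(30, 0.2)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_equal(unname(degree_centrality(g)), unname(rowSums(adj)))
})

test_that("core numbers match the iterative-deletion oracle", {
  # brute-force oracle: for each k delete low-degree nodes to exhaustion
  core_oracle <- function(g) {
    n <- igraph::vcount(g)
    core <- integer(n)
    for (k in 1:n) {
      h <- g
      repeat {
        low <- which(igraph::degree(h) < k)
        if (!length(low)) break
        h <- igraph::delete_vertices(h, low)
      }
      if (igraph::vcount(h) == 0) break
      core[as.integer(igraph::V(h)$orig)] <- k
    }
    core
  }
  tri <- igraph::make_full_graph(3)
  expect_true(all(kcore_decomposition(tri) == 2))
  path4 <- igraph::make_ring(4, circular = FALSE)
  expect_true(all(kcore_decomposition(path4) == 1))

  set.seed(45)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.05, 0.3))
    igraph::V(g)$orig <- seq_len(n)
    expect_equal(unname(kcore_decomposition(g)), core_oracle(g))
    expect_true(all(kcore_decomposition(g) <= igraph::degree(g)))
  }
})

test_that("key genes sort by degree, then core, then name", {
  # K4 (degree 3, core 3) + star of centre X with 3 leaves (degree 3, core 1)
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- c("d", "c", "b", "a")
  star <- igraph::make_star(4, mode = "undirected")
  igraph::V(star)$name <- c("x", "l1", "l2", "l3")
  gu <- igraph::disjoint_union(g, star)
  key <- rank_key_genes(gu, top_n = 5)
  expect_identical(key$gene[1:4], c("a", "b", "c", "d"))  # core beats x at equal degree
  expect_identical(key$gene[5], "x")
  expect_identical(key$degree[1:5], c(3L, 3L, 3L, 3L, 3L))
  expect_identical(key$core[1:5], c(3L, 3L, 3L, 3L, 1L))

  all_rows <- rank_key_genes(gu, top_n = 100)
  expect_identical(nrow(all_rows), igraph::vcount(gu) |> as.integer())
})
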