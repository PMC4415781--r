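oc <- function(k, n, K, N) structure(list(k = k, n_set = n, K = K, N_univ = N),
                                     class = "overlap_counts")

# independent brute-force hypergeometric upper tail
brute_hyper <- function(k, n, K, N) {
  xs <- max(0, n - (N - K)):min(n, K)
  mass <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(mass[xs >= k])
}

test_that("overlap counting is exact and ignores out-of-universe genes", {
  uni <- paste0("g", 1:1000)
  de <- paste0("g", 1:100)
  members <- c(paste0("g", 96:105), "alien")
  cnt <- count_overlap(members, de, uni)
  expect_identical(cnt$k, 5L)
  expect_identical(cnt$n_set, 10L)
  expect_identical(cnt$K, 100L)
  expect_identical(cnt$N_univ, 1000L)
  expect_identical(attr(cnt, "ignored"), 1L)

  expect_identical(count_overlap(paste0("g", 1:10), uni, uni)$k, 10L)
  expect_identical(count_overlap(paste0("g", 500:509), de, uni)$k, 0L)
  expect_error(count_overlap(members, de, character(0)), "empty universe")
  expect_error(count_overlap(members, c(de, "alien"), uni), "subset")
})

test_that("Fisher tail equals brute-force hypergeometric enumeration", {
  expect_equal(fisher_exact_p(oc(5, 10, 100, 1000)),
               brute_hyper(5, 10, 100, 1000), tolerance = 1e-12)
  expect_equal(fisher_exact_p(oc(0, 10, 100, 1000)), 1)
  expect_equal(fisher_exact_p(oc(50, 200, 50, 200)), 1)  # set = universe
  # spot sweep over mixed tables
  set.seed(30)
  for (i in 1:25) {
    N <- sample(10:60, 1); n <- sample(1:N, 1); K <- sample(0:N, 1)
    k <- sample(max(0, n - (N - K)):min(n, K), 1)
    expect_equal(fisher_exact_p(oc(k, n, K, N)), brute_hyper(k, n, K, N),
                 tolerance = 1e-12)
  }
})

test_that("Pearson chi-square matches a direct-formula oracle, with small-cell substitution", {
  chisq_oracle <- function(k, n, K, N) {
    obs <- matrix(c(k, n - k, K - k, N - K - n + k), 2)
    expd <- outer(rowSums(obs), colSums(obs)) / N
    pchisq(sum((obs - expd)^2 / expd), 1, lower.tail = FALSE)
  }
  p <- chisq_p(oc(5, 10, 100, 1000))
  expect_equal(as.numeric(p), chisq_oracle(5, 10, 100, 1000), tolerance = 1e-12)
  expect_false(attr(p, "substituted"))

  # observed equal to expected -> statistic 0, p = 1
  expect_equal(as.numeric(chisq_p(oc(1, 10, 100, 1000))), 1)

  # doubling all cells doubles the statistic at fixed proportions
  stat_of <- function(p) qchisq(as.numeric(p), 1, lower.tail = FALSE)
  s1 <- stat_of(chisq_p(oc(4, 20, 200, 1000)))
  s2 <- stat_of(chisq_p(oc(8, 40, 400, 2000)))
  expect_equal(s2, 2 * s1, tolerance = 1e-9)

  # expected overlap cell below 1 -> Fisher substituted and flagged
  sub <- chisq_p(oc(3, 10, 50, 1000))
  expect_true(attr(sub, "substituted"))
  expect_equal(as.numeric(sub), fisher_exact_p(oc(3, 10, 50, 1000)))
})

test_that("discordance FDR reproduces the hand-evaluated rule", {
  # comparison pattern (<, >=, <, >=) in Fisher order
  rec <- data.frame(p_fisher = c(0.001, 0.01, 0.02, 0.03),
                    p_chisq = c(0.002, 0.005, 0.04, 0.001))
  expect_equal(fisher_chisq_fdr(rec), c(0, 1 / 2, 1 / 2, 1 / 2))

  # boundary cases
  all_lt <- data.frame(p_fisher = 1:4 / 100, p_chisq = 1:4 / 100 + 0.5)
  expect_equal(fisher_chisq_fdr(all_lt), rep(0, 4))
  none_lt <- data.frame(p_fisher = 1:4 / 100 + 0.5, p_chisq = 1:4 / 100)
  expect_equal(fisher_chisq_fdr(none_lt), rep(1, 4))

  # input order does not matter
  perm <- c(3, 1, 4, 2)
  expect_equal(fisher_chisq_fdr(rec[perm, ]), fisher_chisq_fdr(rec)[perm])

  # ties on the Fisher P share the larger rank's value
  tie <- data.frame(p_fisher = c(0.01, 0.01, 0.05),
                    p_chisq = c(0.02, 0.001, 0.001))
  # sorted: ranks 1-2 tied; raw at rank 2 = 1 - 1/2; rank 3 = 1 - 1/3 -> cummax
  expect_equal(fisher_chisq_fdr(tie), c(1 / 2, 1 / 2, 2 / 3))

  expect_error(fisher_chisq_fdr(data.frame(p_fisher = 0.5)), "p_chisq")
  expect_equal(fisher_chisq_fdr(rec, method = "bh"),
               p.adjust(rec$p_fisher, "BH"))
})

test_that("discordance FDR always lies in [0, 1] and is monotone in Fisher P", {
  set.seed(31)
  for (i in 1:20) {
    rec <- data.frame(p_fisher = runif(50), p_chisq = runif(50))
    f <- fisher_chisq_fdr(rec)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f[order(rec$p_fisher)]) >= -1e-12))
  }
})

test_that("enrichment ratio is observed over expected fraction", {
  expect_equal(enrichment_ratio(oc(5, 10, 100, 1000)), 5)
  expect_equal(enrichment_ratio(oc(1, 10, 100, 1000)), 1)
  expect_equal(enrichment_ratio(oc(0, 10, 100, 1000)), 0)
  expect_true(is.na(enrichment_ratio(oc(0, 10, 0, 1000))))
  # a set fully contained in the DE list attains the ceiling N/K
  expect_equal(enrichment_ratio(oc(10, 10, 100, 1000)), 1000 / 100)
})

test_that("ratio increases with overlap while Fisher P decreases, sizes fixed", {
  ks <- 0:10
  ps <- vapply(ks, function(k) fisher_exact_p(oc(k, 10, 100, 1000)), numeric(1))
  rs <- vapply(ks, function(k) enrichment_ratio(oc(k, 10, 100, 1000)), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_true(all(diff(rs) > 0))
})

test_that("planted set leads the up table; empty DE lists degrade gracefully", {
  b <- generate_fixture_bundle(quick_config(n_probes = 2000L, n_de = 150L,
                                            seed = 33L))
  de <- collapse_by_gene(run_diffexpr(b$matrix))
  uni <- unique(de$gene_symbol)
  up <- de$gene_symbol[de$status == "up"]
  dn <- de$gene_symbol[de$status == "down"]
  enr <- run_enrichment(b$go_sets, up, dn, uni)
  up_tab <- enr[enr$direction == "up", ]
  expect_true(up_tab$set_id[1] %in% b$truth$enriched_sets)
  expect_true(all(diff(up_tab$p_fisher) >= 0))

  expect_warning(enr0 <- run_enrichment(b$go_sets, character(0), dn, uni),
                 "empty DE list")
  expect_false("up" %in% enr0$direction)
  expect_true(all(enr0$direction == "down"))
})

test_that("under the no-signal generator almost nothing is ever significant", {
  hits <- vapply(1:5, function(s) {
    b <- generate_fixture_bundle(null_config(n_probes = 1000L, n_sets = 200L,
                                             seed = 200L + s))
    de <- collapse_by_gene(run_diffexpr(b$matrix))
    up <- de$gene_symbol[de$status == "up"]
    dn <- de$gene_symbol[de$status == "down"]
    if (!length(up) && !length(dn)) return(0)
    enr <- suppressWarnings(
      run_enrichment(b$go_sets, up, dn, unique(de$gene_symbol)))
    sum(enr$significant)
  }, numeric(1))
  expect_lte(mean(hits), 1)
})

test_that("ontology tree keeps significant terms plus minimal connectors", {
  terms <- data.frame(set_id = c("A", "B"), direction = c("up", "down"))
  edges <- data.frame(child = c("A", "B", "P"), parent = c("P", "P", "R"))
  g <- build_go_tree(terms, edges)
  expect_setequal(igraph::V(g)$name, c("A", "B", "P"))
  expect_identical(igraph::V(g)$regulation[igraph::V(g)$name == "P"], "connector")

  g0 <- build_go_tree(terms, NULL)
  expect_equal(igraph::ecount(g0), 0)
  expect_setequal(igraph::V(g0)$name, c("A", "B"))

  cyc <- data.frame(child = c("A", "P"), parent = c("P", "A"))
  expect_error(build_go_tree(terms, cyc), "cycle")

  # random DAGs: every connector is an ancestor of >= 2 significant terms
  set.seed(34)
  for (i in 1:5) {
    n <- 15
    nodes <- paste0("t", 1:n)
    edges <- do.call(rbind, lapply(2:n, function(j) {
      np <- sample(1:2, 1)
      data.frame(child = nodes[j],
                 parent = nodes[sample(seq_len(j - 1), min(np, j - 1))])
    }))
    sig <- data.frame(set_id = sample(nodes, 4), direction = "up")
    g <- build_go_tree(sig, edges)
    expect_true(all(sig$set_id %in% igraph::V(g)$name))
    conns <- igraph::V(g)$name[igraph::V(g)$regulation == "connector"]
    # BFS oracle on the raw edge table
    parents_of <- split(edges$parent, edges$child)
    ancestors <- function(x) {
      seen <- character(0); frontier <- x
      while (length(frontier)) {
        nxt <- unique(unlist(parents_of[frontier]))
        nxt <- setdiff(nxt, seen)
        seen <- c(seen, nxt); frontier <- nxt
      }
      seen
    }
    anc_sets <- lapply(sig$set_id, ancestors)
    for (cn in conns) {
      expect_gte(sum(vapply(anc_sets, function(a) cn %in% a, logical(1))), 2)
    }
  }
})
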