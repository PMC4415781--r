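test_that("paired differences are tumor minus normal, robust to pair order", {
  em <- tiny_em()
  d <- paired_differences(em)
  expect_identical(dim(d), c(4L, 3L))
  expect_equal(d[, "PA"], em$values[, 1] - em$values[, 4], ignore_attr = TRUE)

  # tumor column equal to normal column -> zero differences
  v <- em$values
  v[, 4:6] <- v[, 1:3]
  expect_true(all(tiny_em(v) |> paired_differences() == 0))

  # permuting sample order leaves per-pair differences unchanged
  perm <- c(4, 2, 6, 1, 5, 3)
  em_p <- expression_matrix(em$values[, perm], em$probes, em$design[perm, ])
  d_p <- paired_differences(em_p)
  expect_equal(d_p[, colnames(d)], d)
})

test_that("per-probe fits match hand arithmetic and a two-pass oracle", {
  d <- matrix(c(1, 2, 3), 1, 3, dimnames = list("P1", NULL))
  f <- fit_gene_models(d)
  expect_equal(f$log2fc, 2)
  expect_equal(f$s2, 1)
  expect_identical(f$df, 2L)

  f0 <- fit_gene_models(matrix(c(2, 2, 2), 1, 3, dimnames = list("P1", NULL)))
  expect_equal(f0$log2fc, 2)
  expect_equal(f0$s2, 0)

  set.seed(10)
  d <- matrix(rnorm(500 * 8), 500, 8, dimnames = list(paste0("P", 1:500), NULL))
  f <- fit_gene_models(d)
  # independent two-pass oracle
  expect_equal(f$log2fc, apply(d, 1, mean), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(f$s2, apply(d, 1, var), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("EB prior: scale equivariance and the degenerate point-mass limit", {
  set.seed(11)
  s2 <- 0.25 * rchisq(2000, 25) / 25 * (4 / rchisq(2000, 4))
  h1 <- estimate_eb_hyperparams(s2, 25)
  h2 <- estimate_eb_hyperparams(2 * s2, 25)
  expect_equal(h2$d0, h1$d0, tolerance = 1e-9)
  expect_equal(h2$s0_sq, 2 * h1$s0_sq, tolerance = 1e-9)

  h3 <- estimate_eb_hyperparams(rep(0.4, 100), 25)
  expect_identical(h3$d0, Inf)
  expect_equal(h3$s0_sq, 0.4)

  expect_error(estimate_eb_hyperparams(rep(0, 100), 25), "positive variance")
})

test_that("EB prior recovery from data simulated under the scaled-F model", {
  set.seed(12)
  d0 <- 4; s0 <- 0.25; df <- 25
  s2 <- s0 * (d0 / rchisq(5000, d0)) * (rchisq(5000, df) / df)
  h <- estimate_eb_hyperparams(s2, df)
  expect_gt(h$d0, 2.5); expect_lt(h$d0, 6.5)
  expect_lt(abs(h$s0_sq - s0) / s0, 0.2)
})

test_that("trigamma inversion is a true inverse over the useful range", {
  y <- c(0.05, 0.5, 2, 12.5, 200)
  expect_equal(pairedDE:::trigamma_inverse(trigamma(y)), y, tolerance = 1e-8)
})

test_that("moderated t at d0 = 0 reproduces the classical paired t-test", {
  set.seed(13)
  d <- matrix(rnorm(50 * 26, 0, 0.7), 50, 26,
              dimnames = list(paste0("P", 1:50), NULL))
  f <- fit_gene_models(d)
  mt <- moderated_t(f$log2fc, f$s2, f$df,
                    list(d0 = 0, s0_sq = 1), n_pairs = 26)
  for (i in seq_len(nrow(d))) {
    tt <- t.test(d[i, ])
    expect_equal(mt$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(mt$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t limits: zero effect, infinite prior df, zero sample variance", {
  mt0 <- moderated_t(0, 0.5, 25, list(d0 = 4, s0_sq = 0.25), 26)
  expect_equal(mt0$t_mod, 0)
  expect_equal(mt0$p, 1)

  set.seed(14)
  lfc <- rnorm(100); s2 <- rchisq(100, 5) / 5
  mt_inf <- moderated_t(lfc, s2, 25, list(d0 = Inf, s0_sq = 0.3), 26)
  expect_identical(order(abs(mt_inf$t_mod)), order(abs(lfc)))
  expect_true(all(is.infinite(mt_inf$df_total)))

  mt_z <- moderated_t(1, 0, 25, list(d0 = 4, s0_sq = 0.25), 26)
  expect_true(is.finite(mt_z$t_mod) && mt_z$p > 0)
})

test_that("moderated t agrees with the established empirical-Bayes reference", {
  skip_if_not_installed("limma")
  b <- generate_paired_expression(quick_config(n_probes = 1000L, seed = 15L))
  d <- paired_differences(b$matrix)
  fit <- limma::lmFit(d, matrix(1, ncol(d), 1))
  eb <- limma::eBayes(fit)
  f <- fit_gene_models(d)
  h <- estimate_eb_hyperparams(f$s2, f$df[1])
  mt <- moderated_t(f$log2fc, f$s2, f$df, h, ncol(d))
  expect_equal(unname(mt$t_mod), unname(eb$t[, 1]), tolerance = 1e-6)
  expect_equal(unname(mt$p), unname(eb$p.value[, 1]), tolerance = 1e-6)
})

test_that("BH adjustment matches the hand step-up and is order-equivariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(16)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("triple-threshold classification reproduces published calls", {
  rec <- data.frame(log2fc = c(-11.8913, 5.28242, 0.5),
                    p = c(2.90e-15, 4.82e-13, 1e-10),
                    fdr = c(1.25e-11, 3.03e-10, 1e-9))
  out <- classify_de(rec)
  expect_identical(out$status, c("down", "up", "ns"))

  # boundary: log2fc exactly at the gate is not called
  out2 <- classify_de(data.frame(log2fc = 1, p = 1e-5, fdr = 1e-5))
  expect_identical(out2$status, "ns")
})

test_that("label swap negates every log2fc and maps up to down exactly", {
  b <- generate_paired_expression(quick_config(seed = 18L))
  em <- b$matrix
  de1 <- run_diffexpr(em)
  sw <- em
  sw$design$condition <- ifelse(sw$design$condition == "tumor", "normal", "tumor")
  em_sw <- expression_matrix(sw$values, sw$probes, sw$design)
  de2 <- run_diffexpr(em_sw)
  expect_equal(de2$log2fc, -de1$log2fc, tolerance = 1e-12)
  expect_equal(de2$p, de1$p, tolerance = 1e-12)
  expect_identical(de2$status[de1$status == "up"],
                   rep("down", sum(de1$status == "up")))
  expect_identical(de2$status[de1$status == "down"],
                   rep("up", sum(de1$status == "down")))
})

test_that("biotype summary counts add up", {
  b <- generate_paired_expression(quick_config(seed = 20L))
  de <- run_diffexpr(b$matrix)
  s <- de_summary(de)
  expect_identical(sum(s$count), nrow(de))
  expect_identical(sum(s$count[s$status != "ns"]), sum(de$status != "ns"))
})
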