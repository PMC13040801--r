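test_that("the significance filter applies strict thresholds and sign partition", {
  tb <- data.frame(
    gene_id = paste0("g", 1:6),
    log2fc = c(2, -2, 0.5, 3, -1.5, 1.2),
    pvalue = c(0.001, 0.001, 1e-4, 0.1, 0.02, 0.001),
    padj = c(0.01, 0.01, 0.001, 0.2, 0.049, NA)
  )
  ds <- filter_degs(tb)
  expect_equal(ds$up, "g1")
  expect_equal(sort(ds$down), c("g2", "g5"))
  expect_length(intersect(ds$up, ds$down), 0)

  # boundary: log2fc exactly at the threshold is excluded (strict >)
  tb2 <- data.frame(gene_id = "g", log2fc = 1.0, pvalue = 0.001, padj = 0.01)
  expect_length(filter_degs(tb2)$all_significant, 0)
  # boundary: padj exactly at the threshold is excluded (strict <)
  tb3 <- data.frame(gene_id = "g", log2fc = 2, pvalue = 0.01, padj = 0.05)
  expect_length(filter_degs(tb3)$all_significant, 0)
  # missing padj is non-significant
  tb4 <- data.frame(gene_id = "g", log2fc = 2, pvalue = 1e-6, padj = NA)
  expect_length(filter_degs(tb4)$all_significant, 0)
})

test_that("the filter is idempotent and threshold-monotone", {
  deg <- simulate_deg_tables(1000, 20, 10, 0, effect_size = 3, seed = 43)$table_a
  strict <- filter_degs(deg, lfc_threshold = 1, fdr_threshold = 0.05)
  loose_fdr <- filter_degs(deg, lfc_threshold = 1, fdr_threshold = 0.2)
  loose_lfc <- filter_degs(deg, lfc_threshold = 0.5, fdr_threshold = 0.05)
  expect_true(all(strict$all_significant %in% loose_fdr$all_significant))
  expect_true(all(strict$all_significant %in% loose_lfc$all_significant))
})

test_that("disjoint sets give zero overlap, zero factor and p = 1", {
  ov <- overlap_stats(paste0("a", 1:10), paste0("b", 1:20), 1000)
  expect_equal(ov$k, 0)
  expect_equal(ov$representation_factor, 0)
  expect_equal(ov$log_p_upper, 0)
})

test_that("empty sets give an undefined factor and p = 1 by convention", {
  ov <- overlap_stats(character(0), paste0("b", 1:5), 100)
  expect_true(is.na(ov$representation_factor))
  expect_equal(ov$log_p_upper, 0)
})

test_that("a universe smaller than the union is rejected", {
  expect_error(overlap_stats(paste0("g", 1:30), paste0("g", 21:60), 50),
               "n_universe")
})

test_that("the published overlap sizes give a 6.9-fold representation factor", {
  ids <- sprintf("g%05d", 1:20000)
  set_a <- ids[1:77]
  set_b <- c(ids[1:31], ids[1000 + 1:991])
  ov <- overlap_stats(set_a, set_b, 17516)
  expect_equal(ov$k, 31)
  expect_equal(ov$representation_factor, 6.90, tolerance = 0.005 / 6.90)
  expect_lt(ov$log_p_upper, log(1e-15))
  expect_true(is.finite(ov$log_p_upper))
})

test_that("overlap statistics are symmetric in the two sets", {
  set.seed(47)
  a <- sample(sprintf("g%03d", 1:200), 40)
  b <- sample(sprintf("g%03d", 1:200), 60)
  o1 <- overlap_stats(a, b, 500)
  o2 <- overlap_stats(b, a, 500)
  expect_equal(o1$k, o2$k)
  expect_equal(o1$representation_factor, o2$representation_factor)
  expect_equal(o1$log_p_upper, o2$log_p_upper)
})

test_that("the log tail is monotone non-increasing in k and in (0, 1]", {
  lp <- vapply(0:15, log_hyper_tail, 0, n_a = 15, n_b = 40, n_universe = 200)
  expect_true(all(diff(lp) <= 1e-12))
  expect_true(all(lp <= 0))
  expect_true(all(is.finite(lp)))
})

test_that("log-space tails match stats::phyper on extreme inputs", {
  cases <- list(c(31, 77, 1022, 17516), c(500, 600, 700, 1000),
                c(5, 10, 10, 40), c(120, 150, 200, 5000))
  for (cs in cases) {
    got <- log_hyper_tail(cs[1], cs[2], cs[3], cs[4])
    want <- phyper(cs[1] - 1, cs[3], cs[4] - cs[3], cs[2],
                   lower.tail = FALSE, log.p = TRUE)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("small-universe tails match exhaustive subset enumeration", {
  for (N in c(5, 8, 10)) {
    for (n_a in 0:N) {
      for (n_b in 0:N) {
        enum <- enum_hyper_tails(n_a, n_b, N)
        for (k in 0:min(n_a, n_b)) {
          expect_equal(exp(log_hyper_tail(k, n_a, n_b, N)), enum[k + 1],
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH adjustment reproduces hand and textbook step-up results", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(53)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), bh_textbook(p), tolerance = 1e-12)
  }
})

test_that("BH output is permutation-equivariant", {
  set.seed(59)
  p <- runif(100)
  adj <- bh_adjust(p)
  perm <- sample(100)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("planted overlap is recovered exactly at saturating effect size", {
  deg <- simulate_deg_tables(n_genes = 5000, n_shared_de = 25, n_a_only = 15,
                             n_b_only = 100, effect_size = 1e6, seed = 61)
  a <- filter_degs(deg$table_a)
  b <- filter_degs(deg$table_b)
  ov <- overlap_stats(a$all_significant, b$all_significant, 5000)
  expect_equal(ov$k, 25)
  expect_setequal(ov$shared, deg$truth$shared)
})
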