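test_that("upper-quartile factors follow the stated quantile convention", {
  counts <- cbind(s1 = c(2, 4, 6, 8), s2 = c(2, 4, 6, 8))
  f <- upper_quartile_normalize(counts)
  # type-7 quantile of {2,4,6,8} at 0.75 is 6.5; equal samples -> factors 1
  expect_equal(attr(f, "raw_uq"), c(s1 = 6.5, s2 = 6.5))
  expect_equal(as.numeric(f), c(1, 1))

  # doubling one sample doubles its factor relative to the other
  counts2 <- cbind(s1 = c(2, 4, 6, 8), s2 = 2 * c(2, 4, 6, 8))
  f2 <- upper_quartile_normalize(counts2)
  expect_equal(unname(f2[2] / f2[1]), 2)
  # geometric mean stays 1
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-12)

  # zeros are ignored in the quantile
  counts3 <- cbind(s1 = c(0, 0, 2, 4, 6, 8))
  expect_equal(attr(upper_quartile_normalize(counts3), "raw_uq"),
               c(s1 = 6.5))
  expect_error(upper_quartile_normalize(cbind(c(0, 0))), "all-zero")
})

test_that("logCPM matches its defining formula and is scale-free", {
  # hand-computed single cell: count 10, library 1e6, factor 1
  counts <- matrix(c(10, 1e6 - 10), ncol = 1,
                   dimnames = list(c("a", "b"), "s1"))
  lc <- log_cpm(counts, factors = c(s1 = 1))
  expect_equal(lc["a", 1], log2(10.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  # zero counts stay finite
  expect_true(all(is.finite(log_cpm(matrix(c(0, 5), ncol = 1)))))
  # doubling counts (and hence library and UQ factor) changes little
  m <- matrix(rpois(300, 50), nrow = 50)
  rownames(m) <- paste0("g", 1:50)
  l1 <- log_cpm(m)
  l2 <- log_cpm(2 * m)
  expect_equal(l1, l2, tolerance = 0.01)
})

test_that("gene standardization yields unit variance and drops constants", {
  m <- rbind(a = c(0, 2, 4, 9), b = c(5, 5, 5, 5), d = c(0, 2, 1, 7))
  expect_warning(s <- standardize_genes(m), "zero-variance")
  expect_equal(nrow(s), 2L)
  expect_equal(apply(s, 1, var), c(a = 1, d = 1), tolerance = 1e-9)
  # row (0, 2): sd sqrt(2), scaled to variance 1
  expect_equal(unname(standardize_genes(rbind(x = c(0, 2), y = c(1, 3)))[1, ]),
               c(0, 2) / sqrt(2))
  expect_error(standardize_genes(rbind(c(1, 1), c(2, 2))), "zero variance")
})

test_that("the MRPP statistic is the group-weighted mean within-group distance", {
  # 1-gene pathway, samples at 0,1 | 10,11: xi = 1 in both groups
  x <- rbind(g1 = c(0, 1, 10, 11))
  labels <- c("A", "A", "B", "B")
  expect_equal(mrpp_statistic(x, labels), 1)
  # both groups internally identical: delta = 0
  expect_equal(mrpp_statistic(rbind(c(3, 3, 7, 7)), labels), 0)
  # permuting samples within groups changes nothing
  expect_equal(mrpp_statistic(x[, c(2, 1, 4, 3), drop = FALSE], labels),
               mrpp_statistic(x, labels))
  expect_error(mrpp_statistic(x, c("A", "A", "A", "B")), "2 samples")
})

test_that("MRPP delta agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(7)
  m <- matrix(rnorm(60), nrow = 6)  # 6 genes x 10 samples
  labels <- rep(c("A", "B"), each = 5)
  ours <- mrpp_statistic(m, labels)
  ref <- vegan::mrpp(t(m), labels, permutations = 2, weight.type = 1)
  expect_equal(ours, ref$delta, tolerance = 1e-12)
})

test_that("exhaustive permutation p is the exact proportion", {
  x <- rbind(g1 = c(0, 1, 10, 11))
  labels <- c("A", "A", "B", "B")
  delta <- mrpp_statistic(x, labels)
  p <- permutation_pvalue(delta, x, labels)
  expect_equal(attr(p, "method"), "exhaustive")
  # only the true split (of the 3 distinct 2|2 splits) attains delta <= 1
  expect_equal(as.numeric(p), 1 / 3)

  # delta at the permutation maximum gives p = 1
  worst <- max(apply(utils::combn(4, 2), 2, function(i) {
    lab <- rep("B", 4); lab[i] <- "A"
    mrpp_statistic(x, lab)
  }))
  expect_equal(as.numeric(permutation_pvalue(worst, x, labels)), 1)
})

test_that("Monte-Carlo p converges to the exhaustive p", {
  set.seed(11)
  m <- matrix(rnorm(40), nrow = 4)  # 4 genes x 10 samples
  labels <- rep(c("A", "B"), each = 5)
  delta <- mrpp_statistic(m, labels)
  p_ex <- as.numeric(permutation_pvalue(delta, m, labels, exhaustive = TRUE))
  n_mc <- 4000
  p_mc <- as.numeric(permutation_pvalue(delta, m, labels, n_perm = n_mc,
                                        seed = 5, exhaustive = FALSE))
  se <- sqrt(p_ex * (1 - p_ex) / n_mc)
  expect_lt(abs(p_mc - p_ex), 3 * se + 1 / n_mc)
})

test_that("permutation p-values are uniform under the null", {
  # many small null datasets; KS against U(0,1) must not reject at 0.01
  ps <- vapply(1:1000, function(s) {
    set.seed(s)
    m <- matrix(rnorm(16), nrow = 2)  # 2 genes x 8 samples
    labels <- rep(c("A", "B"), each = 4)
    as.numeric(permutation_pvalue(mrpp_statistic(m, labels), m, labels,
                                  n_perm = 99, seed = s + 1,
                                  exhaustive = FALSE))
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH selection reproduces the step-up rule", {
  sel <- fdr_select(c(0.01, 0.02, 0.9), q = 0.05)
  expect_equal(sel$significant, c(TRUE, TRUE, FALSE))
  expect_equal(sel$p_adj, p.adjust(c(0.01, 0.02, 0.9), "BH"))
  expect_false(any(fdr_select(rep(1, 5))$significant))
  expect_equal(nrow(fdr_select(numeric(0))), 0L)
  # an added p = 1 never de-selects existing discoveries
  p <- c(0.001, 0.004, 0.2)
  before <- fdr_select(p)$significant
  after <- fdr_select(c(p, 1))$significant[1:3]
  expect_true(all(after >= before))
})

test_that("the pathway driver detects shifted pathways and honours GMT io", {
  sim <- simulate_counts(count_scenario(
    n_genes = 300, n_pathways = 10, pathway_size = 15, dispersion = 0.05,
    shifts = c(pw001 = 3), seed = 21))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sim$pathways, gmt)
  sets <- read_gmt(gmt)
  expect_identical(lapply(sets, unname), lapply(sim$pathways, unname))
  res <- mrpp_pathways(sim$counts, sim$labels, sets, n_perm = 500, seed = 4)
  expect_equal(nrow(res), 10L)
  expect_true(res$significant[res$pathway == "pw001"])
  expect_lt(res$delta[res$pathway == "pw001"] /
              median(res$delta[res$pathway != "pw001"]), 1)
})
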