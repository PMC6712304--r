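test_that("contingency tables are plain set arithmetic", {
  s8 <- paste0("s", 1:8)
  expect_equal(contingency(s8[1:4], s8[1:4], s8),
               c(a = 4, b = 0, c = 0, d = 4))
  expect_equal(contingency(s8[1:2], s8[3:4], s8[1:4]),
               c(a = 0, b = 2, c = 2, d = 0))
  expect_equal(contingency(character(0), s8[1:3], s8),
               c(a = 0, b = 0, c = 3, d = 5))
})

test_that("two-sided Fisher P matches the worked exact values", {
  expect_equal(fisher_exact(c(4, 0, 0, 4))$p_value, 2 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact(c(10, 0, 0, 10))$p_value, 2 / 184756,
               tolerance = 1e-12)
  # degenerate margin: only one table is consistent, P = 1
  expect_equal(fisher_exact(c(5, 0, 3, 0))$p_value, 1)
  expect_equal(fisher_exact(c(0, 0, 0, 9))$p_value, 1)
})

test_that("Fisher P agrees with by-definition enumeration and is symmetric", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(2:30, 1)
    t <- as.vector(rmultinom(1, n, runif(4, 0.05, 1)))
    p <- fisher_exact(t)$p_value
    expect_equal(p, oracle_fisher_p(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
    # transposing molecule/microbe leaves P unchanged
    expect_equal(fisher_exact(t[c(1, 3, 2, 4)])$p_value, p,
                 tolerance = 1e-12)
  }
})

test_that("Fisher P agrees with stats::fisher.test, including large n", {
  set.seed(102)
  for (i in 1:100) {
    n <- sample(c(4:60, 100, 200, 500), 1)
    t <- as.vector(rmultinom(1, n, runif(4, 0.05, 1)))
    expect_equal(fisher_exact(t)$p_value,
                 stats::fisher.test(matrix(t, 2))$p.value,
                 tolerance = 1e-8)
  }
})

test_that("association sign compares observed with expected cooccurrence", {
  expect_identical(as.character(sign_of_association(c(4, 0, 0, 4))),
                   "positive")
  expect_identical(as.character(sign_of_association(c(0, 2, 2, 0))),
                   "negative")
  tie <- sign_of_association(c(1, 1, 1, 1))
  expect_identical(as.character(tie), "positive")
  expect_true(attr(tie, "tie"))
  expect_false(attr(sign_of_association(c(4, 0, 0, 4)), "tie"))
})

test_that("Pearson test matches closed form and cor.test", {
  x <- 1:4
  expect_equal(pearson_test(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_test(1:4, 4:1)$statistic, -1)
  r <- pearson_test(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$statistic, 0.8)
  expect_equal(r$p_value, 0.104088, tolerance = 1e-5)
  ct <- stats::cor.test(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-10)
  expect_message(out <- pearson_test(rep(1, 5), 1:5), "constant")
  expect_null(out)
})

test_that("Spearman is rank-based and monotone-transform invariant", {
  x <- c(0.3, 1.2, 2.4, 3.3, 9.1)
  expect_equal(spearman_test(x, exp(x))$statistic, 1)
  expect_equal(spearman_test(x, rev(x))$statistic, -1)
  expect_equal(spearman_test(1:5, c(2, 1, 4, 3, 5))$statistic, 0.8)
  y <- c(2, 1, 4, 3, 5)
  expect_equal(spearman_test(x, y)$statistic,
               spearman_test(log(x), y^3)$statistic)
})

test_that("mutual information is the plug-in estimate in bits", {
  s8 <- paste0("s", 1:8)
  expect_equal(mutual_information(s8[1:4], s8[1:4], s8), 1)
  expect_equal(mutual_information(s8[1:4], s8[c(1, 2, 5, 6)], s8), 0)
  expect_equal(mutual_information(character(0), s8[1:3], s8), 0)
  # symmetric and non-negative on random sets
  set.seed(103)
  for (i in 1:25) {
    a <- sample(s8, sample(0:8, 1))
    b <- sample(s8, sample(0:8, 1))
    m1 <- mutual_information(a, b, s8)
    expect_gte(m1, 0)
    expect_equal(m1, mutual_information(b, a, s8), tolerance = 1e-12)
  }
})

test_that("the scan finds a perfectly cooccurring pair and nothing else", {
  s40 <- paste0("s", 1:40)
  mol <- toy_binary(list(molA = s40[1:15]), 40, mz = 250)
  mic <- binary_features(list(otuA = s40[1:15]), s40, kind = "microbial")
  # the (15, 0, 0, 25) table: P from the enumeration oracle is < 1e-10
  expect_lt(oracle_fisher_p(15, 0, 0, 25), 1e-10)
  edges <- association_scan(mol, mic, "fisher", 1e-10)
  expect_equal(nrow(edges), 1L)
  expect_identical(edges$sign, "positive")
  expect_equal(edges$p_value, oracle_fisher_p(15, 0, 0, 25),
               tolerance = 1e-12)
  expect_equal(edges$mz, 250)
  # P values are never negative, so a threshold of 0 retains nothing
  expect_equal(nrow(association_scan(mol, mic, "fisher", 0)), 0L)
})

test_that("the scan is deterministic and rejects unknown tests", {
  inp <- planted_scan_inputs(seed = 5, n_planted = 5L, n_molecules = 30L,
                             n_microbes = 10L, n_samples = 60L)
  e1 <- association_scan(inp$mol, inp$mic, "fisher", 1e-4)
  e2 <- association_scan(inp$mol, inp$mic, "fisher", 1e-4)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_false(is.unsorted(e1$molecule_id))
  expect_error(association_scan(inp$mol, inp$mic, "chi2"), "unknown")
})

test_that("a pure-null scan at 1e-10 finds nothing", {
  for (seed in 1:3) {
    inp <- planted_scan_inputs(seed = seed, n_planted = 0L)
    edges <- association_scan(inp$mol, inp$mic, "fisher", 1e-10)
    expect_equal(nrow(edges), 0L)
  }
})

test_that("continuous scans recover planted pairs and match cor.test", {
  sim <- simulate_dataset(sim_config(n_planted = 10L, mode = "continuous",
                                     seed = 31))
  edges <- association_scan(sim$molecules, sim$microbes, "spearman", 1e-10)
  ev <- evaluate_edges(edges, sim$truth)
  expect_gte(ev$recall, 0.9)
  expect_lte(ev$empirical_fdr, 0.1)
  x <- sim$molecules$values[1, ]
  y <- sim$microbes$values[1, ]
  ours <- edges[edges$molecule_id == "mol_001" &
                  edges$microbe_id == "otu_001", ]
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(ours$statistic, unname(ct$estimate), tolerance = 1e-10)
})
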