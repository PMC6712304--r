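test_that("decoys are size-matched random subsets, reproducible by seed", {
  set.seed(201)
  sets <- lapply(1:30, function(i) {
    sample(paste0("s", 1:50), sample(0:50, 1))
  })
  names(sets) <- sprintf("m%02d", 1:30)
  mol <- toy_binary(sets, 50, mz = runif(30, 100, 1500))
  dec <- make_decoys(mol, seed = 11)
  map <- attr(dec, "source_map")
  expect_equal(nrow(dec$presence), 30L)
  # size matching holds for every decoy, including empty and full targets
  expect_equal(unname(rowSums(dec$presence)),
               unname(rowSums(mol$presence)[map$target_id]))
  # bit-reproducible given the seed; different seed differs
  dec2 <- make_decoys(mol, seed = 11)
  expect_identical(dec$presence, dec2$presence)
  dec3 <- make_decoys(mol, seed = 12)
  expect_false(identical(dec$presence, dec3$presence))
  # edge cases: empty target -> empty decoy, full target -> whole universe
  full <- toy_binary(list(none = character(0), all = paste0("s", 1:50)), 50,
                     mz = c(100, 200))
  dfull <- make_decoys(full, seed = 1)
  expect_equal(unname(rowSums(dfull$presence)), c(0, 50))
})

test_that("decoy overlap with targets matches the hypergeometric mean", {
  # |decoy n target| ~ Hypergeometric: E = k^2 / n = 30^2/200 = 4.5
  sets <- rep(list(paste0("s", 1:30)), 300)
  names(sets) <- sprintf("m%03d", 1:300)
  mol <- toy_binary(sets, 200)
  dec <- make_decoys(mol, seed = 31)
  overlap <- rowSums(dec$presence[, paste0("s", 1:30), drop = FALSE])
  se <- sqrt(30 * (30 / 200) * (1 - 30 / 200) * (170 / 199) / 300)
  expect_lt(abs(mean(overlap) - 4.5), 4 * se)
})

test_that("the TDA estimate is the normalized decoy/target ratio", {
  fake <- function(p, test = "fisher") {
    tibble::tibble(molecule_id = sprintf("m%04d", seq_along(p)),
                   microbe_id = "o1", mz = NA_real_, test = test,
                   statistic = 1, p_value = p, sign = "positive")
  }
  real <- fake(seq(0.001, 0.1, length.out = 100))
  decoy <- fake(c(rep(0.04, 5), rep(0.9, 95)))
  est <- tda_fdr(real, decoy, threshold = 0.2)
  expect_equal(est$n_real, 100L)
  expect_equal(est$n_decoy, 5L)
  expect_equal(est$fdr_tda, 0.05)
  # no real association passing: FDR is 1 by convention
  expect_equal(tda_fdr(real, decoy, threshold = 1e-8)$fdr_tda, 1)
  # capped at 1
  expect_equal(tda_fdr(fake(0.01), fake(c(0.001, 0.002)), 0.05)$fdr_tda, 1)
  # n_per_target normalization
  expect_equal(tda_fdr(real, decoy, 0.2, n_per_target = 5L)$fdr_tda, 0.01)
  # mismatched tests are a hard error
  expect_error(tda_fdr(real, fake(0.5, test = "mi"), 0.05), "different tests")
})

test_that("on pure-null data the TDA estimate at P < 0.05 is about 1", {
  inp <- planted_scan_inputs(seed = 3, n_planted = 0L)
  real <- association_scan(inp$mol, inp$mic, "fisher", 1)
  dec <- make_decoys(inp$mol, seed = 1003, n_per_target = 5L)
  decoy <- association_scan(dec, inp$mic, "fisher", 1)
  est <- tda_fdr(real, decoy, 0.05, n_per_target = 5L)
  expect_gt(est$fdr_tda, 0.75)
  expect_lte(est$fdr_tda, 1)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 6)), rep(1, 6))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(202)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("q values respect the full tested family, not just kept edges", {
  inp <- planted_scan_inputs(seed = 7, n_planted = 5L, n_molecules = 20L,
                             n_microbes = 10L, n_samples = 80L)
  all_edges <- association_scan(inp$mol, inp$mic, "fisher", 1)
  some <- association_scan(inp$mol, inp$mic, "fisher", 1e-3)
  q_all <- adjust_edges(all_edges)
  q_some <- adjust_edges(some)
  key <- paste(q_all$molecule_id, q_all$microbe_id)
  skey <- paste(q_some$molecule_id, q_some$microbe_id)
  matched <- q_all$q_value[match(skey, key)]
  # truncating the family can only make q values conservative, and the
  # strongly significant edges are unaffected
  expect_true(all(q_some$q_value >= matched - 1e-12))
  strong <- matched < 1e-6
  expect_equal(q_some$q_value[strong], matched[strong], tolerance = 1e-12)
})

test_that("the FDR curve is monotone and consistent with tda_fdr", {
  inp <- planted_scan_inputs(seed = 9, n_planted = 10L)
  real <- association_scan(inp$mol, inp$mic, "fisher", 1)
  dec <- make_decoys(inp$mol, seed = 1009, n_per_target = 3L)
  decoy <- association_scan(dec, inp$mic, "fisher", 1)
  grid <- 10^seq(-20, -2, by = 2)
  curve <- fdr_curve(real, decoy, grid, n_per_target = 3L)
  expect_equal(nrow(curve), length(grid))
  # tightening the threshold never increases the discovery count
  expect_false(is.unsorted(curve$n_real))
  expect_false(is.unsorted(curve$n_pass_bh))
  one <- fdr_curve(real, decoy, 1e-6, n_per_target = 3L)
  expect_equal(one[, c("threshold", "n_real", "n_decoy", "fdr_tda")],
               tda_fdr(real, decoy, 1e-6, n_per_target = 3L))
})

test_that("selection returns an empty edge set when no threshold qualifies", {
  fake <- tibble::tibble(molecule_id = "m1", microbe_id = "o1",
                         mz = NA_real_, test = "fisher", statistic = 1,
                         p_value = 0.5, sign = "positive")
  sel <- select_at_fdr(fake, fake, q = 0.05)
  expect_equal(nrow(sel), 0L)
})

test_that("planted associations are recovered at a 1% TDA FDR", {
  inp <- planted_scan_inputs(seed = 13, n_planted = 20L)
  real <- association_scan(inp$mol, inp$mic, "fisher", 1)
  dec <- make_decoys(inp$mol, seed = 1013, n_per_target = 10L)
  decoy <- association_scan(dec, inp$mic, "fisher", 1)
  sel <- select_at_fdr(real, decoy, 0.01, n_per_target = 10L)
  ev <- evaluate_edges(sel, inp$truth)
  expect_gte(ev$recall * 20, 19)
  expect_lte(ev$n_edges - ev$recall * 20, 1)
})
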