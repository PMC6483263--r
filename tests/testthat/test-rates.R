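# Intra-scaffold rate MLE, split flagging, junction optimization, full-map
# refits, interval rates and cross-weighted consensus.

test_that("two-marker intra estimates match the closed-form two-point MLE", {
  set.seed(31)
  d <- cross_design("F2")
  for (r_true in c(0.05, 0.15, 0.3)) {
    sim <- sim_chain_calls(400, r_true, d)
    er <- floor_errors(rownames(sim$calls$calls))
    intra <- estimate_intra_rates(sim$calls, er, d)
    oracle <- two_point_oracle(sim$calls$calls[, 1], sim$calls$calls[, 2], d)
    expect_equal(intra$r, oracle, tolerance = 2e-3)
  }
})

test_that("intra-scaffold rates are recovered and perfect linkage floors", {
  set.seed(32)
  d <- cross_design("F2")
  errs <- replicate(10, {
    sim <- sim_chain_calls(200, c(0.01, 0.01, 0.01), d)
    er <- floor_errors(rownames(sim$calls$calls))
    intra <- estimate_intra_rates(sim$calls, er, d)
    intra$r - 0.01
  })
  expect_lt(abs(median(errs)), 0.01)
  # no recombinant individuals: estimate at the floor
  geno <- matrix(rep(c(1L, 2L, 3L), length.out = 30), 30, 4)
  gc <- geno_calls(geno, define_windows(c(s1 = 4e5)))
  intra0 <- estimate_intra_rates(gc, floor_errors(rownames(gc$calls)), d)
  expect_true(all(intra0$r <= 1e-6 + 1e-9))
  # single-marker scaffold contributes no rows
  gc1 <- geno_calls(matrix(1L, 5, 1), define_windows(c(s1 = 9e4)))
  expect_equal(nrow(estimate_intra_rates(gc1, floor_errors(rownames(gc1$calls)), d)), 0L)
})

test_that("rate recovery correlates with generating values over a wide range", {
  set.seed(33)
  d <- cross_design("F2")
  r_true <- exp(seq(log(0.01), log(0.3), length.out = 50))
  sim <- sim_chain_calls(200, r_true, d)
  er <- floor_errors(rownames(sim$calls$calls))
  intra <- estimate_intra_rates(sim$calls, er, d)
  expect_gt(cor(intra$r, r_true), 0.9)
})

test_that("abnormally high intra rates are flagged and split cleanly", {
  intra <- tibble::tibble(scaffold = "s13", gap = 1:3,
                          marker_from = letters[1:3], marker_to = letters[2:4],
                          r = c(0.004, 0.45, 0.006), loglik = -10)
  fl <- flag_split_candidates(intra, 0.2)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$gap, 2L)
  expect_equal(nrow(flag_split_candidates(dplyr::mutate(intra, r = r / 100), 0.2)), 0L)
  # splitting renumbers windows and rebases coordinates
  gc <- geno_calls(matrix(2L, 3, 4), define_windows(c(s13 = 4e5)))
  gc2 <- split_scaffolds(gc, fl)
  expect_setequal(unique(gc2$markers$scaffold), c("s13a", "s13b"))
  b <- gc2$markers[gc2$markers$scaffold == "s13b", ]
  expect_equal(b$index, 1:2)
  expect_equal(b$start, c(0, 1e5))
})

test_that("junction optimization recovers gaps, saturates bad joins and nests in the full MLE", {
  set.seed(34)
  d <- cross_design("F2")
  sc <- rep(c("s1", "s2", "s3"), each = 5)
  rates <- rep(0.01, 14)
  rates[c(5, 10)] <- c(0.05, 0.08) # junction gaps
  sim <- sim_chain_calls(300, rates, d, scaffold_of = sc)
  er <- floor_errors(rownames(sim$calls$calls))
  intra <- estimate_intra_rates(sim$calls, er, d)
  true_map <- chrom_map(c("s1", "s2", "s3"))
  fit <- fit_map(true_map, sim$calls, er, d, intra, mode = "junction")
  jr <- fit$rates[fit$junctions]
  expect_lt(max(abs(jr - c(0.05, 0.08))), 0.03)
  # a bad join is compensated by inflated junction rates (the joined ends
  # are ~17 cM apart through the interceding scaffold) at a likelihood cost
  bad_map <- chrom_map(c("s1", "s3", "s2"))
  fit_bad <- fit_map(bad_map, sim$calls, er, d, intra, mode = "junction")
  expect_gt(min(fit_bad$rates[fit_bad$junctions]), 0.1)
  expect_lt(fit_bad$loglik, fit$loglik)
  # full MLE frees more parameters: never worse on the same order
  fit_full <- fit_map(true_map, sim$calls, er, d, intra, mode = "full")
  expect_gte(fit_full$loglik, fit$loglik - 1e-6)
  # single scaffold: nothing junction-level to optimize
  one <- sim_chain_calls(50, c(0.01, 0.01), d)
  f1 <- fit_map(chrom_map("s1"), one$calls, floor_errors(rownames(one$calls$calls)),
                d, estimate_intra_rates(one$calls,
                                        floor_errors(rownames(one$calls$calls)), d))
  expect_length(f1$junctions, 0L)
  expect_true(is.finite(f1$loglik))
})

test_that("full-map reversal leaves the likelihood unchanged", {
  set.seed(35)
  d <- cross_design("F2")
  sc <- rep(c("s1", "s2"), c(4, 3))
  sim <- sim_chain_calls(120, rep(0.02, 6), d, scaffold_of = sc)
  er <- floor_errors(rownames(sim$calls$calls))
  intra <- estimate_intra_rates(sim$calls, er, d)
  m <- chrom_map(c("s1", "s2"), c(1L, -1L))
  f1 <- fit_map(m, sim$calls, er, d, intra)
  f2 <- fit_map(reverse_map(m), sim$calls, er, d, intra)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("inserting a distal scaffold into a correct map never increases the likelihood", {
  set.seed(36)
  d <- cross_design("F2")
  sc <- rep(sprintf("s%d", 1:6), each = 3)
  rates <- rep(0.01, 17)
  rates[c(3, 6, 9, 12, 15)] <- 0.05
  sim <- sim_chain_calls(200, rates, d, scaffold_of = sc)
  er <- floor_errors(rownames(sim$calls$calls))
  intra <- estimate_intra_rates(sim$calls, er, d)
  true_map <- chrom_map(sprintf("s%d", 1:6))
  ll_true <- fit_map(true_map, sim$calls, er, d, intra)$loglik
  set.seed(37)
  for (k in 1:20) {
    i <- sample(1:6, 1)
    j <- sample(setdiff(1:6, c(i - 1, i, i + 1)), 1)
    ord <- setdiff(1:6, i)
    at <- which(ord == j)
    ord <- append(ord, i, after = at)
    ll_bad <- fit_map(chrom_map(sprintf("s%d", ord)), sim$calls, er, d, intra)$loglik
    expect_lte(ll_bad, ll_true + 1e-6)
  }
})

test_that("posteriors from the final fit are normalized and confident on clean data", {
  set.seed(38)
  d <- cross_design("F2")
  sim <- sim_chain_calls(60, rep(0.01, 9), d)
  er <- floor_errors(rownames(sim$calls$calls))
  intra <- estimate_intra_rates(sim$calls, er, d)
  fit <- finalize_map(chrom_map("s1"), sim$calls, er, d, intra)
  expect_equal(dim(fit$posterior), c(60L, 3L, 10L))
  sums <- apply(fit$posterior, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  hc <- hard_calls(fit$posterior)
  agree <- mean(hc == c("AA", "AB", "BB")[sim$genotypes], na.rm = TRUE)
  expect_gt(agree, 0.99)
})

test_that("interval rates sum the flanking gaps over the midpoint-to-midpoint span", {
  d <- cross_design("F2")
  gc <- geno_calls(matrix(2L, 4, 3), define_windows(c(s1 = 3e5)))
  er <- floor_errors(rownames(gc$calls))
  fit <- fit_map(chrom_map("s1"), gc, er, d,
                 intra = tibble::tibble(scaffold = "s1", gap = 1:2, r = 0.005),
                 mode = "junction")
  iv <- extract_interval_rates(fit)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$interval_start, 5e4)
  expect_equal(iv$interval_end, 2.5e5)
  expect_equal(iv$rate_cm_per_mb, 2 * haldane_cm(0.005) / 0.2, tolerance = 1e-10)
  # near-linearity at small r: doubling both flanks doubles the rate
  fit2 <- fit_map(chrom_map("s1"), gc, er, d,
                  intra = tibble::tibble(scaffold = "s1", gap = 1:2, r = 0.01),
                  mode = "junction")
  iv2 <- extract_interval_rates(fit2)
  expect_equal(iv2$rate_cm_per_mb / iv$rate_cm_per_mb, 2, tolerance = 0.01)
  # two-marker scaffolds yield no interior intervals
  gc2 <- geno_calls(matrix(2L, 4, 2), define_windows(c(s1 = 2e5)))
  fit3 <- fit_map(chrom_map("s1"), gc2, er, d,
                  intra = tibble::tibble(scaffold = "s1", gap = 1, r = 0.005),
                  mode = "junction")
  expect_equal(nrow(extract_interval_rates(fit3)), 0L)
  # exclusion masks drop named markers
  expect_equal(nrow(extract_interval_rates(fit, exclude = iv$marker)), 0L)
})

test_that("cross-weighted consensus standardizes by map length and honors weights", {
  rates <- tibble::tibble(
    cross = rep(c("c1", "c2", "c3"), each = 2),
    marker = rep(c("m1", "m2"), 3),
    rate_cm_per_mb = c(4, 8, 2, 4, 6, 12))
  lens <- c(c1 = 100, c2 = 50, c3 = 150)
  w <- tibble::tibble(cross = c("c1", "c2", "c3"), weight = c(1, 0.9, 0.4))
  res <- weighted_mean_rates(rates, w, lens)
  expect_equal(res$consensus_rate[res$marker == "m1"], 0.04, tolerance = 1e-12)
  expect_equal(res$consensus_rate[res$marker == "m2"], 0.08, tolerance = 1e-12)
  # single-cross interval passes through
  solo <- weighted_mean_rates(rates[1, ], w, lens)
  expect_equal(solo$consensus_rate, 4 / 100)
  expect_equal(solo$n_crosses, 1L)
})
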