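# Linkage-group assignment, map imposition (delta lnLk), structural-variant
# screens, hard calls, and file round-trips.

test_that("end matching separates chromosomes and links within them", {
  set.seed(51)
  d <- cross_design("F2")
  # two chromosomes simulated independently, 3 scaffolds each
  sim1 <- sim_chain_calls(200, c(rep(0.01, 2), 0.05, rep(0.01, 2), 0.05, rep(0.01, 2)),
                          d, scaffold_of = rep(c("c1s1", "c1s2", "c1s3"), each = 3))
  sim2 <- sim_chain_calls(200, c(rep(0.01, 2), 0.05, rep(0.01, 2), 0.05, rep(0.01, 2)),
                          d, scaffold_of = rep(c("c2s1", "c2s2", "c2s3"), each = 3))
  joint <- geno_calls(cbind(sim1$calls$calls, sim2$calls$calls),
                      dplyr::bind_rows(sim1$calls$markers, sim2$calls$markers))
  lg <- assign_linkage_groups(joint, d)
  expect_equal(dplyr::n_distinct(lg$group), 2L)
  expect_equal(dplyr::n_distinct(lg$group[startsWith(lg$scaffold, "c1")]), 1L)
  expect_equal(dplyr::n_distinct(lg$group[startsWith(lg$scaffold, "c2")]), 1L)
  # unlinked pair: two-point estimate near 0.5, never joined
  tp <- two_point_r(sim1$calls$calls[, 1], sim2$calls$calls[, 1], d)
  expect_gt(tp$r, 0.35)
  # single scaffold forms a single group
  solo <- assign_linkage_groups(sim1$calls, d)
  expect_equal(dplyr::n_distinct(solo$group), 1L)
})

test_that("imposing a map on its own cross gives delta zero; flips of tiny scaffolds too", {
  set.seed(52)
  d <- cross_design("F2")
  sc <- c(rep("s1", 4), "s2", rep("s3", 4))
  sim <- sim_chain_calls(150, rep(0.02, 8), d, scaffold_of = sc)
  er <- floor_errors(rownames(sim$calls$calls))
  m <- chrom_map(c("s1", "s2", "s3"))
  self <- delta_loglik(sim$calls, er, d, m, m)
  expect_lt(abs(self$delta), 1e-6)
  # a single-marker-scaffold flip changes nothing observable
  m_flip <- chrom_map(c("s1", "s2", "s3"), c(1L, -1L, 1L))
  fl <- delta_loglik(sim$calls, er, d, m, m_flip)
  expect_lt(abs(fl$delta), 1e-6)
  expect_error(delta_loglik(sim$calls, er, d, m, chrom_map("zz")), "50%")
})

test_that("a simulated inversion yields positive delta in both directions", {
  set.seed(53)
  d <- cross_design("F2")
  scs <- sprintf("s%d", 1:5)
  sc <- rep(scs, each = 3)
  rates <- rep(0.02, 14)
  map_a <- chrom_map(scs)
  # cross B's genome has scaffolds 2-4 inverted relative to A
  map_b <- chrom_map(c("s1", "s4", "s3", "s2", "s5"),
                     c(1L, -1L, -1L, -1L, 1L))
  sim_a <- sim_chain_calls(200, rates, d, scaffold_of = sc)
  # simulate B on its own arrangement: same chain, markers relabelled so that
  # B's physical order is map_b
  sim_b <- sim_chain_calls(200, rates, d, scaffold_of = sc)
  er <- floor_errors(rownames(sim_a$calls$calls))
  # reorder B's columns so its data are expressed in A's marker frame
  perm <- unlist(lapply(c("s1", "s4", "s3", "s2", "s5"), function(s) {
    ix <- which(sim_b$calls$markers$scaffold == s)
    if (s %in% c("s4", "s3", "s2")) rev(ix) else ix
  }))
  mk_b <- sim_b$calls$markers
  calls_b <- geno_calls(sim_b$calls$calls[, order(perm)],
                        mk_b)
  da <- delta_loglik(sim_a$calls, er, d, map_a, map_b)
  db <- delta_loglik(calls_b, er, d, map_b, map_a)
  expect_gt(da$delta, 20)
  expect_gt(db$delta, 20)
  # pairwise matrix: 2 crosses -> 2 ordered records, positive total
  pr <- pairwise_delta(list(
    A = list(calls = sim_a$calls, errors = er, design = d, map = map_a),
    B = list(calls = calls_b, errors = er, design = d, map = map_b)))
  expect_equal(nrow(pr$pairs), 2L)
  expect_gt(pr$total, 0)
})

test_that("suppression regions are detected against recombining crosses", {
  set.seed(54)
  d <- cross_design("F2")
  M <- 40
  base <- rep(0.008, M - 1)
  supp <- base; supp[10:24] <- 1e-6 # 15-marker suppressed block
  sim_n <- sim_chain_calls(200, base, d)
  sim_s <- sim_chain_calls(200, supp, d)
  er <- floor_errors(rownames(sim_n$calls$calls))
  intra_n <- estimate_intra_rates(sim_n$calls, er, d)
  intra_s <- estimate_intra_rates(sim_s$calls, er, d)
  m <- chrom_map("s1")
  fit_n <- fit_map(m, sim_n$calls, er, d, intra_n, mode = "full")
  fit_s <- fit_map(m, sim_s$calls, er, d, intra_s, mode = "full")
  reg <- detect_suppression(list(norm = fit_n, supp = fit_s))
  expect_gte(nrow(reg), 1L)
  expect_true(all(reg$suppressed_in == "supp"))
  # all crosses recombining: nothing reported
  reg0 <- detect_suppression(list(a = fit_n, b = fit_n))
  expect_equal(nrow(reg0), 0L)
  # degenerate threshold: empty
  reg_z <- detect_suppression(list(norm = fit_n, supp = fit_s),
                              suppressed_cm = 0)
  expect_equal(nrow(reg_z), 0L)
})

test_that("order-reversal detection is exact on constructed instances", {
  a <- chrom_map(sprintf("s%d", 1:8))
  b <- a
  blk <- 3:6
  b$scaffold[blk] <- rev(b$scaffold[blk])
  b$orientation[blk] <- -b$orientation[blk]
  hits <- detect_reversal(a, b)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start_a, 3L)
  expect_equal(hits$end_a, 6L)
  expect_equal(hits$scaffolds, "s3,s4,s5,s6")
  expect_equal(nrow(detect_reversal(a, a)), 0L)
  # a full-map reversal is map-equivalent: canonicalized away
  expect_equal(nrow(detect_reversal(a, reverse_map(a))), 0L)
})

test_that("hard calls apply the strict posterior cutoff", {
  expect_equal(hard_calls(c(0.99, 0.01, 0.00)), "AA")
  expect_true(is.na(hard_calls(c(0.60, 0.35, 0.05))))
  expect_true(is.na(hard_calls(c(0.95, 0.05, 0.00)))) # boundary: strict >
  arr <- array(c(0.99, 0.2, 0.005, 0.5, 0.005, 0.3), c(2, 3, 1),
               dimnames = list(c("i1", "i2"), c("AA", "AB", "BB"), "m1"))
  hc <- hard_calls(arr)
  expect_equal(hc["i1", "m1"], "AA")
  expect_true(is.na(hc["i2", "m1"]))
})

test_that("every tabular format round-trips and malformed input names the line", {
  tmp <- withr::local_tempdir()
  counts <- tibble::tibble(scaffold = c("s1", "s1", "s2"), pos = c(10, 900, 5),
                           individual = c("a", "b", "a"),
                           count_A = c(3L, 0L, 2L), count_B = c(0L, 4L, 2L))
  p <- file.path(tmp, "counts.tsv")
  write_read_counts(counts, p)
  expect_equal(read_read_counts(p), counts, ignore_attr = TRUE)

  w <- define_windows(c(s1 = 2.5e5))
  gc <- geno_calls(matrix(c("AA", "AB", "NN", "BB", "AB", "AA"), 2, 3,
                          dimnames = list(c("a", "b"), NULL)), w)
  pc <- file.path(tmp, "calls.tsv")
  write_call_matrix(gc, pc)
  gc2 <- read_call_matrix(pc)
  expect_equal(gc2$calls, gc$calls)
  expect_equal(gc2$markers$scaffold, gc$markers$scaffold)
  bad <- readLines(pc)
  bad[2] <- sub("AA", "XX", bad[2])
  writeLines(bad, pc)
  expect_error(read_call_matrix(pc), "XX")

  d <- cross_design("F2")
  sim <- sim_chain_calls(30, c(0.02, 0.05), d)
  er <- floor_errors(rownames(sim$calls$calls))
  fit <- finalize_map(chrom_map("s1"), sim$calls, er, d,
                      tibble::tibble(scaffold = "s1", gap = 1:2, r = 0.02))
  pm <- file.path(tmp, "map.tsv")
  write_map(fit, pm)
  m2 <- read_map(pm)
  expect_equal(m2$scaffold, fit$map$scaffold)
  expect_equal(attr(m2, "loglik"), fit$loglik, tolerance = 1e-9)
  # cumulative cM recomputable from the per-gap column
  tb <- attr(m2, "table")
  expect_equal(tb$cum_cm, cumsum(c(0, head(tb$cm_next, -1))), tolerance = 1e-8)

  pp <- file.path(tmp, "post.tsv")
  write_posteriors(fit$posterior, pp)
  post2 <- read_posteriors(pp)
  expect_equal(nrow(post2), 30L * 3L)
  expect_equal(max(abs(post2$p_AA + post2$p_AB + post2$p_BB - 1)), 0,
               tolerance = 1e-6)

  dj <- file.path(tmp, "delta.json")
  rec <- tibble::tibble(home = "A", away = "B", loglik_own = -10.5,
                        loglik_imposed = -12.25, delta = 1.75, n_scaffolds = 3L)
  write_delta_json(rec, dj)
  expect_equal(read_delta_json(dj), rec, ignore_attr = TRUE)

  cfgp <- file.path(tmp, "config.yaml")
  write_config(list(window_size = 1e5, min_depth = 6), cfgp)
  cfg <- read_config(cfgp)
  expect_equal(cfg$window_size, 1e5)
  expect_equal(cfg$schema_version, 1L)

  fa <- file.path(tmp, "scaffolds.fa")
  writeLines(c(">sA some description", "ACGTACGTAC", "GGATC",
               ">sB", "TTTT"), fa)
  lens <- scaffold_lengths_from_fasta(fa)
  expect_equal(lens$scaffold, c("sA", "sB"))
  expect_equal(lens$length, c(15L, 4L))
})
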