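# Mapping-population simulator: tag placement, gametes, designs, reads,
# fracturing, scrambling.

test_that("tag placement respects spacing, density and degenerate lengths", {
  set.seed(1)
  tags <- place_tags(10000, density = 1)
  expect_lte(length(tags), 10)
  expect_true(all(diff(tags) >= 1000))
  expect_equal(length(place_tags(1000, density = 1)), 1L)
  expect_error(place_tags(0, 1), "positive")
  expect_error(place_tags(1e5, 2), "density")
  # mean count over seeds within 10% of density * length / 1000
  counts <- vapply(1:100, function(i) length(place_tags(1e6, 0.5)), 0L)
  expect_lt(abs(mean(counts) - 500) / 500, 0.10)
  expect_true(all(vapply(1:20, function(i) min(diff(place_tags(1e6, 0.9))), 0) >= 1000))
})

test_that("non-recombining gametes are constant; recombinants follow Haldane", {
  set.seed(2)
  m <- uniform_recomb_map(1e6, 10) # 10 cM over 1 Mb
  tags <- c(0, 1e6)
  g <- simulate_gametes(m, tags, n = 2000, recombining = FALSE)
  expect_true(all(g[, 1] == g[, 2]))
  expect_gt(mean(g[, 1]), 0.45) # all-A / all-B equiprobable
  expect_lt(mean(g[, 1]), 0.55)
  # two tags 10 cM apart: recombinant fraction ~ (1 - exp(-0.2))/2
  g <- simulate_gametes(m, tags, n = 10000, recombining = TRUE)
  rf <- mean(g[, 1] != g[, 2])
  r_true <- (1 - exp(-0.2)) / 2
  se <- sqrt(r_true * (1 - r_true) / 10000)
  expect_lt(abs(rf - r_true), 3 * se)
  # zero genetic distance: labels always identical
  m0 <- recomb_map(c(0, 1e6), c(0, 0))
  g0 <- simulate_gametes(m0, tags, n = 500)
  expect_true(all(g0[, 1] == g0[, 2]))
  expect_error(simulate_gametes(m, c(0, 2e6), 5), "range")
})

test_that("F2 genotype marginals are Mendelian and achiasmatic fathers never recombine", {
  set.seed(3)
  m <- uniform_recomb_map(2e6, 5)
  tags <- place_tags(2e6, 0.1)
  cfg <- sim_config("F2", n_individuals = 10000, male_achiasmatic = TRUE)
  cr <- simulate_population(cfg, m, tags)
  # paternal contribution non-recombinant in every individual
  expect_true(all(cr$paternal == cr$paternal[, 1]))
  # single-tag marginals ~ 1:2:1 (chi-square not rejected at alpha = 0.001)
  g <- cr$genotypes[, 1]
  obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  stat <- sum((obs - 10000 * c(.25, .5, .25))^2 / (10000 * c(.25, .5, .25)))
  expect_gt(pchisq(stat, 2, lower.tail = FALSE), 0.001)
})

test_that("F3 and RIL heterozygosity decay as 0.5^generations", {
  set.seed(4)
  m <- uniform_recomb_map(1e6, 5)
  tags <- c(5e5)
  cfg3 <- sim_config("F3", n_individuals = 20000)
  h3 <- mean(simulate_population(cfg3, m, tags)$genotypes == 1)
  expect_lt(abs(h3 - 0.25), 3 * sqrt(0.25 * 0.75 / 20000))
  cfg_r <- sim_config("RIL", n_individuals = 60000, ril_generations = 8)
  hr <- mean(simulate_population(cfg_r, m, tags)$genotypes == 1)
  p <- 0.5^8
  expect_lt(abs(hr - p), 4 * sqrt(p * (1 - p) / 60000))
})

test_that("read sampling conserves depth and has the right allele fractions", {
  set.seed(5)
  m <- uniform_recomb_map(1e6, 5)
  tags <- place_tags(1e6, 0.2)
  cfg <- sim_config("F2", n_individuals = 60, mean_depth = 3, seq_error = 0)
  cr <- simulate_population(cfg, m, tags)
  counts <- sample_reads(cr, tags, cfg)
  expect_true(all(counts$count_A + counts$count_B > 0))
  expect_true(all(counts$count_A >= 0 & counts$count_B >= 0))
  # genotype AA with zero sequencing error emits only A reads
  gtab <- tibble::tibble(individual = rep(rownames(cr$genotypes) %||%
                                            sprintf("ind%03d", 1:60), ncol(cr$genotypes)),
                         pos = rep(tags, each = 60),
                         geno = as.vector(cr$genotypes))
  j <- dplyr::inner_join(counts, gtab, by = c("individual", "pos"))
  expect_true(all(j$count_B[j$geno == 0] == 0))
  expect_true(all(j$count_A[j$geno == 2] == 0))
  # heterozygote mean A fraction ~ 0.5
  het <- j[j$geno == 1, ]
  expect_lt(abs(sum(het$count_A) / sum(het$count_A + het$count_B) - 0.5), 0.02)
  # fixed-depth mode
  cfg_f <- sim_config("F2", n_individuals = 10, mean_depth = 7,
                      depth_dispersion = Inf, seq_error = 0)
  cr_f <- simulate_population(cfg_f, m, tags)
  counts_f <- sample_reads(cr_f, tags, cfg_f)
  expect_true(all(counts_f$count_A + counts_f$count_B == 7))
})

test_that("extreme allele dispersion concentrates heterozygote reads on one parent", {
  set.seed(6)
  cfg <- sim_config("F2", n_individuals = 1, mean_depth = 20,
                    depth_dispersion = Inf, seq_error = 0,
                    allele_dispersion = 0.999)
  geno <- matrix(1L, 1, 2000) # all AB
  counts <- sample_reads(geno, seq(1, 2000) * 1000, cfg)
  extreme <- mean(counts$count_A == 0 | counts$count_B == 0)
  expect_gt(extreme, 0.95)
})

test_that("fracturing partitions tags without reordering and rebases coordinates", {
  set.seed(7)
  tags <- place_tags(5e6, 0.3)
  fr <- fracture_genome(tags, 30, 5e6)
  expect_equal(nrow(fr$scaffolds), 31L)
  expect_true(all(fr$scaffolds$n_tags >= 1))
  expect_true(all(fr$tags$pos >= 0))
  # concatenating scaffolds in true order reproduces the original tag order
  expect_equal(fr$tags$global_pos, tags)
  expect_equal(fr$tags$pos + fr$scaffolds$start[match(fr$tags$scaffold,
                                                      fr$scaffolds$scaffold)],
               tags)
  # zero breaks: single scaffold identical to input
  fr0 <- fracture_genome(tags, 0, 5e6)
  expect_equal(nrow(fr0$scaffolds), 1L)
  expect_equal(fr0$tags$pos, tags)
  expect_error(fracture_genome(c(100, 2000), 5, 1e4), "breaks")
})

test_that("scrambling is uniform over permutations and supports no-op mode", {
  base <- chrom_map(sprintf("s%02d", 1:31))
  set.seed(8)
  fixed <- vapply(1:100, function(i) {
    attr(scramble_map(base), "n_fixed")
  }, 0L)
  # expected fixed points of a uniform permutation = 1 (fraction 1/31)
  expect_lt(abs(mean(fixed) - 1), 0.35)
  same <- scramble_map(base, identity = TRUE)
  expect_identical(same$scaffold, base$scaffold)
  one <- chrom_map("sA")
  s1 <- scramble_map(one)
  expect_equal(s1$scaffold, "sA") # only orientation may change
})

test_that("simulation is fully deterministic given seed and config", {
  run <- function() {
    sim <- simulate_mapping_experiment(seed = 99, n_individuals = 20,
                                       chrom_length_bp = 2e6, tag_density = 0.2,
                                       n_breaks = 4)
    sim[c("counts", "true_map", "input_map", "scaffold_lengths")]
  }
  expect_identical(run(), run())
})
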