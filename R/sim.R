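#' Recombination maps on physical coordinates
#'
#' A recombination map pairs ascending physical positions (bp) with
#' non-decreasing cumulative genetic distance (Morgans), anchored at 0.
#' `uniform_recomb_map()` builds the constant-rate map used when
#' recombination is taken proportional to physical distance (the
#' genomic-average convention of 5.0 cM/Mb for F2 populations and
#' 10.0 cM/Mb for F3/RIL populations). `centromeric_recomb_map()` builds a
#' smooth map with a Gaussian dip in rate around the chromosome midpoint,
#' emulating pericentromeric recombination suppression.
#'
#' @param positions Ascending physical coordinates (bp), starting anywhere.
#' @param cum_morgans Non-decreasing cumulative genetic distance (Morgans),
#'   first element 0.
#' @return A tibble of class `recomb_map` with columns `pos`, `cum_m`.
#' @export
recomb_map <- function(positions, cum_morgans) {
  if (length(positions) < 2 || any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing (>= 2 points)", call. = FALSE)
  }
  if (cum_morgans[1] != 0 || any(diff(cum_morgans) < 0)) {
    stop("cumulative genetic distance must start at 0 and be non-decreasing",
         call. = FALSE)
  }
  structure(tibble::tibble(pos = as.numeric(positions),
                           cum_m = as.numeric(cum_morgans)),
            class = c("recomb_map", "tbl_df", "tbl", "data.frame"))
}

#' @param length_bp Chromosome length in bp.
#' @param rate_cm_per_mb Uniform recombination rate.
#' @rdname recomb_map
#' @export
uniform_recomb_map <- function(length_bp, rate_cm_per_mb) {
  stopifnot(length_bp > 0, rate_cm_per_mb >= 0)
  recomb_map(c(0, length_bp), c(0, length_bp / 1e6 * rate_cm_per_mb / 100))
}

#' @param total_morgans Total genetic length of the chromosome (Morgans).
#' @param suppression Fractional rate reduction at the dip centre (0-1).
#' @param width_frac Gaussian dip width as a fraction of chromosome length.
#' @rdname recomb_map
#' @export
centromeric_recomb_map <- function(length_bp, total_morgans = 1,
                                   suppression = 0.9, width_frac = 0.12) {
  stopifnot(length_bp > 0, total_morgans >= 0,
            suppression >= 0, suppression <= 1)
  x <- seq(0, length_bp, length.out = 401)
  dens <- 1 - suppression * exp(-((x - length_bp / 2) / (width_frac * length_bp))^2)
  cum <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(x)))
  cum <- cum / cum[length(cum)] * total_morgans
  recomb_map(x, cum)
}

#' Cumulative genetic position of physical coordinates
#'
#' Linear interpolation of the map; positions outside the mapped range are
#' rejected.
#'
#' @param map A [recomb_map()].
#' @param pos Physical coordinates (bp).
#' @return Cumulative genetic distance in Morgans.
#' @export
map_gendist <- function(map, pos) {
  if (any(pos < min(map$pos)) || any(pos > max(map$pos))) {
    stop("position outside the recombination map range", call. = FALSE)
  }
  stats::approx(map$pos, map$cum_m, xout = pos)$y
}

#' Simulation configuration for a mapping population
#'
#' Defaults emulate multiplexed shotgun genotyping (MSG) sparsity: mean read
#' depth 2 per tag per individual with negative-binomial dispersion 1, and a
#' small per-read miscall probability.
#'
#' @param design `"F2"`, `"F3"` or `"RIL"`.
#' @param n_individuals Number of recombinant individuals.
#' @param mean_depth Expected reads per tag per individual.
#' @param depth_dispersion Negative-binomial size parameter; `Inf` gives
#'   fixed depth `round(mean_depth)` (exact-depth emulation mode).
#' @param seq_error Per-read miscall probability (in `[0, 0.5)`).
#' @param allele_dispersion Beta-binomial intra-class correlation for allele
#'   sampling (0 = binomial). Positive values reproduce the heterozygote
#'   allele-dropout seen in real MSG libraries.
#' @param male_achiasmatic If `TRUE`, the paternal F2 gamete is formed
#'   without recombination (Drosophila-style achiasmatic male meiosis).
#' @param ril_generations Selfing generations from the F1 for RIL designs.
#' @param seed Optional RNG seed; set for full determinism.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(design = c("F2", "F3", "RIL"), n_individuals = 200L,
                       mean_depth = 2, depth_dispersion = 1, seq_error = 0.005,
                       allele_dispersion = 0, male_achiasmatic = FALSE,
                       ril_generations = 8L, seed = NULL) {
  design <- match.arg(design)
  stopifnot(n_individuals >= 1, mean_depth >= 0,
            seq_error >= 0, seq_error < 0.5,
            allele_dispersion >= 0, allele_dispersion < 1)
  structure(list(design = design, n_individuals = as.integer(n_individuals),
                 mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 seq_error = seq_error, allele_dispersion = allele_dispersion,
                 male_achiasmatic = isTRUE(male_achiasmatic),
                 ril_generations = as.integer(ril_generations), seed = seed),
            class = "sim_config")
}

#' Place RAD-tags along a chromosome
#'
#' Tag positions follow a hard-core renewal process: inter-tag gaps are
#' 1 kb plus an exponential excess, so spacing is always at least 1 kb (at
#' most one tag per kb) while the expected count is `density *
#' chrom_length_bp / 1000`. At `density = 1` the process degenerates to a
#' deterministic 1 kb lattice.
#'
#' @param chrom_length_bp Chromosome length (bp, positive).
#' @param density Tags per kb, in `(0, 1]`.
#' @return Integer-valued numeric vector of strictly increasing positions.
#' @export
place_tags <- function(chrom_length_bp, density = 0.5) {
  if (chrom_length_bp <= 0) stop("chromosome length must be positive", call. = FALSE)
  if (density <= 0 || density > 1) stop("density must be in (0, 1] per kb", call. = FALSE)
  mean_gap <- 1000 / density
  n_max <- ceiling(chrom_length_bp / 1000) + 10L
  gaps <- if (density == 1) rep(1000, n_max) else
    pmax(1000, floor(1000 + stats::rexp(n_max, rate = 1 / (mean_gap - 1000))))
  pos <- cumsum(c(floor(gaps[1] / 2), gaps[-1]))
  pos[pos < chrom_length_bp]
}

# row-wise parity of cumulative switch indicators
.row_parity <- function(m) {
  if (ncol(m) == 1L) return(m %% 2L)
  t(apply(m, 1, cumsum)) %% 2L
}

#' Simulate gametes over a set of tags
#'
#' Crossovers follow a no-interference (Poisson) process on the genetic
#' scale, so the parent-switch probability between adjacent tags is the
#' Haldane transform of their genetic distance. Non-recombining gametes
#' (achiasmatic meiosis) are constant, all-A or all-B with equal
#' probability.
#'
#' @param map A [recomb_map()] covering all tags.
#' @param tags Tag positions (bp).
#' @param n Number of gametes.
#' @param recombining If `FALSE` the gamete carries a single parental
#'   haplotype throughout.
#' @return `n` x `length(tags)` integer matrix of parent labels (0 = A,
#'   1 = B).
#' @export
simulate_gametes <- function(map, tags, n = 1L, recombining = TRUE) {
  T_ <- length(tags)
  start <- matrix(stats::rbinom(n, 1, 0.5), n, 1)
  if (!recombining || T_ == 1L) {
    return(matrix(start, n, T_))
  }
  d <- map_gendist(map, tags)
  r <- (1 - exp(-2 * diff(d))) / 2
  sw <- matrix(stats::rbinom(n * (T_ - 1), 1, rep(r, each = n)), n, T_ - 1)
  .row_parity(cbind(start, sw))
}

# one gamete per individual from a diplotype (pair of haplotype matrices)
.gamete_from_pair <- function(map, tags, H1, H2) {
  n <- nrow(H1); T_ <- ncol(H1)
  strand <- simulate_gametes(map, tags, n, recombining = TRUE)
  H1 * (1L - strand) + H2 * strand
}

#' Simulate a mapping population with known truth
#'
#' Builds true genotypes at every tag for the configured design. F2
#' individuals combine a recombinant maternal gamete with a paternal gamete
#' that is achiasmatic (non-recombinant) when
#' `config$male_achiasmatic = TRUE`. F3 individuals self each F2 once; RIL
#' individuals are produced by single-seed descent with
#' `config$ril_generations` total selfing generations from the F1 (residual
#' heterozygotes are retained).
#'
#' @param config A [sim_config()].
#' @param map A [recomb_map()].
#' @param tags Tag positions from [place_tags()].
#' @return Object of class `sim_cross`: list with `genotypes` (individuals x
#'   tags; 0/1/2 = count of parent-B alleles, i.e. AA/AB/BB), the final
#'   haplotype pair (`hap1`, `hap2`), and for F2 the parental gametes
#'   (`maternal`, `paternal`).
#' @export
simulate_population <- function(config, map, tags) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_individuals
  maternal <- simulate_gametes(map, tags, n, recombining = TRUE)
  paternal <- simulate_gametes(map, tags, n,
                               recombining = !config$male_achiasmatic)
  H1 <- maternal; H2 <- paternal
  extra <- switch(config$design, F2 = 0L, F3 = 1L,
                  RIL = config$ril_generations - 1L)
  if (extra > 0L) {
    for (g in seq_len(extra)) {
      new1 <- .gamete_from_pair(map, tags, H1, H2)
      new2 <- .gamete_from_pair(map, tags, H1, H2)
      H1 <- new1; H2 <- new2
    }
  }
  structure(list(genotypes = H1 + H2, hap1 = H1, hap2 = H2,
                 maternal = maternal, paternal = paternal,
                 tags = tags, config = config),
            class = "sim_cross")
}

#' @export
print.sim_cross <- function(x, ...) {
  cat("<sim_cross> ", x$config$design, ": ", nrow(x$genotypes),
      " individuals x ", ncol(x$genotypes), " tags\n", sep = "")
  invisible(x)
}

#' Sample sequencing reads at each tag
#'
#' Per tag per individual, read depth is negative-binomial
#' (`mean_depth`, `depth_dispersion`; `Inf` dispersion = fixed depth) and
#' `count_A ~ Binomial(depth, p)` with `p = 1 - seq_error`, `0.5`,
#' `seq_error` for genotypes AA, AB, BB. With positive
#' `allele_dispersion` the success probability is drawn from a Beta
#' distribution with that intra-class correlation (beta-binomial allele
#' sampling, emulating allele dropout). Depth is conserved:
#' `count_A + count_B` equals the drawn depth always; zero-depth cells are
#' omitted from the sparse output.
#'
#' @param cross A [simulate_population()] result (or a genotype matrix).
#' @param tags Tibble with columns `scaffold`, `pos` (one row per tag), or a
#'   bare numeric position vector (single scaffold `"chr1"`).
#' @param config A [sim_config()].
#' @return Read-count tibble: `scaffold`, `pos`, `individual`, `count_A`,
#'   `count_B`.
#' @export
sample_reads <- function(cross, tags, config) {
  geno <- if (inherits(cross, "sim_cross")) cross$genotypes else cross
  if (!is.data.frame(tags)) {
    tags <- tibble::tibble(scaffold = "chr1", pos = as.numeric(tags))
  }
  n <- nrow(geno); T_ <- ncol(geno)
  stopifnot(nrow(tags) == T_)
  ncell <- n * T_
  depth <- if (is.infinite(config$depth_dispersion)) {
    rep(round(config$mean_depth), ncell)
  } else {
    stats::rnbinom(ncell, mu = config$mean_depth, size = config$depth_dispersion)
  }
  p <- c(1 - config$seq_error, 0.5, config$seq_error)[as.vector(geno) + 1L]
  if (config$allele_dispersion > 0) {
    rho <- config$allele_dispersion
    shape <- (1 - rho) / rho
    p <- stats::rbeta(ncell, p * shape, (1 - p) * shape)
  }
  count_a <- stats::rbinom(ncell, depth, p)
  keep <- depth > 0
  ind_ids <- rownames(geno) %||% sprintf("ind%03d", seq_len(n))
  tibble::tibble(
    scaffold = rep(tags$scaffold, each = n)[keep],
    pos = rep(tags$pos, each = n)[keep],
    individual = rep(ind_ids, T_)[keep],
    count_A = as.integer(count_a[keep]),
    count_B = as.integer(depth[keep] - count_a[keep]))
}

#' Fracture a chromosome into scaffolds
#'
#' Randomly chooses `n_breaks` distinct inter-tag gaps and cuts the
#' chromosome at their midpoints, producing `n_breaks + 1` scaffolds that
#' each contain at least one tag. Tags keep their order; coordinates are
#' re-based to scaffold-local (0-based). Scaffold ids are zero-padded in
#' true physical order, so the true map is simply the scaffolds in id order,
#' all forward.
#'
#' @param tags Tag positions (bp) on the intact chromosome.
#' @param n_breaks Number of breaks (< number of inter-tag gaps).
#' @param chrom_length_bp Total chromosome length.
#' @return List of class `fracture` with `scaffolds` (tibble: `scaffold`,
#'   `start`, `end`, `length`, `n_tags`), `tags` (tibble: `scaffold`, `pos`
#'   local, `global_pos`), and `true_map` (a [chrom_map()]).
#' @export
fracture_genome <- function(tags, n_breaks, chrom_length_bp) {
  T_ <- length(tags)
  if (n_breaks >= T_) {
    stop("too many breaks: need n_breaks < number of inter-tag gaps",
         call. = FALSE)
  }
  cuts <- if (n_breaks > 0) {
    gap_idx <- sort(sample.int(T_ - 1L, n_breaks))
    floor((tags[gap_idx] + tags[gap_idx + 1L]) / 2)
  } else numeric(0)
  bounds <- c(0, cuts, chrom_length_bp)
  L <- n_breaks + 1L
  ids <- sprintf("s%02d", seq_len(L))
  sc <- tibble::tibble(scaffold = ids, start = bounds[-length(bounds)],
                       end = bounds[-1])
  sc$length <- sc$end - sc$start
  which_sc <- findInterval(tags, bounds, rightmost.closed = TRUE)
  sc$n_tags <- as.integer(table(factor(which_sc, levels = seq_len(L))))
  tag_tbl <- tibble::tibble(scaffold = ids[which_sc],
                            pos = tags - sc$start[which_sc],
                            global_pos = tags)
  structure(list(scaffolds = sc, tags = tag_tbl,
                 true_map = chrom_map(ids)),
            class = "fracture")
}

#' @export
print.fracture <- function(x, ...) {
  cat("<fracture> ", nrow(x$scaffolds), " scaffolds, ",
      nrow(x$tags), " tags\n", sep = "")
  invisible(x)
}
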