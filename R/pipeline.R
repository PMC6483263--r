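#' Simulate a complete scaffold-ordering experiment
#'
#' End-to-end synthetic study with known truth, mirroring a
#' Drosophila-style benchmark: one chromosome with sparse RAD-tags (at most
#' one per kb), a smooth recombination map with pericentromeric
#' suppression, an F2 population whose males produce gametes without
#' recombination, low stochastic read depth per tag, the chromosome
#' fractured into scaffolds at random break locations, and the true
#' scaffold order scrambled to form the input map.
#'
#' @param seed RNG seed (all randomness flows from it).
#' @param n_individuals F2 individuals (default 200).
#' @param chrom_length_bp Chromosome length (default 20 Mb).
#' @param tag_density Tags per kb (default 0.25).
#' @param total_morgans Female genetic map length (default 1 Morgan).
#' @param n_breaks Random break locations (default 30, giving 31 scaffolds).
#' @param design Cross design (default `"F2"`).
#' @param male_achiasmatic Paternal gametes without recombination
#'   (default `TRUE`).
#' @param mean_depth,depth_dispersion,seq_error Read sampling parameters
#'   (defaults 2, 1, 0.005).
#' @return List: `counts` (read-count tibble), `fracture`, `true_map`,
#'   `input_map` (scrambled), `scaffold_lengths`, `recmap`, `tags`, `cross`,
#'   `config`.
#' @export
simulate_mapping_experiment <- function(seed, n_individuals = 200L,
                                        chrom_length_bp = 2e7,
                                        tag_density = 0.25,
                                        total_morgans = 1.0,
                                        n_breaks = 30L,
                                        design = "F2",
                                        male_achiasmatic = TRUE,
                                        mean_depth = 2,
                                        depth_dispersion = 1,
                                        seq_error = 0.005) {
  set.seed(seed)
  recmap <- centromeric_recomb_map(chrom_length_bp, total_morgans)
  tags <- place_tags(chrom_length_bp, tag_density)
  config <- sim_config(design = design, n_individuals = n_individuals,
                       mean_depth = mean_depth,
                       depth_dispersion = depth_dispersion,
                       seq_error = seq_error,
                       male_achiasmatic = male_achiasmatic)
  cross <- simulate_population(config, recmap, tags)
  frac <- fracture_genome(tags, n_breaks, chrom_length_bp)
  counts <- sample_reads(cross, frac$tags, config)
  list(counts = counts,
       fracture = frac,
       true_map = frac$true_map,
       input_map = scramble_map(frac$true_map),
       scaffold_lengths = tibble::tibble(scaffold = frac$scaffolds$scaffold,
                                         length = frac$scaffolds$length),
       recmap = recmap, tags = tags, cross = cross, config = config)
}

#' Run the full scaffold-ordering pipeline
#'
#' Putative window calls, per-individual error rates, intra-scaffold rate
#' MLE, then the genetic-algorithm search from `input_map`, and finally the
#' full-rate refit of the best map. Returns every intermediate so each
#' stage can be inspected.
#'
#' @param counts Read-count tibble.
#' @param scaffold_lengths Tibble (`scaffold`, `length`).
#' @param input_map Starting [chrom_map()].
#' @param design A [cross_design()] (or design string).
#' @param window_size Marker window length (default 100 kb).
#' @param thresholds [call_thresholds()].
#' @param ga [ga_config()].
#' @param seed Seed for the GA search.
#' @param finalize Also refit all rates and emit posteriors (default TRUE).
#' @return List: `calls`, `errors`, `intra`, `input_fit`, `search`
#'   (a `ga_search`), `final` (a `map_fit` or `NULL`), `improvement`.
#' @export
order_genome <- function(counts, scaffold_lengths, input_map, design = "F2",
                         window_size = 1e5, thresholds = call_thresholds(),
                         ga = ga_config(), seed = 1L, finalize = TRUE) {
  if (is.character(design)) design <- cross_design(design)
  windows <- define_windows(scaffold_lengths, window_size)
  calls <- build_call_matrix(counts, windows, thresholds)
  errors <- estimate_error_rates(calls, design)
  intra <- estimate_intra_rates(calls, errors, design)
  input_fit <- fit_map(input_map, calls, errors, design, intra,
                       mode = "junction")
  search <- order_scaffolds(input_map, calls, errors, design, intra,
                            config = ga, seed = seed)
  final <- if (finalize) {
    finalize_map(search$best_map, calls, errors, design, intra)
  }
  list(calls = calls, errors = errors, intra = intra,
       input_fit = input_fit, search = search, final = final,
       improvement = search$loglik - input_fit$loglik)
}
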