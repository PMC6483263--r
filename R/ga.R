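#' Genetic-algorithm configuration
#'
#' Only elitism (`E = 4`) and rank-based selection are fixed conventions;
#' population size, operator probabilities and stopping rules are sized for
#' desk-scale convergence and are all tunable here.
#'
#' @param pop_size Population size `N`.
#' @param elitism Number of best maps copied unchanged each generation.
#' @param p_crossover Probability a child is produced by order crossover
#'   (otherwise it is a mutated copy of one parent).
#' @param p_flip,p_segment,p_relocate,p_swap Per-child probabilities of each
#'   mutation operator (orientation flip, segment reversal-and-flip, single
#'   scaffold relocation, pairwise swap).
#' @param max_generations Hard cap on generations.
#' @param stagnation Stop after this many generations without a best-fitness
#'   improvement larger than `tol`.
#' @param tol Log-likelihood improvement regarded as progress.
#' @param polish Run a greedy local search (orientation flips, adjacent
#'   swaps, short segment reversals, single-scaffold relocations) on the
#'   best map after the GA stops.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(pop_size = 48L, elitism = 4L, p_crossover = 0.7,
                      p_flip = 0.3, p_segment = 0.3, p_relocate = 0.3,
                      p_swap = 0.1, max_generations = 200L, stagnation = 20L,
                      tol = 1e-3, polish = TRUE) {
  stopifnot(elitism < pop_size, stagnation >= 1,
            p_crossover >= 0, p_flip >= 0, p_segment >= 0, p_relocate >= 0,
            p_swap >= 0)
  structure(list(pop_size = as.integer(pop_size), elitism = as.integer(elitism),
                 p_crossover = p_crossover, p_flip = p_flip,
                 p_segment = p_segment, p_relocate = p_relocate,
                 p_swap = p_swap, max_generations = as.integer(max_generations),
                 stagnation = as.integer(stagnation), tol = tol,
                 polish = isTRUE(polish)),
            class = "ga_config")
}

#' Rank-based selection of a parent pair
#'
#' Selection probability is linear in fitness rank: the best of `N`
#' candidates has weight `N`, the worst weight 1, with tied fitnesses
#' receiving their average rank. The two parents are distinct.
#'
#' @param fitness Numeric vector of fitness values.
#' @return Integer vector of two distinct indices.
#' @export
rank_select <- function(fitness) {
  w <- rank(fitness, ties.method = "average")
  sample.int(length(fitness), 2L, prob = w)
}

#' Order crossover of two maps
#'
#' A contiguous block of `parent_a`'s order (with its orientations) is kept
#' in place; the remaining scaffolds fill the other positions in
#' `parent_b`'s relative order with `parent_b`'s orientations. The child is
#' always a valid permutation of the shared scaffold set.
#'
#' @param parent_a,parent_b [chrom_map()] objects over the same scaffolds.
#' @return A [chrom_map()].
#' @export
crossover_maps <- function(parent_a, parent_b) {
  if (!setequal(parent_a$scaffold, parent_b$scaffold)) {
    stop("parents carry different scaffold sets", call. = FALSE)
  }
  L <- length(parent_a$scaffold)
  if (L == 1L) return(parent_a)
  ij <- sort(sample.int(L, 2L))
  block <- ij[1]:ij[2]
  child_sc <- character(L); child_or <- integer(L)
  child_sc[block] <- parent_a$scaffold[block]
  child_or[block] <- parent_a$orientation[block]
  fill <- !(parent_b$scaffold %in% child_sc[block])
  child_sc[-block] <- parent_b$scaffold[fill]
  child_or[-block] <- parent_b$orientation[fill]
  chrom_map(child_sc, child_or)
}

#' Mutate a map
#'
#' Applies each configured operator independently with its probability; if
#' none fires (and `force` is set) one operator is forced so the child
#' differs from its parent. Segment reversal reverses the scaffold order
#' *and* flips orientations within the segment -- an in-map inversion -- so
#' applying the same reversal twice is the identity.
#'
#' @param map A [chrom_map()].
#' @param config A [ga_config()].
#' @param force Guarantee at least one operator is applied.
#' @return A mutated [chrom_map()].
#' @export
mutate_map <- function(map, config = ga_config(), force = FALSE) {
  L <- length(map$scaffold)
  sc <- map$scaffold; or <- map$orientation
  applied <- FALSE
  ops <- c("flip", "segment", "relocate", "swap")
  probs <- c(config$p_flip, config$p_segment, config$p_relocate, config$p_swap)
  todo <- stats::runif(4) < probs
  if (force && !any(todo)) {
    todo[sample.int(4L, 1L, prob = pmax(probs, 1e-9))] <- TRUE
  }
  if (todo[1]) { # orientation flip
    i <- sample.int(L, 1L); or[i] <- -or[i]; applied <- TRUE
  }
  if (todo[2] && L > 1L) { # segment reversal + flip
    ij <- sort(sample.int(L, 2L)); b <- ij[1]:ij[2]
    sc[b] <- rev(sc[b]); or[b] <- -rev(or[b]); applied <- TRUE
  }
  if (todo[3] && L > 1L) { # relocate one scaffold
    i <- sample.int(L, 1L)
    j <- sample.int(L - 1L, 1L)
    s1 <- sc[i]; o1 <- or[i]
    sc <- sc[-i]; or <- or[-i]
    sc <- append(sc, s1, after = j - 1L)
    or <- append(or, o1, after = j - 1L)
    applied <- TRUE
  }
  if (todo[4] && L > 1L) { # pairwise swap
    ij <- sample.int(L, 2L)
    sc[ij] <- sc[rev(ij)]; or[ij] <- or[rev(ij)]
    applied <- TRUE
  }
  chrom_map(sc, or)
}

#' Initial GA population
#'
#' The starting map verbatim at index 1 plus `pop_size - 1` mutated
#' variants.
#'
#' @param start_map A [chrom_map()].
#' @param config A [ga_config()].
#' @return List of [chrom_map()]s of length `config$pop_size`.
#' @export
init_population <- function(start_map, config = ga_config()) {
  c(list(start_map),
    lapply(seq_len(config$pop_size - 1L), function(i)
      mutate_map(start_map, config, force = TRUE)))
}

# fitness evaluation memoized on the canonical map signature; a map and its
# full reversal share one entry
.make_evaluator <- function(ctx, intra_list, ...) {
  cache <- new.env(parent = emptyenv())
  stats <- new.env(parent = emptyenv())
  stats$evals <- 0L; stats$hits <- 0L
  if (is.null(intra_list)) {
    intra_list <- .physical_intra_list(ctx$markers,
                                       .default_fixed_rate(ctx$design))
  }
  ops <- .scaffold_ops(ctx, intra_list)
  fn <- function(map) {
    key <- map_signature(map)
    hit <- cache[[key]]
    if (!is.null(hit)) {
      stats$hits <- stats$hits + 1L
      return(hit)
    }
    stats$evals <- stats$evals + 1L
    fit <- tryCatch(
      .fit_map_ctx(ctx, map, intra_list, mode = "junction", ops = ops, ...),
      error = function(e) NULL)
    val <- if (is.null(fit)) list(loglik = -Inf, fit = NULL)
    else list(loglik = fit$loglik, fit = fit)
    cache[[key]] <- val
    val
  }
  list(evaluate = fn, cache = cache, stats = stats)
}

#' Search scaffold order/orientation space by genetic algorithm
#'
#' Maximizes the chain log-likelihood of the map over orders and
#' orientations. Each generation keeps the best `elitism` maps unchanged and
#' fills the rest with children of rank-selected parents (order crossover
#' then mutation); fitness is the log-likelihood after optimizing the
#' inter-scaffold junction rates with intra-scaffold rates held fixed.
#' Fitness evaluations are memoized on the canonical map signature, so a map
#' and its full reversal cost one optimization. Elitism guarantees the best
#' fitness trace is non-decreasing. Ties between equal-likelihood maps are
#' broken by the lexicographically smallest canonical signature, making the
#' result deterministic for a given seed.
#'
#' @param start_map A [chrom_map()] (for example from [scramble_map()] or a
#'   draft assembly order).
#' @param calls A [geno_calls()] object.
#' @param errors Error-rate tibble ([estimate_error_rates()]).
#' @param design A [cross_design()].
#' @param intra Intra-scaffold rate tibble ([estimate_intra_rates()]).
#' @param config A [ga_config()].
#' @param seed Optional RNG seed.
#' @param quiet Suppress per-generation progress.
#' @return Object of class `ga_search`: `best_map`, `best_fit` (a
#'   `map_fit`), `loglik`, `start_loglik`, `trace` (per-generation tibble),
#'   `n_evaluations`, `cache_hit_rate`.
#' @export
order_scaffolds <- function(start_map, calls, errors, design, intra,
                            config = ga_config(), seed = NULL, quiet = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- .lk_context(calls, errors, design)
  intra_list <- .intra_as_list(intra, ctx$markers)
  ev <- .make_evaluator(ctx, intra_list)
  evaluate <- ev$evaluate

  pop <- init_population(start_map, config)
  fit <- vapply(pop, function(m) evaluate(m)$loglik, 0)
  start_ll <- evaluate(start_map)$loglik

  best_ll <- -Inf; best_map <- NULL
  note_best <- function(maps, lls) {
    top <- max(lls)
    if (top > best_ll + 1e-12) {
      cand <- which(lls >= top)
      sigs <- vapply(maps[cand], map_signature, "")
      best_map <<- maps[[cand[order(sigs)[1]]]]
      best_ll <<- top
    } else if (top == best_ll && !is.null(best_map)) {
      cand <- which(lls >= top)
      sigs <- vapply(maps[cand], map_signature, "")
      if (min(sigs) < map_signature(best_map)) {
        best_map <<- maps[[cand[order(sigs)[1]]]]
      }
    }
  }
  note_best(pop, fit)

  trace <- vector("list", config$max_generations)
  last_improve <- 0L; gen <- 0L
  while (gen < config$max_generations) {
    gen <- gen + 1L
    prev_best <- best_ll
    ord <- order(fit, vapply(pop, map_signature, ""), decreasing = c(TRUE, FALSE),
                 method = "radix")
    elite <- pop[ord[seq_len(config$elitism)]]
    elite_fit <- fit[ord[seq_len(config$elitism)]]
    children <- vector("list", config$pop_size - config$elitism)
    for (k in seq_along(children)) {
      pr <- rank_select(fit)
      child <- if (stats::runif(1) < config$p_crossover) {
        crossover_maps(pop[[pr[1]]], pop[[pr[2]]])
      } else pop[[pr[1]]]
      child <- mutate_map(child, config)
      if (!is.null(ev$cache[[map_signature(child)]])) {
        child <- mutate_map(child, config, force = TRUE)
      }
      children[[k]] <- child
    }
    child_fit <- vapply(children, function(m) evaluate(m)$loglik, 0)
    pop <- c(elite, children)
    fit <- c(elite_fit, child_fit)
    note_best(pop, fit)
    stopifnot(best_ll >= prev_best) # elitism invariant
    trace[[gen]] <- tibble::tibble(
      generation = gen, best_loglik = best_ll,
      n_evaluations = ev$stats$evals, cache_hits = ev$stats$hits)
    if (best_ll > prev_best + config$tol) last_improve <- gen
    if (!quiet) message(sprintf("gen %3d  best lnLk %.3f", gen, best_ll))
    if (gen - last_improve >= config$stagnation) break
  }

  if (config$polish) {
    pol <- .polish_map(best_map, evaluate)
    if (pol$loglik > best_ll ||
        (pol$loglik == best_ll &&
         map_signature(pol$map) < map_signature(best_map))) {
      best_map <- pol$map; best_ll <- pol$loglik
    }
  }

  best <- evaluate(best_map)
  structure(list(
    best_map = canonical_map(best_map),
    best_fit = best$fit,
    loglik = best_ll,
    start_loglik = start_ll,
    improvement = best_ll - start_ll,
    trace = dplyr::bind_rows(trace[seq_len(gen)]),
    n_evaluations = ev$stats$evals,
    cache_hit_rate = ev$stats$hits / max(1L, ev$stats$hits + ev$stats$evals),
    generations = gen), class = "ga_search")
}

# greedy first-improvement local search over a small neighborhood:
# orientation flips, adjacent swaps, short segment reversals and
# single-scaffold relocations within a window
.polish_map <- function(map, evaluate, max_sweeps = 6L, reloc_window = 5L,
                        max_segment = 4L) {
  cur <- map
  cur_ll <- evaluate(cur)$loglik
  L <- length(map$scaffold)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    try_move <- function(cand) {
      ll <- evaluate(cand)$loglik
      if (ll > cur_ll + 1e-9) {
        cur <<- cand; cur_ll <<- ll; improved <<- TRUE
        TRUE
      } else FALSE
    }
    for (i in seq_len(L)) { # orientation flips
      cand <- cur; cand$orientation[i] <- -cand$orientation[i]
      try_move(chrom_map(cand$scaffold, cand$orientation))
    }
    if (L > 1L) {
      for (i in seq_len(L - 1L)) { # adjacent swaps
        sc <- cur$scaffold; or <- cur$orientation
        sc[c(i, i + 1L)] <- sc[c(i + 1L, i)]
        or[c(i, i + 1L)] <- or[c(i + 1L, i)]
        try_move(chrom_map(sc, or))
      }
      for (len in 2:min(max_segment, L)) { # short reversals (+ flips)
        for (i in seq_len(L - len + 1L)) {
          b <- i:(i + len - 1L)
          sc <- cur$scaffold; or <- cur$orientation
          sc[b] <- rev(sc[b]); or[b] <- -rev(or[b])
          try_move(chrom_map(sc, or))
        }
      }
      for (i in seq_len(L)) { # short-range relocations
        for (j in setdiff(pmax(1L, i - reloc_window):pmin(L, i + reloc_window), i)) {
          sc <- cur$scaffold; or <- cur$orientation
          s1 <- sc[i]; o1 <- or[i]
          sc <- append(sc[-i], s1, after = j - 1L)
          or <- append(or[-i], o1, after = j - 1L)
          try_move(chrom_map(sc, or))
        }
      }
    }
    if (!improved) break
  }
  list(map = cur, loglik = cur_ll)
}

#' @export
print.ga_search <- function(x, ...) {
  cat("<ga_search> ", length(x$best_map$scaffold), " scaffolds, ",
      x$generations, " generations, ", x$n_evaluations, " evaluations (",
      sprintf("%.0f%%", 100 * x$cache_hit_rate), " cache hits)\n",
      "  lnLk: ", sprintf("%.3f -> %.3f  (improvement %.1f)",
                          x$start_loglik, x$loglik, x$improvement), "\n",
      sep = "")
  invisible(x)
}

#' @export
glance.ga_search <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, start_loglik = x$start_loglik,
                 improvement = x$improvement, generations = x$generations,
                 n_evaluations = x$n_evaluations,
                 cache_hit_rate = x$cache_hit_rate)
}

#' @export
tidy.ga_search <- function(x, ...) x$trace
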