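#' Two-point recombination fraction between two markers
#'
#' Maximum-likelihood estimate of `r` from the 3x3 joint genotype table of
#' complete (non-`NN`) call pairs, under the design's two-locus transition
#' model, together with the co-segregation LOD against `r = 0.5`.
#'
#' @param g1,g2 Putative calls at the two markers (character or 0-3 codes),
#'   aligned by individual.
#' @param design A [cross_design()].
#' @return List with `r`, `lod`, `n` (jointly scored individuals).
#' @export
two_point_r <- function(g1, g2, design) {
  a <- .as_obs_codes(g1); b <- .as_obs_codes(g2)
  ok <- a != 0L & b != 0L
  n <- sum(ok)
  if (n == 0L) return(list(r = NA_real_, lod = NA_real_, n = 0L))
  tab <- matrix(0, 3, 3)
  for (i in which(ok)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1
  ll <- function(r) {
    P <- design$init * transition_matrix(design, r)
    sum(tab * log(P))
  }
  opt <- stats::optimize(ll, c(1e-6, 0.5), maximum = TRUE, tol = 1e-6)
  r_hat <- if (ll(1e-6) >= opt$objective) 1e-6 else opt$maximum
  list(r = r_hat, lod = (ll(r_hat) - ll(0.5)) / log(10), n = n)
}

#' Assign scaffolds to linkage groups by end matching
#'
#' Estimates two-point recombination fractions between the end markers
#' (first and last window) of every scaffold pair, joins ends with
#' `r < max_r`, LOD `> min_lod` and at least `min_shared` jointly scored
#' individuals, and reports the connected components as linkage groups.
#' Scaffolds whose end markers are entirely `NN` cannot be placed and are
#' returned with group `NA`.
#'
#' @param calls A [geno_calls()] object.
#' @param design A [cross_design()].
#' @param max_r Join threshold on the two-point estimate (default 0.2).
#' @param min_lod Join threshold on the LOD (default 6).
#' @param min_shared Minimum jointly scored individuals (default 20).
#' @return Tibble with columns `scaffold`, `group` (integer id or `NA`).
#' @export
assign_linkage_groups <- function(calls, design, max_r = 0.2, min_lod = 6,
                                  min_shared = 20L) {
  mk <- calls$markers
  scs <- unique(mk$scaffold)
  ends <- lapply(scs, function(sc) {
    w <- mk[mk$scaffold == sc, ]
    w <- w[order(w$index), ]
    unique(c(which(mk$marker == w$marker[1]),
             which(mk$marker == w$marker[nrow(w)])))
  })
  usable <- vapply(seq_along(scs), function(i)
    any(calls$calls[, ends[[i]], drop = FALSE] != 0L), TRUE)

  # union-find over scaffolds
  parent <- seq_along(scs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  L <- length(scs)
  if (L > 1) for (i in 1:(L - 1)) {
    if (!usable[i]) next
    for (j in (i + 1):L) {
      if (!usable[j]) next
      joined <- FALSE
      for (mi in ends[[i]]) {
        for (mj in ends[[j]]) {
          tp <- two_point_r(calls$calls[, mi], calls$calls[, mj], design)
          if (!is.na(tp$r) && tp$n >= min_shared && tp$r < max_r &&
              tp$lod > min_lod) {
            union(i, j); joined <- TRUE; break
          }
        }
        if (joined) break
      }
    }
  }
  roots <- vapply(seq_along(scs), find, 0L)
  roots[!usable] <- NA_integer_
  grp <- match(roots, sort(unique(roots[!is.na(roots)])))
  tibble::tibble(scaffold = scs, group = grp)
}

#' Impose one cross's map on another cross's data
#'
#' Refits all `L - 1 + K` recombination rates under the imposed scaffold
#' order/orientation (so the resulting log-likelihood difference reflects
#' order and orientation alone, not rate differences) and compares with the
#' data's own map refit the same way on the shared scaffold set. Scaffolds
#' present in only one map are dropped with a warning; less than 50%
#' overlap with the home map is refused.
#'
#' @param calls,errors,design The home cross's data.
#' @param map_home The home cross's optimized [chrom_map()].
#' @param map_away The imposed [chrom_map()].
#' @param intra Optional intra-rate tibble for starting values.
#' @param home,away Optional cross labels for the output record.
#' @return A one-row tibble (`home`, `away`, `loglik_own`, `loglik_imposed`,
#'   `delta`, `n_scaffolds`).
#' @export
delta_loglik <- function(calls, errors, design, map_home, map_away,
                         intra = NULL, home = "home", away = "away") {
  shared <- intersect(map_home$scaffold, map_away$scaffold)
  if (length(shared) < 0.5 * length(map_home$scaffold)) {
    stop("imposed map shares <50% of scaffolds with the home map",
         call. = FALSE)
  }
  restrict <- function(m) {
    keep <- m$scaffold %in% shared
    if (!all(keep)) {
      warning("dropping scaffolds absent from the other map: ",
              paste(m$scaffold[!keep], collapse = ", "), call. = FALSE)
    }
    chrom_map(m$scaffold[keep], m$orientation[keep])
  }
  mh <- restrict(map_home); ma <- restrict(map_away)
  keep_mk <- calls$markers$scaffold %in% shared
  sub <- geno_calls(calls$calls[, keep_mk, drop = FALSE],
                    calls$markers[keep_mk, , drop = FALSE])
  own <- fit_map(mh, sub, errors, design, intra, mode = "full")
  imp <- fit_map(ma, sub, errors, design, intra, mode = "full")
  if (own$loglik < imp$loglik - 1e-3) {
    warning(sprintf(
      "imposed map fits better than the home map (delta = %.3f): the home map search is likely under-converged",
      own$loglik - imp$loglik), call. = FALSE)
  }
  tibble::tibble(home = home, away = away,
                 loglik_own = own$loglik, loglik_imposed = imp$loglik,
                 delta = own$loglik - imp$loglik,
                 n_scaffolds = length(shared))
}

#' Pairwise map-imposition matrix across crosses
#'
#' Imposes the optimized map of every cross onto the data of every other
#' cross (all ordered pairs) and reports each ΔlnLk plus the chromosome
#' total. Large sums indicate structurally discrepant maps.
#'
#' @param crosses Named list; each element a list with components `calls`,
#'   `errors`, `design`, `map` and optionally `intra`.
#' @param ordered Use ordered pairs (default) or collapse to unordered
#'   pairs.
#' @return List with `pairs` (tibble of all records) and `total` (sum of
#'   deltas).
#' @export
pairwise_delta <- function(crosses, ordered = TRUE) {
  ids <- names(crosses)
  stopifnot(length(ids) >= 2)
  out <- list()
  for (h in ids) for (a in ids) {
    if (h == a) next
    if (!ordered && match(h, ids) > match(a, ids)) next
    ch <- crosses[[h]]
    out[[paste(h, a)]] <- delta_loglik(
      ch$calls, ch$errors, ch$design, ch$map, crosses[[a]]$map,
      intra = ch$intra, home = h, away = a)
  }
  pairs <- dplyr::bind_rows(out)
  list(pairs = pairs, total = sum(pairs$delta))
}

#' Detect regions of cross-specific recombination suppression
#'
#' Scans a reference marker ordering for maximal spans of at least
#' `min_markers` markers whose summed genetic length is below
#' `suppressed_cm` in at least one cross while exceeding `recombining_cm`
#' in at least one other -- the signature of a segregating inversion
#' (suppressed in heterokaryotypic crosses, freely recombining in
#' homokaryotypes).
#'
#' @param fits Named list of `map_fit` objects (one per cross), all covering
#'   the reference markers.
#' @param reference Name of the cross whose marker order anchors the scan
#'   (default: first).
#' @param min_markers Minimum span length in markers (default 10).
#' @param suppressed_cm Span total below this counts as suppressed
#'   (default 1 cM).
#' @param recombining_cm Span total above this counts as recombining
#'   (default 5 cM).
#' @return Tibble of regions: `start_marker`, `end_marker`, `n_markers`,
#'   `suppressed_in`, `recombining_in`, and `cm_<cross>` columns.
#' @export
detect_suppression <- function(fits, reference = names(fits)[1],
                               min_markers = 10L, suppressed_cm = 1,
                               recombining_cm = 5) {
  stopifnot(length(fits) >= 2, reference %in% names(fits))
  ref <- fits[[reference]]
  ref_markers <- ref$markers$marker
  # cumulative map position of every marker within each cross
  cum_pos <- lapply(fits, function(f) {
    cm <- c(0, cumsum(haldane_cm(pmin(f$rates, 0.5 - 1e-12))))
    stats::setNames(cm, f$markers$marker)
  })
  M <- length(ref_markers)
  if (M < min_markers || suppressed_cm <= 0) {
    return(tibble::tibble(start_marker = character(0), end_marker = character(0),
                          n_markers = integer(0), suppressed_in = character(0),
                          recombining_in = character(0)))
  }
  gap_cm <- vapply(names(fits), function(cx) {
    p <- cum_pos[[cx]][ref_markers]
    abs(diff(p))
  }, numeric(M - 1))
  regions <- list()
  for (cx in names(fits)) {
    g <- gap_cm[, cx]
    i <- 1L
    while (i <= M - 1L) {
      j <- i
      tot <- 0
      while (j <= M - 1L && tot + g[j] < suppressed_cm) {
        tot <- tot + g[j]; j <- j + 1L
      }
      # markers i .. j span j - i + 1 markers with total < suppressed_cm
      if (j - i + 1L >= min_markers) {
        others <- setdiff(names(fits), cx)
        span_cm <- vapply(others, function(o)
          sum(gap_cm[i:(j - 1L), o]), 0)
        if (any(span_cm > recombining_cm)) {
          row <- tibble::tibble(
            start_marker = ref_markers[i], end_marker = ref_markers[j],
            n_markers = j - i + 1L, suppressed_in = cx,
            recombining_in = paste(others[span_cm > recombining_cm],
                                   collapse = ","))
          for (k in names(fits)) {
            row[[paste0("cm_", k)]] <-
              if (k == cx) tot else sum(gap_cm[i:(j - 1L), k])
          }
          regions[[length(regions) + 1L]] <- row
        }
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  dplyr::bind_rows(regions)
}

#' Detect reversed scaffold blocks between two maps
#'
#' Finds maximal contiguous blocks whose scaffold order is reversed and
#' orientations flipped between two maps -- the marker-order reversal
#' expected between crosses homokaryotypic for the two arrangements of an
#' inversion. Both maps are canonicalized first, so a full-map reversal
#' (which is map-equivalent) yields no blocks.
#'
#' @param map_a,map_b [chrom_map()] objects over a shared scaffold set.
#' @param min_scaffolds Minimum reported block size (default 2).
#' @return Tibble of blocks: `start_a`, `end_a` (positions in `map_a`),
#'   `scaffolds` (comma-joined ids).
#' @export
detect_reversal <- function(map_a, map_b, min_scaffolds = 2L) {
  stopifnot(setequal(map_a$scaffold, map_b$scaffold))
  a <- map_a
  # a whole-map reversal of b is map-equivalent; compare against whichever
  # global orientation of b aligns better with a
  b1 <- map_b; b2 <- reverse_map(map_b)
  displ <- function(b) sum(abs(match(a$scaffold, b$scaffold) - seq_along(a$scaffold)))
  b <- if (displ(b2) < displ(b1)) b2 else b1
  pos_b <- match(a$scaffold, b$scaffold)
  ori_rel <- a$orientation * b$orientation[pos_b]
  L <- length(a$scaffold)
  rev_link <- if (L > 1)
    (pos_b[-1] == pos_b[-L] - 1L) & (ori_rel[-1] == -1L) & (ori_rel[-L] == -1L)
  else logical(0)
  blocks <- list()
  i <- 1L
  while (i <= L) {
    j <- i
    while (j < L && rev_link[j]) j <- j + 1L
    n_b <- j - i + 1L
    if (n_b >= min_scaffolds && n_b < L) {
      blocks[[length(blocks) + 1L]] <- tibble::tibble(
        start_a = i, end_a = j, n_scaffolds = n_b,
        scaffolds = paste(a$scaffold[i:j], collapse = ","))
    }
    i <- j + 1L
  }
  if (!length(blocks)) {
    return(tibble::tibble(start_a = integer(0), end_a = integer(0),
                          n_scaffolds = integer(0), scaffolds = character(0)))
  }
  dplyr::bind_rows(blocks)
}

#' Hard genotype calls from posteriors
#'
#' Assigns the genotype whose posterior probability strictly exceeds
#' `cutoff`, otherwise missing (`NA`). The strict inequality makes the
#' boundary case `0.95` missing at the default cutoff.
#'
#' @param posterior Individuals x 3 x markers array (as attached to a
#'   [finalize_map()] fit) or a single marker's length-3 vector.
#' @param cutoff Posterior threshold (default 0.95, strict `>`).
#' @return Character matrix (individuals x markers) with `NA` for missing,
#'   or a single character value for a vector input.
#' @export
hard_calls <- function(posterior, cutoff = 0.95) {
  states <- c("AA", "AB", "BB")
  if (is.null(dim(posterior))) {
    stopifnot(length(posterior) == 3)
    i <- which.max(posterior)
    return(if (posterior[i] > cutoff) states[i] else NA_character_)
  }
  n <- dim(posterior)[1]; M <- dim(posterior)[3]
  out <- matrix(NA_character_, n, M,
                dimnames = dimnames(posterior)[c(1, 3)])
  for (m in seq_len(M)) {
    slab <- matrix(posterior[, , m], n, 3)
    i <- max.col(slab, ties.method = "first")
    p <- slab[cbind(seq_len(n), i)]
    out[, m] <- ifelse(p > cutoff, states[i], NA_character_)
  }
  out
}
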