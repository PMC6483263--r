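#' Putative-call thresholds
#'
#' Decision rules for converting window read counts into putative genotype
#' calls. With fewer than `min_depth` reads the call is `NN`; otherwise the
#' fraction of reads matching parent A decides: strictly above `homo_frac`
#' gives `AA`, strictly below `1 - homo_frac` gives `BB`, inside the closed
#' band `[het_low, het_high]` gives `AB`, and anything else falls through to
#' `NN` (the conservative reading of the boundary cases).
#'
#' @param homo_frac Homozygote threshold (default 0.95, strict `>`).
#' @param het_low,het_high Inclusive heterozygote band (defaults 0.25, 0.75).
#' @param min_depth Minimum reads per window per individual (default 6).
#' @param window_size Window length in bp (default 100 kb).
#' @return A list of class `call_thresholds`.
#' @export
call_thresholds <- function(homo_frac = 0.95, het_low = 0.25, het_high = 0.75,
                            min_depth = 6L, window_size = 1e5) {
  stopifnot(homo_frac > 0.5, homo_frac < 1, het_low < het_high, min_depth >= 1,
            window_size >= 1)
  structure(list(homo_frac = homo_frac, het_low = het_low, het_high = het_high,
                 min_depth = as.integer(min_depth), window_size = window_size),
            class = "call_thresholds")
}

#' Partition scaffolds into window markers
#'
#' Each scaffold is cut into contiguous, non-overlapping windows of
#' `window_size` bp (0-based, half-open). The final sub-size remainder forms
#' its own marker, so a scaffold of length `L` yields `ceiling(L / size)`
#' markers whose union is exactly `[0, L)`. Set `merge_remainder_below` to a
#' positive value to merge terminal remainders shorter than that many bp into
#' the preceding window instead.
#'
#' @param scaffold_lengths A tibble with columns `scaffold`, `length`, or a
#'   named numeric vector of lengths.
#' @param window_size Window length in bp.
#' @param merge_remainder_below Merge terminal remainders shorter than this
#'   many bp into the previous window (default 0 = never).
#' @return A tibble with columns `marker`, `scaffold`, `index`, `start`, `end`.
#' @examples
#' define_windows(c(s1 = 250000))  # [0,1e5), [1e5,2e5), [2e5,2.5e5)
#' @export
define_windows <- function(scaffold_lengths, window_size = 1e5,
                           merge_remainder_below = 0) {
  if (!is.data.frame(scaffold_lengths)) {
    scaffold_lengths <- tibble::tibble(
      scaffold = names(scaffold_lengths) %||% paste0("s", seq_along(scaffold_lengths)),
      length = as.numeric(scaffold_lengths))
  }
  stopifnot(all(c("scaffold", "length") %in% names(scaffold_lengths)))
  if (any(scaffold_lengths$length <= 0)) {
    stop("zero-length scaffold", call. = FALSE)
  }
  one <- function(sc, len) {
    starts <- seq(0, len - 1, by = window_size)
    ends <- pmin(starts + window_size, len)
    if (length(starts) > 1 && merge_remainder_below > 0 &&
        (ends[length(ends)] - starts[length(starts)]) < merge_remainder_below) {
      ends <- ends[-length(ends)]
      starts <- starts[-length(starts)]
      ends[length(ends)] <- len
    }
    tibble::tibble(scaffold = sc, index = seq_along(starts),
                   start = starts, end = ends)
  }
  out <- purrr::map2_dfr(scaffold_lengths$scaffold, scaffold_lengths$length, one)
  out$marker <- sprintf("%s:%d-%d", out$scaffold, out$start, out$end)
  dplyr::select(out, "marker", "scaffold", "index", "start", "end")
}

#' Putative genotype call from window read counts
#'
#' Pure, vectorized decision rule: see [call_thresholds()] for the rule set.
#'
#' @param count_a,count_b Reads matching parent A / parent B (vectors).
#' @param thresholds A [call_thresholds()].
#' @return Character vector in `{"AA","AB","BB","NN"}`.
#' @examples
#' th <- call_thresholds()
#' call_window(20, 0, th)  # "AA"
#' call_window(19, 1, th)  # "NN" -- 0.95 fails the strict > 0.95 test
#' @export
call_window <- function(count_a, count_b, thresholds = call_thresholds()) {
  stopifnot(all(count_a >= 0), all(count_b >= 0))
  depth <- count_a + count_b
  frac <- ifelse(depth > 0, count_a / depth, NA_real_)
  out <- rep("NN", length(depth))
  ok <- depth >= thresholds$min_depth
  out[ok & frac > thresholds$homo_frac] <- "AA"
  # "< 1 - homo_frac" evaluated symmetrically (fraction of B reads) so the
  # 0.05 boundary behaves exactly like the 0.95 one
  out[ok & (1 - frac) > thresholds$homo_frac] <- "BB"
  out[ok & frac >= thresholds$het_low & frac <= thresholds$het_high] <- "AB"
  out
}

#' Putative-call matrix (individuals x window markers)
#'
#' Container for the HMM's emitted states: an integer-coded matrix of
#' putative calls plus the marker table that defines each column. Create it
#' with [build_call_matrix()] or directly from a character matrix.
#'
#' @param calls Character matrix (values `AA`, `AB`, `BB`, `NN`) or 0-3
#'   integer matrix; rows are individuals, columns markers.
#' @param markers Marker tibble as produced by [define_windows()]; one row
#'   per column of `calls`, in order.
#' @param depth Optional matrix of supporting read totals (same shape).
#' @return An object of class `geno_calls`.
#' @export
geno_calls <- function(calls, markers, depth = NULL) {
  code <- if (is.character(calls)) .code_geno(calls) else {
    storage.mode(calls) <- "integer"; calls
  }
  stopifnot(ncol(code) == nrow(markers))
  if (is.null(rownames(code))) rownames(code) <- paste0("ind", seq_len(nrow(code)))
  colnames(code) <- markers$marker
  structure(list(calls = code, markers = tibble::as_tibble(markers), depth = depth),
            class = "geno_calls")
}

#' @export
print.geno_calls <- function(x, ...) {
  cat("<geno_calls> ", nrow(x$calls), " individuals x ", ncol(x$calls),
      " markers over ", length(unique(x$markers$scaffold)), " scaffolds\n", sep = "")
  tab <- table(factor(.decode_geno(x$calls), levels = .GENO))
  cat("  calls: ", paste(sprintf("%s %.1f%%", names(tab), 100 * tab / sum(tab)),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_calls <- function(x) dim(x$calls)

#' Tidy a call matrix into long form
#'
#' @param x A [geno_calls()] object.
#' @param ... Unused.
#' @return A tibble with columns `individual`, `marker`, `scaffold`, `call`.
#' @export
tidy.geno_calls <- function(x, ...) {
  tibble::tibble(
    individual = rep(rownames(x$calls), times = ncol(x$calls)),
    marker = rep(colnames(x$calls), each = nrow(x$calls)),
    scaffold = rep(x$markers$scaffold, each = nrow(x$calls)),
    call = as.vector(.decode_geno(x$calls)))
}

#' Aggregate SNP read counts into window putative calls
#'
#' Sums `count_A`/`count_B` over all diagnostic SNPs falling in each window
#' for each individual and applies [call_window()]. SNPs whose position lies
#' outside every window of their scaffold are an error (their coordinates
#' are reported); individuals with no reads in a window are `NN`.
#'
#' @param counts Read-count table: tibble with columns `scaffold`, `pos`,
#'   `individual`, `count_A`, `count_B`.
#' @param windows Marker tibble from [define_windows()].
#' @param thresholds A [call_thresholds()].
#' @param individuals Optional character vector fixing the row set (useful
#'   when some individuals have no reads at all).
#' @return A [geno_calls()] object (with a `depth` matrix attached).
#' @export
build_call_matrix <- function(counts, windows, thresholds = call_thresholds(),
                              individuals = NULL) {
  stopifnot(all(c("scaffold", "pos", "individual", "count_A", "count_B") %in%
                  names(counts)))
  sc_win <- split(windows, windows$scaffold)
  glob_index <- stats::setNames(seq_len(nrow(windows)), windows$marker)

  counts$.win <- NA_integer_
  for (sc in names(sc_win)) {
    w <- sc_win[[sc]]
    rows <- which(counts$scaffold == sc)
    if (!length(rows)) next
    i <- findInterval(counts$pos[rows], w$start)
    bad <- i < 1 | counts$pos[rows] >= w$end[pmax(i, 1)]
    if (any(bad)) {
      b <- rows[which(bad)[1]]
      stop(sprintf("SNP outside any window: scaffold %s position %d",
                   counts$scaffold[b], as.integer(counts$pos[b])), call. = FALSE)
    }
    counts$.win[rows] <- glob_index[w$marker[i]]
  }
  if (anyNA(counts$.win)) {
    b <- which(is.na(counts$.win))[1]
    stop(sprintf("SNP outside any window: scaffold %s position %d",
                 counts$scaffold[b], as.integer(counts$pos[b])), call. = FALSE)
  }

  inds <- sort(unique(c(individuals, counts$individual)))
  n <- length(inds); M <- nrow(windows)
  ii <- match(counts$individual, inds)
  a_mat <- matrix(0, n, M); b_mat <- matrix(0, n, M)
  idx <- cbind(ii, counts$.win)
  # accumulate with base tapply-free indexing (duplicates summed)
  a_vec <- numeric(n * M); b_vec <- numeric(n * M)
  flat <- (idx[, 2] - 1L) * n + idx[, 1]
  agg_a <- rowsum(counts$count_A, flat)
  agg_b <- rowsum(counts$count_B, flat)
  pos <- as.integer(rownames(agg_a))
  a_vec[pos] <- agg_a[, 1]; b_vec[pos] <- agg_b[, 1]
  a_mat <- matrix(a_vec, n, M); b_mat <- matrix(b_vec, n, M)

  calls <- matrix(call_window(a_mat, b_mat, thresholds), n, M)
  rownames(calls) <- inds
  geno_calls(calls, windows, depth = a_mat + b_mat)
}

#' Filter diagnostic SNPs before window calling
#'
#' Two configurable SNP-level filters: (a) a population allele-frequency
#' rule -- each parental allele must be observed in at least `min_carriers`
#' individuals and in at least `min_carrier_frac` of the individuals scored
#' at the SNP; (b) a neighbor-consistency rule -- at each SNP, every
#' individual's simple allele-ratio category (A-like / het-like / B-like) is
#' compared with the category implied by all *other* SNPs in the same
#' window, and SNPs whose per-individual categories disagree with their
#' window neighbors in more than `max_disagree` of informative individuals
#' are dropped. The consistency statistic is a reconstruction; its
#' thresholds are deliberately configurable.
#'
#' @param counts Read-count tibble (`scaffold`, `pos`, `individual`,
#'   `count_A`, `count_B`).
#' @param min_carriers,min_carrier_frac Allele-frequency filter knobs.
#' @param max_disagree Neighbor-consistency disagreement cap (default 0.5).
#' @param window_size Window used for the neighbor-consistency grouping.
#' @return A list with `counts` (retained rows) and `report`, a tibble of
#'   SNPs removed per rule (removed + retained = input SNP count).
#' @export
filter_snps <- function(counts, min_carriers = 5L, min_carrier_frac = 0.025,
                        max_disagree = 0.5, window_size = 1e5) {
  if (!nrow(counts)) stop("empty read-count table", call. = FALSE)
  counts <- dplyr::mutate(counts, .snp = paste0(.data$scaffold, ":", .data$pos))
  n_snp0 <- dplyr::n_distinct(counts$.snp)

  freq <- counts |>
    dplyr::group_by(.data$.snp) |>
    dplyr::summarise(
      n_scored = sum(.data$count_A + .data$count_B > 0),
      carry_a = sum(.data$count_A > 0),
      carry_b = sum(.data$count_B > 0), .groups = "drop") |>
    dplyr::mutate(pass = .data$carry_a >= min_carriers & .data$carry_b >= min_carriers &
                    .data$carry_a >= min_carrier_frac * .data$n_scored &
                    .data$carry_b >= min_carrier_frac * .data$n_scored)
  keep1 <- freq$.snp[freq$pass]
  n_freq <- n_snp0 - length(keep1)
  counts <- dplyr::filter(counts, .data$.snp %in% keep1)

  # neighbor consistency within windows
  n_neigh <- 0L
  if (nrow(counts)) {
    counts <- dplyr::mutate(counts, .win = paste0(.data$scaffold, ":",
                                                  floor(.data$pos / window_size)))
    cat3 <- function(a, b) {
      f <- a / (a + b)
      ifelse(f > 0.75, 1L, ifelse(f < 0.25, 3L, 2L))
    }
    counts <- dplyr::mutate(counts, .cat = cat3(.data$count_A, .data$count_B))
    win_tot <- counts |>
      dplyr::group_by(.data$.win, .data$individual) |>
      dplyr::summarise(wa = sum(.data$count_A), wb = sum(.data$count_B),
                       n_snp = dplyr::n(), .groups = "drop")
    j <- dplyr::left_join(counts, win_tot, by = c(".win", "individual"))
    j <- dplyr::filter(j, .data$n_snp > 1)
    if (nrow(j)) {
      j <- dplyr::mutate(j,
        rest_cat = cat3(.data$wa - .data$count_A, .data$wb - .data$count_B),
        informative = (.data$wa - .data$count_A + .data$wb - .data$count_B) > 0)
      dis <- j |>
        dplyr::filter(.data$informative) |>
        dplyr::group_by(.data$.snp) |>
        dplyr::summarise(disagree = mean(.data$.cat != .data$rest_cat), .groups = "drop")
      drop2 <- dis$.snp[dis$disagree > max_disagree]
      n_neigh <- length(drop2)
      counts <- dplyr::filter(counts, !(.data$.snp %in% drop2))
    }
  }
  if (!nrow(counts)) warning("all SNPs removed by filters", call. = FALSE)
  report <- tibble::tibble(
    rule = c("allele_frequency", "neighbor_consistency", "retained"),
    n_snps = c(n_freq, n_neigh, dplyr::n_distinct(counts$.snp)))
  list(counts = dplyr::select(counts, -dplyr::starts_with(".")), report = report)
}

#' Flag markers with distorted genotype frequencies
#'
#' Per-marker chi-square test of the called genotype frequencies against the
#' design's expected marginals (for example 1:2:1 in an F2). Markers failing
#' at `alpha` are flagged, not dropped.
#'
#' @param calls A [geno_calls()] object.
#' @param design A [cross_design()].
#' @param alpha Flagging level (default 1e-6).
#' @return Tibble with columns `marker`, `n_called`, `p_value`, `flagged`.
#' @export
flag_marker_distortion <- function(calls, design, alpha = 1e-6) {
  exp_p <- design$init
  M <- ncol(calls$calls)
  res <- lapply(seq_len(M), function(m) {
    x <- calls$calls[, m]
    obs <- c(sum(x == 1L), sum(x == 2L), sum(x == 3L))
    n <- sum(obs)
    if (n == 0) return(c(n, NA_real_))
    stat <- sum((obs - n * exp_p)^2 / (n * exp_p))
    c(n, stats::pchisq(stat, df = 2, lower.tail = FALSE))
  })
  res <- do.call(rbind, res)
  tibble::tibble(marker = calls$markers$marker, n_called = res[, 1],
                 p_value = res[, 2],
                 flagged = !is.na(res[, 2]) & res[, 2] < alpha)
}

#' Cull individuals with excessive missingness or error rates
#'
#' Individuals whose fraction of `NN` calls exceeds `max_missing` or whose
#' estimated genotyping error rates (any of `e0`, `e1`, `e2`) exceed
#' `max_error` are removed. Removing every individual is an error since no
#' downstream analysis is then possible.
#'
#' @param calls A [geno_calls()] object.
#' @param error_report Optional tibble from [estimate_error_rates()].
#' @param max_missing Maximum tolerated `NN` fraction (default 0.5).
#' @param max_error Maximum tolerated error rate (default 0.2).
#' @return List with `calls` (culled [geno_calls()]), `keep` (ids) and
#'   `report` (one row per individual with the culling reason).
#' @export
cull_individuals <- function(calls, error_report = NULL, max_missing = 0.5,
                             max_error = 0.2) {
  miss <- rowMeans(calls$calls == 0L)
  report <- tibble::tibble(individual = rownames(calls$calls),
                           missing_frac = miss)
  if (!is.null(error_report)) {
    er <- error_report[match(report$individual, error_report$individual), ]
    report$max_error_rate <- pmax(er$e0, er$e1, er$e2)
  } else {
    report$max_error_rate <- NA_real_
  }
  report$reason <- dplyr::case_when(
    report$missing_frac > max_missing &
      !is.na(report$max_error_rate) & report$max_error_rate > max_error ~
      "missingness+error",
    report$missing_frac > max_missing ~ "missingness",
    !is.na(report$max_error_rate) & report$max_error_rate > max_error ~ "error_rate",
    TRUE ~ NA_character_)
  report$culled <- !is.na(report$reason)
  keep <- report$individual[!report$culled]
  if (!length(keep)) stop("all individuals culled", call. = FALSE)
  out <- calls
  out$calls <- calls$calls[keep, , drop = FALSE]
  if (!is.null(calls$depth)) out$depth <- calls$depth[keep, , drop = FALSE]
  list(calls = out, keep = keep, report = report)
}
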