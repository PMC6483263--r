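#' Read and write the standard tabular formats
#'
#' All interchange formats are plain TSV (or JSON/YAML where noted) and
#' round-trip exactly: `write_*()` followed by the matching `read_*()`
#' reproduces the object. Malformed inputs fail with the offending line
#' reported.
#'
#' @param path File path.
#' @param counts Read-count tibble (`scaffold`, `pos`, `individual`,
#'   `count_A`, `count_B`).
#' @name scafmap-io
NULL

#' @rdname scafmap-io
#' @export
write_read_counts <- function(counts, path) {
  readr::write_tsv(counts[, c("scaffold", "pos", "individual",
                              "count_A", "count_B")], path)
  invisible(path)
}

#' @rdname scafmap-io
#' @export
read_read_counts <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    scaffold = readr::col_character(), pos = readr::col_double(),
    individual = readr::col_character(), count_A = readr::col_integer(),
    count_B = readr::col_integer()))
  pr <- readr::problems(out)
  if (nrow(pr)) {
    stop(sprintf("parse error at line %d of %s", pr$row[1] + 1L, path),
         call. = FALSE)
  }
  bad <- which(out$count_A < 0 | out$count_B < 0)
  if (length(bad)) {
    stop(sprintf("negative count at line %d of %s", bad[1] + 1L, path),
         call. = FALSE)
  }
  out
}

#' @param calls A [geno_calls()] object.
#' @rdname scafmap-io
#' @export
write_call_matrix <- function(calls, path) {
  m <- .decode_geno(calls$calls)
  df <- data.frame(individual = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @param markers Optional marker tibble; reconstructed from the marker ids
#'   (`scaffold:start-end`) when omitted.
#' @rdname scafmap-io
#' @export
read_call_matrix <- function(path, markers = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$individual
  bad <- which(!(m %in% .GENO))
  if (length(bad)) {
    stop(sprintf("unknown genotype token '%s' at line %d of %s",
                 m[bad[1]], (bad[1] - 1L) %% nrow(m) + 2L, path),
         call. = FALSE)
  }
  if (is.null(markers)) {
    ids <- colnames(m)
    parts <- regmatches(ids, regexec("^(.*):([0-9]+)-([0-9]+)$", ids))
    if (any(lengths(parts) != 4)) {
      stop("marker ids must look like 'scaffold:start-end'", call. = FALSE)
    }
    markers <- tibble::tibble(
      marker = ids,
      scaffold = vapply(parts, `[`, "", 2),
      start = as.numeric(vapply(parts, `[`, "", 3)),
      end = as.numeric(vapply(parts, `[`, "", 4)))
    markers <- markers |>
      dplyr::group_by(.data$scaffold) |>
      dplyr::mutate(index = rank(.data$start)) |>
      dplyr::ungroup()
  }
  geno_calls(m, markers)
}

#' @param fit A `map_fit` from [fit_map()] / [finalize_map()].
#' @param chromosome Chromosome label written into the map file.
#' @rdname scafmap-io
#' @export
write_map <- function(fit, path, chromosome = "chr1") {
  td <- tidy(fit)
  td <- dplyr::mutate(td, chromosome = chromosome, .before = 1)
  readr::write_lines(sprintf("# loglik\t%.10g", fit$loglik), path)
  readr::write_tsv(td, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname scafmap-io
#' @export
read_map <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  loglik <- if (startsWith(first, "# loglik")) {
    as.numeric(strsplit(first, "\t")[[1]][2])
  } else NA_real_
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    chromosome = "c", position = "i", marker = "c", scaffold = "c",
    orientation = "c", junction = "l", r_next = "d", cm_next = "d",
    cum_cm = "d"))
  if (!all(df$orientation %in% c("+", "-"))) {
    bad <- which(!(df$orientation %in% c("+", "-")))[1]
    stop(sprintf("bad orientation token at line %d of %s", bad + 2L, path),
         call. = FALSE)
  }
  sc_first <- !duplicated(df$scaffold)
  map <- chrom_map(df$scaffold[sc_first],
                   ifelse(df$orientation[sc_first] == "+", 1L, -1L))
  attr(map, "loglik") <- loglik
  attr(map, "table") <- df
  map
}

#' @param posterior Posterior array from [finalize_map()].
#' @rdname scafmap-io
#' @export
write_posteriors <- function(posterior, path) {
  n <- dim(posterior)[1]; M <- dim(posterior)[3]
  out <- tibble::tibble(
    individual = rep(dimnames(posterior)[[1]], M),
    marker = rep(dimnames(posterior)[[3]], each = n),
    p_AA = as.vector(posterior[, 1, ]),
    p_AB = as.vector(posterior[, 2, ]),
    p_BB = as.vector(posterior[, 3, ]))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname scafmap-io
#' @export
read_posteriors <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    individual = "c", marker = "c", p_AA = "d", p_AB = "d", p_BB = "d"))
}

#' @param delta Tibble of ΔlnLk records ([delta_loglik()] /
#'   [pairwise_delta()]).
#' @rdname scafmap-io
#' @export
write_delta_json <- function(delta, path) {
  jsonlite::write_json(delta, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname scafmap-io
#' @export
read_delta_json <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname scafmap-io
#' @export
scaffold_lengths_from_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA scaffold lengths requires the Biostrings package",
         call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  tibble::tibble(scaffold = sub("\\s.*$", "", names(seqs)),
                 length = Biostrings::width(seqs))
}

#' @param config A named list of settings.
#' @rdname scafmap-io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(c(list(schema_version = 1L), config), path)
  invisible(path)
}

#' @rdname scafmap-io
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version)) {
    stop("config file missing `schema_version`", call. = FALSE)
  }
  cfg
}
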