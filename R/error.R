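#' Per-individual genotyping error rate MLE
#'
#' Estimates `(e0, e1, e2)` for every individual by maximizing the product
#' of chain likelihoods across that individual's scaffolds, with
#' recombination fixed proportional to physical distance between marker
#' midpoints at a genomic-average rate ([physical_r_vector()]). The bounded
#' quasi-Newton search (L-BFGS-B) is restarted from `n_starts` points to
#' guard against local optima; estimates are confined to
#' `[bounds[1], bounds[2]]` -- the floor avoids `log(0)`, the ceiling
#' prevents label-swap degeneracy -- and boundary solutions are flagged.
#' Individuals with no informative (non-`NN`) calls cannot be estimated and
#' are flagged for culling.
#'
#' @param calls A [geno_calls()] object.
#' @param design A [cross_design()].
#' @param rate_cm_per_mb Fixed homogeneous rate; defaults to 5.0 cM/Mb for
#'   F2 designs and 10.0 cM/Mb for F3/RIL.
#' @param bounds Length-2 numeric, lower/upper bound on each error rate.
#' @param n_starts Number of optimizer restarts (default 3).
#' @return Tibble (one row per individual): `individual`, `e0`, `e1`, `e2`,
#'   `loglik`, `n_informative`, `converged`, `boundary`.
#' @export
estimate_error_rates <- function(calls, design, rate_cm_per_mb = NULL,
                                 bounds = c(1e-6, 0.2), n_starts = 3L) {
  stopifnot(inherits(calls, "geno_calls"), inherits(design, "cross_design"))
  rate0 <- rate_cm_per_mb %||% .default_fixed_rate(design)
  mk <- calls$markers
  sc_ids <- unique(mk$scaffold)
  tf <- .trans_fun(design)

  # per-scaffold marker columns and transition matrices (shared by all
  # individuals -- they depend only on physical distances)
  sc_cols <- lapply(sc_ids, function(sc) {
    w <- mk[mk$scaffold == sc, , drop = FALSE]
    which(mk$scaffold == sc)[order(w$index)]
  })
  sc_trans <- lapply(sc_ids, function(sc) {
    w <- mk[mk$scaffold == sc, , drop = FALSE]
    w <- w[order(w$index), , drop = FALSE]
    lapply(physical_r_vector(w, rate0), tf)
  })

  init <- design$init
  starts <- list(c(0.01, 0.001, 0.02), c(0.05, 0.01, 0.08),
                 c(0.002, 1e-4, 0.005))[seq_len(max(1L, n_starts))]

  one_individual <- function(obs_row) {
    obs_sc <- lapply(sc_cols, function(ix) obs_row[ix])
    keep <- vapply(obs_sc, function(o) any(o != 0L), TRUE)
    obs_sc <- obs_sc[keep]
    trans_sc <- sc_trans[keep]
    n_inf <- sum(obs_row != 0L)
    if (n_inf == 0L) {
      return(list(e = rep(NA_real_, 3), ll = NA_real_, conv = FALSE,
                  n_inf = 0L))
    }
    negll <- function(e) {
      em <- emission_matrix(e[1], e[2], e[3])
      ll <- 0
      for (s in seq_along(obs_sc)) {
        obs <- obs_sc[[s]]; Ts <- trans_sc[[s]]
        a <- init * em[, obs[1] + 1L]
        ss <- sum(a); ll <- ll + log(ss); a <- a / ss
        if (length(obs) > 1L) for (t in 2:length(obs)) {
          a <- c(a %*% Ts[[t - 1L]]) * em[, obs[t] + 1L]
          ss <- sum(a); ll <- ll + log(ss); a <- a / ss
        }
      }
      -ll
    }
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        stats::optim(st, negll, method = "L-BFGS-B",
                     lower = rep(bounds[1], 3), upper = rep(bounds[2], 3)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) {
      return(list(e = rep(NA_real_, 3), ll = NA_real_, conv = FALSE,
                  n_inf = n_inf))
    }
    # rates can be effectively unidentified (e.g. e2 for an individual with
    # no het calls, where re-explaining a terminal marker buys a sliver of
    # likelihood): keep a rate above the floor only if it improves this
    # individual's log-likelihood by more than `support` units
    support <- 0.01
    e <- best$par; v <- best$value
    for (k in 1:3) {
      e_try <- e; e_try[k] <- bounds[1]
      v_try <- negll(e_try)
      if (v_try <= v + support) { e <- e_try; v <- v_try }
    }
    list(e = e, ll = -v, conv = best$convergence == 0, n_inf = n_inf)
  }

  res <- lapply(seq_len(nrow(calls$calls)),
                function(i) one_individual(calls$calls[i, ]))
  e_mat <- do.call(rbind, lapply(res, `[[`, "e"))
  tol <- 1e-8
  tibble::tibble(
    individual = rownames(calls$calls),
    e0 = e_mat[, 1], e1 = e_mat[, 2], e2 = e_mat[, 3],
    loglik = vapply(res, `[[`, 0, "ll"),
    n_informative = vapply(res, function(x) as.integer(x$n_inf), 0L),
    converged = vapply(res, `[[`, TRUE, "conv"),
    boundary = apply(e_mat, 1, function(e)
      any(!is.na(e) & (e <= bounds[1] + tol | e >= bounds[2] - tol))))
}
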