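#' Cross design for the genotype hidden Markov model
#'
#' The hidden chain of the genotype HMM moves over the true genotypes
#' \{AA, AB, BB\} of a single individual along a chromosome. Both the initial
#' state distribution and the transition matrices depend on the breeding
#' design. `"F2"` is a standard intercross (one meiosis per gamete), `"F3"`
#' selfs each F2 once, and `"RIL"` is single-seed descent by selfing for
#' `generations` total generations counted from the F1 (so `"F2"` is the
#' one-generation special case and `"F3"` the two-generation one). Residual
#' heterozygosity after `g` generations is `0.5^g`, which fixes the initial
#' distribution at `((1 - 0.5^g)/2, 0.5^g, (1 - 0.5^g)/2)`.
#'
#' @param kind One of `"F2"`, `"F3"`, `"RIL"`.
#' @param generations Number of selfing generations from the F1 for RIL
#'   designs (default 8). Ignored for F2/F3.
#' @return An object of class `cross_design` with fields `kind`,
#'   `generations` and `init` (the initial genotype distribution).
#' @examples
#' cross_design("F2")$init       # 1/4, 1/2, 1/4
#' cross_design("F3")$init       # 3/8, 1/4, 3/8
#' cross_design("RIL", 8)$init   # heterozygosity 0.5^8
#' @export
cross_design <- function(kind = c("F2", "F3", "RIL"), generations = 8L) {
  kind <- match.arg(kind)
  g <- switch(kind, F2 = 1L, F3 = 2L, RIL = as.integer(generations))
  if (is.na(g) || g < 1L) {
    stop("`generations` must be a positive integer", call. = FALSE)
  }
  h <- 0.5^g
  structure(
    list(kind = kind, generations = g,
         init = c(AA = (1 - h) / 2, AB = h, BB = (1 - h) / 2)),
    class = "cross_design"
  )
}

#' @export
print.cross_design <- function(x, ...) {
  cat("<cross_design> ", x$kind,
      if (x$kind == "RIL") paste0(" (", x$generations, " generations)"),
      "\n  initial distribution: ",
      paste(sprintf("%s=%.4g", names(x$init), x$init), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# closed-form F2 transition: two independent gametes, each switching parent
# with probability r
.f2_trans <- function(r) {
  s <- 1 - r
  matrix(c(s * s,     2 * r * s, r * r,
           r * s,     s * s + r * r, r * s,
           r * r,     2 * r * s, s * s),
         3, 3, byrow = TRUE,
         dimnames = list(c("AA", "AB", "BB"), c("AA", "AB", "BB")))
}

# two-locus haplotypes (allele 0 = parent A, 1 = parent B) and the 10
# unordered diplotypes built from them; used to propagate selfing exactly
.haps <- matrix(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L), ncol = 2, byrow = TRUE)
.dips <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)

.gamete_dist <- function(h, k, r) {
  # gamete haplotype distribution from diplotype {h, k} with one meiosis
  p <- numeric(4)
  hx <- .haps[h, ]; kx <- .haps[k, ]
  idx <- function(a, b) a * 2L + b + 1L
  p[idx(hx[1], hx[2])] <- p[idx(hx[1], hx[2])] + (1 - r) / 2
  p[idx(hx[1], kx[2])] <- p[idx(hx[1], kx[2])] + r / 2
  p[idx(kx[1], kx[2])] <- p[idx(kx[1], kx[2])] + (1 - r) / 2
  p[idx(kx[1], hx[2])] <- p[idx(kx[1], hx[2])] + r / 2
  p
}

.selfing_matrix <- function(r) {
  nd <- nrow(.dips)
  S <- matrix(0, nd, nd)
  for (i in seq_len(nd)) {
    g <- .gamete_dist(.dips[i, 1], .dips[i, 2], r)
    q <- outer(g, g)
    for (j in seq_len(nd)) {
      u <- .dips[j, 1]; v <- .dips[j, 2]
      S[i, j] <- if (u == v) q[u, u] else q[u, v] + q[v, u]
    }
  }
  S
}

.trans_cache <- new.env(parent = emptyenv())

# exact two-locus transition for g generations of selfing from the F1
# (g = 1 reproduces the closed-form F2 matrix)
.selfing_transition <- function(r, generations) {
  key <- sprintf("%d:%.15g", generations, r)
  hit <- .trans_cache[[key]]
  if (!is.null(hit)) return(hit)
  d <- as.numeric(.dips[, 1] == 1L & .dips[, 2] == 4L) # F1 = {(A,A),(B,B)}
  S <- .selfing_matrix(r)
  for (g in seq_len(generations)) d <- as.numeric(d %*% S)
  g1 <- .haps[.dips[, 1], 1] + .haps[.dips[, 2], 1]
  g2 <- .haps[.dips[, 1], 2] + .haps[.dips[, 2], 2]
  J <- matrix(0, 3, 3)
  for (i in seq_len(nrow(.dips))) J[g1[i] + 1L, g2[i] + 1L] <- J[g1[i] + 1L, g2[i] + 1L] + d[i]
  T_ <- J / rowSums(J)
  dimnames(T_) <- list(c("AA", "AB", "BB"), c("AA", "AB", "BB"))
  .trans_cache[[key]] <- T_
  T_
}

#' Genotype transition matrix between adjacent markers
#'
#' Row-stochastic 3x3 matrix of `P(genotype at next marker | genotype here)`
#' for a given recombination fraction `r`. The F2 case is the product of two
#' independent gametes; F3 and RIL matrices are computed exactly by
#' propagating the 10 two-locus diplotype states through the required number
#' of selfing meioses (each with recombination fraction `r`) and conditioning
#' on the first-locus genotype.
#'
#' @param design A [cross_design()].
#' @param r Recombination fraction in `[0, 0.5]`.
#' @return A 3x3 row-stochastic matrix over (AA, AB, BB).
#' @examples
#' transition_matrix(cross_design("F2"), 0.1)["AA", ] # 0.81 0.18 0.01
#' @export
transition_matrix <- function(design, r) {
  stopifnot(inherits(design, "cross_design"))
  if (!is.finite(r) || r < 0 || r > 0.5) {
    stop("recombination fraction must lie in [0, 0.5]", call. = FALSE)
  }
  if (design$generations == 1L) .f2_trans(r) else .selfing_transition(r, design$generations)
}

# dimnames-free F2 transition for hot loops (column-major layout)
.f2_trans_fast <- function(r) {
  s <- 1 - r
  ss <- s * s; rs <- r * s; rr <- r * r
  matrix(c(ss, rs, rr, 2 * rs, ss + rr, 2 * rs, rr, rs, ss), 3, 3)
}

# transition-builder closure for the fast paths
.trans_fun <- function(design) {
  if (design$generations == 1L) .f2_trans_fast
  else {
    g <- design$generations
    function(r) .selfing_transition(r, g)
  }
}

#' Emission probabilities under per-individual genotyping error rates
#'
#' A true homozygote is miscalled heterozygous with probability `e0` and as
#' the opposite homozygote with probability `e1`; a true heterozygote is
#' miscalled as a homozygote with total probability `e2`, split equally
#' between the two homozygotes. A missing observation (`NN`) carries no
#' information and has emission probability 1 under every hidden state.
#'
#' @param hidden Character vector of hidden states (`AA`, `AB`, `BB`).
#' @param observed Character vector of observed putative calls
#'   (`AA`, `AB`, `BB`, `NN`).
#' @param e0,e1,e2 Error rates (scalars).
#' @return Numeric vector of emission probabilities.
#' @examples
#' emission_probability("AA", "AA", 0.01, 0.001, 0.02) # 0.989
#' emission_probability("AB", "AA", 0.01, 0.001, 0.02) # 0.01
#' @export
emission_probability <- function(hidden, observed, e0, e1, e2) {
  em <- emission_matrix(e0, e1, e2)
  h <- match(hidden, c("AA", "AB", "BB"))
  o <- match(observed, .GENO)
  if (anyNA(h)) stop("invalid hidden state", call. = FALSE)
  if (anyNA(o)) stop("invalid observed state", call. = FALSE)
  em[cbind(h, o)]
}

#' Emission matrix (hidden x observed) for one individual
#'
#' @inheritParams emission_probability
#' @return 3x4 matrix, rows (AA, AB, BB), columns (NN, AA, AB, BB).
#' @export
emission_matrix <- function(e0, e1, e2) {
  m <- rbind(
    c(1, 1 - e0 - e1, e0,      e1),
    c(1, e2 / 2,      1 - e2,  e2 / 2),
    c(1, e1,          e0,      1 - e0 - e1))
  dimnames(m) <- list(c("AA", "AB", "BB"), .GENO)
  m
}

#' Haldane map function and its inverse
#'
#' `haldane_r()` converts a genetic distance in centiMorgans to a
#' recombination fraction assuming crossovers occur as a Poisson process with
#' no interference: `r = (1 - exp(-2 d))/2` with `d` in Morgans.
#' `haldane_cm()` is the inverse, `d = -ln(1 - 2 r)/2`.
#'
#' @param cm Genetic distance in centiMorgans (non-negative).
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return Numeric vector.
#' @examples
#' haldane_r(10)                 # 0.09063
#' haldane_cm(haldane_r(25))     # 25
#' @export
haldane_r <- function(cm) {
  if (any(cm < 0)) stop("genetic distance must be non-negative", call. = FALSE)
  (1 - exp(-2 * cm / 100)) / 2
}

#' @rdname haldane_r
#' @export
haldane_cm <- function(r) {
  if (any(r < 0) || any(r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5) for the inverse map function",
         call. = FALSE)
  }
  -50 * log(1 - 2 * r)
}

# ---------------------------------------------------------------------------
# scaled forward-backward machinery, vectorized over individuals
# E: n x 3 x M emission array (already evaluated at the observed calls)

.E_slab <- function(E, m) {
  n <- dim(E)[1]
  matrix(E[, , m], n, 3)
}

.fb_forward <- function(E, rates, design) {
  n <- dim(E)[1]; M <- dim(E)[3]
  tf <- .trans_fun(design)
  alpha <- array(0, dim = dim(E))
  logc <- matrix(0, n, M)
  a <- .E_slab(E, 1) * rep(design$init, each = n)
  s <- .rowSums(a, n, 3)
  logc[, 1] <- log(s); a <- a / s; alpha[, , 1] <- a
  if (M > 1L) {
    for (m in 2:M) {
      a <- (a %*% tf(rates[m - 1])) * .E_slab(E, m)
      s <- .rowSums(a, n, 3)
      logc[, m] <- log(s); a <- a / s; alpha[, , m] <- a
    }
  }
  list(alpha = alpha, logc = logc, loglik = sum(logc))
}

.fb_backward <- function(E, rates, design) {
  n <- dim(E)[1]; M <- dim(E)[3]
  tf <- .trans_fun(design)
  beta <- array(0, dim = dim(E))
  b <- matrix(1, n, 3)
  beta[, , M] <- b
  if (M > 1L) {
    for (m in (M - 1):1) {
      x <- b * .E_slab(E, m + 1)
      b <- x %*% t(tf(rates[m]))
      b <- b / .rowSums(b, n, 3)
      beta[, , m] <- b
    }
  }
  beta
}

.fb_posterior <- function(E, rates, design) {
  fwd <- .fb_forward(E, rates, design)
  beta <- .fb_backward(E, rates, design)
  g <- fwd$alpha * beta
  n <- dim(E)[1]; M <- dim(E)[3]
  for (m in seq_len(M)) {
    slab <- matrix(g[, , m], n, 3)
    g[, , m] <- slab / .rowSums(slab, n, 3)
  }
  list(posterior = g, loglik = fwd$loglik)
}

# build the n x 3 x M emission array from a call-code matrix and a table of
# per-individual error rates (rows aligned with the call matrix)
.emission_array <- function(calls, err) {
  n <- nrow(calls); M <- ncol(calls)
  stopifnot(length(err$e0) == n)
  E <- array(1, c(n, 3, M))
  rows <- list(
    cbind(1, 1 - err$e0 - err$e1, err$e0,     err$e1),
    cbind(1, err$e2 / 2,          1 - err$e2, err$e2 / 2),
    cbind(1, err$e1,              err$e0,     1 - err$e0 - err$e1))
  ij <- cbind(rep(seq_len(n), M), as.vector(calls) + 1L)
  for (s in 1:3) E[, s, ] <- matrix(rows[[s]][ij], n, M)
  E
}

.as_obs_codes <- function(calls) {
  if (is.character(calls)) .code_geno(calls) else as.integer(calls)
}

#' Log-likelihood of one individual's marker sequence
#'
#' Exact marginal log-likelihood of a sequence of putative genotype calls
#' under the non-homogeneous genotype HMM, computed by the scaled forward
#' recursion (numerically safe for chromosomes with tens of thousands of
#' markers). An all-`NN` sequence has probability 1 (log-likelihood 0).
#'
#' @param calls Character (or 0-3 coded integer) vector of putative calls.
#' @param rates Numeric vector of recombination fractions between adjacent
#'   markers; length `length(calls) - 1`.
#' @param design A [cross_design()].
#' @param e0,e1,e2 This individual's genotyping error rates.
#' @return Log-likelihood (scalar).
#' @examples
#' chromosome_loglik("AA", numeric(0), cross_design("F2"), 0, 0, 0) # log(1/4)
#' @export
chromosome_loglik <- function(calls, rates, design, e0 = 0.01, e1 = 0.001, e2 = 0.02) {
  obs <- .as_obs_codes(calls)
  if (length(rates) != length(obs) - 1L) {
    stop("`rates` must have length `length(calls) - 1`", call. = FALSE)
  }
  E <- .emission_array(matrix(obs, 1), data.frame(e0 = e0, e1 = e1, e2 = e2))
  .fb_forward(E, rates, design)$loglik
}

#' Posterior genotype probabilities for one individual
#'
#' Forward-backward smoothed marginal probabilities of the hidden genotype at
#' each marker. Each row sums to one.
#'
#' @inheritParams chromosome_loglik
#' @return A tibble with columns `marker` (index), `p_AA`, `p_AB`, `p_BB`.
#' @export
posterior_decode <- function(calls, rates, design, e0 = 0.01, e1 = 0.001, e2 = 0.02) {
  obs <- .as_obs_codes(calls)
  if (length(rates) != length(obs) - 1L) {
    stop("`rates` must have length `length(calls) - 1`", call. = FALSE)
  }
  E <- .emission_array(matrix(obs, 1), data.frame(e0 = e0, e1 = e1, e2 = e2))
  post <- .fb_posterior(E, rates, design)$posterior
  M <- length(obs)
  tibble::tibble(
    marker = seq_len(M),
    p_AA = vapply(seq_len(M), function(m) post[1, 1, m], 0),
    p_AB = vapply(seq_len(M), function(m) post[1, 2, m], 0),
    p_BB = vapply(seq_len(M), function(m) post[1, 3, m], 0))
}
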