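# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's forward-backward engine: the
# likelihood oracle enumerates all 3^M hidden paths directly from
# transition_matrix()/emission_matrix(), and the transition oracle simulates
# meioses gamete by gamete.

# exhaustive-path log-likelihood for one individual
enum_chrom_loglik <- function(obs, rates, design, e0, e1, e2) {
  em <- emission_matrix(e0, e1, e2)
  M <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(1:3), M)))
  tot <- 0
  Ts <- lapply(rates, function(r) transition_matrix(design, r))
  for (k in seq_len(nrow(paths))) {
    h <- paths[k, ]
    p <- unname(design$init[h[1]]) * em[h[1], obs[1] + 1L]
    if (M > 1) for (t in 2:M) {
      p <- p * Ts[[t - 1]][h[t - 1], h[t]] * em[h[t], obs[t] + 1L]
    }
    tot <- tot + p
  }
  log(tot)
}

# exhaustive-path posterior marginals (M x 3)
enum_posterior <- function(obs, rates, design, e0, e1, e2) {
  em <- emission_matrix(e0, e1, e2)
  M <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(1:3), M)))
  Ts <- lapply(rates, function(r) transition_matrix(design, r))
  post <- matrix(0, M, 3)
  tot <- 0
  for (k in seq_len(nrow(paths))) {
    h <- paths[k, ]
    p <- unname(design$init[h[1]]) * em[h[1], obs[1] + 1L]
    if (M > 1) for (t in 2:M) {
      p <- p * Ts[[t - 1]][h[t - 1], h[t]] * em[h[t], obs[t] + 1L]
    }
    for (t in 1:M) post[t, h[t]] <- post[t, h[t]] + p
    tot <- tot + p
  }
  post / tot
}

# forward-simulation oracle for two-locus transitions: returns the empirical
# 3x3 conditional frequency matrix from n simulated individuals
sim_transition_oracle <- function(design, r, n) {
  gamete <- function(h1, h2) {
    # h1, h2: n x 2 matrices of alleles; one meiosis with recomb fraction r
    s1 <- stats::rbinom(n, 1, 0.5)
    sw <- stats::rbinom(n, 1, r)
    s2 <- (s1 + sw) %% 2
    cbind(ifelse(s1 == 0, h1[, 1], h2[, 1]),
          ifelse(s2 == 0, h1[, 2], h2[, 2]))
  }
  H1 <- matrix(0L, n, 2); H2 <- matrix(1L, n, 2) # F1: AB/ab coupling
  for (g in seq_len(design$generations)) {
    n1 <- gamete(H1, H2); n2 <- gamete(H1, H2)
    H1 <- n1; H2 <- n2
  }
  g1 <- H1[, 1] + H2[, 1]; g2 <- H1[, 2] + H2[, 2]
  tab <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  sweep(unclass(tab), 1, rowSums(tab), "/")
}

# simulate putative calls directly from the hidden genotype chain (optionally
# with emission errors), returning a geno_calls over one or more scaffolds
sim_chain_calls <- function(n, rates, design, e = c(0, 0, 0),
                            scaffold_of = NULL, miss = 0) {
  M <- length(rates) + 1L
  geno <- matrix(0L, n, M)
  geno[, 1] <- sample(1:3, n, replace = TRUE, prob = design$init)
  for (m in seq_len(M - 1L)) {
    T_ <- transition_matrix(design, rates[m])
    for (s in 1:3) {
      rows <- which(geno[, m] == s)
      if (length(rows)) {
        geno[rows, m + 1L] <- sample(1:3, length(rows), replace = TRUE,
                                     prob = T_[s, ])
      }
    }
  }
  obs <- geno
  if (any(e > 0)) {
    em <- emission_matrix(e[1], e[2], e[3])
    for (s in 1:3) {
      rows <- which(geno == s)
      if (length(rows)) {
        obs[rows] <- sample(0:3, length(rows), replace = TRUE,
                            prob = c(0, em[s, 2:4]))
      }
    }
  }
  if (miss > 0) obs[stats::runif(length(obs)) < miss] <- 0L
  if (is.null(scaffold_of)) scaffold_of <- rep("s1", M)
  mk <- do.call(rbind, lapply(split(seq_len(M), scaffold_of)[unique(scaffold_of)],
    function(ix) {
      k <- length(ix)
      data.frame(scaffold = scaffold_of[ix[1]], index = seq_len(k),
                 start = (seq_len(k) - 1) * 1e5, end = seq_len(k) * 1e5)
    }))
  mk$marker <- sprintf("%s:%d-%d", mk$scaffold, as.integer(mk$start),
                       as.integer(mk$end))
  ord <- unlist(split(seq_len(M), scaffold_of)[unique(scaffold_of)],
                use.names = FALSE)
  obs <- obs[, ord, drop = FALSE]
  rownames(obs) <- sprintf("ind%03d", seq_len(n))
  list(calls = geno_calls(obs, tibble::as_tibble(mk)),
       genotypes = geno[, ord, drop = FALSE])
}

# error-rate table at the estimation floor (used for near-perfect data)
floor_errors <- function(ids, e0 = 1e-6, e1 = 1e-6, e2 = 1e-6) {
  tibble::tibble(individual = ids, e0 = e0, e1 = e1, e2 = e2)
}

err_tbl_of <- function(calls, e0, e1, e2) {
  floor_errors(rownames(calls$calls), e0, e1, e2)
}

# closed-form two-point multinomial likelihood maximized on a grid + optimize
# (independent of the HMM engine)
two_point_oracle <- function(g1, g2, design) {
  ok <- g1 != 0L & g2 != 0L
  tab <- table(factor(g1[ok], levels = 1:3), factor(g2[ok], levels = 1:3))
  ll <- function(r) {
    P <- design$init * transition_matrix(design, r)
    sum(unclass(tab) * log(P))
  }
  stats::optimize(ll, c(1e-6, 0.5), maximum = TRUE, tol = 1e-7)$maximum
}
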