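# Internal likelihood engine.
#
# Everything downstream of putative calls works through a "context": the
# emission array evaluated once per individual x marker (it depends only on
# the observed call and that individual's error rates, never on marker
# order), plus the per-scaffold marker index lists. A candidate map is then
# just a permutation of emission-array slabs, which makes genetic-algorithm
# fitness evaluations cheap.

.lk_context <- function(calls, errors, design) {
  stopifnot(inherits(calls, "geno_calls"), inherits(design, "cross_design"))
  ind <- rownames(calls$calls)
  err <- errors[match(ind, errors$individual), , drop = FALSE]
  if (anyNA(err$e0)) stop("error rates missing for some individuals", call. = FALSE)
  E <- .emission_array(calls$calls, err)
  mk <- calls$markers
  ord <- order(match(mk$scaffold, unique(mk$scaffold)), mk$index)
  sc_markers <- split(ord, mk$scaffold[ord])[unique(mk$scaffold)]
  list(E = E, design = design, markers = mk, scaffold_markers = sc_markers,
       n = length(ind), individuals = ind)
}

# marker sequence induced by a map (+ which gaps are junctions)
.map_sequence <- function(ctx, map) {
  miss <- setdiff(map$scaffold, names(ctx$scaffold_markers))
  if (length(miss)) {
    stop("map scaffolds absent from call matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- lapply(seq_along(map$scaffold), function(i) {
    v <- ctx$scaffold_markers[[map$scaffold[i]]]
    if (map$orientation[i] < 0) rev(v) else v
  })
  lens <- lengths(idx)
  cs <- cumsum(lens)
  list(seq = unlist(idx, use.names = FALSE),
       junctions = if (length(lens) > 1) cs[-length(cs)] else integer(0),
       lens = lens)
}

# assemble the rate vector along a map's marker sequence from per-scaffold
# intra-rate chunks (reversed for flipped scaffolds) and junction values
.assemble_rates <- function(map, ms, intra_list, inter = NULL, init_inter = 0.05) {
  M <- length(ms$seq)
  rates <- rep(init_inter, max(M - 1L, 0L))
  pos <- 0L
  for (i in seq_along(map$scaffold)) {
    k <- ms$lens[i]
    if (k > 1L) {
      seg <- intra_list[[map$scaffold[i]]]
      if (is.null(seg)) seg <- rep(1e-6, k - 1L)
      if (map$orientation[i] < 0) seg <- rev(seg)
      rates[(pos + 1L):(pos + k - 1L)] <- seg
    }
    pos <- pos + k
  }
  if (!is.null(inter) && length(ms$junctions)) rates[ms$junctions] <- inter
  rates
}

# Cyclic coordinate-wise bounded maximization of the chain likelihood over
# the gaps flagged in `free`, exact at each step: with beta computed under
# the current right-hand rates and alpha advanced under the already-updated
# left-hand rates, the Brent objective at gap g is the true profile
# likelihood in r_g. Monotone; stops when a full cycle improves the
# log-likelihood by less than `tol`.
.coord_ascent <- function(E, rates, design, free, r_min = 1e-6, r_max = 0.5,
                          tol = 1e-4, min_cycles = 2L, max_cycles = 8L,
                          brent_tol = 1e-5) {
  n <- dim(E)[1]; M <- dim(E)[3]
  if (M == 1L || !any(free)) {
    return(list(rates = rates, loglik = .fb_forward(E, rates, design)$loglik,
                cycles = 0L))
  }
  tf <- .trans_fun(design)
  init <- design$init
  ll <- -Inf
  for (cyc in seq_len(max_cycles)) {
    beta <- .fb_backward(E, rates, design)
    a <- .E_slab(E, 1) * rep(init, each = n)
    s <- .rowSums(a, n, 3)
    ll_new <- sum(log(s)); a <- a / s
    for (g in seq_len(M - 1L)) {
      Em <- .E_slab(E, g + 1L)
      if (free[g]) {
        EB <- Em * matrix(beta[, , g + 1L], n, 3)
        f <- function(r) sum(log(.rowSums((a %*% tf(r)) * EB, n, 3)))
        opt <- stats::optimize(f, c(r_min, r_max), maximum = TRUE, tol = brent_tol)
        cand <- c(opt$maximum, r_min, r_max)
        vals <- c(opt$objective, f(r_min), f(r_max))
        rates[g] <- cand[which.max(vals)]
      }
      a <- (a %*% tf(rates[g])) * Em
      s <- .rowSums(a, n, 3)
      ll_new <- ll_new + sum(log(s)); a <- a / s
    }
    done <- cyc >= min_cycles && (ll_new - ll) < tol
    ll <- ll_new
    if (done) break
  }
  list(rates = rates, loglik = ll, cycles = cyc)
}

# ---------------------------------------------------------------------------
# Coarse-chain machinery for junction-rate fitting. During the GA (and any
# junction-mode fit) intra-scaffold rates and emissions are fixed, so each
# oriented scaffold collapses to one 3x3 transfer operator per individual:
# O = diag(E_1) T_1 diag(E_2) ... T_{k-1} diag(E_k), with a per-individual
# log scale factor. A candidate map is then a chain over L scaffold nodes
# instead of M markers, which makes fitness evaluations roughly M/L times
# cheaper. Results are exactly the fine-chain likelihood.

.build_scaffold_op <- function(E, idx, seg, tf) {
  n <- dim(E)[1]
  O <- array(0, c(n, 3, 3))
  E1 <- matrix(E[, , idx[1]], n, 3)
  for (j in 1:3) O[, j, j] <- E1[, j]
  logc <- numeric(n)
  if (length(idx) > 1L) {
    for (t in 2:length(idx)) {
      T_ <- tf(seg[t - 1L])
      Et <- matrix(E[, , idx[t]], n, 3)
      On <- array(0, c(n, 3, 3))
      for (j in 1:3) {
        On[, , j] <- (O[, , 1] * T_[1, j] + O[, , 2] * T_[2, j] +
                        O[, , 3] * T_[3, j]) * Et[, j]
      }
      s <- .rowSums(matrix(On, n, 9), n, 9)
      O <- On / s
      logc <- logc + log(s)
    }
  }
  list(O = O, logc = logc)
}

# per-scaffold operators for both orientations
.scaffold_ops <- function(ctx, intra_list) {
  tf <- .trans_fun(ctx$design)
  out <- list()
  for (sc in names(ctx$scaffold_markers)) {
    idx <- ctx$scaffold_markers[[sc]]
    seg <- intra_list[[sc]]
    if (is.null(seg)) seg <- rep(1e-6, max(length(idx) - 1L, 0L))
    out[[sc]] <- list(
      fwd = .build_scaffold_op(ctx$E, idx, seg, tf),
      rev = .build_scaffold_op(ctx$E, rev(idx), rev(seg), tf))
  }
  out
}

# a (n x 3) propagated through per-individual operators: row form
.op_row <- function(a, O) {
  n <- nrow(a)
  matrix(c(a[, 1] * O[, 1, 1] + a[, 2] * O[, 2, 1] + a[, 3] * O[, 3, 1],
           a[, 1] * O[, 1, 2] + a[, 2] * O[, 2, 2] + a[, 3] * O[, 3, 2],
           a[, 1] * O[, 1, 3] + a[, 2] * O[, 2, 3] + a[, 3] * O[, 3, 3]),
         n, 3)
}

# column form: (O v) for per-individual column vectors v (n x 3)
.op_col <- function(O, v) {
  n <- nrow(v)
  matrix(c(O[, 1, 1] * v[, 1] + O[, 1, 2] * v[, 2] + O[, 1, 3] * v[, 3],
           O[, 2, 1] * v[, 1] + O[, 2, 2] * v[, 2] + O[, 2, 3] * v[, 3],
           O[, 3, 1] * v[, 1] + O[, 3, 2] * v[, 2] + O[, 3, 3] * v[, 3]),
         n, 3)
}

# coordinate ascent over the L-1 junction rates of the coarse chain
.coarse_junction_fit <- function(ops, design, inter, r_min = 1e-6, r_max = 0.5,
                                 tol = 1e-4, min_cycles = 2L, max_cycles = 8L,
                                 brent_tol = 1e-5) {
  L <- length(ops)
  n <- length(ops[[1]]$logc)
  tf <- .trans_fun(design)
  const <- sum(vapply(ops, function(o) sum(o$logc), 0))
  init <- matrix(design$init, n, 3, byrow = TRUE)
  forward_start <- function() {
    a <- .op_row(init, ops[[1]]$O)
    s <- .rowSums(a, n, 3)
    list(a = a / s, ll = sum(log(s)))
  }
  if (L == 1L) {
    f <- forward_start()
    return(list(rates = numeric(0), loglik = f$ll + const, cycles = 0L))
  }
  rates <- inter
  ll <- -Inf
  for (cyc in seq_len(max_cycles)) {
    # backward scaffold vectors B_g (g = 1..L-1), scaled per individual
    B <- vector("list", L - 1L)
    b <- .op_col(ops[[L]]$O, matrix(1, n, 3))
    b <- b / (b[, 1] + b[, 2] + b[, 3])
    B[[L - 1L]] <- b
    if (L > 2L) {
      for (g in (L - 2L):1L) {
        v <- B[[g + 1L]] %*% t(tf(rates[g + 1L]))
        b <- .op_col(ops[[g + 1L]]$O, v)
        b <- b / (b[, 1] + b[, 2] + b[, 3])
        B[[g]] <- b
      }
    }
    fs <- forward_start()
    a <- fs$a; ll_new <- fs$ll
    f2 <- design$generations == 1L
    for (g in seq_len(L - 1L)) {
      Bg <- B[[g]]
      if (f2) {
        # F2 profile objective in closed form: collecting the transition
        # entries gives sum(log(C1 s^2 + C2 r s + C3 r^2 + Cm (s^2 + r^2)))
        C1 <- a[, 1] * Bg[, 1] + a[, 3] * Bg[, 3]
        C2 <- a[, 2] * (Bg[, 1] + Bg[, 3]) + 2 * (a[, 1] + a[, 3]) * Bg[, 2]
        C3 <- a[, 3] * Bg[, 1] + a[, 1] * Bg[, 3]
        Cm <- a[, 2] * Bg[, 2]
        f <- function(r) {
          s <- 1 - r
          sum(log(C1 * (s * s) + C2 * (r * s) + C3 * (r * r) +
                    Cm * (s * s + r * r)))
        }
      } else {
        f <- function(r) sum(log(.rowSums((a %*% tf(r)) * Bg, n, 3)))
      }
      opt <- stats::optimize(f, c(r_min, r_max), maximum = TRUE, tol = brent_tol)
      cand <- c(opt$maximum, r_min, r_max)
      vals <- c(opt$objective, f(r_min), f(r_max))
      rates[g] <- cand[which.max(vals)]
      a <- .op_row(a %*% tf(rates[g]), ops[[g + 1L]]$O)
      s <- a[, 1] + a[, 2] + a[, 3]
      ll_new <- ll_new + sum(log(s)); a <- a / s
    }
    done <- cyc >= min_cycles && (ll_new - ll) < tol
    ll <- ll_new
    if (done) break
  }
  list(rates = rates, loglik = ll + const, cycles = cyc)
}

# default intra-scaffold rate chunks from physical midpoint distances at a
# fixed cM/Mb rate (the homogeneous-rate model)
.physical_intra_list <- function(markers, rate_cm_per_mb, r_min = 1e-6) {
  mk <- split(markers, markers$scaffold)
  lapply(mk, function(w) {
    w <- w[order(w$index), ]
    if (nrow(w) < 2) return(numeric(0))
    mid <- (w$start + w$end) / 2
    pmax(haldane_r(diff(mid) / 1e6 * rate_cm_per_mb), r_min)
  })
}

.default_fixed_rate <- function(design) if (design$kind == "F2") 5.0 else 10.0

# intra tibble (scaffold, gap, r) -> named list of chunks
.intra_as_list <- function(intra, markers) {
  if (is.null(intra)) return(NULL)
  if (is.list(intra) && !is.data.frame(intra)) return(intra)
  sp <- split(intra, intra$scaffold)
  out <- lapply(sp, function(d) d$r[order(d$gap)])
  # scaffolds absent from the tibble (single-marker) get empty chunks
  out[setdiff(unique(markers$scaffold), names(out))] <- list(numeric(0))
  out
}
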