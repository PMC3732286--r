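# Independent oracles used across the suite.  These deliberately share
# no code with the package internals: transmissions are counted by
# explicit allele bookkeeping, expected counts by brute-force
# enumeration, and likelihood maxima by grid search.

# alleles of a dosage-coded genotype (count of A1)
oracle_alleles <- function(d) switch(d + 1L, c(0L, 0L), c(1L, 0L), c(1L, 1L))

# brute-force transmission counts for one trio; NULL when inconsistent
oracle_transmissions <- function(f, m, c) {
  t <- u <- 0; nv <- 0L
  for (tf in oracle_alleles(f)) {
    for (tm in oracle_alleles(m)) {
      if (tf + tm != c) next
      nv <- nv + 1L
      if (f == 1L) { if (tf == 1L) t <- t + 1 else u <- u + 1 }
      if (m == 1L) { if (tm == 1L) t <- t + 1 else u <- u + 1 }
    }
  }
  if (nv == 0L) return(NULL)
  c(t = t / nv, u = u / nv)
}

# brute-force expected transmissions: enumerate all 27 configurations
oracle_expected <- function(pf, pm, pc) {
  tot_w <- 0; tot_t <- 0; tot_u <- 0
  for (f in 0:2) for (m in 0:2) for (c in 0:2) {
    w <- pf[3 - f] * pm[3 - m] * pc[3 - c]
    cnt <- oracle_transmissions(f, m, c)
    if (is.null(cnt)) next
    tot_w <- tot_w + w
    tot_t <- tot_t + w * cnt["t"]
    tot_u <- tot_u + w * cnt["u"]
  }
  if (tot_w < 1e-9) return(c(t = NA_real_, u = NA_real_))
  c(t = unname(tot_t) / tot_w, u = unname(tot_u) / tot_w)
}

# random Mendelian-consistent trio as dosages (father, mother, child)
random_consistent_trio <- function() {
  repeat {
    f <- sample(0:2, 1L); m <- sample(0:2, 1L)
    tf <- sample(oracle_alleles(f), 1L); tm <- sample(oracle_alleles(m), 1L)
    return(c(f = f, m = m, c = tf + tm))
  }
}

# certainty posterior for a dosage
certain_posterior <- function(d) {
  p <- c(0, 0, 0); p[3 - d] <- 1; p
}

# coarse grid-search maximiser of the two-locus likelihood for a given
# penetrance parameterisation (list of parameter grids -> f matrix)
grid_loglik_max <- function(tables, f_from, grids) {
  p_grid <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  best <- -Inf
  combos <- do.call(expand.grid, grids)
  for (pa in p_grid) for (pb in p_grid) {
    for (r in seq_len(nrow(combos))) {
      f <- f_from(as.numeric(combos[r, ]))
      ll <- two_locus_loglik(tables, pa, pb, f)
      if (ll > best) best <- ll
    }
  }
  best
}

# two-sided permutation test for a difference in group means
permutation_test <- function(x, y, n_perm = 4000L) {
  obs <- abs(mean(x) - mean(y))
  z <- c(x, y); nx <- length(x)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(z), nx)
    if (abs(mean(z[idx]) - mean(z[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# quick null two-locus tables: N families, HWE parents, Mendelian
# transmission, genotype-independent affection (case = first child,
# pseudo-control = untransmitted alleles)
simulate_null_tables <- function(n_fam, p_a = 0.4, p_b = 0.6) {
  draw_locus <- function(p) {
    fh <- matrix(stats::rbinom(2L * n_fam, 1L, p), ncol = 2L)
    mh <- matrix(stats::rbinom(2L * n_fam, 1L, p), ncol = 2L)
    tf <- ifelse(stats::runif(n_fam) < 0.5, fh[, 1L], fh[, 2L])
    tm <- ifelse(stats::runif(n_fam) < 0.5, mh[, 1L], mh[, 2L])
    child <- tf + tm
    pseudo <- rowSums(fh) + rowSums(mh) - child
    cbind(child, pseudo)
  }
  A <- draw_locus(p_a); B <- draw_locus(p_b)
  n <- m <- matrix(0L, 3L, 3L)
  for (i in seq_len(n_fam)) {
    n[A[i, 1L] + 1L, B[i, 1L] + 1L] <- n[A[i, 1L] + 1L, B[i, 1L] + 1L] + 1L
    m[A[i, 2L] + 1L, B[i, 2L] + 1L] <- m[A[i, 2L] + 1L, B[i, 2L] + 1L] + 1L
  }
  two_locus_tables(n, m)
}
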