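# Two-locus interaction machinery: pseudo-controls, tabulation,
# likelihood arithmetic, model fitting, LRT and classification.

test_that("pseudo-control genotype is the untransmitted allele pair", {
  expect_equal(pseudo_control_genotype("AB", "AB", "AA"), 0L)  # BB remains
  expect_equal(pseudo_control_genotype("AB", "AB", "AB"), 1L)  # both phases -> AB
  expect_equal(pseudo_control_genotype("AA", "AA", "AA"), 2L)
  expect_equal(pseudo_control_genotype("AB", "AA", "AB"), 2L)
  expect_error(pseudo_control_genotype("AA", "AA", "AB"), "inconsistent")
})

test_that("case + pseudo-control dosages conserve parental dosages", {
  set.seed(17)
  for (i in 1:100) {
    tr <- random_consistent_trio()
    pc <- pseudo_control_genotype(tr["f"], tr["m"], tr["c"])
    expect_equal(pc + tr[["c"]], tr[["f"]] + tr[["m"]])
  }
})

test_that("tabulate_two_locus conserves family counts", {
  sim <- simulate_families(sim_config(n_families = 95, seed = 19))
  tab <- tabulate_two_locus(sim, "epiA", "epiB")
  expect_equal(sum(tab$n), 95L)
  expect_equal(sum(tab$m), 95L)
  expect_equal(tab$n_families, 95L)
  # one affected offspring per family even with affected sib pairs
  expect_gt(nrow(sim$trios), 95L)
})

test_that("tabulate_two_locus skips pairs with too few complete families", {
  sim <- simulate_families(sim_config(n_families = 10, seed = 20))
  expect_warning(tab <- tabulate_two_locus(sim, "epiA", "epiB",
                                           min_families = 20L), "skipped")
  expect_null(tab)
})

test_that("the log-likelihood matches closed-form multinomial arithmetic", {
  # single case at the double-homozygote cell with p = q = 1 boundary
  n <- matrix(0L, 3, 3); n[3, 3] <- 1L
  m <- matrix(0L, 3, 3); m[3, 3] <- 1L
  tab <- two_locus_tables(n, m)
  expect_equal(two_locus_loglik(tab, 1, 1, matrix(0.5, 3, 3)), 0)
  # HWE-proportional tables at p = q = 0.5: constant-f likelihood equals
  # the saturated multinomial value, which MG cannot improve
  hw <- c(1, 2, 1) / 4
  n2 <- 16 * outer(hw, hw)
  tab2 <- two_locus_tables(n2, n2)
  ll <- two_locus_loglik(tab2, 0.5, 0.5, matrix(0.3, 3, 3))
  saturated <- sum(n2 * log(n2 / 16)) + sum(n2 * log(n2 / 16))
  expect_equal(ll, saturated)
  expect_equal(fit_two_locus(tab2, "MG")$loglik, saturated, tolerance = 1e-9)
})

test_that("the log-likelihood matches a hand-computed two-family example", {
  # family 1: case (AA, AB) -> cell (2,1); pseudo (AB, AA) -> (1,2)
  # family 2: case (AB, AB) -> cell (1,1); pseudo (BB, AB) -> (0,1)
  n <- matrix(0L, 3, 3); n[3, 2] <- 1L; n[2, 2] <- 1L
  m <- matrix(0L, 3, 3); m[2, 3] <- 1L; m[1, 2] <- 1L
  tab <- two_locus_tables(n, m)
  pa <- 0.4; pb <- 0.6
  f <- matrix(c(0.1, 0.2, 0.3, 0.2, 0.4, 0.6, 0.3, 0.6, 0.9), 3, 3)
  hA <- c((1 - pa)^2, 2 * pa * (1 - pa), pa^2)
  hB <- c((1 - pb)^2, 2 * pb * (1 - pb), pb^2)
  g <- outer(hA, hB)
  s <- sum(g * f)
  manual <- log(g[3, 2] * f[3, 2] / s) + log(g[2, 2] * f[2, 2] / s) +
    log(g[2, 3]) + log(g[1, 2])
  expect_equal(two_locus_loglik(tab, pa, pb, f), manual)
})

test_that("the likelihood is invariant to the penetrance scale", {
  set.seed(23)
  tab <- simulate_null_tables(60)
  f <- matrix(stats::runif(9, 0.1, 0.9), 3, 3)
  base <- two_locus_loglik(tab, 0.4, 0.6, f)
  for (cc in c(0.9, 0.5, 0.01)) {
    expect_equal(two_locus_loglik(tab, 0.4, 0.6, cc * f), base)
  }
})

test_that("M0 fits recover saturated-margin allele frequency estimates", {
  set.seed(29)
  tab <- simulate_null_tables(400, p_a = 0.3, p_b = 0.6)
  fit <- fit_two_locus(tab, "M0")
  nm <- tab$n + tab$m
  pa_hat <- sum((0:2) * rowSums(nm)) / (2 * sum(nm))
  pb_hat <- sum((0:2) * colSums(nm)) / (2 * sum(nm))
  expect_equal(unname(fit$p), c(pa_hat, pb_hat), tolerance = 1e-9)
})

test_that("fitted log-likelihoods respect model nesting on random tables", {
  set.seed(37)
  for (i in 1:20) {
    tab <- simulate_null_tables(50 + 10 * i)
    ll <- vapply(c("M0", "MR", "MM", "MG"),
                 function(mod) fit_two_locus(tab, mod, restarts = 5L,
                                             seed = i)$loglik, 0)
    expect_lte(ll[["M0"]], ll[["MR"]] + 1e-6)
    expect_lte(ll[["M0"]], ll[["MM"]] + 1e-6)
    expect_lte(ll[["MR"]], ll[["MG"]] + 1e-6)
    expect_lte(ll[["MM"]], ll[["MG"]] + 1e-6)
  }
})

test_that("fits beat a coarse grid-search oracle", {
  set.seed(41)
  tab <- simulate_null_tables(20)
  grid_const <- grid_loglik_max(tab, function(th) matrix(th[1L], 3, 3),
                                list(c(0.05, 0.2, 0.5)))
  expect_gte(fit_two_locus(tab, "M0")$loglik, grid_const - 1e-9)
  grid_het <- grid_loglik_max(
    tab,
    function(th) 1 - outer(1 - c(th[1L], th[2L], th[2L]),
                           1 - c(th[3L], th[4L], th[4L])),
    list(c(0.05, 0.3), c(0.05, 0.3), c(0.05, 0.3), c(0.05, 0.3))
  )
  expect_gte(fit_two_locus(tab, "MR", seed = 42)$loglik, grid_het - 1e-9)
  grid_mult <- grid_loglik_max(
    tab,
    function(th) outer(c(th[1L], th[2L], th[2L]), c(th[3L], th[4L], th[4L])),
    list(c(0.05, 0.3), c(0.05, 0.3), c(0.05, 0.3), c(0.05, 0.3))
  )
  expect_gte(fit_two_locus(tab, "MM")$loglik, grid_mult - 1e-9)
})

test_that("closed-form MM and MG maxima agree with direct numeric optimisation", {
  set.seed(43)
  tab <- simulate_null_tables(80)
  # numeric MG: optimise frequencies and 9 bounded penetrances
  obj <- function(th) {
    f <- matrix(th[3:11], 3, 3)
    ll <- two_locus_loglik(tab, th[1L], th[2L], f)
    if (!is.finite(ll)) 1e12 else -ll
  }
  best <- Inf
  for (s in 1:5) {
    start <- c(stats::runif(2, 0.2, 0.8), stats::runif(9, 0.05, 0.6))
    o <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0.001, 0.001, rep(1e-6, 9)),
                      upper = c(0.999, 0.999, rep(1 - 1e-6, 9)),
                      control = list(maxit = 500))
    best <- min(best, o$value)
  }
  expect_equal(fit_two_locus(tab, "MG")$loglik, -best, tolerance = 1e-4)
  expect_gte(fit_two_locus(tab, "MG")$loglik, -best - 1e-6)
})

test_that("the LRT reproduces the shared chi-square tail arithmetic", {
  f0 <- structure(list(loglik = 0, converged = TRUE, df_model = 2L),
                  class = "two_locus_fit")
  f1 <- structure(list(loglik = 30.27 / 2, converged = TRUE, df_model = 3L),
                  class = "two_locus_fit")
  out <- lrt(f0, f1)
  expect_equal(out$df, 1L)
  expect_equal(out$p.value, 3.76e-8, tolerance = 1e-3)
  expect_equal(lrt(f0, f0, df = 3)$p.value, 1)
  f_bad <- structure(list(loglik = NA, converged = FALSE, df_model = 10L),
                     class = "two_locus_fit")
  expect_true(is.na(lrt(f0, f_bad)$p.value))
})

test_that("LRT degrees of freedom follow identifiable-parameter counts", {
  set.seed(47)
  tab <- simulate_null_tables(50)
  fits <- lapply(stats::setNames(nm = c("M0", "MR", "MM", "MG")),
                 function(m) fit_two_locus(tab, m, seed = 3))
  expect_equal(lrt(fits$M0, fits$MG)$df, 8L)
  expect_equal(lrt(fits$MR, fits$MG)$df, 3L)
  expect_equal(lrt(fits$MM, fits$MG)$df, 4L)
})

test_that("classification applies the reporting thresholds", {
  expect_equal(classify_pair(2e-5, 3e-6, 0.01), "epistasis")
  expect_equal(classify_pair(2e-5, 0.6, 0.01), "heterogeneity")
  expect_equal(classify_pair(2e-3, 0.5, 0.01), "not-reported")
  expect_equal(classify_pair(2e-5, 0.5, 0.2), "multiplicative-consistent")
  expect_equal(classify_pair(2e-5, 0.01, 0.01), "unlabeled")
  expect_equal(classify_pair(c(2e-5, 1e-3), c(3e-6, 1), c(0.01, 1)),
               c("epistasis", "not-reported"))
})

test_that("expected_null_pairs rounds n * alpha", {
  expect_equal(expected_null_pairs(582, 0.05), 29)
  expect_equal(expected_null_pairs(0, 0.05), 0)
  expect_equal(expected_null_pairs(1000, 0.01), 10)
})

test_that("simulate() from a fitted model returns conserving tables", {
  set.seed(53)
  fit <- fit_two_locus(simulate_null_tables(60), "MG")
  sims <- simulate(fit, nsim = 3L, seed = 54)
  for (s in sims) {
    expect_s3_class(s, "two_locus_tables")
    expect_equal(sum(s$n), 60)
    expect_equal(sum(s$m), 60)
  }
})

test_that("interaction_scan tests only cross-region pairs", {
  sim <- simulate_families(sim_config(n_families = 60, seed = 59))
  sel <- data.frame(snp = c("epiA", "epiB", "hetA"),
                    chrom = c("2", "10", "3"),
                    bp = c(3e7, 5e7, 4e7))
  # put two markers in the same artificial region
  sel2 <- data.frame(snp = c("epiA", "epiB"), chrom = "2", bp = c(3e7, 3e7 + 5e4))
  reg_same <- build_regions(sel2)
  expect_equal(nrow(reg_same$regions), 1L)
  out <- interaction_scan(sim, sel, min_families = 20L, restarts = 3L, seed = 60)
  expect_equal(nrow(out), 3L)  # all pairs cross-region
  expect_true(all(c("p_02", "p_12", "p_m2", "classification") %in% names(out)))
  out_same <- interaction_scan(sim, sel2, regions = reg_same,
                               min_families = 20L, restarts = 3L, seed = 61)
  expect_equal(nrow(out_same), 0L)  # within-region pair excluded
})
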