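# TDT counting and testing: hard-call counts, expected counts from
# posteriors, the chi-square test, allele-swap symmetry, the stratified
# weighted chi-square and null calibration.

test_that("count_transmissions reproduces classical counting", {
  expect_equal(count_transmissions("AB", "AA", "AA"), c(t = 1, u = 0))
  expect_equal(count_transmissions("AB", "AB", "AB"), c(t = 1, u = 1))
  expect_equal(count_transmissions("AB", "AB", "AA"), c(t = 2, u = 0))
  expect_equal(count_transmissions("AA", "AB", "AB"), c(t = 0, u = 1))
  expect_error(count_transmissions("AA", "AA", "AB"), "inconsistent")
  expect_error(count_transmissions("AB", "MISSING", "AA"), "fully-called")
})

test_that("count_transmissions matches the allele-bookkeeping oracle everywhere", {
  for (f in 0:2) for (m in 0:2) for (c in 0:2) {
    oracle <- oracle_transmissions(f, m, c)
    if (is.null(oracle)) {
      expect_error(count_transmissions(f, m, c), "inconsistent")
    } else {
      expect_equal(count_transmissions(f, m, c), oracle)
    }
  }
})

test_that("tdt_test reproduces published transmission-count results", {
  r <- tdt_test(39, 90)
  expect_equal(r$chisq, 20.16, tolerance = 1e-3)
  expect_equal(r$p.value, 7.11e-6, tolerance = 1e-3)
  r2 <- tdt_test(87, 28)
  expect_equal(r2$chisq, 30.27, tolerance = 1e-4)
  expect_equal(r2$p.value, 3.76e-8, tolerance = 1e-3)
  expect_equal(tdt_test(10, 10)$chisq, 0)
  expect_equal(tdt_test(10, 10)$p.value, 1)
})

test_that("tdt_test handles edge counts", {
  r <- tdt_test(0, 0)
  expect_false(r$informative)
  expect_true(is.na(r$p.value))
  expect_true(is.na(tdt_test(5, 0)$odds))
  expect_error(tdt_test(-1, 2), "non-negative")
})

test_that("tdt_test agrees with McNemar's chi-square to machine precision", {
  set.seed(5)
  for (i in 1:50) {
    t <- rpois(1, 40); u <- rpois(1, 40)
    if (t + u == 0) next
    mc <- stats::mcnemar.test(matrix(c(0, t, u, 0), 2L), correct = FALSE)
    r <- tdt_test(t, u)
    expect_equal(r$chisq, unname(mc$statistic))
    expect_equal(r$p.value, mc$p.value)
  }
})

test_that("allele swap exchanges t/u, inverts odds, preserves chisq and p", {
  set.seed(6)
  for (i in 1:25) {
    t <- rpois(1, 30) + 1; u <- rpois(1, 30) + 1
    a <- tdt_test(t, u); b <- tdt_test(u, t)
    expect_equal(a$chisq, b$chisq)
    expect_equal(a$p.value, b$p.value)
    expect_equal(a$odds, 1 / b$odds)
  }
})

test_that("expected counts reduce exactly to hard-call counts for certain posteriors", {
  et <- expected_transmissions(certain_posterior(1), certain_posterior(2),
                               certain_posterior(2))
  expect_equal(et, c(t = 1, u = 0))
})

test_that("expected counts match brute-force enumeration on stated examples", {
  # uncertain father, certain AA mother and child
  et <- expected_transmissions(c(0.5, 0.5, 0), c(1, 0, 0), c(1, 0, 0))
  expect_equal(et, c(t = 0.5, u = 0))
  expect_equal(et, oracle_expected(c(0.5, 0.5, 0), c(1, 0, 0), c(1, 0, 0)))
  # het parents, uncertain child: weighted average of (2,0),(1,1),(0,2)
  et2 <- expected_transmissions(c(0, 1, 0), c(0, 1, 0), c(0.25, 0.5, 0.25))
  expect_equal(et2, c(t = 1, u = 1))
})

test_that("expected counts equal brute-force enumeration on random posteriors", {
  set.seed(9)
  for (i in 1:100) {
    pf <- stats::rexp(3); pf <- pf / sum(pf)
    pm <- stats::rexp(3); pm <- pm / sum(pm)
    pc <- stats::rexp(3); pc <- pc / sum(pc)
    expect_equal(expected_transmissions(pf, pm, pc),
                 oracle_expected(pf, pm, pc), tolerance = 1e-12)
  }
})

test_that("impossible posteriors are skipped with a warning", {
  expect_warning(
    et <- expected_transmissions(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)),
    "skipped"
  )
  expect_true(all(is.na(et)))
})

test_that("exp_tdt_test reproduces published expected-count p-values", {
  expect_equal(exp_tdt_test(61.44, 132.45)$p.value, 3.41e-7, tolerance = 0.02)
  expect_equal(exp_tdt_test(40.16, 98.48)$p.value, 7.30e-7, tolerance = 0.02)
  expect_equal(exp_tdt_test(50, 50)$chisq, 0)
})

test_that("assign_stratum implements the DQ carrier/homozygote rule", {
  expect_equal(assign_stratum(TRUE, 2L), "high")
  expect_equal(assign_stratum(TRUE, 1L), "low")
  expect_equal(assign_stratum(FALSE, 2L), "low")
  expect_true(is.na(assign_stratum(NA, 2L)))
})

test_that("the weighted chi-square reproduces published stratified results", {
  expect_equal(stratified_tdt(list(high = c(26, 35), low = c(87, 28)))$weighted_chisq,
               20.24, tolerance = 1e-3)
  expect_equal(stratified_tdt(list(high = c(41, 35), low = c(22, 69)))$weighted_chisq,
               13.44, tolerance = 1e-3)
  expect_equal(stratified_tdt(list(high = c(20, 25), low = c(53, 15)))$weighted_chisq,
               13.00, tolerance = 1e-3)
})

test_that("the weighted chi-square reduces to the plain chi-square for one stratum", {
  s <- stratified_tdt(list(all = c(39, 90)))
  expect_equal(s$weighted_chisq, tdt_test(39, 90)$chisq)
  # an empty stratum contributes nothing
  s2 <- stratified_tdt(list(a = c(39, 90), b = c(0, 0)))
  expect_equal(s2$weighted_chisq, tdt_test(39, 90)$chisq)
})

test_that("tdt_scan with blurred certain posteriors equals the hard-call scan", {
  sim <- simulate_families(sim_config(n_families = 40, seed = 21))
  certain <- blur_posteriors(sim, lambda = 0, seed = 22)
  hard <- tdt_scan(sim, mode = "hard")
  expd <- tdt_scan(certain, mode = "expected")
  j <- match(hard$snp, expd$snp)
  expect_equal(hard$t, expd$t[j], tolerance = 1e-12)
  expect_equal(hard$u, expd$u[j], tolerance = 1e-12)
})

test_that("stratified scan weights match per-marker recomputation", {
  sim <- simulate_families(sim_config(n_families = 60, seed = 23))
  scan <- tdt_scan(sim, stratified = TRUE)
  k <- which(scan$snp == "risk1")
  w <- stratified_tdt(list(high = c(scan$t_high[k], scan$u_high[k]),
                           low = c(scan$t_low[k], scan$u_low[k])))$weighted_chisq
  expect_equal(scan$weighted_chisq[k], w)
  expect_false(is.unsorted(rev(scan$weighted_chisq)))  # ranked descending
})

test_that("hard and expected TDT hold the nominal null level", {
  set.seed(31)
  n_rep <- 300L
  n_fam <- 80L
  rej_hard <- rej_exp <- logical(n_rep)
  mk <- sim_marker_panel(n_null = 0L)[1:2, ]
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_families = n_fam, markers = mk,
                      disease = list(penetrance_constant(0.5)),
                      stratum_marker = NULL, seed = 1000L + r)
    sim <- simulate_families(cfg)
    hard <- tdt_scan(sim, mode = "hard")
    rej_hard[r] <- hard$p[hard$snp == "risk1"] < 0.05
    blurred <- blur_posteriors(sim, lambda = 0.05, seed = 2000L + r)
    expd <- tdt_scan(blurred, mode = "expected")
    rej_exp[r] <- expd$p[expd$snp == "risk1"] < 0.05
  }
  mc <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej_hard) - 0.05), mc)
  expect_lt(abs(mean(rej_exp) - 0.05), mc)
})

test_that("exclude_hla drops only chr6 27-34 Mb markers", {
  mk <- data.frame(chrom = c("6", "6", "5"),
                   bp = c(30e6, 35e6, 30e6),
                   snp = c("a", "b", "c"))
  out <- exclude_hla(mk)
  expect_equal(out$snp, c("b", "c"))
})
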