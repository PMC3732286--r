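# Transmission disequilibrium testing: classical hard-call counting,
# expected counts from imputation posteriors, the chi-square test on
# either kind of count, and the HLA-stratified weighted chi-square.

#' Count allele transmissions in consistent trios
#'
#' Classical TDT bookkeeping: each heterozygous parent contributes
#' exactly one transmission, to `t` when allele A1 was transmitted to
#' the affected child and to `u` otherwise.  When both parents and the
#' child are heterozygous, the two phase resolutions average to the
#' conventional (1, 1) contribution.
#'
#' @param father,mother,child genotypes (states or A1 dosages),
#'   vectorised over trios.  All members must be called and the trio
#'   Mendelian-consistent; inconsistent trios raise an error (they should
#'   have been masked upstream).
#' @return a one-row-per-trio matrix with columns `t` and `u`; for a
#'   single trio, a named numeric vector `c(t, u)`.
#' @examples
#' count_transmissions("AB", "AA", "AA")   # c(t = 1, u = 0)
#' count_transmissions("AB", "AB", "AB")   # c(t = 1, u = 1)
#' @export
count_transmissions <- function(father, mother, child) {
  f <- as_dosage(father); m <- as_dosage(mother); c_ <- as_dosage(child)
  if (any(is.na(f) | is.na(m) | is.na(c_))) {
    stop("count_transmissions requires fully-called trios")
  }
  idx <- .cfg_index(f, m, c_)
  if (any(!.geno_cfg$consistent[idx])) {
    stop("Mendelian-inconsistent trio passed to count_transmissions")
  }
  out <- cbind(t = .geno_cfg$t[idx], u = .geno_cfg$u[idx])
  if (nrow(out) == 1L) c(t = unname(out[1L, 1L]), u = unname(out[1L, 2L])) else out
}

#' Expected transmission counts from genotype posteriors
#'
#' Enumerates the 27 joint hard-genotype configurations of a trio,
#' weights each by the product of the three members' posterior
#' probabilities, discards Mendelian-inconsistent configurations, and
#' renormalises over the consistent mass, so that each trio contributes
#' on the same scale as a hard-called trio.  The expected `(t, u)` is
#' the weighted average of the classical counts over configurations.
#' Trios whose consistent mass falls below `1e-9` (e.g. an all-zero
#' posterior) are skipped with a warning and return `NA`.
#'
#' @param father,mother,child posterior triplets `(p_AA, p_AB, p_BB)`:
#'   length-3 vectors for one trio or `n x 3` matrices for `n` trios.
#' @return matrix with columns `t`, `u` (or a named vector for a single
#'   trio); real-valued expected counts.
#' @export
expected_transmissions <- function(father, mother, child) {
  scalar <- is.null(dim(father))
  PF <- if (scalar) matrix(father, nrow = 1L) else as.matrix(father)
  PM <- if (scalar) matrix(mother, nrow = 1L) else as.matrix(mother)
  PC <- if (scalar) matrix(child, nrow = 1L) else as.matrix(child)
  .validate_posteriors(PF); .validate_posteriors(PM); .validate_posteriors(PC)
  et <- .exp_trans(PF, PM, PC)
  if (anyNA(et)) {
    warning(sum(is.na(et[, 1L])),
            " trio(s) skipped: no Mendelian-consistent posterior mass")
  }
  if (scalar) c(t = unname(et[1L, 1L]), u = unname(et[1L, 2L])) else et
}

# vectorised core: posterior column for dosage d is 3 - d
.exp_trans <- function(PF, PM, PC) {
  cf <- 3L - .geno_cfg$f
  cm <- 3L - .geno_cfg$m
  cc <- 3L - .geno_cfg$c
  W <- PF[, cf, drop = FALSE] * PM[, cm, drop = FALSE] * PC[, cc, drop = FALSE]
  W[, !.geno_cfg$consistent] <- 0
  mass <- rowSums(W)
  tvec <- as.vector(W %*% .geno_cfg$t) / mass
  uvec <- as.vector(W %*% .geno_cfg$u) / mass
  bad <- !is.finite(mass) | mass < 1e-9
  tvec[bad] <- NA_real_
  uvec[bad] <- NA_real_
  cbind(t = tvec, u = uvec)
}

#' Transmission disequilibrium chi-square test
#'
#' The 1-df McNemar-type statistic `(t - u)^2 / (t + u)` with upper-tail
#' chi-square p-value.  Counts may be integers (hard calls) or reals
#' (expected counts from posteriors); the same functional applies to
#' both, and on expected counts the statistic has approximately the same
#' null distribution as the classical TDT.
#'
#' @param t transmissions of allele A1, or a length-2 vector `c(t, u)`.
#' @param u non-transmissions of A1.
#' @return an object of class `tdt` with components `counts`, `chisq`,
#'   `p.value`, `odds` (the transmission odds `t/u`, `NA` when `u = 0`)
#'   and `informative` (`FALSE` when `t + u = 0`, in which case the
#'   statistic and p-value are `NA`).
#' @examples
#' tdt_test(39, 90)     # chisq 20.16, p 7.1e-06
#' @export
tdt_test <- function(t, u = NULL) {
  if (is.null(u)) { u <- t[[2L]]; t <- t[[1L]] }
  if (any(c(t, u) < 0)) stop("transmission counts must be non-negative")
  informative <- (t + u) > 0
  chisq <- if (informative) (t - u)^2 / (t + u) else NA_real_
  p <- if (informative) stats::pchisq(chisq, df = 1L, lower.tail = FALSE) else NA_real_
  structure(list(
    counts = c(t = unname(t), u = unname(u)),
    chisq = unname(chisq),
    p.value = unname(p),
    odds = if (u > 0) unname(t / u) else NA_real_,
    informative = informative
  ), class = "tdt")
}

#' @rdname tdt_test
#' @details `exp_tdt_test()` is the expected-count form: identical
#'   arithmetic applied to real-valued expected transmission counts.
#' @export
exp_tdt_test <- tdt_test

#' @export
print.tdt <- function(x, ...) {
  cat("Transmission disequilibrium test\n")
  cat(sprintf("  T = %.4g, U = %.4g, odds = %s\n", x$counts["t"], x$counts["u"],
              ifelse(is.na(x$odds), "NA", sprintf("%.3g", x$odds))))
  if (x$informative) {
    cat(sprintf("  chisq = %.4g (1 df), p = %.3g\n", x$chisq, x$p.value))
  } else {
    cat("  non-informative (t + u = 0)\n")
  }
  invisible(x)
}

#' Assign HLA-DQ risk stratum
#'
#' A child belongs to the high-risk stratum when it carries the
#' DQA1*02/05 risk allele and is homozygous for DQB1*02 (two copies);
#' every other combination is low-risk.
#'
#' @param dqa_carrier logical, carrier of DQA1*02/05.
#' @param dqb_copies integer copies (0-2) of DQB1*02.
#' @return character vector `"high"`/`"low"`, `NA` when either input is
#'   missing.
#' @export
assign_stratum <- function(dqa_carrier, dqb_copies) {
  out <- ifelse(dqa_carrier & dqb_copies == 2L, "high", "low")
  out[is.na(dqa_carrier) | is.na(dqb_copies)] <- NA_character_
  out
}

#' Stratified TDT with the weighted chi-square ranking statistic
#'
#' Applies the TDT separately within each stratum and combines the
#' per-stratum counts into the ranking statistic
#' `sum_g (t_g - u_g)^2 / sum_g (t_g + u_g)`.  With a single stratum the
#' weighted statistic equals the plain chi-square.  Strata with
#' `t + u = 0` contribute zero to both sums.  No p-value is attached to
#' the weighted statistic; it is used for ranking markers.
#'
#' @param counts a named list of per-stratum count pairs `c(t, u)`, e.g.
#'   `list(high = c(26, 35), low = c(87, 28))`.
#' @return an object of class `stratified_tdt` with `per_stratum` (a
#'   list of [tdt_test()] results) and `weighted_chisq`.
#' @examples
#' stratified_tdt(list(high = c(26, 35), low = c(87, 28)))  # 20.24
#' @export
stratified_tdt <- function(counts) {
  stopifnot(is.list(counts), length(counts) >= 1L)
  per <- lapply(counts, function(cu) tdt_test(cu[[1L]], cu[[2L]]))
  t_g <- vapply(counts, function(cu) cu[[1L]], 0)
  u_g <- vapply(counts, function(cu) cu[[2L]], 0)
  denom <- sum(t_g + u_g)
  w <- if (denom > 0) sum((t_g - u_g)^2) / denom else NA_real_
  structure(list(per_stratum = per, weighted_chisq = w,
                 counts = cbind(t = t_g, u = u_g)),
            class = "stratified_tdt")
}

#' @export
print.stratified_tdt <- function(x, ...) {
  cat("Stratified TDT\n")
  for (s in names(x$per_stratum)) {
    r <- x$per_stratum[[s]]
    cat(sprintf("  %-6s T = %.4g, U = %.4g, chisq = %s, p = %s\n", s,
                r$counts["t"], r$counts["u"],
                ifelse(is.na(r$chisq), "NA", sprintf("%.4g", r$chisq)),
                ifelse(is.na(r$p.value), "NA", sprintf("%.3g", r$p.value))))
  }
  cat(sprintf("  weighted chisq (ranking) = %.4g\n", x$weighted_chisq))
  invisible(x)
}

# Per-trio hard-call (t, u) across a marker panel.  Returns a list with
# per-marker aggregated counts plus bookkeeping.  Inconsistent trios are
# masked (excluded) marker-wise, mirroring family-wise Mendelian masking.
.hard_counts <- function(panel, threshold = 0.95, trios = NULL) {
  if (is.null(trios)) trios <- panel$trios
  G <- panel$G
  if (!is.null(panel$P)) {
    # hard-call from posteriors marker by marker
    n <- dim(panel$P)[1L]; K <- dim(panel$P)[2L]
    G <- matrix(NA_integer_, n, K, dimnames = list(dimnames(panel$P)[[1L]], panel$markers$id))
    for (k in seq_len(K)) G[, k] <- hard_call(panel$P[, k, ], threshold)
  }
  fi <- match(trios$father_id, rownames(G))
  mi <- match(trios$mother_id, rownames(G))
  oi <- match(trios$offspring_id, rownames(G))
  Fm <- G[fi, , drop = FALSE]; Mm <- G[mi, , drop = FALSE]; Cm <- G[oi, , drop = FALSE]
  idx <- .cfg_index(Fm, Mm, Cm)
  cons <- .geno_cfg$consistent[idx]
  use <- !is.na(idx) & cons
  t_tr <- ifelse(use, .geno_cfg$t[idx], NA_real_)
  u_tr <- ifelse(use, .geno_cfg$u[idx], NA_real_)
  dim(t_tr) <- dim(u_tr) <- dim(Fm)
  list(t = colSums(t_tr, na.rm = TRUE), u = colSums(u_tr, na.rm = TRUE),
       n_masked = colSums(matrix(!is.na(idx) & !cons, nrow(Fm))))
}

.expected_counts <- function(panel, trios = NULL) {
  if (is.null(trios)) trios <- panel$trios
  if (is.null(panel$P)) stop("expected-count TDT requires posterior probabilities")
  P <- panel$P
  fi <- match(trios$father_id, dimnames(P)[[1L]])
  mi <- match(trios$mother_id, dimnames(P)[[1L]])
  oi <- match(trios$offspring_id, dimnames(P)[[1L]])
  K <- dim(P)[2L]
  tt <- uu <- numeric(K)
  for (k in seq_len(K)) {
    et <- .exp_trans(matrix(P[fi, k, ], ncol = 3L),
                     matrix(P[mi, k, ], ncol = 3L),
                     matrix(P[oi, k, ], ncol = 3L))
    tt[k] <- sum(et[, 1L], na.rm = TRUE)
    uu[k] <- sum(et[, 2L], na.rm = TRUE)
  }
  list(t = tt, u = uu)
}

#' Panel-wide TDT scan
#'
#' Runs the TDT at every marker of a trio panel, from hard calls
#' (`mode = "hard"`, with family-wise Mendelian masking) or from
#' imputation posteriors (`mode = "expected"`).  With
#' `stratified = TRUE` the hard-call TDT is run separately in the
#' high- and low-risk strata and markers are ranked by the weighted
#' chi-square.
#'
#' @param panel a [trio_panel()] (or anything [as_trio_panel()] accepts).
#' @param mode `"hard"` or `"expected"`.
#' @param threshold hard-call posterior threshold (strict `>`).
#' @param stratified run the HLA-stratified analysis (requires a
#'   `stratum` column on the trios).
#' @param exclude_hla drop markers in the extended HLA interval
#'   (chromosome 6, 27-34 Mb) from the output.
#' @param one_per_family keep only the first affected offspring per
#'   family (by pedigree order) instead of counting every affected sib's
#'   trio.
#' @return a data frame of class `tdt_scan` with columns `chrom`, `snp`,
#'   `bp`, `a1`, `a2`, `t`, `u`, `odds`, `chisq`, `p`; in stratified mode
#'   per-stratum blocks plus `weighted_chisq`, sorted by decreasing
#'   weighted chi-square.
#' @export
tdt_scan <- function(panel, mode = c("hard", "expected"), threshold = 0.95,
                     stratified = FALSE, exclude_hla = FALSE,
                     one_per_family = FALSE) {
  panel <- as_trio_panel(panel)
  mode <- match.arg(mode)
  trios <- panel$trios
  if (one_per_family) trios <- trios[!duplicated(trios$family_id), , drop = FALSE]
  mk <- panel$markers
  base <- data.frame(chrom = mk$chrom, snp = mk$id, bp = mk$bp,
                     a1 = mk$a1, a2 = mk$a2, stringsAsFactors = FALSE)
  finish <- function(df, order_by) {
    if (exclude_hla) df <- exclude_hla(df)
    df <- df[order(df[[order_by]], decreasing = TRUE), , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("tdt_scan", "data.frame")
    attr(df, "mode") <- mode
    df
  }
  if (!stratified) {
    cnt <- if (mode == "hard") .hard_counts(panel, threshold, trios)
           else .expected_counts(panel, trios)
    stat <- .tdt_vec(cnt$t, cnt$u)
    out <- cbind(base, t = cnt$t, u = cnt$u, odds = stat$odds,
                 chisq = stat$chisq, p = stat$p)
    return(finish(out, "chisq"))
  }
  if (is.null(trios$stratum)) stop("stratified scan requires a stratum column on the trios")
  keep <- !is.na(trios$stratum)
  if (any(!keep)) {
    warning(sum(!keep), " trio(s) without stratum label excluded from stratified TDT")
    trios <- trios[keep, , drop = FALSE]
  }
  if (mode != "hard") stop("the stratified TDT uses hard-call counts")
  hi <- .hard_counts(panel, threshold, trios[trios$stratum == "high", , drop = FALSE])
  lo <- .hard_counts(panel, threshold, trios[trios$stratum == "low", , drop = FALSE])
  sh <- .tdt_vec(hi$t, hi$u); sl <- .tdt_vec(lo$t, lo$u)
  denom <- hi$t + hi$u + lo$t + lo$u
  w <- ifelse(denom > 0, ((hi$t - hi$u)^2 + (lo$t - lo$u)^2) / denom, NA_real_)
  all_ <- .tdt_vec(hi$t + lo$t, hi$u + lo$u)
  out <- cbind(base,
               t_high = hi$t, u_high = hi$u, odds_high = sh$odds,
               chisq_high = sh$chisq, p_high = sh$p,
               t_low = lo$t, u_low = lo$u, odds_low = sl$odds,
               chisq_low = sl$chisq, p_low = sl$p,
               weighted_chisq = w,
               t = hi$t + lo$t, u = hi$u + lo$u, odds = all_$odds,
               chisq = all_$chisq, p = all_$p)
  finish(out, "weighted_chisq")
}

.tdt_vec <- function(t, u) {
  s <- t + u
  chisq <- ifelse(s > 0, (t - u)^2 / s, NA_real_)
  list(chisq = chisq,
       p = ifelse(s > 0, stats::pchisq(chisq, 1L, lower.tail = FALSE), NA_real_),
       odds = ifelse(u > 0, t / u, NA_real_))
}

#' Manhattan-style plot of a TDT scan
#'
#' @param x a `tdt_scan` data frame.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tdt_scan <- function(x, ...) {
  chrom <- factor(x$chrom, levels = unique(x$chrom[order(suppressWarnings(as.numeric(x$chrom)), x$chrom)]))
  off <- c(0, cumsum(tapply(x$bp, chrom, max, na.rm = TRUE)))
  pos <- x$bp + off[as.integer(chrom)]
  graphics::plot(pos, -log10(x$p), pch = 20,
                 col = c("grey30", "steelblue")[1L + as.integer(chrom) %% 2L],
                 xlab = "genome position", ylab = expression(-log[10](p)), ...)
  invisible(x)
}
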