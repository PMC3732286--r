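# Two-locus gene-gene interaction analysis on case / pseudo-control
# genotype tables.
#
# For a pair of unlinked biallelic loci, let n be the 3x3 matrix of
# joint genotype counts among cases (one affected offspring per family)
# and m the matrix of the non-transmitted (pseudo-control) genotype
# combinations.  Under Hardy-Weinberg frequencies g_ij = hA_i * hB_j
# (dosage-indexed, no LD) and a penetrance matrix f, the log-likelihood
# is
#
#   l = sum_ij n_ij log( g_ij f_ij / sum_kl g_kl f_kl ) + sum_ij m_ij log g_ij
#
# Four nested penetrance models are fitted by maximum likelihood:
#   M0 (no association, constant f), MR (heterogeneity,
#   f = 1-(1-a_i)(1-b_j)), MM (multiplicative, f = a_i b_j) and MG
#   (9 free parameters).  Because the case term depends on f only up to
#   scale, the case distribution under MG is unrestricted and under MM it
#   is an arbitrary product distribution, so the M0, MM and MG maxima
#   have closed forms; only MR requires numerical optimisation.
# Likelihood-ratio statistics are referred to chi-square distributions
# with degrees of freedom from identifiable-parameter counts:
# M0 = 2, MM = 6, MR = 7, MG = 10, giving 8 / 4 / 3 df for the
# M0-, MM- and MR-versus-MG tests.

.P_BOUNDS <- c(0.001, 0.999)
.F_BOUNDS <- c(1e-6, 1 - 1e-6)
.MODEL_DF <- c(M0 = 2L, MM = 6L, MR = 7L, MG = 10L)

.hwe <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

.xlogy <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(y[pos])
  out
}

.clamp_p <- function(p) pmin(pmax(p, .P_BOUNDS[1L]), .P_BOUNDS[2L])

# allele-A1 frequency implied by a 3x3 table's row / column margins
.freq_margin <- function(mat, margin) {
  cnt <- if (margin == 1L) rowSums(mat) else colSums(mat)
  tot <- sum(cnt)
  if (tot == 0) return(0.5)
  sum((0:2) * cnt) / (2 * tot)
}

#' Pseudo-control genotype of a trio
#'
#' The genotype formed by the two parental alleles NOT transmitted to
#' the affected child: the multiset difference of (father's alleles +
#' mother's alleles) minus the child's alleles.  In dosage form this is
#' `father + mother - child`, well defined for every
#' Mendelian-consistent trio (both resolutions of the double
#' heterozygote give the same genotype).
#'
#' @param father,mother,child genotypes (states or A1 dosages),
#'   vectorised.
#' @return pseudo-control A1 dosage(s); `NA` when a member is missing.
#' @examples
#' pseudo_control_genotype("AB", "AB", "AA")  # 0 (BB)
#' @export
pseudo_control_genotype <- function(father, mother, child) {
  f <- as_dosage(father); m <- as_dosage(mother); c_ <- as_dosage(child)
  full <- !(is.na(f) | is.na(m) | is.na(c_))
  if (any(full & !.geno_cfg$consistent[.cfg_index(f, m, c_)])) {
    stop("Mendelian-inconsistent trio passed to pseudo_control_genotype")
  }
  out <- f + m - c_
  out[!full] <- NA_integer_
  out
}

#' Tabulate case and pseudo-control counts for a marker pair
#'
#' Builds the paired 3x3 genotype-count matrices for a two-locus
#' interaction test.  One affected offspring per family is used (the
#' first affected by pedigree order); its joint genotype increments the
#' case matrix `n` and the per-locus pseudo-control genotypes increment
#' `m`.  Families with any missing genotype among the six involved, or a
#' Mendelian inconsistency at either locus, are skipped.
#'
#' @param panel a trio panel with hard-call dosages (posteriors are
#'   hard-called at `threshold`).
#' @param snp_a,snp_b marker ids.
#' @param min_families minimum complete families; below it the pair is
#'   skipped with a warning and `NULL` is returned.
#' @param threshold hard-call threshold when the panel holds posteriors.
#' @return an object of class `two_locus_tables`: list with 3x3 integer
#'   matrices `n` and `m` (rows = A-locus dosage 0..2, columns =
#'   B-locus dosage), `n_families`, and the marker ids.
#' @export
tabulate_two_locus <- function(panel, snp_a, snp_b, min_families = 20L,
                               threshold = 0.95) {
  panel <- as_trio_panel(panel)
  trios <- panel$trios[!duplicated(panel$trios$family_id), , drop = FALSE]
  ka <- match(snp_a, panel$markers$id)
  kb <- match(snp_b, panel$markers$id)
  if (is.na(ka) || is.na(kb)) stop("marker not in panel: ", snp_a, " / ", snp_b)
  dos <- function(k) {
    if (!is.null(panel$P)) hard_call(panel$P[, k, ], threshold) else panel$G[, k]
  }
  ga <- dos(ka); gb <- dos(kb)
  ids <- panel$sample_ids
  fi <- match(trios$father_id, ids); mi <- match(trios$mother_id, ids)
  oi <- match(trios$offspring_id, ids)
  fa <- ga[fi]; ma <- ga[mi]; ca <- ga[oi]
  fb <- gb[fi]; mb <- gb[mi]; cb <- gb[oi]
  ok <- !(is.na(fa) | is.na(ma) | is.na(ca) | is.na(fb) | is.na(mb) | is.na(cb))
  ok[ok] <- .geno_cfg$consistent[.cfg_index(fa[ok], ma[ok], ca[ok])] &
    .geno_cfg$consistent[.cfg_index(fb[ok], mb[ok], cb[ok])]
  nfam <- sum(ok)
  if (nfam < min_families) {
    warning("pair ", snp_a, " x ", snp_b, " skipped: only ", nfam,
            " complete families (minimum ", min_families, ")")
    return(NULL)
  }
  pa <- fa[ok] + ma[ok] - ca[ok]
  pb <- fb[ok] + mb[ok] - cb[ok]
  n <- m <- matrix(0L, 3L, 3L, dimnames = list(dosage_a = 0:2, dosage_b = 0:2))
  for (i in seq_len(nfam)) {
    n[ca[ok][i] + 1L, cb[ok][i] + 1L] <- n[ca[ok][i] + 1L, cb[ok][i] + 1L] + 1L
    m[pa[i] + 1L, pb[i] + 1L] <- m[pa[i] + 1L, pb[i] + 1L] + 1L
  }
  two_locus_tables(n, m, snp_a = snp_a, snp_b = snp_b)
}

#' Construct two-locus count tables
#'
#' @param n,m 3x3 case and pseudo-control count matrices (rows = A-locus
#'   A1 dosage 0..2, columns = B-locus dosage).
#' @param snp_a,snp_b optional marker ids.
#' @return an object of class `two_locus_tables`.
#' @export
two_locus_tables <- function(n, m, snp_a = "A", snp_b = "B") {
  n <- as.matrix(n); m <- as.matrix(m)
  stopifnot(all(dim(n) == c(3L, 3L)), all(dim(m) == c(3L, 3L)),
            all(n >= 0), all(m >= 0))
  if (sum(n) != sum(m)) stop("case and pseudo-control totals must agree")
  structure(list(n = n, m = m, n_families = sum(n),
                 snp_a = snp_a, snp_b = snp_b),
            class = "two_locus_tables")
}

#' @export
print.two_locus_tables <- function(x, ...) {
  cat("two-locus tables:", x$snp_a, "x", x$snp_b,
      "(", x$n_families, "families )\n")
  cat("cases:\n"); print(x$n)
  cat("pseudo-controls:\n"); print(x$m)
  invisible(x)
}

#' Two-locus penetrance log-likelihood
#'
#' Evaluates the interaction model log-likelihood for given allele
#' frequencies and penetrance matrix (see the model description in
#' [fit_two_locus()]).  Returns `-Inf` when a genotype class with
#' observed counts has zero frequency.
#'
#' @param tables a `two_locus_tables` object (or a list with `n`, `m`).
#' @param p_a,p_b A1 allele frequencies at the two loci.
#' @param f 3x3 penetrance matrix (entries in (0, 1); only its scale-free
#'   shape enters the likelihood).
#' @return the log-likelihood.
#' @export
two_locus_loglik <- function(tables, p_a, p_b, f) {
  n <- tables$n; m <- tables$m
  f <- as.matrix(f)
  g <- outer(.hwe(p_a), .hwe(p_b))
  if (any(g == 0 & (n + m) > 0)) return(-Inf)
  s <- sum(g * f)
  if (!is.finite(s) || s <= 0) return(-Inf)
  sum(.xlogy(n, g * f / s)) + sum(.xlogy(m, g))
}

# closed-form fits ----------------------------------------------------

.fit_M0 <- function(tables) {
  nm <- tables$n + tables$m
  pa <- .clamp_p(.freq_margin(nm, 1L)); pb <- .clamp_p(.freq_margin(nm, 2L))
  g <- outer(.hwe(pa), .hwe(pb))
  ll <- sum(.xlogy(nm, g))
  list(p = c(pa, pb), pen = c(c = 0.5), f = matrix(0.5, 3L, 3L), loglik = ll)
}

.fit_MM <- function(tables) {
  n <- tables$n; m <- tables$m; N <- sum(n)
  pa <- .clamp_p(.freq_margin(m, 1L)); pb <- .clamp_p(.freq_margin(m, 2L))
  ra <- rowSums(n); cb <- colSums(n)
  case_ll <- sum(.xlogy(ra, ra / N)) + sum(.xlogy(cb, cb / N))
  ll <- case_ll + sum(.xlogy(m, outer(.hwe(pa), .hwe(pb))))
  # report penetrance factors: case margins deflated by HWE, scaled into (0,1)
  rescale <- function(q, h) {
    a <- pmax(q / h, .F_BOUNDS[1L])
    a / max(a) * 0.5
  }
  alpha <- rescale(ra / N, .hwe(pa)); beta <- rescale(cb / N, .hwe(pb))
  list(p = c(pa, pb), pen = c(alpha = alpha, beta = beta),
       f = outer(alpha, beta), loglik = ll)
}

.fit_MG <- function(tables) {
  n <- tables$n; m <- tables$m; N <- sum(n)
  pa <- .clamp_p(.freq_margin(m, 1L)); pb <- .clamp_p(.freq_margin(m, 2L))
  case_ll <- sum(.xlogy(n, n / N))
  ll <- case_ll + sum(.xlogy(m, outer(.hwe(pa), .hwe(pb))))
  g <- outer(.hwe(pa), .hwe(pb))
  f <- pmax((n / N) / g, .F_BOUNDS[1L])
  f <- f / max(f) * 0.5
  list(p = c(pa, pb), pen = f, f = f, loglik = ll)
}

.fit_MR <- function(tables, restarts = 10L, seed = 1L) {
  n <- tables$n; m <- tables$m
  obj <- function(theta) {
    f <- 1 - outer(1 - theta[3:5], 1 - theta[6:8])
    ll <- two_locus_loglik(tables, theta[1L], theta[2L], f)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  lower <- c(.P_BOUNDS[1L], .P_BOUNDS[1L], rep(.F_BOUNDS[1L], 6L))
  upper <- c(.P_BOUNDS[2L], .P_BOUNDS[2L], rep(.F_BOUNDS[2L], 6L))
  pa_m <- .clamp_p(.freq_margin(m, 1L)); pb_m <- .clamp_p(.freq_margin(m, 2L))
  nm <- n + m
  pa_0 <- .clamp_p(.freq_margin(nm, 1L)); pb_0 <- .clamp_p(.freq_margin(nm, 2L))
  starts <- list(
    c(pa_m, pb_m, rep(0.1, 6L)),          # moment start, freqs from m margins
    c(pa_0, pb_0, rep(0.1, 6L))           # constant-f start at the M0 optimum
  )
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  for (r in seq_len(restarts)) {
    starts[[length(starts) + 1L]] <- c(stats::runif(2L, 0.05, 0.95),
                                       stats::runif(6L, 0.01, 0.5))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  best <- NULL; used <- 0L
  for (s in starts) {
    used <- used + 1L
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200L)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best)) {
    return(list(p = c(NA_real_, NA_real_), pen = NULL, f = NULL,
                loglik = NA_real_, converged = FALSE, n_restarts_used = used))
  }
  th <- best$par
  alpha <- th[3:5]; beta <- th[6:8]
  list(p = c(th[1L], th[2L]),
       pen = c(alpha = alpha, beta = beta),
       f = 1 - outer(1 - alpha, 1 - beta),
       loglik = -best$value, converged = TRUE, n_restarts_used = used)
}

#' Fit a two-locus penetrance model
#'
#' Maximises the case / pseudo-control likelihood over allele
#' frequencies and model-specific penetrance parameters:
#' * `M0` - no association, constant penetrance (2 identifiable
#'   parameters; closed form: pooled-margin allele frequencies),
#' * `MR` - heterogeneity, `f_ij = 1 - (1 - alpha_i)(1 - beta_j)`
#'   (7 parameters; bounded L-BFGS-B with seeded random restarts plus a
#'   moment start and a constant-penetrance start),
#' * `MM` - multiplicative, `f_ij = alpha_i * beta_j` (6 parameters;
#'   closed form: independent case margins, control-margin frequencies),
#' * `MG` - general 3x3 penetrance (10 parameters; closed form:
#'   saturated case distribution, control-margin frequencies).
#'
#' The case probabilities depend on `f` only up to scale, so penetrance
#' parameters are reported on a normalised scale.
#'
#' @param tables a [two_locus_tables()] object.
#' @param model one of `"M0"`, `"MR"`, `"MM"`, `"MG"`.
#' @param restarts random restarts for the `MR` optimisation.
#' @param seed seed for the restart draws (the global RNG state is
#'   restored afterwards).
#' @return an object of class `two_locus_fit`: `model`, `p` (allele
#'   frequencies), `pen` (model parameters), `f` (induced penetrance
#'   matrix), `loglik`, `converged`, `n_restarts_used`, `df_model`.
#' @export
fit_two_locus <- function(tables, model = c("MG", "M0", "MR", "MM"),
                          restarts = 10L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(tables, "two_locus_tables") ||
              (is.list(tables) && all(c("n", "m") %in% names(tables))))
  fit <- switch(model,
    M0 = c(.fit_M0(tables), converged = TRUE, n_restarts_used = 0L),
    MM = c(.fit_MM(tables), converged = TRUE, n_restarts_used = 0L),
    MG = c(.fit_MG(tables), converged = TRUE, n_restarts_used = 0L),
    MR = .fit_MR(tables, restarts, seed)
  )
  structure(list(model = model,
                 p = stats::setNames(fit$p, c("p_A", "p_B")),
                 pen = fit$pen, f = fit$f, loglik = fit$loglik,
                 converged = isTRUE(fit$converged),
                 n_restarts_used = fit$n_restarts_used,
                 df_model = .MODEL_DF[[model]],
                 n_families = sum(tables$n),
                 tables = tables),
            class = "two_locus_fit")
}

#' @export
print.two_locus_fit <- function(x, ...) {
  cat(sprintf("two-locus penetrance fit: model %s (%d families)\n",
              x$model, x$n_families))
  cat(sprintf("  allele freqs: p_A = %.3f, p_B = %.3f\n", x$p[1L], x$p[2L]))
  cat(sprintf("  log-likelihood: %.4f  (converged: %s)\n",
              x$loglik, x$converged))
  invisible(x)
}

#' @export
logLik.two_locus_fit <- function(object, ...) {
  structure(object$loglik, df = object$df_model, class = "logLik")
}

#' @export
coef.two_locus_fit <- function(object, ...) {
  c(object$p, unlist(object$pen))
}

#' Simulate tables from a fitted two-locus model
#'
#' Draws case counts from the fitted case cell probabilities
#' (proportional to `g * f`) and pseudo-control counts from the fitted
#' genotype frequencies `g`, each as one multinomial of size
#' `n_families`.
#'
#' @param object a `two_locus_fit`.
#' @param nsim number of simulated table pairs.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of `two_locus_tables`.
#' @export
simulate.two_locus_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  g <- outer(.hwe(object$p[1L]), .hwe(object$p[2L]))
  qcase <- g * object$f; qcase <- qcase / sum(qcase)
  N <- object$n_families
  lapply(seq_len(nsim), function(i) {
    n <- matrix(stats::rmultinom(1L, N, as.vector(qcase)), 3L, 3L)
    m <- matrix(stats::rmultinom(1L, N, as.vector(g)), 3L, 3L)
    two_locus_tables(n, m, object$tables$snp_a, object$tables$snp_b)
  })
}

#' Likelihood-ratio test between nested penetrance models
#'
#' `Lambda = 2 (l_large - l_small)`, clipped at zero (optimizer noise can
#' make nested likelihoods marginally larger), referred to a chi-square
#' with `df` degrees of freedom.  When `df` is omitted it is inferred
#' from the identifiable-parameter counts of the two models
#' (M0-vs-MG: 8, MR-vs-MG: 3, MM-vs-MG: 4).
#'
#' @param fit_small,fit_large `two_locus_fit` objects for the nested and
#'   the larger model.
#' @param df degrees of freedom override.
#' @return list with `lambda`, `df` and `p.value` (`NA` when either fit
#'   failed to converge).
#' @export
lrt <- function(fit_small, fit_large, df = NULL) {
  if (is.null(df)) df <- fit_large$df_model - fit_small$df_model
  if (df <= 0) stop("models are not nested (df <= 0)")
  if (!isTRUE(fit_small$converged) || !isTRUE(fit_large$converged)) {
    return(list(lambda = NA_real_, df = df, p.value = NA_real_))
  }
  lambda <- max(0, 2 * (fit_large$loglik - fit_small$loglik))
  list(lambda = lambda, df = df,
       p.value = stats::pchisq(lambda, df = df, lower.tail = FALSE))
}

#' Classify an interaction pair
#'
#' A pair is reported only when `p_02 < p02_threshold`.  Among reported
#' pairs: consistent with a purely multiplicative model when
#' `p_m2 >= pm2_threshold`; otherwise labelled `epistasis` when
#' `p_12 < p12_epistasis` (the heterogeneity model is also rejected) or
#' `heterogeneity` when `p_12 > p12_heterogeneity` (no convincing
#' deviation from heterogeneity); pairs in between remain reported but
#' unlabelled.
#'
#' @param p_02,p_12,p_m2 LRT p-values (M0-, MR- and MM-versus-MG).
#' @param p02_threshold,pm2_threshold,p12_epistasis,p12_heterogeneity
#'   thresholds, defaulting to the study values.
#' @return character vector in `{"not-reported",
#'   "multiplicative-consistent", "epistasis", "heterogeneity",
#'   "unlabeled"}`; `NA` p-values give `NA`.
#' @export
classify_pair <- function(p_02, p_12, p_m2,
                          p02_threshold = 1e-4, pm2_threshold = 0.05,
                          p12_epistasis = 1e-4, p12_heterogeneity = 0.05) {
  out <- rep(NA_character_, length(p_02))
  known <- !is.na(p_02)
  out[known & p_02 >= p02_threshold] <- "not-reported"
  rep_ <- known & p_02 < p02_threshold
  out[rep_ & !is.na(p_m2) & p_m2 >= pm2_threshold] <- "multiplicative-consistent"
  dev <- rep_ & !is.na(p_m2) & p_m2 < pm2_threshold & !is.na(p_12)
  out[dev & p_12 < p12_epistasis] <- "epistasis"
  out[dev & p_12 > p12_heterogeneity] <- "heterogeneity"
  out[dev & p_12 >= p12_epistasis & p_12 <= p12_heterogeneity] <- "unlabeled"
  out
}

#' Expected number of null pairs
#'
#' @param n_pairs number of pairs tested (or reported).
#' @param alpha significance level of the follow-up test.
#' @return `round(n_pairs * alpha)`.
#' @examples
#' expected_null_pairs(582, 0.05)  # 29
#' @export
expected_null_pairs <- function(n_pairs, alpha = 0.05) {
  round(n_pairs * alpha)
}

#' Full interaction test for one marker pair
#'
#' Fits all four penetrance models and computes the three
#' likelihood-ratio p-values `P_02`, `P_12`, `P_M2` plus the pair
#' classification.
#'
#' @param tables a [two_locus_tables()] object.
#' @param restarts,seed passed to the `MR` fit.
#' @param ... classification thresholds passed to [classify_pair()].
#' @return object of class `two_locus_test` with the fits, p-values and
#'   classification.
#' @export
interaction_test <- function(tables, restarts = 10L, seed = 1L, ...) {
  fits <- list(M0 = fit_two_locus(tables, "M0"),
               MR = fit_two_locus(tables, "MR", restarts = restarts, seed = seed),
               MM = fit_two_locus(tables, "MM"),
               MG = fit_two_locus(tables, "MG"))
  p_02 <- lrt(fits$M0, fits$MG)$p.value
  p_12 <- lrt(fits$MR, fits$MG)$p.value
  p_m2 <- lrt(fits$MM, fits$MG)$p.value
  structure(list(snp_a = tables$snp_a, snp_b = tables$snp_b,
                 n_families = tables$n_families,
                 p_02 = p_02, p_12 = p_12, p_m2 = p_m2,
                 classification = classify_pair(p_02, p_12, p_m2, ...),
                 fits = fits),
            class = "two_locus_test")
}

#' @export
print.two_locus_test <- function(x, ...) {
  cat(sprintf("two-locus interaction test: %s x %s (N = %d)\n",
              x$snp_a, x$snp_b, x$n_families))
  cat(sprintf("  P_02 = %.3g  P_12 = %.3g  P_M2 = %.3g\n",
              x$p_02, x$p_12, x$p_m2))
  cat("  classification:", x$classification, "\n")
  invisible(x)
}

#' Interaction scan over cross-region marker pairs
#'
#' Enumerates every pair of selected markers whose members fall in
#' different regions (within-region pairs are excluded as
#' LD-confounded), tabulates case / pseudo-control counts and runs
#' [interaction_test()] on each pair.
#'
#' @param panel a trio panel.
#' @param selected data frame of selected markers (`snp`, `chrom`, `bp`).
#' @param regions optional region assignment from [build_regions()];
#'   computed from `selected` when omitted.
#' @param min_families minimum complete families per pair.
#' @param restarts,seed passed to the model fits (the per-pair seed is
#'   offset deterministically).
#' @param ... thresholds passed to [classify_pair()].
#' @return data frame with one row per tested pair: `snp1`, `chr1`,
#'   `snp2`, `chr2`, `n`, `p_02`, `p_12`, `p_m2`, `classification`.
#' @export
interaction_scan <- function(panel, selected, regions = NULL,
                             min_families = 20L, restarts = 10L, seed = 1L, ...) {
  panel <- as_trio_panel(panel)
  if (is.null(regions)) regions <- build_regions(selected)
  assignment <- regions$assignment
  snps <- selected$snp
  reg <- assignment[snps]
  rows <- list()
  if (length(snps) >= 2L) {
    pair_i <- utils::combn(seq_along(snps), 2L)
    for (q in seq_len(ncol(pair_i))) {
      i <- pair_i[1L, q]; j <- pair_i[2L, q]
      if (!is.na(reg[i]) && !is.na(reg[j]) && reg[i] == reg[j]) next
      tab <- withCallingHandlers(
        tabulate_two_locus(panel, snps[i], snps[j], min_families = min_families),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (is.null(tab)) next
      tst <- interaction_test(tab, restarts = restarts, seed = seed + q, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        snp1 = snps[i], chr1 = selected$chrom[i],
        snp2 = snps[j], chr2 = selected$chrom[j],
        n = tab$n_families,
        p_02 = tst$p_02, p_12 = tst$p_12, p_m2 = tst$p_m2,
        classification = tst$classification,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp1 = character(), chr1 = character(), snp2 = character(),
               chr2 = character(), n = integer(), p_02 = numeric(),
               p_12 = numeric(), p_m2 = numeric(), classification = character(),
               stringsAsFactors = FALSE)
  out[order(out$p_02), , drop = FALSE]
}
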