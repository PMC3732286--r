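# Seeded generator of ascertained nuclear families with the statistical
# structure the pipeline assumes: founders drawn from Hardy-Weinberg
# equilibrium at unlinked loci, offspring by Mendelian transmission,
# affection from configurable penetrance models, ascertainment on a
# minimum number of affected offspring (the affected-sib-pair design),
# an HLA-like stratification locus, Dirichlet-blurred imputation
# posteriors, external replication tables and qPCR Ct tables.

#' Penetrance specifications
#'
#' Constructors for the disease-model components of [sim_config()].
#' Allele A1 is the risk allele throughout.
#'
#' * `penetrance_constant(k)`: genotype-independent risk `k` (null
#'   model; ascertainment is then unbiased with respect to genotype).
#' * `penetrance_single_locus(marker, baseline, grr)`: risk
#'   `baseline * grr[d + 1]` for A1 dosage `d`, i.e. genotype relative
#'   risks.
#' * `penetrance_two_locus(marker_a, marker_b, f)`: explicit 3x3 joint
#'   penetrance matrix (rows = A-locus dosage 0..2).
#' * `penetrance_multiplicative(marker_a, marker_b, alpha, beta)`:
#'   `f_ij = alpha_i * beta_j`.
#' * `penetrance_heterogeneity(marker_a, marker_b, alpha, beta)`:
#'   Risch heterogeneity `f_ij = 1 - (1 - alpha_i)(1 - beta_j)`.
#' * `penetrance_epistatic(marker_a, marker_b, baseline, risk)`: joint
#'   risk elevated only when both loci carry at least one risk allele.
#'
#' @param k,baseline,risk penetrances in (0, 1).
#' @param marker,marker_a,marker_b marker ids the component acts on.
#' @param grr length-3 genotype relative risks for dosage 0, 1, 2.
#' @param alpha,beta length-3 per-locus penetrance factors.
#' @param f explicit 3x3 penetrance matrix.
#' @return a penetrance component for `sim_config(disease = list(...))`.
#' @name penetrance
NULL

.check_pen <- function(f) {
  if (any(f <= 0 | f >= 1)) stop("penetrances must lie strictly in (0, 1)")
  f
}

#' @rdname penetrance
#' @export
penetrance_constant <- function(k = 0.1) {
  list(kind = "constant", k = .check_pen(k))
}

#' @rdname penetrance
#' @export
penetrance_single_locus <- function(marker, baseline = 0.05, grr = c(1, 2, 4)) {
  stopifnot(length(grr) == 3L)
  .check_pen(baseline * grr)
  list(kind = "single_locus", marker = marker, baseline = baseline, grr = grr)
}

#' @rdname penetrance
#' @export
penetrance_two_locus <- function(marker_a, marker_b, f) {
  f <- as.matrix(f)
  stopifnot(all(dim(f) == c(3L, 3L)))
  .check_pen(f)
  list(kind = "two_locus", marker_a = marker_a, marker_b = marker_b, f = f)
}

#' @rdname penetrance
#' @export
penetrance_multiplicative <- function(marker_a, marker_b, alpha, beta) {
  penetrance_two_locus(marker_a, marker_b, outer(alpha, beta))
}

#' @rdname penetrance
#' @export
penetrance_heterogeneity <- function(marker_a, marker_b, alpha, beta) {
  penetrance_two_locus(marker_a, marker_b, 1 - outer(1 - alpha, 1 - beta))
}

#' @rdname penetrance
#' @export
penetrance_epistatic <- function(marker_a, marker_b, baseline = 0.02, risk = 0.4) {
  f <- matrix(baseline, 3L, 3L)
  f[2:3, 2:3] <- risk
  penetrance_two_locus(marker_a, marker_b, f)
}

#' Default marker panel for simulations
#'
#' A small panel of unlinked biallelic SNPs spread over several
#' chromosomes, including designated risk loci and an HLA-like
#' stratification locus on chromosome 6.
#'
#' @param n_null number of additional null markers.
#' @param freq_null A1 frequency of the null markers (recycled).
#' @return marker data frame with columns `id`, `chrom`, `bp`, `a1`,
#'   `a2`, `freq`.
#' @export
sim_marker_panel <- function(n_null = 10L, freq_null = 0.3) {
  special <- data.frame(
    id = c("risk1", "epiA", "epiB", "hetA", "hetB", "hla_tag"),
    chrom = c("1", "2", "10", "3", "14", "6"),
    bp = c(2e7, 3e7, 5e7, 4e7, 6e7, 32e6),
    freq = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.35),
    stringsAsFactors = FALSE
  )
  if (n_null > 0L) {
    nulls <- data.frame(
      id = sprintf("null%03d", seq_len(n_null)),
      chrom = as.character(rep(c(1:22), length.out = n_null)),
      bp = 1e6 + seq_len(n_null) * 2e6,
      freq = rep(freq_null, length.out = n_null),
      stringsAsFactors = FALSE
    )
    special <- rbind(special, nulls)
  }
  special$a1 <- "A"; special$a2 <- "G"
  special[, c("id", "chrom", "bp", "a1", "a2", "freq")]
}

#' Simulation configuration
#'
#' Bundles the study-design parameters of the family simulator.  The
#' defaults mirror an affected-sib-pair collection: nuclear families
#' with two offspring, ascertained when at least two are affected, and a
#' genotype-independent background risk of 0.10 (the order of the
#' sibling recurrence risk in celiac disease).
#'
#' @param n_families number of ascertained families to deliver.
#' @param n_offspring offspring per family.
#' @param min_affected ascertainment minimum (affected offspring).
#' @param markers marker panel with a `freq` column (A1 frequency).
#' @param disease list of penetrance components (see [penetrance]);
#'   component risks combine as `1 - prod(1 - f_c)`.
#' @param stratum_marker optional id of the HLA-like stratification
#'   locus: offspring homozygous for its risk allele (A1 dosage 2) are
#'   labelled `high`, all others `low`.
#' @param lambda posterior blur in `[0, 1]` applied by
#'   [blur_posteriors()] when the pipeline asks for posteriors.
#' @param seed integer seed fixing all randomness end-to-end.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_families = 97L, n_offspring = 2L, min_affected = 2L,
                       markers = sim_marker_panel(),
                       disease = list(penetrance_constant(0.1)),
                       stratum_marker = "hla_tag",
                       lambda = 0.05, seed = 1L) {
  stopifnot(n_families >= 1L, n_offspring >= 1L,
            min_affected >= 0L, min_affected <= n_offspring,
            all(markers$freq > 0 & markers$freq < 1),
            lambda >= 0, lambda <= 1)
  if (!is.null(stratum_marker) && !stratum_marker %in% markers$id) {
    stop("stratum_marker not in the marker panel")
  }
  structure(list(n_families = as.integer(n_families),
                 n_offspring = as.integer(n_offspring),
                 min_affected = as.integer(min_affected),
                 markers = markers, disease = disease,
                 stratum_marker = stratum_marker,
                 lambda = lambda, seed = as.integer(seed)),
            class = "sim_config")
}

# per-child affection probability from the disease-model components
.risk_prob <- function(disease, CD, marker_ids) {
  p_unaff <- rep(1, nrow(CD))
  for (comp in disease) {
    f <- switch(comp$kind,
      constant = rep(comp$k, nrow(CD)),
      single_locus = {
        d <- CD[, match(comp$marker, marker_ids)]
        pmin(comp$baseline * comp$grr[d + 1L], 1 - 1e-9)
      },
      two_locus = {
        da <- CD[, match(comp$marker_a, marker_ids)]
        db <- CD[, match(comp$marker_b, marker_ids)]
        comp$f[cbind(da + 1L, db + 1L)]
      },
      stop("unknown penetrance kind: ", comp$kind)
    )
    p_unaff <- p_unaff * (1 - f)
  }
  1 - p_unaff
}

#' Simulate ascertained nuclear families
#'
#' Parents are drawn from Hardy-Weinberg equilibrium independently at
#' each locus (no linkage disequilibrium); each offspring receives one
#' parental allele per locus by Mendelian transmission; affection is
#' Bernoulli with the configured penetrance; and families are retained
#' only when the number of affected offspring reaches the ascertainment
#' minimum.  Generation repeats until `n_families` are retained.  All
#' randomness is fixed by `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `trio_sim`: `ped` (FAM-style table), `G`
#'   (true dosage matrix, individuals x markers), `markers`, `trios`
#'   (one row per affected offspring, with `stratum` labels when a
#'   stratification locus is configured) and `config`.
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mk <- config$markers
  K <- nrow(mk); q <- mk$freq
  want <- config$n_families
  noff <- config$n_offspring
  FD <- MD <- NULL
  CD <- vector("list", noff)
  AFF <- NULL
  got <- 0L; attempts <- 0L
  while (got < want) {
    if (attempts >= 2e6 && got == 0L) {
      stop("ascertainment yield below 1 per ", attempts,
           " attempts; penetrance too low for the configured design")
    }
    rate <- (got + 1) / (attempts + 20)
    B <- min(50000L, max(200L, ceiling((want - got) / rate * 1.2)))
    fh1 <- matrix(stats::rbinom(B * K, 1L, rep(q, each = B)), B, K)
    fh2 <- matrix(stats::rbinom(B * K, 1L, rep(q, each = B)), B, K)
    mh1 <- matrix(stats::rbinom(B * K, 1L, rep(q, each = B)), B, K)
    mh2 <- matrix(stats::rbinom(B * K, 1L, rep(q, each = B)), B, K)
    kids <- vector("list", noff)
    aff <- matrix(FALSE, B, noff)
    for (o in seq_len(noff)) {
      pf <- matrix(stats::runif(B * K) < 0.5, B, K)
      pm <- matrix(stats::runif(B * K) < 0.5, B, K)
      kd <- ifelse(pf, fh1, fh2) + ifelse(pm, mh1, mh2)
      kids[[o]] <- kd
      aff[, o] <- stats::runif(B) < .risk_prob(config$disease, kd, mk$id)
    }
    keep <- rowSums(aff) >= config$min_affected
    attempts <- attempts + B
    if (any(keep)) {
      FD <- rbind(FD, (fh1 + fh2)[keep, , drop = FALSE])
      MD <- rbind(MD, (mh1 + mh2)[keep, , drop = FALSE])
      for (o in seq_len(noff)) {
        CD[[o]] <- rbind(CD[[o]], kids[[o]][keep, , drop = FALSE])
      }
      AFF <- rbind(AFF, aff[keep, , drop = FALSE])
      got <- got + sum(keep)
    }
  }
  idx <- seq_len(want)
  fam <- sprintf("fam%04d", idx)
  father <- paste0(fam, "_f"); mother <- paste0(fam, "_m")
  kid_ids <- lapply(seq_len(noff), function(o) paste0(fam, "_o", o))
  ids <- c(rbind(father, mother, do.call(rbind, kid_ids)))
  G <- matrix(NA_integer_, length(ids), K, dimnames = list(ids, mk$id))
  G[father, ] <- FD[idx, , drop = FALSE]
  G[mother, ] <- MD[idx, , drop = FALSE]
  for (o in seq_len(noff)) G[kid_ids[[o]], ] <- CD[[o]][idx, , drop = FALSE]
  # assemble pedigree rows family by family
  ped <- do.call(rbind, lapply(idx, function(i) {
    data.frame(
      family_id = fam[i],
      id = c(father[i], mother[i], vapply(kid_ids, `[`, "", i)),
      father_id = c("0", "0", rep(father[i], noff)),
      mother_id = c("0", "0", rep(mother[i], noff)),
      sex = c("1", "2", rep(c("1", "2"), length.out = noff)),
      phenotype = c("1", "1", ifelse(AFF[i, ], "2", "1")),
      stringsAsFactors = FALSE
    )
  }))
  rownames(ped) <- NULL
  aff_long <- AFF[idx, , drop = FALSE]
  trios <- do.call(rbind, lapply(idx, function(i) {
    o_aff <- which(aff_long[i, ])
    if (!length(o_aff)) return(NULL)
    data.frame(
      family_id = fam[i], father_id = father[i], mother_id = mother[i],
      offspring_id = vapply(kid_ids[o_aff], `[`, "", i),
      offspring_affected = TRUE, stringsAsFactors = FALSE
    )
  }))
  rownames(trios) <- NULL
  if (!is.null(config$stratum_marker)) {
    d <- G[trios$offspring_id, match(config$stratum_marker, mk$id)]
    trios$stratum <- ifelse(d == 2L, "high", "low")
  }
  structure(list(ped = ped, G = G, P = NULL,
                 markers = mk[, c("id", "chrom", "bp", "a1", "a2")],
                 trios = trios, config = config,
                 n_attempted = attempts),
            class = "trio_sim")
}

#' @export
print.trio_sim <- function(x, ...) {
  cat("simulated family panel:", x$config$n_families, "families,",
      nrow(x$markers), "markers,", nrow(x$trios), "affected-offspring trios\n")
  cat(" ascertainment: >=", x$config$min_affected, "affected of",
      x$config$n_offspring, "offspring (", x$n_attempted, "families attempted )\n")
  invisible(x)
}

#' Blur true genotypes into imputation-style posteriors
#'
#' Each genotype's posterior triplet is
#' `(1 - lambda) * indicator(true genotype) + lambda * d`, where `d` is
#' a symmetric Dirichlet(1,1,1) draw.  `lambda = 0` gives certain
#' posteriors (hard calls and expected counts then agree exactly);
#' small `lambda` emulates the high-confidence regime of genotype
#' imputation, where the large majority of genotypes have a posterior
#' above 0.95.
#'
#' @param x a `trio_sim` or `trio_panel` with a dosage matrix.
#' @param lambda blur weight in `[0, 1]`; defaults to the value in the
#'   simulation config (or 0).
#' @param seed seed for the Dirichlet draws.
#' @return the object with a posterior array `P` attached.
#' @export
blur_posteriors <- function(x, lambda = NULL, seed = 1L) {
  if (is.null(lambda)) {
    lambda <- if (!is.null(x$config)) x$config$lambda else 0
  }
  stopifnot(lambda >= 0, lambda <= 1)
  G <- x$G
  if (is.null(G)) stop("blur_posteriors needs true hard genotypes")
  set.seed(seed)
  n <- nrow(G); K <- ncol(G)
  E <- matrix(stats::rexp(n * K * 3L), ncol = 3L)
  D <- E / rowSums(E)
  P <- array(0, dim = c(n, K, 3L),
             dimnames = list(rownames(G), colnames(G), c("p_aa", "p_ab", "p_bb")))
  for (col in 1:3) {
    d <- c(2L, 1L, 0L)[col]
    ind <- (G == d) * 1
    ind[is.na(ind)] <- 0
    P[, , col] <- (1 - lambda) * ind + lambda * matrix(D[, col], n, K)
  }
  x$P <- P
  x
}

#' Synthesise an external replication table
#'
#' Builds a stand-in for an external GWAS results table: designated
#' markers replicate (small p-value, direction matching the internal
#' transmission odds when provided), all other markers receive a
#' uniform p-value and a direction-neutral odds ratio near 1.
#'
#' @param markers marker data frame (`id`, `a1`).
#' @param replicate_ids markers that should replicate.
#' @param internal optional internal scan results (`snp`, `t`, `u`) used
#'   to match the allelic direction of replicating markers.
#' @param seed seed.
#' @return data frame with columns `snp`, `a1`, `or`, `p`.
#' @export
make_external_table <- function(markers, replicate_ids = character(),
                                internal = NULL, seed = 1L) {
  set.seed(seed)
  n <- nrow(markers)
  p <- stats::runif(n)
  or <- exp(stats::rnorm(n, 0, 0.05))
  rep_i <- markers$id %in% replicate_ids
  p[rep_i] <- 10^stats::runif(sum(rep_i), -6, -4)
  if (any(rep_i)) {
    dir <- rep(1, sum(rep_i))
    if (!is.null(internal)) {
      j <- match(markers$id[rep_i], internal$snp)
      dir <- ifelse(!is.na(j) & internal$t[j] >= internal$u[j], 1, -1)
    }
    or[rep_i] <- exp(dir * stats::runif(sum(rep_i), 0.2, 0.6))
  }
  data.frame(snp = markers$id, a1 = markers$a1, or = or, p = p,
             stringsAsFactors = FALSE)
}

#' Synthesise a long-format qPCR Ct table
#'
#' Reference genes get Ct ~ Normal(20, 0.2) per sample; each target's Ct
#' is the sample's mean reference Ct plus a baseline delta-Ct, minus the
#' group effect (cases only, in log2 units, so a `log2fc` of 1 doubles
#' case expression), plus Normal noise.
#'
#' @param n_case,n_control group sizes.
#' @param targets data frame with `gene`, `assay`, `log2fc` (positive =
#'   up-regulated in cases).
#' @param reference_genes reference gene symbols.
#' @param baseline_dct baseline delta-Ct of the targets (cycles).
#' @param noise_sd residual Ct standard deviation (cycles).
#' @param seed seed.
#' @return data frame with columns `sample`, `group`, `gene`, `assay`,
#'   `ct`.
#' @export
make_ct_table <- function(n_case = 46L, n_control = 52L,
                          targets = data.frame(gene = "GENE1",
                                               assay = "GENE1_a1",
                                               log2fc = 1),
                          reference_genes = c("ACTB", "EPCAM", "PGK1"),
                          baseline_dct = 5, noise_sd = 0.4, seed = 1L) {
  set.seed(seed)
  samples <- c(sprintf("case%03d", seq_len(n_case)),
               sprintf("ctrl%03d", seq_len(n_control)))
  group <- rep(c("case", "control"), c(n_case, n_control))
  rows <- list()
  for (s in seq_along(samples)) {
    ref_ct <- stats::rnorm(length(reference_genes), 20, 0.2)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = samples[s], group = group[s], gene = reference_genes,
      assay = paste0(reference_genes, "_ref"), ct = ref_ct,
      stringsAsFactors = FALSE
    )
    eff <- if (group[s] == "case") targets$log2fc else 0
    rows[[length(rows) + 1L]] <- data.frame(
      sample = samples[s], group = group[s], gene = targets$gene,
      assay = targets$assay,
      ct = mean(ref_ct) + baseline_dct - eff + stats::rnorm(nrow(targets), 0, noise_sd),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
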