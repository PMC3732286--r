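# Genotype encodings and trio-level genotype operations.
#
# Biallelic genotypes are carried internally as the integer dosage of
# allele A1: 2 = A1/A1 ("AA"), 1 = A1/A2 ("AB"), 0 = A2/A2 ("BB"),
# NA = missing.  Posterior triplets are ordered (p_AA, p_AB, p_BB),
# matching the three probabilities per sample in an Oxford GEN row.

GENO_STATES <- c("BB", "AB", "AA")

# Enumeration of all 27 father/mother/child dosage configurations.
# For each configuration we record Mendelian consistency and the
# classical TDT contribution: every valid assignment of one transmitted
# allele per parent is enumerated, and the (t, u) contributions of
# heterozygous parents are averaged over valid assignments.  The only
# ambiguous case (both parents and the child heterozygous) averages to
# (1, 1), the classical convention.
.geno_cfg <- local({
  f <- rep(0:2, each = 9L)
  m <- rep(rep(0:2, each = 3L), 3L)
  cc <- rep(0:2, 9L)
  alleles <- list(c(0L, 0L), c(1L, 0L), c(1L, 1L))
  t <- u <- numeric(27L)
  consistent <- logical(27L)
  for (k in seq_len(27L)) {
    fa <- alleles[[f[k] + 1L]]
    ma <- alleles[[m[k] + 1L]]
    tt <- uu <- 0
    nv <- 0L
    for (tf in fa) {
      for (tm in ma) {
        if (tf + tm != cc[k]) next
        nv <- nv + 1L
        if (f[k] == 1L) {
          if (tf == 1L) tt <- tt + 1 else uu <- uu + 1
        }
        if (m[k] == 1L) {
          if (tm == 1L) tt <- tt + 1 else uu <- uu + 1
        }
      }
    }
    if (nv > 0L) {
      consistent[k] <- TRUE
      t[k] <- tt / nv
      u[k] <- uu / nv
    }
  }
  list(f = f, m = m, c = cc, t = t, u = u, consistent = consistent)
})

# index into the 27-configuration tables; NA dosages propagate
.cfg_index <- function(f, m, c) 9L * f + 3L * m + c + 1L

#' Convert genotype states to A1 dosages
#'
#' Maps the genotype states `"AA"`, `"AB"`, `"BB"`, `"MISSING"` to the
#' integer dosage of allele A1 (2, 1, 0, `NA`).  Numeric input already in
#' dosage form is validated and passed through.
#'
#' @param x character vector of states, or numeric dosages.
#' @return integer vector of A1 dosages with `NA` for missing.
#' @seealso [dosage_to_state()]
#' @export
as_dosage <- function(x) {
  if (is.numeric(x)) {
    bad <- !(x %in% c(0, 1, 2) | is.na(x))
    if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
    return(as.integer(x))
  }
  x <- toupper(as.character(x))
  x[x %in% c("MISSING", "NA", "")] <- NA_character_
  out <- c(BB = 0L, AB = 1L, BA = 1L, AA = 2L)[x]
  if (any(is.na(out) & !is.na(x))) {
    stop("unknown genotype state: ", paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", "))
  }
  unname(out)
}

#' Convert A1 dosages to genotype states
#'
#' @param d integer dosages (0, 1, 2 or `NA`).
#' @return character vector in `{"AA","AB","BB","MISSING"}`.
#' @export
dosage_to_state <- function(d) {
  ifelse(is.na(d), "MISSING", GENO_STATES[as.integer(d) + 1L])
}

.validate_posteriors <- function(gp, eps = 1e-6) {
  if (any(gp < -eps | gp > 1 + eps, na.rm = TRUE)) {
    stop("genotype posteriors must lie in [0, 1]")
  }
  s <- rowSums(gp)
  if (any(s > 1 + eps, na.rm = TRUE)) {
    stop("genotype posterior triplets must sum to at most 1")
  }
  invisible(TRUE)
}

#' Hard-call genotypes from imputation posteriors
#'
#' A genotype is called when one of the three posterior probabilities
#' strictly exceeds `threshold` (default 0.95, the conventional
#' imputation cut-off); otherwise the genotype is missing.  Sub-unit
#' triplet sums are allowed and represent residual missingness.
#'
#' @param gp a numeric vector of length 3 `(p_AA, p_AB, p_BB)` or an
#'   `n x 3` matrix of such triplets.
#' @param threshold calling threshold; the comparison is strict (`>`).
#' @return integer A1 dosage(s); `NA` where no posterior exceeds the
#'   threshold.
#' @examples
#' hard_call(c(0.97, 0.02, 0.01))       # 2 (AA)
#' hard_call(c(0.94, 0.05, 0.01))       # NA
#' @export
hard_call <- function(gp, threshold = 0.95) {
  scalar <- is.null(dim(gp))
  if (scalar) gp <- matrix(gp, nrow = 1L)
  if (ncol(gp) != 3L) stop("posterior triplets must have 3 columns")
  .validate_posteriors(gp)
  j <- max.col(gp, ties.method = "first")
  called <- gp[cbind(seq_len(nrow(gp)), j)] > threshold
  d <- c(2L, 1L, 0L)[j]
  d[!called | is.na(called)] <- NA_integer_
  if (scalar) d[1L] else d
}

#' Mask Mendelian-inconsistent trio genotypes
#'
#' If the child genotype is impossible given both parental genotypes, all
#' three genotypes are set to missing (family-wise masking at that
#' marker).  The check applies only to fully-typed trios: any missing
#' member makes the trio vacuously consistent and the genotypes are
#' returned unchanged.
#'
#' @param father,mother,child genotypes as states or A1 dosages
#'   (vectorised; one element per trio).
#' @return a list with components `father`, `mother`, `child` holding the
#'   masked dosages.
#' @examples
#' mendelian_mask("AA", "AA", "AB")   # all MISSING
#' mendelian_mask("AB", "AB", "BB")   # unchanged
#' @export
mendelian_mask <- function(father, mother, child) {
  f <- as_dosage(father)
  m <- as_dosage(mother)
  c_ <- as_dosage(child)
  full <- !(is.na(f) | is.na(m) | is.na(c_))
  bad <- full & !.geno_cfg$consistent[.cfg_index(f, m, c_)]
  f[bad] <- NA_integer_
  m[bad] <- NA_integer_
  c_[bad] <- NA_integer_
  list(father = f, mother = m, child = c_)
}

#' Marker quality control
#'
#' Retains markers whose call rate strictly exceeds `call_rate_min`
#' (markers at or below the threshold are removed) and reports the minor
#' allele frequency computed from founder (parental) genotypes.  The MAF
#' threshold is reported, not enforced, unless `maf_filter = TRUE`.
#'
#' @param G hard-called dosage matrix, samples in rows, markers in
#'   columns (column names are marker ids).
#' @param founders row indices or names of founder samples used for MAF;
#'   defaults to all samples.
#' @param call_rate_min minimum call rate; retention requires
#'   `call rate > call_rate_min`.
#' @param maf_min MAF reporting threshold.
#' @param maf_filter if `TRUE`, markers with founder MAF below `maf_min`
#'   are also removed.
#' @return a list with `keep` (retained marker ids) and `report`, a data
#'   frame with one row per marker (`marker`, `call_rate`, `maf`,
#'   `retained`, `maf_ok`).
#' @export
marker_qc <- function(G, founders = NULL, call_rate_min = 0.97,
                      maf_min = 0.01, maf_filter = FALSE) {
  if (is.null(dim(G)) || ncol(G) == 0L || nrow(G) == 0L) {
    stop("empty genotype panel")
  }
  if (is.null(founders)) founders <- seq_len(nrow(G))
  call_rate <- colMeans(!is.na(G))
  Gf <- G[founders, , drop = FALSE]
  n_called <- colSums(!is.na(Gf))
  freq_a1 <- ifelse(n_called > 0, colSums(Gf, na.rm = TRUE) / (2 * n_called), NA_real_)
  maf <- pmin(freq_a1, 1 - freq_a1)
  retained <- call_rate > call_rate_min
  maf_ok <- !is.na(maf) & maf >= maf_min
  if (maf_filter) retained <- retained & maf_ok
  ids <- colnames(G)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(G)))
  report <- data.frame(
    marker = ids, call_rate = unname(call_rate), maf = unname(maf),
    retained = unname(retained), maf_ok = unname(maf_ok),
    stringsAsFactors = FALSE
  )
  list(keep = ids[retained], report = report)
}
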