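# Marker selection for the downstream pathway/interaction stages: three
# inclusion criteria (internal significance, external replication with
# direction agreement, large transmission-ratio effect), merging of
# selected markers into <100 kb regions, HLA-interval exclusion and
# distance-based gene annotation.

#' Inclusion criterion 1: internal significance
#'
#' @param p internal (expected-count TDT) p-values.
#' @param alpha threshold; the comparison is strict.
#' @return logical; `NA` p-values fail.
#' @export
criterion_significance <- function(p, alpha = 3e-4) {
  !is.na(p) & p < alpha
}

#' Inclusion criterion 2: external replication
#'
#' Passes when the internal p-value is below `p_int_max`, the external
#' p-value below `p_ext_max`, their product below `prod_max`, and the
#' association points in the same allelic direction in both studies
#' (directions must already be harmonised to a common reference allele).
#'
#' @param p_int,p_ext internal and external p-values.
#' @param dir_int,dir_ext allelic directions (`"+"`/`"-"`, or any values
#'   comparable with `==`).
#' @param p_int_max,p_ext_max,prod_max thresholds (all strict).
#' @return logical; missing inputs fail.
#' @export
criterion_replication <- function(p_int, p_ext, dir_int, dir_ext,
                                  p_int_max = 0.01, p_ext_max = 0.05,
                                  prod_max = 5e-5) {
  ok <- !is.na(p_int) & !is.na(p_ext) & !is.na(dir_int) & !is.na(dir_ext) &
    p_int < p_int_max & p_ext < p_ext_max & p_int * p_ext < prod_max &
    dir_int == dir_ext
  ok & !is.na(ok)
}

#' Inclusion criterion 3: large effect size
#'
#' Passes when the transmission ratio `t/u` is below `ratio_low` or
#' above `ratio_high` (a zero `u` counts as an infinite ratio) and the
#' p-value is below `p_max`.
#'
#' @param t,u transmission counts.
#' @param p p-values.
#' @param ratio_low,ratio_high,p_max thresholds (strict).
#' @return logical.
#' @export
criterion_effect_size <- function(t, u, p, ratio_low = 0.2, ratio_high = 5,
                                  p_max = 2e-3) {
  ratio <- ifelse(u > 0, t / u, ifelse(t > 0, Inf, NA_real_))
  ok <- !is.na(ratio) & !is.na(p) & (ratio < ratio_low | ratio > ratio_high) & p < p_max
  ok & !is.na(ok)
}

#' Apply the three inclusion criteria to a scan
#'
#' Evaluates the criteria on a [tdt_scan()] result (expected-count mode
#' by default) and marks a marker selected when it passes any criterion.
#' External directions are harmonised to the internal A1 allele: when the
#' external effect allele equals the internal A2 the external direction
#' is flipped, and markers whose external allele matches neither A1 nor
#' A2 are dropped from criterion 2 with a warning.
#'
#' @param results a `tdt_scan` data frame (columns `snp`, `a1`, `a2`,
#'   `t`, `u`, `p`).
#' @param external optional external results data frame (`snp`, `a1`,
#'   `or`, `p`); without it criterion 2 fails everywhere.
#' @param p1_alpha,p2_int,p2_ext,p2_prod,p3_ratio_low,p3_ratio_high,p3_p
#'   criterion thresholds, defaulting to the study values.
#' @return `results` augmented with logical columns `crit_significance`,
#'   `crit_replication`, `crit_effect_size` and `selected`.
#' @export
select_markers <- function(results, external = NULL,
                           p1_alpha = 3e-4,
                           p2_int = 0.01, p2_ext = 0.05, p2_prod = 5e-5,
                           p3_ratio_low = 0.2, p3_ratio_high = 5, p3_p = 2e-3) {
  res <- as.data.frame(results)
  res$crit_significance <- criterion_significance(res$p, p1_alpha)
  dir_int <- ifelse(res$t > res$u, "+", ifelse(res$t < res$u, "-", NA_character_))
  if (!is.null(external)) {
    j <- match(res$snp, external$snp)
    p_ext <- external$p[j]
    a_ext <- external$a1[j]
    dir_ext <- ifelse(external$or[j] > 1, "+", ifelse(external$or[j] < 1, "-", NA_character_))
    flip <- !is.na(a_ext) & a_ext == res$a2
    dir_ext[flip] <- chartr("+-", "-+", dir_ext[flip])
    mismatch <- !is.na(a_ext) & a_ext != res$a1 & a_ext != res$a2
    if (any(mismatch)) {
      warning(sum(mismatch), " marker(s) dropped from the replication criterion: ",
              "external effect allele matches neither panel allele")
      p_ext[mismatch] <- NA_real_
    }
    res$crit_replication <- criterion_replication(res$p, p_ext, dir_int, dir_ext,
                                                  p2_int, p2_ext, p2_prod)
  } else {
    res$crit_replication <- FALSE
  }
  res$crit_effect_size <- criterion_effect_size(res$t, res$u, res$p,
                                                p3_ratio_low, p3_ratio_high, p3_p)
  res$selected <- res$crit_significance | res$crit_replication | res$crit_effect_size
  res
}

#' Merge markers into regions
#'
#' Single pass over position-sorted markers per chromosome: adjacent
#' markers separated by less than `gap` base pairs belong to the same
#' region; a gap of `gap` or more (default 100 kb) starts a new region.
#' Region membership partitions the input.
#'
#' @param markers data frame with `snp` (or `id`), `chrom`, `bp`.
#' @param gap region-breaking distance in bp.
#' @return a list with `regions` (data frame: `region`, `chrom`,
#'   `start_bp`, `end_bp`, `n_markers`, `members` comma-separated) and
#'   `assignment`, a named integer vector mapping marker id to region.
#' @export
build_regions <- function(markers, gap = 1e5) {
  id_col <- if ("snp" %in% names(markers)) "snp" else "id"
  mk <- data.frame(id = markers[[id_col]], chrom = as.character(markers$chrom),
                   bp = markers$bp, stringsAsFactors = FALSE)
  mk <- mk[order(mk$chrom, mk$bp), , drop = FALSE]
  region <- integer(nrow(mk))
  r <- 0L
  last_chrom <- NULL; last_bp <- NULL
  for (i in seq_len(nrow(mk))) {
    new_region <- is.null(last_chrom) || mk$chrom[i] != last_chrom ||
      (mk$bp[i] - last_bp) >= gap
    if (new_region) r <- r + 1L
    region[i] <- r
    last_chrom <- mk$chrom[i]; last_bp <- mk$bp[i]
  }
  regions <- do.call(rbind, lapply(split(seq_len(nrow(mk)), region), function(ix) {
    data.frame(region = region[ix[1L]], chrom = mk$chrom[ix[1L]],
               start_bp = min(mk$bp[ix]), end_bp = max(mk$bp[ix]),
               n_markers = length(ix),
               members = paste(mk$id[ix], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(regions) <- NULL
  assignment <- stats::setNames(region, mk$id)
  list(regions = regions, assignment = assignment)
}

#' Exclude the HLA interval
#'
#' Removes markers on chromosome 6 between 27 and 34 Mb (inclusive), the
#' extended HLA interval used when reporting associations "outside HLA".
#'
#' @param markers data frame with `chrom` and `bp`.
#' @param start_bp,end_bp interval bounds in bp.
#' @return the data frame without HLA-interval markers.
#' @export
exclude_hla <- function(markers, start_bp = 27e6, end_bp = 34e6) {
  drop <- as.character(markers$chrom) == "6" &
    markers$bp >= start_bp & markers$bp <= end_bp
  out <- markers[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a marker with nearby genes
#'
#' Returns up to `max_genes` genes whose interval lies within `max_dist`
#' of the marker position (distance 0 when the marker falls inside the
#' gene), ordered by distance with ties broken by gene symbol.  When no
#' gene is within range, the single nearest gene on the chromosome is
#' returned as a fallback.
#'
#' @param chrom,bp marker position.
#' @param genes gene interval table (`chrom`, `start`, `end`, `gene`;
#'   1-based inclusive, e.g. from [read_bed_genes()]).
#' @param max_dist annotation window in bp.
#' @param max_genes cap on the number of genes returned.
#' @return data frame with columns `gene` and `distance` (bp), possibly
#'   empty (with a warning) when the chromosome has no genes.
#' @export
annotate_genes <- function(chrom, bp, genes, max_dist = 250e3, max_genes = 5L) {
  g <- genes[as.character(genes$chrom) == as.character(chrom), , drop = FALSE]
  if (nrow(g) == 0L) {
    warning("no genes on chromosome ", chrom)
    return(data.frame(gene = character(), distance = numeric()))
  }
  inside <- bp >= g$start & bp <= g$end
  dist <- ifelse(inside, 0, pmin(abs(bp - g$start), abs(bp - g$end)))
  ord <- order(dist, g$gene)
  g <- g[ord, , drop = FALSE]; dist <- dist[ord]
  near <- dist <= max_dist
  if (!any(near)) {
    return(data.frame(gene = g$gene[1L], distance = dist[1L], stringsAsFactors = FALSE))
  }
  keep <- utils::head(which(near), max_genes)
  data.frame(gene = g$gene[keep], distance = dist[keep], stringsAsFactors = FALSE)
}

#' Annotate many markers at once
#'
#' @param markers data frame with `snp` (or `id`), `chrom`, `bp`.
#' @inheritParams annotate_genes
#' @return data frame `snp`, `gene`, `distance`, one row per annotation.
#' @export
annotate_markers <- function(markers, genes, max_dist = 250e3, max_genes = 5L) {
  id_col <- if ("snp" %in% names(markers)) "snp" else "id"
  out <- lapply(seq_len(nrow(markers)), function(i) {
    ann <- annotate_genes(markers$chrom[i], markers$bp[i], genes, max_dist, max_genes)
    if (nrow(ann) == 0L) return(NULL)
    cbind(snp = markers[[id_col]][i], ann, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(snp = character(), gene = character(),
                                      distance = numeric())
  rownames(out) <- NULL
  out
}
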