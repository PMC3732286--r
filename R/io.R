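# Readers and writers for the plain-text interchange formats the
# pipeline consumes: PLINK PED/FAM pedigrees, Oxford GEN/SAMPLE genotype
# posteriors, HLA stratum tables, external association results, BED gene
# intervals and long-format qPCR Ct tables.  All are whitespace- or
# tab-delimited text.

#' Read a pedigree and assemble affected-offspring trios
#'
#' Parses a whitespace-delimited PLINK FAM/PED-style file (at least six
#' columns: family, individual, father, mother, sex, phenotype) and
#' assembles one trio per offspring whose two parents are both present in
#' the file.  Affection status is mapped from phenotype code 2.
#' Offspring with a missing parent pointer (id `"0"`, or an id absent
#' from the file) are excluded with a warning.
#'
#' @param path path to the pedigree file.
#' @param affected_only if `TRUE` (default) only affected offspring yield
#'   trios; two affected sibs sharing parents yield two trios.
#' @return a data frame of trios with columns `family_id`, `father_id`,
#'   `mother_id`, `offspring_id`, `offspring_affected`; the full
#'   individual table is attached as attribute `"individuals"`.
#' @export
read_pedigree <- function(path, affected_only = TRUE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("malformed pedigree line ", which(nf < 6L)[1L],
         ": expected at least 6 whitespace-delimited columns")
  }
  ind <- data.frame(
    family_id = vapply(fields, `[[`, "", 1L),
    id        = vapply(fields, `[[`, "", 2L),
    father_id = vapply(fields, `[[`, "", 3L),
    mother_id = vapply(fields, `[[`, "", 4L),
    sex       = vapply(fields, `[[`, "", 5L),
    phenotype = vapply(fields, `[[`, "", 6L),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ind$id)) {
    stop("duplicated individual ids in pedigree: ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "))
  }
  has_pointer <- ind$father_id != "0" | ind$mother_id != "0"
  complete <- ind$father_id %in% ind$id & ind$mother_id %in% ind$id &
    ind$father_id != "0" & ind$mother_id != "0"
  dropped <- has_pointer & !complete
  if (any(dropped)) {
    warning(sum(dropped), " offspring excluded for a missing parent: ",
            paste(utils::head(ind$id[dropped], 5L), collapse = ", "))
  }
  off <- ind[complete, , drop = FALSE]
  affected <- off$phenotype == "2"
  if (affected_only) off <- off[affected, , drop = FALSE]
  trios <- data.frame(
    family_id = off$family_id,
    father_id = off$father_id,
    mother_id = off$mother_id,
    offspring_id = off$id,
    offspring_affected = off$phenotype == "2",
    stringsAsFactors = FALSE
  )
  rownames(trios) <- NULL
  attr(trios, "individuals") <- ind
  trios
}

#' Read an Oxford SAMPLE file
#'
#' @param path path to the SAMPLE file (header row, type row, then one
#'   row per sample).
#' @return character vector of sample ids (column `ID_2`).
#' @export
read_sample_file <- function(path) {
  if (!file.exists(path)) stop("sample file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  tab <- tab[-1L, , drop = FALSE]  # drop the type row
  as.character(tab$ID_2)
}

#' Read an Oxford GEN file of genotype posteriors
#'
#' Each marker row holds `chrom id bp a1 a2` followed by three posterior
#' probabilities `(p_AA, p_AB, p_BB)` per sample, where `AA` is the
#' A1/A1 genotype.
#'
#' @param path path to the GEN file.
#' @param sample_ids sample ids in file column order (e.g. from
#'   [read_sample_file()]).
#' @return a list with `markers` (data frame: `id`, `chrom`, `bp`, `a1`,
#'   `a2`) and `P`, a `samples x markers x 3` posterior array.
#' @export
read_gen <- function(path, sample_ids) {
  if (!file.exists(path)) stop("GEN file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(sample_ids)
  K <- length(lines)
  markers <- data.frame(
    id = character(K), chrom = character(K), bp = integer(K),
    a1 = character(K), a2 = character(K), stringsAsFactors = FALSE
  )
  P <- array(NA_real_, dim = c(n, K, 3L),
             dimnames = list(sample_ids, NULL, c("p_aa", "p_ab", "p_bb")))
  for (k in seq_len(K)) {
    f <- strsplit(trimws(lines[k]), "[ \t]+")[[1L]]
    if (length(f) != 5L + 3L * n) {
      stop("malformed GEN line ", k, ": expected ", 5L + 3L * n,
           " fields, found ", length(f))
    }
    markers$chrom[k] <- f[1L]
    markers$id[k] <- f[2L]
    markers$bp[k] <- as.integer(f[3L])
    markers$a1[k] <- f[4L]
    markers$a2[k] <- f[5L]
    probs <- matrix(as.numeric(f[-(1:5)]), ncol = 3L, byrow = TRUE)
    P[, k, ] <- probs
  }
  dimnames(P)[[2]] <- markers$id
  list(markers = markers, P = P)
}

#' Read a per-offspring HLA stratum table
#'
#' Expects a TSV with a header and columns `offspring_id`, `dqa_carrier`
#' (logical or yes/no: carrier of the DQA1*02/05 risk allele) and
#' `dqb_copies` (0, 1 or 2 copies of DQB1*02); alternatively a
#' precomputed `stratum` column (`high`/`low`) is accepted as-is.
#'
#' @param path path to the stratum TSV.
#' @return data frame with columns `offspring_id` and `stratum`.
#' @export
read_strata <- function(path) {
  if (!file.exists(path)) stop("stratum file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"offspring_id" %in% names(tab)) stop("stratum table needs an offspring_id column")
  if ("stratum" %in% names(tab)) {
    return(data.frame(offspring_id = as.character(tab$offspring_id),
                      stratum = as.character(tab$stratum),
                      stringsAsFactors = FALSE))
  }
  if (!all(c("dqa_carrier", "dqb_copies") %in% names(tab))) {
    stop("stratum table needs either a stratum column or dqa_carrier + dqb_copies")
  }
  carrier <- tab$dqa_carrier %in% c(TRUE, "TRUE", "yes", "Yes", "1")
  data.frame(offspring_id = as.character(tab$offspring_id),
             stratum = assign_stratum(carrier, tab$dqb_copies),
             stringsAsFactors = FALSE)
}

#' Read gene intervals from a BED file
#'
#' BED coordinates (0-based, half-open) are converted to 1-based
#' inclusive positions.
#'
#' @param path path to a BED file with at least `chrom start end name`.
#' @return data frame with columns `chrom`, `start`, `end`, `gene`.
#' @export
read_bed_genes <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("gene BED needs 4 columns: chrom start end name")
  data.frame(chrom = as.character(tab[[1L]]),
             start = as.integer(tab[[2L]]) + 1L,
             end = as.integer(tab[[3L]]),
             gene = as.character(tab[[4L]]),
             stringsAsFactors = FALSE)
}

#' Read an external association results table
#'
#' @param path TSV with header and columns `snp`, `a1`, `or`, `p`
#'   (effect allele, odds ratio and p-value of the replication study).
#' @return the data frame.
#' @export
read_external_results <- function(path) {
  if (!file.exists(path)) stop("external results file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp", "a1", "or", "p")
  if (!all(need %in% names(tab))) {
    stop("external results need columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' Read a long-format qPCR Ct table
#'
#' @param path TSV with header and columns `sample`, `group`, `gene`,
#'   `assay`, `ct`.
#' @return the data frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("Ct table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "assay", "ct")
  if (!all(need %in% names(tab))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  tab
}

# tab-separated writer used for every pipeline artifact
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pedigree, GEN and SAMPLE files for a simulated panel
#'
#' @param x a `trio_sim` or `trio_panel` object.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param digits digits for posterior probabilities.
#' @return (invisibly) named vector of the written paths.
#' @export
write_panel_files <- function(x, dir, prefix = "panel", digits = 6) {
  panel <- as_trio_panel(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fam = file.path(dir, paste0(prefix, ".fam")),
    gen = file.path(dir, paste0(prefix, ".gen")),
    sample = file.path(dir, paste0(prefix, ".sample")),
    strata = file.path(dir, paste0(prefix, ".strata.tsv"))
  )
  ped <- panel$ped
  writeLines(apply(ped, 1L, paste, collapse = " "), paths["fam"])
  ids <- panel$sample_ids
  P <- panel$P
  if (is.null(P)) {
    # degenerate posteriors from hard calls
    P <- .indicator_posteriors(panel$G)
  }
  mk <- panel$markers
  con <- file(paths["gen"], "w")
  on.exit(close(con))
  for (k in seq_len(nrow(mk))) {
    probs <- t(P[, k, ])
    probs[is.na(probs)] <- 0
    line <- paste(mk$chrom[k], mk$id[k], mk$bp[k], mk$a1[k], mk$a2[k],
                  paste(formatC(as.vector(probs), digits = digits, format = "g"),
                        collapse = " "))
    writeLines(line, con)
  }
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(ids, ids, "0")), paths["sample"])
  if (!is.null(panel$trios$stratum) && !all(is.na(panel$trios$stratum))) {
    write_tsv(data.frame(offspring_id = panel$trios$offspring_id,
                         stratum = panel$trios$stratum), paths["strata"])
  } else {
    paths <- paths[names(paths) != "strata"]
  }
  invisible(paths)
}

.indicator_posteriors <- function(G) {
  n <- nrow(G); K <- ncol(G)
  P <- array(0, dim = c(n, K, 3L),
             dimnames = list(rownames(G), colnames(G), c("p_aa", "p_ab", "p_bb")))
  for (col in 1:3) {
    d <- c(2L, 1L, 0L)[col]
    P[, , col] <- (G == d) * 1
  }
  # missingness is encoded as an all-zero triplet
  miss <- is.na(G)
  if (any(miss)) {
    for (col in 1:3) {
      tmp <- P[, , col]
      tmp[miss] <- 0
      P[, , col] <- tmp
    }
  }
  P
}

#' Assemble a trio genotype panel
#'
#' Bundles a marker map, a trio table and per-individual genotype data
#' (hard-call dosages and/or posterior triplets) into the container the
#' scan functions operate on.
#'
#' @param markers data frame with `id`, `chrom`, `bp`, `a1`, `a2`.
#' @param trios data frame as returned by [read_pedigree()], optionally
#'   with a `stratum` column.
#' @param G optional dosage matrix (samples x markers, rownames = ids).
#' @param P optional posterior array (samples x markers x 3).
#' @param ped optional raw pedigree table used when writing files.
#' @return an object of class `trio_panel`.
#' @export
trio_panel <- function(markers, trios, G = NULL, P = NULL, ped = NULL) {
  if (is.null(G) && is.null(P)) stop("need G (dosages) or P (posteriors)")
  ids <- if (!is.null(G)) rownames(G) else dimnames(P)[[1L]]
  if (is.null(ids)) stop("genotype rows must be named with sample ids")
  if (nrow(markers) != (if (!is.null(G)) ncol(G) else dim(P)[2L])) {
    stop("marker table and genotype columns disagree")
  }
  miss <- setdiff(unique(c(trios$father_id, trios$mother_id, trios$offspring_id)), ids)
  if (length(miss)) {
    stop("trio members without genotype data: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  if (any(duplicated(markers$id))) stop("marker ids must be unique within a panel")
  structure(list(markers = markers, trios = trios, G = G, P = P,
                 sample_ids = ids, ped = ped),
            class = "trio_panel")
}

#' Coerce to a trio panel
#' @param x object to coerce.
#' @param ... unused.
#' @export
as_trio_panel <- function(x, ...) UseMethod("as_trio_panel")

#' @export
as_trio_panel.trio_panel <- function(x, ...) x

#' @export
as_trio_panel.trio_sim <- function(x, ...) {
  trio_panel(x$markers, x$trios, G = x$G, P = x$P, ped = x$ped)
}

#' @export
print.trio_panel <- function(x, ...) {
  cat("trio genotype panel:", length(x$sample_ids), "samples,",
      nrow(x$markers), "markers,", nrow(x$trios), "trios\n")
  cat(" genotype data:",
      paste(c("hard calls"[!is.null(x$G)], "posteriors"[!is.null(x$P)]),
            collapse = " + "), "\n")
  if (!is.null(x$trios$stratum)) {
    cat(" strata:", paste(names(table(x$trios$stratum)),
                          table(x$trios$stratum), collapse = ", "), "\n")
  }
  invisible(x)
}
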