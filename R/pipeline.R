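# End-to-end orchestration: simulate or load a family panel, run QC,
# both TDT modes, the stratified TDT, marker selection, the two-locus
# interaction scan and (optionally) the expression stage, writing one
# TSV plus a JSON run-manifest per stage.  Outputs are pure functions of
# (inputs, config, seed): manifests carry no timestamps, so re-running
# with identical inputs reproduces every file byte for byte.

#' Pipeline configuration
#'
#' @param seed master seed; stage-level seeds are derived from it.
#' @param sim optional [sim_config()]; when present the input panel is
#'   simulated (and written to the output directory), otherwise `inputs`
#'   must point to pedigree/GEN/SAMPLE files.
#' @param inputs named list of input paths: `fam`, `gen`, `sample`,
#'   optionally `strata`, `external`, `genes`, `ct`.
#' @param stratified run the HLA-stratified TDT stage.
#' @param express run the expression stage (requires a `ct` input or a
#'   simulated Ct table via `sim_ct`).
#' @param sim_ct optional arguments (list) for [make_ct_table()] used
#'   when `express = TRUE` and no `ct` input is given.
#' @param hard_call_threshold posterior hard-call threshold.
#' @param thresholds named list of selection/interaction thresholds
#'   overriding the study defaults (`p1_alpha`, `p2_int`, `p2_ext`,
#'   `p2_prod`, `p3_ratio_low`, `p3_ratio_high`, `p3_p`, `region_gap`,
#'   `min_families`, `restarts`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL, inputs = list(),
                            stratified = TRUE, express = FALSE, sim_ct = NULL,
                            hard_call_threshold = 0.95, thresholds = list()) {
  defaults <- list(p1_alpha = 3e-4, p2_int = 0.01, p2_ext = 0.05,
                   p2_prod = 5e-5, p3_ratio_low = 0.2, p3_ratio_high = 5,
                   p3_p = 2e-3, region_gap = 1e5, min_families = 20L,
                   restarts = 10L)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown)) stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  defaults[names(thresholds)] <- thresholds
  structure(list(seed = as.integer(seed), sim = sim, inputs = inputs,
                 stratified = stratified, express = express, sim_ct = sim_ct,
                 hard_call_threshold = hard_call_threshold,
                 thresholds = defaults),
            class = "pipeline_config")
}

.manifest <- function(out_dir, stage, params, inputs = character(),
                      outputs = character(), counts = list(), status = "ok",
                      error = NULL) {
  hash <- function(paths) {
    paths <- paths[file.exists(paths)]
    if (!length(paths)) return(NULL)
    h <- tools::md5sum(paths)
    names(h) <- basename(paths)   # keys must not leak absolute paths
    as.list(h)
  }
  man <- list(stage = stage, status = status,
              package_version = as.character(utils::packageVersion("trioscan")),
              params = params, input_md5 = hash(inputs),
              output_md5 = hash(outputs), counts = counts)
  if (!is.null(error)) man$error <- error
  jsonlite::write_json(man, file.path(out_dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(man)
}

.run_stage <- function(stage, out_dir, fn) {
  tryCatch(fn(), error = function(e) {
    .manifest(out_dir, stage, params = list(), status = "failed",
              error = conditionMessage(e))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> QC -> TDT (hard and expected modes) ->
#' stratified TDT -> marker selection and regions -> cross-region
#' interaction scan -> (optional) expression analysis.  Each stage
#' writes a TSV artifact and a JSON manifest (parameters, input/output
#' MD5 hashes, record counts) to `out_dir`.  A stage failure halts the
#' pipeline with an error naming the stage, after writing a failure
#' manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory stage results and the
#'   output directory.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  res <- list(out_dir = out_dir)

  # --- input stage: simulate or load ---------------------------------
  panel <- .run_stage("input", out_dir, function() {
    if (!is.null(config$sim)) {
      sim <- simulate_families(config$sim)
      sim <- blur_posteriors(sim, seed = config$seed + 1L)
      paths <- write_panel_files(sim, out_dir, prefix = "input")
      .manifest(out_dir, "input",
                params = list(mode = "simulate", seed = config$sim$seed,
                              n_families = config$sim$n_families,
                              lambda = config$sim$lambda),
                outputs = unname(paths),
                counts = list(families = config$sim$n_families,
                              markers = nrow(sim$markers),
                              trios = nrow(sim$trios)))
      as_trio_panel(sim)
    } else {
      inp <- config$inputs
      need <- c("fam", "gen", "sample")
      if (!all(need %in% names(inp))) {
        stop("inputs must name fam, gen and sample files")
      }
      trios <- read_pedigree(inp$fam)
      ids <- read_sample_file(inp$sample)
      gen <- read_gen(inp$gen, ids)
      if (config$stratified) {
        if (is.null(inp$strata)) stop("stratified mode requires a strata input file")
        strata <- read_strata(inp$strata)
        trios$stratum <- strata$stratum[match(trios$offspring_id, strata$offspring_id)]
      }
      .manifest(out_dir, "input",
                params = list(mode = "load"),
                inputs = unlist(inp, use.names = FALSE),
                counts = list(markers = nrow(gen$markers), trios = nrow(trios)))
      trio_panel(gen$markers, trios, P = gen$P)
    }
  })
  res$panel <- panel

  # --- marker QC -----------------------------------------------------
  qc <- .run_stage("qc", out_dir, function() {
    G <- panel$G
    if (is.null(G)) {
      K <- dim(panel$P)[2L]
      G <- matrix(NA_integer_, dim(panel$P)[1L], K,
                  dimnames = list(dimnames(panel$P)[[1L]], panel$markers$id))
      for (k in seq_len(K)) G[, k] <- hard_call(panel$P[, k, ], config$hard_call_threshold)
    }
    founders <- unique(c(panel$trios$father_id, panel$trios$mother_id))
    out <- marker_qc(G, founders = founders)
    path <- file.path(out_dir, "qc_report.tsv")
    write_tsv(out$report, path)
    .manifest(out_dir, "qc",
              params = list(call_rate_min = 0.97, maf_min = 0.01,
                            hard_call_threshold = config$hard_call_threshold),
              outputs = path,
              counts = list(markers_in = nrow(out$report),
                            markers_kept = length(out$keep)))
    out
  })
  res$qc <- qc
  keep_panel <- .subset_panel(panel, qc$keep)

  # --- TDT, both modes ----------------------------------------------
  res$tdt_hard <- .run_stage("tdt_hard", out_dir, function() {
    scan <- tdt_scan(keep_panel, mode = "hard",
                     threshold = config$hard_call_threshold)
    path <- file.path(out_dir, "tdt_hard.tsv")
    write_tsv(as.data.frame(scan), path)
    .manifest(out_dir, "tdt_hard",
              params = list(mode = "hard", threshold = config$hard_call_threshold),
              outputs = path, counts = list(markers = nrow(scan)))
    scan
  })
  res$tdt_expected <- .run_stage("tdt_expected", out_dir, function() {
    if (is.null(keep_panel$P)) return(NULL)
    scan <- tdt_scan(keep_panel, mode = "expected")
    path <- file.path(out_dir, "tdt_expected.tsv")
    write_tsv(as.data.frame(scan), path)
    .manifest(out_dir, "tdt_expected", params = list(mode = "expected"),
              outputs = path, counts = list(markers = nrow(scan)))
    scan
  })

  # --- stratified TDT ------------------------------------------------
  if (config$stratified) {
    res$tdt_stratified <- .run_stage("tdt_stratified", out_dir, function() {
      scan <- tdt_scan(keep_panel, mode = "hard",
                       threshold = config$hard_call_threshold,
                       stratified = TRUE)
      path <- file.path(out_dir, "tdt_stratified.tsv")
      write_tsv(as.data.frame(scan), path)
      .manifest(out_dir, "tdt_stratified",
                params = list(threshold = config$hard_call_threshold),
                outputs = path, counts = list(markers = nrow(scan)))
      scan
    })
  }

  # --- marker selection + regions ------------------------------------
  sel <- .run_stage("select", out_dir, function() {
    results <- if (!is.null(res$tdt_expected)) res$tdt_expected else res$tdt_hard
    external <- NULL
    if (!is.null(config$inputs$external)) {
      external <- read_external_results(config$inputs$external)
    }
    tab <- select_markers(results, external,
                          p1_alpha = th$p1_alpha, p2_int = th$p2_int,
                          p2_ext = th$p2_ext, p2_prod = th$p2_prod,
                          p3_ratio_low = th$p3_ratio_low,
                          p3_ratio_high = th$p3_ratio_high, p3_p = th$p3_p)
    chosen <- exclude_hla(tab[tab$selected, , drop = FALSE])
    reg <- if (nrow(chosen)) build_regions(chosen, gap = th$region_gap)
           else list(regions = data.frame(), assignment = integer())
    p1 <- file.path(out_dir, "selected.tsv")
    p2 <- file.path(out_dir, "regions.tsv")
    write_tsv(tab, p1)
    write_tsv(reg$regions, p2)
    .manifest(out_dir, "select",
              params = th[c("p1_alpha", "p2_int", "p2_ext", "p2_prod",
                            "p3_ratio_low", "p3_ratio_high", "p3_p", "region_gap")],
              outputs = c(p1, p2),
              counts = list(markers = nrow(tab), selected = nrow(chosen),
                            regions = nrow(reg$regions)))
    list(table = tab, chosen = chosen, regions = reg)
  })
  res$selection <- sel

  # --- interaction scan ----------------------------------------------
  res$interactions <- .run_stage("interact", out_dir, function() {
    out <- interaction_scan(keep_panel, sel$chosen, regions = sel$regions,
                            min_families = th$min_families,
                            restarts = th$restarts, seed = config$seed + 2L)
    path <- file.path(out_dir, "interactions.tsv")
    write_tsv(out, path)
    .manifest(out_dir, "interact",
              params = th[c("min_families", "restarts")],
              outputs = path, counts = list(pairs = nrow(out)))
    out
  })

  # --- expression ----------------------------------------------------
  if (config$express) {
    res$expression <- .run_stage("express", out_dir, function() {
      if (!is.null(config$inputs$ct)) {
        ct <- read_ct_table(config$inputs$ct)
        refs <- c("ACTB", "EPCAM", "PGK1")
      } else if (!is.null(config$sim_ct)) {
        args <- config$sim_ct
        if (is.null(args$seed)) args$seed <- config$seed + 3L
        ct <- do.call(make_ct_table, args)
        refs <- if (!is.null(args$reference_genes)) args$reference_genes
                else c("ACTB", "EPCAM", "PGK1")
      } else {
        stop("express stage needs a ct input file or sim_ct arguments")
      }
      out <- ddct_analysis(ct, reference_genes = refs)
      path <- file.path(out_dir, "expression.tsv")
      write_tsv(as.data.frame(out), path)
      .manifest(out_dir, "express",
                params = list(reference_genes = refs, m = attr(out, "m")),
                outputs = path, counts = list(assays = nrow(out)))
      out
    })
  }
  invisible(res)
}

# restrict a panel to a set of marker ids (QC survivors keep their
# genotype values; only set membership changes)
.subset_panel <- function(panel, keep_ids) {
  k <- match(keep_ids, panel$markers$id)
  panel$markers <- panel$markers[k, , drop = FALSE]
  if (!is.null(panel$G)) panel$G <- panel$G[, k, drop = FALSE]
  if (!is.null(panel$P)) panel$P <- panel$P[, k, , drop = FALSE]
  panel
}
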