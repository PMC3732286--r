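# Marker inclusion criteria, region building and gene annotation.

test_that("criterion 1 uses a strict 3e-4 threshold", {
  expect_true(criterion_significance(2.9e-4))
  expect_false(criterion_significance(3.0e-4))
  expect_true(criterion_significance(7.11e-6))
  expect_false(criterion_significance(NA))
})

test_that("criterion 2 requires both p-values, their product, and direction", {
  expect_true(criterion_replication(0.005, 0.004, "+", "+"))
  expect_false(criterion_replication(0.005, 0.04, "+", "+"))   # product 2e-4
  expect_false(criterion_replication(0.001, 0.01, "+", "-"))   # direction
  expect_false(criterion_replication(0.02, 1e-6, "+", "+"))    # internal p
  expect_false(criterion_replication(NA, 0.01, "+", "+"))
})

test_that("criterion 3 combines extreme transmission ratio with significance", {
  expect_true(criterion_effect_size(20, 2, 1.24e-4))   # ratio 10
  expect_false(criterion_effect_size(36, 8, 2.43e-5))  # ratio 4.5, not > 5
  expect_false(criterion_effect_size(1, 10, 0.01))     # p fails
  expect_true(criterion_effect_size(10, 0, 1e-4))      # u = 0 -> infinite ratio
  expect_true(criterion_effect_size(1, 10, 1e-3))      # ratio 0.1 < 0.2
})

test_that("selection is the union of the criteria and is monotone in thresholds", {
  res <- data.frame(
    snp = c("s1", "s2", "s3", "s4"),
    chrom = "1", bp = c(1e6, 2e6, 3e6, 4e6),
    a1 = "A", a2 = "G",
    t = c(50, 30, 40, 22), u = c(120, 31, 4, 21),
    p = c(1e-5, 0.5, 1e-3, 0.9)
  )
  ext <- data.frame(snp = "s1", a1 = "A", or = 0.5, p = 1e-4)
  sel <- select_markers(res, ext)
  expect_true(sel$selected[1L])                     # criteria 1 and 2
  expect_false(sel$selected[2L])
  expect_true(sel$selected[3L])                     # criterion 3, ratio 10
  expect_false(sel$selected[4L])
  # loosening thresholds never removes a selected marker
  sel_loose <- select_markers(res, ext, p1_alpha = 1e-2, p3_p = 0.05)
  expect_true(all(sel_loose$selected[sel$selected]))
})

test_that("external direction is harmonised to the panel's A1 allele", {
  res <- data.frame(snp = "s1", chrom = "1", bp = 1e6, a1 = "A", a2 = "G",
                    t = 50, u = 120, p = 1e-5)
  # internal direction is "-" (t < u); external OR on allele G must flip
  ext_flipped <- data.frame(snp = "s1", a1 = "G", or = 2.0, p = 1e-4)
  expect_true(select_markers(res, ext_flipped)$crit_replication)
  ext_same <- data.frame(snp = "s1", a1 = "A", or = 2.0, p = 1e-4)
  expect_false(select_markers(res, ext_same)$crit_replication)
  ext_bad <- data.frame(snp = "s1", a1 = "T", or = 0.5, p = 1e-4)
  expect_warning(out <- select_markers(res, ext_bad), "neither panel allele")
  expect_false(out$crit_replication)
})

test_that("regions split at gaps of 100 kb or more", {
  mk <- data.frame(snp = c("a", "b", "c"), chrom = "1",
                   bp = c(100000, 150000, 260000))
  reg <- build_regions(mk)
  expect_equal(nrow(reg$regions), 2L)
  expect_equal(unname(reg$assignment[c("a", "b", "c")]), c(1L, 1L, 2L))
  # boundary: exactly 100 kb splits
  reg2 <- build_regions(data.frame(snp = c("a", "b"), chrom = "1",
                                   bp = c(1e6, 1e6 + 1e5)))
  expect_equal(nrow(reg2$regions), 2L)
  reg3 <- build_regions(data.frame(snp = "solo", chrom = "2", bp = 5e6))
  expect_equal(reg3$regions$n_markers, 1L)
})

test_that("region membership partitions the marker set", {
  set.seed(13)
  mk <- data.frame(snp = sprintf("m%02d", 1:40),
                   chrom = sample(c("1", "2", "7"), 40, replace = TRUE),
                   bp = sample.int(5e6, 40))
  reg <- build_regions(mk)
  expect_setequal(names(reg$assignment), mk$snp)
  members <- unlist(strsplit(reg$regions$members, ","))
  expect_setequal(members, mk$snp)
  expect_equal(anyDuplicated(members), 0L)
  # within-region gaps < 100 kb, cross-region gaps on a chromosome >= 100 kb
  for (ch in unique(mk$chrom)) {
    sub <- mk[mk$chrom == ch, ]
    sub <- sub[order(sub$bp), ]
    gaps <- diff(sub$bp)
    same <- diff(reg$assignment[sub$snp]) == 0L
    expect_true(all(gaps[same] < 1e5))
    expect_true(all(gaps[!same] >= 1e5))
  }
})

test_that("gene annotation orders by distance, caps at 5 and falls back to nearest", {
  genes <- data.frame(
    chrom = "1",
    start = c(900, 5000, 50000, 100000, 150000, 200000, 240000, 600000),
    end = c(1100, 6000, 51000, 101000, 151000, 201000, 241000, 601000),
    gene = paste0("g", 1:8)
  )
  ann <- annotate_genes("1", 1000, genes)
  expect_equal(ann$gene[1L], "g1")
  expect_equal(ann$distance[1L], 0)
  expect_equal(nrow(ann), 5L)                    # 7 genes in range, capped at 5
  # no gene within 250 kb: nearest returned
  far <- annotate_genes("1", 1.5e6, genes[1:2, ])
  expect_equal(far$gene, "g2")
  expect_warning(none <- annotate_genes("9", 1000, genes), "no genes")
  expect_equal(nrow(none), 0L)
})

test_that("annotation distance ties break by gene symbol", {
  genes <- data.frame(chrom = "1", start = c(2000, 2000), end = c(3000, 3000),
                      gene = c("zeta", "alpha"))
  ann <- annotate_genes("1", 1000, genes)
  expect_equal(ann$gene, c("alpha", "zeta"))
})

test_that("BED gene input is converted to 1-based inclusive coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t999\t2000\tGENE1", "2\t0\t100\tGENE2"), path)
  genes <- read_bed_genes(path)
  expect_equal(genes$start, c(1000L, 1L))
  expect_equal(genes$end, c(2000L, 100L))
})

test_that("a planted external fixture selects exactly the planted markers", {
  sim <- simulate_families(sim_config(
    n_families = 120, seed = 33,
    disease = list(penetrance_single_locus("risk1", baseline = 0.05,
                                           grr = c(1, 3, 9)))
  ))
  scan <- tdt_scan(sim, mode = "hard")
  ext <- make_external_table(sim$markers, replicate_ids = "risk1",
                             internal = scan, seed = 34)
  sel <- select_markers(scan, ext)
  # the planted marker replicates; null markers lack any criterion
  expect_true(sel$crit_replication[sel$snp == "risk1"])
  expect_true(sel$selected[sel$snp == "risk1"])
})
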