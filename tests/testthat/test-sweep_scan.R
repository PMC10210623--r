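test_that("window tiling follows the stated convention", {
  w <- make_windows(50000, 20000, 10000)
  expect_equal(nrow(w), 5L)
  expect_equal(w$start[5], 40000L)
  expect_equal(w$end[5], 50000L)
  expect_true(w$partial[5])

  w2 <- make_windows(15000, 20000, 10000)
  expect_equal(nrow(w2), 2L)
  expect_equal(unname(as.matrix(w2[, 1:2])),
               matrix(c(0L, 10000L, 15000L, 15000L), ncol = 2))

  # window = step tiles the chromosome without overlap
  w3 <- make_windows(95000, 10000, 10000)
  expect_equal(sum(w3$end - w3$start), 95000L)
  expect_true(all(diff(w3$start) == 10000L))
})

test_that("percentile selection follows the rank rule and reports min selected value", {
  base <- data.frame(chrom = "chr1",
                     start = seq(0L, by = 10000L, length.out = 100),
                     end = seq(20000L, by = 10000L, length.out = 100),
                     fst_win = 0.01 * (1:100),
                     log2_pi_ratio = rep(0.1, 100))
  sel <- select_outlier_windows(base, scan_config(top_fraction = 0.01))
  expect_equal(sel$thresholds$n_windows_fst, 1L)
  expect_equal(sel$thresholds$fst_threshold, 1.00)
  expect_equal(sel$windows$fst_win[sel$windows$sel_fst], 1.00)

  base200 <- rbind(base, transform(base, chrom = "chr2"))
  sel2 <- select_outlier_windows(base200, scan_config(top_fraction = 0.01))
  expect_equal(sel2$thresholds$n_windows_fst, 2L)
  expect_equal(sel2$thresholds$n_windows_ratio, 2L)

  # too few windows in percentile mode is an error advising fixed thresholds
  expect_error(select_outlier_windows(base[1:50, ], scan_config()),
               "fixed thresholds")
  # fixed-threshold override is honored (strict inequality)
  self <- select_outlier_windows(base[1:50, ],
                                 scan_config(fst_min = 0.40,
                                             abs_log2_ratio_min = 5))
  expect_equal(sum(self$windows$sel_fst), 10L)
  expect_equal(sum(self$windows$sel_ratio), 0L)
})

test_that("region merging, criteria union, and idempotence", {
  sel <- data.frame(chrom = "chr1", start = c(0L, 10000L),
                    end = c(20000L, 30000L),
                    fst_win = c(0.5, 0.6), log2_pi_ratio = c(-2, -1),
                    sel_fst = c(TRUE, FALSE), sel_ratio = c(FALSE, TRUE))
  r <- call_candidate_regions(sel)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(0L, 30000L))
  expect_equal(r$criteria, "FST,PI_RATIO")
  expect_equal(r$peak_fst, 0.6)
  expect_equal(r$peak_abs_log2_ratio, 2)

  disjoint <- data.frame(chrom = "chr1", start = c(0L, 30000L),
                         end = c(20000L, 50000L),
                         fst_win = c(0.5, 0.6), log2_pi_ratio = c(0, 0),
                         sel_fst = TRUE, sel_ratio = FALSE)
  r2 <- call_candidate_regions(disjoint)
  expect_equal(nrow(r2), 2L)

  # idempotent on already-merged regions
  again <- call_candidate_regions(
    data.frame(chrom = r2$chrom, start = r2$start, end = r2$end,
               fst_win = r2$peak_fst, log2_pi_ratio = 0,
               sel_fst = TRUE, sel_ratio = FALSE))
  expect_equal(again[, c("chrom", "start", "end")],
               r2[, c("chrom", "start", "end")])
})

test_that("gene assignment respects half-open boundaries", {
  models <- list(
    gA = gene_model("gA", "gA.t", "chr1", "+",
                    data.frame(start = 5001L, end = 7999L, phase = 0L),
                    gene_span = c(5001L, 8000L)),
    gB = gene_model("gB", "gB.t", "chr1", "+",
                    data.frame(start = 30001L, end = 30999L, phase = 0L),
                    gene_span = c(30001L, 31000L)))
  region <- data.frame(chrom = "chr1", start = 0L, end = 30000L,
                       criteria = "FST", peak_fst = 0.5,
                       peak_abs_log2_ratio = 1, n_windows = 3L)
  out <- assign_genes(region, models)
  # gA (1-based 5001..8000 = 0-based [5000, 8000)) overlaps [0, 30000)
  # gB starts exactly at the region end (0-based 30000) -> excluded
  expect_equal(out$genes, "gA")

  fx <- cached_fixture()
  sweep_regions <- data.frame(chrom = fx$sweeps$chrom, start = fx$sweeps$start,
                              end = fx$sweeps$end, criteria = "FST",
                              peak_fst = NA_real_, peak_abs_log2_ratio = NA_real_,
                              n_windows = 1L)
  out <- assign_genes(sweep_regions, fx$models)
  got <- sort(unique(attr(out, "gene_hits")$gene_id))
  expect_equal(got, truth_manifest(fx)$sweep_genes)
})

test_that("the fixture scan separates planted sweep windows from background", {
  fx <- cached_fixture()
  cfg <- scan_config(top_fraction = fx$config$scan_top_fraction)
  cts <- genotype_counts(fx$gd)
  ws <- window_stats(cts, fx$gd$contig_lengths, cfg)
  sel <- select_outlier_windows(ws, cfg)
  sc <- score_sweep_recovery(ws, sel$windows, fx$sweeps)
  expect_gte(sc$sensitivity, 0.90)
  expect_gte(sc$precision, 0.95)
  # thresholds fall between the planted and background score distributions
  bg_fst <- ws$fst_win[!sc$planted & !is.na(ws$fst_win)]
  pl_fst <- ws$fst_win[sc$planted]
  expect_gt(sel$thresholds$fst_threshold, median(bg_fst))
  expect_lt(sel$thresholds$fst_threshold, median(pl_fst))
  bg_rat <- abs(ws$log2_pi_ratio[!sc$planted])
  pl_rat <- abs(ws$log2_pi_ratio[sc$planted])
  expect_gt(sel$thresholds$log2_ratio_threshold, median(bg_rat, na.rm = TRUE))
  expect_lt(sel$thresholds$log2_ratio_threshold, median(pl_rat))
  # the pi-ratio outliers are ALK diversity losses (negative log2 ratio)
  expect_true(all(ws$log2_pi_ratio[sc$planted] < 0))
})

test_that("fine mapping pads the region and agrees with the coarse scan", {
  fx <- cached_fixture()
  cfg <- scan_config(top_fraction = fx$config$scan_top_fraction)
  cts <- genotype_counts(fx$gd)
  ws <- window_stats(cts, fx$gd$contig_lengths, cfg)
  sel <- select_outlier_windows(ws, cfg)
  regions <- call_candidate_regions(sel$windows)
  reg <- regions[1, ]
  fm <- fine_map(reg, cts, fx$gd$contig_lengths, cfg)
  # one padding window each side of the region, on the fine grid
  expect_equal(fm$start[1], reg$start - cfg$fine_window_bp)
  expect_equal(fm$end[nrow(fm)], reg$end + cfg$fine_window_bp)
  expect_true(all(fm$end - fm$start <= cfg$fine_window_bp))
  # uniform-signal region: fine-grid Fst stays near the coarse value
  interior <- fm$start >= reg$start & fm$end <= reg$end
  expect_true(all(abs(fm$fst_win[interior] - reg$peak_fst) < 0.25))
  # fine windows fully inside the planted sweep carry the strongest signal
  insweep <- vapply(seq_len(nrow(fm)), function(i)
    any(fx$sweeps$chrom == fm$chrom[i] & fm$start[i] >= fx$sweeps$start &
          fm$end[i] <= fx$sweeps$end), logical(1))
  expect_gt(min(fm$fst_win[insweep]), max(fm$fst_win[!insweep], na.rm = TRUE))
})

test_that("scan output is deterministic across reruns", {
  fx <- cached_fixture()
  tmp <- withr::local_tempdir()
  cfg <- scan_config(top_fraction = fx$config$scan_top_fraction)
  d1 <- file.path(tmp, "r1"); d2 <- file.path(tmp, "r2")
  run_scan(fx$gd, gff = fx$models, genome = fx$genome, out_dir = d1,
           config = cfg, verbose = FALSE)
  run_scan(fx$gd, gff = fx$models, genome = fx$genome, out_dir = d2,
           config = cfg, verbose = FALSE)
  for (f in c("windows.tsv", "regions.tsv", "scan.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # refusing to overwrite without force
  expect_error(run_scan(fx$gd, gff = fx$models, genome = fx$genome,
                        out_dir = d1, config = cfg, verbose = FALSE),
               "force")
})
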