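#' Sliding-window scan configuration
#'
#' Defaults follow the coarse scan of the study design this package
#' implements: 20 kb windows advanced in 10 kb steps, the top 1% of windows
#' selected per criterion, and 10 kb windows for fine mapping.
#'
#' @param window_bp window size, bp.
#' @param step_bp step size, bp (must not exceed `window_bp`).
#' @param fine_window_bp fine-mapping window size, bp.
#' @param top_fraction fraction of windows selected per criterion in
#'   percentile mode (0 < f < 1).
#' @param fst_min optional fixed windowed-Fst threshold overriding the
#'   percentile rule.
#' @param abs_log2_ratio_min optional fixed |log2 pi-ratio| threshold
#'   overriding the percentile rule.
#' @param one_sided_ratio select only ALK-depleted windows (negative log2
#'   ratio) instead of two-sided |log2 ratio| outliers.
#' @param max_gap maximum gap (bp) bridged when merging selected windows into
#'   regions; 0 merges overlapping and book-ended windows only.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(window_bp = 20000L, step_bp = 10000L,
                        fine_window_bp = 10000L, top_fraction = 0.01,
                        fst_min = NULL, abs_log2_ratio_min = NULL,
                        one_sided_ratio = FALSE, max_gap = 0L) {
  stopifnot(step_bp <= window_bp, step_bp > 0, window_bp > 0,
            top_fraction > 0, top_fraction < 1, fine_window_bp > 0,
            max_gap >= 0)
  structure(list(window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp),
                 fine_window_bp = as.integer(fine_window_bp),
                 top_fraction = top_fraction, fst_min = fst_min,
                 abs_log2_ratio_min = abs_log2_ratio_min,
                 one_sided_ratio = one_sided_ratio,
                 max_gap = as.integer(max_gap)),
            class = "scan_config")
}

#' Sliding windows over a chromosome
#'
#' 0-based half-open windows starting at 0, `step_bp`, 2*`step_bp`, ... while
#' the start lies inside the chromosome; the end is clipped at the chromosome
#' length and clipped ("partial") windows are flagged, not dropped.
#'
#' @param chrom_length chromosome length, bp.
#' @param window_bp,step_bp window and step size, bp.
#' @return data frame with columns `start`, `end`, `partial`.
#' @export
make_windows <- function(chrom_length, window_bp, step_bp) {
  stopifnot(chrom_length > 0)
  starts <- seq.int(0L, chrom_length - 1L, by = step_bp)
  ends <- pmin(starts + window_bp, chrom_length)
  data.frame(start = as.integer(starts), end = as.integer(ends),
             partial = ends - starts < window_bp)
}

# indices of sites (1-based `pos`) falling in 0-based half-open [start, end)
sites_in_window <- function(pos, start, end) which(pos > start & pos <= end)

#' Windowed statistics over the genome
#'
#' Computes, for every sliding window of every chromosome: the number of
#' sites, per-population per-bp pi, the log2 pi-ratio (ALK/FW; zero
#' diversities replaced by the genome-wide smallest nonzero per-bp pi and
#' flagged), the ratio-of-sums Weir-Cockerham Fst, and per-population
#' Tajima's D.
#'
#' @param counts output of [genotype_counts()].
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param config a [scan_config()].
#' @param windows optional precomputed window table (columns `chrom`, `start`,
#'   `end`); by default [make_windows()] is applied per chromosome.
#' @return data frame: `chrom`, `start`, `end`, `partial`, `n_sites`,
#'   `pi_alk`, `pi_fw`, `log2_pi_ratio`, `pi_floored`, `fst_win`, `tajd_alk`,
#'   `tajd_fw`.
#' @export
window_stats <- function(counts, chrom_lengths, config = scan_config(),
                         windows = NULL) {
  counts <- site_frequencies(counts)
  comp <- wc_fst_components(counts)
  if (is.null(windows)) {
    windows <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
      w <- make_windows(chrom_lengths[[ch]], config$window_bp, config$step_bp)
      cbind(chrom = ch, w)
    }))
  } else if (is.null(windows$partial)) windows$partial <- FALSE
  n <- nrow(windows)
  out <- cbind(windows,
               n_sites = 0L, pi_alk = 0, pi_fw = 0, fst_win = NA_real_,
               tajd_alk = NA_real_, tajd_fw = NA_real_)
  by_chrom <- split(seq_len(nrow(counts)), counts$chrom)
  suppress_n_warn <- function(expr)
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("fewer than 4 chromosomes", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  for (i in seq_len(n)) {
    idx <- by_chrom[[windows$chrom[i]]]
    if (is.null(idx)) next
    sel <- idx[sites_in_window(counts$pos[idx], windows$start[i], windows$end[i])]
    out$n_sites[i] <- length(sel)
    span <- windows$end[i] - windows$start[i]
    out$pi_alk[i] <- window_pi(counts$p_alk[sel], counts$an_alk[sel], span)
    out$pi_fw[i] <- window_pi(counts$p_fw[sel], counts$an_fw[sel], span)
    if (length(sel)) {
      num <- sum(comp$a[sel], na.rm = TRUE); den <- sum(comp$d[sel], na.rm = TRUE)
      out$fst_win[i] <- if (all(is.na(comp$d[sel])) || den == 0) NA_real_ else num / den
      out$tajd_alk[i] <- suppress_n_warn(tajimas_d(counts$p_alk[sel], counts$an_alk[sel]))
      out$tajd_fw[i] <- suppress_n_warn(tajimas_d(counts$p_fw[sel], counts$an_fw[sel]))
    }
  }
  nz <- c(out$pi_alk, out$pi_fw)
  nz <- nz[nz > 0]
  floor_val <- if (length(nz)) min(nz) else 1e-8
  rat <- pi_ratio_log2(out$pi_alk, out$pi_fw, floor_val)
  out$log2_pi_ratio <- rat$log2_pi_ratio
  out$pi_floored <- rat$pi_floored
  attr(out, "pi_pseudo_floor") <- floor_val
  out[, c("chrom", "start", "end", "partial", "n_sites", "pi_alk", "pi_fw",
          "log2_pi_ratio", "pi_floored", "fst_win", "tajd_alk", "tajd_fw")]
}

#' Select outlier windows by the percentile (or fixed-threshold) rule
#'
#' Rank-based "top fraction" selection, applied independently to windowed Fst
#' and to |log2 pi-ratio| (or the ALK-depleted tail when
#' `one_sided_ratio = TRUE`): the top `ceiling(top_fraction * N)` non-`NA`
#' windows are selected per criterion and the reported threshold is the
#' minimum selected value — reproducing "the 1% highest" literally, so the
#' printed cutoffs are computed outputs of the data, not constants.  Fixed
#' thresholds in the config override the percentile rule per criterion.
#'
#' @param ws output of [window_stats()].
#' @param config a [scan_config()].
#' @return list with `thresholds` (named list: `fst_threshold`,
#'   `log2_ratio_threshold`, `n_windows_fst`, `n_windows_ratio`) and
#'   `windows` (`ws` rows selected by either criterion, with logical columns
#'   `sel_fst`, `sel_ratio`).
#' @export
select_outlier_windows <- function(ws, config = scan_config()) {
  score_ratio <- if (isTRUE(config$one_sided_ratio)) -ws$log2_pi_ratio
                 else abs(ws$log2_pi_ratio)
  pick <- function(score, fixed) {
    ok <- which(!is.na(score))
    if (!is.null(fixed)) return(ok[score[ok] > fixed])
    if (length(ok) < 100)
      config_error(paste("fewer than 100 usable windows for percentile",
                         "selection; set fixed thresholds (fst_min /",
                         "abs_log2_ratio_min) instead"))
    k <- ceiling(config$top_fraction * length(ok))
    ok[order(score[ok], decreasing = TRUE)[seq_len(k)]]
  }
  i_fst <- pick(ws$fst_win, config$fst_min)
  i_rat <- pick(score_ratio, config$abs_log2_ratio_min)
  thresholds <- list(
    fst_threshold = if (length(i_fst)) min(ws$fst_win[i_fst]) else NA_real_,
    log2_ratio_threshold = if (length(i_rat)) min(score_ratio[i_rat]) else NA_real_,
    n_windows_fst = length(i_fst), n_windows_ratio = length(i_rat))
  sel <- sort(union(i_fst, i_rat))
  windows <- ws[sel, , drop = FALSE]
  windows$sel_fst <- sel %in% i_fst
  windows$sel_ratio <- sel %in% i_rat
  rownames(windows) <- NULL
  list(thresholds = thresholds, windows = windows)
}

#' Merge selected windows into candidate regions
#'
#' Overlapping or book-ended selected windows (within `max_gap` bp) are merged
#' per chromosome; a region's criteria are the union of its member windows'
#' criteria and its peak statistics the member maxima.  Idempotent: calling it
#' on already-merged regions returns them unchanged.
#'
#' @param selected `windows` element of [select_outlier_windows()] (columns
#'   `chrom`, `start`, `end`, `fst_win`, `log2_pi_ratio`, and logical
#'   `sel_fst` / `sel_ratio`; the two logical columns default to `TRUE` if
#'   absent), sorted by (chrom, start).
#' @param max_gap maximum gap bridged, bp (default 0).
#' @return data frame: `chrom`, `start`, `end`, `criteria` (comma-joined
#'   subset of `FST`, `PI_RATIO`), `peak_fst`, `peak_abs_log2_ratio`,
#'   `n_windows`.
#' @export
call_candidate_regions <- function(selected, max_gap = 0L) {
  if (nrow(selected) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      criteria = character(), peak_fst = numeric(),
                      peak_abs_log2_ratio = numeric(), n_windows = integer()))
  if (is.null(selected$sel_fst)) selected$sel_fst <- TRUE
  if (is.null(selected$sel_ratio)) selected$sel_ratio <- TRUE
  gr <- GenomicRanges::GRanges(selected$chrom,
                               IRanges::IRanges(selected$start + 1L, selected$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  ov <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  agg <- function(f, x) vapply(split(x, grp), f, numeric(1))
  crit <- vapply(split(seq_len(nrow(selected)), grp), function(i) {
    paste(c(if (any(selected$sel_fst[i])) "FST",
            if (any(selected$sel_ratio[i])) "PI_RATIO"), collapse = ",")
  }, character(1))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    criteria = crit,
    peak_fst = agg(function(x) suppressWarnings(max(x, na.rm = TRUE)),
                   selected$fst_win),
    peak_abs_log2_ratio = agg(function(x) suppressWarnings(max(x, na.rm = TRUE)),
                              abs(selected$log2_pi_ratio)),
    n_windows = as.integer(table(grp)))
  out$peak_fst[is.infinite(out$peak_fst)] <- NA_real_
  out$peak_abs_log2_ratio[is.infinite(out$peak_abs_log2_ratio)] <- NA_real_
  ord <- order(out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign genes to candidate regions
#'
#' A gene is listed for a region iff its gene span overlaps the (0-based
#' half-open) region by at least 1 bp; a gene may appear in several regions.
#'
#' @param regions output of [call_candidate_regions()].
#' @param models named list of [gene_model()] objects.
#' @return `regions` with an added `genes` column (comma-joined gene ids,
#'   `""` when none) and attribute `gene_hits`, a long-format data frame
#'   (`region_index`, `gene_id`).
#' @export
assign_genes <- function(regions, models) {
  if (nrow(regions) == 0 || length(models) == 0) {
    regions$genes <- character(nrow(regions))
    attr(regions, "gene_hits") <- data.frame(region_index = integer(),
                                             gene_id = character())
    return(regions)
  }
  g <- GenomicRanges::GRanges(
    vapply(models, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(models, function(m) m$gene_span[1], integer(1)),
                     vapply(models, function(m) m$gene_span[2], integer(1))))
  names(g) <- vapply(models, `[[`, character(1), "gene_id")
  r <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L, regions$end))
  ov <- GenomicRanges::findOverlaps(r, g)
  hits <- data.frame(region_index = S4Vectors::queryHits(ov),
                     gene_id = names(g)[S4Vectors::subjectHits(ov)])
  regions$genes <- vapply(seq_len(nrow(regions)), function(i)
    paste(sort(hits$gene_id[hits$region_index == i]), collapse = ","),
    character(1))
  attr(regions, "gene_hits") <- hits
  regions
}

#' Fine-map a candidate region
#'
#' Recomputes Fst, per-population pi, the log2 pi-ratio and Tajima's D on a
#' non-overlapping fine grid (default 10 kb windows, step = window) covering
#' the region padded by one fine window on each side, so edge signals stay
#' visible.
#'
#' @param region one-row slice of [call_candidate_regions()] output.
#' @param counts output of [genotype_counts()].
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param config a [scan_config()] (`fine_window_bp` is used).
#' @return a [window_stats()]-style data frame over the fine grid.
#' @export
fine_map <- function(region, counts, chrom_lengths, config = scan_config()) {
  fw <- config$fine_window_bp
  L <- chrom_lengths[[region$chrom]]
  lo <- max(0L, region$start - fw)
  hi <- min(L, region$end + fw)
  starts <- seq.int(lo, hi - 1L, by = fw)
  grid <- data.frame(chrom = region$chrom, start = as.integer(starts),
                     end = as.integer(pmin(starts + fw, hi)))
  grid$partial <- grid$end - grid$start < fw
  window_stats(counts[counts$chrom == region$chrom, , drop = FALSE],
               chrom_lengths, config, windows = grid)
}
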