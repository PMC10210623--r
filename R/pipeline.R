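log_msg <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
}

prepare_outdir <- function(out_dir, artifacts, force) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  existing <- file.path(out_dir, artifacts)
  existing <- existing[file.exists(existing)]
  if (length(existing) && !force)
    config_error("output file(s) already present (use force = TRUE): %s",
                 paste(basename(existing), collapse = ", "))
  invisible(out_dir)
}

chrom_lengths_of <- function(gd, genome = NULL) {
  if (!is.null(genome))
    return(setNames(Biostrings::width(genome), names(genome)))
  if (!is.null(gd$contig_lengths)) return(gd$contig_lengths)
  # fall back to the last observed position per chromosome
  tapply(gd$sites$pos, gd$sites$chrom, max)[unique(gd$sites$chrom)]
}

#' Run the coarse selective-sweep scan
#'
#' Reads the inputs (paths or pre-loaded objects), applies the site filter,
#' computes windowed statistics, selects outlier windows, merges them into
#' candidate regions and assigns genes.  Artifacts written to `out_dir`:
#' `windows.tsv` (all windows), `regions.tsv` (BED-compatible 0-based
#' half-open intervals with criteria, peaks and gene lists) and `scan.json`
#' (thresholds, per-criterion window counts, per-region gene lists, and the
#' per-criterion candidate gene lists).  Analysis is a pure function of its
#' inputs: reruns are byte-identical.
#'
#' @param vcf path to a VCF or a [genotype_data()] object.
#' @param popmap population map path or named vector (ignored when `vcf` is
#'   already a `genotype_data`).
#' @param gff gene models: GFF3 path or named list of [gene_model()]s.
#' @param genome optional FASTA path or `DNAStringSet` (chromosome lengths;
#'   otherwise VCF `##contig` headers are used).
#' @param out_dir output directory (created; `NULL` skips writing).
#' @param config a [scan_config()].
#' @param filter a [site_filter()].
#' @param force overwrite existing artifacts.
#' @param verbose log progress to stderr.
#' @return list: `windows`, `thresholds`, `selected`, `regions`,
#'   `genes_fst`, `genes_ratio`, `counts`, `chrom_lengths`.
#' @export
run_scan <- function(vcf, popmap = NULL, gff = NULL, genome = NULL,
                     out_dir = NULL, config = scan_config(),
                     filter = site_filter(), force = FALSE, verbose = TRUE) {
  for (p in c(if (is.character(vcf)) vcf, if (is.character(gff)) gff,
              if (is.character(genome)) genome,
              if (is.character(popmap) && length(popmap) == 1) popmap))
    if (!file.exists(p)) config_error("input not found: %s", p)
  if (is.character(genome)) genome <- read_fasta(genome)
  gd <- if (is.character(vcf)) read_vcf(vcf, popmap) else vcf
  models <- if (is.character(gff)) read_gff3(gff, genome) else gff
  log_msg(verbose, "loaded %d sites, %d samples", nrow(gd$sites), ncol(gd$a1))
  gd <- filter_sites(gd, filter)
  log_msg(verbose, "%d sites after filtering", nrow(gd$sites))
  counts <- genotype_counts(gd)
  cl <- chrom_lengths_of(gd, genome)
  ws <- window_stats(counts, cl, config)
  sel <- select_outlier_windows(ws, config)
  regions <- call_candidate_regions(sel$windows, max_gap = config$max_gap)
  if (!is.null(models)) regions <- assign_genes(regions, models)
  else regions$genes <- ""
  gene_list <- function(which_crit) {
    keep <- vapply(seq_len(nrow(sel$windows)), function(i)
      sel$windows[[which_crit]][i], logical(1))
    r <- call_candidate_regions(sel$windows[keep, , drop = FALSE],
                                max_gap = config$max_gap)
    if (is.null(models) || nrow(r) == 0) return(character(0))
    r <- assign_genes(r, models)
    sort(unique(attr(r, "gene_hits")$gene_id))
  }
  genes_fst <- gene_list("sel_fst")
  genes_ratio <- gene_list("sel_ratio")
  log_msg(verbose,
          "selected %d windows (Fst threshold %.3f, |log2 ratio| threshold %.3f); %d regions; %d / %d candidate genes by Fst / pi-ratio",
          nrow(sel$windows), sel$thresholds$fst_threshold,
          sel$thresholds$log2_ratio_threshold, nrow(regions),
          length(genes_fst), length(genes_ratio))
  res <- list(windows = ws, thresholds = sel$thresholds,
              selected = sel$windows, regions = regions,
              genes_fst = genes_fst, genes_ratio = genes_ratio,
              counts = counts, chrom_lengths = cl)
  if (!is.null(out_dir)) {
    arts <- c("windows.tsv", "regions.tsv", "scan.json")
    prepare_outdir(out_dir, arts, force)
    write_tsv(ws, file.path(out_dir, "windows.tsv"))
    write_tsv(regions, file.path(out_dir, "regions.tsv"))
    jsonlite::write_json(
      list(thresholds = sel$thresholds,
           regions = cbind(regions[, c("chrom", "start", "end", "criteria",
                                       "genes")]),
           candidate_genes_fst = genes_fst,
           candidate_genes_pi_ratio = genes_ratio),
      file.path(out_dir, "scan.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  res
}

#' Run the full pipeline: scan, fine-map, triage, effects, convergence
#'
#' Composes [run_scan()], [fine_map()] per candidate region,
#' [triage_snvs()] under the given presets, [annotate_variants()] on the
#' triaged set, and — when an ortholog alignment and role map are supplied —
#' [detect_convergent_sites()] / [report_convergence()].  Writes a single
#' `report.json` plus the scan artifacts and `triage_<preset>.tsv` tables;
#' every number in the report is traceable to one of those artifacts.
#'
#' @inheritParams run_scan
#' @param fasta genome FASTA path or `DNAStringSet` (required for coding
#'   effects).
#' @param triage_presets named list of [triage_config()]s.
#' @param aln optional ortholog protein alignment (path or `AAStringSet`).
#' @param roles optional role map (path or named vector).
#' @return list: `scan`, `fine` (list of fine-map tables), `triage` (named
#'   list of triage tables with effect columns), `convergence` (report list
#'   or `NULL`), `report` (the JSON-ready summary).
#' @export
run_all <- function(vcf, popmap = NULL, gff = NULL, fasta = NULL,
                    out_dir = NULL, config = scan_config(),
                    filter = site_filter(),
                    triage_presets = list(ca15 = triage_config(preset = "ca15")),
                    aln = NULL, roles = NULL, force = FALSE, verbose = TRUE) {
  genome <- if (is.character(fasta)) read_fasta(fasta) else fasta
  scan <- run_scan(vcf, popmap, gff, genome = genome, out_dir = out_dir,
                   config = config, filter = filter, force = force,
                   verbose = verbose)
  models <- if (is.character(gff)) read_gff3(gff, genome) else gff
  fine <- lapply(seq_len(nrow(scan$regions)), function(i)
    fine_map(scan$regions[i, ], scan$counts, scan$chrom_lengths, config))
  stats <- site_stats(scan$counts)
  triage <- list()
  for (nm in names(triage_presets)) {
    tr <- triage_snvs(stats, triage_presets[[nm]], models)
    if (!is.null(genome) && !is.null(models) && nrow(tr)) {
      eff <- annotate_variants(tr, models, genome)
      tr <- merge(tr, eff[, setdiff(colnames(eff), c("ref", "alt"))],
                  by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
      tr <- tr[order(match(tr$chrom, names(scan$chrom_lengths)), tr$pos), ]
      rownames(tr) <- NULL
      tr$klass[is.na(tr$klass)] <- "noncoding"
    }
    triage[[nm]] <- tr
  }
  convergence <- NULL
  if (!is.null(aln) && !is.null(roles)) {
    if (is.character(aln)) aln <- Biostrings::readAAStringSet(aln)
    if (is.character(roles) && length(roles) == 1) roles <- read_role_map(roles)
    sites <- detect_convergent_sites(aln, roles)
    convergence <- report_convergence(sites)
    log_msg(verbose, "convergence: %d differentiating, %d convergent column(s)",
            convergence$n_differentiating, convergence$n_convergent)
  }
  report <- list(
    thresholds = scan$thresholds,
    n_regions = nrow(scan$regions),
    n_candidate_genes_fst = length(scan$genes_fst),
    n_candidate_genes_pi_ratio = length(scan$genes_ratio),
    triage = lapply(triage, function(tr)
      list(n = nrow(tr),
           by_klass = if (!is.null(tr$klass) && nrow(tr))
             as.list(table(tr$klass)) else list())),
    convergence = if (!is.null(convergence))
      convergence[c("n_differentiating", "n_convergent", "substitutions")]
      else NULL)
  if (!is.null(out_dir)) {
    for (nm in names(triage))
      write_tsv(triage[[nm]], file.path(out_dir, sprintf("triage_%s.tsv", nm)))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(scan = scan, fine = fine, triage = triage, convergence = convergence,
       report = report)
}
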