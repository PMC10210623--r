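#' Read a two-column population map
#'
#' Plain TSV with columns `sample` and `population` (no header required; a
#' header line is detected and dropped).  Population labels must include both
#' `ALK` and `FW` and both must be non-empty.
#'
#' @param path path to the TSV.
#' @return named character vector: `sample -> population`.
#' @export
read_population_map <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("sample", "population"))
  if (nrow(tab) && tab$sample[1] == "sample") tab <- tab[-1, , drop = FALSE]
  pm <- setNames(tab$population, tab$sample)
  validate_population_map(pm)
  pm
}

validate_population_map <- function(pm, samples = NULL) {
  if (!all(c("ALK", "FW") %in% pm))
    config_error("population map must assign both ALK and FW populations")
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(pm))
    if (length(missing))
      config_error("sample(s) not in population map: %s",
                   paste(missing, collapse = ", "))
  }
  invisible(pm)
}

#' Genotype data for two labelled populations
#'
#' Container produced by [read_vcf()] and [simulate_fixture()]: a site table
#' plus two integer allele matrices (`a1`, `a2`, sites x samples; 0 = ref,
#' 1 = alt, `NA` = missing).  A diploid genotype with either allele missing is
#' treated as fully missing downstream, so called-allele counts stay even.
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `is_snp`.
#' @param a1,a2 integer matrices, one row per site, one column per sample.
#' @param popmap named character vector `sample -> {ALK, FW}` covering every
#'   column of `a1`.
#' @param contig_lengths optional named integer vector of chromosome lengths.
#' @return object of class `genotype_data`.
#' @export
genotype_data <- function(sites, a1, a2, popmap, contig_lengths = NULL) {
  stopifnot(nrow(sites) == nrow(a1), all(dim(a1) == dim(a2)),
            !is.null(colnames(a1)))
  validate_population_map(popmap, colnames(a1))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) { a1[half] <- NA_integer_; a2[half] <- NA_integer_ }
  rownames(sites) <- NULL
  structure(list(sites = sites, a1 = a1, a2 = a2,
                 popmap = popmap[colnames(a1)],
                 contig_lengths = contig_lengths),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("<genotype_data> %d sites x %d samples (ALK %d, FW %d), %d chromosome(s)\n",
              nrow(x$sites), ncol(x$a1), sum(x$popmap == "ALK"),
              sum(x$popmap == "FW"), length(unique(x$sites$chrom))))
  invisible(x)
}

parse_gt_matrix <- function(gt, sites_label) {
  # gt: character matrix of GT strings; returns list(a1, a2) of allele indices
  spl <- strsplit(gt, "[/|]")
  n <- lengths(spl)
  bad <- which(!(n %in% c(1L, 2L)))
  if (length(bad))
    config_error("malformed GT at %s", sites_label[(bad[1] - 1) %% nrow(gt) + 1])
  one <- function(k) vapply(spl, function(x) {
    v <- if (length(x) >= k) x[k] else "."
    if (v %in% c(".", "")) NA_integer_ else suppressWarnings(as.integer(v))
  }, integer(1))
  a1 <- matrix(one(1), nrow = nrow(gt), dimnames = dimnames(gt))
  a2 <- matrix(one(2), nrow = nrow(gt), dimnames = dimnames(gt))
  a2[is.na(a2) & !is.na(a1) & lengths(spl) == 1L] <- NA_integer_  # haploid-style call -> missing partner
  list(a1 = a1, a2 = a2)
}

#' Read a multi-sample VCF into a [genotype_data()] object
#'
#' Requires GT fields.  Sites are returned in (chrom, pos) order; within-
#' chromosome order is never changed (an unsorted file is an error).
#' Multi-allelic records are, by default, reduced to their two most frequent
#' alleles (ranked by called-allele count, ties broken toward the lower allele
#' index; genotypes carrying a dropped allele become missing); set
#' `multiallelic = "skip"` to drop such records instead.
#'
#' @param path path to a VCF (v4.x, plain text or bgzipped).
#' @param popmap named character vector or path to a population-map TSV.
#' @param multiallelic `"recode"` (default) or `"skip"`.
#' @return a `genotype_data` object.
#' @export
read_vcf <- function(path, popmap, multiallelic = c("recode", "skip")) {
  multiallelic <- match.arg(multiallelic)
  if (is.character(popmap) && length(popmap) == 1 && file.exists(popmap))
    popmap <- read_population_map(popmap)
  v <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(v)$GT
  if (is.null(gt)) config_error("VCF record without GT field")
  samples <- colnames(gt)
  validate_population_map(popmap, samples)
  rr <- SummarizedExperiment::rowRanges(v)
  altl <- VariantAnnotation::alt(v)
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = vapply(as.list(altl), function(x)
      paste(as.character(x), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  dimnames(gt) <- list(NULL, samples)
  lab <- sprintf("%s:%d", sites$chrom, sites$pos)
  al <- parse_gt_matrix(gt, lab)
  a1 <- al$a1; a2 <- al$a2

  multi <- grepl(",", sites$alt)
  if (any(multi)) {
    if (multiallelic == "skip") {
      keep <- !multi
      sites <- sites[keep, , drop = FALSE]
      a1 <- a1[keep, , drop = FALSE]; a2 <- a2[keep, , drop = FALSE]
    } else {
      for (i in which(multi)) {
        alleles <- c(sites$ref[i], strsplit(sites$alt[i], ",")[[1]])
        cnt <- tabulate(c(a1[i, ], a2[i, ]) + 1L, nbins = length(alleles))
        top <- order(-cnt, seq_along(alleles))[1:2] - 1L   # 0-based indices
        top <- sort(top)                                   # lower index -> ref slot
        new1 <- ifelse(a1[i, ] == top[1], 0L, ifelse(a1[i, ] == top[2], 1L, NA_integer_))
        new2 <- ifelse(a2[i, ] == top[1], 0L, ifelse(a2[i, ] == top[2], 1L, NA_integer_))
        a1[i, ] <- new1; a2[i, ] <- new2
        sites$ref[i] <- alleles[top[1] + 1L]
        sites$alt[i] <- alleles[top[2] + 1L]
      }
    }
  }
  if (any(a1 > 1, na.rm = TRUE) || any(a2 > 1, na.rm = TRUE))
    config_error("allele index > 1 at a biallelic record")
  sites$is_snp <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L
  # enforce (chrom, pos) order without reordering within chromosomes
  ord_within <- unlist(tapply(sites$pos, factor(sites$chrom, unique(sites$chrom)),
                              function(p) all(diff(p) >= 0)), use.names = FALSE)
  if (!all(ord_within))
    config_error("VCF not position-sorted within a chromosome")
  # contig lengths from the header when present
  sl <- GenomeInfoDb::seqlengths(v)
  cl <- if (length(sl) && !anyNA(sl)) setNames(as.integer(sl), names(sl)) else NULL
  genotype_data(sites, a1, a2, popmap, contig_lengths = cl)
}

#' Write a [genotype_data()] object as a plain-text VCF
#'
#' Minimal VCF v4.2 with GT-only genotype columns and `##contig` header lines;
#' round-trips through [read_vcf()].  Used by the synthetic-data generator.
#'
#' @param gd a `genotype_data` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gd, path) {
  s <- gd$sites
  samples <- colnames(gd$a1)
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(gd$contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(gd$contig_lengths), gd$contig_lengths))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples), collapse = "\t"))
  fmt_allele <- function(a) ifelse(is.na(a), ".", as.character(a))
  gt <- matrix(paste0(fmt_allele(gd$a1), "/", fmt_allele(gd$a2)),
               nrow = nrow(s))
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Site-quality filter configuration
#'
#' The study's upstream pipeline filtered low-quality sites without reporting
#' the exact thresholds, so filtering here is a configurable stage with
#' documented defaults and every rule individually switchable (`NULL`/`FALSE`
#' disables a rule).
#'
#' @param snps_only keep SNPs only (default `FALSE`; INDELs participate in
#'   triage downstream).
#' @param max_missing maximum fraction of uncalled individuals per site
#'   (default 0.2; `NULL` disables).
#' @param min_mac minimum minor-allele count across both populations
#'   (default 1, i.e. drop sites monomorphic in the sample; `NULL` disables).
#' @return object of class `site_filter`.
#' @export
site_filter <- function(snps_only = FALSE, max_missing = 0.2, min_mac = 1L) {
  structure(list(snps_only = snps_only, max_missing = max_missing,
                 min_mac = min_mac), class = "site_filter")
}

#' Apply a [site_filter()] to genotype data
#'
#' @param gd a `genotype_data` object.
#' @param filter a `site_filter`.
#' @return filtered `genotype_data`.
#' @export
filter_sites <- function(gd, filter = site_filter()) {
  keep <- rep(TRUE, nrow(gd$sites))
  if (isTRUE(filter$snps_only)) keep <- keep & gd$sites$is_snp
  called <- !is.na(gd$a1)
  if (!is.null(filter$max_missing))
    keep <- keep & (1 - rowMeans(called)) <= filter$max_missing
  if (!is.null(filter$min_mac)) {
    ac <- rowSums(gd$a1 == 1L, na.rm = TRUE) + rowSums(gd$a2 == 1L, na.rm = TRUE)
    an <- 2L * rowSums(called)
    mac <- pmin(ac, an - ac)
    keep <- keep & mac >= filter$min_mac
  }
  genotype_data(gd$sites[keep, , drop = FALSE],
                gd$a1[keep, , drop = FALSE], gd$a2[keep, , drop = FALSE],
                gd$popmap, gd$contig_lengths)
}

#' Per-site allele and heterozygote counts by population
#'
#' The substrate of all estimators: per site and population, the alt-allele
#' count (`ac`), the number of called chromosomes (`an`), the number of called
#' diploid individuals (`nind`) and the observed heterozygote count (`het`).
#'
#' @param gd a `genotype_data` object.
#' @return data frame with one row per site: `chrom`, `pos`, `ref`, `alt`,
#'   `is_snp`, then `ac_alk`, `an_alk`, `nind_alk`, `het_alk` and the
#'   corresponding `_fw` columns.
#' @export
genotype_counts <- function(gd) {
  out <- gd$sites
  for (popl in c("ALK", "FW")) {
    cols <- which(gd$popmap == popl)
    a1 <- gd$a1[, cols, drop = FALSE]; a2 <- gd$a2[, cols, drop = FALSE]
    called <- !is.na(a1)
    nind <- rowSums(called)
    ac <- rowSums(a1 == 1L, na.rm = TRUE) + rowSums(a2 == 1L, na.rm = TRUE)
    het <- rowSums(a1 != a2, na.rm = TRUE)
    suf <- tolower(popl)
    out[[paste0("ac_", suf)]] <- as.integer(ac)
    out[[paste0("an_", suf)]] <- as.integer(2L * nind)
    out[[paste0("nind_", suf)]] <- as.integer(nind)
    out[[paste0("het_", suf)]] <- as.integer(het)
  }
  out
}
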