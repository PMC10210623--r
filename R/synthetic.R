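#' Synthetic-fixture configuration
#'
#' Defaults define the standard study conditions every test runs under: two
#' 500 kb chromosomes, one SNP per 200 bp, 30 diploids per population,
#' background divergence F = 0.05 with two planted 40 kb sweep intervals per
#' chromosome at F = 0.6 where the alkaline population's residual diversity is
#' scaled by 0.1, 2% missing genotypes, 20 genes including designated
#' "ca15-like" and "rhcg-like" genes carrying planted coding variants, and a
#' toy ortholog alignment with 7 differentiating / 2 convergent columns.
#'
#' `scan_top_fraction` is the outlier fraction appropriate to this fixture's
#' sweep prevalence (12 of 100 coarse windows lie fully inside planted
#' sweeps); whole-genome scans of real data keep the 1% default of
#' [scan_config()].
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len_bp chromosome length, bp.
#' @param snp_density expected background variants per bp.
#' @param n_alk,n_fw diploid sample sizes.
#' @param background_F,sweep_F Balding-Nichols divergence parameters outside
#'   and inside sweep intervals.
#' @param sweeps_per_chrom,sweep_len_bp planted sweep count and length.
#' @param alk_diversity_factor multiplier shrinking the ALK frequency's
#'   distance from fixation inside sweeps (0 = full fixation).
#' @param missing_rate per-genotype missingness probability.
#' @param n_genes total gene count (split evenly across chromosomes).
#' @param n_nonsyn,n_syn planted nonsynonymous/synonymous triage-passing SNVs
#'   in the ca15-like gene.
#' @param rhcg_nonsyn planted nonsynonymous triage-passing SNVs in the
#'   rhcg-like gene.
#' @param n_noncoding_pass planted triage-passing SNVs outside genes.
#' @param n_indel_pass planted triage-passing 2-bp deletions in the ca15-like
#'   CDS (frameshift class).
#' @param n_negative_controls planted CDS SNVs at p = 0.5 in both populations
#'   (must fail triage).
#' @param aln_protein_len,aln_n_alk_species,aln_n_fw_refs,aln_n_diff,aln_n_conv
#'   ortholog-alignment fixture shape: protein length, numbers of
#'   alkaline-adapted and freshwater reference lineages, planted
#'   differentiating and convergent column counts (`aln_n_conv <=
#'   aln_n_diff`).
#' @param scan_top_fraction outlier fraction used when scanning this fixture.
#' @param seed master seed (mandatory); all stages draw from sub-seeds derived
#'   from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2L, chrom_len_bp = 500000L,
                       snp_density = 1 / 200, n_alk = 30L, n_fw = 30L,
                       background_F = 0.05, sweep_F = 0.6,
                       sweeps_per_chrom = 2L, sweep_len_bp = 40000L,
                       alk_diversity_factor = 0.1, missing_rate = 0.02,
                       n_genes = 20L, n_nonsyn = 5L, n_syn = 1L,
                       rhcg_nonsyn = 5L, n_noncoding_pass = 4L,
                       n_indel_pass = 2L, n_negative_controls = 2L,
                       aln_protein_len = 150L, aln_n_alk_species = 3L,
                       aln_n_fw_refs = 2L, aln_n_diff = 7L, aln_n_conv = 2L,
                       scan_top_fraction = 0.12, seed) {
  if (missing(seed)) config_error("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  rates <- c(snp_density, background_F, sweep_F, alk_diversity_factor,
             missing_rate, scan_top_fraction)
  stopifnot(all(rates >= 0), all(rates <= 1), n_alk >= 2, n_fw >= 2,
            sweeps_per_chrom * (sweep_len_bp + 20000) < chrom_len_bp)
  if (aln_n_conv > aln_n_diff)
    config_error("aln_n_conv must not exceed aln_n_diff")
  structure(cfg, class = "sim_config")
}

# planted sweep intervals (0-based half-open), snapped to the 10 kb grid
sweep_intervals <- function(config) {
  L <- config$chrom_len_bp
  if (config$sweeps_per_chrom == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  anchors <- seq(0.2, 0.8, length.out = config$sweeps_per_chrom)
  starts <- round(anchors * L / 10000) * 10000
  do.call(rbind, lapply(seq_len(config$n_chrom), function(ci)
    data.frame(chrom = sprintf("chr%d", ci), start = as.integer(starts),
               end = as.integer(starts + config$sweep_len_bp))))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                c("A","C","G","T")), 1, paste, collapse = "")
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

# construct one gene: write its exon sequences into `chrseq` (a character
# scalar) and return list(model, chrseq, codons)
build_gene <- function(gene_id, chrom, chrseq, start, strand, n_codons,
                       n_exons, force_codons = list()) {
  codons <- c("ATG", sample(SENSE_CODONS, n_codons - 2, replace = TRUE), "TAA")
  for (i in seq_along(force_codons))
    codons[as.integer(names(force_codons)[i])] <- force_codons[[i]]
  cds <- paste(codons, collapse = "")
  len <- nchar(cds)
  cuts <- if (n_exons > 1) sort(sample(seq(40L, len - 40L, by = 7L), n_exons - 1)) else integer(0)
  lens <- diff(c(0L, cuts, len))               # exon lengths, transcription order
  introns <- sample(150:300, n_exons - 1, replace = TRUE)
  exon_seqs <- substring(cds, c(1L, cuts + 1L), c(cuts, len))
  phases <- (3L - c(0L, cumsum(lens))[seq_len(n_exons)] %% 3L) %% 3L
  if (strand == "+") {
    part_starts <- start + c(0L, cumsum(lens[-n_exons] + introns))
    tab <- data.frame(start = part_starts, end = part_starts + lens - 1L,
                      phase = phases)
    for (i in seq_len(n_exons))
      substr(chrseq, tab$start[i], tab$end[i]) <- exon_seqs[i]
  } else {
    # transcription order = descending coordinates: last exon sits lowest
    glens <- rev(lens); gintrons <- rev(introns)
    g_starts <- start + c(0L, cumsum(glens[-n_exons] + gintrons))
    tab <- data.frame(start = rev(g_starts), end = rev(g_starts + glens - 1L),
                      phase = phases)      # rows already in transcription order
    for (i in seq_len(n_exons)) {
      rc <- revcomp_chr(exon_seqs[i])
      substr(chrseq, tab$start[i], tab$start[i] + nchar(rc) - 1L) <- rc
    }
  }
  span <- c(min(tab$start) - 50L, max(tab$end) + 50L)
  model <- gene_model(gene_id, paste0(gene_id, ".t1"), chrom, strand, tab,
                      gene_span = span)
  list(model = model, chrseq = chrseq, codons = codons)
}

# single-base substitution of the requested class at a gene codon; returns the
# variant in genomic coordinates or NULL if the codon admits none
codon_substitution <- function(model, codons, codon_index, klass) {
  codon <- codons[codon_index]
  bases <- c("A", "C", "G", "T")
  cands <- list()
  for (cpos in 1:3) for (b in setdiff(bases, substr(codon, cpos, cpos))) {
    alt_codon <- codon
    substr(alt_codon, cpos, cpos) <- b
    ref_aa <- Biostrings::GENETIC_CODE[[codon]]
    alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
    ok <- switch(klass,
                 nonsynonymous = ref_aa != alt_aa && alt_aa != "*" && ref_aa != "*",
                 synonymous = ref_aa == alt_aa)
    if (ok) cands[[length(cands) + 1L]] <- list(cpos = cpos, alt = b)
  }
  if (!length(cands)) return(NULL)
  pickI <- cands[[sample.int(length(cands), 1)]]
  off <- (codon_index - 1L) * 3L + pickI$cpos          # 1-based CDS offset
  gpos <- cds_genomic_positions(model)[off]
  minus <- model$strand == "-"
  ref_c <- substr(codons[codon_index], pickI$cpos, pickI$cpos)
  data.frame(chrom = model$chrom, pos = gpos,
             ref = if (minus) COMPLEMENT[[ref_c]] else ref_c,
             alt = if (minus) COMPLEMENT[[pickI$alt]] else pickI$alt,
             gene = model$gene_id, klass = klass, codon_index = codon_index,
             stringsAsFactors = FALSE)
}

#' Plant coding variants with known effect classes
#'
#' Chooses CDS positions in the designated genes whose alternate allele
#' yields the requested effect class (verified against the genetic code at
#' planting time): `n_nonsyn` nonsynonymous (one of them the canonical
#' GAA->GAC Glu->Asp change) and `n_syn` synonymous SNVs plus `n_indel_pass`
#' 2-bp frameshift deletions in the ca15-like gene, `rhcg_nonsyn`
#' nonsynonymous SNVs in the rhcg-like gene — all at ALK alt frequency 1 and
#' FW 0, so they pass the `Fst > 0.9 & MAF_ALK < 0.1` triage by construction
#' — plus `n_negative_controls` CDS SNVs at p = 0.5 in both populations
#' (triage failures) and `n_noncoding_pass` intergenic ALK-fixed SNVs.
#'
#' @param models named list of [gene_model()]s containing `ca15like` and
#'   `rhcglike`.
#' @param genome named `DNAStringSet` (or character vector) of chromosomes.
#' @param gene_codons named list of codon vectors for the designated genes
#'   (as returned by the generator's gene builder).
#' @param config a [sim_config()].
#' @return data frame of planted variants: `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `klass`, `codon_index`, `p_alk`, `p_fw`, `pass_a`, `role`.
#' @export
plant_coding_variants <- function(models, genome, gene_codons, config) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  plant_in_gene <- function(gene_id, n_nonsyn, n_syn, forced_gaa_codon = NULL) {
    m <- models[[gene_id]]
    codons <- gene_codons[[gene_id]]
    avail <- setdiff(2:(length(codons) - 1), unlist(forced_gaa_codon))
    rows <- list()
    if (!is.null(forced_gaa_codon)) {
      # the canonical GAA -> GAC (E -> D) change at the forced codon
      ci <- forced_gaa_codon
      off <- (ci - 1L) * 3L + 3L
      gpos <- cds_genomic_positions(m)[off]
      minus <- m$strand == "-"
      rows[[1]] <- data.frame(chrom = m$chrom, pos = gpos,
                              ref = if (minus) COMPLEMENT[["A"]] else "A",
                              alt = if (minus) COMPLEMENT[["C"]] else "C",
                              gene = gene_id, klass = "nonsynonymous",
                              codon_index = ci, stringsAsFactors = FALSE)
      n_nonsyn <- n_nonsyn - 1L
    }
    want <- c(rep("nonsynonymous", n_nonsyn), rep("synonymous", n_syn))
    for (k in want) {
      repeat {
        ci <- sample(avail, 1)
        v <- codon_substitution(m, codons, ci, k)
        if (!is.null(v)) { avail <- setdiff(avail, ci); break }
        avail <- setdiff(avail, ci)   # impossible class at this codon: resample
      }
      rows[[length(rows) + 1L]] <- v
    }
    do.call(rbind, rows)
  }
  ca <- plant_in_gene("ca15like", config$n_nonsyn, config$n_syn,
                      forced_gaa_codon = 10L)
  rh <- plant_in_gene("rhcglike", config$rhcg_nonsyn, 0L)
  used_codons <- list(ca15like = ca$codon_index, rhcglike = rh$codon_index)
  pass <- rbind(ca, rh)
  pass$p_alk <- 1; pass$p_fw <- 0; pass$pass_a <- TRUE
  pass$role <- ifelse(pass$klass == "synonymous", "syn_pass", "coding_pass")

  # frameshift deletions inside the ca15-like CDS, clear of planted codons
  m <- models[["ca15like"]]
  codons <- gene_codons[["ca15like"]]
  indels <- list()
  avail <- setdiff(2:(length(codons) - 2), c(used_codons$ca15like,
                                             used_codons$ca15like + 1L,
                                             10L, 11L))
  for (k in seq_len(config$n_indel_pass)) {
    repeat {
      ci <- sample(avail, 1)
      off <- (ci - 1L) * 3L + 1L
      gp <- cds_genomic_positions(m)[c(off, off + 1L, off + 2L)]
      # need 3 consecutive genomic bases inside one CDS part
      if (abs(gp[3] - gp[1]) == 2L) { avail <- setdiff(avail, c(ci, ci + 1L)); break }
      avail <- setdiff(avail, ci)
    }
    p0 <- min(gp)
    chrseq <- genome[[m$chrom]]
    ref3 <- as.character(Biostrings::subseq(chrseq, p0, p0 + 2L))
    indels[[k]] <- data.frame(chrom = m$chrom, pos = p0, ref = ref3,
                              alt = substr(ref3, 1, 1), gene = "ca15like",
                              klass = "frameshift", codon_index = ci,
                              p_alk = 1, p_fw = 0, pass_a = TRUE,
                              role = "indel_pass", stringsAsFactors = FALSE)
  }

  # negative controls: CDS nonsynonymous SNVs, intermediate in both populations
  negs <- list()
  avail <- setdiff(12:(length(codons) - 1), c(used_codons$ca15like,
                                              vapply(indels, `[[`, integer(1), "codon_index"),
                                              vapply(indels, `[[`, integer(1), "codon_index") + 1L))
  for (k in seq_len(config$n_negative_controls)) {
    repeat {
      ci <- sample(avail, 1)
      v <- codon_substitution(m, codons, ci, "nonsynonymous")
      if (!is.null(v)) { avail <- setdiff(avail, ci); break }
      avail <- setdiff(avail, ci)
    }
    v$p_alk <- 0.5; v$p_fw <- 0.5; v$pass_a <- FALSE; v$role <- "negative_control"
    negs[[k]] <- v
  }

  # intergenic ALK-fixed SNVs
  spans <- do.call(rbind, lapply(models, function(mm)
    data.frame(chrom = mm$chrom, s = mm$gene_span[1], e = mm$gene_span[2])))
  noncod <- list()
  ch1 <- names(genome)[1]
  while (length(noncod) < config$n_noncoding_pass) {
    p <- sample.int(Biostrings::width(genome)[1] - 1L, 1)
    insp <- spans$chrom == ch1 & p >= spans$s & p <= spans$e
    if (any(insp)) next
    refb <- as.character(Biostrings::subseq(genome[[ch1]], p, p))
    if (refb == "N") next
    noncod[[length(noncod) + 1L]] <- data.frame(
      chrom = ch1, pos = p, ref = refb,
      alt = sample(setdiff(c("A", "C", "G", "T"), refb), 1),
      gene = "", klass = "noncoding", codon_index = NA_integer_,
      p_alk = 1, p_fw = 0, pass_a = TRUE, role = "noncoding_pass",
      stringsAsFactors = FALSE)
  }
  out <- rbind(pass, do.call(rbind, indels), do.call(rbind, negs),
               do.call(rbind, noncod))
  rownames(out) <- NULL
  out
}

#' Balding-Nichols per-site population frequencies
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); each population's frequency
#' is Beta(p (1 - F) / F, (1 - p)(1 - F) / F) — mean p, variance
#' F p (1 - p).  FW always uses `background_F`.  Sites flagged `in_sweep` use
#' `sweep_F` for ALK and additionally shrink the ALK frequency's distance
#' from the nearer fixation point by `alk_diversity_factor`.  Frequencies are
#' clipped to [0.001, 0.999] so realized data keep a trickle of monomorphic
#' sites without flooding.
#'
#' @param config a [sim_config()].
#' @param in_sweep logical vector, one element per site.
#' @return data frame with `p_anc`, `p_alk`, `p_fw`.
#' @export
simulate_site_frequencies <- function(config, in_sweep) {
  n <- length(in_sweep)
  p_anc <- runif(n, 0.05, 0.95)
  draw <- function(p, F) {
    if (F <= 0) return(p)
    rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  p_alk <- draw(p_anc, config$background_F)
  if (any(in_sweep)) {
    ps <- draw(p_anc[in_sweep], config$sweep_F)
    fac <- config$alk_diversity_factor
    p_alk[in_sweep] <- ifelse(ps >= 0.5, 1 - (1 - ps) * fac, ps * fac)
  }
  p_fw <- draw(p_anc, config$background_F)
  clip <- function(p) pmin(pmax(p, 0.001), 0.999)
  data.frame(p_anc = p_anc, p_alk = clip(p_alk), p_fw = clip(p_fw))
}

#' Sample diploid genotypes from population frequencies
#'
#' Independent Binomial(2, p) alt-allele dosages per sample, with per-genotype
#' missingness.
#'
#' @param p_alk,p_fw per-site alt-allele frequencies.
#' @param config a [sim_config()] (`n_alk`, `n_fw`, `missing_rate`).
#' @return list of integer matrices `a1`, `a2` (sites x samples, ALK columns
#'   first) with column names `ALK01...`/`FW01...`.
#' @export
simulate_genotypes <- function(p_alk, p_fw, config) {
  n <- length(p_alk)
  samples <- c(sprintf("ALK%02d", seq_len(config$n_alk)),
               sprintf("FW%02d", seq_len(config$n_fw)))
  p <- cbind(matrix(rep(p_alk, config$n_alk), nrow = n),
             matrix(rep(p_fw, config$n_fw), nrow = n))
  dose <- matrix(rbinom(length(p), 2L, as.vector(p)), nrow = n,
                 dimnames = list(NULL, samples))
  a1 <- (dose == 2L) * 1L + (dose == 1L) * 0L
  a2 <- (dose >= 1L) * 1L
  a1[dose == 1L] <- 0L
  miss <- matrix(runif(length(dose)) < config$missing_rate, nrow = n)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  dimnames(a1) <- dimnames(a2) <- list(NULL, samples)
  list(a1 = a1, a2 = a2, samples = samples)
}

#' Neutral constant-size site-frequency-spectrum sampler
#'
#' Derived-allele counts drawn with probability proportional to 1/i
#' (i = 1..n-1), the expected spectrum of a constant-size neutral population —
#' under which pairwise diversity and Watterson's theta have equal
#' expectation, making it the calibration null for Tajima's D.
#'
#' @param n_chromosomes sample size.
#' @param n_sites number of segregating sites to draw.
#' @return integer vector of derived-allele counts.
#' @export
simulate_neutral_sfs <- function(n_chromosomes, n_sites) {
  i <- seq_len(n_chromosomes - 1)
  sample(i, n_sites, replace = TRUE, prob = 1 / i)
}

#' Planted ortholog protein alignment with role map and truth
#'
#' Builds a reference protein, a focal-FW sequence equal to it, a focal-ALK
#' sequence differing at `aln_n_diff` planted columns, and related
#' alkaline-adapted / freshwater-reference lineages.  Of the planted columns,
#' `aln_n_conv` satisfy the strict convergence rule (>= 1 alkaline-adapted
#' lineage shares the ALK residue; every freshwater reference keeps the FW
#' residue); the rest fail rule (i) (no alkaline support) except that, when
#' at least two non-convergent columns exist, one fails rule (ii) instead
#' (alkaline support present but a freshwater reference carries a third
#' residue).  Background substitutions (2% per non-focal lineage) and a few
#' gaps are sprinkled outside planted columns.
#'
#' @param config a [sim_config()].
#' @return list: `aln` (named `AAStringSet`), `roles` (named character
#'   vector), `truth` (data frame: `column`, `fw_aa`, `alk_aa`, `status`,
#'   `supporting_species`).
#' @export
build_ortholog_fixture <- function(config) {
  AAs <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
  P <- config$aln_protein_len
  ref <- sample(AAs, P, replace = TRUE)
  d <- config$aln_n_diff; cv <- config$aln_n_conv
  cols <- sort(sample(seq(5L, P - 5L), d))
  conv_cols <- sort(sample(cols, cv))
  noncv <- setdiff(cols, conv_cols)
  fw_focal <- ref
  alk_focal <- ref
  for (j in cols) alk_focal[j] <- sample(setdiff(AAs, ref[j]), 1)
  alk_names <- sprintf("alk_sp%d", seq_len(config$aln_n_alk_species))
  fw_names <- sprintf("fw_ref%d", seq_len(config$aln_n_fw_refs))
  mats <- lapply(c(alk_names, fw_names), function(nm) {
    s <- ref
    mut <- runif(P) < 0.02 & !(seq_len(P) %in% cols)
    s[mut] <- vapply(which(mut), function(j) sample(setdiff(AAs, s[j]), 1),
                     character(1))
    gapat <- sample(setdiff(seq_len(P), cols), 2)
    s[gapat] <- "-"
    s
  })
  names(mats) <- c(alk_names, fw_names)
  truth <- data.frame(column = cols, fw_aa = fw_focal[cols],
                      alk_aa = alk_focal[cols],
                      status = ifelse(cols %in% conv_cols, "convergent",
                                      "differentiating"),
                      supporting_species = "", stringsAsFactors = FALSE)
  for (j in conv_cols) {
    support <- sort(sample(alk_names, sample.int(length(alk_names), 1)))
    for (nm in alk_names)
      mats[[nm]][j] <- if (nm %in% support) alk_focal[j] else fw_focal[j]
    for (nm in fw_names) mats[[nm]][j] <- fw_focal[j]
    truth$supporting_species[truth$column == j] <- paste(support, collapse = ",")
  }
  break_fw <- if (length(noncv) >= 2) noncv[1] else NA_integer_
  for (j in noncv) {
    if (!is.na(break_fw) && j == break_fw) {
      # rule (ii) failure: alkaline support exists but one freshwater
      # reference carries a third residue
      mats[[alk_names[1]]][j] <- alk_focal[j]
      for (nm in alk_names[-1]) mats[[nm]][j] <- fw_focal[j]
      third <- sample(setdiff(AAs, c(alk_focal[j], fw_focal[j])), 1)
      mats[[fw_names[1]]][j] <- third
      for (nm in fw_names[-1]) mats[[nm]][j] <- fw_focal[j]
    } else {
      for (nm in alk_names) mats[[nm]][j] <- fw_focal[j]
      for (nm in fw_names) mats[[nm]][j] <- fw_focal[j]
    }
  }
  seqs <- c(list(focal_ALK = alk_focal, focal_FW = fw_focal), mats)
  aln <- Biostrings::AAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  roles <- c(focal_ALK = "FOCAL_ALK", focal_FW = "FOCAL_FW",
             setNames(rep("ALKALINE_ADAPTED", length(alk_names)), alk_names),
             setNames(rep("FRESHWATER_REF", length(fw_names)), fw_names))
  list(aln = aln, roles = roles, truth = truth)
}

#' Generate a complete truth-annotated fixture
#'
#' Runs every generator stage under sub-seeds derived from the master seed
#' (so the fixture is reproducible piecewise): genome and gene models, planted
#' sweep intervals, planted coding/intergenic variants, Balding-Nichols
#' background frequencies, diploid genotypes, and the ortholog alignment.
#' When `dir` is given, writes `genome.fa`, `genes.gff3`, `variants.vcf`,
#' `popmap.tsv`, `ortholog.aln.fa`, `roles.tsv` and `truth.json` there.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (created if needed).
#' @return list: `config`, `genome` (`DNAStringSet`), `models`, `gd`
#'   ([genotype_data()]), `sweeps` (data frame, 0-based half-open),
#'   `planted` (data frame), `ortholog` (list `aln`, `roles`, `truth`),
#'   `gene_codons`, and `dir` (or `NULL`).
#' @export
simulate_fixture <- function(config, dir = NULL) {
  seeds <- split_seed(config$seed, 5)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chrom))
  L <- config$chrom_len_bp
  sweeps <- sweep_intervals(config)

  ## 1. genome + genes ------------------------------------------------------
  set.seed(seeds[1])
  chrs <- setNames(vapply(chrom_names, function(ch)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)), chrom_names)
  per_chrom <- ceiling(config$n_genes / config$n_chrom)
  models <- list(); gene_codons <- list()
  for (ci in seq_len(config$n_chrom)) {
    ch <- chrom_names[ci]
    sw <- sweeps[sweeps$chrom == ch, , drop = FALSE]
    sweep_slots <- as.integer(outer(c(2000L, 20000L), sw$start, `+`))
    bg_cand <- seq(20000L, L - 20000L, by = 40000L)
    in_sw <- vapply(bg_cand, function(s)
      any(s + 5000L > sw$start & s < sw$end + 5000L), logical(1))
    slots <- c(sweep_slots, bg_cand[!in_sw])
    n_here <- min(per_chrom, config$n_genes - length(models), length(slots))
    for (k in seq_len(n_here)) {
      gid <- if (ci == 1 && k == 1) "ca15like"
             else if (ci == min(2, config$n_chrom) && k == 1) "rhcglike"
             else sprintf("g%d_%02d", ci, k)
      # rhcg-like gene sits on the minus strand so both designated genes
      # exercise strand-aware annotation
      strand <- if (gid == "rhcglike") "-" else if (k %% 2 == 0) "-" else "+"
      force <- if (gid == "ca15like") setNames(list("GAA"), "10") else list()
      n_codons <- sample(100:160, 1)
      built <- build_gene(gid, ch, chrs[[ch]], slots[k], strand, n_codons,
                          sample(2:3, 1), force_codons = force)
      chrs[[ch]] <- built$chrseq
      models[[gid]] <- built$model
      gene_codons[[gid]] <- built$codons
    }
  }
  genome <- Biostrings::DNAStringSet(chrs)

  ## 2. planted variants ----------------------------------------------------
  set.seed(seeds[2])
  planted <- plant_coding_variants(models, genome, gene_codons, config)

  ## 3. background frequencies ----------------------------------------------
  ## designated genes carry planted variants only, so their triaged content is
  ## fully determined by the manifest: background positions avoid their spans
  set.seed(seeds[3])
  designated <- models[intersect(c("ca15like", "rhcglike"), names(models))]
  bg <- do.call(rbind, lapply(chrom_names, function(ch) {
    n_bg <- round(L * config$snp_density)
    excl <- planted$pos[planted$chrom == ch]
    excl <- unique(c(excl, excl + 1L, excl + 2L))
    for (m in designated)
      if (m$chrom == ch) excl <- c(excl, m$gene_span[1]:m$gene_span[2])
    pos <- sort(sample(setdiff(seq_len(L - 1L), excl), n_bg))
    data.frame(chrom = ch, pos = pos,
               ref = substring(chrs[[ch]], pos, pos),
               stringsAsFactors = FALSE)
  }))
  bg$alt <- vapply(bg$ref, function(r) sample(setdiff(c("A","C","G","T"), r), 1),
                   character(1))
  in_sweep <- vapply(seq_len(nrow(bg)), function(i)
    any(sweeps$chrom == bg$chrom[i] & bg$pos[i] > sweeps$start &
          bg$pos[i] <= sweeps$end), logical(1))
  fr <- simulate_site_frequencies(config, in_sweep)
  bg$p_alk <- fr$p_alk; bg$p_fw <- fr$p_fw

  sites <- rbind(bg[, c("chrom", "pos", "ref", "alt", "p_alk", "p_fw")],
                 planted[, c("chrom", "pos", "ref", "alt", "p_alk", "p_fw")])
  sites <- sites[order(match(sites$chrom, chrom_names), sites$pos), ]
  rownames(sites) <- NULL

  ## 4. genotypes ------------------------------------------------------------
  set.seed(seeds[4])
  g <- simulate_genotypes(sites$p_alk, sites$p_fw, config)
  popmap <- setNames(rep(c("ALK", "FW"), c(config$n_alk, config$n_fw)),
                     g$samples)
  site_tab <- sites[, c("chrom", "pos", "ref", "alt")]
  site_tab$is_snp <- nchar(site_tab$ref) == 1L & nchar(site_tab$alt) == 1L
  gd <- genotype_data(site_tab, g$a1, g$a2, popmap,
                      contig_lengths = setNames(rep(L, config$n_chrom),
                                                chrom_names))

  ## 5. ortholog alignment ---------------------------------------------------
  set.seed(seeds[5])
  ortho <- build_ortholog_fixture(config)

  fx <- list(config = config, genome = genome, models = models, gd = gd,
             sweeps = sweeps, planted = planted, ortholog = ortho,
             gene_codons = gene_codons, dir = dir)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(genome, file.path(dir, "genome.fa"))
    write_gff3(models, file.path(dir, "genes.gff3"))
    write_vcf(gd, file.path(dir, "variants.vcf"))
    write_tsv(data.frame(sample = names(popmap), population = unname(popmap)),
              file.path(dir, "popmap.tsv"))
    Biostrings::writeXStringSet(ortho$aln, file.path(dir, "ortholog.aln.fa"))
    write_tsv(data.frame(sequence = names(ortho$roles),
                         role = unname(ortho$roles)),
              file.path(dir, "roles.tsv"))
    jsonlite::write_json(truth_manifest(fx), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(fx)
}

#' Score a scan's selected windows against planted sweep intervals
#'
#' Ground-truth positives are the scan windows lying fully inside a planted
#' sweep interval (partial-overlap edge windows carry diluted signal and are
#' counted for neither sensitivity's denominator nor against precision).
#' Sensitivity is the fraction of those windows selected by either criterion;
#' precision is the fraction of all selected windows overlapping a planted
#' interval by at least 1 bp.
#'
#' @param windows full window table ([window_stats()] output).
#' @param selected selected-window table (`windows` element of
#'   [select_outlier_windows()]).
#' @param sweeps planted sweep intervals (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @return list: `sensitivity`, `precision`, `n_planted`, `n_selected`,
#'   `planted` (logical flag on `windows`).
#' @export
score_sweep_recovery <- function(windows, selected, sweeps) {
  inside <- function(w) vapply(seq_len(nrow(w)), function(i)
    any(sweeps$chrom == w$chrom[i] & w$start[i] >= sweeps$start &
          w$end[i] <= sweeps$end), logical(1))
  overlaps <- function(w) vapply(seq_len(nrow(w)), function(i)
    any(sweeps$chrom == w$chrom[i] & w$start[i] < sweeps$end &
          w$end[i] > sweeps$start), logical(1))
  planted <- inside(windows)
  key <- function(w) paste(w$chrom, w$start, w$end)
  sel_key <- key(selected)
  sens <- if (any(planted)) mean(key(windows)[planted] %in% sel_key) else NA_real_
  prec <- if (nrow(selected)) mean(overlaps(selected)) else NA_real_
  list(sensitivity = sens, precision = prec,
       n_planted = sum(planted), n_selected = nrow(selected), planted = planted)
}

#' Truth manifest of a simulated fixture
#'
#' A plain-list summary that fully determines the expected output of every
#' downstream stage: sweep intervals, planted variants with expected triage
#' labels and effect classes, planted alignment columns, and the generator
#' configuration.
#'
#' @param fx output of [simulate_fixture()].
#' @return a list (JSON-serializable).
#' @export
truth_manifest <- function(fx) {
  list(config = unclass(fx$config),
       sweeps = fx$sweeps,
       planted = fx$planted,
       n_pass_preset_a = sum(fx$planted$pass_a),
       sweep_genes = sort(names(Filter(function(m) {
         any(fx$sweeps$chrom == m$chrom &
               m$gene_span[1] <= fx$sweeps$end &
               m$gene_span[2] >= fx$sweeps$start + 1L)
       }, fx$models))),
       alignment = fx$ortholog$truth)
}
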