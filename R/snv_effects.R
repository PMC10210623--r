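#' Triage configuration for highly differentiated SNVs
#'
#' Two presets mirror the two published filters: `"ca15"` (preset A:
#' `Fst > 0.9` and `MAF_ALK < 0.1`, strict inequalities) and `"rhcg"`
#' (preset B: `Fst > 0.8` and located within CDS).  `"custom"` takes the
#' thresholds as given.
#'
#' @param preset `"ca15"`, `"rhcg"` or `"custom"`.
#' @param fst_min site Fst must exceed this value.
#' @param maf_alk_max ALK minor-allele frequency must be below this value
#'   (`NULL` disables the rule).
#' @param require_cds keep only variants inside a CDS segment.
#' @param restrict_to_genes optional character vector of gene ids; variants
#'   are kept only within these genes' spans.
#' @return object of class `triage_config`.
#' @export
triage_config <- function(preset = c("custom", "ca15", "rhcg"),
                          fst_min = 0.9, maf_alk_max = 0.1,
                          require_cds = FALSE, restrict_to_genes = NULL) {
  preset <- match.arg(preset)
  if (preset == "ca15") { fst_min <- 0.9; maf_alk_max <- 0.1; require_cds <- FALSE }
  if (preset == "rhcg") { fst_min <- 0.8; maf_alk_max <- NULL; require_cds <- TRUE }
  stopifnot(fst_min >= 0, fst_min <= 1,
            is.null(maf_alk_max) || (maf_alk_max >= 0 && maf_alk_max <= 1))
  if (!is.null(restrict_to_genes) && length(restrict_to_genes) == 0)
    config_error("restrict_to_genes set but empty")
  structure(list(preset = preset, fst_min = fst_min,
                 maf_alk_max = maf_alk_max, require_cds = require_cds,
                 restrict_to_genes = restrict_to_genes),
            class = "triage_config")
}

# gene id(s) whose span contains 1-based position (chrom, pos); "" when none
genes_at <- function(chrom, pos, models) {
  hits <- vapply(models, function(m)
    m$chrom == chrom && pos >= m$gene_span[1] && pos <= m$gene_span[2],
    logical(1))
  names(models)[hits]
}

in_cds_of <- function(chrom, pos, models, gene_ids = NULL) {
  for (m in models) {
    if (!is.null(gene_ids) && !(m$gene_id %in% gene_ids)) next
    if (m$chrom != chrom) next
    if (any(pos >= m$cds$start & pos <= m$cds$end)) return(TRUE)
  }
  FALSE
}

#' Triage highly differentiated SNVs
#'
#' Retains variants with `fst > fst_min`, and (when set) `maf_alk <
#' maf_alk_max`, and (when required) located inside a CDS of the listed
#' genes.  Variants with `NA` Fst or MAF never pass.  The output carries Fst,
#' MAF_ALK and delta-H so the three published plot axes are available
#' directly.
#'
#' @param stats output of [site_stats()].
#' @param config a [triage_config()].
#' @param models named list of [gene_model()] objects; required when
#'   `require_cds` or `restrict_to_genes` is set, used for gene labels
#'   otherwise when supplied.
#' @return data frame of retained variants: `chrom`, `pos`, `ref`, `alt`,
#'   `is_snp`, `fst`, `maf_alk`, `delta_h`, `p_alk`, `p_fw`, `gene`
#'   (comma-joined span hits, `""` when none or no models given).
#' @export
triage_snvs <- function(stats, config = triage_config(preset = "ca15"),
                        models = NULL) {
  if ((isTRUE(config$require_cds) || !is.null(config$restrict_to_genes)) &&
      is.null(models))
    config_error("gene models required for CDS/gene-restricted triage")
  keep <- !is.na(stats$fst) & stats$fst > config$fst_min
  if (!is.null(config$maf_alk_max))
    keep <- keep & !is.na(stats$maf_alk) & stats$maf_alk < config$maf_alk_max
  out <- stats[keep, c("chrom", "pos", "ref", "alt", "is_snp",
                       "fst", "maf_alk", "delta_h", "p_alk", "p_fw"),
               drop = FALSE]
  gene_set <- config$restrict_to_genes
  if (!is.null(models)) {
    sub <- if (is.null(gene_set)) models else models[intersect(names(models), gene_set)]
    out$gene <- vapply(seq_len(nrow(out)), function(i)
      paste(genes_at(out$chrom[i], out$pos[i], sub), collapse = ","),
      character(1))
  } else out$gene <- character(nrow(out))
  if (!is.null(gene_set))
    out <- out[out$gene != "", , drop = FALSE]
  if (isTRUE(config$require_cds)) {
    ok <- vapply(seq_len(nrow(out)), function(i)
      in_cds_of(out$chrom[i], out$pos[i], models, gene_set), logical(1))
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(x)
  paste(rev(COMPLEMENT[strsplit(x, "")[[1]]]), collapse = "")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

coding_effect_row <- function(gene_id, klass, cds_offset = NA_integer_,
                              codon_index = NA_integer_,
                              ref_codon = NA_character_, alt_codon = NA_character_,
                              ref_aa = NA_character_, alt_aa = NA_character_) {
  data.frame(gene_id = gene_id, klass = klass, cds_offset = cds_offset,
             codon_index = codon_index, ref_codon = ref_codon,
             alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
             stringsAsFactors = FALSE)
}

#' Annotate the coding effect of one variant on one gene model
#'
#' Maps the genomic position through the model's CDS segments honoring strand
#' (minus-strand alleles are complemented) and the GFF3 phase, rebuilds the
#' affected codon from the reference, substitutes the alternate allele and
#' translates both with the standard nuclear genetic code.  SNPs outside the
#' CDS but inside the gene span are `noncoding`; indels are classed
#' `frameshift` when the length change is not a multiple of 3, else
#' `inframe_indel`, and `splice_unknown` when they cross a CDS boundary.  A
#' phase attribute inconsistent with the cumulative CDS length is trusted
#' (with a warning).
#'
#' @param chrom,pos,ref,alt the variant (VCF conventions, 1-based `pos`).
#' @param model a [gene_model()] whose span contains `pos`.
#' @param genome named `DNAStringSet` containing `chrom`.
#' @return one-row data frame: `gene_id`, `klass`, `cds_offset` (0-based
#'   offset in the spliced CDS), `codon_index` (1-based), `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`.
#' @export
annotate_coding_effect <- function(chrom, pos, ref, alt, model, genome) {
  stopifnot(chrom == model$chrom)
  if (pos < model$gene_span[1] || pos > model$gene_span[2])
    config_error("variant %s:%d outside gene span of %s", chrom, pos, model$gene_id)
  chrseq <- genome[[chrom]]
  genome_ref <- as.character(Biostrings::subseq(chrseq, pos, pos + nchar(ref) - 1L))
  if (genome_ref != ref)
    config_error("reference mismatch at %s:%d (FASTA %s, VCF %s)",
                 chrom, pos, genome_ref, ref)
  is_snp <- nchar(ref) == 1L && nchar(alt) == 1L
  span <- pos:(pos + nchar(ref) - 1L)
  hit <- which(model$cds$start <= max(span) & model$cds$end >= min(span))
  if (!length(hit))
    return(coding_effect_row(model$gene_id, "noncoding"))
  if (length(hit) > 1 ||
      min(span) < model$cds$start[hit] || max(span) > model$cds$end[hit])
    return(coding_effect_row(model$gene_id, "splice_unknown"))
  if (!is_snp) {
    klass <- if (abs(nchar(ref) - nchar(alt)) %% 3L != 0L) "frameshift"
             else "inframe_indel"
    return(coding_effect_row(model$gene_id, klass))
  }
  part <- hit
  minus <- model$strand == "-"
  cum_before <- if (part == 1) 0L else
    sum(model$cds$end[seq_len(part - 1)] - model$cds$start[seq_len(part - 1)] + 1L)
  d <- if (minus) model$cds$end[part] - pos else pos - model$cds$start[part]
  cds_offset <- cum_before + d
  expected_phase <- (3L - cum_before %% 3L) %% 3L
  phase <- model$cds$phase[part]
  if (phase != expected_phase)
    warning(sprintf("gene %s CDS part %d: phase %d inconsistent with cumulative length (expected %d); trusting the annotation",
                    model$gene_id, part, phase, expected_phase))
  pos_in_codon <- (d - phase) %% 3L
  codon_start <- cds_offset - pos_in_codon
  cds <- cds_sequence(model, genome)
  if (codon_start < 0 || codon_start + 3L > nchar(cds))
    return(coding_effect_row(model$gene_id, "splice_unknown",
                             cds_offset = cds_offset))
  ref_codon <- substr(cds, codon_start + 1L, codon_start + 3L)
  ref_allele_cds <- if (minus) COMPLEMENT[[ref]] else ref
  alt_allele_cds <- if (minus) COMPLEMENT[[alt]] else alt
  if (substr(ref_codon, pos_in_codon + 1L, pos_in_codon + 1L) != ref_allele_cds)
    config_error("internal codon/reference inconsistency at %s:%d", chrom, pos)
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon + 1L, pos_in_codon + 1L) <- alt_allele_cds
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  klass <- if (is.na(ref_aa) || is.na(alt_aa)) "splice_unknown"
    else if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gained"
    else if (ref_aa == "*") "stop_lost"
    else "nonsynonymous"
  coding_effect_row(model$gene_id, klass, cds_offset = cds_offset,
                    codon_index = codon_start %/% 3L + 1L,
                    ref_codon = ref_codon, alt_codon = alt_codon,
                    ref_aa = ref_aa, alt_aa = alt_aa)
}

#' Annotate coding effects for a variant table
#'
#' One [annotate_coding_effect()] row per (variant, overlapping gene) pair;
#' variants hitting several overlapping genes get one row per gene.
#'
#' @param variants data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param models named list of [gene_model()] objects.
#' @param genome named `DNAStringSet`.
#' @return data frame: the variant columns plus the effect columns; variants
#'   outside every gene span are omitted.
#' @export
annotate_variants <- function(variants, models, genome) {
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    gids <- genes_at(variants$chrom[i], variants$pos[i], models)
    for (g in gids) {
      eff <- annotate_coding_effect(variants$chrom[i], variants$pos[i],
                                    variants$ref[i], variants$alt[i],
                                    models[[g]], genome)
      rows[[length(rows) + 1L]] <- cbind(
        variants[i, c("chrom", "pos", "ref", "alt"), drop = FALSE], eff)
    }
  }
  if (!length(rows))
    return(cbind(variants[0, c("chrom", "pos", "ref", "alt"), drop = FALSE],
                 coding_effect_row(character(0), character(0))[0, ]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene SNV summary
#'
#' For each requested gene: every variant inside its span with differentiation
#' statistics and coding-effect class, plus counts by class.
#'
#' @param gene_ids character vector of gene ids (unknown id is an error).
#' @param stats output of [site_stats()].
#' @param models named list of [gene_model()] objects.
#' @param genome named `DNAStringSet`.
#' @return list with `table` (per-variant rows: stats + effect columns) and
#'   `counts` (data frame `gene_id`, `klass`, `n`).
#' @export
summarize_gene_snvs <- function(gene_ids, stats, models, genome) {
  unknown <- setdiff(gene_ids, names(models))
  if (length(unknown))
    config_error("unknown gene id(s): %s", paste(unknown, collapse = ", "))
  tabs <- list()
  for (g in gene_ids) {
    m <- models[[g]]
    sel <- stats$chrom == m$chrom & stats$pos >= m$gene_span[1] &
      stats$pos <= m$gene_span[2]
    sub <- stats[sel, , drop = FALSE]
    if (!nrow(sub)) next
    eff <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i)
      annotate_coding_effect(sub$chrom[i], sub$pos[i], sub$ref[i], sub$alt[i],
                             m, genome)))
    tabs[[g]] <- cbind(sub[, c("chrom", "pos", "ref", "alt", "is_snp", "fst",
                               "maf_alk", "delta_h")], eff)
  }
  table <- if (length(tabs)) do.call(rbind, tabs) else
    cbind(stats[0, c("chrom", "pos", "ref", "alt", "is_snp", "fst",
                     "maf_alk", "delta_h")],
          coding_effect_row(character(0), character(0))[0, ])
  rownames(table) <- NULL
  counts <- if (nrow(table))
    aggregate(list(n = seq_len(nrow(table))), by = list(gene_id = table$gene_id, klass = table$klass), FUN = length)
  else data.frame(gene_id = character(), klass = character(), n = integer())
  # genes with zero variants still appear with zero rows in `table`; report them
  missing <- setdiff(gene_ids, unique(table$gene_id))
  list(table = table, counts = counts, genes_without_variants = missing)
}
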