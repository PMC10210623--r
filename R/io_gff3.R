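#' Gene model
#'
#' A single protein-coding gene model: one transcript (the longest-CDS
#' transcript of its gene), its coding segments in transcription order, and
#' the gene span.  Coordinates are 1-based closed, as in GFF3; windows and
#' regions elsewhere in the package are 0-based half-open, and the two systems
#' meet only through interval overlap queries.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds data frame with columns `start`, `end`, `phase`, rows in
#'   transcription order (ascending coordinates on `+`, descending on `-`).
#' @param gene_span length-2 integer vector `(start, end)` covering all CDS.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id = gene_id, chrom, strand, cds,
                       gene_span = NULL) {
  stopifnot(strand %in% c("+", "-"), nrow(cds) >= 1)
  cds <- cds[, c("start", "end", "phase")]
  if (any(cds$end < cds$start)) config_error("gene %s: CDS end < start", gene_id)
  if (!all(cds$phase %in% 0:2)) config_error("gene %s: phase outside 0..2", gene_id)
  ord <- order(cds$start, decreasing = (strand == "-"))
  cds <- cds[ord, , drop = FALSE]
  rownames(cds) <- NULL
  # non-overlap check in genomic order
  g <- cds[order(cds$start), , drop = FALSE]
  if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)]))
    config_error("gene %s: overlapping CDS segments", gene_id)
  if (sum(cds$end - cds$start + 1) < 3)
    config_error("gene %s: total CDS length < 3", gene_id)
  if (is.null(gene_span)) gene_span <- c(min(cds$start), max(cds$end))
  if (gene_span[1] > min(cds$start) || gene_span[2] < max(cds$end))
    config_error("gene %s: gene_span does not cover CDS", gene_id)
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, cds = cds,
                 gene_span = as.integer(gene_span)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d, %d CDS segment(s), %d coding bp\n",
              x$gene_id, x$strand, x$chrom, x$gene_span[1], x$gene_span[2],
              nrow(x$cds), sum(x$cds$end - x$cds$start + 1)))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features linked by `ID`/`Parent` and returns one
#' [gene_model()] per gene, keeping the transcript with the longest total CDS
#' when a gene has several.  Minus-strand CDS segments are ordered by
#' descending coordinate (transcription order).  CDS features without a
#' resolvable parent transcript are skipped with a warning.
#'
#' @param path path to a GFF3 file.
#' @param genome optional `DNAStringSet`; when given, feature coordinates are
#'   validated against sequence lengths (out-of-range is an error).
#' @return named list of `gene_model` objects (names are gene ids).
#' @export
read_gff3 <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ %in% c("mRNA", "transcript")]
  genes <- gr[typ == "gene"]
  cds <- gr[typ == "CDS"]
  if (length(cds) == 0) config_error("no CDS features in %s", path)

  mrna_parent <- vapply(as.list(mrna$Parent), function(p)
    if (length(p)) p[1] else NA_character_, character(1))
  mrna_id <- mrna$ID
  gene_id_of <- setNames(mrna_parent, mrna_id)
  gene_span_of <- setNames(
    lapply(seq_along(genes), function(i)
      c(GenomicRanges::start(genes)[i], GenomicRanges::end(genes)[i])),
    genes$ID)

  cds_parent <- as.list(cds$Parent)
  keep <- lengths(cds_parent) > 0 & unlist(lapply(cds_parent, function(p)
    if (length(p)) p[1] %in% mrna_id else FALSE))
  if (any(!keep)) {
    warning(sprintf("%d CDS feature(s) without a parent transcript skipped in %s",
                    sum(!keep), path))
    cds <- cds[keep]
    cds_parent <- cds_parent[keep]
  }
  parent1 <- vapply(cds_parent, `[`, character(1), 1)

  if (!is.null(genome)) {
    lens <- setNames(Biostrings::width(genome), names(genome))
    ch <- as.character(GenomicRanges::seqnames(cds))
    bad <- !(ch %in% names(lens)) | GenomicRanges::end(cds) > lens[ch] |
      GenomicRanges::start(cds) < 1
    if (any(bad))
      config_error("CDS coordinates out of range of the genome FASTA (first: %s:%d-%d)",
                   ch[bad][1], GenomicRanges::start(cds)[bad][1],
                   GenomicRanges::end(cds)[bad][1])
  }

  models <- list()
  for (gid in unique(unname(gene_id_of))) {
    tids <- mrna_id[gene_id_of[mrna_id] == gid]
    best <- NULL; best_len <- -1L
    for (tid in tids) {
      sel <- parent1 == tid
      if (!any(sel)) next
      len <- sum(GenomicRanges::width(cds[sel]))
      if (len > best_len) { best <- tid; best_len <- len }
    }
    if (is.null(best)) next
    sel <- parent1 == best
    strand <- as.character(GenomicRanges::strand(cds[sel]))[1]
    ph <- cds[sel]$phase
    if (is.null(ph) || all(is.na(ph))) ph <- rep(0L, sum(sel))
    tab <- data.frame(start = GenomicRanges::start(cds[sel]),
                      end = GenomicRanges::end(cds[sel]),
                      phase = as.integer(ph))
    models[[gid]] <- gene_model(
      gene_id = gid, transcript_id = best,
      chrom = as.character(GenomicRanges::seqnames(cds[sel]))[1],
      strand = strand, cds = tab,
      gene_span = gene_span_of[[gid]])
  }
  models
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features with `ID`/`Parent` links; used by the
#' synthetic-data generator.  Round-trips through [read_gff3()].
#'
#' @param models named list of `gene_model` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    sp <- m$gene_span
    lines <- c(lines,
      sprintf("%s\talksweep\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              m$chrom, sp[1], sp[2], m$strand, m$gene_id),
      sprintf("%s\talksweep\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              m$chrom, sp[1], sp[2], m$strand, m$transcript_id, m$gene_id))
    for (i in seq_len(nrow(m$cds))) {
      lines <- c(lines,
        sprintf("%s\talksweep\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s",
                m$chrom, m$cds$start[i], m$cds$end[i], m$strand,
                m$cds$phase[i], m$transcript_id, i, m$transcript_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# genomic positions of the CDS bases in transcription order (5'->3' of mRNA)
cds_genomic_positions <- function(model) {
  parts <- lapply(seq_len(nrow(model$cds)), function(i) {
    s <- model$cds$start[i]; e <- model$cds$end[i]
    if (model$strand == "+") s:e else e:s
  })
  unlist(parts, use.names = FALSE)
}

# coding sequence (mRNA sense) of a model extracted from the genome
cds_sequence <- function(model, genome) {
  chrseq <- genome[[model$chrom]]
  parts <- vapply(seq_len(nrow(model$cds)), function(i) {
    s <- as.character(Biostrings::subseq(chrseq, model$cds$start[i], model$cds$end[i]))
    if (model$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  paste(parts, collapse = "")
}
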