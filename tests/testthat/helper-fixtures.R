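# shared fixtures, built once per test run

.fx_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed = 101, ...) {
  key <- paste0("fx_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- simulate_fixture(sim_config(seed = seed, ...))
  .fx_cache[[key]]
}

# hand-built two-exon gene on a 120 bp toy chromosome, both strand variants.
# plus strand: CDS = ATG GAA CTT TGC | CGA TAA  split 10 + 8
toy_gene_genome <- function(strand = "+") {
  cds <- "ATGGAACTTTGCCGATAA"
  exon1 <- substr(cds, 1, 10); exon2 <- substr(cds, 11, 18)
  pad <- function(n) paste(rep("T", n), collapse = "")
  if (strand == "+") {
    # exon1 at 21..30, intron 31..50, exon2 at 51..58
    seqc <- paste0(pad(20), exon1, pad(20), exon2, paste(rep("A", 62), collapse = ""))
    model <- gene_model("toy", "toy.t1", "chrT", "+",
                        data.frame(start = c(21L, 51L), end = c(30L, 58L),
                                   phase = c(0L, 2L)),
                        gene_span = c(11L, 70L))
  } else {
    rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    # transcription runs right to left: exon1 (5') sits at high coordinates
    seqc <- paste0(pad(20), rc(exon2), pad(20), rc(exon1), paste(rep("A", 62), collapse = ""))
    # exon2 genomic 21..28, exon1 genomic 49..58
    model <- gene_model("toy", "toy.t1", "chrT", "-",
                        data.frame(start = c(49L, 21L), end = c(58L, 28L),
                                   phase = c(0L, 2L)),
                        gene_span = c(11L, 70L))
  }
  genome <- Biostrings::DNAStringSet(setNames(seqc, "chrT"))
  list(genome = genome, model = model, cds = cds)
}

# minimal counts row builder for estimator unit tests
counts_row <- function(ac_alk, an_alk, het_alk, ac_fw, an_fw, het_fw) {
  data.frame(ac_alk = ac_alk, an_alk = an_alk, nind_alk = an_alk %/% 2L,
             het_alk = het_alk,
             ac_fw = ac_fw, an_fw = an_fw, nind_fw = an_fw %/% 2L,
             het_fw = het_fw)
}

# small hand-written VCF text
write_toy_vcf <- function(path, records, samples = "s1",
                          contigs = c(chr1 = 1000L)) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
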