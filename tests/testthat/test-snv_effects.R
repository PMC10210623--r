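test_that("triage applies the preset thresholds as strict inequalities", {
  mk <- function(fst, maf) data.frame(chrom = "chr1", pos = 100L, ref = "A",
                                      alt = "C", is_snp = TRUE, fst = fst,
                                      maf_alk = maf, delta_h = 0.4,
                                      p_alk = 1 - maf, p_fw = 0.1)
  pa <- triage_config(preset = "ca15")
  expect_equal(nrow(triage_snvs(mk(0.95, 0.05), pa)), 1L)
  expect_equal(nrow(triage_snvs(mk(0.95, 0.20), pa)), 0L)
  expect_equal(nrow(triage_snvs(mk(0.90, 0.05), pa)), 0L)  # strict >
  expect_equal(nrow(triage_snvs(mk(0.95, 0.10), pa)), 0L)  # strict <
  expect_equal(nrow(triage_snvs(mk(NA, 0.05), pa)), 0L)
  # empty gene restriction is a configuration error
  expect_error(triage_config(restrict_to_genes = character(0)), "empty")
})

test_that("triage is monotone under threshold tightening", {
  fx <- cached_fixture()
  stats <- site_stats(genotype_counts(fx$gd))
  set.seed(21)
  for (rep in 1:25) {
    f1 <- runif(1, 0.2, 0.9); m1 <- runif(1, 0.05, 0.5)
    f2 <- runif(1, f1, 1); m2 <- runif(1, 0, m1)   # tightened
    loose <- triage_snvs(stats, triage_config(fst_min = f1, maf_alk_max = m1))
    tight <- triage_snvs(stats, triage_config(fst_min = f2, maf_alk_max = m2))
    key <- function(d) paste(d$chrom, d$pos)
    expect_true(all(key(tight) %in% key(loose)))
  }
})

test_that("preset B keeps only CDS variants of higher Fst", {
  fx <- cached_fixture()
  stats <- site_stats(genotype_counts(fx$gd))
  pb <- triage_config(preset = "rhcg")
  tr <- triage_snvs(stats, pb, fx$models)
  expect_true(all(tr$fst > 0.8))
  in_cds <- vapply(seq_len(nrow(tr)), function(i) {
    any(vapply(fx$models, function(m)
      m$chrom == tr$chrom[i] && any(tr$pos[i] >= m$cds$start &
                                      tr$pos[i] <= m$cds$end), logical(1)))
  }, logical(1))
  expect_true(all(in_cds))
})

test_that("codon arithmetic reproduces the canonical substitutions (plus strand)", {
  toy <- toy_gene_genome("+")
  # codon 2 GAA, third base A -> C: Glu (E) -> Asp (D), nonsynonymous
  eff <- annotate_coding_effect("chrT", 26L, "A", "C", toy$model, toy$genome)
  expect_equal(eff$ref_codon, "GAA"); expect_equal(eff$alt_codon, "GAC")
  expect_equal(eff$ref_aa, "E"); expect_equal(eff$alt_aa, "D")
  expect_equal(eff$klass, "nonsynonymous")
  expect_equal(eff$codon_index, 2L)
  # codon 3 CTT, third base T -> C: Leu -> Leu, synonymous
  eff <- annotate_coding_effect("chrT", 29L, "T", "C", toy$model, toy$genome)
  expect_equal(eff$alt_codon, "CTC")
  expect_equal(eff$klass, "synonymous")
  # codon 4 spans the intron: TGC with T on exon 1, GC on exon 2
  eff <- annotate_coding_effect("chrT", 51L, "G", "A", toy$model, toy$genome)
  expect_equal(eff$ref_codon, "TGC")
  expect_equal(eff$codon_index, 4L)
  # intronic SNP inside the gene span
  eff <- annotate_coding_effect("chrT", 40L, "T", "G", toy$model, toy$genome)
  expect_equal(eff$klass, "noncoding")
  # 2 bp deletion inside the CDS
  ref3 <- substr(as.character(toy$genome[["chrT"]]), 24, 26)
  eff <- annotate_coding_effect("chrT", 24L, ref3, substr(ref3, 1, 1),
                                toy$model, toy$genome)
  expect_equal(eff$klass, "frameshift")
  # deletion crossing the exon boundary
  refx <- substr(as.character(toy$genome[["chrT"]]), 29, 32)
  eff <- annotate_coding_effect("chrT", 29L, refx, substr(refx, 1, 1),
                                toy$model, toy$genome)
  expect_equal(eff$klass, "splice_unknown")
  # reference mismatch is an error naming the position
  expect_error(annotate_coding_effect("chrT", 26L, "G", "C", toy$model,
                                      toy$genome), "chrT:26")
})

test_that("minus-strand annotation complements alleles correctly", {
  toy <- toy_gene_genome("-")
  # codon 2 third base (CDS A) sits at genomic 53 as T; T -> G is CDS A -> C
  eff <- annotate_coding_effect("chrT", 53L, "T", "G", toy$model, toy$genome)
  expect_equal(eff$ref_codon, "GAA"); expect_equal(eff$alt_codon, "GAC")
  expect_equal(eff$ref_aa, "E"); expect_equal(eff$alt_aa, "D")
  expect_equal(eff$klass, "nonsynonymous")
  expect_equal(eff$codon_index, 2L)
  expect_equal(eff$cds_offset, 5L)
})

test_that("effect annotation is strand-symmetric under genome mirroring", {
  plus <- toy_gene_genome("+")
  minus <- toy_gene_genome("-")
  L <- 120L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # every CDS base of the plus gene, all three alternates
  gpos_plus <- alksweep:::cds_genomic_positions(plus$model)
  gpos_minus <- alksweep:::cds_genomic_positions(minus$model)
  for (k in seq_along(gpos_plus)) {
    p <- gpos_plus[k]; q <- gpos_minus[k]
    refp <- substr(as.character(plus$genome[["chrT"]]), p, p)
    for (altp in setdiff(c("A", "C", "G", "T"), refp)) {
      e1 <- annotate_coding_effect("chrT", p, refp, altp, plus$model, plus$genome)
      e2 <- annotate_coding_effect("chrT", q, comp[[refp]], comp[[altp]],
                                   minus$model, minus$genome)
      expect_equal(e1$klass, e2$klass)
      expect_equal(e1$ref_aa, e2$ref_aa)
      expect_equal(e1$alt_aa, e2$alt_aa)
      expect_equal(e1$codon_index, e2$codon_index)
    }
  }
})

test_that("per-variant codon calls agree with whole-CDS translation differencing", {
  fx <- cached_fixture()
  snps <- fx$planted[fx$planted$gene != "" & nchar(fx$planted$ref) == 1 &
                       nchar(fx$planted$alt) == 1, ]
  expect_gt(nrow(snps), 5)
  for (i in seq_len(nrow(snps))) {
    v <- snps[i, ]
    m <- fx$models[[v$gene]]
    eff <- annotate_coding_effect(v$chrom, v$pos, v$ref, v$alt, m, fx$genome)
    diffs <- oracle_protein_diff(m, fx$genome, v$pos, v$alt)
    if (eff$klass == "nonsynonymous") {
      expect_equal(length(diffs), 1L)
      expect_equal(eff$codon_index, diffs)
      expect_equal(eff$klass, v$klass)
    } else {
      expect_equal(eff$klass, "synonymous")
      expect_equal(length(diffs), 0L)
    }
  }
})

test_that("per-gene SNV summaries count planted effect classes", {
  fx <- cached_fixture()
  stats <- site_stats(genotype_counts(fx$gd))
  res <- summarize_gene_snvs(c("ca15like", "rhcglike"), stats, fx$models,
                             fx$genome)
  cnt <- res$counts
  want_nonsyn_ca <- sum(fx$planted$gene == "ca15like" &
                          fx$planted$klass == "nonsynonymous")
  expect_equal(cnt$n[cnt$gene_id == "ca15like" & cnt$klass == "nonsynonymous"],
               want_nonsyn_ca)
  expect_equal(cnt$n[cnt$gene_id == "ca15like" & cnt$klass == "synonymous"],
               fx$config$n_syn)
  expect_equal(cnt$n[cnt$gene_id == "ca15like" & cnt$klass == "frameshift"],
               fx$config$n_indel_pass)
  expect_equal(cnt$n[cnt$gene_id == "rhcglike" & cnt$klass == "nonsynonymous"],
               fx$config$rhcg_nonsyn)
  expect_error(summarize_gene_snvs("no_such_gene", stats, fx$models, fx$genome),
               "unknown gene")
})
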