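# Independent brute-force oracles. These transcribe the published component
# formulas / definitions directly, with explicit loops and no shared code with
# the package implementation.

# Weir & Cockerham (1984) theta from per-population genotype class counts:
# n_hom_ref, n_het, n_hom_alt for each of two populations.
oracle_wc_components <- function(g1, g2) {
  gs <- list(g1, g2)
  r <- 2
  n <- numeric(r); p <- numeric(r); h <- numeric(r)
  for (i in 1:r) {
    n[i] <- sum(gs[[i]])
    p[i] <- (2 * gs[[i]][3] + gs[[i]][2]) / (2 * n[i])
    h[i] <- gs[[i]][2] / n[i]
  }
  nbar <- 0; for (i in 1:r) nbar <- nbar + n[i] / r
  ssq <- 0; for (i in 1:r) ssq <- ssq + n[i]^2
  nc <- (r * nbar - ssq / (r * nbar)) / (r - 1)
  pbar <- 0; for (i in 1:r) pbar <- pbar + n[i] * p[i] / (r * nbar)
  s2 <- 0; for (i in 1:r) s2 <- s2 + n[i] * (p[i] - pbar)^2 / ((r - 1) * nbar)
  hbar <- 0; for (i in 1:r) hbar <- hbar + n[i] * h[i] / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

oracle_wc_fst <- function(g1, g2) {
  comp <- oracle_wc_components(g1, g2)
  tot <- sum(comp)
  if (tot == 0) NA_real_ else comp[["a"]] / tot
}

# per-site pairwise diversity by brute-force enumeration of chromosome pairs:
# k derived alleles among n chromosomes -> mean pairwise difference
oracle_pi_site <- function(k, n) {
  if (n < 2) return(0)
  diff_pairs <- k * (n - k)
  diff_pairs / choose(n, 2)
}

# Tajima (1989) D from a vector of derived-allele counts at uniform n
oracle_tajimas_d <- function(counts, n) {
  seg <- counts[counts > 0 & counts < n]
  S <- length(seg)
  if (S == 0 || n < 4) return(NA_real_)
  pi_hat <- 0
  for (k in seg) pi_hat <- pi_hat + oracle_pi_site(k, n)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# textbook paired t-test
oracle_paired_t <- function(x, y) {
  d <- x - y
  k <- length(d)
  t <- mean(d) / (sd(d) / sqrt(k))
  list(t = t, p = 2 * pt(-abs(t), df = k - 1))
}

# random two-population genotype-class tables (<= max_n diploids per
# population) and the corresponding genotype_counts()-style row
random_geno_table <- function(max_n = 6) {
  draw <- function() {
    n <- sample(2:max_n, 1)
    p <- runif(1)
    g <- as.vector(rmultinom(1, n, c((1 - p)^2, 2 * p * (1 - p), p^2)))
    g
  }
  g1 <- draw(); g2 <- draw()
  row <- data.frame(
    ac_alk = 2L * g1[3] + g1[2], an_alk = 2L * sum(g1), nind_alk = sum(g1),
    het_alk = g1[2],
    ac_fw = 2L * g2[3] + g2[2], an_fw = 2L * sum(g2), nind_fw = sum(g2),
    het_fw = g2[2])
  list(g1 = g1, g2 = g2, row = row)
}

# whole-CDS translation differencing: the independent oracle for per-variant
# codon calls (apply the alt allele to the genome, rebuild and translate)
oracle_protein_diff <- function(model, genome, pos, alt) {
  g2 <- genome
  gs <- as.character(g2[[model$chrom]])
  substr(gs, pos, pos) <- alt
  g2[[model$chrom]] <- Biostrings::DNAString(gs)
  tr <- function(g) strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(alksweep:::cds_sequence(model, g)))), "")[[1]]
  p_ref <- tr(genome); p_alt <- tr(g2)
  which(p_ref != p_alt)
}
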