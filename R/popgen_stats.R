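#' Per-site allele frequencies
#'
#' Alt-allele frequency and called-chromosome counts per population; `NA`
#' frequency when a population has no called allele at a site.
#'
#' @param counts output of [genotype_counts()] (any subset of rows).
#' @return `counts` with added columns `p_alk`, `p_fw`.
#' @export
site_frequencies <- function(counts) {
  counts$p_alk <- ifelse(counts$an_alk > 0, counts$ac_alk / counts$an_alk, NA_real_)
  counts$p_fw <- ifelse(counts$an_fw > 0, counts$ac_fw / counts$an_fw, NA_real_)
  counts
}

# Weir & Cockerham (1984) two-population variance components per site.
# Returns a data frame with columns a and d = a + b + c; NA rows where the
# estimator's preconditions fail (< 2 called diploids in either population).
wc_fst_components <- function(counts) {
  n1 <- counts$nind_alk; n2 <- counts$nind_fw
  ok <- n1 >= 2L & n2 >= 2L
  p1 <- counts$ac_alk / (2 * n1); p2 <- counts$ac_fw / (2 * n2)
  h1 <- counts$het_alk / n1; h2 <- counts$het_fw / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- NA_real_
  d <- a + b + cc
  d[!ok] <- NA_real_
  data.frame(a = a, d = d)
}

#' Per-site Weir-Cockerham Fst
#'
#' The Weir & Cockerham (1984) two-population estimator
#' `theta = a / (a + b + c)` from the among-population (`a`),
#' among-individual (`b`) and within-individual (`c`) variance components,
#' using observed heterozygote counts.  `NA` when the site is monomorphic in
#' both populations (`a + b + c = 0`) or fewer than two diploids are called in
#' either population.
#'
#' @param counts output of [genotype_counts()].
#' @return numeric vector of per-site Fst values.
#' @export
wc_fst_site <- function(counts) {
  comp <- wc_fst_components(counts)
  ifelse(is.na(comp$d) | comp$d == 0, NA_real_, comp$a / comp$d)
}

#' Windowed (ratio-of-sums) Weir-Cockerham Fst
#'
#' `sum(a) / sum(a + b + c)` over the sites of a window — the weighted
#' estimator; `NA` when no usable site.
#'
#' @param counts output of [genotype_counts()] restricted to one window.
#' @return single numeric value.
#' @export
wc_fst_window <- function(counts) {
  comp <- wc_fst_components(counts)
  num <- sum(comp$a, na.rm = TRUE); den <- sum(comp$d, na.rm = TRUE)
  if (all(is.na(comp$d)) || den == 0) NA_real_ else num / den
}

# unbiased per-site pairwise diversity 2p(1-p) n/(n-1); 0 for n < 2
pi_site <- function(p, n) ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), 0)

#' Windowed nucleotide diversity (pi) per bp
#'
#' Sum over window sites of the unbiased per-site heterozygosity
#' `2 p (1 - p) n / (n - 1)` (n = called chromosomes at the site), divided by
#' the full window span in bp (the vcftools `--window-pi` convention, not
#' callable sites).  Sites with fewer than two called chromosomes are skipped;
#' sites fixed within the population contribute zero.
#'
#' @param p alt-allele frequencies of the window's sites in one population.
#' @param n called-chromosome counts at those sites.
#' @param span window span in bp (> 0).
#' @return per-bp diversity (single numeric value).
#' @export
window_pi <- function(p, n, span) {
  stopifnot(span > 0)
  keep <- !is.na(p) & n >= 2
  sum(pi_site(p[keep], n[keep])) / span
}

#' log2 diversity ratio (ALK over FW)
#'
#' `log2(pi_alk / pi_fw)`; windows where the alkaline population lost
#' diversity go negative.  When either side is zero it is replaced by
#' `pseudo_floor` (by default the smallest nonzero per-bp pi observed
#' genome-wide, supplied by the caller) and the window is flagged.
#'
#' @param pi_alk,pi_fw per-bp diversities (vectors).
#' @param pseudo_floor positive replacement for zero diversities.
#' @return data frame with columns `log2_pi_ratio`, `pi_floored`.
#' @export
pi_ratio_log2 <- function(pi_alk, pi_fw, pseudo_floor) {
  floored <- (pi_alk == 0 | pi_fw == 0)
  pa <- ifelse(pi_alk == 0, pseudo_floor, pi_alk)
  pf <- ifelse(pi_fw == 0, pseudo_floor, pi_fw)
  data.frame(log2_pi_ratio = log2(pa / pf), pi_floored = floored)
}

# Tajima (1989) constants for sample size n (chromosomes)
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D for one window and one population
#'
#' `D = (pi_win - S / a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' Tajima (1989) constants computed from the window's sample size; `pi_win` is
#' the sum of per-site pairwise diversity (not per-bp).  With missing data the
#' sample size is the modal called-chromosome count across the window's sites
#' (ties resolved toward the larger count); sites whose call count deviates
#' from the mode by more than 20% are excluded.  `NA` when there are no
#' segregating sites, or fewer than 4 chromosomes (with a warning).
#'
#' @param p alt-allele frequencies of the window's sites in one population.
#' @param n called-chromosome counts at those sites.
#' @return single numeric value.
#' @export
tajimas_d <- function(p, n) {
  keep <- !is.na(p) & n >= 2
  p <- p[keep]; n <- n[keep]
  if (!length(p)) return(NA_real_)
  tab <- table(n)
  modes <- as.integer(names(tab)[tab == max(tab)])
  n_mode <- max(modes)
  if (n_mode < 4) {
    warning("Tajima's D undefined for fewer than 4 chromosomes")
    return(NA_real_)
  }
  use <- abs(n - n_mode) <= 0.2 * n_mode
  p <- p[use]; n <- n[use]
  seg <- p > 0 & p < 1
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_win <- sum(pi_site(p[seg], n[seg]))
  k <- tajima_constants(n_mode)
  (pi_win - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Per-site differentiation statistics (the 3D-plot axes)
#'
#' For each site: Weir-Cockerham Fst, expected heterozygosity per population
#' (`h = 2 p (1 - p)`, in `[0, 0.5]`), their difference
#' `delta_h = h_fw - h_alk` (positive where the alkaline population lost
#' diversity), and the within-population minor-allele frequencies
#' `maf = min(p, 1 - p)`.
#'
#' @param counts output of [genotype_counts()].
#' @return `counts` with added columns `p_alk`, `p_fw`, `fst`, `h_alk`,
#'   `h_fw`, `delta_h`, `maf_alk`, `maf_fw`.
#' @export
site_stats <- function(counts) {
  counts <- site_frequencies(counts)
  counts$fst <- wc_fst_site(counts)
  counts$h_alk <- 2 * counts$p_alk * (1 - counts$p_alk)
  counts$h_fw <- 2 * counts$p_fw * (1 - counts$p_fw)
  counts$delta_h <- counts$h_fw - counts$h_alk
  counts$maf_alk <- pmin(counts$p_alk, 1 - counts$p_alk)
  counts$maf_fw <- pmin(counts$p_fw, 1 - counts$p_fw)
  counts
}

#' Paired t-test comparing per-chromosome diversity between populations
#'
#' Two-sided paired t-test on per-chromosome mean pi (ALK vs FW).  When the
#' paired differences have zero variance the test is degenerate: identical
#' vectors give `t = 0, P = 1`; constant nonzero differences give `NA`s; both
#' set `degenerate = TRUE`.
#'
#' @param pi_alk,pi_fw equal-length numeric vectors (one value per
#'   chromosome), length >= 2.
#' @return list with `t`, `p_value`, `df`, `degenerate`.
#' @export
compare_diversity <- function(pi_alk, pi_fw) {
  stopifnot(length(pi_alk) == length(pi_fw), length(pi_alk) >= 2)
  d <- pi_alk - pi_fw
  if (isTRUE(all.equal(stats::sd(d), 0)) || stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p_value = 1, df = length(d) - 1L, degenerate = TRUE))
    return(list(t = NA_real_, p_value = NA_real_, df = length(d) - 1L,
                degenerate = TRUE))
  }
  tt <- t.test(pi_alk, pi_fw, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}
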