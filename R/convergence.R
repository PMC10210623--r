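#' Read a sequence-role map
#'
#' Two-column TSV (`sequence`, `role`).  Roles: exactly one `FOCAL_ALK` and
#' one `FOCAL_FW` (the two population consensus sequences of the focal
#' species), at least one `ALKALINE_ADAPTED` lineage and at least one
#' `FRESHWATER_REF` lineage.
#'
#' @param path path to the TSV.
#' @return named character vector `sequence -> role`.
#' @export
read_role_map <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("sequence", "role"))
  if (nrow(tab) && tab$sequence[1] == "sequence") tab <- tab[-1, , drop = FALSE]
  roles <- setNames(tab$role, tab$sequence)
  validate_roles(roles)
  roles
}

validate_roles <- function(roles, seq_names = NULL) {
  valid <- c("FOCAL_ALK", "FOCAL_FW", "ALKALINE_ADAPTED", "FRESHWATER_REF")
  if (!all(roles %in% valid))
    config_error("unknown role(s): %s",
                 paste(setdiff(roles, valid), collapse = ", "))
  if (sum(roles == "FOCAL_ALK") != 1 || sum(roles == "FOCAL_FW") != 1)
    config_error("role map needs exactly one FOCAL_ALK and one FOCAL_FW")
  if (!any(roles == "ALKALINE_ADAPTED") || !any(roles == "FRESHWATER_REF"))
    config_error("role map needs >= 1 ALKALINE_ADAPTED and >= 1 FRESHWATER_REF")
  if (!is.null(seq_names)) {
    missing <- setdiff(seq_names, names(roles))
    if (length(missing))
      config_error("alignment sequence(s) missing from role map: %s",
                   paste(missing, collapse = ", "))
  }
  invisible(roles)
}

aln_to_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is.character(aln)) aln <- Biostrings::AAStringSet(aln)
  m <- as.matrix(aln)
  rownames(m) <- names(aln)
  m
}

#' Detect population-differentiating and convergent alignment columns
#'
#' A column is *differentiating* iff the two focal consensus residues differ
#' (both non-gap).  It is additionally *convergent* iff (i) at least one
#' alkaline-adapted lineage carries the focal-ALK residue and (ii) every
#' non-gap freshwater reference carries the focal-FW residue (strict
#' freshwater consistency; `freshwater_rule = "majority"` relaxes (ii) to a
#' strict majority).  Columns where either focal sequence is gapped are
#' skipped; gapped non-focal sequences are ignored for the rules they would
#' enter.  The detected set is invariant to row order and row names.
#'
#' @param aln protein multiple alignment: `AAStringSet`, named character
#'   vector, or character matrix (rows = sequences, equal widths).
#' @param roles named character vector `sequence -> role` (see
#'   [read_role_map()]).
#' @param freshwater_rule `"all"` (default) or `"majority"`.
#' @return data frame with one row per differentiating column: `column`
#'   (1-based), `focal_alk_aa`, `focal_fw_aa`, `supporting_species`
#'   (comma-joined, `""` when none), `freshwater_consistent`, `status`
#'   (`"differentiating"` or `"convergent"`).
#' @export
detect_convergent_sites <- function(aln, roles,
                                    freshwater_rule = c("all", "majority")) {
  freshwater_rule <- match.arg(freshwater_rule)
  m <- aln_to_matrix(aln)
  validate_roles(roles, rownames(m))
  gap <- c("-", ".", "X")
  alk_row <- which(rownames(m) == names(roles)[roles == "FOCAL_ALK"])
  fw_row <- which(rownames(m) == names(roles)[roles == "FOCAL_FW"])
  alk_sp <- rownames(m)[rownames(m) %in% names(roles)[roles == "ALKALINE_ADAPTED"]]
  fw_sp <- rownames(m)[rownames(m) %in% names(roles)[roles == "FRESHWATER_REF"]]
  rows <- list()
  for (j in seq_len(ncol(m))) {
    a <- m[alk_row, j]; f <- m[fw_row, j]
    if (a %in% gap || f %in% gap || a == f) next
    alk_res <- m[alk_sp, j]; alk_res <- alk_res[!(alk_res %in% gap)]
    fw_res <- m[fw_sp, j]; fw_res <- fw_res[!(fw_res %in% gap)]
    support <- sort(alk_sp[m[alk_sp, j] == a])
    fw_ok <- if (freshwater_rule == "all") all(fw_res == f)
             else sum(fw_res == f) > length(fw_res) / 2
    convergent <- length(support) > 0 && fw_ok
    rows[[length(rows) + 1L]] <- data.frame(
      column = j, focal_alk_aa = a, focal_fw_aa = f,
      supporting_species = if (convergent) paste(support, collapse = ",") else "",
      freshwater_consistent = fw_ok,
      status = if (convergent) "convergent" else "differentiating",
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(column = integer(), focal_alk_aa = character(),
                      focal_fw_aa = character(), supporting_species = character(),
                      freshwater_consistent = logical(), status = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene convergence report
#'
#' Counts of differentiating and convergent columns plus per-convergent-column
#' substitution notation `"X-Y"` (freshwater residue, dash, alkaline
#' residue).  When a [gene_model()] is supplied, each column is localized to
#' the CDS segment (exon) containing its codon.
#'
#' @param sites output of [detect_convergent_sites()].
#' @param gene_id label for the report.
#' @param model optional `gene_model` for exon localization (assumes the
#'   alignment columns are the gene's codons, 1-based).
#' @return list: `gene_id`, `n_differentiating`, `n_convergent`,
#'   `substitutions` (character vector), and `sites` (the input with added
#'   `substitution` and, when localized, `exon` columns).
#' @export
report_convergence <- function(sites, gene_id = NA_character_, model = NULL) {
  sites$substitution <- if (nrow(sites))
    paste0(sites$focal_fw_aa, "-", sites$focal_alk_aa) else character(0)
  if (!is.null(model)) {
    lens <- model$cds$end - model$cds$start + 1L
    bounds <- cumsum(lens)
    sites$exon <- vapply(sites$column, function(col) {
      off <- (col - 1L) * 3L  # first base of the codon, 0-based CDS offset
      which(off < bounds)[1]
    }, integer(1))
  }
  conv <- sites$status == "convergent"
  list(gene_id = gene_id,
       n_differentiating = nrow(sites),
       n_convergent = sum(conv),
       substitutions = sites$substitution[conv],
       sites = sites)
}

#' Population consensus protein sequences for a gene
#'
#' Applies each population's major allele (strict majority of called
#' chromosomes; exact 50/50 ties resolved toward the reference allele, with a
#' message) at each supplied SNV to the reference CDS, then translates both
#' haplotypes.  A premature stop truncates the protein with a warning.
#' Non-SNP sites are ignored (amino-acid consensus is defined for
#' substitutions only).
#'
#' @param model a [gene_model()].
#' @param genome named `DNAStringSet`.
#' @param freqs data frame with `chrom`, `pos`, `ref`, `alt`, `p_alk`,
#'   `p_fw` (e.g. triaged rows of [site_stats()] output).
#' @return named character vector of two protein sequences, `ALK` and `FW`.
#' @export
build_population_consensus <- function(model, genome, freqs) {
  cds_ref <- cds_sequence(model, genome)
  gpos <- cds_genomic_positions(model)
  minus <- model$strand == "-"
  apply_pop <- function(pcol) {
    cds <- cds_ref
    for (i in seq_len(nrow(freqs))) {
      if (nchar(freqs$ref[i]) != 1L || nchar(freqs$alt[i]) != 1L) next
      if (freqs$chrom[i] != model$chrom) next
      off <- match(freqs$pos[i], gpos)
      if (is.na(off)) next
      p <- freqs[[pcol]][i]
      if (is.na(p)) next
      if (p == 0.5) {
        message(sprintf("50/50 tie at %s:%d resolved toward the reference allele",
                        freqs$chrom[i], freqs$pos[i]))
        next
      }
      if (p > 0.5) {
        allele <- if (minus) COMPLEMENT[[freqs$alt[i]]] else freqs$alt[i]
        substr(cds, off, off) <- allele
      }
    }
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(cds, 1, nchar(cds) - nchar(cds) %% 3)),
      if.fuzzy.codon = "X"))
    stop_at <- regexpr("*", prot, fixed = TRUE)
    if (stop_at > 0 && stop_at < nchar(prot)) {
      warning(sprintf("premature stop in %s consensus of %s at codon %d; truncating",
                      pcol, model$gene_id, stop_at))
      prot <- substr(prot, 1, stop_at - 1)
    } else if (stop_at == nchar(prot)) {
      prot <- substr(prot, 1, nchar(prot) - 1)  # trailing stop codon
    }
    prot
  }
  c(ALK = apply_pop("p_alk"), FW = apply_pop("p_fw"))
}
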