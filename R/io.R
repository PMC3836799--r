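# Plain-text interchange formats: phased-call TSV, phenotype/covariate TSV,
# dosage-matrix TSV, truth TSV, SNP VCF (via vcfR), TSS BED.

#' Write / read a phased-call table
#'
#' Long TSV with columns \code{subject_id}, \code{hap} (1 or 2),
#' \code{locus}, \code{allele}; one row per haplotype call.
#'
#' @param cohort an \code{hla_cohort}.
#' @param path output file.
#' @return \code{write_phased_calls}: the path, invisibly.
#' @export
write_phased_calls <- function(cohort, path) {
  n <- nrow(cohort$hap1); loci <- colnames(cohort$hap1)
  long <- rbind(
    data.frame(subject_id = rep(rownames(cohort$hap1), times = length(loci)),
               hap = 1L, locus = rep(loci, each = n),
               allele = as.vector(cohort$hap1), stringsAsFactors = FALSE),
    data.frame(subject_id = rep(rownames(cohort$hap2), times = length(loci)),
               hap = 2L, locus = rep(loci, each = n),
               allele = as.vector(cohort$hap2), stringsAsFactors = FALSE))
  long <- long[order(long$subject_id, long$locus, long$hap), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phased_calls
#' @param pheno phenotype data.frame as from [read_phenotype()]; when
#'   supplied, subjects are aligned to it.
#' @return \code{read_phased_calls}: an \code{hla_cohort} (no truth record).
#' @export
read_phased_calls <- function(path, pheno = NULL) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "hap", "locus", "allele")
  if (!all(need %in% names(long))) stopf("phased-call table needs columns %s",
                                         paste(need, collapse = ", "))
  subjects <- unique(long$subject_id)
  if (!is.null(pheno)) {
    if (!setequal(subjects, pheno$subject_id))
      stopf("subjects in calls and phenotype differ")
    subjects <- pheno$subject_id
  }
  loci <- unique(long$locus)
  mk <- function(h) {
    sub <- long[long$hap == h, ]
    m <- matrix(NA_character_, length(subjects), length(loci),
                dimnames = list(subjects, loci))
    m[cbind(match(sub$subject_id, subjects), match(sub$locus, loci))] <- sub$allele
    if (anyNA(m)) stopf("missing haplotype-%d call(s)", h)
    m
  }
  loci_tab <- data.frame(name = loci,
                         kind = ifelse(grepl("^(rs|snp_)", loci), "SNP", "HLA"),
                         position = NA_real_, stringsAsFactors = FALSE)
  structure(list(hap1 = mk(1L), hap2 = mk(2L),
                 pheno = pheno %||% data.frame(subject_id = subjects,
                                               stringsAsFactors = FALSE),
                 loci = loci_tab, truth = NULL),
            class = "hla_cohort")
}

#' Write / read the phenotype and covariate table
#'
#' TSV with columns \code{subject_id}, \code{status} (0/1), \code{stratum},
#' \code{PC1..PCk}.
#' @param cohort an \code{hla_cohort}; @param path file path.
#' @export
write_phenotype <- function(cohort, path) {
  utils::write.table(cohort$pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "status") %in% names(ph)))
    stopf("phenotype table needs subject_id and status")
  if (!all(ph$status %in% 0:1)) stopf("status must be 0/1")
  if (is.null(ph$stratum)) ph$stratum <- "all"
  ph
}

#' Write / read a dosage matrix TSV
#'
#' Variants as rows: metadata columns (\code{id}, \code{kind}, \code{locus},
#' \code{allele}, \code{group}, \code{position}, \code{frequency},
#' \code{info}) followed by one dosage column per subject.
#' @param dm a \code{dosage_matrix}; @param path file path.
#' @export
write_dosage_matrix <- function(dm, path) {
  meta <- dm$variants[c("id", "kind", "locus", "allele", "group", "position",
                        "frequency", "info")]
  d <- t(dm$dosages)
  colnames(d) <- rownames(dm$dosages) %||% sprintf("S%06d", seq_len(ncol(d)))
  utils::write.table(cbind(meta, as.data.frame(d)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_matrix
#' @export
read_dosage_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("id", "kind", "locus", "allele", "group", "position",
                 "frequency", "info")
  if (!all(meta_cols %in% names(tab))) stopf("not a dosage matrix TSV")
  d <- t(as.matrix(tab[setdiff(names(tab), meta_cols)]))
  colnames(d) <- tab$id
  dm <- new_dosage_matrix(d, tab[meta_cols])
  rownames(dm$dosages) <- rownames(d)
  dm
}

#' Write the simulation truth table
#'
#' TSV of the planted effects: \code{variant}, \code{log_odds}, \code{OR}.
#' @param cohort a simulated \code{hla_cohort}; @param path file path.
#' @export
write_truth <- function(cohort, path) {
  eff <- cohort$truth$effects
  utils::write.table(
    data.frame(variant = names(eff) %||% character(0),
               log_odds = as.numeric(eff), OR = exp(as.numeric(eff)),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNP markers from a VCF
#'
#' Converts phased GT calls into presence/absence dosage markers, one column
#' per allele of each record (REF and every ALT), grouped by SNP id —
#' multi-allelic records expand to one column per allele exactly like
#' classical HLA alleles. Positions are taken from POS (1-based).
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @return A \code{dosage_matrix} of kind \code{SNP}.
#' @export
read_snp_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) stopf("read_snp_vcf needs the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  parts <- list()
  for (i in seq_len(nrow(fix))) {
    id <- unname(fix[i, "ID"])
    if (is.na(id) || id == ".") id <- paste0("snp_", unname(fix[i, "POS"]))
    alleles <- unname(c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]))
    g <- gt[i, ]
    toks <- strsplit(g, "[|/]")
    idx1 <- as.integer(vapply(toks, `[`, "", 1L)) + 1L
    idx2 <- as.integer(vapply(toks, `[`, "", 2L)) + 1L
    if (anyNA(idx1) || anyNA(idx2)) stopf("missing GT in record %s", id)
    d <- sapply(seq_along(alleles), function(a) (idx1 == a) + (idx2 == a))
    d <- matrix(d, nrow = length(g))
    rownames(d) <- colnames(gt)
    parts[[i]] <- new_dosage_matrix(d, data.frame(
      id = paste0(id, "_", alleles), kind = "SNP", locus = id, allele = alleles,
      group = id, position = as.numeric(unname(fix[i, "POS"])),
      row.names = NULL, stringsAsFactors = FALSE))
  }
  do.call(cbind_dosage, parts)
}

#' Read a TSS BED file
#'
#' BED is 0-based half-open; the TSS is returned 1-based (\code{start + 1}).
#'
#' @param path BED file: chrom, start, end, name.
#' @return data.frame: \code{gene}, \code{chrom}, \code{tss}.
#' @export
read_tss_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stopf("BED needs chrom, start, end, name")
  data.frame(gene = bed[[4]], chrom = bed[[1]], tss = bed[[2]] + 1,
             stringsAsFactors = FALSE)
}

#' Write an expression matrix TSV
#' @param expr genes x subjects matrix; @param path file path.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(data.frame(gene = rownames(expr), expr,
                                check.names = FALSE, stringsAsFactors = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[-1])
  rownames(m) <- tab[[1]]
  m
}
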