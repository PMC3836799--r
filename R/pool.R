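#' Build a haplotype pool
#'
#' A haplotype pool is the population model from which phased MHC cohorts are
#' drawn: a finite set of extended haplotypes, each defining one classical
#' allele at every HLA locus and one base at every SNP, together with a
#' population frequency per haplotype. All linkage disequilibrium in the
#' simulated data (e.g. a DRB1*15:01--DQB1*06:02-style extended haplotype) is
#' encoded by which alleles co-occur on the same pool haplotypes.
#'
#' @param haplotypes data.frame of character allele labels, one row per
#'   haplotype, one column per locus or SNP.
#' @param frequencies numeric vector of haplotype frequencies; non-negative,
#'   summing to 1 within 1e-12.
#' @param loci optional data.frame with columns \code{name}, \code{kind}
#'   (\code{"HLA"} or \code{"SNP"}) and \code{position} (1-based hg18 bp for
#'   SNPs, \code{NA} for classical loci). When omitted, columns whose name
#'   starts with \code{"rs"} or \code{"snp_"} are taken as SNPs.
#' @return An object of class \code{hla_pool}.
#' @seealso [sample_cohort()], [default_mhc_pool()]
#' @examples
#' p <- build_haplotype_pool(
#'   data.frame(DRB1 = c("15:01", "03:01"), DQB1 = c("06:02", "02:01")),
#'   c(0.15, 0.85))
#' pool_allele_freq(p, "DRB1")
#' @export
build_haplotype_pool <- function(haplotypes, frequencies, loci = NULL) {
  haplotypes <- as.data.frame(haplotypes, stringsAsFactors = FALSE)
  if (nrow(haplotypes) == 0L) stopf("empty haplotype table")
  if (length(frequencies) != nrow(haplotypes))
    stopf("need one frequency per haplotype (%d haplotypes, %d frequencies)",
          nrow(haplotypes), length(frequencies))
  if (any(frequencies < 0)) stopf("negative haplotype frequency")
  if (abs(sum(frequencies) - 1) > 1e-12)
    stopf("haplotype frequencies must sum to 1 (got %.15g)", sum(frequencies))
  if (any(is.na(haplotypes)) || any(haplotypes == ""))
    stopf("every haplotype must define an allele at every locus")
  for (j in seq_along(haplotypes)) haplotypes[[j]] <- as.character(haplotypes[[j]])

  if (is.null(loci)) {
    nm <- names(haplotypes)
    loci <- data.frame(
      name = nm,
      kind = ifelse(grepl("^(rs|snp_)", nm), "SNP", "HLA"),
      position = NA_real_,
      stringsAsFactors = FALSE)
  } else {
    loci <- as.data.frame(loci, stringsAsFactors = FALSE)
    if (!all(c("name", "kind") %in% names(loci))) stopf("loci needs name and kind columns")
    if (is.null(loci$position)) loci$position <- NA_real_
    if (!setequal(loci$name, names(haplotypes)))
      stopf("loci table does not match haplotype columns")
    loci <- loci[match(names(haplotypes), loci$name), , drop = FALSE]
  }

  structure(
    list(haplotypes = haplotypes, frequencies = as.numeric(frequencies), loci = loci),
    class = "hla_pool")
}

#' @export
print.hla_pool <- function(x, ...) {
  cat(sprintf("Haplotype pool: %d haplotypes over %d loci (%d HLA, %d SNP)\n",
              nrow(x$haplotypes), nrow(x$loci),
              sum(x$loci$kind == "HLA"), sum(x$loci$kind == "SNP")))
  invisible(x)
}

#' Pool-implied allele frequencies at a locus
#'
#' The marginal frequency of each allele label at one locus: the sum of the
#' frequencies of the haplotypes carrying it.
#'
#' @param pool an \code{hla_pool}.
#' @param locus locus or SNP name (a haplotype column).
#' @return Named numeric vector of allele frequencies (sums to 1).
#' @export
pool_allele_freq <- function(pool, locus) {
  stopifnot(inherits(pool, "hla_pool"))
  if (!locus %in% names(pool$haplotypes)) stopf("unknown locus '%s'", locus)
  f <- tapply(pool$frequencies, pool$haplotypes[[locus]], sum)
  stats::setNames(as.numeric(f), names(f))[sort(names(f))]
}

#' Default synthetic MHC haplotype pool
#'
#' A fixed, deterministic pool of extended MHC haplotypes used as the standard
#' simulation condition of the package. It emulates the salient features of
#' European-ancestry MHC structure that the analysis methods rely on:
#' a DRB1*15:01 class II core in tight LD with DQA1*01:02 and DQB1*06:02 and
#' tagged by a SNP (\code{snp_32742280}); a spread of common DRB1/DQ cores;
#' class I (A, B) and DPB1 alleles recombined across class II cores so that
#' cross-locus LD is incomplete; and SNPs with intermediate frequencies, one
#' of them (\code{rs9277489}) in strong but imperfect LD with DPB1*03:01 and
#' one (\code{rs2516489}) largely independent of class II.
#'
#' Class II cores are each split over several class I / DPB1 / SNP backgrounds
#' (weights 0.5/0.3/0.2) so that no classical allele is a perfect proxy of an
#' allele at another locus unless stated: DQA1*01:02 and DQB1*06:02 also occur
#' on a DRB1*16:01 core, leaving them strong but imperfect tags of DRB1*15:01,
#' while \code{snp_32742280}'s A allele occurs only on 15:01 haplotypes
#' (a perfect proxy, r^2 = 1).
#'
#' @return An \code{hla_pool} over loci A, B, DRB1, DQA1, DQB1, DPB1 and five
#'   SNPs with hg18-style coordinates.
#' @export
default_mhc_pool <- function() {
  cores <- data.frame(
    DRB1 = c("15:01", "03:01", "04:01", "04:04", "13:03", "14:01", "01:01",
             "07:01", "11:01", "13:01", "08:01", "16:01", "12:01", "09:01"),
    DQA1 = c("01:02", "05:01", "03:01", "03:01", "05:05", "01:01", "01:01",
             "02:01", "05:05", "01:03", "04:01", "01:02", "05:05", "03:02"),
    DQB1 = c("06:02", "02:01", "03:02", "03:02", "03:01", "05:03", "05:01",
             "02:02", "03:01", "06:03", "04:02", "06:02", "03:01", "03:03"),
    freq = c(0.150, 0.110, 0.080, 0.040, 0.015, 0.020, 0.105,
             0.130, 0.100, 0.060, 0.030, 0.020, 0.080, 0.060),
    stringsAsFactors = FALSE)
  stopifnot(abs(sum(cores$freq) - 1) < 1e-12)

  # class I / DPB1 / SNP backgrounds assigned by cycling through per-column
  # allele lists with coprime periods, so no background allele is a perfect
  # proxy of another locus or of the class II cores
  A_list  <- c("01:01", "02:01", "03:01", "24:02", "02:01", "26:01", "02:01", "11:01")
  B_list  <- c("08:01", "07:02", "44:02", "35:01", "37:01", "38:01", "07:02")
  DP_list <- c("04:01", "02:01", "03:01", "04:02", "01:01")
  r25_list <- c("C", "T", "C", "T")
  bga_list <- c("A", "G", "A")
  bgb_list <- c("G", "A", "G", "A", "A")
  cyc <- function(lst, k, mult, off) lst[((mult * k + off) %% length(lst)) + 1L]

  w <- c(0.5, 0.3, 0.2)
  rows <- vector("list", nrow(cores) * length(w))
  k <- 0L
  for (i in seq_len(nrow(cores))) {
    for (j in seq_along(w)) {
      dp <- cyc(DP_list, k, 2L, 1L)
      rows[[k <- k + 1L]] <- data.frame(
        cores[i, c("DRB1", "DQA1", "DQB1")],
        A = cyc(A_list, k, 3L, 0L),
        B = cyc(B_list, k, 2L, 3L),
        DPB1 = dp,
        rs2516489 = cyc(r25_list, k, 1L, 2L),
        # tags DPB1*03:01 strongly but imperfectly
        rs9277489 = if (dp == "03:01" || (dp == "04:01" && k %% 7L == 0L)) "C" else "T",
        rs_bg_a = cyc(bga_list, k, 1L, 0L),
        rs_bg_b = cyc(bgb_list, k, 1L, 1L),
        snp_32742280 = if (cores$DRB1[i] == "15:01") "A" else "G",
        freq = cores$freq[i] * w[j],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  haps <- tab[, setdiff(names(tab), "freq")]
  loci <- data.frame(
    name = names(haps),
    kind = ifelse(grepl("^(rs|snp_)", names(haps)), "SNP", "HLA"),
    position = NA_real_,
    stringsAsFactors = FALSE)
  loci$position[match(c("snp_32742280", "rs2516489", "rs9277489", "rs_bg_a", "rs_bg_b"),
                      loci$name)] <- c(32742280, 31540000, 33161000, 30125000, 32410000)
  build_haplotype_pool(haps, tab$freq, loci)
}
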