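#' @title Dosage matrices of presence/absence markers
#' @description All variants — SNP alleles, two- and four-digit classical HLA
#'   alleles, amino-acid residues and diplotypes — are coded as biallelic
#'   presence/absence markers: the dosage of a marker is the number of the
#'   subject's two haplotypes carrying it (0, 1 or 2 for hard calls). A
#'   \code{dosage_matrix} holds the subjects x markers dosage matrix plus
#'   per-marker metadata (\code{id}, \code{kind}, \code{locus}, \code{allele},
#'   \code{group}, \code{position}, \code{frequency}, \code{info}). The
#'   \code{group} key names the omnibus-test unit: the SNP for SNP-allele
#'   columns, gene+position for amino-acid residues, the marker itself for
#'   classical alleles and diplotypes.
#' @param dosages numeric matrix, subjects x markers.
#' @param variants data.frame of marker metadata (one row per column).
#' @return A \code{dosage_matrix}.
#' @export
new_dosage_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(ncol(dosages) == nrow(variants))
  if (anyDuplicated(variants$id)) stopf("duplicate variant ids")
  for (col in c("locus", "allele", "group")) if (is.null(variants[[col]]))
    variants[[col]] <- NA_character_
  if (is.null(variants$position)) variants$position <- NA_real_
  variants$frequency <- colMeans(dosages) / 2
  if (is.null(variants$info)) variants$info <- NA_real_
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants), class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  tab <- table(x$variants$kind)
  cat(sprintf("Dosage matrix: %d subjects x %d markers (%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

# select marker columns by id, preserving metadata
dm_subset <- function(dm, ids) {
  idx <- match(ids, dm$variants$id)
  if (anyNA(idx)) stopf("unknown variant id(s): %s", paste(ids[is.na(idx)], collapse = ", "))
  new_dosage_matrix(dm$dosages[, idx, drop = FALSE], dm$variants[idx, , drop = FALSE])
}

#' Combine dosage matrices over the same subjects
#' @param ... \code{dosage_matrix} objects with equal subject sets.
#' @return A single \code{dosage_matrix}.
#' @export
cbind_dosage <- function(...) {
  dms <- list(...)
  dms <- dms[!vapply(dms, is.null, TRUE)]
  stopifnot(length(dms) > 0)
  n <- unique(vapply(dms, function(d) nrow(d$dosages), 1L))
  if (length(n) != 1L) stopf("subject counts differ")
  new_dosage_matrix(do.call(cbind, lapply(dms, `[[`, "dosages")),
                    do.call(rbind, lapply(dms, `[[`, "variants")))
}

#' Binarize classical HLA calls at one locus
#'
#' One presence/absence marker per observed four-digit allele; the dosage is
#' the number of haplotypes carrying the allele, so a heterozygote scores 1 on
#' two markers and a homozygote 2 on one. When per-call posteriors are
#' supplied the expected dosage is the sum of the posteriors of the calls of
#' that allele (the group-sum invariant then holds only in expectation).
#'
#' @param cohort an \code{hla_cohort} (phased, two haplotypes per subject).
#' @param locus classical locus name, e.g. \code{"DRB1"}.
#' @param posterior optional numeric matrix (subjects x 2) of per-call
#'   posterior probabilities in (0, 1].
#' @return A \code{dosage_matrix} of \code{HLA4d} markers.
#' @export
binarize_classical <- function(cohort, locus, posterior = NULL) {
  stopifnot(inherits(cohort, "hla_cohort"))
  if (!locus %in% colnames(cohort$hap1)) stopf("unknown locus '%s'", locus)
  a1 <- cohort$hap1[, locus]; a2 <- cohort$hap2[, locus]
  if (anyNA(a1) || anyNA(a2)) stopf("missing haplotype call at %s", locus)
  alleles <- sort(unique(c(a1, a2)))
  if (is.null(posterior)) posterior <- matrix(1, length(a1), 2)
  stopifnot(all(posterior > 0), all(posterior <= 1))
  d <- sapply(alleles, function(a) {
    (a1 == a) * posterior[, 1] + (a2 == a) * posterior[, 2]
  })
  d <- matrix(d, nrow = length(a1))
  ids <- paste0(locus, "*", alleles)
  new_dosage_matrix(d, data.frame(
    id = ids, kind = "HLA4d", locus = locus, allele = alleles, group = ids,
    position = NA_real_, stringsAsFactors = FALSE))
}

#' Binarize SNP alleles
#'
#' Multi-allelic SNPs are expanded exactly like classical alleles: one
#' presence/absence column per observed base, grouped under the SNP id so that
#' the omnibus test spans all but the reference base.
#'
#' @param cohort an \code{hla_cohort}.
#' @param snps SNP column names; default all SNP loci of the cohort.
#' @return A \code{dosage_matrix} of \code{SNP} markers, or \code{NULL} if
#'   there are none.
#' @export
binarize_snps <- function(cohort, snps = NULL) {
  stopifnot(inherits(cohort, "hla_cohort"))
  if (is.null(snps)) snps <- cohort$loci$name[cohort$loci$kind == "SNP"]
  if (length(snps) == 0L) return(NULL)
  parts <- lapply(snps, function(s) {
    a1 <- cohort$hap1[, s]; a2 <- cohort$hap2[, s]
    alleles <- sort(unique(c(a1, a2)))
    d <- matrix(sapply(alleles, function(a) (a1 == a) + (a2 == a)), nrow = length(a1))
    pos <- cohort$loci$position[match(s, cohort$loci$name)]
    new_dosage_matrix(d, data.frame(
      id = paste0(s, "_", alleles), kind = "SNP", locus = s, allele = alleles,
      group = s, position = pos, stringsAsFactors = FALSE))
  })
  do.call(cbind_dosage, parts)
}

#' Roll four-digit alleles up to two-digit resolution
#'
#' The two-digit (allele family) dosage is the elementwise sum of its
#' four-digit members' dosages.
#'
#' @param dm a \code{dosage_matrix} containing \code{HLA4d} markers.
#' @return A \code{dosage_matrix} of \code{HLA2d} markers.
#' @export
rollup_two_digit <- function(dm) {
  v <- dm$variants
  four <- which(v$kind == "HLA4d")
  if (length(four) == 0L) stopf("no four-digit markers present")
  fam <- sub(":.*$", "", v$allele[four])
  if (any(!grepl("^[0-9]+:[0-9]+", v$allele[four])))
    stopf("malformed four-digit allele label")
  key <- paste0(v$locus[four], "*", fam)
  groups <- split(four, key)
  d <- sapply(groups, function(ix) rowSums(dm$dosages[, ix, drop = FALSE]))
  d <- matrix(d, nrow = nrow(dm$dosages))
  if (any(d > 2 + 1e-9)) stopf("two-digit dosage exceeds 2; calls inconsistent")
  ids <- names(groups)
  new_dosage_matrix(d, data.frame(
    id = ids, kind = "HLA2d", locus = sub("\\*.*$", "", ids),
    allele = sub("^.*\\*", "", ids), group = ids, position = NA_real_,
    stringsAsFactors = FALSE))
}

#' Amino-acid dictionary
#'
#' Maps (gene, four-digit allele, position) to a residue symbol; the single
#' source of truth for classical-allele-to-amino-acid translation. Positions
#' are integers in mature-protein numbering and may be negative for the
#' leader peptide.
#'
#' @param x data.frame with columns \code{gene}, \code{allele},
#'   \code{position}, \code{residue}.
#' @return An object of class \code{aa_dictionary}.
#' @export
aa_dictionary <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("gene", "allele", "position", "residue")
  if (!all(need %in% names(x))) stopf("dictionary needs columns %s", paste(need, collapse = ", "))
  x$position <- as.integer(x$position)
  if (anyDuplicated(x[c("gene", "allele", "position")]))
    stopf("duplicate (gene, allele, position) entries")
  structure(x[need], class = c("aa_dictionary", "data.frame"))
}

#' Read an amino-acid dictionary TSV
#' @param path TSV with header gene, allele, position, residue.
#' @return An \code{aa_dictionary}.
#' @export
read_aa_dictionary <- function(path) {
  aa_dictionary(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Translate classical-allele dosages to amino-acid residue dosages
#'
#' The residue dosage at a position is the sum of the dosages of the
#' four-digit alleles carrying that residue, i.e. a fixed 0/1 linear map of
#' the classical-allele dosages. Positions carrying a single residue across
#' all alleles are monomorphic and dropped. Alleles absent from the dictionary
#' are an error (never silently dropped).
#'
#' @param dm \code{dosage_matrix} with the gene's \code{HLA4d} markers.
#' @param dict an [aa_dictionary()].
#' @param gene gene name, e.g. \code{"DRB1"}.
#' @return A \code{dosage_matrix} of \code{AA} markers with ids like
#'   \code{"DRB1_pos71_Lys"}, grouped by \code{"DRB1_pos71"}.
#' @export
translate_to_amino_acids <- function(dm, dict, gene) {
  stopifnot(inherits(dict, "aa_dictionary"))
  v <- dm$variants
  ix <- which(v$kind == "HLA4d" & v$locus == gene)
  if (length(ix) == 0L) stopf("no four-digit markers for gene '%s'", gene)
  dd <- dict[dict$gene == gene, , drop = FALSE]
  missing <- setdiff(v$allele[ix], unique(dd$allele))
  if (length(missing))
    stopf("allele(s) missing from dictionary for %s: %s", gene,
          paste(missing, collapse = ", "))
  positions <- sort(unique(dd$position))
  parts <- list()
  for (p in positions) {
    dp <- dd[dd$position == p, ]
    res <- dp$residue[match(v$allele[ix], dp$allele)]
    if (anyNA(res))
      stopf("dictionary for %s position %d does not cover allele(s): %s", gene, p,
            paste(v$allele[ix][is.na(res)], collapse = ", "))
    if (length(unique(res)) < 2L) next  # monomorphic position
    resl <- sort(unique(res))
    d <- sapply(resl, function(r) rowSums(dm$dosages[, ix[res == r], drop = FALSE]))
    d <- matrix(d, nrow = nrow(dm$dosages))
    parts[[as.character(p)]] <- new_dosage_matrix(d, data.frame(
      id = sprintf("%s_pos%d_%s", gene, p, resl), kind = "AA", locus = gene,
      allele = resl, group = sprintf("%s_pos%d", gene, p), position = p,
      stringsAsFactors = FALSE))
  }
  if (length(parts) == 0L) stopf("all positions monomorphic for gene '%s'", gene)
  do.call(cbind_dosage, parts)
}

#' Cis diplotype dosage for an allele pair
#'
#' Counts, per subject, the haplotypes that carry both named alleles in cis;
#' a subject carrying the two alleles in trans scores 0. Requires phased
#' calls.
#'
#' @param cohort an \code{hla_cohort}.
#' @param idA,idB classical-allele marker ids, e.g. \code{"DRB1*15:01"} and
#'   \code{"DQB1*06:02"}.
#' @return A one-column \code{dosage_matrix} of kind \code{DIPLOTYPE}.
#' @export
build_diplotype <- function(cohort, idA, idB) {
  stopifnot(inherits(cohort, "hla_cohort"))
  split_id <- function(id) {
    la <- strsplit(id, "*", fixed = TRUE)[[1]]
    if (length(la) != 2L) stopf("expected a 'LOCUS*allele' id, got '%s'", id)
    la
  }
  a <- split_id(idA); b <- split_id(idB)
  for (loc in c(a[1], b[1])) if (!loc %in% colnames(cohort$hap1))
    stopf("unknown locus '%s'", loc)
  cis1 <- (cohort$hap1[, a[1]] == a[2]) & (cohort$hap1[, b[1]] == b[2])
  cis2 <- (cohort$hap2[, a[1]] == a[2]) & (cohort$hap2[, b[1]] == b[2])
  id <- paste0(idA, "-", idB)
  new_dosage_matrix(matrix(as.numeric(cis1) + as.numeric(cis2)), data.frame(
    id = id, kind = "DIPLOTYPE", locus = paste(a[1], b[1], sep = "-"),
    allele = paste(a[2], b[2], sep = "-"), group = id, position = NA_real_,
    stringsAsFactors = FALSE))
}

#' Minor-allele-frequency filter
#'
#' Removes markers whose minor allele frequency is strictly below the
#' threshold (a marker at exactly the threshold is retained). The removed
#' markers are recorded in the \code{"filter_log"} attribute of the result.
#'
#' @param dm a \code{dosage_matrix}.
#' @param threshold MAF threshold, default 0.01 (1\%).
#' @return The filtered \code{dosage_matrix}.
#' @export
maf_filter <- function(dm, threshold = 0.01) {
  f <- dm$variants$frequency
  maf <- pmin(f, 1 - f)
  drop <- maf < threshold
  log_df <- data.frame(id = dm$variants$id[drop], frequency = f[drop],
                       maf = maf[drop], stringsAsFactors = FALSE)
  out <- new_dosage_matrix(dm$dosages[, !drop, drop = FALSE],
                           dm$variants[!drop, , drop = FALSE])
  attr(out, "filter_log") <- log_df
  out
}

#' Imputation INFO score of a dosage column
#'
#' The ratio of the observed dosage variance to the variance expected under
#' Hardy-Weinberg at the allele frequency, \eqn{2f(1-f)}. Hard calls at
#' Hardy-Weinberg equilibrium give values near 1; shrunken expected dosages
#' give values below 1.
#'
#' @param x dosage vector in \[0, 2\].
#' @param frequency allele frequency in (0, 1); default estimated as
#'   \code{mean(x)/2}.
#' @return The INFO ratio.
#' @export
info_score <- function(x, frequency = mean(x) / 2) {
  if (frequency <= 0 || frequency >= 1) stopf("monomorphic column: frequency must be in (0,1)")
  n <- length(x)
  obs <- sum((x - mean(x))^2) / n
  obs / (2 * frequency * (1 - frequency))
}

#' Encode a phased cohort into the full analysis marker set
#'
#' Runs the standard encoding path: four-digit classical markers per HLA
#' locus, two-digit rollups, amino-acid translation for genes covered by the
#' dictionary, SNP allele expansion, then the MAF filter. INFO scores are
#' attached to every marker.
#'
#' @param cohort an \code{hla_cohort}.
#' @param dict optional [aa_dictionary()].
#' @param maf MAF threshold (strict less-than removal); \code{NULL} to skip.
#' @param two_digit include two-digit rollup markers.
#' @return A \code{dosage_matrix}.
#' @export
encode_cohort <- function(cohort, dict = NULL, maf = 0.01, two_digit = TRUE) {
  stopifnot(inherits(cohort, "hla_cohort"))
  hla_loci <- cohort$loci$name[cohort$loci$kind == "HLA"]
  parts <- lapply(hla_loci, function(l) binarize_classical(cohort, l))
  dm4 <- do.call(cbind_dosage, parts)
  out <- dm4
  if (two_digit) out <- cbind_dosage(out, rollup_two_digit(dm4))
  if (!is.null(dict)) {
    for (g in intersect(unique(dict$gene), hla_loci))
      out <- cbind_dosage(out, translate_to_amino_acids(dm4, dict, g))
  }
  snps <- binarize_snps(cohort)
  if (!is.null(snps)) out <- cbind_dosage(out, snps)
  out$variants$info <- vapply(seq_len(ncol(out$dosages)), function(j) {
    f <- out$variants$frequency[j]
    if (f <= 0 || f >= 1) NA_real_ else info_score(out$dosages[, j], f)
  }, 1)
  if (!is.null(maf)) out <- maf_filter(out, maf)
  out
}
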