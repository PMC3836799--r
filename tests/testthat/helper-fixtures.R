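# Shared in-code fixtures: tiny pools, cohorts and dictionaries built fresh
# at test time.

# two-haplotype pool: perfect DRB1-DQB1 LD
pool_two_hap <- function(f = 0.15) {
  build_haplotype_pool(
    data.frame(DRB1 = c("15:01", "03:01"), DQB1 = c("06:02", "02:01"),
               stringsAsFactors = FALSE),
    c(f, 1 - f))
}

# four-haplotype pool breaking LD: DRB1*15:01 sits on two different DQB1
# backgrounds
pool_four_hap <- function() {
  build_haplotype_pool(
    data.frame(DRB1 = c("15:01", "15:01", "03:01", "01:01"),
               DQB1 = c("06:02", "05:01", "02:01", "05:01"),
               stringsAsFactors = FALSE),
    c(0.25, 0.25, 0.25, 0.25))
}

# small null cohort over the two-locus pool
cohort_null <- function(n = 400, seed = 1, pool = pool_two_hap(), n_pcs = 0) {
  cfg <- simulation_config(
    strata = data.frame(name = "S1", n = n, intercept = 0),
    n_pcs = n_pcs, seed = seed)
  sample_cohort(pool, cfg)
}

# marker ids that are perfect (r^2 = 1) proxies of a given marker column
equivalent_markers_of <- function(dm, id) {
  x <- dm$dosages[, id]
  r2 <- suppressWarnings(cor(x, dm$dosages))^2
  ids <- dm$variants$id[which(r2 > 1 - 1e-12)]
  unique(dm$variants$group[match(ids, dm$variants$id)])
}

# TRUE per truth marker if the scan selected its group or a perfect proxy
selection_covers <- function(dm, sc, truth_ids) {
  vapply(truth_ids, function(t) {
    any(sc$selected %in% equivalent_markers_of(dm, t))
  }, TRUE)
}

# hand-built phased cohort from explicit haplotype label matrices
make_cohort <- function(hap1, hap2, status = NULL, stratum = "S1") {
  n <- nrow(hap1)
  loci <- data.frame(name = colnames(hap1),
                     kind = ifelse(grepl("^(rs|snp_)", colnames(hap1)), "SNP", "HLA"),
                     position = NA_real_, stringsAsFactors = FALSE)
  pheno <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                      status = status %||% rep(0L, n),
                      stratum = rep_len(stratum, n), stringsAsFactors = FALSE)
  rownames(hap1) <- rownames(hap2) <- pheno$subject_id
  structure(list(hap1 = hap1, hap2 = hap2, pheno = pheno, loci = loci, truth = NULL),
            class = "hla_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# toy amino-acid dictionary over the two-locus pool's DRB1 alleles
dict_toy <- function() {
  aa_dictionary(data.frame(
    gene = "DRB1",
    allele = c("15:01", "03:01", "15:01", "03:01"),
    position = c(71L, 71L, 86L, 86L),
    residue = c("Ala", "Lys", "Val", "Val")))
}

# dictionary for the default pool's DRB1 alleles (shipped fixture)
dict_default <- function() {
  read_aa_dictionary(system.file("extdata", "drb1_aa_synthetic.tsv",
                                 package = "hlafinemap"))
}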