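# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

two_sided <- function(z) pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A small long-format summary-statistics file for 2 variants x 3 traits.
make_summary_fixture <- function(path = tempfile(fileext = ".tsv")) {
  df <- data.frame(
    variant_id = rep(c("rs1", "rs2"), each = 3),
    trait_id = rep(c("T1", "T2", "T3"), 2),
    beta = c(0.2, -0.1, 0.05, 0.0, 0.3, -0.2),
    se = c(0.1, 0.1, 0.05, 0.1, 0.15, 0.1))
  df$z <- df$beta / df$se
  df$pval <- two_sided(df$z)
  write_tsv(df, path)
}

make_meta3 <- function() {
  list(trait_meta("T1", "continuous", 1000),
       trait_meta("T2", "continuous", 1000),
       trait_meta("T3", "continuous", 1000))
}

# Null panel with K SNPs whose z columns have correlation R_true.
make_null_panel <- function(K, R_true, seed = 1) {
  p <- nrow(R_true)
  z <- withr_seed(seed, matrix(rnorm(K * p), K, p) %*% chol(R_true))
  null_z_panel(paste0("snp", seq_len(K)), paste0("T", seq_len(p)), z)
}

# Minimal local stand-in for withr::with_seed (withr is available but this
# keeps the helper self-contained).
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Small uncompressed VCF with 2 samples and the given biallelic records.
make_vcf_fixture <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=1000000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT", "0/1", "1/1",
          sep = "\t"),
    paste("1", "200", "rs2", "T", "C", ".", "PASS", ".", "GT", "0/0", "0/1",
          sep = "\t"),
    paste("1", "300", "rs3", "G", "C", ".", "PASS", ".", "GT", "1/1", "0/0",
          sep = "\t"))
  writeLines(lines, path)
  path
}

make_weights_fixture <- function(path = tempfile(fileext = ".tsv"),
                                 weights = c(0.5, -0.2, 0.1)) {
  df <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                   effect_allele = c("G", "C", "G"),
                   other_allele = c("A", "T", "C"),
                   weight = weights)
  write_tsv(df, path)
}
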