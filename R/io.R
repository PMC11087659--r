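# Readers and writers for the external formats: long-format per-trait GWAS
# summary statistics, null-SNP z panels, score weight tables, and reference
# genotypes (VCF or dosage TSV). All tab-delimited with header rows.

#' Describe one trait's metadata
#'
#' Holds the per-trait sample sizes and type needed to interpret summary
#' statistics: total sample size `n` for the score-level regressions, and
#' case/control counts for binary traits (used by the logistic-to-linear
#' conversion factor r/(1+r)^2 with r = n_control/n_case).
#'
#' @param trait_id Trait identifier string.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param n Total sample size.
#' @param n_case,n_control Case/control counts; required for binary traits
#'   (they must sum to `n`), disallowed for continuous ones.
#' @return An object of class `trait_meta`.
#' @export
#' @examples
#' trait_meta("height", "continuous", n = 5000)
#' trait_meta("asthma", "binary", n = 3000, n_case = 1000, n_control = 2000)
trait_meta <- function(trait_id, trait_type = c("continuous", "binary"),
                       n, n_case = NULL, n_control = NULL) {
  trait_type <- match.arg(trait_type)
  if (!is_string(trait_id)) stop_validation("trait_id must be a string")
  n <- assert_count(n, "n", min = 1L)
  if (trait_type == "binary") {
    if (is.null(n_case) || is.null(n_control))
      stop_validation(sprintf("binary trait '%s' needs n_case and n_control",
                              trait_id))
    n_case <- assert_count(n_case, "n_case", min = 1L)
    n_control <- assert_count(n_control, "n_control", min = 1L)
    if (n_case + n_control != n)
      stop_validation(sprintf("trait '%s': n_case + n_control != n", trait_id))
  } else if (!is.null(n_case) || !is.null(n_control)) {
    stop_validation(sprintf(
      "continuous trait '%s' must not carry n_case/n_control", trait_id))
  }
  structure(list(trait_id = trait_id, trait_type = trait_type, n = n,
                 n_case = n_case, n_control = n_control),
            class = "trait_meta")
}

#' Construct a per-variant z-score vector
#'
#' @param variant_id Variant identifier.
#' @param trait_ids Ordered trait identifiers (length p).
#' @param z Numeric z-scores, same length; `NA` marks a trait with no usable
#'   statistic for this variant (dropped, with a warning, at scan time).
#' @return An object of class `zvec`.
#' @export
zvec <- function(variant_id, trait_ids, z) {
  if (!is_string(variant_id)) stop_validation("variant_id must be a string")
  if (length(trait_ids) != length(z))
    stop_validation("trait_ids and z must have the same length")
  if (anyDuplicated(trait_ids))
    stop_validation("duplicated trait ids in zvec")
  structure(list(variant_id = variant_id,
                 trait_ids = as.character(trait_ids),
                 z = as.numeric(z)),
            class = "zvec")
}

#' @export
print.zvec <- function(x, ...) {
  cat(sprintf("<zvec> variant %s, %d traits, %d missing\n",
              x$variant_id, length(x$z), sum(is.na(x$z))))
  invisible(x)
}

#' Read long-format GWAS summary statistics
#'
#' The canonical input: one row per (variant, trait) pair, tab-delimited with
#' a header. Required columns are `variant_id`, `trait_id`, and either both
#' `beta` and `se` or `z`; optional `pval`, `effect_allele`, `other_allele`.
#' `z` is derived as `beta/se` when absent. Rows whose `z` disagrees with
#' `beta/se`, or whose `pval` disagrees with the two-sided normal tail of
#' `z`, beyond `tol` (relative) are a validation error.
#'
#' @param path Path to the TSV file.
#' @param meta List of [trait_meta()] objects fixing trait order and identity.
#' @param tol Relative consistency tolerance for z vs beta/se and pval vs z.
#' @return List with `zvectors` (named list of [zvec()], one per variant,
#'   traits ordered as in `meta`; traits absent for a variant are `NA`),
#'   `records` (the cleaned data.frame) and `report` (data.frame of dropped
#'   rows and reasons).
#' @export
read_summary_long <- function(path, meta, tol = 1e-6) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  if (inherits(meta, "trait_meta")) meta <- list(meta)
  trait_ids <- vapply(meta, function(m) m$trait_id, character(1))
  if (anyDuplicated(trait_ids)) stop_validation("duplicate trait in meta")
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("variant_id", "trait_id")
  if (!all(need %in% names(df)))
    stop_format("missing required columns: variant_id, trait_id")
  has_bs <- all(c("beta", "se") %in% names(df))
  has_z <- "z" %in% names(df)
  if (!has_bs && !has_z)
    stop_format("need columns (beta, se) or z")

  unknown <- setdiff(unique(df$trait_id), trait_ids)
  if (length(unknown))
    stop_validation(sprintf("trait(s) in file but not in meta: %s",
                            paste(unknown, collapse = ", ")))
  key <- paste(df$variant_id, df$trait_id, sep = "\r")
  if (anyDuplicated(key))
    stop_validation(sprintf("duplicate (variant, trait) pair(s): %s",
      paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", ")))

  if (has_bs && any(!is.na(df$se) & df$se <= 0))
    stop_validation("non-positive se encountered")
  z <- if (has_z) as.numeric(df$z) else rep(NA_real_, nrow(df))
  if (has_bs) {
    zbs <- as.numeric(df$beta) / as.numeric(df$se)
    both <- !is.na(z) & !is.na(zbs)
    bad <- both & abs(z - zbs) > tol * pmax(1, abs(z))
    if (any(bad))
      stop_validation(sprintf("z inconsistent with beta/se on %d row(s)",
                              sum(bad)))
    z[is.na(z)] <- zbs[is.na(z)]
  }
  if ("pval" %in% names(df)) {
    pv <- as.numeric(df$pval)
    if (any(!is.na(pv) & (pv <= 0 | pv > 1)))
      stop_validation("pval outside (0, 1]")
    both <- !is.na(z) & !is.na(pv)
    bad <- both & abs(pv - two_sided_p(z)) > tol * pmax(1, pv)
    if (any(bad))
      stop_validation(sprintf(
        "pval inconsistent with two-sided tail of z on %d row(s)", sum(bad)))
  }

  drop <- is.na(z)
  report <- data.frame(row = which(drop),
                       variant_id = df$variant_id[drop],
                       trait_id = df$trait_id[drop],
                       reason = rep("no z and no usable beta/se", sum(drop)),
                       stringsAsFactors = FALSE)
  keep <- df[!drop, c("variant_id", "trait_id"), drop = FALSE]
  keep$z <- z[!drop]

  zvectors <- lapply(split(keep, keep$variant_id), function(d) {
    zv <- rep(NA_real_, length(trait_ids))
    zv[match(d$trait_id, trait_ids)] <- d$z
    zvec(d$variant_id[1], trait_ids, zv)
  })
  list(zvectors = zvectors, records = keep, report = report)
}

#' Read a wide z-score matrix (convenience)
#'
#' First column `variant_id`, remaining columns one per trait.
#' @param path Path to the TSV file.
#' @return Named list of [zvec()] objects.
#' @export
read_wide_z <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop_format("wide z table needs variant_id + >=1 trait")
  ids <- as.character(df[[1]])
  traits <- names(df)[-1]
  out <- lapply(seq_along(ids), function(i)
    zvec(ids[i], traits, as.numeric(df[i, -1])))
  names(out) <- ids
  out
}

#' Write z-vectors as a wide TSV (round-trips with [read_wide_z()])
#' @param zvectors List of [zvec()] with identical trait order.
#' @param path Output path.
#' @export
write_wide_z <- function(zvectors, path) {
  if (inherits(zvectors, "zvec")) zvectors <- list(zvectors)
  traits <- zvectors[[1]]$trait_ids
  for (zv in zvectors)
    if (!identical(zv$trait_ids, traits))
      stop_validation("all zvecs must share trait order")
  m <- do.call(rbind, lapply(zvectors, function(zv) zv$z))
  df <- data.frame(variant_id = vapply(zvectors, `[[`, "", "variant_id"), m,
                   check.names = FALSE)
  names(df) <- c("variant_id", traits)
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a null-SNP z panel
#'
#' Tab-delimited; first column `snp_id`, remaining columns one per trait.
#' Empty cells (or `NA`) are missing values. Needs at least two SNPs and at
#' least two non-missing z-scores per trait.
#'
#' @param path Path to the TSV file.
#' @return An object of class `null_z_panel` with elements `snp_ids`,
#'   `trait_ids`, `z` (K x p matrix), `n_missing` (per-trait missing counts).
#' @export
read_null_panel <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2) stop_format("null panel needs snp_id + >=1 trait column")
  z <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(z) <- "double"
  panel <- null_z_panel(as.character(df[[1]]), colnames(z), z)
  panel
}

#' Construct a null-SNP z panel in memory
#' @param snp_ids SNP identifiers (length K >= 2).
#' @param trait_ids Trait identifiers (length p).
#' @param z K x p numeric matrix of null-SNP z-scores; `NA` = missing.
#' @return Object of class `null_z_panel`.
#' @export
null_z_panel <- function(snp_ids, trait_ids, z) {
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  if (length(snp_ids) < 2)
    ps_stop("null panel needs at least 2 SNPs", "pleioscan_insufficient_data")
  if (nrow(z) != length(snp_ids) || ncol(z) != length(trait_ids))
    stop_validation("panel dimensions do not match snp/trait ids")
  nm <- colSums(is.na(z))
  if (any(nrow(z) - nm < 2))
    ps_stop(sprintf("trait(s) with <2 non-missing z: %s",
                    paste(trait_ids[nrow(z) - nm < 2], collapse = ", ")),
            "pleioscan_insufficient_data")
  dimnames(z) <- list(snp_ids, trait_ids)
  structure(list(snp_ids = as.character(snp_ids),
                 trait_ids = as.character(trait_ids),
                 z = z, n_missing = nm),
            class = "null_z_panel")
}

#' Write a null panel TSV (round-trips with [read_null_panel()])
#' @param panel A `null_z_panel`.
#' @param path Output path.
#' @export
write_null_panel <- function(panel, path) {
  df <- data.frame(snp_id = panel$snp_ids, panel$z, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read genetic-score weights
#'
#' Columns: `variant_id`, `effect_allele`, `other_allele`, `weight`.
#' Zero-weight rows are dropped with a warning; an all-zero score is an error.
#'
#' @param path Path to the TSV file.
#' @return data.frame of retained weights (class `score_weights`).
#' @export
read_score_weights <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "weight")
  if (!all(need %in% names(df)))
    stop_format(sprintf("weights file needs columns: %s",
                        paste(need, collapse = ", ")))
  if (anyDuplicated(df$variant_id))
    stop_validation(sprintf("duplicate variant_id in weights: %s",
      paste(unique(df$variant_id[duplicated(df$variant_id)]), collapse = ", ")))
  w <- as.numeric(df$weight)
  if (all(w == 0))
    ps_stop("all score weights are zero", "pleioscan_empty_score_error")
  if (any(w == 0)) {
    warning(sprintf("dropping %d zero-weight SNP(s)", sum(w == 0)))
    df <- df[w != 0, , drop = FALSE]
  }
  df <- df[, need]
  class(df) <- c("score_weights", "data.frame")
  df
}

# Strand-ambiguous (palindromic) allele pairs.
.ambiguous_pair <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Read reference-panel genotypes as effect-allele dosages
#'
#' Accepts a VCF (hard genotypes; dosage = count of effect alleles, biallelic
#' sites only; the `DS` FORMAT field is honoured when present) or a
#' tab-delimited dosage table whose header row is variant ids (one row per
#' individual, already coded as effect-allele counts). For VCF input, alleles
#' are harmonized against the score's effect allele: when the score's
#' effect/other alleles are swapped relative to ALT/REF, dosage d becomes
#' 2 - d. Strand-ambiguous (A/T, C/G) sites are kept with a warning.
#'
#' @param path VCF (`.vcf`) or dosage TSV path.
#' @param score A `score_weights` data.frame (provides variant ids + alleles).
#' @param format `"auto"` (by extension), `"vcf"`, or `"dosage"`.
#' @return Numeric matrix, individuals x q, columns ordered as in `score`.
#' @export
read_reference_panel <- function(path, score, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  ids <- score$variant_id
  if (any(.ambiguous_pair(score$effect_allele, score$other_allele)))
    warning("strand-ambiguous (A/T or C/G) score SNP(s) kept as-is")
  if (format == "dosage") {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
    missing <- setdiff(ids, names(df))
    if (length(missing))
      ps_stop(sprintf("variant(s) absent from reference panel: %s",
                      paste(missing, collapse = ", ")),
              "pleioscan_lookup_error")
    d <- as.matrix(df[, ids, drop = FALSE])
    storage.mode(d) <- "double"
  } else {
    d <- .read_vcf_dosage(path, score)
  }
  if (any(d < 0 | d > 2, na.rm = TRUE))
    stop_validation("dosages outside [0, 2]")
  d
}

.read_vcf_dosage <- function(path, score) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_format("VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rn <- rownames(vcf)
  ids <- score$variant_id
  missing <- setdiff(ids, rn)
  if (length(missing))
    ps_stop(sprintf("variant(s) absent from reference panel: %s",
                    paste(missing, collapse = ", ")), "pleioscan_lookup_error")
  vcf <- vcf[match(ids, rn), ]
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  if (any(lengths(altl) != 1))
    stop_validation("only biallelic VCF records are supported")
  alt <- vapply(seq_along(altl), function(i) as.character(altl[[i]][1]), "")
  gen <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gen)) {
    d <- t(matrix(as.numeric(gen$DS), nrow = nrow(gen$DS)))
  } else {
    gt <- gen$GT
    cnt <- function(g) {
      ifelse(g %in% c("0/0", "0|0"), 0,
        ifelse(g %in% c("0/1", "1/0", "0|1", "1|0"), 1,
          ifelse(g %in% c("1/1", "1|1"), 2, NA_real_)))
    }
    d <- t(apply(gt, 1, cnt))
    d <- matrix(as.numeric(d), nrow = nrow(gt))
    d <- t(d)
  }
  # d is individuals x q at this point
  for (l in seq_along(ids)) {
    ea <- toupper(score$effect_allele[l]); oa <- toupper(score$other_allele[l])
    if (ea == toupper(alt[l]) && oa == toupper(ref[l])) {
      # already counting effect alleles
    } else if (ea == toupper(ref[l]) && oa == toupper(alt[l])) {
      d[, l] <- 2 - d[, l]
    } else {
      stop_validation(sprintf(
        "alleles for %s (%s/%s) do not match reference panel (%s/%s)",
        ids[l], ea, oa, ref[l], alt[l]))
    }
  }
  colnames(d) <- ids
  d
}

#' Flip a dosage vector to the opposite allele coding
#' @param d Dosages in \[0, 2\].
#' @return `2 - d`.
#' @export
flip_dosage <- function(d) 2 - d

#' Write a scan result as JSON plus a flat per-trait TSV
#' @param result A `scan_result` from [scan_and_test()].
#' @param json_path Output JSON path (full result).
#' @param tsv_path Optional output TSV path (one row per selected trait).
#' @export
write_scan_result <- function(result, json_path, tsv_path = NULL) {
  jsonlite::write_json(unclass(result), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  if (!is.null(tsv_path)) {
    sel <- result$S_combined
    df <- data.frame(variant_id = result$variant_id,
                     trait_id = result$trait_ids[sel],
                     trait_index = sel,
                     winner = result$winner,
                     p_combined = result$p_combined)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}
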