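#' Read a multi-sample VCF into a cohort object
#'
#' Parses a VCF 4.x file (plain or bgzipped) with per-genotype `GT` (and,
#' when present, `DP`) into a `cohort_vcf`: a site table plus aligned
#' genotype/depth matrices. Records are kept in file order. Multiallelic
#' records are decomposed into one pseudo-record per alternate allele; in a
#' pseudo-record, alleles equal to another alternate are set missing (the
#' resulting half-call is treated as a missing genotype, as are half-calls in
#' the input). Non-SNP alternates (indels, symbolic, `*`) are dropped and
#' tallied in `attr(x, "n_dropped_nonsnp")`.
#'
#' @param vcf Path to a VCF file.
#' @return A `cohort_vcf` object: list with
#'   `sites` (tibble: `chrom`, `pos`, `ref`, `alt`, `qual`),
#'   `a1`/`a2` (integer site x sample matrices of allele codes, 0 = ref,
#'   1 = alt, `NA` = missing),
#'   `dp` (numeric site x sample depth matrix, `NA` where absent) and
#'   `samples` (ordered sample ids).
#' @export
read_vcf <- function(vcf) {
  if (!file.exists(vcf)) stop("VCF file not found: ", vcf, call. = FALSE)
  v <- tryCatch(
    vcfR::read.vcfR(vcf, verbose = FALSE),
    error = function(e) stop("malformed VCF (", conditionMessage(e), ")",
                             call. = FALSE)
  )
  if (nrow(v@fix) == 0L) stop("VCF contains no records: ", vcf, call. = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns: ", vcf, call. = FALSE)
  fmt <- v@gt[, 1]
  if (!all(grepl("(^|:)GT($|:)", fmt))) {
    stop("VCF records lack the GT format field", call. = FALSE)
  }
  samples <- colnames(v@gt)[-1]

  gt <- vcfR::extract.gt(v, element = "GT")
  has_dp <- any(grepl("(^|:)DP($|:)", fmt))
  dp <- if (has_dp) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  } else {
    matrix(NA_real_, nrow = nrow(gt), ncol = length(samples))
  }

  sites <- tibble::tibble(
    chrom = as.character(v@fix[, "CHROM"]),
    pos = as.integer(v@fix[, "POS"]),
    ref = as.character(v@fix[, "REF"]),
    alt = as.character(v@fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(v@fix[, "QUAL"]))
  )

  # split GT strings once: unphased or phased separators both accepted
  a_raw <- strsplit(as.vector(gt), "[/|]")
  allele_code <- function(i) {
    vapply(a_raw, function(x) {
      if (length(x) < i || is.na(x[i]) || x[i] == ".") NA_integer_
      else suppressWarnings(as.integer(x[i]))
    }, integer(1))
  }
  a1 <- matrix(allele_code(1L), nrow = nrow(gt))
  a2 <- matrix(allele_code(2L), nrow = nrow(gt))
  # haploid-style single-allele calls are half-calls: treat as missing
  a2[is.na(a2) & !is.na(a1)] <- NA_integer_
  a1[is.na(a2)] <- NA_integer_

  decompose_cohort(sites, a1, a2, dp, samples)
}

is_snp_allele <- function(x) nchar(x) == 1L & x %in% c("A", "C", "G", "T")

# expand multiallelic rows to per-alternate pseudo-records, recode genotypes
decompose_cohort <- function(sites, a1, a2, dp, samples) {
  alt_list <- strsplit(sites$alt, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  row_idx <- rep.int(seq_len(nrow(sites)), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len))
  alt_flat <- unlist(alt_list)

  keep <- is_snp_allele(alt_flat) & is_snp_allele(sites$ref[row_idx])
  n_dropped <- sum(!keep)
  row_idx <- row_idx[keep]
  alt_idx <- alt_idx[keep]
  alt_flat <- alt_flat[keep]

  # per-row alt index: compare each genotype allele against its row's index
  m1 <- a1[row_idx, , drop = FALSE]
  m2 <- a2[row_idx, , drop = FALSE]
  tgt <- matrix(alt_idx, nrow = length(alt_idx), ncol = ncol(m1))
  r1 <- ifelse(m1 == 0L, 0L, ifelse(m1 == tgt, 1L, NA_integer_))
  r2 <- ifelse(m2 == 0L, 0L, ifelse(m2 == tgt, 1L, NA_integer_))
  # a half-missing recode masks the whole genotype
  miss <- is.na(r1) | is.na(r2)
  r1[miss] <- NA_integer_
  r2[miss] <- NA_integer_

  out_sites <- sites[row_idx, c("chrom", "pos", "ref", "qual")]
  out_sites$alt <- alt_flat
  out_sites <- out_sites[, c("chrom", "pos", "ref", "alt", "qual")]

  structure(
    list(sites = tibble::as_tibble(out_sites),
         a1 = r1, a2 = r2,
         dp = dp[row_idx, , drop = FALSE],
         samples = samples),
    n_dropped_nonsnp = n_dropped,
    class = "cohort_vcf"
  )
}

#' @export
print.cohort_vcf <- function(x, ...) {
  cat("<cohort_vcf> ", nrow(x$sites), " biallelic SNP record(s), ",
      length(x$samples), " sample(s)\n", sep = "")
  invisible(x)
}

n_sites <- function(vcf) nrow(vcf$sites)

called_matrix <- function(vcf) !is.na(vcf$a1) & !is.na(vcf$a2)

#' Site and genotype filter settings
#'
#' Defaults reproduce the study filters: drop sex-chromosome records, drop
#' sites with Phred site quality below 30, mask genotypes whose read depth
#' falls outside 5-15x, drop sites called in fewer than 80% of individuals,
#' and drop sites whose mean depth over called genotypes is below 8x.
#'
#' @param min_call_rate Minimum fraction of individuals with a called
#'   genotype (after depth masking) for a site to be kept.
#' @param min_qual Minimum Phred-scaled site QUAL.
#' @param gt_depth_min,gt_depth_max Per-genotype depth window; genotypes with
#'   depth outside it are set missing before the call-rate test.
#' @param min_site_mean_depth Minimum mean depth across called genotypes.
#' @param excluded_chroms Chromosomes removed outright (sex chromosomes).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_call_rate = 0.8,
                          min_qual = 30,
                          gt_depth_min = 5,
                          gt_depth_max = 15,
                          min_site_mean_depth = 8,
                          excluded_chroms = c("chrZ", "chrW")) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1,
            gt_depth_min <= gt_depth_max)
  structure(list(min_call_rate = min_call_rate,
                 min_qual = min_qual,
                 gt_depth_min = gt_depth_min,
                 gt_depth_max = gt_depth_max,
                 min_site_mean_depth = min_site_mean_depth,
                 excluded_chroms = excluded_chroms),
            class = "filter_config")
}

#' Apply site and genotype filters to a cohort
#'
#' Applies, in this fixed order: (1) drop records on excluded chromosomes;
#' (2) drop sites with `QUAL < min_qual` (missing QUAL fails); (3) mask
#' genotypes with depth outside the per-genotype window (missing depth on a
#' called genotype is also masked when any depth data are present); (4) drop
#' sites whose called fraction falls below `min_call_rate`; (5) drop sites
#' whose mean depth over called genotypes falls below `min_site_mean_depth`.
#' The order is part of the contract — it decides which rule a multiply
#' offending site is tallied under.
#'
#' @param vcf A `cohort_vcf` from [read_vcf()].
#' @param config A [filter_config()].
#' @return List with `vcf` (retained `cohort_vcf`) and `report`: a tibble
#'   with one row per rule (`rule`, `n_removed`) plus a `retained` row, and
#'   attribute `n_genotypes_masked`. Removed-per-rule counts plus retained
#'   always equal the input record count.
#' @export
apply_site_filters <- function(vcf, config = filter_config()) {
  stopifnot(inherits(vcf, "cohort_vcf"), inherits(config, "filter_config"))
  n_in <- n_sites(vcf)
  tally <- c(excluded_chrom = 0L, low_qual = 0L,
             low_call_rate = 0L, low_mean_depth = 0L)

  keep <- !(vcf$sites$chrom %in% config$excluded_chroms)
  tally["excluded_chrom"] <- sum(!keep)
  vcf <- subset_sites(vcf, keep)

  keep <- !is.na(vcf$sites$qual) & vcf$sites$qual >= config$min_qual
  tally["low_qual"] <- sum(!keep)
  vcf <- subset_sites(vcf, keep)

  n_masked <- 0L
  if (any(!is.na(vcf$dp))) {
    called <- called_matrix(vcf)
    bad <- called & (is.na(vcf$dp) |
                       vcf$dp < config$gt_depth_min |
                       vcf$dp > config$gt_depth_max)
    n_masked <- sum(bad)
    vcf$a1[bad] <- NA_integer_
    vcf$a2[bad] <- NA_integer_
  }

  called <- called_matrix(vcf)
  keep <- rowMeans(called) >= config$min_call_rate
  tally["low_call_rate"] <- sum(!keep)
  vcf <- subset_sites(vcf, keep)
  called <- called[keep, , drop = FALSE]

  if (any(!is.na(vcf$dp))) {
    dp_called <- vcf$dp
    dp_called[!called] <- NA_real_
    mean_dp <- rowMeans(dp_called, na.rm = TRUE)
    keep <- !is.nan(mean_dp) & mean_dp >= config$min_site_mean_depth
  } else {
    keep <- rep(TRUE, n_sites(vcf))
  }
  tally["low_mean_depth"] <- sum(!keep)
  vcf <- subset_sites(vcf, keep)

  report <- tibble::tibble(
    rule = c(names(tally), "retained"),
    n = c(unname(tally), n_sites(vcf))
  )
  stopifnot(sum(report$n) == n_in)
  attr(report, "n_genotypes_masked") <- n_masked
  list(vcf = vcf, report = report)
}

subset_sites <- function(vcf, keep) {
  vcf$sites <- vcf$sites[keep, , drop = FALSE]
  vcf$a1 <- vcf$a1[keep, , drop = FALSE]
  vcf$a2 <- vcf$a2[keep, , drop = FALSE]
  vcf$dp <- vcf$dp[keep, , drop = FALSE]
  vcf
}

#' Per-sample genotype missingness
#'
#' Fraction of retained variant sites at which each individual's genotype is
#' uncalled. This is the weighting variable of the group-comparison models:
#' lower missingness earns more weight (see [weights_from_missingness()]).
#'
#' @param vcf A filtered `cohort_vcf`.
#' @return Tibble with `sample_id` and `missingness` in `[0, 1]`.
#' @export
compute_missingness <- function(vcf) {
  stopifnot(inherits(vcf, "cohort_vcf"))
  if (n_sites(vcf) == 0L) {
    stop("cannot compute missingness over zero retained sites", call. = FALSE)
  }
  tibble::tibble(
    sample_id = vcf$samples,
    missingness = colMeans(!called_matrix(vcf))
  )
}
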