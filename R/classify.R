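#' Classify a SNP as CpG-loss, CpG-gain, both, or neither
#'
#' The core site-level rule. A biallelic SNP is a *CpG polymorphism*
#' (loss-type) when the reference allele participates in a reference-genome
#' CpG: `ref = C` with a `G` immediately right, or `ref = G` with a `C`
#' immediately left. It is a *polyCpG polymorphism* (gain-type) when the
#' alternative allele creates a CpG with a reference flanking base:
#' `alt = C` with `G` right, or `alt = G` with `C` left. The two flags are
#' independent: a substitution such as `C>G` in a `C_G` context both destroys
#' the reference CpG and creates a new one ("both"). An `N` flank satisfies
#' neither clause.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param ref,alt Single reference / alternative bases (`A`, `C`, `G`, `T`).
#' @param left,right Reference bases immediately flanking the site
#'   (`A`,`C`,`G`,`T` or `N`).
#' @return Tibble with logical `is_loss`, `is_gain` and a `cpg_class` factor
#'   with levels `loss`, `gain`, `both`, `none`.
#' @export
#' @examples
#' classify_variant("C", "T", left = "A", right = "G")  # loss
#' classify_variant("A", "G", left = "C", right = "T")  # gain
#' classify_variant("C", "G", left = "C", right = "G")  # both
classify_variant <- function(ref, alt, left, right) {
  n <- max(length(ref), length(alt), length(left), length(right))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  left <- rep_len(left, n); right <- rep_len(right, n)
  if (!all(is_snp_allele(ref)) || !all(is_snp_allele(alt))) {
    stop("ref and alt must be single bases in {A,C,G,T}", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  if (!all(left %in% c("A", "C", "G", "T", "N")) ||
      !all(right %in% c("A", "C", "G", "T", "N"))) {
    stop("flanks must be in {A,C,G,T,N}", call. = FALSE)
  }
  is_loss <- (ref == "C" & right == "G") | (ref == "G" & left == "C")
  is_gain <- (alt == "C" & right == "G") | (alt == "G" & left == "C")
  tibble::tibble(
    is_loss = is_loss,
    is_gain = is_gain,
    cpg_class = cpg_class_label(is_loss, is_gain)
  )
}

cpg_class_label <- function(is_loss, is_gain) {
  factor(
    dplyr::case_when(
      is_loss & is_gain ~ "both",
      is_loss ~ "loss",
      is_gain ~ "gain",
      .default = "none"
    ),
    levels = c("loss", "gain", "both", "none")
  )
}

#' Classify every retained SNP against the reference genome
#'
#' Pulls the immediate reference flanks of every record and applies
#' [classify_variant()]. Adjacent variants are classified independently
#' against *reference* flanks; no haplotype-aware joint context is attempted.
#'
#' @param vcf A (filtered) `cohort_vcf`.
#' @param genome A `genome_seq` covering every record chromosome.
#' @return Tibble of classified variants: `chrom`, `pos`, `ref`, `alt`,
#'   `left`, `right`, `is_loss`, `is_gain`, `cpg_class`, with class totals
#'   in `attr(x, "class_totals")` (`n_loss`/`n_gain` include "both" sites;
#'   totals conserve the input count as
#'   loss-only + gain-only + both + none = n records).
#' @export
classify_all <- function(vcf, genome) {
  stopifnot(inherits(vcf, "cohort_vcf"), inherits(genome, "genome_seq"))
  missing_chroms <- setdiff(unique(vcf$sites$chrom), genome_chroms(genome))
  if (length(missing_chroms) > 0L) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chroms, collapse = ", "), call. = FALSE)
  }
  sites <- vcf$sites
  if (nrow(sites) == 0L) {
    out <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          left = character(), right = character(),
                          is_loss = logical(), is_gain = logical(),
                          cpg_class = cpg_class_label(logical(), logical()))
    attr(out, "class_totals") <- c(n_loss = 0L, n_gain = 0L, n_none = 0L)
    return(out)
  }
  flanks <- purrr::map_dfr(split(seq_len(nrow(sites)), sites$chrom), function(i) {
    fl <- get_flanks(genome, sites$chrom[i[1]], sites$pos[i])
    fl$row <- i
    fl
  })
  flanks <- flanks[order(flanks$row), ]
  cls <- classify_variant(sites$ref, sites$alt, flanks$left, flanks$right)
  out <- dplyr::bind_cols(sites[, c("chrom", "pos", "ref", "alt")],
                          flanks[, c("left", "right")], cls)
  attr(out, "class_totals") <- c(
    n_loss = sum(out$is_loss),
    n_gain = sum(out$is_gain),
    n_none = sum(!out$is_loss & !out$is_gain)
  )
  out
}

#' Per-individual CpG / polyCpG presence at one site
#'
#' A CpG (or polyCpG) is *present* in an individual when at least one of its
#' two alleles forms the CG pair: at loss-type sites presence means carrying
#' >= 1 reference allele, at gain-type sites >= 1 alternative allele. A
#' missing genotype yields `NA` (unknown) and is excluded from counts. Set
#' `dosage = TRUE` to count CpG-forming alleles (0/1/2) instead of
#' presence/absence.
#'
#' @param is_loss,is_gain Logical site classification (recycled).
#' @param a1,a2 Integer allele codes (0 ref, 1 alt, `NA` missing).
#' @param dosage Count alleles instead of presence.
#' @return Tibble with `cpg_present` and `polycpg_present` (logical, or
#'   integer 0-2 when `dosage = TRUE`; `NA` when genotype missing or the site
#'   is not of the relevant type).
#' @export
individual_presence <- function(is_loss, is_gain, a1, a2, dosage = FALSE) {
  n <- max(length(is_loss), length(is_gain), length(a1), length(a2))
  is_loss <- rep_len(is_loss, n); is_gain <- rep_len(is_gain, n)
  a1 <- rep_len(a1, n); a2 <- rep_len(a2, n)
  n_ref <- (a1 == 0L) + (a2 == 0L)
  n_alt <- (a1 == 1L) + (a2 == 1L)
  if (dosage) {
    cpg <- ifelse(is_loss, n_ref, NA_integer_)
    poly <- ifelse(is_gain, n_alt, NA_integer_)
  } else {
    cpg <- ifelse(is_loss, n_ref >= 1L, NA)
    poly <- ifelse(is_gain, n_alt >= 1L, NA)
  }
  tibble::tibble(cpg_present = cpg, polycpg_present = poly)
}

#' Per-individual epigenetic-potential counts
#'
#' Tallies, for every sample, the number of loss-type sites where the sample
#' still carries the CpG (>= 1 reference allele), the number of gain-type
#' sites where it carries the new CpG (>= 1 alternative allele), their sum
#' (the epigenetic potential, EP), and the number of non-CpG variant sites
#' where the sample carries >= 1 alternative allele (the control count).
#' "Both"-class sites contribute to both the CpG and polyCpG tallies.
#' Missing genotypes contribute nothing.
#'
#' @param classified Output of [classify_all()] for the same records, in the
#'   same order, as `vcf`.
#' @param vcf The `cohort_vcf` the classification came from.
#' @param dosage Count CpG-forming alleles (0/1/2) instead of presence.
#' @return Tibble with one row per sample: `sample_id`, `n_cpg`,
#'   `n_polycpg`, `ep_total`, `n_noncpg`.
#' @export
ep_counts <- function(classified, vcf, dosage = FALSE) {
  stopifnot(inherits(vcf, "cohort_vcf"))
  if (nrow(classified) != n_sites(vcf)) {
    stop("classified table and VCF have different numbers of records",
         call. = FALSE)
  }
  n_ref <- (vcf$a1 == 0L) + (vcf$a2 == 0L)
  n_alt <- (vcf$a1 == 1L) + (vcf$a2 == 1L)
  ref_hit <- if (dosage) n_ref else (n_ref >= 1L)
  alt_hit <- if (dosage) n_alt else (n_alt >= 1L)

  col_count <- function(hit, rows) {
    if (!any(rows)) return(rep(0L, length(vcf$samples)))
    as.integer(colSums(hit[rows, , drop = FALSE], na.rm = TRUE))
  }
  n_cpg <- col_count(ref_hit, classified$is_loss)
  n_polycpg <- col_count(alt_hit, classified$is_gain)
  n_noncpg <- col_count(alt_hit, !classified$is_loss & !classified$is_gain)

  tibble::tibble(
    sample_id = vcf$samples,
    n_cpg = n_cpg,
    n_polycpg = n_polycpg,
    ep_total = n_cpg + n_polycpg,
    n_noncpg = n_noncpg
  )
}

#' Per-individual whole-genome total CpG count
#'
#' Robustness variant of EP: instead of counting variant CpGs only, counts
#' all CpG sites an individual carries: the reference CpG total over the
#' included chromosomes, minus loss-type sites where the individual carries
#' *no* reference allele (hom-alt), plus gain-type sites where the new CpG is
#' present (>= 1 alternative allele). Missing genotypes contribute the
#' reference state, so the total is defined for every sample; the
#' missingness-based weighting of the group models compensates.
#'
#' @inheritParams ep_counts
#' @param genome A `genome_seq`.
#' @param include_chroms Chromosomes entering the reference CpG total;
#'   defaults to the chromosomes present in `classified` (so excluded
#'   chromosomes stay excluded). Supply explicitly when the filtered VCF may
#'   lack records on some included chromosome.
#' @return Tibble with `sample_id` and `total_cpg`.
#' @export
total_cpg_counts <- function(classified, vcf, genome,
                             include_chroms = unique(classified$chrom)) {
  stopifnot(inherits(vcf, "cohort_vcf"), inherits(genome, "genome_seq"))
  if (nrow(classified) != n_sites(vcf)) {
    stop("classified table and VCF have different numbers of records",
         call. = FALSE)
  }
  ref_total <- sum(vapply(include_chroms, function(ch) {
    length(enumerate_cpg_sites(genome, ch))
  }, integer(1)))

  hom_alt <- (vcf$a1 == 1L) & (vcf$a2 == 1L)      # NA genotype -> NA
  any_alt <- (vcf$a1 == 1L) | (vcf$a2 == 1L)
  lost <- if (any(classified$is_loss)) {
    colSums(hom_alt[classified$is_loss, , drop = FALSE], na.rm = TRUE)
  } else rep(0, length(vcf$samples))
  gained <- if (any(classified$is_gain)) {
    colSums(any_alt[classified$is_gain, , drop = FALSE], na.rm = TRUE)
  } else rep(0, length(vcf$samples))

  tibble::tibble(
    sample_id = vcf$samples,
    total_cpg = as.integer(ref_total - lost + gained)
  )
}

#' Full per-individual EP profile table
#'
#' Convenience wrapper joining [ep_counts()], [total_cpg_counts()] and
#' [compute_missingness()] into the per-sample profile used by the group
#' comparison models.
#'
#' @inheritParams total_cpg_counts
#' @param dosage Passed to [ep_counts()].
#' @return Tibble: `sample_id`, `n_cpg`, `n_polycpg`, `ep_total`,
#'   `n_noncpg`, `total_cpg`, `missingness`.
#' @export
ep_profiles <- function(classified, vcf, genome,
                        include_chroms = unique(classified$chrom),
                        dosage = FALSE) {
  ep_counts(classified, vcf, dosage = dosage) |>
    dplyr::left_join(
      total_cpg_counts(classified, vcf, genome, include_chroms),
      by = "sample_id") |>
    dplyr::left_join(compute_missingness(vcf), by = "sample_id")
}
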