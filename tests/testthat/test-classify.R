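test_that("site-level classification follows the loss and gain rules", {
  expect_equal(as.character(classify_variant("C", "T", "A", "G")$cpg_class),
               "loss")
  expect_equal(as.character(classify_variant("A", "G", "C", "T")$cpg_class),
               "gain")
  expect_equal(as.character(classify_variant("A", "T", "C", "G")$cpg_class),
               "none")
  # C>G in a C_G context destroys the right-hand CpG and creates a new one
  # with the left flank: both flags set
  cls <- classify_variant("C", "G", "C", "G")
  expect_true(cls$is_loss && cls$is_gain)
  expect_equal(as.character(cls$cpg_class), "both")
  # N flanks satisfy neither clause
  expect_equal(as.character(classify_variant("C", "T", "N", "N")$cpg_class),
               "none")
  expect_error(classify_variant("C", "C", "A", "A"), "differ")
  expect_error(classify_variant("CA", "T", "A", "A"), "single bases")
})

test_that("classification is strand symmetric", {
  bases <- c("A", "C", "G", "T")
  comp <- function(x) chartr("ACGTN", "TGCAN", x)
  withr::with_seed(5, {
    for (i in 1:50) {
      ra <- sample(bases, 2)
      fl <- sample(c(bases, "N"), 2, replace = TRUE)
      fwd <- classify_variant(ra[1], ra[2], fl[1], fl[2])
      # reverse complement: flanks swap and complement, alleles complement
      rev <- classify_variant(comp(ra[1]), comp(ra[2]),
                              comp(fl[2]), comp(fl[1]))
      expect_equal(fwd$cpg_class, rev$cpg_class)
    }
  })
})

test_that("classify_all classifies each SNP once against reference flanks and conserves totals", {
  #          12345678901234567890
  g <- genome_from_strings(c(chr1 = "AACGATGACGACCGTACAGA"))
  # reference CpGs at C positions 3, 9, 13
  sites <- tibble::tibble(
    chrom = "chr1",
    pos = c(3L, 10L, 6L, 18L, 13L, 16L),
    ref = c("C", "G", "T", "A", "C", "A"),
    alt = c("T", "A", "C", "G", "G", "T"),
    qual = 60
  )
  gt <- matrix("0/1", nrow = 6, ncol = 2, dimnames = list(NULL, c("x", "y")))
  v <- read_vcf(write_vcf_text(sites, gt))
  cl <- classify_all(v, g)
  expect_equal(as.character(cl$cpg_class),
               c("loss", "loss", "gain", "gain", "both", "none"))
  tot <- attr(cl, "class_totals")
  expect_equal(unname(tot), c(3L, 3L, 1L))
  # conservation: loss-only + gain-only + both + none = records
  tab <- table(cl$cpg_class)
  expect_equal(sum(tab), nrow(sites))
  expect_error(classify_all(v, genome_from_strings(c(other = "ACGT"))),
               "absent from genome")
})

test_that("empty and all-none inputs give zero totals", {
  g <- genome_from_strings(c(chr1 = "ATATATATAT"))
  sites <- tibble::tibble(chrom = "chr1", pos = c(2L, 5L), ref = c("T", "T"),
                          alt = c("A", "A"), qual = 60)
  gt <- matrix("0/0", 2, 1, dimnames = list(NULL, "s"))
  v <- read_vcf(write_vcf_text(sites, gt))
  cl <- classify_all(v, g)
  expect_equal(unname(attr(cl, "class_totals")), c(0L, 0L, 2L))
  v0 <- epipotential:::subset_sites(v, c(FALSE, FALSE))
  cl0 <- classify_all(v0, g)
  expect_equal(nrow(cl0), 0L)
  expect_equal(unname(attr(cl0, "class_totals")), c(0L, 0L, 0L))
})

test_that("individual presence follows the >=1-allele rule with dosage option", {
  # loss site, het: at least one haplotype retains the CG pair
  p <- individual_presence(TRUE, FALSE, 0L, 1L)
  expect_true(p$cpg_present)
  expect_true(is.na(p$polycpg_present))
  # gain site, hom-ref: no alternative allele, no new CpG
  p <- individual_presence(FALSE, TRUE, 0L, 0L)
  expect_false(p$polycpg_present)
  # missing genotype -> unknown
  p <- individual_presence(TRUE, TRUE, NA_integer_, NA_integer_)
  expect_true(is.na(p$cpg_present) && is.na(p$polycpg_present))
  # dosage mode counts CpG-forming alleles
  p <- individual_presence(TRUE, FALSE, 0L, 0L, dosage = TRUE)
  expect_equal(p$cpg_present, 2L)
  p <- individual_presence(FALSE, TRUE, 0L, 1L, dosage = TRUE)
  expect_equal(p$polycpg_present, 1L)
})

test_that("EP counts hit their bounds for extreme genotype patterns", {
  g <- genome_from_strings(c(chr1 = "AACGATGACGACCGTACAGA"))
  sites <- tibble::tibble(
    chrom = "chr1", pos = c(3L, 9L, 6L, 18L),
    ref = c("C", "C", "T", "A"), alt = c("T", "A", "C", "G"), qual = 60
  )
  # s1: hom-ref at losses, hom-alt at gains -> n_cpg = n_loss, n_polycpg = n_gain
  # s2: all missing -> zeros and missingness 1
  gt <- matrix(c("0/0", "./.",
                 "0/0", "./.",
                 "1/1", "./.",
                 "1/1", "./."), nrow = 4, byrow = TRUE,
               dimnames = list(NULL, c("s1", "s2")))
  v <- read_vcf(write_vcf_text(sites, gt))
  cl <- classify_all(v, g)
  ep <- ep_counts(cl, v)
  expect_equal(ep$n_cpg, c(2L, 0L))
  expect_equal(ep$n_polycpg, c(2L, 0L))
  expect_equal(ep$ep_total, c(4L, 0L))
  expect_equal(compute_missingness(v)$missingness, c(0, 1))
})

test_that("total CpG count adjusts the reference total by lost and gained sites", {
  g <- genome_from_strings(c(chr1 = "AACGATGACGACCGTACAGA"))  # 3 reference CpGs
  sites <- tibble::tibble(
    chrom = "chr1", pos = c(3L, 6L),
    ref = c("C", "T"), alt = c("T", "C"), qual = 60
  )
  gt_cases <- list(
    hom_ref = c("0/0", "0/0"),   # reference total
    lost_one = c("1/1", "0/0"),  # hom-alt at the loss site: -1
    het_gain = c("0/0", "0/1"),  # het at the gain site: +1
    missing = c("./.", "./.")    # missing contributes the reference state
  )
  for (nm in names(gt_cases)) {
    gt <- matrix(gt_cases[[nm]], nrow = 2, dimnames = list(NULL, "s"))
    v <- read_vcf(write_vcf_text(sites, gt))
    cl <- classify_all(v, g)
    tc <- total_cpg_counts(cl, v, g, include_chroms = "chr1")$total_cpg
    expected <- switch(nm, hom_ref = 3L, lost_one = 2L, het_gain = 4L,
                       missing = 3L)
    expect_equal(tc, expected, info = nm)
  }
})

test_that("a newly carried gain variant raises EP by exactly one", {
  g <- genome_from_strings(c(chr1 = "AACGATGACGACCGTACAGA"))
  sites <- tibble::tibble(chrom = "chr1", pos = c(3L, 6L),
                          ref = c("C", "T"), alt = c("T", "C"), qual = 60)
  gt_without <- matrix(c("0/1", "0/0"), nrow = 2, dimnames = list(NULL, "s"))
  gt_with <- matrix(c("0/1", "0/1"), nrow = 2, dimnames = list(NULL, "s"))
  ep0 <- ep_counts(classify_all(read_vcf(write_vcf_text(sites, gt_without)), g),
                   read_vcf(write_vcf_text(sites, gt_without)))
  ep1 <- ep_counts(classify_all(read_vcf(write_vcf_text(sites, gt_with)), g),
                   read_vcf(write_vcf_text(sites, gt_with)))
  expect_equal(ep1$ep_total, ep0$ep_total + 1L)
})
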