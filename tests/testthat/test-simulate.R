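small_cfg <- function(...) {
  sim_config(seed = 101,
             chrom_lengths = c(chr1 = 30000L, chr2 = 30000L, chrZ = 10000L),
             n_transcripts = 4L, n_loss = 40L, n_gain = 40L, n_none = 60L,
             n_sex_chrom_variants = 10L, ...)
}

test_that("the generator is deterministic per seed, stage by stage", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  g1 <- simulate_reference(cfg, file.path(d1, "ref.fa"))
  g2 <- simulate_reference(cfg, file.path(d2, "ref.fa"))
  expect_identical(readLines(file.path(d1, "ref.fa")),
                   readLines(file.path(d2, "ref.fa")))
  m1 <- simulate_gene_models(cfg, g1, file.path(d1, "genes.bed"))
  m2 <- simulate_gene_models(cfg, g2, file.path(d2, "genes.bed"))
  expect_identical(readLines(file.path(d1, "genes.bed")),
                   readLines(file.path(d2, "genes.bed")))
  c1 <- simulate_cohort(cfg, g1, m1, d1)
  c2 <- simulate_cohort(cfg, g2, m2, d2)
  expect_identical(readLines(c1$paths$vcf), readLines(c2$paths$vcf))
  expect_identical(readLines(c1$paths$metadata),
                   readLines(c2$paths$metadata))
  # different seed changes the data
  g3 <- simulate_reference(sim_config(seed = 202))
  expect_false(identical(g1$seq[["chr1"]],
                         substr(g3$seq[["chr1"]], 1, 30000)))
})

test_that("reference CpG density is controlled and binomially concentrated", {
  cfg0 <- sim_config(seed = 4, cpg_density = 0,
                     chrom_lengths = c(chr1 = 20000L))
  g0 <- simulate_reference(cfg0)
  expect_length(enumerate_cpg_sites(g0, "chr1"), 0)

  cfg <- sim_config(seed = 4, cpg_density = 0.02,
                    chrom_lengths = c(chr1 = 100000L))
  g <- simulate_reference(cfg)
  n_cg <- length(enumerate_cpg_sites(g, "chr1"))
  # planted per 2-base slot: Binomial(L/2, 2 * density)
  mu <- 100000 * 0.02
  sdv <- sqrt(50000 * 0.04 * 0.96)
  expect_lt(abs(n_cg - mu), 3 * sdv)
})

test_that("gene models round-trip through BED12 and respect requested counts", {
  cfg <- small_cfg()
  g <- simulate_reference(cfg)
  path <- withr::local_tempfile(fileext = ".bed")
  m <- simulate_gene_models(cfg, g, path)
  expect_equal(nrow(m), 4L)
  expect_setequal(unique(m$strand), c("+", "-"))
  back <- read_bed12(path)
  expect_equal(back, tibble::as_tibble(m), ignore_attr = TRUE)
  # with a zero flank, TSS positions annotate as exon (first exon starts at
  # the span end), never promoter
  idx0 <- build_feature_index(m, 0L, genome_lengths(g))
  ann <- annotate_position(idx0, m$chrom, m$tss)
  expect_false(any(ann == "promoter"))
})

test_that("planted variants match their class and category and keep spacing", {
  cfg <- small_cfg()
  g <- simulate_reference(cfg)
  m <- simulate_gene_models(cfg, g)
  idx <- build_feature_index(m, cfg$promoter_flank, genome_lengths(g))
  props <- list(loss = c(0.4, 0.1, 0.25, 0.25),
                gain = c(0.4, 0.1, 0.25, 0.25),
                none = c(0.25, 0.25, 0.25, 0.25))
  v <- withr::with_seed(1, plant_variants(g, idx, 40L, 40L, 40L,
                                          chroms = c("chr1", "chr2"),
                                          category_props = props))
  expect_equal(unname(table(v$class)[c("loss", "gain", "none")]),
               rep(40L, 3), ignore_attr = TRUE)
  # category quotas honoured exactly
  tab <- table(v$class, v$category)
  expect_equal(unname(tab["loss", ]), c(16L, 4L, 10L, 10L),
               ignore_attr = TRUE)
  # spacing: planted contexts never interact
  by_chrom <- split(v$pos, v$chrom)
  expect_true(all(unlist(lapply(by_chrom, function(p) diff(sort(p)) >= 3))))
  # classification of planted sites matches the label (loss on CpGs etc.)
  fl <- dplyr::bind_rows(lapply(split(seq_len(nrow(v)), v$chrom), function(i) {
    get_flanks(g, v$chrom[i[1]], v$pos[i])
  }))
  cls <- classify_variant(v$ref, v$alt, fl$left, fl$right)
  expect_equal(as.character(cls$cpg_class), as.character(v$class))
})

test_that("the cohort matches the study shape and the truth excludes the sex chromosome", {
  cfg <- small_cfg()
  dir <- withr::local_tempdir()
  d <- simulate_dataset(cfg, dir)
  md <- d$cohort$metadata
  expect_equal(unname(table(md$group)), c(21L, 19L, 14L, 20L),
               ignore_attr = TRUE)
  expect_equal(unname(table(md$group, md$sex)["3", c("M", "F")]), c(3L, 11L),
               ignore_attr = TRUE)
  expect_true(all(md$year[md$group == 4] == 1998L))
  expect_true(all(md$year[md$group == 3] %in% 2015:2017))
  # chrZ variants are emitted but not in the truth
  expect_true(any(d$cohort$vcf$sites$chrom == "chrZ"))
  expect_false(any(d$cohort$truth$variants$chrom == "chrZ"))
  expect_equal(nrow(d$cohort$vcf$sites), 40L + 40L + 60L + 10L)
  # written VCF re-reads to the same records
  v <- read_vcf(d$paths$vcf)
  expect_equal(v$sites$pos, d$cohort$vcf$sites$pos)
  expect_equal(v$a1, d$cohort$vcf$a1, ignore_attr = TRUE)
})

test_that("a planted group effect raises that group's expected EP", {
  cfg <- small_cfg(ep_effect = c(0, 0, 0, 0.08))
  g <- simulate_reference(cfg)
  m <- simulate_gene_models(cfg, g)
  co <- simulate_cohort(cfg, g, m)
  exp_ep <- co$truth$group_expected_ep
  expect_gt(exp_ep$expected_ep[4], exp_ep$expected_ep[1])
  # and the realised per-sample EP shows the shift on average
  md <- co$metadata
  prof <- co$truth$profiles
  mean4 <- mean(prof$ep_total[md$group == 4])
  mean1 <- mean(prof$ep_total[md$group == 1])
  expect_gt(mean4, mean1)
})

test_that("null generator runs centre group EP differences on zero", {
  # across replicate seeds, the group-4 minus group-1 mean EP difference
  # under a null config is centred: its mean lies within 2 SE of zero
  diffs <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = 1000 + s,
                      chrom_lengths = c(chr1 = 20000L),
                      excluded_chroms = character(0),
                      n_transcripts = 2L, n_loss = 30L, n_gain = 30L,
                      n_none = 0L, n_sex_chrom_variants = 0L,
                      miss_range = c(0, 0))
    g <- simulate_reference(cfg)
    m <- simulate_gene_models(cfg, g)
    co <- simulate_cohort(cfg, g, m)
    md <- co$metadata
    prof <- co$truth$profiles
    mean(prof$ep_total[md$group == 4]) - mean(prof$ep_total[md$group == 1])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("insufficient candidate positions fail with a named class/category", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(chr1 = 2000L),
                    excluded_chroms = character(0))
  g <- simulate_reference(cfg)
  expect_error(
    withr::with_seed(1, plant_variants(g, NULL, n_loss = 5000L,
                                       chroms = "chr1")),
    "insufficient candidate positions for class loss")
})
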