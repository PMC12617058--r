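write_bed_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("BED12 parsing reconstructs exon blocks and strand-aware TSS", {
  # 2-exon transcript on +: span [101, 400] 1-based, exons 101-200, 301-400
  # 1-exon transcript on -: TSS at the rightmost coordinate
  path <- write_bed_lines(c(
    "chr1\t100\t400\ttxA\t0\t+\t100\t400\t0\t2\t100,100,\t0,200,",
    "chr1\t500\t650\ttxB\t0\t-\t500\t650\t0\t1\t150,\t0,"
  ))
  m <- read_bed12(path)
  expect_equal(m$start, c(101L, 501L))
  expect_equal(m$end, c(400L, 650L))
  expect_equal(m$tss, c(101L, 650L))
  expect_equal(m$exons[[1]],
               tibble::tibble(start = c(101L, 301L), end = c(200L, 400L)))
  # the intron of txA is [201, 300]
  idx <- build_feature_index(m, promoter_flank = 0,
                             seqlengths = c(chr1 = 1000L))
  expect_equal(as.character(annotate_position(idx, "chr1", 250)), "intron")
})

test_that("malformed BED12 input is rejected", {
  expect_error(read_bed12(write_bed_lines("chr1\t0\t100\ttx\t0\t+")),
               "12 BED columns")
  expect_error(read_bed12(write_bed_lines(
    "chr1\t100\t400\ttx\t0\t+\t100\t400\t0\t2\t100,xx,\t0,200,")),
    "malformed")
  # blocks exceeding the span
  expect_error(read_bed12(write_bed_lines(
    "chr1\t100\t400\ttx\t0\t+\t100\t400\t0\t2\t100,200,\t0,200,")),
    "exceed")
})

test_that("promoter windows are strand-aware and clipped at chromosome ends", {
  path <- write_bed_lines(
    "chr1\t1000\t2000\ttx\t0\t+\t1000\t2000\t0\t1\t1000,\t0,")
  m <- read_bed12(path)
  idx <- build_feature_index(m, promoter_flank = 1000,
                             seqlengths = c(chr1 = 5000L))
  # TSS = 1001 on +; window [1, 2001] after clipping at the chromosome start
  expect_equal(IRanges::start(idx$promoters), 1L)
  expect_equal(IRanges::end(idx$promoters), 2001L)
  expect_error(build_feature_index(m, 1000, c(chr9 = 100L)),
               "not in seqlengths")
})

test_that("hierarchical precedence is promoter > exon > intron > intergenic", {
  path <- write_bed_lines(c(
    "chr1\t1000\t3000\ttxA\t0\t+\t1000\t3000\t0\t2\t500,500,\t0,1500,",
    "chr1\t6000\t7000\ttxB\t0\t-\t6000\t7000\t0\t1\t1000,\t0,"
  ))
  m <- read_bed12(path)
  idx <- build_feature_index(m, promoter_flank = 1000,
                             seqlengths = c(chr1 = 10000L, chr2 = 5000L))
  # position 1200: inside txA's first exon AND the promoter window -> promoter
  expect_equal(as.character(annotate_position(idx, "chr1", 1200)), "promoter")
  # position 2700: exon of txA, beyond promoter window [1, 2001]
  expect_equal(as.character(annotate_position(idx, "chr1", 2700)), "exon")
  # position 2200: inside txA span, not exon, not promoter -> intron
  expect_equal(as.character(annotate_position(idx, "chr1", 2200)), "intron")
  # far from any feature
  expect_equal(as.character(annotate_position(idx, "chr1", 9500)),
               "intergenic")
  # chromosome without features is all intergenic
  expect_equal(as.character(annotate_position(idx, "chr2", 100)),
               "intergenic")
  expect_error(annotate_position(idx, "chrX", 1), "unknown chromosome")
})

test_that("empty model set annotates everything intergenic", {
  m <- read_bed12(write_bed_lines(
    "chr1\t100\t200\ttx\t0\t+\t100\t200\t0\t1\t100,\t0,"))[0, ]
  idx <- build_feature_index(m, 1000, c(chr1 = 1000L))
  expect_equal(as.character(annotate_position(idx, "chr1", c(1, 500, 1000))),
               rep("intergenic", 3))
})

test_that("shrinking the promoter flank only moves positions out of the promoter class", {
  cfg <- sim_config(seed = 3, n_transcripts = 6L,
                    chrom_lengths = c(chr1 = 50000L))
  g <- simulate_reference(cfg)
  m <- simulate_gene_models(cfg, g)
  pos <- seq(1L, 50000L, by = 97L)
  idx_big <- build_feature_index(m, 1000, genome_lengths(g))
  idx_zero <- build_feature_index(m, 0, genome_lengths(g))
  ann_big <- annotate_position(idx_big, "chr1", pos)
  ann_zero <- annotate_position(idx_zero, "chr1", pos)
  was_prom <- ann_big == "promoter"
  # nothing becomes promoter when the flank shrinks
  expect_true(all(which(ann_zero == "promoter") %in% which(was_prom)))
  # non-promoter classes are unchanged for positions that were not promoter
  expect_equal(ann_big[!was_prom], ann_zero[!was_prom])
})

test_that("annotation counts partition every input set", {
  cfg <- sim_config(seed = 9, chrom_lengths = c(chr1 = 40000L, chr2 = 40000L),
                    n_transcripts = 6L, n_loss = 40L, n_gain = 40L,
                    n_none = 40L, n_sex_chrom_variants = 0L,
                    excluded_chroms = character(0))
  d <- simulate_dataset(cfg, withr::local_tempdir())
  cl <- classify_all(d$cohort$vcf, d$genome)
  idx <- build_feature_index(d$models, 1000, genome_lengths(d$genome))
  bg <- background_positions(d$genome, cl)
  counts <- annotate_sets(cl, bg, idx)
  expect_equal(sum(counts$n[counts$set == "background"]), nrow(bg))
  expect_equal(sum(counts$n[counts$set == "loss"]), sum(cl$is_loss))
  expect_equal(sum(counts$n[counts$set == "gain"]), sum(cl$is_gain))
  expect_equal(sum(counts$n[counts$set == "none"]),
               sum(!cl$is_loss & !cl$is_gain))
  # every set reports all four categories exactly once
  expect_equal(unname(table(counts$set)), rep(4L, 4), ignore_attr = TRUE)
})
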