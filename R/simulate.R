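#' Configuration for the synthetic cohort generator
#'
#' Defines a seeded, fully reproducible synthetic study: a small reference
#' genome (two 100-kb autosomes plus a sex chromosome that downstream
#' filters must exclude), BED12 gene models, and a diploid biallelic-SNP
#' cohort shaped like the study design: four dispersal groups of 21/19/14/20
#' birds with the study's sex ratios and sampling years, per-genotype read
#' depth around 8x, variable site quality, and per-individual missingness.
#' CpG-loss and CpG-gain variants are planted at known positions with known
#' annotation categories; a per-group shift of the CpG-allele frequency
#' plants a true group effect on epigenetic potential.
#'
#' @param seed Integer seed; fixes every downstream draw. Stage sub-seeds
#'   are derived from it so reference, gene models and cohort can be
#'   regenerated independently.
#' @param chrom_lengths Named chromosome lengths.
#' @param excluded_chroms Sex chromosomes (emitted with variants, excluded
#'   from all truth totals).
#' @param gc Background GC content of the simulated reference.
#' @param cpg_density Expected CpG dinucleotides per base (CpG-depleted
#'   vertebrate-like default 0.01).
#' @param n_transcripts Transcript models across the autosomes.
#' @param exon_count_range,exon_size_range,intron_size_range Gene geometry.
#' @param promoter_flank Promoter window half-width used when placing
#'   variants by category.
#' @param n_loss,n_gain,n_none Planted variant counts by CpG class on the
#'   autosomes.
#' @param category_props Optional named list (`loss`, `gain`, `none`) of
#'   4-vectors of target annotation-category proportions
#'   (promoter/exon/intron/intergenic); `NULL` places variants uniformly
#'   over candidate positions.
#' @param n_sex_chrom_variants Variants planted on the excluded chromosome
#'   to exercise the exclusion path.
#' @param group_sizes,group_sexes,group_years Cohort shape: samples per
#'   group, `(M, F)` counts, candidate sampling years per group.
#' @param af_range Range of the base CpG-allele frequency per variant.
#' @param ep_effect Per-group additive shift of the CpG-allele frequency
#'   (planted EP effect); all zero = null cohort.
#' @param depth_mean,depth_size Negative-binomial per-genotype depth
#'   (mean/size); `depth_const` overrides with a fixed depth.
#' @param qual_mean,qual_sd Site QUAL distribution; `qual_const` overrides.
#' @param miss_range Per-sample missing-genotype rate range (uniform).
#' @param min_spacing Minimum distance between planted variants, keeping
#'   their trinucleotide contexts disjoint.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 100000L, chr2 = 100000L,
                                         chrZ = 50000L),
                       excluded_chroms = "chrZ",
                       gc = 0.42,
                       cpg_density = 0.01,
                       n_transcripts = 12L,
                       exon_count_range = c(3L, 6L),
                       exon_size_range = c(100L, 300L),
                       intron_size_range = c(500L, 3000L),
                       promoter_flank = 1000L,
                       n_loss = 300L, n_gain = 300L, n_none = 400L,
                       category_props = NULL,
                       n_sex_chrom_variants = 30L,
                       group_sizes = c(21L, 19L, 14L, 20L),
                       group_sexes = list(c(11L, 10L), c(9L, 10L),
                                          c(3L, 11L), c(11L, 9L)),
                       group_years = list(2016:2019, 2016:2019,
                                          2015:2017, 1998L),
                       af_range = c(0.1, 0.9),
                       ep_effect = c(0, 0, 0, 0),
                       depth_mean = 8, depth_size = 25, depth_const = NULL,
                       qual_mean = 60, qual_sd = 20, qual_const = NULL,
                       miss_range = c(0, 0.1),
                       min_spacing = 3L) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            gc > 0, gc < 1, cpg_density >= 0, cpg_density < 0.5,
            length(group_sizes) == 4L, all(group_sizes >= 2L),
            all(vapply(group_sexes, sum, integer(1)) == group_sizes),
            length(ep_effect) == 4L, min_spacing >= 3L)
  structure(as.list(environment()), class = "sim_config")
}

stage_seed <- function(config, stage) {
  (as.integer(config$seed) + c(reference = 1L, genes = 2L,
                               cohort = 3L)[[stage]]) %% .Machine$integer.max
}

#' Simulate a reference genome
#'
#' Generates per-chromosome sequences with the configured GC content and an
#' exact planted set of CpG dinucleotides: background bases are drawn i.i.d.,
#' accidental CG pairs are broken, and CG pairs are then planted
#' independently at alternate positions with probability `2 * cpg_density`,
#' so the CpG count is binomial with mean `length * cpg_density`.
#' Deterministic per seed.
#'
#' @param config A [sim_config()].
#' @param path Optional FASTA output path.
#' @return A `genome_seq`; when `path` is given the FASTA is written and the
#'   path stored in `attr(x, "path")`.
#' @export
simulate_reference <- function(config, path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seqs <- withr::with_seed(stage_seed(config, "reference"), {
    vapply(names(config$chrom_lengths), function(ch) {
      len <- config$chrom_lengths[[ch]]
      p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
             G = config$gc / 2, T = (1 - config$gc) / 2)
      b <- sample(names(p), len, replace = TRUE, prob = p)
      cg <- which(b[-len] == "C" & b[-1] == "G")
      if (length(cg) > 0) b[cg + 1L] <- "A"   # break background CpGs
      if (config$cpg_density > 0) {
        slots <- seq(1L, len - 1L, by = 2L)
        plant <- slots[stats::runif(length(slots)) < 2 * config$cpg_density]
        b[plant] <- "C"
        b[plant + 1L] <- "G"
      }
      paste(b, collapse = "")
    }, character(1))
  })
  g <- new_genome_seq(seqs)
  if (!is.null(path)) {
    write_fasta(g, path)
    attr(g, "path") <- path
  }
  g
}

#' Simulate BED12 gene models
#'
#' Places non-overlapping multi-exon transcripts on the autosomes, strands
#' alternating, with exon/intron geometry drawn from the configured ranges.
#' Deterministic per seed.
#'
#' @inheritParams simulate_reference
#' @param genome The simulated `genome_seq`.
#' @param path Optional BED12 output path.
#' @return Transcript-model tibble in the [read_bed12()] layout; the BED12
#'   file round-trips to the identical tibble.
#' @export
simulate_gene_models <- function(config, genome, path = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "genome_seq"))
  autosomes <- setdiff(genome_chroms(genome), config$excluded_chroms)
  lens <- genome_lengths(genome)
  models <- withr::with_seed(stage_seed(config, "genes"), {
    occupied <- stats::setNames(vector("list", length(autosomes)), autosomes)
    out <- vector("list", config$n_transcripts)
    for (i in seq_len(config$n_transcripts)) {
      ch <- autosomes[((i - 1L) %% length(autosomes)) + 1L]
      placed <- FALSE
      for (try in 1:200) {
        # geometry is redrawn each attempt so crowded chromosomes can still
        # accommodate a (shorter) transcript
        k <- sample(seq(config$exon_count_range[1],
                        config$exon_count_range[2]), 1)
        sizes <- sample(seq(config$exon_size_range[1],
                            config$exon_size_range[2]), k, replace = TRUE)
        gaps <- if (k > 1) {
          sample(seq(config$intron_size_range[1],
                     config$intron_size_range[2]), k - 1, replace = TRUE)
        } else integer(0)
        span <- sum(sizes) + sum(gaps)
        if (span >= lens[[ch]]) next
        start <- sample.int(lens[[ch]] - span, 1)
        end <- start + span - 1L
        clash <- any(vapply(occupied[[ch]], function(iv) {
          start <= iv[2] + 200L && end >= iv[1] - 200L  # keep a buffer
        }, logical(1)))
        if (!clash) {
          occupied[[ch]] <- c(occupied[[ch]], list(c(start, end)))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place transcript ", i,
             " without overlap after 200 tries", call. = FALSE)
      }
      ex_start <- start + c(0L, cumsum(sizes[-k] + gaps))
      ex_end <- ex_start + sizes - 1L
      strand <- if (i %% 2L == 0L) "-" else "+"
      out[[i]] <- tibble::tibble(
        name = sprintf("tx%02d", i), chrom = ch, strand = strand,
        start = as.integer(start), end = as.integer(end),
        tss = as.integer(if (strand == "+") start else end),
        exons = list(tibble::tibble(start = as.integer(ex_start),
                                    end = as.integer(ex_end)))
      )
    }
    dplyr::bind_rows(out)
  })
  if (!is.null(path)) {
    write_bed12(models, path)
    attr(models, "path") <- path
  }
  models
}

#' Write transcript models to BED12
#'
#' Inverse of [read_bed12()]: 1-based inclusive models are written as
#' 0-based half-open 12-column BED.
#'
#' @param models Transcript-model tibble ([read_bed12()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(models, path) {
  lines <- purrr::pmap_chr(models, function(name, chrom, strand, start, end,
                                            tss, exons) {
    sizes <- exons$end - exons$start + 1L
    offsets <- exons$start - start
    paste(chrom, start - 1L, end, name, 0L, strand, start - 1L, end, "0",
          nrow(exons),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(offsets, collapse = ","), ","),
          sep = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

# candidate positions whose planted substitution yields exactly the target
# CpG class, given reference flanks
variant_candidates <- function(genome, chrom) {
  s <- genome$seq[[chrom]]
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  len <- length(b)
  left <- c("N", b[-len])
  right <- c(b[-1], "N")
  is_loss_site <- (b == "C" & right == "G") | (b == "G" & left == "C")

  loss_c <- which(b == "C" & right == "G")
  loss_g <- which(b == "G" & left == "C")
  gain_c <- which(right == "G" & b != "C" & b != "N" & !is_loss_site)
  gain_g <- which(left == "C" & b != "G" & b != "N" & !is_loss_site)
  none_at <- which(b == "A" | b == "T")

  list(
    loss = tibble::tibble(chrom = chrom, pos = c(loss_c, loss_g),
                          ref = b[c(loss_c, loss_g)], alt = NA_character_),
    gain = tibble::tibble(chrom = chrom, pos = c(gain_c, gain_g),
                          ref = b[c(gain_c, gain_g)],
                          alt = rep(c("C", "G"),
                                    c(length(gain_c), length(gain_g)))),
    none = tibble::tibble(chrom = chrom, pos = none_at, ref = b[none_at],
                          alt = ifelse(b[none_at] == "A", "T", "A"))
  )
}

#' Plant classified variant positions on a genome
#'
#' Samples positions whose substitution produces exactly the requested CpG
#' class (loss variants sit on reference CpGs, gain variants create a CpG
#' with a reference flank, non-CpG variants are A<->T substitutions), with a
#' minimum spacing so planted trinucleotide contexts never interact, and —
#' optionally — with target annotation-category proportions. Loss alleles are
#' drawn from `{A, T}` so a planted loss never simultaneously creates a CpG.
#'
#' Randomness comes from the caller's RNG state (wrap in
#' [withr::with_seed()] for determinism).
#'
#' @param genome A `genome_seq`.
#' @param index A `feature_index` (required when `category_props` given).
#' @param n_loss,n_gain,n_none Planted counts by class.
#' @param chroms Chromosomes to plant on.
#' @param category_props Named list per class (or a single 4-vector applied
#'   to all classes) of promoter/exon/intron/intergenic target proportions.
#' @param min_spacing Minimum distance between planted variants.
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `class`, `category`
#'   (category `NA` when no index supplied), sorted by position.
#' @export
plant_variants <- function(genome, index = NULL,
                           n_loss = 0L, n_gain = 0L, n_none = 0L,
                           chroms = genome_chroms(genome),
                           category_props = NULL, min_spacing = 3L) {
  stopifnot(inherits(genome, "genome_seq"))
  n_by_class_all <- c(loss = n_loss, gain = n_gain, none = n_none)
  classes <- names(n_by_class_all)[n_by_class_all > 0L]
  if (length(classes) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          class = factor(character(),
                                         c("loss", "gain", "both", "none")),
                          category = factor(character(), ANNOTATION_LEVELS)))
  }
  cand <- purrr::map(chroms, function(ch) variant_candidates(genome, ch))
  pools <- purrr::map(classes, function(cl) {
    dplyr::bind_rows(purrr::map(cand, cl))
  })
  names(pools) <- classes

  if (!is.null(index)) {
    pools <- purrr::map(pools, function(p) {
      p$category <- annotate_position(index, p$chrom, p$pos)
      p
    })
  } else {
    if (!is.null(category_props)) {
      stop("category_props requires a feature_index", call. = FALSE)
    }
    pools <- purrr::map(pools, function(p) {
      p$category <- factor(NA_character_, levels = ANNOTATION_LEVELS)
      p
    })
  }

  blocked <- lapply(genome_lengths(genome)[chroms] + 2L * min_spacing,
                    logical)
  names(blocked) <- chroms
  take <- function(pool, n_take) {
    if (n_take == 0L) return(pool[0, ])
    pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
    chosen <- integer(0)
    for (i in seq_len(nrow(pool))) {
      p <- pool$pos[i] + min_spacing          # offset into padded vector
      ch <- pool$chrom[i]
      if (any(blocked[[ch]][(p - min_spacing + 1L):(p + min_spacing - 1L)])) next
      blocked[[ch]][p] <<- TRUE
      chosen <- c(chosen, i)
      if (length(chosen) == n_take) break
    }
    if (length(chosen) < n_take) return(NULL)
    pool[chosen, , drop = FALSE]
  }

  quotas <- function(n, props) {
    q <- diff(c(0, round(cumsum(n * props))))
    stats::setNames(as.integer(q), ANNOTATION_LEVELS)
  }

  out <- purrr::imap(pools, function(pool, cl) {
    n_cl <- n_by_class_all[[cl]]
    props <- if (is.null(category_props)) NULL
             else if (is.list(category_props)) category_props[[cl]]
             else category_props
    if (is.null(props)) {
      res <- take(pool, n_cl)
      if (is.null(res)) {
        stop("insufficient candidate positions for class ", cl, call. = FALSE)
      }
      res
    } else {
      stopifnot(length(props) == 4L, abs(sum(props) - 1) < 1e-8)
      q <- quotas(n_cl, props)
      parts <- purrr::map(ANNOTATION_LEVELS, function(cat) {
        res <- take(pool[pool$category == cat, , drop = FALSE], q[[cat]])
        if (is.null(res)) {
          stop("insufficient candidate positions for class ", cl,
               ", category ", cat, call. = FALSE)
        }
        res
      })
      dplyr::bind_rows(parts)
    }
  })
  out <- dplyr::bind_rows(out, .id = "class")
  # loss alleles drawn last so earlier sampling is unaffected by class mix
  is_l <- out$class == "loss"
  out$alt[is_l] <- sample(c("A", "T"), sum(is_l), replace = TRUE)

  lens <- genome_lengths(genome)[out$chrom]
  lf <- ifelse(out$pos > 1L,
               substring(genome$seq[out$chrom], out$pos - 1L, out$pos - 1L),
               "N")
  rt <- ifelse(out$pos < lens,
               substring(genome$seq[out$chrom], out$pos + 1L, out$pos + 1L),
               "N")
  check <- classify_variant(out$ref, out$alt, left = lf, right = rt)
  stopifnot(all(as.character(check$cpg_class) == out$class))

  out$class <- factor(out$class, levels = c("loss", "gain", "both", "none"))
  dplyr::arrange(out[, c("chrom", "pos", "ref", "alt", "class", "category")],
                 .data$chrom, .data$pos)
}

#' Simulate the genotyped cohort
#'
#' Plants the configured variants, draws a base CpG-allele frequency per
#' variant, shifts it per group by the planted EP effect, samples unphased
#' diploid genotypes under Hardy-Weinberg within group, injects per-genotype
#' depth, site QUAL and per-sample missingness, and writes a VCF 4.2
#' (`GT:DP`), a metadata table and the ground truth. Variants are also
#' planted on the excluded sex chromosome; they appear in the VCF but never
#' in the truth totals. Deterministic per seed.
#'
#' @inheritParams simulate_gene_models
#' @param models Transcript models (used to build the feature index for
#'   category-controlled placement).
#' @param dir Output directory (created if needed); files `cohort.vcf`,
#'   `metadata.tsv`, `truth_variants.tsv`, `truth_profiles.tsv` are written
#'   when non-`NULL`.
#' @return List: `vcf` (a `cohort_vcf` of the emitted records, unfiltered),
#'   `metadata` (tibble), `truth` (list with `variants`, `profiles`,
#'   `group_expected_ep`), `paths` (named file paths or `NULL`).
#' @export
simulate_cohort <- function(config, genome, models, dir = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "genome_seq"))
  autosomes <- setdiff(genome_chroms(genome), config$excluded_chroms)
  index <- build_feature_index(models, config$promoter_flank,
                               genome_lengths(genome))

  res <- withr::with_seed(stage_seed(config, "cohort"), {
    variants <- plant_variants(
      genome, index,
      n_loss = config$n_loss, n_gain = config$n_gain, n_none = config$n_none,
      chroms = autosomes, category_props = config$category_props,
      min_spacing = config$min_spacing
    )
    sex_chroms <- intersect(config$excluded_chroms, genome_chroms(genome))
    if (config$n_sex_chrom_variants > 0L && length(sex_chroms) > 0L) {
      zvar <- plant_variants(genome, index = NULL,
                             n_none = config$n_sex_chrom_variants,
                             chroms = sex_chroms,
                             min_spacing = config$min_spacing)
      variants <- dplyr::bind_rows(variants, zvar)
    }
    chrom_order <- factor(variants$chrom, levels = genome_chroms(genome))
    variants <- variants[order(chrom_order, variants$pos), , drop = FALSE]

    metadata <- simulate_metadata(config)
    n_var <- nrow(variants)
    n_samp <- nrow(metadata)

    # base frequency of the CpG-forming allele (alt allele for none-class)
    f_base <- stats::runif(n_var, config$af_range[1], config$af_range[2])
    shift_mat <- outer(rep(0, n_var), config$ep_effect)
    is_cpg_var <- variants$class %in% c("loss", "gain")
    shift_mat[is_cpg_var, ] <- matrix(config$ep_effect, nrow = sum(is_cpg_var),
                                      ncol = 4L, byrow = TRUE)
    f_group <- pmin(pmax(f_base + shift_mat, 0.02), 0.98)  # n_var x 4

    # per-sample alt-allele probability: CpG allele is ref at loss sites
    f_samp <- f_group[, metadata$group, drop = FALSE]
    p_alt <- f_samp
    loss_rows <- variants$class == "loss"
    p_alt[loss_rows, ] <- 1 - f_samp[loss_rows, , drop = FALSE]
    a1 <- matrix(stats::rbinom(n_var * n_samp, 1L, p_alt), n_var, n_samp)
    a2 <- matrix(stats::rbinom(n_var * n_samp, 1L, p_alt), n_var, n_samp)

    dp <- if (!is.null(config$depth_const)) {
      matrix(config$depth_const, n_var, n_samp)
    } else {
      matrix(stats::rnbinom(n_var * n_samp, size = config$depth_size,
                            mu = config$depth_mean), n_var, n_samp)
    }
    qual <- if (!is.null(config$qual_const)) {
      rep(config$qual_const, n_var)
    } else {
      round(pmax(stats::rnorm(n_var, config$qual_mean, config$qual_sd), 1), 1)
    }
    miss_rate <- stats::runif(n_samp, config$miss_range[1],
                              config$miss_range[2])
    miss <- matrix(stats::runif(n_var * n_samp), n_var, n_samp) <
      rep(miss_rate, each = n_var)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_

    list(variants = variants, metadata = metadata, a1 = a1, a2 = a2,
         dp = dp, qual = qual, f_group = f_group)
  })

  sites <- tibble::tibble(
    chrom = res$variants$chrom, pos = res$variants$pos,
    ref = res$variants$ref, alt = res$variants$alt, qual = res$qual
  )
  vcf <- structure(
    list(sites = sites, a1 = res$a1, a2 = res$a2,
         dp = res$dp * 1.0, samples = res$metadata$sample_id),
    n_dropped_nonsnp = 0L, class = "cohort_vcf"
  )

  truth <- cohort_truth(res, genome, autosomes)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = file.path(dir, "cohort.vcf"),
      metadata = file.path(dir, "metadata.tsv"),
      truth_variants = file.path(dir, "truth_variants.tsv"),
      truth_profiles = file.path(dir, "truth_profiles.tsv")
    )
    write_vcf(vcf, genome, paths$vcf)
    readr::write_tsv(res$metadata, paths$metadata)
    readr::write_tsv(truth$variants, paths$truth_variants)
    readr::write_tsv(truth$profiles, paths$truth_profiles)
  }

  list(vcf = vcf, metadata = res$metadata, truth = truth, paths = paths)
}

simulate_metadata <- function(config) {
  n <- sum(config$group_sizes)
  ids <- sprintf("S%03d", seq_len(n))
  group <- rep(1:4, config$group_sizes)
  sex <- unlist(purrr::map(config$group_sexes,
                           function(ms) rep(c("M", "F"), ms)))
  year <- unlist(purrr::map2(config$group_years, config$group_sizes,
                             function(ys, k) {
                               sample(rep(as.integer(ys), length.out = max(k, length(ys))), k)
                             }))
  tibble::tibble(sample_id = ids, group = group, sex = sex, year = year)
}

# ground truth per-sample counts from the emitted genotypes (autosomes only)
cohort_truth <- function(res, genome, autosomes) {
  v <- res$variants
  keep <- v$chrom %in% autosomes
  a1 <- res$a1[keep, , drop = FALSE]
  a2 <- res$a2[keep, , drop = FALSE]
  v <- v[keep, , drop = FALSE]

  any_ref <- (a1 == 0L) | (a2 == 0L)
  any_alt <- (a1 == 1L) | (a2 == 1L)
  hom_alt <- (a1 == 1L) & (a2 == 1L)
  count_rows <- function(hit, rows) {
    if (!any(rows)) return(rep(0L, ncol(a1)))
    as.integer(colSums(hit[rows, , drop = FALSE], na.rm = TRUE))
  }
  is_loss <- v$class %in% c("loss", "both")
  is_gain <- v$class %in% c("gain", "both")
  n_cpg <- count_rows(any_ref, is_loss)
  n_poly <- count_rows(any_alt, is_gain)
  n_none <- count_rows(any_alt, v$class == "none")
  ref_cpg_total <- sum(vapply(autosomes, function(ch) {
    length(enumerate_cpg_sites(genome, ch))
  }, integer(1)))
  total_cpg <- ref_cpg_total - count_rows(hom_alt, is_loss) +
    count_rows(any_alt, is_gain)

  miss_all <- is.na(res$a1) | is.na(res$a2)
  profiles <- tibble::tibble(
    sample_id = res$metadata$sample_id,
    n_cpg = n_cpg, n_polycpg = n_poly, ep_total = n_cpg + n_poly,
    n_noncpg = n_none, total_cpg = as.integer(total_cpg),
    missingness = colMeans(miss_all[keep, , drop = FALSE])
  )

  # expected mean EP per group from the planted allele frequencies
  f <- res$f_group[keep, , drop = FALSE]
  pres <- 1 - (1 - f)^2                      # P(>=1 CpG-forming allele)
  exp_ep <- colSums(pres[is_loss | is_gain, , drop = FALSE])
  list(
    variants = v,
    profiles = profiles,
    group_expected_ep = tibble::tibble(group = 1:4,
                                       expected_ep = exp_ep)
  )
}

#' Write a cohort to VCF 4.2
#'
#' Emits `GT:DP` per genotype and per-site QUAL, with contig header lines
#' from the genome. Formatting is fixed, so identical inputs yield
#' byte-identical files.
#'
#' @param vcf A `cohort_vcf`.
#' @param genome A `genome_seq` supplying contig lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf, genome, path) {
  stopifnot(inherits(vcf, "cohort_vcf"))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", genome_chroms(genome),
            genome_lengths(genome)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vcf$samples), collapse = "\t")
  )
  gt <- matrix(paste0(
    ifelse(is.na(vcf$a1), ".", vcf$a1), "/",
    ifelse(is.na(vcf$a2), ".", vcf$a2), ":",
    ifelse(is.na(vcf$dp), ".", as.character(vcf$dp))
  ), nrow = nrow(vcf$sites))
  body <- paste(
    vcf$sites$chrom, vcf$sites$pos, ".", vcf$sites$ref, vcf$sites$alt,
    as.character(vcf$sites$qual), "PASS", ".",
    "GT:DP",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_reference()],
#' [simulate_gene_models()] and [simulate_cohort()] and writing FASTA,
#' BED12, VCF, metadata and truth files to one directory.
#'
#' @inheritParams simulate_reference
#' @param dir Output directory.
#' @return List: `genome`, `models`, `cohort` (see [simulate_cohort()]),
#'   `paths` (named file paths: `fasta`, `bed12`, plus the cohort files).
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "reference.fa")
  bed <- file.path(dir, "genes.bed")
  genome <- simulate_reference(config, fasta)
  models <- simulate_gene_models(config, genome, bed)
  cohort <- simulate_cohort(config, genome, models, dir)
  list(genome = genome, models = models, cohort = cohort,
       paths = c(list(fasta = fasta, bed12 = bed), cohort$paths))
}
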