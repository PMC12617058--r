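ANNOTATION_LEVELS <- c("promoter", "exon", "intron", "intergenic")

#' Read transcript models from a BED12 file
#'
#' Parses 12-column BED (0-based, half-open) into transcript models with
#' 1-based inclusive internal coordinates. The TSS is strand-aware: the span
#' start on `+`, the span end on `-`.
#'
#' @param path Path to a BED12 file.
#' @return Tibble of transcript models: `name`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, and a list-column `exons` of per-transcript tibbles with
#'   1-based `start`/`end` exon intervals, sorted and within the span.
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) stop("BED12 file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) != 12L) {
    stop("expected 12 BED columns, found ", ncol(raw), call. = FALSE)
  }
  names(raw) <- c("chrom", "start0", "end0", "name", "score", "strand",
                  "thick_start", "thick_end", "rgb", "block_count",
                  "block_sizes", "block_starts")
  if (!all(raw$strand %in% c("+", "-"))) {
    stop("BED12 strand must be '+' or '-'", call. = FALSE)
  }
  parse_ints <- function(x) {
    out <- suppressWarnings(as.integer(strsplit(sub(",$", "", x), ",")[[1]]))
    if (anyNA(out)) stop("malformed BED12 block list: ", x, call. = FALSE)
    out
  }
  exons <- purrr::pmap(raw, function(chrom, start0, end0, block_count,
                                     block_sizes, block_starts, strand, ...) {
    sizes <- parse_ints(block_sizes)
    offsets <- parse_ints(block_starts)
    if (length(sizes) != block_count || length(offsets) != block_count) {
      stop("BED12 block count disagrees with block lists", call. = FALSE)
    }
    ex_start <- start0 + offsets + 1L       # to 1-based inclusive
    ex_end <- start0 + offsets + sizes
    if (any(ex_end > end0) || any(ex_start <= start0 - 1L) ||
        is.unsorted(ex_start, strictly = TRUE) || any(sizes <= 0L)) {
      stop("BED12 blocks exceed the transcript span or are unsorted",
           call. = FALSE)
    }
    tibble::tibble(start = ex_start, end = ex_end)
  })
  tibble::tibble(
    name = as.character(raw$name),
    chrom = raw$chrom,
    strand = raw$strand,
    start = raw$start0 + 1L,
    end = raw$end0,
    tss = ifelse(raw$strand == "+", raw$start0 + 1L, raw$end0),
    exons = exons
  )
}

#' Build the hierarchical feature index
#'
#' Converts transcript models into per-feature interval sets used for
#' hierarchical position annotation: promoters are strand-aware windows of
#' `TSS +/- promoter_flank` bases clipped at chromosome ends; exons are the
#' union of exon blocks over transcripts; introns are the union of transcript
#' spans minus the exon union. Overlapping transcripts are unioned per
#' feature class before precedence is applied.
#'
#' @param models Transcript models from [read_bed12()].
#' @param promoter_flank Bases up- and downstream of the TSS included in the
#'   promoter window (default 1000, i.e. a 2001-bp window).
#' @param seqlengths Named chromosome lengths (e.g. [genome_lengths()]);
#'   promoter windows are clipped to them. Every model chromosome must be
#'   present.
#' @return A `feature_index` object (GRanges per feature class).
#' @export
build_feature_index <- function(models, promoter_flank = 1000L, seqlengths) {
  stopifnot(is.data.frame(models), promoter_flank >= 0)
  unknown <- setdiff(unique(models$chrom), names(seqlengths))
  if (length(unknown) > 0L) {
    stop("transcript chromosome(s) not in seqlengths: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  empty <- GenomicRanges::GRanges(seqlengths = seqlengths)
  if (nrow(models) == 0L) {
    idx <- list(promoters = empty, exons = empty, introns = empty)
  } else {
    spans <- GenomicRanges::GRanges(
      models$chrom, IRanges::IRanges(models$start, models$end),
      strand = models$strand, seqlengths = seqlengths
    )
    # a zero flank disables the promoter feature entirely
    prom <- if (promoter_flank > 0) {
      GenomicRanges::GRanges(
        models$chrom,
        IRanges::IRanges(pmax(models$tss - promoter_flank, 1L),
                         pmin(models$tss + promoter_flank,
                              seqlengths[models$chrom])),
        seqlengths = seqlengths
      )
    } else empty
    ex_tbl <- dplyr::bind_rows(
      purrr::map2(models$exons, seq_len(nrow(models)),
                  function(e, i) dplyr::mutate(e, chrom = models$chrom[i]))
    )
    ex <- GenomicRanges::GRanges(
      ex_tbl$chrom, IRanges::IRanges(ex_tbl$start, ex_tbl$end),
      seqlengths = seqlengths
    )
    idx <- list(
      promoters = GenomicRanges::reduce(prom),
      exons = GenomicRanges::reduce(ex),
      introns = GenomicRanges::setdiff(
        GenomicRanges::reduce(BiocGenerics::unstrand(spans)),
        GenomicRanges::reduce(ex))
    )
  }
  structure(c(idx, list(promoter_flank = promoter_flank,
                        seqlengths = seqlengths)),
            class = "feature_index")
}

#' @export
print.feature_index <- function(x, ...) {
  cat("<feature_index> promoter flank ", x$promoter_flank, " bp; ",
      length(x$promoters), " promoter / ", length(x$exons), " exon / ",
      length(x$introns), " intron interval(s)\n", sep = "")
  invisible(x)
}

#' Hierarchically annotate genomic positions
#'
#' Assigns each 1-bp position to exactly one category with fixed precedence
#' promoter > exon > intron > intergenic: a position inside both a promoter
#' window and an exon is a promoter position. The position annotated for a
#' CpG is its C position.
#'
#' @param index A `feature_index` from [build_feature_index()].
#' @param chrom,pos Vectors of chromosome ids and 1-based positions
#'   (recycled to a common length).
#' @return Factor with levels `promoter`, `exon`, `intron`, `intergenic`.
#' @export
annotate_position <- function(index, chrom, pos) {
  stopifnot(inherits(index, "feature_index"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  unknown <- setdiff(unique(chrom), names(index$seqlengths))
  if (length(unknown) > 0L) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                              seqlengths = index$seqlengths)
  in_set <- function(set) IRanges::overlapsAny(q, set, ignore.strand = TRUE)
  out <- rep("intergenic", n)
  out[in_set(index$introns)] <- "intron"
  out[in_set(index$exons)] <- "exon"
  out[in_set(index$promoters)] <- "promoter"
  factor(out, levels = ANNOTATION_LEVELS)
}

#' Category counts for variant classes and the CpG background
#'
#' Annotates loss-type variants, gain-type variants, non-CpG variants and
#' the background CpG positions, returning per-category counts for each set.
#' "Both"-class variants enter both the loss and the gain set. Each set's
#' counts sum to the set's size (category partition).
#'
#' @param classified Classified variants from [classify_all()] (an
#'   `annotation` column is also added to a copy returned as attribute
#'   `"classified"`).
#' @param background Tibble of background positions (`chrom`, `pos`),
#'   typically from [background_positions()].
#' @param index A `feature_index`.
#' @return Tibble of counts with columns `set` (`loss`, `gain`, `none`,
#'   `background`), `category` and `n` (all four categories present for each
#'   set, zero-filled).
#' @export
annotate_sets <- function(classified, background, index) {
  ann_var <- annotate_position(index, classified$chrom, classified$pos)
  classified$annotation <- ann_var
  ann_bg <- annotate_position(index, background$chrom, background$pos)

  count_set <- function(ann, set) {
    tibble::tibble(set = set,
                   category = factor(ANNOTATION_LEVELS, ANNOTATION_LEVELS),
                   n = as.integer(table(ann)[ANNOTATION_LEVELS]))
  }
  out <- dplyr::bind_rows(
    count_set(ann_var[classified$is_loss], "loss"),
    count_set(ann_var[classified$is_gain], "gain"),
    count_set(ann_var[!classified$is_loss & !classified$is_gain], "none"),
    count_set(ann_bg, "background")
  )
  attr(out, "classified") <- classified
  out
}

#' Background CpG position set for enrichment
#'
#' The expected category distribution is taken from the genomic CpG
#' background. With `mode = "union"` (default) the background is the union
#' of all reference CpG C-positions on the included chromosomes and all
#' gain-variant positions (so both variant types are covered by one
#' background); `mode = "reference"` uses reference CpGs only.
#'
#' @param genome A `genome_seq`.
#' @param classified Classified variants from [classify_all()].
#' @param include_chroms Chromosomes contributing reference CpGs.
#' @param mode `"union"` or `"reference"`.
#' @return Tibble with `chrom` and `pos`, unique positions.
#' @export
background_positions <- function(genome, classified,
                                 include_chroms = unique(classified$chrom),
                                 mode = c("union", "reference")) {
  mode <- match.arg(mode)
  bg <- cpg_map(genome, include_chroms)
  if (mode == "union") {
    gains <- classified[classified$is_gain, c("chrom", "pos")]
    bg <- dplyr::distinct(dplyr::bind_rows(bg, gains))
  }
  dplyr::arrange(bg, .data$chrom, .data$pos)
}
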