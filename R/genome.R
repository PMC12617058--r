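#' Load a reference genome from FASTA
#'
#' Reads a (possibly line-wrapped, mixed-case) multi-record FASTA into a
#' `genome_seq` object: a chromosome-indexed set of uppercase base strings
#' over `{A, C, G, T, N}` with 1-based position access. IUPAC ambiguity codes
#' other than the four bases are mapped to `N`; an `N` never participates in a
#' CpG and never satisfies a classification rule downstream.
#'
#' @param fasta Path to a FASTA file (plain or gzipped).
#' @return A `genome_seq` object. Use [genome_lengths()] for per-chromosome
#'   lengths, [get_flanks()] for flanking bases and [enumerate_cpg_sites()]
#'   for the reference CpG map.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' g <- load_reference(fa)
#' genome_lengths(g)
load_reference <- function(fasta) {
  if (!file.exists(fasta)) {
    stop("FASTA file not found: ", fasta, call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(fasta)
  if (length(set) == 0L) {
    stop("FASTA contains no records: ", fasta, call. = FALSE)
  }
  # FASTA headers keep only the identifier (first whitespace-separated token)
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms)) {
    stop("duplicate FASTA record names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  # collapse every IUPAC ambiguity code (and gaps) to the N sentinel
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- nms
  new_genome_seq(seqs)
}

new_genome_seq <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  structure(list(seq = seqs), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq> ", length(x$seq), " chromosome(s), ",
      format(sum(nchar(x$seq)), big.mark = ","), " bases\n", sep = "")
  invisible(x)
}

#' Per-chromosome lengths of a genome
#'
#' @param genome A `genome_seq` from [load_reference()].
#' @return Named integer vector of chromosome lengths.
#' @export
genome_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_seq"))
  vapply(genome$seq, nchar, integer(1))
}

#' Chromosome names of a genome
#' @inheritParams genome_lengths
#' @return Character vector of chromosome identifiers, in file order.
#' @export
genome_chroms <- function(genome) {
  stopifnot(inherits(genome, "genome_seq"))
  names(genome$seq)
}

check_chrom <- function(genome, chrom) {
  if (!chrom %in% names(genome$seq)) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
}

#' Bases flanking a genomic position
#'
#' Returns the reference bases immediately left (`pos - 1`) and right
#' (`pos + 1`) of a 1-based position. A side that falls off the chromosome end
#' is reported as the `"N"` sentinel, which downstream CpG rules never match.
#'
#' @inheritParams genome_lengths
#' @param chrom Chromosome identifier.
#' @param pos 1-based position(s) within the chromosome (vectorised).
#' @return A tibble with columns `left` and `right`, one row per position.
#' @export
get_flanks <- function(genome, chrom, pos) {
  stopifnot(inherits(genome, "genome_seq"))
  check_chrom(genome, chrom)
  s <- genome$seq[[chrom]]
  len <- nchar(s)
  if (any(pos < 1L | pos > len)) {
    stop("position out of range for ", chrom, " (length ", len, ")",
         call. = FALSE)
  }
  left <- ifelse(pos > 1L, substring(s, pos - 1L, pos - 1L), "N")
  right <- ifelse(pos < len, substring(s, pos + 1L, pos + 1L), "N")
  tibble::tibble(left = left, right = right)
}

#' Enumerate reference CpG sites on a chromosome
#'
#' Returns the 1-based position of the C of every CG dinucleotide on the
#' forward strand — the reference "CpG map" that defines both the loss-variant
#' substrate and the genomic background used for enrichment. CpG context is
#' self-complementary, so a single forward-strand scan covers both strands.
#'
#' @inheritParams get_flanks
#' @return Strictly increasing integer vector of C positions (possibly empty).
#' @export
enumerate_cpg_sites <- function(genome, chrom) {
  stopifnot(inherits(genome, "genome_seq"))
  check_chrom(genome, chrom)
  hits <- gregexpr("CG", genome$seq[[chrom]], fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits)
}

#' All reference CpG positions on a set of chromosomes
#'
#' @inheritParams genome_lengths
#' @param chroms Chromosomes to scan; defaults to all.
#' @return Tibble with columns `chrom` and `pos` (C position of each CpG).
#' @export
cpg_map <- function(genome, chroms = genome_chroms(genome)) {
  purrr::map_dfr(chroms, function(ch) {
    tibble::tibble(chrom = ch, pos = enumerate_cpg_sites(genome, ch))
  })
}

#' Write a genome to FASTA
#'
#' @inheritParams genome_lengths
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_seq"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(genome$seq)) {
    writeLines(paste0(">", ch), con)
    s <- genome$seq[[ch]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
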