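#' Pipeline run configuration
#'
#' Bundles the input paths and stage settings of a full run:
#' filter -> classify -> count -> annotate -> enrich -> fit.
#'
#' @param fasta,vcf,bed12,metadata Input file paths.
#' @param out_dir Output directory (created if needed).
#' @param filter A [filter_config()].
#' @param promoter_flank Promoter window half-width (bases).
#' @param comparisons Comparison names to fit (see [comparison_spec()]).
#' @param responses Response columns to fit per comparison.
#' @param background Background mode for enrichment
#'   (see [background_positions()]).
#' @return A `run_config` list.
#' @export
run_config <- function(fasta, vcf, bed12, metadata, out_dir,
                       filter = filter_config(),
                       promoter_flank = 1000L,
                       comparisons = c("patch_switching", "immigrants",
                                       "colonisation"),
                       responses = "ep_total",
                       background = c("union", "reference")) {
  for (f in c(fasta, vcf, bed12, metadata)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  structure(list(fasta = fasta, vcf = vcf, bed12 = bed12,
                 metadata = metadata, out_dir = out_dir, filter = filter,
                 promoter_flank = as.integer(promoter_flank),
                 comparisons = comparisons, responses = responses,
                 background = match.arg(background)),
            class = "run_config")
}

run_stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' Run the full epigenetic-potential pipeline
#'
#' Executes all stages in order on the configured inputs and writes every
#' output table to `out_dir`: `filter_report.tsv`,
#' `classified_variants.tsv`, `ep_profiles.tsv`, `annotation_counts.tsv`,
#' `enrichment.tsv`, `model_results.json` and `run_log.txt`. All stages are
#' deterministic, so re-running on identical inputs reproduces identical
#' files.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with the in-memory results: `filter_report`,
#'   `classified`, `profiles`, `annotation_counts`, `enrichment`, `fits`
#'   (list of `ep_fit`), `sex_stratified` (follow-up fits where the
#'   interaction p < 0.07), plus `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  note("epipotential pipeline")
  note("inputs: ", config$vcf, " | ", config$fasta, " | ", config$bed12,
       " | ", config$metadata)

  genome <- run_stage("load_reference", note, load_reference(config$fasta))
  note("reference: ", length(genome_chroms(genome)), " chromosome(s), ",
       sum(genome_lengths(genome)), " bases")

  vcf <- run_stage("read_vcf", note, read_vcf(config$vcf))
  note("vcf: ", nrow(vcf$sites), " biallelic SNP record(s), ",
       length(vcf$samples), " sample(s), ",
       attr(vcf, "n_dropped_nonsnp"), " non-SNP allele(s) dropped")

  filt <- run_stage("filter", note, apply_site_filters(vcf, config$filter))
  vcf <- filt$vcf
  note("filter: ", paste(filt$report$rule, filt$report$n, sep = "=",
                         collapse = ", "),
       "; genotypes masked = ", attr(filt$report, "n_genotypes_masked"))
  if (nrow(vcf$sites) == 0L) {
    stop("pipeline stage 'filter' failed: no sites retained", call. = FALSE)
  }

  classified <- run_stage("classify", note, classify_all(vcf, genome))
  tot <- attr(classified, "class_totals")
  note("classify: n_loss=", tot["n_loss"], " n_gain=", tot["n_gain"],
       " n_none=", tot["n_none"])

  include_chroms <- setdiff(genome_chroms(genome),
                            config$filter$excluded_chroms)
  profiles <- run_stage("count", note,
                        ep_profiles(classified, vcf, genome, include_chroms))

  models <- run_stage("read_bed12", note, read_bed12(config$bed12))
  index <- run_stage("feature_index", note,
                     build_feature_index(models, config$promoter_flank,
                                         genome_lengths(genome)))
  bg <- background_positions(genome, classified, include_chroms,
                             mode = config$background)
  counts <- run_stage("annotate", note,
                      annotate_sets(classified, bg, index))
  classified_ann <- attr(counts, "classified")
  note("annotate: background n=", sum(counts$n[counts$set == "background"]))

  enr <- run_stage("enrich", note, enrichment_table(counts))

  # per-sample promoter CpG count as an additional response
  promoter_cpg <- promoter_response(classified_ann, vcf)
  profiles <- dplyr::left_join(profiles, promoter_cpg, by = "sample_id")

  metadata <- run_stage("metadata", note, read_metadata(config$metadata))
  fits <- list()
  followups <- list()
  for (cmp in config$comparisons) {
    for (resp in config$responses) {
      key <- paste(cmp, resp, sep = ".")
      fit <- run_stage(paste0("fit:", key), note, suppressWarnings(
        fit_ep_model(profiles, metadata, cmp, resp)))
      fits[[key]] <- fit
      note("fit ", key, ": ",
           paste(utils::capture.output(print(fit$terms))[-(1:2)],
                 collapse = " | "))
      inter_p <- fit$terms$p_value[fit$terms$term == "group_x_sex"]
      if (is.finite(inter_p) && inter_p < 0.07) {
        for (sx in c("M", "F")) {
          followups[[paste(key, sx, sep = ".")]] <- suppressWarnings(
            sex_stratified_fit(profiles, metadata, cmp, resp, sx))
        }
      }
    }
  }

  paths <- list(
    filter_report = file.path(config$out_dir, "filter_report.tsv"),
    classified = file.path(config$out_dir, "classified_variants.tsv"),
    profiles = file.path(config$out_dir, "ep_profiles.tsv"),
    annotation_counts = file.path(config$out_dir, "annotation_counts.tsv"),
    enrichment = file.path(config$out_dir, "enrichment.tsv"),
    models = file.path(config$out_dir, "model_results.json"),
    log = file.path(config$out_dir, "run_log.txt")
  )
  readr::write_tsv(filt$report, paths$filter_report)
  readr::write_tsv(as_plain_tbl(classified_ann), paths$classified)
  readr::write_tsv(profiles, paths$profiles)
  readr::write_tsv(as_plain_tbl(counts), paths$annotation_counts)
  readr::write_tsv(as_plain_tbl(enr), paths$enrichment)
  model_json <- c(
    purrr::map(fits, function(f) list(
      comparison = f$comparison$name, response = f$response,
      n = nrow(f$data), year_random = f$used_year_random,
      terms = f$terms)),
    purrr::map(followups, function(f) list(
      comparison = f$comparison$name, response = f$response, sex = f$sex,
      n = nrow(f$data), year_random = f$used_year_random,
      terms = f$terms))
  )
  jsonlite::write_json(model_json, paths$models, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, paths$log)

  invisible(list(filter_report = filt$report, classified = classified_ann,
                 profiles = profiles, annotation_counts = counts,
                 enrichment = enr, fits = fits, sex_stratified = followups,
                 paths = paths))
}

as_plain_tbl <- function(x) {
  out <- tibble::as_tibble(as.data.frame(x))
  attr(out, "classified") <- NULL
  attr(out, "class_totals") <- NULL
  out
}

# loss-type promoter sites where the sample retains the CpG, plus gain-type
# promoter sites where it carries the new one
promoter_response <- function(classified_ann, vcf) {
  any_ref <- (vcf$a1 == 0L) | (vcf$a2 == 0L)
  any_alt <- (vcf$a1 == 1L) | (vcf$a2 == 1L)
  in_prom <- classified_ann$annotation == "promoter"
  count_rows <- function(hit, rows) {
    if (!any(rows)) return(rep(0L, length(vcf$samples)))
    as.integer(colSums(hit[rows, , drop = FALSE], na.rm = TRUE))
  }
  tibble::tibble(
    sample_id = vcf$samples,
    promoter_cpg = count_rows(any_ref, in_prom & classified_ann$is_loss) +
      count_rows(any_alt, in_prom & classified_ann$is_gain)
  )
}

#' Read a sample metadata table
#'
#' Tab-separated text with columns `sample_id`, `group` (1-4), `sex`
#' (`M`/`F`), `year`.
#'
#' @param path Path to the TSV file.
#' @return Metadata tibble.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          group = readr::col_integer(),
                          sex = readr::col_character(),
                          year = readr::col_integer()))
  req <- c("sample_id", "group", "sex", "year")
  if (!all(req %in% names(md))) {
    stop("metadata must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  if (!all(md$group %in% 1:4)) stop("group must be in 1..4", call. = FALSE)
  if (!all(md$sex %in% c("M", "F"))) stop("sex must be M/F", call. = FALSE)
  md
}
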