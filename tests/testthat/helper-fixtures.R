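# Shared fixtures and independent oracles.

# build a genome_seq through the public FASTA path
genome_from_strings <- function(seqs) {
  fa <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  con <- file(fa, "wt")
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  close(con)
  load_reference(fa)
}

# write a VCF from a site tibble (chrom,pos,ref,alt,qual) and genotype-string
# matrix (e.g. "0/1"), optional dp matrix; returns the path
write_vcf_text <- function(sites, gt, dp = NULL, samples = colnames(gt),
                           contigs = NULL) {
  path <- tempfile(fileext = ".vcf")  # session tempdir, cleaned on exit
  fmt <- if (is.null(dp)) "GT" else "GT:DP"
  cells <- if (is.null(dp)) gt else {
    matrix(paste0(gt, ":", ifelse(is.na(dp), ".", dp)), nrow = nrow(gt))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs)
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(dp)) {
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"
    },
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                sites$qual, "PASS", ".", fmt,
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  path
}

# pair-level trinucleotide string oracle: builds ref and alt trinucleotides
# and inspects both overlapping dinucleotide windows
oracle_classify <- function(ref, alt, left, right) {
  ref_tri <- c(left, ref, right)
  alt_tri <- c(left, alt, right)
  win <- list(1:2, 2:3)
  ref_cg <- vapply(win, function(w) paste(ref_tri[w], collapse = "") == "CG",
                   logical(1))
  alt_cg <- vapply(win, function(w) paste(alt_tri[w], collapse = "") == "CG",
                   logical(1))
  list(is_loss = any(ref_cg & !alt_cg), is_gain = any(alt_cg & !ref_cg))
}

# full-pmf enumeration oracle for the minimum-likelihood two-sided binomial
# test (standard relative tolerance on probability ties)
oracle_binom_p <- function(k, n, p) {
  d <- stats::dbinom(0:n, n, p)
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

# closed-form weighted least squares via the normal equations
oracle_wls <- function(X, y, w) {
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% y)
  drop(beta)
}

# brute-force haplotype-reconstruction oracle for per-sample EP profiles:
# rebuilds both haplotype sequences and counts CG pairs around each variant
# and genome-wide. Variants are assumed spaced so contexts do not interact.
oracle_profiles <- function(genome, sites, classes, a1, a2,
                            include_chroms = unique(sites$chrom)) {
  n_samp <- ncol(a1)
  out <- vector("list", n_samp)
  keep <- sites$chrom %in% include_chroms
  for (s in seq_len(n_samp)) {
    haps <- lapply(include_chroms, function(ch) {
      b1 <- strsplit(genome$seq[[ch]], "")[[1]]
      b2 <- b1
      rows <- which(sites$chrom == ch)
      for (i in rows) {
        if (!is.na(a1[i, s]) && a1[i, s] == 1L) b1[sites$pos[i]] <- sites$alt[i]
        if (!is.na(a2[i, s]) && a2[i, s] == 1L) b2[sites$pos[i]] <- sites$alt[i]
      }
      list(b1 = b1, b2 = b2)
    })
    names(haps) <- include_chroms

    n_cpg <- 0L; n_poly <- 0L; n_none <- 0L
    for (i in which(keep)) {
      if (is.na(a1[i, s]) || is.na(a2[i, s])) next
      ch <- sites$chrom[i]; p <- sites$pos[i]
      rbase <- strsplit(genome$seq[[ch]], "")[[1]]
      wins <- list(c(p - 1L, p), c(p, p + 1L))
      wins <- wins[vapply(wins, function(w) {
        w[1] >= 1L && w[2] <= length(rbase)
      }, logical(1))]
      ref_cg <- vapply(wins, function(w) {
        rbase[w[1]] == "C" && rbase[w[2]] == "G"
      }, logical(1))
      abase <- rbase; abase[p] <- sites$alt[i]
      alt_cg <- vapply(wins, function(w) {
        abase[w[1]] == "C" && abase[w[2]] == "G"
      }, logical(1))
      hap_cg <- function(hap, w) hap[w[1]] == "C" && hap[w[2]] == "G"
      loss_wins <- which(ref_cg & !alt_cg)
      gain_wins <- which(alt_cg & !ref_cg)
      h <- haps[[ch]]
      if (length(loss_wins) > 0) {
        present <- any(vapply(loss_wins, function(j) {
          hap_cg(h$b1, wins[[j]]) || hap_cg(h$b2, wins[[j]])
        }, logical(1)))
        if (present) n_cpg <- n_cpg + 1L
      }
      if (length(gain_wins) > 0) {
        present <- any(vapply(gain_wins, function(j) {
          hap_cg(h$b1, wins[[j]]) || hap_cg(h$b2, wins[[j]])
        }, logical(1)))
        if (present) n_poly <- n_poly + 1L
      }
      if (length(loss_wins) == 0 && length(gain_wins) == 0 &&
          (a1[i, s] == 1L || a2[i, s] == 1L)) {
        n_none <- n_none + 1L
      }
    }

    # total CpG: union over haplotypes of CG start positions, with missing
    # genotypes contributing the reference state (they already do: no
    # substitution was applied)
    total <- sum(vapply(include_chroms, function(ch) {
      h <- haps[[ch]]
      s1 <- paste(h$b1, collapse = ""); s2 <- paste(h$b2, collapse = "")
      cg1 <- gregexpr("CG", s1, fixed = TRUE)[[1]]
      cg2 <- gregexpr("CG", s2, fixed = TRUE)[[1]]
      cg1 <- cg1[cg1 > 0]; cg2 <- cg2[cg2 > 0]
      length(union(cg1, cg2))
    }, numeric(1)))

    out[[s]] <- tibble::tibble(n_cpg = n_cpg, n_polycpg = n_poly,
                               ep_total = n_cpg + n_poly,
                               n_noncpg = n_none, total_cpg = total)
  }
  dplyr::bind_rows(out)
}

# small metadata table shaped like the study cohort but truncated
toy_metadata <- function(n_per_group = c(6L, 6L, 6L, 6L)) {
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(sum(n_per_group))),
    group = rep(1:4, n_per_group),
    sex = unlist(lapply(n_per_group, function(k) {
      rep(c("M", "F"), length.out = k)
    })),
    year = unlist(Map(function(g, k) {
      if (g == 4) rep(1998L, k) else rep(2016:2019, length.out = k)
    }, 1:4, n_per_group))
  )
}
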