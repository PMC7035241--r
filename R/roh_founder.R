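## Runs of homozygosity, shared founder haplotype, and mutation-age
## estimation.
##
## Genotypes are QC-filtered (depth and genotype quality), homozygous runs
## are called per sample with PLINK-style parameters (min SNPs, min kb,
## max gap, zero tolerated hets -- with zero tolerated hets any het
## terminates a run, so a direct maximal-run caller is behavior-equivalent
## to the windowed scanner for the retained runs), the runs containing a
## focal variant are intersected across carriers, the shared interval is
## converted to centiMorgans on a recombination map, and the age of the
## founder haplotype is estimated from its genetic length under an
## exponential-erosion model.

#' ROH caller parameters (PLINK-style)
#'
#' @param min_snp Minimum homozygous SNPs per run (default 5).
#' @param min_kb Minimum physical span in kb (default 100).
#' @param max_gap_kb Maximum gap between consecutive SNPs in kb
#'   (default 10,000); larger gaps split runs.
#' @param window_het Tolerated heterozygous calls (only 0 is supported:
#'   any het terminates a run).
#' @return List of class \code{roh_params}.
#' @export
roh_params <- function(min_snp = 5, min_kb = 100, max_gap_kb = 10000,
                       window_het = 0) {
  if (any(c(min_snp, min_kb, max_gap_kb, window_het) < 0))
    abort2("ROH parameters must be non-negative", "validation_error")
  if (window_het != 0)
    abort2("only window_het = 0 is supported (any het breaks a run)",
           "validation_error")
  structure(list(min_snp = min_snp, min_kb = min_kb,
                 max_gap_kb = max_gap_kb, window_het = window_het),
            class = "roh_params")
}

#' Read per-sample genotype records from a multi-sample VCF
#'
#' Expects FORMAT fields GT, DP and GQ. Multiallelic sites are dropped and
#' tallied (homozygosity is defined on biallelic genotypes only); missing
#' FORMAT values become `missing` genotype / NA quality.
#'
#' @param path VCF path.
#' @param region Optional coordinate filter `list(contig=, start=, end=)`
#'   (1-based inclusive), e.g. a region surrounding the focal gene.
#' @return Data frame with columns `sample`, `contig`, `pos`, `genotype`
#'   (`hom_ref`/`het`/`hom_alt`/`missing`), `depth`, `gq`. The number of
#'   dropped multiallelic sites is attached as attribute
#'   `"n_multiallelic"`.
#' @export
read_genotypes_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  keep <- !multi
  samples <- colnames(gt)
  recode <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep("missing", length(g))
    out[g %in% "0/0"] <- "hom_ref"
    out[g %in% c("0/1", "1/0")] <- "het"
    out[g %in% "1/1"] <- "hom_alt"
    out
  }
  rows <- lapply(samples, function(s) {
    data.frame(sample = s, contig = fix$CHROM[keep],
               pos = as.numeric(fix$POS[keep]),
               genotype = recode(gt[keep, s]),
               depth = dp[keep, s], gq = gq[keep, s])
  })
  out <- do.call(rbind, rows)
  if (!is.null(region)) {
    out <- out[out$contig == region$contig & out$pos >= region$start &
                 out$pos <= region$end, ]
  }
  rownames(out) <- NULL
  attr(out, "n_multiallelic") <- sum(multi)
  out
}

#' QC-filter genotype records
#'
#' Keeps records with depth and genotype quality at or above the thresholds
#' (inclusive) and a called, non-missing genotype. Records lacking DP or GQ
#' are dropped and tallied.
#'
#' @param records Data frame as from [read_genotypes_vcf()].
#' @param min_dp Minimum read depth (default 10).
#' @param min_gq Minimum phred-scaled genotype quality (default 50).
#' @return Filtered data frame; attribute `"qc"` tallies dropped records by
#'   reason.
#' @export
filter_genotypes <- function(records, min_dp = 10, min_gq = 50) {
  no_fmt <- is.na(records$depth) | is.na(records$gq)
  missing <- records$genotype == "missing"
  low <- !no_fmt & (records$depth < min_dp | records$gq < min_gq)
  keep <- !no_fmt & !missing & !low
  out <- records[keep, ]
  rownames(out) <- NULL
  attr(out, "qc") <- c(n_missing_format = sum(no_fmt),
                       n_missing_genotype = sum(missing & !no_fmt),
                       n_below_threshold = sum(low & !missing))
  out
}

#' Call runs of homozygosity
#'
#' Maximal runs of homozygous calls per sample and contig, terminated by
#' any heterozygous call, by inter-SNP gaps larger than `max_gap_kb`, and
#' by contig ends; runs are retained iff they contain at least `min_snp`
#' SNPs and span at least `min_kb` kb (span = (last - first)/1000).
#' Input must be position-sorted within sample x contig; unsorted input is
#' an error, never silently sorted.
#'
#' @param records QC-filtered genotype data frame (columns `sample`,
#'   `contig`, `pos`, `genotype`).
#' @param params A [roh_params()] object.
#' @return Data frame of segments: `sample`, `contig`, `start_pos`,
#'   `end_pos` (positions of first/last SNP in the run, 1-based),
#'   `n_snps`.
#' @export
call_roh <- function(records, params = roh_params()) {
  segs <- list()
  for (key in unique(paste(records$sample, records$contig, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    d <- records[records$sample == parts[1] & records$contig == parts[2], ]
    if (is.unsorted(d$pos, strictly = FALSE))
      abort2(sprintf("genotypes not position-sorted for %s on %s",
                     parts[1], parts[2]), "validation_error")
    hom <- d$genotype %in% c("hom_ref", "hom_alt")
    ## break before index i when i starts a new run: non-hom, or gap too big
    gap_break <- c(FALSE, diff(d$pos) > params$max_gap_kb * 1000)
    run_id <- cumsum(!hom | gap_break)
    idx <- which(hom)
    if (!length(idx)) next
    for (r in split(idx, run_id[idx])) {
      n <- length(r)
      span_kb <- (d$pos[r[n]] - d$pos[r[1]]) / 1000
      if (n >= params$min_snp && span_kb >= params$min_kb)
        segs[[length(segs) + 1L]] <- data.frame(
          sample = parts[1], contig = parts[2],
          start_pos = d$pos[r[1]], end_pos = d$pos[r[n]], n_snps = n)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(sample = character(0), contig = character(0),
               start_pos = numeric(0), end_pos = numeric(0),
               n_snps = integer(0))
  rownames(out) <- NULL
  out[order(out$sample, out$contig, out$start_pos), ]
}

#' Intersect the focal ROH across carriers
#'
#' For every sample, the ROH segment containing the focal variant is
#' selected; the shared segment is the interval intersection (max of
#' starts, min of ends). A sample without a focal ROH is an error naming
#' the offending samples -- it falsifies the shared-founder hypothesis
#' rather than shrinking the interval.
#'
#' @param segments Data frame from [call_roh()].
#' @param focal_contig,focal_pos Focal variant location (1-based).
#' @return List of class \code{shared_segment}: `contig`, `start_pos`,
#'   `end_pos`, `supporting_samples`.
#' @export
shared_roh <- function(segments, focal_contig, focal_pos) {
  samples <- unique(segments$sample)
  focal <- segments[segments$contig == focal_contig &
                      segments$start_pos <= focal_pos &
                      segments$end_pos >= focal_pos, ]
  lacking <- setdiff(samples, focal$sample)
  if (length(lacking))
    abort2(paste0("no ROH containing the focal variant for sample(s): ",
                  paste(lacking, collapse = ", ")), "no_shared_segment_error")
  structure(list(contig = focal_contig,
                 start_pos = max(focal$start_pos),
                 end_pos = min(focal$end_pos),
                 supporting_samples = sort(unique(focal$sample))),
            class = "shared_segment")
}

#' @exportS3Method base::print
print.shared_segment <- function(x, ...) {
  cat(sprintf("<shared_segment> %s:%s-%s (%.2f Mb, %d samples)\n",
              x$contig, format(x$start_pos, scientific = FALSE),
              format(x$end_pos, scientific = FALSE),
              (x$end_pos - x$start_pos + 1) / 1e6,
              length(x$supporting_samples)))
  invisible(x)
}

#' Read a genetic map (contig, pos, cM)
#'
#' deCODE-style cumulative map: per contig, physical position anchors with
#' non-decreasing cumulative centiMorgan values.
#'
#' @param path TSV with columns `contig` (or `chrom`/`chr`), `pos`, `cM`.
#' @return Data frame of class \code{genetic_map}.
#' @export
read_genetic_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  nm <- names(df)
  cc <- intersect(c("contig", "chrom", "chr"), nm)[1]
  if (is.na(cc) || !all(c("pos", "cM") %in% nm))
    abort2("genetic map needs columns contig/chrom, pos, cM",
           "validation_error")
  df <- data.frame(contig = df[[cc]], pos = as.numeric(df$pos),
                   cM = as.numeric(df$cM))
  for (ct in unique(df$contig)) {
    d <- df[df$contig == ct, ]
    if (is.unsorted(d$pos) || is.unsorted(d$cM))
      abort2(paste0("genetic map anchors not non-decreasing on ", ct),
             "validation_error")
  }
  structure(df, class = c("genetic_map", "data.frame"))
}

#' Genetic length of a physical interval
#'
#' Piecewise-linear interpolation of cumulative cM between map anchors;
#' positions outside the anchor range are extrapolated flat (cM of the
#' nearest anchor) and flagged via attribute `"extrapolated"`.
#'
#' @param map A \code{genetic_map}.
#' @param contig Contig name.
#' @param start,end Physical interval (bp), `start <= end`.
#' @return Length in cM (non-negative).
#' @export
interval_cM <- function(map, contig, start, end) {
  d <- map[map$contig == contig, ]
  if (nrow(d) == 0L)
    abort2(paste0("contig not in genetic map: ", contig), "lookup_error")
  if (end < start) abort2("end < start", "validation_error")
  y <- approx(d$pos, d$cM, xout = c(start, end), rule = 2, ties = "ordered")$y
  out <- y[2] - y[1]
  attr(out, "extrapolated") <-
    start < min(d$pos) || end > max(d$pos)
  out
}

## inverse interpolation: cumulative cM -> physical position (simulator use)
cM_to_pos <- function(map, contig, cM) {
  d <- map[map$contig == contig, ]
  approx(d$cM, d$pos, xout = cM, rule = 2, ties = "ordered")$y
}

#' Estimate founder-mutation age in generations from shared length
#'
#' Erosion model: each of `n_paths` independent meiotic transmission paths
#' from the founder retains, per side of the focal variant, an
#' exponentially distributed segment with mean 100/g cM after g
#' generations. The observed shared interval is the per-side minimum over
#' paths, so its expected total genetic length is 200/(n_paths * g) cM, and
#' the method-of-moments estimate is g_hat = 200/(n_paths * length_cM).
#' Because the shared length is Gamma(2)-distributed, the raw estimator is
#' median-biased upward by the factor 2/qgamma(0.5, 2) (~1.19);
#' `median_debias = TRUE` multiplies it out, making the estimator
#' median-unbiased under the model. The confidence interval is a seeded
#' parametric bootstrap under the fitted erosion model (central quantiles).
#'
#' @param length_cM Genetic length of the shared segment (> 0).
#' @param n_paths Number of independent meiotic transmission paths from the
#'   founder to the observed haplotypes (a study-design input, not
#'   guessed).
#' @param method Estimator name; `"erosion-mom"` is the method above.
#' @param median_debias Apply the median-bias correction factor.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed for the bootstrap.
#' @return Object of class \code{age_estimate}: `length_cM`, `n_paths`,
#'   `generations`, `ci_low`, `ci_high`, `method`.
#' @export
estimate_generations <- function(length_cM, n_paths, method = "erosion-mom",
                                 median_debias = FALSE, n_boot = 1000,
                                 conf = 0.95, seed = NULL) {
  if (length_cM <= 0) abort2("length_cM must be > 0", "validation_error")
  if (n_paths < 1) abort2("n_paths must be >= 1", "validation_error")
  if (method != "erosion-mom")
    abort2(paste0("unknown method: ", method), "validation_error")
  corr <- if (median_debias) qgamma(0.5, shape = 2) / 2 else 1
  ghat <- 200 / (n_paths * length_cM) * corr
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    lstar <- simulate_shared_length_cM(ghat, n_paths, n_boot)
    gstar <- 200 / (n_paths * lstar) * corr
    a <- (1 - conf) / 2
    ci <- unname(quantile(gstar, c(a, 1 - a)))
  }
  structure(list(length_cM = length_cM, n_paths = n_paths,
                 generations = ghat, ci_low = ci[1], ci_high = ci[2],
                 conf = conf, method = if (median_debias)
                   "erosion-mom (median-debiased)" else "erosion-mom"),
            class = "age_estimate")
}

#' @exportS3Method base::print
print.age_estimate <- function(x, ...) {
  cat(sprintf(paste0("<age_estimate> %.1f generations (%d%% CI %.1f-%.1f)",
                     " from %.3f cM over %d paths [%s]\n"),
              x$generations, round(100 * x$conf), x$ci_low, x$ci_high,
              x$length_cM, x$n_paths, x$method))
  invisible(x)
}

#' Simulate shared-segment genetic lengths under the erosion model
#'
#' Draws the total shared length (left + right of the focal variant, each
#' the minimum of `n_paths` exponential segments with mean 100/g cM) --
#' equivalently Gamma(shape 2, rate n_paths * g / 100).
#'
#' @param g True age in generations.
#' @param n_paths Number of meiotic paths.
#' @param n_rep Number of replicates.
#' @return Numeric vector of lengths in cM.
#' @export
simulate_shared_length_cM <- function(g, n_paths, n_rep) {
  rgamma(n_rep, shape = 2, rate = n_paths * g / 100)
}

#' Convert generations to calendar years
#'
#' @param g Generations (> 0).
#' @param years_per_generation Calendar years per generation (default 25).
#' @param digits Optional rounding.
#' @return Years.
#' @export
years_from_generations <- function(g, years_per_generation = 25,
                                   digits = NULL) {
  if (any(g <= 0)) abort2("generations must be > 0", "validation_error")
  out <- g * years_per_generation
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Genomic inbreeding coefficient from ROH
#'
#' F_ROH: the fraction of the (autosomal) genome covered by runs of
#' homozygosity, an estimate of the probability that a random locus is
#' autozygous.
#'
#' @param roh_lengths_bp Numeric vector of ROH segment lengths in bp (or a
#'   [call_roh()] data frame, from which spans are taken).
#' @param genome_bp Total genome length considered (bp).
#' @return F_ROH in `[0, 1]`.
#' @export
inbreeding_from_roh <- function(roh_lengths_bp, genome_bp) {
  if (is.data.frame(roh_lengths_bp))
    roh_lengths_bp <- roh_lengths_bp$end_pos - roh_lengths_bp$start_pos + 1
  if (genome_bp <= 0) abort2("genome_bp must be > 0", "validation_error")
  sum(roh_lengths_bp) / genome_bp
}
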