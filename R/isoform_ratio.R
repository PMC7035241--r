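## Unique-exon isoform-usage ratio across tissues.
##
## For a longest/shortest isoform pair, reads are counted over the exonic
## territory unique to each transcript; the short-fraction ratio
## short / (short + long) is computed per tissue from tissue-averaged
## counts, and genes whose ratio swings widely across tissues (max - min
## strictly greater than a threshold) are flagged as showing
## tissue-specific isoform usage.

iranges_from0 <- function(df) {
  IRanges::IRanges(start = df$start + 1, end = df$end)
}

df_from_iranges <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
}

#' Exonic regions unique to each isoform of a pair
#'
#' Interval set difference of the two exon unions (0-based half-open):
#' `short_only` is exonic in the short transcript but not the long one, and
#' conversely. Identical exon structures yield two empty sets and are
#' flagged indistinguishable (no read can then discriminate the isoforms).
#'
#' @param long_tx,short_tx \code{transcript_model}s of one gene.
#' @return List of class \code{unique_regions}: `gene_id`, `contig`,
#'   `short_only` and `long_only` (data frames with `start`, `end`),
#'   `indistinguishable` flag.
#' @export
unique_regions <- function(long_tx, short_tx) {
  le <- IRanges::reduce(iranges_from0(long_tx$exons))
  se <- IRanges::reduce(iranges_from0(short_tx$exons))
  so <- IRanges::setdiff(se, le)
  lo <- IRanges::setdiff(le, se)
  structure(
    list(gene_id = long_tx$gene_id, contig = long_tx$contig,
         short_only = df_from_iranges(so), long_only = df_from_iranges(lo),
         indistinguishable = length(so) == 0L && length(lo) == 0L),
    class = "unique_regions")
}

#' Count reads over isoform-unique regions
#'
#' A read contributes 1 to each unique region it overlaps by at least one
#' base, and region counts are summed per isoform; a read spanning unique
#' regions of both isoforms therefore increments both counts (per-region
#' counting, the multicov convention). An alternative mode assigns such a
#' read only to the isoform with the larger overlap.
#'
#' @param regions A \code{unique_regions} object.
#' @param reads Data frame of aligned read intervals with columns `start`,
#'   `end` (0-based half-open; BED convention) and optionally `contig`
#'   (reads on other contigs are skipped and tallied) and `sample`.
#' @param mode `"per-region"` (default, double counting retained) or
#'   `"larger-overlap"`.
#' @return If `reads` has a `sample` column, a data frame with one row per
#'   sample (`sample`, `short_count`, `long_count`); otherwise a named
#'   vector `c(short_count, long_count)`. Skipped off-contig reads are in
#'   attribute `"n_skipped"`.
#' @export
count_region_reads <- function(regions, reads,
                               mode = c("per-region", "larger-overlap")) {
  mode <- match.arg(mode)
  reads <- as.data.frame(reads)
  n_skipped <- 0L
  if ("contig" %in% names(reads)) {
    keep <- reads$contig == regions$contig
    n_skipped <- sum(!keep)
    reads <- reads[keep, , drop = FALSE]
  }
  per_sample <- "sample" %in% names(reads)
  samples <- if (per_sample) unique(reads$sample) else "all"
  so <- iranges_from0(regions$short_only)
  lo <- iranges_from0(regions$long_only)
  count_one <- function(rd) {
    if (nrow(rd) == 0L) return(c(short_count = 0, long_count = 0))
    ir <- iranges_from0(rd)
    hits_s <- IRanges::countOverlaps(ir, so)  # regions hit per read
    hits_l <- IRanges::countOverlaps(ir, lo)
    if (mode == "per-region") {
      c(short_count = sum(hits_s), long_count = sum(hits_l))
    } else {
      ov_s <- ov_width(ir, so); ov_l <- ov_width(ir, lo)
      c(short_count = sum(ov_s > 0 & ov_s >= ov_l),
        long_count = sum(ov_l > 0 & ov_l > ov_s))
    }
  }
  res <- t(vapply(samples, function(s) {
    rd <- if (per_sample) reads[reads$sample == s, , drop = FALSE] else reads
    count_one(rd)
  }, c(short_count = 0, long_count = 0)))
  out <- if (per_sample)
    data.frame(sample = samples, short_count = res[, 1], long_count = res[, 2],
               row.names = NULL)
  else c(short_count = unname(res[1, 1]), long_count = unname(res[1, 2]))
  attr(out, "n_skipped") <- n_skipped
  out
}

## total overlapped width of each query range against a subject set
ov_width <- function(query, subject) {
  hits <- IRanges::findOverlaps(query, subject)
  w <- IRanges::width(IRanges::pintersect(
    query[S4Vectors::queryHits(hits)], subject[S4Vectors::subjectHits(hits)]))
  out <- numeric(length(query))
  if (length(hits))
    out <- vapply(seq_along(query), function(i)
      sum(w[S4Vectors::queryHits(hits) == i]), numeric(1))
  out
}

#' Per-tissue isoform-usage ratios and cross-tissue variability
#'
#' Counts are averaged across the samples of each tissue first, then the
#' short-fraction ratio `short / (short + long)` is computed from the tissue
#' means (not as a ratio of per-sample ratios). Tissues whose mean total
#' count falls below `min_count` are left undefined, which prevents 0/1
#' ratio artifacts from single reads. Variability is the range (max - min)
#' of the defined tissue ratios and is itself undefined for genes with
#' fewer than two defined tissues.
#'
#' @param counts Data frame with columns `sample`, `gene_id`, `short_count`,
#'   `long_count`.
#' @param samples Data frame mapping `sample` to `tissue`.
#' @param min_count Minimum mean total count for a tissue ratio to be
#'   defined (default 10).
#' @return List with `ratios` (gene x tissue long-format data frame:
#'   `gene_id`, `tissue`, `mean_short`, `mean_long`, `ratio`) and `profiles`
#'   (per gene: `n_tissues_defined`, `variability`).
#' @export
tissue_ratios <- function(counts, samples, min_count = 10) {
  counts <- as.data.frame(counts)
  samples <- as.data.frame(samples)
  miss <- setdiff(counts$sample, samples$sample)
  if (length(miss))
    abort2(paste0("samples without tissue label: ",
                  paste(miss, collapse = ", ")), "validation_error")
  counts$tissue <- samples$tissue[match(counts$sample, samples$sample)]
  agg <- stats::aggregate(cbind(mean_short = short_count,
                                mean_long = long_count) ~ gene_id + tissue,
                          data = counts, FUN = mean)
  tot <- agg$mean_short + agg$mean_long
  agg$ratio <- ifelse(tot >= min_count & tot > 0, agg$mean_short / tot, NA)
  agg <- agg[order(agg$gene_id, agg$tissue), ]
  rownames(agg) <- NULL
  prof <- do.call(rbind, lapply(split(agg, agg$gene_id), function(d) {
    r <- d$ratio[!is.na(d$ratio)]
    data.frame(gene_id = d$gene_id[1], n_tissues_defined = length(r),
               variability = if (length(r) >= 2L) max(r) - min(r) else NA_real_)
  }))
  rownames(prof) <- NULL
  list(ratios = agg, profiles = prof)
}

#' Flag genes with high cross-tissue isoform-usage variability
#'
#' A gene is flagged iff its ratio range across defined tissues is strictly
#' greater than `threshold`. Genes with fewer than two defined tissue
#' ratios cannot be assessed and are reported separately.
#'
#' @param profiles The `profiles` data frame from [tissue_ratios()].
#' @param threshold Strict variability threshold (default 0.5).
#' @return Data frame `gene_id`, `variability`, `flagged`; genes excluded
#'   for lack of defined tissues are in attribute `"excluded"`.
#' @export
variability_filter <- function(profiles, threshold = 0.5) {
  assessable <- profiles$n_tissues_defined >= 2L
  out <- data.frame(gene_id = profiles$gene_id[assessable],
                    variability = profiles$variability[assessable])
  out$flagged <- out$variability > threshold
  attr(out, "excluded") <- profiles$gene_id[!assessable]
  out
}

#' Read a counts table (sample, gene, short/long counts)
#' @param path TSV with columns `sample`, `gene_id`, `short_count`,
#'   `long_count`.
#' @return Data frame.
#' @export
read_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "gene_id", "short_count", "long_count")
  if (!all(need %in% names(df)))
    abort2(paste0("counts table must have columns: ",
                  paste(need, collapse = ", ")), "validation_error")
  df
}

#' Read a sample-to-tissue map
#' @param path TSV with columns `sample`, `tissue`.
#' @return Data frame.
#' @export
read_samples <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample", "tissue") %in% names(df)))
    abort2("samples table must have columns: sample, tissue",
           "validation_error")
  df
}
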