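## Genome-wide isoform containment scan and candidate filter cascade.
##
## A gene is a candidate when its shorter protein isoform is an exact,
## in-frame N-terminal truncation of the longer isoform: every residue of
## the short protein matches the long protein from residue k+1 on, and the
## short isoform's start ATG lies inside the long CDS at frame offset 0
## (so a single start-codon variant can ablate the short isoform only).

#' Select the longest/shortest coding isoform pair of a gene
#'
#' The longest and shortest transcripts by spliced CDS length are compared;
#' ties are broken by lexicographic transcript id so the choice is
#' deterministic. Genes with fewer than two coding transcripts yield
#' \code{NULL} (single-transcript genes cannot carry an isoform-specific
#' start-loss).
#'
#' @param transcripts List of \code{transcript_model} for one gene.
#' @return List with elements `long` and `short`, or \code{NULL}.
#' @export
select_isoform_pair <- function(transcripts) {
  if (length(transcripts) < 2L) return(NULL)
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  lens <- vapply(transcripts, cds_length, numeric(1))
  ord <- order(-lens, ids)          # longest first, ties by id
  long <- transcripts[[ord[1L]]]
  rest <- ord[-1L]
  ## shortest among the remaining, ties by id
  short <- transcripts[[rest[order(lens[rest], ids[rest])][1L]]]
  list(long = long, short = short)
}

#' Test whether the short isoform is an in-frame N-terminal truncation
#'
#' Exact-match containment anchored at the in-frame ATG: the short protein
#' must equal the long protein's suffix starting at residue
#' `n_term_truncation_aa + 1`, with no gaps or mismatches. Because the
#' criterion demands complete identity, anchored string equality is
#' equivalent to an ungapped zero-mismatch alignment. Transcripts on
#' different contigs or strands give a structural-mismatch result
#' (`contained = FALSE`), not an error; transcripts whose CDS fails
#' translation propagate a classed error that [scan_annotation()] turns into
#' a logged skip.
#'
#' @param long_tx,short_tx \code{transcript_model}s of one gene.
#' @param genome A \code{genome_sequence}.
#' @param all_offsets Diagnostic mode: also report every ungapped offset at
#'   which the short protein occurs inside the long protein, ATG-anchored or
#'   not.
#' @return One-row data frame with columns `gene_id`, `long_tx`, `short_tx`,
#'   `contained`, `in_frame_atg`, `truncation_aa` (NA unless contained).
#'   With `all_offsets = TRUE`, an attribute `"offsets"` (0-based) is
#'   attached.
#' @export
check_containment <- function(long_tx, short_tx, genome, all_offsets = FALSE) {
  res <- data.frame(
    gene_id = long_tx$gene_id,
    long_tx = long_tx$transcript_id,
    short_tx = short_tx$transcript_id,
    contained = FALSE, in_frame_atg = FALSE,
    truncation_aa = NA_integer_)
  if (long_tx$contig != short_tx$contig || long_tx$strand != short_tx$strand)
    return(res)
  long_p <- transcript_protein(long_tx, genome)
  short_p <- transcript_protein(short_tx, genome)
  atg <- start_codon_gpos(short_tx)
  cpos <- tryCatch(genomic_to_cds(long_tx, atg),
                   not_in_cds_error = function(e) NA_real_)
  if (!is.na(cpos) && (cpos - 1) %% 3 == 0) {
    res$in_frame_atg <- TRUE
    k <- as.integer((cpos - 1) / 3)
    if (nchar(long_p) == k + nchar(short_p) &&
        substr(long_p, k + 1L, nchar(long_p)) == short_p) {
      res$contained <- TRUE
      res$truncation_aa <- k
    }
  }
  if (all_offsets) {
    nl <- nchar(long_p); ns <- nchar(short_p)
    offs <- if (ns <= nl)
      which(vapply(0:(nl - ns), function(j)
        substr(long_p, j + 1L, j + ns) == short_p, logical(1))) - 1L
    else integer(0)
    attr(res, "offsets") <- offs
  }
  res
}

#' Scan an annotation for isoform-containment candidate genes
#'
#' Runs [select_isoform_pair()] and [check_containment()] over every
#' multi-transcript gene. Genes whose chosen transcripts fail translation
#' (no stop, internal stop, ambiguity base) are skipped with a warning, as
#' in tolerant genome-wide scans; output order is deterministic by gene id.
#'
#' @param transcripts List of \code{transcript_model} (any genes).
#' @param genome A \code{genome_sequence}.
#' @return Data frame, one row per multi-transcript gene, columns as in
#'   [check_containment()]. Skipped gene ids are attached as attribute
#'   `"skipped"`.
#' @export
scan_annotation <- function(transcripts, genome) {
  genes <- split(transcripts, vapply(transcripts, `[[`, "", "gene_id"))
  genes <- genes[order(names(genes))]
  rows <- list(); skipped <- character(0)
  for (gid in names(genes)) {
    pair <- select_isoform_pair(genes[[gid]])
    if (is.null(pair)) next
    row <- tryCatch(
      check_containment(pair$long, pair$short, genome),
      startloss_error = function(e) {
        warning(sprintf("skipping gene %s: %s", gid, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(row)) skipped <- c(skipped, gid) else rows[[gid]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), long_tx = character(0),
               short_tx = character(0), contained = logical(0),
               in_frame_atg = logical(0), truncation_aa = integer(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Apply the candidate-gene filter cascade
#'
#' Four nested stages over containment results: (1) containment-positive
#' genes; (2) intersected with an essential-gene list; (3) minus genes with
#' a disease annotation; (4) N-terminal truncation strictly less than
#' `max_truncation_aa` amino acids (the strict inequality excludes a gene
#' at exactly the threshold). Survivor sets are nested, so stage counts are
#' non-increasing.
#'
#' @param results Data frame from [scan_annotation()].
#' @param essential_ids Character vector of essential gene ids.
#' @param disease_ids Character vector of disease-annotated gene ids.
#' @param max_truncation_aa Strict upper bound on truncation length
#'   (default 50 aa).
#' @return An object of class \code{filter_cascade}: list with `stages`
#'   (data frame of stage name and count) and `survivors` (list of gene-id
#'   vectors per stage), plus threshold metadata.
#' @export
apply_filters <- function(results, essential_ids, disease_ids,
                          max_truncation_aa = 50) {
  if (length(essential_ids) == 0L)
    warning("empty essential-gene list: stage 2 will be empty", call. = FALSE)
  s1 <- results$gene_id[results$contained]
  s2 <- s1[s1 %in% essential_ids]
  s3 <- s2[!s2 %in% disease_ids]
  trunc <- results$truncation_aa[match(s3, results$gene_id)]
  s4 <- s3[!is.na(trunc) & trunc < max_truncation_aa]
  survivors <- list(contained = s1, essential = s2,
                    no_disease_annotation = s3, truncation_below_max = s4)
  structure(
    list(stages = data.frame(stage = names(survivors),
                             count = lengths(survivors)),
         survivors = survivors,
         max_truncation_aa = max_truncation_aa),
    class = "filter_cascade")
}

#' @exportS3Method base::print
print.filter_cascade <- function(x, ...) {
  cat("<filter_cascade> (truncation < ", x$max_truncation_aa, " aa)\n",
      sep = "")
  df <- x$stages; rownames(df) <- NULL
  print(df)
  invisible(x)
}

#' Read a one-column gene-id list (TSV)
#'
#' Plain one-column files of gene ids, as used for essential-gene and
#' disease-annotation lists. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort2(paste0("no such file: ", path), "io_error")
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write candidate table and cascade summary
#'
#' @param results Data frame from [scan_annotation()].
#' @param cascade A \code{filter_cascade}.
#' @param candidates_path,cascade_path Output TSV / JSON paths.
#' @return Invisibly, `candidates_path`.
#' @export
write_candidates <- function(results, cascade, candidates_path, cascade_path) {
  out <- results
  for (nm in names(cascade$survivors))
    out[[paste0("stage_", nm)]] <- out$gene_id %in% cascade$survivors[[nm]]
  write.table(out, candidates_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(stages = cascade$stages$stage, counts = cascade$stages$count,
         max_truncation_aa = cascade$max_truncation_aa),
    cascade_path, auto_unbox = TRUE)
  invisible(candidates_path)
}
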