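## Genome / annotation data model.
##
## Internal coordinate convention: 0-based half-open intervals everywhere.
## GTF and VCF are 1-based; conversion happens at the I/O boundary only.

#' Construct a genome sequence object
#'
#' A genome is a named set of contig sequences over the alphabet
#' \code{A,C,G,T,N} (uppercase). This is the sequence substrate for all
#' coordinate-resolved operations (CDS extraction, variant annotation,
#' simulation).
#'
#' @param contigs Named character vector or list, contig name -> sequence.
#' @return An object of class \code{genome_sequence} (named character vector).
#' @export
genome_sequence <- function(contigs) {
  contigs <- unlist(contigs)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    abort2("contig names must be present and unique", "validation_error")
  contigs <- toupper(contigs)
  if (any(nchar(contigs) == 0L))
    abort2("contig sequences must be non-empty", "validation_error")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    abort2(sprintf("contig '%s' contains characters outside A/C/G/T/N",
                   names(contigs)[bad][1]), "validation_error")
  structure(contigs, class = "genome_sequence")
}

#' Read a multi-contig FASTA file as a genome
#'
#' @param path Path to a FASTA file.
#' @return A \code{genome_sequence}.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort2(paste0("no such file: ", path), "io_error")
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  genome_sequence(setNames(as.character(ss), nm))
}

#' Write a genome to FASTA
#'
#' @param genome A \code{genome_sequence}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

contig_seq <- function(genome, contig) {
  if (!contig %in% names(genome))
    abort2(paste0("contig not in genome: ", contig), "lookup_error")
  unclass(genome)[[contig]]
}

#' Construct a transcript model
#'
#' A transcript's exon and CDS structure on a genome, with strand-aware
#' coordinate maps between genomic, CDS and protein spaces. Coordinates are
#' internal 0-based half-open; use [read_gtf()] to ingest 1-based GTF.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end` (0-based half-open),
#'   sorted by genomic position and non-overlapping.
#' @param cds_start,cds_end Genomic bounds of the coding region
#'   (0-based half-open). The spliced CDS length must be a positive multiple
#'   of 3 (at least 6: one codon plus a stop).
#' @return An object of class \code{transcript_model}.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand,
                             exons, cds_start, cds_end) {
  if (!strand %in% c("+", "-"))
    abort2(paste0("invalid strand for ", transcript_id), "validation_error")
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.numeric(exons$start); exons$end <- as.numeric(exons$end)
  if (nrow(exons) == 0L || any(exons$end <= exons$start))
    abort2(paste0("empty or inverted exon in ", transcript_id),
           "validation_error")
  if (is.unsorted(exons$start, strictly = TRUE) && nrow(exons) > 1L)
    abort2(paste0("exons not sorted by genomic position in ", transcript_id),
           "validation_error")
  if (nrow(exons) > 1L && any(exons$start[-1] < exons$end[-nrow(exons)]))
    abort2(paste0("overlapping exons in ", transcript_id), "validation_error")
  cds_start <- as.numeric(cds_start); cds_end <- as.numeric(cds_end)
  if (cds_end <= cds_start)
    abort2(paste0("empty CDS in ", transcript_id), "validation_error")
  tx <- structure(
    list(transcript_id = transcript_id, gene_id = gene_id, contig = contig,
         strand = strand, exons = exons,
         cds_start = cds_start, cds_end = cds_end),
    class = "transcript_model")
  ivl <- cds_exon_intervals(tx)
  ## CDS boundaries must fall inside exons, and the spliced length must code
  if (min(ivl$start) != cds_start || max(ivl$end) != cds_end)
    abort2(paste0("CDS extends outside exons in transcript ", transcript_id),
           "validation_error")
  len <- sum(ivl$end - ivl$start)
  if (len %% 3L != 0L || len < 6)
    abort2(sprintf("spliced CDS length %d invalid (transcript %s)",
                   len, transcript_id), "validation_error")
  tx
}

#' @exportS3Method base::print
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s%s | %d exon(s), CDS %d nt\n",
              x$transcript_id, x$gene_id, x$contig, x$strand,
              nrow(x$exons), cds_length(x)))
  invisible(x)
}

## genomic intervals of the coding footprint (exon ∩ CDS), genomic order
cds_exon_intervals <- function(tx) {
  s <- pmax(tx$exons$start, tx$cds_start)
  e <- pmin(tx$exons$end, tx$cds_end)
  keep <- e > s
  if (!any(keep))
    abort2(paste0("CDS outside exon union in ", tx$transcript_id),
           "validation_error")
  data.frame(start = s[keep], end = e[keep])
}

#' Spliced CDS length of a transcript
#' @param tx A \code{transcript_model}.
#' @return Length in nucleotides (multiple of 3).
#' @export
cds_length <- function(tx) {
  ivl <- cds_exon_intervals(tx)
  sum(ivl$end - ivl$start)
}

#' Read transcript models from a GTF file
#'
#' Parses an Ensembl-dialect GTF (1-based closed coordinates, `exon` and
#' `CDS` features carrying `gene_id`/`transcript_id` attributes) and converts
#' to the internal 0-based half-open convention. Parsing is delegated to
#' rtracklayer; structural validation (CDS within exons, coding length) is
#' performed per transcript.
#'
#' @param path Path to a GTF file.
#' @return A named list of \code{transcript_model} objects.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort2(paste0("no such file: ", path), "io_error")
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   abort2(sprintf("GTF parse error in '%s': %s",
                                  path, conditionMessage(e)), "parse_error"))
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1,   # to 0-based half-open
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type   = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id)
  df <- df[df$type %in% c("exon", "CDS") & !is.na(df$transcript_id), ]
  out <- list()
  for (txid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == txid, ]
    ex <- sub[sub$type == "exon", ]
    cds <- sub[sub$type == "CDS", ]
    if (nrow(ex) == 0L || nrow(cds) == 0L) next  # non-coding or incomplete
    ex <- ex[order(ex$start), ]
    ## every CDS chunk must sit inside some exon
    inside <- vapply(seq_len(nrow(cds)), function(i)
      any(ex$start <= cds$start[i] & cds$end[i] <= ex$end), logical(1))
    if (!all(inside))
      abort2(paste0("CDS outside exons in transcript ", txid),
             "validation_error")
    out[[txid]] <- transcript_model(
      transcript_id = txid, gene_id = ex$gene_id[1], contig = ex$contig[1],
      strand = ex$strand[1], exons = ex[, c("start", "end")],
      cds_start = min(cds$start), cds_end = max(cds$end))
  }
  out
}

#' Write transcript models to a GTF file
#'
#' Emits `exon` and `CDS` features in Ensembl dialect (1-based closed), the
#' exact inverse of [read_gtf()]: a write-then-read round trip reproduces the
#' models.
#'
#' @param transcripts List of \code{transcript_model}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(transcripts, path) {
  rows <- lapply(transcripts, function(tx) {
    ex <- tx$exons
    cds <- cds_exon_intervals(tx)
    ## frame column: bases to skip before the next codon start, per CDS
    ## chunk in coding order
    w <- cds$end - cds$start
    if (tx$strand == "-") w <- rev(w)
    phase <- (3 - cumsum(c(0, w[-length(w)])) %% 3) %% 3
    if (tx$strand == "-") phase <- rev(phase)
    data.frame(
      contig = tx$contig,
      start = c(ex$start, cds$start) + 1,
      end = c(ex$end, cds$end),
      strand = tx$strand,
      type = c(rep("exon", nrow(ex)), rep("CDS", nrow(cds))),
      phase = c(rep(NA_integer_, nrow(ex)), phase),
      gene_id = tx$gene_id, transcript_id = tx$transcript_id)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  gr$source <- "startloss"
  gr$type <- df$type
  gr$phase <- df$phase
  gr$gene_id <- df$gene_id
  gr$transcript_id <- df$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Spliced CDS sequence of a transcript
#'
#' Returns the coding sequence 5'->3' in coding orientation
#' (reverse-complemented for minus-strand transcripts).
#'
#' @param tx A \code{transcript_model}.
#' @param genome A \code{genome_sequence}.
#' @return A nucleotide string whose length is a multiple of 3.
#' @export
cds_sequence <- function(tx, genome) {
  seqc <- contig_seq(genome, tx$contig)
  ivl <- cds_exon_intervals(tx)
  parts <- substring(seqc, ivl$start + 1, ivl$end)
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  s
}

## spliced sequence from CDS start through the transcript 3' end (coding
## orientation) -- the substrate for frameshift termination scanning, which
## may run past the annotated stop into the 3' UTR
coding_and_downstream_sequence <- function(tx, genome) {
  seqc <- contig_seq(genome, tx$contig)
  ex <- tx$exons
  if (tx$strand == "+") {
    s <- pmax(ex$start, tx$cds_start); e <- ex$end
  } else {
    s <- ex$start; e <- pmin(ex$end, tx$cds_end)
  }
  keep <- e > s
  parts <- substring(seqc, s[keep] + 1, e[keep])
  out <- paste(parts, collapse = "")
  if (tx$strand == "-") out <- revcomp(out)
  out
}

#' Translate a coding sequence
#'
#' Standard-code translation that stops at the first stop codon, which must
#' exist within the sequence. Ambiguity bases (N) in a codon raise an error
#' so that genome-wide scans can skip the transcript.
#'
#' @param cds Nucleotide string, length a multiple of 3.
#' @param require_atg Require the sequence to begin with ATG.
#' @return A list with `protein` (residues, no terminator) and
#'   `internal_stop` (TRUE if a stop occurred before the final codon).
#' @export
translate_cds <- function(cds, require_atg = TRUE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    abort2("CDS length not a multiple of 3", "validation_error")
  if (require_atg && substr(cds, 1, 3) != "ATG")
    abort2("CDS does not start with ATG", "validation_error")
  sc <- scan_translation(cds)
  if (!sc$has_stop) abort2("no stop codon in frame", "no_stop_error")
  if (sc$ambiguous_before_stop)
    abort2("ambiguity base (N) in CDS before stop", "ambiguous_base_error")
  list(protein = sc$protein, internal_stop = sc$stop_codon_index < n / 3L)
}

## translate an arbitrary in-frame window until the first stop; trailing
## partial codons are ignored.  Returns the residues before the stop, whether
## a stop was found, and its 1-based codon index.
scan_translation <- function(seq) {
  seq <- toupper(seq)
  nc <- nchar(seq) %/% 3L
  if (nc == 0L)
    return(list(protein = "", has_stop = FALSE, stop_codon_index = NA_integer_,
                ambiguous_before_stop = FALSE))
  starts <- seq.int(1L, by = 3L, length.out = nc)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_idx <- which(!is.na(aa) & aa == "*")[1]
  if (is.na(stop_idx)) {
    list(protein = paste(ifelse(is.na(aa), "X", aa), collapse = ""),
         has_stop = FALSE, stop_codon_index = NA_integer_,
         ambiguous_before_stop = anyNA(aa))
  } else {
    pre <- if (stop_idx > 1L) aa[seq_len(stop_idx - 1L)] else character(0)
    list(protein = paste(ifelse(is.na(pre), "X", pre), collapse = ""),
         has_stop = TRUE, stop_codon_index = stop_idx,
         ambiguous_before_stop = anyNA(pre))
  }
}

#' Map a genomic position to a CDS (c.) position
#'
#' HGVS-style c. numbering: position 1 is the A of the start ATG. Positions
#' outside the coding exonic footprint are rejected (no UTR negative
#' numbering), carrying the nearest CDS boundary in the error condition.
#'
#' @param tx A \code{transcript_model}.
#' @param gpos 1-based genomic position.
#' @return 1-based CDS position.
#' @export
genomic_to_cds <- function(tx, gpos) {
  g0 <- gpos - 1
  ivl <- cds_exon_intervals(tx)
  hit <- which(ivl$start <= g0 & g0 < ivl$end)
  if (length(hit) == 0L) {
    bounds <- c(ivl$start + 1, ivl$end)
    nearest <- bounds[which.min(abs(bounds - gpos))]
    abort2(sprintf("position %s not in CDS of %s (nearest CDS boundary %s)",
                   format(gpos, scientific = FALSE), tx$transcript_id,
                   format(nearest, scientific = FALSE)),
           "not_in_cds_error", nearest = nearest)
  }
  w <- ivl$end - ivl$start
  if (tx$strand == "+") {
    before <- if (hit > 1L) sum(w[seq_len(hit - 1L)]) else 0
    before + (g0 - ivl$start[hit]) + 1
  } else {
    k <- nrow(ivl)
    after <- if (hit < k) sum(w[seq.int(hit + 1L, k)]) else 0
    after + (ivl$end[hit] - 1 - g0) + 1
  }
}

#' Map a CDS (c.) position back to the genome
#'
#' Inverse of [genomic_to_cds()]; the round trip is the identity on every
#' coding position.
#'
#' @param tx A \code{transcript_model}.
#' @param cpos 1-based CDS position.
#' @return 1-based genomic position.
#' @export
cds_to_genomic <- function(tx, cpos) {
  if (cpos < 1) abort2("CDS position must be >= 1", "validation_error")
  ivl <- cds_exon_intervals(tx)
  w <- ivl$end - ivl$start
  if (cpos > sum(w))
    abort2(sprintf("CDS position %d beyond CDS length %d of %s",
                   cpos, sum(w), tx$transcript_id), "not_in_cds_error")
  if (tx$strand == "-") { ivl <- ivl[rev(seq_len(nrow(ivl))), ]; w <- rev(w) }
  cum <- cumsum(w)
  i <- which(cpos <= cum)[1]
  off <- cpos - 1 - (if (i > 1L) cum[i - 1L] else 0)
  if (tx$strand == "+") ivl$start[i] + off + 1 else ivl$end[i] - off
}

#' Codon index and offset of a CDS position
#'
#' @param cpos 1-based CDS position.
#' @return List with `codon_index` (1-based) and `offset` (0..2 within the
#'   codon).
#' @export
cds_to_codon <- function(cpos) {
  if (any(cpos < 1)) abort2("CDS position must be >= 1", "validation_error")
  list(codon_index = (cpos - 1) %/% 3 + 1, offset = (cpos - 1) %% 3)
}

#' Protein sequence of a transcript
#'
#' Convenience composition of [cds_sequence()] and [translate_cds()].
#' Transcripts whose CDS fails translation (no in-frame stop, internal stop,
#' ambiguity bases) raise classed errors that scanning callers treat as
#' skips.
#'
#' @param tx A \code{transcript_model}.
#' @param genome A \code{genome_sequence}.
#' @param require_atg Require the CDS to start with ATG.
#' @return Residue string (no terminator).
#' @export
transcript_protein <- function(tx, genome, require_atg = TRUE) {
  tr <- translate_cds(cds_sequence(tx, genome), require_atg = require_atg)
  if (tr$internal_stop)
    abort2(paste0("internal stop codon in ", tx$transcript_id),
           "internal_stop_error")
  tr$protein
}

## 1-based genomic position of the first coding base (the A of the ATG)
start_codon_gpos <- function(tx) {
  if (tx$strand == "+") tx$cds_start + 1 else tx$cds_end
}
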