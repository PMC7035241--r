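# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the code paths they check.

# per-base walk over exon/CDS structure: build the coding sequence one
# genomic base at a time, complementing for minus strand
oracle_cds_walk <- function(tx, genome) {
  seqc <- unclass(genome)[[tx$contig]]
  pos <- unlist(lapply(seq_len(nrow(tx$exons)), function(i)
    seq(tx$exons$start[i], tx$exons$end[i] - 1L)))
  pos <- pos[pos >= tx$cds_start & pos < tx$cds_end]
  bases <- substring(seqc, pos + 1L, pos + 1L)
  if (tx$strand == "-")
    paste(rev(chartr("ACGT", "TGCA", bases)), collapse = "")
  else paste(bases, collapse = "")
}

# translation oracle via Biostrings::translate (not the codon-table lookup
# the package uses)
oracle_translate <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  sub("\\*.*$", "", aa)
}

# all ungapped offsets (0-based) at which `short` matches inside `long`
# with zero mismatches
oracle_offsets <- function(long_p, short_p) {
  nl <- nchar(long_p); ns <- nchar(short_p)
  if (ns > nl) return(integer(0))
  which(vapply(0:(nl - ns), function(j)
    substr(long_p, j + 1L, j + ns) == short_p, logical(1))) - 1L
}

# brute-force enumeration of maximal homozygous runs satisfying the four
# ROH constraints
oracle_roh <- function(pos, gt, min_snp = 5, min_kb = 100,
                       max_gap_kb = 10000) {
  n <- length(pos)
  hom <- gt %in% c("hom_ref", "hom_alt")
  ok_window <- function(i, j) {
    idx <- i:j
    all(hom[idx]) &&
      (j == i || all(diff(pos[idx]) <= max_gap_kb * 1000))
  }
  segs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!ok_window(i, j)) next
      maximal <- (i == 1 || !ok_window(i - 1, j)) &&
        (j == n || !ok_window(i, j + 1))
      if (maximal && (j - i + 1) >= min_snp &&
          (pos[j] - pos[i]) / 1000 >= min_kb)
        segs[[length(segs) + 1L]] <- c(start_pos = pos[i], end_pos = pos[j],
                                       n_snps = j - i + 1)
    }
  }
  if (!length(segs))
    return(data.frame(start_pos = numeric(0), end_pos = numeric(0),
                      n_snps = integer(0)))
  as.data.frame(do.call(rbind, segs))
}

# rebuild the full mutant CDS after a substitution and diff the
# translations; classify by the same biological definitions, independently
# of annotate_snv's codon arithmetic
oracle_snv <- function(var, tx, genome) {
  seqc <- unclass(genome)[[var$contig]]
  substr(seqc, var$pos, var$pos) <- var$alt
  mut_genome <- structure(setNames(seqc, var$contig),
                          class = "genome_sequence")
  ref_cds <- oracle_cds_walk(tx, genome)
  mut_cds <- oracle_cds_walk(tx, mut_genome)
  d <- which(strsplit(ref_cds, "")[[1]] != strsplit(mut_cds, "")[[1]])
  codon_index <- (d - 1) %/% 3 + 1
  ref_codon <- substr(ref_cds, (codon_index - 1) * 3 + 1, codon_index * 3)
  mut_codon <- substr(mut_cds, (codon_index - 1) * 3 + 1, codon_index * 3)
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  mut_aa <- unname(Biostrings::GENETIC_CODE[mut_codon])
  effect <- if (codon_index == 1 && ref_codon == "ATG" && mut_codon != "ATG")
    "start_lost"
  else if (mut_aa == "*" && ref_aa != "*") "stop_gained"
  else if (mut_aa == ref_aa) "synonymous"
  else "missense"
  list(cds_pos = d, codon_index = codon_index, effect = effect)
}

# a bare transcript with a given CDS length (no genome needed); for
# pair-selection tests
bare_tx <- function(id, gene, cds_len, contig = "c1") {
  transcript_model(id, gene, contig, "+",
                   data.frame(start = 0, end = cds_len + 30),
                   cds_start = 10, cds_end = 10 + cds_len)
}

# one-contig locus with an explicit CDS string at a given offset
mini_locus <- function(cds, utr5 = 12, utr3 = 9, id = "t1", gene = "g1",
                       contig = "mini") {
  set.seed(nchar(cds))
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  seqc <- paste0(pad(utr5), cds, pad(utr3))
  genome <- genome_sequence(setNames(seqc, contig))
  tx <- transcript_model(id, gene, contig, "+",
                         data.frame(start = 0, end = nchar(seqc)),
                         cds_start = utr5, cds_end = utr5 + nchar(cds))
  list(genome = genome, tx = tx)
}

# sample n coding genomic positions of a transcript
coding_positions <- function(tx) {
  ivl <- startloss:::cds_exon_intervals(tx)
  unlist(lapply(seq_len(nrow(ivl)), function(i)
    seq(ivl$start[i] + 1, ivl$end[i])))
}
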