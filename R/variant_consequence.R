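## Dual-isoform variant-consequence annotation.
##
## The same genomic variant can have radically different consequences on
## two isoforms of one gene: a substitution that is a tolerable missense in
## the long isoform can destroy the start codon of the short isoform.
## Start-loss is reported as protein effect "p.?" (unknown downstream
## effect) rather than predicting rescue from a downstream ATG; a
## diagnostic helper lists in-frame downstream ATGs.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_seq <- function(x) {
  paste(COMPLEMENT[strsplit(toupper(x), "")[[1]]], collapse = "")
}

#' Construct a variant (SNV or insertion)
#'
#' VCF conventions: 1-based position; an insertion is left-anchored, with
#' `alt` extending `ref` (one anchor base) at its 3' side.
#'
#' @param contig Contig name.
#' @param pos 1-based genomic position (of the substituted base, or of the
#'   anchor base for an insertion).
#' @param ref,alt Reference and alternate alleles on the forward strand.
#' @return Object of class \code{variant} with a `type` field
#'   (`"SNV"` or `"insertion"`).
#' @export
variant <- function(contig, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  type <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV"
  else if (nchar(ref) == 1L && nchar(alt) > 1L &&
           substr(alt, 1, 1) == ref) "insertion"
  else abort2("only SNVs and left-anchored insertions are supported",
              "validation_error")
  structure(list(contig = contig, pos = pos, ref = ref, alt = alt,
                 type = type), class = "variant")
}

new_consequence <- function(tx, effect, cds_pos = NA_integer_,
                            codon_index = NA_integer_, hgvs_c = NA_character_,
                            hgvs_p = NA_character_,
                            fs_first_residue = NA_integer_,
                            fs_ter_offset = NA_integer_, no_stop = FALSE,
                            nmd_flag = NA) {
  data.frame(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
             effect = effect, cds_pos = cds_pos, codon_index = codon_index,
             hgvs_c = hgvs_c, hgvs_p = hgvs_p,
             fs_first_residue = fs_first_residue,
             fs_ter_offset = fs_ter_offset, no_stop = no_stop,
             nmd_flag = nmd_flag)
}

check_ref <- function(var, genome) {
  seqc <- contig_seq(genome, var$contig)
  obs <- substr(seqc, var$pos, var$pos + nchar(var$ref) - 1L)
  if (obs != var$ref)
    abort2(sprintf("reference mismatch at %s:%s (genome %s, variant %s)",
                   var$contig, format(var$pos, scientific = FALSE),
                   obs, var$ref), "reference_mismatch_error")
}

#' Annotate a single-nucleotide variant on one isoform
#'
#' Maps the genomic substitution onto the transcript's CDS (coding-strand
#' alleles for minus-strand transcripts), retranslates the affected codon
#' and classifies the effect: `start_lost` when codon 1's reference ATG is
#' disrupted (protein effect printed as `p.?`), `stop_gained`, `missense`
#' or `synonymous`. For stop gains, a 50-nt-rule flag annotates whether the
#' premature stop is predicted to trigger nonsense-mediated decay (more
#' than 50 nt upstream of the final exon-exon junction); this is annotation
#' only, not a decay model.
#'
#' @param var A \code{variant} of type SNV.
#' @param tx A \code{transcript_model}; the variant must lie in its CDS
#'   footprint.
#' @param genome A \code{genome_sequence}; the variant `ref` must match it.
#' @return One-row consequence data frame (`effect`, `hgvs_c`, `hgvs_p`,
#'   codon fields).
#' @export
annotate_snv <- function(var, tx, genome) {
  if (var$type != "SNV") abort2("not an SNV", "validation_error")
  check_ref(var, genome)
  cpos <- genomic_to_cds(tx, var$pos)
  ref_c <- if (tx$strand == "+") var$ref else comp_seq(var$ref)
  alt_c <- if (tx$strand == "+") var$alt else comp_seq(var$alt)
  cdn <- cds_to_codon(cpos)
  cds <- cds_sequence(tx, genome)
  cstart <- (cdn$codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds, cstart, cstart + 2L)
  stopifnot(substr(ref_codon, cdn$offset + 1L, cdn$offset + 1L) == ref_c)
  alt_codon <- ref_codon
  substr(alt_codon, cdn$offset + 1L, cdn$offset + 1L) <- alt_c
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  hgvs_c <- sprintf("c.%d%s>%s", cpos, ref_c, alt_c)
  if (cdn$codon_index == 1L && ref_codon == "ATG" && alt_codon != "ATG") {
    effect <- "start_lost"; hgvs_p <- "p.?"
  } else if (alt_aa == "*" && ref_aa != "*") {
    effect <- "stop_gained"
    hgvs_p <- sprintf("p.%s%dTer", AA3[[ref_aa]], cdn$codon_index)
  } else if (alt_aa == ref_aa) {
    effect <- "synonymous"
    hgvs_p <- sprintf("p.%s%d=", AA3[[ref_aa]], cdn$codon_index)
  } else {
    effect <- "missense"
    hgvs_p <- sprintf("p.%s%d%s", AA3[[ref_aa]], cdn$codon_index,
                      AA3[[alt_aa]])
  }
  nmd <- if (effect == "stop_gained")
    nmd_50nt_flag(tx, stop_cds_pos = cstart) else NA
  new_consequence(tx, effect, cds_pos = cpos,
                  codon_index = cdn$codon_index, hgvs_c = hgvs_c,
                  hgvs_p = hgvs_p, nmd_flag = nmd)
}

## 50-nt rule: a premature stop more than 50 nt upstream of the last
## exon-exon junction (in CDS coordinates) is flagged as a predicted NMD
## substrate.  Single-exon transcripts are never flagged.
nmd_50nt_flag <- function(tx, stop_cds_pos) {
  ivl <- cds_exon_intervals(tx)
  if (nrow(ivl) < 2L) return(FALSE)
  w <- ivl$end - ivl$start
  if (tx$strand == "-") w <- rev(w)
  last_junction <- sum(w[-length(w)])  # CDS coordinate of last junction
  (last_junction - stop_cds_pos) > 50
}

#' Annotate an insertion on one isoform
#'
#' A left-anchored insertion is re-expressed internally as "inserted between
#' CDS positions i and i+1" in coding orientation. Insertions of length not
#' divisible by 3 shift the reading frame: the mutant coding sequence
#' (including the 3' UTR, since the new stop may lie past the annotated
#' one) is rebuilt and translated from the first affected codon until the
#' first stop, giving the `X{n}Yfs*{m}` notation where the new stop sits at
#' residue `n + m - 1`. In-frame insertions at codon boundaries are
#' reported as `inframe_insertion`.
#'
#' @param var A \code{variant} of type insertion.
#' @param tx A \code{transcript_model}.
#' @param genome A \code{genome_sequence}.
#' @return One-row consequence data frame; for frameshifts,
#'   `fs_first_residue` and `fs_ter_offset` are filled and `no_stop` flags
#'   a shifted frame that reaches the transcript end without a stop
#'   (`hgvs_p` then ends in `fs*?`).
#' @export
annotate_insertion <- function(var, tx, genome) {
  if (var$type != "insertion") abort2("not an insertion", "validation_error")
  check_ref(var, genome)
  ins_fwd <- substr(var$alt, 2L, nchar(var$alt))
  anchor_cpos <- genomic_to_cds(tx, var$pos)
  if (tx$strand == "+") {
    i <- anchor_cpos                       # between i and i+1
    ins <- ins_fwd
  } else {
    ## on the minus strand the insertion lands between pos and pos+1 on the
    ## genome, i.e. between c(pos)-1 and c(pos) in coding orientation
    i <- anchor_cpos - 1L
    ins <- revcomp(ins_fwd)
  }
  hgvs_c <- sprintf("c.%d_%dins%s", i, i + 1L, ins)
  if (nchar(ins) %% 3L == 0L && i %% 3L == 0L) {
    return(new_consequence(tx, "inframe_insertion", cds_pos = i,
                           codon_index = cds_to_codon(i)$codon_index,
                           hgvs_c = hgvs_c,
                           hgvs_p = sprintf("p.(%daa ins)", nchar(ins) / 3L)))
  }
  if (nchar(ins) %% 3L == 0L) {
    ## in-frame length but splits a codon: still no frameshift
    return(new_consequence(tx, "inframe_insertion", cds_pos = i,
                           codon_index = cds_to_codon(i + 1L)$codon_index,
                           hgvs_c = hgvs_c,
                           hgvs_p = sprintf("p.(%daa ins)", nchar(ins) / 3L)))
  }
  fs_first <- as.integer(i %/% 3L + 1L)    # codon containing position i+1
  ref_prot <- transcript_protein(tx, genome)
  ref_aa <- substr(ref_prot, fs_first, fs_first)
  full <- coding_and_downstream_sequence(tx, genome)
  mut <- paste0(substr(full, 1L, i), ins,
                substr(full, i + 1L, nchar(full)))
  tail_seq <- substr(mut, (fs_first - 1L) * 3L + 1L, nchar(mut))
  sc <- scan_translation(tail_seq)
  new_aa <- substr(sc$protein, 1L, 1L)
  if (sc$has_stop) {
    m <- sc$stop_codon_index
    hgvs_p <- sprintf("p.%s%d%sfs*%d", ref_aa, fs_first, new_aa, m)
    stop_cds <- (fs_first + m - 2L) * 3L + 1L
    new_consequence(tx, "frameshift", cds_pos = i,
                    codon_index = fs_first, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
                    fs_first_residue = fs_first, fs_ter_offset = as.integer(m),
                    nmd_flag = nmd_50nt_flag(tx, stop_cds))
  } else {
    new_consequence(tx, "frameshift", cds_pos = i,
                    codon_index = fs_first, hgvs_c = hgvs_c,
                    hgvs_p = sprintf("p.%s%d%sfs*?", ref_aa, fs_first, new_aa),
                    fs_first_residue = fs_first, no_stop = TRUE)
  }
}

#' Parse frameshift protein notation
#'
#' Parses strings like `D15Rfs*33` (optionally prefixed `p.`): first changed
#' residue, termination offset, and the implied stop position
#' `first + offset - 1`. The no-stop dialect `fs*?` yields undefined offset
#' and stop.
#'
#' @param hgvs_p Notation string.
#' @return List with `first_residue`, `ter_offset`, `stop_position`
#'   (the latter two `NA` for `fs*?`).
#' @export
parse_fs_notation <- function(hgvs_p) {
  m <- regmatches(hgvs_p,
                  regexec("^(?:p\\.)?([A-Z])(\\d+)([A-Z]?)fs\\*(\\d+|\\?)$",
                          hgvs_p))[[1]]
  if (length(m) == 0L)
    abort2(paste0("malformed frameshift notation: ", hgvs_p), "parse_error")
  first <- as.integer(m[3])
  ter <- if (m[5] == "?") NA_integer_ else as.integer(m[5])
  list(first_residue = first, ter_offset = ter,
       stop_position = if (is.na(ter)) NA_integer_ else first + ter - 1L)
}

#' List in-frame downstream ATGs of a transcript
#'
#' Diagnostic companion to start-loss calls: codon indices (> 1) of the
#' reference CDS that are ATG, i.e. candidate re-initiation sites.
#'
#' @param tx A \code{transcript_model}.
#' @param genome A \code{genome_sequence}.
#' @return Integer vector of codon indices.
#' @export
downstream_inframe_atgs <- function(tx, genome) {
  cds <- cds_sequence(tx, genome)
  starts <- seq.int(1L, nchar(cds) - 2L, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  which(codons == "ATG")[-1L]
}

#' Annotate variants against a set of isoforms
#'
#' Applies [annotate_snv()] / [annotate_insertion()] to every
#' variant x transcript combination where the variant falls in the
#' transcript's CDS footprint; other combinations are reported with effect
#' `not_in_cds`.
#'
#' @param variants List of \code{variant} objects, or a data frame with
#'   columns `contig`, `pos`, `ref`, `alt` (e.g. from a minimal VCF).
#' @param transcripts List of \code{transcript_model}.
#' @param genome A \code{genome_sequence}.
#' @return Data frame, one row per variant x isoform, with `contig`, `pos`,
#'   `ref`, `alt` prepended to the consequence columns.
#' @export
annotate_variants <- function(variants, transcripts, genome) {
  if (is.data.frame(variants))
    variants <- lapply(seq_len(nrow(variants)), function(i)
      variant(variants$contig[i], variants$pos[i], variants$ref[i],
              variants$alt[i]))
  rows <- list()
  for (v in variants) {
    for (tx in transcripts) {
      if (tx$contig != v$contig) next
      row <- tryCatch({
        if (v$type == "SNV") annotate_snv(v, tx, genome)
        else annotate_insertion(v, tx, genome)
      }, not_in_cds_error = function(e) new_consequence(tx, "not_in_cds"))
      row <- cbind(data.frame(contig = v$contig, pos = v$pos, ref = v$ref,
                              alt = v$alt), row)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a minimal VCF's variant records
#'
#' Extracts CHROM/POS/REF/ALT from a VCF (via vcfR); multiallelic records
#' are expanded one ALT per row.
#'
#' @param path VCF path.
#' @return Data frame with columns `contig`, `pos`, `ref`, `alt`.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n <- lengths(alts)
  data.frame(contig = rep(fix$CHROM, n), pos = rep(as.numeric(fix$POS), n),
             ref = rep(fix$REF, n), alt = unlist(alts))
}
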