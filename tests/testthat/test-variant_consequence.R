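test_that("the recurrent A>G is missense on the long isoform and start-loss on the short", {
  fx <- ugp2_like_fixture()
  long_cons <- annotate_snv(fx$snv, fx$long, fx$genome)
  expect_equal(long_cons$effect, "missense")
  expect_equal(long_cons$hgvs_c, "c.34A>G")
  expect_equal(long_cons$hgvs_p, "p.Met12Val")
  expect_equal(long_cons$codon_index, 12)

  short_cons <- annotate_snv(fx$snv, fx$short, fx$genome)
  expect_equal(short_cons$effect, "start_lost")
  expect_equal(short_cons$hgvs_c, "c.1A>G")
  expect_equal(short_cons$hgvs_p, "p.?")

  bad_ref <- variant(fx$snv$contig, fx$snv$pos, "C", "G")
  expect_error(annotate_snv(bad_ref, fx$long, fx$genome),
               class = "reference_mismatch_error")
})

test_that("stop gains and synonymous changes classify from the retranslated codon", {
  loc <- mini_locus("ATGTGGCTGTAA")  # Met-Trp-Leu-stop
  g_of <- function(cpos) startloss::cds_to_genomic(loc$tx, cpos)
  stop_gain <- annotate_snv(variant("mini", g_of(6), "G", "A"), loc$tx,
                            loc$genome)  # TGG -> TGA
  expect_equal(stop_gain$effect, "stop_gained")
  expect_equal(stop_gain$hgvs_p, "p.Trp2Ter")

  syn <- annotate_snv(variant("mini", g_of(9), "G", "A"), loc$tx,
                      loc$genome)        # CTG -> CTA, both Leu
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$hgvs_p, "p.Leu3=")
})

test_that("the knockout insertion frameshifts codon 15 to a stop 33 codons on", {
  fx <- ugp2_like_fixture()
  cons <- annotate_insertion(fx$ins, fx$long, fx$genome)
  expect_equal(cons$effect, "frameshift")
  expect_equal(cons$hgvs_c, "c.42_43insA")
  expect_equal(cons$hgvs_p, "p.D15Rfs*33")
  expect_equal(cons$fs_first_residue, 15L)
  expect_equal(cons$fs_ter_offset, 33L)
  # premature termination at residue 47 = 15 + 33 - 1
  parsed <- parse_fs_notation(cons$hgvs_p)
  expect_equal(parsed$stop_position, 47L)

  # the engineered mutant protein really stops there: rebuild independently
  seqc <- unclass(fx$genome)[[fx$ins$contig]]
  mut <- paste0(substr(seqc, 1, fx$ins$pos), "A",
                substr(seqc, fx$ins$pos + 1, nchar(seqc)))
  mg <- genome_sequence(setNames(mut, fx$ins$contig))
  mtx <- fx$long
  mtx$exons$end[2] <- mtx$exons$end[2] + 1
  mtx$cds_end <- mtx$cds_end + 1  # keep frame-multiple for the walk
  walk <- oracle_cds_walk(mtx, mg)
  aa <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(walk, 1, 3 * 60)))),
    "")[[1]]
  expect_equal(which(aa == "*")[1], 47)
  expect_equal(aa[15], "R")
})

test_that("frameshift notation parses and round-trips", {
  expect_equal(parse_fs_notation("D15Rfs*33"),
               list(first_residue = 15L, ter_offset = 33L,
                    stop_position = 47L))
  expect_equal(parse_fs_notation("M1Vfs*2"),
               list(first_residue = 1L, ter_offset = 2L, stop_position = 2L))
  k10 <- parse_fs_notation("K10fs*?")
  expect_equal(k10$first_residue, 10L)
  expect_true(is.na(k10$ter_offset) && is.na(k10$stop_position))
  expect_error(parse_fs_notation("not-a-notation"), class = "parse_error")

  fx <- ugp2_like_fixture()
  cons <- annotate_insertion(fx$ins, fx$long, fx$genome)
  parsed <- parse_fs_notation(cons$hgvs_p)
  expect_equal(parsed$first_residue, cons$fs_first_residue)
  expect_equal(parsed$ter_offset, cons$fs_ter_offset)
})

test_that("in-frame insertions at codon boundaries conserve the downstream frame", {
  loc <- mini_locus(paste(c("ATG", rep("GCT", 8), "TAA"), collapse = ""))
  anchor <- startloss::cds_to_genomic(loc$tx, 6)  # codon boundary after c.6
  base <- substr(unclass(loc$genome)[["mini"]], anchor, anchor)
  v <- variant("mini", anchor, base, paste0(base, "CCT"))
  cons <- annotate_insertion(v, loc$tx, loc$genome)
  expect_equal(cons$effect, "inframe_insertion")

  # downstream protein equals the reference shifted by one residue
  seqc <- unclass(loc$genome)[["mini"]]
  mut <- paste0(substr(seqc, 1, anchor), "CCT",
                substr(seqc, anchor + 1, nchar(seqc)))
  mg <- genome_sequence(setNames(mut, "mini"))
  mtx <- loc$tx; mtx$exons$end <- mtx$exons$end + 3
  mtx$cds_end <- mtx$cds_end + 3
  ref_p <- transcript_protein(loc$tx, loc$genome)
  mut_p <- transcript_protein(mtx, mg)
  expect_equal(nchar(mut_p), nchar(ref_p) + 1)
  expect_equal(substr(mut_p, 4, nchar(mut_p)), substr(ref_p, 3, nchar(ref_p)))
})

test_that("SNV annotation agrees with a full-CDS-rebuild oracle on random variants", {
  set.seed(77)
  n_checked <- 0
  for (seed in c(14, 15)) {
    sim <- simulate_scan_annotation(n_genes = 10, n_planted = 4, seed = seed)
    for (tx in sim$transcripts) {
      pos <- sample(coding_positions(tx), 8)
      for (p in pos) {
        seqc <- unclass(sim$genome)[[tx$contig]]
        ref <- substr(seqc, p, p)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        v <- variant(tx$contig, p, ref, alt)
        got <- annotate_snv(v, tx, sim$genome)
        want <- oracle_snv(v, tx, sim$genome)
        expect_equal(got$effect, want$effect)
        expect_equal(got$codon_index, want$codon_index)
        expect_equal(got$cds_pos, want$cds_pos)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 250)
})

test_that("dual-isoform annotation emits one row per variant and isoform", {
  fx <- ugp2_like_fixture()
  out <- annotate_variants(list(fx$snv, fx$ins),
                           list(fx$long, fx$short), fx$genome)
  expect_equal(nrow(out), 4L)
  snv_rows <- out[out$alt == "G", ]
  expect_setequal(snv_rows$effect, c("missense", "start_lost"))
  ins_short <- out[out$effect == "frameshift" &
                     out$transcript_id == fx$short$transcript_id, ]
  # same genomic insertion hits the short isoform at c.9_10 (42 - 33)
  expect_equal(ins_short$cds_pos, 9)
})

test_that("downstream in-frame ATG diagnostics find the truncation anchor", {
  fx <- ugp2_like_fixture()
  expect_true(12 %in% downstream_inframe_atgs(fx$long, fx$genome))
})
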