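## Seeded synthetic-data generators.
##
## Every input the pipeline consumes can be generated deterministically
## with recorded ground truth: a genome + annotation with planted
## start-loss-susceptible ("UGP2-like") isoform pairs of known truncation
## length, tissue-specific isoform-usage counts with binomial noise, and
## founder probands whose ancestral haplotype has been eroded by g
## generations of recombination. Given (seed, config) every generated file
## is byte-identical across runs.

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"), paste0),
                              c("A", "C", "G", "T"), paste0))
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
rand_codons <- function(n) sample(NONSTOP_CODONS, n, replace = TRUE)

## ---- locus builders ------------------------------------------------------
## Shared topology (plus strand; coordinates 0-based half-open):
##   [pad][E0: 5'UTR + CDS codons 1..k][intron][E1: CDS rest + 3'UTR][pad]
## The long transcript has exons {E0, E1}; the short transcript's single
## exon extends E1 upstream into the intron (its own 5'UTR), so each
## isoform owns unique exonic territory while the short isoform's ATG
## (long codon k+1) is exonic in both -- the alternative-first-exon
## topology of start-loss-susceptible loci.

build_positive_locus <- function(gene_id, k, body = 60, u5L = 50, u3 = 20,
                                 u_short = 40, intron = 80, pad = 100,
                                 codons = NULL) {
  if (k < 1) abort2("truncation k must be >= 1", "config_error")
  if (is.null(codons))
    codons <- c("ATG", rand_codons(k - 1), "ATG", rand_codons(body), "TAA")
  if (3 * k >= length(codons) * 3 - 3)
    abort2("truncation >= long protein length", "config_error")
  cds <- paste(codons, collapse = "")
  len <- nchar(cds)
  e0_s <- pad; e0_e <- pad + u5L + 3 * k
  a1 <- e0_e + intron
  e1_e <- a1 + (len - 3 * k) + u3
  seq <- paste0(rand_bases(pad), rand_bases(u5L), substr(cds, 1, 3 * k),
                rand_bases(intron), substr(cds, 3 * k + 1, len),
                rand_bases(u3), rand_bases(20))
  contig <- paste0("ctg_", gene_id)
  long <- transcript_model(paste0(gene_id, ".t1"), gene_id, contig, "+",
                           data.frame(start = c(e0_s, a1),
                                      end = c(e0_e, e1_e)),
                           cds_start = pad + u5L, cds_end = a1 + len - 3 * k)
  short <- transcript_model(paste0(gene_id, ".t2"), gene_id, contig, "+",
                            data.frame(start = a1 - u_short, end = e1_e),
                            cds_start = a1, cds_end = a1 + len - 3 * k)
  list(contig = contig, seq = seq, transcripts = list(long, short),
       truncation_aa = k)
}

## positive topology but the short transcript splices out one internal
## codon, so its protein is NOT a substring of the long protein
build_mismatch_locus <- function(gene_id, k = 8, body = 60) {
  loc <- build_positive_locus(gene_id, k, body)
  long <- loc$transcripts[[1]]
  a1 <- long$exons$start[2]
  e1_e <- long$exons$end[2]
  m <- 2L  # short keeps m codons, skips the next one
  short <- transcript_model(
    paste0(gene_id, ".t2"), gene_id, loc$contig, "+",
    data.frame(start = c(a1 - 40, a1 + 3 * m + 3),
               end = c(a1 + 3 * m, e1_e)),
    cds_start = a1, cds_end = long$cds_end)
  loc$transcripts <- list(long, short)
  loc$truncation_aa <- NA_integer_
  loc
}

## short isoform's ATG sits inside the long CDS at frame offset 1; the
## rest of the short CDS lives in a private downstream exon
build_outofframe_locus <- function(gene_id, k = 8, body = 60) {
  repeat {
    codons <- c("ATG", rand_codons(k - 1), "CAT", "GGA", rand_codons(body - 1),
                "TAA")
    ## short's first 4 shifted codons read from the long sequence must be
    ## open (no stop)
    shifted <- substr(paste(codons[(k + 1):(k + 5)], collapse = ""), 2, 13)
    cs <- substring(shifted, c(1, 4, 7, 10), c(3, 6, 9, 12))
    if (!any(cs %in% STOP_CODONS)) break
  }
  loc <- build_positive_locus(gene_id, k, body, codons = codons)
  long <- loc$transcripts[[1]]
  a1 <- long$exons$start[2]
  e1_e <- long$exons$end[2]
  atg0 <- a1 + 1                       # CDS offset 3k+1 (0-based): frame +1
  gap <- 50; tail_codons <- 20; u3s <- 10
  exb_s <- e1_e + gap
  tail_seq <- paste(c(rand_codons(tail_codons), "TAA"), collapse = "")
  exb_e <- exb_s + nchar(tail_seq) + u3s
  loc$seq <- paste0(loc$seq, rand_bases(gap - 20), tail_seq, rand_bases(u3s),
                    rand_bases(20))
  short <- transcript_model(
    paste0(gene_id, ".t2"), gene_id, loc$contig, "+",
    data.frame(start = c(atg0, exb_s), end = c(atg0 + 12, exb_e)),
    cds_start = atg0, cds_end = exb_s + nchar(tail_seq))
  loc$transcripts <- list(long, short)
  loc$truncation_aa <- NA_integer_
  loc
}

## two coding transcripts in disjoint regions of one locus (unrelated
## proteins)
build_disjoint_locus <- function(gene_id, body1 = 80, body2 = 40) {
  c1 <- paste(c("ATG", rand_codons(body1), "TAA"), collapse = "")
  c2 <- paste(c("ATG", rand_codons(body2), "TAA"), collapse = "")
  pad <- 100; gap <- 60
  s1 <- pad; e1 <- s1 + nchar(c1) + 20
  s2 <- e1 + gap; e2 <- s2 + nchar(c2) + 20
  seq <- paste0(rand_bases(pad), c1, rand_bases(20), rand_bases(gap),
                c2, rand_bases(20), rand_bases(20))
  contig <- paste0("ctg_", gene_id)
  t1 <- transcript_model(paste0(gene_id, ".t1"), gene_id, contig, "+",
                         data.frame(start = s1, end = e1),
                         cds_start = s1, cds_end = s1 + nchar(c1))
  t2 <- transcript_model(paste0(gene_id, ".t2"), gene_id, contig, "+",
                         data.frame(start = s2, end = e2),
                         cds_start = s2, cds_end = s2 + nchar(c2))
  list(contig = contig, seq = seq, transcripts = list(t1, t2),
       truncation_aa = NA_integer_)
}

build_single_locus <- function(gene_id, body = 50) {
  cds <- paste(c("ATG", rand_codons(body), "TAA"), collapse = "")
  pad <- 100
  seq <- paste0(rand_bases(pad), cds, rand_bases(30))
  contig <- paste0("ctg_", gene_id)
  tx <- transcript_model(paste0(gene_id, ".t1"), gene_id, contig, "+",
                         data.frame(start = pad, end = pad + nchar(cds) + 30),
                         cds_start = pad, cds_end = pad + nchar(cds))
  list(contig = contig, seq = seq, transcripts = list(tx),
       truncation_aa = NA_integer_)
}

## mirror a plus-strand locus onto the minus strand (reverse-complement the
## contig and flip all coordinates)
flip_locus <- function(loc) {
  L <- nchar(loc$seq)
  loc$seq <- revcomp(loc$seq)
  loc$transcripts <- lapply(loc$transcripts, function(tx) {
    ex <- data.frame(start = L - rev(tx$exons$end),
                     end = L - rev(tx$exons$start))
    transcript_model(tx$transcript_id, tx$gene_id, tx$contig, "-",
                     ex, cds_start = L - tx$cds_end,
                     cds_end = L - tx$cds_start)
  })
  loc
}

#' Simulate a genome and annotation with planted start-loss candidates
#'
#' Builds `n_genes` loci, of which `n_planted` are "UGP2-like": two
#' transcripts sharing all downstream coding sequence, with alternative
#' first exons and an in-frame internal ATG at a known truncation depth.
#' Negatives cycle through internal-mismatch pairs, out-of-frame-ATG pairs,
#' disjoint-isoform pairs and single-transcript genes; a configurable
#' fraction of loci is placed on the minus strand. Essential-gene and
#' disease-annotation lists are drawn consistently with the recorded truth.
#'
#' @param n_genes Total genes.
#' @param n_planted Number of planted candidate genes.
#' @param truncations Optional integer vector (length `n_planted`) of
#'   truncation depths in amino acids; by default sampled from 3..60 so
#'   some planted genes exceed the 50-aa filter.
#' @param frac_essential,frac_disease Fractions of genes put on the
#'   essential / disease lists (drawn independently).
#' @param frac_minus Fraction of loci mirrored to the minus strand.
#' @param seed Integer seed; output is byte-deterministic given
#'   (seed, config).
#' @return List with `genome` (a \code{genome_sequence}), `transcripts`
#'   (list of \code{transcript_model}), and `truth` (list: `planted`
#'   data frame of gene_id/truncation_aa, `essential_ids`, `disease_ids`,
#'   `gene_types`, `seed`).
#' @export
simulate_scan_annotation <- function(n_genes = 20, n_planted = 7,
                                     truncations = NULL,
                                     frac_essential = 0.6,
                                     frac_disease = 0.3,
                                     frac_minus = 0.3, seed = 1) {
  if (n_planted > n_genes)
    abort2("n_planted > n_genes", "config_error")
  set.seed(seed)
  gids <- sprintf("G%03d", seq_len(n_genes))
  if (is.null(truncations))
    truncations <- sample(3:60, n_planted, replace = TRUE)
  if (length(truncations) != n_planted)
    abort2("truncations must have length n_planted", "config_error")
  neg_types <- rep(c("mismatch", "out_of_frame", "disjoint", "single"),
                   length.out = n_genes - n_planted)
  types <- c(rep("planted", n_planted), neg_types)
  contigs <- character(0); transcripts <- list()
  for (i in seq_len(n_genes)) {
    loc <- switch(types[i],
      planted = build_positive_locus(gids[i], k = truncations[i]),
      mismatch = build_mismatch_locus(gids[i]),
      out_of_frame = build_outofframe_locus(gids[i]),
      disjoint = build_disjoint_locus(gids[i]),
      single = build_single_locus(gids[i]))
    if (runif(1) < frac_minus) loc <- flip_locus(loc)
    contigs[loc$contig] <- loc$seq
    transcripts <- c(transcripts, loc$transcripts)
  }
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  essential_ids <- sort(gids[runif(n_genes) < frac_essential])
  disease_ids <- sort(gids[runif(n_genes) < frac_disease])
  list(genome = genome_sequence(contigs), transcripts = transcripts,
       truth = list(planted = data.frame(gene_id = gids[types == "planted"],
                                         truncation_aa = truncations),
                    essential_ids = essential_ids,
                    disease_ids = disease_ids,
                    gene_types = setNames(types, gids), seed = seed))
}

#' Write a simulated scan bundle to disk
#'
#' Emits genome.fa, annotation.gtf, essential.tsv, disease.tsv and
#' truth.json under `dir`.
#'
#' @param sim Output of [simulate_scan_annotation()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the written paths.
#' @export
write_scan_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "annotation.gtf"),
             essential = file.path(dir, "essential.tsv"),
             disease = file.path(dir, "disease.tsv"),
             truth = file.path(dir, "truth.json"))
  write_genome(sim$genome, paths["fasta"])
  write_gtf(sim$transcripts, paths["gtf"])
  writeLines(sim$truth$essential_ids, paths["essential"])
  writeLines(sim$truth$disease_ids, paths["disease"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE)
  invisible(paths)
}

#' Simulate per-gene, per-tissue isoform usage
#'
#' A fraction of genes gets strongly tissue-specific usage (brain-like
#' tissue near 1, the others low), the rest a constant moderate usage, so
#' the planted cross-tissue variability is known per gene.
#'
#' @param gene_ids Genes to simulate.
#' @param tissues Tissue names; the first is the "brain-like" high-usage
#'   tissue.
#' @param frac_variable Fraction of genes with tissue-specific usage.
#' @param seed Integer seed.
#' @return Data frame `gene_id`, `tissue`, `usage`, `variable`.
#' @export
simulate_usage <- function(gene_ids,
                           tissues = c("brain", "liver", "heart", "kidney"),
                           frac_variable = 0.5, seed = 1) {
  set.seed(seed)
  rows <- lapply(gene_ids, function(g) {
    variable <- runif(1) < frac_variable
    u <- if (variable)
      c(runif(1, 0.9, 1.0), runif(length(tissues) - 1, 0.05, 0.25))
    else rep(runif(1, 0.3, 0.7), length(tissues))
    data.frame(gene_id = g, tissue = tissues, usage = u, variable = variable)
  })
  do.call(rbind, rows)
}

#' Simulate expression counts over isoform-unique regions
#'
#' Per sample and gene, the short-isoform count is Binomial(depth, usage)
#' and the long count is the remainder, independently across genes and
#' samples (binomial, not negative-binomial: the downstream statistic is a
#' ratio, not a differential-expression test).
#'
#' @param usage Data frame from [simulate_usage()] (columns `gene_id`,
#'   `tissue`, `usage`).
#' @param depth Total reads over the unique regions per sample and gene.
#' @param n_samples_per_tissue Samples per tissue.
#' @param seed Integer seed.
#' @return List with `counts` (sample, gene_id, short_count, long_count),
#'   `samples` (sample, tissue), and `usage` (the truth handed in).
#' @export
simulate_expression_counts <- function(usage, depth = 2000,
                                       n_samples_per_tissue = 3, seed = 1) {
  set.seed(seed)
  tissues <- unique(usage$tissue)
  samples <- data.frame(
    sample = unlist(lapply(tissues, function(t)
      paste0(t, "_s", seq_len(n_samples_per_tissue)))),
    tissue = rep(tissues, each = n_samples_per_tissue))
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    u <- usage[usage$tissue == samples$tissue[i], ]
    short <- rbinom(nrow(u), size = depth, prob = u$usage)
    data.frame(sample = samples$sample[i], gene_id = u$gene_id,
               short_count = short, long_count = depth - short)
  })
  list(counts = do.call(rbind, rows), samples = samples, usage = usage)
}

#' Write a simulated expression bundle (counts.tsv, samples.tsv)
#' @param sim Output of [simulate_expression_counts()].
#' @param dir Output directory.
#' @return Invisibly, named vector of written paths.
#' @export
write_expression_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "usage_truth.tsv"))
  write.table(sim$counts, paths["counts"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$samples, paths["samples"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$usage, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Simulate a deCODE-style genetic map
#'
#' Anchors every megabase with mildly varying local recombination rate
#' around ~1.2 cM/Mb.
#'
#' @param contig Contig name.
#' @param from,to Physical range (bp).
#' @param seed Integer seed.
#' @return A \code{genetic_map} data frame.
#' @export
simulate_genetic_map <- function(contig = "chr2", from = 50e6, to = 80e6,
                                 seed = 1) {
  set.seed(seed)
  pos <- seq(from, to, by = 1e6)
  rate <- runif(length(pos) - 1, 0.6, 1.8)      # cM/Mb
  structure(data.frame(contig = contig, pos = pos,
                       cM = c(0, cumsum(rate))),
            class = c("genetic_map", "data.frame"))
}

#' Simulate founder probands sharing an eroded ancestral haplotype
#'
#' An ancestral haplotype carries the focal allele. Each proband descends
#' from the founder through `paths_per_proband` meiotic paths of `g`
#' generations; each path retains an exponentially eroded segment around
#' the focal variant (per side, mean 100/g cM on the supplied genetic
#' map), and the proband is homozygous for the ancestral haplotype across
#' the per-side minimum of its paths (consanguineous closure). Elsewhere,
#' markers carry background heterozygosity at the configured density. A
#' configurable fraction of genotype entries is made QC-failing
#' (low DP or GQ).
#'
#' @param map A \code{genetic_map} covering one contig.
#' @param g True age in generations (>= 1).
#' @param n_probands Number of probands.
#' @param paths_per_proband Meiotic paths per proband (2 for a proband
#'   autozygous through both parental lineages).
#' @param focal_pos Focal variant position (default: map midpoint).
#' @param n_markers Marker count across the map range.
#' @param het_prob Per-marker heterozygosity probability outside the
#'   retained interval.
#' @param qc_fail_frac Fraction of genotype entries given failing DP/GQ.
#' @param seed Integer seed.
#' @param max_retry Regeneration cap for probands whose retained interval
#'   is narrower than the marker spacing.
#' @return List with `records` (genotype data frame as
#'   [read_genotypes_vcf()] returns), `markers` (pos/ref/alt), and `truth`
#'   (g, n_paths, focal, per-proband retained intervals, their
#'   intersection, seed).
#' @export
simulate_founder_probands <- function(map, g = 26, n_probands = 5,
                                      paths_per_proband = 2,
                                      focal_pos = NULL, n_markers = 2000,
                                      het_prob = 0.3, qc_fail_frac = 0.05,
                                      seed = 1, max_retry = 50) {
  if (g < 1) abort2("g must be >= 1", "config_error")
  set.seed(seed)
  contig <- map$contig[1]
  lo <- min(map$pos); hi <- max(map$pos)
  if (is.null(focal_pos)) focal_pos <- round((lo + hi) / 2)
  spacing <- (hi - lo) / n_markers
  focal_cM <- approx(map$pos, map$cM, xout = focal_pos, rule = 2,
                     ties = "ordered")$y
  draw_interval <- function() {
    left <- min(rexp(paths_per_proband, rate = g / 100))
    right <- min(rexp(paths_per_proband, rate = g / 100))
    c(cM_to_pos(map, contig, focal_cM - left),
      cM_to_pos(map, contig, focal_cM + right))
  }
  intervals <- matrix(NA_real_, n_probands, 2)
  for (i in seq_len(n_probands)) {
    for (try in seq_len(max_retry)) {
      iv <- draw_interval()
      if (iv[2] - iv[1] >= 2 * spacing) break
      if (try == max_retry)
        abort2("retained interval narrower than marker spacing after retries",
               "config_error")
    }
    intervals[i, ] <- iv
  }
  pos <- sort(unique(c(round(runif(n_markers, lo, hi)), focal_pos)))
  n <- length(pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  anc <- rbinom(n, 1, 0.5)                  # ancestral haplotype allele
  anc[pos == focal_pos] <- 1L               # founder carries the focal allele
  samples <- sprintf("proband%02d", seq_len(n_probands))
  rows <- list()
  for (i in seq_len(n_probands)) {
    inside <- pos >= intervals[i, 1] & pos <= intervals[i, 2]
    gt <- ifelse(anc == 1L, "hom_alt", "hom_ref")
    outside_idx <- which(!inside)
    r <- runif(length(outside_idx))
    gt[outside_idx[r < het_prob]] <- "het"
    flip <- outside_idx[r >= het_prob]
    gt[flip] <- sample(c("hom_ref", "hom_alt"), length(flip), replace = TRUE)
    depth <- rpois(n, 40)
    gq <- sample(60:99, n, replace = TRUE)
    fail <- which(runif(n) < qc_fail_frac)
    half <- fail[runif(length(fail)) < 0.5]
    depth[half] <- sample(0:9, length(half), replace = TRUE)
    gq[setdiff(fail, half)] <- sample(0:49, length(setdiff(fail, half)),
                                      replace = TRUE)
    rows[[i]] <- data.frame(sample = samples[i], contig = contig, pos = pos,
                            genotype = gt, depth = depth, gq = gq)
  }
  truth_int <- data.frame(sample = samples,
                          start_pos = intervals[, 1], end_pos = intervals[, 2])
  list(records = do.call(rbind, rows),
       markers = data.frame(pos = pos, ref = ref, alt = alt, anc = anc),
       truth = list(g = g, n_paths = n_probands * paths_per_proband,
                    focal_contig = contig, focal_pos = focal_pos,
                    intervals = truth_int,
                    shared_start = max(intervals[, 1]),
                    shared_end = min(intervals[, 2]),
                    seed = seed))
}

#' Write simulated probands as a minimal multi-sample VCF
#'
#' Biallelic SNVs with FORMAT GT:DP:GQ only, the canonical input of the
#' ROH stage.
#'
#' @param sim Output of [simulate_founder_probands()].
#' @param path Output VCF path.
#' @return Invisibly, `path`.
#' @export
write_probands_vcf <- function(sim, path) {
  rec <- sim$records
  samples <- unique(rec$sample)
  contig <- rec$contig[1]
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  m <- sim$markers
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s>", contig),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
             paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,",
                    "Description=\"Genotype quality\">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  cols <- lapply(samples, function(s) {
    d <- rec[rec$sample == s, ]
    d <- d[match(m$pos, d$pos), ]
    sprintf("%s:%d:%d", gt_code[d$genotype], d$depth, d$gq)
  })
  body <- do.call(paste, c(list(
    contig, format(m$pos, scientific = FALSE, trim = TRUE), ".",
    m$ref, m$alt, ".", "PASS", ".", "GT:DP:GQ"), cols, sep = "\t"))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a genetic map to TSV
#' @param map A \code{genetic_map}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genetic_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' A compact start-loss-susceptible reference locus (synthetic)
#'
#' A deterministic two-isoform locus mirroring the canonical
#' start-loss-susceptible gene structure: the short protein is the long
#' protein minus its first 11 residues (long CDS 1527 nt, short 1494 nt);
#' the recurrent A>G substitution at long c.34 is a missense in the long
#' isoform (p.Met12Val) and a start-loss (c.1A>G) in the short one; and
#' the single-A insertion after long c.42 frameshifts from codon 15 to a
#' stop 33 codons on (p.D15Rfs*33, stop at residue 47). The tail of the
#' CDS is engineered (seeded search) so the shifted reading frame
#' terminates at exactly that position. Also included are
#' coordinate-only transcript models at the locus's published chromosome-2
#' coordinates (no 64-Mb sequence is materialized) for c.-position
#' arithmetic.
#'
#' @param seed Seed for the deterministic sequence search.
#' @return List: `genome`, `long`, `short` (sequence-backed, small
#'   coordinates), `long_chr2`, `short_chr2` (coordinate-only models on
#'   chr2), `snv` (the recurrent A>G on the small-coordinate locus),
#'   `ins` (the knockout single-A insertion), `truncation_aa` (11).
#' @export
ugp2_like_fixture <- function(seed = 42) {
  set.seed(seed)
  k <- 11L; n_codons <- 509L          # 508 aa + stop; short = 497 aa + stop
  repeat {
    codons <- c("ATG", rand_codons(10), "ATG", rand_codons(2), "GAT",
                rand_codons(30), "CCT", "AAA", rand_codons(n_codons - 47 - 1),
                "TAA")
    ## shifted frame after the insertion: mutant codon j (j >= 16) is
    ## ref codon (j-1) base 3 + ref codon j bases 1-2; require codons
    ## 16..46 open (codon 47 is TAA by the CCT/AAA construction)
    shifted <- vapply(16:46, function(j)
      paste0(substr(codons[j - 1], 3, 3), substr(codons[j], 1, 2)), "")
    if (!any(shifted %in% STOP_CODONS)) break
  }
  loc <- build_positive_locus("UGP2L", k = k, codons = codons)
  genome <- genome_sequence(setNames(loc$seq, loc$contig))
  long <- loc$transcripts[[1]]; short <- loc$transcripts[[2]]
  snv_pos <- cds_to_genomic(long, 34)
  ins_pos <- cds_to_genomic(long, 42)
  ins_ref <- substr(loc$seq, ins_pos, ins_pos)
  ## coordinate-only models at the published chr2 location: CDS of the long
  ## isoform starts at chr2:64,083,421, so chr2:64,083,454 is c.34 and the
  ## short isoform's c.1
  ex2 <- data.frame(start = 64083370, end = 64085000)
  long_chr2 <- transcript_model("UGP2L.chr2.t1", "UGP2L", "chr2", "+", ex2,
                                cds_start = 64083420,
                                cds_end = 64083420 + 1527)
  short_chr2 <- transcript_model("UGP2L.chr2.t2", "UGP2L", "chr2", "+", ex2,
                                 cds_start = 64083453,
                                 cds_end = 64083420 + 1527)
  list(genome = genome, long = long, short = short,
       long_chr2 = long_chr2, short_chr2 = short_chr2,
       snv = variant(loc$contig, snv_pos, "A", "G"),
       ins = variant(loc$contig, ins_pos, ins_ref, paste0(ins_ref, "A")),
       truncation_aa = k)
}
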