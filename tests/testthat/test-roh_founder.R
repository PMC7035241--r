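mk_records <- function(pos, gt, sample = "s1", contig = "chr2",
                       depth = 30, gq = 80) {
  data.frame(sample = sample, contig = contig, pos = pos, genotype = gt,
             depth = depth, gq = gq)
}

test_that("genotype QC keeps records at the inclusive thresholds", {
  rec <- data.frame(sample = "s", contig = "c", pos = 1:5,
                    genotype = c("hom_ref", "het", "hom_alt", "hom_ref",
                                 "missing"),
                    depth = c(10, 9, 30, NA, 40),
                    gq = c(50, 99, 49, 80, 90))
  out <- filter_genotypes(rec)
  expect_equal(out$pos, 1L)              # DP 10 / GQ 50 kept ("at least")
  qc <- attr(out, "qc")
  expect_equal(unname(qc["n_missing_format"]), 1L)
  expect_equal(unname(qc["n_missing_genotype"]), 1L)
  expect_equal(unname(qc["n_below_threshold"]), 2L)
})

test_that("ROH caller honours SNP count, span, het break and gap rules", {
  # 6 hom calls over 150 kb
  r <- mk_records(seq(1e6, 1.15e6, length.out = 6), rep("hom_ref", 6))
  seg <- call_roh(r)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 6L)
  expect_equal(seg$start_pos, 1e6); expect_equal(seg$end_pos, 1.15e6)

  # 4 hom calls over 200 kb: below min_snp
  expect_equal(nrow(call_roh(mk_records(seq(1e6, 1.2e6, length.out = 4),
                                        rep("hom_alt", 4)))), 0L)

  # a het at position 6 splits 10 calls into runs of 5 and 4
  gt <- rep("hom_ref", 10); gt[6] <- "het"
  r <- mk_records(seq(1e6, 1.9e6, length.out = 10), gt)
  seg <- call_roh(r)
  expect_equal(nrow(seg), 1L)            # only the 5-run is eligible
  expect_equal(seg$n_snps, 5L)

  # a 12,000-kb gap splits two clusters, each evaluated separately
  pos <- c(seq(1e6, 1.2e6, length.out = 6),
           seq(13.4e6, 13.6e6, length.out = 6))
  seg <- call_roh(mk_records(pos, rep("hom_ref", 12)))
  expect_equal(nrow(seg), 2L)

  expect_error(call_roh(mk_records(c(2e6, 1e6), rep("hom_ref", 2))),
               class = "validation_error")
})

test_that("ROH caller equals the brute-force maximal-run oracle on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    pos <- sort(sample(1:5e7, n))
    gt <- sample(c("hom_ref", "hom_alt", "het"), n, replace = TRUE,
                 prob = c(0.5, 0.3, 0.2))
    got <- call_roh(mk_records(pos, gt))
    want <- oracle_roh(pos, gt)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start_pos, want$start_pos)
      expect_equal(got$end_pos, want$end_pos)
      expect_equal(got$n_snps, as.integer(want$n_snps))
    }
  }
})

test_that("shared ROH is the max-start/min-end intersection over focal segments", {
  segs <- data.frame(sample = c("a", "b", "c"), contig = "chr2",
                     start_pos = c(100, 120, 90), end_pos = c(200, 260, 210),
                     n_snps = 10L)
  sh <- shared_roh(segs, "chr2", 150)
  expect_equal(sh$start_pos, 120); expect_equal(sh$end_pos, 200)
  expect_equal(sh$supporting_samples, c("a", "b", "c"))

  same <- segs; same$start_pos <- 100; same$end_pos <- 200
  sh2 <- shared_roh(same, "chr2", 150)
  expect_equal(c(sh2$start_pos, sh2$end_pos), c(100, 200))

  # idempotent under adding a sample whose segment covers the intersection
  wide <- rbind(segs, data.frame(sample = "d", contig = "chr2",
                                 start_pos = 50, end_pos = 500, n_snps = 20L))
  sh3 <- shared_roh(wide, "chr2", 150)
  expect_equal(c(sh3$start_pos, sh3$end_pos), c(120, 200))

  miss <- segs[segs$sample != "b" | segs$start_pos > 1e9, ]
  miss <- rbind(miss, data.frame(sample = "b", contig = "chr2",
                                 start_pos = 300, end_pos = 400,
                                 n_snps = 5L))
  expect_error(shared_roh(miss, "chr2", 150), "b",
               class = "no_shared_segment_error")
})

test_that("genetic-map interpolation is linear, additive and monotone", {
  map <- structure(data.frame(contig = "chr2", pos = c(0, 10e6),
                              cM = c(0, 12)),
                   class = c("genetic_map", "data.frame"))
  expect_equal(as.numeric(interval_cM(map, "chr2", 2e6, 7e6)), 6.0)
  expect_equal(as.numeric(interval_cM(map, "chr2", 3e6, 3e6)), 0)
  expect_error(interval_cM(map, "chrX", 0, 1), class = "lookup_error")

  # additivity across panels of a multi-anchor map
  m3 <- simulate_genetic_map(seed = 2)
  a <- 52.3e6; b <- 61.7e6; c <- 74.9e6
  expect_equal(as.numeric(interval_cM(m3, "chr2", a, b)) +
                 as.numeric(interval_cM(m3, "chr2", b, c)),
               as.numeric(interval_cM(m3, "chr2", a, c)))
  expect_gte(as.numeric(interval_cM(m3, "chr2", a, c)),
             as.numeric(interval_cM(m3, "chr2", a, b)))

  out <- interval_cM(m3, "chr2", 40e6, 55e6)
  expect_true(attr(out, "extrapolated"))
})

test_that("the erosion estimator inverts the expected shared length", {
  est <- estimate_generations(4, n_paths = 10, n_boot = 200, seed = 1)
  expect_equal(est$generations, 5.0)
  est2 <- estimate_generations(2, n_paths = 10, n_boot = 0)
  expect_equal(est2$generations, 10.0)   # halved length, doubled estimate
  expect_true(est$ci_low < est$generations && est$generations < est$ci_high)
  expect_error(estimate_generations(0, 10), class = "validation_error")
  expect_error(estimate_generations(4, 0), class = "validation_error")

  deb <- estimate_generations(4, n_paths = 10, n_boot = 0,
                              median_debias = TRUE)
  expect_equal(deb$generations, 5.0 * qgamma(0.5, 2) / 2)
})

test_that("age recovery: raw median within 40%, debiased median within 10%", {
  set.seed(2024)
  for (g in c(5, 26, 100)) {
    lens <- simulate_shared_length_cM(g, n_paths = 10, n_rep = 2000)
    raw <- 200 / (10 * lens)
    expect_lt(abs(median(raw) - g) / g, 0.40)
    deb <- raw * qgamma(0.5, 2) / 2
    expect_lt(abs(median(deb) - g) / g, 0.10)
  }
})

test_that("years scale linearly with generations", {
  expect_equal(years_from_generations(26, 23), 598)   # ~600 years
  expect_equal(years_from_generations(10, 25), 250)
  expect_error(years_from_generations(0), class = "validation_error")
})

test_that("F_ROH is the ROH-covered genome fraction", {
  expect_equal(inbreeding_from_roh(50e6, 3.2e9), 1 / 64)
  segs <- data.frame(sample = "s", contig = "c",
                     start_pos = c(1, 1001), end_pos = c(500, 1500),
                     n_snps = 5L)
  expect_equal(inbreeding_from_roh(segs, 1e4), 0.1)
})

test_that("simulated probands recover the planted shared interval and its erosion trend", {
  map <- simulate_genetic_map(seed = 3)
  pb <- simulate_founder_probands(map, g = 8, seed = 19)
  f <- filter_genotypes(pb$records)
  segs <- call_roh(f)
  sh <- shared_roh(segs, pb$truth$focal_contig, pb$truth$focal_pos)
  spacing <- 30e6 / 2000
  # boundaries agree with truth up to marker resolution and background
  # hom extension (geometric, ~3 markers either way)
  expect_lt(abs(sh$start_pos - pb$truth$shared_start), 30 * spacing)
  expect_lt(abs(sh$end_pos - pb$truth$shared_end), 30 * spacing)

  # shared genetic length shrinks with planted age (rank correlation < 0)
  gs <- c(2, 10, 40, 150)
  mean_len <- vapply(gs, function(g) {
    lens <- vapply(1:3, function(i) {
      p <- simulate_founder_probands(map, g = g, seed = 400 + 10 * g + i)
      # an interval eroded below the caller's min-span resolution counts
      # as length zero at that resolution
      tryCatch({
        s <- shared_roh(call_roh(filter_genotypes(p$records)),
                        p$truth$focal_contig, p$truth$focal_pos)
        as.numeric(interval_cM(map, s$contig, s$start_pos, s$end_pos))
      }, no_shared_segment_error = function(e) 0)
    }, numeric(1))
    mean(lens)
  }, numeric(1))
  expect_lt(cor(gs, mean_len, method = "spearman"), 0)
})
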