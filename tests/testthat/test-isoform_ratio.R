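tx_with_exons <- function(id, exons, cds_start = 210, cds_end = 300,
                          gene = "g1", strand = "+") {
  transcript_model(id, gene, "c1", strand, exons, cds_start, cds_end)
}

test_that("unique regions are the interval set difference of exon unions", {
  long <- tx_with_exons("t1", data.frame(start = c(0, 200),
                                         end = c(100, 300)))
  short <- tx_with_exons("t2", data.frame(start = c(50, 200),
                                          end = c(100, 300)))
  ur <- unique_regions(long, short)
  expect_equal(ur$long_only, data.frame(start = 0, end = 50))
  expect_equal(nrow(ur$short_only), 0L)
  expect_false(ur$indistinguishable)

  same <- unique_regions(long, tx_with_exons("t3", long$exons))
  expect_true(same$indistinguishable)

  apart <- unique_regions(
    tx_with_exons("t1", data.frame(start = 0, end = 300)),
    tx_with_exons("t2", data.frame(start = 400, end = 700),
                  cds_start = 410, cds_end = 500))
  expect_equal(apart$long_only, data.frame(start = 0, end = 300))
  expect_equal(apart$short_only, data.frame(start = 400, end = 700))
})

test_that("alternative first exons each contribute their own unique territory", {
  fx <- ugp2_like_fixture()
  ur <- unique_regions(fx$long, fx$short)
  # the long isoform's private first exon, and the short isoform's upstream
  # extension into the intron
  expect_equal(ur$long_only, fx$long$exons[1, ], ignore_attr = TRUE)
  expect_equal(ur$short_only,
               data.frame(start = fx$short$exons$start[1],
                          end = fx$long$exons$start[2]))
})

test_that("read counting honours the per-region double-count convention", {
  regions <- structure(list(gene_id = "g1", contig = "c1",
                            short_only = data.frame(start = 0, end = 100),
                            long_only = data.frame(start = 200, end = 300),
                            indistinguishable = FALSE),
                       class = "unique_regions")
  reads <- data.frame(start = c(seq(0, 95, length.out = 30),
                                seq(200, 290, length.out = 70)),
                      end = c(seq(0, 95, length.out = 30) + 5,
                              seq(200, 290, length.out = 70) + 5))
  expect_equal(count_region_reads(regions, reads),
               c(short_count = 30, long_count = 70), ignore_attr = TRUE)

  spanning <- data.frame(start = 50, end = 250)
  expect_equal(count_region_reads(regions, spanning),
               c(short_count = 1, long_count = 1), ignore_attr = TRUE)
  # assign-to-larger-overlap mode counts it once (short side: 50 vs 50 tie
  # goes to short by >=)
  expect_equal(sum(count_region_reads(regions, spanning,
                                      mode = "larger-overlap")), 1)

  off <- data.frame(contig = "other", start = 10, end = 20)
  res <- count_region_reads(regions, off)
  expect_equal(attr(res, "n_skipped"), 1L)
  expect_equal(sum(res), 0)
})

test_that("counts from a planted-usage sample fall within binomial bounds", {
  sim <- simulate_expression_counts(
    data.frame(gene_id = "g1", tissue = "t", usage = 0.8),
    depth = 2000, n_samples_per_tissue = 1, seed = 3)
  sc <- sim$counts$short_count
  expect_lt(abs(sc - 1600), 3 * sqrt(2000 * 0.8 * 0.2))
  expect_equal(sim$counts$short_count + sim$counts$long_count, 2000)
})

test_that("tissue ratios average counts before forming the ratio", {
  counts <- data.frame(sample = c("a1", "a2", "b1"), gene_id = "g1",
                       short_count = c(30, 50, 0), long_count = c(70, 50, 0))
  samples <- data.frame(sample = c("a1", "a2", "b1"),
                        tissue = c("A", "A", "B"))
  tr <- tissue_ratios(counts, samples)
  expect_equal(tr$ratios$ratio[tr$ratios$tissue == "A"], 0.40)
  expect_true(is.na(tr$ratios$ratio[tr$ratios$tissue == "B"]))
  expect_equal(tr$profiles$n_tissues_defined, 1L)
  expect_true(is.na(tr$profiles$variability))
})

test_that("a short-only expressed tissue yields ratio exactly 1", {
  sim <- simulate_expression_counts(
    data.frame(gene_id = "g1", tissue = "brain", usage = 1.0),
    depth = 500, n_samples_per_tissue = 2, seed = 1)
  tr <- tissue_ratios(sim$counts, sim$samples)
  expect_equal(tr$ratios$ratio, 1.0)
})

test_that("variability flagging is strict and needs two defined tissues", {
  profiles <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                         n_tissues_defined = c(3L, 2L, 2L, 1L),
                         variability = c(0.7, 0.1, 0.5, NA))
  fl <- variability_filter(profiles)
  expect_equal(fl$flagged, c(TRUE, FALSE, FALSE))  # 0.5 is not > 0.5
  expect_equal(attr(fl, "excluded"), "g4")
})

test_that("ratios are bounded and variability is label-invariant and monotone", {
  sim <- simulate_expression_counts(
    simulate_usage(sprintf("g%d", 1:6), seed = 2), depth = 400, seed = 2)
  tr <- tissue_ratios(sim$counts, sim$samples)
  expect_true(all(tr$ratios$ratio >= 0 & tr$ratios$ratio <= 1, na.rm = TRUE))
  # complement symmetry: swapping the isoform roles mirrors the ratio
  swapped <- sim$counts
  names(swapped)[3:4] <- c("long_count", "short_count")
  tr2 <- tissue_ratios(swapped, sim$samples)
  expect_equal(tr$ratios$ratio + tr2$ratios$ratio,
               rep(1, nrow(tr$ratios)))

  # relabeling tissues leaves variability unchanged
  relabeled <- sim$samples
  relabeled$tissue <- paste0("T_", relabeled$tissue)
  tr3 <- tissue_ratios(sim$counts, relabeled)
  expect_equal(sort(tr3$profiles$variability),
               sort(tr$profiles$variability))

  # dropping a tissue never increases the range
  sub <- sim$samples[sim$samples$tissue != "brain", ]
  tr4 <- tissue_ratios(sim$counts[sim$counts$sample %in% sub$sample, ], sub)
  both <- merge(tr$profiles, tr4$profiles, by = "gene_id")
  ok <- stats::complete.cases(both[, c("variability.x", "variability.y")])
  expect_true(all(both$variability.y[ok] <= both$variability.x[ok] + 1e-12))
})
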