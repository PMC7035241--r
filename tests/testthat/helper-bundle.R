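# build a complete on-disk input bundle plus config for pipeline tests and
# the acceptance checks
make_pipeline_bundle <- function(dir, seed = 1, g = 26, n_markers = 1500,
                                 depth = 2000) {
  sim <- simulate_scan_annotation(n_genes = 20, n_planted = 7, seed = seed)
  paths <- write_scan_bundle(sim, dir)
  usage <- simulate_usage(sim$truth$planted$gene_id, seed = seed + 1)
  expr <- simulate_expression_counts(usage, depth = depth, seed = seed + 2)
  epaths <- write_expression_bundle(expr, dir)
  map <- simulate_genetic_map(seed = seed + 3)
  map_path <- file.path(dir, "map.tsv")
  write_genetic_map(map, map_path)
  pb <- simulate_founder_probands(map, g = g, seed = seed + 4,
                                  n_markers = n_markers)
  vcf_path <- file.path(dir, "probands.vcf")
  write_probands_vcf(pb, vcf_path)
  config <- list(
    seed = seed,
    scan = list(gtf = unname(paths[["gtf"]]), fasta = unname(paths[["fasta"]]),
                essential = unname(paths[["essential"]]),
                disease = unname(paths[["disease"]])),
    ratio = list(counts = unname(epaths[["counts"]]),
                 samples = unname(epaths[["samples"]])),
    roh = list(vcf = vcf_path, map = map_path,
               focal = sprintf("%s:%d", pb$truth$focal_contig,
                               pb$truth$focal_pos),
               n_paths = pb$truth$n_paths))
  list(config = config, sim = sim, usage = usage, probands = pb, map = map)
}
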