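## Orchestration: configuration, stage composition, run manifest, report.
##
## The pipeline composes the module APIs in order (scan -> ratio ->
## optional consequence -> roh -> age); no computation lives only here.

#' Read and validate a pipeline configuration (YAML)
#'
#' @param path YAML path.
#' @return Validated config list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' Checks stage blocks and required fields before any compute; missing
#' fields raise a config error naming the field. Thresholds default to the
#' standard values (truncation < 50 aa, variability > 0.5, ROH snp 5 /
#' kb 100 / gap 10,000 / het 0, DP >= 10, GQ >= 50) and are logged into
#' the manifest.
#'
#' @param config Config list (see the vignette for the schema).
#' @return The config with defaults filled in.
#' @export
validate_config <- function(config) {
  req <- function(block, field) {
    if (is.null(config[[block]][[field]]))
      abort2(sprintf("config field missing: %s.%s", block, field),
             "config_error")
  }
  for (f in c("gtf", "fasta", "essential", "disease")) req("scan", f)
  if (is.null(config$scan$max_truncation_aa))
    config$scan$max_truncation_aa <- 50
  for (f in c("counts", "samples")) req("ratio", f)
  if (is.null(config$ratio$threshold)) config$ratio$threshold <- 0.5
  if (is.null(config$ratio$min_count)) config$ratio$min_count <- 10
  if (!is.null(config$roh)) {
    for (f in c("vcf", "map", "focal", "n_paths")) req("roh", f)
    if (is.null(config$roh$dp)) config$roh$dp <- 10
    if (is.null(config$roh$gq)) config$roh$gq <- 50
    p <- config$roh$params
    config$roh$params <- roh_params(
      min_snp = p$min_snp %||% 5, min_kb = p$min_kb %||% 100,
      max_gap_kb = p$max_gap_kb %||% 10000,
      window_het = p$window_het %||% 0)
    if (is.null(config$seed))
      abort2("config field missing: seed (required for the age stage)",
             "config_error")
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_focal <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    abort2(paste0("focal variant must be 'contig:pos', got ", x),
           "config_error")
  list(contig = parts[1], pos = as.numeric(parts[2]))
}

#' Run the full pipeline from a configuration
#'
#' Executes scan -> ratio -> roh -> age; each stage's output feeds the
#' next where applicable, and any stage failure stops the run with a
#' stage-labeled error. Returns a run manifest whose hash is reproducible
#' for identical inputs, config and seeds.
#'
#' @param config Config list or YAML path (see [validate_config()]).
#' @return List of class \code{run_manifest}: tool version, config hash,
#'   input checksums, per-stage counts and results, seed registry.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  else config <- validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort2(sprintf("[%s] %s", name, conditionMessage(e)), "stage_error"))
  }
  inputs <- c(config$scan$gtf, config$scan$fasta, config$scan$essential,
              config$scan$disease, config$ratio$counts, config$ratio$samples,
              config$roh$vcf, config$roh$map)
  checksums <- tools::md5sum(inputs)

  scan <- stage("scan", {
    transcripts <- read_gtf(config$scan$gtf)
    genome <- read_genome(config$scan$fasta)
    results <- scan_annotation(transcripts, genome)
    cascade <- apply_filters(results,
                             read_gene_list(config$scan$essential),
                             read_gene_list(config$scan$disease),
                             config$scan$max_truncation_aa)
    list(results = results, cascade = cascade)
  })

  ratio <- stage("ratio", {
    counts <- read_counts(config$ratio$counts)
    samples <- read_samples(config$ratio$samples)
    ## restrict the usage statistic to containment-positive genes
    keep <- scan$results$gene_id[scan$results$contained]
    counts <- counts[counts$gene_id %in% keep, ]
    tr <- tissue_ratios(counts, samples, min_count = config$ratio$min_count)
    flags <- variability_filter(tr$profiles,
                                threshold = config$ratio$threshold)
    list(ratios = tr$ratios, profiles = tr$profiles, flags = flags)
  })

  roh <- age <- NULL
  if (!is.null(config$roh)) {
    roh <- stage("roh", {
      focal <- parse_focal(config$roh$focal)
      region <- if (!is.null(config$roh$region)) {
        r <- parse_focal(sub("-.*$", "", config$roh$region))
        list(contig = r$contig, start = r$pos,
             end = as.numeric(sub("^.*-", "", config$roh$region)))
      }
      records <- read_genotypes_vcf(config$roh$vcf, region = region)
      filtered <- filter_genotypes(records, min_dp = config$roh$dp,
                                   min_gq = config$roh$gq)
      segments <- call_roh(filtered, config$roh$params)
      shared <- shared_roh(segments, focal$contig, focal$pos)
      map <- read_genetic_map(config$roh$map)
      len_cM <- interval_cM(map, shared$contig, shared$start_pos,
                            shared$end_pos)
      list(segments = segments, shared = shared, length_cM = as.numeric(len_cM))
    })
    age <- stage("age", {
      est <- estimate_generations(roh$length_cM, config$roh$n_paths,
                                  seed = config$seed)
      yrs <- years_from_generations(
        est$generations, config$age$years_per_generation %||% 25)
      list(estimate = est, years = yrs)
    })
  }

  manifest <- list(
    tool = "startloss", version = as.character(utils::packageVersion("startloss")),
    config = config,
    input_checksums = as.list(checksums),
    stages = list(
      scan = list(n_genes_tested = nrow(scan$results),
                  cascade_stages = scan$cascade$stages$stage,
                  cascade_counts = scan$cascade$stages$count,
                  survivors = scan$cascade$survivors),
      ratio = list(n_genes_assessed = nrow(ratio$flags),
                   n_flagged = sum(ratio$flags$flagged),
                   flagged = ratio$flags$gene_id[ratio$flags$flagged]),
      roh = if (!is.null(roh)) list(
        n_segments = nrow(roh$segments),
        shared = list(contig = roh$shared$contig,
                      start_pos = roh$shared$start_pos,
                      end_pos = roh$shared$end_pos,
                      samples = roh$shared$supporting_samples),
        length_cM = roh$length_cM),
      age = if (!is.null(age)) list(
        generations = age$estimate$generations,
        ci_low = age$estimate$ci_low, ci_high = age$estimate$ci_high,
        years = age$years, method = age$estimate$method)),
    seeds = list(seed = config$seed))
  manifest <- structure(manifest, class = "run_manifest")
  attr(manifest, "details") <- list(scan = scan, ratio = ratio, roh = roh,
                                    age = age)
  manifest
}

#' Hash of a run manifest
#'
#' MD5 over the manifest's JSON serialization (no timestamps are stored,
#' so re-running with identical inputs, config and seeds reproduces the
#' hash).
#'
#' @param manifest A \code{run_manifest}.
#' @return Character hash.
#' @export
manifest_hash <- function(manifest) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  attributes(manifest) <- list(names = names(manifest))
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write a human-readable and machine-readable run report
#'
#' Markdown report with the filter-cascade table, the flagged-gene
#' summary, the shared-ROH interval and the age estimate with CI and
#' seed; plus a JSON twin that round-trips the manifest fields.
#'
#' @param manifest A \code{run_manifest}.
#' @param dir Output directory.
#' @return Invisibly, named vector of written paths.
#' @export
write_report <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(md = file.path(dir, "report.md"),
             json = file.path(dir, "report.json"))
  st <- manifest$stages
  lines <- c("# startloss run report", "",
             sprintf("tool: %s %s", manifest$tool, manifest$version),
             sprintf("manifest hash: %s", manifest_hash(manifest)), "",
             "## Candidate filter cascade", "",
             "| stage | genes |", "| --- | --- |",
             sprintf("| %s | %d |", st$scan$cascade_stages,
                     st$scan$cascade_counts), "",
             "## Tissue-variable isoform usage", "",
             sprintf("%d of %d assessable genes flagged (variability > %s)",
                     st$ratio$n_flagged, st$ratio$n_genes_assessed,
                     format(manifest$config$ratio$threshold)))
  if (!is.null(st$roh)) {
    lines <- c(lines, "",
               "## Shared founder haplotype", "",
               sprintf("shared ROH: %s:%s-%s (%.3f cM, %d samples)",
                       st$roh$shared$contig,
                       format(st$roh$shared$start_pos, scientific = FALSE),
                       format(st$roh$shared$end_pos, scientific = FALSE),
                       st$roh$length_cM, length(st$roh$shared$samples)),
               sprintf(paste0("age estimate: %.1f generations ",
                              "(95%% CI %.1f-%.1f), ~%.0f years ",
                              "[seed %s, %s]"),
                       st$age$generations, st$age$ci_low, st$age$ci_high,
                       st$age$years, format(manifest$seeds$seed),
                       st$age$method))
  }
  writeLines(lines, paths["md"])
  m <- manifest; attributes(m) <- list(names = names(m))
  jsonlite::write_json(m, paths["json"], auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(paths)
}

#' @exportS3Method base::print
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$tool, x$version, "\n")
  cat("  cascade:", paste(x$stages$scan$cascade_counts, collapse = " -> "),
      "\n")
  cat("  flagged genes:", x$stages$ratio$n_flagged, "\n")
  if (!is.null(x$stages$age))
    cat(sprintf("  age: %.1f generations\n", x$stages$age$generations))
  invisible(x)
}
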