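#' Assemble a run manifest
#'
#' Bundles the sample table, configuration, seed and output directory that
#' fully determine a pipeline run. No configuration is read from anywhere
#' else; rerunning with an identical manifest reproduces identical outputs.
#'
#' @param samples Sample data.frame (columns \code{sample_id}, \code{path},
#'   \code{role}, \code{pair_id}, \code{read_length}), e.g. from
#'   [read_manifest()].
#' @param config A \code{tropic_config}.
#' @param seed Integer seed recorded with the run (the analysis itself is
#'   deterministic; the seed keys any upstream simulation).
#' @param output_dir Directory for result files.
#' @return A \code{run_manifest} list.
#' @export
run_manifest <- function(samples, config = tropic_config(), seed = 1L,
                         output_dir) {
  structure(list(samples = samples, config = config, seed = as.integer(seed),
                 output_dir = output_dir), class = "run_manifest")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the somatic repeat-expansion pipeline on a cohort
#'
#' Executes the full analysis for one cohort of tumour-normal pairs:
#' per-sample anchored IRR profiling, cross-sample event clustering,
#' global and local depth normalization, the prioritization cascade, the
#' local read-depth refilter, and per-pair expansion calls at surviving
#' loci. All manifest problems are reported before any computation starts.
#' Progress goes to stderr; machine-readable results go to files under the
#' manifest's output directory:
#' \describe{
#'   \item{loci.tsv}{clustered locus catalogue (0-based half-open)}
#'   \item{counts.tsv}{long-format raw anchored IRR counts per locus/sample}
#'   \item{results.tsv}{per-locus cascade results with status and reason}
#'   \item{calls.tsv}{per-pair quotient calls at \code{rre} loci}
#'   \item{local_depth.tsv}{local depth per locus and sample}
#'   \item{run_metadata.json}{config echo, seed, input checksums, version}
#' }
#'
#' @param manifest A \code{run_manifest}.
#' @return Invisibly, a list with \code{results}, \code{calls},
#'   \code{cohort} (the value matrices), and \code{metadata}.
#' @export
run_pipeline <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  samples <- manifest$samples
  config <- manifest$config
  validate_samples(samples)
  if (!dir.exists(manifest$output_dir))
    dir.create(manifest$output_dir, recursive = TRUE)

  message("reading ", nrow(samples), " alignment files")
  alignments <- lapply(seq_len(nrow(samples)), function(i)
    read_alignments(samples$path[i], samples$sample_id[i]))
  names(alignments) <- samples$sample_id

  message("profiling anchored in-repeat reads")
  profiles <- lapply(seq_len(nrow(samples)), function(i)
    scan_alignments(alignments[[i]],
                    min_anchor_mapq = config$min_anchor_mapq,
                    max_irr_mapq = config$max_irr_mapq,
                    min_purity = config$min_purity,
                    sample_id = samples$sample_id[i],
                    role = samples$role[i], pair_id = samples$pair_id[i]))

  message("clustering events into loci")
  clusters <- cluster_events(profiles, config$merge_distance)
  cohort <- build_cohort_matrix(profiles, clusters, config$target_depth)
  cohort <- add_local_values(cohort, alignments, config$flank)

  message("prioritizing ", nrow(cohort$loci), " loci")
  results <- prioritize(cohort, config)
  results <- local_depth_refilter(results, cohort, config)

  rre <- results$locus_id[results$status == "rre"]
  calls <- if (length(rre))
    call_expansions(cohort, rre, config$aiq_threshold, "global")
  else data.frame(pair_id = character(0), locus_id = character(0),
                  tumour_air = numeric(0), normal_air = numeric(0),
                  aiq = numeric(0), called = logical(0))

  out <- manifest$output_dir
  write_tsv(cohort$loci, file.path(out, "loci.tsv"))
  write_tsv(clusters$counts, file.path(out, "counts.tsv"))
  write_tsv(results, file.path(out, "results.tsv"))
  write_tsv(calls, file.path(out, "calls.tsv"))
  ld <- cohort$local_depth
  ld_long <- data.frame(locus_id = rep(rownames(ld), ncol(ld)),
                        sample_id = rep(colnames(ld), each = nrow(ld)),
                        local_depth = as.vector(ld),
                        stringsAsFactors = FALSE)
  write_tsv(ld_long, file.path(out, "local_depth.tsv"))

  metadata <- list(
    package = "tropicr",
    version = as.character(utils::packageVersion("tropicr")),
    seed = manifest$seed,
    config = unclass(config),
    samples = samples[, c("sample_id", "role", "pair_id", "read_length")],
    input_checksums = as.list(tools::md5sum(samples$path)),
    n_loci = nrow(cohort$loci),
    n_rre = length(rre))
  jsonlite::write_json(metadata, file.path(out, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("done: ", length(rre), " expansion loci")
  invisible(list(results = results, calls = calls, cohort = cohort,
                 metadata = metadata))
}
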