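#' Default pipeline thresholds
#'
#' All numeric filter parameters of the pipeline with their defaults: SNV
#' post-filters 4/50/20 (support/depth/quality), deletion post-filters
#' 2/25/10, minimum allele fraction 0.005, read-end border trim 5 bp,
#' DEL/VLRD boundary 15000 bp, repeat search minimum 8 bp at mismatch rate
#' 0.25, identity window flank 10 bp, gap open 10 / extend 0.5, sharing bin
#' 10 bp and profile bin 100 bp.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(snv_min_support = 4L, snv_min_depth = 50L, snv_min_quality = 20,
       del_min_support = 2L, del_min_depth = 25L, del_min_quality = 10,
       min_allele_fraction = 0.005, trim_border = 5L,
       vlrd_boundary = 15000L, repeat_min_len = 8L,
       repeat_max_mismatch_rate = 0.25, identity_flank = 10L,
       gap_open = 10, gap_extend = 0.5, sharing_bin = 10L,
       profile_bin = 100L)
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML file may define `reference` (FASTA path), `annotation` (BED
#' path), `samples` (list of `sample_id: sam_path`), `metadata` (TSV path),
#' `downsample_to`, `seed`, `output_dir` and any subset of
#' [default_thresholds()] under `thresholds`.
#'
#' @param path YAML config path.
#' @return A run-config list with thresholds merged over the defaults.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  thr <- default_thresholds()
  if (!is.null(cfg$thresholds)) thr[names(cfg$thresholds)] <- cfg$thresholds
  cfg$thresholds <- thr
  cfg
}

#' Run the mutation-spectrum pipeline end to end
#'
#' Per sample: optional downsampling, variant extraction against the
#' doubled reference, post-filtering, deletion/VLRD classification and
#' discordant-read counting. Cohort level: direct-repeat catalogue,
#' observed-versus-null breakpoint-distance comparison, breakpoint-window
#' identity, positional summaries and (when metadata is supplied) the
#' factorial ANOVA on per-sample SNV counts. All outputs are written as
#' tidy TSV/JSON under `output_dir` together with a manifest recording
#' seeds, thresholds and per-stage record counts; a rerun with the same
#' config is byte-identical.
#'
#' @param config A config list (see [read_run_config()]) or a YAML path.
#'   Alternatively `samples` may already hold alignment `data.frame`s and
#'   `reference` a [circular_genome()].
#' @return List: `variants` (classified, all samples), `repeats`,
#'   `null_comparison`, `identity`, `summaries`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  thr <- config$thresholds
  if (is.null(thr)) thr <- default_thresholds()
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  g <- config$reference
  if (is.character(g)) g <- read_genome_fasta(g, bed = config$annotation)
  stopifnot(inherits(g, "circular_genome"))

  samples <- config$samples
  if (is.null(samples) || !length(samples)) stop("no samples configured")
  if (is.character(samples[[1L]])) {
    missing <- !vapply(samples, file.exists, logical(1L))
    if (any(missing)) {
      stop("missing alignment file(s): ",
           paste(unlist(samples[missing]), collapse = ", "))
    }
  }

  all_var <- list()
  counts <- data.frame(sample_id = character(), n_records = integer(),
                       n_raw = integer(), n_filtered = integer(),
                       n_discordant = integer(), stringsAsFactors = FALSE)
  for (sid in names(samples)) {
    rec <- samples[[sid]]
    if (is.character(rec)) rec <- read_sam(rec)
    if (!is.null(config$exclude_read_ids)) {
      rec <- rec[!rec$qname %in% config$exclude_read_ids, , drop = FALSE]
    }
    if (!is.null(config$downsample_to)) {
      rec <- downsample_alignments(rec, config$downsample_to, seed,
                                   sample_id = sid)
    }
    raw <- extract_variants(rec, g, trim_border = thr$trim_border,
                            min_fraction = thr$min_allele_fraction)
    filt <- apply_post_filters(raw,
                               snv_min_support = thr$snv_min_support,
                               snv_min_depth = thr$snv_min_depth,
                               snv_min_quality = thr$snv_min_quality,
                               del_min_support = thr$del_min_support,
                               del_min_depth = thr$del_min_depth,
                               del_min_quality = thr$del_min_quality,
                               quiet = TRUE)
    cls <- classify_deletions(filt, boundary = thr$vlrd_boundary,
                              sample_id = sid)
    all_var[[sid]] <- cls
    counts <- rbind(counts, data.frame(
      sample_id = sid, n_records = nrow(rec), n_raw = nrow(raw),
      n_filtered = nrow(filt),
      n_discordant = suppressWarnings(count_discordant(rec)),
      stringsAsFactors = FALSE))
  }
  variants <- do.call(rbind, all_var)
  rownames(variants) <- NULL

  repeats <- find_direct_repeats(g, min_len = thr$repeat_min_len,
                                 max_mismatch_rate = thr$repeat_max_mismatch_rate)
  dels <- variants[variants$class %in% c("DEL", "VLRD"), , drop = FALSE]
  null_comparison <- NULL
  identity <- NULL
  if (nrow(dels) && nrow(repeats)) {
    null_lib <- generate_null_library(dels, g$length, seed)
    null_comparison <- compare_observed_vs_null(dels, null_lib, repeats,
                                                g$length)
    identity <- breakpoint_window_identity(dels, g,
                                           flank = thr$identity_flank,
                                           gap_open = thr$gap_open,
                                           gap_extend = thr$gap_extend)
  }

  snvs <- variants[variants$class == "SNV", , drop = FALSE]
  summaries <- list(
    profile = binned_allele_fraction(snvs, g$length, bin = thr$profile_bin),
    cumulative_snv = if (nrow(snvs)) cumulative_position(snvs$pos5, g$length),
    spectrum = if (nrow(snvs)) mutation_spectrum(snvs, g),
    gene_load = if (nrow(g$genes) && nrow(variants)) per_gene_load(variants, g))
  if (length(samples) > 1L && nrow(snvs)) {
    by_sample <- split(snvs$pos5, snvs$sample_id)
    if (length(by_sample) > 1L) {
      summaries$sharing <- snv_sharing(by_sample, g$length,
                                       bin = thr$sharing_bin)
    }
  }

  stats_out <- NULL
  meta <- config$metadata
  if (!is.null(meta)) {
    if (is.character(meta)) {
      meta <- utils::read.delim(meta, stringsAsFactors = FALSE)
    }
    snv_counts <- table(factor(snvs$sample_id, levels = meta$sample_id))
    meta$snv_count <- as.integer(snv_counts[meta$sample_id])
    fac <- intersect(c("age_weeks", "genotype", "region"), names(meta))
    fac <- fac[vapply(fac, function(f) length(unique(meta[[f]])) > 1L,
                      logical(1L))]
    if (length(fac) >= 1L && nrow(meta) > length(fac) + 2L) {
      stats_out <- tryCatch(
        anova_factorial(meta, "snv_count", fac),
        error = function(e) NULL)
    }
  }

  manifest <- list(seed = seed, thresholds = thr,
                   reference = g$name, reference_length = g$length,
                   n_samples = length(samples), stage_counts = counts,
                   n_repeats = nrow(repeats),
                   n_variants = nrow(variants))

  out <- list(variants = variants, repeats = repeats,
              null_comparison = null_comparison, identity = identity,
              summaries = summaries, stats = stats_out, manifest = manifest)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_variant_tsv(variants, file.path(config$output_dir, "variants.tsv"))
    write_repeat_tsv(repeats, file.path(config$output_dir, "repeats.tsv"))
    jsonlite::write_json(
      list(seed = seed, thresholds = thr, reference = g$name,
           reference_length = g$length, n_samples = length(samples),
           stage_counts = counts, n_repeats = nrow(repeats),
           n_variants = nrow(variants)),
      file.path(config$output_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Write a complete synthetic dataset to disk
#'
#' Generates a genome with planted repeats and variants from a
#' [simulation_config()] (or a YAML file holding its fields), simulates
#' alignments, and writes the genome FASTA, the doubled-reference FASTA,
#' the gene BED, the SAM file and the truth table.
#'
#' @param cfg A [simulation_config()] or path to a YAML file of its fields.
#' @param dir Output directory.
#' @return List with the `genome`, planted `repeats`, `truth` and file
#'   paths, invisibly.
#' @export
make_fixtures <- function(cfg, dir) {
  if (is.character(cfg)) {
    y <- yaml::read_yaml(cfg)
    as_df <- function(x) if (is.null(x)) NULL else do.call(rbind.data.frame, x)
    cfg <- simulation_config(seed = y$seed, L = y$L %||% 16300L,
                             n_genes = y$n_genes %||% 13L,
                             repeat_plan = as_df(y$repeat_plan),
                             snv_plan = as_df(y$snv_plan),
                             deletion_plan = as_df(y$deletion_plan),
                             vlrd_plan = as_df(y$vlrd_plan),
                             read_length = y$read_length %||% 150L,
                             depth = y$depth %||% 100)
  }
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(cfg)
  sim <- simulate_alignments(gen$genome, cfg)
  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    doubled = file.path(dir, "genome_dMT.fasta"),
    bed = file.path(dir, "genes.bed"),
    sam = file.path(dir, "sample01.sam"),
    truth = file.path(dir, "truth.tsv"),
    repeats = file.path(dir, "planted_repeats.tsv"))
  write_genome_fasta(gen$genome, paths$genome)
  write_genome_fasta(build_doubled_reference(gen$genome), paths$doubled)
  write_gene_bed(gen$genome, paths$bed)
  write_sam(sim$records, paths$sam, "dMT", 2L * gen$genome$length)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(gen$repeats, paths$repeats, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(genome = gen$genome, repeats = gen$repeats,
                 truth = sim$truth, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
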