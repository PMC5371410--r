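# Pipeline front end: manifest-driven file workflow tying the stages
# together, with run metadata for reproducibility. The R functions are the
# interface; inst/scripts/rnc-pipeline.R wraps them for shell use.

#' Read a sample manifest
#'
#' A manifest is a TSV with columns `path`, `format`, `strain`,
#' `replicate`, `time_min`, `replicon`, `replicon_length`; paths are
#' resolved relative to the manifest's directory.
#'
#' @param path Manifest path.
#' @param time_zero_offset_min Passed to [sample_set()].
#' @return A [sample_set()].
#' @export
read_manifest <- function(path, time_zero_offset_min = 3.5) {
  if (!file.exists(path)) {
    cr_stop("cleaverate_manifest_error", "manifest does not exist: %s", path)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("path", "format", "strain", "replicate", "time_min",
            "replicon", "replicon_length")
  if (!all(need %in% names(df))) {
    cr_stop("cleaverate_manifest_error", "manifest is missing columns: %s",
            paste(setdiff(need, names(df)), collapse = ", "))
  }
  base <- dirname(path)
  entries <- lapply(seq_len(nrow(df)), function(i) {
    fp <- df$path[i]
    if (!file.exists(fp)) fp <- file.path(base, df$path[i])
    list(strain = df$strain[i], replicate = as.character(df$replicate[i]),
         time = df$time_min[i],
         track = read_coverage(fp, df$format[i], df$replicon_length[i],
                               replicon_id = df$replicon[i]))
  })
  tryCatch(
    sample_set(entries, time_zero_offset_min = time_zero_offset_min),
    cleaverate_validation_error = function(e) {
      cr_stop("cleaverate_manifest_error", "manifest %s: %s", path, conditionMessage(e))
    }
  )
}

# metadata JSON written next to every stage's outputs; no timestamps, so a
# rerun with identical inputs and parameters is byte-identical
write_run_metadata <- function(dir, stage, params, inputs = character()) {
  meta <- list(
    stage = stage,
    package = "cleaverate",
    version = as.character(utils::packageVersion("cleaverate")),
    parameters = params,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)]))
  )
  jsonlite::write_json(meta, file.path(dir, sprintf("%s_metadata.json", stage)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(meta)
}

#' Simulate a dataset to disk
#'
#' Wraps [simulate_dataset()]: writes tracks, annotations, manifest,
#' ground truth and run metadata under `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [synthetic_spec()]; default [synthetic_study_spec()].
#' @param seed Integer seed.
#' @return The [simulate_dataset()] result, invisibly.
#' @export
run_simulate <- function(out_dir, spec = synthetic_study_spec(), seed = spec$seed) {
  res <- simulate_dataset(spec, seed = seed, dir = out_dir)
  write_run_metadata(out_dir, "simulate",
                     list(seed = seed, replicon_length = spec$replicon_length,
                          noise = spec$noise))
  message(sprintf("simulate: wrote %d tracks to %s", nrow(res$samples$index), out_dir))
  invisible(res)
}

#' Detect cleavage sites from a manifest
#'
#' Reads the time-zero tracks named by the manifest, forms the two
#' replicate mutant/WT ratio tracks from raw counts, calls and annotates
#' sites, and writes `sites.tsv`, `sites.bed` and run metadata.
#'
#' @param manifest_path Manifest TSV (see [read_manifest()]).
#' @param out_dir Output directory.
#' @param genes_path Optional BED/GFF3 of genes for annotation.
#' @param genes_format Format of `genes_path`.
#' @param config A [detection_config()].
#' @return The `cleavage_calls` data frame, invisibly.
#' @export
run_detect <- function(manifest_path, out_dir, genes_path = NULL,
                       genes_format = "bed", config = detection_config()) {
  samples <- read_manifest(manifest_path)
  if (length(replicates_at(samples, "mutant", 0)) < 1L) {
    cr_stop("cleaverate_manifest_error", "manifest has no mutant sample at time 0")
  }
  genes <- if (!is.null(genes_path)) read_intervals(genes_path, genes_format, "gene")
  calls <- detect_cleavage_sites(samples, genes = genes, config = config)
  message(sprintf("detect: %d candidate sites called", nrow(calls)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  site_report(calls, file.path(out_dir, "sites.tsv"))
  write_sites_bed(calls, file.path(out_dir, "sites.bed"))
  write_run_metadata(out_dir, "detect",
                     list(threshold = config$threshold,
                          min_spacing = config$min_spacing,
                          pseudocount = config$pseudocount),
                     inputs = c(manifest_path, genes_path))
  invisible(calls)
}

#' Fit decay over every region, strain and replicate
#'
#' @param samples A normalized [sample_set()].
#' @param regions An [interval_set()] of decay regions.
#' @param r2_min,min_t0_coverage Gates passed to [fit_decay()].
#' @return A data frame with one row per (region, strain, replicate):
#'   columns `region`, `strain`, `replicate`, `k`, `r_squared`,
#'   `coverage_t0`, `coverage_gate`, `r2_gate`, `half_life_min`, `n_used`,
#'   `indeterminate`.
#' @export
fit_region_halflives <- function(samples, regions, r2_min = 0.7,
                                 min_t0_coverage = 1) {
  stopifnot(inherits(samples, "sample_set"), inherits(regions, "interval_set"))
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, , drop = FALSE]
    ab <- region_abundance(samples, reg)
    series <- unique(ab[, c("strain", "replicate")])
    for (j in seq_len(nrow(series))) {
      sel <- ab$strain == series$strain[j] & ab$replicate == series$replicate[j]
      fit <- fit_decay(ab$time[sel], ab$abundance[sel],
                       r2_min = r2_min, min_t0_coverage = min_t0_coverage,
                       region = reg, strain = series$strain[j],
                       replicate = series$replicate[j])
      rows[[length(rows) + 1L]] <- summary(fit)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Contrast WT and mutant half-lives per region
#'
#' For each region, the WT half-life is the mean across WT replicates whose
#' gates passed (absent when none did), likewise for the mutant, and the
#' pair is classified with [classify_half_lives()]. Per-replicate values
#' stay available in the fit table.
#'
#' @param fits Output of [fit_region_halflives()].
#' @param fold_threshold See [classify_half_lives()].
#' @return A data frame with columns `region`, `wt_half_life`,
#'   `mutant_half_life`, `classification`.
#' @export
contrast_table <- function(fits, fold_threshold = 1.25) {
  regions <- unique(fits$region)
  mean_hl <- function(sel) {
    h <- fits$half_life_min[sel]
    h <- h[!is.na(h)]
    if (length(h)) mean(h) else NA_real_
  }
  out <- do.call(rbind, lapply(regions, function(r) {
    wt <- mean_hl(fits$region == r & fits$strain == "WT")
    mu <- mean_hl(fits$region == r & fits$strain == "mutant")
    data.frame(region = r, wt_half_life = wt, mutant_half_life = mu,
               classification = classify_half_lives(wt, mu, fold_threshold),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Normalize, fit and contrast a whole experiment in memory
#'
#' The decay stage as one call: compute stable-gene factors, normalize,
#' fit every region for every strain/replicate, and classify the WT vs
#' mutant contrast per region.
#'
#' @param samples A raw [sample_set()].
#' @param stable Stable-gene [interval_set()].
#' @param regions Decay-region [interval_set()].
#' @param r2_min,min_t0_coverage Gates passed to [fit_decay()].
#' @param fold_threshold See [classify_half_lives()].
#' @param normalize Set `FALSE` to skip normalization (negative control).
#' @return A list with `factors`, `fits`, `contrasts`.
#' @export
analyze_decay <- function(samples, stable, regions, r2_min = 0.7,
                          min_t0_coverage = 1, fold_threshold = 1.25,
                          normalize = TRUE) {
  factors <- NULL
  if (normalize) {
    factors <- compute_factors(samples, stable)
    samples <- apply_factors(samples, factors)
  }
  fits <- fit_region_halflives(samples, regions, r2_min, min_t0_coverage)
  list(factors = factors, fits = fits,
       contrasts = contrast_table(fits, fold_threshold))
}

#' Run the decay stage from a manifest
#'
#' Reads the full time course, runs [analyze_decay()], and writes
#' `factors.tsv`, `decay_fits.tsv`, `contrasts.tsv` and run metadata.
#'
#' @param manifest_path Manifest TSV.
#' @param out_dir Output directory.
#' @param stable_path BED/GFF3 of stable genes.
#' @param regions_path BED/GFF3 of decay regions.
#' @param annotation_format Format of the two annotation files.
#' @param r2_min,min_t0_coverage,fold_threshold See [analyze_decay()].
#' @return The [analyze_decay()] result, invisibly.
#' @export
run_decay <- function(manifest_path, out_dir, stable_path, regions_path,
                      annotation_format = "bed", r2_min = 0.7,
                      min_t0_coverage = 1, fold_threshold = 1.25) {
  samples <- read_manifest(manifest_path)
  stable <- read_intervals(stable_path, annotation_format, "stable_gene")
  regions <- read_intervals(regions_path, annotation_format, "decay_region")
  res <- analyze_decay(samples, stable, regions, r2_min = r2_min,
                       min_t0_coverage = min_t0_coverage,
                       fold_threshold = fold_threshold)
  message(sprintf("decay: %d fits over %d regions, %d contrasts",
                  nrow(res$fits), nrow(regions), nrow(res$contrasts)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_factors(res$factors, file.path(out_dir, "factors.tsv"))
  fits <- res$fits
  for (col in c("k", "r_squared", "coverage_t0", "half_life_min")) {
    fits[[col]] <- fmt_num(fits[[col]])
  }
  utils::write.table(fits, file.path(out_dir, "decay_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ct <- res$contrasts
  ct$wt_half_life <- fmt_num(ct$wt_half_life)
  ct$mutant_half_life <- fmt_num(ct$mutant_half_life)
  utils::write.table(ct, file.path(out_dir, "contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_metadata(out_dir, "decay",
                     list(r2_min = r2_min, min_t0_coverage = min_t0_coverage,
                          fold_threshold = fold_threshold),
                     inputs = c(manifest_path, stable_path, regions_path))
  invisible(res)
}
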