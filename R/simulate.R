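# Seeded synthetic WT/mutant coverage time courses.
#
# The generative model mirrors the structure of a real rifampin-chase
# dataset: transcripts decay exponentially at strain-specific rates,
# cleavage depletes WT coverage over a contiguous interval at/downstream of
# each planted site (a trough, not a point spike), stable genes do not
# decay, per-library depth factors rescale whole tracks, and per-base count
# noise is applied last. Expected coverage at base b for strain s,
# replicate r, time t:
#
#   E(b) = expression(b) * 0.5^(t / half_life_s(b)) / depletion_s(b)
#            * depth(s, r, t)
#
# with depletion_s(b) > 1 only for WT bases inside a depleted interval.

#' Specify a synthetic experiment
#'
#' @param replicon_length Replicon length in bp.
#' @param transcripts Data frame with columns `start`, `end`, `name`,
#'   `base_expression` (mean reads/base at time 0), `wt_half_life`,
#'   `mutant_half_life` (minutes; `Inf` = stable).
#' @param cleavage_sites Data frame with columns `position`, `depl_start`,
#'   `depl_end` (the WT-depleted interval), `wt_depletion_factor` (>= 1,
#'   divides expected WT coverage over the interval) and `class`
#'   (`"strong"`/`"weak"`). May have zero rows.
#' @param stable_genes Data frame with columns `start`, `end`, `name`,
#'   `expression`; constant abundance at all times.
#' @param depth_factors Data frame with columns `strain`, `replicate`,
#'   `time`, `depth` (> 0): one row per library to simulate.
#' @param noise `list(type = "lognormal", sdlog = 0.1)` (multiplicative,
#'   natural-log sd) or `list(type = "poisson")` (integer counts) or
#'   `list(type = "none")`.
#' @param seed Default seed used by [simulate_dataset()].
#' @param replicon_id Replicon name.
#'
#' @return A list of class `synthetic_spec`.
#' @details Every cleavage site must lie within exactly one transcript.
#' @export
synthetic_spec <- function(replicon_length, transcripts, cleavage_sites,
                           stable_genes, depth_factors,
                           noise = list(type = "lognormal", sdlog = 0.1),
                           seed = 1L, replicon_id = "chr") {
  transcripts <- as.data.frame(transcripts)
  cleavage_sites <- as.data.frame(cleavage_sites)
  stable_genes <- as.data.frame(stable_genes)
  depth_factors <- as.data.frame(depth_factors)
  if (any(transcripts$end > replicon_length) ||
      (nrow(stable_genes) && any(stable_genes$end > replicon_length))) {
    cr_stop("cleaverate_spec_error", "feature outside replicon")
  }
  for (i in seq_len(nrow(cleavage_sites))) {
    p <- cleavage_sites$position[i]
    host <- which(transcripts$start <= p & transcripts$end >= p)
    if (length(host) != 1L) {
      cr_stop("cleaverate_spec_error",
              "cleavage site at %d lies within %d transcripts (need exactly 1)",
              p, length(host))
    }
  }
  if (any(depth_factors$depth <= 0)) {
    cr_stop("cleaverate_spec_error", "depth factors must be positive")
  }
  if (!noise$type %in% c("lognormal", "poisson", "none")) {
    cr_stop("cleaverate_spec_error", "unknown noise type '%s'", noise$type)
  }
  structure(
    list(replicon_id = replicon_id, replicon_length = as.integer(replicon_length),
         transcripts = transcripts, cleavage_sites = cleavage_sites,
         stable_genes = stable_genes, depth_factors = depth_factors,
         noise = noise, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Canned study-scale synthetic experiment
#'
#' A fixed 200-kb design emulating the shape of a WT vs RNase-deletion
#' rifampin-chase experiment: 30 transcripts of 2 kb; two full WT
#' replicates (A, B) and one mutant replicate sampled at 0, 2.5, 5, 7.5,
#' 10 and 20 min; a partial WT replicate (C) at 0, 2.5 and 7.5 min; three
#' stable genes; 10 strong planted cleavage sites (WT depletion 100-1000)
#' and 5 weak sub-threshold sites (depletion 5-20, negative controls);
#' transcript pairs destabilized by cleavage (WT half-life shorter than
#' mutant), stabilized by it (WT longer), and unchanged; per-library depth
#' factors drifting over the chase (exactly 1 at time 0, since site
#' detection runs on raw time-zero counts) for normalization to undo;
#' multiplicative lognormal count noise (sd 0.1, natural-log scale).
#'
#' @param noise Override the noise model (see [synthetic_spec()]).
#' @return A `synthetic_spec`.
#' @export
synthetic_study_spec <- function(noise = list(type = "lognormal", sdlog = 0.1)) {
  n_tx <- 30L
  tx_len <- 2000L
  starts <- 2000L + (seq_len(n_tx) - 1L) * 6000L
  base_expr <- rep(c(30, 60, 120, 240, 90, 150), length.out = n_tx)
  # transcripts 1-8 destabilized by cleavage, 9-16 stabilized, rest unchanged
  wt_hl <- numeric(n_tx); mut_hl <- numeric(n_tx)
  destab <- list(c(3, 5), c(2, 4), c(4, 8), c(3, 6))
  stab <- list(c(5.5, 3.5), c(14, 6), c(6, 3), c(8, 4))
  for (i in 1:8)  { p <- destab[[(i - 1L) %% 4L + 1L]]; wt_hl[i] <- p[1]; mut_hl[i] <- p[2] }
  for (i in 9:16) { p <- stab[[(i - 9L) %% 4L + 1L]];   wt_hl[i] <- p[1]; mut_hl[i] <- p[2] }
  for (i in 17:n_tx) { wt_hl[i] <- mut_hl[i] <- rep(c(4, 6, 10), length.out = n_tx)[i] }
  transcripts <- data.frame(
    start = starts, end = starts + tx_len - 1L,
    name = sprintf("tx%02d", seq_len(n_tx)),
    base_expression = base_expr, wt_half_life = wt_hl, mutant_half_life = mut_hl
  )
  # strong sites in transcripts 1-10, weak negative controls in 11-15
  strong_depl <- c(100, 150, 200, 300, 500, 100, 250, 400, 120, 1000)
  weak_depl <- c(5, 8, 12, 16, 20)
  site_pos <- starts[1:15] + 500L
  cleavage_sites <- data.frame(
    position = site_pos,
    depl_start = site_pos, depl_end = site_pos + 149L,
    wt_depletion_factor = c(strong_depl, weak_depl),
    class = rep(c("strong", "weak"), c(10L, 5L))
  )
  stable_genes <- data.frame(
    start = c(185000L, 187000L, 189000L),
    end = c(185399L, 187399L, 189399L),
    name = c("stableA", "stableB", "stableC"),
    expression = c(500, 400, 600)
  )
  times <- c(0, 2.5, 5, 7.5, 10, 20)
  drift <- list(
    c(1, 0.9, 1.15, 0.8, 1.25, 0.7),
    c(1, 1.2, 0.75, 1.1, 0.85, 1.3),
    c(1, 0.8, 1.2),
    c(1, 1.1, 0.9, 1.3, 0.7, 1.05)
  )
  depth_factors <- rbind(
    data.frame(strain = "WT", replicate = "A", time = times, depth = drift[[1]]),
    data.frame(strain = "WT", replicate = "B", time = times, depth = drift[[2]]),
    data.frame(strain = "WT", replicate = "C", time = c(0, 2.5, 7.5), depth = drift[[3]]),
    data.frame(strain = "mutant", replicate = "A", time = times, depth = drift[[4]])
  )
  synthetic_spec(200000L, transcripts, cleavage_sites, stable_genes,
                 depth_factors, noise = noise)
}

# expected (noise-free) coverage vector for one library
expected_coverage <- function(spec, strain, time) {
  ev <- numeric(spec$replicon_length)
  tx <- spec$transcripts
  hl <- if (strain == "WT") tx$wt_half_life else tx$mutant_half_life
  for (i in seq_len(nrow(tx))) {
    decay <- if (is.infinite(hl[i])) 1 else 0.5^(time / hl[i])
    ev[tx$start[i]:tx$end[i]] <- tx$base_expression[i] * decay
  }
  sg <- spec$stable_genes
  for (i in seq_len(nrow(sg))) {
    ev[sg$start[i]:sg$end[i]] <- sg$expression[i]
  }
  if (strain == "WT") {
    cs <- spec$cleavage_sites
    for (i in seq_len(nrow(cs))) {
      idx <- cs$depl_start[i]:cs$depl_end[i]
      ev[idx] <- ev[idx] / cs$wt_depletion_factor[i]
    }
  }
  ev
}

#' Generate a synthetic dataset
#'
#' Draws the full set of coverage tracks specified by `spec`, returning an
#' in-memory [sample_set()] together with the gene/stable-gene/decay-region
#' annotations and the ground truth. When `dir` is given, the dataset is
#' also materialized on disk as bedGraph tracks, BED annotations, a
#' manifest TSV consumable by [run_detect()] / [run_decay()], and a ground
#' truth JSON (which the pipeline under test never reads). Identical
#' `spec` and `seed` produce byte-identical files.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @param dir Optional output directory.
#' @return A list with elements `samples` ([sample_set()]), `genes`,
#'   `stable`, `regions` ([interval_set()]s), `truth` (list: planted site
#'   positions and depleted intervals by class, per-transcript true
#'   half-lives, depth factors), and `dir` (or `NULL`).
#' @export
simulate_dataset <- function(spec, seed = spec$seed, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  df <- spec$depth_factors
  entries <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    ev <- expected_coverage(spec, df$strain[i], df$time[i]) * df$depth[i]
    vals <- switch(spec$noise$type,
      none = ev,
      poisson = as.numeric(stats::rpois(length(ev), ev)),
      lognormal = {
        v <- ev
        nz <- ev > 0
        v[nz] <- ev[nz] * stats::rlnorm(sum(nz), 0, spec$noise$sdlog)
        v
      })
    entries[[i]] <- list(strain = df$strain[i], replicate = df$replicate[i],
                         time = df$time[i],
                         track = coverage_track(vals, spec$replicon_id,
                                                provenance = "synthetic"))
  }
  samples <- sample_set(entries)
  genes <- interval_set(spec$replicon_id, spec$transcripts$start,
                        spec$transcripts$end, spec$transcripts$name, "gene")
  stable <- interval_set(spec$replicon_id, spec$stable_genes$start,
                         spec$stable_genes$end, spec$stable_genes$name,
                         "stable_gene")
  regions <- interval_set(spec$replicon_id, spec$transcripts$start,
                          spec$transcripts$end, spec$transcripts$name,
                          "decay_region")
  truth <- list(
    seed = seed,
    sites = spec$cleavage_sites,
    half_lives = data.frame(name = spec$transcripts$name,
                            wt = spec$transcripts$wt_half_life,
                            mutant = spec$transcripts$mutant_half_life),
    depth_factors = df
  )
  out <- list(samples = samples, genes = genes, stable = stable,
              regions = regions, truth = truth, dir = dir)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    idx <- samples$index
    paths <- character(nrow(idx))
    for (i in seq_len(nrow(idx))) {
      paths[i] <- sprintf("%s_%s_t%s.bedgraph", idx$strain[i], idx$replicate[i],
                          gsub("[.]", "p", format(idx$time[i], trim = TRUE)))
      write_coverage(get_track(samples, idx$strain[i], idx$replicate[i], idx$time[i]),
                     file.path(dir, paths[i]), "bedgraph")
    }
    write_intervals(genes, file.path(dir, "genes.bed"), "bed")
    write_intervals(stable, file.path(dir, "stable_genes.bed"), "bed")
    write_intervals(regions, file.path(dir, "decay_regions.bed"), "bed")
    manifest <- data.frame(path = paths, format = "bedgraph",
                           strain = idx$strain, replicate = idx$replicate,
                           time_min = idx$time,
                           replicon = spec$replicon_id,
                           replicon_length = spec$replicon_length,
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  out
}
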