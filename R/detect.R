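# Cleavage-site detection by mutant/WT coverage ratio.
#
# An endoribonuclease cleavage site shows up as a trough in wild-type
# coverage that is absent in the deletion mutant, so the per-base ratio
# mutant/WT spikes there. Candidate bases must clear the ratio threshold in
# BOTH wild-type replicates; a minimum inter-site spacing then collapses the
# shoulders of each peak onto its strongest base.

#' Detection parameters
#'
#' Defaults are the calibrated settings of the ratio search: threshold 30
#' (the lowest ratio observed at a known site, tufB, anchors it), minimum
#' spacing 400 bp, pseudocount 0.01 reads.
#'
#' @param threshold Minimum mutant/WT ratio required in both replicates.
#' @param min_spacing Minimum distance in bp between reported sites;
#'   two sites satisfy it when `|p1 - p2| >= min_spacing`.
#' @param pseudocount Value substituted for zero read counts so ratios are
#'   always defined.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(threshold = 30, min_spacing = 400L, pseudocount = 0.01) {
  if (!is_scalar_num(threshold) || threshold <= 0) {
    cr_stop("cleaverate_config_error", "threshold must be a positive number")
  }
  if (!is_scalar_num(min_spacing) || min_spacing <= 0) {
    cr_stop("cleaverate_config_error", "min_spacing must be a positive integer")
  }
  if (!is_scalar_num(pseudocount) || pseudocount <= 0) {
    cr_stop("cleaverate_config_error", "pseudocount must be a positive number")
  }
  structure(list(threshold = threshold, min_spacing = as.integer(min_spacing),
                 pseudocount = pseudocount),
            class = "detection_config")
}

#' Per-base mutant/WT coverage ratio
#'
#' Computes, per base, `m' / w'` where `m'` is the mutant count if positive
#' and the pseudocount otherwise, and likewise `w'` for the wild type. The
#' pseudocount replaces zeros in either numerator or denominator. Raw
#' (un-normalized) time-zero counts are the intended input: the calibrated
#' threshold refers to raw read ratios.
#'
#' @param mutant_t0 [coverage_track()] of the deletion mutant at time 0.
#' @param wt_t0 [coverage_track()] of one wild-type replicate at time 0.
#' @param pseudocount Positive value substituted for zeros (default 0.01).
#' @param wt_replicate_id Label of the wild-type replicate (carried into
#'   calls).
#' @return An object of class `ratio_track`: list with `replicon_id`,
#'   `ratios`, `wt_replicate_id`, `pseudocount`, and the raw `mutant_counts`
#'   and `wt_counts` the ratios were formed from.
#' @examples
#' m <- coverage_track(c(13954, 158, 0), "chr")
#' w <- coverage_track(c(2, 0, 0), "chr")
#' ratio_track(m, w)$ratios  # 6977, 15800, 1
#' @export
ratio_track <- function(mutant_t0, wt_t0, pseudocount = 0.01, wt_replicate_id = "") {
  stopifnot(inherits(mutant_t0, "coverage_track"), inherits(wt_t0, "coverage_track"))
  if (length(mutant_t0) != length(wt_t0)) {
    cr_stop("cleaverate_shape_error",
            "track lengths differ: mutant %d vs WT %d",
            length(mutant_t0), length(wt_t0))
  }
  if (mutant_t0$replicon_id != wt_t0$replicon_id) {
    cr_stop("cleaverate_shape_error", "tracks are on different replicons")
  }
  if (!is_scalar_num(pseudocount) || pseudocount <= 0) {
    cr_stop("cleaverate_config_error", "pseudocount must be a positive number")
  }
  m <- mutant_t0$values
  w <- wt_t0$values
  mp <- ifelse(m > 0, m, pseudocount)
  wp <- ifelse(w > 0, w, pseudocount)
  structure(
    list(replicon_id = mutant_t0$replicon_id, ratios = mp / wp,
         wt_replicate_id = wt_replicate_id, pseudocount = pseudocount,
         mutant_counts = m, wt_counts = w),
    class = "ratio_track"
  )
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("<ratio_track> %s vs WT '%s': %d bp, max ratio %.4g, pseudocount %g\n",
              x$replicon_id, x$wt_replicate_id, length(x$ratios),
              max(x$ratios), x$pseudocount))
  invisible(x)
}

#' Call cleavage sites from two replicate ratio tracks
#'
#' Candidate bases are those where `min(ratio_a, ratio_b) >= threshold`
#' (inclusive). Spacing is then enforced greedily: candidates are ranked by
#' descending min-ratio (ties: smaller coordinate first) and accepted iff
#' they lie at least `min_spacing` bp from every already-accepted position,
#' so the strongest base of each peak represents it and shoulders are
#' suppressed. Calls are returned sorted by descending min-ratio.
#'
#' @param ratio_a,ratio_b [ratio_track()]s of the same mutant track against
#'   the two wild-type replicates.
#' @param config A [detection_config()].
#' @return A data frame of class `cleavage_calls` with columns `position`,
#'   `ratio_rep_a`, `ratio_rep_b`, `min_ratio`, `wt_reads_a`, `wt_reads_b`,
#'   `mutant_reads`, `annotation`, `affected_genes`; the configuration is
#'   attached as attributes.
#' @export
call_sites <- function(ratio_a, ratio_b, config = detection_config()) {
  stopifnot(inherits(ratio_a, "ratio_track"), inherits(ratio_b, "ratio_track"),
            inherits(config, "detection_config"))
  if (length(ratio_a$ratios) != length(ratio_b$ratios)) {
    cr_stop("cleaverate_shape_error", "ratio tracks have different lengths")
  }
  if (!isTRUE(all.equal(ratio_a$mutant_counts, ratio_b$mutant_counts))) {
    cr_stop("cleaverate_validation_error",
            "ratio tracks must derive from the same mutant track")
  }
  minr <- pmin(ratio_a$ratios, ratio_b$ratios)
  cand <- which(minr >= config$threshold)
  acc <- integer(0)
  if (length(cand)) {
    ord <- cand[order(-minr[cand], cand)]
    for (p in ord) {
      if (!length(acc) || all(abs(p - acc) >= config$min_spacing)) acc <- c(acc, p)
    }
  }
  out <- data.frame(
    position = acc,
    ratio_rep_a = ratio_a$ratios[acc],
    ratio_rep_b = ratio_b$ratios[acc],
    min_ratio = minr[acc],
    wt_reads_a = ratio_a$wt_counts[acc],
    wt_reads_b = ratio_b$wt_counts[acc],
    mutant_reads = ratio_a$mutant_counts[acc],
    annotation = rep(NA_character_, length(acc)),
    affected_genes = rep(NA_character_, length(acc)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$min_ratio, out$position), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cleavage_calls", "data.frame"),
            replicon_id = ratio_a$replicon_id,
            threshold = config$threshold, min_spacing = config$min_spacing,
            pseudocount = config$pseudocount,
            wt_replicates = c(ratio_a$wt_replicate_id, ratio_b$wt_replicate_id))
}

#' @export
print.cleavage_calls <- function(x, ...) {
  cat(sprintf("<cleavage_calls> %d sites on %s (threshold %g, spacing %d bp)\n",
              nrow(x), attr(x, "replicon_id") %||% "?",
              attr(x, "threshold"), attr(x, "min_spacing")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L), digits = 6)
  invisible(x)
}

#' Annotate calls with gene context
#'
#' A call inside one or more gene intervals gets those gene names (sorted,
#' comma-separated). A call outside every gene gets
#' `"intergenic(L-R)"` where `L` is the nearest gene ending before the
#' position and `R` the nearest gene starting after it (`.` when there is
#' none). `affected_genes` defaults to the annotation's genes.
#'
#' @param calls A `cleavage_calls` data frame from [call_sites()].
#' @param genes An [interval_set()] of gene annotations (role `"gene"`).
#' @return `calls` with `annotation` and `affected_genes` filled in.
#' @export
annotate_sites <- function(calls, genes) {
  stopifnot(inherits(calls, "cleavage_calls"), inherits(genes, "interval_set"))
  genes <- genes[genes$role == "gene", , drop = FALSE]
  for (i in seq_len(nrow(calls))) {
    p <- calls$position[i]
    inside <- genes$name[genes$start <= p & genes$end >= p]
    if (length(inside)) {
      calls$annotation[i] <- paste(sort(unique(inside)), collapse = ",")
      calls$affected_genes[i] <- calls$annotation[i]
    } else {
      left <- genes[genes$end < p, , drop = FALSE]
      right <- genes[genes$start > p, , drop = FALSE]
      L <- if (nrow(left)) left$name[which.max(left$end)] else "."
      R <- if (nrow(right)) right$name[which.min(right$start)] else "."
      calls$annotation[i] <- sprintf("intergenic(%s-%s)", L, R)
      flank <- c(if (nrow(left)) L, if (nrow(right)) R)
      calls$affected_genes[i] <- paste(flank, collapse = ",")
    }
  }
  calls
}

#' Write a site report TSV
#'
#' One row per call with the raw counts, full-precision ratios and, for
#' comparison with published integer tables, ratios rounded half away from
#' zero.
#'
#' @param calls An annotated `cleavage_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
site_report <- function(calls, path) {
  stopifnot(inherits(calls, "cleavage_calls"))
  df <- data.frame(
    location = calls$position,
    annotation = calls$annotation,
    ratio_1 = fmt_num(calls$ratio_rep_a),
    ratio_2 = fmt_num(calls$ratio_rep_b),
    ratio_1_rounded = round_half_away(calls$ratio_rep_a),
    ratio_2_rounded = round_half_away(calls$ratio_rep_b),
    wt_reads_a = fmt_num(calls$wt_reads_a),
    wt_reads_b = fmt_num(calls$wt_reads_b),
    mutant_reads = fmt_num(calls$mutant_reads),
    affected_genes = calls$affected_genes,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) cr_stop("cleaverate_io_error", "cannot write %s", path)
  invisible(path)
}

#' Write called sites as BED6+1
#'
#' Score is the min-ratio rounded and capped at 1000 (BED limit); the
#' uncapped min-ratio is kept in column 7.
#'
#' @param calls A `cleavage_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(calls, path) {
  stopifnot(inherits(calls, "cleavage_calls"))
  chrom <- attr(calls, "replicon_id") %||% "chr"
  out <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s",
                 chrom, calls$position - 1L, calls$position,
                 ifelse(is.na(calls$annotation), sprintf("site_%d", calls$position),
                        calls$annotation),
                 pmin(1000L, as.integer(round_half_away(calls$min_ratio))),
                 fmt_num(calls$min_ratio))
  writeLines(out, path)
  invisible(path)
}

#' Detect cleavage sites from a sample set
#'
#' Convenience wrapper: builds the two replicate ratio tracks from the raw
#' time-zero coverage (mutant vs each of two wild-type replicates), calls
#' sites, and annotates them when gene intervals are given.
#'
#' @param samples A [sample_set()] with raw (un-normalized) counts.
#' @param genes Optional [interval_set()] for annotation.
#' @param config A [detection_config()].
#' @param wt_replicates The two WT replicate ids to use; default the first
#'   two (sorted) present at time 0.
#' @return A `cleavage_calls` data frame.
#' @export
detect_cleavage_sites <- function(samples, genes = NULL,
                                  config = detection_config(),
                                  wt_replicates = NULL) {
  stopifnot(inherits(samples, "sample_set"))
  wt_reps <- wt_replicates %||% utils::head(replicates_at(samples, "WT", 0), 2L)
  if (length(wt_reps) != 2L) {
    cr_stop("cleaverate_validation_error", "need exactly two WT replicates at time 0")
  }
  mut_rep <- replicates_at(samples, "mutant", 0)[1L]
  mut <- get_track(samples, "mutant", mut_rep, 0)
  ra <- ratio_track(mut, get_track(samples, "WT", wt_reps[1L], 0),
                    config$pseudocount, wt_reps[1L])
  rb <- ratio_track(mut, get_track(samples, "WT", wt_reps[2L], 0),
                    config$pseudocount, wt_reps[2L])
  calls <- call_sites(ra, rb, config)
  if (!is.null(genes)) calls <- annotate_sites(calls, genes)
  calls
}
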