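#' Per-base read-coverage track
#'
#' A coverage track holds one non-negative read count per base of a single
#' replicon, addressed by 1-based inclusive genomic position. This is the
#' per-base counting convention of IGVtools `count` with window size 1:
#' `values[p]` is the coverage at genomic position `p`.
#'
#' @param values Numeric vector of per-base read counts, one per base,
#'   position 1 first. All values must be finite and >= 0.
#' @param replicon_id Name of the replicon (chromosome/plasmid) the track
#'   covers.
#' @param provenance Optional free-text note on how the per-base counts were
#'   produced (e.g. the counting tool); carried into output metadata.
#'
#' @return An object of class `coverage_track`: a list with elements
#'   `replicon_id`, `values` and `provenance`.
#' @examples
#' tr <- coverage_track(c(5, 5, 5, 0, 0), "chr")
#' length(tr)
#' @export
coverage_track <- function(values, replicon_id = "chr", provenance = NULL) {
  if (!is.numeric(values) || length(values) < 1L) {
    cr_stop("cleaverate_validation_error", "coverage values must be a non-empty numeric vector")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    cr_stop("cleaverate_validation_error", "coverage values must all be finite")
  }
  if (any(values < 0)) {
    cr_stop("cleaverate_validation_error", "coverage values must be non-negative")
  }
  if (!is.character(replicon_id) || length(replicon_id) != 1L || !nzchar(replicon_id)) {
    cr_stop("cleaverate_validation_error", "replicon_id must be a single non-empty string")
  }
  structure(
    list(replicon_id = replicon_id, values = as.numeric(values),
         provenance = provenance),
    class = "coverage_track"
  )
}

#' @export
length.coverage_track <- function(x) length(x$values)

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d bp, total %.4g reads, max %.4g\n",
              x$replicon_id, length(x$values), sum(x$values), max(x$values)))
  invisible(x)
}

# positions must lie in [1, length]; used by every consumer of a track
check_bounds <- function(track, start, end, what = "interval") {
  if (start < 1L || end > length(track$values)) {
    cr_stop("cleaverate_bounds_error",
            "%s [%d, %d] outside replicon '%s' of length %d",
            what, start, end, track$replicon_id, length(track$values))
  }
  invisible(TRUE)
}

#' Genomic interval annotations
#'
#' An interval set is a data frame of 1-based inclusive genomic intervals
#' with a name and a role. Roles distinguish ordinary genes (used for site
#' annotation), stable genes (the normalization anchor set, e.g. ssrA, ssrS
#' and rnpB in E. coli) and decay regions (windows over which half-lives
#' are fitted).
#'
#' @param replicon_id Character vector of replicon names (recycled).
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @param name Interval names.
#' @param role One of `"gene"`, `"stable_gene"`, `"decay_region"` (recycled).
#'
#' @return A data frame of class `interval_set` with columns `replicon_id`,
#'   `start`, `end`, `name`, `role`.
#' @examples
#' interval_set("chr", c(11, 401), c(20, 900), c("ssrA", "rnpB"), "stable_gene")
#' @export
interval_set <- function(replicon_id, start, end, name, role = "gene") {
  n <- max(length(start), length(end), length(name))
  if (n == 0L) {
    df <- data.frame(replicon_id = character(), start = integer(),
                     end = integer(), name = character(), role = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("interval_set", "data.frame")
    return(df)
  }
  role <- match.arg(rep_len(role, n), c("gene", "stable_gene", "decay_region"),
                    several.ok = TRUE)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start > end)) {
    bad <- which(start > end)[1L]
    cr_stop("cleaverate_validation_error",
            "interval '%s' has start %d > end %d", name[bad], start[bad], end[bad])
  }
  if (any(start < 1L)) {
    cr_stop("cleaverate_validation_error", "interval starts must be >= 1")
  }
  df <- data.frame(replicon_id = rep_len(as.character(replicon_id), n),
                   start = start, end = end,
                   name = as.character(name), role = role,
                   stringsAsFactors = FALSE)
  class(df) <- c("interval_set", "data.frame")
  df
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d intervals (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$role)), table(x$role)),
                    collapse = ", ")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

# 1-based base positions covered by the union of a set of intervals
interval_union_positions <- function(intervals) {
  if (nrow(intervals) == 0L) return(integer())
  sort(unique(unlist(mapply(seq.int, intervals$start, intervals$end,
                            SIMPLIFY = FALSE))))
}
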