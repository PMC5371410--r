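# Stable-gene normalization of a rifampin time course.
#
# After transcription arrest, sequencing depth still varies from library to
# library. Transcripts that do not decay over the chase (in E. coli: ssrA,
# ssrS, rnpB) provide an internal anchor: the ratio of their coverage at
# time t to time 0 estimates the relative depth of the t-minute library,
# and dividing by it makes successive time points comparable to time zero.

#' Compute stable-gene normalization factors
#'
#' For each (strain, replicate, time) series member the factor is
#' `S(t) / S(0)`, where `S(t)` is the mean per-base coverage over the
#' stable-gene bases at time `t`. The time-0 factor is exactly 1. Each
#' (strain, replicate) series is anchored to its own time zero.
#'
#' @param samples A [sample_set()].
#' @param stable An [interval_set()] whose `stable_gene` entries define the
#'   anchor set.
#' @param method `"union_mean"` (default): mean per-base coverage over the
#'   union of stable-gene bases, bases in overlapping intervals counted
#'   once — robust to unequal gene lengths. `"gene_mean"`: mean over genes
#'   of per-gene mean coverage.
#'
#' @return An object of class `norm_factors`: a data frame with columns
#'   `strain`, `replicate`, `time`, `factor`, plus attributes
#'   `stable_gene_names` and `method`.
#' @details A series whose stable-gene coverage at time 0 is zero cannot be
#'   anchored and raises a normalization error; stable intervals outside the
#'   replicon raise a bounds error.
#' @export
compute_factors <- function(samples, stable, method = c("union_mean", "gene_mean")) {
  method <- match.arg(method)
  stopifnot(inherits(samples, "sample_set"))
  stable <- stable[stable$role == "stable_gene", , drop = FALSE]
  if (nrow(stable) == 0L) {
    cr_stop("cleaverate_validation_error",
            "no stable_gene intervals available for normalization")
  }
  L <- samples$replicon_length
  if (any(stable$start < 1L) || any(stable$end > L)) {
    cr_stop("cleaverate_bounds_error",
            "stable-gene interval outside replicon of length %d", L)
  }
  pos <- interval_union_positions(stable)

  stat <- function(track) {
    if (method == "union_mean") {
      mean(track$values[pos])
    } else {
      mean(vapply(seq_len(nrow(stable)),
                  function(i) mean(track$values[stable$start[i]:stable$end[i]]), 0))
    }
  }

  idx <- samples$index
  S <- vapply(seq_len(nrow(idx)), function(i) {
    stat(get_track(samples, idx$strain[i], idx$replicate[i], idx$time[i]))
  }, 0)
  fac <- numeric(nrow(idx))
  series <- unique(idx[, c("strain", "replicate")])
  for (i in seq_len(nrow(series))) {
    sel <- idx$strain == series$strain[i] & idx$replicate == series$replicate[i]
    s0 <- S[sel & idx$time == 0]
    if (s0 == 0) {
      cr_stop("cleaverate_normalization_error",
              "stable-gene coverage at time 0 is zero for %s/%s: cannot anchor",
              series$strain[i], series$replicate[i])
    }
    fac[sel] <- S[sel] / s0
  }
  fac[idx$time == 0] <- 1  # exact by construction
  out <- data.frame(strain = idx$strain, replicate = idx$replicate,
                    time = idx$time, factor = fac, stringsAsFactors = FALSE)
  structure(out, class = c("norm_factors", "data.frame"),
            stable_gene_names = sort(unique(stable$name)), method = method)
}

#' Apply normalization factors to a sample set
#'
#' Divides every track's per-base values by its factor (division, not
#' subtraction: sequencing depth acts multiplicatively on coverage).
#' Time-zero tracks are unchanged. The input sample set is not modified.
#'
#' @param samples A [sample_set()].
#' @param factors A `norm_factors` object from [compute_factors()] covering
#'   every track in `samples`.
#' @return A new, normalized [sample_set()].
#' @export
apply_factors <- function(samples, factors) {
  stopifnot(inherits(samples, "sample_set"), inherits(factors, "norm_factors"))
  fkey <- track_key(factors$strain, factors$replicate, factors$time)
  out <- samples
  for (i in seq_len(nrow(samples$index))) {
    key <- track_key(samples$index$strain[i], samples$index$replicate[i],
                     samples$index$time[i])
    j <- match(key, fkey)
    if (is.na(j)) {
      cr_stop("cleaverate_key_error", "no normalization factor for %s", key)
    }
    out$tracks[[key]]$values <- samples$tracks[[key]]$values / factors$factor[j]
  }
  out
}

#' Write normalization factors as TSV
#'
#' @param factors A `norm_factors` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_factors <- function(factors, path) {
  stopifnot(inherits(factors, "norm_factors"))
  df <- as.data.frame(factors)
  df$factor <- fmt_num(df$factor)
  df$stable_gene_set <- paste(attr(factors, "stable_gene_names"), collapse = ",")
  names(df)[names(df) == "time"] <- "time_min"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
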