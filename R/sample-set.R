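#' Organize coverage tracks by strain, replicate and time
#'
#' A sample set holds every coverage track of a rifampin-chase experiment,
#' keyed by strain (`"WT"` or `"mutant"`), replicate id and time label in
#' minutes. The sample labeled 0 min is itself taken a few minutes after
#' rifampin addition (to let the drug reach RNA polymerase); that offset is
#' recorded as metadata and never enters any fit — time labels are minutes
#' relative to the 0-min sample.
#'
#' @param entries A list; each element is a list with fields `strain`
#'   (`"WT"` or `"mutant"`), `replicate` (text), `time` (minutes, numeric)
#'   and `track` (a [coverage_track()]).
#' @param time_zero_offset_min Minutes between rifampin addition and the
#'   sample labeled 0 (default 3.5). Metadata only.
#'
#' @return An object of class `sample_set` with elements `tracks` (named
#'   list), `index` (data frame with columns `strain`, `replicate`, `time`),
#'   `replicon_id`, `replicon_length`, `time_zero_offset_min`.
#' @details Validation: all tracks must share replicon and length; time
#'   labels must be unique per (strain, replicate) and include 0; WT needs
#'   at least two replicates at time 0 and the mutant at least one.
#' @export
sample_set <- function(entries, time_zero_offset_min = 3.5) {
  if (!is.list(entries) || length(entries) == 0L) {
    cr_stop("cleaverate_validation_error", "entries must be a non-empty list")
  }
  idx <- data.frame(
    strain = vapply(entries, function(e) as.character(e$strain), ""),
    replicate = vapply(entries, function(e) as.character(e$replicate), ""),
    time = vapply(entries, function(e) as.numeric(e$time), 0),
    stringsAsFactors = FALSE
  )
  if (!all(idx$strain %in% c("WT", "mutant"))) {
    cr_stop("cleaverate_validation_error", "strain must be 'WT' or 'mutant'")
  }
  tracks <- lapply(entries, `[[`, "track")
  if (!all(vapply(tracks, inherits, TRUE, "coverage_track"))) {
    cr_stop("cleaverate_validation_error", "every entry needs a coverage_track")
  }
  rep_ids <- vapply(tracks, `[[`, "", "replicon_id")
  lens <- vapply(tracks, length, 1L)
  if (length(unique(rep_ids)) != 1L || length(unique(lens)) != 1L) {
    cr_stop("cleaverate_validation_error",
            "all tracks must share one replicon and length")
  }
  key <- track_key(idx$strain, idx$replicate, idx$time)
  if (anyDuplicated(key)) {
    cr_stop("cleaverate_validation_error",
            "duplicate (strain, replicate, time) entry: %s", key[duplicated(key)][1L])
  }
  series <- unique(idx[, c("strain", "replicate")])
  for (i in seq_len(nrow(series))) {
    tt <- idx$time[idx$strain == series$strain[i] & idx$replicate == series$replicate[i]]
    if (!0 %in% tt) {
      cr_stop("cleaverate_validation_error",
              "series %s/%s has no time-0 sample", series$strain[i], series$replicate[i])
    }
  }
  wt0 <- unique(idx$replicate[idx$strain == "WT" & idx$time == 0])
  mut0 <- unique(idx$replicate[idx$strain == "mutant" & idx$time == 0])
  if (length(wt0) < 2L) {
    cr_stop("cleaverate_validation_error",
            "WT needs >= 2 replicates at time 0 (found %d)", length(wt0))
  }
  if (length(mut0) < 1L) {
    cr_stop("cleaverate_validation_error", "mutant needs >= 1 replicate at time 0")
  }
  names(tracks) <- key
  structure(
    list(tracks = tracks, index = idx,
         replicon_id = rep_ids[[1L]], replicon_length = lens[[1L]],
         time_zero_offset_min = time_zero_offset_min),
    class = "sample_set"
  )
}

track_key <- function(strain, replicate, time) {
  sprintf("%s|%s|%g", strain, replicate, time)
}

#' Extract one track from a sample set
#'
#' @param samples A [sample_set()].
#' @param strain `"WT"` or `"mutant"`.
#' @param replicate Replicate id.
#' @param time Time label in minutes.
#' @return A [coverage_track()].
#' @export
get_track <- function(samples, strain, replicate, time) {
  stopifnot(inherits(samples, "sample_set"))
  key <- track_key(strain, replicate, time)
  tr <- samples$tracks[[key]]
  if (is.null(tr)) {
    cr_stop("cleaverate_key_error", "no track for (%s, %s, %g)", strain, replicate, time)
  }
  tr
}

#' Replicates present for a strain at a given time
#' @param samples A [sample_set()].
#' @param strain `"WT"` or `"mutant"`.
#' @param time Time label in minutes (default 0).
#' @return Character vector of replicate ids, sorted.
#' @export
replicates_at <- function(samples, strain, time = 0) {
  stopifnot(inherits(samples, "sample_set"))
  sort(unique(samples$index$replicate[samples$index$strain == strain &
                                        samples$index$time == time]))
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %s (%d bp), %d tracks, t0 offset %.1f min\n",
              x$replicon_id, x$replicon_length, length(x$tracks),
              x$time_zero_offset_min))
  idx <- x$index
  for (s in unique(idx$strain)) for (r in sort(unique(idx$replicate[idx$strain == s]))) {
    tt <- sort(idx$time[idx$strain == s & idx$replicate == r])
    cat(sprintf("  %s/%s: t = %s min\n", s, r, paste(tt, collapse = ", ")))
  }
  invisible(x)
}
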