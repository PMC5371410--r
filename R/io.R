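# Readers and writers for the track and interval formats the pipeline
# consumes. All internal coordinates are 1-based inclusive; conversion to
# and from each format's native convention happens here and nowhere else.
#
# bedGraph intervals are 0-based half-open (UCSC). Overlapping data lines
# are a hard error rather than last-writer-wins: per-base counts silently
# overwritten would corrupt every downstream ratio and fit.

#' Read a per-base coverage track
#'
#' Reads a bedGraph or fixed-step wiggle file into a dense per-base
#' [coverage_track()]. Bases absent from the file get coverage 0.
#'
#' @param path Path to the file.
#' @param format `"bedgraph"` or `"wiggle"` (fixedStep).
#' @param replicon_length Length in bp of the replicon; the returned track is
#'   dense over `1:replicon_length`.
#' @param replicon_id Optional replicon name; defaults to the name found in
#'   the file (or `"chr"` for a file with no data lines).
#'
#' @return A [coverage_track()].
#' @details Malformed lines raise a parse error naming the line number;
#'   intervals extending past `replicon_length` raise a bounds error;
#'   bedGraph lines covering the same base twice raise a parse error.
#' @seealso [write_coverage()]
#' @export
read_coverage <- function(path, format = c("bedgraph", "wiggle"),
                          replicon_length, replicon_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    cr_stop("cleaverate_io_error", "file does not exist: %s", path)
  }
  if (!is_scalar_num(replicon_length) || replicon_length < 1) {
    cr_stop("cleaverate_validation_error", "replicon_length must be a positive integer")
  }
  replicon_length <- as.integer(replicon_length)
  lines <- readLines(path)
  values <- numeric(replicon_length)
  seen_id <- NULL

  if (format == "bedgraph") {
    assigned <- logical(replicon_length)
    for (i in seq_along(lines)) {
      ln <- lines[[i]]
      if (!nzchar(trimws(ln)) || startsWith(ln, "#") ||
          startsWith(ln, "track") || startsWith(ln, "browser")) next
      f <- strsplit(trimws(ln), "[ \t]+")[[1L]]
      if (length(f) < 4L) {
        cr_stop("cleaverate_parse_error",
                "%s line %d: expected 4 bedGraph fields, got %d", path, i, length(f))
      }
      s0 <- suppressWarnings(as.numeric(f[2L]))
      e0 <- suppressWarnings(as.numeric(f[3L]))
      v <- suppressWarnings(as.numeric(f[4L]))
      if (anyNA(c(s0, e0, v)) || s0 != floor(s0) || e0 != floor(e0)) {
        cr_stop("cleaverate_parse_error", "%s line %d: non-numeric bedGraph fields", path, i)
      }
      if (s0 < 0 || e0 <= s0) {
        cr_stop("cleaverate_parse_error",
                "%s line %d: invalid half-open interval [%s, %s)", path, i, f[2L], f[3L])
      }
      if (e0 > replicon_length) {
        cr_stop("cleaverate_bounds_error",
                "%s line %d: interval end %s exceeds replicon length %d",
                path, i, f[3L], replicon_length)
      }
      if (v < 0) {
        cr_stop("cleaverate_parse_error", "%s line %d: negative coverage value", path, i)
      }
      if (!is.null(seen_id) && f[1L] != seen_id) {
        cr_stop("cleaverate_parse_error",
                "%s line %d: multiple replicons in one track ('%s' after '%s')",
                path, i, f[1L], seen_id)
      }
      seen_id <- f[1L]
      idx <- (s0 + 1L):e0  # 0-based half-open -> 1-based inclusive
      if (any(assigned[idx])) {
        cr_stop("cleaverate_parse_error",
                "%s line %d: overlaps a previously covered base (overlap forbidden)",
                path, i)
      }
      assigned[idx] <- TRUE
      values[idx] <- v
    }
  } else {
    pos <- NA_integer_
    step <- 1L
    span <- 1L
    in_block <- FALSE
    for (i in seq_along(lines)) {
      ln <- trimws(lines[[i]])
      if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "track")) next
      if (startsWith(ln, "fixedStep")) {
        kv <- strsplit(strsplit(ln, "[ \t]+")[[1L]][-1L], "=")
        args <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
        if (is.na(args["chrom"]) || is.na(args["start"])) {
          cr_stop("cleaverate_parse_error",
                  "%s line %d: fixedStep header needs chrom= and start=", path, i)
        }
        if (!is.null(seen_id) && args[["chrom"]] != seen_id) {
          cr_stop("cleaverate_parse_error",
                  "%s line %d: multiple replicons in one track", path, i)
        }
        seen_id <- args[["chrom"]]
        pos <- as.integer(args[["start"]])  # wiggle is 1-based
        step <- as.integer(args["step"] %||% "1")
        if (is.na(step)) step <- 1L
        span <- as.integer(args["span"] %||% "1")
        if (is.na(span)) span <- 1L
        in_block <- TRUE
        next
      }
      if (startsWith(ln, "variableStep")) {
        cr_stop("cleaverate_parse_error",
                "%s line %d: variableStep wiggle is not supported", path, i)
      }
      if (!in_block) {
        cr_stop("cleaverate_parse_error",
                "%s line %d: data line before fixedStep header", path, i)
      }
      v <- suppressWarnings(as.numeric(ln))
      if (is.na(v)) {
        cr_stop("cleaverate_parse_error", "%s line %d: non-numeric wiggle value", path, i)
      }
      if (v < 0) {
        cr_stop("cleaverate_parse_error", "%s line %d: negative coverage value", path, i)
      }
      if (pos + span - 1L > replicon_length) {
        cr_stop("cleaverate_bounds_error",
                "%s line %d: position %d exceeds replicon length %d",
                path, i, pos + span - 1L, replicon_length)
      }
      values[pos:(pos + span - 1L)] <- v
      pos <- pos + step
    }
  }

  coverage_track(values, replicon_id %||% seen_id %||% "chr",
                 provenance = sprintf("read_coverage:%s", format))
}

#' Write a per-base coverage track
#'
#' Writes a [coverage_track()] as bedGraph (runs of equal value merged into
#' single intervals, zero runs omitted, sorted by position) or as a
#' fixed-step wiggle (one value per base). Values are printed as decimal
#' text that round-trips exactly, so
#' `read_coverage(write_coverage(t))` reproduces `t` bit for bit.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @param format `"bedgraph"` or `"wiggle"`.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path, format = c("bedgraph", "wiggle")) {
  format <- match.arg(format)
  stopifnot(inherits(track, "coverage_track"))
  if (format == "bedgraph") {
    r <- rle(track$values)
    ends <- cumsum(r$lengths)           # 1-based inclusive run ends
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    lines <- sprintf("%s\t%d\t%d\t%s", track$replicon_id,
                     starts[keep] - 1L, ends[keep], fmt_num(r$values[keep]))
    header <- sprintf("track type=bedGraph name=%s", track$replicon_id)
    out <- c(header, lines)
  } else {
    header <- sprintf("fixedStep chrom=%s start=1 step=1", track$replicon_id)
    out <- c(header, fmt_num(track$values))
  }
  ok <- tryCatch({ writeLines(out, path); TRUE }, error = function(e) FALSE)
  if (!ok) cr_stop("cleaverate_io_error", "cannot write %s", path)
  invisible(path)
}

#' Read interval annotations
#'
#' Reads BED (0-based half-open) or GFF3 (1-based inclusive) intervals,
#' normalizes both to 1-based inclusive coordinates, and tags every entry
#' with `role`. Strand information in GFF3 is read but ignored (the tracks
#' are unstranded); a notice is emitted once per file.
#'
#' @param path Path to the file.
#' @param format `"bed"` or `"gff3"`.
#' @param role Role tag applied to all entries; see [interval_set()].
#' @return An [interval_set()].
#' @export
read_intervals <- function(path, format = c("bed", "gff3"), role = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    cr_stop("cleaverate_io_error", "file does not exist: %s", path)
  }
  lines <- readLines(path)
  rep_id <- character(); start <- integer(); end <- integer(); name <- character()
  stranded <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#") ||
        startsWith(ln, "track") || startsWith(ln, "browser")) next
    f <- strsplit(trimws(ln), "\t|[ ]+")[[1L]]
    if (format == "bed") {
      if (length(f) < 3L) {
        cr_stop("cleaverate_parse_error", "%s line %d: expected >= 3 BED fields", path, i)
      }
      s0 <- suppressWarnings(as.integer(f[2L]))
      e0 <- suppressWarnings(as.integer(f[3L]))
      if (anyNA(c(s0, e0))) {
        cr_stop("cleaverate_parse_error", "%s line %d: non-integer BED coordinates", path, i)
      }
      s1 <- s0 + 1L  # BED 0-based half-open -> 1-based inclusive
      e1 <- e0
      nm <- if (length(f) >= 4L) f[4L] else sprintf("interval_%d", i)
      if (length(f) >= 6L && f[6L] %in% c("+", "-")) stranded <- TRUE
    } else {
      if (length(f) < 9L) {
        cr_stop("cleaverate_parse_error", "%s line %d: expected 9 GFF3 fields", path, i)
      }
      s1 <- suppressWarnings(as.integer(f[4L]))
      e1 <- suppressWarnings(as.integer(f[5L]))
      if (anyNA(c(s1, e1))) {
        cr_stop("cleaverate_parse_error", "%s line %d: non-integer GFF3 coordinates", path, i)
      }
      if (f[7L] %in% c("+", "-")) stranded <- TRUE
      attrs <- strsplit(f[9L], ";", fixed = TRUE)[[1L]]
      kv <- strsplit(attrs, "=", fixed = TRUE)
      keys <- vapply(kv, `[`, "", 1L)
      vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
      nm <- if ("Name" %in% keys) vals[match("Name", keys)]
            else if ("ID" %in% keys) vals[match("ID", keys)]
            else sprintf("interval_%d", i)
    }
    if (is.na(s1) || is.na(e1) || s1 > e1) {
      cr_stop("cleaverate_validation_error",
              "%s line %d: interval start %s > end %s after normalization",
              path, i, s1, e1)
    }
    rep_id <- c(rep_id, f[1L]); start <- c(start, s1); end <- c(end, e1)
    name <- c(name, nm)
  }
  if (stranded) {
    message(sprintf("read_intervals: strand fields in %s are ignored (unstranded tracks)",
                    basename(path)))
  }
  interval_set(rep_id, start, end, name, role)
}

#' Write interval annotations
#'
#' Writes an [interval_set()] as BED4 or GFF3. Reading the file back with
#' [read_intervals()] reproduces the (replicon, start, end, name) columns
#' exactly.
#'
#' @param intervals An [interval_set()].
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  stopifnot(inherits(intervals, "interval_set"))
  if (format == "bed") {
    out <- sprintf("%s\t%d\t%d\t%s", intervals$replicon_id,
                   intervals$start - 1L, intervals$end, intervals$name)
  } else {
    out <- c("##gff-version 3",
             sprintf("%s\tcleaverate\t%s\t%d\t%d\t.\t.\t.\tName=%s",
                     intervals$replicon_id, intervals$role,
                     intervals$start, intervals$end, intervals$name))
  }
  ok <- tryCatch({ writeLines(out, path); TRUE }, error = function(e) FALSE)
  if (!ok) cr_stop("cleaverate_io_error", "cannot write %s", path)
  invisible(path)
}
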