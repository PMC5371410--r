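# Transcript decay kinetics from a rifampin chase.
#
# After transcription arrest, a transcript's abundance follows
# A(t) = A(0) * 10^(-k t). Taking log10 of the t0-anchored ratio gives a
# straight line through the origin with slope -k; an ordinary least-squares
# line (intercept fitted freely) estimates k, and its coefficient of
# determination gates which fits are trustworthy. The half-life is
# t1/2 = -log10(0.5) / k = log10(2) / k, defined only for k > 0.

#' Mean normalized coverage of a region over the time course
#'
#' Aggregates a normalized [sample_set()] to one abundance value per
#' (strain, replicate, time): the mean per-base coverage over the region.
#'
#' @param samples A normalized [sample_set()].
#' @param region Either a 1-row [interval_set()] (or data frame with
#'   `start`/`end`) or a length-2 numeric `c(start, end)`, 1-based
#'   inclusive.
#' @return A data frame with columns `strain`, `replicate`, `time`,
#'   `abundance`.
#' @export
region_abundance <- function(samples, region) {
  stopifnot(inherits(samples, "sample_set"))
  if (is.numeric(region) && length(region) == 2L) {
    start <- as.integer(region[1L]); end <- as.integer(region[2L])
  } else {
    region <- as.data.frame(region)
    if (nrow(region) != 1L) {
      cr_stop("cleaverate_validation_error", "region must be a single interval")
    }
    start <- as.integer(region$start); end <- as.integer(region$end)
  }
  if (start > end) {
    cr_stop("cleaverate_validation_error", "region start > end")
  }
  if (start < 1L || end > samples$replicon_length) {
    cr_stop("cleaverate_bounds_error",
            "region [%d, %d] outside replicon of length %d",
            start, end, samples$replicon_length)
  }
  idx <- samples$index
  ab <- vapply(seq_len(nrow(idx)), function(i) {
    tr <- get_track(samples, idx$strain[i], idx$replicate[i], idx$time[i])
    mean(tr$values[start:end])
  }, 0)
  out <- data.frame(strain = idx$strain, replicate = idx$replicate,
                    time = idx$time, abundance = ab, stringsAsFactors = FALSE)
  out[order(out$strain, out$replicate, out$time), , drop = FALSE]
}

#' Fit the exponential decay model to a time course
#'
#' Fits `A(t) = A(0) * 10^(-k t)` by ordinary least squares of
#' `y = log10(A(t) / A(0))` against `t`. Time points with zero abundance
#' are dropped (their log is undefined); if fewer than 3 usable points
#' remain, or A(0) is zero, the fit is marked indeterminate rather than
#' raising an error. Two gates control whether a half-life is reported:
#' the time-zero coverage must exceed `min_t0_coverage` (default 1 read)
#' and the regression R-squared must reach `r2_min` (default 0.7). When
#' both gates pass and `k > 0`, `half_life_min = log10(2) / k`.
#'
#' @param time Time labels in minutes; must include 0.
#' @param abundance Non-negative abundances, same length as `time`.
#' @param r2_min R-squared gate (default 0.7).
#' @param min_t0_coverage Time-zero coverage gate: requires
#'   `A(0) > min_t0_coverage` (default 1).
#' @param force_zero_intercept If `TRUE`, the regression line is forced
#'   through the origin (the model's theoretical intercept); by default the
#'   intercept is fitted freely.
#' @param region,strain,replicate Optional labels carried into the result.
#'
#' @return An object of class `decay_fit` with elements `k` (decay
#'   constant, log10 units per minute), `r_squared`, `half_life_min` (`NA`
#'   unless both gates pass and `k > 0`), `coverage_t0`, `gates` (logical
#'   flags `coverage` and `r2`), `indeterminate`, `n_used`, the data, and
#'   the fitted coefficients.
#' @details A perfectly flat series has zero response variance; its
#'   R-squared is undefined and is treated as failing the gate.
#' @examples
#' t <- c(0, 2.5, 5, 7.5, 10, 20)
#' fit <- fit_decay(t, 100 * 10^(-0.1 * t))
#' fit$k          # 0.1
#' fit$half_life_min  # log10(2) / 0.1 = 3.0103
#' @export
fit_decay <- function(time, abundance, r2_min = 0.7, min_t0_coverage = 1,
                      force_zero_intercept = FALSE,
                      region = NULL, strain = NA_character_,
                      replicate = NA_character_) {
  if (length(time) != length(abundance)) {
    cr_stop("cleaverate_shape_error", "time and abundance lengths differ")
  }
  if (!0 %in% time) {
    cr_stop("cleaverate_validation_error", "time course must include time 0")
  }
  if (any(abundance < 0)) {
    cr_stop("cleaverate_validation_error", "abundances must be non-negative")
  }
  a0 <- abundance[match(0, time)]
  res <- list(k = NA_real_, r_squared = NA_real_, half_life_min = NA_real_,
              coverage_t0 = a0, intercept = NA_real_,
              gates = list(coverage = a0 > min_t0_coverage, r2 = FALSE),
              indeterminate = TRUE, n_used = 0L,
              time = time, abundance = abundance,
              r2_min = r2_min, min_t0_coverage = min_t0_coverage,
              force_zero_intercept = force_zero_intercept,
              region = region, strain = strain, replicate = replicate)
  class(res) <- "decay_fit"
  if (a0 == 0) return(res)

  keep <- abundance > 0
  t_u <- time[keep]
  y <- log10(abundance[keep] / a0)
  res$n_used <- length(t_u)
  if (length(t_u) < 3L) return(res)

  if (force_zero_intercept) {
    fit <- stats::lm(y ~ 0 + t_u)
    slope <- unname(stats::coef(fit)[1L])
    intercept <- 0
  } else {
    fit <- stats::lm(y ~ t_u)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
  }
  rss <- sum(stats::residuals(fit)^2)
  tss <- if (force_zero_intercept) sum(y^2) else sum((y - mean(y))^2)
  if (tss == 0) {
    # flat series: R^2 is 0/0; treat as failing the gate, keep the slope
    r2 <- NA_real_
  } else {
    r2 <- 1 - rss / tss
  }
  res$k <- -slope
  res$intercept <- intercept
  res$r_squared <- r2
  res$indeterminate <- FALSE
  res$gates$r2 <- is.finite(r2) && r2 >= r2_min
  if (res$gates$coverage && res$gates$r2 && res$k > 0) {
    res$half_life_min <- half_life_from_k(res$k)
  }
  res
}

#' Half-life from a decay constant
#'
#' For the model `A = 10^(-k t)` the half-life is
#' `t1/2 = -log10(0.5) / k = log10(2) / k`, in minutes when `k` is in
#' log10 units per minute. For `k <= 0` (flat or growing signal) there is
#' no half-life and `NA` is returned. Vectorized over `k`.
#'
#' @param k Decay constant(s).
#' @return Half-life in minutes, or `NA` where `k <= 0`.
#' @examples
#' half_life_from_k(0.1)  # 3.0103
#' half_life_from_k(-0.05)  # NA
#' @export
half_life_from_k <- function(k) {
  ifelse(is.finite(k) & k > 0, log10(2) / k, NA_real_)
}

#' @export
print.decay_fit <- function(x, ...) {
  lab <- if (!is.null(x$region)) paste0(" ", x$region$name %||% "") else ""
  cat(sprintf("<decay_fit>%s %s/%s\n", lab,
              x$strain %||% NA, x$replicate %||% NA))
  if (x$indeterminate) {
    cat(sprintf("  indeterminate (n_used = %d, A(0) = %.4g)\n", x$n_used, x$coverage_t0))
  } else {
    cat(sprintf("  k = %.6g /min, R^2 = %.4f, A(0) = %.4g (n = %d)\n",
                x$k, x$r_squared, x$coverage_t0, x$n_used))
    cat(sprintf("  gates: coverage %s, R^2 %s\n",
                ifelse(x$gates$coverage, "pass", "FAIL"),
                ifelse(x$gates$r2, "pass", "FAIL")))
    cat(if (is.na(x$half_life_min)) "  half-life: not reported\n"
        else sprintf("  half-life: %.4g min\n", x$half_life_min))
  }
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  out <- data.frame(
    strain = object$strain, replicate = object$replicate,
    k = object$k, r_squared = object$r_squared,
    coverage_t0 = object$coverage_t0,
    coverage_gate = object$gates$coverage, r2_gate = object$gates$r2,
    half_life_min = object$half_life_min, n_used = object$n_used,
    indeterminate = object$indeterminate,
    stringsAsFactors = FALSE
  )
  if (!is.null(object$region)) {
    out <- cbind(data.frame(region = object$region$name %||% NA_character_,
                            stringsAsFactors = FALSE), out)
  }
  out
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(log10_A0_offset = object$intercept, k = object$k)
}

#' @export
predict.decay_fit <- function(object, time = object$time, ...) {
  if (object$indeterminate) return(rep(NA_real_, length(time)))
  a0 <- object$abundance[match(0, object$time)]
  a0 * 10^(object$intercept - object$k * time)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  if (object$indeterminate) return(rep(NA_real_, length(object$time)))
  a0 <- object$abundance[match(0, object$time)]
  keep <- object$abundance > 0
  y <- log10(object$abundance[keep] / a0)
  y - (object$intercept - object$k * object$time[keep])
}

#' @export
plot.decay_fit <- function(x, ...) {
  keep <- x$abundance > 0
  graphics::plot(x$time[keep], log10(x$abundance[keep]),
                 xlab = "time after rifampin (min)",
                 ylab = "log10 abundance",
                 main = sprintf("%s/%s", x$strain %||% "", x$replicate %||% ""), ...)
  if (!x$indeterminate) {
    a0 <- x$abundance[match(0, x$time)]
    graphics::abline(a = log10(a0) + x$intercept, b = -x$k, col = "firebrick")
    graphics::legend("topright", bty = "n",
                     legend = sprintf("k = %.3g, R^2 = %.3f%s", x$k, x$r_squared,
                                      if (is.na(x$half_life_min)) ""
                                      else sprintf(", t1/2 = %.3g min", x$half_life_min)))
  }
  invisible(x)
}

#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, sdlog = 0.1, ...) {
  if (!is.null(seed)) set.seed(seed)
  pred <- predict.decay_fit(object)
  matrix(pred * stats::rlnorm(length(pred) * nsim, 0, sdlog),
         nrow = length(pred), ncol = nsim,
         dimnames = list(format(object$time), NULL))
}

#' Classify a wild-type vs mutant stability contrast
#'
#' Compares the half-life of a region in the wild type against the
#' deletion mutant. Cleavage that shortens the wild-type half-life (the
#' pnp pattern) classifies as `destabilized_by_cleavage`
#' (`mutant t1/2 / WT t1/2 >= fold_threshold`); cleavage that lengthens it
#' (the pflB/ahpC pattern) as `stabilized_by_cleavage`
#' (`WT t1/2 / mutant t1/2 >= fold_threshold`); otherwise `no_change`.
#' Whenever either half-life is absent (a gate failed or the fit was
#' indeterminate) the classification is `indeterminate`.
#'
#' @param wt_fit,mut_fit `decay_fit` objects for the same region (or `NA`
#'   half-life stand-ins via `wt_half_life`/`mut_half_life`).
#' @param fold_threshold Minimum half-life fold difference called a change
#'   (default 1.25).
#' @return An object of class `half_life_contrast`: list with `region`,
#'   `wt_half_life`, `mutant_half_life` and `classification`.
#' @examples
#' w <- fit_decay(c(0, 2.5, 5, 7.5, 10, 20),
#'                100 * 0.5^(c(0, 2.5, 5, 7.5, 10, 20) / 4))
#' m <- fit_decay(c(0, 2.5, 5, 7.5, 10, 20),
#'                100 * 0.5^(c(0, 2.5, 5, 7.5, 10, 20) / 6))
#' contrast_half_lives(w, m)$classification  # destabilized_by_cleavage
#' @export
contrast_half_lives <- function(wt_fit, mut_fit, fold_threshold = 1.25) {
  stopifnot(inherits(wt_fit, "decay_fit"), inherits(mut_fit, "decay_fit"))
  rn <- function(f) if (is.null(f$region)) NULL else f$region$name %||% NULL
  if (!is.null(rn(wt_fit)) && !is.null(rn(mut_fit)) &&
      !identical(rn(wt_fit), rn(mut_fit))) {
    cr_stop("cleaverate_validation_error",
            "fits are for different regions: '%s' vs '%s'", rn(wt_fit), rn(mut_fit))
  }
  structure(
    list(region = wt_fit$region %||% mut_fit$region,
         wt_half_life = wt_fit$half_life_min,
         mutant_half_life = mut_fit$half_life_min,
         classification = classify_half_lives(wt_fit$half_life_min,
                                              mut_fit$half_life_min,
                                              fold_threshold),
         fold_threshold = fold_threshold),
    class = "half_life_contrast"
  )
}

#' Classification rule on two half-life values
#'
#' The rule behind [contrast_half_lives()], usable directly on numbers
#' (e.g. replicate-averaged half-lives). `NA` in either argument gives
#' `"indeterminate"`.
#'
#' @param wt_half_life,mut_half_life Half-lives in minutes (or `NA`).
#' @param fold_threshold Minimum fold difference called a change.
#' @return One of `"destabilized_by_cleavage"`, `"stabilized_by_cleavage"`,
#'   `"no_change"`, `"indeterminate"`.
#' @export
classify_half_lives <- function(wt_half_life, mut_half_life, fold_threshold = 1.25) {
  if (is.na(wt_half_life) || is.na(mut_half_life)) return("indeterminate")
  if (mut_half_life / wt_half_life >= fold_threshold) return("destabilized_by_cleavage")
  if (wt_half_life / mut_half_life >= fold_threshold) return("stabilized_by_cleavage")
  "no_change"
}

#' @export
print.half_life_contrast <- function(x, ...) {
  cat(sprintf("<half_life_contrast> %s: WT %s min vs mutant %s min -> %s\n",
              if (is.null(x$region)) "?" else x$region$name %||% "?",
              ifelse(is.na(x$wt_half_life), "NA", sprintf("%.3g", x$wt_half_life)),
              ifelse(is.na(x$mutant_half_life), "NA", sprintf("%.3g", x$mutant_half_life)),
              x$classification))
  invisible(x)
}
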