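stable_two <- interval_set("chr", c(101, 201), c(150, 260),
                           c("stbA", "stbB"), "stable_gene")

test_that("sample sets validate their structure", {
  mk <- function(...) coverage_track(rep(1, 300), "chr")
  good <- build_samples(c(0, 5), function(...) rep(1, 300), 300)
  expect_s3_class(good, "sample_set")
  expect_equal(replicates_at(good, "WT", 0), c("A", "B"))

  # series without time zero
  entries <- list(
    list(strain = "WT", replicate = "A", time = 0, track = mk()),
    list(strain = "WT", replicate = "B", time = 0, track = mk()),
    list(strain = "mutant", replicate = "A", time = 5, track = mk())
  )
  expect_error(sample_set(entries), class = "cleaverate_validation_error")

  # only one WT replicate at time zero
  entries <- list(
    list(strain = "WT", replicate = "A", time = 0, track = mk()),
    list(strain = "mutant", replicate = "A", time = 0, track = mk())
  )
  expect_error(sample_set(entries), class = "cleaverate_validation_error")

  # mismatched track lengths
  entries <- list(
    list(strain = "WT", replicate = "A", time = 0, track = mk()),
    list(strain = "WT", replicate = "B", time = 0,
         track = coverage_track(rep(1, 299), "chr")),
    list(strain = "mutant", replicate = "A", time = 0, track = mk())
  )
  expect_error(sample_set(entries), class = "cleaverate_validation_error")
})

test_that("constant stable coverage gives unit factors; halving gives 0.5", {
  s <- build_samples(c(0, 2.5), function(st, r, t) rep(100, 300), 300)
  f <- compute_factors(s, stable_two)
  expect_true(all(f$factor == 1))

  s <- build_samples(c(0, 2.5), function(st, r, t) {
    if (t == 0) rep(100, 300) else rep(50, 300)
  }, 300)
  f <- compute_factors(s, stable_two)
  expect_equal(f$factor[f$time == 2.5], rep(0.5, 3))
  expect_identical(f$factor[f$time == 0], rep(1, 3))
})

test_that("union-mean factors match a flat per-base loop, with overlaps counted once", {
  # three stable genes of unequal length, two overlapping
  stable <- interval_set("chr", c(101, 131, 220), c(130, 190, 280),
                         c("g1", "g2", "g3"), "stable_gene")
  set.seed(5)
  vals0 <- stats::runif(400, 50, 150)
  vals5 <- vals0 * 0.47
  s <- build_samples(c(0, 5), function(st, r, t) if (t == 0) vals0 else vals5, 400)
  f <- compute_factors(s, stable)
  tr0 <- get_track(s, "WT", "A", 0)
  tr5 <- get_track(s, "WT", "A", 5)
  oracle <- brute_force_stable_mean(tr5, stable) / brute_force_stable_mean(tr0, stable)
  expect_equal(f$factor[f$strain == "WT" & f$replicate == "A" & f$time == 5],
               oracle)

  # per-gene means 90/100/110 at t0 and 45/50/55 at t5 -> factor 0.5 either way
  stable3 <- interval_set("chr", c(1, 11, 21), c(10, 20, 30),
                          c("a", "b", "c"), "stable_gene")
  mk <- function(st, r, t) {
    v <- rep(0, 400)
    v[1:10] <- 90; v[11:20] <- 100; v[21:30] <- 110
    if (t != 0) v <- v / 2
    v
  }
  s3 <- build_samples(c(0, 5), mk, 400)
  f3 <- compute_factors(s3, stable3)
  expect_equal(f3$factor[f3$time == 5], rep(0.5, 3))
  f3g <- compute_factors(s3, stable3, method = "gene_mean")
  expect_equal(f3g$factor[f3g$time == 5], rep(0.5, 3))
})

test_that("factors are invariant to stable-interval order", {
  set.seed(11)
  vals <- lapply(1:2, function(i) stats::runif(300, 10, 60))
  s <- build_samples(c(0, 5), function(st, r, t) vals[[match(t, c(0, 5))]], 300)
  f1 <- compute_factors(s, stable_two)
  f2 <- compute_factors(s, stable_two[2:1, ])
  expect_equal(f1$factor, f2$factor)
})

test_that("a zero stable-gene anchor raises a normalization error", {
  s <- build_samples(c(0, 5), function(st, r, t) rep(0, 300), 300)
  expect_error(compute_factors(s, stable_two),
               class = "cleaverate_normalization_error")
  # stable interval outside the replicon is a bounds error
  s2 <- build_samples(c(0, 5), function(st, r, t) rep(1, 100), 100)
  expect_error(compute_factors(s2, stable_two),
               class = "cleaverate_bounds_error")
})

test_that("apply_factors divides, leaves t0 alone, and inverts exactly", {
  set.seed(11)
  vals <- list()
  s <- build_samples(c(0, 2.5, 5), function(st, r, t) {
    key <- paste(st, r, t)
    vals[[key]] <<- stats::runif(300, 0, 50)
    vals[[key]]
  }, 300)
  f <- compute_factors(s, stable_two)
  norm <- apply_factors(s, f)
  # original not mutated
  expect_identical(get_track(s, "WT", "A", 2.5)$values, vals[["WT A 2.5"]])
  # multiply back recovers input elementwise
  for (i in seq_len(nrow(f))) {
    orig <- get_track(s, f$strain[i], f$replicate[i], f$time[i])$values
    scaled <- get_track(norm, f$strain[i], f$replicate[i], f$time[i])$values
    expect_equal(scaled * f$factor[i], orig, tolerance = 1e-12)
    if (f$time[i] == 0) expect_identical(scaled, orig)
  }
  # unit factor everywhere is the identity
  fu <- f
  fu$factor <- rep(1, nrow(fu))
  expect_equal(apply_factors(s, fu)$tracks, s$tracks)
  # factor 0.5 doubles values
  expect_equal(get_track(norm, "WT", "A", 2.5)$values,
               vals[["WT A 2.5"]] / f$factor[f$strain == "WT" & f$replicate == "A" & f$time == 2.5])
})

test_that("normalized stable-gene means are flat across the time course", {
  d <- simulate_dataset(small_spec(), seed = 3)
  f <- compute_factors(d$samples, d$stable)
  norm <- apply_factors(d$samples, f)
  pos <- unlist(mapply(seq.int, d$stable$start, d$stable$end, SIMPLIFY = FALSE))
  idx <- norm$index
  for (st in c("WT", "mutant")) for (r in unique(idx$replicate[idx$strain == st])) {
    tt <- idx$time[idx$strain == st & idx$replicate == r]
    means <- vapply(tt, function(t) mean(get_track(norm, st, r, t)$values[pos]), 0)
    expect_equal(max(abs(means / means[tt == 0] - 1)), 0, tolerance = 1e-9)
  }
  # negative control: without normalization the drifting depths show
  raw_means <- vapply(time_grid, function(t)
    mean(get_track(d$samples, "WT", "A", t)$values[pos]), 0)
  decay_free_dev <- abs(raw_means / raw_means[1] - 1)
  expect_gt(max(decay_free_dev), 0.05)
})

test_that("a missing factor row is a key error", {
  s <- build_samples(c(0, 5), function(st, r, t) rep(10, 300), 300)
  f <- compute_factors(s, stable_two)
  f2 <- f[f$time != 5 | f$strain != "mutant", ]
  class(f2) <- class(f)
  attributes(f2)$stable_gene_names <- attr(f, "stable_gene_names")
  expect_error(apply_factors(s, f2), class = "cleaverate_key_error")
})
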