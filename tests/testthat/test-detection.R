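test_that("pseudocounted ratios reproduce reference arithmetic", {
  m <- coverage_track(c(13954, 158, 0.5, 0), "chr")
  w <- coverage_track(c(2, 0, 0, 0), "chr")
  rt <- ratio_track(m, w, pseudocount = 0.01)
  expect_equal(rt$ratios, c(13954 / 2, 158 / 0.01, 0.5 / 0.01, 1))
  expect_equal(rt$ratios[2], 15800)
  expect_equal(rt$ratios[4], 1)  # 0.01/0.01: symmetric pseudocount
})

test_that("ratio tracks reject mismatched shapes and bad pseudocounts", {
  m <- coverage_track(rep(1, 10), "chr")
  expect_error(ratio_track(m, coverage_track(rep(1, 9), "chr")),
               class = "cleaverate_shape_error")
  expect_error(ratio_track(m, coverage_track(rep(1, 10), "other")),
               class = "cleaverate_shape_error")
  expect_error(ratio_track(m, m, pseudocount = 0),
               class = "cleaverate_config_error")
})

test_that("ratios at doubly-nonzero bases are scale-invariant", {
  set.seed(21)
  for (i in 1:20) {
    m <- stats::rpois(100, 5)
    w <- stats::rpois(100, 5)
    c_mult <- stats::runif(1, 0.1, 50)
    r1 <- ratio_track(coverage_track(m), coverage_track(w))$ratios
    r2 <- ratio_track(coverage_track(m * c_mult), coverage_track(w * c_mult))$ratios
    nz <- m > 0 & w > 0
    expect_equal(r2[nz], r1[nz], tolerance = 1e-12)
  }
})

test_that("candidate filtering, greedy spacing and descending-ratio output", {
  ratios <- rep(1, 1200)
  ratios[100] <- 50; ratios[350] <- 40; ratios[900] <- 35
  pair <- ratio_pair_from_values(ratios)
  calls <- call_sites(pair$a, pair$b, detection_config())
  expect_equal(calls$position, c(100, 900))  # 350 suppressed by 100
  expect_equal(calls$min_ratio, c(50, 35), tolerance = 1e-9)

  # no base above threshold -> empty result
  none <- call_sites(ratio_pair_from_values(rep(1, 500))$a,
                     ratio_pair_from_values(rep(1, 500))$b)
  expect_equal(nrow(none), 0L)
})

test_that("the threshold is inclusive and requires both replicates", {
  # mutant 930, WT A 30, WT B 31 -> ratios exactly (31, 30)
  mut <- coverage_track(c(rep(0, 4), 930), "chr")
  in_pair <- call_sites(
    ratio_track(mut, coverage_track(c(rep(0, 4), 30), "chr")),
    ratio_track(mut, coverage_track(c(rep(0, 4), 31), "chr"))
  )
  expect_equal(in_pair$position, 5L)
  expect_equal(sort(c(in_pair$ratio_rep_a, in_pair$ratio_rep_b)), c(30, 31))

  # one replicate below 30 -> no call
  out_pair <- call_sites(
    ratio_track(mut, coverage_track(c(rep(0, 4), 30), "chr")),
    ratio_track(mut, coverage_track(c(rep(0, 4), 32), "chr"))
  )
  expect_equal(nrow(out_pair), 0L)
})

test_that("equal min-ratios break ties toward the smaller coordinate", {
  ratios <- rep(1, 700)
  ratios[c(200, 400)] <- 60  # mutually exclusive, equal strength
  pair <- ratio_pair_from_values(ratios)
  calls <- call_sites(pair$a, pair$b)
  expect_equal(calls$position, 200)
})

test_that("calls satisfy spacing, dual-threshold and greedy maximality on random tracks", {
  cfg <- detection_config(threshold = 30, min_spacing = 400)
  for (seed in 1:25) {
    set.seed(seed)
    L <- 5000L
    ra <- rep(1, L); rb <- rep(1, L)
    idx <- sample(L, 30)
    ra[idx] <- stats::runif(30, 5, 200)
    rb[idx] <- stats::runif(30, 5, 200)
    pair <- ratio_pair_from_values(ra, rb)
    calls <- call_sites(pair$a, pair$b, cfg)
    if (nrow(calls) > 1L) {
      expect_gte(min(dist(calls$position)), cfg$min_spacing)
    }
    # both replicate ratios clear the threshold, recomputed from raw counts
    re_a <- ifelse(calls$mutant_reads > 0, calls$mutant_reads, 0.01) /
      ifelse(calls$wt_reads_a > 0, calls$wt_reads_a, 0.01)
    re_b <- ifelse(calls$mutant_reads > 0, calls$mutant_reads, 0.01) /
      ifelse(calls$wt_reads_b > 0, calls$wt_reads_b, 0.01)
    expect_true(all(pmin(re_a, re_b) >= cfg$threshold))
    # greedy maximality: every rejected candidate is blocked by an accepted
    # site of equal or higher priority
    minr <- pmin(pair$a$ratios, pair$b$ratios)
    cand <- which(minr >= cfg$threshold)
    rejected <- setdiff(cand, calls$position)
    for (p in rejected) {
      blockers <- calls$position[abs(calls$position - p) < cfg$min_spacing]
      expect_true(any(minr[blockers] > minr[p] |
                        (minr[blockers] == minr[p] & blockers < p)))
    }
  }
})

test_that("detection config rejects non-positive parameters", {
  expect_error(detection_config(threshold = 0), class = "cleaverate_config_error")
  expect_error(detection_config(min_spacing = -1), class = "cleaverate_config_error")
  expect_error(detection_config(pseudocount = 0), class = "cleaverate_config_error")
})

test_that("site annotation labels genic, intergenic and boundary positions", {
  genes <- interval_set("chr", c(100, 500, 500), c(200, 600, 650),
                        c("geneA", "geneB", "geneC"), "gene")
  ratios <- rep(1, 2000)
  ratios[c(150, 300, 550, 50, 1500)] <- c(90, 80, 70, 60, 50)
  pair <- ratio_pair_from_values(ratios)
  cfg <- detection_config(threshold = 30, min_spacing = 1)  # keep all candidates
  calls <- annotate_sites(call_sites(pair$a, pair$b, cfg), genes)
  ann <- calls$annotation[match(c(150, 300, 550, 50, 1500), calls$position)]
  expect_equal(ann, c("geneA",
                      "intergenic(geneA-geneB)",
                      "geneB,geneC",           # overlap tie: all names, sorted
                      "intergenic(.-geneA)",   # before all genes
                      "intergenic(geneC-.)"))  # after all genes
  expect_equal(calls$affected_genes[calls$position == 300], "geneA,geneB")
})

test_that("site reports round half away from zero and handle empty calls", {
  p <- withr::local_tempfile()
  # mutant 3598 vs WT 4 reads: ratio 899.5 must display as 900
  mut <- coverage_track(c(3598, rep(0, 9)), "chr")
  wt <- coverage_track(c(4, rep(0, 9)), "chr")
  calls <- call_sites(ratio_track(mut, wt), ratio_track(mut, wt))
  site_report(calls, p)
  rep_df <- utils::read.table(p, header = TRUE, sep = "\t")
  expect_equal(rep_df$ratio_1_rounded, 900)
  expect_equal(rep_df$ratio_1, 899.5)

  empty <- call_sites(ratio_pair_from_values(rep(1, 10))$a,
                      ratio_pair_from_values(rep(1, 10))$b)
  site_report(empty, p)
  expect_equal(length(readLines(p)), 1L)  # header only

  expect_equal(round_half_away(c(899.5, 2618.5, -1.5, 2.4)),
               c(900, 2619, -2, 2))
})

test_that("BED6+1 output caps the score at 1000 and keeps the true ratio", {
  p <- withr::local_tempfile()
  ratios <- rep(1, 1000); ratios[500] <- 4321.25
  pair <- ratio_pair_from_values(ratios)
  calls <- call_sites(pair$a, pair$b)
  write_sites_bed(calls, p)
  f <- strsplit(readLines(p), "\t")[[1]]
  expect_equal(as.integer(f[2:3]), c(499L, 500L))
  expect_equal(as.integer(f[5]), 1000L)
  expect_equal(as.numeric(f[7]), 4321.25)
})
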