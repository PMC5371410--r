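# Shared builders for the test suite. Everything is generated in code.

time_grid <- c(0, 2.5, 5, 7.5, 10, 20)

# a compact synthetic experiment: 20-kb replicon, four transcripts
# (destabilized, stabilized, unchanged, weak-site host), two strong planted
# sites, one weak negative control, two stable genes, drifting depths
small_spec <- function(noise = list(type = "lognormal", sdlog = 0.1),
                       weak_depletion = 10, strong_depletion = c(200, 120)) {
  transcripts <- data.frame(
    start = c(1001L, 5001L, 9001L, 13001L),
    end = c(3000L, 7000L, 11000L, 15000L),
    name = c("txA", "txB", "txC", "txD"),
    base_expression = c(50, 120, 80, 60),
    wt_half_life = c(3, 8, 5, 4),
    mutant_half_life = c(6, 4, 5, 4)
  )
  cleavage_sites <- data.frame(
    position = c(1501L, 5501L, 13501L),
    depl_start = c(1501L, 5501L, 13501L),
    depl_end = c(1650L, 5650L, 13650L),
    wt_depletion_factor = c(strong_depletion, weak_depletion),
    class = c("strong", "strong", "weak")
  )
  stable_genes <- data.frame(
    start = c(16001L, 17001L), end = c(16400L, 17400L),
    name = c("stbA", "stbB"), expression = c(400, 500)
  )
  depth_factors <- rbind(
    data.frame(strain = "WT", replicate = "A", time = time_grid,
               depth = c(1, 0.9, 1.1, 0.8, 1.2, 0.7)),
    data.frame(strain = "WT", replicate = "B", time = time_grid,
               depth = c(1, 1.15, 0.85, 1.05, 0.95, 1.25)),
    data.frame(strain = "mutant", replicate = "A", time = time_grid,
               depth = c(1, 1.05, 0.9, 1.2, 0.75, 1.1))
  )
  synthetic_spec(20000L, transcripts, cleavage_sites, stable_genes,
                 depth_factors, noise = noise)
}

# minimal three-series sample set built from explicit per-base values;
# `maker` maps (strain, replicate, time) -> numeric vector
build_samples <- function(times, maker, L) {
  series <- list(c("WT", "A"), c("WT", "B"), c("mutant", "A"))
  entries <- list()
  for (s in series) for (t in times) {
    entries[[length(entries) + 1L]] <- list(
      strain = s[1], replicate = s[2], time = t,
      track = coverage_track(maker(s[1], s[2], t), "chr")
    )
  }
  sample_set(entries)
}

# ratio_track pair with prescribed per-base min-ratios: mutant count = ratio,
# both WT replicates = 1 read
ratio_pair_from_values <- function(ratios_a, ratios_b = ratios_a) {
  mut <- coverage_track(pmax(ratios_a, ratios_b, 1e-6), "chr")
  ra <- ratio_track(mut, coverage_track(mut$values / ratios_a, "chr"),
                    wt_replicate_id = "A")
  rb <- ratio_track(mut, coverage_track(mut$values / ratios_b, "chr"),
                    wt_replicate_id = "B")
  list(a = ra, b = rb)
}
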