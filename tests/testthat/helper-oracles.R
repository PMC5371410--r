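# Independent oracles, deliberately naive.

# exhaustive max-cardinality (ties: max total value) selection under the
# pairwise spacing constraint; feasible only for <= ~20 candidates
brute_force_select <- function(pos, val, spacing) {
  n <- length(pos)
  best <- integer(0); best_k <- -1L; best_v <- -Inf
  for (m in 0:(2^n - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) > 1L && min(dist(pos[idx])) < spacing) next
    k <- length(idx); v <- sum(val[idx])
    if (k > best_k || (k == best_k && v > best_v)) {
      best_k <- k; best_v <- v; best <- idx
    }
  }
  sort(pos[best])
}

# flat per-base loop over every stable base (union, duplicates once)
brute_force_stable_mean <- function(track, stable) {
  seen <- logical(length(track$values))
  for (i in seq_len(nrow(stable))) {
    seen[stable$start[i]:stable$end[i]] <- TRUE
  }
  tot <- 0; n <- 0L
  for (p in which(seen)) { tot <- tot + track$values[p]; n <- n + 1L }
  tot / n
}

# per-base assignment scan of a bedGraph file: TRUE iff some base is
# covered by two data lines
bedgraph_has_overlap <- function(lines, L) {
  count <- integer(L)
  for (ln in lines) {
    if (startsWith(ln, "track") || !nzchar(trimws(ln))) next
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    s <- as.integer(f[2]); e <- as.integer(f[3])
    count[(s + 1):e] <- count[(s + 1):e] + 1L
  }
  any(count > 1L)
}
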