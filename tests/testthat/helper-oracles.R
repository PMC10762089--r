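# Independent oracles used to check the package implementations. Each is a
# deliberately naive computation (per-base scans, O(n^2) closures,
# exhaustive enumeration) kept separate from the code paths it validates.

# Per-base signal integration over an interval (tracks < 10 kb only).
oracle_track_sum <- function(track, chrom, start, end) {
  total <- 0
  rows <- track[track$chrom == chrom, , drop = FALSE]
  for (b in seq(start, end - 1)) {
    hit <- which(rows$start <= b & b < rows$end)
    if (length(hit) == 1) total <- total + rows$value[hit]
  }
  total
}

# O(n^2) transitive-closure stitching: segments are adjacent when their gap
# (half-open) is <= d on the same chromosome; components get union spans.
oracle_stitch <- function(segments, d) {
  n <- nrow(segments)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (segments$chrom[i] != segments$chrom[j]) next
      gap <- max(segments$start[i], segments$start[j]) -
        min(segments$end[i], segments$end[j])
      adj[i, j] <- gap <= d
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cm) {
    m <- segments[comp == cm, , drop = FALSE]
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               n_members = nrow(m), stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Slope = 1 tangent point by brute force: over all candidate indices of the
# scaled rank curve, keep those where the slope-1 line through the point
# supports the curve from below; the cutoff is the largest such index.
oracle_tangent_cut <- function(signals) {
  n <- length(signals)
  y <- sort(signals)
  if (y[n] == y[1]) return(y[n])
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (y - y[1]) / (y[n] - y[1])
  supported <- vapply(seq_len(n), function(i) {
    all(ys >= ys[i] + (xs - xs[i]) - 1e-12)
  }, logical(1))
  y[max(which(supported))]
}

# Exhaustive hypergeometric tail P[X >= k] by enumerating all n-subsets of
# the universe (universe size <= 25 in tests).
oracle_hyper_tail <- function(k, K, N, n) {
  total <- choose(N, n)
  sum(vapply(k:min(K, n), function(j) {
    choose(K, j) * choose(N - K, n - j)
  }, numeric(1))) / total
}

# Hand step-up BH: q_i = min_{j >= i} (m p_(j) / j) on the sorted scale.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Random segment set on a small genome for property tests.
random_segments <- function(n, chroms = c("chrA", "chrB"),
                            max_pos = 200000, max_len = 3000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample.int(max_len, n, TRUE),
             stringsAsFactors = FALSE)
}

# Minimal in-memory fixture: one sample, three clusters on one chromosome,
# with known member-level signal.
tiny_sample <- function() {
  segments <- data.frame(
    chrom = "chr1",
    start = c(1000, 3000, 40000, 43000, 90000),
    end = c(2000, 4000, 41000, 44000, 92000),
    state = c("13_EnhA1", "14_EnhA2", "13_EnhA1", "18_EnhAc", "13_EnhA1"),
    sample_id = "s1", stringsAsFactors = FALSE)
  h3k <- signal_track(data.frame(
    chrom = "chr1", start = c(1000, 3000, 40000, 43000, 90000),
    end = c(2000, 4000, 41000, 44000, 92000),
    value = c(4, 4, 4, 4, 40), stringsAsFactors = FALSE))
  inp <- signal_track(data.frame(
    chrom = "chr1", start = 0, end = 100000, value = 1,
    stringsAsFactors = FALSE))
  list(segments = segments, h3k = h3k, inp = inp)
}

write_lines_tsv <- function(lines, path = tempfile()) {
  writeLines(lines, path)
  path
}
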