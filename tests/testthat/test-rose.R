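test_that("active-state filtering keeps only configured labels in order", {
  seg <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                    end = c(50, 150, 250),
                    state = c("13_EnhA1", "17_ReprPC", "1_TssA"),
                    sample_id = "s1")
  kept <- filter_active(seg, rose_config())
  expect_equal(kept$state, c("13_EnhA1", "1_TssA"))
  all_active <- filter_active(seg, rose_config(active_states = seg$state))
  expect_equal(all_active, seg, ignore_attr = TRUE)
  expect_error(rose_config(active_states = character(0)), "non-empty")
})

test_that("stitching follows the 12.5 kb gap rule on the worked example", {
  seg <- data.frame(chrom = "chr1", start = c(0, 5000, 20000),
                    end = c(100, 5100, 20100))
  st <- stitch(seg, 12500)
  expect_equal(nrow(st$regions), 2)  # gaps 4900 <= 12500 merge; 14900 not
  expect_equal(st$regions$start, c(0, 20000))
  expect_equal(st$regions$end, c(5100, 20100))
  expect_equal(st$regions$n_members, c(2L, 1L))
})

test_that("stitch distance 0 merges only overlapping or bookended segments", {
  seg <- data.frame(chrom = "chr1", start = c(0, 100, 300),
                    end = c(100, 200, 400))
  st <- stitch(seg, 0)
  expect_equal(st$regions$start, c(0, 300))  # bookended [0,100)+[100,200)
  expect_equal(st$regions$end, c(200, 400))
})

test_that("stitching matches the O(n^2) transitive-closure oracle", {
  set.seed(11)
  for (rep in 1:5) {
    seg <- random_segments(200)
    d <- sample(c(0, 500, 5000, 12500), 1)
    got <- stitch(seg, d)$regions
    want <- oracle_stitch(seg, d)
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_members, want$n_members)
  }
})

test_that("stitching is idempotent and leaves gaps above the distance", {
  set.seed(12)
  seg <- random_segments(150)
  d <- 3000
  once <- stitch(seg, d)$regions
  twice <- stitch(once[, c("chrom", "start", "end")], d)$regions
  expect_equal(once[, c("chrom", "start", "end")],
               twice[, c("chrom", "start", "end")], ignore_attr = TRUE)
  for (chrom in unique(once$chrom)) {
    r <- once[once$chrom == chrom, ]
    if (nrow(r) > 1) {
      expect_true(all(r$start[-1] - r$end[-nrow(r)] > d))
    }
  }
})

test_that("quantification is the member-restricted input-subtracted sum", {
  # constant h3k27ac=4, input=1 over one 100 bp member -> 300
  st <- stitch(data.frame(chrom = "chr1", start = 1000, end = 1100), 12500)
  h3k <- signal_track(data.frame(chrom = "chr1", start = 0, end = 5000,
                                 value = 4))
  inp <- signal_track(data.frame(chrom = "chr1", start = 0, end = 5000,
                                 value = 1))
  expect_equal(quantify(st, h3k, inp)$signal, 300)
  # input exceeding h3k27ac everywhere floors at 0
  expect_equal(quantify(st, inp, h3k)$signal, 0)
  # gaps between members do not contribute
  st2 <- stitch(data.frame(chrom = "chr1", start = c(0, 2000),
                           end = c(1000, 3000)), 12500)
  expect_equal(quantify(st2, h3k, inp)$signal, 3 * 2000)
})

test_that("quantification matches the per-base oracle on piecewise tracks", {
  set.seed(13)
  mk_track <- function() {
    width <- sample.int(400, 6, replace = TRUE)
    gap <- sample.int(300, 6, replace = TRUE)
    start <- cumsum(gap + c(0, width[-6]))
    signal_track(data.frame(chrom = "chr1", start = start,
                            end = start + width,
                            value = round(stats::runif(6, 0, 8), 2)))
  }
  h3k <- mk_track(); inp <- mk_track()
  seg <- data.frame(chrom = "chr1", start = c(100, 1200),
                    end = c(700, 2100))
  st <- stitch(seg, 12500)
  got <- quantify(st, h3k, inp)$signal
  want <- sum(vapply(seq_len(nrow(seg)), function(i) {
    oracle_track_sum(h3k, "chr1", seg$start[i], seg$end[i]) -
      oracle_track_sum(inp, "chr1", seg$start[i], seg$end[i])
  }, numeric(1)))
  expect_equal(got, max(0, want), tolerance = 1e-10)
})

region_frame <- function(signals) {
  n <- length(signals)
  data.frame(chrom = "chr1", start = seq_len(n) * 100000,
             end = seq_len(n) * 100000 + 1000, signal = signals)
}

test_that("rank-and-cut worked examples", {
  # strictly linear signals: flat scaled difference, tie -> largest index
  lin <- rank_and_cut(region_frame(1:10))
  expect_equal(sum(lin$is_super), 0)
  expect_equal(unique(lin$cutoff_signal), 10)
  # one dominant signal: exactly that region is super
  dom <- rank_and_cut(region_frame(c(1, 1, 1, 1000)))
  expect_equal(sum(dom$is_super), 1)
  expect_equal(dom$signal[dom$is_super], 1000)
  expect_equal(unique(dom$cutoff_signal), 1)
  # all-equal signals: zero superenhancers, no division by zero
  flat <- rank_and_cut(region_frame(rep(7, 6)))
  expect_equal(sum(flat$is_super), 0)
  # hockey-stick example agrees with the tangent-scan oracle
  sig <- c(1, 1, 1, 1, 2, 3, 5, 9, 20, 50)
  got <- rank_and_cut(region_frame(sig))
  expect_equal(unique(got$cutoff_signal), oracle_tangent_cut(sig))
  expect_error(rank_and_cut(region_frame(5)), "at least 2")
})

test_that("rank-and-cut ranks are a coordinate-tie-broken permutation", {
  set.seed(14)
  rg <- region_frame(sample(c(1, 2, 2, 5, 9, 9, 30), 7))
  out <- rank_and_cut(rg)
  expect_setequal(out$rank, 1:7)
  expect_true(all(diff(out$signal) <= 0))  # sorted by rank = desc signal
  expect_equal(sum(out$is_super) + sum(!out$is_super), 7)
})

test_that("rank-and-cut equals the tangent-scan oracle on random vectors", {
  set.seed(15)
  for (rep in 1:200) {
    n <- sample(3:40, 1)
    sig <- switch(sample(3, 1),
                  stats::rexp(n, 1 / 50),            # convex-ish decay
                  stats::runif(n, 0, 100),           # arbitrary
                  c(stats::runif(n - 2, 0, 5), stats::runif(2, 50, 100)))
    sig <- round(sig, 6)
    got <- rank_and_cut(region_frame(sig))
    expect_equal(unique(got$cutoff_signal), oracle_tangent_cut(sig))
  }
})

test_that("super/typical partition is invariant to signal scaling", {
  set.seed(16)
  sig <- c(stats::runif(30, 0, 10), stats::runif(4, 80, 120))
  base <- rank_and_cut(region_frame(sig))
  for (c_mult in c(0.01, 3, 1e4)) {
    scaled <- rank_and_cut(region_frame(sig * c_mult))
    expect_equal(scaled$is_super, base$is_super)
  }
})

test_that("call_sample composes the stages and recovers the strong cluster", {
  fx <- tiny_sample()
  calls <- call_sample(fx$segments, fx$h3k, fx$inp, rose_config())
  expect_equal(nrow(calls), 3)  # three stitched clusters
  expect_equal(sum(calls$is_super), 1)
  expect_equal(calls$start[calls$is_super], 90000)
  expect_equal(calls$sample_id[1], "s1")
  # doubling both tracks preserves the partition
  h2 <- signal_track(transform(as.data.frame(fx$h3k), value = value * 2))
  i2 <- signal_track(transform(as.data.frame(fx$inp), value = value * 2))
  calls2 <- call_sample(fx$segments, h2, i2, rose_config())
  expect_equal(calls2$is_super, calls$is_super)
  # no active segments is a degenerate input
  inactive <- transform(fx$segments, state = "24_ReprPC")
  expect_error(call_sample(inactive, fx$h3k, fx$inp, rose_config()),
               "no active segments")
})

test_that("TSS exclusion drops fully proximal segments when enabled", {
  fx <- tiny_sample()
  genes <- data.frame(gene_id = "g1", name = "g1", biotype = "protein_coding",
                      chrom = "chr1", start = 900, end = 5000, strand = "+",
                      tss = 900)
  cfg <- rose_config(tss_exclusion_bp = 5000)
  calls <- call_sample(fx$segments, fx$h3k, fx$inp, cfg, genes)
  # the two segments within 5 kb of the TSS at 900 are gone
  expect_equal(nrow(calls), 2)
  expect_false(any(calls$start < 5000))
  expect_error(call_sample(fx$segments, fx$h3k, fx$inp, cfg),
               "requires a gene table")
})
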