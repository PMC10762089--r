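mk_genes <- function(df) {
  df$name <- df$gene_id
  if (is.null(df$biotype)) df$biotype <- "protein_coding"
  if (is.null(df$strand)) df$strand <- "+"
  if (is.null(df$tss)) df$tss <- ifelse(df$strand == "+", df$start,
                                        df$end - 1)
  df
}

test_that("gene and TSS overlap follow the half-open boundary rules", {
  regions <- data.frame(chrom = "chr1", start = 100, end = 200)
  genes <- mk_genes(data.frame(gene_id = "g1", chrom = "chr1", start = 150,
                               end = 400))
  ann <- annotate_overlaps(regions, genes)
  expect_equal(ann$n_genes, 1L)
  expect_true(ann$encompasses_tss)     # tss 150 in [100,200)
  genes2 <- mk_genes(data.frame(gene_id = "g1", chrom = "chr1", start = 150,
                                end = 400, strand = "-"))  # tss 399
  ann2 <- annotate_overlaps(regions, genes2)
  expect_equal(ann2$n_genes, 1L)
  expect_false(ann2$encompasses_tss)   # overlapping but TSS outside
  # tss exactly at end is outside the half-open interval
  genes3 <- mk_genes(data.frame(gene_id = "g1", chrom = "chr1", start = 180,
                                end = 300, tss = 200))
  expect_false(annotate_overlaps(regions, genes3)$encompasses_tss)
  genes4 <- mk_genes(data.frame(gene_id = "g1", chrom = "chr1", start = 180,
                                end = 300, tss = 199))
  expect_true(annotate_overlaps(regions, genes4)$encompasses_tss)
})

test_that("overlap annotation matches a brute-force oracle on random data", {
  set.seed(31)
  regions <- random_segments(60, chroms = "chr1", max_pos = 50000)
  genes <- mk_genes(cbind(gene_id = sprintf("g%d", 1:40),
                          random_segments(40, chroms = "chr1",
                                          max_pos = 50000),
                          biotype = sample(c("protein_coding", "lincRNA"),
                                           40, replace = TRUE)))
  ann <- annotate_overlaps(regions, genes)
  for (i in seq_len(nrow(regions))) {
    ov <- genes$start < regions$end[i] & genes$end > regions$start[i]
    expect_equal(ann$n_genes[i], sum(ov))
    expect_equal(ann$n_protein_coding[i],
                 sum(ov & genes$biotype == "protein_coding"))
    tss_in <- regions$start[i] <= genes$tss & genes$tss < regions$end[i]
    expect_equal(ann$encompasses_tss[i], any(tss_in))
  }
  expect_true(all(ann$n_protein_coding <= ann$n_genes))
  expect_equal(ann$encompasses_tss, nzchar(ann$tss_genes))
})

test_that("Yates chi-squared equals the closed form and stats::chisq.test", {
  null_t <- chisq_yates(10, 10, 10, 10)
  expect_equal(null_t$statistic, 0)
  expect_equal(null_t$p_value, 1)
  t2 <- chisq_yates(30, 10, 10, 30)
  want <- 80 * (abs(30 * 30 - 10 * 10) - 40)^2 / (40 * 40 * 40 * 40)
  expect_equal(t2$statistic, want)
  ref <- stats::chisq.test(matrix(c(30, 10, 10, 30), 2), correct = TRUE)
  expect_equal(t2$statistic, unname(ref$statistic))
  expect_equal(t2$p_value, ref$p.value)
  # continuity term clamps to zero when |ad-bc| < N/2
  clamp <- chisq_yates(5, 4, 4, 5)  # |25-16|=9 < 18/2=9? equal -> 0
  expect_equal(clamp$statistic, 0)
  expect_error(chisq_yates(0, 0, 3, 4), "margin")
})

test_that("Yates statistic is symmetric under row and column swaps", {
  set.seed(32)
  for (rep in 1:20) {
    cells <- sample.int(50, 4)
    base <- chisq_yates(cells[1], cells[2], cells[3], cells[4])$statistic
    rows <- chisq_yates(cells[3], cells[4], cells[1], cells[2])$statistic
    cols <- chisq_yates(cells[2], cells[1], cells[4], cells[3])$statistic
    expect_equal(rows, base)
    expect_equal(cols, base)
  }
})

test_that("Yates test is conservative under the null", {
  set.seed(33)
  reps <- 10000
  a <- stats::rbinom(reps, 200, 0.5)
  c_ <- stats::rbinom(reps, 200, 0.5)
  p <- vapply(seq_len(reps), function(i) {
    chisq_yates(a[i], 200 - a[i], c_[i], 200 - c_[i])$p_value
  }, numeric(1))
  rejection <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(rejection, 0.05 + 3 * se)
})

test_that("hypergeometric enrichment gives exact combinatorial p-values", {
  universe <- sprintf("g%02d", 1:20)
  term_map <- data.frame(term_id = "T1", gene_id = universe[1:5])
  res <- hypergeom_enrich(universe[1:5], term_map, universe)
  expect_equal(res$p_value, 1 / choose(20, 5))
  expect_equal(res$k, 5L)
  # k = 0: P[X >= 0] = 1
  res0 <- hypergeom_enrich(universe[6:10], term_map, universe)
  expect_equal(res0$p_value, 1)
  expect_error(hypergeom_enrich(character(0), term_map, universe), "empty")
  expect_error(hypergeom_enrich("not_there", term_map, universe),
               "outside the universe")
})

test_that("enrichment matches exhaustive enumeration on small universes", {
  set.seed(34)
  for (rep in 1:10) {
    N <- sample(10:25, 1)
    universe <- sprintf("u%02d", seq_len(N))
    terms <- do.call(rbind, lapply(1:6, function(t) {
      data.frame(term_id = sprintf("T%d", t),
                 gene_id = sample(universe, sample(2:8, 1)))
    }))
    query <- sample(universe, sample(3:8, 1))
    res <- hypergeom_enrich(query, terms, universe)
    for (i in seq_len(nrow(res))) {
      expect_equal(res$p_value[i],
                   oracle_hyper_tail(res$k[i], res$K[i], N, res$n[i]),
                   tolerance = 1e-12)
    }
    expect_equal(sort(res$p_adjusted), res$p_adjusted)  # sorted output
    expect_true(all(res$p_adjusted >= res$p_value))
  }
})

test_that("BH adjustment equals the hand step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(35)
  for (rep in 1:20) {
    p <- stats::runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # invariance to input order up to the positional contract
  p <- stats::runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 0)), "lie in")
  expect_error(bh_adjust(c(0.5, 1.2)), "lie in")
})

test_that("pairwise class comparison builds the right 2x2 tables", {
  annotated <- data.frame(
    specificity = rep(c("shared", "embryonic", "tissue_specific"),
                      times = c(40, 20, 20)),
    encompasses_tss = c(rep(TRUE, 36), rep(FALSE, 4),   # shared 36/4
                        rep(TRUE, 12), rep(FALSE, 8),   # embryonic 12/8
                        rep(TRUE, 4), rep(FALSE, 16)))  # specific 4/16
  out <- overlap_chisq_pairwise(annotated)
  expect_equal(nrow(out), 3)
  se <- out[out$class_a == "shared" & out$class_b == "embryonic", ]
  expect_equal(unlist(se[, c("a", "b", "c", "d")]),
               c(a = 36, b = 4, c = 12, d = 8))
  ref <- chisq_yates(36, 4, 12, 8)
  expect_equal(se$statistic, ref$statistic)
  expect_true(all(out$testable))
  # a class with no members of one outcome can become untestable
  degenerate <- data.frame(
    specificity = rep(c("shared", "embryonic"), each = 4),
    encompasses_tss = c(rep(TRUE, 4), rep(TRUE, 4)))
  out2 <- overlap_chisq_pairwise(degenerate)
  expect_false(out2$testable[1])
  expect_true(is.na(out2$p_value[1]))
})
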