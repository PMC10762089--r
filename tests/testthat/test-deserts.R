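desert_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC", "nc1"),
    name = c("gA", "gB", "gC", "nc1"),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "lincRNA"),
    chrom = "chr1",
    start = c(900000, 1600000, 2400000, 1200000),
    end = c(1000000, 1700000, 2500000, 1210000),
    strand = c("+", "+", "-", "+"),
    stringsAsFactors = FALSE)
}

test_that("desert detection applies the >= 500 kb protein-coding gap rule", {
  genes <- desert_genes()
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  sizes <- c(chr1 = 3000000)
  des <- find_deserts(genes, sizes, min_length = 500000)
  # gap gA-gB is 600 kb (noncoding nc1 inside does not disqualify it);
  # gap gB-gC is exactly 700 kb; telomeric gaps are 900 kb and 500 kb
  expect_equal(nrow(des), 4)
  expect_equal(des$start, c(0, 1000000, 1700000, 2500000))
  expect_equal(des$end, c(900000, 1600000, 2400000, 3000000))
  expect_equal(des$left_gene, c(NA, "gA", "gB", "gC"))
  expect_equal(des$right_gene, c("gA", "gB", "gC", NA))
  # boundary: a gap of exactly min_length is included
  des2 <- find_deserts(genes, c(chr1 = 3000000), min_length = 600000)
  expect_true(any(des2$length == 600000))
  # unknown chromosome is an error
  expect_error(find_deserts(genes, c(chr2 = 100), 500000), "absent")
})

test_that("detected deserts never overlap a protein-coding gene", {
  set.seed(41)
  genes <- cbind(gene_id = sprintf("g%d", 1:60),
                 random_segments(60, chroms = c("chr1", "chr2"),
                                 max_pos = 5000000, max_len = 60000))
  genes$name <- genes$gene_id
  genes$biotype <- sample(c("protein_coding", "lincRNA"), 60, replace = TRUE)
  genes$strand <- "+"
  genes$tss <- genes$start
  sizes <- c(chr1 = 6000000, chr2 = 6000000)
  des <- find_deserts(genes, sizes, 200000)
  pc <- genes[genes$biotype == "protein_coding", ]
  for (i in seq_len(nrow(des))) {
    hits <- pc$chrom == des$chrom[i] & pc$start < des$end[i] &
      pc$end > des$start[i]
    expect_equal(sum(hits), 0)
  }
  expect_true(all(des$length >= 200000))
})

test_that("noncoding annotation: containment, flanks and TSS distance", {
  genes <- desert_genes()
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  sizes <- c(chr1 = 3000000)
  des <- find_deserts(genes, sizes, 500000)
  regions <- data.frame(chrom = "chr1",
                        start = c(2000000, 1590000),
                        end = c(2100000, 1650000))
  expect_error(annotate_noncoding(regions, genes, des),
               "overlaps protein-coding gene gB")
  regions <- data.frame(chrom = "chr1", start = c(2000000, 1100000),
                        end = c(2100000, 1150000))
  out <- annotate_noncoding(regions, genes, des)
  ann <- out$annotations
  expect_true(all(ann$in_desert))
  # nearest TSS to [2.0,2.1) Mb: gC is "-" so tss=2499999 -> gap 399999;
  # gB tss 1600000 -> left gap 2000000-1600001=399999
  expect_equal(ann$distance_to_nearest_tss[1], 399999)
  expect_equal(ann$flank_left[1], "gB")
  expect_equal(ann$flank_right[1], "gC")
  # flanking genes deduplicated across regions: gA,gB,gC = 3 not 4
  expect_equal(out$summary$n_flanking_genes, 3)
  # full-containment rule, checked against a hand-built desert interval
  sub_desert <- data.frame(desert_id = 1L, chrom = "chr1",
                           start = 1000000, end = 1300000)
  poking <- data.frame(chrom = "chr1", start = 1250000, end = 1350000)
  expect_false(annotate_noncoding(poking, genes,
                                  sub_desert)$annotations$in_desert[1])
  contained <- data.frame(chrom = "chr1", start = 1250000, end = 1300000)
  expect_true(annotate_noncoding(contained, genes,
                                 sub_desert)$annotations$in_desert[1])
})

test_that("TSS distances equal a brute-force minimum over all genes", {
  set.seed(42)
  genes <- cbind(gene_id = sprintf("g%d", 1:30),
                 random_segments(30, chroms = "chr1", max_pos = 900000,
                                 max_len = 5000))
  genes$name <- genes$gene_id
  genes$biotype <- "lincRNA"  # noncoding so regions never violate contract
  genes$strand <- sample(c("+", "-"), 30, replace = TRUE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  deserts <- find_deserts(genes, c(chr1 = 1000000), 1000000)
  regions <- random_segments(50, chroms = "chr1", max_pos = 900000,
                             max_len = 2000)
  out <- annotate_noncoding(regions, genes, deserts)
  for (i in seq_len(nrow(regions))) {
    d <- vapply(genes$tss, function(t) {
      if (t >= regions$end[i]) t - regions$end[i]
      else if (t + 1 <= regions$start[i]) regions$start[i] - t - 1
      else 0
    }, numeric(1))
    expect_equal(out$annotations$distance_to_nearest_tss[i], min(d))
  }
})

test_that("desert prioritization counts tested and positive elements", {
  fx <- load_desert_fixture()
  pr <- prioritize_deserts(fx$deserts, fx$elements, "craniofacial")
  chr7 <- pr[pr$chrom == "chr7", ]
  expect_equal(chr7$n_tested, 10L)
  expect_equal(chr7$n_positive, 6L)
  expect_equal(chr7$priority_rank, 1L)
  # ranking: positives desc, then tested desc, then coordinates
  expect_equal(order(-pr$n_positive, -pr$n_tested, pr$chrom, pr$start),
               seq_len(nrow(pr)))
  expect_equal(pr$priority_rank, seq_len(nrow(pr)))
  # desert with no elements scores (0, 0)
  empty <- prioritize_deserts(
    data.frame(desert_id = 1L, chrom = "chrZ", start = 0, end = 600000),
    fx$elements, "craniofacial")
  expect_equal(empty$n_tested, 0L)
  expect_equal(empty$n_positive, 0L)
})

test_that("prioritization is invariant to element order; boundary elements count twice", {
  fx <- load_desert_fixture()
  set.seed(43)
  shuffled <- fx$elements[sample(nrow(fx$elements)), ]
  a <- prioritize_deserts(fx$deserts, fx$elements, "craniofacial")
  b <- prioritize_deserts(fx$deserts, shuffled, "craniofacial")
  expect_equal(a[, c("chrom", "start", "n_tested", "n_positive")],
               b[, c("chrom", "start", "n_tested", "n_positive")],
               ignore_attr = TRUE)
  # an element spanning a shared boundary is counted in both deserts
  deserts <- data.frame(desert_id = 1:2, chrom = "chr1",
                        start = c(0, 600000), end = c(600000, 1200000))
  el <- data.frame(element_id = "spanner", chrom = "chr1", start = 599000,
                   end = 601000, stringsAsFactors = FALSE)
  el$positive_tissues <- list("craniofacial")
  pr <- prioritize_deserts(deserts, el, "craniofacial")
  expect_equal(pr$n_tested, c(1L, 1L))
  expect_equal(pr$n_positive, c(1L, 1L))
})

test_that("published desert fixture intervals all satisfy the length rule", {
  fx <- load_desert_fixture()
  expect_equal(nrow(fx$deserts), 9)
  expect_true(all(fx$deserts$length >= 500000))
  # every positive element id listed on a desert row lies inside that desert
  for (i in seq_len(nrow(fx$deserts))) {
    ids <- strsplit(fx$deserts$vista_ids[i], ",")[[1]]
    el <- fx$elements[fx$elements$element_id %in% ids, ]
    expect_true(all(el$chrom == fx$deserts$chrom[i]))
    expect_true(all(el$start >= fx$deserts$start[i] &
                      el$end <= fx$deserts$end[i]))
    expect_true(all(vapply(el$positive_tissues, function(t) {
      "craniofacial" %in% t
    }, logical(1))))
  }
})
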