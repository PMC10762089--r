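#' Annotate gene and TSS overlap of atlas regions
#'
#' A gene overlaps a region when their spans intersect by >= 1 bp; a TSS is
#' encompassed when `region.start <= tss < region.end`.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (a `region_id`
#'   column is carried through when present).
#' @param genes gene table from [read_gene_table()].
#' @return data.frame, one row per region: `n_genes`, `n_protein_coding`,
#'   `encompasses_tss`, `overlapping_genes` and `tss_genes` (comma-joined
#'   gene ids).
#' @export
annotate_overlaps <- function(regions, genes) {
  validate_intervals(regions, what = "region")
  n <- nrow(regions)
  out <- regions
  out$n_genes <- integer(n)
  out$n_protein_coding <- integer(n)
  out$encompasses_tss <- logical(n)
  out$overlapping_genes <- character(n)
  out$tss_genes <- character(n)
  if (n == 0 || nrow(genes) == 0) return(out)

  gp <- gr_pair(regions, genes)
  hits <- GenomicRanges::findOverlaps(gp$a, gp$b)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (length(hits) > 0) {
    by_region <- split(sh, qh)
    idx <- as.integer(names(by_region))
    out$n_genes[idx] <- lengths(by_region)
    out$n_protein_coding[idx] <- vapply(by_region, function(g) {
      sum(genes$biotype[g] == "protein_coding")
    }, integer(1))
    out$overlapping_genes[idx] <- vapply(by_region, function(g) {
      paste(sort(unique(genes$gene_id[g])), collapse = ",")
    }, character(1))
  }
  # TSS containment: a TSS is a single base, so treat it as [tss, tss+1)
  tss_iv <- data.frame(chrom = genes$chrom, start = genes$tss,
                       end = genes$tss + 1)
  gpt <- gr_pair(regions, tss_iv)
  th <- GenomicRanges::findOverlaps(gpt$a, gpt$b)
  if (length(th) > 0) {
    by_region <- split(S4Vectors::subjectHits(th), S4Vectors::queryHits(th))
    idx <- as.integer(names(by_region))
    out$encompasses_tss[idx] <- TRUE
    out$tss_genes[idx] <- vapply(by_region, function(g) {
      paste(sort(unique(genes$gene_id[g])), collapse = ",")
    }, character(1))
  }
  out
}

#' Pearson chi-squared test with Yates continuity correction on a 2x2 table
#'
#' Statistic: `N * (max(0, |ad - bc| - N/2))^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' with the p-value from the upper tail of the chi-squared distribution with
#' one degree of freedom (the two-tailed test of association).
#'
#' @param a,b,c_,d non-negative integer cell counts (group x outcome); `a`
#'   and `b` are the first group's outcome counts.
#' @return list with `statistic`, `p_value`, and `expected_ok` (all expected
#'   counts under independence > 0).
#' @export
chisq_yates <- function(a, b, c_, d) {
  cells <- c(a, b, c_, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(cells)
  if (n == 0) stop("empty 2x2 table", call. = FALSE)
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    stop("degenerate 2x2 table: a row or column margin is zero",
         call. = FALSE)
  }
  num <- max(0, abs(a * d - b * c_) - n / 2)
  statistic <- n * num^2 / prod(margins)
  expected <- outer(margins[1:2], margins[3:4]) / n
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
       expected_ok = all(expected > 0))
}

#' Pairwise chi-squared comparison of TSS-overlap proportions by class
#'
#' For each pair of specificity classes, builds the 2x2 table of
#' (class) x (encompasses a TSS or not) and applies [chisq_yates()]. Tables
#' with a zero margin or a non-positive expected count are reported as
#' untestable rather than silently switched to another test.
#'
#' @param annotated atlas with `specificity` and `encompasses_tss` columns
#'   (see [classify_specificity()] and [annotate_overlaps()]).
#' @return data.frame, one row per class pair: counts, `statistic`,
#'   `p_value`, `testable`.
#' @export
overlap_chisq_pairwise <- function(annotated) {
  stopifnot(all(c("specificity", "encompasses_tss") %in% names(annotated)))
  classes <- intersect(c("shared", "embryonic", "tissue_specific"),
                       unique(annotated$specificity))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    x1 <- annotated$encompasses_tss[annotated$specificity == p[1]]
    x2 <- annotated$encompasses_tss[annotated$specificity == p[2]]
    a <- sum(x1); b <- sum(!x1); c_ <- sum(x2); d <- sum(!x2)
    res <- tryCatch(chisq_yates(a, b, c_, d), error = function(e) NULL)
    testable <- !is.null(res) && res$expected_ok
    data.frame(class_a = p[1], class_b = p[2],
               a = a, b = b, c = c_, d = d,
               statistic = if (testable) res$statistic else NA_real_,
               p_value = if (testable) res$p_value else NA_real_,
               testable = testable, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment returned in input order. Input p-values
#' must lie in (0, 1].
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, clipped at 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation test with FDR control
#'
#' For each term, tests whether the query gene set over-represents the term's
#' genes relative to the universe: `p = P[X >= k]` for
#' `X ~ Hypergeometric(N, K, n)` with `N` the universe size, `K` the term
#' size, `n` the query size and `k` the intersection size. P-values are
#' Benjamini-Hochberg adjusted across all tested terms.
#'
#' @param query_genes character vector, subset of `universe`.
#' @param term_map data.frame with columns `term_id`, `gene_id`.
#' @param universe character vector of all considered genes.
#' @return data.frame `term_id`, `k`, `K`, `n`, `N`, `p_value`,
#'   `p_adjusted`, sorted by `p_adjusted` then `p_value`.
#' @export
hypergeom_enrich <- function(query_genes, term_map, universe) {
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (length(query_genes) == 0) stop("empty query", call. = FALSE)
  if (!all(query_genes %in% universe)) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query_genes, universe), 3),
               collapse = ", "), call. = FALSE)
  }
  stopifnot(all(c("term_id", "gene_id") %in% names(term_map)))
  terms <- split(term_map$gene_id, term_map$term_id)
  terms <- lapply(terms, function(g) intersect(unique(g), universe))
  N <- length(universe)
  n <- length(query_genes)
  rows <- lapply(names(terms), function(t) {
    K <- length(terms[[t]])
    k <- length(intersect(terms[[t]], query_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out <- out[order(out$p_adjusted, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a two-column term map (term_id, gene_id)
#'
#' @param path tab-separated file.
#' @return data.frame `term_id`, `gene_id`.
#' @export
read_term_map <- function(path) {
  x <- read_tsv_strict(path, n_min_cols = 2, what = "term map")
  data.frame(term_id = x$V1, gene_id = x$V2, stringsAsFactors = FALSE)
}
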