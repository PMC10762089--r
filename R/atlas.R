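#' Merge per-sample superenhancer calls into distinct atlas regions
#'
#' Single-linkage union: superenhancer intervals from any samples that share
#' at least 1 bp are merged transitively into one region spanning their
#' union. Bookended intervals (gap 0 in half-open coordinates) are not
#' merged. Supporting samples are the union of contributors.
#'
#' @param calls data.frame of superenhancer intervals with columns `chrom`,
#'   `start`, `end`, `sample_id` — typically the `is_super` rows of
#'   [call_sample()] results row-bound across samples.
#' @return data.frame `region_id`, `chrom`, `start`, `end`, `n_samples`,
#'   `samples` (comma-joined, sorted unique sample ids), sorted by
#'   coordinates.
#' @export
merge_distinct <- function(calls) {
  stopifnot(is.data.frame(calls), "sample_id" %in% names(calls))
  if (nrow(calls) == 0) {
    stop("merge_distinct needs at least one superenhancer call", call. = FALSE)
  }
  validate_intervals(calls, what = "superenhancer call")
  gr <- df_to_gr(calls)
  # min.gapwidth = 0: merge only on true overlap, never bookended intervals
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  out <- gr_to_df(red)
  revmap <- S4Vectors::mcols(red)$revmap
  out$samples <- vapply(revmap, function(ix) {
    paste(sort(unique(calls$sample_id[ix])), collapse = ",")
  }, character(1))
  out$n_samples <- vapply(revmap, function(ix) {
    length(unique(calls$sample_id[ix]))
  }, integer(1))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out$region_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("region_id", "chrom", "start", "end", "n_samples", "samples")]
}

#' Declare a reference superenhancer catalog
#'
#' @param name unique catalog name.
#' @param kind `"general"` (any-tissue compendium) or `"embryonic"`.
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @return a `reference_catalog` list.
#' @export
reference_catalog <- function(name, kind, regions) {
  kind <- match.arg(kind, c("general", "embryonic"))
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  validate_intervals(regions, what = sprintf("catalog '%s' region", name))
  structure(list(name = name, kind = kind, regions = regions),
            class = "reference_catalog")
}

#' Classify atlas regions as shared, embryonic or tissue-specific
#'
#' Precedence rule: a region overlapping (by at least `min_overlap_frac` of
#' its length, default any overlap >= 1 bp) any `general` catalog is
#' `shared`; otherwise overlapping any `embryonic` catalog makes it
#' `embryonic`; otherwise it is `tissue_specific`. The three labels
#' partition the atlas and are invariant to catalog ordering.
#'
#' @param atlas result of [merge_distinct()].
#' @param catalogs list of [reference_catalog()] objects.
#' @param min_overlap_frac minimum overlap as a fraction of the atlas
#'   region's length; 0 means any >= 1 bp overlap.
#' @return `atlas` with `specificity` and `catalogs_hit` (comma-joined)
#'   columns added.
#' @export
classify_specificity <- function(atlas, catalogs, min_overlap_frac = 0) {
  if (length(catalogs) == 0) {
    stop("classify_specificity requires at least one reference catalog",
         call. = FALSE)
  }
  stopifnot(all(vapply(catalogs, inherits, logical(1), "reference_catalog")))
  nms <- vapply(catalogs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicated catalog name: ", nms[duplicated(nms)][1], call. = FALSE)
  }
  hit <- matrix(FALSE, nrow = nrow(atlas), ncol = length(catalogs))
  for (j in seq_along(catalogs)) {
    regs <- catalogs[[j]]$regions
    if (nrow(regs) == 0) next
    gp <- gr_pair(atlas, regs)
    q <- gp$a
    s <- gp$b
    hits <- GenomicRanges::findOverlaps(q, s)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits)
    if (min_overlap_frac > 0) {
      ov <- IRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(q)[qh],
        GenomicRanges::ranges(s)[S4Vectors::subjectHits(hits)]))
      frac <- ov / (atlas$end[qh] - atlas$start[qh])
      qh <- qh[frac >= min_overlap_frac]
    }
    hit[unique(qh), j] <- TRUE
  }
  kinds <- vapply(catalogs, `[[`, character(1), "kind")
  any_general <- rowSums(hit[, kinds == "general", drop = FALSE]) > 0
  any_embryonic <- rowSums(hit[, kinds == "embryonic", drop = FALSE]) > 0
  out <- atlas
  out$specificity <- ifelse(any_general, "shared",
                            ifelse(any_embryonic, "embryonic",
                                   "tissue_specific"))
  out$catalogs_hit <- apply(hit, 1, function(h) {
    paste(sort(nms[h]), collapse = ",")
  })
  out
}

#' Load catalogs declared in a table
#'
#' @param decl data.frame with columns `name`, `kind`, `path` (BED files).
#' @param chrom_sizes optional named vector for bounds validation.
#' @return list of [reference_catalog()] objects.
#' @export
load_catalogs <- function(decl, chrom_sizes = NULL) {
  stopifnot(all(c("name", "kind", "path") %in% names(decl)))
  lapply(seq_len(nrow(decl)), function(i) {
    reference_catalog(decl$name[i], decl$kind[i],
                      read_bed(decl$path[i], chrom_sizes))
  })
}
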