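#' Detect gene deserts
#'
#' A gene desert is an interval of at least `min_length` bp containing no
#' protein-coding gene sequence. Per chromosome, protein-coding gene spans
#' are merged and the gaps between consecutive spans (and between chromosome
#' ends and the outermost spans) of sufficient length are returned. Only
#' `biotype == "protein_coding"` genes bound deserts; noncoding genes inside
#' a gap do not disqualify it. Telomeric gaps have the missing flank
#' recorded as `NA`.
#'
#' @param genes gene table from [read_gene_table()].
#' @param chrom_sizes named vector (chromosome -> length); every chromosome
#'   carrying a gene must be present.
#' @param min_length minimum desert length in bp (default 500000; the `>=`
#'   boundary is inclusive).
#' @return data.frame `desert_id`, `chrom`, `start`, `end`, `length`,
#'   `left_gene`, `right_gene`, sorted by coordinates.
#' @export
find_deserts <- function(genes, chrom_sizes, min_length = 500000) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  unknown <- setdiff(unique(pc$chrom), names(chrom_sizes))
  if (length(unknown) > 0) {
    stop("gene chromosome(s) absent from chrom sizes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (chrom in names(chrom_sizes)) {
    len <- chrom_sizes[[chrom]]
    g <- pc[pc$chrom == chrom, , drop = FALSE]
    if (nrow(g) == 0) {
      if (len >= min_length) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, start = 0, end = len,
          left_gene = NA_character_, right_gene = NA_character_,
          stringsAsFactors = FALSE)
      }
      next
    }
    g <- g[order(g$start, g$end), , drop = FALSE]
    # Walk merged spans, remembering the id of the rightmost-ending gene.
    cur_start <- g$start[1]; cur_end <- g$end[1]; cur_id <- g$gene_id[1]
    spans <- list()
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] < cur_end) {  # overlap: extend the merged span
        if (g$end[i] > cur_end) { cur_end <- g$end[i]; cur_id <- g$gene_id[i] }
      } else {
        spans[[length(spans) + 1]] <- list(start = cur_start, end = cur_end,
                                           id = cur_id)
        cur_start <- g$start[i]; cur_end <- g$end[i]; cur_id <- g$gene_id[i]
      }
    }
    spans[[length(spans) + 1]] <- list(start = cur_start, end = cur_end,
                                       id = cur_id)
    bounds_start <- c(0, vapply(spans, `[[`, numeric(1), "end"))
    bounds_end <- c(vapply(spans, `[[`, numeric(1), "start"), len)
    left_ids <- c(NA_character_, vapply(spans, `[[`, character(1), "id"))
    # the left flank of the gap after span i is the gene ending that span;
    # the right flank is the first gene of the next span
    right_ids <- c(vapply(spans, function(s) {
      first <- g$gene_id[g$start == s$start]
      first[1]
    }, character(1)), NA_character_)
    keep <- which(bounds_end - bounds_start >= min_length)
    for (i in keep) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = bounds_start[i], end = bounds_end[i],
        left_gene = left_ids[i], right_gene = right_ids[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(desert_id = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      length = numeric(0), left_gene = character(0),
                      right_gene = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$length <- out$end - out$start
  out$desert_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("desert_id", "chrom", "start", "end", "length",
          "left_gene", "right_gene")]
}

#' Annotate noncoding regions with deserts, flanking genes and TSS distance
#'
#' The input regions must overlap no protein-coding gene (they are the
#' noncoding members of the atlas); a violating region is a contract error.
#' A region is `in_desert` only when fully contained in a desert interval.
#' Flanks are the nearest protein-coding genes on each side (by span).
#' `distance_to_nearest_tss` is the interval gap between the region and the
#' closest TSS (a TSS treated as the 1-bp interval `[tss, tss+1)`; an
#' immediately adjacent TSS has distance 0).
#'
#' @param regions data.frame with `chrom`, `start`, `end` (+ optional
#'   `region_id`).
#' @param genes gene table.
#' @param deserts result of [find_deserts()].
#' @return list with `annotations` (per-region data.frame: `in_desert`,
#'   `desert_id`, `flank_left`, `flank_right`, `distance_to_nearest_tss`)
#'   and `summary` (`n_regions`, `n_in_desert`, `mean_distance_bp`,
#'   `max_distance_bp`, `n_flanking_genes` — flanks deduplicated across
#'   regions).
#' @export
annotate_noncoding <- function(regions, genes, deserts) {
  validate_intervals(regions, what = "noncoding region")
  pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  if (nrow(regions) == 0) {
    stop("annotate_noncoding needs at least one region", call. = FALSE)
  }
  if (nrow(pc) > 0) {
    gp <- gr_pair(regions, pc)
    hits <- GenomicRanges::findOverlaps(gp$a, gp$b)
    if (length(hits) > 0) {
      i <- S4Vectors::queryHits(hits)[1]
      stop(sprintf(
        "region %s:%d-%d overlaps protein-coding gene %s; not noncoding",
        regions$chrom[i], regions$start[i], regions$end[i],
        pc$gene_id[S4Vectors::subjectHits(hits)[1]]), call. = FALSE)
    }
  }
  n <- nrow(regions)
  ann <- regions
  ann$in_desert <- FALSE
  ann$desert_id <- NA_integer_
  ann$flank_left <- NA_character_
  ann$flank_right <- NA_character_
  ann$distance_to_nearest_tss <- NA_real_
  if (nrow(deserts) > 0) {
    gp <- gr_pair(regions, deserts)
    within <- GenomicRanges::findOverlaps(gp$a, gp$b, type = "within")
    if (length(within) > 0) {
      qh <- S4Vectors::queryHits(within)
      sh <- S4Vectors::subjectHits(within)
      first <- !duplicated(qh)
      ann$in_desert[qh[first]] <- TRUE
      ann$desert_id[qh[first]] <- deserts$desert_id[sh[first]]
    }
  }
  for (i in seq_len(n)) {
    g <- pc[pc$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(g) > 0) {
      left <- g[g$end <= regions$start[i], , drop = FALSE]
      if (nrow(left) > 0) {
        ann$flank_left[i] <- left$gene_id[which.max(left$end)]
      }
      right <- g[g$start >= regions$end[i], , drop = FALSE]
      if (nrow(right) > 0) {
        ann$flank_right[i] <- right$gene_id[which.min(right$start)]
      }
    }
    gt <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(gt) > 0) {
      d_left <- regions$start[i] - (gt$tss + 1)   # tss occupies [tss, tss+1)
      d_right <- gt$tss - regions$end[i]
      ann$distance_to_nearest_tss[i] <- min(pmax(0, pmax(d_left, d_right)))
    }
  }
  flanks <- stats::na.omit(c(ann$flank_left, ann$flank_right))
  list(
    annotations = ann,
    summary = list(
      n_regions = n,
      n_in_desert = sum(ann$in_desert),
      mean_distance_bp = mean(ann$distance_to_nearest_tss, na.rm = TRUE),
      max_distance_bp = if (all(is.na(ann$distance_to_nearest_tss))) NA_real_
                        else max(ann$distance_to_nearest_tss, na.rm = TRUE),
      n_flanking_genes = length(unique(flanks))
    )
  )
}

#' Prioritize gene deserts by validated-element support
#'
#' Per desert, counts the validated elements overlapping it (>= 1 bp) and
#' the subset scored positive in `tissue_label`; an element spanning a
#' desert boundary counts in every desert it touches. Deserts are ranked by
#' descending positives, then descending tested, then coordinates.
#'
#' @param deserts result of [find_deserts()] (or any interval table with a
#'   `desert_id` column).
#' @param elements validated-element catalog from
#'   [read_validated_elements()].
#' @param tissue_label tissue whose positives drive the ranking.
#' @return `deserts` with `n_tested`, `n_positive` and `priority_rank`
#'   columns, sorted by rank.
#' @export
prioritize_deserts <- function(deserts, elements, tissue_label) {
  stopifnot(is.character(tissue_label), length(tissue_label) == 1)
  out <- deserts
  out$n_tested <- 0L
  out$n_positive <- 0L
  if (nrow(deserts) > 0 && nrow(elements) > 0) {
    gp <- gr_pair(deserts, elements)
    hits <- GenomicRanges::findOverlaps(gp$a, gp$b)
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      pos <- vapply(elements$positive_tissues[sh], function(tv) {
        tissue_label %in% tv
      }, logical(1))
      tested <- tapply(rep(1L, length(qh)), qh, sum)
      out$n_tested[as.integer(names(tested))] <- as.integer(tested)
      posct <- tapply(as.integer(pos), qh, sum)
      out$n_positive[as.integer(names(posct))] <- as.integer(posct)
    }
  }
  o <- order(-out$n_positive, -out$n_tested, out$chrom, out$start)
  out <- out[o, , drop = FALSE]
  out$priority_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Published gene-desert fixture table
#'
#' Loads the craniofacial gene-desert intervals shipped with the package
#' (hg19 labels kept as text) and, optionally, the accompanying synthetic
#' validated-element catalog whose element intervals were constructed inside
#' those deserts (the source table prints element ids, not coordinates).
#'
#' @return list with `deserts` (data.frame with `desert_id`, `chrom`,
#'   `start`, `end`, `length`, `vista_ids`) and `elements`
#'   (validated-element data.frame).
#' @export
load_desert_fixture <- function() {
  dpath <- system.file("extdata", "table1_deserts.tsv", package = "seatlas")
  epath <- system.file("extdata", "table1_elements_synthetic.tsv",
                       package = "seatlas")
  x <- read_tsv_strict(dpath, n_min_cols = 4, what = "desert fixture")
  deserts <- data.frame(
    chrom = x$V1,
    start = as.numeric(x$V2),
    end = as.numeric(x$V3),
    vista_ids = x$V4,
    stringsAsFactors = FALSE
  )
  deserts$length <- deserts$end - deserts$start
  deserts$desert_id <- seq_len(nrow(deserts))
  list(
    deserts = deserts[, c("desert_id", "chrom", "start", "end", "length",
                          "vista_ids")],
    elements = read_validated_elements(epath)
  )
}
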