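#' Active chromatin states of the 25-state segmentation model
#'
#' State labels treated as active regulatory chromatin when filtering a
#' 25-state segmentation before stitching.
#' @export
ACTIVE_STATES_25 <- c(
  "1_TssA", "2_PromU", "3_PromD1", "4_PromD2", "9_TxReg", "10_TxEnh5'",
  "11_TxEnh3'", "12_TxEnhW", "13_EnhA1", "14_EnhA2", "15_EnhAF", "16_EnhW1",
  "17_EnhW2", "18_EnhAc", "19_DNase", "22_PromP", "23_PromBiv"
)

#' Active chromatin states of the 18-state segmentation model
#' @export
ACTIVE_STATES_18 <- c(
  "1_TssA", "2_TssFlnk", "3_TssFlnkU", "4_TssFlnkD", "7_EnhG1", "8_EnhG2",
  "9_EnhA1", "10_EnhA2", "11_EnhWk", "14_TssBiv", "15_EnhBiv"
)

#' Configuration for per-sample superenhancer calling
#'
#' @param stitch_distance maximum gap (bp) between active segments merged into
#'   one candidate region; default 12500.
#' @param active_states state labels kept before stitching; defaults to the
#'   25-state active list ([ACTIVE_STATES_25]).
#' @param tss_exclusion_bp if > 0 and a gene table is supplied to
#'   [call_sample()], active segments lying entirely within this distance of
#'   any TSS are removed before stitching. Default 0 (off).
#' @param signal_floor lower bound applied to each region's
#'   input-subtracted signal. Default 0.
#' @return a `rose_config` list.
#' @export
rose_config <- function(stitch_distance = 12500,
                        active_states = ACTIVE_STATES_25,
                        tss_exclusion_bp = 0,
                        signal_floor = 0) {
  if (!is.numeric(stitch_distance) || length(stitch_distance) != 1 ||
      stitch_distance < 0) {
    stop("stitch_distance must be a single non-negative number", call. = FALSE)
  }
  if (length(active_states) == 0) {
    stop("active_states must be non-empty", call. = FALSE)
  }
  if (tss_exclusion_bp < 0) stop("tss_exclusion_bp must be >= 0", call. = FALSE)
  structure(list(
    stitch_distance = as.numeric(stitch_distance),
    active_states = as.character(active_states),
    tss_exclusion_bp = as.numeric(tss_exclusion_bp),
    signal_floor = as.numeric(signal_floor)
  ), class = "rose_config")
}

#' Keep only segments in active chromatin states
#'
#' @param segments segment data.frame from [read_state_segments()].
#' @param config a [rose_config()].
#' @return the active subset, input order preserved.
#' @export
filter_active <- function(segments, config = rose_config()) {
  stopifnot(inherits(config, "rose_config"))
  keep <- segments$state %in% config$active_states
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stitch nearby segments into candidate regions
#'
#' Per chromosome, segments are merged transitively whenever the gap between
#' them (next start minus previous end, half-open coordinates) is at most
#' `stitch_distance`; bookended or overlapping segments always merge.
#' Singletons become their own region.
#'
#' @param segments data.frame with `chrom`, `start`, `end`.
#' @param stitch_distance maximum merged gap in bp.
#' @return list with `regions` (data.frame `region_id`, `chrom`, `start`,
#'   `end`, `n_members`, sorted by coordinates) and `members` (data.frame
#'   `region_id`, `chrom`, `start`, `end`).
#' @export
stitch <- function(segments, stitch_distance = 12500) {
  validate_intervals(segments, what = "segment")
  if (nrow(segments) == 0) {
    empty <- data.frame(region_id = integer(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        n_members = integer(0), stringsAsFactors = FALSE)
    return(list(regions = empty,
                members = empty[, c("region_id", "chrom", "start", "end")]))
  }
  gr <- df_to_gr(segments)
  # min.gapwidth merges ranges whose 1-based gap is < min.gapwidth; the
  # half-open gap (next.start0 - prev.end0) equals that 1-based gap, so
  # gap <= d maps to min.gapwidth = d + 1.
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitch_distance + 1,
                               with.revmap = TRUE)
  regions <- gr_to_df(red)
  revmap <- S4Vectors::mcols(red)$revmap
  regions$region_id <- seq_len(nrow(regions))
  regions$n_members <- lengths(revmap)
  regions <- regions[order(regions$chrom, regions$start, regions$end),
                     c("region_id", "chrom", "start", "end", "n_members")]
  # renumber in sorted order, remapping members accordingly
  old_to_new <- integer(nrow(regions))
  old_to_new[regions$region_id] <- seq_len(nrow(regions))
  mem_old_region <- rep(seq_along(revmap), lengths(revmap))
  mem_idx <- unlist(revmap, use.names = FALSE)
  members <- data.frame(
    region_id = old_to_new[mem_old_region],
    chrom = segments$chrom[mem_idx],
    start = segments$start[mem_idx],
    end = segments$end[mem_idx],
    stringsAsFactors = FALSE
  )
  regions$region_id <- seq_len(nrow(regions))
  rownames(regions) <- NULL
  members <- members[order(members$region_id, members$start), , drop = FALSE]
  rownames(members) <- NULL
  list(regions = regions, members = members)
}

#' Quantify input-subtracted H3K27ac signal per stitched region
#'
#' The score is the member-restricted sum of per-base (H3K27ac - input)
#' coverage, i.e. `track_sum(h3k27ac, members) - track_sum(input, members)`
#' aggregated over each region's members, floored at `signal_floor`.
#' Gaps between members do not contribute.
#'
#' @param stitched result of [stitch()].
#' @param h3k27ac,input_track `signal_track`s.
#' @param signal_floor per-region lower bound (default 0).
#' @return the `regions` data.frame with a `signal` column added.
#' @export
quantify <- function(stitched, h3k27ac, input_track, signal_floor = 0) {
  regions <- stitched$regions
  members <- stitched$members
  if (nrow(regions) == 0) {
    regions$signal <- numeric(0)
    return(regions)
  }
  net <- track_sum(h3k27ac, members) - track_sum(input_track, members)
  per_region <- tapply(net, members$region_id, sum)
  signal <- numeric(nrow(regions))
  signal[as.integer(names(per_region))] <- as.numeric(per_region)
  regions$signal <- pmax(signal_floor, signal)
  regions
}

#' Rank regions and apply the slope = 1 cutoff
#'
#' Signals are sorted ascending and both axes rescaled to the unit square:
#' `x_i = (i-1)/(N-1)`, `y_i = (s_i - s_1)/(s_N - s_1)`. The cutoff is the
#' tangent point where a line of slope 1 touches the rank curve from below,
#' i.e. the index minimizing `y_i - x_i` (ties broken toward the largest
#' index, the more conservative cutoff). Regions with signal strictly above
#' the cutoff signal are superenhancers.
#'
#' @param regions data.frame with `chrom`, `start`, `end`, `signal` (and any
#'   other columns, carried through).
#' @return the input with `rank` (1 = highest signal; ties broken by
#'   coordinates), `is_super`, and `cutoff_signal` columns, sorted by rank.
#' @export
rank_and_cut <- function(regions) {
  if (!is.data.frame(regions) || nrow(regions) < 2) {
    stop("rank_and_cut needs at least 2 regions", call. = FALSE)
  }
  s <- regions$signal
  if (any(!is.finite(s))) stop("non-finite signal", call. = FALSE)
  n <- length(s)
  y <- sort(s)
  if (y[n] == y[1]) {
    cutoff <- y[n]  # degenerate flat curve: no region exceeds the cutoff
  } else {
    xs <- (seq_len(n) - 1) / (n - 1)
    ys <- (y - y[1]) / (y[n] - y[1])
    d <- ys - xs
    i_star <- max(which(d == min(d)))
    cutoff <- y[i_star]
  }
  out <- regions
  out$rank <- rank_with_coord_ties(out)
  out$is_super <- out$signal > cutoff
  out$cutoff_signal <- cutoff
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Rank 1 = highest signal; equal signals ordered by (chrom, start).
rank_with_coord_ties <- function(regions) {
  o <- order(-regions$signal, regions$chrom, regions$start, regions$end)
  r <- integer(nrow(regions))
  r[o] <- seq_len(nrow(regions))
  r
}

#' Call superenhancers for one sample
#'
#' Composition: filter to active states, optionally drop TSS-proximal
#' segments, stitch, quantify input-subtracted H3K27ac, rank and apply the
#' slope = 1 cutoff. Deterministic given its inputs.
#'
#' @param segments state segments for one sample ([read_state_segments()]).
#' @param h3k27ac,input_track `signal_track`s for the same sample.
#' @param config a [rose_config()].
#' @param genes optional gene table; required only when
#'   `config$tss_exclusion_bp > 0`.
#' @return data.frame of calls: `region_id`, `chrom`, `start`, `end`,
#'   `n_members`, `signal`, `rank`, `is_super`, `cutoff_signal`, `sample_id`.
#' @export
call_sample <- function(segments, h3k27ac, input_track,
                        config = rose_config(), genes = NULL) {
  stopifnot(inherits(config, "rose_config"))
  if (length(unique(segments$sample_id)) > 1) {
    stop("call_sample expects segments from a single sample", call. = FALSE)
  }
  active <- filter_active(segments, config)
  if (config$tss_exclusion_bp > 0) {
    if (is.null(genes)) {
      stop("tss_exclusion_bp > 0 requires a gene table", call. = FALSE)
    }
    active <- exclude_tss_proximal(active, genes, config$tss_exclusion_bp)
  }
  if (nrow(active) == 0) {
    stop("no active segments after filtering; cannot call superenhancers",
         call. = FALSE)
  }
  stitched <- stitch(active, config$stitch_distance)
  quantified <- quantify(stitched, h3k27ac, input_track, config$signal_floor)
  calls <- rank_and_cut(quantified)
  calls$sample_id <- segments$sample_id[1]
  calls
}

# Drop segments fully contained in [tss - x, tss + x) of any gene TSS.
exclude_tss_proximal <- function(segments, genes, x) {
  if (nrow(segments) == 0 || nrow(genes) == 0) return(segments)
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(0, genes$tss - x),
                    end = genes$tss + x)
  gp <- gr_pair(segments, win)
  hits <- GenomicRanges::findOverlaps(gp$a, gp$b, type = "within")
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == 0) return(segments)
  out <- segments[-drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a per-sample call table
#'
#' @param calls result of [call_sample()].
#' @param path output path (tab-separated with header).
#' @return `path`, invisibly.
#' @export
write_call_table <- function(calls, path) {
  cols <- c("chrom", "start", "end", "n_members", "signal", "rank",
            "is_super", "cutoff_signal", "sample_id")
  utils::write.table(calls[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rank-vs-signal ("hockey stick") plot for one sample's calls
#'
#' Plots scaled signal against scaled rank with the slope = 1 cutoff marked.
#'
#' @param calls result of [call_sample()] or [rank_and_cut()].
#' @param main plot title.
#' @return invisibly, the data.frame of plotted coordinates.
#' @export
plot_hockey_stick <- function(calls, main = "H3K27ac rank ordering") {
  s <- sort(calls$signal)
  n <- length(s)
  xs <- (seq_len(n) - 1) / max(1, n - 1)
  ys <- if (s[n] > s[1]) (s - s[1]) / (s[n] - s[1]) else rep(0, n)
  graphics::plot(xs, ys, type = "l", xlab = "scaled rank",
                 ylab = "scaled signal", main = main)
  cutoff <- calls$cutoff_signal[1]
  graphics::abline(v = xs[max(which(s <= cutoff))], lty = 2)
  graphics::points(xs[s > cutoff], ys[s > cutoff], pch = 16, col = "red3")
  invisible(data.frame(x = xs, y = ys))
}
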