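#' Read a two-column chromosome-sizes file
#'
#' @param path tab-separated file: chromosome name, length in bp.
#' @return named integer-valued numeric vector (name -> length).
#' @export
read_chrom_sizes <- function(path) {
  x <- read_tsv_strict(path, n_min_cols = 2, what = "chrom.sizes")
  if (nrow(x) == 0) stop("empty chrom.sizes file: ", path, call. = FALSE)
  sizes <- suppressWarnings(as.numeric(x[[2]]))
  bad <- which(is.na(sizes) | sizes <= 0 | sizes != floor(sizes))
  if (length(bad) > 0) {
    stop(sprintf("chrom.sizes line %d: length '%s' is not a positive integer",
                 bad[1], x[[2]][bad[1]]), call. = FALSE)
  }
  nm <- as.character(x[[1]])
  if (anyDuplicated(nm)) {
    stop("chrom.sizes has duplicated chromosome name: ",
         nm[duplicated(nm)][1], call. = FALSE)
  }
  stats::setNames(sizes, nm)
}

# Shared low-level reader: tab-separated, no header, comment lines with '#'
# allowed, strict column-count check with line numbers in errors.
read_tsv_strict <- function(path, n_min_cols, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    out <- as.data.frame(stats::setNames(
      replicate(n_min_cols, character(0), simplify = FALSE),
      paste0("V", seq_len(n_min_cols))), stringsAsFactors = FALSE)
    attr(out, "lineno") <- integer(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  short <- which(nf < n_min_cols)
  if (length(short) > 0) {
    stop(sprintf("%s line %d: expected >= %d tab-separated columns, found %d",
                 what, lineno[short[1]], n_min_cols, nf[short[1]]),
         call. = FALSE)
  }
  cols <- lapply(seq_len(n_min_cols), function(j) {
    vapply(parts, `[[`, character(1), j)
  })
  out <- as.data.frame(cols, stringsAsFactors = FALSE,
                       col.names = paste0("V", seq_len(n_min_cols)))
  attr(out, "lineno") <- lineno
  out
}

parse_coords <- function(x, lineno, what, field) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad) > 0) {
    stop(sprintf("%s line %d: %s '%s' is not an integer",
                 what, lineno[bad[1]], field, x[bad[1]]), call. = FALSE)
  }
  v
}

#' Read chromatin-state segments (ChromHMM dense-BED dialect)
#'
#' Expects 4+ tab-separated columns: chrom, start, end, state label, with
#' 0-based half-open coordinates. Malformed lines are fatal and reported with
#' their line number; nothing is silently skipped.
#'
#' @param path segment BED file.
#' @param sample_id identifier attached to every segment.
#' @param chrom_sizes optional named vector for bounds validation.
#' @return data.frame `chrom`, `start`, `end`, `state`, `sample_id`
#'   in file order.
#' @export
read_state_segments <- function(path, sample_id, chrom_sizes = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1, nzchar(sample_id))
  x <- read_tsv_strict(path, n_min_cols = 4, what = "state segment")
  lineno <- attr(x, "lineno")
  out <- data.frame(
    chrom = x$V1,
    start = parse_coords(x$V2, lineno, "state segment", "start"),
    end = parse_coords(x$V3, lineno, "state segment", "end"),
    state = x$V4,
    sample_id = rep(sample_id, nrow(x)),
    stringsAsFactors = FALSE
  )
  bad <- which(out$end <= out$start)
  if (length(bad) > 0) {
    stop(sprintf("state segment line %d: empty or inverted interval %s:%s-%s",
                 lineno[bad[1]], out$chrom[bad[1]], out$start[bad[1]],
                 out$end[bad[1]]), call. = FALSE)
  }
  if (any(!nzchar(out$state))) {
    stop("state segment with empty state label at line ",
         lineno[which(!nzchar(out$state))[1]], call. = FALSE)
  }
  validate_intervals(out, chrom_sizes, what = "state segment")
  out
}

#' Read a bedGraph coverage track
#'
#' Four tab-separated columns: chrom, start, end, value (0-based half-open).
#' The track is piecewise constant; positions not covered by any row have
#' value 0. Overlapping rows within a chromosome are a format error.
#'
#' @param path bedGraph file.
#' @param chrom_sizes optional named vector for bounds validation.
#' @return `signal_track`: a data.frame `chrom`, `start`, `end`, `value`,
#'   sorted by (chrom, start).
#' @export
read_bedgraph <- function(path, chrom_sizes = NULL) {
  x <- read_tsv_strict(path, n_min_cols = 4, what = "bedGraph")
  lineno <- attr(x, "lineno")
  out <- data.frame(
    chrom = x$V1,
    start = parse_coords(x$V2, lineno, "bedGraph", "start"),
    end = parse_coords(x$V3, lineno, "bedGraph", "end"),
    value = suppressWarnings(as.numeric(x$V4)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$value) | !is.finite(out$value))) {
    stop("bedGraph line ",
         lineno[which(is.na(out$value) | !is.finite(out$value))[1]],
         ": value is not a finite number", call. = FALSE)
  }
  validate_intervals(out, chrom_sizes, what = "bedGraph row")
  signal_track(out)
}

#' Construct a signal track from interval/value rows
#'
#' @param x data.frame with `chrom`, `start`, `end`, `value`.
#' @return sorted `signal_track` data.frame; overlapping rows are an error.
#' @export
signal_track <- function(x) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  rownames(x) <- NULL
  if (nrow(x) > 1) {
    same <- x$chrom[-1] == x$chrom[-nrow(x)]
    olap <- which(same & x$start[-1] < x$end[-nrow(x)])
    if (length(olap) > 0) {
      i <- olap[1]
      stop(sprintf(
        "signal track rows overlap: %s:%d-%d and %s:%d-%d",
        x$chrom[i], x$start[i], x$end[i],
        x$chrom[i + 1], x$start[i + 1], x$end[i + 1]), call. = FALSE)
    }
  }
  class(x) <- c("signal_track", "data.frame")
  x
}

#' Integrate a signal track over query intervals
#'
#' For each query interval returns the sum over covering rows of
#' `value * overlap-in-bp`; uncovered bases contribute 0.
#'
#' @param track a `signal_track`.
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @return numeric vector, one value per query interval.
#' @export
track_sum <- function(track, intervals) {
  stopifnot(inherits(track, "signal_track"))
  n <- nrow(intervals)
  if (n == 0) return(numeric(0))
  if (nrow(track) == 0) return(numeric(n))
  gp <- gr_pair(intervals, track)
  q <- gp$a
  s <- gp$b
  hits <- GenomicRanges::findOverlaps(q, s)
  if (length(hits) == 0) return(numeric(n))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(q)[qh], GenomicRanges::ranges(s)[sh]))
  contrib <- ov * track$value[sh]
  out <- numeric(n)
  agg <- tapply(contrib, qh, sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Read a pre-flattened gene table
#'
#' Seven tab-separated columns: gene_id, name, biotype, chrom, start, end,
#' strand (0-based half-open span). The TSS is derived from the strand:
#' `start` for `+`, `end - 1` for `-` (last base of the half-open span).
#'
#' @param path gene table file.
#' @param chrom_sizes optional named vector for bounds validation.
#' @return data.frame sorted by (chrom, start) with columns `gene_id`, `name`,
#'   `biotype`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
read_gene_table <- function(path, chrom_sizes = NULL) {
  x <- read_tsv_strict(path, n_min_cols = 7, what = "gene table")
  lineno <- attr(x, "lineno")
  strand <- x$V7
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0) {
    stop(sprintf("gene table line %d: unknown strand symbol '%s'",
                 lineno[bad[1]], strand[bad[1]]), call. = FALSE)
  }
  if (any(!nzchar(x$V3))) {
    stop("gene table line ", lineno[which(!nzchar(x$V3))[1]],
         ": empty biotype", call. = FALSE)
  }
  out <- data.frame(
    gene_id = x$V1,
    name = x$V2,
    biotype = x$V3,
    chrom = x$V4,
    start = parse_coords(x$V5, lineno, "gene table", "start"),
    end = parse_coords(x$V6, lineno, "gene table", "end"),
    strand = strand,
    stringsAsFactors = FALSE
  )
  validate_intervals(out, chrom_sizes, what = "gene")
  out$tss <- ifelse(out$strand == "+", out$start, out$end - 1)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a validated-element catalog
#'
#' Five tab-separated columns: element_id, chrom, start, end, comma-joined
#' positive tissue labels (`.` or empty = tested, no positive tissue).
#'
#' @param path catalog file.
#' @param chrom_sizes optional named vector for bounds validation.
#' @return data.frame `element_id`, `chrom`, `start`, `end`,
#'   `positive_tissues` (list-column of character vectors).
#' @export
read_validated_elements <- function(path, chrom_sizes = NULL) {
  x <- read_tsv_strict(path, n_min_cols = 5, what = "validated element")
  lineno <- attr(x, "lineno")
  out <- data.frame(
    element_id = x$V1,
    chrom = x$V2,
    start = parse_coords(x$V3, lineno, "validated element", "start"),
    end = parse_coords(x$V4, lineno, "validated element", "end"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$element_id)) {
    stop("duplicated element_id in catalog: ",
         out$element_id[duplicated(out$element_id)][1], call. = FALSE)
  }
  validate_intervals(out, chrom_sizes, what = "validated element")
  out$positive_tissues <- lapply(x$V5, function(s) {
    if (identical(trimws(s), ".")) return(character(0))
    v <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    v[nzchar(v)]
  })
  out
}

#' Read a BED3/BED4 region file
#'
#' @param path BED file (chrom, start, end, optional name).
#' @param chrom_sizes optional named vector for bounds validation.
#' @return data.frame `chrom`, `start`, `end` (+ `name` if 4 columns present)
#'   in file order.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  x <- read_tsv_strict(path, n_min_cols = 3, what = "BED")
  lineno <- attr(x, "lineno")
  out <- data.frame(
    chrom = x$V1,
    start = parse_coords(x$V2, lineno, "BED", "start"),
    end = parse_coords(x$V3, lineno, "BED", "end"),
    stringsAsFactors = FALSE
  )
  validate_intervals(out, chrom_sizes, what = "BED region")
  # Carry a 4th column through when every line has one.
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  if (length(raw) > 0) {
    parts <- strsplit(raw, "\t", fixed = TRUE)
    if (all(lengths(parts) >= 4)) {
      out$name <- vapply(parts, `[[`, character(1), 4)
    }
  }
  out
}

#' Write regions as BED3/BED4
#'
#' Writes 0-based half-open, tab-separated, sorted by (chrom, start, end).
#' An empty region set yields an empty file with no header.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param path output path.
#' @param name_field optional column name to emit as the 4th BED column.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path, name_field = NULL) {
  validate_intervals(regions, what = "region")
  regions <- order_intervals(regions)
  cols <- data.frame(
    regions$chrom,
    format(regions$start, scientific = FALSE, trim = TRUE),
    format(regions$end, scientific = FALSE, trim = TRUE),
    stringsAsFactors = FALSE
  )
  if (!is.null(name_field)) {
    stopifnot(name_field %in% names(regions))
    cols[[4]] <- as.character(regions[[name_field]])
  }
  ok <- tryCatch({
    utils::write.table(cols, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write BED file ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}
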