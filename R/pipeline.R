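#' Build and validate a pipeline configuration
#'
#' Accepts either a YAML file path or an R list with the same structure:
#' `chrom_sizes`, `genes`, `elements` (paths), `samples` (list of
#' `sample_id`, `segments`, `h3k27ac`, `input`), `catalogs` (list of `name`,
#' `kind`, `path`, or the path of a declaration table with those columns),
#' `tissue_label`, `out_dir`, optional `rose` overrides (`stitch_distance`,
#' `state_model` "25"/"18" or `active_states`, `tss_exclusion_bp`,
#' `signal_floor`), optional `min_desert_length`, `min_overlap_frac`,
#' `manifest` (truth manifest for run stamping). Every referenced file must
#' exist at validation time.
#'
#' @param x YAML path or list.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    yaml::read_yaml(x)
  } else if (is.list(x)) x else {
    stop("pipeline_config expects a YAML path or a list", call. = FALSE)
  }
  for (f in c("chrom_sizes", "genes", "elements", "samples", "catalogs",
              "tissue_label", "out_dir")) {
    if (is.null(cfg[[f]])) stop("config field missing: ", f, call. = FALSE)
  }
  check_file <- function(p, what) {
    if (!is.character(p) || length(p) != 1 || !file.exists(p)) {
      stop(sprintf("config validation: %s file not found: %s", what,
                   as.character(p)[1]), call. = FALSE)
    }
  }
  check_file(cfg$chrom_sizes, "chrom_sizes")
  check_file(cfg$genes, "genes")
  check_file(cfg$elements, "elements")
  if (is.character(cfg$catalogs)) {
    check_file(cfg$catalogs, "catalog declaration")
    decl <- utils::read.delim(cfg$catalogs, stringsAsFactors = FALSE)
    base <- dirname(cfg$catalogs)
    decl$path <- ifelse(grepl("^(/|[A-Za-z]:)", decl$path), decl$path,
                        file.path(base, decl$path))
    cfg$catalogs <- lapply(seq_len(nrow(decl)), function(i) {
      as.list(decl[i, c("name", "kind", "path")])
    })
  }
  for (cat in cfg$catalogs) check_file(cat$path, paste0("catalog ", cat$name))
  for (s in cfg$samples) {
    for (f in c("segments", "h3k27ac", "input")) {
      check_file(s[[f]], sprintf("sample %s %s", s$sample_id, f))
    }
  }
  if (!is.null(cfg$manifest)) check_file(cfg$manifest, "manifest")
  rose_args <- cfg$rose
  if (!is.null(rose_args$state_model)) {
    rose_args$active_states <- switch(
      as.character(rose_args$state_model),
      "25" = ACTIVE_STATES_25, "18" = ACTIVE_STATES_18,
      stop("state_model must be '25' or '18'", call. = FALSE))
    rose_args$state_model <- NULL
  }
  cfg$rose <- do.call(rose_config, if (is.null(rose_args)) list()
                      else rose_args)
  if (is.null(cfg$min_desert_length)) cfg$min_desert_length <- 500000
  if (is.null(cfg$min_overlap_frac)) cfg$min_overlap_frac <- 0
  structure(cfg, class = "pipeline_config")
}

pipe_log <- function(level, stage, msg) {
  message(sprintf("%s [%s] %s: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, stage, msg))
}

#' Run the full superenhancer atlas pipeline
#'
#' Stages, in order: per-sample superenhancer calling; merging into distinct
#' atlas regions; specificity classification against the reference catalogs;
#' gene/TSS overlap annotation with pairwise chi-squared comparisons of
#' overlap proportions; gene-desert detection; noncoding tissue-specific
#' region annotation; desert prioritization by validated-element support.
#' Every intermediate table is written under `out_dir`, together with a
#' machine-readable `report.json`. Identical inputs give identical outputs;
#' any stage error halts the run with the failing stage named.
#'
#' @param config a [pipeline_config()] (or something accepted by it).
#' @return invisibly, a list: `calls` (per-sample data.frames), `atlas`
#'   (classified + annotated), `size_summary`, `chisq`, `deserts`,
#'   `noncoding`, `priorities`, `report`, `run_id`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  result <- tryCatch({
    pipe_log("INFO", stage, "reading genome inputs")
    chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
    genes <- read_gene_table(config$genes, chrom_sizes)
    elements <- read_validated_elements(config$elements, chrom_sizes)
    catalogs <- lapply(config$catalogs, function(cat) {
      reference_catalog(cat$name, cat$kind, read_bed(cat$path, chrom_sizes))
    })
    run_id <- if (!is.null(config$manifest)) {
      read_manifest(config$manifest)$run_id
    } else NULL

    stage <- "call"
    calls <- list()
    for (s in config$samples) {
      segments <- read_state_segments(s$segments, s$sample_id, chrom_sizes)
      h3k <- read_bedgraph(s$h3k27ac, chrom_sizes)
      inp <- read_bedgraph(s$input, chrom_sizes)
      res <- call_sample(segments, h3k, inp, config$rose, genes)
      calls[[s$sample_id]] <- res
      write_call_table(res, file.path(out_dir,
                                      paste0(s$sample_id, ".calls.tsv")))
      write_bed(res[res$is_super, , drop = FALSE],
                file.path(out_dir, paste0(s$sample_id,
                                          ".superenhancers.bed")))
      pipe_log("INFO", stage, sprintf("%s: %d regions, %d superenhancers",
                                      s$sample_id, nrow(res),
                                      sum(res$is_super)))
    }

    stage <- "merge"
    supers <- do.call(rbind, lapply(calls, function(x) {
      x[x$is_super, c("chrom", "start", "end", "sample_id"), drop = FALSE]
    }))
    atlas <- merge_distinct(supers)
    pipe_log("INFO", stage, sprintf("%d distinct atlas regions", nrow(atlas)))

    stage <- "classify"
    atlas <- classify_specificity(atlas, catalogs, config$min_overlap_frac)
    partition <- table(factor(atlas$specificity,
                              levels = c("shared", "embryonic",
                                         "tissue_specific")))

    stage <- "annotate"
    atlas <- annotate_overlaps(atlas, genes)
    chisq <- overlap_chisq_pairwise(atlas)
    sizes <- size_summary(atlas)
    pc_means <- vapply(calls, function(x) {
      sup <- x[x$is_super, c("chrom", "start", "end"), drop = FALSE]
      if (nrow(sup) == 0) return(NA_real_)
      mean(annotate_overlaps(sup, genes)$n_protein_coding)
    }, numeric(1))

    stage <- "deserts"
    deserts <- find_deserts(genes, chrom_sizes, config$min_desert_length)
    specific <- atlas[atlas$specificity == "tissue_specific" &
                        atlas$n_protein_coding == 0, , drop = FALSE]
    noncoding <- if (nrow(specific) > 0) {
      annotate_noncoding(specific[, c("region_id", "chrom", "start", "end")],
                         genes, deserts)
    } else list(annotations = NULL,
                summary = list(n_regions = 0, n_in_desert = 0,
                               mean_distance_bp = NA_real_,
                               max_distance_bp = NA_real_,
                               n_flanking_genes = 0))

    stage <- "prioritize"
    priorities <- prioritize_deserts(deserts, elements, config$tissue_label)

    stage <- "report"
    write_tsv <- function(x, name) {
      if (!is.null(x)) {
        utils::write.table(x, file.path(out_dir, name), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
    write_tsv(atlas, "atlas.tsv")
    for (lab in names(partition)) {
      write_bed(atlas[atlas$specificity == lab, , drop = FALSE],
                file.path(out_dir, paste0("atlas_", lab, ".bed")))
    }
    write_tsv(chisq, "overlap_chisq.tsv")
    write_tsv(deserts, "deserts.tsv")
    write_tsv(noncoding$annotations, "noncoding_annotations.tsv")
    write_tsv(priorities[, setdiff(names(priorities), "desert_id")],
              "desert_priorities.tsv")

    report <- list(
      run_id = run_id,
      n_samples = length(calls),
      per_sample_superenhancers = vapply(calls, function(x) {
        sum(x$is_super)
      }, numeric(1)),
      mean_superenhancers_per_sample = mean(vapply(calls, function(x) {
        sum(x$is_super)
      }, numeric(1))),
      atlas_size = nrow(atlas),
      specificity_counts = as.list(partition),
      size_summary = sizes,
      pct_gene_overlapping = 100 * mean(atlas$n_genes > 0),
      pct_tss_encompassing = 100 * mean(atlas$encompasses_tss),
      mean_protein_coding_per_sample = mean(pc_means, na.rm = TRUE),
      overlap_chisq = chisq,
      n_deserts = nrow(deserts),
      noncoding_summary = noncoding$summary,
      top_priorities = utils::head(
        priorities[, c("chrom", "start", "end", "n_tested", "n_positive",
                       "priority_rank")], 5)
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    pipe_log("INFO", stage, "pipeline complete")
    list(calls = calls, atlas = atlas, size_summary = sizes, chisq = chisq,
         deserts = deserts, noncoding = noncoding, priorities = priorities,
         report = report, run_id = run_id)
  }, error = function(e) {
    pipe_log("ERROR", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
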