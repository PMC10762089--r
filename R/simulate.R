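#' Configuration for the synthetic atlas generator
#'
#' Defaults emulate the structure of a multi-sample embryonic H3K27ac atlas
#' at desk scale: 17 samples over a 2 x 12 Mb genome, clustered enhancer
#' segments with elevated H3K27ac over input, a minority of planted
#' superenhancer clusters with ~10x the typical per-bp signal, reference
#' catalogs realizing a 60/20/20 shared/embryonic/tissue-specific split,
#' protein-coding gene landscapes with planted >= 500 kb gene-free gaps, and
#' a validated-element catalog with per-tissue positivity.
#'
#' @param seed integer seed; every emitted file draws from its own stream
#'   derived from `(seed, file role)`, so adding samples never perturbs
#'   existing files.
#' @param n_chroms,chrom_length_bp genome geometry.
#' @param n_genes,protein_coding_fraction gene landscape; protein-coding
#'   genes tile the non-desert genome densely enough that only planted gaps
#'   reach desert length.
#' @param n_desert_gaps,desert_gap_bp planted protein-coding-free gaps.
#' @param n_typical_clusters,n_super_clusters enhancer cluster counts.
#' @param segments_per_cluster,segment_length_bp,intra_cluster_gap_bp
#'   ranges (2-vectors, bp rounded to the coverage bin); intra-cluster gaps
#'   must stay below the 12.5 kb stitch distance.
#' @param inter_cluster_gap_bp minimum gap between clusters (must exceed
#'   12.5 kb so distinct clusters never stitch together).
#' @param typical_signal_mean,super_signal_mean,input_signal_mean,noise_sd
#'   per-bp coverage means and Gaussian bin noise.
#' @param n_samples number of samples sharing the planted layout.
#' @param n_reference_catalogs number of general (any-tissue) catalogs; one
#'   embryonic catalog is always emitted.
#' @param shared_fraction,embryonic_fraction planted specificity mix of the
#'   super clusters (remainder is tissue-specific, placed inside deserts
#'   first so they are noncoding).
#' @param n_validated_elements,positive_fraction validated-element catalog;
#'   positives are labelled with `tissue_label`.
#' @param tissue_label tissue name used for element positivity.
#' @param bin_bp coverage bin width (bp).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2,
                       chrom_length_bp = 12e6,
                       n_genes = 300,
                       protein_coding_fraction = 0.8,
                       n_desert_gaps = 3,
                       desert_gap_bp = 700000,
                       n_typical_clusters = 50,
                       n_super_clusters = 10,
                       segments_per_cluster = c(4, 6),
                       segment_length_bp = c(1000, 2000),
                       intra_cluster_gap_bp = c(500, 5000),
                       inter_cluster_gap_bp = 20000,
                       typical_signal_mean = 5,
                       super_signal_mean = 50,
                       input_signal_mean = 1,
                       noise_sd = 1,
                       n_samples = 17,
                       n_reference_catalogs = 3,
                       shared_fraction = 0.6,
                       embryonic_fraction = 0.2,
                       n_validated_elements = 24,
                       positive_fraction = 0.5,
                       tissue_label = "craniofacial",
                       bin_bp = 50) {
  cfg <- as.list(environment())
  if (super_signal_mean <= typical_signal_mean) {
    stop("super_signal_mean must exceed typical_signal_mean", call. = FALSE)
  }
  if (inter_cluster_gap_bp <= 12500) {
    stop("inter_cluster_gap_bp must exceed the 12.5 kb stitch distance",
         call. = FALSE)
  }
  if (max(intra_cluster_gap_bp) >= 12500) {
    stop("intra_cluster_gap_bp must stay below the 12.5 kb stitch distance",
         call. = FALSE)
  }
  fr <- c(shared_fraction, embryonic_fraction, protein_coding_fraction,
          positive_fraction)
  if (any(fr < 0 | fr > 1) || shared_fraction + embryonic_fraction > 1) {
    stop("fractions must lie in [0,1] with shared + embryonic <= 1",
         call. = FALSE)
  }
  if (desert_gap_bp < 500000) {
    stop("desert_gap_bp must be >= 500000 to qualify as a gene desert",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Deterministic per-role stream: polynomial hash of the role string folded
# into [0, 2^31 - 2] and offset by the user seed.
seed_for <- function(seed, role) {
  h <- 0
  for (b in utf8ToInt(role)) h <- (h * 31 + b) %% 2147480009
  as.integer((seed + h) %% 2147480009)
}

round_to_bin <- function(x, bin) round(x / bin) * bin

# Lay out clusters, deserts and genes on the genome (one shared layout for
# all samples). Returns the full planted truth.
build_layout <- function(cfg) {
  set.seed(seed_for(cfg$seed, "layout"))
  bin <- cfg$bin_bp
  n_clusters <- cfg$n_typical_clusters + cfg$n_super_clusters

  # Which clusters are super, and their planted specificity labels.
  super_ix <- sort(sample.int(n_clusters, cfg$n_super_clusters))
  n_shared <- round(cfg$shared_fraction * cfg$n_super_clusters)
  n_embryonic <- round(cfg$embryonic_fraction * cfg$n_super_clusters)
  n_specific <- cfg$n_super_clusters - n_shared - n_embryonic

  # Deserts host the tissue-specific (noncoding) super clusters.
  n_desert_supers <- min(n_specific, cfg$n_desert_gaps)

  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  chrom_of_cluster <- rep(chroms, length.out = n_clusters)
  chrom_of_desert <- rep(chroms, length.out = cfg$n_desert_gaps)

  clusters <- list()
  deserts <- list()
  desert_cluster_ids <- integer(0)

  for (ci in seq_len(cfg$n_chroms)) {
    chrom <- chroms[ci]
    pos <- 200000
    my_clusters <- which(chrom_of_cluster == chrom)
    my_deserts <- which(chrom_of_desert == chrom)
    # interleave deserts roughly evenly among this chromosome's clusters
    desert_after <- if (length(my_deserts) > 0) {
      pmax(1, round(seq_along(my_deserts) * length(my_clusters) /
                      (length(my_deserts) + 1)))
    } else integer(0)
    for (k in seq_along(my_clusters)) {
      id <- my_clusters[k]
      n_seg <- sample(seq(cfg$segments_per_cluster[1],
                          cfg$segments_per_cluster[2]), 1)
      seg_len <- round_to_bin(stats::runif(n_seg, cfg$segment_length_bp[1],
                                           cfg$segment_length_bp[2]), bin)
      gaps <- round_to_bin(stats::runif(max(0, n_seg - 1),
                                        cfg$intra_cluster_gap_bp[1],
                                        cfg$intra_cluster_gap_bp[2]), bin)
      starts <- pos + cumsum(c(0, seg_len[-n_seg] + gaps))
      ends <- starts + seg_len
      clusters[[id]] <- data.frame(
        cluster_id = id, chrom = chrom, start = starts, end = ends,
        stringsAsFactors = FALSE)
      pos <- ends[n_seg] +
        round_to_bin(cfg$inter_cluster_gap_bp +
                       stats::runif(1, 0, 10000), bin)
      # drop a planted desert after this cluster, if scheduled
      hit <- which(desert_after == k)
      for (d in my_deserts[hit]) {
        deserts[[d]] <- data.frame(
          desert_id_planted = d, chrom = chrom, start = pos,
          end = pos + cfg$desert_gap_bp, stringsAsFactors = FALSE)
        pos <- pos + cfg$desert_gap_bp +
          round_to_bin(cfg$inter_cluster_gap_bp, bin)
      }
    }
    # any deserts scheduled after the final cluster
    if (length(my_deserts) > 0) {
      for (d in my_deserts[which(desert_after > length(my_clusters))]) {
        deserts[[d]] <- data.frame(
          desert_id_planted = d, chrom = chrom, start = pos,
          end = pos + cfg$desert_gap_bp, stringsAsFactors = FALSE)
        pos <- pos + cfg$desert_gap_bp +
          round_to_bin(cfg$inter_cluster_gap_bp, bin)
      }
    }
    if (pos + 200000 > cfg$chrom_length_bp) {
      stop(sprintf(
        "infeasible geometry: %s needs %d bp but chrom_length_bp is %d",
        chrom, pos + 200000, cfg$chrom_length_bp), call. = FALSE)
    }
  }
  deserts <- do.call(rbind, deserts)

  # Move the tissue-specific super clusters into deserts: re-plant the first
  # n_desert_supers specific clusters centred inside distinct deserts.
  labels <- rep(NA_character_, n_clusters)
  labels[super_ix] <- c(rep("tissue_specific", n_specific),
                        rep("embryonic", n_embryonic),
                        rep("shared", n_shared))[
                          order(order(stats::runif(cfg$n_super_clusters)))]
  # guarantee the first deserts host specific supers: overwrite a sampled
  # specific cluster's position per desert
  specific_ids <- super_ix[labels[super_ix] == "tissue_specific"]
  for (j in seq_len(n_desert_supers)) {
    id <- specific_ids[j]
    d <- deserts[j, ]
    cl <- clusters[[id]]
    span <- max(cl$end) - min(cl$start)
    shift <- round_to_bin(d$start + (d$end - d$start - span) / 2, cfg$bin_bp) -
      min(cl$start)
    cl$start <- cl$start + shift
    cl$end <- cl$end + shift
    cl$chrom <- d$chrom
    clusters[[id]] <- cl
  }

  cluster_tbl <- do.call(rbind, clusters)
  spans <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id[1], chrom = cl$chrom[1],
               start = min(cl$start), end = max(cl$end),
               stringsAsFactors = FALSE)
  }))
  spans$is_super <- seq_len(n_clusters) %in% super_ix
  spans$label <- labels

  # Protein-coding genes tile the non-desert, non-specific-cluster genome so
  # that only planted gaps reach 500 kb. Desert edges get explicit flanks.
  n_pc <- max(4 * cfg$n_chroms, round(cfg$n_genes *
                                        cfg$protein_coding_fraction))
  n_nc <- max(0, cfg$n_genes - n_pc)
  genes <- list()
  gid <- 0
  avoid_deserts <- deserts[, c("chrom", "start", "end"), drop = FALSE]
  avoid_deserts$exact <- rep(TRUE, nrow(avoid_deserts))
  avoid_spans <- spans[spans$label %in% "tissue_specific" &
                         !is.na(spans$label),
                       c("chrom", "start", "end"), drop = FALSE]
  avoid_spans$exact <- rep(FALSE, nrow(avoid_spans))
  avoid <- rbind(avoid_deserts, avoid_spans)
  pc_per_chrom <- table(factor(rep(chroms, length.out = n_pc),
                               levels = chroms))
  for (ci in seq_len(cfg$n_chroms)) {
    chrom <- chroms[ci]
    n_here <- as.integer(pc_per_chrom[[chrom]])
    slots <- seq(100000, cfg$chrom_length_bp - 150000, length.out = n_here)
    for (s in slots) {
      start <- round(s + stats::runif(1, -15000, 15000))
      glen <- round(stats::runif(1, 20000, 60000))
      cand <- c(start, start + glen)
      a <- avoid[avoid$chrom == chrom, , drop = FALSE]
      # Nudge genes that would fall into a protected interval to its edge.
      # Desert flanks sit exactly at the planted boundary so the recovered
      # gap equals the planted interval; cluster flanks keep 2 kb clearance.
      bad <- which(cand[1] < a$end + 2000 & cand[2] > a$start - 2000)
      if (length(bad) > 0) {
        b <- a[bad[1], ]
        clearance <- if (b$exact) 0 else 2000
        if (cand[1] + glen / 2 < (b$start + b$end) / 2) {
          cand <- c(b$start - clearance - glen, b$start - clearance)
        } else {
          cand <- c(b$end + clearance, b$end + clearance + glen)
        }
      }
      gid <- gid + 1
      genes[[gid]] <- data.frame(
        gene_id = sprintf("PCG%04d", gid), name = sprintf("PCG%04d", gid),
        biotype = "protein_coding", chrom = chrom,
        start = max(0, cand[1]), end = cand[2],
        strand = if (gid %% 2 == 0) "+" else "-", stringsAsFactors = FALSE)
    }
  }
  # sentinel protein-coding flanks pinning each desert boundary exactly
  if (nrow(deserts) > 0) {
    for (i in seq_len(nrow(deserts))) {
      d <- deserts[i, ]
      gid <- gid + 1
      genes[[gid]] <- data.frame(
        gene_id = sprintf("PCGDL%02d", i), name = sprintf("PCGDL%02d", i),
        biotype = "protein_coding", chrom = d$chrom,
        start = d$start - 30000, end = d$start,
        strand = "+", stringsAsFactors = FALSE)
      gid <- gid + 1
      genes[[gid]] <- data.frame(
        gene_id = sprintf("PCGDR%02d", i), name = sprintf("PCGDR%02d", i),
        biotype = "protein_coding", chrom = d$chrom,
        start = d$end, end = d$end + 30000,
        strand = "-", stringsAsFactors = FALSE)
    }
  }
  # noncoding genes: half sprinkled anywhere, half inside deserts
  for (j in seq_len(n_nc)) {
    gid <- gid + 1
    if (j %% 2 == 0 && nrow(deserts) > 0) {
      # keep desert-resident noncoding genes near the desert edge so they
      # never overlap the centrally planted cluster
      d <- deserts[1 + (j %% nrow(deserts)), ]
      start <- round(stats::runif(1, d$start + 20000, d$start + 150000))
      chrom <- d$chrom
    } else {
      chrom <- chroms[1 + (j %% cfg$n_chroms)]
      start <- round(stats::runif(1, 100000, cfg$chrom_length_bp - 120000))
    }
    genes[[gid]] <- data.frame(
      gene_id = sprintf("NCG%04d", j), name = sprintf("NCG%04d", j),
      biotype = "lincRNA", chrom = chrom, start = start, end = start + 10000,
      strand = if (j %% 2 == 0) "+" else "-", stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  # Validated elements: most inside deserts, remainder elsewhere.
  elements <- list()
  n_el <- cfg$n_validated_elements
  n_pos <- round(cfg$positive_fraction * n_el)
  is_pos <- rep(FALSE, n_el)
  if (n_pos > 0) is_pos[sample.int(n_el, n_pos)] <- TRUE
  for (j in seq_len(n_el)) {
    if (nrow(deserts) > 0 && j %% 4 != 0) {
      d <- deserts[1 + (j %% nrow(deserts)), ]
      start <- round(stats::runif(1, d$start + 5000, d$end - 10000))
      chrom <- d$chrom
    } else {
      chrom <- chroms[1 + (j %% cfg$n_chroms)]
      start <- round(stats::runif(1, 100000, cfg$chrom_length_bp - 110000))
    }
    elements[[j]] <- data.frame(
      element_id = sprintf("el%04d", j), chrom = chrom,
      start = start, end = start + round(stats::runif(1, 1000, 3000)),
      positive = is_pos[j], stringsAsFactors = FALSE)
  }
  elements <- do.call(rbind, elements)

  list(chroms = stats::setNames(rep(cfg$chrom_length_bp, cfg$n_chroms),
                                chroms),
       segments = cluster_tbl, spans = spans, deserts = deserts,
       genes = genes, elements = elements)
}

#' Generate the full synthetic input bundle
#'
#' Writes, per sample, a state-segment BED (active labels on cluster
#' members, inactive labels in the gaps), an H3K27ac bedGraph (binned
#' Gaussian coverage around the planted cluster mean, floored at 0) and an
#' input bedGraph (flat low coverage with the same noise); plus the genome
#' chrom.sizes, gene table, reference catalogs with a declaration table, the
#' validated-element catalog, and a ground-truth manifest
#' (`manifest.json`, format version 1).
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with all file `paths` and the `manifest`.
#' @export
simulate_atlas <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  layout <- build_layout(config)  # errors on infeasible geometry pre-write
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "samples"), showWarnings = FALSE)
  dir.create(file.path(outdir, "catalogs"), showWarnings = FALSE)
  bin <- config$bin_bp

  paths <- list(chrom_sizes = file.path(outdir, "chrom.sizes"),
                genes = file.path(outdir, "genes.tsv"),
                elements = file.path(outdir, "elements.tsv"),
                catalog_decl = file.path(outdir, "catalogs", "catalogs.tsv"),
                manifest = file.path(outdir, "manifest.json"))

  writeLines(sprintf("%s\t%d", names(layout$chroms),
                     as.integer(layout$chroms)), paths$chrom_sizes)
  utils::write.table(
    layout$genes[, c("gene_id", "name", "biotype", "chrom", "start", "end",
                     "strand")],
    paths$genes, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  el <- layout$elements
  el_tissues <- ifelse(el$positive, config$tissue_label, ".")
  writeLines(sprintf("%s\t%s\t%d\t%d\t%s", el$element_id, el$chrom,
                     as.integer(el$start), as.integer(el$end), el_tissues),
             paths$elements)

  # --- per-sample files -----------------------------------------------------
  sample_ids <- sprintf("sample_%02d", seq_len(config$n_samples))
  active_labels <- rep(c("13_EnhA1", "14_EnhA2", "18_EnhAc", "1_TssA"),
                       length.out = nrow(layout$segments))
  seg <- layout$segments
  seg$state <- active_labels
  # inactive filler between clusters so filtering has something to drop
  spans <- layout$spans
  filler <- data.frame(chrom = spans$chrom,
                       start = spans$end + 2000,
                       end = spans$end + 4000,
                       state = "24_ReprPC", stringsAsFactors = FALSE)
  is_super_cluster <- spans$is_super[seg$cluster_id]
  mean_of_seg <- ifelse(is_super_cluster, config$super_signal_mean,
                        config$typical_signal_mean)

  paths$samples <- list()
  for (sid in sample_ids) {
    segf <- file.path(outdir, "samples", paste0(sid, ".segments.bed"))
    h3kf <- file.path(outdir, "samples", paste0(sid, ".h3k27ac.bedgraph"))
    inpf <- file.path(outdir, "samples", paste0(sid, ".input.bedgraph"))
    seg_all <- rbind(seg[, c("chrom", "start", "end", "state")], filler)
    seg_all <- order_intervals(seg_all)
    utils::write.table(
      data.frame(seg_all$chrom,
                 format(seg_all$start, scientific = FALSE, trim = TRUE),
                 format(seg_all$end, scientific = FALSE, trim = TRUE),
                 seg_all$state),
      segf, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

    # binned coverage over cluster members only (implicit 0 elsewhere)
    bins <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
      bs <- seq(seg$start[i], seg$end[i] - bin, by = bin)
      data.frame(chrom = seg$chrom[i], start = bs, end = bs + bin,
                 mean = mean_of_seg[i], stringsAsFactors = FALSE)
    }))
    bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
    set.seed(seed_for(config$seed, paste0("h3k27ac:", sid)))
    h3k_val <- pmax(0, stats::rnorm(nrow(bins), bins$mean, config$noise_sd))
    set.seed(seed_for(config$seed, paste0("input:", sid)))
    inp_val <- pmax(0, stats::rnorm(nrow(bins), config$input_signal_mean,
                                    config$noise_sd / 2))
    write_bedgraph_rows(bins, h3k_val, h3kf)
    write_bedgraph_rows(bins, inp_val, inpf)
    paths$samples[[sid]] <- list(sample_id = sid, segments = segf,
                                 h3k27ac = h3kf, input = inpf)
  }

  # --- reference catalogs ---------------------------------------------------
  set.seed(seed_for(config$seed, "catalogs"))
  spans_super <- spans[spans$is_super, , drop = FALSE]
  catalog_names <- sprintf("tissue_catalog_%02d",
                           seq_len(config$n_reference_catalogs))
  decl <- data.frame(name = c(catalog_names, "embryonic_reference"),
                     kind = c(rep("general", length(catalog_names)),
                              "embryonic"),
                     stringsAsFactors = FALSE)
  catalog_regions <- stats::setNames(
    replicate(nrow(decl), list(), simplify = FALSE), decl$name)
  add_region <- function(cat, chrom, start, end) {
    catalog_regions[[cat]][[length(catalog_regions[[cat]]) + 1]] <<-
      data.frame(chrom = chrom, start = start, end = end,
                 stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(spans_super))) {
    sp <- spans_super[i, ]
    jit <- function() round(stats::runif(1, 0, 4000))
    if (identical(sp$label, "shared")) {
      ncat <- 1 + (i %% 2)
      for (cat in sample(catalog_names, min(ncat, length(catalog_names)))) {
        add_region(cat, sp$chrom, max(0, sp$start - jit()), sp$end + jit())
      }
    } else if (identical(sp$label, "embryonic")) {
      add_region("embryonic_reference", sp$chrom,
                 max(0, sp$start - jit()), sp$end + jit())
    }
  }
  # decoy catalog entries over typical (non-super) clusters
  typical_spans <- spans[!spans$is_super, , drop = FALSE]
  for (cat in decl$name) {
    pick <- sample(nrow(typical_spans), min(5, nrow(typical_spans)))
    for (i in pick) {
      add_region(cat, typical_spans$chrom[i], typical_spans$start[i],
                 typical_spans$end[i])
    }
  }
  decl$path <- file.path(outdir, "catalogs", paste0(decl$name, ".bed"))
  for (i in seq_len(nrow(decl))) {
    regs <- do.call(rbind, catalog_regions[[decl$name[i]]])
    if (is.null(regs)) {
      regs <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0))
    }
    write_bed(regs, decl$path[i])
  }
  # paths in the declaration are relative to the declaration file, so the
  # bundle is relocatable and byte-identical across output directories
  decl_rel <- decl
  decl_rel$path <- paste0(decl$name, ".bed")
  utils::write.table(decl_rel, paths$catalog_decl, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    manifest_version = 1,
    run_id = sprintf("sim-seed%d-%s", config$seed,
                     substr(digest_layout(layout), 1, 10)),
    config = unclass(config),
    truth_superenhancers = spans_super[, c("cluster_id", "chrom", "start",
                                           "end", "label")],
    samples = sample_ids,
    deserts = layout$deserts[, c("chrom", "start", "end")],
    elements = data.frame(element_id = el$element_id,
                          positive = el$positive,
                          stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, manifest = manifest,
                 catalog_decl = decl))
}

write_bedgraph_rows <- function(bins, values, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", bins$chrom, as.integer(bins$start),
                     as.integer(bins$end),
                     formatC(values, format = "f", digits = 4)), path)
}

# Cheap deterministic fingerprint of the planted layout for run matching.
digest_layout <- function(layout) {
  s <- paste(c(layout$spans$chrom, layout$spans$start, layout$spans$end,
               layout$spans$label), collapse = "|")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147480009
  sprintf("%010d", h)
}

#' Read a manifest written by [simulate_atlas()]
#'
#' @param path path to `manifest.json`.
#' @return manifest list with data.frame components restored.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$manifest_version) || m$manifest_version != 1) {
    stop("unsupported manifest version", call. = FALSE)
  }
  m
}

#' Score pipeline output against the planted truth
#'
#' Per-sample superenhancer precision/recall at >= 50% reciprocal overlap
#' with the planted intervals, a specificity confusion matrix over atlas
#' regions matched to truth regions by overlap, and the count of planted
#' deserts recovered exactly.
#'
#' @param pipeline_output result list of [run_pipeline()].
#' @param manifest manifest from [simulate_atlas()] / [read_manifest()].
#' @param min_reciprocal minimum reciprocal overlap fraction (default 0.5).
#' @return list with `per_sample` (data.frame `sample_id`, `n_called`,
#'   `n_truth`, `precision`, `recall`), `precision`, `recall` (pooled),
#'   `confusion` (truth x called label matrix), `desert_exact_matches`,
#'   `n_truth_deserts`.
#' @export
recovery_report <- function(pipeline_output, manifest,
                            min_reciprocal = 0.5) {
  if (!is.null(pipeline_output$run_id) && !is.null(manifest$run_id) &&
      !identical(pipeline_output$run_id, manifest$run_id)) {
    stop("run id mismatch: output is from a different simulation run",
         call. = FALSE)
  }
  truth <- as.data.frame(manifest$truth_superenhancers)
  calls <- pipeline_output$calls
  per_sample <- lapply(names(calls), function(sid) {
    sup <- calls[[sid]][calls[[sid]]$is_super, , drop = FALSE]
    m <- match_reciprocal(sup, truth, min_reciprocal)
    data.frame(sample_id = sid, n_called = nrow(sup), n_truth = nrow(truth),
               precision = if (nrow(sup) > 0) sum(m$called_matched) /
                 nrow(sup) else NA_real_,
               recall = sum(m$truth_matched) / nrow(truth),
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, per_sample)
  pooled_tp <- sum(per_sample$recall * per_sample$n_truth)
  pooled_called <- sum(per_sample$n_called)

  atlas <- pipeline_output$atlas
  truth_lab <- truth$label
  called_lab <- rep("unmatched", nrow(truth))
  if (!is.null(atlas) && nrow(atlas) > 0) {
    gp <- gr_pair(truth, atlas)
    hits <- GenomicRanges::findOverlaps(gp$a, gp$b)
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      first <- !duplicated(qh)
      called_lab[qh[first]] <- atlas$specificity[sh[first]]
    }
  }
  confusion <- table(truth = truth_lab,
                     called = factor(called_lab,
                                     levels = c("shared", "embryonic",
                                                "tissue_specific",
                                                "unmatched")))

  truth_des <- as.data.frame(manifest$deserts)
  found_des <- pipeline_output$deserts
  exact <- 0L
  if (!is.null(found_des) && nrow(truth_des) > 0) {
    key_t <- paste(truth_des$chrom, truth_des$start, truth_des$end)
    key_f <- paste(found_des$chrom, found_des$start, found_des$end)
    exact <- sum(key_t %in% key_f)
  }
  list(per_sample = per_sample,
       precision = if (pooled_called > 0)
         sum(per_sample$precision * per_sample$n_called) / pooled_called
       else NA_real_,
       recall = pooled_tp / sum(per_sample$n_truth),
       confusion = confusion,
       desert_exact_matches = exact,
       n_truth_deserts = nrow(truth_des))
}

# Reciprocal-overlap matching between called and truth interval sets.
match_reciprocal <- function(called, truth, min_frac) {
  if (nrow(called) == 0 || nrow(truth) == 0) {
    return(list(called_matched = logical(nrow(called)),
                truth_matched = logical(nrow(truth))))
  }
  gp <- gr_pair(called, truth)
  hits <- GenomicRanges::findOverlaps(gp$a, gp$b)
  cm <- logical(nrow(called)); tm <- logical(nrow(truth))
  if (length(hits) > 0) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(gp$a)[qh],
      GenomicRanges::ranges(gp$b)[sh]))
    ok <- ov >= min_frac * (called$end[qh] - called$start[qh]) &
      ov >= min_frac * (truth$end[sh] - truth$start[sh])
    cm[unique(qh[ok])] <- TRUE
    tm[unique(sh[ok])] <- TRUE
  }
  list(called_matched = cm, truth_matched = tm)
}
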