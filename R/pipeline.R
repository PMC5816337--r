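#' Read a run configuration file
#'
#' YAML key-value file; see [run_pipeline()] for the recognised keys.
#' Overrides supplied as `...` win over file values.
#'
#' @param path YAML file.
#' @param ... named overrides.
#' @return named list.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  cfg
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config[order(names(config))], tf)
  unname(tools::md5sum(tf))
}

.load_bundles_from_sheet <- function(sheet_path, chrom_lengths) {
  base <- dirname(sheet_path)
  sheet <- as.data.frame(data.table::fread(sheet_path, header = TRUE, sep = "\t"))
  lapply(seq_len(nrow(sheet)), function(i) {
    depth <- read_bedgraph(file.path(base, sheet$bedgraph[i]), chrom_lengths)
    jt <- read_junction_tsv(file.path(base, sheet$junctions[i]))
    jc <- setNames(as.numeric(jt$read_count),
                   intron_key(jt$chrom, jt$start, jt$end))
    coverage_bundle(sheet$sample_id[i], sheet$condition[i], sheet$replicate[i],
                    depth, jc, tissue = sheet$tissue[i], phase = sheet$phase[i])
  })
}

#' Run the full analysis workflow
#'
#' Wires the stages together: (synthetic or provided) inputs -> junction
#' extraction/classification/filtering/novelty -> long-read isoform
#' collapse and AS-event classification -> DIR calling with summaries and
#' set intersections -> co-regulation clustering -> ddPCR quantification.
#' Every output TSV carries a header comment with the config hash and seed;
#' reruns with the same config are byte-identical.
#'
#' @param config named list (or path to a YAML file, loaded via
#'   [read_run_config()]). Keys: `out_dir`, `seed` (required);
#'   `annotation`, `genome`, `samples` (sample-sheet TSV with per-library
#'   bedGraph/junction paths), `isoseq` (BED12), `wells` (ddPCR TSV) to
#'   analyse existing data — any missing input is simulated; `alpha`
#'   (0.05), `max_fold` (5), `min_junction_count` (2), `min_overhang` (8),
#'   `cluster_cut` (0.3), `permutations` (500), and the [sim_config()]
#'   fields `n_genes`, `n_replicates`, `tissues`, `stresses`, `phases`.
#' @return invisible list with the run report (paths, counts, config hash).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  for (k in c("out_dir", "seed")) if (is.null(config[[k]]))
    stop("run_pipeline: config key '", k, "' is required")
  defaults <- list(alpha = 0.05, max_fold = 5, min_junction_count = 2L,
                   min_overhang = 8L, cluster_cut = 0.3, permutations = 500L,
                   n_genes = 20L, n_replicates = 3L,
                   tissues = c("leaf", "root", "xylem"),
                   stresses = c("cold", "drought", "salt", "heat"),
                   phases = c("short", "prolonged"))
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config[setdiff(names(config), "out_dir")])
  stamp <- c(paste0("dirseq ", as.character(utils::packageVersion("dirseq"))),
             paste0("config_hash ", hash), paste0("seed ", config$seed))
  emit <- function(df, name) write_result_tsv(df, file.path(out, name), comments = stamp)
  report <- list(config_hash = hash, seed = config$seed, outputs = character(0))
  note <- function(name) report$outputs <<- c(report$outputs, file.path(out, name))

  simulated <- is.null(config$annotation) || is.null(config$samples)
  if (simulated) {
    scfg <- sim_config(n_genes = config$n_genes,
                       n_replicates = config$n_replicates,
                       tissues = config$tissues, stresses = config$stresses,
                       phases = config$phases, seed = config$seed)
    sim <- make_genome(scfg)
    genome <- sim$genome
    genes <- sim$genes
    bundles <- simulate_all_coverage(sim, seed = config$seed + 1000L)
    iso_sim <- simulate_isoseq(sim, seed = config$seed + 2000L)
    iso_reads <- iso_sim$reads
    fix_dir <- file.path(out, "fixtures")
    write_simulation(sim, fix_dir, bundles = bundles, isoseq = iso_sim)
  } else {
    genome <- if (!is.null(config$genome)) read_genome_fasta(config$genome) else NULL
    genes <- read_annotation(config$annotation)
    chrlen <- setNames(Biostrings::width(genome), names(genome))
    bundles <- .load_bundles_from_sheet(config$samples, chrlen)
    iso_reads <- if (!is.null(config$isoseq)) read_bed12(config$isoseq) else NULL
  }
  introns <- enumerate_introns_all(genes)

  # --- junctions ---------------------------------------------------------
  jc_all <- list()
  for (b in bundles) {
    ks <- strsplit(names(b$junction_counts), ":", fixed = TRUE)
    jc_all[[length(jc_all) + 1L]] <- data.frame(
      chrom = vapply(ks, `[[`, "", 1L),
      start = as.integer(vapply(ks, `[[`, "", 2L)),
      end = as.integer(vapply(ks, `[[`, "", 3L)),
      strand = ".", read_count = as.numeric(unname(b$junction_counts)),
      max_overhang = 50L, stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, jc_all)
  pooled <- pooled[pooled$read_count > 0, , drop = FALSE]
  pooled <- pooled[order(pooled$chrom, pooled$start), , drop = FALSE]
  juncs <- extract_junctions(pooled)
  if (!is.null(genome)) juncs <- classify_motif(juncs, genome)
  juncs <- annotate_novelty(juncs, introns)
  filt <- filter_junctions(juncs, min_count = config$min_junction_count,
                           min_overhang = config$min_overhang)
  emit(filt$kept, "junctions.tsv"); note("junctions.tsv")
  jsum <- summarize_junctions(filt$kept)
  jsum$n_total <- attr(jsum, "n_total"); jsum$n_novel <- attr(jsum, "n_novel")
  emit(jsum, "junction_summary.tsv"); note("junction_summary.tsv")

  # --- AS events from long reads ----------------------------------------
  events <- .empty_events(); as_sum <- NULL; novel <- NULL
  if (!is.null(iso_reads)) {
    isoforms <- collapse_isoforms(iso_reads)
    events <- classify_events_all(isoforms, genes)
    emit(events, "as_events.tsv"); note("as_events.tsv")
    as_sum <- summarize_event_distribution(events)
    emit(as_sum, "as_summary.tsv"); note("as_summary.tsv")
    novel <- detect_novel_regions(isoforms, genes, genome = genome)
    emit(novel, "novel_regions.tsv"); note("novel_regions.tsv")
  }

  # --- DIR calling -------------------------------------------------------
  dirs <- call_dirs(bundles, genes, alpha = config$alpha,
                    max_fold = config$max_fold)
  emit(dirs, "dir_results.tsv"); note("dir_results.tsv")
  dsum <- summarize_dir_calls(dirs)
  emit(dsum, "dir_summary.tsv"); note("dir_summary.tsv")
  if (sum(dirs$significant) > 0L) {
    emit(dir_intersections(dirs, by = "stress"), "dir_intersections.tsv")
    note("dir_intersections.tsv")
  }

  # --- co-regulation clustering -----------------------------------------
  sig <- dirs[dirs$significant, , drop = FALSE]
  if (length(unique(sig$intron_id)) >= 2L) {
    m <- build_ratio_matrix(dirs[dirs$intron_id %in% sig$intron_id, , drop = FALSE])
    if (nrow(m) >= 2L) {
      cl <- coreg_analysis(m, cut_height = config$cluster_cut,
                           n_permutations = max(200L, config$permutations),
                           seed = config$seed + 3000L)
      emit(cl, "coreg_clusters.tsv"); note("coreg_clusters.tsv")
      long <- data.frame(intron_id = rep(rownames(m), ncol(m)),
                         condition = rep(colnames(m), each = nrow(m)),
                         ratio_difference = as.vector(m))
      emit(long[!is.na(long$ratio_difference), ], "ratio_matrix.tsv")
      note("ratio_matrix.tsv")
    }
  }

  # --- ddPCR -------------------------------------------------------------
  wells <- if (!is.null(config$wells)) read_wells_tsv(config$wells) else {
    # seeded two-condition series with an isoform-ratio switch
    simulate_ddpcr(data.frame(
      target = c("spliced", "I1R", "spliced", "I1R"),
      condition = c("control", "control", "stress", "stress"),
      lambda = c(0.1, 0.05, 0.4, 0.1)), seed = config$seed + 4000L)
  }
  ratios <- quantify_ddpcr(wells)
  emit(ratios, "ddpcr_ratios.tsv"); note("ddpcr_ratios.tsv")
  base_cond <- if (!is.null(config$ddpcr_baseline)) config$ddpcr_baseline else "control"
  if (base_cond %in% ratios$condition && length(unique(ratios$condition)) > 1L) {
    emit(ratio_switch(ratios, baseline = base_cond), "ddpcr_switch.tsv")
    note("ddpcr_switch.tsv")
  }

  # --- run manifest ------------------------------------------------------
  inputs <- unlist(config[c("annotation", "genome", "samples", "isoseq", "wells")])
  manifest <- data.frame(
    key = c("config_hash", "seed", "version",
            if (length(inputs)) paste0("md5:", names(inputs))),
    value = c(hash, as.character(config$seed),
              as.character(utils::packageVersion("dirseq")),
              if (length(inputs)) unname(tools::md5sum(inputs))),
    stringsAsFactors = FALSE)
  emit(manifest, "run_manifest.tsv"); note("run_manifest.tsv")

  report$n_junctions <- nrow(filt$kept)
  report$n_events <- nrow(events)
  report$n_dirs <- sum(dirs$significant)
  invisible(report)
}
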