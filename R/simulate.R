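#' Configuration for the synthetic-data generator
#'
#' The defaults mirror the shape of a multi-tissue abiotic-stress study at
#' toy scale: 3 tissues x 4 stresses x 2 treatment phases, 3 replicates per
#' condition plus per-tissue controls, 20 multi-exon genes. Coverage follows
#' a negative-binomial model (variance `mu + mu^2 * dispersion`); each
#' intron has a generative inclusion level `psi` (the probability a
#' transcript retains it), shifted by `dir_delta` in the conditions where a
#' differential-retention event is seeded.
#'
#' @param n_genes number of genes (default 20).
#' @param exons_per_gene integer range (default 3..8).
#' @param exon_length,intron_length length ranges in nt (defaults 80..300
#'   and 80..400; introns comfortably above the 20 nt artifact floor).
#' @param base_depth mean exonic per-base coverage at expression 1
#'   (default 100).
#' @param nb_dispersion negative-binomial dispersion (default 0.1).
#' @param psi_control baseline inclusion level (default 0.15).
#' @param dir_fraction fraction of introns seeded as DIR (default 0.1).
#' @param dir_delta inclusion shift of seeded DIRs (default 0.3).
#' @param frac_expr_change fraction of genes given a strong expression
#'   change under treatment (default 0.1), at `expr_change_fold` (default 8,
#'   beyond the fivefold filter).
#' @param tissues,stresses,phases design labels.
#' @param n_replicates replicates per condition (default 3).
#' @param motif_fractions donor/acceptor motif mix for generated introns.
#' @param n_novel_regions intergenic long-read loci (default 5), of which
#'   `n_novel_as` carry an alternative isoform (default 2).
#' @param seed integer seed (required; every generator call derives its
#'   stream from it).
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(n_genes = 20L, exons_per_gene = c(3L, 8L),
                       exon_length = c(80L, 300L), intron_length = c(80L, 400L),
                       base_depth = 100, nb_dispersion = 0.1,
                       psi_control = 0.15, dir_fraction = 0.1, dir_delta = 0.3,
                       frac_expr_change = 0.1, expr_change_fold = 8,
                       tissues = c("leaf", "root", "xylem"),
                       stresses = c("cold", "drought", "salt", "heat"),
                       phases = c("short", "prolonged"),
                       n_replicates = 3L,
                       motif_fractions = c("GT/AG" = 0.9, "GC/AG" = 0.08,
                                           "AT/AC" = 0.02),
                       n_novel_regions = 5L, n_novel_as = 2L,
                       seed) {
  if (missing(seed)) stop("sim_config: a seed is required")
  stopifnot(base_depth > 0, nb_dispersion > 0,
            psi_control >= 0, psi_control < 1,
            intron_length[1L] >= 40L)
  structure(as.list(environment()), class = "SimulationConfig")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# sample() treats a scalar first argument as 1:x; these never do.
.pick1 <- function(v) v[sample.int(length(v), 1L)]
.sample_range <- function(lo, hi, n) (lo:hi)[sample.int(hi - lo + 1L, n, replace = TRUE)]

# All (tissue x stress x phase) treatment labels of a config.
sim_conditions <- function(config) {
  g <- expand.grid(tissue = config$tissues, stress = config$stresses,
                   phase = config$phases, stringsAsFactors = FALSE)
  g <- g[order(g$tissue, g$stress, g$phase), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Generate a synthetic genome, annotation and truth manifest
#'
#' Genes are laid out along one chromosome with random strands and
#' intergenic spacers; intron boundary dinucleotides are written into the
#' sequence according to `motif_fractions` (strand-aware), so junction motif
#' classification can be validated against the manifest. A second,
#' gene-free chromosome hosts the intergenic loci used by the novel-region
#' stage. The manifest records the generative truth of every later stage:
#' per-intron inclusion levels per condition, the seeded DIR set with
#' directions, per-gene expression fold changes, the junction set and its
#' motifs.
#'
#' Deterministic: the same config (including its seed) yields byte-identical
#' FASTA/GFF3 on disk via [write_simulation()].
#'
#' @param config from [sim_config()].
#' @return list of class `Simulation`: `genome` (`DNAStringSet`), `genes`
#'   (list of `GeneModel`), `manifest` (list), `config`.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  genes <- list()
  intron_rows <- list()
  pos <- 0L
  chrom <- "chr1"
  seq_chunks <- character(0)
  add_seq <- function(s) seq_chunks[[length(seq_chunks) + 1L]] <<- s

  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%03d", g)
    strand <- sample(c("+", "-"), 1L)
    gap <- .pick1(500:2000)
    add_seq(.rand_dna(gap)); pos <- pos + gap
    n_ex <- .pick1(config$exons_per_gene[1L]:config$exons_per_gene[2L])
    ex_len <- .sample_range(config$exon_length[1L], config$exon_length[2L], n_ex)
    in_len <- if (n_ex > 1L)
      .sample_range(config$intron_length[1L], config$intron_length[2L], n_ex - 1L)
    else integer(0)
    starts <- integer(n_ex); ends <- integer(n_ex)
    for (k in seq_len(n_ex)) {
      starts[k] <- pos
      add_seq(.rand_dna(ex_len[k])); pos <- pos + ex_len[k]
      ends[k] <- pos
      if (k < n_ex) {
        motif <- sample(names(config$motif_fractions), 1L,
                        prob = config$motif_fractions)
        halves <- strsplit(motif, "/", fixed = TRUE)[[1L]]
        body <- .rand_dna(in_len[k] - 4L)
        iseq <- paste0(halves[1L], body, halves[2L])
        if (strand == "-") iseq <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(iseq)))
        add_seq(iseq)
        intron_rows[[length(intron_rows) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = pos + in_len[k], strand = strand,
          gene_id = gid, motif = motif, stringsAsFactors = FALSE)
        pos <- pos + in_len[k]
      }
    }
    tx <- transcript_model(paste0(gid, ".1"), chrom, strand, cbind(starts, ends))
    genes[[gid]] <- gene_model(gid, list(tx))
  }
  add_seq(.rand_dna(1000L)); pos <- pos + 1000L
  chr1 <- paste(seq_chunks, collapse = "")
  chr2 <- .rand_dna(max(20000L, config$n_novel_regions * 3000L + 2000L))
  genome <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))

  introns <- do.call(rbind, intron_rows)
  # align intron ids with enumerate_introns ordinals
  enum <- enumerate_introns_all(genes, min_intron_length = 1L)
  key_enum <- intron_key(enum$chrom, enum$start, enum$end)
  introns$intron_id <- enum$intron_id[match(
    intron_key(introns$chrom, introns$start, introns$end), key_enum)]

  conds <- sim_conditions(config)
  cond_labels <- paste(conds$tissue, conds$stress, conds$phase, sep = ":")
  ctrl_labels <- paste(unique(config$tissues), "control", "all", sep = ":")
  all_labels <- c(ctrl_labels, cond_labels)

  n_int <- nrow(introns)
  psi <- matrix(config$psi_control, n_int, length(all_labels),
                dimnames = list(introns$intron_id, all_labels))
  n_dir <- round(config$dir_fraction * n_int)
  dir_idx <- if (n_dir > 0L) sort(sample.int(n_int, n_dir)) else integer(0)
  dir_rows <- list()
  for (i in dir_idx) {
    dir_up <- sample(c(TRUE, FALSE), 1L)
    # each seeded DIR responds in a random non-empty subset of stress:phase
    sp <- unique(paste(conds$stress, conds$phase, sep = ":"))
    hit <- sp[sample(c(TRUE, FALSE), length(sp), replace = TRUE)]
    if (!length(hit)) hit <- .pick1(sp)
    delta <- if (dir_up) config$dir_delta else -config$dir_delta
    target_psi <- min(max(config$psi_control + delta, 0.02), 0.95)
    for (h in hit) {
      cols <- cond_labels[paste(conds$stress, conds$phase, sep = ":") == h]
      psi[i, cols] <- target_psi
    }
    dir_rows[[length(dir_rows) + 1L]] <- data.frame(
      intron_id = introns$intron_id[i], gene_id = introns$gene_id[i],
      direction = if (dir_up) "increased IR" else "decreased IR",
      stress_phases = paste(hit, collapse = ","), stringsAsFactors = FALSE)
  }
  dir_truth <- if (length(dir_rows)) do.call(rbind, dir_rows) else
    data.frame(intron_id = character(0), gene_id = character(0),
               direction = character(0), stress_phases = character(0),
               stringsAsFactors = FALSE)

  gene_ids <- names(genes)
  expr <- matrix(1, length(gene_ids), length(all_labels),
                 dimnames = list(gene_ids, all_labels))
  n_ch <- round(config$frac_expr_change * length(gene_ids))
  expr_changed <- if (n_ch > 0L) sort(sample(gene_ids, n_ch)) else character(0)
  if (length(expr_changed)) expr[expr_changed, cond_labels] <- config$expr_change_fold

  structure(list(
    genome = genome, genes = genes, config = config,
    manifest = list(
      introns = introns, dir_truth = dir_truth,
      psi = psi, expression = expr, expr_changed = expr_changed,
      condition_labels = all_labels, control_labels = ctrl_labels
    )
  ), class = "Simulation")
}

#' @export
print.Simulation <- function(x, ...) {
  cat(sprintf("Simulation: %d genes, %d introns, %d seeded DIRs, seed %d\n",
              length(x$genes), nrow(x$manifest$introns),
              nrow(x$manifest$dir_truth), x$config$seed))
  invisible(x)
}

#' Simulate short-read coverage and junction counts for one library
#'
#' Per gene, the expression level is the manifest fold change for the
#' condition; exonic per-base depth is drawn NB(mean = E * base_depth,
#' dispersion). Each intron's reads partition into retained (`psi`) versus
#' spliced (`1 - psi`): intronic per-base depth is NB with mean
#' `psi * E * base_depth` (exact zeros when `psi = 0` — no noise is added to
#' absent signal), and the spliced-junction count is Binomial over the
#' spliced fraction of an NB-drawn transcript total. Replicates are
#' independent given distinct seeds.
#'
#' @param sim a `Simulation` from [make_genome()].
#' @param condition_label one of `sim$manifest$condition_labels`
#'   (`"tissue:stress:phase"`; controls are `"tissue:control:all"`).
#' @param replicate replicate index (recorded in the bundle).
#' @param seed integer seed for this library's stream.
#' @return `CoverageBundle`.
#' @export
simulate_coverage <- function(sim, condition_label, replicate, seed) {
  stopifnot(inherits(sim, "Simulation"))
  man <- sim$manifest
  if (!condition_label %in% man$condition_labels)
    stop("unknown condition label: ", condition_label)
  set.seed(seed)
  cfg <- sim$config
  size <- 1 / cfg$nb_dispersion
  depth <- lapply(Biostrings::width(sim$genome), numeric)
  names(depth) <- names(sim$genome)
  jc <- numeric(0)
  for (gid in names(sim$genes)) {
    g <- sim$genes[[gid]]
    E <- man$expression[gid, condition_label]
    mu_ex <- E * cfg$base_depth
    u <- .gene_exon_union(g)
    for (r in seq_len(nrow(u))) {
      idx <- (u[r, 1L] + 1L):u[r, 2L]
      depth[[g$chrom]][idx] <- rnbinom(length(idx), mu = mu_ex, size = size)
    }
    gint <- man$introns[man$introns$gene_id == gid, , drop = FALSE]
    for (r in seq_len(nrow(gint))) {
      psi <- man$psi[gint$intron_id[r], condition_label]
      idx <- (gint$start[r] + 1L):gint$end[r]
      if (psi > 0) depth[[gint$chrom[r]]][idx] <-
          rnbinom(length(idx), mu = psi * mu_ex, size = size)
      total <- rnbinom(1L, mu = mu_ex, size = size)
      jc[intron_key(gint$chrom[r], gint$start[r], gint$end[r])] <-
        rbinom(1L, total, 1 - psi)
    }
  }
  parts <- strsplit(condition_label, ":", fixed = TRUE)[[1L]]
  coverage_bundle(
    sample_id = paste0(gsub(":", "_", condition_label), "_r", replicate),
    condition = parts[2L], tissue = parts[1L], phase = parts[3L],
    replicate = replicate, depth = depth, junction_counts = jc
  )
}

#' Simulate all libraries of the study design
#'
#' One bundle per condition label per replicate, with per-library sub-seeds
#' derived deterministically from `seed`.
#'
#' @param sim `Simulation`.
#' @param seed base seed.
#' @return list of `CoverageBundle`.
#' @export
simulate_all_coverage <- function(sim, seed) {
  labels <- sim$manifest$condition_labels
  out <- list()
  k <- 0L
  for (lab in labels) for (r in seq_len(sim$config$n_replicates)) {
    k <- k + 1L
    out[[length(out) + 1L]] <- simulate_coverage(sim, lab, r, seed = seed + k)
  }
  out
}

# Build the truth isoform for one seeded event from the reference transcript.
.event_isoform <- function(tx, type, shift = 9L) {
  ex <- tx$exons
  n <- nrow(ex)
  j <- transcript_junctions(tx)
  if (type == "IR") {
    k <- .pick1(seq_len(n - 1L))
    ex2 <- ex
    ex2[k, 2L] <- ex2[k + 1L, 2L]
    ex2 <- ex2[-(k + 1L), , drop = FALSE]
    list(exons = ex2, coords = c(j[k, 1L], j[k, 2L]))
  } else if (type %in% c("Alt5", "Alt3")) {
    k <- .pick1(seq_len(n - 1L))
    s <- j[k, 1L]; e <- j[k, 2L]
    plus <- tx$strand == "+"
    move_start <- (type == "Alt5") == plus  # donor side on + is the start
    ex2 <- ex
    if (move_start) { ex2[k, 2L] <- s + shift; s <- s + shift }
    else { ex2[k + 1L, 1L] <- e - shift; e <- e - shift }
    list(exons = ex2, coords = c(s, e))
  } else if (type == "ES") {
    k <- .pick1(2L:(n - 1L))
    list(exons = ex[-k, , drop = FALSE], coords = c(ex[k - 1L, 2L], ex[k + 1L, 1L]))
  } else if (type == "MXE") {
    k <- .pick1(2L:(n - 1L))
    gap_s <- ex[k, 2L]; gap_e <- ex[k + 1L, 1L]
    stopifnot(gap_e - gap_s >= 80L)
    nov <- c(gap_s + 25L, gap_s + 55L)
    ex2 <- rbind(ex[seq_len(k - 1L), , drop = FALSE],
                 matrix(nov, 1L), ex[(k + 1L):n, , drop = FALSE])
    list(exons = ex2, coords = c(ex[k, 1L], ex[k, 2L]), coords2 = nov)
  } else stop("unknown event type: ", type)
}

#' Simulate long-read isoform alignments with seeded AS events
#'
#' For each selected gene one alternative isoform is built from the
#' reference transcript by applying a single event (type cycling through
#' IR, Alt5, Alt3, ES, MXE as gene structure allows); reads are emitted for
#' both the reference and the alternative isoform with uniform 5'
#' truncation noise that never removes an internal junction. Additional
#' intergenic loci are placed on the gene-free chromosome, a configurable
#' number carrying a second isoform differing at one donor (the seeded AS
#' signal for novel-region detection).
#'
#' @param sim `Simulation`.
#' @param seed integer seed.
#' @param reads_per_isoform range of read support (default 3..8).
#' @param max_truncation maximum 5' truncation in nt (default 30, below the
#'   minimum exon length).
#' @return list: `reads` (list of `TranscriptModel`), `truth` (data.frame
#'   of seeded events per alternative isoform), `novel_truth` (data.frame
#'   of intergenic loci with their AS flag).
#' @export
simulate_isoseq <- function(sim, seed, reads_per_isoform = c(3L, 8L),
                            max_truncation = 30L) {
  stopifnot(inherits(sim, "Simulation"))
  set.seed(seed)
  cfg <- sim$config
  types <- c("IR", "Alt5", "Alt3", "ES", "MXE")
  reads <- list()
  truth <- list()
  emit_reads <- function(tx, n, tag) {
    for (r in seq_len(n)) {
      ex <- tx$exons
      tr <- sample.int(max_truncation + 1L, 1L) - 1L
      if (tx$strand == "+") ex[1L, 1L] <- ex[1L, 1L] + tr
      else ex[nrow(ex), 2L] <- ex[nrow(ex), 2L] - tr
      reads[[length(reads) + 1L]] <<- transcript_model(
        sprintf("%s_read%02d", tag, r), tx$chrom, tx$strand, ex)
    }
  }
  for (gi in seq_along(sim$genes)) {
    g <- sim$genes[[gi]]
    ref <- g$transcripts[[1L]]
    n_ex <- nrow(ref$exons)
    type <- types[(gi - 1L) %% length(types) + 1L]
    # feasibility: ES/MXE need an internal exon; MXE needs a wide-enough gap
    if (type %in% c("ES", "MXE") && n_ex < 3L) type <- "IR"
    if (type == "MXE") {
      gaps <- ref$exons[-1L, 1L] - ref$exons[-n_ex, 2L]
      if (all(gaps[-c(1L)] < 80L) || n_ex < 3L) type <- "ES"
    }
    nref <- .pick1(reads_per_isoform[1L]:reads_per_isoform[2L])
    emit_reads(ref, nref, paste0(g$gene_id, "_ref"))
    evi <- .event_isoform(ref, type)
    alt <- transcript_model(paste0(g$gene_id, ".alt"), g$chrom, g$strand, evi$exons)
    nalt <- .pick1(reads_per_isoform[1L]:reads_per_isoform[2L])
    emit_reads(alt, nalt, paste0(g$gene_id, "_alt"))
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = g$gene_id, event_type = type,
      start = evi$coords[1L], end = evi$coords[2L],
      start2 = if (!is.null(evi$coords2)) evi$coords2[1L] else NA_integer_,
      end2 = if (!is.null(evi$coords2)) evi$coords2[2L] else NA_integer_,
      chain = .chain_string(alt), n_ref_reads = nref, n_alt_reads = nalt,
      stringsAsFactors = FALSE)
  }
  # intergenic loci on chr2
  novel <- list()
  pos <- 500L
  for (k in seq_len(cfg$n_novel_regions)) {
    ex <- cbind(c(pos, pos + 400L), c(pos + 200L, pos + 600L))
    base <- transcript_model(sprintf("NOV%02d", k), "chr2", "+", ex)
    emit_reads(base, 3L, sprintf("NOV%02d_a", k))
    with_as <- k <= cfg$n_novel_as
    if (with_as) {
      ex2 <- ex; ex2[1L, 2L] <- ex2[1L, 2L] - 12L  # shifted donor
      emit_reads(transcript_model(sprintf("NOV%02d.b", k), "chr2", "+", ex2),
                 3L, sprintf("NOV%02d_b", k))
    }
    novel[[k]] <- data.frame(region = sprintf("NOV%02d", k), chrom = "chr2",
                             start = pos, end = pos + 600L, has_AS = with_as,
                             stringsAsFactors = FALSE)
    pos <- pos + 2500L
  }
  list(reads = reads, truth = do.call(rbind, truth),
       novel_truth = do.call(rbind, novel))
}

#' Simulate droplet digital PCR wells
#'
#' Each well partitions the template into `droplets_total` droplets; a
#' droplet is positive when it received at least one template molecule, so
#' `droplets_positive ~ Binomial(total, 1 - exp(-lambda))`.
#'
#' @param targets data.frame with columns `target`, `condition`, `lambda`
#'   (true copies per droplet), or a named numeric vector of lambdas (one
#'   condition `"control"` assumed).
#' @param droplets_total droplets per well (default 20000).
#' @param n_wells replicate wells per target/condition (default 1).
#' @param seed integer seed.
#' @return wells data.frame compatible with [quantify_ddpcr()].
#' @export
simulate_ddpcr <- function(targets, droplets_total = 20000L, n_wells = 1L,
                           seed) {
  if (missing(seed)) stop("simulate_ddpcr: a seed is required")
  if (!is.data.frame(targets)) {
    targets <- data.frame(target = names(targets), condition = "control",
                          lambda = as.numeric(targets), stringsAsFactors = FALSE)
  }
  stopifnot(all(targets$lambda >= 0))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(targets))) for (w in seq_len(n_wells)) {
    pos <- rbinom(1L, droplets_total, 1 - exp(-targets$lambda[i]))
    rows[[length(rows) + 1L]] <- data.frame(
      well_id = sprintf("%s_%s_w%d", targets$condition[i], targets$target[i], w),
      target = targets$target[i], condition = targets$condition[i],
      droplets_total = droplets_total, droplets_positive = pos,
      dilution_factor = 1, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write synthetic SAM reads spanning a junction set
#'
#' Emits, for each junction record, `read_count` gapped alignments with
#' CIGAR `<anchor>M<gap>N<anchor>M`, so the BAM extraction path can be
#' exercised from plain-text input (convert with `Rsamtools::asBam`).
#'
#' @param junctions junction data.frame (`chrom`, `start`, `end`, `strand`,
#'   `read_count`).
#' @param genome `DNAStringSet` (for header lengths).
#' @param path output SAM path.
#' @param anchor aligned block length on each side (default 25 nt).
#' @export
write_junction_sam <- function(junctions, genome, path, anchor = 25L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ch in names(genome))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, length(genome[[ch]])), con)
  j <- junctions[order(junctions$chrom, junctions$start), , drop = FALSE]
  rid <- 0L
  for (i in seq_len(nrow(j))) {
    gap <- j$end[i] - j$start[i]
    pos1 <- j$start[i] - anchor + 1L  # 1-based leftmost aligned base
    cigar <- sprintf("%dM%dN%dM", anchor, gap, anchor)
    flag <- if (j$strand[i] == "-") 16L else 0L
    seq <- paste(rep("A", 2L * anchor), collapse = "")
    for (r in seq_len(j$read_count[i])) {
      rid <- rid + 1L
      writeLines(paste(sprintf("read%05d", rid), flag, j$chrom[i], pos1, 60L,
                       cigar, "*", 0L, 0L, seq, "*", "NH:i:1", sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a simulation's fixtures to disk
#'
#' FASTA, GFF3, per-library bedGraph + junction TSV, long-read BED12 and a
#' JSON truth manifest, all plain text and byte-deterministic for a given
#' config.
#'
#' @param sim `Simulation`.
#' @param dir output directory (created if needed).
#' @param bundles optional list from [simulate_all_coverage()].
#' @param isoseq optional result of [simulate_isoseq()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, bundles = NULL, isoseq = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"), width = 70L)
  write_annotation_gff3(sim$genes, file.path(dir, "annotation.gff3"))
  if (!is.null(bundles)) {
    sheet <- list()
    for (b in bundles) {
      write_bedgraph(b$depth, file.path(dir, paste0(b$sample_id, ".bedgraph")))
      ks <- strsplit(names(b$junction_counts), ":", fixed = TRUE)
      jt <- data.frame(
        chrom = vapply(ks, `[[`, "", 1L),
        start = as.integer(vapply(ks, `[[`, "", 2L)),
        end = as.integer(vapply(ks, `[[`, "", 3L)),
        strand = sim$manifest$introns$strand[match(
          names(b$junction_counts),
          intron_key(sim$manifest$introns$chrom, sim$manifest$introns$start,
                     sim$manifest$introns$end))],
        read_count = as.integer(unname(b$junction_counts)),
        max_overhang = 50L, stringsAsFactors = FALSE)
      write_junction_tsv(jt, file.path(dir, paste0(b$sample_id, ".junctions.tsv")))
      sheet[[length(sheet) + 1L]] <- data.frame(
        sample_id = b$sample_id, condition = b$condition, tissue = b$tissue,
        phase = b$phase, replicate = b$replicate,
        bedgraph = paste0(b$sample_id, ".bedgraph"),
        junctions = paste0(b$sample_id, ".junctions.tsv"),
        stringsAsFactors = FALSE)
    }
    write_result_tsv(do.call(rbind, sheet), file.path(dir, "samples.tsv"))
  }
  if (!is.null(isoseq)) {
    write_bed12(isoseq$reads, file.path(dir, "isoseq_reads.bed12"))
  }
  man <- sim$manifest
  json <- list(
    seed = sim$config$seed,
    introns = man$introns, dir_truth = man$dir_truth,
    psi = as.data.frame(man$psi), expression = as.data.frame(man$expression),
    expr_changed = man$expr_changed, condition_labels = man$condition_labels
  )
  writeLines(jsonlite::toJSON(json, digits = NA, pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
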