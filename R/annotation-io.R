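#' Read a gene annotation (GFF3 or GTF) into gene models
#'
#' Parses with \pkg{rtracklayer} and converts the 1-based inclusive GFF/GTF
#' coordinates to the package-internal 0-based half-open convention. Exon
#' features are grouped under transcripts under genes; genes are returned in
#' deterministic (chrom, start, gene_id) order.
#'
#' @param path GFF3 or GTF file; dialect chosen from the extension
#'   (`.gtf` vs `.gff`/`.gff3`) or forced with `format`.
#' @param format `"auto"`, `"gff3"` or `"gtf"`.
#' @return Named list of [gene_model()] objects.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "gff3"
  }
  .validate_feature_lines(path)
  gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ex <- gr[type == "exon"]
  if (length(ex) == 0L) stop("annotation contains no exon features: ", path)
  exd <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE
  )
  exm <- S4Vectors::mcols(ex)
  if (format == "gtf") {
    exd$transcript_id <- as.character(exm$transcript_id)
    exd$gene_id <- as.character(exm$gene_id)
  } else {
    parent <- exm$Parent
    exd$transcript_id <- vapply(as.list(parent), function(p) as.character(p)[1L], "")
    # map transcript -> gene through the mRNA/transcript features' Parent
    txf <- gr[type %in% c("mRNA", "transcript")]
    txm <- S4Vectors::mcols(txf)
    tx2gene <- setNames(
      vapply(as.list(txm$Parent), function(p) as.character(p)[1L], ""),
      as.character(txm$ID)
    )
    exd$gene_id <- unname(tx2gene[exd$transcript_id])
    if (anyNA(exd$gene_id))
      stop("exon Parent transcript without a gene parent in ", path)
  }
  genes <- list()
  for (gid in unique(exd$gene_id)) {
    sub <- exd[exd$gene_id == gid, , drop = FALSE]
    txs <- lapply(split(sub, sub$transcript_id), function(s) {
      transcript_model(s$transcript_id[1L], s$chrom[1L], s$strand[1L],
                       cbind(s$start, s$end))
    })
    txs <- txs[order(names(txs))]
    genes[[gid]] <- gene_model(gid, unname(txs))
  }
  ord <- order(
    vapply(genes, `[[`, "", "chrom"),
    vapply(genes, function(g) g$span[1L], integer(1)),
    vapply(genes, `[[`, "", "gene_id")
  )
  genes[ord]
}

# Cheap structural validation so malformed lines are reported by number
# (rtracklayer's own errors do not carry line context).
.validate_feature_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("malformed feature line ", i, " in ", path, ": expected 9 tab-separated fields")
    if (is.na(suppressWarnings(as.integer(f[4L]))) ||
        is.na(suppressWarnings(as.integer(f[5L]))))
      stop("malformed feature line ", i, " in ", path, ": non-numeric coordinates")
  }
  invisible(TRUE)
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon features with ID/Parent attributes, converting the
#' internal 0-based half-open intervals back to 1-based inclusive. Output
#' order is deterministic (chrom, start, gene_id), so identical model sets
#' produce byte-identical files.
#'
#' @param genes list of `GeneModel`.
#' @param path output file.
#' @export
write_annotation_gff3 <- function(genes, path) {
  ord <- order(
    vapply(genes, `[[`, "", "chrom"),
    vapply(genes, function(g) g$span[1L], integer(1)),
    vapply(genes, `[[`, "", "gene_id")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes[ord]) {
    writeLines(sprintf("%s\tdirseq\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$span[1L] + 1L, g$span[2L], g$strand, g$gene_id), con)
    for (tx in g$transcripts[order(names(g$transcripts))]) {
      writeLines(sprintf("%s\tdirseq\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         g$chrom, min(tx$exons[, 1L]) + 1L, max(tx$exons[, 2L]),
                         g$strand, tx$transcript_id, g$gene_id), con)
      for (k in seq_len(nrow(tx$exons))) {
        writeLines(sprintf("%s\tdirseq\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                           g$chrom, tx$exons[k, 1L] + 1L, tx$exons[k, 2L],
                           g$strand, tx$transcript_id), con)
      }
    }
  }
  invisible(path)
}

#' Read per-base coverage from a bedGraph file
#'
#' @param path bedGraph (0-based half-open intervals, 4th column depth).
#' @param chrom_lengths named integer vector giving the length of each
#'   chromosome the returned depth vectors should span.
#' @return Named list of numeric depth vectors, one per chromosome in
#'   `chrom_lengths`; positions without a bedGraph interval are 0.
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  bg <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "depth"))
  depth <- lapply(chrom_lengths, function(L) numeric(L))
  for (ch in unique(bg$chrom)) {
    if (!ch %in% names(depth)) stop("bedGraph chromosome not in genome: ", ch)
    sub <- bg[bg$chrom == ch, ]
    v <- depth[[ch]]
    for (r in seq_len(nrow(sub))) {
      v[(sub$start[r] + 1L):sub$end[r]] <- sub$depth[r]
    }
    depth[[ch]] <- v
  }
  depth
}

#' Write per-base coverage as bedGraph
#'
#' Run-length encodes each chromosome's depth vector; zero-depth runs are
#' omitted, matching common bedGraph practice.
#'
#' @param depth named list of numeric per-base depth vectors.
#' @param path output file.
#' @export
write_bedgraph <- function(depth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in sort(names(depth))) {
    r <- rle(depth[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                         format(r$values[keep], trim = TRUE, scientific = FALSE)),
                 con)
    }
  }
  invisible(path)
}

#' Read a junction table
#'
#' Tab-separated with header; columns `chrom`, `start`, `end`, `strand`,
#' `read_count` and optionally `max_overhang`, `motif_class`, `annotated`.
#' Coordinates are intron coordinates, 0-based half-open.
#'
#' @param path file path.
#' @return data.frame with one row per junction record.
#' @export
read_junction_tsv <- function(path) {
  j <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("chrom", "start", "end", "strand", "read_count")
  miss <- setdiff(need, names(j))
  if (length(miss)) stop("junction table missing column(s): ", paste(miss, collapse = ", "))
  if (!"max_overhang" %in% names(j)) j$max_overhang <- NA_integer_
  if (!"motif_class" %in% names(j)) j$motif_class <- NA_character_
  if (!"annotated" %in% names(j)) j$annotated <- NA
  j
}

#' Write a junction table
#'
#' @param junctions data.frame as returned by [extract_junctions()].
#' @param path output file.
#' @export
write_junction_tsv <- function(junctions, path) {
  cols <- c("chrom", "start", "end", "strand", "read_count", "max_overhang",
            "motif_class", "annotated")
  for (cl in setdiff(cols, names(junctions))) junctions[[cl]] <- NA
  j <- junctions[cols]
  j <- j[order(j$chrom, j$start, j$end, j$strand), , drop = FALSE]
  write.table(j, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript models from BED12
#'
#' @param path BED12 file; blocks become exons, converted to the internal
#'   0-based half-open convention (BED already uses it).
#' @return list of `TranscriptModel`.
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- rtracklayer::blocks(gr)
  out <- vector("list", length(gr))
  nm <- as.character(S4Vectors::mcols(gr)$name)
  for (i in seq_along(gr)) {
    b <- blocks[[i]]
    out[[i]] <- transcript_model(
      nm[i],
      as.character(GenomicRanges::seqnames(gr[i])),
      as.character(GenomicRanges::strand(gr[i])),
      cbind(GenomicRanges::start(b) - 1L, GenomicRanges::end(b))
    )
  }
  out
}

#' Write transcript models as BED12
#'
#' @param models list of `TranscriptModel`.
#' @param path output file.
#' @param scores optional numeric vector (e.g. read support), recycled 0.
#' @export
write_bed12 <- function(models, path, scores = 0L) {
  scores <- rep_len(scores, length(models))
  lines <- character(length(models))
  for (i in seq_along(models)) {
    tx <- models[[i]]
    ex <- tx$exons
    s <- min(ex[, 1L]); e <- max(ex[, 2L])
    lines[i] <- paste(
      tx$chrom, s, e, tx$transcript_id, scores[i], tx$strand, s, e, "0",
      nrow(ex),
      paste0(paste(ex[, 2L] - ex[, 1L], collapse = ","), ","),
      paste0(paste(ex[, 1L] - s, collapse = ","), ","),
      sep = "\t"
    )
  }
  ord <- order(vapply(models, `[[`, "", "chrom"),
               vapply(models, function(t) min(t$exons[, 1L]), integer(1)),
               vapply(models, `[[`, "", "transcript_id"))
  writeLines(lines[ord], path)
  invisible(path)
}

#' Write a generic results table
#'
#' Tab-separated, header line, deterministic row order as given; optional
#' `#`-prefixed header comments (used by the pipeline to stamp config hash
#' and seed).
#'
#' @param df data.frame.
#' @param path output file.
#' @param comments character vector of comment lines (without the `#`).
#' @export
write_result_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
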