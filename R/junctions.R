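#' Read a genome FASTA into a sequence store
#'
#' @param path FASTA file.
#' @return `DNAStringSet` named by the first whitespace-delimited token of
#'   each header.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Extract splice junctions from alignment evidence
#'
#' Accepts either a coordinate-sorted BAM of gapped alignments or a
#' junction table (TSV path or data.frame). Distinct junctions are keyed by
#' (chrom, start, end, strand); read counts are summed and the maximum
#' observed anchor overhang retained. For BAM input, reads flagged as
#' multi-mappers (NH tag > 1) are excluded so only uniquely aligned reads
#' contribute, and the per-read anchor of a junction is the shorter of its
#' two flanking aligned blocks.
#'
#' @param alignments BAM path, junction TSV path, or junction data.frame.
#' @param min_overhang junction observations with anchors shorter than this
#'   are dropped at extraction (default 1 nt keeps everything).
#' @return data.frame of junction records (`chrom`, `start`, `end`,
#'   `strand`, `read_count`, `max_overhang`, `motif_class`, `annotated`),
#'   sorted by position. Zero junctions yield an empty frame with a warning.
#' @export
extract_junctions <- function(alignments, min_overhang = 1L) {
  if (is.character(alignments) && grepl("\\.bam$", alignments, ignore.case = TRUE)) {
    obs <- .junctions_from_bam(alignments)
  } else {
    j <- if (is.data.frame(alignments)) alignments else read_junction_tsv(alignments)
    if (nrow(j) > 0L) {
      o <- order(j$chrom, j$start)
      if (!identical(o, seq_len(nrow(j)))) stop("junction input is not position-sorted")
    }
    ov <- if ("max_overhang" %in% names(j)) j$max_overhang else rep(NA_integer_, nrow(j))
    obs <- data.frame(chrom = j$chrom, start = j$start, end = j$end,
                      strand = j$strand, count = j$read_count,
                      overhang = ov, stringsAsFactors = FALSE)
  }
  obs <- obs[is.na(obs$overhang) | obs$overhang >= min_overhang, , drop = FALSE]
  if (nrow(obs) == 0L) {
    warning("no junctions extracted")
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), read_count = integer(0),
                      max_overhang = integer(0), motif_class = character(0),
                      annotated = logical(0), stringsAsFactors = FALSE))
  }
  key <- paste(obs$chrom, obs$start, obs$end, obs$strand, sep = "\t")
  agg_count <- tapply(obs$count, key, sum)
  agg_over <- tapply(obs$overhang, key, function(x) {
    if (all(is.na(x))) NA_integer_ else max(x, na.rm = TRUE)
  })
  parts <- do.call(rbind, strsplit(names(agg_count), "\t", fixed = TRUE))
  out <- data.frame(
    chrom = parts[, 1L], start = as.integer(parts[, 2L]),
    end = as.integer(parts[, 3L]), strand = parts[, 4L],
    read_count = as.integer(agg_count),
    max_overhang = as.integer(agg_over),
    motif_class = NA_character_, annotated = NA,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.junctions_from_bam <- function(path) {
  hdr <- Rsamtools::scanBamHeader(path)[[1L]]$text
  so <- hdr[["@HD"]]
  if (!is.null(so) && !any(grepl("SO:coordinate", so)))
    stop("BAM is not coordinate-sorted: ", path)
  param <- Rsamtools::ScanBamParam(tag = "NH")
  galn <- GenomicAlignments::readGAlignments(path, param = param)
  nh <- S4Vectors::mcols(galn)$NH
  if (!is.null(nh)) galn <- galn[is.na(nh) | nh == 1L]  # uniquely aligned only
  blocks <- GenomicAlignments::grglist(galn)
  nblk <- S4Vectors::elementNROWS(blocks)
  gapped <- which(nblk > 1L)
  if (!length(gapped)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), count = integer(0),
                      overhang = integer(0), stringsAsFactors = FALSE))
  }
  rows <- vector("list", length(gapped))
  for (k in seq_along(gapped)) {
    b <- blocks[[gapped[k]]]
    n <- length(b)
    w <- GenomicRanges::width(b)
    rows[[k]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(b))[1L],
      start = GenomicRanges::end(b)[-n],            # 1-based end == 0-based start of gap
      end = GenomicRanges::start(b)[-1L] - 1L,
      strand = as.character(GenomicRanges::strand(b))[1L],
      count = 1L,
      overhang = pmin(w[-n], w[-1L]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$strand[out$strand == "*"] <- "."
  out
}

#' Classify splice-junction boundary motifs
#'
#' The donor motif is the first two intronic nucleotides and the acceptor
#' motif the last two, read in transcript orientation: on the minus strand
#' both are taken from the reverse complement of the intron. Junctions with
#' unknown strand (`"."`) are tried in both orientations; the orientation
#' producing a whitelisted motif (GT/AG, GC/AG, AT/AC) wins and its strand is
#' recorded, with ties or double misses left as strand `"."`, class `other`.
#'
#' @param junctions junction data.frame (see [extract_junctions()]).
#' @param genome `DNAStringSet` covering all junction coordinates.
#' @return The data.frame with `motif_class` (and possibly `strand`) filled.
#' @export
classify_motif <- function(junctions, genome) {
  whitelist <- c("GT/AG", "GC/AG", "AT/AC")
  motif_of <- function(chrom, start, end, strand) {
    if (!chrom %in% names(genome)) stop("junction chromosome not in genome: ", chrom)
    L <- length(genome[[chrom]])
    if (start < 0L || end > L || end - start < 4L)
      stop("junction outside genome bounds or too short: ",
           chrom, ":", start, "-", end)
    intron <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
    if (strand == "-") intron <- Biostrings::reverseComplement(intron)
    d <- as.character(Biostrings::subseq(intron, 1L, 2L))
    a <- as.character(Biostrings::subseq(intron, length(intron) - 1L,
                                         length(intron)))
    m <- paste0(d, "/", a)
    if (m %in% whitelist) m else "other"
  }
  for (i in seq_len(nrow(junctions))) {
    st <- junctions$strand[i]
    if (st %in% c("+", "-")) {
      junctions$motif_class[i] <- motif_of(junctions$chrom[i], junctions$start[i],
                                           junctions$end[i], st)
    } else {
      mp <- motif_of(junctions$chrom[i], junctions$start[i], junctions$end[i], "+")
      mm <- motif_of(junctions$chrom[i], junctions$start[i], junctions$end[i], "-")
      okp <- mp %in% whitelist; okm <- mm %in% whitelist
      if (okp && !okm) {
        junctions$strand[i] <- "+"; junctions$motif_class[i] <- mp
      } else if (okm && !okp) {
        junctions$strand[i] <- "-"; junctions$motif_class[i] <- mm
      } else {
        junctions$strand[i] <- "."; junctions$motif_class[i] <- "other"
      }
    }
  }
  junctions
}

#' Filter likely false-positive junctions with transparent rules
#'
#' A rule-based stand-in for a trained junction classifier: junctions are
#' kept when their motif is whitelisted, their read support and their anchor
#' overhang reach configurable minima. The partition is exhaustive and
#' disjoint.
#'
#' @param junctions classified junction data.frame.
#' @param motifs motif whitelist.
#' @param min_count minimum summed read count (default 2).
#' @param min_overhang minimum anchor overhang in nt (default 8); records
#'   with unknown overhang (`NA`) are not penalised by this rule.
#' @return list with elements `kept` and `discarded`.
#' @export
filter_junctions <- function(junctions,
                             motifs = c("GT/AG", "GC/AG", "AT/AC"),
                             min_count = 2L, min_overhang = 8L) {
  ok_motif <- junctions$motif_class %in% motifs
  ok_count <- junctions$read_count >= min_count
  ok_over <- is.na(junctions$max_overhang) | junctions$max_overhang >= min_overhang
  keep <- ok_motif & ok_count & ok_over
  list(kept = junctions[keep, , drop = FALSE],
       discarded = junctions[!keep, , drop = FALSE])
}

#' Flag junction novelty against the annotation
#'
#' A junction is annotated when its (chrom, start, end) exactly matches a
#' distinct intron enumerated from the gene models; any coordinate shift
#' makes it novel.
#'
#' @param junctions junction data.frame.
#' @param genes list of `GeneModel` (or a pre-computed intron data.frame
#'   from [enumerate_introns_all()]).
#' @return The data.frame with the `annotated` flag filled.
#' @export
annotate_novelty <- function(junctions, genes) {
  introns <- if (is.data.frame(genes)) genes else enumerate_introns_all(genes)
  ann <- intron_key(introns$chrom, introns$start, introns$end)
  junctions$annotated <- intron_key(junctions$chrom, junctions$start,
                                    junctions$end) %in% ann
  junctions
}

#' Summarize junction motif classes and novelty
#'
#' @param junctions classified, novelty-annotated junction data.frame.
#' @return data.frame of per-class junction counts and summed read counts,
#'   plus total and novel tallies as attributes-free extra rows.
#' @export
summarize_junctions <- function(junctions) {
  classes <- c("GT/AG", "GC/AG", "AT/AC", "other")
  out <- data.frame(
    motif_class = classes,
    n_junctions = vapply(classes, function(m) sum(junctions$motif_class == m), integer(1)),
    total_reads = vapply(classes, function(m)
      sum(junctions$read_count[junctions$motif_class == m]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_total") <- nrow(junctions)
  attr(out, "n_novel") <- sum(!junctions$annotated, na.rm = TRUE)
  out
}
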