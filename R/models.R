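#' dirseq: differential intron retention from short- and long-read RNA-seq
#'
#' Tools to quantify intron retention (IR) from per-base coverage and splice
#' junction counts, call differential intron retention (DIR) between stress
#' and control conditions with a pseudo-count-adjusted log-fold-change
#' statistic, classify alternative-splicing events from long-read isoform
#' models, cluster co-regulated retention profiles, and quantify isoform
#' ratios from droplet digital PCR counts. All genomic intervals are handled
#' internally as 0-based half-open; GFF/GTF (1-based inclusive) and BED
#' (0-based half-open) conventions are converted at I/O boundaries.
#'
#' @importFrom stats pt p.adjust var cor hclust cutree as.dist rbinom rnbinom
#'   runif rlnorm setNames complete.cases sd qnorm
#' @importFrom utils head tail write.table read.table
#' @keywords internal
"_PACKAGE"

#' Construct a transcript model
#'
#' A transcript is an ordered chain of exons on one strand. Exons are stored
#' as a two-column matrix of 0-based half-open intervals sorted by start;
#' consecutive exons must be separated by a positive-length gap (the intron).
#'
#' @param transcript_id character scalar.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column numeric matrix (or data.frame) of `start`,`end`
#'   intervals, 0-based half-open.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1L) stop("transcript ", transcript_id, ": needs >= 1 exon")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("transcript ", transcript_id, ": empty or inverted exon interval")
  if (nrow(exons) > 1L) {
    gaps <- exons[-1L, 1L] - exons[-nrow(exons), 2L]
    if (any(gaps <= 0L))
      stop("transcript ", transcript_id, ": overlapping or abutting exons")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(
    list(transcript_id = as.character(transcript_id), chrom = as.character(chrom),
         strand = strand, exons = exons),
    class = "TranscriptModel"
  )
}

#' Junction chain of a transcript
#'
#' @param tx `TranscriptModel`.
#' @return Two-column integer matrix of intron intervals (`start`,`end`,
#'   0-based half-open: first and one-past-last intronic base), one row per
#'   junction in left-to-right genomic order; zero rows for single-exon
#'   transcripts.
#' @export
transcript_junctions <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ex[-n, 2L], end = ex[-1L, 1L])
}

#' Construct a gene model
#'
#' @param gene_id character scalar.
#' @param transcripts list of `TranscriptModel`, all on the same chromosome
#'   and strand.
#' @return An object of class `GeneModel` whose `span` covers all exons.
#' @export
gene_model <- function(gene_id, transcripts) {
  if (length(transcripts) < 1L) stop("gene ", gene_id, ": needs >= 1 transcript")
  chrom <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strand <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chrom) != 1L || length(strand) != 1L)
    stop("gene ", gene_id, ": transcripts on mixed chrom/strand")
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  span <- c(
    min(vapply(transcripts, function(t) min(t$exons[, 1L]), integer(1))),
    max(vapply(transcripts, function(t) max(t$exons[, 2L]), integer(1)))
  )
  structure(
    list(gene_id = as.character(gene_id), chrom = chrom, strand = strand,
         transcripts = transcripts, span = span),
    class = "GeneModel"
  )
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s %s:%d-%d (%s), %d transcript(s)\n",
              x$gene_id, x$chrom, x$span[1L], x$span[2L], x$strand,
              length(x$transcripts)))
  invisible(x)
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s %s (%s), %d exon(s)\n",
              x$transcript_id, x$chrom, x$strand, nrow(x$exons)))
  invisible(x)
}

#' Enumerate the distinct introns of a gene
#'
#' Collects the exon gaps of every transcript of the gene and reduces them to
#' the distinct set keyed by (chrom, start, end, strand), so an intron shared
#' by several isoforms is reported once. Ordinals are assigned in transcript
#' (5'->3') orientation: ordinal 1 is the leftmost gap on a plus-strand gene
#' and the rightmost gap on a minus-strand gene. Donor/acceptor flank
#' positions are the interval boundaries oriented by strand (donor = the
#' boundary at the 5' end of the intron).
#'
#' @param gene `GeneModel`.
#' @param min_intron_length gaps shorter than this are treated as alignment
#'   artifacts and dropped (default 20 nt).
#' @return data.frame with columns `intron_id`, `chrom`, `start`, `end`,
#'   `strand`, `parent_gene`, `ordinal`, `flank_donor`, `flank_acceptor`.
#'   Zero rows when the gene has no multi-exon transcript.
#' @export
enumerate_introns <- function(gene, min_intron_length = 20L) {
  stopifnot(inherits(gene, "GeneModel"))
  jl <- lapply(gene$transcripts, transcript_junctions)
  j <- do.call(rbind, jl)
  empty <- data.frame(
    intron_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), parent_gene = character(0),
    ordinal = integer(0), flank_donor = integer(0), flank_acceptor = integer(0),
    stringsAsFactors = FALSE
  )
  if (is.null(j) || nrow(j) == 0L) return(empty)
  j <- unique(as.data.frame(j))
  j <- j[(j$end - j$start) >= min_intron_length, , drop = FALSE]
  if (nrow(j) == 0L) return(empty)
  j <- j[order(j$start, j$end), , drop = FALSE]
  n <- nrow(j)
  ordinal <- if (gene$strand == "+") seq_len(n) else rev(seq_len(n))
  donor <- if (gene$strand == "+") j$start else j$end
  acceptor <- if (gene$strand == "+") j$end else j$start
  out <- data.frame(
    intron_id = paste0(gene$gene_id, ".i", ordinal),
    chrom = gene$chrom, start = as.integer(j$start), end = as.integer(j$end),
    strand = gene$strand, parent_gene = gene$gene_id,
    ordinal = as.integer(ordinal),
    flank_donor = as.integer(donor), flank_acceptor = as.integer(acceptor),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Enumerate introns for a list of genes
#'
#' @param genes list of `GeneModel`.
#' @param min_intron_length see [enumerate_introns()].
#' @return One data.frame, rows ordered by (chrom, start, parent gene).
#' @export
enumerate_introns_all <- function(genes, min_intron_length = 20L) {
  tabs <- lapply(genes, enumerate_introns, min_intron_length = min_intron_length)
  out <- do.call(rbind, tabs)
  if (is.null(out) || nrow(out) == 0L) {
    return(enumerate_introns(genes[[1L]], min_intron_length)[0L, ])
  }
  out <- out[order(out$chrom, out$start, out$parent_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Canonical key used everywhere a junction must be matched to an intron.
intron_key <- function(chrom, start, end) paste(chrom, start, end, sep = ":")
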