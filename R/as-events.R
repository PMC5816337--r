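.chain_string <- function(tx) {
  j <- transcript_junctions(tx)
  if (nrow(j) == 0L) return("")
  paste(paste(j[, 1L], j[, 2L], sep = "-"), collapse = ";")
}

#' Collapse aligned transcript models into unique isoforms
#'
#' Multi-exon models sharing an identical (chrom, strand, junction chain)
#' are merged into one isoform whose terminal exons take the outermost
#' observed ends; single-exon models are merged when they overlap on the
#' same strand. Support records the number of merged input models. The
#' result is deterministic: isoforms are ordered by (chrom, start, chain)
#' and ids assigned in that order.
#'
#' @param models list of `TranscriptModel` (e.g. from [read_bed12()]).
#' @param stranded when `FALSE`, strand is ignored for grouping.
#' @return list of isoforms; each is a list with `isoform_id`, `model`
#'   (`TranscriptModel`), `support`, `source_gene` (`NA` until assigned).
#' @export
collapse_isoforms <- function(models, stranded = TRUE) {
  if (!length(models)) return(list())
  multi <- Filter(function(m) nrow(m$exons) > 1L, models)
  single <- Filter(function(m) nrow(m$exons) == 1L, models)
  out <- list()

  if (length(multi)) {
    keys <- vapply(multi, function(m) {
      paste(m$chrom, if (stranded) m$strand else "*", .chain_string(m), sep = "|")
    }, "")
    for (k in unique(keys)) {
      grp <- multi[keys == k]
      first <- grp[[1L]]
      j <- transcript_junctions(first)
      left <- min(vapply(grp, function(m) min(m$exons[, 1L]), integer(1)))
      right <- max(vapply(grp, function(m) max(m$exons[, 2L]), integer(1)))
      starts <- c(left, j[, 2L])
      ends <- c(j[, 1L], right)
      merged <- transcript_model(first$transcript_id, first$chrom, first$strand,
                                 cbind(starts, ends))
      out[[length(out) + 1L]] <- list(isoform_id = NA_character_, model = merged,
                                      support = length(grp), source_gene = NA_character_)
    }
  }

  if (length(single)) {
    keys <- vapply(single, function(m)
      paste(m$chrom, if (stranded) m$strand else "*", sep = "|"), "")
    for (k in unique(keys)) {
      grp <- single[keys == k]
      iv <- cbind(vapply(grp, function(m) m$exons[1L, 1L], integer(1)),
                  vapply(grp, function(m) m$exons[1L, 2L], integer(1)))
      o <- order(iv[, 1L], iv[, 2L])
      iv <- iv[o, , drop = FALSE]
      grp <- grp[o]
      cl <- integer(nrow(iv)); cur <- 1L; cl[1L] <- 1L
      if (nrow(iv) > 1L) {
        hi <- iv[1L, 2L]
        for (i in 2L:nrow(iv)) {
          if (iv[i, 1L] < hi) { cl[i] <- cur; hi <- max(hi, iv[i, 2L]) }
          else { cur <- cur + 1L; cl[i] <- cur; hi <- iv[i, 2L] }
        }
      }
      for (g in unique(cl)) {
        idx <- which(cl == g)
        first <- grp[[idx[1L]]]
        merged <- transcript_model(first$transcript_id, first$chrom, first$strand,
                                   cbind(min(iv[idx, 1L]), max(iv[idx, 2L])))
        out[[length(out) + 1L]] <- list(isoform_id = NA_character_, model = merged,
                                        support = length(idx), source_gene = NA_character_)
      }
    }
  }

  ord <- order(vapply(out, function(x) x$model$chrom, ""),
               vapply(out, function(x) min(x$model$exons[, 1L]), integer(1)),
               vapply(out, function(x) .chain_string(x$model), ""))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$isoform_id <- sprintf("iso%04d", i)
  out
}

.empty_events <- function() {
  data.frame(event_type = character(0), gene_id = character(0),
             isoform_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0),
             start2 = integer(0), end2 = integer(0),
             ref_transcript = character(0), stringsAsFactors = FALSE)
}

#' Classify alternative-splicing events of one isoform against a gene
#'
#' The isoform is compared against the reference transcript of the gene that
#' shares the most splice junctions with it (ties broken by longest exonic
#' length, then lexicographic id). Event definitions, with donor/acceptor in
#' transcript orientation:
#' \itemize{
#'   \item IR — a reference intron fully contained inside one isoform exon.
#'   \item Alt5 (alternative donor) — an isoform junction sharing its
#'     acceptor, but not its donor, with a reference junction.
#'   \item Alt3 (alternative acceptor) — shares the donor, differs at the
#'     acceptor.
#'   \item ES — one or more complete reference exons fall inside the gap
#'     spanned by a single isoform junction.
#'   \item MXE — an internal isoform exon overlapping no reference exon,
#'     whose flanking junctions span exactly one skipped reference exon: the
#'     isoform swaps one exon for another. Reported with both exon intervals
#'     and counted under ES in summaries.
#' }
#' Terminal-exon end differences are not events.
#'
#' @param isoform isoform list (from [collapse_isoforms()]) or a
#'   `TranscriptModel`.
#' @param reference_gene `GeneModel` overlapping the isoform on the same
#'   strand.
#' @return data.frame of events (possibly zero rows): `event_type`,
#'   `gene_id`, `isoform_id`, `chrom`, `start`, `end`, `start2`, `end2`
#'   (second exon interval, MXE only), `ref_transcript`.
#' @export
classify_events <- function(isoform, reference_gene) {
  tx <- if (inherits(isoform, "TranscriptModel")) isoform else isoform$model
  iso_id <- if (inherits(isoform, "TranscriptModel")) tx$transcript_id else isoform$isoform_id
  g <- reference_gene
  iso_span <- c(min(tx$exons[, 1L]), max(tx$exons[, 2L]))
  if (tx$chrom != g$chrom || tx$strand != g$strand ||
      iso_span[2L] <= g$span[1L] || iso_span[1L] >= g$span[2L])
    stop("isoform ", iso_id, " has no strand-consistent overlap with gene ",
         g$gene_id, ": likely misassignment")

  ij <- transcript_junctions(tx)
  ij_keys <- paste(ij[, 1L], ij[, 2L])
  # reference transcript: maximal shared junctions, then longest, then id
  cand <- g$transcripts[order(names(g$transcripts))]
  shared <- vapply(cand, function(r) {
    rj <- transcript_junctions(r)
    sum(paste(rj[, 1L], rj[, 2L]) %in% ij_keys)
  }, integer(1))
  exlen <- vapply(cand, function(r) sum(r$exons[, 2L] - r$exons[, 1L]), integer(1))
  ref <- cand[[order(-shared, -exlen, names(cand))[1L]]]
  rj <- transcript_junctions(ref)
  re <- ref$exons
  rj_keys <- paste(rj[, 1L], rj[, 2L])

  plus <- tx$strand == "+"
  ev <- list()
  add <- function(type, s, e, s2 = NA_integer_, e2 = NA_integer_) {
    ev[[length(ev) + 1L]] <<- data.frame(
      event_type = type, gene_id = g$gene_id, isoform_id = iso_id,
      chrom = tx$chrom, start = as.integer(s), end = as.integer(e),
      start2 = as.integer(s2), end2 = as.integer(e2),
      ref_transcript = ref$transcript_id, stringsAsFactors = FALSE)
  }

  # IR: reference intron inside one isoform exon (with flanking exonic
  # sequence on both sides, so the exon genuinely bridges the intron)
  for (r in seq_len(nrow(rj))) {
    s <- rj[r, 1L]; e <- rj[r, 2L]
    hit <- tx$exons[, 1L] < s & tx$exons[, 2L] > e
    if (any(hit)) add("IR", s, e)
  }

  # per-junction candidates, indexed so MXE reclassification can drop them
  jcand <- vector("list", nrow(ij))
  for (k in seq_len(nrow(ij))) {
    s <- ij[k, 1L]; e <- ij[k, 2L]
    if (paste(s, e) %in% rj_keys) next
    skipped <- which(re[, 1L] >= s & re[, 2L] <= e)
    if (length(skipped)) {
      jcand[[k]] <- data.frame(type = "ES", s = s, e = e, stringsAsFactors = FALSE)
      next
    }
    donor_i <- if (plus) s else e
    acceptor_i <- if (plus) e else s
    rdon <- if (plus) rj[, 1L] else rj[, 2L]
    racc <- if (plus) rj[, 2L] else rj[, 1L]
    if (acceptor_i %in% racc && !donor_i %in% rdon[racc == acceptor_i]) {
      jcand[[k]] <- data.frame(type = "Alt5", s = s, e = e, stringsAsFactors = FALSE)
    } else if (donor_i %in% rdon && !acceptor_i %in% racc[rdon == donor_i]) {
      jcand[[k]] <- data.frame(type = "Alt3", s = s, e = e, stringsAsFactors = FALSE)
    }
  }

  # MXE: internal isoform exon with no reference-exon overlap, flanked by
  # junctions that together skip exactly one reference exon
  n_ex <- nrow(tx$exons)
  drop_j <- logical(nrow(ij))
  if (n_ex >= 3L) {
    for (x in 2L:(n_ex - 1L)) {
      xs <- tx$exons[x, 1L]; xe <- tx$exons[x, 2L]
      overlaps_ref <- any(re[, 1L] < xe & re[, 2L] > xs)
      if (overlaps_ref) next
      jl <- x - 1L; jr <- x  # junctions flanking exon x
      span_s <- ij[jl, 1L]; span_e <- ij[jr, 2L]
      skipped <- which(re[, 1L] >= span_s & re[, 2L] <= span_e &
                         !(re[, 1L] < xe & re[, 2L] > xs))
      if (length(skipped) == 1L) {
        if (plus) add("MXE", re[skipped, 1L], re[skipped, 2L], xs, xe)
        else add("MXE", re[skipped, 1L], re[skipped, 2L], xs, xe)
        drop_j[c(jl, jr)] <- TRUE
      }
    }
  }
  for (k in seq_len(nrow(ij))) {
    if (drop_j[k] || is.null(jcand[[k]])) next
    add(jcand[[k]]$type, jcand[[k]]$s, jcand[[k]]$e)
  }

  if (!length(ev)) return(.empty_events())
  out <- do.call(rbind, ev)
  out <- out[order(out$start, out$event_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify events for many isoforms against an annotation
#'
#' Assigns each isoform to the gene whose span it overlaps on the same
#' strand (largest overlap wins) and classifies; isoforms overlapping no
#' gene are skipped (see [detect_novel_regions()] for those).
#'
#' @param isoforms list from [collapse_isoforms()].
#' @param genes list of `GeneModel`.
#' @return Combined event data.frame.
#' @export
classify_events_all <- function(isoforms, genes) {
  gch <- vapply(genes, `[[`, "", "chrom")
  gst <- vapply(genes, `[[`, "", "strand")
  gs <- vapply(genes, function(g) g$span[1L], integer(1))
  ge <- vapply(genes, function(g) g$span[2L], integer(1))
  evs <- list()
  for (iso in isoforms) {
    m <- iso$model
    s <- min(m$exons[, 1L]); e <- max(m$exons[, 2L])
    ov <- pmin(ge, e) - pmax(gs, s)
    ov[gch != m$chrom | gst != m$strand] <- -1L
    if (all(ov <= 0L)) next
    evs[[length(evs) + 1L]] <- classify_events(iso, genes[[which.max(ov)]])
  }
  if (!length(evs)) return(.empty_events())
  out <- do.call(rbind, evs)
  rownames(out) <- NULL
  out
}

#' Summarize the distribution of AS event classes
#'
#' MXE is a subcategory of ES and is folded into ES. Percentages are
#' `100 * count / total`, reported to one decimal. Given an event
#' data.frame, an isoform-level tally (each isoform counted once per class
#' it exhibits) is reported alongside the event-level tally, since an
#' isoform can carry several events of one class.
#'
#' @param x named counts (`c(IR=, Alt3=, Alt5=, ES=)`) or an event
#'   data.frame from [classify_events()].
#' @return data.frame with `event_type`, `count`, `percentage` (and, for
#'   event input, `n_isoforms`, `pct_isoforms`). Zero totals give `NA`
#'   percentages.
#' @export
summarize_event_distribution <- function(x) {
  classes <- c("IR", "Alt3", "Alt5", "ES")
  if (is.data.frame(x)) {
    et <- x$event_type
    et[et == "MXE"] <- "ES"
    counts <- vapply(classes, function(cl) sum(et == cl), numeric(1))
    iso_counts <- vapply(classes, function(cl)
      length(unique(x$isoform_id[et == cl])), numeric(1))
  } else {
    counts <- setNames(numeric(4L), classes)
    nm <- names(x)
    nm[nm == "MXE"] <- "ES"
    for (i in seq_along(x)) {
      if (!nm[i] %in% classes) stop("unknown event class: ", nm[i])
      counts[nm[i]] <- counts[nm[i]] + x[i]
    }
    iso_counts <- NULL
  }
  total <- sum(counts)
  pct <- if (total > 0) round(100 * counts / total, 1L) else rep(NA_real_, 4L)
  out <- data.frame(event_type = classes, count = as.numeric(counts),
                    percentage = as.numeric(pct), stringsAsFactors = FALSE)
  if (!is.null(iso_counts)) {
    iso_total <- sum(iso_counts)
    out$n_isoforms <- as.numeric(iso_counts)
    out$pct_isoforms <- if (iso_total > 0) round(100 * iso_counts / iso_total, 1L)
                        else rep(NA_real_, 4L)
  }
  rownames(out) <- NULL
  out
}

# Longest open reading frame, in codons (ATG..stop, stop excluded; an ORF
# still open at the sequence end counts to the end).
longest_orf_codons <- function(seq) {
  s <- as.character(seq)
  n <- nchar(s)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    pos <- seq(1L + frame, n - 2L, by = 3L)
    if (!length(pos)) next
    codons <- substring(s, pos, pos + 2L)
    open_at <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open_at) && codons[i] == "ATG") open_at <- i
      if (!is.na(open_at) && codons[i] %in% stops) {
        best <- max(best, i - open_at)
        open_at <- NA_integer_
      }
    }
    if (!is.na(open_at)) best <- max(best, length(codons) - open_at + 1L)
  }
  best
}

# Spliced (mature) sequence of a transcript model, 5'->3'.
spliced_sequence <- function(tx, genome) {
  chunks <- lapply(seq_len(nrow(tx$exons)), function(k)
    Biostrings::subseq(genome[[tx$chrom]], tx$exons[k, 1L] + 1L, tx$exons[k, 2L]))
  s <- do.call(Biostrings::xscat, chunks)
  if (tx$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Detect novel transcribed regions from collapsed isoforms
#'
#' Isoforms overlapping no annotated gene span are grouped into strand-aware
#' overlap clusters. A region shows AS when at least two of its isoforms
#' differ in junction chain; coding capacity is called from the longest ORF
#' across the region's spliced isoform sequences.
#'
#' @param isoforms list from [collapse_isoforms()].
#' @param genes list of `GeneModel`.
#' @param genome optional `DNAStringSet`; when absent `coding_capacity` is
#'   `NA`.
#' @param min_orf_codons ORF threshold for the coding call (default 100).
#' @return data.frame: `region_id`, `chrom`, `start`, `end`, `strand`,
#'   `n_isoforms`, `has_AS`, `coding_capacity`, `isoform_ids`.
#' @export
detect_novel_regions <- function(isoforms, genes, genome = NULL,
                                 min_orf_codons = 100L) {
  gch <- vapply(genes, `[[`, "", "chrom")
  gs <- vapply(genes, function(g) g$span[1L], integer(1))
  ge <- vapply(genes, function(g) g$span[2L], integer(1))
  inter <- Filter(function(iso) {
    m <- iso$model
    s <- min(m$exons[, 1L]); e <- max(m$exons[, 2L])
    !any(gch == m$chrom & gs < e & ge > s)
  }, isoforms)
  if (!length(inter)) {
    return(data.frame(region_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      n_isoforms = integer(0), has_AS = logical(0),
                      coding_capacity = character(0), isoform_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- vapply(inter, function(iso) paste(iso$model$chrom, iso$model$strand), "")
  rows <- list()
  for (k in unique(key)) {
    grp <- inter[key == k]
    iv <- cbind(vapply(grp, function(i) min(i$model$exons[, 1L]), integer(1)),
                vapply(grp, function(i) max(i$model$exons[, 2L]), integer(1)))
    o <- order(iv[, 1L], iv[, 2L]); iv <- iv[o, , drop = FALSE]; grp <- grp[o]
    cl <- integer(nrow(iv)); cur <- 1L; cl[1L] <- 1L
    if (nrow(iv) > 1L) {
      hi <- iv[1L, 2L]
      for (i in 2L:nrow(iv)) {
        if (iv[i, 1L] < hi) { cl[i] <- cur; hi <- max(hi, iv[i, 2L]) }
        else { cur <- cur + 1L; cl[i] <- cur; hi <- iv[i, 2L] }
      }
    }
    for (g in unique(cl)) {
      idx <- which(cl == g)
      members <- grp[idx]
      chains <- vapply(members, function(i) .chain_string(i$model), "")
      coding <- NA_character_
      if (!is.null(genome)) {
        orf <- max(vapply(members, function(i)
          longest_orf_codons(spliced_sequence(i$model, genome)), integer(1)))
        coding <- if (orf >= min_orf_codons) "coding" else "noncoding"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = NA_character_,
        chrom = members[[1L]]$model$chrom,
        start = min(iv[idx, 1L]), end = max(iv[idx, 2L]),
        strand = members[[1L]]$model$strand,
        n_isoforms = length(idx),
        has_AS = length(unique(chains)) >= 2L,
        coding_capacity = coding,
        isoform_ids = paste(vapply(members, `[[`, "", "isoform_id"), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  out$region_id <- sprintf("NR%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
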