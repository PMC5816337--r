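#' Construct a coverage bundle for one sequencing library
#'
#' Holds the short-read evidence of one replicate of one condition: per-base
#' depth vectors keyed by chromosome and read counts for spliced junctions
#' keyed by intron coordinates. The library size used for normalization is
#' the total number of aligned bases (the sum of all depth values).
#'
#' @param sample_id character scalar.
#' @param condition condition label (`"control"` or a stress label).
#' @param tissue,phase optional design labels (default `""`).
#' @param replicate integer replicate index.
#' @param depth named list of numeric per-base depth vectors (0-based
#'   position `i` of the chromosome is element `i + 1`).
#' @param junction_counts named numeric vector; names are
#'   `"chrom:start:end"` intron keys (see [extract_junctions()] coordinates).
#' @return An object of class `CoverageBundle`.
#' @export
coverage_bundle <- function(sample_id, condition, replicate, depth,
                            junction_counts, tissue = "", phase = "") {
  stopifnot(is.list(depth), !is.null(names(depth)))
  if (any(vapply(depth, function(v) any(v < 0), logical(1))))
    stop("negative depth values in bundle ", sample_id)
  structure(
    list(sample_id = as.character(sample_id), condition = as.character(condition),
         tissue = as.character(tissue), phase = as.character(phase),
         replicate = as.integer(replicate), depth = depth,
         junction_counts = junction_counts,
         lib_size = sum(vapply(depth, sum, numeric(1)))),
    class = "CoverageBundle"
  )
}

#' @export
print.CoverageBundle <- function(x, ...) {
  cat(sprintf("CoverageBundle %s [%s%s rep %d], %d chrom(s), %.3g aligned bases\n",
              x$sample_id, x$condition,
              if (nzchar(x$tissue)) paste0(", ", x$tissue, "/", x$phase) else "",
              x$replicate, length(x$depth), x$lib_size))
  invisible(x)
}

#' Measure intron retention in one bundle
#'
#' The relative IR score of an intron is its average per-base read depth
#' divided by the number of reads supporting that intron's spliced junction
#' (its exact donor-acceptor pair) — a retention:splicing odds measure.
#' When no junction reads exist but intronic coverage does, the denominator
#' falls back to a pseudo-count of 1 and the record is flagged
#' `no_splice_support`; introns with neither coverage nor junction reads are
#' unscored (`NA`).
#'
#' @param bundle `CoverageBundle`.
#' @param introns intron data.frame from [enumerate_introns_all()] (a single
#'   row works for one intron).
#' @return data.frame: `intron_id`, `sample_id`, `mean_depth`,
#'   `junction_reads`, `ir_ratio`, `no_splice_support`.
#' @export
measure_intron <- function(bundle, introns) {
  stopifnot(inherits(bundle, "CoverageBundle"))
  n <- nrow(introns)
  mean_depth <- numeric(n)
  cums <- lapply(bundle$depth, function(v) c(0, cumsum(v)))
  for (ch in unique(introns$chrom)) {
    if (!ch %in% names(cums))
      stop("intron(s) on chromosome absent from bundle ", bundle$sample_id, ": ",
           introns$intron_id[introns$chrom == ch][1L])
    idx <- which(introns$chrom == ch)
    cs <- cums[[ch]]
    L <- length(cs) - 1L
    if (any(introns$end[idx] > L))
      stop("intron beyond coverage bounds in bundle ", bundle$sample_id, ": ",
           introns$intron_id[idx[introns$end[idx] > L][1L]])
    mean_depth[idx] <- (cs[introns$end[idx] + 1L] - cs[introns$start[idx] + 1L]) /
      (introns$end[idx] - introns$start[idx])
  }
  keys <- intron_key(introns$chrom, introns$start, introns$end)
  jr <- unname(bundle$junction_counts[keys])
  jr[is.na(jr)] <- 0
  ratio <- ifelse(jr > 0, mean_depth / jr,
                  ifelse(mean_depth > 0, mean_depth / 1, NA_real_))
  data.frame(
    intron_id = introns$intron_id, sample_id = bundle$sample_id,
    mean_depth = mean_depth, junction_reads = as.numeric(jr),
    ir_ratio = ratio,
    no_splice_support = jr == 0 & mean_depth > 0,
    stringsAsFactors = FALSE
  )
}

#' Splicing ratio difference
#'
#' @param r_control,r_treatment relative IR scores.
#' @return `r_control - r_treatment`; antisymmetric under argument swap. A
#'   positive value means the control retains more, a negative value means
#'   retention increased under treatment.
#' @export
splicing_ratio_difference <- function(r_control, r_treatment) {
  stopifnot(all(is.finite(r_control)), all(is.finite(r_treatment)))
  r_control - r_treatment
}

#' Pseudo-count-adjusted log-fold change of intron coverage
#'
#' For each pseudo-count `c` in the grid, computes
#' `aLFC(c) = log2((m_t + c) / (m_c + c)) / SE(c)` where `m_t`, `m_c` are
#' the replicate means of intron depth on the treatment and control side and
#' `SE(c)` is the pooled standard error of the replicate `log2(depth + c)`
#' values, floored at `se_floor`. The reported statistic is the `aLFC` of
#' minimal absolute value over the grid — the most conservative stabilized
#' effect — together with the pseudo-count achieving it.
#'
#' @param depth_treatment,depth_control numeric replicate vectors (>= 1
#'   value each; with a single replicate the SE floor carries the scaling).
#' @param pseudo_grid positive pseudo-count grid (default
#'   `c(1, 2, 4, 8, 16, 32)`).
#' @param se_floor lower bound on the standard-error measure (default 0.05).
#' @return list with `alfc` and `pseudo_count`.
#' @export
adjusted_lfc <- function(depth_treatment, depth_control,
                         pseudo_grid = c(1, 2, 4, 8, 16, 32),
                         se_floor = 0.05) {
  if (!length(depth_treatment) || !length(depth_control))
    stop("adjusted_lfc needs >= 1 replicate per side")
  if (!length(pseudo_grid) || any(pseudo_grid <= 0))
    stop("pseudo_grid must be non-empty and positive")
  nt <- length(depth_treatment); nc <- length(depth_control)
  best <- NULL
  for (cc in pseudo_grid) {
    m_t <- mean(depth_treatment); m_c <- mean(depth_control)
    vt <- if (nt > 1L) var(log2(depth_treatment + cc)) else 0
    vc <- if (nc > 1L) var(log2(depth_control + cc)) else 0
    se <- max(sqrt(vt / nt + vc / nc), se_floor)
    a <- log2((m_t + cc) / (m_c + cc)) / se
    if (is.null(best) || abs(a) < abs(best$alfc)) best <- list(alfc = a, pseudo_count = cc)
  }
  best
}

#' Test for differential intron retention between two conditions
#'
#' The default parametric path is a two-sided Welch t-test on the replicate
#' values (the caller supplies expression-normalized log measures, see
#' [call_dirs()]); it requires >= 2 replicates per side, otherwise `NA` is
#' returned with a warning. The permutation path enumerates all label
#' assignments (requires >= 6 total exchangeable units) and uses the
#' absolute mean difference as statistic, so identical data give p = 1.
#'
#' @param values_treatment,values_control numeric replicate vectors.
#' @param method `"welch"` (default) or `"permutation"`.
#' @return two-sided p-value in `[0, 1]`, or `NA`.
#' @export
dir_test <- function(values_treatment, values_control,
                     method = c("welch", "permutation")) {
  method <- match.arg(method)
  nt <- length(values_treatment); nc <- length(values_control)
  if (method == "welch") {
    if (nt < 2L || nc < 2L) {
      warning("dir_test: < 2 replicates on one side; returning NA")
      return(NA_real_)
    }
    mt <- mean(values_treatment); mc <- mean(values_control)
    vt <- var(values_treatment); vc <- var(values_control)
    se2 <- vt / nt + vc / nc
    if (se2 == 0) return(if (mt == mc) 1 else 0)
    tstat <- (mt - mc) / sqrt(se2)
    df <- se2^2 / ((vt / nt)^2 / (nt - 1L) + (vc / nc)^2 / (nc - 1L))
    2 * pt(-abs(tstat), df)
  } else {
    if (nt + nc < 6L) {
      warning("dir_test: < 6 exchangeable units for permutation; returning NA")
      return(NA_real_)
    }
    pooled <- c(values_treatment, values_control)
    obs <- abs(mean(values_treatment) - mean(values_control))
    idx <- utils::combn(nt + nc, nt)
    stats <- apply(idx, 2L, function(sel)
      abs(mean(pooled[sel]) - mean(pooled[-sel])))
    mean(stats >= obs - 1e-12)
  }
}

#' Fivefold expression filter
#'
#' Introns are only scored for DIR in genes whose expression changes at most
#' `max_fold` in either direction between the conditions, so that coverage
#' shifts from transcription are not mistaken for retention shifts.
#'
#' @param expr_control,expr_treatment positive normalized expression values.
#' @param max_fold maximum tolerated fold change (default 5).
#' @return `TRUE` when `max(fc, 1/fc) <= max_fold`.
#' @export
expression_filter <- function(expr_control, expr_treatment, max_fold = 5) {
  if (any(c(expr_control, expr_treatment) <= 0))
    stop("expression_filter: expressions must be > 0")
  fc <- expr_treatment / expr_control
  pmax(fc, 1 / fc) <= max_fold
}

# Per-gene exon-union intervals, for expression summaries.
.gene_exon_union <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, `[[`, "exons"))
  ex <- ex[order(ex[, 1L], ex[, 2L]), , drop = FALSE]
  out <- ex[1L, , drop = FALSE]
  if (nrow(ex) > 1L) for (i in 2L:nrow(ex)) {
    if (ex[i, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], ex[i, 2L])
    } else out <- rbind(out, ex[i, , drop = FALSE])
  }
  out
}

# Median-of-ratios size factors from a genes x samples matrix of mean
# exonic depths: each sample's factor is the median ratio of its gene
# depths to the per-gene geometric mean across samples. Robust to a
# minority of strongly regulated genes, unlike total-count scaling.
.size_factors <- function(expr_mat) {
  gm <- exp(rowMeans(log(expr_mat)))
  use <- is.finite(gm) & gm > 0
  if (!any(use)) return(rep(1, ncol(expr_mat)))
  sf <- apply(expr_mat[use, , drop = FALSE] / gm[use], 2L, stats::median)
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf
}

# Mean exonic depth per gene for one bundle (raw, unnormalized).
.gene_expression <- function(bundle, genes) {
  cums <- lapply(bundle$depth, function(v) c(0, cumsum(v)))
  vapply(genes, function(g) {
    cs <- cums[[g$chrom]]
    u <- .gene_exon_union(g)
    tot <- sum(cs[u[, 2L] + 1L] - cs[u[, 1L] + 1L])
    tot / sum(u[, 2L] - u[, 1L])
  }, numeric(1))
}

#' Call differential intron retention events across a sample set
#'
#' For every (tissue, stress, phase) treatment group, each distinct intron
#' of the annotation is compared against the same tissue's controls:
#' \enumerate{
#'   \item depths are library-size normalized with median-of-ratios size
#'     factors computed from per-gene exonic depths (robust to a minority of
#'     strongly regulated genes, which bias total-count scaling);
#'   \item genes failing the `max_fold` expression filter are excluded;
#'   \item the pseudo-count-adjusted log-fold change ([adjusted_lfc()]) on
#'     the normalized intron depths gives the effect and its direction;
#'   \item [dir_test()] on the replicate within-sample ratios
#'     `log2((intron mean depth + 1) / (gene mean exonic depth + 1))` —
#'     library scale cancels inside each sample — gives the p-value,
#'     Benjamini-Hochberg adjusted within the comparison;
#'   \item the splicing ratio difference is the control-mean minus
#'     treatment-mean relative IR score.
#' }
#'
#' @param bundles list of `CoverageBundle`; controls are the bundles whose
#'   `condition == control_label`, matched to treatments by tissue.
#' @param genes list of `GeneModel`.
#' @param alpha significance cutoff on the adjusted p-value (default 0.05).
#' @param max_fold expression filter threshold (default 5).
#' @param pseudo_grid,se_floor see [adjusted_lfc()].
#' @param method see [dir_test()].
#' @param control_label condition label identifying controls.
#' @param min_intron_length see [enumerate_introns()].
#' @return data.frame with one row per scored intron per comparison:
#'   `intron_id`, `gene_id`, `comparison`, `tissue`, `stress`, `phase`,
#'   `alfc`, `pseudo_count`, `p_value`, `p_adj`, `direction`,
#'   `ratio_difference`, `passed_expression_filter`, `significant`.
#' @export
call_dirs <- function(bundles, genes, alpha = 0.05, max_fold = 5,
                      pseudo_grid = c(1, 2, 4, 8, 16, 32), se_floor = 0.05,
                      method = "welch", control_label = "control",
                      min_intron_length = 20L) {
  introns <- enumerate_introns_all(genes, min_intron_length)
  if (nrow(introns) == 0L) stop("annotation yields no introns to score")
  conds <- vapply(bundles, `[[`, "", "condition")
  tissues <- vapply(bundles, `[[`, "", "tissue")
  phases <- vapply(bundles, `[[`, "", "phase")
  is_ctrl <- conds == control_label
  if (!any(is_ctrl)) stop("no control bundles (condition == '", control_label, "')")
  if (all(is_ctrl)) stop("no treatment bundles")

  meas <- lapply(bundles, measure_intron, introns = introns)
  gexpr <- lapply(bundles, .gene_expression, genes = genes)
  nf <- 1 / .size_factors(do.call(cbind, gexpr))
  gene_ids <- vapply(genes, `[[`, "", "gene_id")
  intron_gene_idx <- match(introns$parent_gene, gene_ids)

  groups <- unique(data.frame(tissue = tissues[!is_ctrl], stress = conds[!is_ctrl],
                              phase = phases[!is_ctrl], stringsAsFactors = FALSE))
  groups <- groups[order(groups$tissue, groups$stress, groups$phase), , drop = FALSE]

  res <- list()
  for (gi in seq_len(nrow(groups))) {
    tis <- groups$tissue[gi]; str_ <- groups$stress[gi]; pha <- groups$phase[gi]
    t_idx <- which(conds == str_ & tissues == tis & phases == pha)
    c_idx <- which(is_ctrl & tissues == tis)
    if (!length(c_idx)) stop("no controls for tissue '", tis, "'")
    cmp <- paste(tis, str_, pha, sep = ":")

    dmat_t <- vapply(t_idx, function(i) meas[[i]]$mean_depth * nf[i],
                     numeric(nrow(introns)))
    dmat_c <- vapply(c_idx, function(i) meas[[i]]$mean_depth * nf[i],
                     numeric(nrow(introns)))
    emat_t <- vapply(t_idx, function(i) gexpr[[i]] * nf[i], numeric(length(genes)))
    emat_c <- vapply(c_idx, function(i) gexpr[[i]] * nf[i], numeric(length(genes)))
    rmat_t <- vapply(t_idx, function(i) meas[[i]]$ir_ratio, numeric(nrow(introns)))
    rmat_c <- vapply(c_idx, function(i) meas[[i]]$ir_ratio, numeric(nrow(introns)))
    if (nrow(introns) == 1L) {  # vapply drops to vector shape consistency
      dmat_t <- matrix(dmat_t, 1L); dmat_c <- matrix(dmat_c, 1L)
      rmat_t <- matrix(rmat_t, 1L); rmat_c <- matrix(rmat_c, 1L)
    }
    if (length(genes) == 1L) { emat_t <- matrix(emat_t, 1L); emat_c <- matrix(emat_c, 1L) }

    ge_t <- rowMeans(emat_t); ge_c <- rowMeans(emat_c)
    expressed <- ge_t > 0 & ge_c > 0
    passed_gene <- expressed
    passed_gene[expressed] <- expression_filter(ge_c[expressed], ge_t[expressed],
                                                max_fold = max_fold)
    passed <- passed_gene[intron_gene_idx]

    n <- nrow(introns)
    alfc <- rep(NA_real_, n); pc <- rep(NA_real_, n); pv <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      if (!passed[k]) next
      al <- adjusted_lfc(dmat_t[k, ], dmat_c[k, ], pseudo_grid, se_floor)
      alfc[k] <- al$alfc; pc[k] <- al$pseudo_count
      g <- intron_gene_idx[k]
      # within-sample retention measure: library scale cancels exactly
      vt <- log2((dmat_t[k, ] / nf[t_idx] + 1) / (emat_t[g, ] / nf[t_idx] + 1))
      vc <- log2((dmat_c[k, ] / nf[c_idx] + 1) / (emat_c[g, ] / nf[c_idx] + 1))
      pv[k] <- suppressWarnings(dir_test(vt, vc, method = method))
    }
    padj <- rep(NA_real_, n)
    tested <- which(!is.na(pv))
    padj[tested] <- p.adjust(pv[tested], method = "BH")
    dr <- rowMeans(rmat_c, na.rm = TRUE) - rowMeans(rmat_t, na.rm = TRUE)

    res[[gi]] <- data.frame(
      intron_id = introns$intron_id, gene_id = introns$parent_gene,
      comparison = cmp, tissue = tis, stress = str_, phase = pha,
      alfc = alfc, pseudo_count = pc, p_value = pv, p_adj = padj,
      direction = ifelse(is.na(alfc), NA_character_,
                         ifelse(alfc >= 0, "increased IR", "decreased IR")),
      ratio_difference = dr,
      passed_expression_filter = passed,
      significant = !is.na(padj) & padj < alpha,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Table-style bookkeeping of DIR calls
#'
#' Per comparison and pooled: the number of significant DIR events, the
#' number of non-redundant associated loci (unique genes), and the number of
#' loci carrying two or more DIRs, plus the mean DIRs per locus.
#'
#' @param dir_results output of [call_dirs()].
#' @return data.frame, one row per comparison plus a `"combined"` row.
#' @export
summarize_dir_calls <- function(dir_results) {
  sig <- dir_results[dir_results$significant, , drop = FALSE]
  one <- function(d, label) {
    per_gene <- table(unique(d[c("intron_id", "gene_id")])$gene_id)
    data.frame(comparison = label,
               n_events = nrow(unique(d[c("intron_id", "comparison")])),
               n_loci = length(per_gene),
               n_multi_dir_loci = sum(per_gene >= 2L),
               mean_dirs_per_locus = if (length(per_gene)) round(mean(per_gene), 2) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(split(sig, sig$comparison), function(d) one(d, d$comparison[1L]))
  rows <- rows[order(names(rows))]
  combined <- one(sig, "combined")
  combined$n_events <- length(unique(paste(sig$intron_id, sig$comparison)))
  out <- rbind(do.call(rbind, rows), combined)
  rownames(out) <- NULL
  out
}

#' Set intersections of DIR-associated loci across comparisons
#'
#' Groups significant calls by a design factor (stress by default) and
#' reports, for every combination of groups, how many loci are shared by
#' all of them and how many are exclusive to exactly that combination —
#' the bookkeeping behind multi-way Venn summaries.
#'
#' @param dir_results output of [call_dirs()].
#' @param by grouping column (`"stress"`, `"tissue"`, `"phase"` or
#'   `"comparison"`).
#' @param what count `"gene_id"` (loci, default) or `"intron_id"` (events).
#' @return data.frame: `combination`, `n_groups`, `n_common`, `n_exclusive`.
#' @export
dir_intersections <- function(dir_results, by = "stress", what = "gene_id") {
  sig <- dir_results[dir_results$significant, , drop = FALSE]
  sets <- lapply(split(sig[[what]], sig[[by]]), unique)
  sets <- sets[order(names(sets))]
  gn <- names(sets)
  combos <- unlist(lapply(seq_along(gn), function(k)
    utils::combn(gn, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(combos, function(cb) {
    inside <- Reduce(intersect, sets[cb])
    outside <- unique(unlist(sets[setdiff(gn, cb)]))
    data.frame(combination = paste(cb, collapse = "&"),
               n_groups = length(cb),
               n_common = length(inside),
               n_exclusive = length(setdiff(inside, outside)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
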