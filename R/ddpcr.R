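#' Read a ddPCR wells table
#'
#' Tab-separated with header: `well_id`, `target`, `condition`,
#' `droplets_total`, `droplets_positive`, and optionally `dilution_factor`
#' (default 1).
#'
#' @param path file path.
#' @return data.frame of wells.
#' @export
read_wells_tsv <- function(path) {
  w <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("well_id", "target", "condition", "droplets_total", "droplets_positive")
  miss <- setdiff(need, names(w))
  if (length(miss)) stop("wells table missing column(s): ", paste(miss, collapse = ", "))
  if (!"dilution_factor" %in% names(w)) w$dilution_factor <- 1
  w
}

#' Absolute concentration from droplet counts by Poisson correction
#'
#' Droplet digital PCR partitions the sample into droplets; template
#' molecules land in droplets as a Poisson process, so the mean copies per
#' droplet is `lambda = -ln(1 - positive/total)` and the concentration is
#' `lambda / droplet_volume * dilution_factor` in copies per microlitre.
#' A normal-approximation confidence interval on the log scale is reported
#' alongside (standard ddPCR practice; not used for gating).
#'
#' @param droplets_positive,droplets_total droplet counts (vectors allowed).
#' @param droplet_volume_nl droplet volume in nanolitres (default 0.85,
#'   QX200-class instruments).
#' @param dilution_factor pre-partition dilution to scale back up.
#' @param conf confidence level (default 0.95).
#' @return data.frame: `lambda` (copies per droplet), `copies_per_ul`,
#'   `ci_lower`, `ci_upper` (copies per microlitre).
#' @export
poisson_concentration <- function(droplets_positive, droplets_total,
                                  droplet_volume_nl = 0.85,
                                  dilution_factor = 1, conf = 0.95) {
  if (any(droplets_total <= 0)) stop("droplets_total must be > 0")
  if (any(droplets_positive < 0) || any(droplets_positive > droplets_total))
    stop("droplets_positive must lie in [0, droplets_total]")
  if (any(droplets_positive == droplets_total))
    stop("all droplets positive: assay saturated, concentration unbounded")
  if (droplet_volume_nl <= 0 || any(dilution_factor <= 0))
    stop("droplet volume and dilution factor must be > 0")
  p <- droplets_positive / droplets_total
  lambda <- -log(1 - p)
  vol_ul <- droplet_volume_nl * 1e-3
  conc <- lambda / vol_ul * dilution_factor
  # delta method: var(lambda_hat) = p / ((1 - p) * n); CI on log(lambda)
  se_lambda <- sqrt(p / ((1 - p) * droplets_total))
  z <- qnorm(1 - (1 - conf) / 2)
  lo <- hi <- rep(NA_real_, length(lambda))
  pos <- lambda > 0
  lo[pos] <- exp(log(lambda[pos]) - z * se_lambda[pos] / lambda[pos]) / vol_ul *
    dilution_factor
  hi[pos] <- exp(log(lambda[pos]) + z * se_lambda[pos] / lambda[pos]) / vol_ul *
    dilution_factor
  lo[!pos] <- 0
  data.frame(lambda = lambda, copies_per_ul = conc,
             ci_lower = lo, ci_upper = hi)
}

#' Relative isoform ratio
#'
#' @param spliced,retained absolute concentrations (copies per microlitre)
#'   of the fully spliced and the intron-retaining isoform.
#' @return `100 * retained / spliced` (percent); `NA` when `spliced` is 0.
#' @export
isoform_ratio <- function(spliced, retained) {
  if (any(spliced < 0) || any(retained < 0))
    stop("concentrations must be >= 0")
  ifelse(spliced == 0, NA_real_, 100 * retained / spliced)
}

#' Quantify isoform concentrations and retention ratios from wells
#'
#' Replicate wells of the same (condition, target) are combined by pooling
#' droplet counts before Poisson correction, which preserves the Poisson
#' likelihood (averaging concentrations would not). The `spliced_target`
#' provides the denominator for each condition's retention ratios.
#'
#' @param wells data.frame from [read_wells_tsv()].
#' @param spliced_target target label of the fully spliced assay
#'   (default `"spliced"`).
#' @inheritParams poisson_concentration
#' @return data.frame: `condition`, `target`, `droplets_total`,
#'   `droplets_positive`, `lambda`, `copies_per_ul`, `relative_ratio`
#'   (percent vs the spliced assay; `NA` for the spliced rows themselves).
#' @export
quantify_ddpcr <- function(wells, spliced_target = "spliced",
                           droplet_volume_nl = 0.85) {
  if (any(wells$dilution_factor != wells$dilution_factor[1L]))
    stop("pooling wells with mixed dilution factors is not supported")
  agg <- stats::aggregate(
    cbind(droplets_total, droplets_positive) ~ condition + target,
    data = wells, FUN = sum)
  agg <- agg[order(agg$condition, agg$target), , drop = FALSE]
  pc <- poisson_concentration(agg$droplets_positive, agg$droplets_total,
                              droplet_volume_nl = droplet_volume_nl,
                              dilution_factor = wells$dilution_factor[1L])
  agg$lambda <- pc$lambda
  agg$copies_per_ul <- pc$copies_per_ul
  agg$relative_ratio <- NA_real_
  for (cond in unique(agg$condition)) {
    sp <- agg$copies_per_ul[agg$condition == cond & agg$target == spliced_target]
    if (!length(sp)) stop("condition '", cond, "' lacks the spliced assay")
    sel <- agg$condition == cond & agg$target != spliced_target
    agg$relative_ratio[sel] <- isoform_ratio(sp, agg$copies_per_ul[sel])
  }
  rownames(agg) <- NULL
  agg
}

#' Detect condition-dependent isoform-ratio switches
#'
#' For each retained-intron target and non-baseline condition, reports the
#' fold change of spliced copy number and of the relative retention ratio
#' versus the baseline; a switch is flagged when the two fold changes lie
#' on opposite sides of 1 — the spliced isoform and the retention ratio
#' move in opposite directions.
#'
#' @param ratios output of [quantify_ddpcr()].
#' @param baseline baseline condition label (default `"control"`).
#' @param spliced_target target label of the fully spliced assay.
#' @return data.frame: `target`, `condition`, `fold_spliced`, `fold_ratio`,
#'   `switch`.
#' @export
ratio_switch <- function(ratios, baseline = "control",
                         spliced_target = "spliced") {
  if (!baseline %in% ratios$condition) stop("baseline condition '", baseline,
                                            "' absent from ratios")
  base <- ratios[ratios$condition == baseline, , drop = FALSE]
  sp_base <- base$copies_per_ul[base$target == spliced_target]
  if (!length(sp_base)) stop("baseline lacks the spliced assay")
  rows <- list()
  for (tg in setdiff(unique(ratios$target), spliced_target)) {
    r_base <- base$relative_ratio[base$target == tg]
    if (!length(r_base)) stop("baseline lacks target '", tg, "'")
    for (cond in setdiff(unique(ratios$condition), baseline)) {
      sp <- ratios$copies_per_ul[ratios$condition == cond &
                                   ratios$target == spliced_target]
      rr <- ratios$relative_ratio[ratios$condition == cond & ratios$target == tg]
      if (!length(sp) || !length(rr)) next
      fs <- sp / sp_base
      fr <- rr / r_base
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, condition = cond, fold_spliced = fs, fold_ratio = fr,
        switch = isTRUE((fs - 1) * (fr - 1) < 0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
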