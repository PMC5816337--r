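#' Assemble the DIR-by-condition splicing-ratio-difference matrix
#'
#' Rows are introns, columns are comparison labels (tissue x stress x
#' phase), values are the splicing ratio differences. Rows present in fewer
#' than `min_present` of the columns are dropped (with a message), since a
#' profile observed in too few conditions cannot be clustered meaningfully.
#'
#' @param dir_results output of [call_dirs()], usually filtered to
#'   significant calls by the caller.
#' @param min_present minimum fraction of non-missing columns per row
#'   (default 0.5).
#' @return numeric matrix with `NA` for missing cells, rows and columns in
#'   deterministic sorted order.
#' @export
build_ratio_matrix <- function(dir_results, min_present = 0.5) {
  d <- dir_results[!is.na(dir_results$ratio_difference), , drop = FALSE]
  key <- paste(d$intron_id, d$comparison, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    for (k in unique(key[dup])) {
      v <- d$ratio_difference[key == k]
      if (length(unique(v)) > 1L)
        stop("conflicting ratio differences for ", sub("\r", " in ", k))
    }
    d <- d[!dup, , drop = FALSE]
  }
  rows <- sort(unique(d$intron_id)); cols <- sort(unique(d$comparison))
  m <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(match(d$intron_id, rows), match(d$comparison, cols))] <- d$ratio_difference
  present <- rowMeans(!is.na(m))
  if (any(present < min_present)) {
    message(sum(present < min_present),
            " intron profile(s) dropped for missingness (< ",
            min_present * 100, "% of conditions)")
    m <- m[present >= min_present, , drop = FALSE]
  }
  m
}

# Mean pairwise Pearson correlation of the rows of a matrix.
.coherence <- function(m) {
  cm <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
  mean(cm[upper.tri(cm)], na.rm = TRUE)
}

#' Cluster co-regulated DIR profiles
#'
#' Rows are z-scored, distances are correlation distances (1 - Pearson),
#' and average-linkage hierarchical clustering is cut at `cut_height`.
#' Zero-variance rows are excluded with a warning (their correlation is
#' undefined); singleton clusters are discarded. The procedure is
#' deterministic and invariant to row order and to affine rescaling of any
#' row.
#'
#' @param matrix ratio matrix from [build_ratio_matrix()].
#' @param cut_height tree cut on correlation distance (default 0.3, i.e.
#'   members correlate at >= 0.7 with their cluster neighbourhood).
#' @param min_size minimum cluster size to report (default 2).
#' @return list of clusters, each a list with `cluster_id`, `members`,
#'   `centroid` (mean z-scored profile), `coherence` (mean pairwise
#'   correlation), `p_value` (`NA` until [coreg_significance()]).
#' @export
cluster_profiles <- function(matrix, cut_height = 0.3, min_size = 2L) {
  if (nrow(matrix) < 2L) stop("need >= 2 profiles to cluster")
  sds <- apply(matrix, 1L, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    warning(sum(sds == 0 | is.na(sds)), " constant profile(s) excluded from clustering")
    matrix <- matrix[!(sds == 0 | is.na(sds)), , drop = FALSE]
    if (nrow(matrix) < 2L) return(list())
  }
  z <- t(scale(t(matrix)))
  cm <- suppressWarnings(cor(t(z), use = "pairwise.complete.obs"))
  d <- as.dist(1 - cm)
  d[is.na(d)] <- 2  # uncorrelatable pairs are maximally distant
  hc <- hclust(d, method = "average")
  grp <- cutree(hc, h = cut_height)
  out <- list()
  for (g in sort(unique(grp))) {
    members <- rownames(matrix)[grp == g]
    if (length(members) < min_size) next
    sub <- z[members, , drop = FALSE]
    out[[length(out) + 1L]] <- list(
      cluster_id = sprintf("C%03d", length(out) + 1L),
      members = members,
      centroid = colMeans(sub, na.rm = TRUE),
      coherence = .coherence(sub),
      p_value = NA_real_
    )
  }
  out
}

#' Permutation significance of cluster coherence
#'
#' The coherence statistic is the mean pairwise Pearson correlation of the
#' member profiles. The null distribution is built by independently
#' permuting each member row's condition labels, which preserves each
#' profile's marginal distribution while destroying coordination. The
#' p-value uses the add-one rule `p = (1 + #null >= observed) /
#' (1 + n_permutations)`, so it is never exactly zero.
#'
#' @param cluster one cluster from [cluster_profiles()].
#' @param matrix the ratio matrix the cluster was built from.
#' @param n_permutations at least 200 (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return the cluster with `p_value` filled.
#' @export
coreg_significance <- function(cluster, matrix, n_permutations = 1000L, seed) {
  if (length(cluster$members) < 2L) stop("cluster has < 2 members")
  if (n_permutations < 200L) stop("need >= 200 permutations")
  if (missing(seed)) stop("a seed is required for the permutation stream")
  sub <- matrix[cluster$members, , drop = FALSE]
  obs <- .coherence(sub)
  set.seed(seed)
  k <- ncol(sub); nr <- nrow(sub)
  ge <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sub
    for (r in seq_len(nr)) perm[r, ] <- sub[r, sample.int(k)]
    if (.coherence(perm) >= obs - 1e-12) ge <- ge + 1L
  }
  cluster$p_value <- (1 + ge) / (1 + n_permutations)
  cluster
}

#' Cluster profiles and attach permutation p-values
#'
#' Convenience wrapper: [cluster_profiles()] then [coreg_significance()]
#' per cluster (each cluster gets its own sub-seed derived from `seed`),
#' with optional Benjamini-Hochberg adjustment across clusters.
#'
#' @inheritParams cluster_profiles
#' @inheritParams coreg_significance
#' @param bh adjust p-values across clusters (default `FALSE`).
#' @return data.frame of cluster statistics plus a `membership` attribute
#'   (named vector intron -> cluster_id).
#' @export
coreg_analysis <- function(matrix, cut_height = 0.3, min_size = 2L,
                           n_permutations = 1000L, seed, bh = FALSE) {
  clusters <- cluster_profiles(matrix, cut_height, min_size)
  if (!length(clusters)) {
    return(data.frame(cluster_id = character(0), n_members = integer(0),
                      coherence = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  clusters <- lapply(seq_along(clusters), function(i)
    coreg_significance(clusters[[i]], matrix, n_permutations,
                       seed = seed + i))
  out <- data.frame(
    cluster_id = vapply(clusters, `[[`, "", "cluster_id"),
    n_members = vapply(clusters, function(cl) length(cl$members), integer(1)),
    coherence = vapply(clusters, `[[`, 0, "coherence"),
    p_value = vapply(clusters, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE
  )
  if (bh) out$p_adj <- p.adjust(out$p_value, method = "BH")
  membership <- unlist(lapply(clusters, function(cl)
    setNames(rep(cl$cluster_id, length(cl$members)), cl$members)))
  attr(out, "membership") <- membership
  out
}
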