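intron_row <- function(start = 200L, end = 300L, id = "gA.i1") {
  data.frame(intron_id = id, chrom = "chr1", start = start, end = end,
             strand = "+", parent_gene = "gA", ordinal = 1L,
             flank_donor = start, flank_acceptor = end, stringsAsFactors = FALSE)
}

test_that("the relative IR score is mean intron depth over junction reads", {
  key <- intron_key("chr1", 200L, 300L)
  b <- flat_bundle(10, junction_counts = setNames(20, key))
  m <- measure_intron(b, intron_row())
  expect_equal(m$mean_depth, 10)
  expect_equal(m$junction_reads, 20)
  expect_equal(m$ir_ratio, 0.5)

  b0 <- flat_bundle(0, junction_counts = setNames(20, key))
  expect_equal(measure_intron(b0, intron_row())$ir_ratio, 0)
})

test_that("zero junction support falls back to a unit denominator with a flag", {
  b <- flat_bundle(7)
  m <- measure_intron(b, intron_row())
  expect_equal(m$ir_ratio, 7)
  expect_true(m$no_splice_support)
  b0 <- flat_bundle(0)
  m0 <- measure_intron(b0, intron_row())
  expect_true(is.na(m0$ir_ratio))  # neither coverage nor junctions: unscored
})

test_that("ir_ratio is invariant to depth/junction rescaling", {
  key <- intron_key("chr1", 200L, 300L)
  b1 <- flat_bundle(12, junction_counts = setNames(30, key))
  b2 <- flat_bundle(24, junction_counts = setNames(60, key))
  expect_equal(measure_intron(b1, intron_row())$ir_ratio,
               measure_intron(b2, intron_row())$ir_ratio)
})

test_that("introns outside the bundle raise a named error", {
  b <- flat_bundle(5, chrom_len = 250L)
  expect_error(measure_intron(b, intron_row()), "gA.i1")
  expect_error(measure_intron(b, intron_row(id = "x.i9")), "x.i9")
})

test_that("splicing ratio difference is antisymmetric", {
  expect_equal(splicing_ratio_difference(0.5, 0.5), 0)
  expect_equal(splicing_ratio_difference(0.8, 0.2), 0.6)
  expect_equal(splicing_ratio_difference(0.2, 0.8), -0.6)
})

test_that("equal replicate means give zero adjusted log-fold change", {
  out <- adjusted_lfc(c(10, 12, 11), c(10, 12, 11))
  expect_equal(out$alfc, 0)
  for (cc in c(1, 2, 4, 8, 16, 32)) {
    expect_equal(adjusted_lfc(c(5, 5), c(5, 5), pseudo_grid = cc)$alfc, 0)
  }
})

test_that("raw log-fold change magnitude shrinks as pseudo-counts grow", {
  a <- 40; b <- 10
  grid <- c(1, 2, 4, 8, 16, 32)
  lfc <- abs(log2((a + grid) / (b + grid)))
  expect_true(all(diff(lfc) < 0))
  out <- adjusted_lfc(a, b, pseudo_grid = grid)
  expect_lte(abs(out$alfc),
             abs(adjusted_lfc(a, b, pseudo_grid = grid[1L])$alfc))
  expect_error(adjusted_lfc(numeric(0), 5), "replicate")
  expect_error(adjusted_lfc(5, 5, pseudo_grid = -1), "positive")
})

test_that("a seeded 4-fold coverage increase gives a positive statistic", {
  set.seed(314)
  signs <- replicate(300, {
    t_reps <- rnbinom(3, mu = 400, size = 10)
    c_reps <- rnbinom(3, mu = 100, size = 10)
    sign(adjusted_lfc(t_reps, c_reps)$alfc)
  })
  expect_gte(mean(signs > 0), 0.97)
})

test_that("dir_test handles degenerate and asymmetric inputs", {
  expect_equal(dir_test(c(3, 3, 3), c(3, 3, 3), method = "permutation"), 1)
  expect_warning(p <- dir_test(5, c(1, 2, 3)), "replicates")
  expect_true(is.na(p))
  expect_warning(p2 <- dir_test(c(1, 2), c(3, 4), method = "permutation"),
                 "exchangeable")
  expect_true(is.na(p2))
  # label swap leaves the two-sided p unchanged
  set.seed(2)
  x <- rnorm(3); y <- rnorm(3) + 1
  expect_equal(dir_test(x, y), dir_test(y, x))
  expect_equal(dir_test(x, y, method = "permutation"),
               dir_test(y, x, method = "permutation"))
  p3 <- dir_test(x, y)
  expect_true(p3 >= 0 && p3 <= 1)
})

test_that("the expression filter is symmetric around unity", {
  expect_true(expression_filter(1, 4.9))
  expect_false(expression_filter(1, 5.1))
  expect_false(expression_filter(1, 0.19))  # ~5.26-fold down
  expect_true(expression_filter(1, 0.21))
  expect_error(expression_filter(0, 1), "> 0")
})

test_that("genes seeded with large expression changes are excluded from calls", {
  cfg <- sim_config(n_genes = 10L, tissues = "t", stresses = "s", phases = "p",
                    dir_fraction = 0, frac_expr_change = 0.3,
                    expr_change_fold = 8, seed = 55)
  sim <- make_genome(cfg)
  bundles <- simulate_all_coverage(sim, seed = 77)
  res <- call_dirs(bundles, sim$genes)
  changed <- sim$manifest$expr_changed
  expect_length(changed, 3L)
  expect_true(all(!res$passed_expression_filter[res$gene_id %in% changed]))
  expect_true(all(res$passed_expression_filter[!res$gene_id %in% changed]))
  expect_true(all(is.na(res$p_value[!res$passed_expression_filter])))
})

test_that("seeded DIRs are called with the seeded direction", {
  cfg <- sim_config(n_genes = 20L, tissues = "t", stresses = "s", phases = "p",
                    psi_control = 0.35, dir_delta = 0.3, dir_fraction = 0.15,
                    frac_expr_change = 0, seed = 66)
  sim <- make_genome(cfg)
  bundles <- simulate_all_coverage(sim, seed = 88)
  res <- call_dirs(bundles, sim$genes)
  truth <- sim$manifest$dir_truth
  expect_gt(nrow(truth), 0L)
  hit <- res[res$intron_id %in% truth$intron_id, ]
  expect_true(all(hit$significant))
  expect_equal(hit$direction,
               truth$direction[match(hit$intron_id, truth$intron_id)])
  # seeded increase in retention appears as a negative ratio difference
  up <- hit[hit$direction == "increased IR", ]
  if (nrow(up)) expect_true(all(up$ratio_difference < 0))
  # BH adjustment is monotone in p within the comparison
  tested <- res[!is.na(res$p_value), ]
  o <- order(tested$p_value)
  expect_true(all(diff(tested$p_adj[o]) > -1e-12))
  expect_true(all(tested$p_adj >= tested$p_value - 1e-12))
})

test_that("summary bookkeeping equals brute-force set arithmetic", {
  cfg <- sim_config(n_genes = 15L, tissues = "t", stresses = c("s1", "s2"),
                    phases = "p", psi_control = 0.35, dir_delta = 0.3,
                    dir_fraction = 0.2, frac_expr_change = 0, seed = 91)
  sim <- make_genome(cfg)
  bundles <- simulate_all_coverage(sim, seed = 92)
  res <- call_dirs(bundles, sim$genes)
  summ <- summarize_dir_calls(res)
  sig <- res[res$significant, ]
  for (cmp in unique(sig$comparison)) {
    s <- sig[sig$comparison == cmp, ]
    row <- summ[summ$comparison == cmp, ]
    expect_equal(row$n_events, length(unique(s$intron_id)))
    expect_equal(row$n_loci, length(unique(s$gene_id)))
    per_gene <- tapply(s$intron_id, s$gene_id, function(x) length(unique(x)))
    expect_equal(row$n_multi_dir_loci, sum(per_gene >= 2))
  }
  comb <- summ[summ$comparison == "combined", ]
  expect_equal(comb$n_events, length(unique(paste(sig$intron_id, sig$comparison))))
  expect_equal(comb$n_loci, length(unique(sig$gene_id)))

  inter <- dir_intersections(res, by = "stress")
  sets <- lapply(split(sig$gene_id, sig$stress), unique)
  both <- inter[inter$combination == "s1&s2", ]
  if (nrow(both)) {
    expect_equal(both$n_common, length(intersect(sets$s1, sets$s2)))
  }
  only1 <- inter[inter$combination == "s1", ]
  expect_equal(only1$n_common, length(sets$s1))
  expect_equal(only1$n_exclusive, length(setdiff(sets$s1, sets$s2)))
})

test_that("call_dirs validates its design", {
  b <- flat_bundle(5, junction_counts = setNames(10, intron_key("chr1", 200L, 300L)))
  expect_error(call_dirs(list(b), list(three_exon_gene())), "treatment")
})
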