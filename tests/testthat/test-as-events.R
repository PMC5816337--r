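test_that("reads with shared junction chains merge to one isoform", {
  r1 <- transcript_model("r1", "chr1", "+", cbind(c(100L, 300L, 500L),
                                                  c(200L, 400L, 600L)))
  r2 <- transcript_model("r2", "chr1", "+", cbind(c(150L, 300L, 500L),
                                                  c(200L, 400L, 650L)))
  out <- collapse_isoforms(list(r1, r2))
  expect_length(out, 1L)
  expect_equal(out[[1L]]$support, 2L)
  # outermost observed ends are kept
  expect_equal(unname(out[[1L]]$model$exons[1L, 1L]), 100L)
  expect_equal(unname(out[[1L]]$model$exons[3L, 2L]), 650L)
})

test_that("a 3 nt acceptor shift keeps isoforms separate", {
  r1 <- transcript_model("r1", "chr1", "+", cbind(c(100L, 300L), c(200L, 400L)))
  r2 <- transcript_model("r2", "chr1", "+", cbind(c(100L, 303L), c(200L, 400L)))
  expect_length(collapse_isoforms(list(r1, r2)), 2L)
})

test_that("single-exon reads merge by same-strand overlap", {
  r <- list(transcript_model("a", "chr1", "+", cbind(100L, 300L)),
            transcript_model("b", "chr1", "+", cbind(250L, 500L)),
            transcript_model("c", "chr1", "-", cbind(100L, 300L)),
            transcript_model("d", "chr1", "+", cbind(900L, 1000L)))
  out <- collapse_isoforms(r)
  expect_length(out, 3L)
  sup <- vapply(out, `[[`, integer(1), "support")
  expect_equal(sort(sup), c(1L, 1L, 2L))
})

test_that("collapse is idempotent and recovers the generating isoform set", {
  sim <- make_genome(sim_config(n_genes = 12L, seed = 31))
  iso <- simulate_isoseq(sim, seed = 8)
  once <- collapse_isoforms(iso$reads)
  again <- collapse_isoforms(lapply(once, `[[`, "model"))
  expect_equal(length(once), length(again))
  expect_equal(lapply(once, function(x) x$model$exons),
               lapply(again, function(x) x$model$exons))
  # supports match the generator's per-isoform read counts
  truth_n <- c(iso$truth$n_ref_reads, iso$truth$n_alt_reads)
  gene_iso <- Filter(function(x) x$model$chrom == "chr1", once)
  expect_equal(sort(vapply(gene_iso, `[[`, integer(1), "support")),
               sort(truth_n))
})

test_that("an isoform identical to the reference yields no events", {
  g <- three_exon_gene("+")
  expect_equal(nrow(classify_events(g$transcripts[[1L]], g)), 0L)
})

test_that("an exon bridging a reference intron is intron retention", {
  g <- three_exon_gene("+")
  iso <- transcript_model("i1", "chr1", "+", cbind(c(100L, 500L), c(400L, 600L)))
  ev <- classify_events(iso, g)
  expect_equal(ev$event_type, "IR")
  expect_equal(ev$start, 200L)
  expect_equal(ev$end, 300L)
  # the IR interval is an enumerated intron of the gene
  introns <- enumerate_introns(g)
  expect_true(intron_key(ev$chrom, ev$start, ev$end) %in%
                intron_key(introns$chrom, introns$start, introns$end))
})

test_that("misassigned isoforms are rejected", {
  g <- three_exon_gene("+")
  far <- transcript_model("far", "chr1", "+", cbind(5000L, 5500L))
  wrong_strand <- transcript_model("ws", "chr1", "-",
                                   cbind(c(100L, 300L), c(200L, 400L)))
  expect_error(classify_events(far, g), "overlap")
  expect_error(classify_events(wrong_strand, g), "overlap")
})

test_that("seeded events of all five classes are recovered exactly", {
  sim <- make_genome(sim_config(n_genes = 25L, seed = 17))
  iso <- simulate_isoseq(sim, seed = 4)
  isoforms <- collapse_isoforms(iso$reads)
  ev <- classify_events_all(isoforms, sim$genes)
  truth <- iso$truth
  expect_setequal(unique(truth$event_type), c("IR", "Alt5", "Alt3", "ES", "MXE"))
  expect_equal(nrow(ev), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    hit <- ev[ev$gene_id == truth$gene_id[i], , drop = FALSE]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$event_type, truth$event_type[i])
    expect_equal(hit$start, truth$start[i])
    expect_equal(hit$end, truth$end[i])
    if (truth$event_type[i] == "MXE") {
      expect_equal(hit$start2, truth$start2[i])
      expect_equal(hit$end2, truth$end2[i])
    }
  }
})

test_that("event calls are invariant to isoform input order", {
  sim <- make_genome(sim_config(n_genes = 10L, seed = 23))
  iso <- simulate_isoseq(sim, seed = 5)
  isoforms <- collapse_isoforms(iso$reads)
  ev1 <- classify_events_all(isoforms, sim$genes)
  set.seed(1)
  ev2 <- classify_events_all(isoforms[sample.int(length(isoforms))], sim$genes)
  key <- function(e) sort(paste(e$gene_id, e$event_type, e$start, e$end))
  expect_equal(key(ev1), key(ev2))
})

test_that("event distributions fold MXE into ES and sum to 100%", {
  out <- summarize_event_distribution(c(IR = 1, Alt3 = 1, Alt5 = 1, ES = 1))
  expect_equal(out$percentage, rep(25, 4L))
  out2 <- summarize_event_distribution(c(IR = 2, Alt3 = 1, Alt5 = 1, ES = 1, MXE = 1))
  expect_equal(out2$count[out2$event_type == "ES"], 2)
  expect_lt(abs(sum(out2$percentage) - 100), 0.2)
  empty <- summarize_event_distribution(c(IR = 0, Alt3 = 0, Alt5 = 0, ES = 0))
  expect_true(all(is.na(empty$percentage)))
})

test_that("intergenic isoforms group into novel regions with AS flags", {
  g <- three_exon_gene("+")
  lone <- list(isoform_id = "n1", support = 1L, source_gene = NA,
               model = transcript_model("n1", "chr1", "+",
                                        cbind(c(10000L, 10400L), c(10200L, 10600L))))
  variant <- list(isoform_id = "n2", support = 1L, source_gene = NA,
                  model = transcript_model("n2", "chr1", "+",
                                           cbind(c(10000L, 10400L), c(10188L, 10600L))))
  out1 <- detect_novel_regions(list(lone), list(g))
  expect_equal(nrow(out1), 1L)
  expect_false(out1$has_AS)
  out2 <- detect_novel_regions(list(lone, variant), list(g))
  expect_equal(nrow(out2), 1L)
  expect_true(out2$has_AS)

  sim <- make_genome(sim_config(n_genes = 8L, seed = 41))
  iso <- simulate_isoseq(sim, seed = 2)
  nr <- detect_novel_regions(collapse_isoforms(iso$reads), sim$genes,
                             genome = sim$genome)
  expect_equal(nrow(nr), sim$config$n_novel_regions)
  expect_equal(sum(nr$has_AS), sim$config$n_novel_as)
  expect_true(all(nr$coding_capacity %in% c("coding", "noncoding")))
})

test_that("ORF scan finds the longest reading frame", {
  # 5 codons ATG..stop in frame 1
  s <- Biostrings::DNAString(paste0("CC", "ATGAAACCCGGGTTTTAA", "CC"))
  expect_equal(dirseq:::longest_orf_codons(s), 5L)
  expect_equal(dirseq:::longest_orf_codons(Biostrings::DNAString("CCCCCC")), 0L)
  # ORF without a stop runs to the end
  expect_equal(dirseq:::longest_orf_codons(Biostrings::DNAString("ATGAAAAAA")), 3L)
})
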