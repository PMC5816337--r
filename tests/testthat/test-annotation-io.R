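test_that("GTF coordinates convert from 1-based inclusive to 0-based half-open", {
  gtf <- tempfile(fileext = ".gtf")
  attrs <- 'gene_id "g1"; transcript_id "g1.t1";'
  writeLines(c(
    paste("chr1", "src", "exon", 101, 200, ".", "+", ".", attrs, sep = "\t"),
    paste("chr1", "src", "exon", 301, 400, ".", "+", ".", attrs, sep = "\t"),
    paste("chr1", "src", "exon", 501, 600, ".", "+", ".", attrs, sep = "\t")
  ), gtf)
  genes <- read_annotation(gtf)
  expect_length(genes, 1L)
  tx <- genes[["g1"]]$transcripts[[1L]]
  expect_equal(unname(tx$exons[, 1L]), c(100L, 300L, 500L))
  expect_equal(unname(tx$exons[, 2L]), c(200L, 400L, 600L))
})

test_that("two genes on opposite strands keep their strands through GFF3", {
  genes <- list(three_exon_gene("+", "gA"),
                gene_model("gB", list(transcript_model(
                  "gB.1", "chr1", "-", cbind(c(1000L, 1300L), c(1100L, 1400L))))))
  path <- tempfile(fileext = ".gff3")
  write_annotation_gff3(genes, path)
  back <- read_annotation(path)
  expect_equal(back[["gA"]]$strand, "+")
  expect_equal(back[["gB"]]$strand, "-")
})

test_that("synthetic annotation round-trips through write/read unchanged", {
  sim <- make_genome(sim_config(n_genes = 20L, seed = 7))
  path <- tempfile(fileext = ".gff3")
  write_annotation_gff3(sim$genes, path)
  back <- read_annotation(path)
  expect_same_models(back, sim$genes[order(names(sim$genes))])
})

test_that("malformed feature lines are reported by line number", {
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tsrc\texon\tnotanumber\t100"), bad)
  expect_error(read_annotation(bad), "line 3")
})

test_that("overlapping exons in one transcript raise an error naming it", {
  expect_error(
    transcript_model("tx.bad", "chr1", "+", cbind(c(0L, 50L), c(100L, 150L))),
    "tx.bad")
})

test_that("intron enumeration assigns ordinals in transcript orientation", {
  plus <- enumerate_introns(three_exon_gene("+"))
  expect_equal(nrow(plus), 2L)
  expect_equal(plus$ordinal[order(plus$start)], c(1L, 2L))
  expect_equal(plus$start, c(200L, 400L))
  expect_equal(plus$end, c(300L, 500L))

  minus <- enumerate_introns(three_exon_gene("-"))
  expect_equal(minus$ordinal[order(minus$start)], c(2L, 1L))
  # intervals are strand-independent, only ordinals flip
  expect_equal(minus[order(minus$start), c("start", "end")],
               plus[order(plus$start), c("start", "end")])
  # donor is the strand-oriented 5' boundary
  expect_equal(plus$flank_donor, plus$start)
  expect_equal(minus$flank_donor, minus$end)
})

test_that("isoforms sharing one intron but not another yield distinct records", {
  g <- gene_model("gC", list(
    transcript_model("gC.1", "chr1", "+", cbind(c(0L, 200L, 500L), c(100L, 300L, 600L))),
    transcript_model("gC.2", "chr1", "+", cbind(c(0L, 200L, 480L), c(100L, 300L, 600L)))
  ))
  introns <- enumerate_introns(g)
  # brute force: distinct gaps across both junction chains
  gaps <- unique(rbind(transcript_junctions(g$transcripts[[1L]]),
                       transcript_junctions(g$transcripts[[2L]])))
  expect_equal(nrow(introns), nrow(gaps))
  expect_equal(nrow(introns), 3L)
})

test_that("every transcript junction maps to exactly one enumerated intron", {
  sim <- make_genome(sim_config(n_genes = 10L, seed = 3))
  introns <- enumerate_introns_all(sim$genes)
  keys <- intron_key(introns$chrom, introns$start, introns$end)
  expect_false(any(duplicated(keys)))
  for (g in sim$genes) for (tx in g$transcripts) {
    j <- transcript_junctions(tx)
    if (nrow(j)) expect_true(all(intron_key(g$chrom, j[, 1L], j[, 2L]) %in% keys))
  }
})

test_that("single-exon genes enumerate zero introns without error", {
  g <- gene_model("gS", list(transcript_model("gS.1", "chr1", "+",
                                              cbind(0L, 500L))))
  expect_equal(nrow(enumerate_introns(g)), 0L)
})

test_that("gaps below the minimum intron length are dropped as artifacts", {
  g <- gene_model("gT", list(transcript_model(
    "gT.1", "chr1", "+", cbind(c(0L, 110L, 400L), c(100L, 300L, 500L)))))
  introns <- enumerate_introns(g, min_intron_length = 20L)
  expect_equal(nrow(introns), 1L)  # the 10 nt gap is discarded
  expect_equal(introns$start, 300L)
})

test_that("bedGraph depth round-trips through write/read", {
  depth <- list(chr1 = c(rep(0, 10), rep(5, 20), rep(0, 5), rep(2, 15)),
                chr2 = rep(0, 30))
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(depth, path)
  back <- read_bedgraph(path, c(chr1 = 50L, chr2 = 30L))
  expect_equal(back$chr1, depth$chr1)
  expect_equal(back$chr2, depth$chr2)
})

test_that("junction tables and BED12 models round-trip", {
  j <- data.frame(chrom = "chr1", start = c(100L, 500L), end = c(200L, 700L),
                  strand = c("+", "-"), read_count = c(7L, 3L),
                  max_overhang = c(25L, 30L), motif_class = c("GT/AG", "other"),
                  annotated = c(TRUE, FALSE), stringsAsFactors = FALSE)
  jp <- tempfile(fileext = ".tsv")
  write_junction_tsv(j, jp)
  expect_equal(read_junction_tsv(jp), j)

  models <- list(
    transcript_model("t1", "chr1", "+", cbind(c(10L, 200L), c(100L, 350L))),
    transcript_model("t2", "chr1", "-", cbind(c(400L, 600L, 800L),
                                              c(500L, 700L, 900L))))
  bp <- tempfile(fileext = ".bed")
  write_bed12(models, bp)
  back <- read_bed12(bp)
  expect_equal(length(back), 2L)
  expect_equal(back[[1L]]$exons, models[[1L]]$exons)
  expect_equal(back[[2L]]$exons, models[[2L]]$exons)
  expect_equal(back[[2L]]$strand, "-")
})
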