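test_that("junction observations aggregate by coordinates", {
  obs <- data.frame(chrom = "chr1", start = 200L, end = 300L, strand = "+",
                    read_count = rep(1L, 5), max_overhang = c(4L, 30L, 10L, 8L, 12L))
  out <- extract_junctions(obs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$read_count, 5L)
  expect_equal(out$max_overhang, 30L)
})

test_that("unsorted junction input is rejected", {
  obs <- data.frame(chrom = "chr1", start = c(500L, 100L), end = c(600L, 200L),
                    strand = "+", read_count = 2L, max_overhang = 20L)
  expect_error(extract_junctions(obs), "sorted")
})

test_that("zero junctions give an empty frame with a warning", {
  obs <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    strand = character(0), read_count = integer(0),
                    max_overhang = integer(0))
  expect_warning(out <- extract_junctions(obs), "no junctions")
  expect_equal(nrow(out), 0L)
})

test_that("junctions extracted from BAM match the text-table path", {
  skip_if_not_installed("Rsamtools")
  genome <- tiny_genome()
  j <- data.frame(chrom = "chr1", start = c(200L, 200L, 600L),
                  end = c(300L, 300L, 700L), strand = c("+", "+", "-"),
                  read_count = c(3L, 2L, 4L), stringsAsFactors = FALSE)
  sam <- tempfile(fileext = ".sam")
  write_junction_sam(j, genome, sam, anchor = 25L)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  out <- extract_junctions(bam)
  expect_equal(nrow(out), 2L)
  expect_equal(out$start, c(200L, 600L))
  expect_equal(out$read_count, c(5L, 4L))   # counts pooled per coordinate
  expect_equal(out$max_overhang, c(25L, 25L))
})

test_that("motif classification reads donors and acceptors strand-aware", {
  # GT...AG on the plus strand
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 10), "GT", strrep("C", 16), "AG", strrep("A", 10))))
  j <- function(strand) data.frame(chrom = "chr1", start = 10L, end = 30L,
                                   strand = strand, read_count = 5L,
                                   max_overhang = 20L, motif_class = NA_character_,
                                   annotated = NA)
  expect_equal(classify_motif(j("+"), genome)$motif_class, "GT/AG")
  # minus-strand intron whose forward sequence is CT...AC reads as GT/AG
  genome2 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 10), "CT", strrep("C", 16), "AC", strrep("A", 10))))
  expect_equal(classify_motif(j("-"), genome2)$motif_class, "GT/AG")
  # AT...AC is its own class; CA...GG falls through to "other"
  genome3 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 10), "AT", strrep("C", 16), "AC", strrep("A", 10))))
  expect_equal(classify_motif(j("+"), genome3)$motif_class, "AT/AC")
  genome4 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 10), "CA", strrep("C", 16), "GG", strrep("A", 10))))
  expect_equal(classify_motif(j("+"), genome4)$motif_class, "other")
  # unknown strand: the orientation with a whitelisted motif is adopted
  out <- classify_motif(j("."), genome2)
  expect_equal(out$strand, "-")
  expect_equal(out$motif_class, "GT/AG")
  expect_error(classify_motif(
    data.frame(chrom = "chr1", start = 30L, end = 5000L, strand = "+",
               read_count = 1L, max_overhang = 1L, motif_class = NA, annotated = NA),
    genome), "bounds")
})

test_that("motif calls are invariant under reverse-complement mirroring", {
  sim <- make_genome(sim_config(n_genes = 15L, seed = 21))
  introns <- sim$manifest$introns
  j <- data.frame(chrom = introns$chrom, start = introns$start,
                  end = introns$end, strand = introns$strand,
                  read_count = 1L, max_overhang = 20L,
                  motif_class = NA_character_, annotated = NA)
  out <- classify_motif(j, sim$genome)
  expect_equal(out$motif_class, introns$motif)
})

test_that("rule-based junction filtering partitions the input", {
  make_j <- function(n, motif, count, over) data.frame(
    chrom = "chr1", start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 100L,
    strand = "+", read_count = count, max_overhang = over,
    motif_class = motif, annotated = NA)
  expect_equal(nrow(filter_junctions(make_j(1, "other", 10L, 20L))$kept), 0L)
  expect_equal(nrow(filter_junctions(make_j(1, "GT/AG", 1L, 20L))$kept), 0L)

  set.seed(5)
  good <- make_j(83, "GT/AG", 10L, 20L)
  bad <- rbind(make_j(6, "other", 10L, 20L),
               make_j(5, "GT/AG", 1L, 20L),
               make_j(6, "GT/AG", 10L, 3L))
  all_j <- rbind(good, bad)[sample.int(100L), ]
  out <- filter_junctions(all_j)
  expect_equal(nrow(out$kept), 83L)
  expect_equal(nrow(out$discarded), 17L)
  expect_equal(nrow(out$kept) + nrow(out$discarded), nrow(all_j))
  expect_length(intersect(rownames(out$kept), rownames(out$discarded)), 0L)
})

test_that("novelty is an exact-coordinate match against annotated introns", {
  g <- three_exon_gene("+")
  j <- data.frame(chrom = "chr1", start = c(200L, 201L), end = c(300L, 300L),
                  strand = "+", read_count = 5L, max_overhang = 20L,
                  motif_class = "GT/AG", annotated = NA)
  out <- annotate_novelty(j, list(g))
  expect_true(out$annotated[1L])
  expect_false(out$annotated[2L])  # 1 nt shift makes it novel
})

test_that("seeded perturbed junctions are counted as novel", {
  sim <- make_genome(sim_config(n_genes = 10L, seed = 13))
  introns <- sim$manifest$introns
  ann <- introns[seq_len(10L), ]
  novel <- introns[11:13, ]
  novel$start <- novel$start + 2L
  j <- rbind(ann, novel)
  j <- data.frame(chrom = j$chrom, start = j$start, end = j$end,
                  strand = j$strand, read_count = 3L, max_overhang = 20L,
                  motif_class = NA_character_, annotated = NA)
  out <- annotate_novelty(j, sim$genes)
  expect_equal(sum(!out$annotated), 3L)
  expect_equal(attr(summarize_junctions(out), "n_novel"), 3L)
})
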