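# Small in-code fixtures shared across test files.

# three-exon plus-strand gene: exons (100,200) (300,400) (500,600)
three_exon_gene <- function(strand = "+", gene_id = "gA") {
  gene_model(gene_id, list(
    transcript_model(paste0(gene_id, ".1"), "chr1", strand,
                     cbind(c(100L, 300L, 500L), c(200L, 400L, 600L)))
  ))
}

# uniform-depth bundle over one chromosome
flat_bundle <- function(depth_value, chrom_len = 1000L,
                        junction_counts = numeric(0), sample_id = "s1",
                        condition = "control", replicate = 1L) {
  coverage_bundle(sample_id, condition, replicate,
                  depth = list(chr1 = rep(depth_value, chrom_len)),
                  junction_counts = junction_counts)
}

# deterministic tiny genome with one GT/AG intron at (200, 300) on chr1
tiny_genome <- function() {
  set.seed(99)
  s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  s <- paste0(substr(s, 1, 200), "GT", substr(s, 203, 298), "AG",
              substr(s, 301, 1000))
  Biostrings::DNAStringSet(c(chr1 = s))
}

expect_same_models <- function(a, b) {
  expect_equal(length(a), length(b))
  expect_equal(names(a), names(b))
  for (g in names(a)) {
    expect_equal(a[[g]]$strand, b[[g]]$strand)
    expect_equal(a[[g]]$span, b[[g]]$span)
    expect_equal(names(a[[g]]$transcripts), names(b[[g]]$transcripts))
    for (t in names(a[[g]]$transcripts))
      expect_equal(a[[g]]$transcripts[[t]]$exons, b[[g]]$transcripts[[t]]$exons)
  }
}
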