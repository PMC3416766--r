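make_alignments <- function(contig, pos, length = 30L, unique = TRUE) {
  n <- max(length(contig), length(pos))
  data.frame(read_id = sprintf("r%04d", seq_len(n)),
             contig = contig, pos = pos,
             length = rep_len(length, n), unique = rep_len(unique, n),
             stringsAsFactors = FALSE)
}

test_that("reads are classified by containing region", {
  ann <- two_region_annotation()
  al <- make_alignments("chrR", c(100L, 1500L))
  lab <- classify_reads(al, ann)
  expect_equal(as.character(lab), c("rRNA_18S", "rRNA_nontargeted"))
})

test_that("an intron read with no exon overlap is intron; exon beats intron", {
  ann <- regions(contig = "chr1", start = c(0L, 300L, 900L),
                 end = c(300L, 900L, 1200L),
                 label = c("exon", "intron", "exon"), gene_id = "g1")
  al <- make_alignments("chr1", c(400L, 290L))  # inside intron; straddling
  lab <- classify_reads(al, ann)
  expect_equal(as.character(lab), c("intron", "exon"))
})

test_that("a read straddling a class boundary takes the higher priority", {
  ann <- two_region_annotation()
  # 30-base read starting at 990 overlaps 18S [0,1000) and spacer [1000,2000)
  al <- make_alignments("chrR", 990L)
  expect_equal(as.character(classify_reads(al, ann)), "rRNA_18S")
  # and a spacer/mito comparison: spacer outranks mt_12S
  ann2 <- regions(contig = "chrR", start = c(0L, 1000L),
                  end = c(1000L, 2000L),
                  label = c("mt_12S", "rRNA_nontargeted"))
  expect_equal(as.character(classify_reads(make_alignments("chrR", 990L),
                                           ann2)),
               "rRNA_nontargeted")
})

test_that("reads on unknown contigs fall back to intergenic with a warning", {
  ann <- two_region_annotation()
  al <- make_alignments(c("chrR", "chrX"), c(10L, 10L))
  expect_warning(lab <- classify_reads(al, ann), "unannotated")
  expect_equal(as.character(lab), c("rRNA_18S", "intergenic"))
  expect_equal(attr(lab, "unknown_contig"), 1L)
})

test_that("non-unique reads are excluded from classification", {
  ann <- two_region_annotation()
  al <- make_alignments("chrR", c(10L, 20L), unique = c(TRUE, FALSE))
  expect_length(classify_reads(al, ann), 1)
})

test_that("class table reproduces a 944/56 rRNA split as 94.4%/5.6%", {
  ann <- regions(contig = c("chrR", "chr1"), start = c(0L, 0L),
                 end = c(5000L, 5000L), label = c("rRNA_18S", "exon"),
                 gene_id = c(NA, "g1"))
  al <- make_alignments(c(rep("chrR", 944), rep("chr1", 56)),
                        rep(100L, 1000))
  ct <- class_table(al, ann)
  expect_equal(ct$total_unique, 1000L)
  expect_equal(unname(ct$rollup["rRNA"]), 0.944)
  expect_equal(unname(ct$rollup["non_rRNA"]), 0.056)
  expect_equal(sum(ct$proportions), 1, tolerance = 1e-9)
  expect_equal(sum(ct$counts), ct$total_unique)

  # order invariance
  perm <- al[sample(nrow(al)), ]
  expect_equal(class_table(perm, ann)$counts, ct$counts)

  # degenerate cases
  expect_equal(unname(class_table(al[1:10, ], ann)$proportions["rRNA_18S"]),
               1)
  expect_error(class_table(al[al$pos < 0, ], ann), "zero unique")
})

test_that("the mitochondrial rRNAs roll up into the rRNA category", {
  ann <- regions(contig = c("chrM", "chrM", "chr1"),
                 start = c(0L, 1000L, 0L), end = c(1000L, 2000L, 1000L),
                 label = c("mt_12S", "mt_other", "exon"),
                 gene_id = c(NA, NA, "g1"))
  al <- make_alignments(c("chrM", "chrM", "chr1"), c(10L, 1010L, 10L))
  ct <- class_table(al, ann)
  expect_equal(unname(ct$rollup["rRNA"]), 1 / 3)  # mt_other is non-rRNA
})

test_that("depletion efficiency follows the odds-ratio formula", {
  expect_equal(depletion_efficiency(0.605, 0.019), 0.9874, tolerance = 1e-4)
  expect_equal(depletion_efficiency(0.944, 0.062), 0.9961, tolerance = 1e-4)
  expect_equal(depletion_efficiency(0.3, 0.3), 0)
  # naive variant underestimates removal relative to the odds form
  expect_equal(depletion_efficiency(0.5, 0.05, method = "naive"), 0.9)
  expect_gt(depletion_efficiency(0.5, 0.05), 0.9)
  expect_error(depletion_efficiency(1, 0.1), "f_u")
  expect_error(depletion_efficiency(0.5, 1), "f_d")
})

test_that("correlation is 1 for identical and scaled libraries", {
  lib <- data.frame(gene_id = sprintf("g%d", 1:50),
                    count = c(0, rpois(49, 100) + 1),
                    biotype = "other", homolog = "none",
                    stringsAsFactors = FALSE)
  tc <- transcript_correlation(lib, lib)
  expect_equal(tc$R, 1)
  expect_equal(tc$n_genes, 49)  # the zero-count gene is excluded pairwise
  scaled <- lib
  scaled$count <- lib$count * 10
  expect_equal(transcript_correlation(lib, scaled)$R, 1)
})

test_that("correlation matches a hand-computed Pearson on log10 counts", {
  lib_a <- data.frame(gene_id = sprintf("g%d", 1:5),
                      count = c(10, 100, 1000, 50, 5),
                      biotype = "other", homolog = "none",
                      stringsAsFactors = FALSE)
  lib_b <- lib_a
  lib_b$count <- c(12, 80, 1500, 40, 3)
  tc <- transcript_correlation(lib_a, lib_b)
  expect_equal(tc$R, 0.9926790992, tolerance = 1e-9)
  expect_equal(tc$data$residual,
               log10(lib_b$count) - log10(lib_a$count))
})

test_that("correlation stratifies by biotype and homolog flags", {
  set.seed(61)
  n <- 60
  lib_a <- data.frame(
    gene_id = sprintf("g%d", 1:n), count = rpois(n, 200) + 1,
    biotype = rep(c("other", "sno", "mir"), each = 20),
    homolog = rep(c("none", "none", "SDRNA"), each = 20),
    stringsAsFactors = FALSE)
  lib_b <- lib_a
  lib_b$count <- lib_a$count + rpois(n, 10)
  tc <- transcript_correlation(lib_a, lib_b)
  expect_setequal(tc$strata$stratum, c("other", "small_RNA", "SDRNA"))
  expect_true(all(tc$strata$R >= -1 & tc$strata$R <= 1, na.rm = TRUE))
  expect_error(transcript_correlation(lib_a[1:2, ], lib_b[1:2, ]),
               "fewer than")
})

test_that("broad-class profile matches a constructed mixture and sums to 1", {
  ann <- regions(contig = c("chr1", "chr1", "chrR"),
                 start = c(0L, 1000L, 0L), end = c(1000L, 2000L, 1000L),
                 label = c("exon", "intron", "rRNA_nontargeted"),
                 gene_id = c("g1", "g1", NA))
  al <- make_alignments(
    c(rep("chr1", 48), rep("chr1", 36), rep("chrR", 16)),
    c(rep(10L, 48), rep(1010L, 36), rep(10L, 16)))
  prof <- exon_intron_intergenic_profile(al, ann)
  expect_equal(unname(prof["exon"]), 0.48)
  expect_equal(unname(prof["intron"]), 0.36)
  expect_equal(unname(prof["rRNA"]), 0.16)
  expect_equal(sum(prof), 1)
  # all-exon edge case
  al2 <- make_alignments(rep("chr1", 5), rep(10L, 5))
  expect_equal(unname(exon_intron_intergenic_profile(al2, ann)["exon"]), 1)
})

test_that("class conservation: labels always partition the unique reads", {
  set.seed(62)
  ref <- make_reference(seed = 5, sizes = reference_sizes(n_genes = 10))
  cfg <- sim_config(seed = 5, n_reads = 5000, emit_reads = FALSE)
  sim <- simulate_library(ref, cfg)
  ct <- class_table(sim$alignments, ref$annotation)
  expect_equal(sum(ct$counts), sum(sim$alignments$unique))
  expect_equal(sum(ct$proportions), 1, tolerance = 1e-9)
})
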