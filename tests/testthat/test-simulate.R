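test_that("the synthetic reference is deterministic and internally consistent", {
  ref1 <- make_reference(seed = 3, sizes = reference_sizes(n_genes = 8))
  ref2 <- make_reference(seed = 3, sizes = reference_sizes(n_genes = 8))
  expect_identical(as.character(ref1$sequences),
                   as.character(ref2$sequences))
  expect_identical(ref1$annotation, ref2$annotation)
  ref3 <- make_reference(seed = 4, sizes = reference_sizes(n_genes = 8))
  expect_false(identical(as.character(ref1$sequences),
                         as.character(ref3$sequences)))

  ann <- ref1$annotation
  # regions tile without overlap on every contig
  for (ct in unique(ann$contig)) {
    d <- ann[ann$contig == ct, ]
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]), info = ct)
  }
  # annotation survives a BED round trip
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(ann, f)
  back <- read_bed(f)
  srt <- ann[order(ann$contig, ann$start), ]
  rownames(srt) <- NULL
  expect_equal(back, srt)
})

test_that("the synthetic 18S region reproduces the reference probe layout", {
  ref <- make_reference(seed = 3, sizes = reference_sizes(n_genes = 2))
  r18 <- ref$annotation[ref$annotation$label == "rRNA_18S", ]
  expect_equal(r18$end - r18$start, 1976L)
  seq18 <- substr(as.character(ref$sequences[["rRNA_unit"]]),
                  r18$start + 1, r18$end)
  panel <- build_panel(list(target_spec("18S", seq18)))
  expect_equal(nrow(panel$probes), 25L)
  expect_equal(sum(panel$probes$length == 80), 24L)
  expect_equal(sum(panel$probes$length == 56), 1L)
})

test_that("simulation is seed-deterministic and honours class fractions", {
  ref <- make_reference(seed = 6, sizes = reference_sizes(n_genes = 15))
  cfg <- sim_config(seed = 8, n_reads = 20000, emit_reads = FALSE)
  s1 <- simulate_library(ref, cfg)
  s2 <- simulate_library(ref, cfg)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$truth, s2$truth)

  # with e = 0, realized class fractions match the configured ones (3 sigma)
  n <- nrow(s1$truth)
  targeted <- s1$truth$class %in% c("rRNA_18S", "rRNA_5_8S", "rRNA_28S")
  p <- cfg$frac_rRNA_targeted
  expect_lt(abs(mean(targeted) - p), 3 * sqrt(p * (1 - p) / n))
  p_mt <- cfg$frac_mt_rRNA
  mt <- s1$truth$class %in% c("mt_12S", "mt_16S")
  expect_lt(abs(mean(mt) - p_mt), 3 * sqrt(p_mt * (1 - p_mt) / n))
})

test_that("full depletion removes every targeted fragment", {
  ref <- make_reference(seed = 6, sizes = reference_sizes(n_genes = 5))
  cfg <- sim_config(seed = 8, n_reads = 5000, depletion_efficiency = 1,
                    emit_reads = FALSE)
  sim <- simulate_library(ref, cfg)
  expect_false(any(sim$truth$class %in%
                     c("rRNA_18S", "rRNA_5_8S", "rRNA_28S", "mt_12S",
                       "mt_16S")))
  expect_gt(nrow(sim$truth), 0)
})

test_that("classification on truth alignments recovers the true class", {
  ref <- make_reference(seed = 9, sizes = reference_sizes(n_genes = 20))
  cfg <- sim_config(seed = 10, n_reads = 30000, emit_reads = FALSE)
  sim <- simulate_library(ref, cfg)
  lab <- classify_reads(sim$alignments, ref$annotation)
  recovery <- mean(as.character(lab) == sim$truth$class)
  expect_gte(recovery, 0.999)
})

test_that("simulated reads carry the reference sequence at their position", {
  ref <- make_reference(seed = 12, sizes = reference_sizes(n_genes = 5))
  cfg <- sim_config(seed = 12, n_reads = 200)
  sim <- simulate_library(ref, cfg)
  expect_equal(length(sim$reads), nrow(sim$alignments))
  i <- c(1L, 57L, 200L)
  for (k in i) {
    al <- sim$alignments[k, ]
    expect_equal(as.character(sim$reads[[k]]),
                 substr(as.character(ref$sequences[[al$contig]]),
                        al$pos + 1, al$pos + al$length))
  }
  # FASTQ output round-trips
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_sim_fastq(sim, fq)
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_equal(as.character(back), as.character(sim$reads),
               ignore_attr = TRUE)
})

test_that("simulated depletion is recovered by the odds-ratio estimator", {
  ref <- make_reference(seed = 14, sizes = reference_sizes(n_genes = 15))
  base <- list(n_reads = 2e5, frac_rRNA_targeted = 0.60,
               frac_rRNA_nontargeted = 0, frac_mt_rRNA = 0,
               frac_mt_other = 0.005, frac_intergenic = 0.04,
               emit_reads = FALSE)
  cfg_u <- do.call(sim_config, c(base, seed = 15))
  cfg_d <- do.call(sim_config, c(base, seed = 16,
                                 depletion_efficiency = 0.98))
  f_u <- class_table(simulate_library(ref, cfg_u)$alignments,
                     ref$annotation)$rollup[["rRNA"]]
  f_d <- class_table(simulate_library(ref, cfg_d)$alignments,
                     ref$annotation)$rollup[["rRNA"]]
  e_est <- depletion_efficiency(f_u, f_d)
  expect_lt(abs(e_est - 0.98), 0.01)
})

test_that("replicate libraries correlate as expected", {
  cfg <- sim_config(seed = 17, n_reads = 1e6)
  reps <- simulate_replicates(cfg, n_genes = 5000)
  # same seed, same generator -> identical libraries, R = 1
  reps2 <- simulate_replicates(cfg, n_genes = 5000)
  expect_identical(reps, reps2)
  expect_equal(transcript_correlation(reps$a, reps$a)$R, 1)
  # two deep technical replicates of one abundance vector correlate highly
  tc <- transcript_correlation(reps$a, reps$b)
  expect_gte(tc$R, 0.95)
})

test_that("configuration validation rejects impossible fractions", {
  expect_error(sim_config(frac_rRNA_targeted = 0.9, frac_mt_rRNA = 0.2),
               "fractions")
  expect_error(sim_config(frac_rRNA_targeted = -0.1), "fractions")
  expect_error(sim_config(n_reads = 0))
})
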