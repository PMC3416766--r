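#' Synthetic reference sizes
#'
#' Dimensions of the synthetic reference built by [make_reference()]: a
#' pseudo ribosomal repeating-unit contig carrying 18S/5.8S/28S regions
#' separated by non-targeted spacers, a pseudo-mitochondrial contig carrying
#' the 12S and 16S rRNAs, and a nuclear contig of protein-coding genes with
#' alternating exon/intron blocks. Subunit length defaults (1976, 157, 5025,
#' 954, 1559 nt) match the probe-panel arithmetic of the reference design, so
#' tiling the synthetic subunits reproduces the published probe counts.
#'
#' @param rrna_unit Ribosomal contig length (nt).
#' @param len_18S,len_5_8S,len_28S Nuclear rRNA subunit lengths.
#' @param mito Mitochondrial contig length.
#' @param len_12S,len_16S Mitochondrial rRNA lengths.
#' @param n_genes Number of mRNA gene models.
#' @return Named list of sizes.
#' @export
reference_sizes <- function(rrna_unit = 13000, len_18S = 1976,
                            len_5_8S = 157, len_28S = 5025,
                            mito = 4800, len_12S = 954, len_16S = 1559,
                            n_genes = 60) {
  sz <- list(rrna_unit = rrna_unit, len_18S = len_18S, len_5_8S = len_5_8S,
             len_28S = len_28S, mito = mito, len_12S = len_12S,
             len_16S = len_16S, n_genes = n_genes)
  if (rrna_unit < 700 + len_18S + 924 + len_5_8S + 943 + len_28S)
    stop("rrna_unit too short for the embedded subunits and spacers")
  if (mito < 600 + len_12S + 146 + len_16S)
    stop("mito contig too short for the embedded rRNAs")
  sz
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a synthetic reference genome and annotation
#'
#' Generates random-sequence contigs with the region layout described in
#' [reference_sizes()]. Deterministic: the same seed yields byte-identical
#' sequences and annotation.
#'
#' @param seed Integer seed fixing the whole stream.
#' @param sizes A [reference_sizes()] list.
#' @return List with `sequences` (named [Biostrings::DNAStringSet]:
#'   `rRNA_unit`, `chrM`, `chr1`) and `annotation` (region `data.frame`).
#' @export
make_reference <- function(seed = 1, sizes = reference_sizes()) {
  set.seed(as.integer(seed))
  # ribosomal repeating unit: spacers are non-targeted rRNA transcript
  s18 <- 700L
  e18 <- s18 + sizes$len_18S
  s58 <- e18 + 924L
  e58 <- s58 + sizes$len_5_8S
  s28 <- e58 + 943L
  e28 <- s28 + sizes$len_28S
  rr <- regions(
    contig = "rRNA_unit",
    start = c(0L, s18, e18, s58, e58, s28, e28),
    end = c(s18, e18, s58, e58, s28, e28, sizes$rrna_unit),
    label = c("rRNA_nontargeted", "rRNA_18S", "rRNA_nontargeted",
              "rRNA_5_8S", "rRNA_nontargeted", "rRNA_28S",
              "rRNA_nontargeted"))
  # mitochondrial contig
  s12 <- 600L
  e12 <- s12 + sizes$len_12S
  s16 <- e12 + 146L
  e16 <- s16 + sizes$len_16S
  mt <- regions(
    contig = "chrM",
    start = c(0L, s12, e12, s16, e16),
    end = c(s12, e12, s16, e16, sizes$mito),
    label = c("mt_other", "mt_12S", "mt_other", "mt_16S", "mt_other"))
  # nuclear gene space: alternating exon/intron blocks separated by gaps
  gene_rows <- vector("list", sizes$n_genes)
  pos <- 0L
  for (g in seq_len(sizes$n_genes)) {
    pos <- pos + sample(400:1500, 1)          # intergenic gap
    n_ex <- sample(2:5, 1)
    gid <- sprintf("gene_%04d", g)
    starts <- ends <- integer(0)
    labs <- character(0)
    for (e in seq_len(n_ex)) {
      exl <- sample(120:400, 1)
      starts <- c(starts, pos); ends <- c(ends, pos + exl)
      labs <- c(labs, "exon")
      pos <- pos + exl
      if (e < n_ex) {
        inl <- sample(200:1200, 1)
        starts <- c(starts, pos); ends <- c(ends, pos + inl)
        labs <- c(labs, "intron")
        pos <- pos + inl
      }
    }
    gene_rows[[g]] <- regions(contig = "chr1", start = starts, end = ends,
                              label = labs, gene_id = gid)
  }
  chr1_len <- pos + sample(400:1500, 1)
  genes <- do.call(rbind, gene_rows)
  sequences <- Biostrings::DNAStringSet(c(
    rRNA_unit = .random_dna(sizes$rrna_unit),
    chrM = .random_dna(sizes$mito),
    chr1 = .random_dna(chr1_len)))
  list(sequences = sequences, annotation = rbind(rr, mt, genes))
}

#' Simulation configuration
#'
#' Class fractions, abundance model and fragmentation parameters for
#' [simulate_library()]. Defaults emulate an untreated FFPE total-RNA
#' library: combined rRNA content 60.5% of unique reads (54% targeted
#' nuclear rRNA, 1.5% non-targeted spacers, 5% mitochondrial rRNA), short
#' gamma-distributed fragments (mean 60 nt), and intron-heavy gene-derived
#' reads (`intron_retention = 0.7`). Gene-derived fragments take the
#' remaining probability mass after the rRNA, mitochondrial and intergenic
#' fractions.
#'
#' @param seed Integer seed fixing the whole stream.
#' @param n_reads Number of fragments drawn (reads before depletion).
#' @param frac_rRNA_targeted Fraction from targeted nuclear rRNA
#'   (18S/5.8S/28S).
#' @param frac_rRNA_nontargeted Fraction from the non-targeted spacers of
#'   the ribosomal transcript.
#' @param frac_mt_rRNA Fraction from mitochondrial 12S/16S rRNA.
#' @param frac_mt_other Fraction from the rest of the mitochondrial contig.
#' @param frac_intergenic Fraction from intergenic space.
#' @param intron_retention Fraction of gene-derived fragments drawn from
#'   introns rather than exons.
#' @param abundance_meanlog,abundance_sdlog Log-normal gene-abundance model.
#' @param fragment_mean,fragment_shape Gamma fragment-length model (FFPE-like
#'   default mean 60 nt; use ~200 for fresh-frozen-like libraries).
#' @param depletion_efficiency Probability `e` that a fragment overlapping a
#'   targeted region is removed before sequencing.
#' @param read_len Read length (bases; reads are truncated to fragment
#'   length when shorter).
#' @param emit_reads Extract read sequences (set `FALSE` to skip FASTQ-level
#'   output and return alignments/truth only).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_reads = 1e5,
                       frac_rRNA_targeted = 0.54,
                       frac_rRNA_nontargeted = 0.015,
                       frac_mt_rRNA = 0.05, frac_mt_other = 0.005,
                       frac_intergenic = 0.04, intron_retention = 0.7,
                       abundance_meanlog = 2, abundance_sdlog = 1.5,
                       fragment_mean = 60, fragment_shape = 4,
                       depletion_efficiency = 0, read_len = 51,
                       emit_reads = TRUE) {
  fr <- c(frac_rRNA_targeted, frac_rRNA_nontargeted, frac_mt_rRNA,
          frac_mt_other, frac_intergenic)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("class fractions must lie in [0, 1] and sum to at most 1")
  stopifnot(n_reads >= 1, intron_retention >= 0, intron_retention <= 1,
            depletion_efficiency >= 0, depletion_efficiency <= 1,
            read_len >= 1, fragment_mean > 0, fragment_shape > 0)
  structure(as.list(environment()), class = "sim_config")
}

# sampling table: one row per drawable region with a class label, an optional
# gene id and a draw probability
.sampling_table <- function(reference, config) {
  ann <- reference$annotation
  tab_for <- function(labels, mass, weights = NULL) {
    d <- ann[ann$label %in% labels, , drop = FALSE]
    if (!nrow(d) || mass <= 0) return(NULL)
    w <- if (is.null(weights)) d$end - d$start else weights
    d$prob <- mass * w / sum(w)
    d
  }
  # intergenic gaps on the gene contig
  chr1_len <- Biostrings::width(reference$sequences)[
    names(reference$sequences) == "chr1"]
  gr_genes <- regions_to_granges(ann[ann$contig == "chr1", , drop = FALSE])
  gaps <- IRanges::gaps(IRanges::reduce(IRanges::ranges(gr_genes)),
                        start = 1L, end = chr1_len)
  intergenic <- if (length(gaps)) regions(
    contig = "chr1", start = IRanges::start(gaps) - 1L,
    end = IRanges::end(gaps), label = "intergenic") else NULL
  if (!is.null(intergenic) && config$frac_intergenic > 0)
    intergenic$prob <- config$frac_intergenic *
      (intergenic$end - intergenic$start) /
      sum(intergenic$end - intergenic$start)
  else intergenic <- NULL
  # gene-derived mass split between exons and introns, genes weighted by a
  # log-normal abundance, regions within a gene by length
  frac_gene <- 1 - config$frac_rRNA_targeted -
    config$frac_rRNA_nontargeted - config$frac_mt_rRNA -
    config$frac_mt_other - config$frac_intergenic
  gene_ids <- sort(unique(ann$gene_id[!is.na(ann$gene_id)]))
  ab <- stats::setNames(
    rlnorm(length(gene_ids), config$abundance_meanlog,
           config$abundance_sdlog), gene_ids)
  ab <- ab / sum(ab)
  gene_part <- function(label, mass) {
    d <- ann[ann$label == label & !is.na(ann$gene_id), , drop = FALSE]
    if (!nrow(d) || mass <= 0) return(NULL)
    len <- d$end - d$start
    within <- stats::ave(len, d$gene_id, FUN = function(x) x / sum(x))
    d$prob <- mass * ab[d$gene_id] * within
    d
  }
  tab <- rbind(
    tab_for(c("rRNA_18S", "rRNA_5_8S", "rRNA_28S"),
            config$frac_rRNA_targeted),
    tab_for("rRNA_nontargeted", config$frac_rRNA_nontargeted),
    tab_for(c("mt_12S", "mt_16S"), config$frac_mt_rRNA),
    tab_for("mt_other", config$frac_mt_other),
    intergenic,
    gene_part("exon", frac_gene * (1 - config$intron_retention)),
    gene_part("intron", frac_gene * config$intron_retention))
  tab$prob <- tab$prob / sum(tab$prob)
  rownames(tab) <- NULL
  tab
}

.targeted_labels <- c("rRNA_18S", "rRNA_5_8S", "rRNA_28S", "mt_12S",
                      "mt_16S")

#' Simulate a sequencing library with known truth
#'
#' Draws `n_reads` fragments across region classes according to the
#' configured fractions (gene-derived fragments weighted by log-normal gene
#' abundances), removes fragments overlapping targeted regions with
#' probability `depletion_efficiency` — depletion acts on fragments, before
#' sequencing, so efficiency composes correctly with abundance — and emits
#' one read per surviving fragment. Fragments are placed entirely within
#' their region of origin, so the emitted alignment table is exact truth and
#' no external mapper is needed; all reads are uniquely mapped by
#' construction.
#'
#' @param reference A [make_reference()] result.
#' @param config A [sim_config()].
#' @return A `sim_library`: list with `alignments` (truth alignment
#'   `data.frame` in the [read_alignments()] schema), `truth`
#'   (`read_id`, `class`, `gene_id`), `reads` (named
#'   [Biostrings::DNAStringSet], or `NULL` when `emit_reads = FALSE`) and
#'   the `config` used.
#' @export
simulate_library <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_reads < 1) stop("n_reads must be at least 1")
  set.seed(as.integer(config$seed))
  tab <- .sampling_table(reference, config)
  n <- as.integer(config$n_reads)
  ridx <- sample.int(nrow(tab), n, replace = TRUE, prob = tab$prob)
  rlen <- tab$end[ridx] - tab$start[ridx]
  frag <- pmax(20L, as.integer(round(
    rgamma(n, shape = config$fragment_shape,
           rate = config$fragment_shape / config$fragment_mean))))
  frag <- pmin(frag, rlen)
  off <- as.integer(floor(runif(n) * (rlen - frag + 1)))
  pos <- tab$start[ridx] + off
  targeted <- tab$label[ridx] %in% .targeted_labels
  keep <- !targeted | (runif(n) >= config$depletion_efficiency)
  ridx <- ridx[keep]; pos <- pos[keep]; frag <- frag[keep]
  read_len <- pmin(as.integer(config$read_len), frag)
  ids <- sprintf("read_%07d", seq_along(ridx))
  alignments <- data.frame(read_id = ids, contig = tab$contig[ridx],
                           pos = pos, length = read_len, unique = TRUE,
                           stringsAsFactors = FALSE)
  truth <- data.frame(read_id = ids, class = tab$label[ridx],
                      gene_id = tab$gene_id[ridx], stringsAsFactors = FALSE)
  reads <- NULL
  if (isTRUE(config$emit_reads) && length(ids)) {
    seqs <- character(length(ids))
    for (ct in unique(alignments$contig)) {
      sel <- alignments$contig == ct
      v <- Biostrings::extractAt(
        reference$sequences[[ct]],
        IRanges::IRanges(start = pos[sel] + 1L,
                         width = read_len[sel]))
      seqs[sel] <- as.character(v)
    }
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- ids
  }
  structure(list(alignments = alignments, truth = truth, reads = reads,
                 config = config),
            class = "sim_library")
}

#' Write simulated reads as FASTQ
#'
#' @param sim A `sim_library` with `emit_reads = TRUE`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_sim_fastq <- function(sim, path) {
  if (is.null(sim$reads))
    stop("simulation was run with emit_reads = FALSE")
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(sim$reads)))
  Biostrings::writeXStringSet(sim$reads, path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Write simulation truth labels
#'
#' @param sim A `sim_library`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(sim, path) {
  write.table(sim$truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate technical-replicate count libraries
#'
#' Two independent multinomial draws of `n_reads` reads over `n_genes` genes
#' from a shared log-normal abundance vector, optionally perturbed per
#' replicate by log-normal noise (`sdlog = noise`), emulating technical
#' replication of transcript abundance. A small fraction of genes is
#' annotated with small-RNA biotypes so stratified correlation is
#' exercisable.
#'
#' @param config A [sim_config()] (uses `seed`, `n_reads`, `n_genes` via
#'   `n_genes` argument, and the abundance model).
#' @param n_genes Number of genes (default 2000).
#' @param noise Between-replicate log-normal noise sd (default 0 =
#'   identical expected abundances).
#' @return List of two library-counts `data.frame`s `a` and `b`
#'   (`gene_id`, `count`, `biotype`, `homolog`).
#' @export
simulate_replicates <- function(config, n_genes = 2000, noise = 0) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(config$seed))
  gene_id <- sprintf("gene_%05d", seq_len(n_genes))
  ab <- rlnorm(n_genes, config$abundance_meanlog, config$abundance_sdlog)
  biotype <- sample(c("other", "sno", "sn", "sc", "mir"), n_genes,
                    replace = TRUE, prob = c(0.9, 0.025, 0.025, 0.025,
                                             0.025))
  p_a <- ab * if (noise > 0) rlnorm(n_genes, 0, noise) else 1
  p_b <- ab * if (noise > 0) rlnorm(n_genes, 0, noise) else 1
  mk <- function(p) data.frame(
    gene_id = gene_id,
    count = as.integer(rmultinom(1, size = as.integer(config$n_reads),
                                 prob = p)),
    biotype = biotype, homolog = "none", stringsAsFactors = FALSE)
  list(a = mk(p_a), b = mk(p_b))
}
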