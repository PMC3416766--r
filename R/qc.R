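#' Classify uniquely mapped reads by annotated region
#'
#' Each read is assigned the label of the annotated region it overlaps by at
#' least one base, using a fixed priority ladder when a read spans more than
#' one class: targeted rRNA (18S/28S/5.8S) > non-targeted rRNA >
#' mitochondrial 12S/16S > other mitochondrial > exon > intron > intergenic.
#' Reads overlapping nothing — including reads on contigs absent from the
#' annotation, which are counted in `attr(result, "unknown_contig")` — are
#' `intergenic`.
#'
#' @param alignments Alignment `data.frame` (see [read_alignments()]); only
#'   rows with `unique == TRUE` are classified, all others are dropped.
#' @param annotation Region `data.frame` (see [regions()]).
#' @return Factor of class labels (levels = [region_labels()]), one per
#'   unique read, with attribute `unknown_contig` (count of unique reads on
#'   unannotated contigs).
#' @export
classify_reads <- function(alignments, annotation) {
  validate_regions(annotation)
  al <- alignments[alignments$unique, , drop = FALSE]
  n <- nrow(al)
  labels <- factor(rep("intergenic", n), levels = region_labels())
  n_unknown <- 0L
  if (n > 0 && nrow(annotation) > 0) {
    known <- al$contig %in% unique(annotation$contig)
    n_unknown <- sum(!known)
    if (n_unknown > 0)
      warning(n_unknown, " unique read(s) on unannotated contig(s), ",
              "classified as intergenic")
    if (any(known)) {
      idx <- which(known)
      gr_reads <- GenomicRanges::GRanges(
        al$contig[idx],
        IRanges::IRanges(start = al$pos[idx] + 1L,
                         width = al$length[idx]))
      gr_ann <- regions_to_granges(annotation)
      ov <- GenomicRanges::findOverlaps(gr_reads, gr_ann,
                                        minoverlap = 1L,
                                        ignore.strand = TRUE)
      if (length(ov)) {
        qh <- S4Vectors::queryHits(ov)
        lab <- annotation$label[S4Vectors::subjectHits(ov)]
        prio <- .label_priority[lab]
        # tie-break equal priority by label enum order
        ord <- order(qh, prio, match(lab, region_labels()))
        first <- !duplicated(qh[ord])
        labels[idx[qh[ord][first]]] <- lab[ord][first]
      }
    }
  }
  attr(labels, "unknown_contig") <- n_unknown
  labels
}

#' Per-class read tallies and the rRNA / non-rRNA rollup
#'
#' Counts uniquely mapped reads per region class and reports proportions,
#' plus the two-way rollup in which the rRNA category comprises all nuclear
#' rRNA labels (targeted and non-targeted) together with the mitochondrial
#' 12S and 16S rRNAs; everything else is non-rRNA. Proportions are kept at
#' full precision; the print method displays them rounded to 0.1%.
#'
#' @inheritParams classify_reads
#' @return A `class_counts` object: list with `counts` (named integer),
#'   `proportions`, `total_unique`, and `rollup` (named fractions `rRNA`,
#'   `non_rRNA`).
#' @export
class_table <- function(alignments, annotation) {
  lab <- classify_reads(alignments, annotation)
  total <- length(lab)
  if (total == 0) stop("zero unique reads")
  counts <- table(lab)
  counts <- stats::setNames(as.integer(counts), names(counts))
  prop <- counts / total
  rrna <- sum(prop[.rrna_rollup_labels])
  structure(list(counts = counts, proportions = prop,
                 total_unique = total,
                 rollup = c(rRNA = rrna, non_rRNA = 1 - rrna)),
            class = "class_counts")
}

#' @export
print.class_counts <- function(x, ...) {
  cat(sprintf("Class counts over %d uniquely mapped reads\n",
              x$total_unique))
  for (nm in names(x$counts))
    if (x$counts[[nm]] > 0)
      cat(sprintf("  %-18s %9d  %5.1f%%\n", nm, x$counts[[nm]],
                  round(100 * x$proportions[[nm]], 1)))
  cat(sprintf("  rollup: rRNA %.1f%%, non-rRNA %.1f%%\n",
              round(100 * x$rollup[["rRNA"]], 1),
              round(100 * x$rollup[["non_rRNA"]], 1)))
  invisible(x)
}

#' Depletion efficiency from before/after read-class proportions
#'
#' Estimates the fraction of targeted RNA removed by treatment from the
#' targeted-class read fractions of an untreated (`f_u`) and a depleted
#' (`f_d`) library. The default odds-ratio form,
#' `E = 1 - [f_d / (1 - f_d)] / [f_u / (1 - f_u)]`,
#' is compositionally correct: removing targeted molecules inflates the
#' apparent proportion of everything else, which the odds normalization
#' cancels. The naive form `1 - f_d / f_u` is also available and
#' underestimates removal when depletion is strong.
#'
#' @param f_u,f_d Targeted-class fractions of unique reads in the untreated
#'   and depleted libraries; `0 < f_u < 1`, `0 <= f_d < 1`.
#' @param method `"odds"` (default) or `"naive"`.
#' @return Numeric efficiency in `[0, 1]` when `f_d <= f_u`.
#' @export
depletion_efficiency <- function(f_u, f_d, method = c("odds", "naive")) {
  method <- match.arg(method)
  if (!(f_u > 0 && f_u < 1)) stop("f_u must be strictly inside (0, 1)")
  if (!(f_d >= 0 && f_d < 1)) stop("f_d must be in [0, 1)")
  if (method == "odds")
    1 - (f_d / (1 - f_d)) / (f_u / (1 - f_u))
  else
    1 - f_d / f_u
}

#' Cross-library transcript-abundance correlation
#'
#' Pearson correlation of log10 read counts across genes detected (count
#' greater than zero) in both libraries — zero-count genes are excluded
#' pairwise, which is required for log10 on both axes. Per-stratum
#' correlations are reported for small-RNA biotypes (sno/sn/sc/mir) and
#' probe-homolog flags, along with identity-line residuals
#' (`log10(b) - log10(a)`) for outlier listing.
#'
#' @param lib_a,lib_b Library-counts `data.frame`s (`gene_id`, `count`,
#'   `biotype`, `homolog`; see [read_library_counts()]). Biotype/homolog
#'   annotations are taken from `lib_a`.
#' @param min_genes Minimum number of shared nonzero genes (default 3).
#' @return List with `R` (overall Pearson R on log10 counts), `n_genes`,
#'   `data` (per-gene log10 counts, annotations and residuals) and `strata`
#'   (`data.frame` of stratum, n, R).
#' @export
transcript_correlation <- function(lib_a, lib_b, min_genes = 3) {
  m <- merge(lib_a[, c("gene_id", "count", "biotype", "homolog")],
             lib_b[, c("gene_id", "count")],
             by = "gene_id", suffixes = c("_a", "_b"))
  m <- m[m$count_a > 0 & m$count_b > 0, , drop = FALSE]
  if (nrow(m) < min_genes)
    stop("fewer than ", min_genes, " genes with nonzero counts in both ",
         "libraries")
  m$log10_a <- log10(m$count_a)
  m$log10_b <- log10(m$count_b)
  m$residual <- m$log10_b - m$log10_a
  overall <- stats::cor(m$log10_a, m$log10_b)
  m$stratum <- ifelse(m$homolog != "none", m$homolog,
                      ifelse(m$biotype %in% c("sno", "sn", "sc", "mir"),
                             "small_RNA", "other"))
  strata <- do.call(rbind, lapply(split(m, m$stratum), function(d) {
    data.frame(stratum = d$stratum[1], n = nrow(d),
               R = if (nrow(d) >= 3 && stats::sd(d$log10_a) > 0 &&
                       stats::sd(d$log10_b) > 0)
                 stats::cor(d$log10_a, d$log10_b) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(strata) <- NULL
  list(R = overall, n_genes = nrow(m),
       data = m[, c("gene_id", "log10_a", "log10_b", "biotype", "homolog",
                    "stratum", "residual")],
       strata = strata)
}

#' Broad RNA-class distribution of uniquely mapped reads
#'
#' Rolls the per-label classification up to five broad classes: `rRNA` (all
#' reads on the ribosomal repeating-unit transcript, targeted or not),
#' `Mito` (all reads on the mitochondrial contig), `exon`, `intron` and
#' `intergenic`. Uses the same overlap priority rule as [classify_reads()].
#'
#' @inheritParams classify_reads
#' @return Named numeric vector of proportions summing to 1, plus
#'   `attr(x, "counts")`.
#' @export
exon_intron_intergenic_profile <- function(alignments, annotation) {
  lab <- classify_reads(alignments, annotation)
  if (!length(lab)) stop("zero unique reads")
  broad <- c(rRNA_18S = "rRNA", rRNA_28S = "rRNA", rRNA_5_8S = "rRNA",
             rRNA_nontargeted = "rRNA",
             mt_12S = "Mito", mt_16S = "Mito", mt_other = "Mito",
             exon = "exon", intron = "intron", intergenic = "intergenic")
  b <- factor(broad[as.character(lab)],
              levels = c("rRNA", "Mito", "exon", "intron", "intergenic"))
  counts <- table(b)
  out <- as.numeric(counts) / length(lab)
  names(out) <- names(counts)
  attr(out, "counts") <- stats::setNames(as.integer(counts), names(counts))
  out
}

#' Write a Table-1-style class-proportion row
#'
#' @param x A `class_counts` object.
#' @param library_id,treatment,depletion Annotation strings for the row.
#' @param path Output TSV path; the file is created with a header if absent,
#'   appended otherwise.
#' @return `path`, invisibly.
#' @export
write_class_row <- function(x, library_id, treatment, depletion, path) {
  stopifnot(inherits(x, "class_counts"))
  row <- data.frame(library_id = library_id, treatment = treatment,
                    depletion = depletion,
                    non_rRNA_pct = round(100 * x$rollup[["non_rRNA"]], 1),
                    rRNA_pct = round(100 * x$rollup[["rRNA"]], 1),
                    stringsAsFactors = FALSE)
  write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
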