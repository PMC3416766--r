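#' Region class labels
#'
#' The closed vocabulary of annotation labels used throughout the package.
#' Targeted ribosomal subunits (`rRNA_18S`, `rRNA_28S`, `rRNA_5_8S`) are the
#' regions covered by depletion probes; `rRNA_nontargeted` marks the spacer
#' portions of the ribosomal repeating-unit transcript that carry no probes;
#' `mt_12S`/`mt_16S` are the mitochondrial rRNAs and `mt_other` the rest of
#' the mitochondrial contig; `exon`, `intron` and `intergenic` describe the
#' nuclear gene space.
#'
#' @return Character vector of the ten valid labels, in classification
#'   priority order (highest first).
#' @export
region_labels <- function() {
  c("rRNA_18S", "rRNA_28S", "rRNA_5_8S", "rRNA_nontargeted",
    "mt_12S", "mt_16S", "mt_other", "exon", "intron", "intergenic")
}

# classification priority ladder; smaller = wins when a read spans two classes
.label_priority <- c(
  rRNA_18S = 1L, rRNA_28S = 1L, rRNA_5_8S = 1L,
  rRNA_nontargeted = 2L, mt_12S = 3L, mt_16S = 3L, mt_other = 4L,
  exon = 5L, intron = 6L, intergenic = 7L
)

# labels rolled up into the "rRNA" category: nuclear + mitochondrial rRNAs,
# including the non-targeted spacers of the ribosomal transcript
.rrna_rollup_labels <- c("rRNA_18S", "rRNA_28S", "rRNA_5_8S",
                         "rRNA_nontargeted", "mt_12S", "mt_16S")

#' Construct a region table
#'
#' Regions are labeled genomic intervals in 0-based half-open coordinates,
#' the package-wide convention (1-based coordinates appear only at the SAM
#' boundary).
#'
#' @param contig Character vector of contig names.
#' @param start,end Integer vectors; `0 <= start < end`, end exclusive.
#' @param label Character vector drawn from [region_labels()].
#' @param gene_id Optional character vector of gene identifiers (`NA` where
#'   not applicable).
#' @return A `data.frame` with columns `contig`, `start`, `end`, `label`,
#'   `gene_id`.
#' @export
regions <- function(contig = character(), start = integer(), end = integer(),
                    label = character(), gene_id = NA_character_) {
  df <- data.frame(contig = as.character(contig),
                   start = as.integer(start), end = as.integer(end),
                   label = as.character(label),
                   gene_id = rep_len(as.character(gene_id),
                                     length(contig)),
                   stringsAsFactors = FALSE)
  validate_regions(df)
  df
}

validate_regions <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("contig", "start", "end", "label") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("invalid region coordinates: require 0 <= start < end")
  bad <- setdiff(unique(df$label), region_labels())
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  invisible(df)
}

regions_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    label = df$label,
    gene_id = if ("gene_id" %in% names(df)) df$gene_id else NA_character_)
}

#' Read a FASTA file of DNA (or RNA) sequences
#'
#' Sequences are uppercased and U is converted to T, so RNA targets are
#' handled on the DNA alphabet. Only A/C/G/T/N are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id (first token of
#'   each header); the remainder of the header is kept in
#'   `mcols(x)$description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out)$description <- character(0)
    return(out)
  }
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA (", path, "): ",
                         conditionMessage(e), call. = FALSE))
  seqs <- toupper(chartr("Uu", "Tt", as.character(raw)))
  if (any(!nzchar(seqs)))
    stop("malformed FASTA (", path, "): empty sequence record '",
         names(raw)[which(!nzchar(seqs))[1]], "'")
  if (any(grepl("[^ACGTN]", seqs))) {
    lines <- readLines(path, warn = FALSE)
    is_seq <- !startsWith(lines, ">")
    off <- which(is_seq & grepl("[^ACGTNUacgtnu[:space:]]", lines))
    stop(sprintf("illegal sequence character at line %d of %s",
                 if (length(off)) off[1] else NA_integer_, path))
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write sequences to FASTA
#'
#' @param x Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read alignments from SAM or a plain alignment table
#'
#' Supports a minimal SAM subset (header plus the 11 mandatory columns, with
#' the optional `NH` tag honoured) or a 5-column TSV
#' (`read_id contig pos length unique`, 0-based positions, `unique` as 0/1).
#' Unmapped SAM records (FLAG bit 0x4) are dropped. A read is considered
#' uniquely mapped iff its `NH` tag is absent or 1 and `MAPQ >= min_mapq`
#' (SAM), or its explicit unique column is 1 (TSV).
#'
#' @param path Input file.
#' @param min_mapq Minimum MAPQ for the SAM uniqueness rule (default 10).
#' @param dialect `"sam"` or `"tsv"`.
#' @return `data.frame` with columns `read_id`, `contig`, `pos` (0-based
#'   leftmost), `length` (reference span in bases), `unique` (logical).
#' @export
read_alignments <- function(path, min_mapq = 10, dialect = c("sam", "tsv")) {
  dialect <- match.arg(dialect)
  empty <- data.frame(read_id = character(), contig = character(),
                      pos = integer(), length = integer(), unique = logical(),
                      stringsAsFactors = FALSE)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "sam") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
    if (!length(lines)) return(empty)
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 11))
      stop("SAM record with fewer than 11 mandatory fields in ", path)
    flag <- as.integer(vapply(f, `[[`, "", 2L))
    mapped <- bitwAnd(flag, 4L) == 0L
    f <- f[mapped]
    if (!length(f)) return(empty)
    pos1 <- as.integer(vapply(f, `[[`, "", 4L))
    if (anyNA(pos1) || any(pos1 < 1L))
      stop("invalid (non-positive) mapped position in ", path)
    mapq <- as.integer(vapply(f, `[[`, "", 5L))
    cigar <- vapply(f, `[[`, "", 6L)
    len <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
    nh <- vapply(f, function(x) {
      if (length(x) <= 11L) return(NA_integer_)
      t <- grep("^NH:i:", x[-seq_len(11L)], value = TRUE)
      if (length(t)) as.integer(sub("^NH:i:", "", t[1])) else NA_integer_
    }, integer(1))
    data.frame(read_id = vapply(f, `[[`, "", 1L),
               contig = vapply(f, `[[`, "", 3L),
               pos = pos1 - 1L, length = as.integer(len),
               unique = (is.na(nh) | nh == 1L) & mapq >= min_mapq,
               stringsAsFactors = FALSE)
  } else {
    if (file.size(path) == 0) return(empty)
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("read_id", "contig", "pos", "length",
                                   "unique"),
                     colClasses = c("character", "character", "integer",
                                    "integer", "integer"),
                     stringsAsFactors = FALSE)
    if (any(df$pos < 0)) stop("negative coordinate in ", path)
    if (any(df$length < 1)) stop("non-positive read length in ", path)
    df$unique <- df$unique == 1L
    df
  }
}

#' Write an alignment table (TSV dialect)
#'
#' @param alignments Alignment `data.frame` as returned by
#'   [read_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path) {
  out <- alignments[, c("read_id", "contig", "pos", "length", "unique")]
  out$unique <- as.integer(out$unique)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write regions to BED
#'
#' BED is 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged. The class label is stored in the BED
#' name column (as `label|gene_id` when a gene id is present). Exact
#' duplicate rows are removed with a warning.
#'
#' @param reg Region `data.frame` (see [regions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(reg, path) {
  validate_regions(reg)
  key <- paste(reg$contig, reg$start, reg$end, reg$label)
  if (anyDuplicated(key)) {
    warning("duplicate region rows removed")
    reg <- reg[!duplicated(key), , drop = FALSE]
  }
  if (nrow(reg) == 0) {
    file.create(path)
    return(invisible(path))
  }
  has_gene <- !is.na(reg$gene_id) & nzchar(reg$gene_id)
  nm <- ifelse(has_gene, paste0(reg$label, "|", reg$gene_id), reg$label)
  gr <- GenomicRanges::GRanges(reg$contig,
                               IRanges::IRanges(reg$start + 1L, reg$end),
                               name = nm, score = 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read regions from BED
#'
#' @param path BED file written by [write_bed()] (label in the name column).
#' @return Region `data.frame`, sorted by (contig, start).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(regions())
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  label <- sub("\\|.*$", "", nm)
  gene <- ifelse(grepl("|", nm, fixed = TRUE),
                 sub("^[^|]*\\|", "", nm), NA_character_)
  df <- regions(contig = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr),
                label = label, gene_id = gene)
  df[order(df$contig, df$start), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Read / write per-transcript count tables
#'
#' Tab-separated tables with columns `gene_id`, `count`, `biotype`
#' (`sno`/`sn`/`sc`/`mir`/`other`) and `homolog`
#' (`none`/`SDRNA`/`SDRNA2-only`), the library-counts container used by the
#' correlation analytics.
#'
#' @param path File path.
#' @return `read_library_counts`: a `data.frame` with the four columns.
#' @export
read_library_counts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "numeric", "character",
                                  "character"),
                   stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "count", "biotype", "homolog") %in% names(df)))
  if (any(df$count < 0)) stop("negative count in ", path)
  df
}

#' @param counts Library-counts `data.frame`.
#' @rdname read_library_counts
#' @export
write_library_counts <- function(counts, path) {
  write.table(counts[, c("gene_id", "count", "biotype", "homolog")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
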