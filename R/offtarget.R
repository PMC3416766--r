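#' BLASTN-style local alignment scoring scheme
#'
#' Default values reproduce low-stringency blastn screening parameters:
#' match +2, mismatch -3, gap open cost 5, gap extension cost 2 (a gap of
#' length k costs `5 + 2k`), word size 11 for the seeded search.
#'
#' @param match Positive match score.
#' @param mismatch Negative mismatch score.
#' @param gap_open,gap_extend Positive gap costs.
#' @param word_size Seed word length for the seeded fast path.
#' @return A `scoring_scheme` list.
#' @export
blast_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                          gap_extend = 2, word_size = 11) {
  stopifnot(match > 0, mismatch < 0, gap_open > 0, gap_extend > 0,
            word_size >= 4)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 word_size = as.integer(word_size)),
            class = "scoring_scheme")
}

# exact DP on one strand of a (sub)sequence; returns the raw C++ hit list
.align_one <- function(query, subject, scoring) {
  cpp_local_align(query, subject, scoring$match, scoring$mismatch,
                  scoring$gap_open, scoring$gap_extend)
}

# seed windows: merged intervals of the subject around exact word matches of
# the query; empty when the query contains N or no word matches
.seed_windows <- function(query, subject, word_size, margin) {
  n <- nchar(query)
  if (n < word_size || grepl("N", query, fixed = TRUE) ||
      grepl("N", subject, fixed = TRUE))
    return(NULL)
  words <- unique(substring(query, seq_len(n - word_size + 1L),
                            seq_len(n - word_size + 1L) + word_size - 1L))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(words))
  hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject))
  ir <- unlist(hits, use.names = FALSE)
  if (!length(ir)) return(NULL)
  win <- IRanges::IRanges(
    start = pmax(1L, IRanges::start(ir) - margin),
    end = pmin(nchar(subject), IRanges::end(ir) + margin))
  IRanges::reduce(win)
}

# best hit of query against one strand; seeded mode restricts the DP to
# windows around exact word matches and falls back to full DP when no seed
# exists (so scores match the exhaustive search whenever seeding is moot)
.align_strand <- function(query, subject, scoring, seeded) {
  if (seeded) {
    win <- .seed_windows(query, subject, scoring$word_size,
                         margin = 2L * nchar(query))
    if (!is.null(win)) {
      best <- NULL
      for (k in seq_along(win)) {
        ws <- IRanges::start(win)[k]
        h <- .align_one(query, substr(subject, ws, IRanges::end(win)[k]),
                        scoring)
        if (h$score > 0) {
          h$s_start <- h$s_start + ws - 1L
          h$s_end <- h$s_end + ws - 1L
        }
        if (is.null(best) || .hit_better(h, best)) best <- h
      }
      return(best)
    }
  }
  .align_one(query, subject, scoring)
}

# tie-break order: higher score, then longer alignment, then smaller subject
# start
.hit_better <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  if (a$aln_len != b$aln_len) return(a$aln_len > b$aln_len)
  a$s_start < b$s_start
}

#' Best local alignment of a probe against a subject sequence
#'
#' Exact affine-gap Smith-Waterman local alignment under a blastn-style
#' scoring scheme. Both strands of the subject are searched; minus-strand
#' coordinates are reported on the original (plus-strand) subject. With
#' `seeded = TRUE` the dynamic programming is restricted to windows around
#' exact `word_size`-mers shared between query and subject, with a full-DP
#' fallback when no seed exists.
#'
#' @param query,subject Non-empty ACGTN character scalars.
#' @param scoring A [blast_scoring()] scheme.
#' @param seeded Use the word-seeded fast path (default `FALSE` = exhaustive
#'   DP).
#' @return One-row `data.frame`: `score`, `aln_len`, `identities`,
#'   `identity_frac` (identities / query length), `q_start`, `q_end`,
#'   `s_start`, `s_end` (1-based inclusive spans), `strand`.
#' @export
local_align <- function(query, subject, scoring = blast_scoring(),
                        seeded = FALSE) {
  stopifnot(is.character(query), is.character(subject),
            length(query) == 1L, length(subject) == 1L)
  query <- toupper(query); subject <- toupper(subject)
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  if (grepl("[^ACGTN]", query) || grepl("[^ACGTN]", subject))
    stop("sequences must be ACGTN")
  fwd <- .align_strand(query, subject, scoring, seeded)
  rc <- antisense(subject)
  rev_ <- .align_strand(query, rc, scoring, seeded)
  n <- nchar(subject)
  if (rev_$score > 0) {  # map minus-strand span back to plus coordinates
    s1 <- n - rev_$s_end + 1L
    s2 <- n - rev_$s_start + 1L
    rev_$s_start <- s1; rev_$s_end <- s2
  }
  pick_fwd <- !.hit_better(rev_, fwd)  # prefer + strand on full ties
  h <- if (pick_fwd) fwd else rev_
  data.frame(score = h$score, aln_len = h$aln_len,
             identities = h$identities,
             identity_frac = h$identities / nchar(query),
             q_start = h$q_start, q_end = h$q_end,
             s_start = h$s_start, s_end = h$s_end,
             strand = if (pick_fwd) "+" else "-",
             stringsAsFactors = FALSE)
}

#' Screen a probe panel against a transcriptome
#'
#' Aligns every probe to every transcript (both strands), keeps the best hit
#' per pair with raw score at or above `score_floor`, and flags pairs whose
#' nucleotide identity — identities divided by probe length — is at least
#' `threshold`. Flagged genes are classified by the probes that hit them:
#' genes homologous to any core-target probe (default cores 18S/28S, the
#' probes shared by both panel versions) are flagged `"SDRNA"`, genes
#' homologous only to the added targets are flagged `"SDRNA2-only"`.
#'
#' @param panel A `probe_panel` from [build_panel()].
#' @param transcriptome Named [Biostrings::DNAStringSet] or named character
#'   vector of transcript sequences.
#' @param threshold Identity fraction required to flag a probe-gene pair
#'   (default 0.5).
#' @param score_floor Minimum raw alignment score to report a hit
#'   (default 20).
#' @param scoring A [blast_scoring()] scheme.
#' @param seeded Use the word-seeded fast path (default `TRUE`).
#' @param core_targets Target names whose probes belong to both panel
#'   versions.
#' @param mask_low_complexity Apply a DUST-style low-complexity mask to the
#'   probes before alignment (default `FALSE`).
#' @return List with `hits` (`data.frame`: `probe_id`, `gene_id`, `score`,
#'   `aln_len`, `identities`, `identity_frac`, `strand`, `flagged`),
#'   `probe_genes` (flagged pairs only) and `gene_flags`
#'   (`gene_id`, `flag` in `{SDRNA, SDRNA2-only}`).
#' @export
screen_panel <- function(panel, transcriptome, threshold = 0.5,
                         score_floor = 20, scoring = blast_scoring(),
                         seeded = TRUE, core_targets = c("18S", "28S"),
                         mask_low_complexity = FALSE) {
  stopifnot(inherits(panel, "probe_panel"), nrow(panel$probes) > 0)
  if (is.character(transcriptome))
    transcriptome <- Biostrings::DNAStringSet(transcriptome)
  if (!length(transcriptome)) stop("empty transcriptome")
  if (is.null(names(transcriptome)) || any(!nzchar(names(transcriptome))))
    stop("transcriptome sequences must be named")
  tx <- as.character(transcriptome)
  probes <- panel$probes
  qseq <- probes$sequence
  if (mask_low_complexity) qseq <- dust_mask(qseq)
  rows <- vector("list", nrow(probes) * length(tx))
  k <- 0L
  for (i in seq_len(nrow(probes))) {
    for (j in seq_along(tx)) {
      h <- local_align(qseq[i], tx[j], scoring, seeded)
      if (h$score >= score_floor) {
        k <- k + 1L
        h$probe_id <- probes$id[i]
        h$gene_id <- names(tx)[j]
        rows[[k]] <- h
      }
    }
  }
  hits <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(score = numeric(), aln_len = integer(),
               identities = integer(), identity_frac = numeric(),
               q_start = integer(), q_end = integer(), s_start = integer(),
               s_end = integer(), strand = character(),
               probe_id = character(), gene_id = character(),
               stringsAsFactors = FALSE)
  hits <- hits[, c("probe_id", "gene_id", "score", "aln_len", "identities",
                   "identity_frac", "strand"), drop = FALSE]
  hits$flagged <- hits$identity_frac >= threshold
  fl <- hits[hits$flagged, , drop = FALSE]
  target_of <- structure(probes$target_name, names = probes$id)
  gene_flags <- if (nrow(fl)) {
    spl <- split(target_of[fl$probe_id], fl$gene_id)
    data.frame(gene_id = names(spl),
               flag = vapply(spl, function(tg)
                 if (any(tg %in% core_targets)) "SDRNA" else "SDRNA2-only",
                 ""),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(gene_id = character(), flag = character(),
               stringsAsFactors = FALSE)
  }
  list(hits = hits,
       probe_genes = fl[, c("probe_id", "gene_id", "identity_frac"),
                        drop = FALSE],
       gene_flags = gene_flags)
}

#' DUST-style low-complexity masking
#'
#' Replaces low-complexity stretches with N. Complexity is scored per window
#' from triplet frequencies (`sum n_t (n_t - 1) / 2`, scaled by window
#' length); windows above `threshold` are masked. Off by default in
#' [screen_panel()].
#'
#' @param seq Character vector of sequences.
#' @param window Window width (default 64).
#' @param threshold DUST score above which a window is masked (default 2).
#' @return Masked character vector.
#' @export
dust_mask <- function(seq, window = 64, threshold = 2) {
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n < 3) return(s)
    chars <- strsplit(s, "")[[1]]
    masked <- logical(n)
    starts <- seq(1L, max(1L, n - 2L), by = max(1L, window %/% 2L))
    for (ws in starts) {
      we <- min(n, ws + window - 1L)
      if (we - ws + 1L < 3L) next
      tri <- paste0(chars[ws:(we - 2L)], chars[(ws + 1L):(we - 1L)],
                    chars[(ws + 2L):we])
      cnt <- table(tri)
      score <- sum(cnt * (cnt - 1) / 2) / (we - ws - 1L)
      if (score > threshold) masked[ws:we] <- TRUE
    }
    if (any(masked)) {
      chars[masked] <- "N"
      paste(chars, collapse = "")
    } else s
  }, "", USE.NAMES = FALSE)
}

#' Write / read the off-target hit table and gene homolog flags
#'
#' @param screen Result of [screen_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(screen, path) {
  write.table(screen$hits, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
write_gene_flags <- function(screen, path) {
  write.table(screen$gene_flags, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_gene_flags <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = "character", stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "flag") %in% names(df)))
  df
}
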