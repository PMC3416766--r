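#' 3'-adapter trimming policy
#'
#' Describes how adapter content is removed from read 3' ends: the full
#' adapter is shortened one base at a time and each prefix is compared
#' (Hamming distance, no gaps) to the read suffix of the same length; the
#' longest prefix within the mismatch allowance is trimmed. A fixed number
#' of additional bases can then be removed from both read ends.
#'
#' @param adapter Adapter sequence (ACGTN character scalar).
#' @param k_min Shortest adapter prefix tested (default 5).
#' @param mismatch_allowance Function of match length `k` returning the
#'   maximum tolerated mismatches; must be non-negative and non-decreasing.
#'   Default `floor(k / 10)`, i.e. roughly 10% tolerance.
#' @param fixed_5p,fixed_3p Fixed bases removed from the 5' and 3' ends
#'   after adapter trimming (defaults 6 and 8).
#' @return A `trim_policy` list.
#' @export
trim_policy <- function(adapter, k_min = 5,
                        mismatch_allowance = function(k) k %/% 10,
                        fixed_5p = 6, fixed_3p = 8) {
  adapter <- toupper(adapter)
  if (!is.character(adapter) || length(adapter) != 1L || !nzchar(adapter))
    stop("adapter must be a non-empty sequence")
  if (grepl("[^ACGTN]", adapter)) stop("adapter must be ACGTN")
  stopifnot(k_min >= 1, is.function(mismatch_allowance),
            fixed_5p >= 0, fixed_3p >= 0)
  ks <- seq_len(nchar(adapter))
  allow <- vapply(ks, mismatch_allowance, numeric(1))
  if (any(allow < 0) || any(diff(allow) < 0))
    stop("mismatch_allowance must be non-negative and non-decreasing")
  structure(list(adapter = adapter, k_min = as.integer(k_min),
                 allowance = as.integer(allow),
                 fixed_5p = as.integer(fixed_5p),
                 fixed_3p = as.integer(fixed_3p)),
            class = "trim_policy")
}

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Trim adapter content from read 3' ends
#'
#' For each read, adapter prefixes are tested longest-first (from the full
#' adapter length down to `policy$k_min`) against the read suffix of equal
#' length; the first prefix matching with at most `allowance(k)` mismatches
#' trims `k` bases. Reads with no qualifying suffix are returned unchanged.
#' The output is always a prefix of the input read.
#'
#' @param reads Character vector of read sequences.
#' @param policy A [trim_policy()].
#' @return List with `sequence` (trimmed reads) and `trim_len` (bases
#'   removed per read).
#' @export
trim_adapter <- function(reads, policy) {
  stopifnot(inherits(policy, "trim_policy"))
  if (any(!nzchar(reads))) stop("empty read")
  amax <- nchar(policy$adapter)
  trim_len <- integer(length(reads))
  out <- reads
  for (i in seq_along(reads)) {
    r <- reads[i]
    n <- nchar(r)
    for (k in seq(min(amax, n), policy$k_min)) {
      if (k < policy$k_min) break
      if (.hamming(substr(r, n - k + 1L, n),
                   substr(policy$adapter, 1L, k)) <= policy$allowance[k]) {
        out[i] <- substr(r, 1L, n - k)
        trim_len[i] <- k
        break
      }
    }
  }
  list(sequence = out, trim_len = trim_len)
}

#' Fixed-length end trimming
#'
#' Removes `n5` bases from the 5' end and `n3` bases from the 3' end of each
#' read. Reads too short to retain at least one base are dropped; the number
#' dropped is available as `attr(result, "n_dropped")` and the surviving
#' indices as `attr(result, "kept")`.
#'
#' @param reads Character vector of read sequences.
#' @param n5,n3 Bases to remove from each end.
#' @return Character vector of trimmed reads (with attributes `n_dropped`
#'   and `kept`).
#' @export
trim_fixed <- function(reads, n5 = 6, n3 = 8) {
  stopifnot(n5 >= 0, n3 >= 0)
  len <- nchar(reads)
  keep <- len > n5 + n3
  out <- substr(reads[keep], n5 + 1L, len[keep] - n3)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "kept") <- which(keep)
  out
}

#' Trim a FASTQ file (adapter, then fixed ends)
#'
#' Applies [trim_adapter()] followed by [trim_fixed()] (that composition
#' order is fixed), trimming quality strings identically, and writes the
#' surviving reads to `outfile`. A JSON statistics log (reads in/out,
#' adapter-trimmed count, dropped count, mean trim length) is written when
#' `stats_path` is given.
#'
#' @param infile,outfile FASTQ paths.
#' @param policy A [trim_policy()].
#' @param stats_path Optional path for the JSON trim-statistics log.
#' @return The statistics list, invisibly.
#' @export
trim_fastq <- function(infile, outfile, policy, stats_path = NULL) {
  fq <- Biostrings::readDNAStringSet(infile, format = "fastq",
                                     with.qualities = TRUE)
  seqs <- as.character(fq)
  quals <- as.character(S4Vectors::mcols(fq)$qualities)
  ta <- trim_adapter(seqs, policy)
  quals <- substr(quals, 1L, nchar(ta$sequence))
  tf <- trim_fixed(ta$sequence, policy$fixed_5p, policy$fixed_3p)
  kept <- attr(tf, "kept")
  quals <- substr(quals[kept], policy$fixed_5p + 1L,
                  nchar(ta$sequence[kept]) - policy$fixed_3p)
  out <- Biostrings::DNAStringSet(tf)
  names(out) <- names(fq)[kept]
  Biostrings::writeXStringSet(out, outfile, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  stats <- list(reads_in = length(seqs), reads_out = length(tf),
                adapter_trimmed = sum(ta$trim_len > 0),
                dropped = attr(tf, "n_dropped"),
                mean_trim_len = if (length(seqs)) mean(ta$trim_len) else 0)
  if (!is.null(stats_path))
    jsonlite::write_json(stats, stats_path, auto_unbox = TRUE)
  invisible(stats)
}
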