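#' Specify a depletion target
#'
#' A target is one RNA species to be removed by RNase H depletion: its name,
#' sense-strand sequence and concentration group. Group "A" probes are pooled
#' at 0.5 uM each (the 18S/28S nuclear rRNA probes); group "B" probes at
#' 0.05 uM each (5.8S and the mitochondrial 12S/16S rRNA probes). When
#' `conc_group` is not given it is inferred from the target name under that
#' convention.
#'
#' @param name Target name, e.g. `"18S"`.
#' @param sequence Sense-strand DNA sequence (character; U is converted to T).
#' @param target_class `"nuclear_rRNA"` or `"mito_rRNA"`.
#' @param conc_group `"A"` (0.5 uM/probe) or `"B"` (0.05 uM/probe);
#'   default inferred from `name`.
#' @return A `target_spec` object (list).
#' @export
target_spec <- function(name, sequence,
                        target_class = c("nuclear_rRNA", "mito_rRNA"),
                        conc_group = NULL) {
  target_class <- match.arg(target_class)
  sequence <- toupper(chartr("Uu", "Tt", as.character(sequence)))
  if (grepl("[^ACGTN]", sequence))
    stop("target sequence contains characters outside ACGTN")
  if (is.null(conc_group))
    conc_group <- if (name %in% c("18S", "28S")) "A" else "B"
  conc_group <- match.arg(conc_group, c("A", "B"))
  structure(list(name = name, sequence = sequence,
                 target_class = target_class, conc_group = conc_group),
            class = "target_spec")
}

# per-probe molar concentration (uM) by group
.conc_uM <- c(A = 0.5, B = 0.05)

#' Tile a target length into probe intervals
#'
#' Partitions `[0, L)` into adjacent, non-overlapping probe windows. The
#' greedy policy lays consecutive `max_len` windows from position 0 and
#' appends one remainder window of length `L mod max_len` when that remainder
#' is at least `min_len`; when the remainder is shorter (but nonzero) the
#' target falls back to the balanced policy so that coverage is not lost.
#' The balanced policy uses `ceiling(L / max_len)` windows whose lengths
#' differ by at most one base.
#'
#' Either way the number of windows is `ceiling(L / max_len)` and the windows
#' exactly cover `[0, L)` except for a possible uncovered greedy remainder
#' shorter than `min_len` (which the fallback prevents by default).
#'
#' @param L Target length in nt.
#' @param max_len,min_len Probe length bounds (defaults 80 and 39 nt; 39 nt
#'   is the shortest probe in the reference panels, the 16S remainder).
#' @param policy `"greedy"` (with balanced fallback) or `"balanced"`.
#' @return `data.frame` with 0-based half-open `start`, `end` columns,
#'   sorted by `start`.
#' @export
tile_intervals <- function(L, max_len = 80, min_len = 39,
                           policy = c("greedy", "balanced")) {
  policy <- match.arg(policy)
  L <- as.integer(L)
  stopifnot(max_len >= min_len, min_len >= 1)
  if (L < min_len)
    stop("design error: target length ", L, " is shorter than min_len ",
         min_len)
  if (policy == "greedy") {
    r <- L %% max_len
    if (r != 0L && r < min_len)
      return(tile_intervals(L, max_len, min_len, "balanced"))
    k <- L %/% max_len
    starts <- seq.int(0L, by = max_len, length.out = k)
    ends <- starts + max_len
    if (r > 0L) {
      starts <- c(starts, k * max_len)
      ends <- c(ends, L)
    }
  } else {
    n <- ceiling(L / max_len)
    base <- L %/% n
    extra <- L %% n
    lens <- c(rep.int(base + 1L, extra), rep.int(base, n - extra))
    if (any(lens < min_len) || any(lens > max_len))
      stop("balanced tiling cannot satisfy probe length bounds for L = ", L)
    ends <- cumsum(lens)
    starts <- ends - lens
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' @param target A [target_spec()].
#' @rdname tile_intervals
#' @export
tile_target <- function(target, max_len = 80, min_len = 39,
                        policy = c("greedy", "balanced")) {
  stopifnot(inherits(target, "target_spec"))
  tile_intervals(nchar(target$sequence), max_len, min_len, policy)
}

#' Antisense (reverse complement) of a DNA sequence
#'
#' The probe sequence complementary to a sense-strand window. An involution:
#' `antisense(antisense(x)) == x`.
#'
#' @param seq Character vector of ACGTN sequences.
#' @return Character vector of reverse complements.
#' @export
antisense <- function(seq) {
  if (!length(seq)) return(character())
  if (any(grepl("[^ACGTN]", seq)))
    stop("illegal character: sequences must be ACGTN")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Build a versioned probe panel
#'
#' Tiles each target and assembles the antisense probes into a pool with
#' per-probe molar concentrations set by each target's concentration group.
#' The `SDRNA1` version is built from the 18S and 28S nuclear rRNA targets;
#' `SDRNA2` extends it with the 5.8S, 12S and 16S targets. Probe ids are
#' deterministic (`<target>_<ordinal>`, 5'->3' along the sense strand, in
#' target order).
#'
#' @param targets List of [target_spec()] objects with unique names.
#' @param version Panel label: `"SDRNA1"`, `"SDRNA2"` or any custom string.
#'   The two named versions enforce their expected target sets.
#' @param max_len,min_len,policy Passed to [tile_target()].
#' @return A `probe_panel`: list with `version`, `probes` (`data.frame` of
#'   `id`, `target_name`, `start`, `end`, `length`, `sequence`, `conc_uM`)
#'   and `total_conc` (uM).
#' @export
build_panel <- function(targets, version = "custom",
                        max_len = 80, min_len = 39,
                        policy = c("greedy", "balanced")) {
  policy <- match.arg(policy)
  if (!length(targets)) stop("empty target list")
  stopifnot(all(vapply(targets, inherits, TRUE, "target_spec")))
  nms <- vapply(targets, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate target names")
  expected <- switch(version,
                     SDRNA1 = c("18S", "28S"),
                     SDRNA2 = c("18S", "28S", "5.8S", "12S", "16S"),
                     NULL)
  if (!is.null(expected) && !setequal(nms, expected))
    stop(version, " panels are built from targets {",
         paste(expected, collapse = ", "), "}")
  per_target <- lapply(targets, function(tg) {
    iv <- tile_target(tg, max_len, min_len, policy)
    window <- substring(tg$sequence, iv$start + 1L, iv$end)
    data.frame(id = sprintf("%s_%d", tg$name, seq_len(nrow(iv))),
               target_name = tg$name,
               start = iv$start, end = iv$end,
               length = iv$end - iv$start,
               sequence = antisense(window),
               conc_uM = .conc_uM[[tg$conc_group]],
               stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, per_target)
  rownames(probes) <- NULL
  structure(list(version = version, probes = probes,
                 total_conc = sum(probes$conc_uM)),
            class = "probe_panel")
}

#' @export
print.probe_panel <- function(x, ...) {
  cat(sprintf("Probe panel '%s': %d probes over %d target(s), %.2f uM total\n",
              x$version, nrow(x$probes),
              length(unique(x$probes$target_name)), x$total_conc))
  tab <- table(x$probes$target_name)
  for (nm in unique(x$probes$target_name))
    cat(sprintf("  %-6s %3d probes\n", nm, tab[[nm]]))
  invisible(x)
}

#' Summarize a probe panel
#'
#' @param panel A `probe_panel` from [build_panel()].
#' @return List with `probe_table` (per-probe row: id, target, coordinates,
#'   length, GC percentage, concentration, sequence — the pool recipe),
#'   `target_summary` (per-target probe counts and length range) and
#'   `length_hist` (probe-length tally).
#' @export
panel_report <- function(panel) {
  stopifnot(inherits(panel, "probe_panel"))
  p <- panel$probes
  gc <- Biostrings::letterFrequency(Biostrings::DNAStringSet(p$sequence),
                                    letters = "GC")
  probe_table <- data.frame(
    id = p$id, target_name = p$target_name, start = p$start, end = p$end,
    length = p$length, gc_pct = round(100 * as.numeric(gc) / p$length, 2),
    conc_uM = p$conc_uM, sequence = p$sequence, stringsAsFactors = FALSE)
  spl <- split(p, factor(p$target_name, levels = unique(p$target_name)))
  target_summary <- data.frame(
    target_name = names(spl),
    n_probes = vapply(spl, nrow, 1L),
    min_len = vapply(spl, function(d) min(d$length), 1L),
    max_len = vapply(spl, function(d) max(d$length), 1L),
    conc_uM_per_probe = vapply(spl, function(d) d$conc_uM[1], 1),
    stringsAsFactors = FALSE, row.names = NULL)
  lh <- table(p$length)
  length_hist <- data.frame(length = as.integer(names(lh)),
                            n = as.integer(lh))
  list(probe_table = probe_table, target_summary = target_summary,
       length_hist = length_hist,
       version = panel$version, total_conc = panel$total_conc)
}

#' Write panel outputs
#'
#' `write_probe_fasta` writes the antisense probe sequences;
#' `write_pool_recipe` writes the per-probe recipe TSV (id, target,
#' coordinates, length, GC%, uM, sequence); `write_probe_bed` writes probe
#' intervals in target coordinates. Output is byte-deterministic for
#' identical panels.
#'
#' @param panel A `probe_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(panel, path) {
  seqs <- Biostrings::DNAStringSet(panel$probes$sequence)
  names(seqs) <- panel$probes$id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_probe_fasta
#' @export
write_pool_recipe <- function(panel, path) {
  rep_ <- panel_report(panel)
  write.table(rep_$probe_table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_fasta
#' @export
write_probe_bed <- function(panel, path) {
  p <- panel$probes
  df <- data.frame(contig = p$target_name, start = p$start, end = p$end,
                   name = p$id, score = 0L, strand = "-",
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
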