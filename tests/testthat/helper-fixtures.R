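# shared fixture builders; all fixtures are generated in code

rnd_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate k random positions of a sequence
mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  idx <- sample(length(ch), k)
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# the five reference panel targets as random sequences of the design lengths
panel_targets <- function() {
  list(target_spec("18S", rnd_dna(1976)),
       target_spec("28S", rnd_dna(5025)),
       target_spec("5.8S", rnd_dna(157)),
       target_spec("12S", rnd_dna(954), target_class = "mito_rRNA"),
       target_spec("16S", rnd_dna(1559), target_class = "mito_rRNA"))
}

# Biostrings local alignment as the independent scoring oracle
oracle_align <- function(q, s, gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  list(score = Biostrings::score(pa), identities = Biostrings::nmatch(pa))
}

# two-region annotation on one contig for priority tests
two_region_annotation <- function() {
  regions(contig = c("chrR", "chrR"), start = c(0L, 1000L),
          end = c(1000L, 2000L),
          label = c("rRNA_18S", "rRNA_nontargeted"))
}

sam_header <- "@HD\tVN:1.6\n@SQ\tSN:chrR\tLN:10000"

sam_line <- function(qname, flag, rname, pos, mapq, cigar, seq = "ACGT",
                     tags = character()) {
  paste(c(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq, "IIII",
          tags), collapse = "\t")
}
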