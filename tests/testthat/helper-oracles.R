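# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's scan/DP code paths: the naive scanner maximizes with
# explicit double loops, the distribution oracle enumerates all 4^w
# sequences, and the interval oracle is a direct linear filter.

BASES <- c("A", "C", "G", "T")

# reverse-complement log-odds built locally (not via reverse_complement())
rc_lods_of <- function(m) {
  m$lods[m$width:1, c(4L, 3L, 2L, 1L), drop = FALSE]
}

# Naive O(L*w) double-strand scan; ties keep the first candidate in
# (window ascending, '+' before '-') order, i.e. the documented tie-break.
naive_best_match <- function(seq, m) {
  w <- m$width
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  rc <- rc_lods_of(m)
  best <- NULL
  if (L >= w) for (j in seq_len(L - w + 1L)) {
    idx <- match(chars[j:(j + w - 1L)], BASES)
    if (anyNA(idx)) next
    for (strand in c("+", "-")) {
      lod <- if (strand == "+") m$lods else rc
      s <- 0
      for (i in seq_len(w)) s <- s + lod[i, idx[i]]
      if (is.null(best) || s > best$score)
        best <- list(score = unname(s), strand = strand,
                     win_start = j - 1L)
    }
  }
  best
}

# Exact null distribution by enumeration of all 4^w sequences, binned with
# the same granularity convention as the package (round to multiples of eps).
brute_distribution <- function(m, eps) {
  w <- m$width
  km <- round(m$lods / eps)
  total <- 4L^w
  idx <- 0:(total - 1)
  sc <- numeric(total)
  pr <- rep(1, total)
  for (i in seq_len(w)) {
    d <- (idx %/% 4^(i - 1)) %% 4 + 1
    sc <- sc + km[i, d]
    pr <- pr * m$background[d]
  }
  agg <- rowsum(pr, sc)
  list(support = as.numeric(rownames(agg)), mass = as.numeric(agg))
}

# Upper-tail probability from the enumeration oracle at a raw-score query,
# using the package's documented query-binning rule.
brute_pvalue <- function(bd, eps, raw) {
  b <- floor(raw / eps + 0.5)
  b <- min(max(b, min(bd$support)), max(bd$support))
  sum(bd$mass[bd$support >= b])
}

# Direct linear-scan half-open interval overlap filter.
linear_overlaps <- function(peaks, chrom, start, end) {
  if (end == start)
    keep <- peaks$chrom == chrom & peaks$start < start & peaks$end > start
  else
    keep <- peaks$chrom == chrom & peaks$start < end & peaks$end > start
  peaks[keep, , drop = FALSE]
}

# Apply an edit to a sequence string (0-based half-open span).
apply_edit <- function(seq, start0, ref, alt) {
  stopifnot(substr(seq, start0 + 1L, start0 + nchar(ref)) == ref)
  paste0(substr(seq, 1L, start0), alt,
         substr(seq, start0 + nchar(ref) + 1L, nchar(seq)))
}

random_dna <- function(len) paste(sample(BASES, len, replace = TRUE),
                                  collapse = "")

# One-row variant data.frame without re-normalization (for symmetry tests
# where the raw edit is already canonical by construction).
raw_variant_row <- function(chrom, start, ref, alt, vid = "v") {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + nchar(ref)), ref = ref, alt = alt,
             vid = vid,
             vclass = if (nchar(ref) == 1 && nchar(alt) == 1) "SNV"
                      else if (nchar(ref) == 0) "INS"
                      else if (nchar(alt) == 0) "DEL"
                      else if (nchar(ref) == nchar(alt)) "MNV"
                      else "DELINS",
             stringsAsFactors = FALSE)
}

# A small sharply informative hand-made motif with a given consensus.
consensus_motif <- function(cons, id = "HM1", tf = "HMTF") {
  chars <- strsplit(cons, "")[[1]]
  counts <- matrix(1, length(chars), 4)
  for (i in seq_along(chars)) counts[i, match(chars[i], BASES)] <- 18
  motif(counts, id = id, tf_name = tf)
}

make_allele_seq <- function(seq, v_s, v_e, genome_offset = 0L) {
  structure(list(seq = seq, v_s = v_s, v_e = v_e,
                 genome_offset = genome_offset), class = "allele_seq")
}

make_match <- function(win_start) {
  structure(list(matched = TRUE, win_start = as.integer(win_start)),
            class = "allele_match")
}
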