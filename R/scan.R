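#' Build reference and alternate allele sequences for a variant
#'
#' Extracts the reference sequence around the variant with exactly
#' `width - 1` bases of genomic context on each side, and constructs the
#' alternate-allele sequence by substituting the ALT string. This context
#' width is the minimal complete window set: every width-`w` window that
#' overlaps at least one varying position is contained in the sequence, and
#' no window that cannot overlap the variant is scanned. Context is clipped
#' (with a message) at chromosome ends.
#'
#' @param v one-row variant `data.frame` (see [variant_table()]).
#' @param m a `motif` (only its width is used), or an integer width.
#' @param genome a [Biostrings::DNAStringSet].
#' @return A list of two `allele_seq` objects, `ref` and `alt`, each with
#'   `seq` (character), `v_s`/`v_e` (0-based half-open span of the allele's
#'   variant bases within `seq`; empty interval at the breakpoint for the
#'   allele lacking bases), and `genome_offset` (genomic 0-based coordinate
#'   of `seq[1]`).
#' @export
build_allele_seqs <- function(v, m, genome) {
  w <- if (inherits(m, "motif")) m$width else as.integer(m)
  stopifnot(w >= 1L)
  chrom <- v$chrom
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' absent from genome")
  clen <- Biostrings::width(genome[names(genome) == chrom])[1]
  if (v$end > clen || v$start < 0L)
    stop("variant span [", v$start, ",", v$end, ") outside ", chrom,
         " (length ", clen, ")")
  win_s <- v$start - (w - 1L)
  win_e <- v$end + (w - 1L)
  if (win_s < 0L || win_e > clen) {
    message("clipping scan context for ", v$vid, " at chromosome edge")
    win_s <- max(0L, win_s)
    win_e <- min(clen, win_e)
  }
  refctx <- genome_subseq(genome, chrom, win_s, win_e)
  v_s <- v$start - win_s
  v_e <- v_s + (v$end - v$start)
  altseq <- paste0(substr(refctx, 1L, v_s), v$alt,
                   substr(refctx, v_e + 1L, nchar(refctx)))
  mk <- function(seq, vs, ve) structure(
    list(seq = seq, v_s = vs, v_e = ve, genome_offset = win_s),
    class = "allele_seq")
  list(ref = mk(refctx, v_s, v_e),
       alt = mk(altseq, v_s, v_s + nchar(v$alt)))
}

seq_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
}

# Per-window raw scores for one lods matrix over one strand of `codes`;
# windows containing non-ACGT characters come back NA. Additions run in
# ascending position order so float sums are reproducible.
window_scores <- function(lods, codes, w) {
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (i in seq_len(w)) {
    s <- s + lods[i, ][codes[seq.int(i, i + n - 1L)]]
  }
  s
}

no_match_sentinel <- function() {
  structure(list(raw_score = NA_real_, rel_score = 0, pvalue = 1,
                 strand = NA_character_, win_start = NA_integer_,
                 matched_seq = NA_character_, matched = FALSE),
            class = "allele_match")
}

#' Best motif match on one allele sequence
#'
#' Scans every width-`w` window of the sequence on both strands (the minus
#' strand is scored with the reverse-complement motif on the forward
#' sequence) and returns the highest-scoring match — equivalently, the match
#' with the lowest p-value, since the p-value is monotone non-increasing in
#' the raw score. Ties are broken deterministically: smaller window start,
#' then the plus strand. Windows containing non-ACGT characters are skipped;
#' if every window is skipped (or the sequence is shorter than the motif) a
#' flagged sentinel with p-value 1 and relative score 0 is returned.
#'
#' @param a an `allele_seq` (or a plain character sequence).
#' @param m a `motif`.
#' @param sd optional `score_distribution` for `m`; when supplied the match
#'   p-value is computed, otherwise it is `NA`.
#' @return An `allele_match`: list with `raw_score`, `rel_score` (min-max
#'   normalized to [0,1]), `pvalue`, `strand` (`"+"`/`"-"`), `win_start`
#'   (0-based offset within the allele sequence), `matched_seq` (the window
#'   as read by the motif, i.e. reverse-complemented for minus-strand
#'   matches), `matched` (FALSE for the sentinel), and `n_windows` (number
#'   of strand-windows scanned, for users who want to correct the per-match
#'   p-value).
#' @export
best_match <- function(a, m, sd = NULL) {
  seq <- if (inherits(a, "allele_seq")) a$seq else as.character(a)
  w <- m$width
  codes <- seq_codes(seq)
  n <- length(codes) - w + 1L
  if (n < 1L) return(no_match_sentinel())
  sp <- window_scores(m$lods, codes, w)
  sm <- window_scores(reverse_complement(m)$lods, codes, w)
  if (all(is.na(sp)) && all(is.na(sm)))
    return(no_match_sentinel())
  best <- max(c(sp, sm), na.rm = TRUE)
  # deterministic tie-break: leftmost window, then '+' strand
  ip <- which(!is.na(sp) & sp == best)
  im <- which(!is.na(sm) & sm == best)
  if (length(ip) > 0L && (length(im) == 0L || min(ip) <= min(im))) {
    j <- min(ip); strand <- "+"
  } else {
    j <- min(im); strand <- "-"
  }
  win <- substr(seq, j, j + w - 1L)
  rng <- m$max_score - m$min_score
  structure(list(
    raw_score = best,
    rel_score = if (rng > 0) (best - m$min_score) / rng else 1,
    pvalue = if (is.null(sd)) NA_real_ else pwm_pvalue(sd, best),
    strand = strand,
    win_start = j - 1L,
    matched_seq = if (strand == "+") win else revcomp_str(win),
    matched = TRUE,
    n_windows = sum(!is.na(sp)) + sum(!is.na(sm))
  ), class = "allele_match")
}

#' Edge-relative coordinates and overlap geometry of a match
#'
#' Locates a motif match relative to the edges of the variant on its allele
#' sequence. With `m_s`/`m_e` the first/last base of the match (0-based,
#' inclusive) and `[v_s, v_e)` the variant span on the allele:
#' `coord_start = m_s - v_s` and `coord_end = (m_e + 1) - v_e`. Negative
#' values are upstream of the corresponding variant edge, positive values
#' downstream, and 0 means the motif edge coincides exactly with that
#' variant edge. The geometry classifies the four ways a motif can lie
#' against an indel: `spanning` (motif extends past both edges),
#' `contained` (motif entirely within the variant bases),
#' `upstream_overlap` (motif covers the start edge), `downstream_overlap`
#' (motif covers the end edge).
#'
#' @param match an `allele_match` (must not be the no-match sentinel).
#' @param a the `allele_seq` the match was found on.
#' @param w motif width.
#' @return List with `geometry`, `coord_start`, `coord_end`.
#' @export
indel_coordinates <- function(match, a, w) {
  if (!isTRUE(match$matched))
    return(list(geometry = NA_character_, coord_start = NA_integer_,
                coord_end = NA_integer_))
  m_s <- match$win_start
  m_e <- m_s + w - 1L
  cs <- m_s - a$v_s
  ce <- (m_e + 1L) - a$v_e
  nonempty <- a$v_e > a$v_s
  geometry <-
    if (cs < 0L && ce > 0L) "spanning"
    else if (cs >= 0L && ce <= 0L && nonempty) "contained"
    else if (cs < 0L && ce <= 0L) "upstream_overlap"
    else "downstream_overlap"
  list(geometry = geometry, coord_start = cs, coord_end = ce)
}

match_overlaps_variant <- function(match, a, w) {
  if (!isTRUE(match$matched)) return(FALSE)
  m_s <- match$win_start
  m_e1 <- m_s + w  # half-open end
  if (a$v_e > a$v_s) m_s < a$v_e && m_e1 > a$v_s
  else m_s < a$v_s && m_e1 > a$v_s  # window straddles the breakpoint
}

#' Score one variant against one motif
#'
#' The core disruption call: builds the two allele sequences, finds the best
#' match on each, and reports the effect size
#' `effect = alt_rel_score - ref_rel_score` (negative = the alternate allele
#' weakens the best site, i.e. disruption; positive = creation). The
#' geometry and edge-relative coordinates are computed from the
#' better-scoring allele's match. Insertions and deletions are treated
#' symmetrically: swapping REF and ALT negates the effect and swaps the
#' per-allele matches.
#'
#' @param v one-row variant `data.frame`.
#' @param m a `motif`.
#' @param genome a [Biostrings::DNAStringSet].
#' @param sd optional precomputed `score_distribution` for `m`.
#' @param strong_threshold,weak_threshold thresholds on `|effect|` defining
#'   the `strong`/`weak`/`neutral` strength call. Defaults 0.4 and 0.1.
#' @return A one-row `data.frame` (see [score_variants()] for columns).
#' @export
score_variant <- function(v, m, genome, sd = NULL,
                          strong_threshold = 0.4, weak_threshold = 0.1) {
  if (is.null(sd)) sd <- score_distribution(m)
  al <- build_allele_seqs(v, m, genome)
  rm_ <- best_match(al$ref, m, sd)
  am_ <- best_match(al$alt, m, sd)
  effect <- am_$rel_score - rm_$rel_score
  direction <- if (effect < 0) "disrupted" else "created"
  abseff <- abs(effect)
  strength <- if (abseff >= strong_threshold) "strong"
              else if (abseff >= weak_threshold) "weak" else "neutral"
  better <- if (rm_$rel_score >= am_$rel_score) "ref" else "alt"
  bm <- if (better == "ref") rm_ else am_
  ba <- if (better == "ref") al$ref else al$alt
  cc <- indel_coordinates(bm, ba, m$width)
  geometry <- if (v$vclass %in% c("SNV", "MNV")) "snv_window" else
    cc$geometry
  data.frame(
    vid = v$vid, chrom = v$chrom, start = v$start, end = v$end,
    ref = v$ref, alt = v$alt, vclass = v$vclass,
    motif_id = m$id, tf_name = m$tf_name, motif_width = m$width,
    ref_raw = rm_$raw_score, ref_rel = rm_$rel_score,
    ref_pvalue = rm_$pvalue, ref_strand = rm_$strand,
    ref_win_start = rm_$win_start, ref_match = rm_$matched_seq,
    ref_overlaps = match_overlaps_variant(rm_, al$ref, m$width),
    alt_raw = am_$raw_score, alt_rel = am_$rel_score,
    alt_pvalue = am_$pvalue, alt_strand = am_$strand,
    alt_win_start = am_$win_start, alt_match = am_$matched_seq,
    alt_overlaps = match_overlaps_variant(am_, al$alt, m$width),
    effect = effect, direction = direction, strength = strength,
    better_allele = better, geometry = geometry,
    coord_start = cc$coord_start, coord_end = cc$coord_end,
    better_genome_offset = ba$genome_offset,
    n_windows = (if (isTRUE(rm_$matched)) rm_$n_windows else 0L) +
                (if (isTRUE(am_$matched)) am_$n_windows else 0L),
    stringsAsFactors = FALSE
  )
}

#' Score a set of variants against a motif library
#'
#' Runs [score_variant()] for every (variant, motif) pair, reusing one
#' exact null score distribution per motif.
#'
#' @param variants variant `data.frame` from [variant_table()] /
#'   [read_vcf_variants()] / [read_custom_bed()] / [read_rsid_tsv()].
#' @param motifs list of `motif` objects.
#' @param genome a [Biostrings::DNAStringSet].
#' @param granularity score discretization step passed to
#'   [score_distribution()]; `NULL` for the per-motif default.
#' @param strong_threshold,weak_threshold see [score_variant()].
#' @return A `data.frame` with one row per (variant, motif) pair; per-allele
#'   best-match statistics (raw score, relative score, exact p-value,
#'   strand, window offset, matched sequence, variant-overlap flag), the
#'   effect size and direction/strength calls, the overlap geometry, and
#'   the edge-relative motif coordinates of the better allele's match.
#' @export
score_variants <- function(variants, motifs, genome, granularity = NULL,
                           strong_threshold = 0.4, weak_threshold = 0.1) {
  sds <- lapply(motifs, score_distribution, granularity = granularity)
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    for (k in seq_along(motifs)) {
      rows[[length(rows) + 1L]] <-
        score_variant(v, motifs[[k]], genome, sd = sds[[k]],
                      strong_threshold = strong_threshold,
                      weak_threshold = weak_threshold)
    }
  }
  if (length(rows) == 0L) return(empty_results())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_results <- function() {
  score_variant(
    data.frame(vid = "x", chrom = "z", start = 1L, end = 2L, ref = "A",
               alt = "C", vclass = "SNV", stringsAsFactors = FALSE),
    motif(matrix(c(2, 0, 0, 0), 1, 4), "tmp"),
    Biostrings::DNAStringSet(c(z = "AAAA")))[0, , drop = FALSE]
}
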