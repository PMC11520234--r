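scan_genome <- function(seed = 3, len = 600) {
  set.seed(seed)
  Biostrings::DNAStringSet(c(chrS = random_dna(len)))
}

test_that("allele sequences carry w-1 context and the variant span", {
  g <- scan_genome()
  m <- consensus_motif("ACGTTG")  # w = 6
  snv <- raw_variant_row("chrS", 100, "A", "C")
  snv$ref <- substr(as.character(g[[1]]), 101, 101)
  snv$alt <- setdiff(c("A", "C", "G", "T"), snv$ref)[1]
  al <- build_allele_seqs(snv, m, g)
  expect_equal(nchar(al$ref$seq), 11L)  # 2(w-1) + 1
  expect_equal(nchar(al$alt$seq), 11L)
  expect_equal(al$ref$v_s, 5L)
  expect_equal(substr(al$alt$seq, 6, 6), snv$alt)
  expect_equal(al$ref$genome_offset, 95L)

  del <- raw_variant_row("chrS", 100,
                         substr(as.character(g[[1]]), 101, 104), "")
  ald <- build_allele_seqs(del, m, g)
  expect_equal(nchar(ald$ref$seq), 14L)  # 2(w-1) + 4
  expect_equal(nchar(ald$alt$seq), 10L)
  expect_equal(c(ald$alt$v_s, ald$alt$v_e), c(5L, 5L))  # breakpoint

  ins <- raw_variant_row("chrS", 100, "", "GGGGGGGGGG")
  ali <- build_allele_seqs(ins, m, g)
  expect_equal(nchar(ali$ref$seq), 10L)
  expect_equal(nchar(ali$alt$seq), 20L)
  expect_equal(c(ali$ref$v_s, ali$ref$v_e), c(5L, 5L))
  expect_equal(c(ali$alt$v_s, ali$alt$v_e), c(5L, 15L))

  expect_error(build_allele_seqs(raw_variant_row("nope", 5, "A", "C"),
                                 m, g), "absent")
})

test_that("best_match hits consensus and minimum-score endpoints", {
  m <- consensus_motif("ACGTTGCA")
  bm <- best_match(consensus_string(m), m)
  expect_equal(bm$rel_score, 1)
  expect_equal(bm$win_start, 0L)
  expect_equal(bm$strand, "+")
  # the per-column-minimum sequence attains min_score on the plus strand,
  # but the scan maximizes over both strands, so the reported best is the
  # (generally higher) minus-strand reading; the naive oracle agrees
  worst <- paste(c("A", "C", "G", "T")[apply(m$lods, 1, which.min)],
                 collapse = "")
  bw <- best_match(worst, m)
  expect_identical(bw$raw_score, naive_best_match(worst, m)$score)
  expect_gte(bw$rel_score, 0)
  # revcomp of consensus matches on the minus strand with the same score
  cons_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(consensus_string(m))))
  rcb <- best_match(cons_rc, m)
  expect_equal(rcb$strand, "-")
  expect_equal(rcb$raw_score, m$max_score, tolerance = 1e-12)
})

test_that("best_match equals the naive double-strand scan oracle", {
  set.seed(41)
  for (rep in 1:60) {
    w <- sample(2:10, 1)
    m <- random_motifs(1, widths = w, seed = 1000 + rep)[[1]]
    seq <- random_dna(sample(w:50, 1))
    got <- best_match(seq, m)
    want <- naive_best_match(seq, m)
    expect_identical(got$raw_score, want$score)
    expect_identical(got$strand, want$strand)
    expect_identical(got$win_start, want$win_start)
  }
})

test_that("N-containing windows are skipped; all-N gives the sentinel", {
  m <- consensus_motif("ACGT")
  s <- "NNNNNNNN"
  bm <- best_match(s, m)
  expect_false(bm$matched)
  expect_equal(bm$pvalue, 1)
  expect_equal(bm$rel_score, 0)
  # one clean window among N's is found
  s2 <- "NNNACGTNNN"
  bm2 <- best_match(s2, m)
  expect_true(bm2$matched)
  expect_equal(bm2$win_start, 3L)
  expect_equal(bm2$rel_score, 1)
  # sequence shorter than the motif also yields the sentinel
  expect_false(best_match("AC", m)$matched)
})

test_that("reverse-complement consistency of the scan", {
  set.seed(43)
  for (rep in 1:20) {
    w <- sample(2:8, 1)
    m <- random_motifs(1, widths = w, seed = 2000 + rep)[[1]]
    L <- sample(w:40, 1)
    seq <- random_dna(L)
    rcseq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    a <- best_match(seq, m)
    b <- best_match(rcseq, reverse_complement(m))
    expect_equal(b$raw_score, a$raw_score, tolerance = 1e-9)
    # mirrored window position whenever the best score is attained by a
    # single (window, strand) candidate with a clear margin ((near-)ties
    # legitimately break the mirror under the leftmost tie-break)
    rc_l <- rc_lods_of(m)
    codes <- match(strsplit(seq, "")[[1]], BASES)
    n_best <- 0L
    for (j in seq_len(L - w + 1L)) for (lod in list(m$lods, rc_l)) {
      s <- 0
      for (i in seq_len(w)) s <- s + lod[i, codes[j + i - 1L]]
      if (unname(s) >= a$raw_score - 1e-9) n_best <- n_best + 1L
    }
    if (n_best == 1L)
      expect_equal(b$win_start, L - w - a$win_start)
  }
})

test_that("SNV effects follow planted disruption and symmetry", {
  set.seed(47)
  g <- scan_genome(5)
  m <- consensus_motif("ACGTTGCA")
  s <- as.character(g[[1]])
  # plant the consensus at [200, 208)
  s <- apply_edit(s, 200, substr(s, 201, 208), consensus_string(m))
  g2 <- Biostrings::DNAStringSet(c(chrS = s))
  sd <- score_distribution(m)
  j <- which.max(apply(m$lods, 1, max) - apply(m$lods, 1, min))
  cons <- strsplit(consensus_string(m), "")[[1]]
  worst <- c("A", "C", "G", "T")[which.min(m$lods[j, ])]
  v <- raw_variant_row("chrS", 200 + j - 1, cons[j], worst)
  r <- score_variant(v, m, g2, sd)
  expect_equal(r$ref_rel, 1)
  expect_lt(r$effect, 0)
  expect_equal(r$direction, "disrupted")
  expect_equal(r$geometry, "snv_window")
  # a variant whose two alleles score equally -> effect 0, neutral
  # (apply the SNV to the genome and swap ref/alt: mirrored exactly)
  g3 <- Biostrings::DNAStringSet(c(chrS = apply_edit(s, 200 + j - 1,
                                                     cons[j], worst)))
  v2 <- raw_variant_row("chrS", 200 + j - 1, worst, cons[j])
  r2 <- score_variant(v2, m, g3, sd)
  expect_identical(r2$effect, -r$effect)
  expect_equal(r2$direction, "created")
  expect_identical(r2$ref_raw, r$alt_raw)
  expect_identical(r2$alt_raw, r$ref_raw)
})

test_that("weakening the alt allele never increases the effect", {
  g <- scan_genome(9)
  m <- consensus_motif("TTGACGCA")
  s <- as.character(g[[1]])
  s <- apply_edit(s, 300, substr(s, 301, 308), consensus_string(m))
  g2 <- Biostrings::DNAStringSet(c(chrS = s))
  sd <- score_distribution(m)
  cons <- strsplit(consensus_string(m), "")[[1]]
  # progressively degrade more consensus positions in the MNV alt
  effects <- numeric(0)
  for (k in 1:4) {
    alt <- cons[1:4]
    for (i in seq_len(k))
      alt[i] <- c("A", "C", "G", "T")[which.min(m$lods[i, ])]
    v <- raw_variant_row("chrS", 300, paste(cons[1:4], collapse = ""),
                         paste(alt, collapse = ""))
    effects <- c(effects, score_variant(v, m, g2, sd)$effect)
  }
  expect_true(all(diff(effects) <= 1e-12))
})

test_that("edge-relative coordinates follow the documented convention", {
  # 10-bp insertion allele, w=6 motif starting at inserted offset 2
  a <- make_allele_seq(strrep("A", 25), v_s = 5L, v_e = 15L)
  cc <- indel_coordinates(make_match(7L), a, 6L)
  expect_equal(cc[c("coord_start", "coord_end")],
               list(coord_start = 2L, coord_end = -2L))
  expect_equal(cc$geometry, "contained")
  # motif starting 2 bases before the insertion, ending at inserted base 4
  cc2 <- indel_coordinates(make_match(3L), a, 6L)
  expect_equal(cc2[c("coord_start", "coord_end")],
               list(coord_start = -2L, coord_end = -6L))
  expect_equal(cc2$geometry, "upstream_overlap")
  # motif starting at inserted offset 6 and running 1 base past the end
  cc3 <- indel_coordinates(make_match(11L), a, 6L)
  expect_equal(cc3[c("coord_start", "coord_end")],
               list(coord_start = 6L, coord_end = 2L))
  expect_equal(cc3$geometry, "downstream_overlap")
  # reference allele of a 4-bp deletion, motif 1 base beyond each edge
  ad <- make_allele_seq(strrep("A", 15), v_s = 5L, v_e = 9L)
  cc4 <- indel_coordinates(make_match(4L), ad, 6L)
  expect_equal(cc4[c("coord_start", "coord_end")],
               list(coord_start = -1L, coord_end = 1L))
  expect_equal(cc4$geometry, "spanning")
})

test_that("indel scoring is symmetric under ref/alt swap", {
  set.seed(53)
  g0 <- scan_genome(11, len = 2000)
  s0 <- as.character(g0[[1]])
  for (rep in 1:30) {
    w <- sample(3:9, 1)
    m <- random_motifs(1, widths = w, seed = 3000 + rep)[[1]]
    sd <- score_distribution(m)
    start <- sample(100:1800, 1)
    if (runif(1) < 0.5) {  # deletion
      ref <- substr(s0, start + 1, start + sample(1:6, 1))
      alt <- ""
    } else {               # insertion
      ref <- ""
      alt <- random_dna(sample(1:8, 1))
    }
    v <- raw_variant_row("chrS", start, ref, alt)
    r <- score_variant(v, m, g0, sd)
    s1 <- apply_edit(s0, start, ref, alt)
    g1 <- Biostrings::DNAStringSet(c(chrS = s1))
    v2 <- raw_variant_row("chrS", start, alt, ref)
    r2 <- score_variant(v2, m, g1, sd)
    expect_identical(r2$effect, -r$effect)
    expect_identical(r2$ref_raw, r$alt_raw)
    expect_identical(r2$alt_raw, r$ref_raw)
    expect_identical(r2$ref_win_start, r$alt_win_start)
    expect_identical(r2$alt_win_start, r$ref_win_start)
    # geometry of the better allele's match agrees
    expect_identical(r2$geometry, r$geometry)
    expect_identical(r2$coord_start, r$coord_start)
    expect_identical(r2$coord_end, r$coord_end)
  }
})
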