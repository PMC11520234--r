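write_bed_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("ReMap name fields parse; malformed names are skipped", {
  f <- write_bed_lines(c(
    "chr1\t100\t300\tGSE41466.CTCF.colon\t10\t.",
    "chr1\t500\t700\tGSE1.FOXA1.liver.adult\t5\t.",
    "chr1\t900\t950\tbadname\t1\t."))
  expect_warning(db <- build_peak_db(f), "malformed name")
  expect_equal(nrow(db$peaks), 2L)
  expect_equal(db$n_skipped, 1L)
  expect_equal(db$peaks$accession[1], "GSE41466")
  expect_equal(db$peaks$tf[1], "CTCF")
  expect_equal(db$peaks$biotype[1], "colon")
  # periods beyond the first two belong to the biotype
  expect_equal(db$peaks$biotype[2], "liver.adult")
})

test_that("database build is deterministic, deduplicating, serializable", {
  lines <- c("chr2\t10\t50\tA1.TF1.t1\t0\t.",
             "chr1\t5\t40\tA2.TF2.t2\t0\t.",
             "chr2\t10\t50\tA1.TF1.t1\t0\t.")  # exact duplicate
  f1 <- write_bed_lines(lines)
  f2 <- write_bed_lines(rev(lines))
  out1 <- withr::local_tempfile(); out2 <- withr::local_tempfile()
  suppressMessages(build_peak_db(f1, out = out1))
  suppressMessages(build_peak_db(f2, out = out2))
  expect_identical(readLines(out1), readLines(out2))
  db <- load_peak_db(out1)
  expect_equal(nrow(db$peaks), 2L)
  expect_equal(db$peaks$chrom, c("chr1", "chr2"))  # sorted
  # two files sum their valid records
  db2 <- suppressMessages(build_peak_db(c(f1, f2)))
  expect_equal(nrow(db2$peaks), 2L)
  expect_error(load_peak_db(write_bed_lines("chr1\t1\t2\tx\t0\t.")),
               "magic")
})

test_that("overlap queries use half-open semantics and match linear scan", {
  f <- write_bed_lines("chr1\t50\t150\tA1.CTCF.colon\t0\t.")
  db <- build_peak_db(f)
  expect_equal(nrow(query_overlaps(db, "chr1", 100, 101)), 1L)
  expect_equal(nrow(query_overlaps(db, "chr1", 150, 151)), 0L)  # half-open
  expect_equal(nrow(query_overlaps(db, "chr1", 49, 50)), 0L)
  expect_equal(nrow(query_overlaps(db, "chrX", 100, 101)), 0L)
  # zero-length breakpoint query: strict containment
  expect_equal(nrow(query_overlaps(db, "chr1", 100, 100)), 1L)
  expect_equal(nrow(query_overlaps(db, "chr1", 50, 50)), 0L)

  set.seed(61)
  n_peaks <- 800
  peaks <- data.frame(
    chrom = sample(c("c1", "c2"), n_peaks, replace = TRUE),
    start = sample.int(5000, n_peaks, replace = TRUE))
  peaks$end <- peaks$start + sample.int(200, n_peaks, replace = TRUE)
  peaks$accession <- sprintf("A%d", seq_len(n_peaks))
  peaks$tf <- "TF1"; peaks$biotype <- "t"
  f2 <- write_bed_lines(paste(peaks$chrom, peaks$start, peaks$end,
                              paste(peaks$accession, peaks$tf,
                                    peaks$biotype, sep = "."),
                              sep = "\t"))
  db2 <- build_peak_db(f2)
  for (rep in 1:200) {
    ch <- sample(c("c1", "c2", "c3"), 1)
    s <- sample.int(5200, 1)
    e <- s + sample.int(100, 1)
    got <- query_overlaps(db2, ch, s, e)
    want <- linear_overlaps(db2$peaks, ch, s, e)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("annotation filters on the better allele and attaches evidence", {
  fx <- write_fixture_bundle(withr::local_tempdir(), seed = 19L)
  db <- build_peak_db(fx$peaks_bed)
  res <- score_variants(fx$variants, fx$motifs, fx$genome)
  tf_map <- read_tf_map(fx$tf_map)
  ann <- annotate_results(res, db, tf_map = tf_map)
  better_p <- pmin(ann$ref_pvalue, ann$alt_pvalue)
  expect_true(all(ann$evidence_status[better_p >= 1e-4] == "not-evaluated"))
  expect_true(all(ann$peak_count[ann$evidence_status != "evaluated"] == 0L))
  # every passing disruption of a planted site gets exactly its one peak
  mv <- fx$manifest$variants
  planted <- merge(ann, mv[, c("vid", "intended_direction", "site_motif")],
                   by = "vid")
  hits <- planted[planted$motif_id == planted$site_motif &
                    planted$intended_direction %in% "disrupted" &
                    planted$evidence_status == "evaluated", ]
  expect_gt(nrow(hits), 0L)
  expect_true(all(hits$peak_count == 1L))
  expect_true(all(hits$peak_biotypes == "synthetic-tissue"))
  # nothing passing alpha is silently dropped
  expect_equal(nrow(ann), nrow(res))
})

test_that("family expansion attaches family peaks only when enabled", {
  dirx <- withr::local_tempdir()
  fx <- write_fixture_bundle(dirx, seed = 23L)
  peaks2 <- make_peaks(fx$manifest, fx$motifs, family_decoy_tf = "TFDECOY",
                       seed = 77L)
  bed2 <- file.path(dirx, "peaks2.bed")
  write_peaks_bed(peaks2, bed2)
  db <- build_peak_db(bed2)
  res <- score_variants(fx$variants, fx$motifs, fx$genome)
  tf_map <- read_tf_map(fx$tf_map)
  fams <- c(setNames(rep("FAMX", length(fx$motifs)),
                     normalize_tf_name(vapply(fx$motifs, `[[`, "",
                                              "tf_name"))),
            TFDECOY = "FAMX")
  plain <- annotate_results(res, db, tf_map = tf_map)
  fam <- annotate_results(res, db, tf_map = tf_map, families = fams,
                          family_expand = TRUE)
  ev <- plain$evidence_status == "evaluated" & plain$peak_count > 0
  expect_true(any(ev))
  expect_true(all(grepl("TFDECOY", fam$peak_tfs[ev])))
  expect_false(any(grepl("TFDECOY", plain$peak_tfs)))
  # annotation count is monotone under family expansion
  expect_true(all(fam$peak_count >= plain$peak_count))
  expect_error(annotate_results(res, db, family_expand = TRUE),
               "family table")
})

test_that("TF name normalization bridges punctuation and case", {
  expect_equal(normalize_tf_name(c("NKX2-1", "nkx2.1", "NKX2_1")),
               rep("NKX21", 3))
  # motif absent from an explicit map is marked unmappable
  fx <- write_fixture_bundle(withr::local_tempdir(), seed = 29L)
  db <- build_peak_db(fx$peaks_bed)
  res <- score_variants(fx$variants, fx$motifs, fx$genome)
  empty_map <- setNames(character(0), character(0))
  suppressMessages(ann <- annotate_results(res, db, tf_map = empty_map))
  better_p <- pmin(ann$ref_pvalue, ann$alt_pvalue)
  expect_true(all(ann$evidence_status[better_p < 1e-4] == "unmappable"))
})
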