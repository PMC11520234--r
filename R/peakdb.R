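PEAKDB_MAGIC <- "#MOTIFDISRUPTR_PEAKDB\tv1"

#' Build a local TF-binding peak database from ReMap-layout BED files
#'
#' Parses BED files (>= 4 columns, plain or gzipped) whose name field uses
#' the ReMap2022 layout `accession.TF.biotype` — periods beyond the first
#' two belong to the biotype. Records with fewer than two periods in the
#' name are skipped with a warning (and counted); identical duplicate
#' records are deduplicated. Peaks are stably sorted by
#' (chrom, start, end, name) so the build is deterministic and idempotent,
#' and serialized to a single indexed text file with a magic header.
#'
#' @param bed_paths character vector of BED file paths.
#' @param out optional path; when supplied the database is serialized there.
#' @return A `peak_db` object: list with `peaks` (data.frame: `chrom`,
#'   `start`, `end` 0-based half-open, `accession`, `tf`, `biotype`), `gr`
#'   (a [GenomicRanges::GRanges] interval index), and `n_skipped`.
#' @export
build_peak_db <- function(bed_paths, out = NULL) {
  all <- list()
  n_skipped <- 0L
  for (p in bed_paths) {
    if (!file.exists(p)) stop("no such file: ", p)
    con <- if (grepl("\\.gz$", p)) gzfile(p, "rt") else file(p, "rt")
    lines <- readLines(con, warn = FALSE)
    close(con)
    lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
    if (length(lines) == 0L) next
    f <- strsplit(lines, "\t")
    short <- lengths(f) < 4L
    if (any(short)) {
      n_skipped <- n_skipped + sum(short)
      warning(sum(short), " record(s) with <4 columns skipped in ", p)
      f <- f[!short]
    }
    chrom <- vapply(f, `[`, "", 1L)
    start <- as.integer(vapply(f, `[`, "", 2L))
    end <- as.integer(vapply(f, `[`, "", 3L))
    name <- vapply(f, `[`, "", 4L)
    parts <- strsplit(name, ".", fixed = TRUE)
    badname <- lengths(parts) < 3L
    if (any(badname)) {
      n_skipped <- n_skipped + sum(badname)
      warning(sum(badname), " record(s) with malformed name field ",
              "(need accession.TF.biotype) skipped in ", p, ": ",
              paste(utils::head(name[badname], 3L), collapse = ", "))
    }
    keep <- !badname & !is.na(start) & !is.na(end) & end > start
    all[[length(all) + 1L]] <- data.frame(
      chrom = chrom[keep], start = start[keep], end = end[keep],
      accession = vapply(parts[keep], `[`, "", 1L),
      tf = vapply(parts[keep], `[`, "", 2L),
      biotype = vapply(parts[keep], function(x)
        paste(x[-(1:2)], collapse = "."), ""),
      stringsAsFactors = FALSE)
  }
  peaks <- if (length(all) > 0L) do.call(rbind, all) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               accession = character(), tf = character(),
               biotype = character(), stringsAsFactors = FALSE)
  ndup <- nrow(peaks)
  peaks <- unique(peaks)
  if (nrow(peaks) < ndup)
    message("deduplicated ", ndup - nrow(peaks), " identical peak record(s)")
  ord <- order(peaks$chrom, peaks$start, peaks$end, peaks$accession,
               peaks$tf, peaks$biotype, method = "radix")
  peaks <- peaks[ord, , drop = FALSE]
  rownames(peaks) <- NULL
  db <- structure(list(peaks = peaks, gr = peaks_granges(peaks),
                       n_skipped = n_skipped), class = "peak_db")
  if (!is.null(out)) write_peak_db(db, out)
  db
}

peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
}

#' @export
print.peak_db <- function(x, ...) {
  cat(sprintf("<peak_db> %d peaks, %d TFs, %d chromosomes\n",
              nrow(x$peaks), length(unique(x$peaks$tf)),
              length(unique(x$peaks$chrom))))
  invisible(x)
}

#' Serialize a peak database to a single indexed text file
#'
#' @param db a `peak_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_db <- function(db, path) {
  con <- file(path, "wb")  # binary mode: fixed '\n', byte-reproducible
  on.exit(close(con))
  writeLines(PEAKDB_MAGIC, con, sep = "\n")
  writeLines(paste("#n_peaks", nrow(db$peaks), sep = "\t"), con, sep = "\n")
  writeLines(paste("chrom", "start", "end", "accession", "tf", "biotype",
                   sep = "\t"), con, sep = "\n")
  if (nrow(db$peaks) > 0L)
    writeLines(do.call(paste, c(db$peaks, sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Load a serialized peak database
#'
#' @param path a file written by [write_peak_db()].
#' @return A `peak_db`.
#' @export
load_peak_db <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || lines[1] != PEAKDB_MAGIC)
    stop(path, " is not a motifdisruptr peak database (bad magic)")
  body <- lines[-(1:3)]
  peaks <- if (length(body) == 0L)
    data.frame(chrom = character(), start = integer(), end = integer(),
               accession = character(), tf = character(),
               biotype = character(), stringsAsFactors = FALSE)
  else {
    f <- strsplit(body, "\t")
    data.frame(chrom = vapply(f, `[`, "", 1L),
               start = as.integer(vapply(f, `[`, "", 2L)),
               end = as.integer(vapply(f, `[`, "", 3L)),
               accession = vapply(f, `[`, "", 4L),
               tf = vapply(f, `[`, "", 5L),
               biotype = vapply(f, `[`, "", 6L),
               stringsAsFactors = FALSE)
  }
  structure(list(peaks = peaks, gr = peaks_granges(peaks), n_skipped = 0L),
            class = "peak_db")
}

#' Query peaks overlapping an interval
#'
#' Half-open overlap semantics: a peak `[ps, pe)` overlaps the query
#' `[start, end)` iff `ps < end` and `pe > start`.
#'
#' @param db a `peak_db`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open query interval.
#' @return The overlapping subset of `db$peaks` (possibly empty; empty for
#'   unknown chromosomes).
#' @export
query_overlaps <- function(db, chrom, start, end) {
  stopifnot(end >= start)
  if (end == start) {
    # zero-length breakpoint: the half-open rule (ps < end, pe > start)
    # reduces to peaks strictly containing the breakpoint
    keep <- db$peaks$chrom == chrom & db$peaks$start < start &
      db$peaks$end > start
    return(db$peaks[keep, , drop = FALSE])
  }
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start + 1L, end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, db$gr, type = "any"))
  idx <- sort(S4Vectors::subjectHits(hits))
  db$peaks[idx, , drop = FALSE]
}

#' Read a motif-to-TF mapping table
#'
#' Tab-separated, header required, columns `motif_id` and `tf`.
#'
#' @param path TSV path.
#' @return Named character vector: motif id -> canonical TF name.
#' @export
read_tf_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("motif_id", "tf") %in% names(tab)))
    stop("TF map must have columns motif_id, tf")
  if (anyDuplicated(tab$motif_id))
    stop("duplicate motif ids in TF map")
  setNames(tab$tf, tab$motif_id)
}

#' Read a TF family table
#'
#' Tab-separated, header required, columns `tf` and `family_id`. TFs
#' sharing a `family_id` are treated as interchangeable when family
#' expansion is enabled in [annotate_results()].
#'
#' @param path TSV path.
#' @return Named character vector: TF name -> family id.
#' @export
read_tf_families <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("tf", "family_id") %in% names(tab)))
    stop("family table must have columns tf, family_id")
  setNames(tab$family_id, normalize_tf_name(tab$tf))
}

#' Normalize a TF name for matching
#'
#' Peak sources and motif sources disagree on case and on punctuation in
#' names like `NKX2-1`/`NKX2.1`; matching is done on the uppercased name
#' with separator characters (`-`, `.`, `_`, space) removed.
#'
#' @param x character vector of TF names.
#' @return Normalized names.
#' @export
normalize_tf_name <- function(x) {
  gsub("[-._ ]", "", toupper(x))
}

#' Annotate disruption results with overlapping TF peaks
#'
#' For every result whose better-allele match p-value passes the evidence
#' filter (`p < alpha`, default 1e-4), attaches all peaks that (a) overlap
#' the variant's reference-genome span — pure insertions use the zero-length
#' breakpoint widened by one base on each side, since they could otherwise
#' never overlap any peak — and (b) are for the TF matching the disrupted
#' motif (case/punctuation-insensitive), optionally expanded to the whole
#' TF family. Results failing the filter are explicitly marked
#' `not-evaluated`, never dropped; motifs absent from a supplied mapping
#' are marked `unmappable`.
#'
#' @param results a results `data.frame` from [score_variants()].
#' @param db a `peak_db`.
#' @param tf_map optional named vector (motif id -> TF) from
#'   [read_tf_map()]; when `NULL` each result's own `tf_name` is used.
#' @param families optional named vector (TF -> family id) from
#'   [read_tf_families()].
#' @param family_expand logical; match any TF in the same family.
#' @param alpha evidence p-value filter, default `1e-4`.
#' @return `results` with appended columns `evidence_status`
#'   (`evaluated` / `not-evaluated` / `unmappable`), `peak_count`,
#'   `peak_accessions`, `peak_tfs` and `peak_biotypes` (comma-separated,
#'   distinct, sorted).
#' @export
annotate_results <- function(results, db, tf_map = NULL, families = NULL,
                             family_expand = FALSE, alpha = 1e-4) {
  if (family_expand && is.null(families))
    stop("family_expand requires a family table")
  n <- nrow(results)
  status <- character(n)
  pk_n <- integer(n)
  pk_acc <- character(n); pk_tf <- character(n); pk_bio <- character(n)
  db_tf_norm <- normalize_tf_name(db$peaks$tf)
  for (i in seq_len(n)) {
    r <- results[i, ]
    better_p <- suppressWarnings(min(r$ref_pvalue, r$alt_pvalue,
                                     na.rm = TRUE))
    if (!is.finite(better_p) || better_p >= alpha) {
      status[i] <- "not-evaluated"
      next
    }
    tf <- if (is.null(tf_map)) r$tf_name else {
      if (!r$motif_id %in% names(tf_map)) {
        status[i] <- "unmappable"
        message("motif ", r$motif_id, " absent from TF map; ",
                "result marked unmappable")
        next
      }
      tf_map[[r$motif_id]]
    }
    tf_norm <- normalize_tf_name(tf)
    wanted <- tf_norm
    if (family_expand) {
      fam <- families[tf_norm]
      if (!is.na(fam))
        wanted <- union(wanted, names(families)[families == fam])
    }
    qs <- r$start; qe <- r$end
    if (qe == qs) { qs <- qs - 1L; qe <- qe + 1L }  # insertion breakpoint
    ov <- query_overlaps(db, r$chrom, qs, qe)
    ov <- ov[normalize_tf_name(ov$tf) %in% wanted, , drop = FALSE]
    status[i] <- "evaluated"
    pk_n[i] <- nrow(ov)
    pk_acc[i] <- paste(sort(unique(ov$accession)), collapse = ",")
    pk_tf[i] <- paste(sort(unique(ov$tf)), collapse = ",")
    pk_bio[i] <- paste(sort(unique(ov$biotype)), collapse = ",")
  }
  results$evidence_status <- status
  results$peak_count <- pk_n
  results$peak_accessions <- pk_acc
  results$peak_tfs <- pk_tf
  results$peak_biotypes <- pk_bio
  results
}
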