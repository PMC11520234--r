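#' Load a reference genome from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that keeps only the
#' first whitespace-delimited token of each FASTA header as the chromosome
#' name (matching how `.fai`-indexed tools name sequences).
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
load_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

genome_subseq <- function(genome, chrom, start0, end0) {
  # start0/end0: 0-based half-open
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' absent from genome")
  as.character(Biostrings::subseq(genome[[chrom]], start0 + 1L, end0))
}

revcomp_str <- function(s) {
  vapply(s, function(x) {
    if (!nzchar(x)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }, character(1), USE.NAMES = FALSE)
}

classify_variant <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "SNV",
  ifelse(nr == 0L & na > 0L, "INS",
  ifelse(na == 0L & nr > 0L, "DEL",
  ifelse(nr == na & nr > 1L, "MNV", "DELINS"))))
}

#' Assemble and normalize a table of variants
#'
#' Builds the canonical variant table from raw edits: trims shared
#' prefixes/suffixes, optionally left-aligns pure indels against a genome,
#' verifies REF against the genome, and classifies each record. All
#' coordinates are 0-based half-open; `start == end` denotes a pure
#' insertion breakpoint.
#'
#' @param chrom,start,end,ref,alt,vid parallel vectors describing raw edits
#'   (0-based half-open coordinates; `ref`/`alt` are ACGT strings, possibly
#'   empty, with `"-"` accepted as an empty-allele spelling).
#' @param genome optional [Biostrings::DNAStringSet]; when supplied, REF is
#'   validated and pure indels are left-aligned through repeat tracts.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `ref`,
#'   `alt`, `vid`, `vclass` (one of SNV, MNV, INS, DEL, DELINS).
#' @export
variant_table <- function(chrom, start, end, ref, alt, vid = NULL,
                          genome = NULL) {
  ref <- toupper(ifelse(ref %in% c("-", ".", NA), "", ref))
  alt <- toupper(ifelse(alt %in% c("-", ".", NA), "", alt))
  n <- length(chrom)
  if (is.null(vid))
    vid <- sprintf("%s:%d:%s:%s", chrom, start + 1L,
                   ifelse(nzchar(ref), ref, "-"),
                   ifelse(nzchar(alt), alt, "-"))
  bad <- grepl("[^ACGT]", ref) | grepl("[^ACGT]", alt)
  if (any(bad))
    stop("non-ACGT alleles in record(s): ", paste(vid[bad], collapse = ", "))
  if (any(nchar(ref) != end - start))
    stop("end - start inconsistent with REF length for: ",
         paste(vid[nchar(ref) != end - start], collapse = ", "))
  out <- data.frame(chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    ref = ref, alt = alt, vid = as.character(vid),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    v <- normalize_variant(out$chrom[i], out$start[i], out$ref[i],
                           out$alt[i], genome = genome)
    out$start[i] <- v$start; out$end[i] <- v$end
    out$ref[i] <- v$ref; out$alt[i] <- v$alt
  }
  out$vclass <- classify_variant(out$ref, out$alt)
  drop <- out$ref == out$alt
  if (any(drop)) {
    warning("dropping ", sum(drop), " record(s) where REF == ALT: ",
            paste(out$vid[drop], collapse = ", "))
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Normalize a single raw edit
#'
#' Trims the longest shared prefix, then the longest shared suffix, of the
#' REF/ALT pair (adjusting coordinates), and — when a genome is supplied and
#' the trimmed edit is a pure insertion or deletion — left-aligns it through
#' repeat tracts by shifting the edit leftward while the resulting haplotype
#' is unchanged. The operation is idempotent. When a genome is supplied the
#' REF string is validated against it.
#'
#' @param chrom chromosome name.
#' @param start 0-based start of the REF span.
#' @param ref,alt allele strings (ACGT, possibly empty).
#' @param genome optional [Biostrings::DNAStringSet].
#' @return A list with `chrom`, `start`, `end`, `ref`, `alt`.
#' @export
normalize_variant <- function(chrom, start, ref, alt, genome = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  start <- as.integer(start)
  if (!is.null(genome)) {
    obs <- genome_subseq(genome, chrom, start, start + nchar(ref))
    if (!identical(obs, ref))
      stop("REF mismatch at ", chrom, ":", start + 1L, ": expected '",
           ref, "', genome has '", obs, "'")
  }
  # shared prefix
  np <- 0L
  while (np < nchar(ref) && np < nchar(alt) &&
         substr(ref, np + 1L, np + 1L) == substr(alt, np + 1L, np + 1L))
    np <- np + 1L
  if (np > 0L) {
    ref <- substr(ref, np + 1L, nchar(ref))
    alt <- substr(alt, np + 1L, nchar(alt))
    start <- start + np
  }
  # shared suffix
  ns <- 0L
  while (ns < nchar(ref) && ns < nchar(alt) &&
         substr(ref, nchar(ref) - ns, nchar(ref) - ns) ==
         substr(alt, nchar(alt) - ns, nchar(alt) - ns))
    ns <- ns + 1L
  if (ns > 0L) {
    ref <- substr(ref, 1L, nchar(ref) - ns)
    alt <- substr(alt, 1L, nchar(alt) - ns)
  }
  # left-align pure indels through repeats
  if (!is.null(genome) && xor(nchar(ref) == 0L, nchar(alt) == 0L)) {
    ins <- nchar(ref) == 0L
    seq_allele <- if (ins) alt else ref
    while (start > 0L) {
      prev <- genome_subseq(genome, chrom, start - 1L, start)
      last <- substr(seq_allele, nchar(seq_allele), nchar(seq_allele))
      if (prev != last) break
      seq_allele <- paste0(prev, substr(seq_allele, 1L,
                                        nchar(seq_allele) - 1L))
      start <- start - 1L
    }
    if (ins) alt <- seq_allele else ref <- seq_allele
  }
  list(chrom = chrom, start = start, end = start + nchar(ref),
       ref = ref, alt = alt)
}

#' Read variants from a VCF file
#'
#' Reads a VCF 4.x file through [VariantAnnotation::readVcf()], expands
#' multi-allelic records into one variant per ALT, undoes the VCF
#' anchor-base convention by prefix/suffix trimming, and converts to
#' 0-based half-open coordinates. Symbolic ALT alleles (`<DEL>`, breakends)
#' and non-ACGT alleles are skipped with a warning.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param genome optional [Biostrings::DNAStringSet] for REF validation and
#'   indel left-alignment.
#' @return A variant `data.frame` as from [variant_table()].
#' @export
read_vcf_variants <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  ids <- names(SummarizedExperiment::rowRanges(vcf))
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  vcf <- VariantAnnotation::expand(vcf)  # one row per ALT; drops names
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos1 <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  vid <- if (is.null(ids)) sprintf("%s:%d", chrom, pos1) else
    rep(ids, times = pmax(nalt, 1L))
  sym <- grepl("[<>\\[\\]]", alt) | !nzchar(alt)
  nonacgt <- !sym & (grepl("[^ACGTacgt]", alt) | grepl("[^ACGTacgt]", ref))
  skip <- sym | nonacgt
  if (any(skip))
    warning("skipping ", sum(skip),
            " record(s) with symbolic or non-ACGT alleles: ",
            paste(utils::head(vid[skip], 5L), collapse = ", "))
  keep <- !skip
  variant_table(chrom = chrom[keep], start = pos1[keep] - 1L,
                end = pos1[keep] - 1L + nchar(ref[keep]),
                ref = ref[keep], alt = alt[keep], vid = vid[keep],
                genome = genome)
}

#' Read variants from the custom BED-derived format
#'
#' A BED6 dialect whose name field encodes the edit as
#' `chrom:position:REF:ALT` with a 1-based position; `-` denotes an empty
#' allele (so insertions have `start == end` and REF `-`). The strand column
#' must be `+` or `.` — variants are always expressed on the forward strand.
#'
#' @param path path to the BED file.
#' @param genome optional [Biostrings::DNAStringSet] for validation and
#'   left-alignment.
#' @return A variant `data.frame` as from [variant_table()].
#' @export
read_custom_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L)
    return(variant_table(character(), integer(), integer(),
                         character(), character()))
  fields <- strsplit(lines, "\t| +")
  n <- length(fields)
  get <- function(i, j) if (length(fields[[i]]) >= j) fields[[i]][j] else NA
  chrom <- character(n); start <- integer(n); end <- integer(n)
  ref <- character(n); alt <- character(n); vid <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 6L)
      stop("line ", i, ": expected 6 BED columns, got ", length(f))
    strand <- f[6]
    if (!strand %in% c("+", "."))
      stop("line ", i, ": strand must be '+' or '.', got '", strand, "'")
    nm <- strsplit(f[4], ":")[[1]]
    if (length(nm) != 4L)
      stop("line ", i, ": name field '", f[4],
           "' is not chrom:position:REF:ALT")
    chrom[i] <- f[1]
    start[i] <- as.integer(f[2]); end[i] <- as.integer(f[3])
    ref[i] <- nm[3]; alt[i] <- nm[4]; vid[i] <- f[4]
    reflen <- if (nm[3] %in% c("-", ".")) 0L else nchar(nm[3])
    if (end[i] - start[i] != reflen)
      stop("line ", i, ": end - start (", end[i] - start[i],
           ") inconsistent with REF length (", reflen, ")")
    pos1 <- suppressWarnings(as.integer(nm[2]))
    if (is.na(pos1))
      stop("line ", i, ": unparseable position in name field '", f[4], "'")
  }
  variant_table(chrom, start, end, ref, alt, vid, genome = genome)
}

#' Read variants from a local rsID lookup table
#'
#' A tab-separated table with columns `id`, `chrom`, `pos_1based`, `ref`,
#' `alt` mapping rsIDs to edits; this is the hermetic, offline substitute
#' for a dbSNP query.
#'
#' @param path path to the TSV file (header required).
#' @param genome optional [Biostrings::DNAStringSet].
#' @return A variant `data.frame` as from [variant_table()].
#' @export
read_rsid_tsv <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "chrom", "pos_1based", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop("rsID table must have columns: ", paste(need, collapse = ", "))
  ref <- toupper(ifelse(tab$ref %in% c("-", "."), "", tab$ref))
  pos0 <- as.integer(tab$pos_1based) - 1L
  variant_table(tab$chrom, pos0, pos0 + nchar(ref), ref, tab$alt,
                vid = tab$id, genome = genome)
}
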