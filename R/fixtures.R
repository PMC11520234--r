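#' Generate a random toy genome
#'
#' Draws i.i.d. bases from a background distribution; deterministic for a
#' given seed.
#'
#' @param seed integer seed.
#' @param chrom_lengths named integer vector of chromosome lengths
#'   (each >= 200).
#' @param background length-4 base probability vector (A,C,G,T).
#' @return A named [Biostrings::DNAStringSet].
#' @export
make_genome <- function(seed, chrom_lengths = c(chrA = 10000L,
                                                chrB = 8000L),
                        background = rep(0.25, 4)) {
  stopifnot(all(chrom_lengths >= 200L), !is.null(names(chrom_lengths)))
  set.seed(seed)
  seqs <- vapply(chrom_lengths, function(len)
    paste(sample(DNA_BASES, len, replace = TRUE, prob = background),
          collapse = ""), character(1))
  Biostrings::DNAStringSet(seqs)
}

#' Generate random informative motifs
#'
#' Each position gets a dominant base with a large count and small counts
#' elsewhere, giving sharply informative columns; motifs whose consensus is
#' a homopolymer are redrawn (they make indel placement ambiguous under
#' left-alignment).
#'
#' @param n number of motifs.
#' @param widths integer vector of candidate widths, sampled per motif.
#' @param seed integer seed.
#' @param tf_names optional TF names (default `TF1..TFn`).
#' @return Named list of `motif` objects with ids `SYNM001..`.
#' @export
random_motifs <- function(n = 3L, widths = 8:12, seed = 1L,
                          tf_names = NULL) {
  set.seed(seed)
  if (is.null(tf_names)) tf_names <- paste0("TF", seq_len(n))
  out <- list()
  for (k in seq_len(n)) {
    repeat {
      w <- if (length(widths) == 1L) widths else sample(widths, 1L)
      counts <- matrix(0, w, 4)
      for (i in seq_len(w)) {
        dom <- sample(1:4, 1L)
        counts[i, ] <- sample(0:3, 4, replace = TRUE)
        counts[i, dom] <- sample(12:20, 1L)
      }
      id <- sprintf("SYNM%03d", k)
      m <- motif(counts, id = id, tf_name = tf_names[k])
      cons <- consensus_string(m)
      if (w == 1L || length(unique(strsplit(cons, "")[[1]])) > 1L) break
    }
    out[[id]] <- m
  }
  out
}

#' Plant motif consensus sites and construct variants over them
#'
#' Writes motif consensus sequences at well-separated genomic positions
#' (at least `3 * width` apart) and constructs one variant per entry of
#' `variant_plan`, realizing the requested disruption/creation class:
#' \describe{
#'   \item{snv_disrupt}{SNV at the motif's most informative position,
#'     consensus base -> worst base (intended geometry `snv_window`,
#'     direction `disrupted`).}
#'   \item{del_span}{deletion of interior motif bases, leaving at least one
#'     motif base on each side (`spanning`, `disrupted`).}
#'   \item{ins_split}{insertion of random bases inside the motif
#'     (`spanning`, `disrupted`).}
#'   \item{ins_create_contained}{insertion whose ALT carries the consensus
#'     flanked by pad bases, at a position with no planted site — the motif
#'     exists only on the alternate allele (`contained`, `created`).}
#'   \item{ins_create_edge}{the genome carries the consensus prefix just
#'     before the breakpoint and the insertion supplies the remainder plus
#'     pad, so the created motif overlaps the insertion's start edge
#'     (`upstream_overlap`, `created`).}
#'   \item{neutral_far}{an SNV far (>= 3 * width) from every planted site
#'     (`snv_window`, no intended direction).}
#' }
#' Insertion ALT strings are constructed so VCF-style left-alignment cannot
#' shift them, keeping the realized geometry deterministic.
#'
#' @param genome a [Biostrings::DNAStringSet] (will be modified).
#' @param motifs named list of `motif`s; sites cycle through them.
#' @param variant_plan character vector of the classes above.
#' @param seed integer seed.
#' @return List with `genome` (the mutated reference) and `manifest`: a
#'   list with `seed`, `planted_sites` (data.frame motif_id, chrom, start,
#'   strand), and `variants` (data.frame: the raw edits plus
#'   `intended_class`, `intended_geometry`, `intended_direction`,
#'   `site_motif`).
#' @export
plant_and_mutate <- function(genome, motifs, variant_plan, seed = 1L) {
  set.seed(seed)
  chroms <- names(genome)
  clens <- setNames(as.integer(Biostrings::width(genome)), chroms)
  seqs <- as.list(as.character(genome))
  occupied <- lapply(chroms, function(x) matrix(integer(), ncol = 2))
  names(occupied) <- chroms

  maxw <- max(vapply(motifs, `[[`, 0L, "width"))
  # separation must exceed both the 3w window-interference bound and the
  # site-peak footprint (half-width 50 each side in make_peaks), so a
  # site's peak can never reach a neighboring variant
  margin <- max(3L * maxw, 150L)
  place <- function(len_needed) {
    for (try in 1:2000) {
      ch <- sample(chroms, 1L)
      pos <- sample.int(clens[[ch]] - len_needed - 2L * margin, 1L) + margin
      occ <- occupied[[ch]]
      if (nrow(occ) == 0L ||
          all(pos + len_needed + margin <= occ[, 1] |
              pos - margin >= occ[, 2])) {
        occupied[[ch]] <<- rbind(occ, c(pos, pos + len_needed))
        return(list(chrom = ch, start = pos))
      }
    }
    stop("insufficient room to place non-overlapping sites")
  }
  put <- function(ch, start0, s) {
    substr(seqs[[ch]], start0 + 1L, start0 + nchar(s)) <<- s
  }
  geta <- function(ch, start0, end0) substr(seqs[[ch]], start0 + 1L, end0)

  geom_of <- c(snv_disrupt = "snv_window", del_span = "spanning",
               ins_split = "spanning", ins_create_contained = "contained",
               ins_create_edge = "upstream_overlap",
               neutral_far = "snv_window")
  dir_of <- c(snv_disrupt = "disrupted", del_span = "disrupted",
              ins_split = "disrupted", ins_create_contained = "created",
              ins_create_edge = "created", neutral_far = NA)

  sites <- list(); vars <- list()
  motif_cycle <- rep(seq_along(motifs),
                     length.out = length(variant_plan))
  rand_base_not <- function(exclude) sample(setdiff(DNA_BASES, exclude), 1L)
  rand_seq <- function(len) paste(sample(DNA_BASES, len, replace = TRUE),
                                  collapse = "")

  for (k in seq_along(variant_plan)) {
    plan <- variant_plan[k]
    m <- motifs[[motif_cycle[k]]]
    w <- m$width
    cons <- strsplit(consensus_string(m), "")[[1]]
    vid <- sprintf("var%03d_%s", k, plan)

    if (plan %in% c("snv_disrupt", "del_span", "ins_split")) {
      loc <- place(w)
      put(loc$chrom, loc$start, paste(cons, collapse = ""))
      sites[[length(sites) + 1L]] <- data.frame(
        motif_id = m$id, chrom = loc$chrom, start = loc$start,
        strand = "+", stringsAsFactors = FALSE)
      if (plan == "snv_disrupt") {
        info <- apply(m$lods, 1, max) - apply(m$lods, 1, min)
        j <- which.max(info)
        worst <- DNA_BASES[which.min(m$lods[j, ])]
        vars[[length(vars) + 1L]] <- data.frame(
          chrom = loc$chrom, start = loc$start + j - 1L,
          end = loc$start + j, ref = cons[j], alt = worst, vid = vid,
          stringsAsFactors = FALSE)
      } else if (plan == "del_span") {
        # interior deletion [s+a, s+b) with cons[a] != cons[b] so
        # left-alignment cannot shift it out of the motif
        ab <- NULL
        for (a in 1:2) for (b in (w - 1L):(a + 1L))
          if (is.null(ab) && cons[a] != cons[b]) ab <- c(a, b)
        if (is.null(ab)) stop("no stable interior deletion for ", m$id)
        vars[[length(vars) + 1L]] <- data.frame(
          chrom = loc$chrom, start = loc$start + ab[1],
          end = loc$start + ab[2],
          ref = paste(cons[(ab[1] + 1L):ab[2]], collapse = ""), alt = "",
          vid = vid, stringsAsFactors = FALSE)
      } else {  # ins_split
        j <- sample(seq_len(w - 1L), 1L)  # breakpoint inside the motif
        # first base must not extend the consensus prefix, last base must
        # neither complete the suffix junction nor allow left-alignment
        ins <- paste0(rand_base_not(cons[j + 1L]), rand_seq(3L),
                      rand_base_not(cons[j]))
        vars[[length(vars) + 1L]] <- data.frame(
          chrom = loc$chrom, start = loc$start + j,
          end = loc$start + j, ref = "", alt = ins, vid = vid,
          stringsAsFactors = FALSE)
      }
    } else if (plan == "ins_create_contained") {
      loc <- place(1L)
      p <- loc$start
      prev <- geta(loc$chrom, p - 1L, p)
      ins <- paste0(rand_seq(2L), paste(cons, collapse = ""),
                    rand_seq(1L), rand_base_not(prev))
      vars[[length(vars) + 1L]] <- data.frame(
        chrom = loc$chrom, start = p, end = p, ref = "", alt = ins,
        vid = vid, stringsAsFactors = FALSE)
    } else if (plan == "ins_create_edge") {
      kpre <- max(1L, w %/% 2L)
      loc <- place(kpre + 1L)
      p <- loc$start + kpre
      put(loc$chrom, loc$start, paste(cons[1:kpre], collapse = ""))
      ins <- paste0(paste(cons[(kpre + 1L):w], collapse = ""),
                    rand_seq(1L), rand_base_not(cons[kpre]))
      vars[[length(vars) + 1L]] <- data.frame(
        chrom = loc$chrom, start = p, end = p, ref = "", alt = ins,
        vid = vid, stringsAsFactors = FALSE)
    } else if (plan == "neutral_far") {
      loc <- place(1L)
      refb <- geta(loc$chrom, loc$start, loc$start + 1L)
      vars[[length(vars) + 1L]] <- data.frame(
        chrom = loc$chrom, start = loc$start, end = loc$start + 1L,
        ref = refb, alt = rand_base_not(refb), vid = vid,
        stringsAsFactors = FALSE)
    } else stop("unknown plan class: ", plan)

    vars[[length(vars)]]$intended_class <- plan
    vars[[length(vars)]]$intended_geometry <- geom_of[[plan]]
    vars[[length(vars)]]$intended_direction <- dir_of[[plan]]
    vars[[length(vars)]]$site_motif <- m$id
  }
  genome2 <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome2) <- chroms
  manifest <- list(
    seed = seed,
    chrom_lengths = as.list(clens),
    planted_sites = if (length(sites) > 0L) do.call(rbind, sites) else
      data.frame(motif_id = character(), chrom = character(),
                 start = integer(), strand = character()),
    variants = do.call(rbind, vars))
  list(genome = genome2, manifest = manifest)
}

#' Generate a ReMap-layout peak BED over planted sites
#'
#' Emits one peak per planted site (for that site's TF), with optional
#' boundary jitter, plus optional decoy peaks: random-position peaks with a
#' wrong TF, and/or same-position peaks with a named family-decoy TF for
#' exercising family expansion.
#'
#' @param manifest manifest from [plant_and_mutate()].
#' @param motifs the motif list used for planting (for TF names/widths).
#' @param jitter max uniform boundary jitter in bp (default 0).
#' @param decoys number of random wrong-TF decoy peaks (default 0).
#' @param family_decoy_tf optional TF name; when set, adds one peak with
#'   that name over every planted site.
#' @param halfwidth peak half-width around the site (default 50).
#' @param seed integer seed.
#' @return A peak `data.frame` (`chrom`, `start`, `end`, `accession`, `tf`,
#'   `biotype`).
#' @export
make_peaks <- function(manifest, motifs, jitter = 0L, decoys = 0L,
                       family_decoy_tf = NULL, halfwidth = 50L,
                       seed = 1L) {
  set.seed(seed)
  ps <- manifest$planted_sites
  clens <- manifest$chrom_lengths
  rows <- list()
  for (i in seq_len(nrow(ps))) {
    m <- motifs[[ps$motif_id[i]]]
    j1 <- if (jitter > 0L) sample(-jitter:jitter, 1L) else 0L
    j2 <- if (jitter > 0L) sample(-jitter:jitter, 1L) else 0L
    s <- max(0L, ps$start[i] - halfwidth + j1)
    e <- min(clens[[ps$chrom[i]]], ps$start[i] + m$width + halfwidth + j2)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ps$chrom[i], start = s, end = e,
      accession = sprintf("SYNEXP%03d", i), tf = m$tf_name,
      biotype = "synthetic-tissue", stringsAsFactors = FALSE)
    if (!is.null(family_decoy_tf))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ps$chrom[i], start = s, end = e,
        accession = sprintf("SYNFAM%03d", i), tf = family_decoy_tf,
        biotype = "synthetic-tissue", stringsAsFactors = FALSE)
  }
  for (d in seq_len(decoys)) {
    ch <- sample(names(clens), 1L)
    s <- sample.int(clens[[ch]] - 120L, 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, start = s, end = s + 100L,
      accession = sprintf("SYNDEC%03d", d), tf = "DECOYTF",
      biotype = "decoy-tissue", stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), accession = character(),
                      tf = character(), biotype = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a peak table as a ReMap-layout BED file
#'
#' @param peaks peak `data.frame` (as from [make_peaks()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(peaks) > 0L)
    writeLines(paste(peaks$chrom, peaks$start, peaks$end,
                     paste(peaks$accession, peaks$tf, peaks$biotype,
                           sep = "."),
                     sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Write variants as a minimal VCF 4.2 file
#'
#' Indels get the standard VCF anchor base (the reference base before the
#' edit); coordinates convert to 1-based.
#'
#' @param variants variant `data.frame` (normalized, 0-based half-open).
#' @param genome [Biostrings::DNAStringSet] (for anchor bases and contig
#'   headers).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, genome, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con, sep = "\n")
  for (ch in names(genome))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                       length(genome[[ch]])), con, sep = "\n")
  writeLines(paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (nzchar(v$ref) && nzchar(v$alt)) {
      pos1 <- v$start + 1L; ref <- v$ref; alt <- v$alt
    } else {
      anchor <- genome_subseq(genome, v$chrom, v$start - 1L, v$start)
      pos1 <- v$start  # 1-based position of the anchor base
      ref <- paste0(anchor, v$ref)
      alt <- paste0(anchor, v$alt)
    }
    writeLines(paste(v$chrom, pos1, v$vid, ref, alt, ".", "PASS", ".",
                     sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Write variants in the custom BED-derived dialect
#'
#' @param variants variant `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_custom_bed <- function(variants, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    name <- sprintf("%s:%d:%s:%s", v$chrom, v$start + 1L,
                    if (nzchar(v$ref)) v$ref else "-",
                    if (nzchar(v$alt)) v$alt else "-")
    writeLines(paste(v$chrom, v$start, v$end, name, 0L, "+", sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Write a complete seeded fixture bundle
#'
#' Generates a toy genome, an informative motif library, one variant per
#' plan class, a matching peak BED, motif-to-TF and family tables, and a
#' ground-truth manifest; everything lands in `dir` as plain text. The
#' defaults cover all six plan classes over three motifs.
#'
#' @param dir output directory (created if needed).
#' @param seed master integer seed; sub-steps derive seeds `seed`,
#'   `seed + 1`, `seed + 2`.
#' @param n_motifs number of motifs.
#' @param variant_plan plan classes; default covers every class twice.
#' @param jitter,decoys passed to [make_peaks()].
#' @return Invisibly, a list of paths plus the in-memory `genome`,
#'   `motifs`, `manifest`, `peaks`.
#' @export
write_fixture_bundle <- function(dir, seed = 42L, n_motifs = 3L,
                                 variant_plan = rep(c(
                                   "snv_disrupt", "del_span", "ins_split",
                                   "ins_create_contained",
                                   "ins_create_edge", "neutral_far"), 2L),
                                 jitter = 0L, decoys = 0L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  motifs <- random_motifs(n_motifs, seed = seed)
  genome0 <- make_genome(seed)
  pm <- plant_and_mutate(genome0, motifs, variant_plan, seed = seed + 1L)
  genome <- pm$genome
  manifest <- pm$manifest
  peaks <- make_peaks(manifest, motifs, jitter = jitter, decoys = decoys,
                      seed = seed + 2L)

  paths <- list(
    genome_fa = file.path(dir, "genome.fa"),
    motifs_file = file.path(dir, "motifs.jaspar"),
    vcf = file.path(dir, "variants.vcf"),
    custom_bed = file.path(dir, "variants.custom.bed"),
    peaks_bed = file.path(dir, "peaks.bed"),
    tf_map = file.path(dir, "tf_map.tsv"),
    tf_families = file.path(dir, "tf_families.tsv"),
    manifest_json = file.path(dir, "manifest.json"))

  Biostrings::writeXStringSet(genome, paths$genome_fa)
  write_fai(genome, paste0(paths$genome_fa, ".fai"))
  write_jaspar(motifs, paths$motifs_file)
  vt <- variant_table(manifest$variants$chrom, manifest$variants$start,
                      manifest$variants$end, manifest$variants$ref,
                      manifest$variants$alt, manifest$variants$vid,
                      genome = genome)
  write_variants_vcf(vt, genome, paths$vcf)
  write_variants_custom_bed(vt, paths$custom_bed)
  write_peaks_bed(peaks, paths$peaks_bed)

  tfs <- vapply(motifs, `[[`, "", "tf_name")
  writeLines(c("motif_id\ttf",
               paste(names(motifs), tfs, sep = "\t")), paths$tf_map)
  writeLines(c("tf\tfamily_id",
               paste(unique(tfs), "FAM1", sep = "\t"),
               "DECOYTF\tFAM_DECOY"), paths$tf_families)
  jsonlite::write_json(
    list(seed = seed,
         chrom_lengths = manifest$chrom_lengths,
         planted_sites = manifest$planted_sites,
         variants = manifest$variants),
    paths$manifest_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, list(genome = genome, motifs = motifs,
                          manifest = manifest, peaks = peaks,
                          variants = vt)))
}

write_fai <- function(genome, path) {
  # FASTA written by writeXStringSet: header '>name', 80 bases per line
  offs <- integer(length(genome))
  off <- 0L
  lens <- Biostrings::width(genome)
  for (i in seq_along(genome)) {
    off <- off + nchar(names(genome)[i]) + 2L  # '>' + name + '\n'
    offs[i] <- off
    nlines <- ceiling(lens[i] / 80)
    off <- off + lens[i] + nlines  # bases + newlines
  }
  writeLines(paste(names(genome), lens, offs, 80L, 81L, sep = "\t"), path)
}
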