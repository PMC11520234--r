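#' Construct a motif object
#'
#' Builds the package's motif representation from a position count or
#' frequency matrix. Columns (positions) are smoothed by adding
#' `pseudocount * background[b]` to each cell and renormalizing, so every
#' probability is strictly positive and log-odds scores are finite. Log-odds
#' are in bits: `lods[i, b] = log2(ppm[i, b] / background[b])`.
#'
#' @param mat numeric matrix, width x 4 (rows = motif positions, columns =
#'   A, C, G, T), holding counts or frequencies. Rows are the scanning
#'   positions; each row is smoothed and normalized independently.
#' @param id motif identifier.
#' @param tf_name transcription factor name (defaults to `id`).
#' @param background length-4 probability vector over A,C,G,T; must be
#'   strictly positive and sum to 1.
#' @param pseudocount non-negative smoothing mass distributed proportionally
#'   to the background. Default 0.8.
#' @return An object of class `"motif"`: a list with elements `id`,
#'   `tf_name`, `width`, `ppm` (width x 4 probability matrix), `background`,
#'   `pseudocount`, `lods` (width x 4 log2-odds matrix), `min_score`,
#'   `max_score`, and `counts` (the raw input matrix, kept for round-trip
#'   serialization).
#' @export
motif <- function(mat, id, tf_name = id,
                  background = rep(0.25, 4), pseudocount = 0.8) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L)
    stop("motif matrix must have 4 columns (A, C, G, T)")
  if (nrow(mat) < 1L)
    stop("motif must have width >= 1")
  if (any(mat < 0))
    stop("motif '", id, "': negative counts are not allowed")
  if (any(!is.finite(mat)))
    stop("motif '", id, "': non-finite entries")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 strictly positive probabilities")
  background <- background / sum(background)
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  colnames(mat) <- DNA_BASES

  # Smoothing: works identically for count rows (sum >> 1) and frequency
  # rows (sum ~ 1): add pseudocount * background, renormalize the row.
  sm <- sweep(mat, 2, background * pseudocount, "+")
  ppm <- sm / rowSums(sm)
  lods <- log2(sweep(ppm, 2, background, "/"))
  m <- structure(list(
    id = as.character(id),
    tf_name = as.character(tf_name),
    width = nrow(ppm),
    ppm = ppm,
    background = setNames(background, DNA_BASES),
    pseudocount = pseudocount,
    lods = lods,
    min_score = sum(apply(lods, 1, min)),
    max_score = sum(apply(lods, 1, max)),
    counts = mat
  ), class = "motif")
  validate_motif(m)
  m
}

validate_motif <- function(m) {
  stopifnot(inherits(m, "motif"))
  if (any(abs(rowSums(m$ppm) - 1) > 1e-9))
    stop("motif '", m$id, "': ppm rows do not sum to 1")
  if (any(m$ppm <= 0) || any(m$ppm > 1))
    stop("motif '", m$id, "': ppm entries outside (0, 1]")
  if (abs(sum(m$background) - 1) > 1e-9 || any(m$background <= 0))
    stop("motif '", m$id, "': invalid background")
  invisible(m)
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s (%s), width %d, score range [%.3f, %.3f] bits\n",
              x$id, x$tf_name, x$width, x$min_score, x$max_score))
  cat("consensus:", consensus_string(x), "\n")
  invisible(x)
}

#' Consensus sequence of a motif
#'
#' The per-position argmax base string; it attains exactly `max_score` under
#' the motif's log-odds matrix. Ties go to the earlier base in A,C,G,T order.
#'
#' @param m a `motif`.
#' @return A character scalar of length `m$width`.
#' @export
consensus_string <- function(m) {
  paste(DNA_BASES[apply(m$lods, 1, which.max)], collapse = "")
}

#' Reverse-complement a motif
#'
#' Reverses the position order and swaps complementary base columns
#' (A with T, C with G); the background is permuted the same way. Applying it
#' twice returns the original motif; `min_score` and `max_score` are
#' unchanged.
#'
#' @param m a `motif`.
#' @return The reverse-complement `motif`.
#' @export
reverse_complement <- function(m) {
  stopifnot(inherits(m, "motif"))
  perm <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G
  rc <- m
  rc$ppm <- m$ppm[m$width:1, perm, drop = FALSE]
  rc$lods <- m$lods[m$width:1, perm, drop = FALSE]
  rc$counts <- m$counts[m$width:1, perm, drop = FALSE]
  rc$background <- setNames(m$background[perm], DNA_BASES)
  dimnames(rc$ppm) <- dimnames(rc$lods) <- dimnames(rc$counts) <-
    list(NULL, DNA_BASES)
  rc
}

#' Read motifs from a JASPAR PFM file
#'
#' Parses JASPAR position frequency matrix text (2020 dialect): a header
#' line `>ID name` followed by four labeled rows `A [ ... ]`, `C [ ... ]`,
#' `G [ ... ]`, `T [ ... ]`. Brackets are optional and whitespace (tabs or
#' spaces) is tolerated. Count matrices are smoothed as described in
#' [motif()].
#'
#' @param path path to a JASPAR PFM text file.
#' @param background length-4 background probability vector (default
#'   uniform).
#' @param pseudocount smoothing mass, default 0.8.
#' @return A named list of `motif` objects (names = motif ids).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no JASPAR '>' header found in ", path)
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    h <- lines[hdr[k]]
    fields <- strsplit(sub("^>\\s*", "", h), "\\s+")[[1]]
    if (length(fields) < 1L || !nzchar(fields[1]))
      stop("malformed JASPAR header at line ", hdr[k], ": '", h, "'")
    id <- fields[1]
    tf <- if (length(fields) >= 2L) paste(fields[-1], collapse = " ") else id
    body <- lines[seq(hdr[k] + 1L, bounds[k + 1L] - 1L)]
    if (length(body) < 4L)
      stop("motif '", id, "': expected 4 base rows, got ", length(body))
    rows <- vector("list", 4L)
    for (b in seq_len(4L)) {
      ln <- body[b]
      lab <- sub("^\\s*([ACGTacgt])\\s*[\\[]?.*$", "\\1", ln)
      if (!toupper(lab) %in% DNA_BASES)
        stop("motif '", id, "': row ", b, " lacks an A/C/G/T label: '",
             ln, "'")
      nums <- gsub("[][]", " ", sub("^\\s*[ACGTacgt]", "", ln))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums),
                                                   "\\s+")[[1]]))
      if (any(is.na(vals)))
        stop("motif '", id, "': unparseable numbers in row '", ln, "'")
      rows[[match(toupper(lab), DNA_BASES)]] <- vals
    }
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L)
      stop("motif '", id, "': rows have unequal widths (",
           paste(widths, collapse = ","), ")")
    mat <- t(do.call(rbind, rows))  # width x 4
    out[[id]] <- motif(mat, id = id, tf_name = tf,
                       background = background, pseudocount = pseudocount)
  }
  out
}

#' Write motifs to a JASPAR PFM file
#'
#' Serializes the stored raw matrices (counts or frequencies as originally
#' read), so `read_jaspar()` followed by `write_jaspar()` reproduces the
#' input matrix exactly.
#'
#' @param motifs a list of `motif` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m$id, m$tf_name), con)
    for (b in seq_len(4L)) {
      vals <- m$counts[, b]
      txt <- ifelse(vals == round(vals), format(vals, scientific = FALSE,
                                                trim = TRUE),
                    format(vals, trim = TRUE))
      writeLines(sprintf("%s  [ %s ]", DNA_BASES[b],
                         paste(txt, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read motifs from a MEME minimal-format file
#'
#' Supports the MEME minimal text format: a `MEME version` line, optional
#' `ALPHABET= ACGT`, an optional `Background letter frequencies` block, and
#' one or more `MOTIF` records each with a `letter-probability matrix:`
#' block. The file background (or uniform if absent) becomes each motif's
#' background; probabilities are smoothed as in [motif()].
#'
#' @param path path to a MEME minimal text file.
#' @param pseudocount smoothing mass, default 0.8.
#' @return A named list of `motif` objects.
#' @export
read_meme <- function(path, pseudocount = 0.8) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  al <- grep("^\\s*ALPHABET\\s*=", lines, value = TRUE)
  if (length(al) > 0L) {
    alpha <- gsub("\\s", "", sub("^\\s*ALPHABET\\s*=", "", al[1]))
    if (toupper(alpha) != "ACGT")
      stop("unsupported alphabet '", alpha, "': only ACGT is supported")
  }
  background <- rep(0.25, 4)
  bgline <- grep("^\\s*Background letter frequencies", lines)
  if (length(bgline) > 0L && bgline[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bgline[1] + 1L]), "\\s+")[[1]]
    if (length(toks) >= 8L) {
      labs <- toupper(toks[seq(1, 7, by = 2)])
      vals <- as.numeric(toks[seq(2, 8, by = 2)])
      if (!any(is.na(vals)) && setequal(labs, DNA_BASES))
        background <- vals[match(DNA_BASES, labs)]
    }
  }
  starts <- grep("^\\s*MOTIF\\b", lines)
  if (length(starts) == 0L) stop("no MOTIF records in ", path)
  out <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    toks <- strsplit(trimws(lines[starts[k]]), "\\s+")[[1]]
    id <- if (length(toks) >= 2L) toks[2] else stop(
      "MOTIF line ", starts[k], " lacks an identifier")
    tf <- if (length(toks) >= 3L) toks[3] else id
    block <- lines[seq(starts[k], bounds[k + 1L] - 1L)]
    lp <- grep("^\\s*letter-probability matrix", block)
    if (length(lp) == 0L)
      stop("motif '", id, "': missing letter-probability matrix block")
    w <- NA_integer_
    wm <- regmatches(block[lp[1]],
                     regexpr("w\\s*=\\s*[0-9]+", block[lp[1]]))
    if (length(wm) == 1L) w <- as.integer(sub("w\\s*=\\s*", "", wm))
    rows <- list()
    i <- lp[1] + 1L
    while (i <= length(block)) {
      ln <- trimws(block[i])
      if (!nzchar(ln) || !grepl("^[0-9.eE+-]", ln)) break
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(vals) != 4L || any(is.na(vals)))
        stop("motif '", id, "': bad probability row '", ln, "'")
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    if (length(rows) == 0L)
      stop("motif '", id, "': empty letter-probability matrix")
    if (!is.na(w) && length(rows) != w)
      stop("motif '", id, "': matrix has ", length(rows),
           " rows but header says w=", w)
    mat <- do.call(rbind, rows)
    out[[id]] <- motif(mat, id = id, tf_name = tf,
                       background = background, pseudocount = pseudocount)
  }
  out
}
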