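#' Default export color ramp
#'
#' A 5-step single-hue blue ramp, light to dark (strictly decreasing
#' luminance), used to color BED9 tracks: darker means a larger mapped
#' value (stronger effect, or smaller p-value).
#'
#' @return Character vector of 5 hex colors.
#' @export
default_color_ramp <- function() {
  c("#EFF3FF", "#BDD7E7", "#6BAED6", "#3182BD", "#08519C")
}

#' Export configuration for BED tracks
#'
#' @param mode `"score_colored"` (color by `|effect|`, disruptiveness) or
#'   `"pvalue_colored"` (color by motif quality, `1 - p/alpha` floored at
#'   0).
#' @param alpha_filter p-value scale/filter in (0, 1], default 1e-4.
#' @param top_n keep only the `top_n` rows by `|effect|` (`Inf` = all).
#' @param color_ramp ordered light-to-dark color vector.
#' @return An `export_config` list.
#' @export
export_config <- function(mode = c("score_colored", "pvalue_colored"),
                          alpha_filter = 1e-4, top_n = Inf,
                          color_ramp = default_color_ramp()) {
  mode <- match.arg(mode)
  if (!(alpha_filter > 0 && alpha_filter <= 1))
    stop("alpha_filter must be in (0, 1]")
  lum <- apply(grDevices::col2rgb(color_ramp), 2,
               function(x) sum(x * c(0.299, 0.587, 0.114)))
  if (any(diff(lum) >= 0))
    stop("color_ramp luminance must be strictly decreasing (light to dark)")
  structure(list(mode = mode, alpha_filter = alpha_filter, top_n = top_n,
                 color_ramp = color_ramp), class = "export_config")
}

RESULT_NUM_COLS <- c("start", "end", "motif_width", "ref_raw", "ref_rel",
                     "ref_pvalue", "ref_win_start", "alt_raw", "alt_rel",
                     "alt_pvalue", "alt_win_start", "effect",
                     "coord_start", "coord_end", "better_genome_offset",
                     "n_windows", "peak_count")
RESULT_LGL_COLS <- c("ref_overlaps", "alt_overlaps")

#' Export results to TSV
#'
#' One row per (variant, motif) pair with all fields in a stable column
#' order; the file round-trips losslessly through [read_results_tsv()].
#' Fields containing tabs or newlines are rejected at write time.
#'
#' @param results results `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_tsv <- function(results, path) {
  chr_cols <- names(results)[vapply(results, is.character, TRUE)]
  for (cc in chr_cols)
    if (any(grepl("[\t\n]", results[[cc]])))
      stop("field '", cc, "' contains tab or newline characters")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(results), collapse = "\t"), con, sep = "\n")
  if (nrow(results) > 0L) {
    cells <- vapply(seq_along(results), function(j)
      format_cell(results[[j]]), character(nrow(results)))
    if (nrow(results) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1, paste, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

format_cell <- function(x) {
  if (is.numeric(x) && !is.integer(x))
    ifelse(is.na(x), "NA", sprintf("%.17g", x))
  else
    ifelse(is.na(x), "NA", as.character(x))
}

#' Read results back from a TSV export
#'
#' @param path a file written by [export_tsv()].
#' @return A results `data.frame` with column types restored.
#' @export
read_results_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA",
                           colClasses = "character", check.names = FALSE)
  for (cc in intersect(RESULT_NUM_COLS, names(tab))) {
    v <- as.numeric(tab[[cc]])
    if (cc %in% c("start", "end", "motif_width", "ref_win_start",
                  "alt_win_start", "coord_start", "coord_end",
                  "better_genome_offset", "n_windows", "peak_count"))
      v <- as.integer(v)
    tab[[cc]] <- v
  }
  for (cc in intersect(RESULT_LGL_COLS, names(tab)))
    tab[[cc]] <- as.logical(tab[[cc]])
  tab
}

#' Export results as a SQL script
#'
#' Writes a database-agnostic `CREATE TABLE` plus `INSERT` statements with
#' the same columns as the TSV export.
#'
#' @param results results `data.frame`.
#' @param path output path.
#' @param table table name, default `"motif_disruptions"`.
#' @return `path`, invisibly.
#' @export
export_sql <- function(results, path, table = "motif_disruptions") {
  con <- file(path, "wb")
  on.exit(close(con))
  types <- vapply(results, function(x) {
    if (is.integer(x)) "INTEGER"
    else if (is.numeric(x)) "DOUBLE PRECISION"
    else if (is.logical(x)) "BOOLEAN"
    else "TEXT"
  }, character(1))
  writeLines(sprintf("CREATE TABLE %s (\n%s\n);", table,
                     paste(sprintf("  %s %s", names(results), types),
                           collapse = ",\n")), con, sep = "\n")
  for (i in seq_len(nrow(results))) {
    vals <- vapply(seq_along(results), function(j) {
      x <- results[[j]][i]
      if (is.na(x)) "NULL"
      else if (is.numeric(x)) format_cell(results[[j]])[i]
      else if (is.logical(x)) if (x) "TRUE" else "FALSE"
      else paste0("'", gsub("'", "''", as.character(x)), "'")
    }, character(1))
    writeLines(sprintf("INSERT INTO %s (%s) VALUES (%s);", table,
                       paste(names(results), collapse = ", "),
                       paste(vals, collapse = ", ")), con, sep = "\n")
  }
  invisible(path)
}

#' Export results as a BED9 browser track
#'
#' Writes a UCSC-style BED9 file (`itemRgb` dialect, with a `track` header
#' line) for display in genome browsers. The score column and color encode
#' `x = |effect|` in score mode, or `x = max(0, 1 - pvalue/alpha_filter)`
#' (better-allele p-value) in p-value mode: `score = round(1000 * x)`
#' clipped to [0, 1000], color = the ramp step `floor(x * (len - 1))`, so a
#' darker color always means a larger `x`. Each row spans the better
#' allele's motif match on the reference genome when that is representable;
#' matches lying on the alternate allele of an insertion have no
#' reference coordinates and are drawn over the breakpoint widened by one
#' base each side, with a note appended to the name field.
#'
#' @param results results `data.frame`.
#' @param path output path.
#' @param cfg an [export_config()].
#' @return `path`, invisibly.
#' @export
export_bed <- function(results, path, cfg = export_config()) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0('track name="motifdisruptr" description=',
                    '"TF motif disruption (', cfg$mode,
                    ')" itemRgb="On"'), con, sep = "\n")
  if (nrow(results) > 0L && is.finite(cfg$top_n) &&
      nrow(results) > cfg$top_n) {
    ord <- order(-abs(results$effect), results$vid, results$motif_id)
    results <- results[ord[seq_len(cfg$top_n)], , drop = FALSE]
  }
  ramp <- t(grDevices::col2rgb(cfg$color_ramp))
  nr <- nrow(ramp)
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    x <- if (cfg$mode == "score_colored") abs(r$effect) else {
      p <- suppressWarnings(min(r$ref_pvalue, r$alt_pvalue, na.rm = TRUE))
      if (!is.finite(p)) 0 else max(0, 1 - p / cfg$alpha_filter)
    }
    x <- min(max(x, 0), 1)
    note <- ""
    if (r$better_allele == "ref" && !is.na(r$ref_win_start)) {
      bs <- r$better_genome_offset + r$ref_win_start
      be <- bs + r$motif_width
      strand <- r$ref_strand
    } else if (r$better_allele == "alt" &&
               r$vclass %in% c("SNV", "MNV") && !is.na(r$alt_win_start)) {
      bs <- r$better_genome_offset + r$alt_win_start
      be <- bs + r$motif_width
      strand <- r$alt_strand
    } else if (!is.na(r$alt_win_start)) {
      # match on the alternate allele of an indel: no reference
      # coordinates; draw over the variant span widened by 1 each side
      bs <- max(0L, r$start - 1L)
      be <- r$end + 1L
      strand <- r$alt_strand
      note <- "|alt-allele-match"
    } else {
      warning("result ", r$vid, "/", r$motif_id,
              " has no drawable interval; skipped")
      next
    }
    score <- min(1000L, max(0L, as.integer(round(1000 * x))))
    col <- ramp[min(nr, floor(x * (nr - 1)) + 1L), ]
    writeLines(paste(r$chrom, bs, be,
                     paste0(r$vid, "|", r$motif_id, "|", r$geometry, note),
                     score, strand, bs, be,
                     paste(col, collapse = ","), sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}
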