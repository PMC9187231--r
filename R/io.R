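# Plain-text interchange: pairs TSV, BED, bedGraph, dense matrix TSV.
# All files use 0-based half-open coordinates (BED convention); 1-based
# inputs must be converted by the caller.

#' Read a pairs TSV file
#'
#' Four tab-separated columns (`chrom1 pos1 chrom2 pos2`); lines starting
#' with `#` are header/comment lines. Malformed lines are counted and, by
#' default, reported with a warning; with `strict = TRUE` they are an
#' error carrying the first offending line number.
#'
#' @param path input file.
#' @param strict error instead of warning on malformed lines.
#' @return a `pairs_table`; attribute `n_malformed` records skipped lines.
#' @export
read_pairs <- function(path, strict = FALSE) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) {
    out <- pairs_table(data.frame(chrom1 = character(0), pos1 = integer(0),
                                  chrom2 = character(0), pos2 = integer(0)))
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  p1 <- suppressWarnings(as.integer(vapply(fields, function(f) f[2] %||% NA_character_, "")))
  p2 <- suppressWarnings(as.integer(vapply(fields, function(f) f[4] %||% NA_character_, "")))
  bad <- nf < 4L | is.na(p1) | is.na(p2)
  if (any(bad)) {
    msg <- sprintf("%d malformed pairs line(s); first at data line %d",
                   sum(bad), which(bad)[1L])
    if (strict) stopf("%s", msg) else warning(msg)
  }
  ok <- !bad
  out <- pairs_table(data.frame(
    chrom1 = vapply(fields[ok], `[`, "", 1L),
    pos1 = p1[ok],
    chrom2 = vapply(fields[ok], `[`, "", 3L),
    pos2 = p2[ok],
    stringsAsFactors = FALSE
  ))
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Write a pairs table as TSV
#' @param pairs a `pairs_table`.
#' @param path output file.
#' @export
write_pairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom1\tpos1\tchrom2\tpos2", con)
  if (nrow(pairs)) {
    utils::write.table(pairs, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a BED file
#'
#' Standard BED, 0-based half-open. Columns beyond the third are optional;
#' strand is taken from column 6 when present.
#'
#' @param path input file.
#' @return data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`. Empty file yields an empty data.frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (!length(lines)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- min(lengths(fields))
  nc <- min(nc, 6L)
  out <- as.data.frame(do.call(rbind, lapply(fields, `[`, seq_len(nc))),
                       stringsAsFactors = FALSE)
  names(out) <- cols[seq_len(nc)]
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if (any(is.na(out$start)) || any(is.na(out$end))) {
    stopf("non-numeric BED coordinates in %s", path)
  }
  if (any(out$end <= out$start)) {
    stopf("BED interval with end <= start at line %d",
          which(out$end <= out$start)[1L])
  }
  if ("score" %in% names(out)) {
    out$score <- suppressWarnings(as.numeric(out$score))
  }
  out
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` and, when present, `name`, `score`,
#' `strand` columns.
#'
#' @param features data.frame; needs `start` and `end`, `chrom` optional
#'   (filled with `chrom` argument).
#' @param path output file.
#' @param chrom default chromosome name.
#' @export
write_bed <- function(features, path, chrom = "chrS") {
  df <- features
  if (!"chrom" %in% names(df)) df <- cbind(chrom = chrom, df)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  # BED columns are positional: fill gaps up to the last present column
  full <- c("chrom", "start", "end", "name", "score", "strand")
  last <- max(match(cols, full))
  use <- full[seq_len(last)]
  for (cl in setdiff(use, names(df))) {
    df[[cl]] <- if (cl == "name") "." else if (cl == "score") 0 else "."
  }
  utils::write.table(df[, use, drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a fold-enrichment track
#'
#' Four columns: chrom, start, end, value. Intervals must tile a uniform
#' bin grid.
#'
#' @param path input file.
#' @param sample_name label for the track.
#' @return an `fe_track`.
#' @export
read_bedgraph <- function(path, sample_name = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("empty bedGraph: %s", path)
  if (any(df$end <= df$start)) stopf("bedGraph interval with end <= start")
  bs <- unique(df$end - df$start)
  if (length(bs) != 1L) stopf("bedGraph bins are not uniform")
  n <- max(df$end) %/% bs
  vals <- numeric(n)
  vals[df$start %/% bs + 1L] <- df$value
  fe_track(vals, chrom = df$chrom[[1L]], bin_size_bp = bs,
           sample_name = sample_name)
}

#' Write a fold-enrichment track as bedGraph
#' @param track an `fe_track`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  bs <- track$bin_size_bp
  n <- length(track$values)
  df <- data.frame(chrom = track$chrom, start = (seq_len(n) - 1L) * bs,
                   end = seq_len(n) * bs, value = track$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a contact matrix as dense TSV
#'
#' Header lines (prefixed `#`) carry chromosome, bin size, normalization
#' and total read pairs; the body is the dense matrix.
#'
#' @param M a `contact_matrix`.
#' @param path output file.
#' @export
write_matrix_tsv <- function(M, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# chrom=%s", M$chrom),
    sprintf("# bin_size_bp=%d", M$bin_size_bp),
    sprintf("# normalized=%s",
            if (identical(M$normalized, FALSE)) "raw" else M$normalized),
    sprintf("# total_read_pairs=%.0f", M$total_read_pairs),
    sprintf("# n_bins=%d", nrow(M$counts))
  ), con)
  utils::write.table(M$counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dense matrix TSV written by [write_matrix_tsv()]
#' @param path input file.
#' @return a `contact_matrix`.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  get <- function(key) {
    m <- hdr[grepl(paste0("^# ", key, "="), hdr)]
    if (!length(m)) return(NA_character_)
    sub(paste0("^# ", key, "="), "", m[[1L]])
  }
  n_declared <- suppressWarnings(as.integer(get("n_bins")))
  counts <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE),
                                  as.numeric))
  if (!is.na(n_declared) && nrow(counts) != n_declared) {
    stopf("matrix file truncated: %d rows declared, %d found",
          n_declared, nrow(counts))
  }
  norm <- get("normalized")
  contact_matrix(counts,
                 chrom = get("chrom"),
                 bin_size_bp = as.integer(get("bin_size_bp")),
                 normalized = if (identical(norm, "raw")) FALSE else norm,
                 total_read_pairs = as.numeric(get("total_read_pairs")))
}

#' Export a genome annotation as BED files
#'
#' Writes `genes.bed` (strand in column 6, expression in the score
#' column), `origins.bed`, `centromere.bed`, `ltrs.bed` and
#' `convergent_sites.bed` into a directory.
#'
#' @param ann a `genome_annotation`.
#' @param dir output directory (created if absent).
#' @return invisible vector of the written paths.
#' @export
write_genome_bed <- function(ann, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- ann$genes
  paths <- c(
    genes = file.path(dir, "genes.bed"),
    origins = file.path(dir, "origins.bed"),
    centromere = file.path(dir, "centromere.bed"),
    ltrs = file.path(dir, "ltrs.bed"),
    convergent = file.path(dir, "convergent_sites.bed")
  )
  write_bed(data.frame(start = g$start, end = g$end,
                       name = ifelse(g$is_stress_gene, "stress", "gene"),
                       score = round(g$expression_level, 4),
                       strand = g$strand),
            paths["genes"], chrom = ann$chrom)
  o <- ann$origins
  write_bed(data.frame(start = o$position, end = o$position + 1L,
                       name = ifelse(o$is_early, "early", "late")),
            paths["origins"], chrom = ann$chrom)
  write_bed(data.frame(start = ann$centromere_bp,
                       end = ann$centromere_bp + 1L, name = "CEN"),
            paths["centromere"], chrom = ann$chrom)
  write_bed(ann$ltrs, paths["ltrs"], chrom = ann$chrom)
  cs <- as.integer(ann$convergent_sites)
  write_bed(data.frame(start = cs, end = cs + 1L), paths["convergent"],
            chrom = ann$chrom)
  invisible(paths)
}
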