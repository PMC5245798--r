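#' Construct a peak set
#'
#' A `peak_set` is the substrate of all overlap statistics: a
#' coordinate-sorted collection of fixed-coordinate genomic intervals
#' (0-based, half-open) with unique ids, optionally carrying per-peak tag
#' counts for one or more conditions and per-condition library totals.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based start (inclusive) and end
#'   (exclusive). Requires `0 <= start < end`.
#' @param id Unique peak identifiers; autogenerated `<name>_<i>` if `NULL`.
#' @param score Optional numeric score per peak (e.g. control tag count).
#' @param strand Optional strand (`"+"`, `"-"` or `"*"`).
#' @param name Name of the set.
#' @param tags Optional data.frame of non-negative tag counts, one column per
#'   condition, one row per peak (aligned with `id`).
#' @param library_total Optional named numeric of mapped tags per condition.
#'
#' @return An object of class `peak_set` with elements `name`, `peaks`
#'   (sorted data.frame), `tags`, `library_total`.
#' @export
peak_set <- function(chrom, start, end, id = NULL, score = NA_real_,
                     strand = "*", name = "peaks", tags = NULL,
                     library_total = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- length(start)
  if (length(chrom) == 1L) chrom <- rep_len(chrom, n)
  if (length(chrom) != n || length(end) != n) {
    stop("chrom, start, end must have equal length")
  }
  if (n > 0 && (any(start < 0) || any(start >= end))) {
    stop("intervals must satisfy 0 <= start < end")
  }
  if (any(!nzchar(chrom))) stop("chromosome names must be nonempty")
  if (is.null(id)) id <- if (n > 0) paste0(name, "_", seq_len(n)) else character()
  if (anyDuplicated(id)) stop("peak ids must be unique")
  df <- data.frame(
    chrom = as.character(chrom), start = start, end = end,
    id = as.character(id),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(tags)) {
    tags <- as.data.frame(tags)[ord, , drop = FALSE]
    if (nrow(tags) != n) stop("tags must have one row per peak")
    if (any(as.matrix(tags) < 0)) stop("tag counts must be >= 0")
    rownames(tags) <- df$id
  }
  structure(
    list(name = name, peaks = df, tags = tags, library_total = library_total),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d peaks on %d chromosome(s)\n",
              x$name, nrow(x$peaks), length(unique(x$peaks$chrom))))
  if (!is.null(x$tags)) {
    cat("  tag conditions:", paste(colnames(x$tags), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.peak_set <- function(x) nrow(x$peaks)

# GRanges view of a peak_set (1-based closed coordinates)
ps_granges <- function(ps) {
  df <- ps$peaks
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  )
}

# integer-floor midpoint of 0-based half-open intervals
peak_midpoints <- function(ps) floor((ps$peaks$start + ps$peaks$end) / 2)

#' Read a BED or narrowPeak file into a peak set
#'
#' Columns beyond the sixth (the narrowPeak signal/p/q/summit columns) are
#' ignored. Coordinates are kept 0-based half-open, bit-exact.
#'
#' @param path File path.
#' @param name Set name; defaults to the file base name.
#' @return A [peak_set].
#' @export
read_bed <- function(path, name = NULL) {
  name <- name %||% sub("\\.(bed|narrowPeak)$", "", basename(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  nc <- ncol(df)
  peak_set(
    chrom = df[[1]], start = df[[2]], end = df[[3]],
    id = if (nc >= 4) as.character(df[[4]]) else NULL,
    score = if (nc >= 5) as.numeric(df[[5]]) else NA_real_,
    strand = if (nc >= 6) as.character(df[[6]]) else "*",
    name = name
  )
}

#' Write a peak set as 6-column BED
#'
#' @param ps A [peak_set].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(ps, path) {
  df <- ps$peaks
  out <- data.frame(df$chrom, format_bp(df$start), format_bp(df$end), df$id,
                    ifelse(is.na(df$score), 0, df$score), df$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a gene annotation table
#'
#' Expected TSV columns: `gene_id`, `chrom`, `strand` (+/-), `tss_bp`,
#' `tx_start`, `tx_end` (0-based). The TSS must lie within the transcript
#' span and sit at the strand-appropriate transcript end.
#'
#' @param path File path.
#' @return A data.frame of class `gene_annotation`.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  gene_annotation(df)
}

#' Validate a gene annotation data.frame
#'
#' @param df data.frame with columns gene_id, chrom, strand, tss_bp,
#'   tx_start, tx_end.
#' @return `df`, sorted by (chrom, tx_start), with class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "strand", "tss_bp", "tx_start", "tx_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("gene ids must be unique")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  bad <- df$tss_bp < df$tx_start | df$tss_bp > df$tx_end
  if (any(bad)) stop("TSS outside transcript span for: ",
                     paste(utils::head(df$gene_id[bad], 5), collapse = ", "))
  df <- df[order(df$chrom, df$tx_start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Write a gene annotation table
#' @param genes A `gene_annotation` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-peak tag-count table
#'
#' TSV with a `peak_id` column plus one column per condition; library totals
#' are carried in `#library_total <condition> <count>` header lines.
#'
#' @param path File path.
#' @return list(tags = data.frame keyed by peak_id, library_total = named
#'   numeric).
#' @export
read_peak_tags <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#library_total\t", lines, value = TRUE)
  lt <- NULL
  if (length(hdr)) {
    parts <- strsplit(hdr, "\t", fixed = TRUE)
    lt <- stats::setNames(as.numeric(vapply(parts, `[`, "", 3)),
                          vapply(parts, `[`, "", 2))
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  rownames(df) <- df$peak_id
  list(tags = df[, setdiff(names(df), "peak_id"), drop = FALSE],
       library_total = lt)
}

#' Write a per-peak tag-count table
#' @param ps A [peak_set] carrying `tags` (and optionally `library_total`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_peak_tags <- function(ps, path) {
  if (is.null(ps$tags)) stop("peak set carries no tag counts")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(ps$library_total)) {
    for (cond in names(ps$library_total)) {
      writeLines(sprintf("#library_total\t%s\t%s", cond,
                         format_bp(ps$library_total[[cond]])), con)
    }
  }
  out <- cbind(peak_id = ps$peaks$id, ps$tags)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
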