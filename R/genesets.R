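# Core-gene-list construction from differential-expression contrasts and
# binding-combination expression summaries.

#' Read a differential-expression contrast table
#'
#' TSV with columns `gene`, `log2fc`, `padj`. Fold changes are oriented so
#' that positive values mean higher expression in the condition of
#' interest.
#'
#' @param path File path.
#' @param name Contrast name (defaults to file base name).
#' @return data.frame with attribute `name`.
#' @export
read_contrast <- function(path, name = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "padj")
  if (!all(need %in% names(df))) {
    stop("contrast table must have columns ", paste(need, collapse = ", "))
  }
  attr(df, "name") <- name %||% sub("\\.tsv$", "", basename(path))
  df
}

check_contrast <- function(df, nm) {
  if (anyDuplicated(df$gene)) {
    dup <- unique(df$gene[duplicated(df$gene)])
    conflicting <- vapply(dup, function(g) {
      sub <- df[df$gene == g, c("log2fc", "padj")]
      nrow(unique(sub)) > 1
    }, logical(1))
    if (any(conflicting)) {
      stop(sprintf("contrast '%s' has conflicting records for gene(s): %s",
                   nm, paste(utils::head(dup[conflicting], 5),
                             collapse = ", ")))
    }
    df <- df[!duplicated(df$gene), , drop = FALSE]
  }
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE)) {
    stop(sprintf("contrast '%s' has adjusted p outside [0, 1]", nm))
  }
  df
}

#' Intersect differential-expression contrasts into a core gene list
#'
#' A gene joins the core list iff it passes every contrast: adjusted
#' p < `params$padj_cutoff` and, with `require_direction = TRUE` (the
#' default), log2 fold change > 0 (i.e. consistently upregulated). The
#' per-contrast fold changes of every member are kept as provenance.
#'
#' @param contrasts Named list of contrast data.frames (columns `gene`,
#'   `log2fc`, `padj`).
#' @param params [analysis_params].
#' @param require_direction Require log2fc > 0 in every contrast
#'   (default TRUE); FALSE accepts any significant change.
#' @return list of class `core_gene_list`: `genes` (ids) and `provenance`
#'   (data.frame of per-contrast log2fc and padj for members).
#' @export
core_gene_intersection <- function(contrasts, params = analysis_params(),
                                   require_direction = TRUE) {
  if (!length(contrasts)) {
    return(structure(list(genes = character(),
                          provenance = data.frame(gene = character())),
                     class = "core_gene_list"))
  }
  if (is.null(names(contrasts)) || any(!nzchar(names(contrasts)))) {
    names(contrasts) <- paste0("contrast_", seq_along(contrasts))
  }
  contrasts <- Map(check_contrast, contrasts, names(contrasts))
  pass <- lapply(contrasts, function(df) {
    ok <- !is.na(df$padj) & df$padj < params$padj_cutoff
    if (require_direction) ok <- ok & df$log2fc > 0
    df$gene[ok]
  })
  core <- Reduce(intersect, pass)
  prov <- data.frame(gene = core, stringsAsFactors = FALSE)
  for (nm in names(contrasts)) {
    df <- contrasts[[nm]]
    idx <- match(core, df$gene)
    prov[[paste0("log2fc_", nm)]] <- df$log2fc[idx]
    prov[[paste0("padj_", nm)]] <- df$padj[idx]
  }
  structure(list(genes = core, provenance = prov),
            class = "core_gene_list")
}

#' @export
print.core_gene_list <- function(x, ...) {
  cat(sprintf("core_gene_list: %d genes\n", length(x$genes)))
  invisible(x)
}

#' Promoter binding matrix
#'
#' Boolean gene-by-factor table: a factor is bound at a gene iff any of its
#' peak midpoints lies within the promoter window of the gene's TSS.
#'
#' @param genes A [gene_annotation] data.frame.
#' @param factor_peaks Named list of [peak_set] objects.
#' @param params [analysis_params] (`promoter_window`).
#' @return data.frame with `gene_id` and one 0/1 column per factor.
#' @export
promoter_binding_matrix <- function(genes, factor_peaks,
                                    params = analysis_params()) {
  w <- params$promoter_window
  tss <- point_gr(genes$chrom, genes$tss_bp)
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (nm in names(factor_peaks)) {
    ps <- factor_peaks[[nm]]
    mids <- point_gr(ps$peaks$chrom, peak_midpoints(ps))
    out[[nm]] <- as.integer(overlaps_any(tss, mids, maxgap = w - 1L))
  }
  out
}

#' Expression summary per binding combination
#'
#' Groups genes by the exact combination of factors bound at their
#' promoters and summarizes the per-gene log2 fold changes of each group.
#' Combinations with no genes are omitted; the groups partition the gene
#' set.
#'
#' @param binding data.frame with `gene_id` and one 0/1 column per factor
#'   (see [promoter_binding_matrix()]).
#' @param foldchanges Named numeric of per-gene log2 fold changes.
#' @return data.frame with `combination` (factor names joined by `+`,
#'   `none` for unbound), `n`, `median`, `q1`, `q3`.
#' @export
binding_combination_expression <- function(binding, foldchanges) {
  factors <- setdiff(names(binding), "gene_id")
  if (!length(factors)) stop("binding matrix has no factor columns")
  missing <- setdiff(binding$gene_id, names(foldchanges))
  if (length(missing)) {
    stop("genes missing from foldchanges: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)",
                                          length(missing) - 5) else "")
  }
  bm <- as.matrix(binding[factors]) != 0
  combo <- apply(bm, 1, function(row) {
    if (!any(row)) "none" else paste(factors[row], collapse = "+")
  })
  fc <- foldchanges[binding$gene_id]
  out <- do.call(rbind, lapply(split(seq_along(combo), combo), function(ix) {
    qs <- stats::quantile(fc[ix], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(combination = combo[ix[1]], n = length(ix),
               median = qs[2], q1 = qs[1], q3 = qs[3],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(-out$median), , drop = FALSE]
}

#' Write a core gene list with provenance
#' @param cgl A `core_gene_list`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_core_genes <- function(cgl, path) {
  utils::write.table(cgl$provenance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
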