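# Tabular I/O. One dialect everywhere: tab-separated, UTF-8, Unix
# newlines, header row; gene columns always in panel order; floats
# written at 6 significant digits.

write_tsv <- function(df, path, sig = 6L) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, sig))
  con <- file(path, open = "wb")
  on.exit(close(con))
  ok <- try(utils::write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, eol = "\n"), silent = TRUE)
  if (inherits(ok, "try-error")) abort_data(sprintf("cannot write '%s'", path))
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("file not found: '%s'", path))
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a read-count table and its sample-to-group map
#'
#' The count table is a TSV whose first column holds sample IDs and whose
#' remaining header names are gene symbols (matched case-sensitively
#' against the panel); the group map is a two-column TSV `sample<TAB>group`.
#' All 12 marker genes and at least one normalizer candidate must be
#' present; counts must be non-negative integers.
#'
#' @param path Path to the count TSV.
#' @param group_map Path to the sample-to-group TSV.
#' @param panel A [gene_panel()].
#' @return A `gtx_counts` object: list with `counts` (samples x genes
#'   integer matrix) and `groups` (named character vector, sample -> group).
#' @export
read_count_table <- function(path, group_map, panel = gene_panel()) {
  df <- read_tsv(path)
  if (nrow(df) == 0L) abort_data(sprintf("no samples in '%s'", path))
  if (ncol(df) < 2L) abort_data(sprintf("no gene columns in '%s'", path))
  samples <- as.character(df[[1L]])
  genes <- colnames(df)[-1L]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    abort_data(sprintf(
      "non-integer or negative count at sample '%s', gene '%s'",
      samples[bad[1, 1]], genes[bad[1, 2]]
    ))
  }
  storage.mode(mat) <- "integer"
  dimnames(mat) <- list(samples, genes)

  gm <- read_tsv(group_map)
  if (ncol(gm) < 2L) abort_data("group map needs columns sample, group")
  groups <- stats::setNames(as.character(gm[[2L]]), as.character(gm[[1L]]))
  missing <- setdiff(samples, names(groups))
  if (length(missing)) {
    abort_data(sprintf("sample(s) missing from group map: %s",
                       paste(missing, collapse = ", ")))
  }
  count_matrix(mat, groups[samples], panel = panel)
}

#' Construct and validate a read-count matrix
#'
#' @param counts Samples x genes matrix of non-negative integers, with
#'   sample IDs as rownames and gene symbols as colnames.
#' @param groups Character vector of group labels, one per sample (named
#'   by sample or positional).
#' @param panel A [gene_panel()].
#' @return A `gtx_counts` object.
#' @export
count_matrix <- function(counts, groups, panel = gene_panel()) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_data("count matrix needs sample rownames and gene colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_data("counts must be non-negative integers")
  }
  if (anyDuplicated(colnames(counts))) abort_data("duplicate gene columns")
  need <- setdiff(panel$marker_genes, colnames(counts))
  if (length(need)) {
    abort_data(sprintf("marker gene(s) absent from count table: %s",
                       paste(need, collapse = ", ")))
  }
  if (!any(panel$normalizer_genes %in% colnames(counts))) {
    abort_data(sprintf("no normalizer gene (%s) in count table",
                       paste(panel$normalizer_genes, collapse = "/")))
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(counts)) {
    abort_data("one group label per sample required")
  }
  names(groups) <- rownames(counts)
  keep <- panel_order_cols(colnames(counts), panel)
  counts <- counts[, keep, drop = FALSE]
  storage.mode(counts) <- "integer"
  gtx_log("count matrix: %d samples x %d genes, %d groups",
          nrow(counts), ncol(counts), length(unique(groups)))
  structure(list(counts = counts, groups = groups), class = "gtx_counts")
}

panel_order_cols <- function(genes, panel) {
  full <- c(panel$marker_genes, panel$normalizer_genes)
  c(intersect(full, genes), setdiff(genes, full))
}

#' @export
print.gtx_counts <- function(x, ...) {
  cat(sprintf("read-count matrix: %d samples x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$groups)
  cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a read-count table (and optionally its group map)
#'
#' @param x A `gtx_counts` object.
#' @param path Output TSV path for the counts.
#' @param group_map_path Optional output path for the sample-to-group TSV.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, group_map_path = NULL) {
  stopifnot(inherits(x, "gtx_counts"))
  df <- data.frame(sample = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(group_map_path)) {
    write_tsv(data.frame(sample = names(x$groups), group = unname(x$groups),
                         stringsAsFactors = FALSE), group_map_path)
  }
  invisible(path)
}

#' Read a labeled reference ratio panel
#'
#' Expects columns `point_id`, `chemical`, `dose`, `time`, `class`
#' (GTHC / NGTHC / NGTNHC / QUERY) followed by one log2(exp/cont) ratio
#' column per marker gene.
#'
#' @param path Path to the panel TSV.
#' @param panel A [gene_panel()].
#' @return A `gtx_refpanel` data.frame.
#' @export
read_reference_panel <- function(path, panel = gene_panel()) {
  df <- read_tsv(path)
  reference_panel(df, panel = panel)
}

#' Construct and validate a reference panel from a data.frame
#'
#' @param df data.frame with the columns described in
#'   [read_reference_panel()].
#' @param panel A [gene_panel()].
#' @return A `gtx_refpanel` data.frame.
#' @export
reference_panel <- function(df, panel = gene_panel()) {
  meta <- c("point_id", "chemical", "dose", "time", "class")
  miss <- setdiff(meta, colnames(df))
  if (length(miss)) {
    abort_data(sprintf("reference panel missing column(s): %s",
                       paste(miss, collapse = ", ")))
  }
  gmiss <- setdiff(panel$marker_genes, colnames(df))
  if (length(gmiss)) {
    abort_data(sprintf("reference panel missing gene column(s): %s",
                       paste(gmiss, collapse = ", ")))
  }
  bad <- setdiff(unique(df$class), CLASS_LABELS)
  if (length(bad)) {
    abort_data(sprintf("unknown class label(s): %s (expected %s)",
                       paste(bad, collapse = ", "),
                       paste(CLASS_LABELS, collapse = "/")))
  }
  if (anyDuplicated(df$point_id)) abort_data("duplicate point_id values")
  vals <- as.matrix(df[, panel$marker_genes, drop = FALSE])
  if (!all(is.finite(vals))) abort_data("non-finite ratio values in panel")
  df <- df[, c(meta, panel$marker_genes)]
  df$point_id <- as.character(df$point_id)
  df$class <- as.character(df$class)
  class(df) <- c("gtx_refpanel", "data.frame")
  df
}

#' Write a reference panel TSV
#'
#' @param x A `gtx_refpanel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_panel <- function(x, path) {
  stopifnot(inherits(x, "gtx_refpanel"))
  write_tsv(as.data.frame(x), path)
}

#' Ratio-matrix I/O
#'
#' A ratio matrix (samples x 12 marker genes of normalizer-adjusted
#' log2(exp/cont) values) is written with `#`-prefixed header lines
#' carrying its control label, normalizer gene and group map so the
#' round-trip is lossless.
#'
#' @param x A `gtx_ratio` object (see [ratio_vs_control()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratio_matrix <- function(x, path) {
  stopifnot(inherits(x, "gtx_ratio"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("# control: %s", attr(x, "control")),
    sprintf("# normalizer: %s", attr(x, "normalizer")),
    sprintf("# groups: %s", paste(sprintf("%s=%s", rownames(x),
                                          attr(x, "groups")), collapse = ","))
  ), con)
  df <- data.frame(sample = rownames(x), signif(unclass(x), 6L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_ratio_matrix
#' @export
read_ratio_matrix <- function(path) {
  hdr <- readLines(path, n = 3L)
  field <- function(key) sub(sprintf("^# %s: ", key), "", hdr[grepl(key, hdr)][1])
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  pairs <- strsplit(strsplit(field("groups"), ",")[[1]], "=")
  groups <- stats::setNames(vapply(pairs, `[`, "", 2L),
                            vapply(pairs, `[`, "", 1L))
  structure(m, class = "gtx_ratio", control = field("control"),
            normalizer = field("normalizer"),
            groups = unname(groups[rownames(m)]))
}

#' Write a pipeline product to disk
#'
#' Dispatches on the product type: Tukey results become one TSV row per
#' (gene, comparison); a PCA result becomes a scores TSV and a loadings
#' TSV (suffixes `_scores.tsv`, `_loadings.tsv` on `path` minus its
#' extension); a score table is written as-is.
#'
#' @param x A pipeline product (`gtx_tukey`, `gtx_pca`, or a score
#'   data.frame from [score_batch()]).
#' @param path Output path (or prefix for multi-file products).
#' @param ... Unused.
#' @return Character vector of the path(s) written, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

#' @export
write_results.gtx_tukey <- function(x, path, ...) {
  write_tsv(as.data.frame(x), path)
  invisible(path)
}

#' @export
write_results.gtx_pca <- function(x, path, ...) {
  stem <- sub("\\.tsv$", "", path)
  scores <- data.frame(point_id = rownames(x$scores),
                       class = x$labels,
                       x$scores[, 1:2, drop = FALSE],
                       check.names = FALSE, stringsAsFactors = FALSE)
  loadings <- data.frame(gene = rownames(x$loadings),
                         x$loadings[, 1:2, drop = FALSE],
                         mu = x$mu, sigma = x$sigma,
                         check.names = FALSE, stringsAsFactors = FALSE)
  p1 <- write_tsv(scores, paste0(stem, "_scores.tsv"))
  p2 <- write_tsv(loadings, paste0(stem, "_loadings.tsv"))
  invisible(c(p1, p2))
}

#' @export
write_results.data.frame <- function(x, path, ...) {
  write_tsv(x, path)
  invisible(path)
}

#' Fixed-score constants file I/O
#'
#' Plain-text format, one line per gene `symbol<TAB>a<TAB>mu<TAB>sigma`,
#' then `border<TAB>value` and `provenance<TAB>label`.
#'
#' @param x A `gtx_constants` object (see [default_constants()]).
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, a
#'   `gtx_constants` object.
#' @export
write_constants <- function(x, path) {
  stopifnot(inherits(x, "gtx_constants"))
  lines <- c(
    sprintf("%s\t%.15g\t%.15g\t%.15g", x$gene, x$a, x$mu, x$sigma),
    sprintf("border\t%.15g", attr(x, "border")),
    sprintf("provenance\t%s", attr(x, "provenance"))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_constants
#' @export
read_constants <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[`, "", 1L)
  border <- as.numeric(parts[[which(keys == "border")]][2])
  prov <- parts[[which(keys == "provenance")]][2]
  rows <- parts[!(keys %in% c("border", "provenance"))]
  df <- data.frame(
    gene = vapply(rows, `[`, "", 1L),
    a = as.numeric(vapply(rows, `[`, "", 2L)),
    mu = as.numeric(vapply(rows, `[`, "", 3L)),
    sigma = as.numeric(vapply(rows, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  fixed_constants(df, border = border, provenance = prov)
}
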