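# Reference-gene normalization: raw counts -> log2 -> per-sample
# subtraction of the normalizer gene -> centering on the control-group
# mean, yielding the log2(exp/cont) ratio matrix used everywhere
# downstream. Because every step after the log is a subtraction, the
# whole pipeline is exactly invariant to per-sample depth scaling.

#' Log2-transform a count matrix
#'
#' @param counts A `gtx_counts` object.
#' @param pseudocount Non-negative value added to every count before the
#'   log; with `pseudocount = 0` all counts must be positive. Default 1.
#' @return A `gtx_log2` object: samples x genes numeric matrix with
#'   `groups` and `pseudocount` attributes.
#' @export
log2_transform <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "gtx_counts"))
  if (pseudocount < 0) abort_data("pseudocount must be >= 0")
  if (pseudocount == 0 && any(counts$counts == 0)) {
    idx <- which(counts$counts == 0, arr.ind = TRUE)[1L, ]
    abort_data(sprintf(
      "zero count at sample '%s', gene '%s'; set pseudocount > 0",
      rownames(counts$counts)[idx[1]], colnames(counts$counts)[idx[2]]
    ))
  }
  m <- log2(counts$counts + pseudocount)
  structure(m, class = "gtx_log2", groups = counts$groups,
            pseudocount = pseudocount)
}

#' Normalize log2 counts by a reference gene
#'
#' Subtracts the normalizer gene's log2 count from every gene within the
#' same sample (equivalently, divides raw counts by the normalizer
#' count), then drops the normalizer column. This cancels per-sample
#' sequencing-depth factors exactly.
#'
#' @param m A `gtx_log2` matrix.
#' @param normalizer Gene symbol, default `"Dazap2"`.
#' @return A `gtx_log2` matrix without the normalizer column and with a
#'   `normalizer` attribute.
#' @export
normalize_by_gene <- function(m, normalizer = "Dazap2") {
  stopifnot(inherits(m, "gtx_log2"))
  if (!normalizer %in% colnames(m)) {
    abort_data(sprintf("normalizer gene '%s' not in matrix", normalizer))
  }
  res <- unclass(m) - unclass(m)[, normalizer]
  res <- res[, setdiff(colnames(m), normalizer), drop = FALSE]
  structure(res, class = "gtx_log2", groups = attr(m, "groups"),
            pseudocount = attr(m, "pseudocount"), normalizer = normalizer)
}

#' Express log2 values as ratios against the control-group mean
#'
#' Per gene, subtracts the arithmetic mean of the control samples' log2
#' values (the geometric mean of their counts), so the control group
#' averages exactly 0 and every other value is a log2(exp/cont) ratio.
#' The result is restricted to the 12 marker genes.
#'
#' @param m A `gtx_log2` matrix (normally normalizer-adjusted).
#' @param control_label Group label of the control group (>= 2 samples).
#' @param panel A [gene_panel()].
#' @return A `gtx_ratio` object: samples x 12 matrix with `groups`,
#'   `control` and `normalizer` attributes.
#' @export
ratio_vs_control <- function(m, control_label = "cont", panel = gene_panel()) {
  stopifnot(inherits(m, "gtx_log2"))
  groups <- attr(m, "groups")
  ctrl <- which(groups == control_label)
  if (length(ctrl) == 0L) {
    abort_data(sprintf("control group '%s' absent", control_label))
  }
  if (length(ctrl) < 2L) {
    abort_data(sprintf("control group '%s' has < 2 samples", control_label))
  }
  miss <- setdiff(panel$marker_genes, colnames(m))
  if (length(miss)) {
    abort_data(sprintf("marker gene(s) absent: %s", paste(miss, collapse = ", ")))
  }
  x <- unclass(m)[, panel$marker_genes, drop = FALSE]
  ctrl_mean <- colMeans(x[ctrl, , drop = FALSE])
  res <- sweep(x, 2L, ctrl_mean)
  structure(res, class = "gtx_ratio", groups = groups,
            control = control_label,
            normalizer = attr(m, "normalizer") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group-mean log2 ratio profile
#'
#' Condenses a ratio matrix to a single 12-gene profile by averaging the
#' samples of one group (the chi vector of the fixed Y1 score).
#'
#' @param r A `gtx_ratio` matrix.
#' @param group Group label to average over.
#' @return Named numeric vector of 12 log2(exp/cont) values with a
#'   `label` attribute.
#' @export
condition_profile <- function(r, group) {
  stopifnot(inherits(r, "gtx_ratio"))
  idx <- which(attr(r, "groups") == group)
  if (length(idx) == 0L) abort_data(sprintf("unknown group '%s'", group))
  prof <- colMeans(unclass(r)[idx, , drop = FALSE])
  attr(prof, "label") <- group
  prof
}

#' Rank normalizer candidates by cross-group stability
#'
#' Stability score = standard deviation, across groups, of the per-group
#' mean log2 count (lower = more stable); ties broken in favor of the
#' higher-expressed gene, since a normalizer should also be abundant.
#'
#' @param m A `gtx_log2` matrix (raw log2 counts, all genes).
#' @return data.frame `gene`, `stability`, `mean_log2`, ranked ascending
#'   by stability.
#' @export
rank_normalizer_candidates <- function(m) {
  stopifnot(inherits(m, "gtx_log2"))
  groups <- attr(m, "groups")
  if (length(unique(groups)) < 2L) abort_data("need >= 2 groups")
  x <- unclass(m)
  rs <- rowsum(x, groups)  # ordered by sorted group label
  gm <- rs / as.vector(table(groups)[rownames(rs)])
  stability <- apply(gm, 2L, stats::sd)
  overall <- colMeans(x)
  ord <- order(stability, -overall)
  data.frame(gene = colnames(x)[ord], stability = unname(stability[ord]),
             mean_log2 = unname(overall[ord]), stringsAsFactors = FALSE)
}
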