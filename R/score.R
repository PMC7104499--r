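# The portable fixed-coefficient score: an approximate PC1 (Y1) computed
# as Y1 = sum_g a_g (chi_g - mu_g)/sigma_g over the 12 marker genes,
# with published constants derived from the reference chemical panel.
# Y1 below the border indicates a GTHC-like expression profile.

#' Construct a fixed-score constants object
#'
#' @param df data.frame with columns `gene`, `a` (PC1 eigenvector
#'   coefficient), `mu`, `sigma` (reference mean and SD of the
#'   log2(exp/cont) ratio); exactly one row per marker gene.
#' @param border PC1 decision threshold.
#' @param provenance Label recording where the constants came from.
#' @return A `gtx_constants` data.frame with `border` and `provenance`
#'   attributes.
#' @export
fixed_constants <- function(df, border, provenance = "custom") {
  need <- c("gene", "a", "mu", "sigma")
  if (!all(need %in% colnames(df))) {
    abort_data("constants need columns gene, a, mu, sigma")
  }
  miss <- setdiff(marker_genes(), df$gene)
  if (length(miss)) {
    abort_data(sprintf("constants missing gene(s): %s",
                       paste(miss, collapse = ", ")))
  }
  df <- df[match(marker_genes(), df$gene), need]
  rownames(df) <- NULL
  if (any(df$sigma <= 0)) abort_data("sigma must be > 0")
  ss <- sum(df$a^2)
  if (abs(ss - 1) > 0.02) {
    abort_data(sprintf("loading vector not unit norm: sum a^2 = %.4f", ss))
  }
  structure(df, class = c("gtx_constants", "data.frame"),
            border = border, provenance = provenance)
}

#' The published fixed-score constants
#'
#' Returns the 12 printed (a, mu, sigma) triples of the Y1 equation,
#' verbatim at their published 3-significant-figure precision, and the
#' published decision border -0.710. These were derived from a PCA of
#' the 124-point reference chemical panel (24-h and 29-day rat liver
#' data); they are never re-derived silently, and their provenance label
#' (`"published-2020"`) distinguishes them from constants fitted to a
#' panel with [extract_fixed_constants()].
#'
#' @return A `gtx_constants` object.
#' @examples
#' cc <- default_constants()
#' sum(cc$a)    # -2.685
#' attr(cc, "border")
#' @export
default_constants <- function() {
  df <- data.frame(
    gene = c("Aen", "Bax", "Btg2", "Ccnf", "Ccng1", "Cdkn1a", "Gdf15",
             "Lrp1", "Mbd1", "Phlda3", "Plk2", "Tubb4b"),
    a = c(-0.327, -0.336, -0.324, 0.076, -0.344, -0.312, -0.312,
          0.263, -0.207, -0.306, -0.313, -0.243),
    mu = c(0.316, 0.320, 0.264, -0.0767, 0.563, 0.405, 0.354,
           -0.094, 0.0309, 0.211, 0.172, 0.276),
    sigma = c(0.952, 0.790, 0.945, 0.413, 1.16, 1.35, 1.10,
              0.338, 0.344, 1.12, 0.602, 0.431),
    stringsAsFactors = FALSE
  )
  fixed_constants(df, border = -0.710, provenance = "published-2020")
}

#' @export
print.gtx_constants <- function(x, ...) {
  cat(sprintf("fixed Y1 score constants [%s], border %.4g\n",
              attr(x, "provenance"), attr(x, "border")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Approximate PC1 (Y1) score of a 12-gene ratio profile
#'
#' `Y1 = sum_g a_g (chi_g - mu_g) / sigma_g`, accumulated in panel gene
#' order in double precision. `chi_g` is the normalizer-adjusted
#' log2(exp/cont) ratio of gene g (see [condition_profile()]).
#'
#' @param profile Named numeric vector covering all 12 marker genes.
#' @param constants A `gtx_constants` object; default the published one.
#' @return The Y1 score (scalar).
#' @examples
#' cc <- default_constants()
#' approximate_pc1(setNames(cc$mu, cc$gene), cc)  # 0 by construction
#' @export
approximate_pc1 <- function(profile, constants = default_constants()) {
  stopifnot(inherits(constants, "gtx_constants"))
  miss <- setdiff(constants$gene, names(profile))
  if (length(miss)) {
    abort_data(sprintf("profile missing gene(s): %s",
                       paste(miss, collapse = ", ")))
  }
  chi <- as.numeric(profile[constants$gene])
  if (!all(is.finite(chi))) {
    abort_data(sprintf("non-finite ratio for gene(s): %s",
                       paste(constants$gene[!is.finite(chi)], collapse = ", ")))
  }
  sum(constants$a * (chi - constants$mu) / constants$sigma)
}

#' Classify a Y1 score against the decision border
#'
#' Scores strictly below the border are called `"GTHC-like"`; scores at
#' or above it `"non-GTHC-like"` (a tie is the conservative, non-call).
#'
#' @param y1 Numeric Y1 score(s).
#' @param constants A `gtx_constants` carrying the border.
#' @return Character vector of labels.
#' @export
classify_fixed <- function(y1, constants = default_constants()) {
  if (any(!is.finite(y1))) abort_data("non-finite Y1 score")
  border <- attr(constants, "border")
  ifelse(y1 < border, "GTHC-like", "non-GTHC-like")
}

#' Score a batch of profiles
#'
#' @param profiles A matrix/data.frame with one profile per row (gene
#'   columns), or a named list of profile vectors, or a `gtx_ratio`
#'   matrix (per-sample scoring).
#' @param constants A `gtx_constants` object.
#' @return data.frame `id`, `Y1`, `label`, one row per profile in input
#'   order.
#' @export
score_batch <- function(profiles, constants = default_constants()) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    mat <- do.call(rbind, profiles)
    rownames(mat) <- names(profiles) %||% sprintf("p%d", seq_along(profiles))
  } else {
    mat <- as.matrix(profiles)
  }
  if (nrow(mat) == 0L) {
    return(data.frame(id = character(0), Y1 = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("p%d", seq_len(nrow(mat)))
  y1 <- vapply(seq_len(nrow(mat)), function(i) {
    tryCatch(approximate_pc1(mat[i, ], constants), gtx_error = function(e) {
      abort_data(sprintf("profile '%s': %s", rownames(mat)[i],
                         conditionMessage(e)))
    })
  }, numeric(1))
  data.frame(id = rownames(mat), Y1 = y1,
             label = classify_fixed(y1, constants),
             stringsAsFactors = FALSE, row.names = NULL)
}
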