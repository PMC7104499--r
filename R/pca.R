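# Combined-panel PCA: queries are pooled with the labeled reference
# points, the matrix is standardized gene-wise (correlation-matrix PCA,
# forced by the (chi - mu)/sigma canonicalization of the fixed score),
# and PC1 is oriented so GTHC points score negative. The PC1 border is
# the midpoint between the flanking class extremes.

#' Standardize a ratio matrix gene-wise
#'
#' @param x Points x genes numeric matrix (>= 3 rows).
#' @return List with `z` (standardized matrix), `mu`, `sigma` (named
#'   per-gene column mean and sample SD, n-1 denominator).
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) abort_data("need >= 3 rows to standardize")
  mu <- colMeans(x)
  sigma <- apply(x, 2L, stats::sd)
  zero <- sigma <= 0 | !is.finite(sigma)
  if (any(zero)) {
    abort_numeric(sprintf("zero variance in gene(s): %s",
                          paste(colnames(x)[zero], collapse = ", ")))
  }
  z <- sweep(sweep(x, 2L, mu), 2L, sigma, `/`)
  list(z = z, mu = mu, sigma = sigma)
}

#' Fit a combined-panel PCA
#'
#' Principal components from the singular value decomposition of the
#' standardized matrix. After the fit, PC1 is sign-flipped if needed so
#' the mean PC1 of GTHC-labeled rows lies below the mean of
#' NGTHC/NGTNHC rows (genotoxic profiles score negative); PC2 is flipped
#' so its largest-magnitude loading is positive. QUERY rows take part in
#' the fit but not in orientation.
#'
#' @param x Points x genes ratio matrix (or a `gtx_refpanel`).
#' @param labels Class labels per row (`GTHC`/`NGTHC`/`NGTNHC`/`QUERY`);
#'   taken from the panel if `x` is a `gtx_refpanel`.
#' @return A `gtx_pca` object: list with `loadings` (genes x PCs, unit
#'   columns), `scores` (points x PCs), `explained` (variance
#'   fractions), `mu`, `sigma`, `labels`, `flipped` (logical per PC).
#' @export
fit_pca <- function(x, labels = NULL) {
  if (inherits(x, "gtx_refpanel")) {
    labels <- labels %||% x$class
    ids <- x$point_id
    x <- as.matrix(x[, marker_genes()])
    rownames(x) <- ids
  }
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("row%d", seq_len(nrow(x)))
  std <- standardize(x)
  sv <- svd(std$z)
  loadings <- sv$v
  scores <- std$z %*% loadings
  eig <- sv$d^2 / (nrow(x) - 1L)
  explained <- eig / sum(eig)
  npc <- ncol(loadings)
  dimnames(loadings) <- list(colnames(x), sprintf("PC%d", seq_len(npc)))
  dimnames(scores) <- list(rownames(x), sprintf("PC%d", seq_len(npc)))

  flipped <- stats::setNames(rep(FALSE, npc), colnames(loadings))
  if (!is.null(labels)) {
    is_g <- labels == "GTHC"
    is_n <- labels %in% c("NGTHC", "NGTNHC")
    if (any(is_g) && any(is_n)) {
      if (mean(scores[is_g, 1L]) > mean(scores[is_n, 1L])) {
        loadings[, 1L] <- -loadings[, 1L]
        scores[, 1L] <- -scores[, 1L]
        flipped[1L] <- TRUE
      }
    } else {
      warning("orientation skipped: need labeled GTHC and non-GTHC rows")
    }
  } else {
    warning("orientation skipped: no labels")
  }
  if (npc >= 2L) {
    top <- which.max(abs(loadings[, 2L]))
    if (loadings[top, 2L] < 0) {
      loadings[, 2L] <- -loadings[, 2L]
      scores[, 2L] <- -scores[, 2L]
      flipped[2L] <- TRUE
    }
  }
  structure(
    list(loadings = loadings, scores = scores, explained = explained,
         mu = std$mu, sigma = std$sigma,
         labels = labels %||% rep(NA_character_, nrow(x)),
         flipped = flipped),
    class = "gtx_pca"
  )
}

#' @export
print.gtx_pca <- function(x, ...) {
  cat(sprintf("PCA fit: %d points x %d genes\n", nrow(x$scores),
              nrow(x$loadings)))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' Project new profiles onto an existing PCA fit
#'
#' Standardizes `newdata` with the fit's own mu/sigma and applies its
#' loadings without refitting ("project-only" mode).
#'
#' @param fit A `gtx_pca`.
#' @param newdata Points x genes matrix covering the fitted genes.
#' @return Scores matrix (points x PCs).
#' @export
project_onto <- function(fit, newdata) {
  stopifnot(inherits(fit, "gtx_pca"))
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) colnames(newdata) <- names(fit$mu)
  miss <- setdiff(names(fit$mu), colnames(newdata))
  if (length(miss)) {
    abort_data(sprintf("missing gene(s): %s", paste(miss, collapse = ", ")))
  }
  z <- sweep(sweep(newdata[, names(fit$mu), drop = FALSE], 2L, fit$mu),
             2L, fit$sigma, `/`)
  z %*% fit$loadings
}

#' PC1 decision border between GTHC and non-GTHC reference points
#'
#' The border is the midpoint between the largest PC1 score among
#' GTHC-labeled points and the smallest among NGTHC/NGTNHC points. If
#' the classes overlap on PC1 the border is still reported but flagged
#' non-separable.
#'
#' @param fit An oriented `gtx_pca` with both classes present.
#' @return A `gtx_border` list: `border`, `gthc_max` / `nongthc_min`
#'   (named scores of the flanking points), `separable`.
#' @export
pc1_border <- function(fit) {
  stopifnot(inherits(fit, "gtx_pca"))
  is_g <- fit$labels == "GTHC"
  is_n <- fit$labels %in% c("NGTHC", "NGTNHC")
  if (!any(is_g) || !any(is_n)) {
    abort_data("both GTHC and non-GTHC labeled points required")
  }
  pc1 <- fit$scores[, 1L]
  hi_g <- which.max(ifelse(is_g, pc1, -Inf))
  lo_n <- which.min(ifelse(is_n, pc1, Inf))
  structure(
    list(border = unname((pc1[hi_g] + pc1[lo_n]) / 2),
         gthc_max = pc1[hi_g], nongthc_min = pc1[lo_n],
         separable = pc1[hi_g] < pc1[lo_n]),
    class = "gtx_border"
  )
}

#' @export
print.gtx_border <- function(x, ...) {
  cat(sprintf("PC1 border: %.4g (%s)\n", x$border,
              if (x$separable) "classes separated" else "classes OVERLAP"))
  cat(sprintf("  flanking: GTHC max %.4g (%s), non-GTHC min %.4g (%s)\n",
              x$gthc_max, names(x$gthc_max), x$nongthc_min,
              names(x$nongthc_min)))
  invisible(x)
}

#' Classify query points by their PC1 score
#'
#' PC1 below the border is called "GTHC-like"; at or above it (including
#' exactly on it) "non-GTHC-like".
#'
#' @param fit A `gtx_pca` containing the queries.
#' @param border Numeric border (e.g. `pc1_border(fit)$border`).
#' @param query_ids Point IDs to classify (default: rows labeled QUERY).
#' @return Named character vector of labels.
#' @export
classify_by_pca <- function(fit, border, query_ids = NULL) {
  stopifnot(inherits(fit, "gtx_pca"))
  if (inherits(border, "gtx_border")) border <- border$border
  query_ids <- query_ids %||% rownames(fit$scores)[fit$labels == "QUERY"]
  unknown <- setdiff(query_ids, rownames(fit$scores))
  if (length(unknown)) {
    abort_data(sprintf("unknown query ID(s): %s",
                       paste(unknown, collapse = ", ")))
  }
  pc1 <- fit$scores[query_ids, 1L]
  stats::setNames(ifelse(pc1 < border, "GTHC-like", "non-GTHC-like"),
                  query_ids)
}

#' Extract portable fixed-score constants from a PCA fit
#'
#' Bundles each gene's PC1 loading with the fit's standardization mu and
#' sigma, plus the PC1 border, so new profiles can be scored with
#' [approximate_pc1()] without refitting. By construction the resulting
#' Y1 of any fitted row equals its PCA PC1 score exactly.
#'
#' @param fit An oriented `gtx_pca`.
#' @param border Optional border; defaults to `pc1_border(fit)$border`
#'   when both classes are present, otherwise `NA`.
#' @return A `gtx_constants` object (see [fixed_constants()]).
#' @export
extract_fixed_constants <- function(fit, border = NULL) {
  stopifnot(inherits(fit, "gtx_pca"))
  if (is.null(border)) {
    border <- tryCatch(pc1_border(fit)$border, gtx_error = function(e) NA_real_)
  }
  df <- data.frame(gene = rownames(fit$loadings), a = fit$loadings[, 1L],
                   mu = fit$mu, sigma = fit$sigma, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  fixed_constants(df, border = border, provenance = "panel-fit")
}
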