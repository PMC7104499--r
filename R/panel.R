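#' The 12-gene marker panel and its normalizer candidates
#'
#' The panel comprises twelve rat marker genes, nine of which (Aen, Bax,
#' Btg2, Ccng1, Cdkn1a, Gdf15, Mbd1, Phlda3, Plk2) belong to the intrinsic
#' apoptotic signaling pathway activated by p53 in response to DNA damage;
#' Ccnf, Lrp1 and Tubb4b are cancer-associated. Dazap2 and Ube2d3 are the
#' stably expressed normalizer candidates measured alongside them, Dazap2
#' being the default normalizer. Gene order is fixed and used for every
#' table the package emits.
#'
#' @param normalizer_genes Character vector of normalizer candidate gene
#'   symbols, most-preferred first.
#' @return An object of class `gtx_panel`: a list with `marker_genes`
#'   (ordered character vector of 12 symbols), `normalizer_genes`, and
#'   `gene_ids` (named integer vector, NCBI Gene IDs).
#' @examples
#' p <- gene_panel()
#' p$marker_genes
#' @export
gene_panel <- function(normalizer_genes = c("Dazap2", "Ube2d3")) {
  gene_ids <- c(
    Aen = 361594L, Bax = 24887L, Btg2 = 29619L, Ccnf = 117524L,
    Ccng1 = 25405L, Cdkn1a = 114851L, Gdf15 = 29455L, Lrp1 = 299858L,
    Mbd1 = 291439L, Phlda3 = 363989L, Plk2 = 83722L, Tubb4b = 296554L,
    Dazap2 = 300235L, Ube2d3 = 81920L
  )
  marker <- names(gene_ids)[1:12]
  if (!all(normalizer_genes %in% names(gene_ids))) {
    abort_data(sprintf(
      "unknown normalizer gene(s): %s",
      paste(setdiff(normalizer_genes, names(gene_ids)), collapse = ", ")
    ))
  }
  structure(
    list(
      marker_genes = marker,
      normalizer_genes = normalizer_genes,
      gene_ids = gene_ids
    ),
    class = "gtx_panel"
  )
}

#' @export
print.gtx_panel <- function(x, ...) {
  cat("12-gene GTHC marker panel\n")
  cat("  markers:    ", paste(x$marker_genes, collapse = ", "), "\n")
  cat("  normalizers:", paste(x$normalizer_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Marker gene symbols in panel order
#'
#' @return Character vector of the 12 marker gene symbols.
#' @export
marker_genes <- function() gene_panel()$marker_genes

# Order genes by panel position; genes outside the panel keep their
# incoming relative order, after the panel genes.
panel_order <- function(genes) {
  ord <- match(genes, marker_genes())
  ord[is.na(ord)] <- length(marker_genes()) + seq_len(sum(is.na(ord)))
  genes[order(ord)]
}

CLASS_LABELS <- c("GTHC", "NGTHC", "NGTNHC", "QUERY")
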