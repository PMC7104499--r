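# End-to-end pipeline: normalize -> group stats -> (combined PCA when a
# reference panel is given) -> fixed Y1 score, with every stage output
# and a run manifest written under one output directory.

# Minimal "key: value" config reader (one pair per line, '#' comments).
read_config <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("config not found: '%s'", path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) {
    abort_usage(sprintf("bad config line: '%s'", lines[bad][1]))
  }
  stats::setNames(
    lapply(kv, function(m) trimws(m[3])),
    vapply(kv, function(m) trimws(m[2]), "")
  )
}

#' Run the full pipeline
#'
#' Executes normalization, per-gene Tukey HSD, combined-panel PCA (only
#' if a reference panel is configured; otherwise skipped with a warning)
#' and fixed Y1 scoring, writing each stage's tables plus a JSON run
#' manifest to `outdir`.
#'
#' @param config Path to a `key: value` config file, or an equivalent
#'   named list. Recognized keys: `counts`, `groups` (paths, required),
#'   `control` (default `cont`), `normalizer` (default `Dazap2`),
#'   `pseudocount` (default 1), `panel` (optional reference-panel path),
#'   `outdir` (default `.`), `seed` (default 1).
#' @return Invisibly, a list with the stage products and the manifest.
#' @export
run_all <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  need <- c("counts", "groups")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    abort_usage(sprintf("config missing key(s): %s",
                        paste(miss, collapse = ", ")))
  }
  control <- cfg$control %||% "cont"
  normalizer <- cfg$normalizer %||% "Dazap2"
  pseudocount <- as.numeric(cfg$pseudocount %||% 1)
  outdir <- cfg$outdir %||% "."
  seed <- as.integer(cfg$seed %||% 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  gtx_log("run_all: counts=%s control=%s normalizer=%s", cfg$counts,
          control, normalizer)
  counts <- read_count_table(cfg$counts, cfg$groups)
  ratio <- ratio_vs_control(
    normalize_by_gene(log2_transform(counts, pseudocount), normalizer),
    control
  )
  write_ratio_matrix(ratio, file.path(outdir, "ratio.tsv"))

  tk <- tukey_hsd(ratio)
  write_results(tk, file.path(outdir, "tukey.tsv"))

  pca <- NULL
  border <- NULL
  treated <- setdiff(unique(attr(ratio, "groups")), control)
  profiles <- do.call(rbind, lapply(treated, function(g) {
    condition_profile(ratio, g)
  }))
  rownames(profiles) <- treated

  if (!is.null(cfg$panel)) {
    ref <- read_reference_panel(cfg$panel)
    combined <- rbind(as.matrix(ref[, marker_genes()]), profiles)
    rownames(combined) <- c(ref$point_id, treated)
    labels <- c(ref$class, rep("QUERY", length(treated)))
    pca <- fit_pca(combined, labels)
    border <- pc1_border(pca)
    write_results(pca, file.path(outdir, "pca.tsv"))
    bdf <- data.frame(border = border$border, separable = border$separable,
                      gthc_max = unname(border$gthc_max),
                      nongthc_min = unname(border$nongthc_min))
    write_tsv(bdf, file.path(outdir, "pca_border.tsv"))
  } else {
    warning("no reference panel configured; PCA stage skipped")
  }

  scores <- score_batch(profiles)
  write_results(scores, file.path(outdir, "scores.tsv"))

  manifest <- list(
    subcommand = "all",
    parameters = list(control = control, normalizer = normalizer,
                      pseudocount = pseudocount),
    inputs = list(counts = cfg$counts, groups = cfg$groups,
                  panel = cfg$panel %||% NA),
    outdir = outdir, seed = seed,
    version = as.character(utils::packageVersion("gtxpanel")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(counts = counts, ratio = ratio, tukey = tk, pca = pca,
                 border = border, scores = scores, manifest = manifest))
}
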