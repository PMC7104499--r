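# Synthetic data generators: negative binomial count tables shaped like
# a targeted liver RNA-Seq run (15 samples, 12 markers + 2 normalizer
# candidates), and labeled reference ratio panels with GTHC / NGTHC /
# NGTNHC class structure separable along PC1.
#
# All magnitudes here are the package's own synthetic choices, fixed once:
# the real study reports only bar directions and significance, not effect
# sizes or dispersions.

#' Preset per-group effect profiles
#'
#' Three presets are provided. `gthc_like` mimics a strong genotoxic
#' hepatocarcinogen response: up-regulation of exactly the eight marker
#' genes that respond to a typical GTHC exposure (Aen, Bax, Btg2, Ccng1,
#' Gdf15, Mbd1, Phlda3, Tubb4b). `ngthc_like` mimics a non-genotoxic
#' hepatocarcinogen: Gdf15 is the only changed gene. `null` is no effect.
#' Magnitudes (log2 fold-changes, range 1.2-3.0) are synthetic defaults
#' and freely overridable via [effect_profile()].
#'
#' @return Named list of `gtx_profile` effect profiles.
#' @export
preset_profiles <- function() {
  zero <- stats::setNames(numeric(12L), marker_genes())
  gthc <- zero
  gthc[c("Aen", "Bax", "Btg2", "Ccng1", "Gdf15", "Mbd1", "Phlda3",
         "Tubb4b")] <- c(2.5, 2.0, 2.5, 2.0, 3.0, 1.2, 2.8, 1.2)
  ngthc <- zero
  ngthc["Gdf15"] <- 1.0
  list(
    gthc_like = effect_profile("gthc_like", gthc),
    ngthc_like = effect_profile("ngthc_like", ngthc),
    null = effect_profile("null", zero)
  )
}

#' Construct an effect profile
#'
#' @param name Profile label.
#' @param lfc Named numeric vector of log2 fold-changes vs control; must
#'   cover all 12 marker genes (zero allowed). Normalizer genes default to
#'   0 unless explicitly included.
#' @return A `gtx_profile`: named numeric vector with a `name` attribute.
#' @export
effect_profile <- function(name, lfc) {
  miss <- setdiff(marker_genes(), names(lfc))
  if (length(miss)) {
    abort_data(sprintf("effect profile '%s' missing gene(s): %s", name,
                       paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(lfc))) abort_data("non-finite log2 fold-change")
  structure(lfc, name = name, class = "gtx_profile")
}

default_baseline_means <- function(panel = gene_panel()) {
  # Normalizer Dazap2 high (order 5e4 reads/sample, mirroring its ~10%
  # share of control reads), markers 1e2-1e4, Gdf15 deliberately lowest.
  c(Aen = 800, Bax = 2000, Btg2 = 600, Ccnf = 400, Ccng1 = 3000,
    Cdkn1a = 1500, Gdf15 = 150, Lrp1 = 1200, Mbd1 = 900, Phlda3 = 300,
    Plk2 = 500, Tubb4b = 4000, Dazap2 = 50000, Ube2d3 = 8000)
}

#' Simulation configuration for read-count tables
#'
#' Counts for sample s and gene g are drawn
#' `NB(mean = L_s * baseline_mean[g] * 2^lfc[g], size = dispersion[g])`
#' with `L_s ~ LogNormal(0, library_size_sd)`, i.e. variance
#' `m + m^2/k` in the (mean, size) parameterization (Poisson is the
#' `k -> Inf` limit).
#'
#' @param n_per_group Animals per group (>= 2).
#' @param profiles Named list mapping group label to a `gtx_profile` (or a
#'   preset name). Default: the study layout `cont`/`AAF`-like/`CRE`-like.
#' @param baseline_mean Named vector of expected control counts per gene.
#' @param dispersion NB size parameter k, scalar or named per gene;
#'   default 50 (biological CV ~0.14, typical for inbred rats under
#'   controlled feeding).
#' @param library_size_sd Log-normal sigma of the per-sample depth factor.
#' @param seed Integer seed for reproducibility.
#' @return A `gtx_sim_config` list.
#' @export
sim_config <- function(n_per_group = 5L,
                       profiles = list(cont = "null", GTX = "gthc_like",
                                       NGT = "ngthc_like"),
                       baseline_mean = default_baseline_means(),
                       dispersion = 50,
                       library_size_sd = 0.2,
                       seed = 1L) {
  if (n_per_group < 2L) abort_data("n_per_group must be >= 2")
  if (any(baseline_mean <= 0)) abort_data("baseline_mean must be > 0")
  if (any(dispersion <= 0)) abort_data("dispersion must be > 0")
  if (library_size_sd < 0) abort_data("library_size_sd must be >= 0")
  presets <- preset_profiles()
  profiles <- lapply(profiles, function(p) {
    if (is.character(p)) {
      if (!p %in% names(presets)) {
        abort_data(sprintf("unknown preset profile '%s'", p))
      }
      presets[[p]]
    } else p
  })
  genes <- names(baseline_mean)
  k <- if (length(dispersion) == 1L) {
    stats::setNames(rep(dispersion, length(genes)), genes)
  } else dispersion[genes]
  structure(
    list(n_per_group = as.integer(n_per_group), profiles = profiles,
         baseline_mean = baseline_mean, dispersion = k,
         library_size_sd = library_size_sd, seed = as.integer(seed)),
    class = "gtx_sim_config"
  )
}

#' Simulate a targeted RNA-Seq read-count table
#'
#' @param cfg A [sim_config()].
#' @param panel A [gene_panel()].
#' @return A `gtx_counts` object with an attached `truth` attribute (the
#'   per-group true log2 fold-change matrix).
#' @export
simulate_counts <- function(cfg, panel = gene_panel()) {
  stopifnot(inherits(cfg, "gtx_sim_config"))
  genes <- names(cfg$baseline_mean)
  groups_def <- names(cfg$profiles)
  n <- cfg$n_per_group
  with_seed(cfg$seed, {
    rows <- list()
    groups <- character(0)
    for (grp in groups_def) {
      lfc <- stats::setNames(numeric(length(genes)), genes)
      p <- cfg$profiles[[grp]]
      lfc[names(p)[names(p) %in% genes]] <- p[names(p) %in% genes]
      mu_g <- cfg$baseline_mean * 2^lfc
      for (i in seq_len(n)) {
        L <- if (cfg$library_size_sd > 0) {
          stats::rlnorm(1L, meanlog = 0, sdlog = cfg$library_size_sd)
        } else 1
        rows[[sprintf("%s-%d", grp, i)]] <-
          stats::rnbinom(length(genes), mu = L * mu_g, size = cfg$dispersion)
        groups <- c(groups, grp)
      }
    }
    counts <- do.call(rbind, rows)
    colnames(counts) <- genes
    truth <- do.call(rbind, lapply(cfg$profiles, function(p) {
      v <- stats::setNames(numeric(12L), marker_genes())
      v[names(p)[names(p) %in% names(v)]] <- p[names(p) %in% names(v)]
      v
    }))
    gtx_log("simulated %d x %d counts, seed %d", nrow(counts), ncol(counts),
            cfg$seed)
    out <- count_matrix(counts, groups, panel = panel)
    attr(out, "truth") <- truth
    out
  })
}

default_class_means <- function() {
  g <- marker_genes()
  m <- rbind(
    GTHC = c(2.2, 1.8, 2.0, 0.1, 2.3, 1.8, 2.0, -0.6, 0.8, 2.2, 1.6, 0.9),
    NGTHC = c(0, 0.1, 0, 0.15, 0.1, 0.2, 0.4, 0.2, 0, 0.1, 0, 0.1),
    NGTNHC = rep(0, 12L)
  )
  colnames(m) <- g
  m
}

#' Configuration for reference-panel simulation
#'
#' Each class's 12-gene ratio vectors are drawn from a multivariate
#' normal. Default class means put the GTHC centroid far below the fixed
#' Y1 decision border and the NGTHC/NGTNHC centroids above it; default
#' spread is an independent SD of 0.5 per gene (chemical-to-chemical and
#' dose-to-dose variability).
#'
#' @param n_per_class Points per class *per timepoint*, named or in order
#'   GTHC, NGTHC, NGTNHC.
#' @param timepoints Character vector of timepoint labels; the class
#'   layout is replicated across them (default 2 timepoints, giving a
#'   124-row panel: (14 + 20 + 28) x 2).
#' @param class_means 3 x 12 matrix of class mean ratio vectors.
#' @param class_sds Per-gene SD (scalar, vector, or named list of
#'   per-class covariance matrices for correlated draws).
#' @param seed Integer seed.
#' @return A `gtx_panel_sim_config` list.
#' @export
panel_sim_config <- function(n_per_class = c(GTHC = 14L, NGTHC = 20L,
                                             NGTNHC = 28L),
                             timepoints = c("24h", "29d"),
                             class_means = default_class_means(),
                             class_sds = 0.5,
                             seed = 1L) {
  if (is.null(names(n_per_class))) {
    names(n_per_class) <- c("GTHC", "NGTHC", "NGTNHC")
  }
  if (any(n_per_class < 1L)) abort_data("need >= 1 point per class")
  covs <- lapply(c("GTHC", "NGTHC", "NGTNHC"), function(cl) {
    if (is.list(class_sds)) {
      class_sds[[cl]]
    } else if (length(class_sds) == 1L) {
      diag(rep(class_sds^2, 12L))
    } else {
      diag(class_sds^2)
    }
  })
  names(covs) <- c("GTHC", "NGTHC", "NGTNHC")
  for (cl in names(covs)) {
    if (any(diag(covs[[cl]]) < 0)) abort_data("variances must be >= 0")
  }
  structure(
    list(n_per_class = n_per_class, timepoints = timepoints,
         class_means = class_means, class_covs = covs,
         seed = as.integer(seed)),
    class = "gtx_panel_sim_config"
  )
}

# Draw n MVN(mean, cov) rows; zero covariance degenerates to the mean.
rmvn <- function(n, mean, cov) {
  if (all(cov == 0)) {
    return(matrix(mean, n, length(mean), byrow = TRUE))
  }
  ch <- tryCatch(chol(cov), error = function(e) {
    abort_numeric("class covariance is not positive definite")
  })
  z <- matrix(stats::rnorm(n * length(mean)), n)
  sweep(z %*% ch, 2L, mean, `+`)
}

#' Simulate a labeled reference ratio panel
#'
#' @param cfg A [panel_sim_config()].
#' @param panel A [gene_panel()].
#' @return A `gtx_refpanel` data.frame with a `truth` attribute recording
#'   the class means used.
#' @export
simulate_reference_panel <- function(cfg, panel = gene_panel()) {
  stopifnot(inherits(cfg, "gtx_panel_sim_config"))
  n_chem <- c(GTHC = 5L, NGTHC = 7L, NGTNHC = 11L)  # synthetic chemical pool
  doses <- c("L", "M", "H")
  with_seed(cfg$seed, {
    blocks <- list()
    for (tp in cfg$timepoints) {
      for (cl in c("GTHC", "NGTHC", "NGTNHC")) {
        n <- cfg$n_per_class[[cl]]
        vals <- rmvn(n, cfg$class_means[cl, ], cfg$class_covs[[cl]])
        colnames(vals) <- marker_genes()
        chem <- sprintf("%s%02d", substr(cl, 1L, 1L),
                        ((seq_len(n) - 1L) %% n_chem[[cl]]) + 1L)
        dose <- doses[((seq_len(n) - 1L) %/% n_chem[[cl]]) %% 3L + 1L]
        blocks[[paste(tp, cl)]] <- data.frame(
          point_id = sprintf("%s_%s_%s", chem, tp, dose),
          chemical = chem, dose = dose, time = tp, class = cl,
          vals, check.names = FALSE, stringsAsFactors = FALSE
        )
      }
    }
    df <- do.call(rbind, blocks)
    rownames(df) <- NULL
    df$point_id <- make.unique(df$point_id, sep = "_r")
    out <- reference_panel(df, panel = panel)
    attr(out, "truth") <- cfg$class_means
    gtx_log("simulated reference panel: %d rows, seed %d", nrow(out), cfg$seed)
    out
  })
}
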