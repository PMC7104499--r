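# Shared fixture builders; everything is generated in code at test time.

toy_counts <- function(n_per_group = 2L, groups = c("cont", "trt"),
                       base = 100L) {
  genes <- c(marker_genes(), "Dazap2", "Ube2d3")
  n <- n_per_group * length(groups)
  set.seed(42)
  m <- matrix(rpois(n * length(genes), base), nrow = n,
              dimnames = list(sprintf("s%d", seq_len(n)), genes))
  count_matrix(m, rep(groups, each = n_per_group))
}

toy_ratio <- function(n = 9L, k = 3L, seed = 1L, effect = NULL) {
  # n samples split into k groups over the 12 markers, N(0,1) noise;
  # optional named `effect` added to group g2
  set.seed(seed)
  groups <- sort(rep_len(sprintf("g%d", seq_len(k)), n))
  m <- matrix(rnorm(n * 12L), nrow = n,
              dimnames = list(sprintf("s%d", seq_len(n)), marker_genes()))
  if (!is.null(effect)) {
    for (g in names(effect)) {
      m[groups == "g2", g] <- m[groups == "g2", g] + effect[[g]]
    }
  }
  structure(m, class = "gtx_ratio", groups = groups, control = "g1",
            normalizer = "Dazap2")
}

toy_panel <- function(seed = 11L, n = c(GTHC = 8L, NGTHC = 10L, NGTNHC = 12L)) {
  simulate_reference_panel(panel_sim_config(n_per_class = n,
                                            timepoints = "24h", seed = seed))
}

tmpf <- function(ext = ".tsv") tempfile(fileext = ext)
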