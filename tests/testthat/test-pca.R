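test_that("standardize matches per-column hand computation", {
  set.seed(7)
  x <- matrix(rnorm(4 * 12, mean = 2, sd = 3), 4,
              dimnames = list(NULL, marker_genes()))
  std <- standardize(x)
  expect_equal(std$mu, colMeans(x))
  expect_equal(std$sigma, apply(x, 2, sd))
  expect_equal(std$z[2, 3], (x[2, 3] - mean(x[, 3])) / sd(x[, 3]))
  expect_true(all(abs(colMeans(std$z)) < 1e-12))
  expect_equal(unname(apply(std$z, 2, sd)), rep(1, 12))

  # duplicated rows -> zero variance is fatal, naming the gene
  dup <- x[c(1, 1, 1), ]
  expect_error(standardize(dup), "Aen", class = "gtx_numeric_error")
  expect_error(standardize(x[1:2, ]), ">= 3 rows", class = "gtx_data_error")
})

test_that("fit_pca satisfies the spectral identities", {
  p <- toy_panel(seed = 21L)
  fit <- fit_pca(p)

  # unit-norm loading columns
  expect_equal(unname(colSums(fit$loadings^2)), rep(1, 12))
  # scores = z . loadings
  std <- standardize(as.matrix(as.data.frame(p)[, marker_genes()]))
  expect_lt(max(abs(abs(std$z %*% fit$loadings) - abs(fit$scores))), 1e-9)
  # score covariance is diagonal with the eigenvalue spectrum
  cv <- cov(fit$scores)
  eig <- fit$explained * sum(diag(cv))
  expect_equal(unname(diag(cv)), unname(eig), tolerance = 1e-9)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-9)
  # explained fractions valid and non-increasing
  expect_true(all(fit$explained >= 0 & fit$explained <= 1))
  expect_true(all(diff(fit$explained) <= 1e-12))

  # rank-1 data puts all variance on PC1
  pattern <- rnorm(12)
  r1 <- outer(c(1, 2, 3, 4.5), pattern)
  colnames(r1) <- marker_genes()
  f1 <- suppressWarnings(fit_pca(r1))
  expect_equal(f1$explained[1], 1, tolerance = 1e-12)
})

test_that("orientation: GTHC scores negative, stable under permutation", {
  p <- toy_panel(seed = 22L)
  fit <- fit_pca(p)
  pc1 <- fit$scores[, 1]
  expect_lt(mean(pc1[p$class == "GTHC"]),
            mean(pc1[p$class != "GTHC"]))
  # PC2 sign convention: largest-|loading| gene positive
  expect_gt(fit$loadings[which.max(abs(fit$loadings[, 2])), 2], 0)

  # row permutation leaves loadings identical and permutes scores
  perm <- sample(nrow(p))
  fit2 <- fit_pca(as.data.frame(p)[perm, ] |> reference_panel())
  expect_equal(fit2$loadings[, 1:2], fit$loadings[, 1:2], tolerance = 1e-9)
  expect_equal(fit2$scores[rownames(fit$scores), 1:2],
               fit$scores[, 1:2], tolerance = 1e-9)

  # flipping the input's sign flips raw SVD signs; orientation undoes it
  m <- as.matrix(as.data.frame(p)[, marker_genes()])
  rownames(m) <- p$point_id
  fit3 <- fit_pca(-m, p$class)  # mirrored data, same correlation structure
  expect_equal(abs(fit3$scores[, 1]), abs(fit$scores[, 1]), tolerance = 1e-9)

  expect_warning(fit_pca(m), "no labels")
})

test_that("synthetic panel separates classes along PC1", {
  p <- simulate_reference_panel(panel_sim_config(seed = 23L))
  fit <- fit_pca(p)
  pc1 <- fit$scores[, 1]
  expect_lt(max(pc1[p$class == "GTHC"]), min(pc1[p$class != "GTHC"]))
  b <- pc1_border(fit)
  expect_true(b$separable)
  expect_lt(max(pc1[p$class == "GTHC"]), b$border)
  expect_gt(min(pc1[p$class != "GTHC"]), b$border)
})

test_that("pc1_border follows the midpoint rule and flags overlap", {
  fake <- function(pc1, labels) {
    structure(list(scores = cbind(PC1 = pc1, PC2 = 0),
                   labels = labels,
                   loadings = diag(2), mu = c(a = 0, b = 0),
                   sigma = c(a = 1, b = 1),
                   explained = c(0.8, 0.2), flipped = c(FALSE, FALSE)),
              class = "gtx_pca")
  }
  # the two flanking reference scores reported for the combined panel
  fit <- fake(setNames(c(-0.637, -0.159), c("DENlike", "FENlike")),
              c("GTHC", "NGTHC"))
  b <- pc1_border(fit)
  expect_equal(b$border, -0.398)
  expect_true(b$separable)

  b2 <- pc1_border(fake(c(-1, 1), c("GTHC", "NGTNHC")))
  expect_equal(b2$border, 0)

  b3 <- pc1_border(fake(c(0.5, -0.5, 1), c("GTHC", "NGTHC", "NGTNHC")))
  expect_false(b3$separable)

  expect_error(pc1_border(fake(c(1, 2), c("GTHC", "GTHC"))),
               class = "gtx_data_error")
})

test_that("classify_by_pca applies the border with the documented tie rule", {
  p <- toy_panel(seed = 24L)
  m <- rbind(as.matrix(as.data.frame(p)[, marker_genes()]),
             q1 = attr(p, "truth")["GTHC", ],
             q2 = attr(p, "truth")["NGTNHC", ])
  rownames(m) <- c(p$point_id, "q1", "q2")
  fit <- fit_pca(m, c(p$class, "QUERY", "QUERY"))
  b <- pc1_border(fit)
  cls <- classify_by_pca(fit, b)
  expect_identical(unname(cls), c("GTHC-like", "non-GTHC-like"))

  # tie scores exactly at the border are non-calls
  expect_identical(
    unname(classify_by_pca(fit, fit$scores["q1", 1], "q1")),
    "non-GTHC-like"
  )
  expect_error(classify_by_pca(fit, b, "nope"), "unknown query",
               class = "gtx_data_error")
})

test_that("extracted constants reproduce PC1 scores exactly", {
  p <- toy_panel(seed = 25L)
  fit <- fit_pca(p)
  cc <- extract_fixed_constants(fit)
  expect_equal(sum(cc$a^2), 1, tolerance = 1e-9)
  m <- as.matrix(as.data.frame(p)[, marker_genes()])
  y1 <- apply(m, 1, approximate_pc1, constants = cc)
  expect_lt(max(abs(y1 - fit$scores[, 1])), 1e-9)
  expect_identical(attr(cc, "provenance"), "panel-fit")
  expect_equal(attr(cc, "border"), pc1_border(fit)$border)
})

test_that("project_onto scores new rows without refitting", {
  p <- toy_panel(seed = 26L)
  fit <- fit_pca(p)
  m <- as.matrix(as.data.frame(p)[, marker_genes()])
  sc <- project_onto(fit, m[1:3, ])
  expect_equal(sc[, 1], fit$scores[1:3, 1], ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(project_onto(fit, m[1:3, -1]), "missing gene",
               class = "gtx_data_error")
})
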