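test_that("connectome construction validates and cleans its inputs", {
  w <- matrix(c(0, 1, 1, 0), 2)
  d <- matrix(c(0, 50, 50, 0), 2)
  cn <- connectome(w, d)
  expect_s3_class(cn, "sgm_connectome")
  expect_equal(cn$n_regions, 2)

  # atlas-scale input with 86 labels (68 cortical + 18 subcortical regions)
  big <- synth_connectome(86, seed = 1)
  cn86 <- connectome(big$weights, big$distances,
                     labels = paste0("dk_", 1:86))
  expect_equal(cn86$n_regions, 86)
  expect_equal(length(cn86$labels), 86)

  expect_error(connectome(matrix(0, 2, 3), d), "not square")
  expect_error(connectome(w, matrix(0, 3, 3)), "size mismatch")
  wneg <- w; wneg[1, 2] <- -1
  expect_error(connectome(wneg, d), "negative entries at indices.*\\(1,2\\)")
  expect_error(connectome(w, d, labels = c("a", "a")), "not unique")
})

test_that("asymmetric weights are averaged with a warning and logged", {
  w <- matrix(c(0, 2, 4, 0), 2, byrow = TRUE)
  d <- matrix(c(0, 50, 50, 0), 2)
  expect_warning(cn <- connectome(w, d), "asymmetric")
  expect_equal(unname(cn$weights), matrix(c(0, 3, 3, 0), 2))
  expect_true(any(grepl("symmetrized", attr(cn, "provenance"))))
})

test_that("symmetrize averages directions, zeroes the diagonal, is idempotent", {
  expect_equal(symmetrize(matrix(c(0, 2, 4, 0), 2, byrow = TRUE)),
               matrix(c(0, 3, 3, 0), 2))
  sym <- matrix(c(0, 5, 5, 0), 2)
  expect_identical(symmetrize(sym), sym)
  set.seed(3)
  a <- matrix(runif(25), 5)
  ref <- (a + t(a)) / 2; diag(ref) <- 0
  expect_equal(symmetrize(a), ref, tolerance = 1e-15)
  expect_equal(symmetrize(symmetrize(a)), symmetrize(a))
  expect_error(symmetrize(matrix(c(0, -1, 1, 0), 2)), "negative")
})

test_that("degree normalization matches hand arithmetic and preserves structure", {
  expect_equal(degree_normalize(matrix(c(0, 1, 1, 0), 2), "row"),
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  m <- matrix(c(0, 2, 2, 2, 0, 0, 2, 0, 0), 3, byrow = TRUE)
  rn <- degree_normalize(m, "row")
  expect_equal(rowSums(rn), c(1, 1, 1), tolerance = 1e-12)
  # hand case: explicit division by row sums
  h <- matrix(c(0, 1, 3, 2, 0, 2, 1, 1, 0), 3, byrow = TRUE)
  expect_equal(unclass(degree_normalize(h, "row")),
               h / rowSums(h), tolerance = 1e-12, ignore_attr = TRUE)
  sn <- degree_normalize(h2 <- symmetrize(h), "symmetric")
  deg <- rowSums(h2)
  expect_equal(unclass(sn), h2 / sqrt(deg %o% deg),
               tolerance = 1e-12, ignore_attr = TRUE)
  # spectral radius of the symmetric normalization is at most 1
  expect_lte(max(abs(eigen(sn, only.values = TRUE)$values)), 1 + 1e-12)

  # zero rows stay zero; zero pattern preserved
  z <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, byrow = TRUE)
  zn <- degree_normalize(z, "row")
  expect_equal(zn[3, ], c(0, 0, 0))
  expect_identical(unname(zn == 0), unname(z == 0))
  expect_error(degree_normalize(matrix(0, 3, 3), "row"), "degenerate")
})

test_that("synthetic connectomes are reproducible and satisfy the invariants", {
  c1 <- synth_connectome(68, seed = 42)
  c2 <- synth_connectome(68, seed = 42)
  expect_identical(c1$weights, c2$weights)
  expect_identical(c1$distances, c2$distances)
  expect_equal(c1$weights, t(c1$weights))
  expect_true(all(diag(c1$weights) == 0))
  expect_true(all(c1$weights >= 0))
  expect_equal(c1$distances, t(c1$distances))
  expect_true(all(diag(c1$distances) == 0))
  off <- upper.tri(c1$weights)
  expect_lt(cor(c1$weights[off], c1$distances[off], method = "spearman"), 0)
  expect_error(synth_connectome(1), "at least 2")
})

test_that("connectomes round-trip through CSV", {
  cn <- synth_connectome(10, seed = 5)
  wp <- withr::local_tempfile(fileext = ".csv")
  dp <- withr::local_tempfile(fileext = ".csv")
  write_connectome(cn, wp, dp)
  back <- load_connectome(wp, dp)
  expect_equal(back$weights, cn$weights, tolerance = 1e-12)
  expect_equal(back$distances, cn$distances, tolerance = 1e-12)
  expect_identical(back$labels, cn$labels)
})
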