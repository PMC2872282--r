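test_that("ICAR kernel penalises pairwise differences", {
  g <- path_graph(5)
  # a constant (zero after centering) field has no pairwise penalty
  expect_equal(icar_logpdf_kernel(rep(0, 5), g, 1),
               icar_logpdf_kernel(rep(0, 5), g, 1))
  g2 <- path_graph(2)
  d <- 1.4
  quad <- icar_logpdf_kernel(c(d / 2, -d / 2), g2, 1) -
    icar_logpdf_kernel(c(0, 0), g2, 1)
  expect_equal(quad, -d^2 / 2, tolerance = 1e-12)
})

test_that("ICAR kernel equals the degenerate Gaussian of the Laplacian", {
  g <- path_graph(5)
  L <- g$laplacian
  eg <- eigen(L, symmetric = TRUE)
  pos <- eg$values > 1e-9
  set.seed(3)
  for (sigma2 in c(0.3, 1, 2.7)) {
    x <- rnorm(5)
    x <- x - mean(x)
    # density on the sum-to-zero subspace via the spectral decomposition
    z <- drop(t(eg$vectors[, pos]) %*% x)
    oracle <- sum(dnorm(z, 0, sqrt(sigma2 / eg$values[pos]), log = TRUE))
    expect_equal(icar_logpdf_kernel(x, g, sigma2), oracle,
                 tolerance = 1e-8)
  }
})

test_that("ICAR kernel scale property: doubling sigma2 halves the
           quadratic penalty", {
  g <- path_graph(6)
  set.seed(8)
  x <- rnorm(6)
  x <- x - mean(x)
  q1 <- icar_logpdf_kernel(x, g, 1) - icar_logpdf_kernel(numeric(6), g, 1)
  q2 <- icar_logpdf_kernel(x, g, 2) - icar_logpdf_kernel(numeric(6), g, 2)
  expect_equal(q2, q1 / 2, tolerance = 1e-12)
})

test_that("ICAR kernel is invariant to adding a constant before centering",
          {
  g <- path_graph(7)
  set.seed(11)
  x <- rnorm(7)
  x <- x - mean(x)
  shifted <- apply_constraints(param_set(n_counties = 7,
                                         v = x + 3.3))$v
  expect_equal(icar_logpdf_kernel(shifted, g, 0.7),
               icar_logpdf_kernel(x, g, 0.7), tolerance = 1e-10)
})

test_that("ICAR kernel rejects invalid input", {
  g <- path_graph(4)
  expect_equal(icar_logpdf_kernel(numeric(4), g, -1), -Inf)
  expect_error(icar_logpdf_kernel(numeric(4), list(n = 4), 1), "jp_graph")
  expect_error(adjacency_graph(list(2L, integer(0))), "not symmetric")
})

test_that("sampled ICAR fields are centered and deterministic in scale 0",
          {
  g <- path_graph(9)
  set.seed(2)
  x <- sample_icar(g, 0.5)
  expect_equal(sum(x), 0, tolerance = 1e-10)
  expect_equal(sample_icar(g, 0), numeric(9))
  # disconnected graph: per-component centering, islands at zero
  g_disc <- adjacency_graph(list(2L, 1L, integer(0)))
  y <- sample_icar(g_disc, 1)
  expect_equal(y[1] + y[2], 0, tolerance = 1e-12)
  expect_identical(y[3], 0)
})

test_that("sampled ICAR fields are spatially autocorrelated (Moran's I)", {
  geo <- make_lattice_geography(100, 5)
  set.seed(21)
  v <- sample_icar(geo$county_graph, 0.3)
  Wmat <- -geo$county_graph$laplacian
  diag(Wmat) <- 0
  mi <- ape::Moran.I(v, Wmat)
  expect_gt(mi$observed, mi$expected)
  expect_lt(mi$p.value, 0.01)
})
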