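test_that("knots sit at the prescribed quantiles of the unique values", {
  # 5 unique values, K = 3: probabilities 0.4, 0.6, 0.8; linear interpolation
  # of the order statistics gives 0.25 + 0.6*0.25 = 0.4 etc.
  ks <- place_knots(c(0, 0.25, 0.5, 0.75, 1), 3)
  expect_equal(ks$knots, c(0.4, 0.6, 0.8))
  expect_identical(ks$K, 3L)

  # duplicated data values do not move the knots (quantiles of unique values)
  ks2 <- place_knots(rep(c(0, 0.25, 0.5, 0.75, 1), each = 7), 3)
  expect_equal(ks2$knots, ks$knots)

  expect_error(place_knots(rep(1, 50), 1), "insufficient unique")
  expect_error(place_knots(c(1:5, NA), 2), "non-finite")

  # determinism
  x <- runif(100)
  expect_identical(place_knots(x, 7), place_knots(x, 7))
})

test_that("knot placement is permutation-invariant and scale-equivariant", {
  set.seed(42)
  for (rep in 1:5) {
    x <- rnorm(60)
    K <- sample(2:8, 1)
    base <- place_knots(x, K)
    expect_equal(place_knots(sample(x), K), base)
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    expect_equal(place_knots(a * x + b, K)$knots, a * base$knots + b)
  }
})

test_that("Wand's rule caps the knot count at 35", {
  expect_identical(wand_K(seq_len(200)), 35L)
  expect_identical(wand_K(seq_len(80)), 20L)
  expect_error(wand_K(c(1, 2, 3)), "K must be >= 1")
  expect_error(wand_K(numeric(0)), "empty")
})

test_that("the cubic distance matrix matches its closed form", {
  kn2 <- structure(list(knots = c(0, 1), K = 2L), class = "knot_set")
  expect_equal(omega_matrix(kn2), matrix(c(0, 1, 1, 0), 2))
  kn3 <- structure(list(knots = c(0, 0.5, 1), K = 3L), class = "knot_set")
  expect_equal(omega_matrix(kn3),
               matrix(c(0, 0.125, 1, 0.125, 0, 0.125, 1, 0.125, 0), 3))
  kn1 <- structure(list(knots = 0.3, K = 1L), class = "knot_set")
  expect_equal(omega_matrix(kn1), matrix(0, 1, 1))

  # symmetric with zero diagonal for arbitrary knot sets
  set.seed(5)
  for (rep in 1:10) {
    kn <- structure(list(knots = sort(runif(sample(2:9, 1))), K = NULL),
                    class = "knot_set")
    om <- omega_matrix(kn)
    expect_equal(om, t(om))
    expect_equal(diag(om), rep(0, nrow(om)))
  }
})

test_that("the SVD inverse square root inverts positive-definite matrices", {
  expect_equal(matrix_inv_sqrt(diag(3)), diag(3))
  expect_equal(matrix_inv_sqrt(diag(c(4, 9))), diag(c(1 / 2, 1 / 3)))

  set.seed(11)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    A <- matrix(rnorm(k * k), k)
    M <- crossprod(A) + diag(k)  # PD
    R <- matrix_inv_sqrt(M)
    expect_equal(R, t(R), tolerance = 1e-8)
    expect_equal(R %*% M %*% R, diag(k), tolerance = 1e-8)
  }

  # indefinite exchange matrix: SVD rule agrees with the eigendecomposition
  # oracle built from absolute eigenvalues (here both equal M itself)
  M <- matrix(c(0, 1, 1, 0), 2)
  e <- eigen(M)
  oracle <- e$vectors %*% diag(sign(e$values) / sqrt(abs(e$values))) %*%
    t(e$vectors)
  expect_equal(matrix_inv_sqrt(M), oracle)
  expect_equal(matrix_inv_sqrt(M), M)

  expect_error(matrix_inv_sqrt(matrix(c(1, 1, 1, 1), 2)), "singular")
  expect_error(matrix_inv_sqrt(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("the thin-plate design reproduces the basis definition", {
  set.seed(3)
  x <- c(0.05, 0.35, 0.6, 0.95)
  kn <- structure(list(knots = c(0.25, 0.75), K = 2L), class = "knot_set")
  d <- lrtp_design(x, kn)
  expect_equal(d$X[, 1], rep(1, 4))
  expect_equal(d$X[, 2], x)
  expect_identical(ncol(d$Z), 2L)

  # brute-force double loop over b_k(x) = sum_i |x - t_i|^3 w_i(k)
  tr <- d$transform
  Zo <- matrix(0, 4, 2)
  for (i in 1:4) {
    for (k in 1:2) {
      for (j in 1:2) {
        Zo[i, k] <- Zo[i, k] + abs(x[i] - kn$knots[j])^3 * tr[j, k]
      }
    }
  }
  expect_equal(d$Z, Zo)

  # evaluated at the knots, C = Omega so Z.Z equals the spectral absolute
  # value of Omega (they coincide only for PD penalty matrices; Omega has
  # zero trace and is indefinite)
  x2 <- sort(runif(6))
  kn6 <- structure(list(knots = x2, K = 6L), class = "knot_set")
  d6 <- lrtp_design(x2, kn6)
  om <- omega_matrix(kn6)
  e <- eigen(om)
  om_abs <- e$vectors %*% diag(abs(e$values)) %*% t(e$vectors)
  expect_equal(d6$Z %*% d6$Z, om_abs, tolerance = 1e-8)
  # and the transform inverts Omega up to its spectral sign
  sgn <- e$vectors %*% diag(sign(e$values)) %*% t(e$vectors)
  expect_equal(d6$transform %*% om %*% d6$transform, sgn, tolerance = 1e-8)
})

test_that("truncated quadratic basis obeys the plus-function boundary", {
  kn <- structure(list(knots = c(0.3, 0.7), K = 2L), class = "knot_set")
  d <- truncated_quadratic_design(c(0.1, 0.3, 0.8, 1.2), kn)
  expect_equal(ncol(d$X), 3L)            # 1, x, x^2
  expect_equal(d$X[, 3], c(0.1, 0.3, 0.8, 1.2)^2)
  expect_equal(d$Z[1, ], c(0, 0))        # below every knot
  expect_equal(d$Z[2, 1], 0)             # exactly at a knot
  expect_equal(d$Z[3, 1], 0.25)          # 0.3 + 0.5
  expect_equal(d$Z[4, 2], 0.25)          # 0.7 + 0.5
  expect_equal(d$transform, diag(2))
})

test_that("natural cubic basis is linear beyond the boundary knots", {
  kn <- structure(list(knots = c(0.2, 0.5, 0.8), K = 3L), class = "knot_set")
  h <- 0.01
  for (x0 in c(-3, 2.5)) {                # far left and far right
    g <- seq(x0, x0 + 10 * h, by = h)
    d <- natural_cubic_design(g, kn)
    d2 <- apply(d$Z, 2, function(col) diff(diff(col)) / h^2)
    expect_lt(max(abs(d2)), 1e-8)
  }

  # K = 3 equally spaced knots: compare to the restricted-cubic closed form
  # evaluated independently term by term
  x <- seq(0, 1, length.out = 9)
  t <- c(0.25, 0.5, 0.75)
  kn3 <- structure(list(knots = t, K = 3L), class = "knot_set")
  d <- natural_cubic_design(x, kn3)
  pc <- function(v) pmax(v, 0)^3
  oracle <- pc(x - t[1]) - pc(x - t[2]) * (t[3] - t[1]) / (t[3] - t[2]) +
    pc(x - t[3]) * (t[2] - t[1]) / (t[3] - t[2])
  expect_equal(d$Z[, 1], oracle)
  expect_identical(ncol(d$Z), 1L)        # K - 2 penalized columns

  # evaluated at K knots the penalized block has full column rank K - 2
  t5 <- seq(0.1, 0.9, length.out = 5)
  kn5 <- structure(list(knots = t5, K = 5L), class = "knot_set")
  d5 <- natural_cubic_design(t5, kn5)
  expect_identical(ncol(d5$Z), 3L)
  expect_identical(qr(d5$Z)$rank, 3L)

  expect_error(natural_cubic_design(x, kn), NA)
  kn2 <- structure(list(knots = c(0.2, 0.8), K = 2L), class = "knot_set")
  expect_error(natural_cubic_design(x, kn2), "K >= 3")
})

test_that("build_design dispatches on the basis spec and applies Wand's rule", {
  x <- seq(0, 1, length.out = 120)
  d <- build_design(x, basis_spec("lrtp", K = "wand_rule"))
  expect_identical(ncol(d$Z), 30L)  # 120 unique / 4
  d2 <- build_design(x, basis_spec("truncated_quadratic", K = 4))
  expect_identical(d2$kind, "truncated_quadratic")
  expect_identical(ncol(d2$Z), 4L)
})
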