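test_that("net merit variance is the quadratic form w'Cw", {
  expect_equal(net_merit_variance(diag(2), c(3, 4)), 25)
  expect_equal(net_merit_variance(diag(3), c(0, 0, 0)), 0)

  set.seed(42)
  for (rep in 1:5) {
    t <- sample(2:6, 1)
    C <- rand_pd(t)
    w <- rnorm(t)
    brute <- sum(outer(w, w) * C)   # double sum over i, j
    expect_equal(net_merit_variance(C, w), brute, tolerance = 1e-10)
  }
  expect_error(net_merit_variance(diag(3), c(1, 2)), "length")
})

test_that("Smith coefficients solve P b = C w and reduce correctly", {
  set.seed(7)
  C <- rand_pd(3)
  w <- c(1, -2, 3)
  expect_equal(lpsi_coefficients(C, C, w), setNames(w, NULL),
               tolerance = 1e-10, ignore_attr = TRUE)
  # scalar case: heritability-shrunk weight
  expect_equal(
    unname(lpsi_coefficients(matrix(2), matrix(0.8), 5)),
    0.8 / 2 * 5, tolerance = 1e-12)
})

test_that("LPSI maximizes the correlation with net merit over random indices", {
  set.seed(99)
  for (rep in 1:5) {
    cp <- rand_cp(4)
    w <- rnorm(4)
    b <- lpsi_coefficients(cp$P, cp$C, w)
    rho_b <- rho_analytic(b, w, cp$C, cp$P)
    a <- matrix(rnorm(4 * 1000), 4)
    rho_a <- apply(a, 2, rho_analytic, w = w, C = cp$C, P = cp$P)
    expect_true(all(rho_a <= rho_b + 1e-10))
  }
})

test_that("Mallard contrast matrix matches its defining pattern", {
  expect_equal(mallard_D(c(1, 1)), matrix(c(1, -1), 1, 2))
  expect_equal(mallard_D(c(2, 3, 5)),
               rbind(c(5, 0, -2), c(0, 5, -3)))
  # every row annihilates d
  set.seed(3)
  for (r in 2:5) {
    d <- rnorm(r)
    expect_equal(drop(mallard_D(d) %*% d), rep(0, r - 1), tolerance = 1e-12)
  }
  expect_equal(dim(mallard_D(3)), c(0L, 1L))
  expect_error(mallard_D(c(0, 0)), "nonzero")
})

test_that("no restriction returns exactly the Smith coefficients", {
  set.seed(5)
  cp <- rand_cp(4)
  w <- rnorm(4)
  m <- restricted_coefficients(cp$P, cp$C, w, restriction = NULL)
  expect_identical(m$b, m$beta)
  expect_equal(m$scenario, "LPSI")
  # single proportional restriction carries no contrast: also b = beta
  r1 <- restriction_spec("tr1", cp$traits, d = 2)
  m1 <- restricted_coefficients(cp$P, cp$C, w, r1)
  expect_equal(m1$b, m1$beta, tolerance = 1e-12)
})

test_that("null restriction zeroes the restricted gains and uses an idempotent projector", {
  set.seed(17)
  for (rep in 1:10) {
    cp <- rand_cp(4)
    w <- rnorm(4)
    restricted <- sample(cp$traits, sample(1:2, 1))
    rs <- restriction_spec(restricted, cp$traits)
    m <- restricted_coefficients(cp$P, cp$C, w, rs)
    # U'Cb = 0
    expect_lt(max(abs(rs$U_t %*% cp$C %*% m$b)), 1e-8)
    # independent reconstruction of Q; idempotency of Q and K = I - Q
    M <- t(rs$U_t %*% cp$C)
    PinvM <- solve(cp$P, M)
    Q <- PinvM %*% solve(t(M) %*% PinvM, t(M))
    K <- diag(4) - Q
    expect_lt(max(abs(Q %*% Q - Q)), 1e-8)
    expect_lt(max(abs(K %*% K - K)), 1e-8)
    expect_equal(as.numeric(m$b), unname(drop(K %*% m$beta)),
                 tolerance = 1e-10)
  }
})

test_that("proportional restriction makes gains proportional to d", {
  set.seed(23)
  cp <- rand_cp(5)
  w <- rnorm(5)
  d <- c(2, -1)
  rs <- restriction_spec(c("tr1", "tr3"), cp$traits, d = d)
  m <- restricted_coefficients(cp$P, cp$C, w, rs)
  gains <- drop(rs$U_t %*% cp$C %*% m$b)
  # gains on the restricted traits are collinear with d
  expect_equal(unname(gains[1] * d[2]), unname(gains[2] * d[1]),
               tolerance = 1e-8)
})

test_that("index scores are dot products aligned by trait", {
  blues <- tibble::tibble(genotype = c("g1", "g2", "g3"),
                          yield = c(5, 6, 5), gpc = c(14, 13, 14))
  cp <- rand_cp(2, traits = c("yield", "gpc"))
  unit <- structure(list(scenario = "unit", b = c(yield = 0, gpc = 1),
                         beta = NULL, C = cp$C, P = cp$P,
                         w = c(yield = 0, gpc = 1), restriction = NULL),
                    class = "index_model")
  expect_equal(index_values(unit, blues)$score, blues$gpc)

  set.seed(9)
  b <- rnorm(2)
  mod <- structure(list(scenario = "x", b = setNames(b, c("yield", "gpc")),
                        beta = NULL, C = cp$C, P = cp$P,
                        w = c(yield = 1, gpc = 1), restriction = NULL),
                   class = "index_model")
  sc <- index_values(mod, blues)
  expect_equal(sc$score,
               b[1] * blues$yield + b[2] * blues$gpc, tolerance = 1e-12)
  # identical BLUEs give identical scores
  expect_equal(sc$score[1], sc$score[3])
  expect_error(index_values(mod, blues[, c("genotype", "yield")]), "gpc")
})

test_that("selection intensity matches normal truncation theory", {
  expect_equal(selection_intensity(0.5), 2 * dnorm(0), tolerance = 1e-12)
  # independent oracle: numerical integration of the truncated normal mean
  k_int <- integrate(function(z) z * dnorm(z), qnorm(0.9), Inf)$value / 0.1
  expect_equal(selection_intensity(0.10), k_int, tolerance = 1e-7)
  expect_equal(selection_intensity(0.10), 1.755, tolerance = 1e-3)
  expect_lt(selection_intensity(0.999), 0.01)
  expect_error(selection_intensity(0), "0, 1")
  expect_error(selection_intensity(1), "0, 1")

  # finite-population value is smaller and matches a Monte-Carlo oracle
  k_fin <- selection_intensity(0.10, n = 196)
  expect_lt(k_fin, selection_intensity(0.10))
  set.seed(31)
  sims <- replicate(2000, mean(sort(rnorm(196), decreasing = TRUE)[1:20]))
  expect_lt(abs(k_fin - mean(sims)), 3 * sd(sims) / sqrt(2000))
})

test_that("evaluate_index reproduces the breeder's equation at t = 1", {
  s2g <- 0.8; s2p <- 2.0; k <- selection_intensity(0.2)
  m <- lpsi(matrix(s2p), matrix(s2g), 1)
  ev <- evaluate_index(m, k)
  h2 <- s2g / s2p
  expect_equal(unname(ev$E), k * h2 * sqrt(s2p), tolerance = 1e-12)
  expect_equal(ev$rho_HI, sqrt(h2), tolerance = 1e-12)
})

test_that("selection parameters are scale-equivariant in the weights", {
  set.seed(41)
  cp <- rand_cp(4)
  w <- rnorm(4)
  k <- selection_intensity(0.1)
  e1 <- evaluate_index(lpsi(cp$P, cp$C, w), k)
  e2 <- evaluate_index(lpsi(cp$P, cp$C, 3 * w), k)
  expect_equal(as.numeric(e2$b), 3 * as.numeric(e1$b), tolerance = 1e-10)
  expect_equal(e2$sigma_H, 3 * e1$sigma_H, tolerance = 1e-10)
  expect_equal(e2$sigma_I, 3 * e1$sigma_I, tolerance = 1e-10)
  expect_equal(e2$R, 3 * e1$R, tolerance = 1e-10)
  expect_equal(e2$rho_HI, e1$rho_HI, tolerance = 1e-10)
  expect_equal(e2$E, e1$E, tolerance = 1e-10)

  # unrestricted identity w'C beta = beta'P beta, hence R = k sigma_I
  expect_equal(e1$R, k * e1$sigma_I, tolerance = 1e-10)
})

test_that("restriction can only reduce the index-merit correlation", {
  set.seed(53)
  for (rep in 1:10) {
    cp <- rand_cp(4)
    w <- rnorm(4)
    k <- selection_intensity(0.1)
    rho_l <- evaluate_index(lpsi(cp$P, cp$C, w), k)$rho_HI
    rs <- restriction_spec(sample(cp$traits, 1), cp$traits)
    rho_r <- evaluate_index(
      restricted_coefficients(cp$P, cp$C, w, rs), k)$rho_HI
    expect_lte(rho_r, rho_l + 1e-10)
  }
})
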