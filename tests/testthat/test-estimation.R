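test_that("BLUEs on balanced data equal plain genotype means to machine precision", {
  trial <- simulate_met(small_spec(seed = 2))
  blues <- compute_blues(trial, "combined")
  manual <- aggregate(cbind(yield, gpc) ~ genotype, data = trial, FUN = mean)
  manual <- manual[order(manual$genotype), ]
  expect_equal(blues$yield, manual$yield, tolerance = 1e-12)
  expect_equal(blues$gpc, manual$gpc, tolerance = 1e-12)

  # noise-free: BLUE = trait mean + mean environment effect, identical rows
  nf <- simulate_met(noiseless_spec(env_sd = 2))
  b_nf <- compute_blues(nf, "combined")
  env_means <- aggregate(yield ~ environment, nf, mean)$yield
  expect_equal(b_nf$yield, rep(mean(nf$yield), 5), tolerance = 1e-12)
  expect_equal(unique(round(b_nf$gpc, 10)), round(mean(nf$gpc), 10))
})

test_that("BLUEs with a masked plot match the two-way normal-equation oracle", {
  trial <- simulate_met(small_spec(seed = 9, n_genotypes = 12))
  trial$yield[5] <- NA  # unbalance one plot

  blues <- suppressWarnings(compute_blues(trial, "combined"))

  # brute-force oracle: explicit normal equations of y ~ genotype + environment
  d <- trial[!is.na(trial$yield), ]
  G <- sort(unique(d$genotype)); E <- sort(unique(d$environment))
  X <- cbind(1,
             outer(d$genotype, G[-1], "==") * 1,
             outer(d$environment, E[-1], "==") * 1)
  beta <- solve(crossprod(X), crossprod(X, d$yield))
  ng <- length(G); ne <- length(E)
  geno_eff <- c(0, beta[2:ng])
  env_eff <- c(0, beta[(ng + 1):(ng + ne - 1)])
  oracle <- beta[1] + geno_eff + mean(env_eff)
  expect_equal(blues$yield, as.numeric(oracle), tolerance = 1e-9)
})

test_that("variance components equal the hand-computed two-way ANOVA oracle", {
  # 2 genotypes x 2 environments x 2 reps, values chosen by hand
  d <- tibble::tibble(
    genotype = rep(c("g1", "g2"), each = 4),
    management = "conventional",
    environment = rep(rep(c("e1", "e2"), each = 2), 2),
    replicate = rep(1:2, 4),
    y = c(10, 12, 20, 22, 14, 16, 16, 18)
  )
  vc <- variance_components(d, traits = "y")

  # explicit expected-mean-square arithmetic
  cellm <- with(d, tapply(y, list(genotype, environment), mean))
  gm <- rowMeans(cellm); em <- colMeans(cellm); mu <- mean(d$y)
  r <- 2; e <- 2; g <- 2
  ms_g <- r * e * sum((gm - mu)^2) / (g - 1)
  ms_e_int <- r * sum((cellm - outer(gm, rep(1, e)) -
                         outer(rep(1, g), em) + mu)^2) / ((g - 1) * (e - 1))
  ms_err <- sum((d$y - cellm[cbind(d$genotype, d$environment)])^2) /
    (g * e * (r - 1))
  expect_equal(vc$sigma2_e, ms_err, tolerance = 1e-12)
  expect_equal(vc$sigma2_ge, max((ms_e_int - ms_err) / r, 0), tolerance = 1e-12)
  expect_equal(vc$sigma2_g, max((ms_g - ms_e_int) / (r * e), 0),
               tolerance = 1e-12)
})

test_that("zero genetic variance is estimated at (truncated) zero", {
  z <- matrix(0, 1, 1)
  spec <- simulation_spec(
    n_genotypes = 30, trait_names = "y", trait_means = 0,
    C_true = z, gxe_cov = matrix(0.3, 1, 1), residual_cov = matrix(1, 1, 1),
    n_env = c(conventional = 3), n_rep = 2, seed = 21
  )
  vc <- suppressMessages(variance_components(simulate_met(spec), "y"))
  expect_gte(vc$sigma2_g, 0)
  expect_lt(vc$sigma2_g, 0.2)
})

test_that("heritability follows its closed form and monotonicity", {
  vc <- tibble::tibble(trait = "t", sigma2_g = 1, sigma2_ge = 1, sigma2_e = 1,
                       n_env = 4, n_rep = 2, truncated = FALSE)
  expect_equal(unname(broad_sense_heritability(vc)), 1 / (1 + 0.25 + 0.125),
               tolerance = 1e-12)
  expect_equal(unname(broad_sense_heritability(vc)), 0.727272727,
               tolerance = 1e-6)

  h2_of <- function(g, ge, e2, ne, nr) {
    unname(broad_sense_heritability(tibble::tibble(
      trait = "t", sigma2_g = g, sigma2_ge = ge, sigma2_e = e2,
      n_env = ne, n_rep = nr, truncated = FALSE)))
  }
  base <- h2_of(1, 1, 1, 4, 2)
  expect_gt(h2_of(2, 1, 1, 4, 2), base)   # more genetic variance
  expect_gt(h2_of(1, 1, 1, 8, 2), base)   # more environments
  expect_gt(h2_of(1, 1, 1, 4, 4), base)   # more reps
  expect_lt(h2_of(1, 2, 1, 4, 2), base)   # more GxE
  expect_lt(h2_of(1, 1, 2, 4, 2), base)   # more residual

  zero <- tibble::tibble(trait = "t", sigma2_g = 0, sigma2_ge = 0,
                         sigma2_e = 0, n_env = 2, n_rep = 2, truncated = FALSE)
  expect_warning(h0 <- broad_sense_heritability(zero), "zero")
  expect_equal(unname(h0), 0)
})

test_that("multivariate C is consistent with univariate components and with P", {
  trial <- simulate_met(small_spec(seed = 13, n_genotypes = 60))
  cp <- covariance_matrices(trial, "combined")
  vc <- variance_components(trial, subset = "combined")
  # diagonal of C equals the univariate sigma2_g trait by trait
  expect_equal(unname(diag(cp$C)), vc$sigma2_g, tolerance = 1e-10)
  expect_true(is_symmetric(cp$C) && is_symmetric(cp$P))
  expect_true(all(diag(cp$P) >= diag(cp$C) - 1e-10))

  # without GxE and residual noise, C and P coincide
  C <- matrix(c(1, 0.3, 0.3, 0.6), 2, 2)
  z <- matrix(0, 2, 2)
  pure <- simulate_met(simulation_spec(
    n_genotypes = 25, trait_names = c("a", "b"), trait_means = c(0, 0),
    C_true = C, gxe_cov = z, residual_cov = z, env_sd = c(1, 1),
    n_env = c(conventional = 2, organic = 2), n_rep = 2, seed = 5
  ))
  cp_pure <- covariance_matrices(pure, "combined")
  expect_equal(cp_pure$C, cp_pure$P, tolerance = 1e-6)
})

test_that("ensure_psd floors only offending eigenvalues", {
  expect_equal(ensure_psd(diag(3), floor = 1e-8), diag(3))

  # spectral construction with one negative eigenvalue
  set.seed(1)
  V <- qr.Q(qr(matrix(rnorm(9), 3)))
  M <- V %*% diag(c(2, 1, -0.01)) %*% t(V)
  M <- (M + t(M)) / 2
  out <- suppressMessages(ensure_psd(M, floor = 1e-8))
  ev_out <- eigen(out, symmetric = TRUE)
  expect_gte(min(ev_out$values), 1e-9)
  expect_equal(sort(ev_out$values, decreasing = TRUE)[1:2], c(2, 1),
               tolerance = 1e-8)
  # perturbation bounded by |most negative eigenvalue| + floor
  expect_lte(norm(out - M, "2"), 0.01 + 1e-8 + 1e-12)

  expect_error(ensure_psd(matrix(1:4, 2, 2)), "symmetric")
})

test_that("estimation rejects unbalanced or empty inputs", {
  trial <- simulate_met(small_spec(seed = 2))
  expect_error(trial_subset(trial, "no-such-management"), "selects no records")
  unbal <- trial[-1, ]
  expect_error(variance_components(unbal, "yield"), "balanced")
  expect_error(covariance_matrices(unbal), "balanced")
})
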