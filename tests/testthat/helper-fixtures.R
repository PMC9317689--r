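# fixtures are generated in code; seeds are fixed per test for repeatability

# random symmetric positive-definite matrix
rand_pd <- function(t, jitter = 0.1) {
  a <- matrix(rnorm(t * t), t, t)
  crossprod(a) / t + diag(jitter, t)
}

# a plausible (C, P) pair on the entry-mean basis: P = C + positive noise,
# so P is invertible and diag(P) >= diag(C)
rand_cp <- function(t, traits = paste0("tr", seq_len(t))) {
  C <- rand_pd(t)
  P <- C + rand_pd(t, jitter = 0.2)
  dimnames(C) <- dimnames(P) <- list(traits, traits)
  list(C = C, P = P, traits = traits)
}

# small fast trial spec: 2 traits, tiny panel
small_spec <- function(seed = 1, n_genotypes = 40,
                       n_env = c(conventional = 3, organic = 2), n_rep = 2) {
  C <- matrix(c(1, 0.4, 0.4, 0.8), 2, 2)
  simulation_spec(
    n_genotypes = n_genotypes,
    trait_names = c("yield", "gpc"),
    trait_means = c(yield = 5, gpc = 14),
    C_true = C,
    gxe_cov = 0.5 * C,
    residual_cov = C,
    env_sd = c(0.5, 0.5),
    n_env = n_env, n_rep = n_rep, seed = seed
  )
}

# noise-free spec: phenotype is exactly the deterministic mean structure
noiseless_spec <- function(seed = 1, env_sd = 0) {
  z <- matrix(0, 2, 2)
  simulation_spec(
    n_genotypes = 5, trait_names = c("yield", "gpc"),
    trait_means = c(yield = 5, gpc = 14),
    C_true = z, gxe_cov = z, residual_cov = z,
    env_sd = env_sd,
    n_env = c(conventional = 2, organic = 2), n_rep = 2, seed = seed
  )
}

# analytic correlation between merit H = w'g and a candidate index a'y
rho_analytic <- function(a, w, C, P) {
  drop(t(w) %*% C %*% a) /
    sqrt(drop(t(w) %*% C %*% w) * drop(t(a) %*% P %*% a))
}
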