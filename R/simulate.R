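#' Specify a multi-environment trial simulation
#'
#' A simulation spec fixes the genetic architecture (genetic, genotype-by-
#' environment and plot-residual covariance matrices), the trial layout
#' (environments per management system, replicates) and the seed. The
#' simulator draws true genotypic values `g_i` from a multivariate normal
#' with mean `trait_means` and covariance `C_true`, so the truth underlying
#' every simulated phenotype is known and recoverable.
#'
#' @param n_genotypes number of genotypes (lines) in the trial.
#' @param trait_names character vector of trait labels (length `t`).
#' @param trait_means numeric vector of population trait means, length `t`.
#' @param C_true `t x t` genetic covariance matrix (symmetric PSD).
#' @param gxe_cov `t x t` covariance of genotype-by-environment deviations,
#'   independent across environments (compound-symmetry genotype effect).
#' @param residual_cov `t x t` plot-residual covariance.
#' @param env_sd per-trait standard deviation of environment main effects;
#'   these cancel out of all genotype contrasts, so the scale is free.
#' @param n_env named integer vector: environments per management label,
#'   e.g. `c(conventional = 5, organic = 4)`.
#' @param n_rep replicates per environment.
#' @param seed integer RNG seed stored in the spec.
#'
#' @return an object of class `simulation_spec`.
#' @seealso [simulate_met()], [default_wheat_spec()]
#' @export
simulation_spec <- function(n_genotypes, trait_names, trait_means,
                            C_true, gxe_cov, residual_cov,
                            env_sd = rep(0, length(trait_names)),
                            n_env = c(conventional = 5, organic = 4),
                            n_rep = 2, seed = 1) {
  t <- length(trait_names)
  if (t < 1) abort("need at least one trait")
  if (length(trait_means) != t) abort("trait_means must have one entry per trait")
  if (n_genotypes < 1 || n_rep < 1 || any(n_env < 1)) {
    abort("n_genotypes, n_rep and all environment counts must be positive")
  }
  if (is.null(names(n_env)) || any(!nzchar(names(n_env)))) {
    abort("n_env must be a named vector of management labels")
  }
  for (nm in c("C_true", "gxe_cov", "residual_cov")) {
    m <- get(nm)
    if (!is.matrix(m) || any(dim(m) != t)) {
      abort(sprintf("%s must be a %d x %d matrix", nm, t, t))
    }
    if (!is_psd(m)) {
      abort(sprintf("%s is not symmetric positive semi-definite", nm))
    }
  }
  if (length(env_sd) == 1) env_sd <- rep(env_sd, t)
  structure(
    list(
      n_genotypes = as.integer(n_genotypes),
      trait_names = trait_names,
      trait_means = setNames(as.numeric(trait_means), trait_names),
      C_true = structure(C_true, dimnames = list(trait_names, trait_names)),
      gxe_cov = structure(gxe_cov, dimnames = list(trait_names, trait_names)),
      residual_cov = structure(residual_cov,
                               dimnames = list(trait_names, trait_names)),
      env_sd = setNames(as.numeric(env_sd), trait_names),
      n_env = vapply(n_env, as.integer, integer(1)),
      n_rep = as.integer(n_rep),
      seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("<simulation_spec>\n")
  cat(sprintf("  %d genotypes x %d traits (%s)\n", x$n_genotypes,
              length(x$trait_names), paste(x$trait_names, collapse = ", ")))
  cat(sprintf("  environments: %s; %d rep(s); seed %d\n",
              paste(sprintf("%s=%d", names(x$n_env), x$n_env), collapse = ", "),
              x$n_rep, x$seed))
  invisible(x)
}

#' Default spring-wheat simulation spec
#'
#' Emulates a 196-genotype Canadian spring-wheat panel phenotyped for days to
#' maturity (d), plant height (cm), grain yield (t/ha) and grain protein
#' content (GPC, %) across five conventionally and four organically managed
#' environments with two replicates. Genetic correlations are set to the
#' values observed in this germplasm: yield-GPC -0.56, yield-height -0.47,
#' yield-maturity +0.50. Variance components are chosen so that entry-mean
#' broad-sense heritability per management system falls within 0.32-0.80.
#'
#' @param seed integer seed stored in the spec.
#' @return a [simulation_spec()].
#' @export
default_wheat_spec <- function(seed = 1) {
  traits <- c("maturity", "height", "yield", "gpc")
  means <- c(maturity = 89, height = 89, yield = 4.8, gpc = 14.2)
  sds <- c(maturity = 2.7, height = 6.0, yield = 0.65, gpc = 1.2)
  corr <- matrix(c(
    1.00, 0.15, 0.50, -0.15,
    0.15, 1.00, -0.47, 0.10,
    0.50, -0.47, 1.00, -0.56,
    -0.15, 0.10, -0.56, 1.00
  ), 4, 4, byrow = TRUE, dimnames = list(traits, traits))
  C <- diag(sds) %*% corr %*% diag(sds)
  # per-trait noise-to-genetic variance ratios; GPC is the most heritable
  # trait and yield the least, mirroring field experience with this panel
  gxe_mult <- c(maturity = 2.0, height = 2.0, yield = 3.0, gpc = 0.8)
  res_mult <- c(maturity = 4.0, height = 4.0, yield = 5.0, gpc = 1.6)
  gxe <- diag(sds * sqrt(gxe_mult)) %*% corr %*% diag(sds * sqrt(gxe_mult))
  res <- diag(sds * sqrt(res_mult)) %*% corr %*% diag(sds * sqrt(res_mult))
  simulation_spec(
    n_genotypes = 196,
    trait_names = traits,
    trait_means = means,
    C_true = C,
    gxe_cov = gxe,
    residual_cov = res,
    env_sd = c(maturity = 3, height = 5, yield = 0.8, gpc = 0.8),
    n_env = c(conventional = 5, organic = 4),
    n_rep = 2,
    seed = seed
  )
}

#' Simulate a balanced multi-environment trial
#'
#' Generates one phenotype record per genotype x environment x replicate:
#' `phenotype = g_i + env_j + ge_ij + eps_ijr`, where `g_i` is the true
#' genotypic value (multivariate normal, mean `trait_means`, covariance
#' `C_true`), `env_j` an environment main effect, `ge_ij` an independent
#' genotype-by-environment deviation and `eps_ijr` a plot residual. The
#' layout is complete and balanced; use [mask_plots()] to inject
#' missingness.
#'
#' @param spec a [simulation_spec()].
#' @return a tibble with columns `genotype`, `management`, `environment`,
#'   `replicate` and one column per trait. The true genotypic values are
#'   attached as a tibble in `attr(, "truth")` and the spec as
#'   `attr(, "spec")`.
#' @export
simulate_met <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  t <- length(spec$trait_names)
  n_g <- spec$n_genotypes
  geno_ids <- sprintf("G%03d", seq_len(n_g))
  env_tbl <- tidyr::expand_grid(
    management = names(spec$n_env),
    idx = seq_len(max(spec$n_env))
  ) |>
    dplyr::group_by(.data$management) |>
    dplyr::filter(.data$idx <= spec$n_env[unique(.data$management)]) |>
    dplyr::ungroup() |>
    dplyr::mutate(environment = sprintf("%s_%d",
                                        substr(.data$management, 1, 4),
                                        .data$idx)) |>
    dplyr::select("management", "environment")
  n_e <- nrow(env_tbl)

  g <- rmvn(n_g, spec$trait_means, spec$C_true)
  env_eff <- matrix(rnorm(n_e * t, 0, rep(spec$env_sd, each = n_e)), n_e, t)
  ge <- rmvn(n_g * n_e, rep(0, t), spec$gxe_cov)
  eps <- rmvn(n_g * n_e * spec$n_rep, rep(0, t), spec$residual_cov)

  layout <- tidyr::expand_grid(
    genotype = geno_ids,
    environment = env_tbl$environment,
    replicate = seq_len(spec$n_rep)
  ) |>
    dplyr::left_join(env_tbl, by = "environment") |>
    dplyr::select("genotype", "management", "environment", "replicate")

  gi <- match(layout$genotype, geno_ids)
  ei <- match(layout$environment, env_tbl$environment)
  cell <- (gi - 1L) * n_e + ei
  pheno <- g[gi, , drop = FALSE] + env_eff[ei, , drop = FALSE] +
    ge[cell, , drop = FALSE] + eps[, , drop = FALSE]
  colnames(pheno) <- spec$trait_names

  out <- dplyr::bind_cols(layout, as_tibble(pheno))
  truth <- dplyr::bind_cols(tibble(genotype = geno_ids),
                            as_tibble(structure(g, dimnames = list(
                              NULL, spec$trait_names))))
  attr(out, "truth") <- truth
  attr(out, "spec") <- spec
  class(out) <- c("met_trial", class(out))
  out
}

#' @export
print.met_trial <- function(x, ...) {
  cat(sprintf("<met_trial> %d records: %d genotypes x %d environments x %d replicate(s)\n",
              nrow(x), dplyr::n_distinct(x$genotype),
              dplyr::n_distinct(x$environment),
              max(x$replicate)))
  NextMethod()
}

#' True genotypic values of a simulated trial
#'
#' @param trial a trial tibble from [simulate_met()].
#' @return tibble `genotype` x trait columns of true genotypic values, or
#'   `NULL` for real data.
#' @export
trial_truth <- function(trial) attr(trial, "truth")

#' Trait columns of a trial or BLUE table
#'
#' @param data a trial or BLUE tibble.
#' @return character vector of trait column names.
#' @export
trait_names <- function(data) {
  setdiff(names(data), c("genotype", "management", "environment", "replicate"))
}

#' Mask plot records to create missingness
#'
#' Estimation assumes a balanced layout; this is the one sanctioned way to
#' make a simulated trial unbalanced (sets trait values of sampled plots to
#' `NA`).
#'
#' @param trial trial tibble.
#' @param frac fraction of plots to mask.
#' @param seed RNG seed.
#' @return the trial with masked trait values.
#' @export
mask_plots <- function(trial, frac = 0.05, seed = 1) {
  set.seed(seed)
  traits <- trait_names(trial)
  n_mask <- round_half_up(frac * nrow(trial))
  idx <- sample(nrow(trial), n_mask)
  trial[idx, traits] <- NA_real_
  inform(sprintf("masked %d of %d plot records", n_mask, nrow(trial)))
  trial
}

#' Write / read trial data as delimited text
#'
#' @param trial trial tibble.
#' @param path CSV path for the records.
#' @param truth_path optional CSV path for the truth table.
#' @return `path`, invisibly.
#' @export
write_trial_data <- function(trial, path, truth_path = NULL) {
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE)
  truth <- trial_truth(trial)
  if (!is.null(truth_path) && !is.null(truth)) {
    utils::write.csv(as.data.frame(truth), truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path, truth_path = NULL) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                   comment.char = "#"))
  if (!is.null(truth_path)) {
    attr(out, "truth") <- as_tibble(utils::read.csv(
      truth_path, stringsAsFactors = FALSE, comment.char = "#"))
  }
  class(out) <- c("met_trial", class(out))
  out
}
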