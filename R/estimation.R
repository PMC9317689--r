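#' Subset trial records by management system
#'
#' Dataset labels follow the three analysis sets used throughout: each
#' management label on its own, or `"combined"` for all environments.
#'
#' @param trial trial tibble.
#' @param subset `"combined"` or a management label present in the data.
#' @return the filtered trial tibble.
#' @export
trial_subset <- function(trial, subset = "combined") {
  if (identical(subset, "combined")) return(trial)
  out <- dplyr::filter(trial, .data$management == subset)
  if (nrow(out) == 0) {
    abort(sprintf("subset '%s' selects no records (managements: %s)",
                  subset, paste(unique(trial$management), collapse = ", ")))
  }
  out
}

is_balanced <- function(trial) {
  traits <- trait_names(trial)
  if (any(!complete.cases(trial[traits]))) return(FALSE)
  counts <- dplyr::count(trial, .data$genotype, .data$environment)
  n_env <- dplyr::n_distinct(trial$environment)
  n_gen <- dplyr::n_distinct(trial$genotype)
  nrow(counts) == n_env * n_gen && dplyr::n_distinct(counts$n) == 1
}

#' Genotype adjusted means (BLUEs)
#'
#' Fits a two-way genotype + environment fixed-effects model per trait on the
#' selected records and returns each genotype's adjusted mean (its predicted
#' value averaged over all environments in the subset). On complete balanced
#' data this equals the plain arithmetic genotype mean, and the balanced
#' closed form is used directly.
#'
#' @param trial trial tibble.
#' @param subset dataset label, see [trial_subset()].
#' @return a `blue_table`: tibble with `genotype` plus one column per trait;
#'   the dataset label is attached as `attr(, "dataset")`.
#' @export
compute_blues <- function(trial, subset = "combined") {
  dat <- trial_subset(trial, subset)
  traits <- trait_names(dat)
  obs <- dplyr::count(dat, .data$genotype, name = "n_obs")
  none <- dplyr::filter(
    dat |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(traits),
                                     ~ sum(!is.na(.x)))) |>
      tidyr::pivot_longer(-"genotype"),
    .data$value == 0)
  if (nrow(none) > 0) {
    warn(sprintf("genotypes with no data excluded: %s",
                 paste(unique(none$genotype), collapse = ", ")))
    dat <- dplyr::filter(dat, !.data$genotype %in% unique(none$genotype))
  }
  if (is_balanced(dat)) {
    out <- dat |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(traits), mean)) |>
      dplyr::arrange(.data$genotype)
  } else {
    envs <- sort(unique(dat$environment))
    genos <- sort(unique(dat$genotype))
    adj <- purrr::map(traits, function(tr) {
      d <- dat[!is.na(dat[[tr]]), c("genotype", "environment", tr)]
      names(d)[3] <- "y"
      d$genotype <- factor(d$genotype, levels = genos)
      d$environment <- factor(d$environment, levels = envs)
      fit <- lm(y ~ genotype + environment, data = d)
      grid <- expand.grid(genotype = factor(genos, levels = genos),
                          environment = factor(envs, levels = envs))
      pred <- matrix(predict(fit, newdata = grid), nrow = length(genos))
      rowMeans(pred)
    })
    names(adj) <- traits
    out <- dplyr::bind_cols(tibble(genotype = genos), as_tibble(adj))
  }
  attr(out, "dataset") <- subset
  class(out) <- c("blue_table", class(out))
  out
}

#' Variance components from the balanced two-way ANOVA
#'
#' Method-of-moments estimates from the expected mean squares of the
#' genotype x environment ANOVA with replicates:
#' `sigma2_e = MS_error`, `sigma2_ge = (MS_GE - MS_error) / r`,
#' `sigma2_g = (MS_G - MS_GE) / (r * e)`. Negative estimates are truncated
#' at zero and flagged. The subset must be complete and balanced.
#'
#' @param trial trial tibble.
#' @param traits trait columns to analyse (default: all).
#' @param subset dataset label.
#' @return tibble with one row per trait: `sigma2_g`, `sigma2_ge`,
#'   `sigma2_e`, `n_env`, `n_rep`, `truncated`.
#' @export
variance_components <- function(trial, traits = NULL, subset = "combined") {
  dat <- trial_subset(trial, subset)
  traits <- traits %||% trait_names(dat)
  if (!is_balanced(dat)) {
    abort("variance_components requires complete balanced data; mask-completion or genotype dropping must be applied first")
  }
  e <- dplyr::n_distinct(dat$environment)
  r <- max(dat$replicate)
  dat$genotype <- factor(dat$genotype)
  dat$environment <- factor(dat$environment)
  purrr::map_dfr(traits, function(tr) {
    truncated <- FALSE
    if (e == 1) {
      warn("single environment: genotype-by-environment variance inestimable, set to 0")
      fit <- aov(as.formula(paste(tr, "~ genotype")), data = dat)
      ms <- summary(fit)[[1]][["Mean Sq"]]
      s2_eps <- if (r > 1) ms[2] else 0
      s2_ge <- 0
      s2_g <- (ms[1] - s2_eps) / r
    } else {
      fit <- aov(as.formula(paste(tr, "~ genotype * environment")), data = dat)
      ms <- setNames(summary(fit)[[1]][["Mean Sq"]],
                     trimws(rownames(summary(fit)[[1]])))
      s2_eps <- if (r > 1) ms[["Residuals"]] else 0
      s2_ge <- (ms[["genotype:environment"]] - s2_eps) / r
      s2_g <- (ms[["genotype"]] - ms[["genotype:environment"]]) / (r * e)
    }
    if (s2_ge < 0 || s2_g < 0) {
      truncated <- TRUE
      inform(sprintf("trait %s: negative variance component truncated at 0", tr))
    }
    tibble(trait = tr,
           sigma2_g = max(s2_g, 0), sigma2_ge = max(s2_ge, 0),
           sigma2_e = s2_eps, n_env = e, n_rep = r, truncated = truncated)
  })
}

#' Broad-sense heritability on the entry-mean basis
#'
#' `H^2 = sigma2_g / (sigma2_g + sigma2_ge / e + sigma2_e / (e * r))`, the
#' repeatability of a genotype's mean across `e` environments and `r`
#' replicates.
#'
#' @param vc variance-component tibble from [variance_components()].
#' @return named numeric vector of heritabilities in `[0, 1]`, one per trait.
#' @export
broad_sense_heritability <- function(vc) {
  denom <- vc$sigma2_g + vc$sigma2_ge / vc$n_env +
    vc$sigma2_e / (vc$n_env * vc$n_rep)
  h2 <- ifelse(denom > 0, vc$sigma2_g / denom, 0)
  if (any(denom == 0)) warn("all variance components zero: heritability defined as 0")
  setNames(h2, vc$trait)
}

#' Genetic and phenotypic covariance matrices
#'
#' Multivariate analogue of [variance_components()] built from the mean
#' cross-product (MCP) matrices of the balanced two-way MANOVA:
#' `C = (MCP_G - MCP_GE) / (r * e)` is the genetic covariance and
#' `P = MCP_G / (r * e)` the phenotypic covariance of genotype entry means
#' (the basis on which selection indices are applied to BLUEs). Both are
#' passed through [ensure_psd()]; `P` additionally gets a small eigenvalue
#' floor so it is invertible.
#'
#' @param trial trial tibble (balanced subset, at least two traits).
#' @param subset dataset label.
#' @param floor eigenvalue floor passed to [ensure_psd()] for `P` (scaled by
#'   the mean diagonal); `C` is floored at zero.
#' @return a `cov_pair` object: list with matrices `C` and `P`, `traits`,
#'   `dataset`, `basis`, `n_env`, `n_rep`.
#' @export
covariance_matrices <- function(trial, subset = "combined", floor = 1e-8) {
  dat <- trial_subset(trial, subset)
  traits <- trait_names(dat)
  if (length(traits) < 2) abort("need at least two traits")
  if (!is_balanced(dat)) abort("covariance_matrices requires complete balanced data")
  e <- dplyr::n_distinct(dat$environment)
  r <- max(dat$replicate)
  g <- dplyr::n_distinct(dat$genotype)
  y <- as.matrix(dat[traits])
  gm <- rowsum(y, dat$genotype) / (e * r)              # genotype means
  em <- rowsum(y, dat$environment) / (g * r)           # environment means
  cm <- rowsum(y, paste(dat$genotype, dat$environment)) / r  # cell means
  grand <- colMeans(y)

  dev_g <- sweep(gm, 2, grand)
  scp_g <- r * e * crossprod(dev_g)
  key <- unique(paste(dat$genotype, dat$environment))
  cg <- sub(" .*", "", rownames(cm))
  ce <- sub(".* ", "", rownames(cm))
  dev_ge <- cm - gm[cg, , drop = FALSE] - em[ce, , drop = FALSE] +
    matrix(grand, nrow(cm), length(traits), byrow = TRUE)
  scp_ge <- r * crossprod(dev_ge)
  mcp_g <- scp_g / (g - 1)
  mcp_ge <- scp_ge / ((g - 1) * (e - 1))

  C <- ensure_psd((mcp_g - mcp_ge) / (r * e), floor = 0)
  P <- (mcp_g) / (r * e)
  P <- ensure_psd(P, floor = floor * mean(diag(P)))
  if (kappa(P) > 1e12) {
    abort("phenotypic covariance P is numerically singular after conditioning")
  }
  dimnames(C) <- dimnames(P) <- list(traits, traits)
  structure(
    list(C = C, P = P, traits = traits, dataset = subset,
         basis = "entry-mean", n_env = e, n_rep = r),
    class = "cov_pair"
  )
}

#' @export
print.cov_pair <- function(x, ...) {
  cat(sprintf("<cov_pair> %d traits, dataset '%s' (%s basis, e = %d, r = %d)\n",
              length(x$traits), x$dataset, x$basis, x$n_env, x$n_rep))
  cat("genetic covariance C:\n"); print(round(x$C, 4))
  cat("phenotypic covariance P:\n"); print(round(x$P, 4))
  invisible(x)
}

#' @export
tidy.cov_pair <- function(x, ...) {
  tidyr::expand_grid(trait1 = x$traits, trait2 = x$traits) |>
    dplyr::mutate(genetic = as.vector(t(x$C)),
                  phenotypic = as.vector(t(x$P)))
}

#' @export
glance.cov_pair <- function(x, ...) {
  tibble(n_traits = length(x$traits), dataset = x$dataset,
         basis = x$basis, n_env = x$n_env, n_rep = x$n_rep,
         kappa_P = kappa(x$P))
}

#' Repair a covariance matrix to positive semi-definiteness
#'
#' Eigenvalues below `floor` are raised to `floor`; eigenvectors and all
#' eigenvalues above the floor are untouched, so a well-conditioned matrix
#' passes through unchanged.
#'
#' @param M square symmetric matrix.
#' @param floor minimum admissible eigenvalue (>= 0).
#' @return the repaired symmetric matrix.
#' @export
ensure_psd <- function(M, floor = 1e-8) {
  if (!is_symmetric(M)) abort("ensure_psd requires a symmetric matrix")
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(ev$values) >= floor) return((M + t(M)) / 2)
  inform(sprintf("PSD repair: %d eigenvalue(s) below %.3g floored",
                 sum(ev$values < floor), floor))
  out <- ev$vectors %*% diag(pmax(ev$values, floor), nrow(M)) %*% t(ev$vectors)
  dimnames(out) <- dimnames(M)
  (out + t(out)) / 2
}
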