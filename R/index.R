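#' Variance of the net genetic merit
#'
#' The net merit of a genotype is `H = w'g`, the economically weighted sum of
#' its true genotypic values; its variance is `w' C w`.
#'
#' @param C genetic covariance matrix (symmetric PSD).
#' @param w numeric vector of economic weights (merit units per trait unit).
#' @return scalar `w' C w >= 0`.
#' @export
net_merit_variance <- function(C, w) {
  w <- align_weights(w, C)
  if (!is_symmetric(C)) abort("C must be symmetric")
  drop(t(w) %*% C %*% w)
}

align_weights <- function(w, C) {
  t <- nrow(C)
  if (length(w) != t) {
    abort(sprintf("weight vector has length %d but C is %d x %d",
                  length(w), t, t))
  }
  if (!is.null(names(w)) && !is.null(rownames(C))) {
    if (!setequal(names(w), rownames(C))) {
      abort("weight names do not match trait names of C")
    }
    w <- w[rownames(C)]
  }
  as.numeric(w)
}

#' Smith LPSI coefficients
#'
#' Solves `P b = C w` for the index coefficients that maximize the
#' correlation between the index `I = b'y` and the net merit `H = w'g`.
#'
#' @param P phenotypic covariance matrix (invertible).
#' @param C genetic covariance matrix.
#' @param w economic weights.
#' @return numeric coefficient vector `b`, named by trait when `C` carries
#'   trait names.
#' @export
lpsi_coefficients <- function(P, C, w) {
  w <- align_weights(w, C)
  if (any(dim(P) != dim(C))) abort("P and C must have the same dimension")
  b <- tryCatch(solve(P, C %*% w),
                error = function(e) {
                  abort(paste0("P is singular; condition it first, e.g. ",
                               "ensure_psd(P, floor = 1e-8 * mean(diag(P)))"))
                })
  setNames(drop(b), rownames(C))
}

#' Mallard contrast matrix for predetermined proportional gains
#'
#' For desired gains `d = (d_1, ..., d_r)` on the restricted traits, builds
#' the `(r-1) x r` contrast matrix `D'` whose row `q` carries `d_r` in
#' column `q` and `-d_q` in column `r`. Every row annihilates `d`
#' (`D'd = 0`), so constraining `D' U' C b = 0` forces the restricted
#' traits' gains to be proportional to `d` without pinning their magnitude.
#'
#' @param d numeric vector of predetermined proportional gains (length `r`).
#' @return `(r-1) x r` matrix; a `0 x 1` matrix when `r = 1` (a single
#'   proportional restriction imposes no contrast).
#' @export
mallard_D <- function(d) {
  if (any(!is.finite(d)) || all(d == 0)) abort("d must be finite and nonzero")
  r <- length(d)
  if (r == 1) return(matrix(numeric(0), 0, 1))
  Dt <- matrix(0, r - 1, r)
  for (q in seq_len(r - 1)) {
    Dt[q, q] <- d[r]
    Dt[q, r] <- -d[q]
  }
  Dt
}

#' Define a restriction on expected genetic gains
#'
#' A null restriction (Kempthorne-Nordskog) forces the expected gain of the
#' named traits to zero; a proportional restriction (Mallard) forces the
#' gains of the named traits to be proportional to desired gains `d`.
#'
#' @param restricted character vector of restricted trait names (or integer
#'   positions).
#' @param traits full ordered trait vector of the analysis.
#' @param d optional desired gains, one per restricted trait; supplying `d`
#'   selects proportional mode.
#' @return a `restriction_spec` with the indicator matrix `U_t` (`U'`,
#'   `r x t`), the mode and `d`.
#' @export
restriction_spec <- function(restricted, traits, d = NULL) {
  if (is.numeric(restricted)) restricted <- traits[restricted]
  if (!all(restricted %in% traits)) {
    abort("restricted traits must be a subset of the trait list")
  }
  if (anyDuplicated(restricted)) abort("duplicated restricted trait")
  r <- length(restricted)
  if (r >= length(traits)) abort("must leave at least one trait unrestricted")
  if (r < 1) abort("no restricted trait given; use restriction = NULL for the LPSI")
  Ut <- matrix(0, r, length(traits), dimnames = list(restricted, traits))
  Ut[cbind(seq_len(r), match(restricted, traits))] <- 1
  mode <- if (is.null(d)) "null" else "proportional"
  if (mode == "proportional" && length(d) != r) {
    abort("d must have one desired gain per restricted trait")
  }
  structure(list(U_t = Ut, restricted = restricted, traits = traits,
                 mode = mode, d = d),
            class = "restriction_spec")
}

#' @export
print.restriction_spec <- function(x, ...) {
  cat(sprintf("<restriction_spec> %s mode: %s\n", x$mode,
              if (x$mode == "null") {
                paste0(x$restricted, " = 0", collapse = ", ")
              } else {
                paste0(x$restricted, " ~ ", x$d, collapse = ", ")
              }))
  invisible(x)
}

scenario_label <- function(restriction) {
  if (is.null(restriction)) return("LPSI")
  if (restriction$mode == "null") {
    sprintf("RLPSI (%s = 0)", paste(restriction$restricted, collapse = ", "))
  } else {
    sprintf("RLPSI (%s ~ %s)", paste(restriction$restricted, collapse = ", "),
            paste(restriction$d, collapse = ", "))
  }
}

#' Constrained (restricted) selection-index coefficients
#'
#' Computes the Smith coefficients `beta = P^{-1} C w` and projects them onto
#' the constraint set: with `Psi' = U'C`, `M' = D'Psi'` (null mode:
#' `M' = U'C`), `Q = P^{-1} M (M' P^{-1} M)^{-1} M'` and `K = I - Q`, the
#' constrained coefficients are `b = K beta`. With no restriction `b = beta`
#' exactly, so the LPSI is the unconstrained special case.
#'
#' @param P phenotypic covariance matrix.
#' @param C genetic covariance matrix.
#' @param w economic weights.
#' @param restriction a [restriction_spec()], or `NULL` for the plain LPSI.
#' @return an `index_model`: list with `scenario`, coefficients `b`, the
#'   unconstrained `beta`, and the `(C, P, w, restriction)` provenance.
#' @export
restricted_coefficients <- function(P, C, w, restriction = NULL) {
  w <- align_weights(w, C)
  beta <- lpsi_coefficients(P, C, w)
  if (is.null(restriction)) {
    b <- beta
  } else {
    stopifnot(inherits(restriction, "restriction_spec"))
    Psi_t <- restriction$U_t %*% C
    M_t <- if (restriction$mode == "null") {
      Psi_t
    } else {
      mallard_D(restriction$d) %*% Psi_t
    }
    if (nrow(M_t) == 0) {
      b <- beta
    } else {
      M <- t(M_t)
      PinvM <- solve(P, M)
      gram <- M_t %*% PinvM
      if (kappa(gram) > 1e12) {
        abort("restrictions are redundant (rank-deficient M); drop one")
      }
      Q <- PinvM %*% solve(gram, M_t)
      K <- diag(nrow(P)) - Q
      b <- setNames(drop(K %*% beta), names(beta))
    }
  }
  structure(
    list(scenario = scenario_label(restriction), b = b, beta = beta,
         C = C, P = P, w = setNames(w, rownames(C)),
         restriction = restriction),
    class = "index_model"
  )
}

#' @rdname restricted_coefficients
#' @export
lpsi <- function(P, C, w) restricted_coefficients(P, C, w, restriction = NULL)

#' @export
print.index_model <- function(x, ...) {
  cat(sprintf("<index_model> %s\n", x$scenario))
  print(round(x$b, 5))
  invisible(x)
}

#' @export
tidy.index_model <- function(x, ...) {
  tibble(trait = names(x$b) %||% paste0("trait", seq_along(x$b)),
         weight = as.numeric(x$w),
         coefficient = as.numeric(x$b))
}

#' Index scores for each genotype
#'
#' `I_i = b' y_i` applied to a BLUE table. Ranking is invariant under adding
#' a common constant vector to every genotype's BLUEs.
#'
#' @param model an `index_model`.
#' @param blues a BLUE table from [compute_blues()] (or any tibble with a
#'   `genotype` column and the model's trait columns).
#' @return tibble with `genotype` and `score`.
#' @export
index_values <- function(model, blues) {
  traits <- names(model$b)
  missing <- setdiff(traits, names(blues))
  if (length(missing) > 0) {
    abort(sprintf("BLUE table lacks trait column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  y <- as.matrix(blues[traits])
  tibble(genotype = blues$genotype,
         score = drop(y %*% model$b))
}

#' Standardized selection intensity
#'
#' For truncation selection of the top fraction `p`, the selection intensity
#' is the mean standardized deviation of the selected group. With `n = Inf`
#' (the default) this is the classical normal truncation value
#' `k = phi(z_p) / p` with `z_p` the upper-`p` quantile. With finite `n`,
#' the exact expectation of the mean of the top `m = round(p n)` standard
#' normal order statistics is computed by numerical integration, which is
#' noticeably smaller than the infinite-population value for small panels.
#'
#' @param p selected fraction, in (0, 1).
#' @param n population size, or `Inf` for the asymptotic value.
#' @return scalar intensity `k`.
#' @export
selection_intensity <- function(p, n = Inf) {
  if (!is.finite(p) || p <= 0 || p >= 1) abort("p must lie strictly in (0, 1)")
  if (is.infinite(n)) {
    z <- qnorm(1 - p)
    return(dnorm(z) / p)
  }
  m <- max(1L, round_half_up(p * n))
  ev_order <- function(j) {
    # E[Z_(j:n)] via the order-statistic density
    f <- function(z) {
      z * exp(lchoose(n, j) + log(j) + (j - 1) * pnorm(z, log.p = TRUE) +
                (n - j) * pnorm(z, lower.tail = FALSE, log.p = TRUE)) * dnorm(z)
    }
    integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
  }
  mean(vapply(seq(n - m + 1, n), ev_order, numeric(1)))
}

#' Selection parameters of a fitted index
#'
#' Computes, for the index `I = b'y` and merit `H = w'g`:
#' `sigma_I = sqrt(b'Pb)`, `sigma_H = sqrt(w'Cw)`,
#' `rho_HI = w'Cb / (sigma_H sigma_I)`, the response to selection
#' `R = k sigma_H rho_HI`, and the expected genetic gain per trait
#' `E = k C b / sigma_I`. Under a null restriction the restricted entries of
#' `Cb` — hence of `E` — are zero.
#'
#' @param model an `index_model`.
#' @param k selection intensity, see [selection_intensity()].
#' @return an `index_evaluation` with fields `scenario`, `w`, `b`, `R`,
#'   `E`, `rho_HI`, `sigma_I`, `sigma_H`, `k`.
#' @export
evaluate_index <- function(model, k = selection_intensity(0.10)) {
  b <- as.numeric(model$b)
  w <- as.numeric(model$w)
  C <- model$C; P <- model$P
  sigma_I <- sqrt(max(drop(t(b) %*% P %*% b), 0))
  sigma_H <- sqrt(max(drop(t(w) %*% C %*% w), 0))
  if (sigma_I <= 0) abort("index has zero variance; check restrictions and P")
  if (sigma_H <= 0) abort("net merit has zero variance; check C and w")
  Cb <- drop(C %*% b)
  rho <- drop(t(w) %*% Cb) / (sigma_H * sigma_I)
  structure(
    list(scenario = model$scenario,
         w = model$w, b = model$b,
         R = k * sigma_H * rho,
         E = setNames(k * Cb / sigma_I, names(model$b)),
         rho_HI = rho, sigma_I = sigma_I, sigma_H = sigma_H, k = k),
    class = "index_evaluation"
  )
}

#' @export
print.index_evaluation <- function(x, ...) {
  cat(sprintf("<index_evaluation> %s (k = %.3f)\n", x$scenario, x$k))
  cat(sprintf("  response R = %.3f, rho_HI = %.3f, sigma_I = %.3f, sigma_H = %.3f\n",
              x$R, x$rho_HI, x$sigma_I, x$sigma_H))
  cat("  expected gains E:\n")
  print(round(x$E, 4))
  invisible(x)
}

#' @export
tidy.index_evaluation <- function(x, ...) {
  tibble(trait = names(x$E) %||% paste0("trait", seq_along(x$E)),
         weight = as.numeric(x$w),
         coefficient = as.numeric(x$b),
         expected_gain = as.numeric(x$E))
}

#' @export
glance.index_evaluation <- function(x, ...) {
  tibble(scenario = x$scenario, response = x$R, rho_HI = x$rho_HI,
         sigma_I = x$sigma_I, sigma_H = x$sigma_H, k = x$k)
}
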