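#' Economic-weight grids
#'
#' A weight grid is the Cartesian product of per-trait level lists, one row
#' per candidate weight vector. `default_grid()` is the 2304-combination
#' wheat grid: maturity and height each in \{-1, -5, -10, -15\} (negative,
#' to push toward earlier and shorter plants), grain yield in
#' \{1, 10, 20, ..., 150\} (16 levels) and GPC in \{1, 10, 20, ..., 80\}
#' (9 levels), so 4 x 4 x 16 x 9 = 2304.
#'
#' @param levels named list of per-trait weight levels, in trait order.
#' @return tibble with one weight column per trait and class `weight_grid`.
#' @export
weight_grid <- function(levels) {
  if (is.null(names(levels)) || any(!nzchar(names(levels)))) {
    abort("levels must be a named list (one entry per trait)")
  }
  if (any(vapply(levels, anyDuplicated, integer(1)) > 0)) {
    abort("duplicated level within a trait")
  }
  out <- tidyr::expand_grid(!!!levels)
  class(out) <- c("weight_grid", class(out))
  out
}

#' @rdname weight_grid
#' @export
default_grid <- function() {
  weight_grid(list(
    maturity = c(-1, -5, -10, -15),
    height = c(-1, -5, -10, -15),
    yield = c(1, seq(10, 150, by = 10)),
    gpc = c(1, seq(10, 80, by = 10))
  ))
}

#' Shortlisted benchmark weights for the wheat analysis
#'
#' The five economic-weight vectors (maturity, height, yield, GPC) retained
#' for final wheat analyses after sweeping the full grid; shipped as a
#' convenience for reproduction runs.
#'
#' @return a 5-row [weight_grid()]-shaped tibble.
#' @export
shortlisted_weights <- function() {
  out <- tibble(
    maturity = c(-1, -1, -1, -5, -5),
    height = c(-1, -1, -1, -1, -1),
    yield = c(120, 130, 150, 130, 150),
    gpc = c(70, 70, 70, 70, 70)
  )
  class(out) <- c("weight_grid", class(out))
  out
}

weight_label <- function(grid) {
  apply(as.matrix(grid), 1, function(r) {
    paste0("w(", paste(format(r, trim = TRUE), collapse = ", "), ")")
  })
}

#' Evaluate every weight vector under every selection scenario
#'
#' For each scenario the map from weight vector to constrained coefficients
#' is linear (`b = K P^{-1} C w`), so whole grids are evaluated with a
#' handful of matrix products. Cells whose index computation fails are kept
#' as rows of `NA` and flagged in `ok`.
#'
#' @param grid a [weight_grid()]; column order must match the trait order of
#'   `C`/`P`.
#' @param C,P genetic and phenotypic covariance matrices.
#' @param scenarios named list; each element `NULL` (plain LPSI) or a
#'   [restriction_spec()].
#' @param k selection intensity.
#' @return a `sweep_result` tibble: weight columns prefixed `w_`, then
#'   `scenario`, per-trait expected gains prefixed `E_`, `response`,
#'   `rho_HI`, `ok`.
#' @export
evaluate_grid <- function(grid, C, P,
                          scenarios = list(LPSI = NULL),
                          k = selection_intensity(0.10)) {
  if (nrow(grid) == 0) abort("empty weight grid")
  traits <- rownames(C) %||% names(grid)
  if (!setequal(names(grid), traits)) {
    abort("grid columns must match the trait names of C")
  }
  W <- t(as.matrix(grid[traits]))      # t x n_weights
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, scenario_label, character(1))
  }
  rows <- purrr::imap(scenarios, function(restr, sc_name) {
    res <- tryCatch({
      # b = K P^{-1} C w for every w at once
      ref <- restricted_coefficients(P, C, W[, 1], restr)
      A <- if (is.null(restr)) {
        solve(P, C)
      } else {
        # recover the linear map from the reference solve: K P^{-1} C
        Psi_t <- restr$U_t %*% C
        M_t <- if (restr$mode == "null") Psi_t else mallard_D(restr$d) %*% Psi_t
        PinvC <- solve(P, C)
        if (nrow(M_t) == 0) PinvC else {
          M <- t(M_t)
          PinvM <- solve(P, M)
          (diag(nrow(P)) - PinvM %*% solve(M_t %*% PinvM, M_t)) %*% PinvC
        }
      }
      B <- A %*% W                                   # t x n_weights
      sigma_I <- sqrt(pmax(colSums(B * (P %*% B)), 0))
      sigma_H <- sqrt(pmax(colSums(W * (C %*% W)), 0))
      CB <- C %*% B
      wCb <- colSums(W * CB)
      rho <- wCb / (sigma_H * sigma_I)
      E <- sweep(CB, 2, sigma_I, "/") * k            # t x n_weights
      lbl <- scenario_label(restr)
      dplyr::bind_cols(
        setNames(as_tibble(as.matrix(grid[traits])), paste0("w_", traits)),
        tibble(scenario = lbl),
        setNames(as_tibble(t(E)), paste0("E_", traits)),
        tibble(response = k * sigma_H * rho, rho_HI = rho, ok = TRUE)
      )
    }, error = function(e) {
      warn(sprintf("scenario '%s' failed: %s", sc_name, conditionMessage(e)))
      dplyr::bind_cols(
        setNames(as_tibble(as.matrix(grid[traits])), paste0("w_", traits)),
        tibble(scenario = sc_name),
        setNames(as_tibble(matrix(NA_real_, nrow(grid), length(traits))),
                 paste0("E_", traits)),
        tibble(response = NA_real_, rho_HI = NA_real_, ok = FALSE)
      )
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "traits") <- traits
  attr(out, "k") <- k
  class(out) <- c("sweep_result", class(out))
  out
}

#' Compare weight levels of one trait by one-way ANOVA
#'
#' Treats the chosen trait's weight as a factor and compares a selection
#' parameter (an expected-gain column, `response` or `rho_HI`) across its
#' levels, the per-factor analysis used when screening a large grid. A
#' factorial model over all weight factors is available via
#' `factorial = TRUE`.
#'
#' @param rows a `sweep_result` (optionally pre-filtered by scenario).
#' @param response column to compare, e.g. `"E_yield"`.
#' @param factor weight column used as the factor, e.g. `"w_yield"`.
#' @param tukey add pairwise Tukey HSD comparisons.
#' @param factorial fit all `w_` columns as additive factors instead.
#' @return a `weight_anova`: list with `anova` (term, df, F, p), `means`
#'   (per-level means of the response), optional `tukey`.
#' @export
compare_weight_levels <- function(rows, response, factor,
                                  tukey = FALSE, factorial = FALSE) {
  if (!response %in% names(rows)) abort(sprintf("no column '%s'", response))
  facs <- if (factorial) grep("^w_", names(rows), value = TRUE) else factor
  if (!all(facs %in% names(rows))) abort("factor column not found")
  d <- rows[stats::complete.cases(rows[c(response, facs)]), , drop = FALSE]
  d <- as.data.frame(d)
  for (f in facs) d[[f]] <- base::factor(d[[f]])
  if (any(vapply(d[facs], nlevels, integer(1)) < 2) ||
      min(table(d[[facs[1]]])) < 2) {
    abort("need at least 2 levels with at least 2 rows each")
  }
  fml <- as.formula(paste(response, "~", paste(facs, collapse = " + ")))
  fit <- aov(fml, data = d)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  anova_tbl <- tibble(term = terms, df = sm$Df, sumsq = sm$`Sum Sq`,
                      meansq = sm$`Mean Sq`, statistic = sm$`F value`,
                      p.value = sm$`Pr(>F)`)
  # all rows identical across levels: no between-variation, report F = 0;
  # between-variation with zero within-variation: F undefined
  resid_ms <- anova_tbl$meansq[anova_tbl$term == "Residuals"]
  if (length(resid_ms) == 1 && resid_ms <= .Machine$double.eps) {
    idx <- anova_tbl$term != "Residuals"
    anova_tbl$statistic[idx] <- ifelse(
      anova_tbl$meansq[idx] <= .Machine$double.eps, 0, NA_real_)
    anova_tbl$p.value[idx] <- NA_real_
    if (any(is.na(anova_tbl$statistic[idx]))) {
      warn("zero within-level variance: F undefined")
    }
  }
  means <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(facs[1]))) |>
    dplyr::summarise(mean = mean(.data[[response]]), n = dplyr::n(),
                     .groups = "drop") |>
    setNames(c("level", "mean", "n"))
  out <- list(anova = anova_tbl, means = means, response = response,
              factor = facs)
  if (tukey) {
    out$tukey <- as_tibble(TukeyHSD(fit)[[facs[1]]], rownames = "contrast")
  }
  structure(out, class = "weight_anova")
}

#' @export
print.weight_anova <- function(x, ...) {
  cat(sprintf("<weight_anova> %s ~ %s\n", x$response,
              paste(x$factor, collapse = " + ")))
  print(x$anova)
  invisible(x)
}

#' @export
tidy.weight_anova <- function(x, ...) x$anova

#' @export
glance.weight_anova <- function(x, ...) {
  i <- which(x$anova$term != "Residuals")[1]
  tibble(response = x$response, factor = x$factor[1],
         statistic = x$anova$statistic[i], p.value = x$anova$p.value[i],
         df = x$anova$df[i], df.residual = x$anova$df[x$anova$term == "Residuals"])
}

#' Thresholds for shortlisting economic weights
#'
#' @param max_gain named upper bounds on expected gains (e.g. maturity and
#'   height must not increase too much).
#' @param min_gain named lower bounds on expected gains (e.g. yield, GPC).
#' @param min_response minimum response to selection.
#' @param min_rho minimum correlation between index and merit.
#' @return a `selection_criteria` list.
#' @export
selection_criteria <- function(max_gain = NULL, min_gain = NULL,
                               min_response = -Inf, min_rho = -Inf) {
  structure(list(max_gain = max_gain, min_gain = min_gain,
                 min_response = min_response, min_rho = min_rho),
            class = "selection_criteria")
}

#' Shortlist the best economic weights
#'
#' Filters sweep rows by [selection_criteria()], then ranks the survivors by
#' the target trait's expected gain (descending) with deterministic
#' tie-breaks: higher `rho_HI`, then higher `response`, then lexicographic
#' weight order. The result is invariant to the input row order.
#'
#' @param rows a `sweep_result`, usually filtered to one scenario.
#' @param criteria a [selection_criteria()].
#' @param rank_by gain column used for ranking, e.g. `"E_gpc"`.
#' @param top_n maximum number of weight vectors returned.
#' @return tibble of the ranked surviving rows (up to `top_n`).
#' @export
select_best_weights <- function(rows, criteria, rank_by, top_n = 5) {
  if (nrow(rows) == 0) abort("no sweep rows supplied")
  keep <- rep(TRUE, nrow(rows))
  for (tr in names(criteria$max_gain)) {
    keep <- keep & rows[[paste0("E_", tr)]] <= criteria$max_gain[[tr]]
  }
  for (tr in names(criteria$min_gain)) {
    keep <- keep & rows[[paste0("E_", tr)]] >= criteria$min_gain[[tr]]
  }
  keep <- keep & rows$response >= criteria$min_response &
    rows$rho_HI >= criteria$min_rho
  keep[is.na(keep)] <- FALSE
  out <- rows[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warn("no weight combination satisfies the criteria")
    return(out)
  }
  wcols <- grep("^w_", names(out), value = TRUE)
  ord <- do.call(order, c(
    list(-out[[rank_by]], -out$rho_HI, -out$response),
    lapply(wcols, function(cc) out[[cc]])
  ))
  utils::head(out[ord, , drop = FALSE], top_n)
}
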