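#' Truncation selection of the top fraction
#'
#' Selects the `m = round(p * n)` (half-up) highest-scoring genotypes. Ties
#' exactly at the cut score are all included, so the set may exceed `m`;
#' the expansion is reported. Selection is invariant under any strictly
#' monotone transform of the scores.
#'
#' @param scores tibble with columns `genotype` and `score` (e.g. from
#'   [index_values()]).
#' @param p selected fraction in (0, 1).
#' @param direction `"max"` (default) or `"min"`.
#' @param context optional named list recorded with the set (dataset,
#'   scenario, weight label, ...).
#' @return a `selection_set`: list with `genotypes`, `p`, `m_nominal`,
#'   `expanded`, `context`, `universe`.
#' @export
select_top_fraction <- function(scores, p, direction = c("max", "min"),
                                context = list()) {
  direction <- match.arg(direction)
  if (p <= 0 || p >= 1) abort("p must lie strictly in (0, 1)")
  if (any(!is.finite(scores$score))) abort("scores must be finite")
  n <- nrow(scores)
  m <- round_half_up(p * n)
  if (m < 1) {
    warn("p * n < 1: selecting a single genotype")
    m <- 1L
  }
  s <- if (direction == "max") -scores$score else scores$score
  ord <- order(s, scores$genotype)
  cut <- s[ord[m]]
  sel <- ord[seq_len(m)]
  extra <- setdiff(which(s == cut), sel)
  if (length(extra) > 0) {
    inform(sprintf("tie at the cut: selection expanded from %d to %d",
                   m, m + length(extra)))
    sel <- c(sel, extra)
  }
  structure(
    list(genotypes = sort(scores$genotype[sel]), p = p, m_nominal = m,
         expanded = length(extra) > 0, direction = direction,
         context = context, universe = sort(scores$genotype)),
    class = "selection_set"
  )
}

#' @export
print.selection_set <- function(x, ...) {
  ctx <- if (length(x$context)) {
    paste0(" [", paste(names(x$context), unlist(x$context),
                       sep = "=", collapse = ", "), "]")
  } else ""
  cat(sprintf("<selection_set> %d of %d genotypes (p = %.2f%s)%s\n",
              length(x$genotypes), length(x$universe), x$p,
              if (x$expanded) ", tie-expanded" else "", ctx))
  invisible(x)
}

#' @export
tidy.selection_set <- function(x, ...) {
  tibble(genotype = x$universe, selected = x$universe %in% x$genotypes)
}

#' Single-trait truncation selection
#'
#' The baseline every index is compared against: select on one trait's
#' BLUEs alone, ignoring all others.
#'
#' @param blues a BLUE table.
#' @param trait trait column to select on.
#' @param p selected fraction.
#' @param direction `"max"` for upward selection, `"min"` for e.g. earliness.
#' @param context optional context list.
#' @return a `selection_set`.
#' @export
single_trait_selection <- function(blues, trait, p,
                                   direction = c("max", "min"),
                                   context = list()) {
  direction <- match.arg(direction)
  if (!trait %in% names(blues)) abort(sprintf("no trait column '%s'", trait))
  context <- utils::modifyList(list(trait = trait), context)
  select_top_fraction(
    tibble(genotype = blues$genotype, score = blues[[trait]]),
    p = p, direction = direction, context = context
  )
}

#' Realized selection differential per trait
#'
#' `mean(selected) - mean(population)` for each trait column of `values`.
#' Applied to BLUEs this is the phenotypic differential; applied to the
#' truth table of a simulated trial it is the realized genetic gain, the
#' quantity predicted by the expected-gain vector `E`.
#'
#' @param selected a `selection_set`.
#' @param values tibble with `genotype` plus trait columns (BLUEs or truth).
#' @param traits trait columns to report (default: all).
#' @return tibble with `trait`, `selected_mean`, `population_mean`,
#'   `differential`.
#' @export
realized_differential <- function(selected, values, traits = NULL) {
  traits <- traits %||% setdiff(names(values), "genotype")
  sel <- values$genotype %in% selected$genotypes
  if (!any(sel)) abort("selection is empty on this table")
  if (all(sel)) abort("selection covers the whole population: differential undefined")
  purrr::map_dfr(traits, function(tr) {
    tibble(trait = tr,
           selected_mean = mean(values[[tr]][sel]),
           population_mean = mean(values[[tr]]),
           differential = mean(values[[tr]][sel]) - mean(values[[tr]]))
  })
}

#' Cross-scenario consistency of selected genotypes
#'
#' Builds the genotype x context membership table over a list of selection
#' sets and extracts the consensus set: genotypes selected under at least
#' `min_weights` distinct weight vectors within at least `min_scenarios`
#' scenarios. A genotype counts as selected for a (scenario, weight) pair
#' if it was selected in any dataset under that pair. Consensus sets are
#' nested: tightening either threshold can only shrink them.
#'
#' @param sets list of `selection_set`s whose `context` carries `scenario`
#'   and `weight` labels (and optionally `dataset`).
#' @param min_weights minimum distinct weight vectors per scenario.
#' @param min_scenarios minimum qualifying scenarios.
#' @return a `consistency_report`: list with `membership` (long tibble),
#'   `counts` (per genotype x scenario weight counts), `consensus`
#'   (character vector), `union` and the thresholds.
#' @export
consistency_analysis <- function(sets, min_weights, min_scenarios) {
  if (length(sets) == 0) abort("no selection sets supplied")
  uni <- lapply(sets, `[[`, "universe")
  if (length(unique(lapply(uni, paste, collapse = "\r"))) != 1) {
    abort("selection sets do not share one genotype universe")
  }
  membership <- purrr::map_dfr(sets, function(s) {
    tibble(genotype = s$genotypes,
           scenario = s$context$scenario %||% "scenario",
           weight = s$context$weight %||% "weight",
           dataset = s$context$dataset %||% "dataset")
  })
  counts <- membership |>
    dplyr::distinct(.data$genotype, .data$scenario, .data$weight) |>
    dplyr::count(.data$genotype, .data$scenario, name = "n_weights")
  qualifying <- counts |>
    dplyr::filter(.data$n_weights >= min_weights) |>
    dplyr::count(.data$genotype, name = "n_scenarios")
  consensus <- sort(qualifying$genotype[qualifying$n_scenarios >= min_scenarios])
  structure(
    list(membership = membership, counts = counts, consensus = consensus,
         union = sort(unique(membership$genotype)),
         min_weights = min_weights, min_scenarios = min_scenarios,
         universe = uni[[1]]),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "<consistency_report> %d genotypes selected at least once; %d in consensus (>= %d weights in >= %d scenarios)\n",
    length(x$union), length(x$consensus), x$min_weights, x$min_scenarios))
  if (length(x$consensus)) {
    cat("  consensus:", paste(x$consensus, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.consistency_report <- function(x, ...) {
  x$counts |>
    dplyr::mutate(consensus = .data$genotype %in% x$consensus)
}

#' @export
glance.consistency_report <- function(x, ...) {
  tibble(n_union = length(x$union), n_consensus = length(x$consensus),
         min_weights = x$min_weights, min_scenarios = x$min_scenarios)
}

#' Overlap between two selection sets
#'
#' Symmetric in its arguments; useful for comparing single-trait selections
#' on negatively correlated traits.
#'
#' @param a,b `selection_set`s.
#' @return tibble with intersection size, union size and Jaccard index.
#' @export
selection_overlap <- function(a, b) {
  inter <- length(intersect(a$genotypes, b$genotypes))
  uni <- length(union(a$genotypes, b$genotypes))
  tibble(n_a = length(a$genotypes), n_b = length(b$genotypes),
         n_common = inter, n_union = uni,
         jaccard = if (uni > 0) inter / uni else NA_real_)
}
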