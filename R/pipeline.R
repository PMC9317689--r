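#' Write / read pipeline artifacts
#'
#' All pipeline tables are comma-delimited UTF-8 with a `#`-prefixed header
#' recording the package version, seed and config hash, so any artifact is
#' self-describing and stage re-runs are byte-reproducible.
#'
#' @param x data frame (or matrix with row/col names for
#'   `write_matrix_artifact`).
#' @param path file path.
#' @param meta named list written into the header (seed, config hash, ...).
#' @return `path` invisibly.
#' @export
write_artifact <- function(x, path, meta = list()) {
  hdr <- c(
    sprintf("# metsel %s", as.character(utils::packageVersion("metsel"))),
    sprintf("# %s: %s", names(meta), vapply(meta, as.character, character(1)))
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(as.data.frame(x), con, sep = ",", row.names = FALSE,
              quote = TRUE, qmethod = "double")
  invisible(path)
}

#' @rdname write_artifact
#' @export
read_artifact <- function(path) {
  as_tibble(utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE))
}

#' @rdname write_artifact
#' @export
write_matrix_artifact <- function(x, path, meta = list()) {
  df <- data.frame(trait = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  write_artifact(df, path, meta)
}

#' @rdname write_artifact
#' @export
read_matrix_artifact <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

parse_scenarios <- function(labels, traits) {
  out <- lapply(labels, function(s) {
    if (tolower(s) %in% c("lpsi", "none")) return(NULL)
    if (grepl("^rlpsi-", tolower(s))) {
      tr <- sub("^rlpsi-", "", tolower(s))
      if (!tr %in% traits) {
        abort(sprintf("unknown restricted trait '%s' in scenario '%s'", tr, s))
      }
      return(restriction_spec(tr, traits))
    }
    abort(sprintf("unknown scenario '%s' (use 'lpsi' or 'rlpsi-<trait>')", s))
  })
  names(out) <- vapply(out, scenario_label, character(1))
  out
}

#' Pipeline configuration
#'
#' @param spec a [simulation_spec()] (the input is simulated), or `NULL`
#'   with `data_path`/`truth_path` pointing at existing trial CSVs.
#' @param data_path,truth_path trial data files used when `spec` is `NULL`.
#' @param grid a [weight_grid()]; default [default_grid()].
#' @param scenarios character scenario labels: `"lpsi"` or
#'   `"rlpsi-<trait>"`.
#' @param p selection fraction in (0, 1).
#' @param criteria a [selection_criteria()] for weight shortlisting.
#' @param rank_by gain column used to rank shortlisted weights.
#' @param rank_scenario scenario label whose sweep rows are shortlisted.
#' @param top_n number of shortlisted weights.
#' @param min_weights,min_scenarios consensus thresholds.
#' @param use_combined_cov use the combined-dataset C/P for per-management
#'   selection instead of management-specific matrices.
#' @param seed integer seed for the run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(spec = default_wheat_spec(),
                            data_path = NULL, truth_path = NULL,
                            grid = default_grid(),
                            scenarios = c("lpsi", "rlpsi-yield", "rlpsi-gpc"),
                            p = 0.10,
                            criteria = selection_criteria(),
                            rank_by = "E_yield",
                            rank_scenario = NULL,
                            top_n = 5,
                            min_weights = NULL, min_scenarios = 2,
                            use_combined_cov = FALSE,
                            seed = 1) {
  if (p <= 0 || p >= 1) abort("p must lie in (0, 1)")
  if (is.null(spec) && is.null(data_path)) {
    abort("either a simulation spec or a data_path is required")
  }
  structure(
    list(spec = spec, data_path = data_path, truth_path = truth_path,
         grid = grid, scenarios = scenarios, p = p, criteria = criteria,
         rank_by = rank_by, rank_scenario = rank_scenario, top_n = top_n,
         min_weights = min_weights %||% top_n, min_scenarios = min_scenarios,
         use_combined_cov = use_combined_cov, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys mirror [pipeline_config()]; simulation specs are given as
#' `simulation: {n_genotypes: ..., seed: ...}` overriding
#' [default_wheat_spec()] fields, or `data_path` points at existing records.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- if (!is.null(y$data_path)) NULL else {
    s <- default_wheat_spec(seed = y$seed %||% 1)
    if (!is.null(y$simulation)) {
      for (nm in intersect(names(y$simulation),
                           c("n_genotypes", "n_rep", "seed"))) {
        s[[nm]] <- as.integer(y$simulation[[nm]])
      }
      if (!is.null(y$simulation$n_env)) {
        s$n_env <- vapply(y$simulation$n_env, as.integer, integer(1))
      }
    }
    s
  }
  grid <- if (is.null(y$grid) || identical(y$grid, "default")) {
    default_grid()
  } else {
    weight_grid(lapply(y$grid, as.numeric))
  }
  crit <- selection_criteria(
    max_gain = y$criteria$max_gain,
    min_gain = y$criteria$min_gain,
    min_response = y$criteria$min_response %||% -Inf,
    min_rho = y$criteria$min_rho %||% -Inf
  )
  pipeline_config(
    spec = spec, data_path = y$data_path, truth_path = y$truth_path,
    grid = grid,
    scenarios = y$scenarios %||% c("lpsi", "rlpsi-yield", "rlpsi-gpc"),
    p = y$p %||% 0.10, criteria = crit,
    rank_by = y$rank_by %||% "E_yield",
    rank_scenario = y$rank_scenario,
    top_n = y$top_n %||% 5,
    min_weights = y$min_weights, min_scenarios = y$min_scenarios %||% 2,
    use_combined_cov = isTRUE(y$use_combined_cov),
    seed = y$seed %||% 1
  )
}

config_hash <- function(config) rlang::hash(config)

pipeline_meta <- function(config) {
  list(seed = config$seed, config_hash = config_hash(config))
}

stage_simulate <- function(config, outdir) {
  meta <- pipeline_meta(config)
  if (is.null(config$spec)) {
    trial <- read_trial_data(config$data_path, config$truth_path)
  } else {
    spec <- config$spec
    spec$seed <- config$seed
    trial <- simulate_met(spec)
  }
  write_artifact(trial, file.path(outdir, "trial.csv"), meta)
  truth <- trial_truth(trial)
  if (!is.null(truth)) {
    write_artifact(truth, file.path(outdir, "truth.csv"), meta)
  }
  invisible(trial)
}

pipeline_datasets <- function(trial) {
  c(sort(unique(trial$management)), "combined")
}

stage_estimate <- function(config, outdir) {
  meta <- pipeline_meta(config)
  trial <- read_trial_data(file.path(outdir, "trial.csv"))
  h2_rows <- list()
  for (ds in pipeline_datasets(trial)) {
    blues <- compute_blues(trial, ds)
    write_artifact(blues, file.path(outdir, sprintf("blues_%s.csv", ds)), meta)
    cp <- covariance_matrices(trial, ds)
    write_matrix_artifact(cp$C, file.path(outdir, sprintf("C_%s.csv", ds)), meta)
    write_matrix_artifact(cp$P, file.path(outdir, sprintf("P_%s.csv", ds)), meta)
    vc <- variance_components(trial, subset = ds)
    vc$H2 <- broad_sense_heritability(vc)
    vc$dataset <- ds
    h2_rows[[ds]] <- vc
  }
  write_artifact(dplyr::bind_rows(h2_rows),
                 file.path(outdir, "variance_components.csv"), meta)
  invisible(NULL)
}

stage_sweep <- function(config, outdir) {
  meta <- pipeline_meta(config)
  C <- read_matrix_artifact(file.path(outdir, "C_combined.csv"))
  P <- read_matrix_artifact(file.path(outdir, "P_combined.csv"))
  traits <- rownames(C)
  scen <- parse_scenarios(config$scenarios, traits)
  k <- selection_intensity(config$p)
  sweep_tbl <- evaluate_grid(config$grid, C, P, scen, k)
  write_artifact(sweep_tbl, file.path(outdir, "sweep.csv"), meta)
  rank_scen <- config$rank_scenario %||% names(scen)[1]
  rows <- dplyr::filter(sweep_tbl, .data$scenario == rank_scen)
  best <- select_best_weights(rows, config$criteria, config$rank_by,
                              config$top_n)
  write_artifact(best, file.path(outdir, "best_weights.csv"), meta)
  invisible(sweep_tbl)
}

stage_select <- function(config, outdir) {
  meta <- pipeline_meta(config)
  best <- read_artifact(file.path(outdir, "best_weights.csv"))
  if (nrow(best) == 0) abort("stage select: no shortlisted weights")
  trial <- read_trial_data(file.path(outdir, "trial.csv"))
  mgmts <- sort(unique(trial$management))
  wcols <- grep("^w_", names(best), value = TRUE)
  traits <- sub("^w_", "", wcols)
  scen <- parse_scenarios(config$scenarios, traits)
  sets <- list()
  for (ds in mgmts) {
    blues <- read_artifact(file.path(outdir, sprintf("blues_%s.csv", ds)))
    cov_ds <- if (config$use_combined_cov) "combined" else ds
    C <- read_matrix_artifact(file.path(outdir, sprintf("C_%s.csv", cov_ds)))
    P <- read_matrix_artifact(file.path(outdir, sprintf("P_%s.csv", cov_ds)))
    for (i in seq_len(nrow(best))) {
      w <- setNames(as.numeric(unlist(best[i, wcols])), traits)
      wl <- weight_label(best[i, wcols])
      for (sc in names(scen)) {
        model <- restricted_coefficients(P, C, w, scen[[sc]])
        scores <- index_values(model, blues)
        sets[[length(sets) + 1]] <- select_top_fraction(
          scores, config$p,
          context = list(dataset = ds, scenario = sc, weight = wl))
      }
    }
  }
  membership <- purrr::map_dfr(sets, function(s) {
    dplyr::mutate(tidy(s),
                  dataset = s$context$dataset, scenario = s$context$scenario,
                  weight = s$context$weight)
  })
  write_artifact(membership, file.path(outdir, "selections.csv"), meta)
  invisible(sets)
}

stage_report <- function(config, outdir) {
  meta <- pipeline_meta(config)
  membership <- read_artifact(file.path(outdir, "selections.csv"))
  universe <- sort(unique(membership$genotype))
  sets <- membership |>
    dplyr::filter(.data$selected) |>
    dplyr::group_by(.data$dataset, .data$scenario, .data$weight) |>
    dplyr::group_split() |>
    lapply(function(d) {
      structure(list(genotypes = sort(d$genotype), p = config$p,
                     m_nominal = length(d$genotype), expanded = FALSE,
                     direction = "max",
                     context = list(dataset = d$dataset[1],
                                    scenario = d$scenario[1],
                                    weight = d$weight[1]),
                     universe = universe),
                class = "selection_set")
    })
  rep <- consistency_analysis(sets, config$min_weights, config$min_scenarios)
  write_artifact(tidy(rep), file.path(outdir, "consistency.csv"), meta)
  write_artifact(tibble(genotype = rep$consensus),
                 file.path(outdir, "consensus.csv"), meta)
  rep
}

#' Run the full selection-index pipeline
#'
#' Orchestrates simulate (or load) -> estimate -> sweep -> select -> report,
#' writing every intermediate as a commented CSV so that any stage can be
#' re-run from saved artifacts. Identical config and seed give byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if absent).
#' @param stages subset of `c("simulate", "estimate", "sweep", "select",
#'   "report")`, in order; default all.
#' @return the `consistency_report` of the report stage (invisibly `NULL`
#'   when the report stage is not run).
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "estimate", "sweep",
                                    "select", "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "estimate", "sweep", "select", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  result <- NULL
  for (st in stages) {
    inform(sprintf("[metsel] stage %s", st))
    result <- tryCatch(
      switch(st,
             simulate = stage_simulate(config, outdir),
             estimate = stage_estimate(config, outdir),
             sweep = stage_sweep(config, outdir),
             select = stage_select(config, outdir),
             report = stage_report(config, outdir)),
      error = function(e) {
        abort(sprintf("pipeline stage '%s' failed: %s", st,
                      conditionMessage(e)),
              class = "metsel_stage_error")
      })
  }
  manifest <- list(
    package = "metsel",
    version = as.character(utils::packageVersion("metsel")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = stages,
    p = config$p,
    scenarios = config$scenarios,
    files = sort(list.files(outdir, pattern = "\\.csv$"))
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  if ("report" %in% stages) result else invisible(NULL)
}
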