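#' Experiment configuration
#'
#' Assembles and validates the configuration consumed by
#' [run_experiment()]: phantom parameters, uncertainty-model overrides,
#' strategy list, dose-engine and objective parameters, sample counts and
#' seed. Defaults reproduce the study conditions (all six strategies, both
#' evaluation sets, the literature error model).
#'
#' @param n_phantoms Number of phantoms (tumor texture seed varies per
#'   phantom; geometry via `phantom`).
#' @param phantom Named list of [generate_phantom()] arguments.
#' @param strategies Character vector of strategy names.
#' @param eval_sets Subset of `c("A", "B")`.
#' @param n_samples Simulated treatments per plan per set (study value 10000).
#' @param seed Integer master seed; all sub-seeds derive from it.
#' @param um An [uncertainty_model()].
#' @param pars [dose_engine_params()].
#' @param obj [objective_config()].
#' @param maxit Optimizer iteration cap.
#' @param dry_run Bookkeeping only (no dose computation).
#' @return A validated `experiment_config` list.
#' @export
experiment_config <- function(n_phantoms = 1L,
                              phantom = list(),
                              strategies = planning_strategies()$name,
                              eval_sets = c("A", "B"),
                              n_samples = 10000L,
                              seed = 1L,
                              um = uncertainty_model(),
                              pars = dose_engine_params(),
                              obj = objective_config(),
                              maxit = 120L,
                              dry_run = FALSE) {
  cfg <- structure(as.list(environment()), class = "experiment_config")
  validate_experiment_config(cfg)
  cfg
}

validate_experiment_config <- function(cfg) {
  required <- c("n_phantoms", "phantom", "strategies", "eval_sets",
                "n_samples", "seed", "um", "pars", "obj", "maxit", "dry_run")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("experiment_config: missing key(s): ", paste(missing, collapse = ", "))
  }
  valid <- planning_strategies(cfg$um)$name
  bad <- setdiff(cfg$strategies, valid)
  if (length(bad)) stop("experiment_config: unknown strategies: ",
                        paste(bad, collapse = ", "))
  if (!all(cfg$eval_sets %in% c("A", "B"))) {
    stop("experiment_config: eval_sets must be within c('A', 'B')")
  }
  if (cfg$n_samples < 1 || cfg$n_phantoms < 1) {
    stop("experiment_config: n_samples and n_phantoms must be positive")
  }
  invisible(cfg)
}

#' Read an experiment configuration from YAML
#'
#' Reads a YAML file with keys matching [experiment_config()] arguments
#' (uncertainty-model overrides under `um:`, engine parameters under
#' `pars:`, objective under `obj:`) and validates it; unknown keys are an
#' error naming the key.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("read_experiment_config: unknown key(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$um)) raw$um <- do.call(uncertainty_model, raw$um)
  if (!is.null(raw$pars)) raw$pars <- do.call(dose_engine_params, raw$pars)
  if (!is.null(raw$obj)) raw$obj <- do.call(objective_config, raw$obj)
  do.call(experiment_config, raw)
}

#' Write an experiment configuration to YAML
#' @param cfg An `experiment_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$um <- unclass(out$um)
  yaml::write_yaml(out, path)
  invisible(path)
}
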