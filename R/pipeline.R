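#' Read and validate a pipeline run configuration
#'
#' Configurations are flat YAML (or an equivalent named list): file paths,
#' the selection thresholds, the estimator settings and an output
#' directory. Unknown keys are errors (fail-closed), so typos cannot
#' silently fall back to defaults.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated list of class `mr_run_config`.
#' @section Keys:
#' * `exposure`, `outcome` (required file paths), `ld`, `confounders`
#'   (optional: LD table path; named list/vector of confounder table paths)
#' * `fixture`: alternatively, the name of a packaged dataset
#'   ([mr_fixture()]) instead of `exposure`/`outcome`
#' * `selection`: any field of [selection_config()]
#' * `estimation`: `ivw_model` (default `"multiplicative_random"`),
#'   `n_boot` (1000), `n_sim` (10000), `seed` (required)
#' * `palindrome_policy` (default `"infer_by_eaf"`), `sd` (trait SD for
#'   variance explained, default 1), `n_exposure` (exposure GWAS sample
#'   size, optional), `r2_total` (override variance explained, optional)
#' * `out_dir`: output directory (required for [mr_run()] unless passed
#'   there)
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("config must be a YAML file path or a named list",
          class = "mrkit_config_error")
  }
  known <- c("exposure", "outcome", "ld", "confounders", "fixture",
             "selection", "estimation", "palindrome_policy", "sd",
             "n_exposure", "r2_total", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "mrkit_config_error")
  }
  if (is.null(config$fixture) &&
      (is.null(config$exposure) || is.null(config$outcome))) {
    abort("config needs either 'fixture' or both 'exposure' and 'outcome'",
          class = "mrkit_config_error")
  }
  sel_known <- names(formals(selection_config))
  sel <- config$selection %||% list()
  if (length(setdiff(names(sel), sel_known)) > 0) {
    abort(paste0("unknown selection key(s): ",
                 paste(setdiff(names(sel), sel_known), collapse = ", ")),
          class = "mrkit_config_error")
  }
  est_known <- c("ivw_model", "n_boot", "n_sim", "seed")
  est <- config$estimation %||% list()
  if (length(setdiff(names(est), est_known)) > 0) {
    abort(paste0("unknown estimation key(s): ",
                 paste(setdiff(names(est), est_known), collapse = ", ")),
          class = "mrkit_config_error")
  }
  if (is.null(est$seed)) {
    abort("estimation.seed is required (bootstrap and MR-PRESSO are stochastic)",
          class = "mrkit_config_error")
  }
  config$selection <- do.call(selection_config, sel)
  config$estimation <- utils::modifyList(
    list(ivw_model = "multiplicative_random", n_boot = 1000, n_sim = 10000),
    est)
  config$palindrome_policy <- config$palindrome_policy %||% "infer_by_eaf"
  config$sd <- config$sd %||% 1
  structure(config, class = "mr_run_config")
}

#' Run the full MR pipeline
#'
#' Executes the complete workflow on one exposure/outcome pair: instrument
#' selection (significance filter, optional LD clumping, proxy
#' substitution for instruments missing from the outcome, outcome and
#' confounder screens), harmonization, the estimator panel (IVW, MR-Egger,
#' WME) and the sensitivity suite (Q, leave-one-out, MR-PRESSO, funnel and
#' forest coordinates). With fewer than 3 instruments the run degrades to
#' IVW and Q only, with a warning; with none it fails.
#'
#' Outputs written to `out_dir`: `results.tsv` (published table shape,
#' 3 decimals), `results.json` (full precision), `sensitivity.json`,
#' `loo.tsv`, `funnel.tsv`, `forest.tsv`, `exclusions.tsv`, and
#' `manifest.json` (package/R versions, seed and the full config echo,
#' sufficient to replay the run). Outputs are byte-identical across runs
#' of the same config.
#'
#' @param config A [read_run_config()] input (path or list).
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return Invisibly, a list: `harmonized`, `results`, `sensitivity`,
#'   `strength` (when `n_exposure` is configured), `exclusions`, `files`.
#' @export
mr_run <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) {
    abort("out_dir is required", class = "mrkit_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$fixture)) {
    fx <- mr_fixture(cfg$fixture)
    exposure <- fx$exposure
    outcome <- fx$outcome
  } else {
    exposure <- read_summary_stats(cfg$exposure, trait_label = "exposure")
    outcome <- read_summary_stats(cfg$outcome, trait_label = "outcome",
                                  trait_type = "binary")
  }
  ld <- if (!is.null(cfg$ld)) read_ld_table(cfg$ld) else NULL
  confounders <- purrr::map(cfg$confounders %||% list(), read_summary_stats)

  excl <- list()
  note_excl <- function(tab) {
    e <- attr(tab, "exclusions")
    if (!is.null(e) && nrow(e) > 0) excl[[length(excl) + 1L]] <<- e
    tab
  }

  sel <- cfg$selection
  cand <- filter_significant(exposure, sel$p_threshold)
  if (nrow(cand) == 0) {
    abort("no genome-wide significant instruments", class = "mrkit_run_error")
  }
  if (!is.null(ld)) {
    cand <- clump_instruments(cand, ld, sel)
  }
  # instruments absent from the outcome: substitute a proxy (using the
  # proxy's own exposure record) or drop the instrument
  missing_ids <- setdiff(cand$snp_id, outcome$snp_id)
  proxy_map <- NULL
  if (length(missing_ids) > 0) {
    if (!is.null(ld)) {
      sub <- substitute_proxies(missing_ids, outcome, ld, sel$proxy_r2_floor)
      proxy_map <- sub$proxies
      drop_ids <- sub$unresolved
      if (nrow(proxy_map) > 0) {
        in_exp <- proxy_map$proxy_id %in% exposure$snp_id
        if (any(!in_exp)) {
          excl[[length(excl) + 1L]] <- tibble::tibble(
            snp_id = proxy_map$snp_id[!in_exp],
            reason = "proxy_not_in_exposure",
            detail = paste0("proxy ", proxy_map$proxy_id[!in_exp],
                            " absent from exposure GWAS"))
          drop_ids <- c(drop_ids, proxy_map$snp_id[!in_exp])
          proxy_map <- proxy_map[in_exp, , drop = FALSE]
        }
        for (i in seq_len(nrow(proxy_map))) {
          repl <- exposure[exposure$snp_id == proxy_map$proxy_id[i], ,
                           drop = FALSE]
          cand[cand$snp_id == proxy_map$snp_id[i],
               intersect(names(cand), names(repl))] <-
            repl[intersect(names(cand), names(repl))]
        }
      }
    } else {
      drop_ids <- missing_ids
    }
    if (length(drop_ids) > 0) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        snp_id = drop_ids, reason = "missing_from_outcome",
        detail = "no proxy at or above proxy_r2_floor")
      cand <- cand[!cand$snp_id %in% drop_ids, , drop = FALSE]
    }
  }
  cand <- note_excl(screen_outcome_association(cand, outcome,
                                               sel$outcome_p_threshold))
  cand <- note_excl(screen_confounders(cand, confounders, sel$p_threshold))
  if (nrow(cand) == 0) {
    abort("no instruments left after screening", class = "mrkit_run_error")
  }

  set <- harmonize(cand, outcome, palindrome_policy = cfg$palindrome_policy)
  if (!is.null(proxy_map) && nrow(proxy_map) > 0) {
    hit <- match(proxy_map$proxy_id, set$snp_id)
    set$proxy_for[stats::na.omit(hit)] <- proxy_map$snp_id[!is.na(hit)]
  }
  excl[[length(excl) + 1L]] <- exclusion_log(set)
  k <- nrow(set)

  est <- cfg$estimation
  degraded <- k < 3
  if (degraded) {
    warn(sprintf(paste0("only %d instrument(s) after selection; ",
                        "reporting IVW and Q only"), k),
         class = "mrkit_degraded_run")
    ivw_model <- if (k >= 2) est$ivw_model else "fixed"
    results <- glance(mr_ivw(set, model = ivw_model))
  } else {
    results <- mr_all(set, ivw_model = est$ivw_model,
                      n_boot = est$n_boot, seed = est$seed)
  }
  sens <- sensitivity_report(set, results = results, n_sim = est$n_sim,
                             seed = est$seed)
  strength <- NULL
  if (!is.null(cfg$n_exposure) && !any(is.na(set$eaf))) {
    strength <- instrument_strength(set, n = cfg$n_exposure, sd = cfg$sd,
                                    r2_total = cfg$r2_total)
  }
  exclusions <- if (length(excl) > 0) dplyr::bind_rows(excl) else
    tibble::tibble(snp_id = character(), reason = character(),
                   detail = character())

  files <- write_run_outputs(out_dir, cfg, set, results, sens, strength,
                             exclusions)
  invisible(list(harmonized = set, results = results, sensitivity = sens,
                 strength = strength, exclusions = exclusions,
                 files = files))
}

write_run_outputs <- function(out_dir, cfg, set, results, sens, strength,
                              exclusions) {
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(format_mr_table(results), p("results.tsv"))
  jsonlite::write_json(results, p("results.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  sens_json <- list(
    heterogeneity = if (!is.null(sens$heterogeneity))
      as.list(glance(sens$heterogeneity)),
    presso = if (!is.null(sens$presso)) c(
      as.list(glance(sens$presso)),
      list(outliers = sens$presso$outliers,
           per_snp = sens$presso$per_snp)),
    strength = if (!is.null(strength)) as.list(glance(strength))
  )
  jsonlite::write_json(sens_json, p("sensitivity.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(sens$leave_one_out)) {
    readr::write_tsv(tibble::as_tibble(sens$leave_one_out), p("loo.tsv"))
  }
  funnel <- tibble::as_tibble(sens$funnel)
  funnel$reference <- attr(sens$funnel, "reference")
  readr::write_tsv(funnel, p("funnel.tsv"))
  readr::write_tsv(tibble::as_tibble(sens$forest), p("forest.tsv"))
  readr::write_tsv(exclusions, p("exclusions.tsv"))
  manifest <- list(
    package = "mrkit",
    package_version = as.character(utils::packageVersion("mrkit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_snp = nrow(set),
    config = unclass_config(cfg))
  jsonlite::write_json(manifest, p("manifest.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(vapply(c("results.tsv", "results.json", "sensitivity.json",
                     "funnel.tsv", "forest.tsv", "exclusions.tsv",
                     "manifest.json"), p, ""))
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$selection <- unclass(cfg$selection)
  cfg$out_dir <- NULL   # a location, not an analysis parameter
  cfg
}

#' Validate a summary-statistics file
#'
#' Schema check for a summary-statistic file: parses it and reports every
#' row-level problem without modifying anything.
#'
#' @inheritParams read_summary_stats
#' @return A tibble of problems (zero rows when the file is valid), as
#'   from [validate_summary_stats()].
#' @export
validate_summary_file <- function(path, column_map = default_column_map()) {
  res <- tryCatch(
    suppressWarnings(read_summary_stats(path, column_map = column_map)),
    error = function(e) e)
  if (inherits(res, "error")) {
    return(tibble::tibble(row = NA_integer_, snp_id = NA_character_,
                          problem = conditionMessage(res)))
  }
  rej <- attr(res, "rejected")
  if (is.null(rej)) {
    tibble::tibble(row = integer(), snp_id = character(),
                   problem = character())
  } else {
    rej$problems
  }
}
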