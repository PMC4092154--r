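# End-to-end pipeline: data preparation -> correlation screen -> model-type
# adjudication -> spatiotemporal models -> forward stepwise environmental
# model -> assemblage statistics, with every stage's report written as
# delimited text plus a machine-readable JSON run log. Stages communicate
# only through their declared outputs.

#' Pipeline run configuration
#'
#' Either a path to a raw fishing-set table (`set_table` + `schema`) or a
#' synthetic scenario (the default) feeds the pipeline.
#'
#' @param species count columns to analyse (required).
#' @param seed integer seed for every stochastic stage.
#' @param set_table optional path to a delimited set table; when `NULL` a
#'   synthetic survey is generated with [default_scenario()].
#' @param schema schema for [read_set_table()].
#' @param covariates covariates entering the correlation screen.
#' @param adjudication_predictors predictors for the model-type adjudication.
#' @param env_candidates candidate covariates of the stepwise ENV stage.
#' @param k univariate basis dimension used across stages.
#' @param k_grid basis-dimension grid (documented in the run log).
#' @param alpha significance level for assemblage tests.
#' @param out_dir output directory for the stage reports.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(species, seed = 1, set_table = NULL, schema = list(),
                       covariates = env_covariates(),
                       adjudication_predictors = c("month", "temp", "tidamp"),
                       env_candidates = c("temp", "visib", "tidamp", "pluvio"),
                       k = 5, k_grid = c(4, 6, 8, 10, 12), alpha = 0.05,
                       out_dir = tempfile("ziga_run_")) {
  if (missing(species) || !length(species)) {
    stop("validation error: config must name at least one species")
  }
  if (!is.numeric(seed) || length(seed) != 1) {
    stop("validation error: a single integer seed is required")
  }
  structure(list(species = species, seed = as.integer(seed),
                 set_table = set_table, schema = schema,
                 covariates = covariates,
                 adjudication_predictors = adjudication_predictors,
                 env_candidates = env_candidates, k = k, k_grid = k_grid,
                 alpha = alpha, out_dir = out_dir),
            class = "RunConfig")
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full survey-analysis pipeline
#'
#' Executes read/filter/aggregate (or synthetic generation), the covariate
#' correlation screen, model-type adjudication, the SPT1/SPT2 spatiotemporal
#' fits, the forward stepwise ENV selection under the screen's exclusions,
#' and the assemblage composition statistics. Each stage's report is written
#' to `config$out_dir` as delimited text; the run configuration and seed go
#' to `run_log.json`. Reruns with the same config and seed are reproducible.
#'
#' @param config a [run_config()].
#' @return invisibly, the output directory; the reports are
#'   `cruises.csv`, `screening.csv`, `adjudication.csv`, `spt_summary.csv`,
#'   `env_trace.csv`, `env_summary.csv`, `assemblage.csv` and
#'   `run_log.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  stage_msg("data", "preparing cruise table")
  captures <- NULL
  cruises <- run_stage("data", {
    if (!is.null(config$set_table)) {
      sets <- read_set_table(config$set_table, config$schema)
      aggregate_by_cruise(apply_standardization_filters(sets))
    } else {
      syn <- default_scenario(seed = config$seed)
      captures <- syn$captures
      syn$cruises
    }
  })
  missing_sp <- setdiff(config$species, names(cruises))
  if (length(missing_sp)) {
    stop(sprintf("validation error: species column(s) absent: %s",
                 paste(missing_sp, collapse = ", ")))
  }
  write_cruise_table(cruises, out("cruises.csv"))

  stage_msg("screen", "correlation screening of %d covariates",
            length(config$covariates))
  scr <- run_stage("screen",
                   screen_covariates(cruises, config$covariates))
  write_cruise_table(scr, out("screening.csv"))
  exclusions <- attr(scr, "exclusions")

  stage_msg("adjudicate", "univariate GAM/ZIGAM/COZIGAM comparison")
  adj <- run_stage("adjudicate", adjudicate_model_type(
    cruises, config$species, config$adjudication_predictors, k = config$k))
  write_cruise_table(adj$table, out("adjudication.csv"))

  stage_msg("spt", "spatiotemporal models (type %s)", adj$chosen_type)
  spt_rows <- run_stage("spt", {
    rows <- list()
    for (spn in config$species) {
      specs <- build_spt_specs(spn, sites = unique(cruises$site),
                               model_type = adj$chosen_type,
                               k_year = config$k, k_month = config$k,
                               k_2d = 3 * config$k)
      for (mn in names(specs)) {
        ft <- suppressWarnings(fit_model(specs[[mn]], cruises))
        su <- summarize_fit(ft)
        rows[[length(rows) + 1]] <- data.frame(
          species = spn, model = mn,
          term = if (nrow(su)) su$term else "(none)",
          edf = if (nrow(su)) su$edf else NA_real_,
          chisq = if (nrow(su)) su$chisq else NA_real_,
          p = if (nrow(su)) su$p else NA_real_,
          logE = ft$logE, r2_adj = ft$r2_adj, dev_expl = ft$dev_expl,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  write_cruise_table(spt_rows, out("spt_summary.csv"))

  stage_msg("env", "forward stepwise ENV selection")
  env_out <- run_stage("env", {
    traces <- list(); sums <- list()
    for (spn in config$species) {
      tr <- forward_stepwise_env(cruises, spn, config$env_candidates,
                                 exclusions = exclusions,
                                 model_type = adj$chosen_type, k = config$k)
      st <- tr$steps
      if (nrow(st)) st <- cbind(species = spn, st)
      traces[[spn]] <- st
      su <- summarize_fit(tr$final_fit)
      sums[[spn]] <- data.frame(
        species = spn,
        model = if (length(tr$included)) paste(tr$included, collapse = "+")
                else "(null)",
        term = if (nrow(su)) su$term else "(none)",
        edf = if (nrow(su)) su$edf else NA_real_,
        chisq = if (nrow(su)) su$chisq else NA_real_,
        p = if (nrow(su)) su$p else NA_real_,
        logE = tr$final_fit$logE, r2_adj = tr$final_fit$r2_adj,
        dev_expl = tr$final_fit$dev_expl, stringsAsFactors = FALSE)
    }
    list(trace = do.call(rbind, traces), summary = do.call(rbind, sums))
  })
  write_cruise_table(env_out$trace, out("env_trace.csv"))
  write_cruise_table(env_out$summary, out("env_summary.csv"))

  stage_msg("assemblage", "composition statistics")
  asm <- run_stage("assemblage", {
    if (is.null(captures)) {
      data.frame(species = config$species, note = "no capture table supplied")
    } else {
      comp <- summarize_composition(captures)
      comp$sex_chisq <- NA_real_; comp$sex_p <- NA_real_
      comp$kw_quarter_H <- NA_real_; comp$kw_quarter_p <- NA_real_
      for (i in seq_len(nrow(comp))) {
        g <- captures[captures$species == comp$species[i], ]
        m <- sum(g$sex == "M"); f <- sum(g$sex == "F")
        if (m + f >= 1) {
          gof <- sex_ratio_gof(m, f)
          comp$sex_chisq[i] <- gof$statistic; comp$sex_p[i] <- gof$p
        }
        q <- ceiling(as.POSIXlt(g$date)$mon %/% 3 + 1)
        grp <- split(g$tl_cm, q)
        if (length(grp) >= 2) {
          kw <- suppressWarnings(kruskal_wallis(grp))
          comp$kw_quarter_H[i] <- kw$statistic
          comp$kw_quarter_p[i] <- kw$p
        }
      }
      comp
    }
  })
  write_cruise_table(asm, out("assemblage.csv"))

  log <- list(
    config = unclass(config)[setdiff(names(config), c("schema", "out_dir"))],
    seed = config$seed,
    exclusions = if (nrow(exclusions)) apply(exclusions, 1, paste,
                                             collapse = ":") else character(0),
    chosen_model_type = adj$chosen_type,
    r_version = as.character(getRversion()),
    package_version = tryCatch(
      as.character(utils::packageVersion("zigamsurvey")),
      error = function(e) "dev")
  )
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(config$out_dir)
}
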