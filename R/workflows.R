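#' Path to a packaged example table
#'
#' The printed validation and survey summary tables ship as plain-CSV
#' fixtures: `table3_wells.csv` (reproducibility wells),
#' `table4_dilution.csv` (dilution-series droplet counts),
#' `table7_survey_summary.csv` (per population-month prevalence and
#' aggregation summaries) and `table1_sample_sizes.csv` (hosts sampled per
#' population-month).
#'
#' @param file Fixture file name; with no argument, lists the available
#'   fixtures.
#' @return A file path (or a vector of file names).
#' @export
ddquant_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "ddquant")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop("ddquant_example: no fixture named '", file, "'", call. = FALSE)
  path
}

#' Assay validation workflow
#'
#' Runs the validation battery over a dilution-series count table and
#' (optionally) a reproducibility table: per-well quantification with QC,
#' per-level replicate summaries, dynamic-range linearity on both scales,
#' the limit of detection, and — when a reproducibility table with a
#' `cartridge_id` column is supplied — the between-cartridge rank-sum
#' comparison with the Hodges–Lehmann shift.
#'
#' @param counts A `well_counts` data.frame with a `dilution_fold` column,
#'   or a path to its CSV.
#' @param repro Optional reproducibility table (or CSV path) with columns
#'   `conc_copies_ul`, `cartridge_id` and optionally `sample_id`.
#' @param cfg A [quant_config()].
#' @return A list of class `validation_report`: `quant`, `level_summaries`,
#'   `linearity_log10`, `linearity_linear`, `lod`, `cartridge` (or `NULL`),
#'   `qc_failures`.
#' @export
run_validation_workflow <- function(counts, repro = NULL,
                                    cfg = quant_config()) {
  if (is.character(counts)) counts <- read_well_counts_csv(counts)
  quant <- quantify_wells(counts, cfg)
  if (!"dilution_fold" %in% names(quant))
    stop("run_validation_workflow: counts need a 'dilution_fold' column",
         call. = FALSE)
  qc_pass <- quant[quant$qc_pass, ]
  folds <- sort(unique(qc_pass$dilution_fold), decreasing = TRUE)
  level_summaries <- do.call(rbind, lapply(folds, function(f) {
    s <- replicate_summary(qc_pass$conc_copies_ul[qc_pass$dilution_fold == f],
                           sd_mode = "sample")
    data.frame(dilution_fold = f, m = s$m, mean = s$mean, sd = s$sd,
               se = s$se, cv_pct = s$cv_pct)
  }))
  cartridge <- NULL
  if (!is.null(repro)) {
    if (is.character(repro))
      repro <- utils::read.csv(repro, stringsAsFactors = FALSE)
    stopifnot(all(c("conc_copies_ul", "cartridge_id") %in% names(repro)))
    carts <- unique(repro$cartridge_id)
    if (length(carts) == 2) {
      cartridge <- rank_sum_test(
        repro$conc_copies_ul[repro$cartridge_id == carts[1]],
        repro$conc_copies_ul[repro$cartridge_id == carts[2]])
    }
  }
  structure(
    list(quant = quant,
         level_summaries = level_summaries,
         linearity_log10 = dilution_linearity(quant, scale = "log10"),
         linearity_linear = dilution_linearity(quant, scale = "linear"),
         lod = limit_of_detection(quant, cfg),
         cartridge = cartridge,
         qc_failures = quant$well_id[!quant$qc_pass]),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("== ddPCR assay validation ==\n")
  cat(sprintf("%d wells, %d QC failure(s)%s\n", nrow(x$quant),
              length(x$qc_failures),
              if (length(x$qc_failures))
                paste0(" (", paste(x$qc_failures, collapse = ", "), ")")
              else ""))
  cat("\nPer-level replicate summaries (QC-passing wells):\n")
  print(format(x$level_summaries, digits = 4), row.names = FALSE)
  cat(sprintf("\nLinearity: r2 = %.4f (linear scale), %.4f (log-log); log-log slope %.3f\n",
              x$linearity_linear$r2, x$linearity_log10$r2,
              x$linearity_log10$slope))
  print(x$lod)
  if (!is.null(x$cartridge)) print(x$cartridge)
  invisible(x)
}

#' Population survey workflow
#'
#' Computes infection loads, the per-group prevalence/aggregation summary,
#' and — unless disabled — the pooled regression stage: PMM imputation of
#' missing covariates, per-imputation GLM fits, Rubin's-rules pooling, and
#' odds ratios for the logistic response.
#'
#' @param hosts A `host_survey` data.frame or a path to its CSV.
#' @param config A [run_config()] (imputation settings and seed).
#' @param spec A [design_spec()] for the regression stage.
#' @param fit_models Run the regression stage (default `TRUE`).
#' @return A list of class `survey_report`: `summary` (per-group table),
#'   `pooled` (or `NULL`), `odds_ratios` (logistic response only),
#'   `n_hosts`, `n_infected`.
#' @export
run_survey_workflow <- function(hosts, config = run_config(),
                                spec = design_spec(), fit_models = TRUE) {
  if (is.character(hosts)) hosts <- read_survey_csv(hosts)
  hosts <- as.data.frame(hosts)
  if (!"load_copies_ng" %in% names(hosts))
    hosts <- survey_loads(hosts, config$quant)
  summary_tab <- survey_summary(hosts)
  n_inf <- sum(infected_flag(hosts$load_copies_ng), na.rm = TRUE)
  pooled <- ors <- NULL
  if (fit_models && n_inf == 0) {
    message("run_survey_workflow: no infected hosts; model stage skipped")
    fit_models <- FALSE
  }
  if (fit_models) {
    needs_impute <- any(vapply(
      intersect(c("length_um", "organic_content_pct"), spec$predictors),
      function(v) anyNA(hosts[[v]]), logical(1)))
    completed <- if (needs_impute)
      pmm_impute(hosts, m = config$impute_m, iters = config$impute_iters,
                 donors = config$impute_donors, seed = config$seed)
    else list(hosts)
    fits <- lapply(completed, fit_glm, spec = spec)
    pooled <- rubin_pool(fits)
    if (spec$response == "infected") ors <- odds_ratios(pooled)
  }
  structure(
    list(summary = summary_tab, pooled = pooled, odds_ratios = ors,
         n_hosts = sum(!is.na(hosts$load_copies_ng)), n_infected = n_inf),
    class = "survey_report"
  )
}

#' @export
print.survey_report <- function(x, ...) {
  cat("== Host population survey ==\n")
  cat(sprintf("%d hosts with measured load, %d infected (%.1f%%)\n",
              x$n_hosts, x$n_infected, 100 * x$n_infected / max(x$n_hosts, 1)))
  cat("\nPer-group summary:\n")
  print(format(x$summary, digits = 4), row.names = FALSE)
  if (!is.null(x$pooled)) { cat("\n"); print(x$pooled) }
  if (!is.null(x$odds_ratios)) {
    cat("\nOdds ratios:\n")
    print(format(x$odds_ratios, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Command-line interface
#'
#' Subcommand dispatcher used by the `inst/cli/ddquant` script:
#' `quantify --counts FILE [-o OUT]`, `validate --counts FILE [-o OUT]`,
#' `survey --hosts FILE [-o OUT]`, and
#' `simulate well|dilution|survey --seed N -o OUT`. Returns the exit
#' status (0 ok, 2 validation error, 3 QC failure) instead of calling
#' `quit()`, so it is testable in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
ddquant_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  flag <- function(name, default = NULL) {
    i <- which(args == name)
    if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
  }
  out <- flag("-o", flag("--out"))
  status <- 0L
  res <- tryCatch({
    switch(
      args[1],
      quantify = {
        cfg <- quant_config(
          droplet_volume_ul = as.numeric(
            flag("--droplet-volume-nl", "0.85")) / 1000,
          min_droplets = as.integer(flag("--min-droplets", "10000")))
        q <- quantify_wells(read_well_counts_csv(flag("--counts")), cfg)
        if (!is.null(out)) utils::write.csv(q, out, row.names = FALSE)
        if (!all(q$qc_pass)) status <- 3L
        q
      },
      validate = {
        rep <- run_validation_workflow(flag("--counts"),
                                       repro = flag("--repro"))
        print(rep)
        if (!is.null(out))
          utils::write.csv(rep$quant, out, row.names = FALSE)
        if (length(rep$qc_failures) &&
            !("--allow-qc-fail" %in% args)) status <- 3L
        rep
      },
      survey = {
        rep <- run_survey_workflow(
          flag("--hosts"),
          config = run_config(seed = as.integer(flag("--seed", "1"))))
        print(rep)
        if (!is.null(out))
          utils::write.csv(rep$summary, out, row.names = FALSE)
        rep
      },
      simulate = {
        seed <- as.integer(flag("--seed", "1"))
        obj <- switch(
          args[2],
          well = {
            w <- simulate_well(as.numeric(flag("--conc", "100")),
                               as.integer(flag("--droplets", "15000")),
                               seed = seed)
            data.frame(well_id = w$well_id, sample_id = w$sample_id,
                       cartridge_id = w$cartridge_id,
                       amplitude = w$amplitudes)
          },
          dilution = simulate_dilution_series(
            as.numeric(flag("--conc", "100")), seed = seed),
          survey = simulate_survey(seed = seed),
          stop("unknown simulate target: ", args[2]))
        if (!is.null(out)) utils::write.csv(obj, out, row.names = FALSE)
        obj
      },
      stop("unknown subcommand: ", args[1])
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    status <<- 2L
    NULL
  })
  invisible(status)
}
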