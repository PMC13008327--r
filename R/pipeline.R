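# Config-driven end-to-end orchestration: simulate/load -> QC -> features ->
# association -> prediction -> report, with deterministic seeds and a
# machine-readable manifest.

#' Build a run configuration
#'
#' Either `input` (paths to the recordings/clinical CSV pair) or `simulate`
#' (a [sim_params()] list) must be present. Every field of the QC, wavelet
#' and simulation configurations can be overridden from a YAML file; unknown
#' keys are rejected.
#'
#' @param input List with `recordings` and `clinical` paths, or `NULL`.
#' @param simulate A [sim_params()] (or plain list of overrides), or `NULL`.
#' @param qc List of [qc_config()] overrides.
#' @param wavelet List of [wavelet_config()] overrides.
#' @param windows Window labels to analyse.
#' @param cv_windows Windows on which the cross-validated source comparison
#'   runs (needs enough eligible patients per fold).
#' @param inference List: `k` folds, `ridge`, `alpha`.
#' @param seed Master seed (simulation and fold assignment derive from it).
#' @param outdir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL, qc = list(),
                       wavelet = list(), windows = c("P1", "P2", "P3", "FULL24"),
                       cv_windows = "P1",
                       inference = list(k = 10L, ridge = 1, alpha = 0.05),
                       seed = 1L, outdir = "bpvar_run") {
  if (is.null(input) && is.null(simulate)) {
    stop("run_config: either input paths or simulation parameters are required")
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_params")) {
    simulate <- do.call(sim_params, simulate)
  }
  if (!is.null(simulate)) simulate$seed <- seed
  inf <- utils::modifyList(list(k = 10L, ridge = 1, alpha = 0.05), inference)
  structure(list(input = input, simulate = simulate,
                 qc = do.call(qc_config, qc),
                 wavelet = do.call(wavelet_config, wavelet),
                 windows = windows, cv_windows = cv_windows,
                 inference = inf, seed = seed, outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with any of the [run_config()] sections.
#' @param ... Overrides applied after the file (e.g. `seed`, `outdir`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  for (nm in names(over)) raw[[nm]] <- over[[nm]]
  allowed <- c("input", "simulate", "qc", "wavelet", "windows", "cv_windows",
               "inference", "seed", "outdir")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Stages: acquire (simulate or load) -> preprocess/QC -> per-window
#' eligibility report and feature table -> association scan (OR per 1 SD,
#' univariable and adjusted) -> cross-validated continuous-vs-intermittent
#' comparison on the configured windows -> JSON manifest. All outputs are
#' CSV; re-running with the same configuration reproduces every file
#' bit-identically. A stage failure aborts with the stage name; files
#' already written are preserved.
#'
#' @param config A `run_config`.
#' @param stages Stages to execute after acquisition (subset of
#'   `c("qc", "features", "associate", "predict")`, in this fixed order);
#'   later stages require the earlier ones.
#' @return A run report (list) with the in-memory results and output paths,
#'   class `run_report`.
#' @export
run_pipeline <- function(config,
                         stages = c("qc", "features", "associate", "predict")) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  stage <- "acquire"
  report <- list(config = config, outdir = config$outdir, windows = list())
  tryCatch({
    if (!is.null(config$simulate)) {
      sim <- simulate_cohort(config$simulate)
      records <- sim$records
      write_cohort(records, out("recordings.csv"), out("clinical.csv"))
      write_table(sim$truth, out("ground_truth.csv"))
    } else {
      loaded <- load_cohort(config$input$recordings, config$input$clinical)
      records <- loaded$records
      report$load_report <- loaded$report
    }
    if (!length(records)) stop("empty cohort")

    if ("qc" %in% stages && length(config$windows)) {
      stage <- "qc"
      records <- lapply(records, preprocess_record, cfg = config$qc)
      elig <- eligibility_report(records, config$windows, config$qc)
      write_table(elig, out("eligibility.csv"))
      report$eligibility <- elig
      if (!any(elig$eligible)) stop("no eligible patients in any window")
    } else {
      class(report) <- "run_report"
      return(finish_run(report, config, out))
    }

    if (!"features" %in% stages) {
      class(report) <- "run_report"
      return(finish_run(report, config, out))
    }
    for (w in config$windows) {
      stage <- paste0("features:", w)
      ew <- elig[elig$window == w, ]
      wres <- list(n_eligible = sum(ew$eligible))
      if (wres$n_eligible >= 3) {
        ft <- build_feature_table(records, w, config$qc, config$wavelet,
                                  eligibility = elig)
        write_table(ft, out(sprintf("features_%s.csv", w)))
        oc <- outcome_covariates(records, ft)
        wres$n_ht <- sum(oc$outcome)

        if ("associate" %in% stages) {
          stage <- paste0("associate:", w)
          scan <- run_association_scan(ft, oc$outcome, oc$covariates,
                                       alpha = config$inference$alpha)
          if (nrow(scan)) write_table(scan, out(sprintf("associations_%s.csv", w)))
          wres$associations <- scan
        }

        if ("predict" %in% stages && w %in% config$cv_windows &&
            min(table(oc$outcome)) >= config$inference$k) {
          stage <- paste0("predict:", w)
          is_cont <- grepl("^cont_", names(ft))
          is_int <- grepl("^int_", names(ft))
          cv <- crossval_compare(ft[, is_cont, drop = FALSE],
                                 ft[, is_int, drop = FALSE],
                                 oc$outcome, k = config$inference$k,
                                 seed = config$seed,
                                 ridge = config$inference$ridge)
          write_table(cv_result_table(cv), out(sprintf("cv_%s.csv", w)))
          curves <- rbind(cbind(source = "continuous", cv$continuous$curves),
                          cbind(source = "intermittent", cv$intermittent$curves))
          write_table(curves, out(sprintf("cv_%s_curves.csv", w)))
          wres$cv <- cv
        }
      }
      report$windows[[w]] <- wres
    }

    stage <- "manifest"
    class(report) <- "run_report"
    finish_run(report, config, out)
  }, error = function(e) {
    stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

finish_run <- function(report, config, out) {
  cfg_yaml <- yaml::as.yaml(strip_config(config))
  manifest <- list(
    package = "bpvar",
    package_version = as.character(utils::packageVersion("bpvar")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    windows = config$windows,
    band_convention = config$wavelet$band_convention,
    config_sha = substr(config_hash(cfg_yaml), 1, 16),
    outputs = sort(list.files(config$outdir, pattern = "\\.csv$")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  report$manifest <- manifest
  report
}

strip_config <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL          # the hash covers the analysis, not its location
  cfg$qc <- unclass(cfg$qc)
  cfg$wavelet <- unclass(cfg$wavelet)
  if (!is.null(cfg$simulate)) cfg$simulate <- unclass(cfg$simulate)
  cfg
}

config_hash <- function(yaml_text) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml_text, tmp)
  unname(tools::md5sum(tmp))
}

#' Human-readable run summary
#'
#' Per window: eligible n, HT n and %, top associated features by adjusted
#' p-value; for CV windows the AUC/AP of each source with CIs and the paired
#' comparison p-values.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param n_top Number of top features to list.
#' @return Character vector of summary lines (also printed invisibly usable).
#' @export
summarize_run <- function(report, n_top = 5L) {
  lines <- c(sprintf("bpvar run (seed %d), %d window(s)",
                     report$config$seed, length(report$windows)))
  for (w in names(report$windows)) {
    wr <- report$windows[[w]]
    lines <- c(lines, sprintf("== window %s: eligible n=%d", w, wr$n_eligible))
    if (!is.null(wr$n_ht)) {
      lines <- c(lines, sprintf("   HT: %d (%.0f%%)", wr$n_ht,
                                100 * wr$n_ht / wr$n_eligible))
    }
    if (!is.null(wr$associations) && nrow(wr$associations)) {
      adj <- wr$associations[wr$associations$model == "multivariable", ]
      adj <- adj[order(adj$p), ]
      sig <- sum(adj$p < report$config$inference$alpha)
      if (sig == 0) {
        lines <- c(lines, sprintf(
          "   no feature significant at alpha=%.2f (adjusted models)",
          report$config$inference$alpha))
      } else {
        top <- utils::head(adj, n_top)
        lines <- c(lines, sprintf(
          "   top adjusted features: %s",
          paste(sprintf("%s (OR %.2f, p=%.3g)", top$feature, top$or, top$p),
                collapse = "; ")))
      }
    }
    if (!is.null(wr$cv)) {
      f <- function(a) sprintf("%.2f (%.2f-%.2f)", a["mean"], a["lo"], a["hi"])
      lines <- c(lines,
        sprintf("   CV AUC continuous %s vs intermittent %s (paired p=%.3g)",
                f(wr$cv$continuous$auc), f(wr$cv$intermittent$auc),
                wr$cv$comparison$auc["p"]),
        sprintf("   CV AP  continuous %s vs intermittent %s (paired p=%.3g)",
                f(wr$cv$continuous$ap), f(wr$cv$intermittent$ap),
                wr$cv$comparison$ap["p"]))
    }
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(summarize_run(x), sep = "\n")
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `qc`, `features`, `associate`, `predict`,
#' `run-all` (each runs the pipeline up to and including the named stage).
#' Flags: `--config <yaml>`, `--seed <int>`, `--windows P1,P2`,
#' `--outdir <dir>`, `--band-convention finest-1-2min|finest-2-4min`.
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return The run report, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: bpvar <simulate|qc|features|associate|predict|run-all> ",
         "[--config F] [--seed N] [--windows W1,W2] [--outdir D] ",
         "[--band-convention C]")
  }
  cmd <- args[1]
  stopifnot(cmd %in% c("simulate", "qc", "features", "associate", "predict",
                       "run-all"))
  opt <- list(config = NULL, seed = NULL, windows = NULL, outdir = NULL,
              `band-convention` = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) stop("bad flag: ", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  over <- list()
  if (!is.null(opt$seed)) over$seed <- as.integer(opt$seed)
  if (!is.null(opt$windows)) over$windows <- strsplit(opt$windows, ",")[[1]]
  if (!is.null(opt$outdir)) over$outdir <- opt$outdir
  cfg <- if (!is.null(opt$config)) {
    do.call(read_run_config, c(list(opt$config), over))
  } else {
    do.call(run_config, c(list(simulate = list()), over))
  }
  if (!is.null(opt$`band-convention`)) {
    cfg$wavelet$band_convention <- match.arg(
      opt$`band-convention`, c("finest-1-2min", "finest-2-4min"))
  }
  if (cmd == "simulate" && is.null(cfg$simulate)) {
    stop("subcommand 'simulate' requires simulation parameters")
  }
  stages <- switch(cmd,
    simulate = character(),
    qc = "qc",
    features = c("qc", "features"),
    associate = c("qc", "features", "associate"),
    predict = ,
    `run-all` = c("qc", "features", "associate", "predict"))
  report <- run_pipeline(cfg, stages = stages)
  cat(summarize_run(report), sep = "\n")
  invisible(report)
}
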