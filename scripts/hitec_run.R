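#!/usr/bin/env Rscript
# Thin command-line front end over the packaged experiments.
#
#   Rscript scripts/hitec_run.R run --experiment simon --trials 100 --seed 1 \
#       --out results/ [--params FILE] [--trace]
#   Rscript scripts/hitec_run.R trace --experiment simon --condition neutral \
#       --trial 1 --seed 1 --out results/
#   Rscript scripts/hitec_run.R calibrate --space FILE --out results/
#
# Outputs: <out>/<experiment>_results.csv (canonical), provenance JSON, and
# optional per-trial trace CSVs. Plots are deliberately left to the package's
# plot() methods; CSV is the canonical output.

suppressMessages({
  library(hitec)
  have_optparse <- requireNamespace("optparse", quietly = TRUE)
})

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) {
  cat("usage: hitec_run.R {run|trace|calibrate} [options]\n")
  quit(status = 1)
}
cmd <- argv[1]
rest <- argv[-1]

if (have_optparse) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--experiment", type = "character", default = "simon"),
    optparse::make_option("--params", type = "character", default = NULL),
    optparse::make_option("--trials", type = "integer", default = 100L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "results"),
    optparse::make_option("--condition", type = "character", default = NULL),
    optparse::make_option("--trial", type = "integer", default = 1L),
    optparse::make_option("--space", type = "character", default = NULL),
    optparse::make_option("--trace", action = "store_true", default = FALSE)
  )), args = rest)
} else {
  # minimal fallback parser: --flag value pairs, --trace switch
  opts <- list(experiment = "simon", params = NULL, trials = 100L, seed = 1L,
               out = "results", condition = NULL, trial = 1L, space = NULL,
               trace = FALSE)
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (key == "trace") { opts$trace <- TRUE; i <- i + 1; next }
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }
  opts$trials <- as.integer(opts$trials)
  opts$seed <- as.integer(opts$seed)
  opts$trial <- as.integer(opts$trial)
}

die <- function(msg) { cat("error:", msg, "\n"); quit(status = 1) }
if (!cmd %in% c("run", "trace", "calibrate")) die(paste("unknown command", cmd))
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)

load_pars <- function() {
  if (is.null(opts$params)) {
    list(network = network_params(), learning = learning_params())
  } else {
    if (!file.exists(opts$params)) die(paste("no such file:", opts$params))
    read_params(opts$params)
  }
}

if (cmd == "run") {
  if (!opts$experiment %in% EXPERIMENT_NAMES) {
    die(paste("unknown experiment", opts$experiment))
  }
  pars <- load_pars()
  es <- hitec_experiment(opts$experiment, params = pars$network,
                         learning = pars$learning,
                         n_trials = opts$trials, seed = opts$seed)
  res <- run_experiment(es)
  print(res)
  csv <- file.path(opts$out, paste0(opts$experiment, "_results.csv"))
  write_results(res, csv)
  write_report(res, file.path(opts$out, paste0(opts$experiment, "_report.json")))
  for (g in names(res$histories)) {
    write_weight_history(res$histories[[g]],
                         file.path(opts$out,
                                   sprintf("%s_%s_weights.csv",
                                           opts$experiment, g)))
  }
  cat("results written to", csv, "\n")
} else if (cmd == "trace") {
  pars <- load_pars()
  es <- hitec_experiment(opts$experiment, params = pars$network,
                         learning = pars$learning,
                         n_trials = opts$trials, seed = opts$seed)
  if (is.null(opts$condition) || !opts$condition %in% names(es$conditions)) {
    die(paste("unknown condition; pick one of:",
              paste(names(es$conditions), collapse = ", ")))
  }
  for (gn in names(es$groups)) {
    g <- es$groups[[gn]]
    nw <- learning_phase(build_model(g$spec), seed = opts$seed)$network
    if (!is.null(g$task2)) nw <- internalize_task(nw, g$task2)
    tr <- run_trial(nw, es$conditions[[opts$condition]],
                    seed = opts$seed + opts$trial, record_trace = TRUE)
    print(tr)
    f <- file.path(opts$out, sprintf("%s_%s_%s_trial%d.csv",
                                     opts$experiment, gn, opts$condition,
                                     opts$trial))
    trace_df(tr, file = f, network = nw)
    cat("trace written to", f, "\n")
  }
} else if (cmd == "calibrate") {
  if (is.null(opts$space)) die("calibrate needs --space FILE (YAML)")
  space <- yaml::read_yaml(opts$space)
  out <- calibrate_params(space, seed = opts$seed)
  utils::write.csv(out$log, file.path(opts$out, "calibration_log.csv"),
                   row.names = FALSE)
  cat(if (out$satisfied) "satisfying parameter set found\n"
      else "no satisfying set; nearest misses logged\n")
}
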