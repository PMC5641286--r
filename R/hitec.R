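#' Fit a perception-action model: build, instruct, learn
#'
#' The central entry point. Builds the layered network from a declarative
#' spec, internalizes the task instruction, and runs the motor-babbling
#' learning phase that acquires the feature-to-motor (action-effect)
#' weights. The result is a fitted model: `coef()` returns the learned
#' weights, `predict()` runs a noiseless trial for a stimulus, `simulate()`
#' runs seeded noisy trials, and `plot()` draws activation time courses or
#' the learning trajectory.
#'
#' @param spec A [model_spec()] (its `$task`, if set, is the instruction in
#'   place during learning).
#' @param instruction Optional [task_instruction()] applied *after* the
#'   learning phase (second-phase rewiring; learned weights are untouched).
#' @param seed Integer seed for the learning phase's noise streams.
#' @param learn Run the learning phase (default TRUE).
#' @return An object of class `"hitec"`: list with `network`, `spec`,
#'   `history` (learning weight trajectory), `seed`, `call`.
#' @export
#' @examples
#' es <- hitec_experiment("simon")
#' fit <- hitec(es$groups$instructed$spec, seed = 1)
#' round(coef(fit), 2)
#' predict(fit, c("Auditory high", "Auditory left"))
hitec <- function(spec, instruction = NULL, seed = 1L, learn = TRUE) {
  stopifnot(inherits(spec, "hitec_spec"))
  nw <- build_model(spec)
  history <- NULL
  if (learn) {
    if (!length(spec$effects)) {
      stop("learning requires an action-effect schedule in the spec",
           call. = FALSE)
    }
    lp <- learning_phase(nw, seed = seed)
    nw <- lp$network
    history <- lp$history
  }
  if (!is.null(instruction)) nw <- internalize_task(nw, instruction)
  structure(list(network = nw, spec = spec, history = history,
                 seed = as.integer(seed), call = match.call()),
            class = "hitec")
}

#' @export
print.hitec <- function(x, ...) {
  cat("Fitted perception-action network ('", x$spec$name, "')\n", sep = "")
  print(x$network)
  if (!is.null(x$history)) {
    cat(sprintf("  learning: %d trials; strongest learned weight %.3f\n",
                max(x$history$trial), max(coef(x))))
  }
  invisible(x)
}

#' @export
coef.hitec <- function(object, ...) learned_weights(object$network)

#' @export
summary.hitec <- function(object, ...) {
  w <- coef(object)
  structure(list(spec = object$spec, weights = w,
                 n_units = nrow(object$network$units),
                 n_trials = if (is.null(object$history)) 0L else
                   max(object$history$trial)),
            class = "summary.hitec")
}

#' @export
print.summary.hitec <- function(x, ...) {
  print(x$spec)
  cat(sprintf("%d units; %d learning trials\n", x$n_units, x$n_trials))
  cat("Learned feature-to-motor weights:\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Predict the selected response for a stimulus
#'
#' Runs a single noise-free trial (noise SD forced to zero) and reports the
#' winning motor code and the cycles-to-threshold, the model's deterministic
#' reaction-time proxy.
#'
#' @param object A fitted `hitec` model.
#' @param stimulus Stimulus map.
#' @param ... Unused.
#' @return A one-row data.frame: `winner`, `cycles`, `tie`, `omission`.
#' @export
predict.hitec <- function(object, stimulus, ...) {
  nw <- object$network
  nw$params$noise_sd <- 0
  nw$params$noise_mean <- 0
  tr <- run_trial(nw, stimulus, record_trace = FALSE)
  data.frame(winner = tr$winner, cycles = tr$cycles, tie = tr$tie,
             omission = tr$omission, stringsAsFactors = FALSE)
}

#' Simulate seeded trials of a fitted model
#'
#' @param object A fitted `hitec` model.
#' @param nsim Number of trials.
#' @param seed Base seed; trial `i` uses a stream derived from `(seed, i)`.
#' @param stimulus Stimulus map held constant across trials.
#' @param ... Unused.
#' @return A data.frame with one row per trial: `trial`, `winner`, `cycles`,
#'   `tie`, `omission`.
#' @export
simulate.hitec <- function(object, nsim = 1, seed = 1L,
                           stimulus = character(), ...) {
  rows <- lapply(seq_len(nsim), function(i) {
    tr <- run_trial(object$network, stimulus, seed = derive_seed(seed, i),
                    record_trace = FALSE)
    data.frame(trial = i, winner = tr$winner, cycles = tr$cycles,
               tie = tr$tie, omission = tr$omission, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot activation time courses or the learning trajectory
#'
#' @param x A fitted `hitec` model.
#' @param type `"trace"` draws per-cycle activations of selected units for
#'   one noise-free trial of `stimulus`; `"learning"` draws the learned
#'   weight trajectories over babbling trials.
#' @param stimulus Stimulus map (for `type = "trace"`).
#' @param units Unit ids to draw (default: feature and motor units).
#' @param ... Passed to [graphics::matplot()].
#' @return The plotted data, invisibly.
#' @export
plot.hitec <- function(x, type = c("trace", "learning"),
                       stimulus = character(), units = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    nw <- x$network
    nw$params$noise_sd <- 0
    tr <- run_trial(nw, stimulus, record_trace = TRUE)
    if (is.null(units)) {
      u <- nw$units
      units <- u$id[u$polarity == "excitatory" & u$level %in% c("feature", "motor")]
    }
    m <- tr$trace[, units, drop = FALSE]
    graphics::matplot(seq_len(nrow(m)) - 1L, m, type = "l", lty = 1,
                      xlab = "cycle", ylab = "activation", ylim = c(0, 1), ...)
    graphics::abline(h = nw$params$response_threshold, lty = 3)
    graphics::legend("topleft", legend = units, col = seq_along(units),
                     lty = 1, cex = 0.7, bty = "n")
    return(invisible(m))
  }
  if (is.null(x$history)) stop("model has no learning history", call. = FALSE)
  h <- x$history
  h$edge <- paste(h$src, h$dst, sep = " -> ")
  # draw only edges that moved appreciably, to keep the panel readable
  final <- h[h$trial == max(h$trial), ]
  keep <- final$edge[final$weight > 0.02]
  wide <- stats::reshape(h[h$edge %in% keep, c("trial", "edge", "weight")],
                         idvar = "trial", timevar = "edge",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub("^weight\\.", "", colnames(m))
  graphics::matplot(wide$trial, m, type = "l", lty = 1,
                    xlab = "learning trial", ylab = "connection weight",
                    ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = colnames(m), col = seq_len(ncol(m)),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(m)
}

#' Provenance hash of a model or experiment specification
#'
#' A small FNV-1a hash over the serialized object, embedded in result files
#' so outputs can be traced to the exact configuration that produced them.
#'
#' @param x Any R object.
#' @return An 8-hex-digit character scalar.
#' @export
spec_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Write a provenance report for an experiment run
#'
#' Bundles the parameter set, spec hashes and condition summaries as JSON.
#'
#' @param results A `hitec_results` object.
#' @param file Output path.
#' @return The report list, invisibly.
#' @export
write_report <- function(results, file) {
  espec <- results$espec
  report <- list(
    experiment = espec$name,
    n_trials = espec$n_trials,
    seed = espec$seed,
    spec_hash = spec_hash(lapply(espec$groups, `[[`, "spec")),
    params = unclass(espec$groups[[1]]$spec$params),
    learning = unclass(espec$groups[[1]]$spec$learning),
    weights = espec$groups[[1]]$spec$weights,
    summary = results$summary
  )
  jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(report)
}
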