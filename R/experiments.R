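#' Built-in experiment names
#' @export
EXPERIMENT_NAMES <- c("elsner_hommel", "kunde", "simon", "stroop",
                      "hommel_inversion")

#' Experiment specification
#'
#' Bundles the model instances (groups), the task instructions per phase, the
#' named stimulus maps (conditions) and the trial counts of one simulated
#' behavioral study. Groups share all spec content except the task
#' instruction or the action-effect schedule, mirroring between-subject
#' manipulations.
#'
#' @param name Experiment name.
#' @param groups Named list; each group is `list(spec =, task2 = NULL)`:
#'   `spec` a [model_spec()] (its `$task` is the instruction in place during
#'   learning), `task2` an optional second-phase [task_instruction()] applied
#'   after learning.
#' @param conditions Named list of stimulus maps shared by all groups.
#' @param n_trials Trials per condition.
#' @param seed Base seed; every trial's noise stream derives from it.
#' @return An object of class `"hitec_experiment"`.
#' @export
experiment_spec <- function(name, groups, conditions, n_trials = 100L,
                            seed = 1L) {
  stopifnot(length(groups) >= 1, length(conditions) >= 1)
  if (is.null(names(groups)) || is.null(names(conditions))) {
    stop("groups and conditions must be named", call. = FALSE)
  }
  for (g in groups) {
    codes <- spec_codes(g$spec)
    for (stim in conditions) {
      ids <- if (is.null(names(stim))) as.character(stim) else names(stim)
      bad <- setdiff(ids, codes)
      if (length(bad)) {
        stop("condition references unknown code(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(list(name = name, groups = groups, conditions = conditions,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "hitec_experiment")
}

#' Run one experimental condition
#'
#' Runs `n_trials` seeded trials of a constant stimulus on a network whose
#' learned weights are already in place and summarizes cycles-to-threshold.
#' The mean and SD are computed over non-omission trials; omissions and exact
#' ties are counted, not dropped silently.
#'
#' @param nw A `hitec_network` (post learning phase).
#' @param stimulus Stimulus map for the condition.
#' @param n_trials Number of trials.
#' @param seed Base seed; trial `i` uses a stream derived from `(seed, i)`.
#' @param condition Condition label for the summary row.
#' @return A one-row data.frame: `condition`, `n`, `mean_cycles`,
#'   `sd_cycles`, `omissions`, `ties`, with the per-trial cycle counts in
#'   `attr(, "cycles")`.
#' @export
run_condition <- function(nw, stimulus, n_trials = 100L, seed = 1L,
                          condition = "condition") {
  cycles <- integer(n_trials)
  omit <- logical(n_trials)
  tie <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    tr <- run_trial(nw, stimulus, seed = derive_seed(seed, i),
                    record_trace = FALSE)
    cycles[i] <- tr$cycles
    omit[i] <- tr$omission
    tie[i] <- tr$tie
  }
  ok <- !omit
  if (mean(omit) > 0.1) {
    warning(sprintf("condition '%s': omission rate %.0f%%", condition,
                    100 * mean(omit)), call. = FALSE)
  }
  out <- data.frame(
    condition = condition, n = n_trials,
    mean_cycles = if (any(ok)) mean(cycles[ok]) else NA_real_,
    sd_cycles = if (sum(ok) > 1) stats::sd(cycles[ok]) else 0,
    omissions = sum(omit), ties = sum(tie),
    stringsAsFactors = FALSE)
  attr(out, "cycles") <- cycles[ok]
  out
}

#' Run a full two-phase experiment
#'
#' For each group: builds the model, internalizes the learning-phase task
#' instruction, runs the motor-babbling learning phase, optionally rewires
#' the task codes to a second-phase instruction, then runs every condition.
#'
#' @param espec A [experiment_spec()].
#' @return An object of class `"hitec_results"`: list with `summary` (one
#'   data.frame row per group x condition), `networks` (post-learning,
#'   post-rewiring networks per group), `histories` (learning weight
#'   histories per group), and the originating `espec`.
#' @export
run_experiment <- function(espec) {
  stopifnot(inherits(espec, "hitec_experiment"))
  rows <- list()
  networks <- list()
  histories <- list()
  for (gi in seq_along(espec$groups)) {
    gname <- names(espec$groups)[gi]
    grp <- espec$groups[[gi]]
    nw <- build_model(grp$spec)
    lp <- learning_phase(nw, seed = derive_seed(espec$seed, 10000L + gi))
    nw <- lp$network
    if (!is.null(grp$task2)) nw <- internalize_task(nw, grp$task2)
    networks[[gname]] <- nw
    histories[[gname]] <- lp$history
    for (ci in seq_along(espec$conditions)) {
      cname <- names(espec$conditions)[ci]
      row <- run_condition(nw, espec$conditions[[ci]],
                           n_trials = espec$n_trials,
                           seed = derive_seed(espec$seed, 100L * gi + ci),
                           condition = cname)
      row <- cbind(data.frame(experiment = espec$name, group = gname,
                              stringsAsFactors = FALSE), row)
      attr(row, "cycles") <- NULL
      rows[[length(rows) + 1L]] <- row
    }
  }
  structure(list(summary = do.call(rbind, rows), networks = networks,
                 histories = histories, espec = espec),
            class = "hitec_results")
}

#' @export
print.hitec_results <- function(x, ...) {
  cat(sprintf("Experiment '%s' (%d trials/condition):\n",
              x$espec$name, x$espec$n_trials))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %-16s %6.1f cycles (SD %.1f, omissions %d)\n",
                s$group[i], s$condition[i], s$mean_cycles[i], s$sd_cycles[i],
                s$omissions[i]))
  }
  invisible(x)
}

#' Export an experiment summary as CSV
#'
#' @param results A `hitec_results` object.
#' @param file Output path.
#' @return The summary data.frame, invisibly.
#' @export
write_results <- function(results, file) {
  utils::write.csv(results$summary, file, row.names = FALSE)
  invisible(results$summary)
}

# ---------------------------------------------------------------------------
# Built-in model instances and experiments
# ---------------------------------------------------------------------------

#' Built-in experiment configurations
#'
#' Constructs the seeded configuration of one of the five packaged
#' stimulus-response compatibility studies:
#' \describe{
#'   \item{elsner_hommel}{Action-effect learning. Free-choice keypresses
#'     produce tones during learning; afterwards the tones become imperative
#'     stimuli under a non-reversal or reversal mapping (two groups differing
#'     in the second-phase instruction only).}
#'   \item{kunde}{Response-effect compatibility. Two groups learn consistent
#'     vs inconsistent intensity effects (forceful press with loud vs soft
#'     tone) and then respond to color cues.}
#'   \item{simon}{Auditory Simon task: respond to pitch with a left/right
#'     key; tone location is task-irrelevant (compatible / neutral /
#'     incompatible).}
#'   \item{stroop}{Color-word interference, structurally isomorphic to the
#'     Simon configuration under code renaming.}
#'   \item{hommel_inversion}{Inverted Simon task: keypresses flash a light on
#'     the opposite side; a Key-instruction group and a Light-instruction
#'     group differ in the task wiring alone.}
#' }
#'
#' @param name One of `EXPERIMENT_NAMES`.
#' @param params A [network_params()] object.
#' @param learning A [learning_params()] object.
#' @param weights Hand-set weights, see [default_weights()].
#' @param n_trials Trials per condition.
#' @param seed Base seed.
#' @return A [experiment_spec()].
#' @export
#' @examples
#' es <- hitec_experiment("simon", n_trials = 5)
#' names(es$conditions)
hitec_experiment <- function(name = EXPERIMENT_NAMES,
                             params = network_params(),
                             learning = learning_params(),
                             weights = default_weights(),
                             n_trials = 100L,
                             seed = 1L) {
  name <- match.arg(name)
  builder <- switch(name,
    elsner_hommel = experiment_elsner_hommel,
    kunde = experiment_kunde,
    simon = experiment_simon,
    stroop = experiment_stroop,
    hommel_inversion = experiment_hommel_inversion)
  builder(params, learning, weights, n_trials, seed)
}

spec_sim1 <- function(params, learning, weights) {
  model_spec(
    name = "action_effect_learning",
    layers = list(
      list(name = "visual_shape", level = "sensory", codes = "Visual square"),
      list(name = "auditory_pitch", level = "sensory",
           codes = c("Auditory high", "Auditory low")),
      list(name = "haptic_location", level = "sensory",
           codes = c("Haptic left", "Haptic right")),
      list(name = "shape", level = "feature", codes = "Square"),
      list(name = "pitch", level = "feature", codes = c("High", "Low")),
      list(name = "location", level = "feature", codes = c("Left", "Right")),
      list(name = "object", level = "feature", codes = c("Sound", "Key")),
      list(name = "task", level = "task", codes = c("T1", "T2")),
      list(name = "motor", level = "motor", codes = c("M1", "M2"))
    ),
    sensory_feature_map = list(
      "Square" = "Visual square",
      "High" = "Auditory high",
      "Low" = "Auditory low",
      "Left" = "Haptic left",
      "Right" = "Haptic right",
      "Sound" = c("Auditory high", "Auditory low"),
      "Key" = c("Haptic left", "Haptic right")
    ),
    effects = list(
      "M1" = c("Haptic left", "Auditory low"),
      "M2" = c("Haptic right", "Auditory high")
    ),
    weights = weights, params = params, learning = learning
  )
}

#' @rdname hitec_experiment
#' @export
experiment_elsner_hommel <- function(params = network_params(),
                                     learning = learning_params(),
                                     weights = default_weights(),
                                     n_trials = 100L, seed = 1L) {
  spec <- spec_sim1(params, learning, weights)
  # learning phase: "press a key when the cue appears"; the key choice itself
  # is free (the babbling schedule drives the motor codes directly)
  spec$task <- task_instruction(
    list(stimulus = "Square", task = "T1", response = "Key"),
    list(stimulus = "Square", task = "T2", response = "Key"))
  non_reversal <- task_instruction(
    list(stimulus = "Low", task = "T1", response = c("Left", "Key")),
    list(stimulus = "High", task = "T2", response = c("Right", "Key")))
  reversal <- task_instruction(
    list(stimulus = "Low", task = "T1", response = c("Right", "Key")),
    list(stimulus = "High", task = "T2", response = c("Left", "Key")))
  experiment_spec(
    name = "elsner_hommel",
    groups = list(
      non_reversal = list(spec = spec, task2 = non_reversal),
      reversal = list(spec = spec, task2 = reversal)
    ),
    conditions = list(
      tone_low = "Auditory low",
      tone_high = "Auditory high"
    ),
    n_trials = n_trials, seed = seed
  )
}

spec_sim2 <- function(params, learning, weights) {
  spec <- model_spec(
    name = "response_effect_compatibility",
    layers = list(
      list(name = "visual_color", level = "sensory",
           codes = c("Visual red", "Visual green")),
      list(name = "auditory_intensity", level = "sensory",
           codes = c("Auditory loud", "Auditory soft")),
      list(name = "haptic_intensity", level = "sensory",
           codes = c("Haptic forceful", "Haptic gentle")),
      list(name = "color", level = "feature", codes = c("Red", "Green")),
      list(name = "intensity", level = "feature",
           codes = c("Forceful", "Gentle")),
      list(name = "object", level = "feature", codes = c("Sound", "Key")),
      list(name = "task", level = "task", codes = c("T1", "T2")),
      list(name = "motor", level = "motor", codes = c("M1", "M2"))
    ),
    # auditory and haptic intensity sensations share the distal intensity
    # feature codes: that sharing is what makes effect consistency matter
    sensory_feature_map = list(
      "Red" = "Visual red",
      "Green" = "Visual green",
      "Forceful" = c("Auditory loud", "Haptic forceful"),
      "Gentle" = c("Auditory soft", "Haptic gentle"),
      "Sound" = c("Auditory loud", "Auditory soft"),
      "Key" = c("Haptic forceful", "Haptic gentle")
    ),
    weights = weights, params = params, learning = learning
  )
  spec$task <- task_instruction(
    list(stimulus = "Red", task = "T1", response = c("Forceful", "Key")),
    list(stimulus = "Green", task = "T2", response = c("Gentle", "Key")))
  spec
}

#' @rdname hitec_experiment
#' @export
experiment_kunde <- function(params = network_params(),
                             learning = learning_params(),
                             weights = default_weights(),
                             n_trials = 100L, seed = 1L) {
  spec_c <- spec_sim2(params, learning, weights)
  spec_c$effects <- list(
    "M1" = c("Haptic forceful", "Auditory loud"),
    "M2" = c("Haptic gentle", "Auditory soft"))
  spec_i <- spec_sim2(params, learning, weights)
  spec_i$effects <- list(
    "M1" = c("Haptic forceful", "Auditory soft"),
    "M2" = c("Haptic gentle", "Auditory loud"))
  experiment_spec(
    name = "kunde",
    groups = list(
      consistent = list(spec = spec_c),
      inconsistent = list(spec = spec_i)
    ),
    conditions = list(
      cue_red = "Visual red",
      cue_green = "Visual green"
    ),
    n_trials = n_trials, seed = seed
  )
}

spec_sim3 <- function(params, learning, weights) {
  spec <- model_spec(
    name = "simon",
    layers = list(
      list(name = "auditory_pitch", level = "sensory",
           codes = c("Auditory high", "Auditory low")),
      list(name = "auditory_location", level = "sensory",
           codes = c("Auditory left", "Auditory right")),
      list(name = "haptic_location", level = "sensory",
           codes = c("Haptic left", "Haptic right")),
      list(name = "pitch", level = "feature", codes = c("High", "Low")),
      list(name = "location", level = "feature", codes = c("Left", "Right")),
      list(name = "object", level = "feature", codes = "Key"),
      list(name = "task", level = "task", codes = c("T1", "T2")),
      list(name = "motor", level = "motor", codes = c("M1", "M2"))
    ),
    # the location feature codes encode both stimulus location and response
    # location: the code overlap that produces the compatibility effect
    sensory_feature_map = list(
      "High" = "Auditory high",
      "Low" = "Auditory low",
      "Left" = c("Auditory left", "Haptic left"),
      "Right" = c("Auditory right", "Haptic right"),
      "Key" = c("Haptic left", "Haptic right")
    ),
    effects = list(
      "M1" = "Haptic left",
      "M2" = "Haptic right"
    ),
    weights = weights, params = params, learning = learning
  )
  spec$task <- task_instruction(
    list(stimulus = "High", task = "T1", response = c("Left", "Key")),
    list(stimulus = "Low", task = "T2", response = c("Right", "Key")))
  spec
}

#' @rdname hitec_experiment
#' @export
experiment_simon <- function(params = network_params(),
                             learning = learning_params(),
                             weights = default_weights(),
                             n_trials = 100L, seed = 1L) {
  spec <- spec_sim3(params, learning, weights)
  experiment_spec(
    name = "simon",
    groups = list(instructed = list(spec = spec)),
    conditions = list(
      compatible = c("Auditory high", "Auditory left"),
      neutral = "Auditory high",
      incompatible = c("Auditory high", "Auditory right")
    ),
    n_trials = n_trials, seed = seed
  )
}

# Rename map from the Simon instance onto the color-word instance. Applying
# it to the Simon spec yields a structurally identical network in the same
# unit order, so matched seeds give bit-identical trials.
stroop_rename <- c(
  "Auditory high" = "Ink red", "Auditory low" = "Ink green",
  "Auditory left" = "Word RED", "Auditory right" = "Word GREEN",
  "Haptic left" = "Heard red", "Haptic right" = "Heard green",
  "High" = "RedColor", "Low" = "GreenColor",
  "Left" = "RedWord", "Right" = "GreenWord",
  "Key" = "Verbal",
  "auditory_pitch" = "ink_color", "auditory_location" = "visual_word",
  "haptic_location" = "auditory_word",
  "pitch" = "color", "location" = "word", "object" = "modality",
  "simon" = "stroop"
)

rename_spec <- function(spec, map) {
  ren <- function(x) {
    hit <- x %in% names(map)
    x[hit] <- unname(map[x[hit]])
    x
  }
  spec$name <- ren(spec$name)
  spec$layers <- lapply(spec$layers, function(l) {
    l$name <- ren(l$name); l$codes <- ren(l$codes); l
  })
  if (!is.null(spec$sensory_feature_map)) {
    spec$sensory_feature_map <- stats::setNames(
      lapply(spec$sensory_feature_map, ren),
      ren(names(spec$sensory_feature_map)))
  }
  if (!is.null(spec$connections)) {
    spec$connections$src <- ren(spec$connections$src)
    spec$connections$dst <- ren(spec$connections$dst)
  }
  spec$effects <- stats::setNames(lapply(spec$effects, ren),
                                  ren(names(spec$effects)))
  if (!is.null(spec$task)) {
    spec$task$rules <- lapply(spec$task$rules, function(r) {
      list(stimulus = ren(r$stimulus), task = ren(r$task),
           response = ren(r$response))
    })
  }
  spec
}

#' @rdname hitec_experiment
#' @export
experiment_stroop <- function(params = network_params(),
                              learning = learning_params(),
                              weights = default_weights(),
                              n_trials = 100L, seed = 1L) {
  spec <- rename_spec(spec_sim3(params, learning, weights), stroop_rename)
  experiment_spec(
    name = "stroop",
    groups = list(instructed = list(spec = spec)),
    conditions = list(
      compatible = c("Ink red", "Word RED"),
      neutral = "Ink red",
      incompatible = c("Ink red", "Word GREEN")
    ),
    n_trials = n_trials, seed = seed
  )
}

spec_sim5 <- function(params, learning, weights) {
  model_spec(
    name = "inverted_simon",
    layers = list(
      list(name = "auditory_pitch", level = "sensory",
           codes = c("Auditory high", "Auditory low")),
      list(name = "auditory_location", level = "sensory",
           codes = c("Auditory left", "Auditory right")),
      list(name = "haptic_location", level = "sensory",
           codes = c("Haptic left", "Haptic right")),
      list(name = "visual_location", level = "sensory",
           codes = c("Light left", "Light right")),
      list(name = "pitch", level = "feature", codes = c("High", "Low")),
      list(name = "location", level = "feature", codes = c("Left", "Right")),
      list(name = "object", level = "feature", codes = c("Key", "Light")),
      list(name = "task", level = "task", codes = c("T1", "T2")),
      list(name = "motor", level = "motor", codes = c("M1", "M2"))
    ),
    sensory_feature_map = list(
      "High" = "Auditory high",
      "Low" = "Auditory low",
      "Left" = c("Auditory left", "Haptic left", "Light left"),
      "Right" = c("Auditory right", "Haptic right", "Light right"),
      "Key" = c("Haptic left", "Haptic right"),
      "Light" = c("Light left", "Light right")
    ),
    # pressing a key flashes the light on the opposite side
    effects = list(
      "M1" = c("Haptic left", "Light right"),
      "M2" = c("Haptic right", "Light left")
    ),
    weights = weights, params = params, learning = learning
  )
}

#' @rdname hitec_experiment
#' @export
experiment_hommel_inversion <- function(params = network_params(),
                                        learning = learning_params(),
                                        weights = default_weights(),
                                        n_trials = 100L, seed = 1L) {
  key_instruction <- task_instruction(
    list(stimulus = "High", task = "T1", response = c("Left", "Key")),
    list(stimulus = "Low", task = "T2", response = c("Right", "Key")))
  # "flash the right light when you hear a high tone": the right light is
  # flashed by the left key, so the required movement is the same as under
  # the key instruction -- only the goal coding differs
  light_instruction <- task_instruction(
    list(stimulus = "High", task = "T1", response = c("Right", "Light")),
    list(stimulus = "Low", task = "T2", response = c("Left", "Light")))
  spec_key <- spec_sim5(params, learning, weights)
  spec_key$task <- key_instruction
  spec_light <- spec_sim5(params, learning, weights)
  spec_light$task <- light_instruction
  experiment_spec(
    name = "hommel_inversion",
    groups = list(
      key = list(spec = spec_key),
      light = list(spec = spec_light)
    ),
    # high tone: the instructed response is the left key (right light);
    # congruency labels refer to the stimulus-key relation
    conditions = list(
      congruent_key = c("Auditory high", "Auditory left"),
      neutral = "Auditory high",
      incongruent_key = c("Auditory high", "Auditory right")
    ),
    n_trials = n_trials, seed = seed
  )
}

# ---------------------------------------------------------------------------
# Calibration
# ---------------------------------------------------------------------------

#' Check the qualitative effect orderings across all five experiments
#'
#' @param results Named list of `hitec_results`, keyed by experiment name
#'   (any subset of `EXPERIMENT_NAMES`).
#' @return A named logical vector, one entry per checked ordering, plus an
#'   `omission_free` entry.
#' @export
check_orderings <- function(results) {
  m <- function(res, group, condition = NULL) {
    s <- res$summary
    keep <- s$group == group
    if (!is.null(condition)) keep <- keep & s$condition == condition
    mean(s$mean_cycles[keep])
  }
  out <- logical()
  if (!is.null(r <- results$elsner_hommel)) {
    out["sim1_nonreversal_faster"] <-
      m(r, "non_reversal") < m(r, "reversal")
  }
  if (!is.null(r <- results$kunde)) {
    out["sim2_consistent_faster"] <-
      m(r, "consistent") < m(r, "inconsistent")
  }
  if (!is.null(r <- results$simon)) {
    out["sim3_compatible_fastest"] <-
      m(r, "instructed", "compatible") < m(r, "instructed", "neutral") &&
      m(r, "instructed", "neutral") < m(r, "instructed", "incompatible")
  }
  if (!is.null(r <- results$stroop)) {
    out["sim4_compatible_fastest"] <-
      m(r, "instructed", "compatible") < m(r, "instructed", "neutral") &&
      m(r, "instructed", "neutral") < m(r, "instructed", "incompatible")
  }
  if (!is.null(r <- results$hommel_inversion)) {
    out["sim5_key_standard"] <-
      m(r, "key", "congruent_key") < m(r, "key", "neutral") &&
      m(r, "key", "neutral") < m(r, "key", "incongruent_key")
    out["sim5_light_inverted"] <-
      m(r, "light", "incongruent_key") < m(r, "light", "neutral") &&
      m(r, "light", "neutral") < m(r, "light", "congruent_key")
  }
  out["omission_free"] <-
    all(vapply(results, function(r) sum(r$summary$omissions) == 0, logical(1)))
  out
}

#' Run all five built-in experiments
#'
#' @param params,learning,weights Shared parameter set.
#' @param n_trials Trials per condition.
#' @param seed Base seed.
#' @param names Which experiments to run.
#' @return Named list of `hitec_results`.
#' @export
run_all_experiments <- function(params = network_params(),
                                learning = learning_params(),
                                weights = default_weights(),
                                n_trials = 100L, seed = 1L,
                                names = EXPERIMENT_NAMES) {
  res <- lapply(names, function(nm) {
    run_experiment(hitec_experiment(nm, params = params, learning = learning,
                                    weights = weights, n_trials = n_trials,
                                    seed = seed))
  })
  stats::setNames(res, names)
}

#' Search a parameter space for a set reproducing the effect orderings
#'
#' Grid (or random subsample) search over ranges of dynamics, learning and
#' weight parameters. A candidate satisfies the search when all qualitative
#' orderings of the five experiments hold with zero omissions.
#'
#' @param search_space Named list of candidate value vectors; names must be
#'   [network_params()], [learning_params()] or [default_weights()] fields.
#' @param n_trials Trials per condition per evaluation (small values suffice
#'   for ordering checks).
#' @param seed Base seed for all evaluations.
#' @param max_evals Cap on evaluated candidates; a larger grid is randomly
#'   subsampled (seeded).
#' @param experiments Which experiments to include in the check.
#' @return A list: `params`, `learning`, `weights` of the first satisfying
#'   candidate (or NULL if none), `satisfied` flag, and `log`, a data.frame
#'   of every evaluated candidate with its per-ordering outcomes and the
#'   number of orderings missed (nearest-miss diagnostics).
#' @export
calibrate_params <- function(search_space, n_trials = 10L, seed = 1L,
                             max_evals = 200L,
                             experiments = EXPERIMENT_NAMES) {
  net_fields <- names(formals(network_params))
  lrn_fields <- names(formals(learning_params))
  wt_fields <- names(formals(default_weights))
  unknown <- setdiff(names(search_space), c(net_fields, lrn_fields, wt_fields))
  if (length(unknown)) {
    stop("unknown search-space field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  grid <- expand.grid(search_space, stringsAsFactors = FALSE)
  if (nrow(grid) > max_evals) {
    set.seed(derive_seed(seed, 0L))
    grid <- grid[sample.int(nrow(grid), max_evals), , drop = FALSE]
  }
  log <- list()
  best <- NULL
  best_miss <- Inf
  for (i in seq_len(nrow(grid))) {
    cand <- as.list(grid[i, , drop = FALSE])
    params <- do.call(network_params, cand[intersect(names(cand), net_fields)])
    learning <- do.call(learning_params, cand[intersect(names(cand), lrn_fields)])
    weights <- do.call(default_weights, cand[intersect(names(cand), wt_fields)])
    ok_vec <- tryCatch({
      res <- suppressWarnings(
        run_all_experiments(params, learning, weights, n_trials = n_trials,
                            seed = seed, names = experiments))
      check_orderings(res)
    }, error = function(e) c(run_failed = FALSE))
    miss <- sum(!ok_vec)
    log[[i]] <- cbind(grid[i, , drop = FALSE],
                      as.data.frame(t(ok_vec)), missed = miss)
    if (miss < best_miss) {
      best_miss <- miss
      best <- list(params = params, learning = learning, weights = weights)
    }
    if (miss == 0) break
  }
  log <- do.call(rbind, lapply(log, function(d) {
    # pad columns so rows with run failures still bind
    all_cols <- unique(unlist(lapply(log, names)))
    d[setdiff(all_cols, names(d))] <- NA
    d[all_cols]
  }))
  c(best, list(satisfied = best_miss == 0, log = log))
}
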