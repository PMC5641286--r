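#' Global network dynamics parameters
#'
#' One parameter set governs every layer of a model instance: the leak rate of
#' the shunting activation equation, the input scaling, the output
#' nonlinearity, the voltage threshold gating top-down feedback, the trial
#' noise, the magnitude of external stimulation, and the response threshold
#' that terminates a trial.
#'
#' @param d_a Activation decay (leak) rate per cycle, in `[0, 1]`. With zero
#'   input a unit's activation decays as `(1 - d_a)^k`.
#' @param gamma Input scaling term applied to the net excitatory and
#'   inhibitory drive, `> 0`.
#' @param na Exponent of the sigmoid output function, `> 0`.
#' @param qa Half-saturation constant of the output function, in `(0, 1)`:
#'   a unit at activation `qa` emits output 0.5.
#' @param VT Voltage threshold, in `[0, 1)`. Top-down (voltage-dependent)
#'   input to a sensory unit is discarded while the unit's leak-scaled
#'   activation is at or below `VT`, so mere feedback cannot
#'   "hallucinate" a stimulus.
#' @param noise_sd Standard deviation of the Gaussian input noise drawn
#'   independently per excitatory unit per cycle, `>= 0`.
#' @param noise_mean Mean of that Gaussian.
#' @param ext_input Magnitude of external stimulation applied to a stimulated
#'   sensory unit (or to a directly driven motor unit during babbling),
#'   `> 0`.
#' @param response_threshold Motor activation level that terminates a trial,
#'   in `(0, 1]`.
#' @param resting_level Activation toward which units decay absent input.
#' @param max_cycles Hard cap on cycles per trial.
#' @param na_inh,qa_inh Output-function parameters of the inhibitory units;
#'   default to `na` and `qa`. A lower `qa_inh` makes paired units propagate
#'   inhibition at moderate activation, sharpening within-layer competition.
#'
#' @return An object of class `"hitec_params"` (a validated named list).
#' @seealso [learning_params()], [read_params()]
#' @export
#' @examples
#' p <- network_params(noise_sd = 0)
#' p$d_a
network_params <- function(d_a = 0.143,
                           gamma = 0.598,
                           na = 2.99,
                           qa = 0.612,
                           VT = 0.383,
                           noise_sd = 5e-04,
                           noise_mean = 0,
                           ext_input = 0.35,
                           response_threshold = 0.76,
                           resting_level = 0,
                           max_cycles = 250L,
                           na_inh = 8,
                           qa_inh = 0.49) {
  p <- list(
    d_a = d_a, gamma = gamma, na = na, qa = qa, VT = VT,
    noise_sd = noise_sd, noise_mean = noise_mean, ext_input = ext_input,
    response_threshold = response_threshold, resting_level = resting_level,
    max_cycles = as.integer(max_cycles),
    na_inh = na_inh, qa_inh = qa_inh
  )
  validate_network_params(p)
  class(p) <- "hitec_params"
  p
}

validate_network_params <- function(p) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("d_a", "gamma", "na", "qa", "VT", "noise_sd", "noise_mean",
              "ext_input", "response_threshold", "resting_level",
              "na_inh", "qa_inh")) {
    stop_if(!num1(p[[f]]), sprintf("parameter '%s' must be a finite number", f))
  }
  stop_if(p$d_a < 0 || p$d_a > 1, "d_a must be in [0, 1]")
  stop_if(p$gamma <= 0, "gamma must be > 0")
  stop_if(p$na <= 0, "na must be > 0")
  stop_if(p$qa <= 0 || p$qa >= 1, "qa must be in (0, 1)")
  stop_if(p$VT < 0 || p$VT >= 1, "VT must be in [0, 1)")
  stop_if(p$noise_sd < 0, "noise_sd must be >= 0")
  stop_if(p$ext_input <= 0, "ext_input must be > 0")
  stop_if(p$response_threshold <= 0 || p$response_threshold > 1,
          "response_threshold must be in (0, 1]")
  stop_if(p$resting_level < 0 || p$resting_level > 1,
          "resting_level must be in [0, 1]")
  stop_if(!is.numeric(p$max_cycles) || length(p$max_cycles) != 1L ||
            p$max_cycles < 1, "max_cycles must be >= 1")
  invisible(p)
}

#' Ideomotor learning parameters
#'
#' Parameters of the Hebbian feature-to-motor weight update applied at the end
#' of each learning (motor babbling) trial.
#'
#' @param d_w Weight decay rate per learning trial, in `[0, 1]`. Decay ensures
#'   only repeated co-activation yields stable weights, and bounds the fixed
#'   point of the update below 1.
#' @param LT Learning threshold on activation, in `[0, 1)`: both the feature
#'   and the motor unit must exceed `LT` for their connection to strengthen.
#' @param n_learning_trials Number of babbling trials; motor codes are driven
#'   in round-robin order.
#' @param effect_cycles Cycles of action-effect presentation per learning
#'   trial after the driven motor unit crosses the response threshold.
#' @param clamp_motor If TRUE the driven motor unit is pinned at full
#'   activation for the rest of the trial once selected, instead of being
#'   driven through the input equation. Keeps the babbled response immune to
#'   lateral suppression from competitor motor codes that earlier trials have
#'   already wired up.
#'
#' @return An object of class `"hitec_learning_params"`.
#' @export
learning_params <- function(d_w = 0.02,
                            LT = 0.312,
                            n_learning_trials = 20L,
                            effect_cycles = 50L,
                            clamp_motor = TRUE) {
  stopifnot(is.numeric(d_w), length(d_w) == 1L, d_w >= 0, d_w <= 1)
  stopifnot(is.numeric(LT), length(LT) == 1L, LT >= 0, LT < 1)
  stopifnot(n_learning_trials >= 1, effect_cycles >= 1)
  stopifnot(is.logical(clamp_motor), length(clamp_motor) == 1L)
  structure(list(d_w = d_w, LT = LT,
                 n_learning_trials = as.integer(n_learning_trials),
                 effect_cycles = as.integer(effect_cycles),
                 clamp_motor = clamp_motor),
            class = "hitec_learning_params")
}

#' Read a parameter file
#'
#' Reads a flat YAML (or JSON) map of [network_params()] and/or
#' [learning_params()] fields. Unknown keys are rejected.
#'
#' @param path Path to a YAML or JSON file.
#' @return A list with elements `network` and `learning`.
#' @export
read_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  net_fields <- names(formals(network_params))
  lrn_fields <- names(formals(learning_params))
  unknown <- setdiff(names(raw), c(net_fields, lrn_fields))
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  list(
    network = do.call(network_params, raw[intersect(names(raw), net_fields)]),
    learning = do.call(learning_params, raw[intersect(names(raw), lrn_fields)])
  )
}

#' @export
print.hitec_params <- function(x, ...) {
  cat("Network dynamics parameters:\n")
  for (f in names(x)) cat(sprintf("  %-18s %g\n", f, x[[f]]))
  invisible(x)
}

#' @export
print.hitec_learning_params <- function(x, ...) {
  cat("Ideomotor learning parameters:\n")
  for (f in names(x)) cat(sprintf("  %-18s %g\n", f, x[[f]]))
  invisible(x)
}

# Seed the RNG for one simulation while arranging for the caller's RNG state
# to be restored when `envir`'s frame exits (the convention stats::simulate()
# uses): seeded runs are reproducible without clobbering the global stream.
use_trial_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  do.call(on.exit, list(substitute(assign(".Random.seed", old, globalenv()),
                                   list(old = old)), add = TRUE),
          envir = envir)
  set.seed(seed)
  invisible(NULL)
}

# Derive a per-trial RNG seed from the experiment seed and a trial index so
# conditions are reproducible independently of execution order. Kept within
# the 32-bit integer range R's set.seed() accepts.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271) %% 2147483647
  x <- (x + as.double(index) * 69621) %% 2147483647
  as.integer(x)
}
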