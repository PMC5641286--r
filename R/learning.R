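#' Hebbian update of a learnable feature-to-motor weight
#'
#' Both activations are rescaled in proportion to the learning threshold,
#' `Act = max(0, (a - LT) / (1 - LT))`, and the weight moves as
#' `w' = (1 - d_w) w + Act_j Act_k (1 - w)`. The multiplicative `(1 - w)`
#' term and the decay keep every weight in `[0, 1]` and give repeated
#' identical co-activation the fixed point `w* = c / (d_w + c)` with
#' `c = Act_j Act_k`.
#'
#' @param w Current weight(s) in `[0, 1]`.
#' @param a_j Feature unit activation(s) in `[0, 1]`.
#' @param a_k Motor unit activation(s) in `[0, 1]`.
#' @param learning A [learning_params()] object (uses `d_w` and `LT`).
#' @return Updated weight(s), in `[0, 1]`.
#' @export
#' @examples
#' lp <- learning_params(d_w = 0.1, LT = 0.35)
#' hebbian_update(0, a_j = 1, a_k = 1, lp)  # jumps straight to 1
hebbian_update <- function(w, a_j, a_k, learning) {
  act <- function(a) pmax(0, (a - learning$LT) / (1 - learning$LT))
  c_jk <- act(a_j) * act(a_k)
  (1 - learning$d_w) * w + c_jk * (1 - w)
}

#' One motor-babbling learning trial
#'
#' From the resting state the designated motor unit is driven with external
#' input. When it crosses the response threshold the response counts as
#' executed and its action effects appear: the scheduled sensory codes
#' receive external input for `effect_cycles` cycles while the motor unit
#' continues to be driven (the default) or is clamped at full activation.
#' At the end of the trial every learnable feature-to-motor weight is updated
#' once by [hebbian_update()], with each unit's activation taken as its mean
#' over the effect window — the sustained co-activation the association
#' should reflect, robust to settling transients. No other weight changes.
#'
#' @param nw A `hitec_network`.
#' @param motor_id The motor code to drive.
#' @param effects Action-effect schedule: named list, motor code -> character
#'   vector of effect sensory codes (defaults to the spec's schedule).
#' @param learning A [learning_params()] object (defaults to the spec's).
#' @param seed Optional integer seed for the trial's noise draws.
#' @param clamp_motor If TRUE the driven motor unit is pinned at activation 1
#'   instead of being driven through the input equation.
#' @param record_trace Keep the activation trace.
#' @return A list: `network` (updated weights), `trace`, `selection_cycles`
#'   (cycles until the motor unit crossed threshold).
#' @export
learning_trial <- function(nw, motor_id, effects = NULL, learning = NULL,
                           seed = NULL, clamp_motor = NULL,
                           record_trace = FALSE) {
  if (is.null(effects)) effects <- nw$spec$effects
  if (is.null(learning)) learning <- nw$spec$learning
  stopifnot(!is.null(effects), !is.null(learning))
  if (is.null(clamp_motor)) clamp_motor <- isTRUE(learning$clamp_motor)
  if (!motor_id %in% names(effects)) {
    stop("no effect schedule for motor code '", motor_id, "'", call. = FALSE)
  }
  mi <- unit_index(nw, motor_id)
  if (!nw$units$is_motor[mi]) {
    stop("'", motor_id, "' is not a motor unit", call. = FALSE)
  }
  use_trial_seed(seed)
  p <- nw$params
  nw <- reset_network(nw)
  drive <- stats::setNames(1, motor_id)
  traces <- list()
  note <- function() if (record_trace) traces[[length(traces) + 1L]] <<- nw$A
  note()
  # phase A: drive the motor code until the response is selected
  selected <- FALSE
  for (t in seq_len(p$max_cycles)) {
    nw <- step_network(nw, drive)
    if (clamp_motor) nw$A[mi] <- 1
    note()
    if (nw$A[mi] >= p$response_threshold) {
      selected <- TRUE
      selection_cycles <- t
      break
    }
  }
  if (!selected) {
    stop("driven motor unit '", motor_id,
         "' never crossed the response threshold", call. = FALSE)
  }
  # phase B: the executed response produces perceivable effects
  effect_codes <- effects[[motor_id]]
  stim <- stats::setNames(rep(1, 1 + length(effect_codes)),
                          c(motor_id, effect_codes))
  A_sum <- numeric(length(nw$A))
  for (t in seq_len(learning$effect_cycles)) {
    nw <- step_network(nw, stim)
    if (clamp_motor) nw$A[mi] <- 1
    A_sum <- A_sum + nw$A
    note()
  }
  A_bar <- A_sum / learning$effect_cycles
  # synchronous Hebbian update of all learnable weights from the mean
  # activations over the effect window
  ln <- nw$edges$kind == "LEARNED"
  a_j <- A_bar[unit_index(nw, nw$edges$src[ln])]
  a_k <- A_bar[unit_index(nw, nw$edges$dst[ln])]
  nw$edges$weight[ln] <- hebbian_update(nw$edges$weight[ln], a_j, a_k, learning)
  nw <- compile_network(nw)
  trace <- if (record_trace) {
    m <- do.call(rbind, traces)
    colnames(m) <- nw$units$id
    m
  }
  list(network = nw, trace = trace, selection_cycles = selection_cycles)
}

#' The full motor-babbling learning phase
#'
#' Runs `n_learning_trials` trials, driving the motor codes in round-robin
#' order (M1, M2, M1, ...), and records the trajectory of every learnable
#' weight.
#'
#' @param nw A `hitec_network`.
#' @param effects,learning See [learning_trial()].
#' @param seed Integer seed; each trial's noise stream is derived from
#'   `(seed, trial index)`.
#' @param clamp_motor Passed to [learning_trial()].
#' @return A list: `network` (with learned weights), `history` (data.frame
#'   `trial`, `src`, `dst`, `weight`; trial 0 holds the initial weights).
#' @export
learning_phase <- function(nw, effects = NULL, learning = NULL, seed = 1L,
                           clamp_motor = NULL) {
  if (is.null(effects)) effects <- nw$spec$effects
  if (is.null(learning)) learning <- nw$spec$learning
  stopifnot(!is.null(effects), !is.null(learning))
  motors <- nw$units$id[nw$units$is_motor]
  hist <- list()
  snap <- function(trial) {
    ln <- nw$edges$kind == "LEARNED"
    hist[[length(hist) + 1L]] <<- data.frame(
      trial = trial, src = nw$edges$src[ln], dst = nw$edges$dst[ln],
      weight = nw$edges$weight[ln], stringsAsFactors = FALSE)
  }
  snap(0L)
  for (trial in seq_len(learning$n_learning_trials)) {
    motor_id <- motors[((trial - 1L) %% length(motors)) + 1L]
    res <- learning_trial(nw, motor_id, effects, learning,
                          seed = derive_seed(seed, trial),
                          clamp_motor = clamp_motor)
    nw <- res$network
    snap(trial)
  }
  list(network = nw, history = do.call(rbind, hist))
}

#' Learned feature-to-motor weight matrix
#'
#' @param nw A `hitec_network`.
#' @return A features x motor-codes matrix of learned weights.
#' @export
learned_weights <- function(nw) {
  ln <- nw$edges[nw$edges$kind == "LEARNED", ]
  feats <- unique(ln$src)
  motors <- unique(ln$dst)
  m <- matrix(0, length(feats), length(motors),
              dimnames = list(feats, motors))
  m[cbind(ln$src, ln$dst)] <- ln$weight
  m
}

#' Export a learning-phase weight history as CSV
#'
#' @param history The `history` data.frame from [learning_phase()].
#' @param file Output path.
#' @return The history, invisibly.
#' @export
write_weight_history <- function(history, file) {
  utils::write.csv(history, file, row.names = FALSE)
  invisible(history)
}
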