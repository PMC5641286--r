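#' @keywords internal
"_PACKAGE"

# A hitec_network is a list:
#   units : data.frame(id, layer, level, polarity, pair, is_sensory, is_motor)
#           pair: for an excitatory unit, the row index of its inhibitory
#           partner (NA for inhibitory units).
#   edges : data.frame(src, dst, weight, kind) with kind in
#           VI | VD | INH | LEARNED | PAIR (excitatory -> its inhibitory unit)
#   W_vi, W_vd, W_in : n x n weight matrices compiled from edges
#           ([src, dst] orientation); PAIR and LEARNED edges live in W_vi.
#   A     : numeric activation vector (current state)
#   params: hitec_params

EDGE_KINDS <- c("VI", "VD", "INH", "LEARNED", "PAIR")

#' Sigmoid output function of a coding unit
#'
#' Maps a unit's activation to its output signal:
#' `F(a) = a^na / (qa^na + a^na)`, strictly increasing on `[0, 1]`, equal to
#' 0.5 at `a = qa`. The steepness around `qa` supplies the nonlinearity of
#' both excitatory signalling and the paired-unit inhibition.
#'
#' @param a Activation value(s) in `[0, 1]`.
#' @param na Exponent, `> 0`.
#' @param qa Half-saturation constant, `> 0`.
#' @return Output value(s) in `[0, 1)`.
#' @export
#' @examples
#' unit_output(0.5, na = 2, qa = 0.5)  # 0.5 by construction
unit_output <- function(a, na, qa) {
  if (any(a < 0)) stop("activation must be >= 0", call. = FALSE)
  an <- a^na
  an / (qa^na + an)
}


# Output vector with per-polarity nonlinearity parameters.
unit_F <- function(nw) {
  p <- nw$params
  inh <- nw$units$polarity == "inhibitory"
  F <- unit_output(nw$A, p$na, p$qa)
  if (any(inh) && (p$na_inh != p$na || p$qa_inh != p$qa)) {
    F[inh] <- unit_output(nw$A[inh], p$na_inh, p$qa_inh)
  }
  F
}

new_network <- function(units, edges, params) {
  nw <- list(units = units, edges = edges, params = params,
             A = rep(params$resting_level, nrow(units)))
  nw <- compile_network(nw)
  class(nw) <- "hitec_network"
  nw
}

# Rebuild the dense weight matrices from the edge table. Cheap at the model
# sizes used (tens of units); called after any wiring change.
compile_network <- function(nw) {
  n <- nrow(nw$units)
  idx <- stats::setNames(seq_len(n), nw$units$id)
  e <- nw$edges
  W_vi <- matrix(0, n, n)
  W_vd <- matrix(0, n, n)
  W_in <- matrix(0, n, n)
  if (nrow(e)) {
    si <- idx[e$src]; di <- idx[e$dst]
    # parallel edges between the same pair (e.g. a fixed connection beside a
    # learnable one) each contribute to the summed input, so accumulate
    acc <- function(W, keep) {
      if (!any(keep)) return(W)
      lin <- (di[keep] - 1L) * n + si[keep]
      sums <- tapply(e$weight[keep], lin, sum)
      W[as.integer(names(sums))] <- as.numeric(sums)
      W
    }
    W_vi <- acc(W_vi, e$kind %in% c("VI", "LEARNED", "PAIR"))
    W_vd <- acc(W_vd, e$kind == "VD")
    W_in <- acc(W_in, e$kind == "INH")
  }
  nw$W_vi <- W_vi
  nw$W_vd <- W_vd
  nw$W_in <- W_in
  nw$idx <- idx
  nw
}

unit_index <- function(nw, id) {
  i <- nw$idx[id]
  if (anyNA(i)) {
    stop("unknown unit id(s): ", paste(id[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  unname(i)
}

# External input vector from a named stimulus map (code name -> TRUE or a
# multiplier of ext_input).
ext_vector <- function(nw, stimulus) {
  ext <- numeric(nrow(nw$units))
  if (length(stimulus) == 0) return(ext)
  if (is.null(names(stimulus))) {
    ids <- as.character(stimulus)
    mult <- rep(1, length(ids))
  } else {
    ids <- names(stimulus)
    mult <- as.numeric(stimulus)
  }
  i <- unit_index(nw, ids)
  bad <- !(nw$units$is_sensory[i] | nw$units$is_motor[i])
  if (any(bad)) {
    stop("external input only applies to sensory or motor units: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  ext[i] <- mult * nw$params$ext_input
  ext
}

#' Voltage-dependent (top-down) input to a sensory unit
#'
#' Feedback from feature units to a sensory unit is gated by the sensory
#' unit's own activation: the summed weighted feature output is multiplied by
#' `max(A_i (1 - d_a) - VT, 0) / (1 - VT)`, so the input is exactly zero
#' until the unit's leak-scaled activation exceeds the voltage threshold.
#'
#' @param nw A `hitec_network`.
#' @param unit Unit id (must be a sensory unit).
#' @return The voltage-dependent input value.
#' @export
voltage_dependent_input <- function(nw, unit) {
  i <- unit_index(nw, unit)
  if (!nw$units$is_sensory[i]) {
    stop("voltage-dependent input applies to sensory units only", call. = FALSE)
  }
  p <- nw$params
  F <- unit_F(nw)
  raw <- sum(F * nw$W_vd[, i])
  gate <- max(nw$A[i] * (1 - p$d_a) - p$VT, 0) / (1 - p$VT)
  raw * gate
}

#' Inhibitory input to an excitatory unit
#'
#' Sums the negatively weighted outputs of the inhibitory units paired with
#' the *other* excitatory units of the same layer; a unit never inhibits
#' itself through its own pair.
#'
#' @param nw A `hitec_network`.
#' @param unit Unit id (must be excitatory).
#' @return A value `<= 0`.
#' @export
inhibitory_input <- function(nw, unit) {
  i <- unit_index(nw, unit)
  if (nw$units$polarity[i] != "excitatory") {
    stop("inhibitory input applies to excitatory units", call. = FALSE)
  }
  p <- nw$params
  F <- unit_F(nw)
  sum(F * nw$W_in[, i])
}

#' Excitatory input to a unit
#'
#' The sum of voltage-independent input (weighted outputs over incoming
#' fixed and learned excitatory edges), voltage-dependent top-down input
#' (sensory units only), external stimulation, and Gaussian noise.
#'
#' @param nw A `hitec_network`.
#' @param unit Unit id.
#' @param stimulus Stimulus map: character vector of stimulated codes, or a
#'   named numeric vector of multipliers of `ext_input`.
#' @param noise Noise value to add (default 0; [step_network()] draws it).
#' @return The excitatory input value.
#' @export
excitatory_input <- function(nw, unit, stimulus = character(), noise = 0) {
  i <- unit_index(nw, unit)
  p <- nw$params
  F <- unit_F(nw)
  exc_vi <- sum(F * nw$W_vi[, i])
  exc_vd <- if (nw$units$is_sensory[i]) voltage_dependent_input(nw, unit) else 0
  ext <- ext_vector(nw, stimulus)[i]
  exc_vi + exc_vd + ext + noise
}

#' Advance the network one synchronous cycle
#'
#' All inputs are computed from the cycle-t activations, then every unit
#' (excitatory and inhibitory alike) is committed together to
#' `(1 - d_a) A + gamma (Exc (1 - A) + Inh A)`, clamped to `[0, 1]`.
#' Inhibitory units receive excitatory input only from their paired
#' excitatory unit and no noise.
#'
#' @param nw A `hitec_network`.
#' @param stimulus Stimulus map (see [excitatory_input()]), held constant
#'   over the cycle.
#' @return The network with updated activations; `attr(, "clamped")` counts
#'   units clamped this cycle.
#' @export
step_network <- function(nw, stimulus = character()) {
  p <- nw$params
  A <- nw$A
  F <- unit_F(nw)
  exc_vi <- drop(F %*% nw$W_vi)
  gate <- pmax(A * (1 - p$d_a) - p$VT, 0) / (1 - p$VT)
  exc_vd <- drop(F %*% nw$W_vd) * gate
  inh <- drop(F %*% nw$W_in)
  ext <- ext_vector(nw, stimulus)
  exc_units <- nw$units$polarity == "excitatory"
  noise <- numeric(length(A))
  if (p$noise_sd > 0 || p$noise_mean != 0) {
    noise[exc_units] <- stats::rnorm(sum(exc_units), p$noise_mean, p$noise_sd)
  }
  Exc <- exc_vi + exc_vd + ext + noise
  A_new <- (1 - p$d_a) * A + p$gamma * (Exc * (1 - A) + inh * A)
  clamped <- sum(A_new < 0 | A_new > 1)
  nw$A <- pmin(pmax(A_new, 0), 1)
  attr(nw, "clamped") <- clamped
  nw
}

reset_network <- function(nw) {
  nw$A <- rep(nw$params$resting_level, nrow(nw$units))
  nw
}

#' Run one trial to response selection
#'
#' Resets all activations to the resting level, then iterates
#' [step_network()] under a constant stimulus until a motor unit's activation
#' reaches the response threshold or `max_cycles` elapse. The cycle count at
#' threshold crossing is the model's reaction-time proxy.
#'
#' @param nw A `hitec_network` with at least one motor unit.
#' @param stimulus Stimulus map held constant for the whole trial.
#' @param seed Optional integer seed for the trial's noise draws.
#' @param record_trace Keep the full per-unit activation trace (default TRUE).
#' @return An object of class `"hitec_trial"`: a list with `winner` (motor
#'   code id, or `NA` for an omission), `cycles`, `tie` (TRUE if two motor
#'   units crossed at exactly equal activation), `trace` (cycles x units
#'   matrix, cycle 0 = resting state), and `clamp_events`.
#' @export
run_trial <- function(nw, stimulus = character(), seed = NULL,
                      record_trace = TRUE) {
  motor <- which(nw$units$is_motor)
  if (!length(motor)) stop("network has no motor units", call. = FALSE)
  use_trial_seed(seed)
  p <- nw$params
  nw <- reset_network(nw)
  ids <- nw$units$id
  trace <- if (record_trace) {
    matrix(nw$A, nrow = 1, dimnames = list(NULL, ids))
  }
  traces <- if (record_trace) vector("list", p$max_cycles)
  clamp_events <- 0L
  winner <- NA_character_
  tie <- FALSE
  cycles <- p$max_cycles
  for (t in seq_len(p$max_cycles)) {
    nw <- step_network(nw, stimulus)
    clamp_events <- clamp_events + attr(nw, "clamped")
    if (record_trace) traces[[t]] <- nw$A
    am <- nw$A[motor]
    if (any(am >= p$response_threshold)) {
      cycles <- t
      top <- max(am)
      cand <- motor[am == top & am >= p$response_threshold]
      winner <- ids[cand[1]]
      tie <- length(cand) > 1
      break
    }
  }
  if (record_trace) {
    done <- !vapply(traces, is.null, logical(1))
    trace <- rbind(trace, do.call(rbind, traces[done]))
    rownames(trace) <- NULL
  } else {
    trace <- NULL
  }
  structure(list(winner = winner, cycles = cycles, tie = tie,
                 omission = is.na(winner), trace = trace,
                 clamp_events = clamp_events, stimulus = stimulus),
            class = "hitec_trial")
}

#' @export
print.hitec_trial <- function(x, ...) {
  if (x$omission) {
    cat(sprintf("Trial: omission (no motor unit reached threshold in %d cycles)\n",
                x$cycles))
  } else {
    cat(sprintf("Trial: '%s' reached response threshold in %d cycles%s\n",
                x$winner, x$cycles, if (x$tie) " (tie)" else ""))
  }
  invisible(x)
}

#' @export
print.hitec_network <- function(x, ...) {
  u <- x$units
  cat("Interactive-activation network\n")
  cat(sprintf("  %d units (%d excitatory + %d inhibitory) in %d layers\n",
              nrow(u), sum(u$polarity == "excitatory"),
              sum(u$polarity == "inhibitory"),
              length(unique(u$layer))))
  tab <- table(x$edges$kind)
  cat("  edges:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Export a trial trace as tidy long-format data
#'
#' @param trial A `hitec_trial` with a recorded trace.
#' @param file Optional path; when given, written as CSV (activations to six
#'   decimal places) and the data frame returned invisibly.
#' @param units Optional character vector restricting exported unit ids.
#' @param network Optional `hitec_network` used to label layers.
#' @return A data.frame with columns `cycle`, `unit_id`, `layer_id`,
#'   `activation`.
#' @export
trace_df <- function(trial, file = NULL, units = NULL, network = NULL) {
  if (is.null(trial$trace)) stop("trial has no recorded trace", call. = FALSE)
  tr <- trial$trace
  keep <- if (is.null(units)) colnames(tr) else intersect(colnames(tr), units)
  layer <- if (!is.null(network)) {
    stats::setNames(network$units$layer, network$units$id)[keep]
  } else {
    rep(NA_character_, length(keep))
  }
  out <- data.frame(
    cycle = rep(seq_len(nrow(tr)) - 1L, times = length(keep)),
    unit_id = rep(keep, each = nrow(tr)),
    layer_id = rep(unname(layer), each = nrow(tr)),
    activation = round(as.vector(tr[, keep, drop = FALSE]), 6),
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
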