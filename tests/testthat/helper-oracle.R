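# Independent cycle-by-cycle evaluation of the activation equations, working
# directly off the edge table with explicit per-unit loops. Used as the
# reference implementation against the vectorized update.
oracle_step <- function(units, edges, A, params, ext = numeric(nrow(units))) {
  Fout <- function(a) a^params$na / (params$qa^params$na + a^params$na)
  n <- nrow(units)
  A_new <- numeric(n)
  for (i in seq_len(n)) {
    id <- units$id[i]
    exc_vi <- 0
    exc_vd_raw <- 0
    inh <- 0
    for (e in seq_len(nrow(edges))) {
      if (edges$dst[e] != id) next
      k <- match(edges$src[e], units$id)
      out_k <- Fout(A[k])
      if (edges$kind[e] %in% c("VI", "LEARNED", "PAIR")) {
        exc_vi <- exc_vi + edges$weight[e] * out_k
      } else if (edges$kind[e] == "VD") {
        exc_vd_raw <- exc_vd_raw + edges$weight[e] * out_k
      } else if (edges$kind[e] == "INH") {
        inh <- inh + edges$weight[e] * out_k
      }
    }
    gate <- max(A[i] * (1 - params$d_a) - params$VT, 0) / (1 - params$VT)
    exc <- exc_vi + exc_vd_raw * gate + ext[i]
    A_new[i] <- (1 - params$d_a) * A[i] +
      params$gamma * (exc * (1 - A[i]) + inh * A[i])
    A_new[i] <- min(max(A_new[i], 0), 1)
  }
  A_new
}

# A small hand-assembled network: two sensory units feeding two feature
# units (with top-down VD feedback), a lone motor unit, plus the paired
# inhibitory units the builder would create.
toy_spec <- function(params = network_params(noise_sd = 0),
                     weights = default_weights()) {
  model_spec(
    layers = list(
      list(name = "sense", level = "sensory", codes = c("sA", "sB")),
      list(name = "feat", level = "feature", codes = c("fA", "fB")),
      list(name = "motor", level = "motor", codes = "m")
    ),
    sensory_feature_map = list(fA = "sA", fB = "sB"),
    effects = list(m = "sA"),
    weights = weights, params = params
  )
}
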