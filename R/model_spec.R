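#' Declarative model specification
#'
#' Describes a model instance: its layers and codes, the hand-set
#' sensory-feature wiring, default weights, the action-effect schedule used
#' by the learning phase, and the dynamics/learning parameters. Task codes
#' carry no connections until a [task_instruction()] is applied with
#' [internalize_task()].
#'
#' @param layers A list of layers, each `list(name =, level =, codes =)` with
#'   `level` one of `"sensory"`, `"feature"`, `"task"`, `"motor"`.
#' @param connections A data.frame (`src`, `dst`, `weight`, `kind`) of fixed
#'   edges, or NULL to derive them from `sensory_feature_map`.
#' @param sensory_feature_map A named list mapping each feature code to the
#'   sensory codes it is grounded in; expands to a forward VI edge
#'   (sensory to feature, weight `weights$sensory_feature`) and a backward
#'   VD edge (feature to sensory, weight `weights$feature_sensory`) per pair.
#' @param effects Named list mapping each motor code to the sensory codes
#'   stimulated as its action effect.
#' @param weights Default hand-set weights; see [default_weights()].
#' @param params A [network_params()] object.
#' @param learning A [learning_params()] object.
#' @param name Optional instance name.
#' @return An object of class `"hitec_spec"`.
#' @export
model_spec <- function(layers,
                       connections = NULL,
                       sensory_feature_map = NULL,
                       effects = list(),
                       weights = default_weights(),
                       params = network_params(),
                       learning = learning_params(),
                       name = "model") {
  if (!length(layers)) stop("a model spec needs at least one layer", call. = FALSE)
  layers <- lapply(layers, function(l) {
    stopifnot(all(c("name", "level", "codes") %in% names(l)))
    l$level <- match.arg(l$level, c("sensory", "feature", "task", "motor"))
    l$codes <- as.character(l$codes)
    l
  })
  codes <- unlist(lapply(layers, `[[`, "codes"))
  if (anyDuplicated(codes)) {
    stop("duplicate code names: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  }
  weights <- utils::modifyList(default_weights(), as.list(weights))
  spec <- structure(list(
    name = name, layers = layers, connections = connections,
    sensory_feature_map = sensory_feature_map, effects = effects,
    weights = weights, params = params, learning = learning,
    task = NULL
  ), class = "hitec_spec")
  validate_spec(spec)
  spec
}

#' Default hand-set connection weights
#'
#' Fixed weights standing for long-term perceptual experience
#' (sensory-feature), for instruction wiring (feature-task, task-feature;
#' forward and backward values may differ), and for the within-layer
#' competition machinery (excitatory unit to its paired inhibitory unit, and
#' the negative lateral weight from an inhibitory unit to the other
#' excitatory units of its layer).
#'
#' @param sensory_feature Weight of sensory-to-feature VI edges.
#' @param feature_sensory Weight of feature-to-sensory VD (top-down) edges.
#' @param feature_task Weight of stimulus-feature-to-task VI edges.
#' @param task_feature Weight of task-to-response-feature VI edges (the
#'   forward drive of the instructed response).
#' @param response_task Weight of response-feature-to-task VI edges. Kept
#'   below `feature_task` so the instructed stimulus dimension, not the
#'   response features it shares codes with, decides which task option wins.
#' @param task_stimulus Weight of task-to-stimulus-feature VI edges (the
#'   recurrent feedback that sensitizes the instructed stimulus dimension).
#'   Kept below `task_feature` so feedback biases, but does not impersonate,
#'   stimulation.
#' @param pair Weight of each excitatory-to-paired-inhibitory edge.
#' @param lateral Negative weight of inhibitory-to-competitor edges.
#' @return A named list.
#' @export
default_weights <- function(sensory_feature = 0.295,
                            feature_sensory = 0.914,
                            feature_task = 0.95,
                            task_feature = 0.975,
                            response_task = 0.466,
                            task_stimulus = 0.576,
                            pair = 0.6,
                            lateral = -1.93) {
  stopifnot(lateral <= 0)
  list(sensory_feature = sensory_feature, feature_sensory = feature_sensory,
       feature_task = feature_task, task_feature = task_feature,
       response_task = response_task, task_stimulus = task_stimulus,
       pair = pair, lateral = lateral)
}

spec_codes <- function(spec, level = NULL) {
  keep <- if (is.null(level)) spec$layers else
    Filter(function(l) l$level %in% level, spec$layers)
  unlist(lapply(keep, `[[`, "codes"), use.names = FALSE)
}

validate_spec <- function(spec) {
  codes <- spec_codes(spec)
  bad <- character()
  check <- function(x) bad <<- c(bad, setdiff(x, codes))
  if (!is.null(spec$sensory_feature_map)) {
    check(names(spec$sensory_feature_map))
    check(unlist(spec$sensory_feature_map))
  }
  if (!is.null(spec$connections)) {
    check(spec$connections$src); check(spec$connections$dst)
  }
  check(names(spec$effects))
  check(unlist(spec$effects))
  if (!is.null(spec$task)) {
    for (r in spec$task$rules) check(c(r$stimulus, r$task, r$response))
  }
  if (length(bad)) {
    stop("unknown code reference(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  motor <- spec_codes(spec, "motor")
  if (length(spec$effects) && !all(motor %in% names(spec$effects))) {
    stop("effect schedule must cover every motor code", call. = FALSE)
  }
  invisible(spec)
}

#' A task instruction as feature-task-feature rules
#'
#' Each rule reads "when the stimulus features are active, task option T
#' applies, which stands for producing the response features": e.g.
#' High -> T1 -> {Left, Key}. Internalizing a rule wires each stimulus
#' feature bidirectionally to the task code and the task code bidirectionally
#' to each response feature (plain voltage-independent edges both ways;
#' forward and backward weights may differ).
#'
#' @param ... Rules, each `list(stimulus =, task =, response =)`.
#' @param rules Alternatively, a list of such rules.
#' @return An object of class `"hitec_instruction"`.
#' @export
#' @examples
#' task_instruction(list(stimulus = "High", task = "T1",
#'                       response = c("Left", "Key")))
task_instruction <- function(..., rules = NULL) {
  rules <- c(list(...), rules)
  rules <- lapply(rules, function(r) {
    stopifnot(all(c("stimulus", "task", "response") %in% names(r)))
    list(stimulus = as.character(r$stimulus), task = as.character(r$task),
         response = as.character(r$response))
  })
  structure(list(rules = rules), class = "hitec_instruction")
}

#' Build a runnable network from a model specification
#'
#' Realizes the declarative spec as a layered network: one excitatory unit
#' per code, one auto-generated paired inhibitory unit per excitatory unit,
#' within-layer lateral inhibition edges, the fixed sensory-feature wiring,
#' and a dense set of learnable feature-to-motor edges initialized at weight
#' 0 (in principle any feature code can become associated with any motor
#' code; which ones do is decided by the learning phase). Deterministic and
#' idempotent given the spec.
#'
#' @param spec A `hitec_spec`.
#' @return A `hitec_network`.
#' @export
build_model <- function(spec) {
  validate_spec(spec)
  rows <- list()
  for (l in spec$layers) {
    for (code in l$codes) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = code, layer = l$name, level = l$level, polarity = "excitatory",
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(code, ":inh"), layer = l$name, level = l$level,
        polarity = "inhibitory", stringsAsFactors = FALSE)
    }
  }
  units <- do.call(rbind, rows)
  units$is_sensory <- units$level == "sensory" & units$polarity == "excitatory"
  units$is_motor <- units$level == "motor" & units$polarity == "excitatory"
  units$pair <- ifelse(units$polarity == "excitatory",
                       match(paste0(units$id, ":inh"), units$id), NA_integer_)

  w <- spec$weights
  edges <- list()
  add <- function(src, dst, weight, kind) {
    edges[[length(edges) + 1L]] <<- data.frame(
      src = src, dst = dst, weight = weight, kind = kind,
      stringsAsFactors = FALSE)
  }
  # competition machinery: pair edge + lateral inhibition to other excitatory
  # units of the same layer
  exc <- units[units$polarity == "excitatory", ]
  for (layer in unique(exc$layer)) {
    ids <- exc$id[exc$layer == layer]
    for (id in ids) {
      add(id, paste0(id, ":inh"), w$pair, "PAIR")
      others <- setdiff(ids, id)
      if (length(others)) add(rep(paste0(id, ":inh"), length(others)),
                              others, w$lateral, "INH")
    }
  }
  # hand-set sensory <-> feature grounding
  if (!is.null(spec$sensory_feature_map)) {
    for (feat in names(spec$sensory_feature_map)) {
      for (sens in spec$sensory_feature_map[[feat]]) {
        add(sens, feat, w$sensory_feature, "VI")
        add(feat, sens, w$feature_sensory, "VD")
      }
    }
  }
  # any explicitly listed fixed edges
  if (!is.null(spec$connections) && nrow(spec$connections)) {
    for (i in seq_len(nrow(spec$connections))) {
      e <- spec$connections[i, ]
      add(e$src, e$dst, e$weight, e$kind)
    }
  }
  # dense learnable feature -> motor edges at weight 0
  feats <- spec_codes(spec, "feature")
  motors <- spec_codes(spec, "motor")
  for (f in feats) for (m in motors) add(f, m, 0, "LEARNED")

  edges <- do.call(rbind, edges)
  validate_edges(units, edges)
  nw <- new_network(units, edges, spec$params)
  nw$spec <- spec
  if (!is.null(spec$task)) nw <- internalize_task(nw, spec$task)
  nw
}

validate_edges <- function(units, edges) {
  stopifnot(all(edges$kind %in% EDGE_KINDS))
  lev <- stats::setNames(units$level, units$id)
  pol <- stats::setNames(units$polarity, units$id)
  pos <- edges$kind %in% c("VI", "VD", "LEARNED", "PAIR")
  if (any(edges$weight[pos] < 0 | edges$weight[pos] > 1)) {
    stop("excitatory weights must lie in [0, 1]", call. = FALSE)
  }
  if (any(edges$weight[edges$kind == "INH"] > 0)) {
    stop("inhibitory weights must be <= 0", call. = FALSE)
  }
  vd <- edges$kind == "VD"
  if (any(lev[edges$dst[vd]] != "sensory")) {
    stop("voltage-dependent edges must terminate on sensory units",
         call. = FALSE)
  }
  ln <- edges$kind == "LEARNED"
  if (any(lev[edges$src[ln]] != "feature" | lev[edges$dst[ln]] != "motor")) {
    stop("learnable edges run feature -> motor only", call. = FALSE)
  }
  if (any(pol[edges$src[edges$kind == "INH"]] != "inhibitory")) {
    stop("lateral inhibition must originate from inhibitory units",
         call. = FALSE)
  }
  invisible(edges)
}

#' Internalize a task instruction as feature-task wiring
#'
#' Removes any existing feature-task edges, then adds, per rule,
#' bidirectional voltage-independent edges stimulus-feature <-> task and
#' task <-> response-feature. All other wiring — including learned
#' feature-to-motor weights — is untouched, so a model can be re-instructed
#' between phases without forgetting.
#'
#' @param nw A `hitec_network`.
#' @param instruction A [task_instruction()].
#' @return The rewired network.
#' @export
internalize_task <- function(nw, instruction) {
  stopifnot(inherits(instruction, "hitec_instruction"))
  lev <- stats::setNames(nw$units$level, nw$units$id)
  e <- nw$edges
  task_edge <- e$kind == "VI" &
    (lev[e$src] == "task" | lev[e$dst] == "task")
  e <- e[!task_edge, ]
  w <- nw$spec$weights
  if (is.null(w)) w <- default_weights()
  add <- list()
  push <- function(src, dst, weight) {
    add[[length(add) + 1L]] <<- data.frame(src = src, dst = dst,
                                           weight = weight, kind = "VI",
                                           stringsAsFactors = FALSE)
  }
  for (r in instruction$rules) {
    unit_index(nw, c(r$stimulus, r$task, r$response))
    if (any(lev[r$task] != "task")) {
      stop("rule task code must be in the task layer", call. = FALSE)
    }
    for (s in r$stimulus) {
      push(s, r$task, w$feature_task)
      push(r$task, s, w$task_stimulus)
    }
    for (resp in r$response) {
      push(r$task, resp, w$task_feature)
      push(resp, r$task, w$response_task)
    }
  }
  if (length(add)) e <- rbind(e, do.call(rbind, add))
  # bidirectional rules can nominate the same edge twice (e.g. a feature that
  # is both stimulus and response of one task code); keep the first
  e <- e[!duplicated(e[, c("src", "dst", "kind")]), ]
  rownames(e) <- NULL
  nw$edges <- e
  nw$task <- instruction
  compile_network(nw)
}

#' Edge-level difference between two networks
#'
#' @param a,b Two `hitec_network`s over the same code inventory.
#' @return A data.frame of differing edges with columns `src`, `dst`, `kind`,
#'   `weight_a`, `weight_b`, `status` (`added`, `removed`, `reweighted`);
#'   zero rows when the wiring is identical.
#' @export
diff_models <- function(a, b) {
  if (!setequal(a$units$id, b$units$id)) {
    stop("networks have different code inventories", call. = FALSE)
  }
  key <- function(e) paste(e$src, e$dst, e$kind, sep = "\r")
  ea <- a$edges; eb <- b$edges
  ka <- key(ea); kb <- key(eb)
  removed <- ea[!(ka %in% kb), c("src", "dst", "kind", "weight")]
  added <- eb[!(kb %in% ka), c("src", "dst", "kind", "weight")]
  common <- intersect(ka, kb)
  wa <- ea$weight[match(common, ka)]
  wb <- eb$weight[match(common, kb)]
  chg <- which(wa != wb)
  parts <- strsplit(common[chg], "\r", fixed = TRUE)
  out <- rbind(
    if (nrow(removed)) data.frame(src = removed$src, dst = removed$dst,
                                  kind = removed$kind, weight_a = removed$weight,
                                  weight_b = NA_real_, status = "removed",
                                  stringsAsFactors = FALSE),
    if (nrow(added)) data.frame(src = added$src, dst = added$dst,
                                kind = added$kind, weight_a = NA_real_,
                                weight_b = added$weight, status = "added",
                                stringsAsFactors = FALSE),
    if (length(chg)) data.frame(src = vapply(parts, `[`, "", 1),
                                dst = vapply(parts, `[`, "", 2),
                                kind = vapply(parts, `[`, "", 3),
                                weight_a = wa[chg], weight_b = wb[chg],
                                status = "reweighted",
                                stringsAsFactors = FALSE)
  )
  if (is.null(out)) {
    out <- data.frame(src = character(), dst = character(), kind = character(),
                      weight_a = numeric(), weight_b = numeric(),
                      status = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read or write a model specification file
#'
#' Model specs round-trip losslessly through YAML: sections `name`, `layers`,
#' `sensory_feature_map`, `connections`, `effects`, `task`, `weights`,
#' `params`, `learning`.
#'
#' @param path File path.
#' @param spec A `hitec_spec` (for writing).
#' @return `read_model_spec()` returns a `hitec_spec`; `write_model_spec()`
#'   returns `path` invisibly.
#' @export
read_model_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  conns <- if (!is.null(raw$connections)) {
    do.call(rbind, lapply(raw$connections, function(e) {
      data.frame(src = e$src, dst = e$dst, weight = e$weight, kind = e$kind,
                 stringsAsFactors = FALSE)
    }))
  }
  spec <- model_spec(
    layers = raw$layers,
    connections = conns,
    sensory_feature_map = raw$sensory_feature_map,
    effects = if (is.null(raw$effects)) list() else raw$effects,
    weights = if (is.null(raw$weights)) default_weights() else raw$weights,
    params = do.call(network_params, if (is.null(raw$params)) list() else raw$params),
    learning = do.call(learning_params, if (is.null(raw$learning)) list() else raw$learning),
    name = if (is.null(raw$name)) "model" else raw$name
  )
  if (!is.null(raw$task)) spec$task <- task_instruction(rules = raw$task$rules)
  validate_spec(spec)
  spec
}

#' @rdname read_model_spec
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "hitec_spec"))
  out <- list(
    name = spec$name,
    layers = lapply(spec$layers, function(l) l[c("name", "level", "codes")]),
    sensory_feature_map = spec$sensory_feature_map,
    connections = if (!is.null(spec$connections)) {
      lapply(seq_len(nrow(spec$connections)), function(i)
        as.list(spec$connections[i, c("src", "dst", "weight", "kind")]))
    },
    effects = spec$effects,
    task = if (!is.null(spec$task)) list(rules = spec$task$rules),
    weights = spec$weights,
    params = unclass(spec$params),
    learning = unclass(spec$learning)
  )
  out <- Filter(Negate(is.null), out)
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' @export
print.hitec_spec <- function(x, ...) {
  cat(sprintf("Model spec '%s': %d layers, %d codes\n", x$name,
              length(x$layers), length(spec_codes(x))))
  for (l in x$layers) {
    cat(sprintf("  [%s] %s: %s\n", l$level, l$name,
                paste(l$codes, collapse = ", ")))
  }
  if (!is.null(x$task)) {
    cat(sprintf("  task: %d rule(s)\n", length(x$task$rules)))
  }
  invisible(x)
}
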