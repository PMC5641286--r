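test_that("building realizes paired units, lateral wiring, dense learnables", {
  spec <- model_spec(
    layers = list(
      list(name = "s1", level = "sensory", codes = c("a1", "a2")),
      list(name = "s2", level = "sensory", codes = c("b1", "b2")),
      list(name = "feat", level = "feature",
           codes = c("f1", "f2", "f3", "f4", "f5", "f6")),
      list(name = "task", level = "task", codes = c("T1", "T2")),
      list(name = "motor", level = "motor", codes = c("M1", "M2"))
    ),
    sensory_feature_map = list(f1 = "a1", f2 = "a2", f3 = "b1", f4 = "b2"),
    effects = list(M1 = "a1", M2 = "a2")
  )
  nw <- build_model(spec)
  n_codes <- 2 + 2 + 6 + 2 + 2
  expect_equal(sum(nw$units$polarity == "excitatory"), n_codes)
  expect_equal(sum(nw$units$polarity == "inhibitory"), n_codes)
  expect_equal(sum(nw$edges$kind == "LEARNED"), 6 * 2)
  expect_equal(sum(nw$edges$kind == "PAIR"), n_codes)
  # every excitatory unit has exactly one pair in its own layer
  exc <- nw$units[nw$units$polarity == "excitatory", ]
  for (i in seq_len(nrow(exc))) {
    pair <- nw$edges[nw$edges$kind == "PAIR" & nw$edges$src == exc$id[i], ]
    expect_equal(nrow(pair), 1)
    expect_equal(nw$units$layer[hitec:::unit_index(nw, pair$dst)], exc$layer[i])
  }
  # no cross-layer inhibition
  layer_of <- setNames(nw$units$layer, nw$units$id)
  inh <- nw$edges[nw$edges$kind == "INH", ]
  expect_true(all(layer_of[inh$src] == layer_of[inh$dst]))
  # deterministic and idempotent from the spec
  nw2 <- build_model(spec)
  expect_identical(nw$edges, nw2$edges)
  expect_identical(nw$units, nw2$units)
})

test_that("degenerate and inconsistent specs are rejected", {
  expect_error(model_spec(layers = list()), "at least one layer")
  expect_error(
    model_spec(layers = list(list(name = "f", level = "feature", codes = "x")),
               sensory_feature_map = list(x = "nope")),
    "unknown code")
  bad <- model_spec(
    layers = list(list(name = "f", level = "feature", codes = c("x", "y"))))
  bad$effects <- list(M9 = "x")
  expect_error(hitec:::validate_spec(bad), "unknown code")
})

test_that("task internalization wires each rule link both ways", {
  es <- hitec_experiment("simon", n_trials = 1)
  spec <- es$groups$instructed$spec
  spec$task <- NULL
  nw <- build_model(spec)
  expect_equal(nrow(task_edges <- nw$edges[
    nw$edges$kind == "VI" & (nw$edges$src %in% c("T1", "T2") |
                               nw$edges$dst %in% c("T1", "T2")), ]), 0)
  rule <- task_instruction(
    list(stimulus = "High", task = "T1", response = c("Left", "Key")))
  nw1 <- internalize_task(nw, rule)
  d <- diff_models(nw, nw1)
  expect_true(all(d$status == "added"))
  # three rule links (High-T1, T1-Left, T1-Key), each a forward+backward pair
  expect_equal(nrow(d), 6)
  expect_setequal(paste(d$src, d$dst),
                  c("High T1", "T1 High", "T1 Left", "Left T1",
                    "T1 Key", "Key T1"))
  # re-instructing replaces, never accumulates
  nw2 <- internalize_task(nw1, rule)
  expect_equal(nrow(diff_models(nw1, nw2)), 0)
  # an empty instruction clears all task wiring
  nw3 <- internalize_task(nw1, task_instruction())
  expect_equal(nrow(diff_models(nw, nw3)), 0)
})

test_that("rewiring the task touches no other edge, learned included", {
  es <- hitec_experiment("elsner_hommel", n_trials = 1)
  g <- es$groups$non_reversal
  nw <- learning_phase(build_model(g$spec), seed = 2)$network
  w_before <- learned_weights(nw)
  nw2 <- internalize_task(nw, g$task2)
  expect_identical(learned_weights(nw2), w_before)
  d <- diff_models(nw, nw2)
  lev <- setNames(nw$units$level, nw$units$id)
  expect_true(all(lev[d$src] == "task" | lev[d$dst] == "task"))
})

test_that("the two inverted-Simon instances differ in task edges only", {
  es <- hitec_experiment("hommel_inversion", n_trials = 1)
  nw_key <- build_model(es$groups$key$spec)
  nw_light <- build_model(es$groups$light$spec)
  d <- diff_models(nw_key, nw_light)
  expect_gt(nrow(d), 0)
  expect_true(all(d$src %in% c("T1", "T2") | d$dst %in% c("T1", "T2")))
})

test_that("the color-word instance is a rename of the Simon instance", {
  simon <- hitec_experiment("simon", n_trials = 1)$groups$instructed$spec
  stroop <- hitec_experiment("stroop", n_trials = 1)$groups$instructed$spec
  ns <- build_model(simon)
  nt <- build_model(stroop)
  expect_equal(nrow(ns$units), nrow(nt$units))
  expect_identical(ns$units$level, nt$units$level)
  expect_identical(ns$units$polarity, nt$units$polarity)
  # same weights edge for edge once ids are mapped positionally
  map <- setNames(nt$units$id, ns$units$id)
  es <- ns$edges[order(ns$edges$src, ns$edges$dst, ns$edges$kind), ]
  et <- nt$edges
  et$src <- names(map)[match(et$src, map)]
  et$dst <- names(map)[match(et$dst, map)]
  et <- et[order(et$src, et$dst, et$kind), ]
  expect_equal(es$weight, et$weight)
  expect_equal(es$kind, et$kind)
})

test_that("model specs round-trip through YAML", {
  es <- hitec_experiment("hommel_inversion", n_trials = 1)
  spec <- es$groups$light$spec
  f <- tempfile(fileext = ".yaml")
  write_model_spec(spec, f)
  back <- read_model_spec(f)
  expect_equal(back$layers, spec$layers)
  expect_equal(back$sensory_feature_map, spec$sensory_feature_map)
  expect_equal(back$effects, spec$effects)
  expect_equal(back$weights, spec$weights)
  expect_equal(unclass(back$params), unclass(spec$params))
  expect_equal(unclass(back$learning), unclass(spec$learning))
  expect_equal(back$task$rules, spec$task$rules)
  # identical networks from original and round-tripped spec
  expect_equal(build_model(back)$edges, build_model(spec)$edges)
  unlink(f)
})

test_that("parameter files reject unknown keys", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("d_a: 0.05", "gamma: 0.3", "typo_key: 1"), f)
  expect_error(read_params(f), "typo_key")
  writeLines(c("d_a: 0.05", "LT: 0.5"), f)
  p <- read_params(f)
  expect_equal(p$network$d_a, 0.05)
  expect_equal(p$learning$LT, 0.5)
  unlink(f)
})
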