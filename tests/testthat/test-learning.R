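test_that("hebbian update obeys its closed form", {
  lp <- learning_params(d_w = 0.1, LT = 0.4)
  # below-threshold activation: pure decay
  expect_equal(hebbian_update(0.5, a_j = 0.4, a_k = 1, lp), 0.45)
  expect_equal(hebbian_update(0.5, a_j = 0.2, a_k = 0.9, lp), 0.45)
  # full co-activation from zero jumps to the ceiling
  expect_equal(hebbian_update(0, a_j = 1, a_k = 1, lp), 1)
  # general value, hand-computed
  act <- function(a) max(0, (a - lp$LT) / (1 - lp$LT))
  w <- 0.3; aj <- 0.7; ak <- 0.85
  expect_equal(hebbian_update(w, aj, ak, lp),
               (1 - lp$d_w) * w + act(aj) * act(ak) * (1 - w))
})

test_that("repeated co-activation converges to c / (d_w + c)", {
  lp <- learning_params(d_w = 0.08, LT = 0.5)
  act <- function(a) max(0, (a - lp$LT) / (1 - lp$LT))
  for (pair in list(c(0.9, 0.95), c(0.7, 0.8), c(0.6, 1))) {
    cc <- act(pair[1]) * act(pair[2])
    w <- 0
    repeat {
      w_new <- hebbian_update(w, pair[1], pair[2], lp)
      if (abs(w_new - w) < 1e-9) break
      w <- w_new
    }
    expect_equal(w, cc / (lp$d_w + cc), tolerance = 1e-6)
  }
})

test_that("weights remain in [0,1] under arbitrary update sequences", {
  set.seed(1)
  lp <- learning_params(d_w = 0.2, LT = 0.3)
  w <- runif(200)
  for (i in 1:50) {
    w <- hebbian_update(w, runif(200), runif(200), lp)
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("learning strengthens effect features and only them", {
  es <- hitec_experiment("elsner_hommel", n_trials = 1)
  nw <- build_model(es$groups$non_reversal$spec)
  lp <- learning_phase(nw, seed = 3)
  w <- learned_weights(lp$network)
  # M1's effects are the left key and the low tone; the haptic (key) side is
  # task-enhanced during learning and ends up stronger than the pitch side
  expect_gt(w["Left", "M1"], 0.3)
  expect_gt(w["Low", "M1"], 0.15)
  expect_lt(w["Right", "M1"], 0.05)
  expect_lt(w["High", "M1"], 0.05)
  expect_gt(w["Right", "M2"], 0.3)
  expect_gt(w["High", "M2"], 0.15)
  # consistently co-activated pairs grow across their own babbling trials
  # (global decay nibbles at them on the partner's trials)
  h <- lp$history
  own_trial <- list(c("Left", "M1"), c("Low", "M1"), c("Right", "M2"))
  for (k in seq_along(own_trial)) {
    tr <- own_trial[[k]]
    traj <- h$weight[h$src == tr[1] & h$dst == tr[2]]
    own <- traj[seq(2 - (tr[2] == "M2"), length(traj), by = 2)]
    expect_true(all(diff(own) >= -1e-9))
    expect_gt(traj[length(traj)], 0.15)
  }
})

test_that("an empty effect set yields pure decay of learned weights", {
  es <- hitec_experiment("simon", n_trials = 1,
                         params = network_params(noise_sd = 0))
  nw <- build_model(es$groups$instructed$spec)
  # seed a nonzero learned weight, then run a trial whose motor code has no
  # perceivable effects
  ln <- which(nw$edges$kind == "LEARNED")
  nw$edges$weight[ln] <- 0.5
  nw <- hitec:::compile_network(nw)
  lpar <- nw$spec$learning
  res <- learning_trial(nw, "M1", effects = list(M1 = character()),
                        learning = lpar)
  expect_true(all(res$network$edges$weight[ln] <= 0.5 * (1 - lpar$d_w) + 1e-9))
})

test_that("learning is one-way: no motor-to-feature edge ever appears", {
  es <- hitec_experiment("simon", n_trials = 1)
  nw <- build_model(es$groups$instructed$spec)
  nw2 <- learning_phase(nw, seed = 1)$network
  lev <- setNames(nw2$units$level, nw2$units$id)
  pol <- setNames(nw2$units$polarity, nw2$units$id)
  from_motor <- nw2$edges[lev[nw2$edges$src] == "motor" &
                            pol[nw2$edges$src] == "excitatory", ]
  # the only edges out of a motor coding unit feed its own inhibitory pair
  expect_true(all(from_motor$kind == "PAIR"))
})

test_that("round-robin babbling drives each motor code equally", {
  es <- hitec_experiment("simon", n_trials = 1)
  spec <- es$groups$instructed$spec
  expect_identical(spec$learning$n_learning_trials %% 2L, 0L)
  # count via the weight history: M1-linked weights grow on odd trials and
  # only decay on M2's trials
  nw <- build_model(spec)
  lp <- learning_phase(nw, seed = 2)
  h <- lp$history
  w_m1 <- h$weight[h$src == "Left" & h$dst == "M1"]
  gains <- which(diff(w_m1) > 1e-9)
  expect_true(all(gains %% 2 == 1))  # trials 1, 3, 5, ...
  expect_length(gains, spec$learning$n_learning_trials / 2)
  losses <- diff(w_m1)[seq(2, length(w_m1) - 1, by = 2)]
  expect_true(all(losses <= 0))
})

test_that("weights plateau: doubling the trials changes them < 5%", {
  # decay caps the fixed point, so weights that have converged stop moving;
  # a faster decay makes 20 trials enough for every co-activated pair
  es <- hitec_experiment("simon", n_trials = 1)
  spec <- es$groups$instructed$spec
  nw <- build_model(spec)
  lp20 <- learning_params(d_w = 0.1)
  lp40 <- learning_params(d_w = 0.1, n_learning_trials = 40L)
  w20 <- learned_weights(learning_phase(nw, learning = lp20, seed = 5)$network)
  w40 <- learned_weights(learning_phase(nw, learning = lp40, seed = 5)$network)
  big <- w20 > 0.2
  expect_true(any(big))
  expect_true(all(abs(w40[big] - w20[big]) / w20[big] < 0.05))
})

test_that("task wiring to the key feature biases effect learning", {
  # two identical intensity effects (haptic + auditory); wiring the task to
  # 'Key' must boost the haptic route and with it the learned weight of the
  # haptically grounded intensity feature
  es <- hitec_experiment("kunde", n_trials = 1)
  spec <- es$groups$consistent$spec
  spec_nokey <- spec
  spec_nokey$task <- task_instruction(
    list(stimulus = "Red", task = "T1", response = "Forceful"),
    list(stimulus = "Green", task = "T2", response = "Gentle"))
  w_key <- learned_weights(learning_phase(build_model(spec), seed = 4)$network)
  w_nokey <- learned_weights(learning_phase(build_model(spec_nokey), seed = 4)$network)
  expect_gt(w_key["Forceful", "M1"], 0)
  expect_gte(w_key["Forceful", "M1"], w_nokey["Forceful", "M1"])
})

test_that("consistent effects outlearn inconsistent effects", {
  es <- hitec_experiment("kunde", n_trials = 1)
  w_cons <- learned_weights(
    learning_phase(build_model(es$groups$consistent$spec), seed = 6)$network)
  w_incons <- learned_weights(
    learning_phase(build_model(es$groups$inconsistent$spec), seed = 6)$network)
  expect_gt(w_cons["Forceful", "M1"], w_incons["Forceful", "M1"])
  expect_gt(w_cons["Gentle", "M2"], w_incons["Gentle", "M2"])
})
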