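# Gradient processing and the capped update rule.

test_that("repeat gradients average elementwise and reject mixed proteins", {
  b1 <- list(protein_id = "A", repeat_id = 1L, gradient = c(1, 2, 3),
             loss = 0.1)
  b2 <- list(protein_id = "A", repeat_id = 2L, gradient = c(3, 0, -1),
             loss = 0.2)
  expect_equal(combine_repeat_gradients(list(b1)), c(1, 2, 3))
  expect_equal(combine_repeat_gradients(list(b1, b2)), c(2, 1, 1))
  bneg <- b2; bneg$gradient <- -b1$gradient
  expect_equal(combine_repeat_gradients(list(b1, bneg)), c(0, 0, 0))
  bB <- b2; bB$protein_id <- "B"
  expect_error(combine_repeat_gradients(list(b1, bB)), "mix")
})

test_that("median normalisation is scale-invariant and median-based", {
  expect_equal(median_normalize(c(0.1, -0.2, 0.4)), c(0.5, -1, 2))
  g <- c(0.3, -0.3, 0.3)
  expect_equal(abs(median_normalize(g)), rep(1, 3))
  set.seed(3)
  g2 <- rnorm(108)
  expect_equal(median_normalize(5 * g2), median_normalize(g2))
  expect_warning(out <- median_normalize(rep(0, 4)), "median")
  expect_equal(out, rep(0, 4))
})

test_that("class weighting hits LJ sigma and hydrogen entries only", {
  pv <- ff_params(ff_registry())
  labels <- attr(pv, "labels"); hyd <- attr(pv, "hydrogen")
  g <- rep(1, 108)
  w <- apply_class_weights(g, labels, hyd, 0.02)
  sel <- labels == "lj_sigma" | hyd
  expect_equal(w[sel], rep(0.02, sum(sel)))
  expect_equal(w[!sel], rep(1, sum(!sel)))
  expect_equal(apply_class_weights(g, labels, hyd, 1), g)
})

test_that("per-protein and per-epoch caps are enforced exactly", {
  cfg <- training_config()
  pv <- ff_params(ff_registry())
  p1 <- pv; p1[] <- 1
  # one protein proposing a +2 % change is capped at +0.5 %
  g <- rep(0, 108); g[5] <- -0.02 / cfg$learning_rate
  out <- cap_and_update(p1, list(g), cfg)
  expect_equal(unname(out[5]), 1.005)
  expect_equal(as.numeric(out[-5]), as.numeric(p1[-5]))
  # 8 proteins each at the 0.5 % cap combine to +3 %, not +4 %
  out8 <- cap_and_update(p1, rep(list(g), 8), cfg)
  expect_equal(unname(out8[5]), 1.03)
  # tiny gradients pass through unclamped: change = -lr * sum(g)
  gt <- rep(1e-3, 108)
  outt <- cap_and_update(p1, list(gt, gt), cfg)
  expect_equal(as.numeric(outt), as.numeric(p1) - cfg$learning_rate * 2e-3)
})

test_that("the learning-rate path matches a hand-computed 3-parameter toy", {
  cfg <- training_config(learning_rate = 4e-4)
  p <- ff_params(ff_registry())
  p[] <- 0; p[1:3] <- c(1, 2, 4)
  g1 <- rep(0, 108); g1[1:3] <- c(2, -1, 0.5)
  g2 <- rep(0, 108); g2[1:3] <- c(-1, 1, 1)
  out <- cap_and_update(p, list(g1, g2), cfg)
  # per-protein changes: -4e-4*g, all below the 0.5 % caps here
  expect_equal(unname(out[1:3]), c(1, 2, 4) - 4e-4 * c(1, 0, 1.5))
})

test_that("the update rule converges on a convex quadratic toy objective", {
  # loss = (p1 - a)^2 + (p2 - b)^2, analytic gradients, no dynamics
  cfg <- training_config(learning_rate = 4e-4, n_epochs = 5L)
  p <- ff_params(ff_registry())
  target <- as.numeric(p)
  target[1] <- p[1] * 1.02   # within reach of the 3 % epoch cap over epochs
  target[47] <- p[47] * 0.97
  cur <- p
  for (ep in 1:60) {
    g <- 2 * (as.numeric(cur) - target) * 1000
    cur <- cap_and_update(cur, list(g), cfg)
  }
  expect_equal(unname(cur[1]), target[1], tolerance = 2e-3)
  expect_equal(unname(cur[47]), target[47], tolerance = 2e-3)
})

test_that("run selection takes the lowest final loss with index tie-break", {
  mk <- function(id, losses) structure(list(run_id = id,
                                            mean_loss = losses),
                                       class = "train_run")
  runs <- list(mk(1, c(1, 0.4)), mk(2, c(1, 0.2)), mk(3, c(1, 0.3)))
  expect_equal(select_best_run(runs)$run_id, 2)
  expect_equal(select_best_run(runs[1])$run_id, 1)
  ties <- list(mk(1, 0.2), mk(2, 0.2))
  expect_equal(select_best_run(ties)$run_id, 1)
})

test_that("a toy epoch respects the cap invariant and is reproducible", {
  toy <- make_toy_chain(toy_spec(2, "extended"))
  pv <- ff_params(toy$system$registry)
  cfg <- simulation_config(n_steps = 200, record_interval = 50,
                           checkpoint_interval = 100, seed = 5L)
  ref <- make_stats(0.45, 0.06, 2L, frames = 4L)
  proteins <- list(list(id = "toy", system = toy$system, ref = ref,
                        idp = FALSE))
  tc <- training_config(n_epochs = 2L)
  out1 <- run_epoch(proteins, pv, cfg, tc, seed = 3L)
  out2 <- run_epoch(proteins, pv, cfg, tc, seed = 3L)
  expect_identical(out1$report, out2$report)
  expect_identical(as.numeric(out1$params), as.numeric(out2$params))
  rel <- abs(as.numeric(out1$params) - as.numeric(pv)) / abs(as.numeric(pv))
  expect_true(all(rel <= tc$per_epoch_cap + 1e-12))
  expect_true(any(rel > 0))
  # a multi-epoch run reports per-epoch losses and tidies
  tr <- train_forcefield(proteins, pv, cfg, tc, seed = 3L)
  expect_length(tr$mean_loss, 2L)
  td <- tidy(tr)
  expect_equal(nrow(td), 2L)
  expect_true(all(c("epoch", "protein", "loss") %in% names(td)))
  gl <- glance(tr)
  expect_equal(gl$final_mean_loss, tr$mean_loss[2])
})
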