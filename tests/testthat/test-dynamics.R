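# Langevin integration, checkpointing, adjoint machinery, minimisation.

test_that("with zero friction and zero noise BAOAB reduces to velocity Verlet", {
  k <- 800; m <- 12
  eng <- make_harmonic_system(k, mass = m)
  x0 <- matrix(c(0.1, 0, 0), 1, 3)
  st <- list(x = x0, v = matrix(0, 1, 3), F = eng$eval(x0)$forces)
  zero <- matrix(0, 1, 3)
  dt <- 0.001
  E0 <- 0.5 * k * sum(st$x^2) + 0.5 * m * sum(st$v^2)
  Es <- numeric(10000)
  for (s in 1:10000) {
    st <- langevin_step(st, eng, dt, gamma = 0, temperature = 300, zero)
    Es[s] <- 0.5 * k * sum(st$x^2) + 0.5 * m * sum(st$v^2)
  }
  # energy conserved to O(dt^2) over 10^4 steps
  expect_lt(max(abs(Es - E0)) / E0, 5e-3)
  # and the trajectory is periodic with omega = sqrt(k/m)
  expect_equal(st$x[1], 0.1 * cos(sqrt(k / m) * dt * 10000), tolerance = 1e-2)
})

test_that("the tethered particle samples the Gibbs variance kB T / k", {
  k <- 1000; temp <- 300
  eng <- make_harmonic_system(k, mass = 12, temperature = temp)
  cfg <- simulation_config(n_steps = 200000, record_interval = 200000,
                           checkpoint_interval = 1000, gamma = 2,
                           temperature = temp, seed = 4L)
  set.seed(cfg$seed)
  v <- maxwell_velocities(eng, temp)
  st <- list(x = matrix(0, 1, 3), v = v, F = eng$eval(matrix(0, 1, 3))$forces)
  xs <- vs <- matrix(0, 200000 / 10, 3)
  c0 <- 0L
  for (s in seq_len(200000)) {
    noise <- matrix(rnorm(3), 1, 3)
    st <- langevin_step(st, eng, cfg$dt, cfg$gamma, temp, noise)
    if (s %% 10 == 0) { c0 <- c0 + 1L; xs[c0, ] <- st$x; vs[c0, ] <- st$v }
  }
  target_x <- KB * temp / k
  target_v <- KB * temp / 12
  expect_equal(mean(apply(xs, 2, var)), target_x, tolerance = 0.05)
  # velocity variance satisfies equipartition kB T / m per component
  expect_equal(mean(apply(vs, 2, var)), target_v, tolerance = 0.05)
})

test_that("simulations are deterministic given a seed and replay bit-for-bit", {
  toy <- make_toy_chain(toy_spec(3, "extended"))
  eng <- system_engine(toy$system)
  cfg <- simulation_config(n_steps = 300, record_interval = 100,
                           checkpoint_interval = 100, seed = 9L)
  s1 <- simulate_with_checkpoints(eng, cfg)
  s2 <- simulate_with_checkpoints(eng, cfg)
  expect_identical(s1$final_state, s2$final_state)
  expect_identical(s1$sum_x, s2$sum_x)
  # replaying the final block from its checkpoint reproduces the final state
  ck <- s1$checkpoints[[3]]
  st <- list(x = ck$x, v = ck$v, F = eng$eval(ck$x)$forces)
  set.seed(ck$seed)
  for (s in 1:100) {
    noise <- matrix(rnorm(eng$n * 3), eng$n, 3)
    st <- langevin_step(st, eng, cfg$dt, cfg$gamma, cfg$temperature, noise)
  }
  expect_identical(st$x, s1$final_state$x)
  expect_identical(st$v, s1$final_state$v)
})

test_that("a rigid two-residue toy records mu equal to the fixed distance", {
  # statistics of a constant distance: mu = d, sigma floored
  d <- c(0.5, 0.5, 0.5, 0.5)
  st <- finalize_statistics(sum(d), sum(d^2), 4L, 2L)
  expect_equal(st$mu, 0.5)
  expect_equal(st$sigma, 1e-3)  # sigma_min floor
})

test_that("adjoint clipping rescales norms exactly and never divides by zero", {
  a <- matrix(c(0.12, 0.16, 0, 0, 0, 0), 2, 3)  # norm 0.2
  b <- matrix(0.01, 2, 3)
  cl <- clip_adjoints(a, b, 0.1)
  expect_equal(cl$adjoint_coords, a * 0.5)
  expect_equal(cl$adjoint_vels, b)
  expect_equal(sqrt(sum(cl$adjoint_coords^2)), 0.1)
  z <- clip_adjoints(matrix(0, 2, 3), matrix(0, 2, 3), 0.1)
  expect_true(all(z$adjoint_coords == 0))
  # below threshold: unchanged
  small <- matrix(0.01, 2, 3)
  expect_equal(clip_adjoints(small, small, 0.1)$adjoint_coords, small)
})

test_that("checkpointed and full-graph reverse passes agree exactly", {
  toy <- make_toy_chain(toy_spec(3, "extended"))
  eng <- system_engine(toy$system)
  cfg <- simulation_config(n_steps = 500, record_interval = 100,
                           checkpoint_interval = 100, seed = 13L)
  sim <- simulate_with_checkpoints(eng, cfg, store_full = TRUE)
  st <- simulation_statistics(sim, 3L)
  ref <- st; ref$mu <- ref$mu * 1.1
  dl <- loss_accumulator_grad(st, ref)
  g_ck <- backprop_gradients(sim, eng, dl)
  g_full <- backprop_gradients(sim, eng, dl, use_checkpoints = FALSE)
  expect_identical(g_ck, g_full)
  # clipping with a huge threshold equals clipping disabled
  cfg2 <- cfg; cfg2$clip_threshold <- 1e12
  sim2 <- simulate_with_checkpoints(eng, cfg2)
  g_big <- backprop_gradients(sim2, eng, dl, clip = TRUE)
  g_off <- backprop_gradients(sim2, eng, dl, clip = FALSE)
  expect_identical(g_big, g_off)
})

test_that("trajectory gradients match a finite-difference oracle", {
  sys <- small_digly()
  pv <- ff_params(sys$registry)
  cfg <- simulation_config(n_steps = 100, record_interval = 25,
                           checkpoint_interval = 50, seed = 21L)
  ref <- make_stats(0.45, 0.05, 2L, frames = 4L)
  lossfun <- function(p) {
    eng <- system_engine(sys, p)
    aggregate_loss(simulation_statistics(
      simulate_with_checkpoints(eng, cfg), 2L), ref)
  }
  eng <- system_engine(sys, pv)
  sim <- simulate_with_checkpoints(eng, cfg)
  st <- simulation_statistics(sim, 2L)
  g <- backprop_gradients(sim, eng, loss_accumulator_grad(st, ref),
                          clip = FALSE)
  set.seed(31)
  ks <- sample(108L, 16L)
  fd <- vapply(ks, function(k) {
    hk <- 1e-5 * max(abs(pv[k]), 1e-2)
    pp <- pv; pp[k] <- pp[k] + hk
    pm <- pv; pm[k] <- pm[k] - hk
    (lossfun(pp) - lossfun(pm)) / (2 * hk)
  }, 0)
  # compare where the gradient is non-negligible; tiny entries are FD noise
  sel <- abs(fd) > 1e-3 * max(abs(fd))
  expect_gt(sum(sel), 3L)
  rel <- abs(g[ks[sel]] - fd[sel]) / abs(fd[sel])
  expect_lt(max(rel), 1e-4)
})

test_that("minimisation descends and solves analytic cases", {
  # stretched harmonic bond converges to r0
  sys <- small_digly()
  s <- sys
  b <- s$bonds[1, ]
  s$bonds <- b; s$bonds$i <- 1L; s$bonds$j <- 2L
  s$angles <- s$angles[0, ]; s$torsions <- s$torsions[0, ]
  s$pairflag <- matrix(0L, 2, 2)
  s$atoms <- s$atoms[c(b$i, b$j), ]
  s$coords <- rbind(c(0, 0, 0), c(b$r0 * 1.5, 0, 0))
  for (f in c("gb_rho", "gb_screen", "gb_alpha", "gb_beta", "gb_gamma",
              "sigma_i", "eps_i"))
    s[[f]] <- s[[f]][c(b$i, b$j)]
  s$radius_class <- s$radius_class[c(b$i, b$j)]
  s$elem_class <- s$elem_class[c(b$i, b$j)]
  s$type_index <- s$type_index[c(b$i, b$j)]
  eng <- system_engine(s, gb = FALSE)
  mn <- minimize(eng, max_iter = 2000, tolerance = 1)
  r_fin <- sqrt(sum((mn$coords[2, ] - mn$coords[1, ])^2))
  expect_equal(r_fin, b$r0, tolerance = 1e-3)
  # already-minimised configuration stays put
  mn2 <- minimize(eng, coords = mn$coords, tolerance = 5)
  expect_equal(mn2$coords, mn$coords, tolerance = 1e-6)
  # clashed full system: energy decreases
  eng3 <- system_engine(small_triala())
  x0 <- jitter_coords(small_triala(), sd = 0.004, seed = 3)
  e0 <- eng3$eval(x0)$total
  mn3 <- minimize(eng3, max_iter = 50, coords = x0)
  expect_lt(mn3$energy, e0)
})

test_that("single-precision mode rounds the state through IEEE floats", {
  toy <- make_toy_chain(toy_spec(2, "extended"))
  eng <- system_engine(toy$system)
  cfg <- simulation_config(n_steps = 100, record_interval = 50,
                           checkpoint_interval = 50, seed = 2L,
                           precision = "single")
  sim <- simulate_with_checkpoints(eng, cfg)
  x <- sim$final_state$x
  expect_identical(x, cpp_round_float(x))
  # deterministic too
  sim2 <- simulate_with_checkpoints(eng, cfg)
  expect_identical(sim$final_state, sim2$final_state)
})
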