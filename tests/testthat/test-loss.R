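# Distance statistics and the two-way Gaussian KL loss.

test_that("finalize_statistics computes population moments with a sigma floor", {
  # frames 1.0 and 3.0 nm: mu = 2, sigma = 1 (population)
  st <- finalize_statistics(sum(c(1, 3)), sum(c(1, 9)), 2L, 2L)
  expect_equal(st$mu, 2)
  expect_equal(st$sigma, 1)
  # constant distance engages the floor
  st2 <- finalize_statistics(4 * 0.7, 4 * 0.49, 4L, 2L)
  expect_equal(st2$sigma, 1e-3)
  # round-off negative variance is clamped, never NaN
  st3 <- finalize_statistics(2, 2 * (1 - 1e-16) / 2, 2L, 2L)
  expect_false(anyNA(st3$sigma))
  expect_equal(st3$sigma, 1e-3)
  expect_error(finalize_statistics(1, 1, 1L, 2L), "2")
})

test_that("gaussian_kl matches its closed form and numerical quadrature", {
  expect_equal(gaussian_kl(1, 0.2, 1, 0.2), 0)
  # mu_s - mu_r = sigma_r, sigma_s = sigma_r -> exactly 0.5
  expect_equal(gaussian_kl(1.3, 0.3, 1.0, 0.3), 0.5)
  # quadrature oracle value for (0, 0.5) vs (0, 1)
  expect_equal(gaussian_kl(0, 0.5, 0, 1), kl_quadrature(0, 0.5, 0, 1),
               tolerance = 1e-8)
  expect_equal(round(gaussian_kl(0, 0.5, 0, 1), 4), 0.3181)
  expect_error(gaussian_kl(0, -1, 0, 1), "positive")
  # 100 random moment pairs against quadrature
  set.seed(8)
  for (r in 1:100) {
    mu_s <- runif(1, -2, 2); mu_r <- runif(1, -2, 2)
    sg_s <- runif(1, 0.1, 2); sg_r <- runif(1, 0.1, 2)
    expect_equal(gaussian_kl(mu_s, sg_s, mu_r, sg_r),
                 kl_quadrature(mu_s, sg_s, mu_r, sg_r), tolerance = 1e-6)
  }
})

test_that("pair_loss is symmetric, log-compressed and zero at zero", {
  expect_equal(pair_loss(0, 0), 0)
  expect_equal(pair_loss(0.4, 1.7), pair_loss(1.7, 0.4))
  d1 <- gaussian_kl(0, 0.5, 0, 1); d2 <- gaussian_kl(0, 1, 0, 0.5)
  expect_equal(round(pair_loss(d1, d2), 4), 0.8679, tolerance = 2e-4)
  expect_equal(pair_loss(d1, d2), log(d1 + 1) + log(d2 + 1))
})

test_that("separation weights are 0, 0.5, 1 at separations 0, 5, >= 10", {
  expect_equal(separation_weight(3, 3), 0)
  expect_equal(separation_weight(0, 5), 0.5)
  expect_equal(separation_weight(0, 10), 1)
  expect_equal(separation_weight(0, 12), 1)
  expect_equal(separation_weight(12, 0), 1)
  expect_equal(separation_weight(0, 0:12), c(0:9 / 10, 1, 1, 1))
})

test_that("aggregate_loss vanishes iff weighted moments match", {
  sim <- make_stats(c(0.5, 0.7, 0.9), c(0.1, 0.2, 0.1), 3L)
  expect_equal(aggregate_loss(sim, sim), 0)
  # only zero-weight pairs differ -> still zero (no |i-j| = 0 pairs exist,
  # so perturb nothing and instead check a 3-residue hand computation)
  ref <- sim
  ref$mu[2] <- 0.9  # pair (0,2), separation 2, weight 0.2
  d1 <- gaussian_kl(sim$mu[2], sim$sigma[2], ref$mu[2], ref$sigma[2])
  d2 <- gaussian_kl(ref$mu[2], ref$sigma[2], sim$mu[2], sim$sigma[2])
  by_hand <- 0.2 * pair_loss(d1, d2) / 3
  expect_equal(aggregate_loss(sim, ref), by_hand)
  # excluding zero-weight pairs changes only the denominator
  expect_equal(aggregate_loss(sim, ref, include_zero_weight = FALSE),
               0.2 * pair_loss(d1, d2) / 3)
  expect_error(aggregate_loss(sim, make_stats(0.5, 0.1, 4L)), "mismatch")
})

test_that("accumulator gradients match finite differences on a static toy", {
  nres <- 4L
  npair <- choose(nres, 2)
  set.seed(12)
  sum_x <- runif(npair, 2, 6)
  sum_x2 <- sum_x^2 / 10 + runif(npair, 0.5, 1.5)
  nf <- 10L
  ref <- make_stats(runif(npair, 0.3, 0.8), runif(npair, 0.05, 0.2), nres)
  lossfun <- function(sx, sx2) {
    aggregate_loss(finalize_statistics(sx, sx2, nf, nres), ref)
  }
  st <- finalize_statistics(sum_x, sum_x2, nf, nres)
  gr <- loss_accumulator_grad(st, ref)
  h <- 1e-7
  for (p in seq_len(npair)) {
    sp <- sum_x; sp[p] <- sp[p] + h
    sm <- sum_x; sm[p] <- sm[p] - h
    expect_equal(gr$d_sum_x[p], (lossfun(sp, sum_x2) -
                                   lossfun(sm, sum_x2)) / (2 * h),
                 tolerance = 1e-6)
    sp2 <- sum_x2; sp2[p] <- sp2[p] + h
    sm2 <- sum_x2; sm2[p] <- sm2[p] - h
    expect_equal(gr$d_sum_x2[p], (lossfun(sum_x, sp2) -
                                    lossfun(sum_x, sm2)) / (2 * h),
                 tolerance = 1e-6)
  }
})

test_that("reference statistics round-trip through the TSV format", {
  st <- make_stats(c(0.5, 0.712345678, 0.9), c(0.1, 0.2, 0.15), 3L,
                   frames = 17L)
  path <- tempfile(fileext = ".tsv")
  write_reference_stats(st, path)
  st2 <- read_reference_stats(path)
  expect_equal(st2$mu, st$mu)
  expect_equal(st2$sigma, st$sigma)
  expect_equal(attr(st2, "n_residues"), 3L)
  expect_equal(attr(st2, "frame_count"), 17L)
  unlink(path)
})
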