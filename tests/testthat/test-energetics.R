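# Potential terms: analytic examples, oracles, and derivative checks.

test_that("bonded terms reproduce analytic special cases", {
  sys <- small_digly()
  # bonds at their rest lengths contribute zero
  X <- sys$coords
  for (k in seq_len(nrow(sys$bonds))) {
    i <- sys$bonds$i[k]; j <- sys$bonds$j[k]
    d <- X[j, ] - X[i, ]
    X[j, ] <- X[i, ] + d / sqrt(sum(d^2)) * sys$bonds$r0[k]
  }
  # direct single-bond evaluation: k (r - r0)^2
  s1 <- sys
  s1$angles <- s1$angles[0, ]; s1$torsions <- s1$torsions[0, ]
  s1$pairflag[] <- 0L
  b <- s1$bonds[1, ]
  s1$bonds <- b
  x0 <- matrix(0, 2, 3); x0[2, 1] <- b$r0
  s1$coords <- s1$coords[c(b$i, b$j), ]
  s1$bonds$i <- 1L; s1$bonds$j <- 2L
  e0 <- eval_potential(s1, coords = x0, gb = FALSE)$energies
  expect_equal(unname(e0["bond"]), 0)
  x1 <- x0; x1[2, 1] <- b$r0 + 0.01
  e1 <- eval_potential(s1, coords = x1, gb = FALSE)$energies
  expect_equal(unname(e1["bond"]), b$k * 0.01^2, tolerance = 1e-10)
})

test_that("a periodic torsion hits its cosine extrema", {
  # 4-atom chain with one torsion term k=1, n=1, delta=0
  sys <- small_digly()
  s <- sys
  s$bonds <- s$bonds[0, ]; s$angles <- s$angles[0, ]
  s$pairflag[] <- 0L
  s$torsions <- tibble::tibble(i = 1L, j = 2L, k = 3L, l = 4L, n = 1,
                               kf = 1, phase = 0, bin = 1L)
  # build coordinates with an exact dihedral phi around the 2-3 bond
  coords_phi <- function(phi) {
    p1 <- c(1, 1, 0); p2 <- c(1, 0, 0); p3 <- c(0, 0, 0)
    p4 <- place_atom(p3, p2, p1, 1, pi / 2, phi)
    rbind(p1, p2, p3, p4)[, , drop = FALSE]
  }
  s$coords <- coords_phi(0)
  e_pi <- eval_potential(s, coords = coords_phi(pi), gb = FALSE)$energies
  e_0 <- eval_potential(s, coords = coords_phi(0), gb = FALSE)$energies
  expect_equal(unname(e_pi["torsion"]), 0, tolerance = 1e-10)
  expect_equal(unname(e_0["torsion"]), 2, tolerance = 1e-10)
})

test_that("LJ and Coulomb match closed forms on two-atom systems", {
  sys <- small_digly()
  reg <- sys$registry
  # pick two CT atoms, make an isolated interacting pair
  ct <- which(sys$atoms$type == "CT")[1:2]
  s <- sys
  s$bonds <- s$bonds[0, ]; s$angles <- s$angles[0, ]
  s$torsions <- s$torsions[0, ]
  s$pairflag[] <- 0L
  s$pairflag[ct[1], ct[2]] <- 1L; s$pairflag[ct[2], ct[1]] <- 1L
  sig <- reg$atom_types$sigma[reg$atom_types$type == "CT"]
  eps <- reg$atom_types$epsilon[reg$atom_types$type == "CT"]
  at_r <- function(r) {
    X <- s$coords; X[ct[2], ] <- X[ct[1], ] + c(r, 0, 0); X
  }
  q1 <- sys$atoms$charge[ct[1]]; q2 <- sys$atoms$charge[ct[2]]
  e_sig <- eval_potential(s, coords = at_r(sig), gb = FALSE)$energies
  expect_equal(unname(e_sig["lj"]), 0, tolerance = 1e-10)
  e_min <- eval_potential(s, coords = at_r(2^(1 / 6) * sig),
                          gb = FALSE)$energies
  expect_equal(unname(e_min["lj"]), -eps, tolerance = 1e-10)
  e_1nm <- eval_potential(s, coords = at_r(1), gb = FALSE)$energies
  expect_equal(unname(e_1nm["coulomb"]), 138.935458 * q1 * q2,
               tolerance = 1e-10)
  # kernel agrees with the plain-R oracle on the full system
  e_full <- eval_potential(sys, coords = jitter_coords(sys),
                           gb = FALSE)$energies
  orc <- r_nonbonded_oracle(sys, jitter_coords(sys))
  expect_equal(unname(e_full["lj"]), unname(orc["lj"]), tolerance = 1e-10)
  expect_equal(unname(e_full["coulomb"]), unname(orc["coulomb"]),
               tolerance = 1e-10)
})

test_that("mixed-type LJ pairs use Lorentz-Berthelot combining", {
  sys <- small_digly()
  i <- which(sys$atoms$type == "CT")[1]
  j <- which(sys$atoms$type == "O")[1]
  s <- sys
  s$bonds <- s$bonds[0, ]; s$angles <- s$angles[0, ]
  s$torsions <- s$torsions[0, ]
  s$pairflag[] <- 0L
  s$pairflag[i, j] <- 1L; s$pairflag[j, i] <- 1L
  at <- sys$registry$atom_types
  sigij <- (at$sigma[at$type == "CT"] + at$sigma[at$type == "O"]) / 2
  epsij <- sqrt(at$epsilon[at$type == "CT"] * at$epsilon[at$type == "O"])
  X <- s$coords; X[j, ] <- X[i, ] + c(2^(1 / 6) * sigij, 0, 0)
  q12 <- sys$atoms$charge[i] * sys$atoms$charge[j]
  e <- eval_potential(s, coords = X, gb = FALSE)$energies
  expect_equal(unname(e["lj"]), -epsij, tolerance = 1e-10)
})

test_that("1-4 pairs are scaled by the trainable couplings", {
  sys <- small_triala()
  X <- jitter_coords(sys)
  e1 <- eval_potential(sys, coords = X, gb = FALSE)$energies
  reg2 <- sys$registry
  reg2$scale_14[["coulomb_14"]] <- reg2$scale_14[["coulomb_14"]] / 2
  sys2 <- refresh_system_parameters(sys, reg2)
  e2 <- eval_potential(sys2, coords = X, gb = FALSE)$energies
  # halving the 1-4 Coulomb scale changes the energy by half the 1-4 sum
  ke <- 138.935458
  q <- sys$atoms$charge
  s14 <- 0
  for (k in seq_len(nrow(sys$pairs_14))) {
    i <- sys$pairs_14[k, 1]; j <- sys$pairs_14[k, 2]
    s14 <- s14 + ke * q[i] * q[j] / sqrt(sum((X[i, ] - X[j, ])^2))
  }
  expect_equal(unname(e1["coulomb"] - e2["coulomb"]),
               s14 * sys$registry$scale_14[["coulomb_14"]] / 2,
               tolerance = 1e-8)
})

test_that("Born radii obey analytic limits and burial monotonicity", {
  sys <- small_digly()
  gl <- sys$registry$gb$globals
  # isolated atom: effective radius equals the offset-reduced radius
  s1 <- sys
  s1$coords <- s1$coords[1, , drop = FALSE]
  for (f in c("gb_rho", "gb_screen", "gb_alpha", "gb_beta", "gb_gamma"))
    s1[[f]] <- s1[[f]][1]
  s1$radius_class <- s1$radius_class[1]; s1$elem_class <- s1$elem_class[1]
  r1 <- born_radii(s1)
  expect_equal(r1, s1$gb_rho[1] - gl[["offset"]], tolerance = 1e-10)
  # two atoms approaching: radii non-decreasing as separation shrinks
  s2 <- sys
  s2$coords <- s2$coords[1:2, , drop = FALSE]
  for (f in c("gb_rho", "gb_screen", "gb_alpha", "gb_beta", "gb_gamma"))
    s2[[f]] <- s2[[f]][1:2]
  s2$radius_class <- s2$radius_class[1:2]; s2$elem_class <- s2$elem_class[1:2]
  seps <- seq(1.2, 0.3, by = -0.1)
  rads <- sapply(seps, function(d) {
    X <- rbind(c(0, 0, 0), c(d, 0, 0))
    born_radii(s2, coords = X)
  })
  expect_true(all(diff(rads[1, ]) >= -1e-12))
  expect_true(all(diff(rads[2, ]) >= -1e-12))
})

test_that("descreening matches a Monte-Carlo quadrature oracle within 15 %", {
  # 5-atom cluster, neck disabled so the oracle integral is the whole story
  sys <- small_digly()
  idx <- c(1, 5, 7, 8, 9)
  s <- sys
  set.seed(3)
  s$coords <- sys$coords[idx, ] + matrix(rnorm(15, 0, 0.05), ncol = 3)
  for (f in c("gb_rho", "gb_screen", "gb_alpha", "gb_beta", "gb_gamma"))
    s[[f]] <- s[[f]][idx]
  s$radius_class <- s$radius_class[idx]; s$elem_class <- s$elem_class[idx]
  reg <- s$registry
  reg$gb$globals[["neck_scale"]] <- 0
  s <- refresh_system_parameters(s, reg)
  gl <- reg$gb$globals
  rho_red <- s$gb_rho - gl[["offset"]]
  I_mc <- mc_descreening_oracle(s$coords, rho_red, s$gb_screen * rho_red)
  R_pkg <- born_radii(s)
  psi_mc <- I_mc * rho_red
  phi <- s$gb_alpha * psi_mc - s$gb_beta * psi_mc^2 + s$gb_gamma * psi_mc^3
  R_mc <- 1 / (1 / rho_red - tanh(phi) / s$gb_rho)
  expect_true(all(abs(R_pkg - R_mc) / R_mc < 0.15))
})

test_that("the single-ion polar energy reproduces the Born formula", {
  sys <- small_digly()
  s1 <- sys
  s1$coords <- matrix(0, 1, 3)
  s1$atoms <- s1$atoms[1, ]; s1$atoms$charge <- 1
  R <- 0.15
  e <- gb_energy(s1, radii = R, kappa = 0)
  born <- -138.935458 * (1 - 1 / 78.5) / (2 * R)
  expect_equal(e, born, tolerance = 1e-9)
  # large kappa kills the solvent contribution
  e_inf <- gb_energy(s1, radii = R, kappa = 1e6)
  expect_equal(e_inf, -138.935458 / (2 * R) * 1, tolerance = 1e-6)
  expect_error(gb_energy(s1, radii = -0.1), "positive")
})

test_that("the GB pair function approaches sqrt(Ri Rj) at contact", {
  sys <- small_digly()
  s <- sys
  s$coords <- rbind(c(0, 0, 0), c(1e-7, 0, 0))
  s$atoms <- s$atoms[1:2, ]
  s$atoms$charge <- c(1, -1)
  Ri <- 0.15; Rj <- 0.2
  e <- gb_energy(s, radii = c(Ri, Rj), kappa = 0)
  f0 <- sqrt(Ri * Rj)
  expected <- -138.935458 * (1 - 1 / 78.5) *
    (1 / (2 * Ri) + 1 / (2 * Rj) - 1 / f0)
  expect_equal(e, expected, tolerance = 1e-5)
})

test_that("surface-area energy has the single-sphere and buried limits", {
  sys <- small_digly()
  s1 <- sys
  s1$coords <- matrix(0, 1, 3)
  s1$atoms <- s1$atoms[1, ]
  s1$gb_rho <- s1$gb_rho[1]
  gl <- sys$registry$gb$globals
  rt <- s1$gb_rho - gl[["offset"]]
  # isolated atom (R = rt): factor * 4 pi (rho + probe)^2
  e <- surface_area_energy(s1, radii = rt)
  expect_equal(e, gl[["sa_factor"]] * 4 * pi *
                 (s1$gb_rho + gl[["probe_radius"]])^2, tolerance = 1e-10)
  expect_equal(surface_area_energy(s1, radii = rt,
                                   surface_area_factor = 0), 0)
  # deeply buried: contribution vanishes as (rt/R)^6
  expect_lt(surface_area_energy(s1, radii = 100 * rt), 1e-10 * e)
})

test_that("forces are exact gradients and respect rigid-body invariance", {
  sys <- small_digly()
  X <- jitter_coords(sys)
  p <- eval_potential(sys, coords = X)
  h <- 1e-6
  set.seed(2)
  for (k in sample(length(X), 15)) {
    Xp <- X; Xp[k] <- Xp[k] + h
    Xm <- X; Xm[k] <- Xm[k] - h
    fd <- -(eval_potential(sys, Xp)$total -
              eval_potential(sys, Xm)$total) / (2 * h)
    expect_equal(p$forces[k], fd,
                 tolerance = 1e-5 * max(1, abs(fd)))
  }
  # translation invariance
  e_t <- eval_potential(sys, coords = X + rep(c(0.3, -0.2, 0.5),
                                              each = nrow(X)))
  expect_equal(e_t$total, p$total, tolerance = 1e-8 * abs(p$total))
  expect_lt(max(abs(colSums(p$forces))), 1e-6)
  # rotation invariance
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  e_r <- eval_potential(sys, coords = X %*% Rz)
  expect_equal(e_r$total, p$total, tolerance = 1e-8 * abs(p$total))
})

test_that("parameter gradients of the total energy match finite differences", {
  sys <- small_digly()
  X <- jitter_coords(sys)
  p <- eval_potential(sys, coords = X, want_pgrad = TRUE)
  pv <- ff_params(sys$registry)
  for (k in seq_len(108L)) {
    hk <- 1e-4 * max(abs(pv[k]), 1e-2)
    pp <- pv; pp[k] <- pp[k] + hk
    pm <- pv; pm[k] <- pm[k] - hk
    fd <- (eval_potential(apply_parameter_vector(sys, pp), coords = X)$total -
           eval_potential(apply_parameter_vector(sys, pm),
                          coords = X)$total) / (2 * hk)
    expect_equal(p$pgrad[k], fd,
                 tolerance = 1e-5 * max(1, abs(fd)),
                 label = paste("pgrad", names(pv)[k]))
  }
})

test_that("energy breakdown components sum to the total", {
  sys <- small_triala()
  p <- eval_potential(sys)
  expect_equal(sum(p$energies), p$total)
  expect_named(p$energies, c("bond", "angle", "torsion", "lj", "coulomb",
                             "gb_polar", "gb_surface"))
})
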