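# Trajectory analysis operators.

test_that("radius of gyration matches analytic cases", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  # two equal masses at distance d -> d/2
  d <- 0.8
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(d, 0, 0))), d / 2)
  # 4 equal masses at alternating unit-cube corners (regular tetrahedron):
  # each corner sits sqrt(3)/2 from the centre
  tet <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  expect_equal(radius_of_gyration(tet), sqrt(3) / 2)
  # mass weighting: heavy atom pins the centre of mass
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0)),
                                  masses = c(3, 1)),
               sqrt((3 * 0.25^2 + 0.75^2) / 4))
  expect_error(radius_of_gyration(matrix(0, 1, 3), masses = 0), "mass")
})

test_that("windowed RMSD removes rigid motion and matches the loop oracle", {
  set.seed(6)
  ref <- matrix(rnorm(30), 10, 3)
  # identical frames -> zero
  traj <- replicate(8, ref, simplify = FALSE)
  out <- windowed_rmsd(traj, ref, window = 2)
  expect_equal(out$rmsd, rep(0, 8), tolerance = 1e-10)
  # rigid rotation + translation -> still zero after superposition
  th <- 0.9
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  out2 <- windowed_rmsd(list(ref %*% Rz + 5), ref, window = 0)
  expect_equal(out2$rmsd, 0, tolerance = 1e-10)
  # two-conformation trajectory: window means equal the naive loop oracle
  alt <- ref + matrix(rnorm(30, 0, 0.3), 10, 3)
  traj2 <- rep(list(ref, alt), 6)
  out3 <- windowed_rmsd(traj2, ref, window = 3)
  expect_equal(out3$rmsd_smooth, naive_windowed_rmsd(out3$rmsd, 3))
  # window 0 equals the per-frame RMSD
  out4 <- windowed_rmsd(traj2, ref, window = 0)
  expect_equal(out4$rmsd_smooth, out4$rmsd)
  expect_error(windowed_rmsd(list(), ref), "empty")
})

test_that("ligand contacts use a strict 6 Angstrom side-chain rule", {
  # 3 "residues" along x, ligand approaching residue 2
  frame_far <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 10, 0))
  sets <- list(1L, 2L, 3L)
  out <- ligand_contact_fraction(list(frame_far), 4L, sets)
  expect_equal(out$contact_fraction, c(0, 0, 0))
  frame_near <- frame_far; frame_near[4, ] <- c(1, 0.3, 0)
  out2 <- ligand_contact_fraction(list(frame_far, frame_near), 4L, sets)
  expect_equal(out2$contact_fraction, c(0, 0.5, 0))
  # exactly at the cutoff is not a contact (strict <)
  frame_edge <- frame_far; frame_edge[4, ] <- c(1, 0.6, 0)
  out3 <- ligand_contact_fraction(list(frame_edge), 4L, sets)
  expect_equal(out3$contact_fraction[2], 0)
  expect_error(ligand_contact_fraction(list(frame_far), integer(0), sets),
               "empty")
})

test_that("oligomer sizes equal connected components of the contact graph", {
  fx <- make_dimer_fixture(5, n_peptides = 6L)
  out <- oligomer_sizes(fx$coords, fx$groups)
  expect_equal(out$sizes, rep(1L, 6))
  expect_equal(out$largest, 1L)
  # two triples, each internally in contact
  fx2 <- make_dimer_fixture(0.35, n_peptides = 6L,
                            centres = rbind(c(0, 0, 0), c(0.35, 0, 0),
                                            c(0.7, 0, 0), c(10, 0, 0),
                                            c(10.35, 0, 0), c(10.7, 0, 0)))
  out2 <- oligomer_sizes(fx2$coords, fx2$groups)
  expect_equal(out2$sizes, c(3L, 3L))
  # chain A-B-C joined transitively into one component
  fx3 <- make_dimer_fixture(0.35, n_peptides = 3L)
  out3 <- oligomer_sizes(fx3$coords, fx3$groups)
  expect_equal(out3$sizes, 3L)
  expect_error(oligomer_sizes(fx$coords, list(1:5, 5:9)), "overlap")
})

test_that("oligomer clustering agrees with brute-force union-find", {
  set.seed(17)
  for (rep in 1:5) {
    np <- sample(3:8, 1)
    centres <- matrix(runif(np * 3, 0, 3), np, 3)
    fx <- make_dimer_fixture(1, n_peptides = np, centres = centres)
    out <- oligomer_sizes(fx$coords, fx$groups, cutoff = 0.7)
    orc <- union_find_sizes(fx$coords, fx$groups, cutoff = 0.7)
    expect_equal(out$sizes, orc)
    expect_equal(sum(out$sizes), np)
  }
})

test_that("minimum-image distances respect a cubic box", {
  # two peptides on opposite box faces are neighbours through the boundary
  fx <- make_dimer_fixture(1, n_peptides = 2L,
                           centres = rbind(c(0.3, 0, 0), c(4.5, 0, 0)))
  far <- oligomer_sizes(fx$coords, fx$groups, cutoff = 0.8)
  expect_equal(far$sizes, c(1L, 1L))
  near <- oligomer_sizes(fx$coords, fx$groups, cutoff = 0.8, box = 5)
  expect_equal(near$sizes, 2L)
})

test_that("multi-model PDB trajectories round-trip", {
  toy <- make_toy_chain(toy_spec(2, "extended"))
  sys <- toy$system
  frames <- list(sys$coords, sys$coords + 0.1)
  path <- tempfile(fileext = ".pdb")
  write_pdb(sys, path, frames = frames)
  back <- read_pdb_trajectory(path)
  expect_length(back, 2L)
  expect_equal(back[[1]], unname(sys$coords), tolerance = 2e-4,
               ignore_attr = TRUE)
  expect_equal(back[[2]] - back[[1]], matrix(0.1, nrow(sys$coords), 3),
               tolerance = 2e-4, ignore_attr = TRUE)
  unlink(path)
})
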