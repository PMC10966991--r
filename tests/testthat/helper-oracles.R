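# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (brute force, quadrature, direct loops) and
# never call the code paths they check.

# small cached systems ------------------------------------------------------

fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

small_digly <- function() get_fixture("digly", function() {
  ch <- build_ideal_coords(c("NGLY", "CGLY"))
  build_system(ch$atoms, ch$coords)
})

small_triala <- function() get_fixture("triala", function() {
  ch <- build_ideal_coords(c("NALA", "ALA", "CALA"))
  build_system(ch$atoms, ch$coords)
})

# jittered coordinates that avoid exact symmetry
jitter_coords <- function(sys, sd = 0.002, seed = 11) {
  set.seed(seed)
  sys$coords + matrix(rnorm(length(sys$coords), 0, sd), ncol = 3)
}

# energy oracle: plain-R non-bonded sum -------------------------------------

r_nonbonded_oracle <- function(sys, coords = NULL) {
  X <- if (is.null(coords)) sys$coords else coords
  reg <- sys$registry
  at <- reg$atom_types
  sig <- at$sigma[sys$type_index]
  eps <- at$epsilon[sys$type_index]
  q <- sys$atoms$charge
  n <- nrow(X)
  ke <- 138.935458
  e_lj <- e_c <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      fl <- sys$pairflag[i, j]
      if (fl == 0) next
      r <- sqrt(sum((X[i, ] - X[j, ])^2))
      ls <- if (fl == 2) reg$scale_14[["lj_14"]] else 1
      cs <- if (fl == 2) reg$scale_14[["coulomb_14"]] else 1
      epsij <- sqrt(eps[i] * eps[j])
      if (epsij > 0) {
        sigij <- (sig[i] + sig[j]) / 2
        e_lj <- e_lj + ls * 4 * epsij * ((sigij / r)^12 - (sigij / r)^6)
      }
      e_c <- e_c + cs * ke * q[i] * q[j] / r
    }
  }
  c(lj = e_lj, coulomb = e_c)
}

# bond-graph oracle: all-pairs shortest paths by repeated relaxation --------

bond_distance_oracle <- function(n, edges) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    D[edges[k, 1], edges[k, 2]] <- 1
    D[edges[k, 2], edges[k, 1]] <- 1
  }
  for (m in seq_len(n)) # Floyd-Warshall
    for (i in seq_len(n))
      D[i, ] <- pmin(D[i, ], D[i, m] + D[m, ])
  D
}

# union-find oracle for oligomer clustering ---------------------------------

union_find_sizes <- function(frame, groups, cutoff, box = NULL) {
  np <- length(groups)
  parent <- seq_len(np)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  d2 <- function(A, B) {
    out <- Inf
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      d <- A[i, ] - B[j, ]
      if (!is.null(box)) d <- d - box * round(d / box)
      out <- min(out, sum(d^2))
    }
    out
  }
  if (np > 1) {
    for (a in seq_len(np - 1)) for (b in (a + 1):np) {
      if (d2(frame[groups[[a]], , drop = FALSE],
             frame[groups[[b]], , drop = FALSE]) < cutoff^2) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(np), find, 1L)
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# KL quadrature oracle -------------------------------------------------------

kl_quadrature <- function(mu_s, sg_s, mu_r, sg_r) {
  f <- function(x) {
    dnorm(x, mu_s, sg_s) * (dnorm(x, mu_s, sg_s, log = TRUE) -
                              dnorm(x, mu_r, sg_r, log = TRUE))
  }
  integrate(f, mu_s - 12 * sg_s, mu_s + 12 * sg_s,
            rel.tol = 1e-10, subdivisions = 500L)$value
}

# Monte-Carlo descreening oracle (Coulomb-field approximation):
# I_i = (1/4pi) sum_j int_{scaled sphere j} |y - x_i|^-4 dy, integrated by
# uniform sampling inside each scaled sphere, excluding the region inside
# atom i's own reduced sphere.
mc_descreening_oracle <- function(X, rho_red, sr, nsamp = 40000, seed = 99) {
  set.seed(seed)
  n <- nrow(X)
  I <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      u <- matrix(rnorm(3 * nsamp), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      rad <- sr[j] * runif(nsamp)^(1 / 3)
      y <- sweep(u * rad, 2, X[j, ], "+")
      d2 <- rowSums(sweep(y, 2, X[i, ])^2)
      vol <- 4 / 3 * pi * sr[j]^3
      integrand <- ifelse(d2 > rho_red[i]^2, 1 / d2^2, 0)
      acc <- acc + vol * mean(integrand)
    }
    I[i] <- acc / (4 * pi)
  }
  I
}

# naive windowed-RMSD oracle (direct double loop over window) ---------------

naive_windowed_rmsd <- function(raw, window) {
  n <- length(raw)
  out <- numeric(n)
  for (t in seq_len(n)) {
    lo <- max(1, t - window); hi <- min(n, t + window)
    out[t] <- mean(raw[lo:hi])
  }
  out
}

# synthetic distance_stats builder ------------------------------------------

make_stats <- function(mu, sigma, n_residues, frames = 10L) {
  pr <- utils::combn(n_residues, 2) - 1L
  structure(tibble::tibble(i = pr[1, ], j = pr[2, ],
                           mu = rep_len(mu, ncol(pr)),
                           sigma = rep_len(sigma, ncol(pr))),
            n_residues = as.integer(n_residues),
            frame_count = as.integer(frames), sigma_min = 1e-3,
            class = c("distance_stats", "tbl_df", "tbl", "data.frame"))
}
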