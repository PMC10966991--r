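# Langevin dynamics with reverse-mode gradient propagation.
#
# Forward integration uses the BAOAB splitting; the reverse pass re-simulates
# each checkpoint block from its stored state and seed, propagating adjoints
# of coordinates and velocities backwards through every substep and
# accumulating parameter adjoints.  The potential supplies analytic first
# derivatives (forces and dE/dtheta); the second-order products the reverse
# pass needs -- Hessian-vector products (dF/dx) u and mixed products
# (dF/dtheta)^T u -- are formed as central directional finite differences of
# those analytic first derivatives, so each reversed step costs a constant
# small number of kernel evaluations regardless of parameter count.

#' Simulation configuration
#'
#' @param n_steps Number of integration steps.
#' @param dt Time step (ps); default 0.001 (1 fs, unconstrained bonds).
#' @param temperature Thermostat temperature (K).
#' @param gamma Langevin friction (1/ps); default 0.1.
#' @param kappa Debye-Huckel screening (1/nm); default 0.7.
#' @param record_interval Steps between distance recordings; default 5000
#'   (5 ps at a 1 fs step).
#' @param checkpoint_interval Steps per checkpoint block; default 100.
#' @param clip_threshold Adjoint norm threshold; default 0.1.
#' @param seed Integer seed controlling initial velocities and noise.
#' @param precision "double" or "single" (state rounded through IEEE single
#'   each step).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_steps, dt = 0.001, temperature = 300,
                              gamma = 0.1, kappa = 0.7,
                              record_interval = 5000,
                              checkpoint_interval = 100,
                              clip_threshold = 0.1, seed = 1L,
                              precision = c("double", "single")) {
  precision <- match.arg(precision)
  stopifnot(dt > 0, n_steps >= 1, clip_threshold > 0)
  if (n_steps %% record_interval != 0)
    stop("record_interval must divide n_steps", call. = FALSE)
  if (n_steps %% checkpoint_interval != 0)
    stop("checkpoint_interval must divide n_steps", call. = FALSE)
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 temperature = temperature, gamma = gamma, kappa = kappa,
                 record_interval = as.integer(record_interval),
                 checkpoint_interval = as.integer(checkpoint_interval),
                 clip_threshold = clip_threshold, seed = as.integer(seed),
                 precision = precision),
            class = "sim_config")
}

#' Build a simulation engine from a molecular system
#'
#' An engine bundles coordinates, masses and a potential evaluator
#' `eval(coords, want_pgrad)`; the dynamics and training machinery operate on
#' engines, so analytic toy systems can stand in for molecular ones.
#'
#' @param system A `mol_system`.
#' @param params Optional `param_vector` applied before building.
#' @param kappa Debye-Huckel screening (1/nm).
#' @param gb,sa Include GB polar / surface-area terms.
#' @return An engine list with `n`, `masses`, `coords`, `eval`, `ca_indices`.
#' @export
system_engine <- function(system, params = NULL, kappa = 0.7, gb = TRUE,
                          sa = TRUE) {
  if (!is.null(params)) system <- apply_parameter_vector(system, params)
  ka <- kernel_args(system)
  reg <- system$registry
  q <- system$atoms$charge
  mapper <- pgrad_mapper(system)
  gl <- unname(reg$gb$globals)
  c14 <- reg$scale_14[["coulomb_14"]]
  l14 <- reg$scale_14[["lj_14"]]
  force(kappa)
  tsig <- reg$atom_types$sigma
  teps <- reg$atom_types$epsilon
  ev <- function(X, want_pgrad = FALSE) {
    out <- cpp_eval_potential(
      X, q, system$type_index, tsig, teps, system$pairflag,
      ka$bonds, ka$angles, ka$torsions, 33L,
      system$gb_rho, system$gb_screen, system$gb_alpha, system$gb_beta,
      system$gb_gamma, system$radius_class, system$elem_class,
      gl, kappa, c14, l14, gb, sa, want_pgrad)
    res <- list(total = sum(out$energies), energies = out$energies,
                forces = out$F)
    if (want_pgrad) res$pgrad <- map_param_gradient(system, out, mapper)
    res
  }
  list(n = nrow(system$atoms), masses = system$atoms$mass,
       coords = system$coords, eval = ev, ca_indices = system$ca_indices,
       has_pgrad = TRUE, system = system)
}

#' Single particle in an isotropic harmonic well
#'
#' Analytic toy engine for Langevin sampling checks: `E = k |x|^2 / 2`, so
#' the Gibbs configurational variance per axis is `kB T / k`.
#'
#' @param k Spring constant (kJ/mol/nm^2).
#' @param mass Particle mass (amu).
#' @param temperature Reference temperature (K), stored for convenience.
#' @return An engine list.
#' @export
make_harmonic_system <- function(k, mass = 12.011, temperature = 300) {
  stopifnot(k > 0, mass > 0)
  ev <- function(X, want_pgrad = FALSE) {
    list(total = 0.5 * k * sum(X^2), forces = -k * X, pgrad = NULL)
  }
  list(n = 1L, masses = mass, coords = matrix(0, 1, 3), eval = ev,
       ca_indices = integer(0), has_pgrad = FALSE, k = k,
       temperature = temperature)
}

#' One BAOAB Langevin step
#'
#' Symmetric-splitting Langevin integration; with `gamma = 0` and zero noise
#' it reduces exactly to velocity Verlet.
#'
#' @param state List with `x` (N x 3 nm), `v` (N x 3 nm/ps), `F` (forces at
#'   `x`, kJ/mol/nm).
#' @param engine An engine (see [system_engine()]).
#' @param dt Time step (ps).
#' @param gamma Friction (1/ps).
#' @param temperature Temperature (K).
#' @param noise N x 3 matrix of standard normal draws (zero matrix for a
#'   deterministic step).
#' @return Updated state list.
#' @export
langevin_step <- function(state, engine, dt, gamma, temperature, noise,
                          want_pgrad = FALSE) {
  m <- engine$masses
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(KB * temperature * (1 - c1^2) / m)
  v <- state$v + 0.5 * dt * state$F / m
  x <- state$x + 0.5 * dt * v
  v <- c1 * v + c2 * noise
  x <- x + 0.5 * dt * v
  ev <- engine$eval(x, want_pgrad)
  v <- v + 0.5 * dt * ev$forces / m
  list(x = x, v = v, F = ev$forces, pgrad = ev$pgrad)
}

block_seed <- function(seed, block) {
  as.integer((as.double(seed) * 7919 + as.double(block) * 104729) %% 2147483629)
}

maxwell_velocities <- function(engine, temperature) {
  matrix(stats::rnorm(engine$n * 3), engine$n, 3) *
    sqrt(KB * temperature / engine$masses)
}

ca_pair_index <- function(engine) {
  ca <- engine$ca_indices
  nres <- length(ca)
  if (nres < 2L) return(list(i = integer(0), j = integer(0), ca = ca))
  pr <- utils::combn(nres, 2)
  list(i = pr[1, ], j = pr[2, ], ca = ca)
}

ca_distances <- function(x, cp) {
  xi <- x[cp$ca[cp$i], , drop = FALSE]
  xj <- x[cp$ca[cp$j], , drop = FALSE]
  sqrt(rowSums((xi - xj)^2))
}

#' Forward Langevin simulation with checkpointing
#'
#' Runs BAOAB dynamics, saving the state and RNG seed at the start of every
#' checkpoint block and accumulating the running sums of Calpha pair
#' distances X and X^2 at every recording step.  Deterministic given the
#' seed and precision; block replay from a stored checkpoint reproduces the
#' forward trajectory bit for bit.
#'
#' @param engine An engine.
#' @param config A `sim_config`.
#' @param coords Optional starting coordinates (default: engine coordinates).
#' @param store_full Keep every per-step set of coordinates in memory
#'   (enables the exact non-checkpointed reverse pass, which skips block
#'   replay at an O(atoms x n_steps) memory cost).
#' @param store_derivs Additionally keep per-step forces and parameter
#'   gradients (requires `store_full`); enables the one-sided reverse pass
#'   (`fd_mode = "forward"` in [backprop_gradients()]).
#' @param store_snapshots Keep coordinates at recording steps.
#' @return A `sim_result` list with checkpoints, final state, distance
#'   accumulators (`sum_x`, `sum_x2`, `frame_count`) and metadata.
#' @export
simulate_with_checkpoints <- function(engine, config, coords = NULL,
                                      store_full = FALSE,
                                      store_derivs = FALSE,
                                      store_snapshots = FALSE) {
  x <- if (is.null(coords)) engine$coords else coords
  single <- config$precision == "single"
  if (single) x <- cpp_round_float(x)
  set.seed(config$seed)
  v <- maxwell_velocities(engine, config$temperature)
  if (single) v <- cpp_round_float(v)
  if (store_derivs && !store_full)
    stop("store_derivs requires store_full", call. = FALSE)
  wp <- store_derivs && isTRUE(engine$has_pgrad)
  ev0 <- engine$eval(x, wp)
  st <- list(x = x, v = v, F = ev0$forces, pgrad = ev0$pgrad)
  cp <- ca_pair_index(engine)
  npair <- length(cp$i)
  sum_x <- numeric(npair); sum_x2 <- numeric(npair)
  frame_count <- 0L
  L <- config$checkpoint_interval
  nblocks <- config$n_steps %/% L
  checkpoints <- vector("list", nblocks)
  full_states <- if (store_full) vector("list", config$n_steps + 1L) else NULL
  full_F <- if (store_derivs) vector("list", config$n_steps + 1L) else NULL
  full_pg <- if (store_derivs) vector("list", config$n_steps + 1L) else NULL
  snapshots <- if (store_snapshots) list() else NULL
  times <- numeric(0)
  gs <- 0L
  for (b in seq_len(nblocks)) {
    sd <- block_seed(config$seed, b)
    checkpoints[[b]] <- list(x = st$x, v = st$v, seed = sd)
    set.seed(sd)
    for (s in seq_len(L)) {
      if (store_full) {
        full_states[[gs + 1L]] <- st$x
        if (store_derivs) { full_F[[gs + 1L]] <- st$F
                            full_pg[[gs + 1L]] <- st$pgrad }
      }
      noise <- matrix(stats::rnorm(engine$n * 3), engine$n, 3)
      st <- langevin_step(st, engine, config$dt, config$gamma,
                          config$temperature, noise, wp)
      if (single) {
        st$x <- cpp_round_float(st$x); st$v <- cpp_round_float(st$v)
        ev1 <- engine$eval(st$x, wp)
        st$F <- ev1$forces; st$pgrad <- ev1$pgrad
      }
      if (!all(is.finite(st$x)))
        stop("non-finite coordinates at step ", gs + 1L, call. = FALSE)
      gs <- gs + 1L
      if (gs %% config$record_interval == 0L && npair > 0L) {
        d <- ca_distances(st$x, cp)
        sum_x <- sum_x + d
        sum_x2 <- sum_x2 + d * d
        frame_count <- frame_count + 1L
        times <- c(times, gs * config$dt)
        if (store_snapshots) snapshots[[length(snapshots) + 1L]] <- st$x
      }
    }
  }
  if (store_full) {
    full_states[[gs + 1L]] <- st$x
    if (store_derivs) { full_F[[gs + 1L]] <- st$F
                        full_pg[[gs + 1L]] <- st$pgrad }
  }
  structure(list(config = config, checkpoints = checkpoints,
                 final_state = st[c("x", "v")], sum_x = sum_x,
                 sum_x2 = sum_x2, frame_count = frame_count, times = times,
                 snapshots = snapshots, full_states = full_states,
                 full_F = full_F, full_pg = full_pg,
                 ca_pairs = cp), class = "sim_result")
}

#' Rescale reverse-pass adjoints to a norm threshold
#'
#' If the Euclidean norm of either adjoint block (coordinates, velocities)
#' exceeds the threshold, that block is rescaled to have norm exactly equal
#' to the threshold, preserving direction.  Zero adjoints pass through.
#'
#' @param adjoint_coords,adjoint_vels Adjoint matrices.
#' @param threshold Positive norm threshold (default 0.1).
#' @return List with clipped `adjoint_coords` and `adjoint_vels`.
#' @export
clip_adjoints <- function(adjoint_coords, adjoint_vels, threshold = 0.1) {
  stopifnot(threshold > 0)
  clip1 <- function(a) {
    nrm <- sqrt(sum(a * a))
    if (nrm > threshold) a * (threshold / nrm) else a
  }
  list(adjoint_coords = clip1(adjoint_coords),
       adjoint_vels = clip1(adjoint_vels))
}

# Directional second-derivative products at x along direction u:
# returns list(hvp = (dF/dx) u, gdir = (dF/dtheta)^T u).  Central differences
# of the analytic first derivatives by default; when base values of F and
# dE/dtheta at x are supplied (stored during the forward pass), a one-sided
# difference against them costs a single kernel evaluation at O(h) accuracy,
# which is far below the stochastic variation of trajectory gradients.
directional_products <- function(engine, x, u, want_pgrad, base = NULL) {
  unorm <- sqrt(sum(u * u))
  if (unorm < 1e-300) return(NULL)
  if (is.null(base)) {
    h <- 1e-5 / unorm
    ep <- engine$eval(x + h * u, want_pgrad)
    em <- engine$eval(x - h * u, want_pgrad)
    out <- list(hvp = (ep$forces - em$forces) / (2 * h))
    if (want_pgrad && !is.null(ep$pgrad))
      out$gdir <- -(ep$pgrad - em$pgrad) / (2 * h)
  } else {
    h <- 3e-6 / unorm
    ep <- engine$eval(x + h * u, want_pgrad)
    out <- list(hvp = (ep$forces - base$F) / h)
    if (want_pgrad && !is.null(ep$pgrad))
      out$gdir <- -(ep$pgrad - base$pgrad) / h
  }
  out
}

#' Reverse-mode gradient of a trajectory loss via checkpointed replay
#'
#' Re-simulates each checkpoint block from its stored state and seed and
#' walks the BAOAB step backwards, propagating adjoints of coordinates and
#' velocities and accumulating the gradient of the loss with respect to the
#' trainable parameters.  Loss sensitivities enter at the recording steps as
#' gradients with respect to the accumulated distance sums.  Adjoints are
#' clipped to the configured norm at every block boundary of the reverse
#' pass; memory is bounded by one block regardless of trajectory length.
#'
#' @param sim A `sim_result` from [simulate_with_checkpoints()].
#' @param engine The engine used for the forward run.
#' @param dloss List with `d_sum_x` and `d_sum_x2`: gradients of the loss
#'   with respect to the per-pair distance accumulators (see
#'   [loss_accumulator_grad()]).
#' @param clip Apply adjoint clipping (default TRUE).
#' @param use_checkpoints Replay blocks from checkpoints (default); if FALSE
#'   the simulation must have been run with `store_full = TRUE`.
#' @param fd_mode "central" (default) forms the second-order directional
#'   products from two kernel evaluations; "forward" uses one evaluation
#'   against first derivatives stored during the forward pass (requires
#'   `store_derivs = TRUE`), trading O(h) truncation (relative error around
#'   1e-4 per product) for half the cost.
#' @return Gradient vector (length 108) of the loss w.r.t. the parameters.
#' @export
backprop_gradients <- function(sim, engine, dloss, clip = TRUE,
                               use_checkpoints = TRUE,
                               fd_mode = c("central", "forward")) {
  fd_mode <- match.arg(fd_mode)
  if (fd_mode == "forward" && (use_checkpoints || is.null(sim$full_F)))
    stop("fd_mode = \"forward\" requires a simulation run with ",
         "store_full = TRUE and store_derivs = TRUE, and ",
         "use_checkpoints = FALSE", call. = FALSE)
  config <- sim$config
  n <- engine$n
  m <- engine$masses
  dt <- config$dt
  c1 <- exp(-config$gamma * dt)
  cp <- sim$ca_pairs
  a_x <- matrix(0, n, 3); a_v <- matrix(0, n, 3)
  g <- numeric(108L)
  dp_cache <- NULL
  want_pgrad <- isTRUE(engine$has_pgrad)
  L <- config$checkpoint_interval
  nblocks <- config$n_steps %/% L

  inject <- function(a_x, x) {
    d <- ca_distances(x, cp)
    coef <- dloss$d_sum_x + 2 * d * dloss$d_sum_x2
    xi <- x[cp$ca[cp$i], , drop = FALSE]
    xj <- x[cp$ca[cp$j], , drop = FALSE]
    u <- (xi - xj) / d
    gi <- coef * u
    for (p in seq_along(cp$i)) {
      a_x[cp$ca[cp$i[p]], ] <- a_x[cp$ca[cp$i[p]], ] + gi[p, ]
      a_x[cp$ca[cp$j[p]], ] <- a_x[cp$ca[cp$j[p]], ] - gi[p, ]
    }
    a_x
  }

  for (b in rev(seq_len(nblocks))) {
    # replay the block to recover per-step starting coordinates
    if (use_checkpoints) {
      ck <- sim$checkpoints[[b]]
      st <- list(x = ck$x, v = ck$v, F = engine$eval(ck$x)$forces)
      xs <- vector("list", L + 1L)
      single <- config$precision == "single"
      set.seed(ck$seed)
      for (s in seq_len(L)) {
        xs[[s]] <- st$x
        noise <- matrix(stats::rnorm(n * 3), n, 3)
        st <- langevin_step(st, engine, dt, config$gamma,
                            config$temperature, noise)
        if (single) {
          st$x <- cpp_round_float(st$x); st$v <- cpp_round_float(st$v)
          st$F <- engine$eval(st$x)$forces
        }
      }
      xs[[L + 1L]] <- st$x
    } else {
      if (is.null(sim$full_states))
        stop("simulation was not run with store_full = TRUE", call. = FALSE)
      xs <- sim$full_states[((b - 1L) * L + 1L):(b * L + 1L)]
    }
    for (s in rev(seq_len(L))) {
      gs <- (b - 1L) * L + s
      x0 <- xs[[s]]; x2 <- xs[[s + 1L]]
      if (gs %% config$record_interval == 0L && length(cp$i) > 0L)
        a_x <- inject(a_x, x2)
      # reverse B (second half-kick at x2).  In BAOAB the force at a step
      # boundary is shared by the closing kick of one step and the opening
      # kick of the next, and a_v is unchanged between the two reversed
      # kicks unless clipping intervened, so the directional product cached
      # from the previous iteration's opening kick can be reused exactly.
      if (!is.null(dp_cache)) {
        dp <- dp_cache
      } else {
        u <- (0.5 * dt / m) * a_v
        base <- if (fd_mode == "forward")
          list(F = sim$full_F[[gs + 1L]], pgrad = sim$full_pg[[gs + 1L]])
        dp <- directional_products(engine, x2, u, want_pgrad, base)
      }
      if (!is.null(dp)) {
        a_x <- a_x + dp$hvp
        if (!is.null(dp$gdir)) g <- g + dp$gdir
      }
      # reverse A, O, A
      a_v <- a_v + 0.5 * dt * a_x
      a_v <- c1 * a_v
      a_v <- a_v + 0.5 * dt * a_x
      # reverse B (first half-kick at x0)
      u <- (0.5 * dt / m) * a_v
      base <- if (fd_mode == "forward")
        list(F = sim$full_F[[gs]], pgrad = sim$full_pg[[gs]])
      dp <- directional_products(engine, x0, u, want_pgrad, base)
      if (!is.null(dp)) {
        a_x <- a_x + dp$hvp
        if (!is.null(dp$gdir)) g <- g + dp$gdir
      }
      dp_cache <- dp
    }
    if (clip) {
      cl <- clip_adjoints(a_x, a_v, config$clip_threshold)
      a_x <- cl$adjoint_coords; a_v <- cl$adjoint_vels
      dp_cache <- NULL  # clipping changes a_v; cached product invalid
    }
  }
  g
}

#' Steepest-descent energy minimisation with backtracking line search
#'
#' @param engine An engine (or a `mol_system`, converted with defaults).
#' @param max_iter Maximum iterations.
#' @param tolerance Convergence threshold on the maximum force component
#'   (kJ/mol/nm); default 10.
#' @param coords Optional starting coordinates.
#' @return List with `coords`, `energy`, `converged`, `iterations`.
#' @export
minimize <- function(engine, max_iter = 500L, tolerance = 10,
                     coords = NULL) {
  if (inherits(engine, "mol_system")) engine <- system_engine(engine)
  x <- if (is.null(coords)) engine$coords else coords
  ev <- engine$eval(x)
  if (!is.finite(ev$total)) stop("non-finite starting energy", call. = FALSE)
  alpha <- 1e-4
  it <- 0L
  while (it < max_iter) {
    fmax <- max(abs(ev$forces))
    if (fmax < tolerance) break
    dir <- ev$forces / fmax
    accepted <- FALSE
    while (alpha > 1e-12) {
      xn <- x + alpha * dir
      en <- engine$eval(xn)
      if (is.finite(en$total) && en$total <= ev$total) {
        x <- xn; ev <- en; accepted <- TRUE
        alpha <- alpha * 1.2
        break
      }
      alpha <- alpha * 0.5
    }
    if (!accepted) break
    it <- it + 1L
  }
  list(coords = x, energy = ev$total, converged = max(abs(ev$forces)) <
         tolerance, iterations = it)
}
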