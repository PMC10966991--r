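# Distance-distribution statistics and the two-way Gaussian KL training loss.
#
# Per residue pair the simulation records running sums of the Calpha distance
# X and X^2; the per-pair mean mu = E[X] and standard deviation
# sigma = sqrt(E[X^2] - E[X]^2) summarise the distance distribution.  The
# loss compares (mu_s, sigma_s) against reference moments (mu_r, sigma_r)
# with the closed-form KL divergence between 1-D Gaussians in both
# directions, compresses each direction with ln(D + 1), downweights pairs
# close in sequence, and averages over pairs.

#' Finalise distance statistics from running sums
#'
#' @param sum_x,sum_x2 Per-pair running sums of X and X^2 (nm, nm^2).
#' @param frame_count Number of recorded frames (>= 2).
#' @param n_residues Number of residues (pairs are the i < j upper triangle).
#' @param sigma_min Floor applied to sigma (nm); prevents divide-by-zero for
#'   rigid pairs.  Default 1e-3.
#' @return A `distance_stats` object: tibble with columns `i`, `j` (0-based
#'   residue indices), `mu`, `sigma`, plus attributes `n_residues` and
#'   `frame_count`.
#' @export
finalize_statistics <- function(sum_x, sum_x2, frame_count, n_residues,
                                sigma_min = 1e-3) {
  if (frame_count < 2) stop("need at least 2 recorded frames", call. = FALSE)
  mu <- sum_x / frame_count
  v <- pmax(sum_x2 / frame_count - mu^2, 0)
  sigma <- pmax(sqrt(v), sigma_min)
  pr <- utils::combn(n_residues, 2) - 1L
  out <- tibble::tibble(i = pr[1, ], j = pr[2, ], mu = mu, sigma = sigma)
  structure(out, n_residues = as.integer(n_residues),
            frame_count = as.integer(frame_count), sigma_min = sigma_min,
            class = c("distance_stats", class(out)))
}

#' Distance statistics of a finished simulation
#'
#' @param sim A `sim_result`.
#' @param n_residues Number of residues.
#' @param sigma_min Sigma floor (nm).
#' @return A `distance_stats` object.
#' @export
simulation_statistics <- function(sim, n_residues, sigma_min = 1e-3) {
  finalize_statistics(sim$sum_x, sim$sum_x2, sim$frame_count, n_residues,
                      sigma_min)
}

#' Closed-form KL divergence between two 1-D Gaussians
#'
#' `KL(P || Q) = ln(sigma_r / sigma_s) + (sigma_s^2 + (mu_s - mu_r)^2) /
#' (2 sigma_r^2) - 1/2`, non-negative and zero iff the moments coincide.
#'
#' @param mu_s,sigma_s Moments of P (simulation).
#' @param mu_r,sigma_r Moments of Q (reference).
#' @return Divergence (dimensionless); vectorised.
#' @export
gaussian_kl <- function(mu_s, sigma_s, mu_r, sigma_r) {
  if (any(sigma_s <= 0) || any(sigma_r <= 0))
    stop("standard deviations must be positive", call. = FALSE)
  log(sigma_r / sigma_s) + (sigma_s^2 + (mu_s - mu_r)^2) / (2 * sigma_r^2) -
    0.5
}

#' Log-compressed two-way pair loss
#'
#' `L = ln(D_PQ + 1) + ln(D_QP + 1)`; symmetric in its arguments and zero
#' iff both divergences vanish.
#'
#' @param d_pq,d_qp Non-negative KL divergences in the two directions.
#' @return Loss value; vectorised.
#' @export
pair_loss <- function(d_pq, d_qp) log(d_pq + 1) + log(d_qp + 1)

#' Sequence-separation weight
#'
#' 0 at separation 0, 1 at separation >= 10, linear between:
#' `w = min(|i - j|, 10) / 10`.
#'
#' @param i,j Residue indices (any base; only the difference matters).
#' @return Weight in `[0, 1]`; vectorised.
#' @export
separation_weight <- function(i, j) pmin(abs(i - j), 10) / 10

#' Aggregate training loss over all residue pairs
#'
#' Mean over unordered pairs i < j of the separation-weighted two-way pair
#' loss.  By default the mean divides by the number of all pairs including
#' zero-weight ones; set `include_zero_weight = FALSE` to average over
#' positive-weight pairs only.
#'
#' @param sim A `distance_stats` from the simulation.
#' @param ref A `distance_stats` (same shape) holding reference moments.
#' @param include_zero_weight Include zero-weight pairs in the denominator.
#' @return Scalar loss.
#' @export
aggregate_loss <- function(sim, ref, include_zero_weight = TRUE) {
  check_stats_match(sim, ref)
  w <- separation_weight(sim$i, sim$j)
  L <- pair_loss(gaussian_kl(sim$mu, sim$sigma, ref$mu, ref$sigma),
                 gaussian_kl(ref$mu, ref$sigma, sim$mu, sim$sigma))
  denom <- if (include_zero_weight) length(w) else sum(w > 0)
  if (denom == 0) return(0)
  sum(w * L) / denom
}

check_stats_match <- function(sim, ref) {
  if (nrow(sim) != nrow(ref) ||
      !identical(as.integer(sim$i), as.integer(ref$i)) ||
      !identical(as.integer(sim$j), as.integer(ref$j)))
    stop("simulation and reference statistics have mismatched shapes",
         call. = FALSE)
  invisible(TRUE)
}

#' Gradient of the aggregate loss w.r.t. the distance accumulators
#'
#' Differentiates the loss through the moment computation back to the
#' per-pair running sums `sum_x`, `sum_x2`, which is where the reverse pass
#' through the integrator picks it up.  Pairs whose sigma sits on the floor
#' (rigid pairs) receive zero gradient through sigma.
#'
#' @param sim Simulation `distance_stats`.
#' @param ref Reference `distance_stats`.
#' @param include_zero_weight As in [aggregate_loss()].
#' @return List with `d_sum_x` and `d_sum_x2` (per pair).
#' @export
loss_accumulator_grad <- function(sim, ref, include_zero_weight = TRUE) {
  check_stats_match(sim, ref)
  nf <- attr(sim, "frame_count")
  sigma_min <- attr(sim, "sigma_min")
  w <- separation_weight(sim$i, sim$j)
  denom <- if (include_zero_weight) length(w) else sum(w > 0)
  mu_s <- sim$mu; sg_s <- sim$sigma; mu_r <- ref$mu; sg_r <- ref$sigma
  d_pq <- gaussian_kl(mu_s, sg_s, mu_r, sg_r)
  d_qp <- gaussian_kl(mu_r, sg_r, mu_s, sg_s)
  dL_dpq <- 1 / (d_pq + 1)
  dL_dqp <- 1 / (d_qp + 1)
  # partials of the two divergences w.r.t. the simulation moments
  dpq_dmu <- (mu_s - mu_r) / sg_r^2
  dpq_dsg <- -1 / sg_s + sg_s / sg_r^2
  dqp_dmu <- (mu_s - mu_r) / sg_s^2
  dqp_dsg <- 1 / sg_s - (sg_r^2 + (mu_s - mu_r)^2) / sg_s^3
  dmu <- (w / denom) * (dL_dpq * dpq_dmu + dL_dqp * dqp_dmu)
  dsg <- (w / denom) * (dL_dpq * dpq_dsg + dL_dqp * dqp_dsg)
  floored <- sg_s <= sigma_min
  dsg[floored] <- 0
  # chain to the running sums: mu = Sx/n, sigma = sqrt(Sx2/n - mu^2)
  d_sum_x <- dmu / nf + dsg * (-mu_s / (sg_s * nf))
  d_sum_x2 <- dsg / (2 * sg_s * nf)
  list(d_sum_x = d_sum_x, d_sum_x2 = d_sum_x2)
}

#' Read / write reference distance statistics as TSV
#'
#' Columns `i`, `j`, `mu_nm`, `sigma_nm` with a version header line.
#'
#' @param stats A `distance_stats`.
#' @param path File path.
#' @return `write_reference_stats` returns the path invisibly;
#'   `read_reference_stats` returns a `distance_stats`.
#' @export
write_reference_stats <- function(stats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gbdms reference statistics v1 n_residues=%d frames=%d",
                     attr(stats, "n_residues"), attr(stats, "frame_count")),
             con)
  writeLines("i\tj\tmu_nm\tsigma_nm", con)
  writeLines(sprintf("%d\t%d\t%.10g\t%.10g", stats$i, stats$j, stats$mu,
                     stats$sigma), con)
  invisible(path)
}

#' @rdname write_reference_stats
#' @export
read_reference_stats <- function(path) {
  hdr <- readLines(path, n = 1L)
  nres <- as.integer(sub(".*n_residues=(\\d+).*", "\\1", hdr))
  nfr <- as.integer(sub(".*frames=(\\d+).*", "\\1", hdr))
  d <- utils::read.delim(path, skip = 1L)
  out <- tibble::tibble(i = as.integer(d$i), j = as.integer(d$j),
                        mu = d$mu_nm, sigma = d$sigma_nm)
  structure(out, n_residues = nres, frame_count = nfr, sigma_min = 1e-3,
            class = c("distance_stats", class(out)))
}

#' Loss and parameter gradient for one protein simulation
#'
#' Convenience wrapper: forward simulation with checkpointing, loss against
#' reference statistics, reverse pass for the parameter gradient.
#'
#' @param engine An engine built from the protein system.
#' @param ref Reference `distance_stats`.
#' @param config A `sim_config`.
#' @param include_zero_weight As in [aggregate_loss()].
#' @param mode "checkpoint" (default) keeps memory bounded by one block and
#'   replays blocks exactly; "full" stores per-step coordinates and first
#'   derivatives during the forward pass and runs the cheaper one-sided
#'   reverse pass (see [backprop_gradients()]).
#' @return List with `loss`, `gradient` (length 108), `stats`, `sim`.
#' @export
loss_gradient <- function(engine, ref, config, include_zero_weight = TRUE,
                          mode = c("checkpoint", "full")) {
  mode <- match.arg(mode)
  full <- mode == "full"
  sim <- simulate_with_checkpoints(engine, config, store_full = full,
                                   store_derivs = full)
  stats <- simulation_statistics(sim, attr(ref, "n_residues"))
  lv <- aggregate_loss(stats, ref, include_zero_weight)
  dl <- loss_accumulator_grad(stats, ref, include_zero_weight)
  grad <- backprop_gradients(sim, engine, dl, use_checkpoints = !full,
                             fd_mode = if (full) "forward" else "central")
  sim$full_states <- sim$full_F <- sim$full_pg <- NULL
  list(loss = lv, gradient = grad, stats = stats, sim = sim)
}
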