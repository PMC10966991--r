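# The epoch loop: combining per-protein stochastic gradients, median
# normalisation, class weighting, capped gradient-descent updates and run
# selection.

#' Training configuration
#'
#' @param learning_rate Gradient-descent learning rate; default 4e-4.
#' @param per_protein_cap Maximum absolute change of a parameter from one
#'   protein in one epoch, as a fraction of its epoch-start magnitude;
#'   default 0.005 (0.5 percent).
#' @param per_epoch_cap Maximum combined absolute change per epoch; default
#'   0.03 (3 percent).
#' @param class_weight Down-weighting applied to LJ sigma entries and to
#'   entries of hydrogen atom types; default 0.02.
#' @param n_epochs Number of epochs; default 5.
#' @param idp_repeats Repeats per disordered protein; default 2.
#' @param include_zero_weight Passed through to [aggregate_loss()].
#' @param normalize_before_weighting Apply median normalisation before the
#'   class weighting (default TRUE).
#' @return A `train_config` list.
#' @export
training_config <- function(learning_rate = 4e-4, per_protein_cap = 0.005,
                            per_epoch_cap = 0.03, class_weight = 0.02,
                            n_epochs = 5L, idp_repeats = 2L,
                            include_zero_weight = TRUE,
                            normalize_before_weighting = TRUE) {
  stopifnot(learning_rate > 0, per_protein_cap > 0, per_protein_cap < 1,
            per_epoch_cap > 0, per_epoch_cap < 1)
  structure(list(learning_rate = learning_rate,
                 per_protein_cap = per_protein_cap,
                 per_epoch_cap = per_epoch_cap, class_weight = class_weight,
                 n_epochs = as.integer(n_epochs),
                 idp_repeats = as.integer(idp_repeats),
                 include_zero_weight = include_zero_weight,
                 normalize_before_weighting = normalize_before_weighting),
            class = "train_config")
}

#' Average gradients over the repeats of one protein
#'
#' @param bundles List of gradient bundles (each with `protein_id`,
#'   `gradient`, `loss`).
#' @return Elementwise mean gradient (length 108).
#' @export
combine_repeat_gradients <- function(bundles) {
  stopifnot(length(bundles) >= 1)
  ids <- unique(vapply(bundles, function(b) b$protein_id, ""))
  if (length(ids) != 1)
    stop("bundles mix protein ids: ", paste(ids, collapse = ", "),
         call. = FALSE)
  gs <- vapply(bundles, function(b) b$gradient,
               numeric(length(bundles[[1]]$gradient)))
  rowMeans(as.matrix(gs))
}

#' Divide a gradient by the median of its absolute entries
#'
#' Makes every protein contribute similarly to the update regardless of
#' gradient scale; the median resists outliers.  If the median is zero the
#' gradient is returned unchanged with a warning.
#'
#' @param gradient Numeric vector.
#' @return Normalised gradient.
#' @export
median_normalize <- function(gradient) {
  med <- stats::median(abs(gradient))
  if (med == 0) {
    warning("median of absolute gradients is zero; skipping normalisation")
    return(gradient)
  }
  gradient / med
}

#' Down-weight LJ sigma and hydrogen-type gradient entries
#'
#' Entries labelled `lj_sigma`, and entries belonging to atom types whose
#' name begins with H, are multiplied by the class weight (default 0.02);
#' their gradients are large relative to other parameters and unchecked
#' changes destabilise simulations.
#'
#' @param gradient Numeric vector aligned with the parameter vector.
#' @param labels Category labels per entry (from `attr(params, "labels")`).
#' @param hydrogen_flags Logical per entry (from `attr(params, "hydrogen")`).
#' @param weight Multiplier; default 0.02.
#' @return Weighted gradient.
#' @export
apply_class_weights <- function(gradient, labels, hydrogen_flags,
                                weight = 0.02) {
  sel <- labels == "lj_sigma" | hydrogen_flags
  gradient[sel] <- gradient[sel] * weight
  gradient
}

#' Capped gradient-descent update
#'
#' Each protein's proposed change `-lr * g` is clamped elementwise to
#' `+/- per_protein_cap` of the parameter's epoch-start magnitude; the summed
#' change is then clamped to `+/- per_epoch_cap` of the same base.  A
#' parameter whose epoch-start value is exactly zero falls back to an
#' absolute cap equal to the cap fraction in native units.
#'
#' @param params `param_vector` at the start of the epoch.
#' @param gradients List of processed (normalised, weighted) per-protein
#'   gradients.
#' @param config A `train_config`.
#' @return Updated `param_vector`.
#' @export
cap_and_update <- function(params, gradients, config) {
  base <- abs(as.numeric(params))
  base[base == 0] <- 1  # absolute fallback cap for zero-valued parameters
  cap1 <- config$per_protein_cap * base
  cap2 <- config$per_epoch_cap * base
  total <- numeric(length(params))
  for (g in gradients) {
    ch <- -config$learning_rate * g
    total <- total + pmin(pmax(ch, -cap1), cap1)
  }
  total <- pmin(pmax(total, -cap2), cap2)
  out <- params
  out[] <- as.numeric(params) + total
  out
}

#' Run one training epoch
#'
#' Simulates every protein (with repeats for disordered ones), computes the
#' distance-distribution loss and its parameter gradient by checkpointed
#' reverse-mode, averages repeats, median-normalises and class-weights each
#' protein's gradient, and applies the capped update.
#'
#' @param proteins List of protein entries, each a list with `id`, `system`
#'   (a `mol_system`), `ref` (reference `distance_stats`), `idp` (logical)
#'   and optionally `coords`.
#' @param params `param_vector` at the start of the epoch.
#' @param sim_config A `sim_config` template (its seed is combined with the
#'   epoch seed).
#' @param config A `train_config`.
#' @param seed Epoch seed.
#' @return List with `params` (updated), `report` (tibble: protein, repeat,
#'   loss, gradient norm) and `gradients` (processed per-protein gradients).
#' @export
run_epoch <- function(proteins, params, sim_config, config = training_config(),
                      seed = 1L) {
  labels <- attr(params, "labels")
  hyd <- attr(params, "hydrogen")
  processed <- list()
  rows <- list()
  for (pi in seq_along(proteins)) {
    pr <- proteins[[pi]]
    nrep <- if (isTRUE(pr$idp)) config$idp_repeats else 1L
    bundles <- vector("list", nrep)
    for (rep_i in seq_len(nrep)) {
      cfg <- sim_config
      cfg$seed <- block_seed(seed, pi * 131L + rep_i)
      eng <- system_engine(pr$system, params, kappa = cfg$kappa)
      if (!is.null(pr$coords)) eng$coords <- pr$coords
      lg <- loss_gradient(eng, pr$ref, cfg, config$include_zero_weight)
      bundles[[rep_i]] <- list(protein_id = pr$id, repeat_id = rep_i,
                               gradient = lg$gradient, loss = lg$loss,
                               seed = cfg$seed)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein = pr$id, rep = rep_i, loss = lg$loss,
        grad_norm = sqrt(sum(lg$gradient^2)), seed = cfg$seed)
    }
    g <- combine_repeat_gradients(bundles)
    if (config$normalize_before_weighting) {
      g <- median_normalize(g)
      g <- apply_class_weights(g, labels, hyd, config$class_weight)
    } else {
      g <- apply_class_weights(g, labels, hyd, config$class_weight)
      g <- median_normalize(g)
    }
    processed[[pr$id]] <- g
  }
  new_params <- cap_and_update(params, processed, config)
  list(params = new_params, report = do.call(rbind, rows),
       gradients = processed)
}

#' Multi-epoch training run
#'
#' @inheritParams run_epoch
#' @param run_id Identifier stored in the result.
#' @return A `train_run` list: `params` (final), `history` (list of epoch
#'   outputs), `epoch_params` (parameter vector after each epoch),
#'   `mean_loss` (per epoch), `run_id`.
#' @export
train_forcefield <- function(proteins, params, sim_config,
                             config = training_config(), seed = 1L,
                             run_id = 1L) {
  history <- list()
  epoch_params <- list()
  mean_loss <- numeric(config$n_epochs)
  for (ep in seq_len(config$n_epochs)) {
    out <- run_epoch(proteins, params, sim_config, config,
                     seed = block_seed(seed, ep * 7L))
    params <- out$params
    history[[ep]] <- out
    epoch_params[[ep]] <- params
    mean_loss[ep] <- mean(out$report$loss)
  }
  structure(list(params = params, history = history,
                 epoch_params = epoch_params, mean_loss = mean_loss,
                 run_id = run_id),
            class = "train_run")
}

#' Select the best of several training runs
#'
#' The run with the lowest mean training loss at its final epoch wins; ties
#' break to the lowest run index.
#'
#' @param runs List of `train_run` objects.
#' @return The chosen `train_run`.
#' @export
select_best_run <- function(runs) {
  stopifnot(length(runs) >= 1)
  finals <- vapply(runs, function(r) r$mean_loss[length(r$mean_loss)], 0)
  runs[[which.min(finals)]]
}

#' Tidy summary of a training run
#'
#' @param x A `train_run`.
#' @param ... Unused.
#' @return Tibble with one row per protein per repeat per epoch.
#' @exportS3Method generics::tidy
tidy.train_run <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$history), function(ep) {
    cbind(tibble::tibble(epoch = ep), x$history[[ep]]$report)
  }))
}

#' One-line summary of a training run
#'
#' @param x A `train_run`.
#' @param ... Unused.
#' @return Tibble with final mean loss and epoch count.
#' @exportS3Method generics::glance
glance.train_run <- function(x, ...) {
  tibble::tibble(run_id = x$run_id, n_epochs = length(x$mean_loss),
                 final_mean_loss = x$mean_loss[length(x$mean_loss)],
                 best_mean_loss = min(x$mean_loss))
}
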