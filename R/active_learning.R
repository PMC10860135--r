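# Query-by-committee active learning over a candidate CSP landscape:
# candidate filtering by an energy window, seeded initial selection (random
# or FPS), batchwise retraining with three query strategies, stopping rules,
# and a fully logged, reproducible state.

#' Active-learning configuration
#'
#' Defaults follow the settings found to balance accuracy and cost for
#' landscape correction: delta-learning with a 6-member committee, an
#' uncertainty threshold of 1.0 kJ/mol, batches of 30 and a 5% uncertain-
#' candidate target.
#'
#' @param sigma_threshold uncertainty threshold in kJ/mol per molecule (> 0).
#' @param batch_size structures added per retraining round.
#' @param pct_uncertain_target stop once fewer than this percentage of the
#'   remaining candidates is above the threshold (0 < pct <= 100).
#' @param max_training_size optional hard cap on the training-set size.
#' @param strategy `"highest_uncertainty"` (default), `"random"`, or
#'   `"highest_uncertainty_fps"`.
#' @param seed_mode initial-batch selection: `"random"` or `"fps"`.
#' @param committee_size members during active learning (default 6).
#' @param final_committee_size optional larger committee retrained on the
#'   final selected set (e.g. 18); default: same as `committee_size`.
#' @param energy_window optional window (kJ/mol above the baseline global
#'   minimum) restricting the candidate pool.
#' @param mode `"delta"` (learn target - baseline) or `"total"`.
#' @param descriptor_k symmetry functions kept per element by CUR.
#' @param hidden hidden-layer widths of the atomic subnets.
#' @param master_seed seed from which all randomness flows.
#' @param chunk_iters,max_chunks optimizer schedule forwarded to [cnnp()].
#' @return list of class `al_config`.
#' @export
al_config <- function(sigma_threshold = 1.0, batch_size = 30,
                      pct_uncertain_target = 5.0, max_training_size = NULL,
                      strategy = c("highest_uncertainty", "random",
                                   "highest_uncertainty_fps"),
                      seed_mode = c("random", "fps"),
                      committee_size = 6, final_committee_size = NULL,
                      energy_window = NULL, mode = c("delta", "total"),
                      descriptor_k = 64, hidden = c(16, 16), master_seed = 1,
                      chunk_iters = 150, max_chunks = 6) {
  stopifnot(sigma_threshold > 0, batch_size >= 1,
            pct_uncertain_target > 0, pct_uncertain_target <= 100)
  structure(list(sigma_threshold = sigma_threshold, batch_size = batch_size,
                 pct_uncertain_target = pct_uncertain_target,
                 max_training_size = max_training_size,
                 strategy = match.arg(strategy),
                 seed_mode = match.arg(seed_mode),
                 committee_size = committee_size,
                 final_committee_size = final_committee_size %||% committee_size,
                 energy_window = energy_window, mode = match.arg(mode),
                 descriptor_k = descriptor_k, hidden = hidden,
                 master_seed = as.integer(master_seed),
                 chunk_iters = chunk_iters, max_chunks = max_chunks),
            class = "al_config")
}

#' Filter landscape candidates by an energy window
#'
#' Keeps entries with `e_baseline <= min(e_baseline) + window`, the usual way
#' of focusing a potential on the low-energy region of a landscape. A missing
#' window keeps everything.
#'
#' @param x a `landscape`.
#' @param energy_window window in kJ/mol per molecule, or `NULL`.
#' @return character vector of retained ids.
#' @export
filter_candidates <- function(x, energy_window = NULL) {
  stopifnot(inherits(x, "landscape"))
  if (length(x) == 0) stop("empty landscape")
  if (is.null(energy_window)) return(x$ids)
  x$ids[x$e_baseline <= min(x$e_baseline) + energy_window]
}

#' Select the initial training batch
#'
#' @param candidate_ids candidate ids.
#' @param k batch size.
#' @param mode `"random"` (seeded uniform without replacement) or `"fps"`
#'   (farthest point sampling on the supplied structure descriptors, first
#'   point seeded random).
#' @param seed RNG seed.
#' @param descriptors matrix of structure descriptors (rows aligned with
#'   `candidate_ids`); required for fps.
#' @return selected ids.
#' @export
seed_initial <- function(candidate_ids, k, mode = c("random", "fps"), seed = 1,
                         descriptors = NULL) {
  mode <- match.arg(mode)
  stopifnot(k <= length(candidate_ids))
  if (mode == "random") {
    idx <- with_local_seed(seed, sample.int(length(candidate_ids), k))
  } else {
    if (is.null(descriptors)) stop("fps seeding needs structure descriptors")
    idx <- farthest_point_sample(descriptors, k, start = "random", seed = seed)
  }
  candidate_ids[idx]
}

#' Select a batch of high-uncertainty candidates
#'
#' Only candidates at or above the uncertainty threshold are ever returned.
#' `highest_uncertainty` sorts descending by sigma (ties by id);
#' `highest_uncertainty_fps` runs farthest point sampling restricted to
#' above-threshold candidates, seeded at the most uncertain one; `random`
#' preserves the supplied (shuffled) evaluation order.
#'
#' @param strategy query strategy.
#' @param preds data.frame with columns `id` and `sigma` for every remaining
#'   candidate, in evaluation order for the random strategy.
#' @param config an `al_config`.
#' @param descriptors structure-descriptor matrix aligned with `preds` rows
#'   (needed for the fps strategy).
#' @return ids (possibly fewer than `batch_size`, possibly none).
#' @export
select_batch <- function(strategy, preds, config, descriptors = NULL) {
  above <- which(preds$sigma >= config$sigma_threshold)
  if (!length(above)) return(character(0))
  k <- min(config$batch_size, length(above))
  if (strategy == "highest_uncertainty") {
    ord <- above[order(-preds$sigma[above], preds$id[above])]
    preds$id[ord[seq_len(k)]]
  } else if (strategy == "highest_uncertainty_fps") {
    if (is.null(descriptors)) stop("fps strategy needs descriptors")
    sub <- descriptors[above, , drop = FALSE]
    smax <- order(-preds$sigma[above], preds$id[above])[1]
    sel <- farthest_point_sample(sub, k, start = smax)
    preds$id[above[sel]]
  } else if (strategy == "random") {
    preds$id[above[seq_len(k)]]
  } else stop("unknown strategy: ", strategy)
}

label_for_mode <- function(oracle, structure, e_baseline, mode) {
  e_t <- oracle_eval(oracle, structure)
  if (mode == "delta") e_t - e_baseline else e_t
}

#' Run query-by-committee active learning on a landscape
#'
#' Iterates: train the committee on the current training set, predict all
#' remaining candidates, record the fraction above the uncertainty threshold,
#' stop when that fraction drops below the target (or the pool is exhausted,
#' or the training set hits its cap), otherwise select a batch, label it with
#' the oracle and retrain. The final committee (optionally larger) is
#' retrained on the identical selected set. Fully reproducible from
#' `config$master_seed`.
#'
#' @param x a `landscape` with baseline energies.
#' @param oracle an `energy_oracle` providing target energies on demand.
#' @param config an `al_config`.
#' @param params optional `acsf_params`; defaults to a deterministic pool
#'   with CUR selection on the candidate set.
#' @param holdout optional list(`structures`, `labels`) evaluated after every
#'   retrain (labels on the mode's scale).
#' @return list of class `al_result`: `model` (final `cnnp`), `state`
#'   (`al_state` with per-iteration records), `params`.
#' @export
run_active_learning <- function(x, oracle, config = al_config(), params = NULL,
                                holdout = NULL) {
  stopifnot(inherits(x, "landscape"), inherits(config, "al_config"))
  cand_ids <- filter_candidates(x, config$energy_window)
  excluded <- setdiff(x$ids, cand_ids)
  pos <- match(cand_ids, x$ids)
  structures <- x$structures[pos]
  e_base <- stats::setNames(x$e_baseline[pos], cand_ids)

  elements <- sort(unique(unlist(lapply(structures, function(s) s$species))))
  if (is.null(params)) {
    params <- acsf_param_pool(elements)
    params <- select_descriptors(structures, params, k = config$descriptor_k)
  }
  feats <- lapply(structures, compute_acsf, params = params)
  names(feats) <- cand_ids
  sdesc <- structure_descriptor_matrix(structures, params)
  sdesc <- scale(sdesc)
  sdesc[!is.finite(sdesc)] <- 0
  rownames(sdesc) <- cand_ids

  labels <- stats::setNames(rep(NA_real_, length(cand_ids)), cand_ids)
  oracle_log <- list()
  failed <- character(0)
  get_label <- function(id) {
    if (!is.na(labels[[id]])) return(labels[[id]])
    val <- tryCatch(label_for_mode(oracle, x$structures[[match(id, x$ids)]],
                                   e_base[[id]], config$mode),
                    error = function(e) NA_real_)
    oracle_log[[length(oracle_log) + 1]] <<- list(id = id, value = val)
    labels[id] <<- val
    val
  }

  seed_ids <- seed_initial(cand_ids, min(config$batch_size, length(cand_ids)),
                           config$seed_mode,
                           seed = substream_seed(config$master_seed, "seed"),
                           descriptors = sdesc)
  training <- character(0)
  for (id in seed_ids) {
    if (is.na(get_label(id))) failed <- c(failed, id) else training <- c(training, id)
  }
  remaining <- setdiff(cand_ids, c(training, failed))
  queue <- if (config$strategy == "random") {
    with_local_seed(substream_seed(config$master_seed, "queue"),
                    sample(remaining))
  } else NULL

  history <- list()
  iter <- 0L
  model <- NULL
  stop_reason <- NULL
  repeat {
    iter <- iter + 1L
    model <- cnnp(x$structures[match(training, x$ids)], labels[training],
                  descriptor = params, mode = config$mode,
                  n_members = config$committee_size, hidden = config$hidden,
                  seed = substream_seed(config$master_seed, "train", iter),
                  features = feats[training],
                  chunk_iters = config$chunk_iters,
                  max_chunks = config$max_chunks)
    rem_ids <- if (is.null(queue)) remaining else queue
    preds <- if (length(rem_ids)) {
      p <- predict(model, x$structures[match(rem_ids, x$ids)],
                   features = feats[rem_ids])
      data.frame(id = rem_ids, mean = p$mean, sigma = p$sigma,
                 stringsAsFactors = FALSE)
    } else data.frame(id = character(0), mean = numeric(0), sigma = numeric(0))
    pct_above <- if (nrow(preds)) 100 * mean(preds$sigma >= config$sigma_threshold) else 0
    rec <- list(iteration = iter, n_training = length(training),
                pct_above = pct_above, ids_added = character(0),
                sigma_at_selection = numeric(0))
    if (!is.null(holdout)) {
      hp <- predict(model, holdout$structures)
      rec$holdout_mae <- mean(abs(hp$mean - holdout$labels))
      rec$holdout_rmse <- sqrt(mean((hp$mean - holdout$labels)^2))
    }
    if (!nrow(preds)) stop_reason <- "pool_exhausted"
    else if (pct_above < config$pct_uncertain_target) stop_reason <- "pct_target"
    else if (!is.null(config$max_training_size) &&
             length(training) >= config$max_training_size) stop_reason <- "max_size"
    if (!is.null(stop_reason)) { history[[iter]] <- rec; break }

    batch <- select_batch(config$strategy, preds, config,
                          descriptors = sdesc[preds$id, , drop = FALSE])
    if (!is.null(config$max_training_size))
      batch <- utils::head(batch,
                           max(0, config$max_training_size - length(training)))
    if (!length(batch)) { stop_reason <- "no_uncertain"; history[[iter]] <- rec; break }
    rec$ids_added <- batch
    rec$sigma_at_selection <- preds$sigma[match(batch, preds$id)]
    ok <- character(0)
    for (id in batch) {
      if (is.na(get_label(id))) failed <- c(failed, id) else ok <- c(ok, id)
    }
    training <- c(training, ok)
    if (config$strategy == "random") {
      # each candidate is evaluated once: everything scanned up to the last
      # selected candidate leaves the queue
      last <- max(match(batch, queue))
      below <- setdiff(queue[seq_len(last)], batch)
      queue <- queue[-seq_len(last)]
      remaining <- setdiff(remaining, c(batch, below, failed))
    } else {
      remaining <- setdiff(remaining, c(batch, failed))
    }
    history[[iter]] <- rec
  }

  final <- cnnp(x$structures[match(training, x$ids)], labels[training],
                descriptor = params, mode = config$mode,
                n_members = config$final_committee_size, hidden = config$hidden,
                seed = substream_seed(config$master_seed, "final"),
                features = feats[training],
                chunk_iters = config$chunk_iters,
                max_chunks = config$max_chunks)
  state <- structure(list(training_ids = training,
                          remaining_ids = setdiff(cand_ids, c(training, failed)),
                          excluded_ids = c(excluded, failed),
                          failed_ids = failed,
                          seed_ids = intersect(seed_ids, training),
                          history = history, stop_reason = stop_reason,
                          config = config, oracle_log = oracle_log),
                     class = "al_state")
  structure(list(model = final, state = state, params = params),
            class = "al_result")
}

#' @export
print.al_state <- function(x, ...) {
  cat(sprintf("<al_state> %d iterations, %d training / %d remaining / %d excluded; stop: %s\n",
              length(x$history), length(x$training_ids),
              length(x$remaining_ids), length(x$excluded_ids), x$stop_reason))
  invisible(x)
}

#' @export
print.al_result <- function(x, ...) {
  print(x$state)
  print(x$model)
  invisible(x)
}

#' Audit an active-learning state
#'
#' Verifies the selection invariants from the logged history: every structure
#' added after seeding had sigma at or above the threshold at its selection
#' time, and on normal convergence the final fraction of uncertain remaining
#' candidates is below the target.
#'
#' @param state an `al_state`.
#' @return list with `ok` and the individual checks.
#' @export
audit_al_state <- function(state) {
  cfg <- state$config
  sig <- unlist(lapply(state$history, `[[`, "sigma_at_selection"))
  membership_ok <- all(sig >= cfg$sigma_threshold)
  added <- unlist(lapply(state$history, `[[`, "ids_added"))
  coverage_ok <- setequal(setdiff(state$training_ids, state$seed_ids),
                          intersect(added, state$training_ids))
  last <- state$history[[length(state$history)]]
  stop_ok <- if (identical(state$stop_reason, "pct_target"))
    last$pct_above < cfg$pct_uncertain_target else TRUE
  list(ok = membership_ok && coverage_ok && stop_ok,
       membership_ok = membership_ok, coverage_ok = coverage_ok,
       stop_ok = stop_ok)
}

#' Rerank a landscape with a trained committee
#'
#' Predicts every entry (baseline-corrected in delta mode), flags entries
#' whose committee uncertainty exceeds `flag_threshold` (default 6 kJ/mol),
#' and — when an oracle is supplied — evaluates flagged entries directly with
#' it, the standard treatment of the few structures the model cannot be
#' trusted on.
#'
#' @param model a `cnnp`.
#' @param x a `landscape`.
#' @param oracle optional `energy_oracle` for direct evaluation of flagged
#'   entries.
#' @param flag_threshold high-uncertainty flag level, kJ/mol per molecule.
#' @return data.frame (class `reranked_landscape`) with id, e_baseline,
#'   density, mean, sigma, flag_high_uncertainty, e_direct.
#' @export
rerank_landscape <- function(model, x, oracle = NULL, flag_threshold = 6) {
  stopifnot(inherits(model, "cnnp"), inherits(x, "landscape"))
  p <- predict(model, x$structures)
  mean_e <- if (model$mode == "delta") x$e_baseline + p$mean else p$mean
  flag <- p$sigma > flag_threshold
  e_direct <- rep(NA_real_, length(x))
  if (!is.null(oracle) && any(flag))
    e_direct[flag] <- vapply(x$structures[flag],
                             function(s) oracle_eval(oracle, s), 0)
  out <- data.frame(id = x$ids, e_baseline = x$e_baseline,
                    density = x$density, mean = mean_e, sigma = p$sigma,
                    flag_high_uncertainty = flag, e_direct = e_direct,
                    stringsAsFactors = FALSE)
  class(out) <- c("reranked_landscape", "data.frame")
  out
}

#' Landscape scatter plot (energy vs density with uncertainty bars)
#' @param x a `reranked_landscape`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.reranked_landscape <- function(x, ...) {
  rel <- x$mean - min(x$mean)
  graphics::plot(x$density, rel, pch = 16, cex = 0.6,
                 xlab = "density (g/cm^3)",
                 ylab = "relative energy (kJ/mol per molecule)", ...)
  # bars shorter than ~0.2% of the energy range render as zero-length
  bar <- x$sigma > 0.002 * max(diff(range(rel)), 1e-6)
  if (any(bar))
    graphics::arrows(x$density[bar], rel[bar] - x$sigma[bar],
                     x$density[bar], rel[bar] + x$sigma[bar],
                     length = 0.02, angle = 90, code = 3, col = "grey60")
  if (any(x$flag_high_uncertainty))
    graphics::points(x$density[x$flag_high_uncertainty],
                     rel[x$flag_high_uncertainty], col = "orange", pch = 1, cex = 1.2)
  invisible(x)
}
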