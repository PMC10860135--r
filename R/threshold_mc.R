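# Threshold Monte Carlo for rigid-molecule crystals: energy-lid acceptance,
# a rigid-body + cell moveset, a downhill variant, and optional on-the-fly
# committee training triggered by high uncertainty.

#' Monte Carlo configuration
#'
#' @param lid_offset energy lid above the starting energy, kJ/mol per
#'   molecule (fixed for the whole run).
#' @param max_steps proposals per trajectory.
#' @param max_rot maximum molecular rotation, radians.
#' @param max_trans maximum molecular translation, Angstrom.
#' @param max_cell_len maximum cell-length change, Angstrom.
#' @param max_cell_ang maximum cell-angle change, degrees.
#' @param vol_range isotropic volume-scale range per move.
#' @param mode `"threshold"` (accept iff below the lid) or `"downhill"`
#'   (accept iff the energy decreases).
#' @param otf enable on-the-fly training.
#' @param sigma_otf uncertainty trigger for oracle evaluation + training
#'   (kJ/mol per molecule).
#' @param sigma_terminate with `otf = FALSE`, abort the trajectory when the
#'   committee uncertainty exceeds this level; must exceed `sigma_otf`.
#' @param retrain_every retrain the committee after this many added
#'   structures (warm start).
#' @param hardcore proposals creating intermolecular contacts below this
#'   distance (Angstrom) are auto-rejected.
#' @param master_seed seed for the proposal stream.
#' @return list of class `mc_config`.
#' @export
mc_config <- function(lid_offset = 20, max_steps = 1000, max_rot = 0.3,
                      max_trans = 0.3, max_cell_len = 0.3, max_cell_ang = 3,
                      vol_range = c(0.97, 1.03),
                      mode = c("threshold", "downhill"), otf = FALSE,
                      sigma_otf = 2.0, sigma_terminate = 50.0,
                      retrain_every = 5, hardcore = 0.7, master_seed = 1) {
  stopifnot(max_rot > 0, max_trans > 0, max_cell_len > 0, max_cell_ang > 0,
            vol_range[1] > 0, vol_range[2] > vol_range[1])
  if (otf == FALSE && sigma_terminate <= sigma_otf)
    stop("sigma_terminate must exceed sigma_otf")
  structure(list(lid_offset = lid_offset, max_steps = max_steps,
                 max_rot = max_rot, max_trans = max_trans,
                 max_cell_len = max_cell_len, max_cell_ang = max_cell_ang,
                 vol_range = vol_range, mode = match.arg(mode), otf = otf,
                 sigma_otf = sigma_otf, sigma_terminate = sigma_terminate,
                 retrain_every = retrain_every, hardcore = hardcore,
                 master_seed = as.integer(master_seed)),
            class = "mc_config")
}

MOVE_TYPES <- c("rotate", "translate", "cell_length", "cell_angle", "volume")

# decompose a structure into rigid-body degrees of freedom: cell parameters,
# per-molecule fractional centroid and rigid Cartesian offsets (molecules
# unwrapped by minimum image from their first atom)
mc_state_from_structure <- function(s) {
  latt <- s$lattice
  linv <- solve(latt)
  z <- max(s$mol)
  mols <- vector("list", z)
  for (m in seq_len(z)) {
    idx <- which(s$mol == m)
    f <- s$frac[idx, , drop = FALSE]
    df <- sweep(f, 2, f[1, ])
    df <- df - round(df)                        # unwrap around the anchor atom
    cart <- sweep(df, 2, f[1, ], "+") %*% latt
    cen <- colMeans(cart)
    mols[[m]] <- list(idx = idx, offsets = sweep(cart, 2, cen),
                      centroid_frac = drop(cen %*% linv))
  }
  list(cellp = unname(cell_params(latt)), mols = mols,
       species = s$species, mol = s$mol, id = s$id, n = length(s$species))
}

structure_from_mc_state <- function(st) {
  latt <- lattice_matrix(st$cellp[1], st$cellp[2], st$cellp[3],
                         st$cellp[4], st$cellp[5], st$cellp[6])
  linv <- solve(latt)
  frac <- matrix(0, st$n, 3)
  for (mo in st$mols) {
    cart <- sweep(mo$offsets, 2, drop(mo$centroid_frac %*% latt), "+")
    frac[mo$idx, ] <- cart %*% linv
  }
  xtal(latt, st$species, frac, st$mol, id = st$id, check_overlap = FALSE)
}

#' Propose one rigid-molecule Monte Carlo move
#'
#' One move type is drawn uniformly from: rotate one molecule about its
#' centroid, translate one molecule, perturb one cell length, perturb one
#' cell angle, isotropically scale the volume. Rigid-body moves preserve
#' intramolecular geometry exactly; cell moves rescale molecular centroids
#' fractionally while keeping each molecule rigid in Cartesian space. Uses
#' the current RNG stream.
#'
#' @param st internal MC state (from `mc_state_from_structure`).
#' @param config an `mc_config`.
#' @return list with the new state and the move `type`.
#' @keywords internal
propose_move <- function(st, config) {
  type <- MOVE_TYPES[sample.int(5, 1)]
  if (type == "rotate") {
    m <- sample.int(length(st$mols), 1)
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, -config$max_rot, config$max_rot)
    R <- rotvec_matrix(ax * ang)
    st$mols[[m]]$offsets <- st$mols[[m]]$offsets %*% t(R)
  } else if (type == "translate") {
    m <- sample.int(length(st$mols), 1)
    latt <- lattice_matrix(st$cellp[1], st$cellp[2], st$cellp[3],
                           st$cellp[4], st$cellp[5], st$cellp[6])
    dcart <- stats::runif(3, -config$max_trans, config$max_trans)
    st$mols[[m]]$centroid_frac <- st$mols[[m]]$centroid_frac +
      drop(dcart %*% solve(latt))
  } else if (type == "cell_length") {
    k <- sample.int(3, 1)
    st$cellp[k] <- max(3, st$cellp[k] +
                         stats::runif(1, -config$max_cell_len, config$max_cell_len))
  } else if (type == "cell_angle") {
    k <- 3 + sample.int(3, 1)
    st$cellp[k] <- min(140, max(40, st$cellp[k] +
                                  stats::runif(1, -config$max_cell_ang,
                                               config$max_cell_ang)))
  } else {                                     # volume
    sc <- stats::runif(1, config$vol_range[1], config$vol_range[2])
    st$cellp[1:3] <- st$cellp[1:3] * sc^(1 / 3)
  }
  list(state = st, type = type)
}

new_trajectory <- function(start_id, e0, lid, mode) {
  structure(list(records = list(), start_id = start_id, e0 = e0, lid = lid,
                 mode = mode, terminated = FALSE, reason = "completed"),
            class = "mc_trajectory")
}

traj_df <- function(traj) {
  do.call(rbind, lapply(traj$records, function(r)
    data.frame(step = r$step, type = r$type, accepted = r$accepted,
               energy = r$energy, sigma = r$sigma, otf_event = r$otf_event,
               stringsAsFactors = FALSE)))
}

#' @export
print.mc_trajectory <- function(x, ...) {
  df <- traj_df(x)
  cat(sprintf("<mc_trajectory '%s'> %s mode, %d steps, %d accepted, lid %.3f; %s\n",
              x$start_id, x$mode, length(x$records),
              if (is.null(df)) 0L else sum(df$accepted), x$lid,
              if (x$terminated) paste("terminated:", x$reason) else "completed"))
  invisible(x)
}

#' @export
as.data.frame.mc_trajectory <- function(x, ...) traj_df(x)

#' Run a threshold (or downhill) Monte Carlo trajectory
#'
#' The energy lid is fixed at `E(start) + lid_offset` for the whole run; in
#' threshold mode a move is accepted iff the new energy is below the lid, in
#' downhill mode iff it decreases the current energy. Proposals creating
#' hard-core overlaps are rejected without an energy call. With a
#' model-backed energy function (finite sigma) and `otf = FALSE`, the
#' trajectory aborts once sigma exceeds `sigma_terminate`.
#'
#' @param start an `xtal`.
#' @param energy_fn function (`xtal` -> list(mean, sigma)); sigma may be `NA`
#'   for exact oracles.
#' @param config an `mc_config`.
#' @param seed optional seed overriding `config$master_seed`.
#' @return an `mc_trajectory`; use [as.data.frame()] for the step records.
#' @export
run_threshold_mc <- function(start, energy_fn, config = mc_config(), seed = NULL) {
  seed <- seed %||% config$master_seed
  st <- mc_state_from_structure(start)
  e0r <- energy_fn(start)
  ecur <- e0r$mean
  if (!is.finite(ecur)) stop("non-finite energy of the start structure")
  lid <- ecur + config$lid_offset
  traj <- new_trajectory(start$id, ecur, lid, config$mode)
  with_local_seed(seed, {
    for (step in seq_len(config$max_steps)) {
      prop <- propose_move(st, config)
      cand <- tryCatch(structure_from_mc_state(prop$state),
                       error = function(e) NULL)
      rec <- list(step = step, type = prop$type, accepted = FALSE,
                  energy = NA_real_, sigma = NA_real_, otf_event = FALSE)
      if (is.null(cand) ||
          min_intermolecular_distance(cand, max(2 * config$hardcore, 2)) <
            config$hardcore) {
        traj$records[[step]] <- rec          # auto-rejected proposal
        next
      }
      er <- energy_fn(cand)
      rec$energy <- er$mean
      rec$sigma <- if (is.null(er$sigma)) NA_real_ else er$sigma
      rec$otf_event <- isTRUE(er$otf)
      if (!is.finite(er$mean)) {
        traj$records[[step]] <- rec
        traj$terminated <- TRUE
        traj$reason <- "non_finite_energy"
        break
      }
      if (is.finite(rec$sigma) && !config$otf &&
          rec$sigma > config$sigma_terminate) {
        traj$records[[step]] <- rec
        traj$terminated <- TRUE
        traj$reason <- "high_uncertainty"
        break
      }
      accept <- if (config$mode == "threshold") er$mean < lid else er$mean < ecur
      if (accept) {
        st <- prop$state
        ecur <- er$mean
        rec$accepted <- TRUE
      }
      traj$records[[step]] <- rec
    }
  })
  traj$final_state <- st
  traj
}

#' Monte Carlo with on-the-fly committee training
#'
#' Runs one trajectory per start structure, sequentially, with a shared
#' committee. At each step the committee predicts the (baseline-corrected)
#' energy; if the uncertainty exceeds `config$sigma_otf`, the target oracle
#' evaluates the configuration, the configuration joins the training set
#' with its oracle label, the oracle energy supersedes the model energy for
#' the acceptance decision, and the committee is retrained (warm start)
#' every `config$retrain_every` additions.
#'
#' @param starts list of `xtal` start structures (typically chosen by
#'   farthest point sampling).
#' @param model a `cnnp` fitted with `keep_data = TRUE`.
#' @param oracle target `energy_oracle`.
#' @param config an `mc_config` (with `otf = TRUE` for training; with
#'   `otf = FALSE` this reduces to plain model-backed trajectories with the
#'   high-uncertainty abort rule).
#' @param baseline_fn for delta-mode committees: function (`xtal` -> baseline
#'   energy, kJ/mol per molecule).
#' @return list: updated `model`, `trajectories`, and `additions`
#'   (data.frame: trajectory, sigma at evaluation time, oracle label).
#' @export
run_otf <- function(starts, model, oracle, config = mc_config(otf = TRUE),
                    baseline_fn = NULL) {
  stopifnot(inherits(model, "cnnp"))
  if (model$mode == "delta" && is.null(baseline_fn))
    stop("delta-mode committee needs a baseline_fn")
  if (config$otf && is.null(model$train))
    stop("on-the-fly training needs a model fitted with keep_data = TRUE")
  additions <- list()
  pending <- list()
  trajectories <- vector("list", length(starts))
  titer <- 0L

  for (ti in seq_along(starts)) {
    titer <- ti
    energy_fn <- function(s) {
      G <- compute_acsf(s, model$descriptor)
      vals <- member_predictions(model, s, G)
      sg <- stats::sd(vals)
      eb <- if (model$mode == "delta") baseline_fn(s) else 0
      emodel <- eb + mean(vals)
      if (config$otf && is.finite(sg) && sg > config$sigma_otf) {
        et <- tryCatch(oracle_eval(oracle, s), error = function(e) NA_real_)
        if (!is.finite(et))                   # oracle failure: reject the move
          return(list(mean = Inf, sigma = sg, otf = FALSE))
        lab <- if (model$mode == "delta") et - eb else et
        pending[[length(pending) + 1]] <<- list(structure = s, label = lab,
                                                features = G)
        additions[[length(additions) + 1]] <<- list(trajectory = titer,
                                                    sigma = sg, label = lab)
        if (length(pending) >= config$retrain_every) {
          tr <- model$train
          tr$structures <- c(tr$structures, lapply(pending, `[[`, "structure"))
          tr$labels <- c(tr$labels, vapply(pending, `[[`, "label", FUN.VALUE = 0))
          tr$features <- c(tr$features, lapply(pending, `[[`, "features"))
          model <<- cnnp(tr$structures, tr$labels, model$descriptor,
                         mode = model$mode, n_members = model$n_members,
                         hidden = model$hidden,
                         seed = substream_seed(config$master_seed, "otf",
                                               length(tr$labels)),
                         features = tr$features, warm_start = model,
                         chunk_iters = 40, max_chunks = 3, patience = 1)
          pending <<- list()
        }
        return(list(mean = et, sigma = sg, otf = TRUE))  # oracle energy decides acceptance
      }
      list(mean = emodel, sigma = sg)
    }
    trajectories[[ti]] <- run_threshold_mc(starts[[ti]], energy_fn, config,
                                           seed = substream_seed(config$master_seed,
                                                                 "traj", ti))
  }
  # flush structures still pending when the runs end
  if (config$otf && length(pending)) {
    tr <- model$train
    tr$structures <- c(tr$structures, lapply(pending, `[[`, "structure"))
    tr$labels <- c(tr$labels, vapply(pending, `[[`, "label", FUN.VALUE = 0))
    tr$features <- c(tr$features, lapply(pending, `[[`, "features"))
    model <- cnnp(tr$structures, tr$labels, model$descriptor,
                  mode = model$mode, n_members = model$n_members,
                  hidden = model$hidden,
                  seed = substream_seed(config$master_seed, "otf-final"),
                  features = tr$features, warm_start = model,
                  chunk_iters = 40, max_chunks = 3, patience = 1)
  }
  adf <- if (length(additions))
    do.call(rbind, lapply(additions, function(a)
      data.frame(trajectory = a$trajectory, sigma = a$sigma, label = a$label)))
  else data.frame(trajectory = integer(0), sigma = numeric(0), label = numeric(0))
  list(model = model, trajectories = trajectories, additions = adf)
}

#' Audit Monte Carlo trajectories
#'
#' Checks the acceptance invariants: no accepted configuration above the lid
#' (threshold mode) and strictly decreasing accepted energies (downhill
#' mode).
#'
#' @param traj an `mc_trajectory`.
#' @return list with `ok`, `lid_violations`, `monotone_ok`.
#' @export
audit_trajectory <- function(traj) {
  df <- as.data.frame(traj)
  acc <- df[df$accepted, , drop = FALSE]
  lid_viol <- if (traj$mode == "threshold")
    sum(acc$energy >= traj$lid) else 0L
  mono_ok <- TRUE
  if (traj$mode == "downhill" && nrow(acc) >= 1)
    mono_ok <- all(diff(c(traj$e0, acc$energy)) < 0)
  list(ok = lid_viol == 0 && mono_ok, lid_violations = lid_viol,
       monotone_ok = mono_ok)
}

#' Write a trajectory as JSON-lines plus a summary CSV row
#' @param traj an `mc_trajectory`.
#' @param path output JSON-lines path.
#' @export
write_trajectory <- function(traj, path) {
  recs <- lapply(traj$records, function(r)
    list(step = r$step, type = r$type, accepted = r$accepted,
         energy = r$energy, sigma = r$sigma, otf_event = r$otf_event))
  write_jsonl(recs, path)
  invisible(path)
}
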