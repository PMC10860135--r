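oracle_energy_fn <- function(params = surrogate_params()) {
  function(s) list(mean = as.numeric(surrogate_energy(s, params = params)),
                   sigma = NA_real_)
}

test_that("rigid-body moves preserve intramolecular geometry", {
  s <- random_structure(2)
  st <- cspal:::mc_state_from_structure(s)
  intra_dists <- function(s) {
    cart <- frac_to_cart(s)
    lapply(seq_len(max(s$mol)), function(m) {
      idx <- which(s$mol == m)
      # unwrap via the state decomposition so distances are molecular
      as.vector(dist(cspal:::mc_state_from_structure(s)$mols[[m]]$offsets))
    })
  }
  ref <- intra_dists(s)
  cfg <- mc_config(master_seed = 1)
  set.seed(42)
  for (k in 1:50) {
    prop <- cspal:::propose_move(st, cfg)
    s2 <- cspal:::structure_from_mc_state(prop$state)
    expect_equal(intra_dists(s2), ref, tolerance = 1e-10)
  }
})

test_that("volume moves scale the cell volume exactly and cell round-trips", {
  s <- random_structure(3)
  st <- cspal:::mc_state_from_structure(s)
  # state -> structure -> state round-trip preserves geometry
  s_rt <- cspal:::structure_from_mc_state(st)
  expect_equal(sort(neighbor_list(s_rt, 6)$d), sort(neighbor_list(s, 6)$d),
               tolerance = 1e-9)
  v0 <- cell_volume(cspal:::lattice_matrix(st$cellp[1], st$cellp[2], st$cellp[3],
                                           st$cellp[4], st$cellp[5], st$cellp[6]))
  st2 <- st
  sc <- 1.02
  st2$cellp[1:3] <- st$cellp[1:3] * sc^(1 / 3)
  s2 <- cspal:::structure_from_mc_state(st2)
  expect_equal(cell_volume(s2$lattice), v0 * sc, tolerance = 1e-9)
})

test_that("the five move types are drawn uniformly", {
  s <- random_structure(4)
  st <- cspal:::mc_state_from_structure(s)
  cfg <- mc_config()
  set.seed(7)
  types <- replicate(1000, cspal:::propose_move(st, cfg)$type)
  counts <- table(factor(types, levels = cspal:::MOVE_TYPES))
  # binomial(1000, 1/5) 99% interval: qbinom gives [168, 233]
  lo <- qbinom(0.005, 1000, 0.2); hi <- qbinom(0.995, 1000, 0.2)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("threshold trajectories never accept above the lid", {
  f <- small_landscape_fixture()
  cfg <- mc_config(lid_offset = 20, max_steps = 600, mode = "threshold",
                   master_seed = 2)
  efn <- oracle_energy_fn()
  total_acc <- 0
  for (i in 1:4) {
    tr <- run_threshold_mc(f$small_ls$structures[[i]], efn, cfg, seed = 100 + i)
    df <- as.data.frame(tr)
    acc <- df[df$accepted, ]
    expect_true(all(acc$energy < tr$lid))
    aud <- audit_trajectory(tr)
    expect_equal(aud$lid_violations, 0)
    total_acc <- total_acc + nrow(acc)
  }
  expect_gt(total_acc, 100)   # the lid actually admits moves
  # boundary: a zero lid offset rejects every uphill proposal
  cfg0 <- mc_config(lid_offset = 0, max_steps = 100, master_seed = 2)
  tr0 <- run_threshold_mc(f$small_ls$structures[[1]], efn, cfg0, seed = 9)
  df0 <- as.data.frame(tr0)
  expect_true(all(df0$energy[df0$accepted] < tr0$e0))
})

test_that("downhill trajectories decrease strictly monotonically", {
  f <- small_landscape_fixture()
  cfg <- mc_config(mode = "downhill", max_steps = 400, master_seed = 3)
  efn <- oracle_energy_fn()
  for (i in 5:7) {
    tr <- run_threshold_mc(f$small_ls$structures[[i]], efn, cfg, seed = i)
    df <- as.data.frame(tr)
    acc <- df$energy[df$accepted]
    expect_true(all(diff(c(tr$e0, acc)) < 0))
    expect_true(audit_trajectory(tr)$monotone_ok)
  }
})

test_that("trajectories are reproducible under a fixed energy function and seed", {
  f <- small_landscape_fixture()
  cfg <- mc_config(max_steps = 200, master_seed = 17)
  efn <- oracle_energy_fn()
  t1 <- run_threshold_mc(f$small_ls$structures[[2]], efn, cfg)
  t2 <- run_threshold_mc(f$small_ls$structures[[2]], efn, cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("a huge OTF trigger reproduces the plain model-backed trajectory", {
  f <- small_landscape_fixture()
  m <- cnnp(f$small_ls$structures[1:20], f$small_delta[1:20], f$small_params,
            mode = "delta", n_members = 3, seed = 5, max_chunks = 2)
  baseline_fn <- function(s) as.numeric(surrogate_energy(s))
  cfg_plain <- mc_config(mode = "downhill", max_steps = 120, otf = FALSE,
                         sigma_terminate = 1e9, master_seed = 23)
  efn <- function(s) {
    ce <- corrected_energy(m, s, baseline_fn(s))
    list(mean = ce$mean, sigma = ce$sigma)
  }
  plain <- run_threshold_mc(f$small_ls$structures[[25]], efn, cfg_plain,
                            seed = substream_seed(23, "traj", 1))
  cfg_otf <- mc_config(mode = "downhill", max_steps = 120, otf = TRUE,
                       sigma_otf = 1e8, master_seed = 23)
  res <- run_otf(f$small_ls$structures[25], m, f$small_pair$target, cfg_otf,
                 baseline_fn = baseline_fn)
  expect_equal(nrow(res$additions), 0)
  expect_identical(res$model$members, m$members)   # no retraining happened
  expect_identical(as.data.frame(res$trajectories[[1]]),
                   as.data.frame(plain))
})

test_that("OTF additions all exceeded the trigger and carry oracle labels", {
  f <- small_landscape_fixture()
  m <- cnnp(f$small_ls$structures[1:20], f$small_delta[1:20], f$small_params,
            mode = "delta", n_members = 3, seed = 5, max_chunks = 2)
  baseline_fn <- function(s) as.numeric(surrogate_energy(s))
  # a deliberately low trigger so the oracle is consulted often
  cfg <- mc_config(mode = "downhill", max_steps = 60, otf = TRUE,
                   sigma_otf = 0.02, retrain_every = 10, master_seed = 29)
  res <- run_otf(f$small_ls$structures[21:22], m, f$small_pair$target, cfg,
                 baseline_fn = baseline_fn)
  expect_gt(nrow(res$additions), 0)
  expect_true(all(res$additions$sigma > cfg$sigma_otf))
  # labels are target - baseline evaluated by the oracles, not the model
  expect_true(all(abs(res$additions$label) < 50))
  n_added <- nrow(res$additions)
  expect_equal(length(res$model$train$labels), 20 + n_added)
  added_labels <- utils::tail(res$model$train$labels, n_added)
  added_structs <- utils::tail(res$model$train$structures, n_added)
  relabel <- vapply(added_structs, function(s)
    oracle_eval(f$small_pair$target, s) - baseline_fn(s), 0)
  expect_equal(added_labels, relabel, tolerance = 1e-10)
})

test_that("with OTF off, trajectories abort once sigma exceeds the terminate level", {
  f <- small_landscape_fixture()
  m <- cnnp(f$small_ls$structures[1:20], f$small_delta[1:20], f$small_params,
            mode = "delta", n_members = 3, seed = 5, max_chunks = 2)
  baseline_fn <- function(s) as.numeric(surrogate_energy(s))
  efn <- function(s) {
    ce <- corrected_energy(m, s, baseline_fn(s))
    list(mean = ce$mean, sigma = ce$sigma)
  }
  cfg <- mc_config(mode = "downhill", max_steps = 150, otf = FALSE,
                   sigma_otf = 1e-4, sigma_terminate = 1e-3, master_seed = 31)
  tr <- run_threshold_mc(f$small_ls$structures[[23]], efn, cfg, seed = 3)
  expect_true(tr$terminated)
  expect_equal(tr$reason, "high_uncertainty")
  expect_lt(length(tr$records), cfg$max_steps)
})

test_that("config invariants are enforced", {
  expect_error(mc_config(max_rot = -1), "not TRUE")
  expect_error(mc_config(otf = FALSE, sigma_otf = 5, sigma_terminate = 2),
               "must exceed")
})
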