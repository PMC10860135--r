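# Shared fixtures. Small structures are built in code; the expensive default
# landscape (and models derived from it) is generated lazily once per test
# run and cached in this environment.

fixture_cache <- new.env(parent = emptyenv())

# a random valid triclinic structure of rigid toy molecules
random_structure <- function(seed, z = 2, id = paste0("rnd", seed)) {
  tm <- toy_molecule()
  set.seed(seed)
  repeat {
    cellp <- c(runif(3, 6, 9), runif(3, 75, 105))
    rots <- lapply(seq_len(z), function(m) cspal:::rotation_from_uniforms(runif(3)))
    cents <- rbind(0, matrix(runif(3 * (z - 1)), z - 1, 3))
    s <- tryCatch(cspal:::build_packed_structure(tm, cellp, rots, cents, id = id),
                  error = function(e) NULL)
    if (!is.null(s) && cspal:::min_intermolecular_distance(s, 3) > 1.8) return(s)
  }
}

# brute-force periodic neighbor enumeration over a supercell (oracle)
brute_neighbors <- function(s, cutoff, nrep = 5) {
  cart <- frac_to_cart(s)
  n <- nrow(cart)
  half <- nrep %/% 2
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n))
    for (a in -half:half) for (b in -half:half) for (cc in -half:half) {
      if (i == j && a == 0 && b == 0 && cc == 0) next
      v <- cart[j, ] - cart[i, ] + a * s$lattice[1, ] + b * s$lattice[2, ] +
        cc * s$lattice[3, ]
      d <- sqrt(sum(v^2))
      if (d <= cutoff)
        out[[length(out) + 1]] <- c(i, j, a, b, cc, d)
    }
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5]), , drop = FALSE]
}

# the shared default synthetic landscape (full pipeline scale), labelled,
# with selected descriptors -- built once
default_landscape_fixture <- function() {
  if (!is.null(fixture_cache$ls)) return(fixture_cache)
  pair <- surrogate_pair()
  ls <- generate_landscape(n = 300, z = 2, seed = 20240901, minimize = TRUE)
  ls <- label_with_target(ls, pair)
  params <- acsf_param_pool(c("C", "O"))
  # near-duplicate pool columns can exhaust rank before 64 picks; the
  # resulting shorter selection is expected here
  params <- suppressWarnings(
    select_descriptors(ls$structures[seq(1, length(ls), by = 3)],
                       params, k = 64))
  fixture_cache$ls <- ls
  fixture_cache$pair <- pair
  fixture_cache$params <- params
  fixture_cache$delta <- ls$e_target - ls$e_baseline
  fixture_cache
}

# a small landscape for quick model tests
small_landscape_fixture <- function() {
  if (!is.null(fixture_cache$small_ls)) return(fixture_cache)
  pair <- surrogate_pair()
  ls <- generate_landscape(n = 60, z = 2, seed = 77, minimize = TRUE)
  ls <- label_with_target(ls, pair)
  params <- acsf_param_pool(c("C", "O"), n_radial = 16, n_ang_eta = 2)
  params <- select_descriptors(ls$structures[1:30], params, k = 32)
  fixture_cache$small_ls <- ls
  fixture_cache$small_pair <- pair
  fixture_cache$small_params <- params
  fixture_cache$small_delta <- ls$e_target - ls$e_baseline
  fixture_cache
}
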