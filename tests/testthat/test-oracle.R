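# naive R implementation of the periodic pairwise + three-body target sum,
# used as an independent oracle for the compiled kernels
naive_surrogate <- function(s, tm, p, component = "baseline", nrep = 3) {
  cart <- frac_to_cart(s)
  n <- nrow(cart)
  q <- cspal:::template_charges(tm, s)
  fc <- function(r) ifelse(r < p$cutoff, 0.5 * (cos(pi * r / p$cutoff) + 1), 0)
  E <- 0
  for (i in 1:n) for (j in 1:n) for (a in -nrep:nrep) for (b in -nrep:nrep)
    for (cc in -nrep:nrep) {
      v <- cart[j, ] - cart[i, ] + a * s$lattice[1, ] + b * s$lattice[2, ] +
        cc * s$lattice[3, ]
      r <- sqrt(sum(v^2))
      if (r > p$cutoff || r < 1e-12) next
      # minimum-image copy of a same-molecule pair is intramolecular
      if (s$mol[i] == s$mol[j]) {
        dmin <- Inf
        for (a2 in -nrep:nrep) for (b2 in -nrep:nrep) for (c2 in -nrep:nrep) {
          v2 <- cart[j, ] - cart[i, ] + a2 * s$lattice[1, ] +
            b2 * s$lattice[2, ] + c2 * s$lattice[3, ]
          dmin <- min(dmin, sqrt(sum(v2^2)))
        }
        if (abs(r - dmin) < 1e-9) next
      }
      reff <- max(r, 0.5)
      ei <- match(s$species[i], p$elements); ej <- match(s$species[j], p$elements)
      u <- 0
      if (component != "delta") {
        sr6 <- (p$sig[ei, ej] / reff)^6
        u <- u + 4 * p$eps[ei, ej] * (sr6^2 - sr6) +
          p$coulk * q[i] * q[j] / reff +
          p$osc_amp * cos(2 * pi * reff / p$osc_wavelength)
      }
      if (component != "baseline")
        u <- u + p$delA[ei, ej] * exp(-(reff - p$delR0[ei, ej])^2 / (2 * p$delta_w^2))
      E <- E + 0.5 * u * fc(r)
    }
  E / max(s$mol)
}

test_that("surrogate energies match a naive periodic double sum", {
  tm <- toy_molecule()
  p <- surrogate_params(atm3b = 0)   # three-body handled separately below
  for (seed in c(2, 8, 15)) {
    s <- random_structure(seed)
    for (comp in c("baseline", "delta")) {
      got <- as.numeric(surrogate_energy(s, tm, p, comp))
      ref <- naive_surrogate(s, tm, p, comp)
      expect_equal(got, ref, tolerance = 1e-9)
    }
  }
})

test_that("target minus baseline equals the delta component exactly", {
  tm <- toy_molecule()
  p <- surrogate_params()
  s <- random_structure(4)
  eb <- as.numeric(surrogate_energy(s, tm, p, "baseline"))
  et <- as.numeric(surrogate_energy(s, tm, p, "target"))
  ed <- as.numeric(surrogate_energy(s, tm, p, "delta"))
  expect_equal(et - eb, ed, tolerance = 1e-9)
})

test_that("molecules beyond the cutoff in a huge cell do not interact", {
  tm <- toy_molecule()
  big <- diag(3) * 60
  fr <- rbind(sweep(tm$sites, 2, c(10, 10, 10), "+"),
              sweep(tm$sites, 2, c(40, 40, 40), "+")) %*% solve(big)
  s <- xtal(big, rep(tm$elements, 2), fr, rep(1:2, each = 4), id = "far")
  expect_equal(as.numeric(surrogate_energy(s)), 0)
  expect_equal(as.numeric(surrogate_energy(s, component = "delta")), 0)
})

test_that("the repulsion-dispersion pair minimum sits at 2^(1/6) sigma", {
  # two uncharged single-element sites with an effectively infinite cutoff:
  # the analytic 12-6 minimum
  p <- surrogate_params(cutoff = 60, osc_amp = 0)
  p$coulk <- 0
  p$atm3b <- 0
  tm <- list(sites = rbind(c(0, 0, 0), c(0, 0, 30)), elements = c("C", "C"),
             charges = c(0, 0))
  e_at <- function(r) {
    big <- diag(3) * 200
    fr <- rbind(c(100, 100, 100), c(100, 100, 130),
                c(100 + r, 100, 100), c(100 + r, 100, 130)) %*% solve(big)
    s <- xtal(big, rep("C", 4), fr, c(1L, 1L, 2L, 2L), check_overlap = FALSE)
    as.numeric(surrogate_energy(s, tm, p, "baseline"))
  }
  rmin <- optimize(e_at, c(2.5, 5))$minimum
  expect_equal(rmin, 2^(1 / 6) * 3.4, tolerance = 1e-3)
})

test_that("overlapping molecules give a large finite positive flagged energy", {
  tm <- toy_molecule()
  big <- diag(3) * 30
  fr <- rbind(sweep(tm$sites, 2, c(10, 10, 10), "+"),
              sweep(tm$sites, 2, c(10.3, 10, 10), "+")) %*% solve(big)
  s <- xtal(big, rep(tm$elements, 2), fr, rep(1:2, each = 4),
            check_overlap = FALSE)
  e <- surrogate_energy(s)
  expect_true(is.finite(e))
  expect_gt(as.numeric(e), 1e4)
  expect_true(attr(e, "overlap"))
})

test_that("per-molecule energy is intensive under supercell doubling", {
  # replicate molecules as rigid wholes so the molecule partition stays
  # physical even when a molecule wraps across the doubled boundary
  for (seed in c(3, 9)) {
    s <- random_structure(seed)
    e1 <- as.numeric(surrogate_energy(s, component = "target"))
    st <- cspal:::mc_state_from_structure(s)
    latt2 <- s$lattice; latt2[1, ] <- latt2[1, ] * 2
    linv2 <- solve(latt2)
    frac <- NULL; mol <- NULL; species <- NULL
    mno <- 0L
    for (shift in c(0, 0.5)) {
      for (mo in st$mols) {
        cen <- mo$centroid_frac
        cen2 <- c(cen[1] / 2 + shift, cen[2], cen[3])
        cart <- sweep(mo$offsets, 2, drop(cen2 %*% latt2), "+")
        frac <- rbind(frac, cart %*% linv2)
        mno <- mno + 1L
        mol <- c(mol, rep(mno, nrow(mo$offsets)))
        species <- c(species, s$species[mo$idx])
      }
    }
    s2 <- xtal(latt2, species, frac, mol, check_overlap = FALSE)
    e2 <- as.numeric(surrogate_energy(s2, component = "target"))
    expect_equal(e2, e1, tolerance = 1e-8)
  }
})

test_that("zero perturbation makes target and baseline coincide", {
  pair0 <- surrogate_pair(perturbation = 0)
  s <- random_structure(6)
  expect_identical(oracle_eval(pair0$baseline, s), oracle_eval(pair0$target, s))
})

test_that("landscape generation is seeded-reproducible and overlap-free", {
  ls1 <- generate_landscape(n = 6, z = 2, seed = 123, minimize = FALSE)
  ls2 <- generate_landscape(n = 6, z = 2, seed = 123, minimize = FALSE)
  expect_identical(lapply(ls1$structures, `[[`, "frac"),
                   lapply(ls2$structures, `[[`, "frac"))
  expect_identical(ls1$e_baseline, ls2$e_baseline)
  for (s in ls1$structures)
    expect_gte(cspal:::min_intermolecular_distance(s, 3), 0.7)
  expect_true(all(is.finite(ls1$e_baseline)))
  ls3 <- generate_landscape(n = 1, z = 1, seed = 5, minimize = FALSE)
  expect_equal(length(ls3), 1)
})

test_that("minimized landscape entries are baseline local minima", {
  ls <- generate_landscape(n = 8, z = 2, seed = 31, minimize = TRUE)
  tm <- toy_molecule(); p <- surrogate_params()
  for (i in seq_along(ls$structures)) {
    s <- ls$structures[[i]]
    st <- cspal:::mc_state_from_structure(s)
    raised <- 0
    set.seed(1000 + i)
    for (k in 1:20) {
      st2 <- st
      mmol <- sample.int(length(st2$mols), 1)
      if (runif(1) < 0.5) {
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        R <- cspal:::rotvec_matrix(ax * 0.01)
        st2$mols[[mmol]]$offsets <- st2$mols[[mmol]]$offsets %*% t(R)
      } else {
        latt <- s$lattice
        dx <- rnorm(3); dx <- dx / sqrt(sum(dx^2)) * 0.01
        st2$mols[[mmol]]$centroid_frac <- st2$mols[[mmol]]$centroid_frac +
          drop(dx %*% solve(latt))
      }
      s2 <- cspal:::structure_from_mc_state(st2)
      if (as.numeric(surrogate_energy(s2, tm, p)) > ls$e_baseline[i])
        raised <- raised + 1
    }
    expect_gte(raised, 19)
  }
})

test_that("the delta surface is smooth and non-trivial over a landscape", {
  f <- small_landscape_fixture()
  de <- f$small_delta
  expect_gt(sd(de), 0.1)
  expect_true(all(is.finite(de)))
  # finite-difference gradient of the delta component is bounded along a
  # random rigid-body direction
  s <- f$small_ls$structures[[1]]
  st <- cspal:::mc_state_from_structure(s)
  d0 <- as.numeric(surrogate_energy(s, component = "delta"))
  h <- 1e-4
  st2 <- st
  st2$mols[[1]]$centroid_frac <- st$mols[[1]]$centroid_frac + c(h, 0, 0)
  d1 <- as.numeric(surrogate_energy(cspal:::structure_from_mc_state(st2),
                                    component = "delta"))
  expect_lt(abs(d1 - d0) / h, 1e3)
})

test_that("an external command oracle round-trips an energy", {
  skip_on_os("windows")
  script <- withr::local_tempfile(fileext = ".R")
  writeLines(c("args <- commandArgs(trailingOnly = TRUE)",
               "suppressMessages(library(cspal))",
               "s <- read_xyz(args[1])[[1]]",
               "cat(as.numeric(surrogate_energy(s)), '\\n')"), script)
  oracle <- external_oracle(paste(file.path(R.home("bin"), "Rscript"), script))
  s <- random_structure(12)
  expect_equal(oracle_eval(oracle, s), as.numeric(surrogate_energy(s)),
               tolerance = 1e-5)
})
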