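# Surrogate energy oracles and a synthetic CSP-landscape generator. The
# baseline oracle is an intermolecular 12-6 repulsion-dispersion plus damped
# point-charge Coulomb potential on rigid sites; the target oracle adds a
# smooth per-pair Gaussian perturbation. Their difference is a bounded,
# smooth, structure-varying function — the correction a delta-learning model
# is meant to learn. The pair stands in for the roles of a cheap force field
# and an expensive reference method so the whole workflow runs at desk scale;
# no physical fidelity to any particular compound is claimed.

COULOMB_K <- 1389.35458  # kJ mol^-1 Angstrom per e^2

#' Default rigid toy molecule template
#'
#' A planar four-site molecule with two elements and small, neutralizing
#' point charges: large enough to exercise per-element subnets and angular
#' descriptors, small enough for fast landscape generation.
#'
#' @return list with `sites` (4 x 3 Cartesian coordinates, Angstrom),
#'   `elements`, `charges` (sum zero).
#' @export
toy_molecule <- function() {
  list(sites = rbind(c( 0.65, 0.0, 0.0),
                     c(-0.65, 0.0, 0.0),
                     c( 0.0,  1.10, 0.0),
                     c( 0.0, -1.10, 0.0)),
       elements = c("C", "C", "O", "O"),
       charges = c(0.45, 0.45, -0.45, -0.45))
}

#' Surrogate potential parameters
#'
#' @param elements element alphabet (order fixes matrix indexing).
#' @param cutoff interaction cutoff in Angstrom.
#' @param hardcore hard-core distance below which structures are flagged.
#' @param delta_w width (Angstrom) of the Gaussian perturbation wells.
#' @param atm3b strength (kJ/mol A^9) of the triple-dipole three-body term in
#'   the target potential; the baseline is strictly pairwise, so this is the
#'   many-body part of the correction the delta model must learn.
#' @param osc_amp,osc_wavelength amplitude (kJ/mol) and wavelength (Angstrom)
#'   of a short-range oscillatory pair term present in BOTH baseline and
#'   target. It cancels exactly in the correction, but gives the baseline
#'   landscape the short-length-scale structure of a multipolar force field,
#'   so learning total energies is much harder than learning the correction.
#' @return list of per-element-pair parameter matrices: `eps`/`sig`
#'   (12-6 well depth kJ/mol and diameter Angstrom), `delA`/`delR0`
#'   (perturbation amplitude kJ/mol and center Angstrom).
#' @export
surrogate_params <- function(elements = c("C", "O"), cutoff = 7.5,
                             hardcore = 0.7, delta_w = 0.15, atm3b = 4000,
                             osc_amp = 1.5, osc_wavelength = 0.7) {
  ne <- length(elements)
  eps_el <- c(C = 0.40, O = 0.60)[elements]
  sig_el <- c(C = 3.40, O = 3.00)[elements]
  eps <- sqrt(outer(eps_el, eps_el))
  sig <- outer(sig_el, sig_el, function(a, b) (a + b) / 2)
  delA <- matrix(0, ne, ne, dimnames = list(elements, elements))
  delR0 <- matrix(3.5, ne, ne, dimnames = list(elements, elements))
  amp <- rbind(C = c(C = -7.2, O = 4.8), O = c(C = 4.8, O = -9.0))
  r0 <- rbind(C = c(C = 3.8, O = 3.5), O = c(C = 3.5, O = 3.2))
  for (i in elements) for (j in elements) {
    delA[i, j] <- amp[i, j]; delR0[i, j] <- r0[i, j]
  }
  list(elements = elements, cutoff = cutoff, hardcore = hardcore,
       eps = eps, sig = sig, delA = delA, delR0 = delR0, delta_w = delta_w,
       atm3b = atm3b, osc_amp = osc_amp, osc_wavelength = osc_wavelength,
       coulk = COULOMB_K)
}

template_charges <- function(template, structure) {
  # charges are per template site, repeated per molecule in site order
  z <- max(structure$mol)
  q <- numeric(length(structure$species))
  for (m in seq_len(z)) {
    idx <- which(structure$mol == m)
    q[idx] <- template$charges[seq_along(idx)]
  }
  q
}

#' Surrogate lattice energy of a structure
#'
#' Intermolecular-only pairwise sum over all periodic images within the
#' cutoff, divided by the number of molecules Z (kJ/mol per molecule).
#' Overlaps below the hard core give a large finite positive energy and set
#' the attribute `overlap`.
#'
#' @param structure an `xtal` whose molecules follow `template`'s site order.
#' @param template rigid molecule template (for site charges).
#' @param params output of [surrogate_params()].
#' @param component `"baseline"`, `"target"`, or `"delta"` (target minus
#'   baseline).
#' @return energy in kJ/mol per molecule, with attributes `overlap` and
#'   `min_dist`.
#' @export
surrogate_energy <- function(structure, template = toy_molecule(),
                             params = surrogate_params(),
                             component = c("baseline", "target", "delta")) {
  component <- match.arg(component)
  comp <- match(component, c("baseline", "target", "delta")) - 1L
  codes <- match(structure$species, params$elements)
  if (anyNA(codes)) stop("element(s) outside surrogate alphabet")
  q <- template_charges(template, structure)
  res <- cpp_pair_energy(structure$lattice, structure$frac,
                         as.integer(structure$mol), as.integer(codes), q,
                         params$cutoff, params$eps, params$sig,
                         params$delA, params$delR0, params$delta_w,
                         params$atm3b, params$osc_amp, params$osc_wavelength,
                         params$coulk, params$hardcore, comp)
  e <- res$energy / max(structure$mol)
  attr(e, "overlap") <- res$overlap
  attr(e, "min_dist") <- res$min_dist
  e
}

#' Construct an energy oracle
#' @param fun function (`xtal` -> energy in kJ/mol per molecule).
#' @param name oracle label.
#' @param deterministic logical: same structure always gives the same energy.
#' @export
energy_oracle <- function(fun, name, deterministic = TRUE) {
  structure(list(fun = fun, name = name, deterministic = deterministic),
            class = "energy_oracle")
}

#' Evaluate an oracle on a structure
#' @param oracle an `energy_oracle`.
#' @param structure an `xtal`.
#' @export
oracle_eval <- function(oracle, structure) {
  stopifnot(inherits(oracle, "energy_oracle"))
  as.numeric(oracle$fun(structure))
}

#' @export
print.energy_oracle <- function(x, ...) {
  cat(sprintf("<energy_oracle '%s'>%s\n", x$name,
              if (x$deterministic) " (deterministic)" else ""))
  invisible(x)
}

#' Baseline/target surrogate oracle pair
#'
#' @inheritParams surrogate_energy
#' @param perturbation scale factor on the Gaussian perturbation amplitudes
#'   (0 makes target identical to baseline).
#' @return list with `baseline`, `target` and `delta` oracles.
#' @export
surrogate_pair <- function(template = toy_molecule(), params = surrogate_params(),
                           perturbation = 1) {
  p <- params
  p$delA <- p$delA * perturbation
  p$atm3b <- p$atm3b * perturbation
  list(baseline = energy_oracle(function(s)
         surrogate_energy(s, template, p, "baseline"), "surrogate-baseline"),
       target = energy_oracle(function(s)
         surrogate_energy(s, template, p, "target"), "surrogate-target"),
       delta = energy_oracle(function(s)
         surrogate_energy(s, template, p, "delta"), "surrogate-delta"))
}

#' Wrap an external command as an energy oracle
#'
#' The command receives the path of an extended-XYZ file with a single
#' structure and must print one energy (kJ/mol per molecule) to standard
#' output. This is the hook through which a real electronic-structure or
#' tight-binding backend attaches.
#'
#' @param command shell command.
#' @param name oracle label.
#' @export
external_oracle <- function(command, name = command) {
  energy_oracle(function(s) {
    f <- tempfile(fileext = ".xyz")
    on.exit(unlink(f))
    write_xyz(s, f)
    out <- system(paste(command, shQuote(f)), intern = TRUE)
    val <- suppressWarnings(as.numeric(utils::tail(trimws(out[nzchar(out)]), 1)))
    if (length(val) != 1 || is.na(val))
      stop("external oracle did not print a single energy: ", command)
    val
  }, name = name, deterministic = TRUE)
}

# --------------------------------------------------------------------------
# quasi-random sampling (Halton sequence with seeded Cranley-Patterson shift)

halton_point <- function(i, bases) {
  vapply(bases, function(b) {
    f <- 1; r <- 0; n <- i
    while (n > 0) {
      f <- f / b
      r <- r + f * (n %% b)
      n <- n %/% b
    }
    r
  }, 0)
}

HALTON_BASES <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47,
                  53, 59, 61, 67, 71, 73, 79, 83, 89, 97, 101)

# uniform random rotation matrix from three uniforms (Shoemake quaternions)
rotation_from_uniforms <- function(u) {
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z), 2*(x*z + w*y)),
        c(2*(x*y + w*z), 1 - 2*(x^2 + z^2), 2*(y*z - w*x)),
        c(2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2)))
}

# Rodrigues rotation matrix from a rotation vector (axis * angle)
rotvec_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# build a crystal from packing degrees of freedom: cell parameters, one
# rotation matrix per molecule, fractional centroids (molecule 1 at origin)
build_packed_structure <- function(template, cellp, rots, cents, id = "s") {
  latt <- lattice_matrix(cellp[1], cellp[2], cellp[3],
                         cellp[4], cellp[5], cellp[6])
  z <- length(rots)
  sites0 <- sweep(template$sites, 2, colMeans(template$sites))
  frac <- NULL; species <- NULL; mol <- NULL
  linv <- solve(latt)
  for (m in seq_len(z)) {
    cart <- sites0 %*% t(rots[[m]])
    cart <- sweep(cart, 2, drop(cents[m, ] %*% latt), "+")
    frac <- rbind(frac, cart %*% linv)
    species <- c(species, template$elements)
    mol <- c(mol, rep(m, nrow(sites0)))
  }
  xtal(latt, species, frac, mol, id = id, check_overlap = FALSE)
}

pack_dof <- function(theta, z) {
  # theta: a,b,c,al,be,ga, rotvec1, (cent2, rotvec2), ...
  cellp <- theta[1:6]
  rots <- list(rotvec_matrix(theta[7:9]))
  cents <- matrix(0, z, 3)
  off <- 9
  if (z > 1) for (m in 2:z) {
    cents[m, ] <- theta[(off + 1):(off + 3)]
    rots[[m]] <- rotvec_matrix(theta[(off + 4):(off + 6)])
    off <- off + 6
  }
  list(cellp = cellp, rots = rots, cents = cents)
}

#' Generate a synthetic CSP landscape
#'
#' Quasi-randomly samples rigid-molecule packings in P1 (Halton sequence over
#' cell parameters, molecular positions and orientations, with a seeded
#' Cranley-Patterson shift), rejects overlapping packings, optionally relaxes
#' each packing to a local minimum of the baseline surrogate potential
#' (bounded L-BFGS over cell + rigid-body degrees of freedom), and
#' de-duplicates by (energy, density). Entries carry baseline energies in
#' kJ/mol per molecule.
#'
#' @param template rigid molecule template (see [toy_molecule()]).
#' @param n number of landscape entries to produce.
#' @param z molecules per cell (1..4).
#' @param seed master seed (generation is fully reproducible).
#' @param minimize relax each sample to a baseline local minimum (default
#'   `TRUE`).
#' @param params surrogate parameters.
#' @param maxit L-BFGS iteration budget per relaxation.
#' @return a `landscape` with `e_baseline` filled in.
#' @export
generate_landscape <- function(template = toy_molecule(), n = 300, z = 2,
                               seed = 1, minimize = TRUE,
                               params = surrogate_params(), maxit = 200) {
  stopifnot(n >= 1, z >= 1, z <= 4)
  ndof <- 9 + 6 * (z - 1)
  nsamp_dims <- 6 + 3 * z + 3 * (z - 1)   # cell + rotations + centroids(2..z)
  bases <- HALTON_BASES[seq_len(nsamp_dims)]
  shift <- with_local_seed(substream_seed(seed, "halton"), stats::runif(nsamp_dims))
  len_lo <- 5.5; len_hi <- 9; ang_lo <- 75; ang_hi <- 105
  lower <- c(rep(4.5, 3), rep(70, 3), rep(-Inf, ndof - 6))
  upper <- c(rep(12, 3), rep(110, 3), rep(Inf, ndof - 6))
  entries <- list(); e_base <- numeric(0); seen <- character(0)
  idx <- 0L; attempts <- 0L
  while (length(entries) < n && attempts < 60L * n) {
    idx <- idx + 1L; attempts <- attempts + 1L
    u <- (halton_point(idx, bases) + shift) %% 1
    cellp <- c(len_lo + u[1:3] * (len_hi - len_lo),
               ang_lo + u[4:6] * (ang_hi - ang_lo))
    rots <- list(); off <- 6
    for (m in seq_len(z)) {
      rots[[m]] <- rotation_from_uniforms(u[(off + 1):(off + 3)])
      off <- off + 3
    }
    cents <- matrix(0, z, 3)
    if (z > 1) for (m in 2:z) {
      cents[m, ] <- u[(off + 1):(off + 3)]
      off <- off + 3
    }
    s0 <- tryCatch(build_packed_structure(template, cellp, rots, cents),
                   error = function(e) NULL)
    if (is.null(s0)) next
    if (min_intermolecular_distance(s0, 3) < 1.2) next   # pre-relaxation screen
    if (minimize) {
      # rotation-vector increments act on the sampled reference orientations
      rot0 <- rots
      rot0_mat <- do.call(rbind, rot0)
      sites0 <- sweep(template$sites, 2, colMeans(template$sites))
      site_spec <- as.integer(match(template$elements, params$elements))
      theta0 <- c(cellp, rep(0, 3), if (z > 1) as.vector(t(cbind(cents[-1, , drop = FALSE],
                                                                 matrix(0, z - 1, 3)))))
      hvec <- c(rep(1e-4, 3), rep(1e-3, 3), rep(1e-5, ndof - 6))
      obj2 <- function(theta)
        cpp_pack_energy(theta, z, sites0, rot0_mat, site_spec,
                        template$charges, params$cutoff, params$eps,
                        params$sig, params$coulk, params$hardcore,
                        params$osc_amp, params$osc_wavelength)
      grad2 <- function(theta)
        cpp_pack_grad(theta, hvec, z, sites0, rot0_mat, site_spec,
                      template$charges, params$cutoff, params$eps,
                      params$sig, params$coulk, params$hardcore,
                      params$osc_amp, params$osc_wavelength)
      ctrl <- list(maxit = maxit, factr = 1e4,
                   parscale = c(rep(1, 3), rep(5, 3), rep(0.3, ndof - 6)))
      fit <- tryCatch(stats::optim(theta0, obj2, grad2, method = "L-BFGS-B",
                                   lower = lower, upper = upper, control = ctrl),
                      error = function(e) NULL)
      if (is.null(fit)) next
      # polish to tighten the gradient at the minimum
      fit2 <- tryCatch(stats::optim(fit$par, obj2, grad2, method = "L-BFGS-B",
                                    lower = lower, upper = upper, control = ctrl),
                       error = function(e) NULL)
      if (!is.null(fit2) && fit2$value <= fit$value) fit <- fit2
      d <- pack_dof(fit$par, z)
      d$rots <- lapply(seq_len(z), function(m) d$rots[[m]] %*% rot0[[m]])
      s1 <- tryCatch(build_packed_structure(template, d$cellp, d$rots, d$cents),
                     error = function(e) NULL)
      if (is.null(s1)) next
      e <- fit$value
    } else {
      s1 <- s0
      e <- as.numeric(surrogate_energy(s1, template, params, "baseline"))
    }
    if (!is.finite(e) || e > 0) next            # unbound / unphysical packing
    if (min_intermolecular_distance(s1, 3) < params$hardcore) next
    dens <- xtal_density(s1)
    key <- sprintf("%.4f|%.3f", e, dens)        # de-duplicate by (energy, density)
    if (key %in% seen) next
    seen <- c(seen, key)
    s1$id <- sprintf("s%04d", length(entries) + 1L)
    entries[[length(entries) + 1L]] <- s1
    e_base <- c(e_base, e)
  }
  if (length(entries) < n)
    warning(sprintf("generated only %d of %d requested structures", length(entries), n))
  if (!length(entries)) stop("failed to generate any structure")
  landscape(entries, e_base)
}

#' Label a landscape with target energies
#'
#' Single-point evaluation of the target oracle at each fixed geometry (no
#' re-relaxation), filling `e_target`.
#'
#' @param x a `landscape`.
#' @param pair list with a `target` oracle (see [surrogate_pair()]), or an
#'   `energy_oracle`.
#' @export
label_with_target <- function(x, pair) {
  stopifnot(inherits(x, "landscape"))
  oracle <- if (inherits(pair, "energy_oracle")) pair else pair$target
  x$e_target <- vapply(x$structures, function(s) oracle_eval(oracle, s), 0)
  x
}
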