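# independent single-threaded reference implementations used as oracles
naive_acsf_nonperiodic <- function(cart, species, params) {
  n <- nrow(cart)
  rad <- params$radial; ang <- params$angular
  G <- matrix(0, n, nrow(rad) + nrow(ang))
  fc <- function(r) cutoff_fn(r, params$cutoff)
  for (i in seq_len(n)) {
    for (p in seq_len(nrow(rad))) {
      for (j in seq_len(n)) {
        if (j == i || species[j] != rad$el[p]) next
        r <- sqrt(sum((cart[j, ] - cart[i, ])^2))
        if (r > params$cutoff) next
        G[i, p] <- G[i, p] + exp(-rad$eta[p] * (r - rad$rs[p])^2) * fc(r)
      }
    }
    for (p in seq_len(nrow(ang))) {
      for (j in seq_len(n)) for (k in seq_len(n)) {
        if (j >= k || j == i || k == i) next
        pp <- sort(c(species[j], species[k]))
        if (!identical(pp, sort(c(ang$el1[p], ang$el2[p])))) next
        rij <- sqrt(sum((cart[j, ] - cart[i, ])^2))
        rik <- sqrt(sum((cart[k, ] - cart[i, ])^2))
        rjk <- sqrt(sum((cart[k, ] - cart[j, ])^2))
        if (rij > params$cutoff || rik > params$cutoff || rjk > params$cutoff) next
        cosq <- sum((cart[j, ] - cart[i, ]) * (cart[k, ] - cart[i, ])) / (rij * rik)
        base <- 1 + ang$lambda[p] * cosq
        if (base <= 0) next
        G[i, nrow(rad) + p] <- G[i, nrow(rad) + p] +
          2^(1 - ang$zeta[p]) * base^ang$zeta[p] *
          exp(-ang$eta[p] * (rij^2 + rik^2 + rjk^2)) * fc(rij) * fc(rik) * fc(rjk)
      }
    }
  }
  G
}

brute_cur <- function(X, k) {
  picked <- integer(0)
  cols <- seq_len(ncol(X))
  R <- X
  for (it in seq_len(k)) {
    v <- svd(R)$v[, 1]
    sc <- v^2
    b <- which.max(sc)
    picked <- c(picked, cols[b])
    cvec <- R[, b]
    R <- apply(R, 2, function(col) col - cvec * sum(cvec * col) / sum(cvec^2))
    R <- R[, -b, drop = FALSE]
    cols <- cols[-b]
  }
  picked
}

brute_fps <- function(X, m, start) {
  sel <- start
  while (length(sel) < m) {
    dmin <- apply(X, 1, function(p)
      min(vapply(sel, function(s) sqrt(sum((p - X[s, ])^2)), 0)))
    sel <- c(sel, which.max(dmin))
  }
  sel
}

test_that("cosine cutoff has the Behler form", {
  expect_equal(cutoff_fn(0, 8), 1)
  expect_equal(cutoff_fn(8, 8), 0)
  expect_equal(cutoff_fn(4, 8), 0.5)
  expect_equal(cutoff_fn(9, 8), 0)
  expect_error(cutoff_fn(1, -1), "positive")
  # continuous first derivative at the cutoff: slope -> 0 from inside
  h <- 1e-6
  expect_lt(abs((cutoff_fn(8 - h, 8) - cutoff_fn(8 - 2 * h, 8)) / h), 1e-5)
})

test_that("parameter pool is deterministic with the documented counts", {
  p1 <- acsf_param_pool(c("C", "O"), n_radial = 8, n_ang_eta = 2)
  p2 <- acsf_param_pool(c("C", "O"), n_radial = 8, n_ang_eta = 2)
  expect_identical(p1$radial, p2$radial)
  expect_identical(p1$angular, p2$angular)
  # 8 radial functions per neighbor element
  expect_equal(sum(p1$radial$el == "C"), 8)
  expect_equal(sum(p1$radial$el == "O"), 8)
  # zeta/lambda/eta grid over 3 unordered element pairs
  expect_equal(nrow(p1$angular), 3 * 4 * 2 * 2)
  expect_true(max(p1$radial$rs) < p1$cutoff)
  expect_true(all(p1$radial$eta > 0))
  expect_true(all(p1$angular$zeta >= 1))
  expect_true(all(p1$angular$lambda %in% c(-1, 1)))
})

test_that("ACSFs match a direct non-periodic summation on an isolated cluster", {
  params <- acsf_param_pool(c("C", "O"), cutoff = 6, n_radial = 6, n_ang_eta = 2)
  cart <- rbind(c(15, 15, 15), c(16.2, 15, 15), c(15.5, 16.1, 14.7))
  species <- c("C", "O", "C")
  big <- diag(3) * 40   # isolated: no periodic images within the cutoff
  s <- xtal(big, species, cart %*% solve(big), rep(1L, 3), check_overlap = FALSE)
  G <- compute_acsf(s, params)
  ref <- naive_acsf_nonperiodic(cart, species, params)
  expect_equal(unclass(G), ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("single neighbor at R_s gives G2 = fc(R_s); isolated atom gives zeros", {
  params <- acsf_param_pool("C", cutoff = 6, n_radial = 4, n_ang_eta = 1)
  params$radial <- data.frame(el = "C", eta = 2.0, rs = 2.5)
  big <- diag(3) * 50
  s <- xtal(big, c("C", "C"), rbind(c(10, 10, 10), c(12.5, 10, 10)) %*% solve(big),
            c(1L, 2L), check_overlap = FALSE)
  G <- compute_acsf(s, params)
  expect_equal(G[1, 1], cutoff_fn(2.5, 6), tolerance = 1e-12)
  lone <- xtal(big, "C", matrix(0.5, 1, 3), 1L)
  expect_true(all(compute_acsf(lone, params) == 0))
})

test_that("ACSFs are invariant to rotation, translation, permutation, wrapping and supercell replication", {
  params <- acsf_param_pool(c("C", "O"), n_radial = 6, n_ang_eta = 1)
  for (seed in 1:6) {
    s <- random_structure(seed)
    G <- compute_acsf(s, params)
    scale_ref <- max(abs(G))
    # rigid rotation of the whole crystal (lattice and coordinates together)
    R <- cspal:::rotation_from_uniforms(c(0.3, 0.7, 0.2))
    s_rot <- s; s_rot$lattice <- s$lattice %*% t(R)
    expect_lt(max(abs(compute_acsf(s_rot, params) - G)) / scale_ref, 1e-8)
    # global translation
    s_tr <- s; s_tr$frac <- (s$frac + matrix(c(.21, .43, .37), nrow(s$frac), 3,
                                             byrow = TRUE)) %% 1
    expect_lt(max(abs(compute_acsf(s_tr, params) - G)) / scale_ref, 1e-8)
    # permutation of identical atoms (swap the two C atoms of molecule 1)
    cs <- which(s$species == "C")[1:2]
    perm <- seq_along(s$species); perm[cs] <- rev(cs)
    s_pm <- s; s_pm$frac <- s$frac[perm, ]
    expect_lt(max(abs(compute_acsf(s_pm, params)[perm, ] - G)) / scale_ref, 1e-8)
    # wrapping
    s_wr <- s; s_wr$frac <- (s$frac + 1) %% 1
    expect_lt(max(abs(compute_acsf(s_wr, params) - G)) / scale_ref, 1e-8)
    # 2x2x1 supercell: per-atom rows replicate
    s_sc <- local({
      f <- s$frac
      fr <- rbind(cbind(f[, 1] / 2, f[, 2] / 2, f[, 3]),
                  cbind(f[, 1] / 2 + .5, f[, 2] / 2, f[, 3]),
                  cbind(f[, 1] / 2, f[, 2] / 2 + .5, f[, 3]),
                  cbind(f[, 1] / 2 + .5, f[, 2] / 2 + .5, f[, 3]))
      latt <- s$lattice; latt[1, ] <- latt[1, ] * 2; latt[2, ] <- latt[2, ] * 2
      xtal(latt, rep(s$species, 4), fr,
           rep(s$mol, 4) + rep(0:3, each = length(s$mol)) * max(s$mol),
           check_overlap = FALSE)
    })
    Gsc <- compute_acsf(s_sc, params)
    expect_lt(max(abs(Gsc - rbind(G, G, G, G))) / scale_ref, 1e-8)
  }
})

test_that("CUR selection matches an independent implementation with tie rules", {
  set.seed(9)
  for (k in 1:20) {
    X <- matrix(rnorm(30 * 60), 30, 60)
    expect_identical(cur_select(X, 10), brute_cur(X, 10))
  }
  # a dominant orthogonal column is picked first
  X <- cbind(matrix(rnorm(40, sd = 0.05), 20, 2), c(rep(10, 10), rep(-10, 10)))
  expect_equal(cur_select(X, 1), 3L)
  # k = ncol returns every column exactly once
  X <- matrix(rnorm(50), 10, 5)
  expect_setequal(cur_select(X, 5), 1:5)
  # rank deficiency: fewer picks with a warning
  X <- cbind(1:6, (1:6) * 2, (1:6) * 3)
  expect_warning(got <- cur_select(X, 3), "rank")
  expect_lt(length(got), 3)
})

test_that("structure descriptors are intensive per-element means", {
  p <- small_landscape_fixture()
  params <- p$small_params
  s <- p$small_ls$structures[[1]]
  v <- structure_descriptor(s, params)
  expect_equal(length(v), sum(lengths(params$per_element)))
  # explicit recomputation through a different path
  G <- compute_acsf(s, params)
  ref <- c(colMeans(G[s$species == "C", params$per_element$C, drop = FALSE]),
           colMeans(G[s$species == "O", params$per_element$O, drop = FALSE]))
  expect_equal(v, ref, tolerance = 1e-12)
  # doubling the cell leaves the vector unchanged
  s2 <- local({
    latt <- s$lattice; latt[1, ] <- latt[1, ] * 2
    f <- s$frac; f[, 1] <- f[, 1] / 2
    xtal(latt, rep(s$species, 2), rbind(f, cbind(f[, 1] + .5, f[, 2], f[, 3])),
         c(s$mol, s$mol + max(s$mol)), check_overlap = FALSE)
  })
  expect_equal(structure_descriptor(s2, params), v, tolerance = 1e-8)
})

test_that("farthest point sampling matches the brute-force max-min oracle", {
  expect_equal(farthest_point_sample(matrix(c(0, 1, 10)), 3, start = 1), c(1L, 3L, 2L))
  expect_equal(farthest_point_sample(matrix(rnorm(10), 5, 2), 1, start = 4), 4L)
  set.seed(31)
  for (k in 1:20) {
    X <- matrix(rnorm(200 * 8), 200, 8)
    start <- sample.int(200, 1)
    expect_identical(farthest_point_sample(X, 20, start = start),
                     as.integer(brute_fps(X, 20, start)))
  }
  # duplicates: zero distances resolved by lowest index
  X <- rbind(c(0, 0), c(0, 0), c(5, 5))
  expect_identical(farthest_point_sample(X, 3, start = 1), c(1L, 3L, 2L))
  # seeded random start is reproducible
  X <- matrix(rnorm(40), 20, 2)
  expect_identical(farthest_point_sample(X, 5, seed = 11),
                   farthest_point_sample(X, 5, seed = 11))
})
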