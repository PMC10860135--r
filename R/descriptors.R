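# Atom-centered symmetry function (ACSF) descriptors, CUR column selection,
# structure-level descriptors and farthest point sampling.

#' Behler cosine cutoff function
#'
#' \code{fc(r) = 0.5 * (cos(pi * r / rc) + 1)} for \code{r < rc}, zero beyond; continuous
#' with a continuous first derivative at the cutoff.
#'
#' @param r distance(s) in Angstrom, non-negative.
#' @param rc cutoff radius in Angstrom (> 0).
#' @export
cutoff_fn <- function(r, rc) {
  if (rc <= 0) stop("cutoff must be positive")
  ifelse(r < rc, 0.5 * (cos(pi * r / rc) + 1), 0)
}

#' Deterministic pool of ACSF parameters
#'
#' Builds the "larger set" of radial and angular symmetry functions from which
#' an informative subset is later chosen by CUR. Radial functions come in a
#' centered family (R_s = 0, geometrically spaced widths) and a shifted family
#' (equally spaced R_s in (0, cutoff), width set from the grid spacing);
#' angular G4 functions cover zeta in {1, 2, 4, 16}, lambda in {-1, +1} and a
#' small set of eta values, one family per element pair. The same pool is used
#' for every central element; per-element column subsets are chosen later.
#'
#' @param elements character vector of element symbols (fixed order defines
#'   descriptor block order everywhere).
#' @param cutoff radial cutoff in Angstrom (default 8, the package-wide
#'   descriptor cutoff).
#' @param n_radial number of radial functions per neighbor element.
#' @param n_ang_eta number of angular eta values.
#' @return object of class `acsf_params` with data.frames `radial`
#'   (el, eta, rs) and `angular` (el1, el2, eta, zeta, lambda); `per_element`
#'   starts as all columns for every element.
#' @export
acsf_param_pool <- function(elements, cutoff = 8, n_radial = 16, n_ang_eta = 2) {
  stopifnot(cutoff > 0, n_radial >= 1, n_ang_eta >= 1)
  elements <- as.character(elements)
  n_cent <- max(1L, n_radial %/% 2L)
  n_shift <- n_radial - n_cent
  # centered: widths geometric from cutoff/2 down to 0.5 A; eta = 1/(2 w^2)
  w <- if (n_cent > 1) (cutoff / 2) * (0.5 * 2 / cutoff)^((seq_len(n_cent) - 1) / (n_cent - 1)) else cutoff / 4
  cent <- data.frame(eta = 1 / (2 * w^2), rs = 0)
  shift <- NULL
  if (n_shift > 0) {
    rs <- cutoff * seq_len(n_shift) / (n_shift + 1)   # largest R_s < cutoff
    drs <- cutoff / (n_shift + 1)
    shift <- data.frame(eta = 1 / (2 * drs^2), rs = rs)
  }
  fam <- rbind(cent, shift)
  radial <- do.call(rbind, lapply(elements, function(el)
    data.frame(el = el, eta = fam$eta, rs = fam$rs, stringsAsFactors = FALSE)))
  pairs <- expand.grid(i = seq_along(elements), j = seq_along(elements))
  pairs <- pairs[pairs$i <= pairs$j, , drop = FALSE]
  eta_ang <- 0.005 * 4^(seq_len(n_ang_eta) - 1)
  ang <- expand.grid(p = seq_len(nrow(pairs)), eta = eta_ang,
                     zeta = c(1, 2, 4, 16), lambda = c(-1, 1))
  angular <- data.frame(el1 = elements[pairs$i[ang$p]],
                        el2 = elements[pairs$j[ang$p]],
                        eta = ang$eta, zeta = ang$zeta, lambda = ang$lambda,
                        stringsAsFactors = FALSE)
  ncol_total <- nrow(radial) + nrow(angular)
  per_element <- stats::setNames(
    rep(list(seq_len(ncol_total)), length(elements)), elements)
  structure(list(elements = elements, cutoff = cutoff,
                 radial = radial, angular = angular,
                 per_element = per_element),
            class = "acsf_params")
}

#' @export
print.acsf_params <- function(x, ...) {
  cat(sprintf("<acsf_params> cutoff %.1f A, %d radial + %d angular functions, elements: %s\n",
              x$cutoff, nrow(x$radial), nrow(x$angular),
              paste(x$elements, collapse = ", ")))
  sel <- vapply(x$per_element, length, 0L)
  cat("  selected per element: ", paste(sprintf("%s=%d", names(sel), sel), collapse = ", "), "\n")
  invisible(x)
}

n_acsf <- function(params) nrow(params$radial) + nrow(params$angular)

#' Compute per-atom ACSF descriptors
#'
#' Radial G2 and angular G4 functions summed over all periodic neighbors
#' within the cutoff. Elements referenced in the parameters but absent from
#' the structure simply contribute zero-valued columns.
#'
#' @param structure an `xtal`; all its elements must appear in
#'   `params$elements`.
#' @param params an `acsf_params` object.
#' @return numeric matrix, one row per atom, one column per pool function
#'   (column subsetting per element happens downstream), with attribute
#'   `species`.
#' @export
compute_acsf <- function(structure, params) {
  stopifnot(inherits(structure, "xtal"), inherits(params, "acsf_params"))
  codes <- match(structure$species, params$elements)
  if (anyNA(codes))
    stop("structure contains element(s) not covered by the descriptor definition: ",
         paste(unique(structure$species[is.na(codes)]), collapse = ", "))
  G <- cpp_acsf(structure$lattice, structure$frac, as.integer(codes),
                params$cutoff,
                as.integer(match(params$radial$el, params$elements)),
                params$radial$eta, params$radial$rs,
                as.integer(match(params$angular$el1, params$elements)),
                as.integer(match(params$angular$el2, params$elements)),
                params$angular$eta, params$angular$zeta, params$angular$lambda)
  attr(G, "species") <- structure$species
  G
}

#' CUR-style iterative descriptor selection
#'
#' Leverage scores are computed from the top right-singular vector; the
#' highest-score column is picked (ties broken by lowest column index), the
#' remaining columns are orthogonalized against the pick, and the procedure
#' repeats k times. Deterministic given its input.
#'
#' @param X numeric matrix (rows: observations, e.g. atoms of the central
#'   element; columns: candidate descriptor functions).
#' @param k number of columns to select (at most `ncol(X)`).
#' @return integer vector of selected column indices in selection order; if
#'   the matrix runs out of rank before k picks, fewer indices are returned
#'   with a warning.
#' @export
cur_select <- function(X, k) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 1, k >= 1, k <= ncol(X))
  R <- X
  picked <- integer(0)
  remaining <- seq_len(ncol(X))
  for (step in seq_len(k)) {
    norms <- colSums(R * R)
    if (max(norms) < 1e-12 * max(1, sum(X^2) / ncol(X))) {
      warning(sprintf("rank deficiency: only %d of %d columns selected", length(picked), k))
      break
    }
    sv <- svd(R, nu = 0, nv = 1)
    lev <- sv$v[, 1]^2
    best <- which(lev == max(lev))[1]   # ties: lowest column index
    picked <- c(picked, remaining[best])
    cvec <- R[, best]
    cn2 <- sum(cvec^2)
    # deflate: orthogonalize all remaining columns against the pick
    R <- R - outer(cvec, as.vector(crossprod(cvec, R)) / cn2)
    R <- R[, -best, drop = FALSE]
    remaining <- remaining[-best]
    if (ncol(R) == 0) break
  }
  picked
}

#' Select per-element descriptor subsets for a training collection
#'
#' For each element, stacks the ACSF rows of that element's atoms across all
#' structures and runs [cur_select()] to pick `k` informative columns.
#'
#' @param structures list of `xtal` objects.
#' @param params `acsf_params` pool.
#' @param k number of functions to keep per element (default 64).
#' @return `params` with `per_element` replaced by the selected column index
#'   vectors (in selection order).
#' @export
select_descriptors <- function(structures, params, k = 64) {
  feats <- lapply(structures, compute_acsf, params = params)
  species <- unlist(lapply(feats, attr, "species"))
  allG <- do.call(rbind, feats)
  for (el in params$elements) {
    rows <- species == el
    if (!any(rows)) next
    Xel <- allG[rows, , drop = FALSE]
    kk <- min(k, ncol(Xel))
    params$per_element[[el]] <- cur_select(Xel, kk)
  }
  params
}

#' Structure-level descriptor vector
#'
#' Per-element mean of the atomic ACSF rows (that element's selected columns),
#' concatenated in the fixed element order of the parameter set; elements
#' absent from the structure contribute a zero block. The mean makes the
#' vector intensive: supercell replicas map to the same point.
#'
#' @param structure an `xtal`.
#' @param params `acsf_params` (with per-element selections).
#' @param G optional precomputed output of [compute_acsf()] for `structure`.
#' @return numeric vector of fixed length for a given `params`.
#' @export
structure_descriptor <- function(structure, params, G = NULL) {
  if (is.null(G)) G <- compute_acsf(structure, params)
  species <- attr(G, "species")
  blocks <- lapply(params$elements, function(el) {
    cols <- params$per_element[[el]]
    rows <- species == el
    if (!any(rows)) return(numeric(length(cols)))
    colMeans(G[rows, cols, drop = FALSE])
  })
  unlist(blocks, use.names = FALSE)
}

#' Structure descriptors for a collection
#' @param structures list of `xtal` objects (or a `landscape`).
#' @param params `acsf_params`.
#' @return matrix, one row per structure.
#' @export
structure_descriptor_matrix <- function(structures, params) {
  if (inherits(structures, "landscape")) structures <- structures$structures
  t(vapply(structures, structure_descriptor, params = params,
           numeric(sum(lengths(params$per_element)))))
}

#' Farthest point sampling
#'
#' Greedy max-min selection under Euclidean distance: each pick is the point
#' farthest from the already-selected set. Ties are broken by lowest index;
#' duplicate points are allowed.
#'
#' @param X numeric matrix, one row per point.
#' @param m number of points to select.
#' @param start index of the first point, or `"random"` (seeded).
#' @param seed RNG seed used only when `start = "random"`.
#' @return integer vector of m row indices in selection order.
#' @export
farthest_point_sample <- function(X, m, start = "random", seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(m >= 1, m <= n)
  if (identical(start, "random")) {
    start <- with_local_seed(as.integer(seed), sample.int(n, 1))
  }
  start <- as.integer(start)
  stopifnot(start >= 1, start <= n)
  sel <- integer(m)
  sel[1] <- start
  if (m == 1) return(sel)
  d2 <- rowSums((X - matrix(X[start, ], n, ncol(X), byrow = TRUE))^2)
  d2[start] <- -Inf                     # selected points never re-picked
  for (t in 2:m) {
    nxt <- which(d2 == max(d2))[1]
    sel[t] <- nxt
    nd2 <- rowSums((X - matrix(X[nxt, ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, nd2)
    d2[nxt] <- -Inf
  }
  sel
}

# per-element standardization constants over a training set of feature rows
acsf_standardizer <- function(feats, params) {
  species <- unlist(lapply(feats, attr, "species"))
  allG <- do.call(rbind, feats)
  out <- list()
  for (el in params$elements) {
    rows <- species == el
    cols <- params$per_element[[el]]
    if (!any(rows)) {
      out[[el]] <- list(mean = numeric(length(cols)), sd = rep(1, length(cols)),
                        keep = seq_along(cols))
      next
    }
    Xel <- allG[rows, cols, drop = FALSE]
    mu <- colMeans(Xel)
    sdv <- apply(Xel, 2, stats::sd)
    if (nrow(Xel) == 1) sdv <- rep(0, length(mu))
    keep <- which(sdv > 1e-10)
    if (length(keep) < length(sdv))
      warning(sprintf("dropping %d constant descriptor column(s) for element %s",
                      length(sdv) - length(keep), el))
    if (length(keep) == 0) keep <- seq_along(mu)  # degenerate: keep raw
    sdv[sdv <= 1e-10] <- 1
    out[[el]] <- list(mean = mu, sd = sdv, keep = keep)
  }
  out
}

# apply selection + standardization to one structure's raw pool matrix,
# returning a list of per-element matrices (rows: that element's atoms)
standardized_blocks <- function(G, params, std) {
  species <- attr(G, "species")
  out <- list()
  for (el in params$elements) {
    rows <- which(species == el)
    if (!length(rows)) next
    cols <- params$per_element[[el]]
    Xel <- G[rows, cols, drop = FALSE]
    s <- std[[el]]
    Xel <- sweep(Xel, 2, s$mean, "-")
    Xel <- sweep(Xel, 2, s$sd, "/")
    out[[el]] <- Xel[, s$keep, drop = FALSE]
  }
  out
}
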