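# Committee of per-element feed-forward atomic-energy networks with
# query-by-committee uncertainty. The structure energy is the sum of atomic
# subnet outputs divided by the number of molecules Z, so all energies are in
# kJ/mol per molecule. Member diversity comes from seeded weight
# initialization and per-member train/validation splits.

arch_dims <- function(d_in, hidden) {
  h1 <- hidden[1]; h2 <- hidden[2]
  c(W1 = d_in * h1, b1 = h1, W2 = h1 * h2, b2 = h2, w3 = h2, b3 = 1)
}

init_member_par <- function(dims_per_el, hidden, seed) {
  with_local_seed(seed, {
    unlist(lapply(dims_per_el, function(d) {
      h1 <- hidden[1]; h2 <- hidden[2]
      c(stats::rnorm(d * h1, sd = sqrt(1 / d)), rep(0, h1),
        stats::rnorm(h1 * h2, sd = sqrt(1 / h1)), rep(0, h2),
        stats::rnorm(h2, sd = sqrt(1 / h2)), 0)
    }))
  })
}

# split the flat parameter vector into per-element weight matrices
unpack_par <- function(par, dims_per_el, hidden) {
  h1 <- hidden[1]; h2 <- hidden[2]
  out <- list(); off <- 0L
  for (el in names(dims_per_el)) {
    d <- dims_per_el[[el]]
    take <- function(n) { v <- par[(off + 1):(off + n)]; off <<- off + n; v }
    out[[el]] <- list(W1 = matrix(take(d * h1), d, h1), b1 = take(h1),
                      W2 = matrix(take(h1 * h2), h1, h2), b2 = take(h2),
                      w3 = take(h2), b3 = take(1))
  }
  out
}

# forward pass + optional backprop over stacked per-element atom matrices.
# xs: list per element of (rows: atoms) matrices; sidx: structure index per
# row; zs: molecules per structure; returns per-structure energies (sum of
# atomic outputs / Z) and, if y given, loss and gradient.
net_eval <- function(par, xs, sidx, zs, nstruct, dims_per_el, hidden, y = NULL,
                     lambda = 1e-6) {
  W <- unpack_par(par, dims_per_el, hidden)
  pred <- numeric(nstruct)
  cache <- list()
  for (el in names(xs)) {
    w <- W[[el]]; X <- xs[[el]]
    Z1 <- sweep(X %*% w$W1, 2, w$b1, "+"); A1 <- tanh(Z1)
    Z2 <- sweep(A1 %*% w$W2, 2, w$b2, "+"); A2 <- tanh(Z2)
    out <- drop(A2 %*% w$w3) + w$b3
    agg <- rowsum(out, sidx[[el]], reorder = FALSE)
    pred[as.integer(rownames(agg))] <- pred[as.integer(rownames(agg))] + agg[, 1]
    cache[[el]] <- list(A1 = A1, A2 = A2)
  }
  pred <- pred / zs
  if (is.null(y)) return(list(pred = pred))
  r <- pred - y
  loss <- mean(r^2) + lambda * sum(par^2)
  dpred <- 2 * r / nstruct / zs          # d loss / d (atomic-output sum)
  grad <- numeric(0)
  for (el in names(dims_per_el)) {
    w <- W[[el]]
    if (is.null(xs[[el]])) {             # element absent from this subset
      grad <- c(grad, numeric(sum(arch_dims(dims_per_el[[el]], hidden))))
      next
    }
    X <- xs[[el]]; A1 <- cache[[el]]$A1; A2 <- cache[[el]]$A2
    g3 <- dpred[sidx[[el]]]
    dw3 <- drop(crossprod(A2, g3)); db3 <- sum(g3)
    dZ2 <- (g3 %o% w$w3) * (1 - A2^2)
    dW2 <- crossprod(A1, dZ2); db2 <- colSums(dZ2)
    dZ1 <- (dZ2 %*% t(w$W2)) * (1 - A1^2)
    dW1 <- crossprod(X, dZ1); db1 <- colSums(dZ1)
    grad <- c(grad, as.vector(dW1), db1, as.vector(dW2), db2, dw3, db3)
  }
  grad <- grad + 2 * lambda * par
  list(pred = pred, loss = loss, grad = grad)
}

subset_xs <- function(blocks_per_struct, zs, keep) {
  # blocks_per_struct: list (per structure) of per-element standardized
  # matrices; build stacked matrices restricted to structures in `keep`
  els <- unique(unlist(lapply(blocks_per_struct, names)))
  xs <- list(); sidx <- list()
  for (el in els) {
    mats <- list(); idx <- list()
    for (s in keep) {
      B <- blocks_per_struct[[s]][[el]]
      if (is.null(B)) next
      mats[[length(mats) + 1]] <- B
      idx[[length(idx) + 1]] <- rep(s, nrow(B))
    }
    if (length(mats)) {
      xs[[el]] <- do.call(rbind, mats)
      sidx[[el]] <- unlist(idx)
    }
  }
  list(xs = xs, sidx = sidx)
}

train_member <- function(par0, blocks, zs, y, dims_per_el, hidden, seed,
                         lambda, chunk_iters, max_chunks, patience) {
  n <- length(y)
  # bootstrap resample per member; out-of-bag structures form the validation
  # set, so members see genuinely different data and the committee spread
  # does not collapse
  split <- with_local_seed(seed, {
    if (n >= 10) {
      bag <- sort(unique(sample.int(n, n, replace = TRUE)))
      oob <- setdiff(seq_len(n), bag)
      if (!length(oob)) {
        oob <- bag[length(bag)]
        bag <- bag[-length(bag)]
      }
      list(train = bag, val = oob)
    } else list(train = seq_len(n), val = integer(0))
  })
  tr <- subset_xs(blocks, zs, split$train)
  # remap structure indices to positions within the training subset
  remap <- integer(n); remap[split$train] <- seq_along(split$train)
  sidx_tr <- lapply(tr$sidx, function(v) remap[v])
  ytr <- y[split$train]; ztr <- zs[split$train]
  ntr <- length(split$train)
  fn <- function(p) net_eval(p, tr$xs, sidx_tr, ztr, ntr, dims_per_el, hidden,
                             y = ytr, lambda = lambda)$loss
  gr <- function(p) net_eval(p, tr$xs, sidx_tr, ztr, ntr, dims_per_el, hidden,
                             y = ytr, lambda = lambda)$grad
  has_val <- length(split$val) > 0
  if (has_val) {
    va <- subset_xs(blocks, zs, split$val)
    remv <- integer(n); remv[split$val] <- seq_along(split$val)
    sidx_va <- lapply(va$sidx, function(v) remv[v])
    yva <- y[split$val]; zva <- zs[split$val]
    val_loss <- function(p) {
      pr <- net_eval(p, va$xs, sidx_va, zva, length(split$val), dims_per_el,
                     hidden)$pred
      mean((pr - yva)^2)
    }
  }
  par <- par0
  best_par <- par
  best_val <- if (has_val) val_loss(par) else Inf
  bad <- 0L
  for (ch in seq_len(max_chunks)) {
    # small factr: restarting L-BFGS loses curvature memory, and the default
    # relative-reduction test would then fire before real convergence
    res <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = chunk_iters, factr = 1e3))
    par <- res$par
    if (has_val) {
      vl <- val_loss(par)
      if (vl < best_val - 1e-12) { best_val <- vl; best_par <- par; bad <- 0L }
      else bad <- bad + 1L
      if (bad >= patience) break
    } else best_par <- par
    if (res$convergence == 0 && ch > 1) break
  }
  best_par
}

#' Fit a committee neural-network potential
#'
#' Trains `n_members` independent per-element feed-forward atomic-energy
#' networks on per-molecule energies. Each member gets its own seeded weight
#' initialization and its own bootstrap resample of the training structures
#' (out-of-bag structures serve as its validation set for early stopping).
#' Predictions average the members; the
#' committee disagreement (sample standard deviation) is the query-by-
#' committee uncertainty.
#'
#' In `"delta"` mode the labels are energy corrections (target minus
#' baseline); in `"total"` mode they are total lattice energies, which are
#' first centered by least-squares per-element atomic reference energies.
#' Internally labels are standardized for optimization; predictions are
#' returned on the original kJ/mol-per-molecule scale.
#'
#' @param structures list of `xtal` training structures.
#' @param labels numeric energies, kJ/mol per molecule (corrections in delta
#'   mode).
#' @param descriptor `acsf_params` with per-element column selections.
#' @param mode `"delta"` or `"total"`.
#' @param n_members committee size (>= 2; default 6).
#' @param hidden hidden-layer widths of each atomic subnet (default 16, 16;
#'   tanh activations).
#' @param seed master seed; member seeds are derived substreams.
#' @param features optional precomputed list of [compute_acsf()] matrices.
#' @param weight_decay L2 penalty on weights.
#' @param chunk_iters,max_chunks,patience optimizer schedule: L-BFGS runs in
#'   chunks of `chunk_iters` iterations, up to `max_chunks`, stopping after
#'   `patience` chunks without validation improvement.
#' @param warm_start optional existing `cnnp` whose member weights (and
#'   frozen standardization) initialize the fit.
#' @param keep_data store training structures/features in the object (needed
#'   for later on-the-fly updates; default `TRUE`).
#' @return object of class `cnnp`.
#' @export
cnnp <- function(structures, labels, descriptor, mode = c("delta", "total"),
                 n_members = 6, hidden = c(16, 16), seed = 1,
                 features = NULL, weight_decay = 1e-6,
                 chunk_iters = 150, max_chunks = 6, patience = 2,
                 warm_start = NULL, keep_data = TRUE) {
  mode <- match.arg(mode)
  n <- length(structures)
  if (n < max(10, n_members))
    stop(sprintf("need at least max(10, n_members) = %d training examples, got %d",
                 max(10, n_members), n))
  labels <- as.numeric(labels)
  if (any(!is.finite(labels))) stop("non-finite training labels")
  if (n_members < 2) stop("committee needs at least 2 members")
  if (is.null(features))
    features <- lapply(structures, compute_acsf, params = descriptor)
  zs <- vapply(structures, function(s) max(s$mol), 0L)
  elements_present <- sort(unique(unlist(lapply(features, attr, "species"))))

  # per-element atomic reference energies (total mode only)
  ref <- NULL
  y <- labels
  if (mode == "total") {
    counts <- t(vapply(structures, function(s)
      vapply(descriptor$elements, function(el) sum(s$species == el), 0),
      numeric(length(descriptor$elements))))
    A <- counts / zs
    fit <- stats::lm.fit(A, y)
    ref <- stats::setNames(ifelse(is.na(fit$coefficients), 0, fit$coefficients),
                           descriptor$elements)
    y <- y - drop(A %*% ref)
  }
  mu <- mean(y)
  s_lab <- stats::sd(y)
  if (!is.finite(s_lab) || s_lab < 1e-8) s_lab <- 1
  yn <- (y - mu) / s_lab

  if (!is.null(warm_start)) {
    std <- warm_start$std              # frozen so old weights stay meaningful
  } else {
    std <- acsf_standardizer(features, descriptor)
  }
  blocks <- lapply(features, standardized_blocks, params = descriptor, std = std)
  dims_per_el <- stats::setNames(lapply(descriptor$elements, function(el)
    length(std[[el]]$keep)), descriptor$elements)
  dims_per_el <- dims_per_el[vapply(dims_per_el, `>`, TRUE, 0)]

  members <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    mseed <- substream_seed(seed, "member", m)
    par0 <- if (!is.null(warm_start) && m <= length(warm_start$members))
      warm_start$members[[m]] else init_member_par(dims_per_el, hidden, mseed)
    members[[m]] <- unname(train_member(par0, blocks, zs, yn, dims_per_el, hidden,
                                 seed = substream_seed(mseed, "split"),
                                 lambda = weight_decay,
                                 chunk_iters = chunk_iters,
                                 max_chunks = max_chunks, patience = patience))
  }
  model <- structure(list(descriptor = descriptor, std = std, mode = mode,
                          hidden = hidden, dims_per_el = dims_per_el,
                          members = members, n_members = n_members,
                          label_mu = mu, label_s = s_lab, ref = ref,
                          elements_trained = elements_present,
                          seed = seed, units = "kJ/mol/molecule",
                          weight_decay = weight_decay,
                          train = if (keep_data)
                            list(structures = structures, labels = labels,
                                 features = features) else NULL),
                     class = "cnnp")
  model$fitted_values <- predict(model, structures, features = features)$mean
  model
}

member_predictions <- function(model, structure, G = NULL) {
  if (!all(structure$species %in% model$elements_trained))
    stop("out-of-scope structure: element(s) unseen in training: ",
         paste(setdiff(unique(structure$species), model$elements_trained),
               collapse = ", "))
  if (is.null(G)) G <- compute_acsf(structure, model$descriptor)
  blocks <- standardized_blocks(G, model$descriptor, model$std)
  z <- max(structure$mol)
  xs <- blocks[names(blocks) %in% names(model$dims_per_el)]
  sidx <- lapply(xs, function(B) rep(1L, nrow(B)))
  vals <- vapply(model$members, function(par)
    net_eval(par, xs, sidx, z, 1L, model$dims_per_el, model$hidden)$pred,
    numeric(1))
  out <- model$label_mu + model$label_s * vals
  if (model$mode == "total") {
    cnt <- vapply(model$descriptor$elements, function(el)
      sum(structure$species == el), 0)
    out <- out + sum(cnt * model$ref) / z
  }
  out
}

#' Predict energies with committee uncertainty
#'
#' The committee mean is the average of member predictions; the uncertainty
#' is their sample standard deviation (denominator n - 1). In delta mode the
#' returned mean is the energy correction only (see [corrected_energy()] for
#' the baseline-shifted value).
#'
#' @param object a `cnnp`.
#' @param newdata an `xtal` or list of them.
#' @param features optional list of precomputed [compute_acsf()] matrices.
#' @param ... unused.
#' @return data.frame with columns `mean` and `sigma` (kJ/mol per molecule)
#'   and attribute `"members"`: the matrix of per-member predictions.
#' @export
predict.cnnp <- function(object, newdata, features = NULL, ...) {
  if (inherits(newdata, "xtal")) newdata <- list(newdata)
  M <- matrix(NA_real_, length(newdata), object$n_members)
  for (i in seq_along(newdata))
    M[i, ] <- member_predictions(object, newdata[[i]],
                                 G = if (!is.null(features)) features[[i]])
  res <- data.frame(mean = rowMeans(M), sigma = apply(M, 1, stats::sd))
  attr(res, "members") <- M
  res
}

#' Baseline-corrected energy with uncertainty
#'
#' For a delta-mode committee: `mean = e_baseline + mean(delta members)`; the
#' uncertainty is unchanged because the baseline is deterministic.
#'
#' @param model a delta-mode `cnnp`.
#' @param structure an `xtal`.
#' @param e_baseline baseline energy, kJ/mol per molecule.
#' @param G optional precomputed descriptor matrix.
#' @return list with `mean`, `sigma`, `member_values` (each baseline-shifted).
#' @export
corrected_energy <- function(model, structure, e_baseline, G = NULL) {
  if (model$mode != "delta") stop("corrected_energy requires a delta-mode committee")
  if (!is.finite(e_baseline)) stop("e_baseline must be finite")
  vals <- member_predictions(model, structure, G)
  list(mean = e_baseline + mean(vals), sigma = stats::sd(vals),
       member_values = e_baseline + vals)
}

#' @export
print.cnnp <- function(x, ...) {
  cat(sprintf("<cnnp> %d-member committee, mode '%s', hidden %s, elements: %s\n",
              x$n_members, x$mode, paste(x$hidden, collapse = "x"),
              paste(x$elements_trained, collapse = ", ")))
  if (!is.null(x$train))
    cat(sprintf("  trained on %d structures (labels sd %.3f %s)\n",
                length(x$train$labels), x$label_s, x$units))
  invisible(x)
}

#' @export
summary.cnnp <- function(object, ...) {
  res <- if (!is.null(object$train))
    object$fitted_values - object$train$labels else NULL
  out <- list(n_members = object$n_members, mode = object$mode,
              elements = object$elements_trained,
              n_train = if (!is.null(object$train)) length(object$train$labels) else NA,
              train_mae = if (!is.null(res)) mean(abs(res)) else NA,
              train_rmse = if (!is.null(res)) sqrt(mean(res^2)) else NA)
  class(out) <- "summary.cnnp"
  out
}

#' @export
print.summary.cnnp <- function(x, ...) {
  cat(sprintf("Committee NNP: %d members, mode '%s'\n", x$n_members, x$mode))
  cat(sprintf("  training set: %d structures, MAE %.4f, RMSE %.4f kJ/mol\n",
              x$n_train, x$train_mae, x$train_rmse))
  invisible(x)
}

#' @export
residuals.cnnp <- function(object, ...) {
  if (is.null(object$train)) stop("model was fitted with keep_data = FALSE")
  object$fitted_values - object$train$labels
}

#' @export
plot.cnnp <- function(x, ...) {
  if (is.null(x$train)) stop("model was fitted with keep_data = FALSE")
  graphics::plot(x$train$labels, x$fitted_values,
                 xlab = sprintf("label (%s)", x$units),
                 ylab = "committee mean prediction",
                 main = "committee fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

# --------------------------------------------------------------------------
# checkpointing: JSON metadata + one binary weight blob per member.
# Floating-point metadata goes through C99 hex-float strings so the text
# checkpoint restores bitwise-identical values.

num_hex <- function(x) sprintf("%a", as.numeric(x))
hex_num <- function(s) as.numeric(s)

#' Save a committee checkpoint
#' @param model a `cnnp`.
#' @param dir checkpoint directory (created).
#' @export
save_cnnp <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- model$descriptor
  meta <- list(mode = model$mode, hidden = model$hidden,
               n_members = model$n_members,
               label_mu = num_hex(model$label_mu),
               label_s = num_hex(model$label_s),
               ref = as.list(stats::setNames(num_hex(model$ref),
                                             names(model$ref))),
               elements_trained = model$elements_trained,
               seed = model$seed, units = model$units,
               weight_decay = model$weight_decay,
               dims_per_el = model$dims_per_el,
               descriptor = list(elements = d$elements,
                                 cutoff = num_hex(d$cutoff),
                                 radial = list(el = d$radial$el,
                                               eta = num_hex(d$radial$eta),
                                               rs = num_hex(d$radial$rs)),
                                 angular = list(el1 = d$angular$el1,
                                                el2 = d$angular$el2,
                                                eta = num_hex(d$angular$eta),
                                                zeta = num_hex(d$angular$zeta),
                                                lambda = num_hex(d$angular$lambda)),
                                 per_element = d$per_element),
               std = lapply(model$std, function(s)
                 list(mean = num_hex(s$mean), sd = num_hex(s$sd),
                      keep = s$keep)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (m in seq_len(model$n_members)) {
    con <- file(file.path(dir, sprintf("member%02d.bin", m)), "wb")
    writeBin(model$members[[m]], con)
    close(con)
  }
  if (!is.null(model$train)) {
    write_xyz(model$train$structures, file.path(dir, "train.xyz"))
    utils::write.csv(data.frame(id = vapply(model$train$structures,
                                            function(s) s$id, ""),
                                label = num_hex(model$train$labels)),
                     file.path(dir, "train_labels.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(dir)
}

#' Load a committee checkpoint
#'
#' Restores bitwise-identical predictions (weights round-trip through full
#' double precision).
#'
#' @param dir checkpoint directory written by [save_cnnp()].
#' @export
load_cnnp <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  params <- structure(list(elements = meta$descriptor$elements,
                           cutoff = hex_num(meta$descriptor$cutoff),
                           radial = data.frame(el = meta$descriptor$radial$el,
                                               eta = hex_num(meta$descriptor$radial$eta),
                                               rs = hex_num(meta$descriptor$radial$rs),
                                               stringsAsFactors = FALSE),
                           angular = data.frame(el1 = meta$descriptor$angular$el1,
                                                el2 = meta$descriptor$angular$el2,
                                                eta = hex_num(meta$descriptor$angular$eta),
                                                zeta = hex_num(meta$descriptor$angular$zeta),
                                                lambda = hex_num(meta$descriptor$angular$lambda),
                                                stringsAsFactors = FALSE),
                           per_element = lapply(meta$descriptor$per_element,
                                                as.integer)),
                      class = "acsf_params")
  std <- lapply(meta$std, function(s)
    list(mean = hex_num(s$mean), sd = hex_num(s$sd),
         keep = as.integer(s$keep)))
  members <- list()
  for (m in seq_len(meta$n_members)) {
    f <- file.path(dir, sprintf("member%02d.bin", m))
    con <- file(f, "rb")
    members[[m]] <- readBin(con, "double", n = file.size(f) / 8)
    close(con)
  }
  train <- NULL
  if (file.exists(file.path(dir, "train.xyz"))) {
    structs <- read_xyz(file.path(dir, "train.xyz"))
    labs <- utils::read.csv(file.path(dir, "train_labels.csv"),
                            colClasses = "character")
    train <- list(structures = structs, labels = hex_num(labs$label),
                  features = lapply(structs, compute_acsf, params = params))
  }
  model <- structure(list(descriptor = params, std = std, mode = meta$mode,
                          hidden = as.numeric(meta$hidden),
                          dims_per_el = lapply(meta$dims_per_el, as.integer),
                          members = members, n_members = meta$n_members,
                          label_mu = hex_num(meta$label_mu),
                          label_s = hex_num(meta$label_s),
                          ref = if (length(meta$ref))
                            stats::setNames(hex_num(unlist(meta$ref)),
                                            names(meta$ref)) else NULL,
                          elements_trained = meta$elements_trained,
                          seed = meta$seed, units = meta$units,
                          weight_decay = meta$weight_decay,
                          train = train),
                     class = "cnnp")
  if (!is.null(train))
    model$fitted_values <- predict(model, train$structures,
                                   features = train$features)$mean
  model
}
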