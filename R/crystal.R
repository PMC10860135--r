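#' @useDynLib cspal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                   S = 32.06, Cl = 35.45, X = 10.0)

# amu / A^3 -> g / cm^3
AMU_PER_A3_TO_G_CM3 <- 1.66053906660

#' Build a lattice matrix from cell parameters
#'
#' Rows of the returned 3x3 matrix are the cell vectors a, b, c (row-vector
#' convention: `cart = frac %*% lattice`). The standard orientation places a
#' along x and b in the xy plane.
#'
#' @param a,b,c cell lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @return 3x3 numeric matrix with positive determinant.
#' @export
lattice_matrix <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  al <- alpha * pi / 180; be <- beta * pi / 180; ga <- gamma * pi / 180
  v2 <- 1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 + 2 * cos(al) * cos(be) * cos(ga)
  if (v2 <= 0) stop("degenerate cell: angles give non-positive volume")
  cx <- c * cos(be)
  cy <- c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- c * sqrt(v2) / sin(ga)
  rbind(c(a, 0, 0),
        c(b * cos(ga), b * sin(ga), 0),
        c(cx, cy, cz))
}

#' Cell parameters (lengths and angles) of a lattice matrix
#' @param latt 3x3 lattice matrix (rows are cell vectors).
#' @return named numeric vector a, b, c (Angstrom), alpha, beta, gamma (deg).
#' @export
cell_params <- function(latt) {
  len <- sqrt(rowSums(latt^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  c(a = len[1], b = len[2], c = len[3],
    alpha = ang(latt[2, ], latt[3, ]),
    beta  = ang(latt[1, ], latt[3, ]),
    gamma = ang(latt[1, ], latt[2, ]))
}

#' Cell volume in cubic Angstrom
#' @param latt 3x3 lattice matrix.
#' @export
cell_volume <- function(latt) abs(det(latt))

#' Construct a periodic crystal structure of rigid molecules
#'
#' Fractional coordinates are wrapped into `[0, 1)`. The molecule partition is
#' supplied by the caller (molecules are treated as given rigid units, never
#' inferred by bond perception). By default, construction fails if two atoms
#' of different molecules come closer than the hard-core tolerance, which
#' protects downstream energy oracles from pathological inputs.
#'
#' @param lattice 3x3 lattice matrix, rows are cell vectors (Angstrom);
#'   determinant must be positive.
#' @param species character vector of element symbols, one per atom.
#' @param frac n x 3 matrix of fractional coordinates.
#' @param mol integer molecule index per atom (1..Z, every index non-empty).
#' @param id opaque structure label.
#' @param check_overlap if `TRUE`, error when any intermolecular distance is
#'   below `hardcore`.
#' @param hardcore hard-core overlap tolerance in Angstrom (default 0.7).
#' @return object of class `xtal`.
#' @export
xtal <- function(lattice, species, frac, mol = rep(1L, length(species)),
                 id = "structure", check_overlap = TRUE, hardcore = 0.7) {
  lattice <- as.matrix(lattice)
  frac <- as.matrix(frac)
  storage.mode(lattice) <- "double"
  storage.mode(frac) <- "double"
  if (!all(dim(lattice) == c(3, 3))) stop("lattice must be 3x3")
  if (det(lattice) <= 0) stop("lattice must be right-handed (determinant > 0)")
  n <- length(species)
  if (nrow(frac) != n) stop("frac must have one row per species entry")
  mol <- as.integer(mol)
  if (length(mol) != n) stop("mol must have one entry per atom")
  z <- max(mol)
  if (!setequal(unique(mol), seq_len(z))) stop("every molecule index 1..Z must be non-empty")
  frac <- frac - floor(frac)            # wrap into [0, 1)
  s <- structure(list(lattice = lattice, species = as.character(species),
                      frac = frac, mol = mol, id = as.character(id)),
                 class = "xtal")
  if (check_overlap && n > 1) {
    md <- min_intermolecular_distance(s, max(2 * hardcore, 2))
    if (is.finite(md) && md < hardcore)
      stop(sprintf("intermolecular hard-core overlap: min distance %.3f A < %.2f A", md, hardcore))
  }
  s
}

#' @export
print.xtal <- function(x, ...) {
  cp <- cell_params(x$lattice)
  cat(sprintf("<xtal '%s'> %d atoms, %d molecule(s)\n", x$id,
              length(x$species), max(x$mol)))
  cat(sprintf("  cell: a=%.3f b=%.3f c=%.3f alpha=%.2f beta=%.2f gamma=%.2f  V=%.2f A^3\n",
              cp["a"], cp["b"], cp["c"], cp["alpha"], cp["beta"], cp["gamma"],
              cell_volume(x$lattice)))
  invisible(x)
}

#' Fractional to Cartesian coordinates
#' @param structure an `xtal`, or a 3x3 lattice matrix.
#' @param frac optional n x 3 fractional coordinates (defaults to the
#'   structure's own atoms).
#' @return n x 3 matrix of Cartesian coordinates in Angstrom.
#' @export
frac_to_cart <- function(structure, frac = NULL) {
  latt <- if (inherits(structure, "xtal")) structure$lattice else as.matrix(structure)
  if (abs(det(latt)) < 1e-12) stop("degenerate cell: singular lattice")
  if (is.null(frac)) frac <- structure$frac
  as.matrix(frac) %*% latt
}

#' Cartesian to fractional coordinates
#' @inheritParams frac_to_cart
#' @param cart n x 3 Cartesian coordinates (Angstrom).
#' @export
cart_to_frac <- function(structure, cart) {
  latt <- if (inherits(structure, "xtal")) structure$lattice else as.matrix(structure)
  if (abs(det(latt)) < 1e-12) stop("degenerate cell: singular lattice")
  as.matrix(cart) %*% solve(latt)
}

#' Periodic neighbor list
#'
#' Every periodic-image pair with distance at most `cutoff`, including images
#' of the same atom, excluding the self pair at zero offset. Images are
#' replicated as far as needed, so cells thinner than twice the cutoff are
#' handled exactly. The list is symmetric: for each (i, j, image) the entry
#' (j, i, -image) is also present.
#'
#' @param structure an `xtal`.
#' @param cutoff radial cutoff in Angstrom (> 0).
#' @return data.frame with columns i, j (1-based atom indices), ia, ib, ic
#'   (image offsets), d (distance, Angstrom) and dx, dy, dz (Cartesian
#'   displacement from i to j's image).
#' @export
neighbor_list <- function(structure, cutoff) {
  stopifnot(inherits(structure, "xtal"), cutoff > 0)
  res <- cpp_neighbor_list(structure$lattice, structure$frac, cutoff)
  as.data.frame(res)
}

# minimum-image convention: for same-molecule pairs the nearest periodic
# copy is the bonded (intramolecular) one and is skipped
min_intermolecular_distance <- function(structure, cutoff = 3) {
  cpp_min_intermol_dist(structure$lattice, structure$frac,
                        as.integer(structure$mol), cutoff)
}

#' Crystal density in g/cm^3
#' @param structure an `xtal`.
#' @export
xtal_density <- function(structure) {
  m <- ATOMIC_MASSES[structure$species]
  if (anyNA(m)) stop("unknown element(s): ",
                     paste(unique(structure$species[is.na(m)]), collapse = ", "))
  sum(m) * AMU_PER_A3_TO_G_CM3 / cell_volume(structure$lattice)
}

# ---------------------------------------------------------------------------
# extended-XYZ I/O
# dialect: comment line carries Lattice="ax ay az bx by bz cx cy cz" and
# id=...; per-atom columns are: species x y z mol_id

fmt_num <- function(x) formatC(x, format = "g", digits = 15)

#' Write structures to an extended-XYZ file
#' @param structures an `xtal` or list of them.
#' @param path output file path.
#' @export
write_xyz <- function(structures, path) {
  if (inherits(structures, "xtal")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    cart <- frac_to_cart(s)
    writeLines(as.character(length(s$species)), con)
    writeLines(sprintf('Lattice="%s" Properties=species:S:1:pos:R:3:mol_id:I:1 id=%s',
                       paste(fmt_num(t(s$lattice)), collapse = " "), s$id), con)
    writeLines(sprintf("%s %s %s %s %d", s$species,
                       fmt_num(cart[, 1]), fmt_num(cart[, 2]), fmt_num(cart[, 3]),
                       s$mol), con)
  }
  invisible(path)
}

#' Read structures from an extended-XYZ file
#'
#' @param path input file path.
#' @param single_molecule_fallback if `TRUE`, files whose atom lines lack the
#'   mol_id column are read as one molecule per structure; if `FALSE`
#'   (default) such files are an error.
#' @return list of `xtal` objects.
#' @export
read_xyz <- function(path, single_molecule_fallback = FALSE) {
  lines <- readLines(path)
  out <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[ln]))
      stop(sprintf("parse error at line %d: expected atom count", ln))
    nat <- as.integer(lines[ln])
    if (ln + 1 + nat > length(lines))
      stop(sprintf("parse error at line %d: truncated frame (%d atoms declared)", ln, nat))
    comment <- lines[ln + 1]
    m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(m) < 2)
      stop(sprintf("parse error at line %d: missing or malformed Lattice", ln + 1))
    lv <- suppressWarnings(as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]]))
    if (length(lv) != 9 || anyNA(lv))
      stop(sprintf("parse error at line %d: lattice needs 9 numbers", ln + 1))
    latt <- matrix(lv, 3, 3, byrow = TRUE)
    idm <- regmatches(comment, regexec('id=(\\S+)', comment))[[1]]
    id <- if (length(idm) >= 2) idm[2] else sprintf("frame%d", length(out) + 1)
    body <- lines[(ln + 2):(ln + 1 + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    nf <- lengths(toks)
    if (any(nf < 4))
      stop(sprintf("parse error at line %d: atom line needs species x y z [mol_id]",
                   ln + 1 + which(nf < 4)[1]))
    species <- vapply(toks, `[[`, "", 1)
    cart <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (all(nf >= 5)) {
      mol <- as.integer(vapply(toks, `[[`, "", 5))
    } else if (single_molecule_fallback) {
      mol <- rep(1L, nat)
    } else {
      stop(sprintf("parse error at line %d: missing mol_id column (set single_molecule_fallback = TRUE to read as one molecule)",
                   ln + 2))
    }
    frac <- cart %*% solve(latt)
    out[[length(out) + 1]] <- xtal(latt, species, frac, mol, id = id,
                                   check_overlap = FALSE)
    ln <- ln + 2L + nat
  }
  out
}

# ---------------------------------------------------------------------------
# Landscape container

#' Build a landscape from structures and energies
#'
#' A landscape is an ordered collection of locally minimized candidate crystal
#' structures with baseline (and optionally target) lattice energies, the
#' package-wide energy unit being kJ/mol per molecule.
#'
#' @param structures list of `xtal` objects with unique ids.
#' @param e_baseline baseline lattice energies (kJ/mol per molecule).
#' @param e_target optional target energies (kJ/mol per molecule), NA if
#'   unknown.
#' @return object of class `landscape`.
#' @export
landscape <- function(structures, e_baseline, e_target = rep(NA_real_, length(structures))) {
  stopifnot(length(structures) == length(e_baseline),
            length(structures) == length(e_target))
  structures <- unname(structures)
  ids <- vapply(structures, function(s) s$id, "")
  if (anyDuplicated(ids)) stop("landscape ids must be unique")
  structure(list(structures = structures,
                 ids = ids,
                 e_baseline = as.numeric(e_baseline),
                 e_target = as.numeric(e_target),
                 density = vapply(structures, xtal_density, 0),
                 units_note = "kJ/mol/molecule"),
            class = "landscape")
}

#' @export
length.landscape <- function(x) length(x$structures)

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d entries (energies in %s)\n", length(x), x$units_note))
  cat(sprintf("  e_baseline: [%.3f, %.3f]   targets known: %d\n",
              min(x$e_baseline), max(x$e_baseline), sum(!is.na(x$e_target))))
  invisible(x)
}

#' @export
as.data.frame.landscape <- function(x, ...) {
  data.frame(id = x$ids, e_baseline = x$e_baseline, e_target = x$e_target,
             density = x$density, stringsAsFactors = FALSE)
}

#' Write a landscape as extended-XYZ files plus a CSV manifest
#'
#' The manifest has columns id, file, e_baseline, e_target (blank when
#' unknown); all energies kJ/mol per molecule.
#'
#' @param x a `landscape`.
#' @param dir output directory (created if missing).
#' @export
write_landscape <- function(x, dir) {
  stopifnot(inherits(x, "landscape"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  file <- "structures.xyz"
  write_xyz(x$structures, file.path(dir, file))
  et <- ifelse(is.na(x$e_target), "", fmt_num(x$e_target))
  man <- data.frame(id = x$ids, file = file,
                    e_baseline = fmt_num(x$e_baseline), e_target = et,
                    stringsAsFactors = FALSE)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a landscape from a manifest directory
#' @param dir directory containing manifest.csv and the referenced XYZ files.
#' @export
read_landscape <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("missing manifest: ", man_path)
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character", file = "character"))
  need <- c("id", "file", "e_baseline", "e_target")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  structs <- list()
  for (f in unique(man$file)) {
    frames <- read_xyz(file.path(dir, f))
    names(frames) <- vapply(frames, function(s) s$id, "")
    structs <- c(structs, frames)
  }
  missing <- setdiff(man$id, names(structs))
  if (length(missing)) stop("structures missing from XYZ files: ",
                            paste(missing, collapse = ", "))
  et <- suppressWarnings(as.numeric(man$e_target))
  landscape(structs[man$id], as.numeric(man$e_baseline), et)
}
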