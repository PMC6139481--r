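# Real-space packing metrics: symmetry expansion, crystal-contact
# counting (grid-accelerated), contacts ratio, asymmetric-unit mass,
# Matthews coefficient and solvent content.

# standard atomic masses (Da) for elements common in macromolecular models
.atomic_mass <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078,
  MN = 54.938, CU = 63.546, "NA" = 22.990, K = 39.098, CL = 35.45,
  F = 18.998, BR = 79.904, I = 126.904, CO = 58.933, NI = 58.693,
  MO = 95.95, W = 183.84, CD = 112.414, HG = 200.592
)

# translation range per axis; widened while an axis is shorter than twice
# the cutoff so that all images within reach are generated
.shell_range <- function(cell, cutoff) {
  ax <- c(cell$a, cell$b, cell$c)
  n <- pmax(1L, ceiling(2 * cutoff / ax))
  if (any(ax < cutoff / 2)) {
    warning("pathological cell (axis < cutoff/2): widening translation shell")
  }
  n
}

# symmetry images relevant to contact counting: for each operator, the
# lattice-translation range is derived from the fractional bounding boxes
# of the ASU and the rotated copy plus a cutoff margin, so the count is
# independent of where the model sits relative to the origin. The margin
# is exact: a Cartesian separation <= cutoff bounds the fractional
# separation along axis i by cutoff * |row i of the deorthogonalization|.
.contact_images <- function(asu, cell, sg, cutoff) {
  m <- orthogonalization_matrix(cell)
  minv <- solve(m)
  frac <- t(minv %*% t(asu))
  margin <- cutoff * sqrt(rowSums(minv^2))
  images <- list()
  for (op in sg$ops) {
    ident <- max(abs(op$rot - diag(3))) == 0 && max(abs(op$trans)) < 1e-9
    base <- frac %*% t(op$rot) + matrix(op$trans, nrow(frac), 3, byrow = TRUE)
    lo <- floor(apply(frac, 2, min) - apply(base, 2, max) - margin)
    hi <- ceiling(apply(frac, 2, max) - apply(base, 2, min) + margin)
    for (tx in lo[1]:hi[1]) for (ty in lo[2]:hi[2]) for (tz in lo[3]:hi[3]) {
      if (ident && tx == 0 && ty == 0 && tz == 0) next
      shifted <- base + matrix(c(tx, ty, tz), nrow(base), 3, byrow = TRUE)
      images[[length(images) + 1]] <- t(m %*% t(shifted))
    }
  }
  images
}

#' Symmetry-expand a structure model
#'
#' Generates the Cartesian coordinates of every symmetry copy of the model
#' over the space-group operators combined with lattice translations in a
#' {-1,0,1}^3 neighborhood (widened automatically for small cells). The
#' identity operator with zero translation — the model itself — is
#' excluded.
#'
#' @param model A `structure_model` (see [parse_structure()]).
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param shell Optional integer vector of per-axis translation ranges; by
#'   default derived from the cell and a 4 Angstrom contact cutoff.
#' @return List of n x 3 Cartesian coordinate matrices, one per copy.
#' @export
expand_symmetry <- function(model, cell, sg, shell = NULL) {
  stopifnot(inherits(model, "structure_model"), inherits(cell, "unit_cell"),
            inherits(sg, "space_group"))
  if (model$n_atoms_total == 0) stop("empty model")
  if (is.null(shell)) shell <- .shell_range(cell, 4.0)
  if (length(shell) == 1) shell <- rep(shell, 3)
  m <- orthogonalization_matrix(cell)
  frac <- t(solve(m) %*% t(as.matrix(model$atoms[, c("x", "y", "z")])))
  copies <- list()
  for (k in seq_along(sg$ops)) {
    op <- sg$ops[[k]]
    base <- frac %*% t(op$rot) +
      matrix(op$trans, nrow(frac), 3, byrow = TRUE)
    is_identity <- max(abs(op$rot - diag(3))) == 0 &&
      max(abs(op$trans)) < 1e-9
    for (tx in -shell[1]:shell[1]) for (ty in -shell[2]:shell[2])
      for (tz in -shell[3]:shell[3]) {
        if (is_identity && tx == 0 && ty == 0 && tz == 0) next
        shifted <- base + matrix(c(tx, ty, tz), nrow(base), 3, byrow = TRUE)
        copies[[length(copies) + 1]] <- t(m %*% t(shifted))
      }
  }
  copies
}

#' Count crystal contacts
#'
#' Number of ordered atom pairs (i in the asymmetric unit, j in any
#' symmetry copy) separated by at most `cutoff` Angstrom, the contact
#' definition of the ncont program. Self-image pairs (an atom meeting its
#' own image at distance ~0, as happens for atoms on special positions)
#' are excluded. Implemented with a uniform cell-list grid; the exhaustive
#' scan [contact_count_exhaustive()] is the reference it must agree with.
#'
#' @param model A `structure_model`.
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param cutoff Contact distance cutoff in Angstrom (default 4.0).
#' @return Integer contact count.
#' @examples
#' toy <- gen_crystal("P1", unit_cell(3.9, 20, 20),
#'                    data.frame(element = "C", fx = 0, fy = 0, fz = 0))
#' count_crystal_contacts(toy$model, toy$cell, toy$sg)  # 2
#' @export
count_crystal_contacts <- function(model, cell, sg, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  if (any(c(cell$a, cell$b, cell$c) < cutoff / 2)) {
    warning("pathological cell (axis < cutoff/2): widening translation shell")
  }
  asu <- as.matrix(model$atoms[, c("x", "y", "z")])
  img <- do.call(rbind, .contact_images(asu, cell, sg, cutoff))

  # cell-list grid over the images, cube edge = cutoff
  key_of <- function(xyz) floor(sweep(xyz, 2, rep(cutoff, 3), "/"))
  ik <- key_of(img)
  kmin <- apply(rbind(ik, key_of(asu)), 2, min)
  dims <- apply(rbind(ik, key_of(asu)), 2, max) - kmin + 3L
  lin <- function(k) {
    (k[, 1] - kmin[1] + 1) + dims[1] * ((k[, 2] - kmin[2] + 1) +
      dims[2] * (k[, 3] - kmin[3] + 1))
  }
  buckets <- split(seq_len(nrow(img)), lin(ik))

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  n_contacts <- 0L
  ak <- key_of(asu)
  for (i in seq_len(nrow(asu))) {
    nb_keys <- sweep(offs, 2, ak[i, ], "+")
    cand <- unlist(buckets[as.character(lin(nb_keys))], use.names = FALSE)
    if (!length(cand)) next
    dx <- img[cand, 1] - asu[i, 1]
    dy <- img[cand, 2] - asu[i, 2]
    dz <- img[cand, 3] - asu[i, 3]
    dd <- dx * dx + dy * dy + dz * dz
    n_contacts <- n_contacts + sum(dd <= cutoff^2 & dd > 1e-12)
  }
  as.integer(n_contacts)
}

#' Crystal-contacts ratio
#'
#' The contact count divided by the total number of atoms in the model —
#' heteroatoms and waters included in the denominator.
#'
#' @param n_contacts Contact count from [count_crystal_contacts()].
#' @param model A `structure_model`.
#' @return Dimensionless ratio.
#' @export
contacts_ratio <- function(n_contacts, model) {
  stopifnot(inherits(model, "structure_model"))
  if (model$n_atoms_total == 0) stop("empty model")
  n_contacts / model$n_atoms_total
}

#' Asymmetric-unit macromolecular mass
#'
#' Sum of standard atomic masses over polymer atoms only (waters and
#' heterogens excluded), multiplied by 1.05 to account for the hydrogens
#' absent from typical X-ray models (about 5% of protein mass).
#'
#' @param model A `structure_model`.
#' @return Mass in Dalton. A model without polymer atoms returns 0 with a
#'   warning.
#' @export
asu_mass <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  poly <- model$atoms[model$atoms$kind == "polymer", ]
  if (nrow(poly) == 0) {
    warning("no polymer atoms: asymmetric-unit mass is 0")
    return(0)
  }
  el <- toupper(poly$element)
  unknown <- setdiff(unique(el), names(.atomic_mass))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(.atomic_mass[el]) * 1.05
}

#' Matthews coefficient and solvent content
#'
#' V_M = V_cell / (Z * mass) with Z the number of asymmetric units per
#' cell; solvent percentage = 100 (1 - 1.23 / V_M), the CCP4
#' matthews_coef convention (1.23 is the reciprocal of the 0.74 cm^3/g
#' protein partial specific volume in V_M units). Negative solvent values
#' for over-packed hypothetical cells are flagged, not clamped.
#'
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param mass Asymmetric-unit mass in Dalton (> 0).
#' @return List with `matthews` (A^3/Da) and `solvent_pct` (percent).
#' @examples
#' matthews_solvent(unit_cell(50, 50, 40), space_group("P1"), 20000)
#' @export
matthews_solvent <- function(cell, sg, mass) {
  stopifnot(inherits(cell, "unit_cell"), inherits(sg, "space_group"))
  if (!is.finite(mass) || mass <= 0) stop("mass must be positive")
  vm <- cell_volume(cell) / (sg$z_asu * mass)
  solv <- 100 * (1 - 1.23 / vm)
  if (solv < 0) warning("negative solvent content (over-packed cell)")
  list(matthews = vm, solvent_pct = solv)
}

#' All packing metrics for one model
#'
#' @param model A `structure_model`.
#' @param cell A [unit_cell()].
#' @param sg A [space_group()].
#' @param cutoff Contact cutoff, Angstrom (default 4.0).
#' @return Object of class `packing_result`: `n_contacts`,
#'   `n_atoms_total`, `contacts_ratio`, `asu_mass`, `matthews`,
#'   `solvent_pct`.
#' @export
packing_metrics <- function(model, cell, sg, cutoff = 4.0) {
  nc <- count_crystal_contacts(model, cell, sg, cutoff)
  mass <- withCallingHandlers(asu_mass(model),
                              warning = function(w) invokeRestart("muffleWarning"))
  ms <- if (mass > 0) matthews_solvent(cell, sg, mass)
        else list(matthews = NA_real_, solvent_pct = NA_real_)
  structure(list(n_contacts = nc, n_atoms_total = model$n_atoms_total,
                 contacts_ratio = contacts_ratio(nc, model),
                 asu_mass = mass, matthews = ms$matthews,
                 solvent_pct = ms$solvent_pct),
            class = "packing_result")
}

#' @export
print.packing_result <- function(x, ...) {
  cat("packing metrics\n")
  cat(sprintf("  crystal contacts: %d over %d atoms (ratio %.4f)\n",
              x$n_contacts, x$n_atoms_total, x$contacts_ratio))
  cat(sprintf("  ASU mass: %.1f Da\n", x$asu_mass))
  if (is.finite(x$matthews)) {
    cat(sprintf("  Matthews: %.2f A^3/Da, solvent %.1f%%\n",
                x$matthews, x$solvent_pct))
  }
  invisible(x)
}
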