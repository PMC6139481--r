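#' Reflection set
#'
#' Container for indexed structure-factor data: Miller indices with
#' amplitudes (F, sigF) and/or intensities (I, sigI), plus the unit cell
#' and space group giving them geometric meaning. At least one of the two
#' data paths must be fully present.
#'
#' @param hkl Integer n x 3 matrix of Miller indices; (0,0,0) forbidden.
#' @param f,sig_f Optional amplitude data (arbitrary scale) and
#'   uncertainties.
#' @param i,sig_i Optional intensity data and uncertainties.
#' @param cell A [unit_cell()].
#' @param spacegroup A [space_group()].
#'
#' @details Stored indices are kept exactly as supplied (anisotropy fitting
#'   needs the original direction vectors); mapping to a canonical
#'   asymmetric wedge is done only to detect duplicates, which are an
#'   error. All supplied sigmas must be non-negative.
#'
#' @return An object of class `reflection_set` with fields `hkl`, `f`,
#'   `sig_f`, `i`, `sig_i`, `cell`, `spacegroup`, `n`.
#' @export
reflection_set <- function(hkl, f = NULL, sig_f = NULL, i = NULL,
                           sig_i = NULL, cell, spacegroup = space_group("P1")) {
  hkl <- as.matrix(hkl)
  storage.mode(hkl) <- "integer"
  if (ncol(hkl) != 3) stop("hkl must be an n x 3 integer matrix")
  n <- nrow(hkl)
  if (n == 0) stop("empty reflection set")
  if (any(rowSums(hkl != 0) == 0)) stop("(0,0,0) is not a reflection")
  has_f <- !is.null(f) && !is.null(sig_f)
  has_i <- !is.null(i) && !is.null(sig_i)
  if (!has_f && !has_i) {
    stop("need a complete amplitude (f, sig_f) or intensity (i, sig_i) path")
  }
  for (v in list(f, sig_f, i, sig_i)) {
    if (!is.null(v) && length(v) != n) stop("data column length != nrow(hkl)")
  }
  if (has_f && any(sig_f < 0, na.rm = TRUE)) stop("negative sigma(F)")
  if (has_i && any(sig_i < 0, na.rm = TRUE)) stop("negative sigma(I)")
  stopifnot(inherits(cell, "unit_cell"), inherits(spacegroup, "space_group"))
  canon <- canonical_hkl(hkl, spacegroup)
  if (anyDuplicated(canon)) {
    stop("duplicate reflections after reduction to the asymmetric wedge")
  }
  structure(list(hkl = hkl,
                 f = if (has_f) as.numeric(f) else NULL,
                 sig_f = if (has_f) as.numeric(sig_f) else NULL,
                 i = if (has_i) as.numeric(i) else NULL,
                 sig_i = if (has_i) as.numeric(sig_i) else NULL,
                 cell = cell, spacegroup = spacegroup, n = n),
            class = "reflection_set")
}

#' Canonical (asymmetric-wedge) representatives of Miller indices
#'
#' Maps each index triple to a canonical representative of its orbit under
#' the point-group rotations and Friedel inversion: the lexicographically
#' largest equivalent triple. Used for duplicate detection only.
#'
#' @param hkl Integer n x 3 matrix.
#' @param sg A [space_group()].
#' @return An n x 3 integer matrix of canonical representatives.
#' @export
canonical_hkl <- function(hkl, sg) {
  hkl <- as.matrix(hkl)
  # reciprocal indices transform with the transposed rotation part
  rots <- lapply(sg$ops, function(op) t(op$rot))
  keys <- vapply(rots, function(r) paste(r, collapse = ","), "")
  rots <- rots[!duplicated(keys)]
  cand <- vector("list", 2 * length(rots))
  for (k in seq_along(rots)) {
    hr <- hkl %*% rots[[k]]
    cand[[2 * k - 1]] <- hr
    cand[[2 * k]] <- -hr  # Friedel mate
  }
  best <- cand[[1]]
  for (k in seq_along(cand)[-1]) {
    m <- cand[[k]]
    gt <- (m[, 1] > best[, 1]) |
      (m[, 1] == best[, 1] & m[, 2] > best[, 2]) |
      (m[, 1] == best[, 1] & m[, 2] == best[, 2] & m[, 3] > best[, 3])
    best[gt, ] <- m[gt, ]
  }
  storage.mode(best) <- "integer"
  best
}

#' d-spacings of a reflection set
#' @param refl A [reflection_set()].
#' @return Numeric vector of resolutions (Angstrom).
#' @export
refl_d <- function(refl) {
  stopifnot(inherits(refl, "reflection_set"))
  d_spacing(refl$hkl, refl$cell)
}

# working intensities for a chosen source; amplitudes enter squared
.working_intensity <- function(refl, source = c("amplitudes", "intensities")) {
  source <- match.arg(source)
  if (source == "amplitudes") {
    if (is.null(refl$f)) stop("reflection set has no amplitude data")
    refl$f^2
  } else {
    if (is.null(refl$i)) stop("reflection set has no intensity data")
    refl$i
  }
}

#' @export
print.reflection_set <- function(x, ...) {
  d <- refl_d(x)
  cat(sprintf("reflection set: %d reflections, %.2f - %.2f A, %s\n",
              x$n, max(d), min(d), x$spacegroup$hm_symbol))
  cat(sprintf("  data: %s%s\n",
              if (!is.null(x$f)) "F/sigF " else "",
              if (!is.null(x$i)) "I/sigI" else ""))
  invisible(x)
}
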