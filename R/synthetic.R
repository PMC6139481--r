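# Synthetic-data generators: Wilson-distributed reflection sets with a
# directional Debye-Waller tensor, toy crystals with analytically known
# contact counts, header fixtures, and audit populations with planted
# curation ground truth. Everything is deterministic under a seed.

#' Simulation specification for synthetic reflection data
#'
#' @param cell A [unit_cell()] (default a 45 Angstrom cube, giving around
#'   24,000 unique reflections at dmin = 2).
#' @param sg_symbol Space-group symbol (default "P1"; reflection
#'   generation models no systematic absences, so P1 is the intended
#'   setting).
#' @param dmin High-resolution limit in Angstrom.
#' @param b_tensor Symmetric 3x3 anisotropic B tensor (A^2) imposed on the
#'   intensity falloff.
#' @param scale Overall intensity scale K.
#' @param sigma_model Either `list(type = "relative", f)` — sigma(I) is
#'   `f` times the shell mean intensity — or `list(type = "axis", f,
#'   axis, factor, d_break, cone_deg)`, which additionally inflates sigma
#'   by `factor` for reflections within `cone_deg` of `axis` at
#'   resolutions finer than `d_break`. Default relative, f = 0.1.
#' @param noise_free When TRUE intensities are the exact Wilson means (no
#'   exponential draw).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(cell = unit_cell(45, 45, 45), sg_symbol = "P1",
                            dmin = 2, b_tensor = diag(0, 3), scale = 1e4,
                            sigma_model = list(type = "relative", f = 0.1),
                            noise_free = FALSE, seed = 1) {
  b_tensor <- as.matrix(b_tensor)
  if (max(abs(b_tensor - t(b_tensor))) > 1e-9) stop("b_tensor must be symmetric")
  if (dmin <= 0) stop("dmin must be positive")
  structure(list(cell = cell, sg_symbol = sg_symbol, dmin = dmin,
                 b_tensor = b_tensor, scale = scale,
                 sigma_model = sigma_model, noise_free = noise_free,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a synthetic reflection set
#'
#' Enumerates all lattice points with d >= dmin (one Friedel mate each,
#' origin excluded) and draws acentric Wilson intensities: I_h is
#' exponential with mean K exp(-2 s^2 n' B n), s = 1/(2d). In noise-free
#' mode I_h is the mean itself. Amplitudes are F = sqrt(I) with
#' sigF = sigI / (2F).
#'
#' @param spec A [simulation_spec()].
#' @return A [reflection_set()] carrying both data paths.
#' @export
gen_reflections <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  cell <- spec$cell
  hmax <- ceiling(cell$a / spec$dmin) + 1
  kmax <- ceiling(cell$b / spec$dmin) + 1
  lmax <- ceiling(cell$c / spec$dmin) + 1
  g <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  # one representative per Friedel pair, origin excluded
  g <- g[g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
           (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0), , drop = FALSE]
  d <- d_spacing(g, cell)
  g <- g[d >= spec$dmin, , drop = FALSE]
  d <- d[d >= spec$dmin]
  n <- nrow(g)
  if (n < 100) warning("only ", n, " reflections at dmin = ", spec$dmin)

  svec <- scattering_vector(g, cell)
  slen2 <- rowSums(svec^2)
  nhat <- svec / sqrt(slen2)
  s2 <- slen2 / 4
  proj <- rowSums((nhat %*% spec$b_tensor) * nhat)
  mean_i <- spec$scale * exp(-2 * s2 * proj)

  i_obs <- if (spec$noise_free) mean_i else stats::rexp(n, rate = 1 / mean_i)

  # sigma labels from the shell means of the observed intensities
  ord <- order(d, decreasing = TRUE)
  k <- min(20, n)
  base <- n %/% k; extra <- n %% k
  shell <- integer(n)
  shell[ord] <- rep(seq_len(k), times = rep(base, k) +
                      c(rep(1L, extra), rep(0L, k - extra)))
  shell_mean <- as.numeric(tapply(i_obs, shell, mean))[shell]
  sm <- spec$sigma_model
  sig_i <- sm$f * shell_mean
  if (identical(sm$type, "axis")) {
    ca <- abs(nhat %*% (sm$axis / sqrt(sum(sm$axis^2))))
    cone <- if (is.null(sm$cone_deg)) 20 else sm$cone_deg
    infl <- ca >= cos(cone * pi / 180) & d < sm$d_break
    sig_i[infl] <- sig_i[infl] * sm$factor
  }

  f <- sqrt(i_obs)
  sig_f <- sig_i / (2 * f)
  reflection_set(g, f = f, sig_f = sig_f, i = i_obs, sig_i = sig_i,
                 cell = cell, spacegroup = space_group(spec$sg_symbol))
}

#' Exhaustive crystal-contact count
#'
#' Reference implementation: a plain all-pairs distance scan of the
#' asymmetric unit against every symmetry image, with no spatial indexing.
#' [count_crystal_contacts()] must agree with it exactly; tests rely on
#' the two code paths being independent.
#'
#' @inheritParams count_crystal_contacts
#' @return Integer contact count.
#' @export
contact_count_exhaustive <- function(model, cell, sg, cutoff = 4.0) {
  m <- orthogonalization_matrix(cell)
  minv <- solve(m)
  asu_frac <- t(minv %*% t(as.matrix(model$atoms[, c("x", "y", "z")]))) %% 1
  asu <- t(m %*% t(asu_frac))
  # wrapped coordinates sit within one cell, so +/- (1 + margin) cells of
  # translation reach every image within the cutoff of any ASU atom
  nt <- 1L + ceiling(cutoff * sqrt(rowSums(minv^2)))
  total <- 0L
  for (op in sg$ops) {
    ident <- max(abs(op$rot - diag(3))) == 0 && max(abs(op$trans)) < 1e-9
    base <- (asu_frac %*% t(op$rot) +
               matrix(op$trans, nrow(asu_frac), 3, byrow = TRUE)) %% 1
    for (tx in -nt[1]:nt[1]) for (ty in -nt[2]:nt[2]) for (tz in -nt[3]:nt[3]) {
      if (ident && tx == 0 && ty == 0 && tz == 0) next
      imgf <- base + matrix(c(tx, ty, tz), nrow(base), 3, byrow = TRUE)
      img <- t(m %*% t(imgf))
      # all-pairs squared distances, no spatial indexing
      d2 <- outer(rowSums(asu^2), rowSums(img^2), `+`) - 2 * asu %*% t(img)
      total <- total + sum(d2 <= cutoff^2 & d2 > 1e-12)
    }
  }
  as.integer(total)
}

#' Generate a toy crystal with a known contact count
#'
#' Places atoms at given fractional positions in the cell and computes the
#' ground-truth crystal-contact count by the exhaustive scan.
#'
#' @param sg_symbol Space-group symbol.
#' @param cell A [unit_cell()].
#' @param atom_spec data.frame with columns `element`, `fx`, `fy`, `fz`
#'   (fractional coordinates in [0,1)) and optionally `kind` (default
#'   "polymer").
#' @param cutoff Contact cutoff for the oracle count (default 4.0).
#' @return List with `model` (a `structure_model`), `cell`, `sg`, and
#'   `oracle_contacts`.
#' @export
gen_crystal <- function(sg_symbol, cell, atom_spec, cutoff = 4.0) {
  stopifnot(is.data.frame(atom_spec),
            all(c("element", "fx", "fy", "fz") %in% names(atom_spec)))
  fr <- as.matrix(atom_spec[, c("fx", "fy", "fz")])
  if (any(fr < 0 | fr >= 1)) stop("fractional positions must lie in [0,1)")
  xyz <- frac_to_cart(fr, cell)
  if (nrow(xyz) > 1) {
    dmin_pair <- min(stats::dist(xyz))
    if (dmin_pair < 0.5) {
      stop("overlapping atoms (", signif(dmin_pair, 3), " A apart)")
    }
  }
  kind <- if ("kind" %in% names(atom_spec)) atom_spec$kind else "polymer"
  atoms <- data.frame(element = toupper(atom_spec$element),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = 1, kind = kind, chain = "A",
                      stringsAsFactors = FALSE)
  model <- structure(list(atoms = atoms, n_atoms_total = nrow(atoms)),
                     class = "structure_model")
  sg <- space_group(sg_symbol)
  list(model = model, cell = cell, sg = sg,
       oracle_contacts = contact_count_exhaustive(model, cell, sg, cutoff))
}

#' Generate a legacy-PDB header fixture
#'
#' Emits fixed-column header records for the given fields; fields left NA
#' or empty produce no record, so absence round-trips too.
#'
#' @param entry_id 4-character code.
#' @param year Revision year (REVDAT).
#' @param resolution Angstrom (REMARK 2).
#' @param cell A [unit_cell()] (CRYST1), or NULL.
#' @param sg_symbol Space-group symbol for CRYST1.
#' @param temperature Kelvin (REMARK 200).
#' @param solvent_content Percent (REMARK 280).
#' @param het_ids Character vector of 3-letter codes (HETNAM).
#' @param keywords Character vector (KEYWDS).
#' @return Character vector of PDB header lines.
#' @export
gen_header <- function(entry_id = "SYNT", year = NA, resolution = NA,
                       cell = NULL, sg_symbol = "P 1", temperature = NA,
                       solvent_content = NA, het_ids = character(0),
                       keywords = character(0)) {
  lines <- sprintf("HEADER    %-40s%9s   %-4s", "SYNTHETIC ENTRY",
                   if (is.na(year)) "01-JAN-00"
                   else sprintf("01-JAN-%02d", year %% 100), entry_id)
  if (!is.na(year)) {
    lines <- c(lines, sprintf("REVDAT   1   %9s %-4s    0",
                              sprintf("01-JAN-%02d", year %% 100), entry_id))
  }
  if (!is.na(resolution)) {
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION.  %6.2f ANGSTROMS.",
                              resolution))
  }
  if (!is.na(temperature)) {
    lines <- c(lines, sprintf(
      "REMARK 200  TEMPERATURE           (KELVIN) : %.1f", temperature))
  }
  if (!is.na(solvent_content)) {
    lines <- c(lines, sprintf(
      "REMARK 280  SOLVENT CONTENT, VS   (%%): %.2f", solvent_content))
  }
  if (length(keywords)) {
    lines <- c(lines, sprintf("KEYWDS    %-69s",
                              paste(keywords, collapse = ", ")))
  }
  for (h in het_ids) {
    lines <- c(lines, sprintf("HETNAM     %-3s %s", h, "SYNTHETIC LIGAND"))
  }
  if (!is.null(cell)) {
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
      sg_symbol, 1L))
  }
  lines
}

#' Generate an audit population with planted curation ground truth
#'
#' Builds `n` audit records of which known fractions violate exactly one
#' curation rule each; metric values are drawn just inside or outside the
#' rule boundaries. The planted verdict and reason are carried in the
#' `planted_verdict` / `planted_reason` columns for comparison with
#' [curate()].
#'
#' @param n Number of records.
#' @param violation_fractions Named fractions for `year`, `resolution`,
#'   `aniso_b` and `contacts_ratio` violators; must sum to at most 1.
#' @param seed Integer seed.
#' @return data.frame of audit records (see [build_record()] for the
#'   schema) plus the two planted columns.
#' @export
gen_audit_population <- function(n,
                                 violation_fractions = c(year = 0.1,
                                                         resolution = 0.1,
                                                         aniso_b = 0.1,
                                                         contacts_ratio = 0.1),
                                 seed = 1) {
  vf <- violation_fractions
  need <- c("year", "resolution", "aniso_b", "contacts_ratio")
  vf <- vf[need]; vf[is.na(vf)] <- 0; names(vf) <- need
  if (sum(vf) > 1) stop("violation fractions must sum to at most 1")
  set.seed(seed)
  counts <- round(n * vf)
  reason <- c(rep("year", counts[1]), rep("resolution", counts[2]),
              rep("aniso_b", counts[3]), rep("contacts_ratio", counts[4]))
  reason <- c(reason, rep("none", n - length(reason)))
  reason <- sample(reason)

  year <- ifelse(reason == "year", sample(1990:2005, n, replace = TRUE),
                 sample(2006:2016, n, replace = TRUE))
  resolution <- ifelse(reason == "resolution", stats::runif(n, 5.01, 9),
                       stats::runif(n, 1.0, 5.0))
  aniso <- ifelse(reason == "aniso_b", stats::runif(n, 150.1, 400),
                  stats::runif(n, 0, 150))
  ratio <- ifelse(reason == "contacts_ratio", stats::runif(n, 1.01, 3),
                  stats::runif(n, 0, 1))

  rec <- .empty_records(n)
  rec$entry_id <- sprintf("%04d", seq_len(n))
  rec$year <- as.integer(year)
  rec$resolution <- resolution
  rec$aniso_b_amp <- aniso
  rec$contacts_ratio <- ratio
  rec$sg_symbol <- "P1"
  rec$planted_verdict <- ifelse(reason == "none", "kept", "dropped")
  rec$planted_reason <- reason
  rec
}
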