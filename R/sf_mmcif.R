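# Minimal mmCIF reader/writer for reflection (refln) loops plus the cell
# and symmetry items. This is not a general CIF parser: it understands
# whitespace-separated loop rows, quoted values and the "?" / "." missing
# sentinels, which covers deposited structure-factor files' refln loops.

.cif_fields <- function(line) {
  # split a data row into fields, honouring single/double quotes
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  f <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", f)
}

.cif_num <- function(x) {
  x[x %in% c("?", ".")] <- NA
  suppressWarnings(as.numeric(x))
}

.cif_item <- function(lines, tag) {
  hit <- grep(paste0("^", gsub("([.\\-])", "\\\\\\1", tag), "\\s"), lines)
  if (!length(hit)) return(NA_character_)
  f <- .cif_fields(lines[hit[1]])
  if (length(f) < 2) NA_character_ else f[2]
}

#' Read a structure-factor mmCIF file
#'
#' Parses the first `_refln` loop into a [reflection_set()]. Recognized
#' data items: `_refln.index_h/k/l`, `_refln.F_meas_au` /
#' `_refln.F_meas_sigma_au` (or the `_refln.F_meas` variants) and
#' `_refln.intensity_meas` / `_refln.intensity_sigma`. Rows whose value in
#' a present data path is missing ("?" or ".") or non-numeric keep `NA`
#' there; rows unusable on every present path are dropped and counted in
#' the `qc` attribute. Cell and space group are taken from the file's
#' `_cell` / `_symmetry` items when present, else from the arguments.
#'
#' @param text Lines of an mmCIF file or a path to one.
#' @param cell,spacegroup Fallbacks when the file carries no cell/symmetry.
#' @return A [reflection_set()]; attribute `qc` is a list with
#'   `n_rows_read`, `n_dropped` and per-path missing counts.
#' @export
read_sf_mmcif <- function(text, cell = NULL, spacegroup = NULL) {
  lines <- .as_lines(text)

  loop_starts <- which(trimws(lines) == "loop_")
  refl_loop <- NULL
  for (ls in loop_starts) {
    j <- ls + 1
    tags <- character(0)
    while (j <= length(lines) && startsWith(trimws(lines[j]), "_")) {
      tags <- c(tags, trimws(lines[j]))
      j <- j + 1
    }
    if (any(startsWith(tags, "_refln."))) {
      rows <- character(0)
      while (j <= length(lines)) {
        l <- trimws(lines[j])
        if (!nzchar(l) || startsWith(l, "#") || l == "loop_" ||
            startsWith(l, "_") || startsWith(l, "data_")) break
        rows <- c(rows, l)
        j <- j + 1
      }
      refl_loop <- list(tags = tags, rows = rows)
      break
    }
  }
  if (is.null(refl_loop)) stop("no refln loop found in mmCIF input")

  tags <- refl_loop$tags
  need <- function(tag) match(tag, tags)
  ih <- need("_refln.index_h"); ik <- need("_refln.index_k")
  il <- need("_refln.index_l")
  if (any(is.na(c(ih, ik, il)))) stop("refln loop lacks Miller index items")
  cf <- if (!is.na(need("_refln.F_meas_au"))) need("_refln.F_meas_au") else need("_refln.F_meas")
  csf <- if (!is.na(need("_refln.F_meas_sigma_au"))) need("_refln.F_meas_sigma_au") else need("_refln.F_meas_sigma")
  ci <- need("_refln.intensity_meas"); csi <- need("_refln.intensity_sigma")
  has_f <- !is.na(cf) && !is.na(csf)
  has_i <- !is.na(ci) && !is.na(csi)
  if (!has_f && !has_i) {
    stop("refln loop carries neither amplitude nor intensity columns")
  }

  cells <- lapply(refl_loop$rows, .cif_fields)
  ncol_expected <- length(tags)
  ok_len <- vapply(cells, length, 0L) == ncol_expected
  if (!all(ok_len)) stop("refln loop rows with wrong field count")
  tab <- do.call(rbind, cells)

  hkl <- cbind(.cif_num(tab[, ih]), .cif_num(tab[, ik]), .cif_num(tab[, il]))
  if (any(is.na(hkl))) stop("non-numeric Miller indices in refln loop")

  f <- sig_f <- i <- sig_i <- NULL
  if (has_f) { f <- .cif_num(tab[, cf]); sig_f <- .cif_num(tab[, csf]) }
  if (has_i) { i <- .cif_num(tab[, ci]); sig_i <- .cif_num(tab[, csi]) }
  if (has_f && any(sig_f < 0, na.rm = TRUE)) stop("negative sigma(F) in file")
  if (has_i && any(sig_i < 0, na.rm = TRUE)) stop("negative sigma(I) in file")

  f_ok <- if (has_f) is.finite(f) & is.finite(sig_f) else rep(FALSE, nrow(hkl))
  i_ok <- if (has_i) is.finite(i) & is.finite(sig_i) else rep(FALSE, nrow(hkl))
  usable <- f_ok | i_ok
  qc <- list(n_rows_read = nrow(hkl), n_dropped = sum(!usable),
             n_missing_amplitude = if (has_f) sum(!f_ok) else NA_integer_,
             n_missing_intensity = if (has_i) sum(!i_ok) else NA_integer_)
  if (!any(usable)) stop("no usable reflections in refln loop")

  file_cell <- {
    ca <- .cif_num(.cif_item(lines, "_cell.length_a"))
    if (is.finite(ca)) {
      unit_cell(ca,
                .cif_num(.cif_item(lines, "_cell.length_b")),
                .cif_num(.cif_item(lines, "_cell.length_c")),
                .cif_num(.cif_item(lines, "_cell.angle_alpha")),
                .cif_num(.cif_item(lines, "_cell.angle_beta")),
                .cif_num(.cif_item(lines, "_cell.angle_gamma")))
    } else NULL
  }
  file_sg <- .cif_item(lines, "_symmetry.space_group_name_H-M")
  use_cell <- if (!is.null(file_cell)) file_cell else cell
  if (is.null(use_cell)) stop("no cell in file and none supplied")
  use_sg <- if (!is.na(file_sg)) space_group(file_sg)
            else if (!is.null(spacegroup)) spacegroup else space_group("P1")

  refl <- reflection_set(hkl[usable, , drop = FALSE],
                         f = if (has_f) f[usable] else NULL,
                         sig_f = if (has_f) sig_f[usable] else NULL,
                         i = if (has_i) i[usable] else NULL,
                         sig_i = if (has_i) sig_i[usable] else NULL,
                         cell = use_cell, spacegroup = use_sg)
  attr(refl, "qc") <- qc
  refl
}

#' Write a reflection set as a structure-factor mmCIF file
#'
#' Emits cell and symmetry items plus one refln loop with the data paths
#' present in the set. Numeric values are written with 9 significant
#' digits; missing values become "?".
#'
#' @param refl A [reflection_set()].
#' @param path Optional output file.
#' @return Character vector of mmCIF lines (invisibly when `path` given).
#' @export
write_sf_mmcif <- function(refl, path = NULL) {
  stopifnot(inherits(refl, "reflection_set"))
  fmt <- function(x) ifelse(is.finite(x), sprintf("%.9g", x), "?")
  cl <- refl$cell
  lines <- c(
    "data_synthetic",
    "#",
    sprintf("_cell.length_a    %.4f", cl$a),
    sprintf("_cell.length_b    %.4f", cl$b),
    sprintf("_cell.length_c    %.4f", cl$c),
    sprintf("_cell.angle_alpha %.4f", cl$alpha),
    sprintf("_cell.angle_beta  %.4f", cl$beta),
    sprintf("_cell.angle_gamma %.4f", cl$gamma),
    sprintf("_symmetry.space_group_name_H-M '%s'", refl$spacegroup$hm_symbol),
    "#",
    "loop_",
    "_refln.index_h",
    "_refln.index_k",
    "_refln.index_l")
  cols <- list(refl$hkl[, 1], refl$hkl[, 2], refl$hkl[, 3])
  if (!is.null(refl$f)) {
    lines <- c(lines, "_refln.F_meas_au", "_refln.F_meas_sigma_au")
    cols <- c(cols, list(fmt(refl$f), fmt(refl$sig_f)))
  }
  if (!is.null(refl$i)) {
    lines <- c(lines, "_refln.intensity_meas", "_refln.intensity_sigma")
    cols <- c(cols, list(fmt(refl$i), fmt(refl$sig_i)))
  }
  rows <- do.call(paste, cols)
  lines <- c(lines, rows, "#")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
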