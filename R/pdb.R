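# Fixed-column legacy-PDB reading and writing. Column ranges follow the
# wwPDB format specification; header records that are absent stay absent
# (NA / empty), they are never defaulted.

.substr_trim <- function(x, a, b) trimws(substr(x, a, b))

.num_or_na <- function(x) {
  x <- trimws(x)
  if (!nzchar(x)) return(NA_real_)
  suppressWarnings(as.numeric(x))
}

# "13-JUL-11" / "13-JUL-1998" -> 4-digit year; two-digit years pivot at 50
.revdat_year <- function(datefield) {
  yy <- sub(".*-", "", trimws(datefield))
  if (!grepl("^[0-9]{2,4}$", yy)) return(NA_integer_)
  y <- as.integer(yy)
  if (nchar(yy) == 2) y <- if (y >= 50) 1900L + y else 2000L + y
  y
}

#' Parse a legacy-PDB file header
#'
#' Extracts the audit-relevant header records: entry id (HEADER), the most
#' recent revision year (REVDAT), resolution (REMARK 2), unit cell and
#' space-group symbol (CRYST1), data-collection temperature (REMARK 200),
#' solvent content (REMARK 280), heterogen ids (HETNAM) and keywords
#' (KEYWDS). Records that are absent yield `NA` (scalars) or empty vectors,
#' never defaults.
#'
#' @param text Character: either lines of a PDB file or a path to one.
#' @return An object of class `entry_header`: list with fields `entry_id`,
#'   `year`, `resolution` (Angstrom), `cell` ([unit_cell()] or NULL),
#'   `sg_symbol`, `temperature` (Kelvin), `solvent_content` (percent),
#'   `het_ids`, `keywords`.
#' @export
parse_pdb_header <- function(text) {
  lines <- .as_lines(text)
  hdr <- list(entry_id = NA_character_, year = NA_integer_,
              resolution = NA_real_, cell = NULL, sg_symbol = NA_character_,
              temperature = NA_real_, solvent_content = NA_real_,
              het_ids = character(0), keywords = character(0))

  hl <- lines[startsWith(lines, "HEADER")]
  if (length(hl)) {
    id <- .substr_trim(hl[1], 63, 66)
    if (nzchar(id)) hdr$entry_id <- id
  }

  rv <- lines[startsWith(lines, "REVDAT")]
  if (length(rv)) {
    years <- vapply(rv, function(l) .revdat_year(substr(l, 14, 22)), 0L)
    years <- years[!is.na(years)]
    if (length(years)) hdr$year <- max(years)
  }

  r2 <- lines[grepl("^REMARK   2 RESOLUTION\\.", lines)]
  if (length(r2)) {
    tail2 <- substr(r2[1], 23, 80)
    m <- regmatches(tail2, regexpr("[0-9]+\\.?[0-9]*", tail2))
    if (length(m)) hdr$resolution <- as.numeric(m)
  }

  r200 <- lines[startsWith(lines, "REMARK 200") &
                  grepl("TEMPERATURE", lines, fixed = TRUE)]
  if (length(r200)) {
    after <- sub(".*:", "", r200[1])
    v <- .num_or_na(sub(";.*", "", after))
    if (!is.na(v)) hdr$temperature <- v
  }

  r280 <- lines[startsWith(lines, "REMARK 280") &
                  grepl("SOLVENT CONTENT", lines, fixed = TRUE)]
  if (length(r280)) {
    v <- .num_or_na(sub(".*:", "", r280[1]))
    if (!is.na(v)) hdr$solvent_content <- v
  }

  cr <- lines[startsWith(lines, "CRYST1")]
  if (length(cr)) {
    l <- cr[1]
    nums <- c(.num_or_na(substr(l, 7, 15)), .num_or_na(substr(l, 16, 24)),
              .num_or_na(substr(l, 25, 33)), .num_or_na(substr(l, 34, 40)),
              .num_or_na(substr(l, 41, 47)), .num_or_na(substr(l, 48, 54)))
    if (any(is.na(nums))) {
      stop("malformed CRYST1 numeric fields in line: ", l)
    }
    hdr$cell <- unit_cell(nums[1], nums[2], nums[3], nums[4], nums[5], nums[6])
    sgs <- .substr_trim(l, 56, 66)
    if (nzchar(sgs)) hdr$sg_symbol <- sgs
  }

  hn <- lines[startsWith(lines, "HETNAM")]
  if (length(hn)) {
    ids <- unique(vapply(hn, function(l) .substr_trim(l, 12, 14), ""))
    hdr$het_ids <- ids[nzchar(ids)]
  }

  kw <- lines[startsWith(lines, "KEYWDS")]
  if (length(kw)) {
    txt <- paste(vapply(kw, function(l) .substr_trim(l, 11, 79), ""),
                 collapse = " ")
    words <- trimws(strsplit(txt, ",", fixed = TRUE)[[1]])
    hdr$keywords <- words[nzchar(words)]
  }

  structure(hdr, class = "entry_header")
}

#' Parse ATOM/HETATM coordinates from a legacy-PDB file
#'
#' Reads the first model only. Waters (residue HOH) are flagged `water`,
#' other HETATM records `hetero`, ATOM records `polymer`. When alternate
#' locations are present only the first-listed altloc of each atom is
#' kept. No occupancy filtering is applied.
#'
#' @param text Character: lines of a PDB file or a path to one.
#' @return An object of class `structure_model`: list with `atoms` (a
#'   data.frame with columns element, x, y, z, occ, kind, chain) and
#'   `n_atoms_total`.
#' @export
parse_structure <- function(text) {
  lines <- .as_lines(text)
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1)]
  sel <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  rec <- lines[sel]
  if (!length(rec)) stop("no ATOM/HETATM records: entry unusable")

  resname <- toupper(vapply(rec, function(l) .substr_trim(l, 18, 20), ""))
  is_het <- startsWith(rec, "HETATM")
  kind <- ifelse(resname == "HOH", "water", ifelse(is_het, "hetero", "polymer"))

  xyz <- t(vapply(rec, function(l) {
    c(.num_or_na(substr(l, 31, 38)), .num_or_na(substr(l, 39, 46)),
      .num_or_na(substr(l, 47, 54)))
  }, numeric(3)))
  if (any(!is.finite(xyz))) stop("non-numeric coordinates in ATOM/HETATM record")

  occ <- vapply(rec, function(l) .num_or_na(substr(l, 55, 60)), 0)
  occ[is.na(occ)] <- 1
  elem <- vapply(rec, function(l) .substr_trim(l, 77, 78), "")
  # fall back to the atom-name field when the element column is blank
  blank <- !nzchar(elem)
  if (any(blank)) {
    nm <- vapply(rec[blank], function(l) .substr_trim(l, 13, 16), "")
    elem[blank] <- sub("[0-9'].*$", "", nm)
  }
  elem <- toupper(elem)
  chain <- vapply(rec, function(l) substr(l, 22, 22), "")

  # altloc: keep the first-listed location of each atom
  altloc <- vapply(rec, function(l) substr(l, 17, 17), "")
  atom_id <- paste(chain, vapply(rec, function(l) .substr_trim(l, 23, 27), ""),
                   resname, vapply(rec, function(l) .substr_trim(l, 13, 16), ""))
  keep <- altloc == " " | !duplicated(atom_id)
  atoms <- data.frame(element = elem, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = occ, kind = kind, chain = chain,
                      stringsAsFactors = FALSE, row.names = NULL)[keep, ]
  row.names(atoms) <- NULL
  structure(list(atoms = atoms, n_atoms_total = nrow(atoms)),
            class = "structure_model")
}

#' Write a structure model as legacy-PDB ATOM/HETATM records
#'
#' @param model A `structure_model`.
#' @param cell Optional [unit_cell()] written to a CRYST1 record.
#' @param sg_symbol Space-group symbol for CRYST1 (default "P 1").
#' @param path Optional output file; when NULL the lines are returned.
#' @return Character vector of PDB lines (invisibly when `path` given).
#' @export
write_pdb <- function(model, cell = NULL, sg_symbol = "P 1", path = NULL) {
  stopifnot(inherits(model, "structure_model"))
  lines <- character(0)
  if (!is.null(cell)) {
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
      sg_symbol, 1L))
  }
  at <- model$atoms
  for (k in seq_len(nrow(at))) {
    tag <- if (at$kind[k] == "polymer") "ATOM  " else "HETATM"
    res <- switch(at$kind[k], water = "HOH", hetero = "LIG", "ALA")
    lines <- c(lines, sprintf(
      "%s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      tag, k, substr(paste0(at$element[k], k), 1, 4), res,
      if (nzchar(at$chain[k])) at$chain[k] else "A",
      k %% 10000, at$x[k], at$y[k], at$z[k], at$occ[k], 20.0, at$element[k]))
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

.as_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    readLines(text, warn = FALSE)
  } else if (length(text) == 1 && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
}

#' @export
print.entry_header <- function(x, ...) {
  cat("entry", if (is.na(x$entry_id)) "<unknown>" else x$entry_id, "\n")
  cat(sprintf("  year: %s  resolution: %s A  temperature: %s K\n",
              x$year, x$resolution, x$temperature))
  if (!is.null(x$cell)) {
    cat("  "); print(x$cell)
  }
  cat(sprintf("  space group: %s  solvent: %s%%\n", x$sg_symbol,
              x$solvent_content))
  if (length(x$het_ids)) cat("  het ids:", paste(x$het_ids, collapse = " "), "\n")
  if (length(x$keywords)) cat("  keywords:", paste(x$keywords, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.structure_model <- function(x, ...) {
  tab <- table(x$atoms$kind)
  cat(sprintf("structure model: %d atoms (%s)\n", x$n_atoms_total,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}
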