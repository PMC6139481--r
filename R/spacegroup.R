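# Bundled symmetry-operator table. Operators are given as coordinate
# triplets (International Tables style) and parsed once at load; the set
# covers the space groups exercised by the audit and its tests. Unknown
# symbols raise an error rather than guessing.
.sg_table <- list(
  "P1" = c("x,y,z"),
  "P2" = c("x,y,z", "-x,y,-z"),
  "P21" = c("x,y,z", "-x,y+1/2,-z"),
  "C2" = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "P222" = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z"),
  "P21212" = c("x,y,z", "-x,-y,z", "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z"),
  "P212121" = c("x,y,z", "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2",
                "-x+1/2,-y,z+1/2"),
  "P43212" = c("x,y,z", "-x,-y,z+1/2",
               "-y+1/2,x+1/2,z+3/4", "y+1/2,-x+1/2,z+1/4",
               "-x+1/2,y+1/2,-z+3/4", "x+1/2,-y+1/2,-z+1/4",
               "y,x,-z", "-y,-x,-z+1/2")
)

# parse one "x,y,z"-style triplet into a (rotation, translation) pair
.parse_symop <- function(triplet) {
  parts <- strsplit(gsub(" ", "", triplet), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("malformed symmetry triplet: ", triplet)
  rot <- matrix(0, 3, 3)
  tr <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (term in terms) {
      sgn <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      if (body %in% c("x", "y", "z")) {
        rot[i, match(body, c("x", "y", "z"))] <- sgn
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        num <- as.numeric(strsplit(body, "/")[[1]])
        tr[i] <- tr[i] + sgn * num[1] / num[2]
      } else {
        stop("cannot parse symmetry term '", term, "' in ", triplet)
      }
    }
  }
  list(rot = rot, trans = tr)
}

#' Space group
#'
#' Look up a space group by Hermann-Mauguin symbol in the bundled operator
#' table. Spaces in the symbol are ignored, so `"P 21 21 21"` and
#' `"P212121"` are equivalent.
#'
#' @param symbol Hermann-Mauguin symbol. Supported: P1, P2, P21, C2, P222,
#'   P21212, P212121, P43212.
#' @return An object of class `space_group`: list with `hm_symbol`, `ops`
#'   (each a list with 3x3 `rot` and length-3 `trans`, fractional) and
#'   `z_asu`, the number of asymmetric units per cell.
#' @examples
#' sg <- space_group("P 21 21 21")
#' sg$z_asu  # 4
#' @export
space_group <- function(symbol) {
  key <- toupper(gsub("[[:space:]]", "", symbol))
  if (!key %in% names(.sg_table)) {
    stop("unknown space-group symbol '", symbol, "'; supported: ",
         paste(names(.sg_table), collapse = ", "))
  }
  ops <- lapply(.sg_table[[key]], .parse_symop)
  structure(list(hm_symbol = key, ops = ops, z_asu = length(ops)),
            class = "space_group")
}

#' Point-group rotations in the Cartesian frame
#'
#' The rotation parts of the space-group operators, conjugated into the
#' Cartesian frame of the given cell (Q = M R M^-1). Used to symmetrize a
#' fitted anisotropic B tensor over the crystal point group. The cell must
#' be metrically compatible with the space group for the result to be
#' orthogonal.
#'
#' @param sg A [space_group()].
#' @param cell A [unit_cell()].
#' @return List of 3x3 orthogonal matrices (duplicates from centering
#'   removed).
#' @export
point_group_rotations <- function(sg, cell) {
  m <- orthogonalization_matrix(cell)
  minv <- solve(m)
  rots <- lapply(sg$ops, function(op) m %*% op$rot %*% minv)
  # centering repeats rotation parts; deduplicate
  keys <- vapply(rots, function(r) paste(round(r, 8), collapse = ","), "")
  rots <- rots[!duplicated(keys)]
  for (q in rots) {
    if (max(abs(t(q) %*% q - diag(3))) > 1e-6) {
      warning("cell metric incompatible with ", sg$hm_symbol,
              ": point-group rotation is not orthogonal in Cartesian frame")
    }
  }
  rots
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group %s (%d symmetry operators)\n", x$hm_symbol,
              length(x$ops)))
  invisible(x)
}
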