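# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

cubic_cell <- function(a = 10) unit_cell(a, a, a, 90, 90, 90)

# small reflection sets for fast unit tests (cell 25 A, ~4100 reflections)
quick_spec <- function(...) {
  simulation_spec(cell = unit_cell(25, 25, 25), ...)
}

# independent triclinic d-spacing formula (textbook closed form), used as
# the oracle against the scattering-vector route
d_triclinic <- function(hkl, cell) {
  a <- cell$a; b <- cell$b; cc <- cell$c
  al <- cell$alpha * pi / 180; be <- cell$beta * pi / 180
  ga <- cell$gamma * pi / 180
  h <- hkl[1]; k <- hkl[2]; l <- hkl[3]
  V <- cell_volume(cell)
  s11 <- (b * cc * sin(al))^2
  s22 <- (a * cc * sin(be))^2
  s33 <- (a * b * sin(ga))^2
  s12 <- a * b * cc^2 * (cos(al) * cos(be) - cos(ga))
  s23 <- a^2 * b * cc * (cos(be) * cos(ga) - cos(al))
  s13 <- a * b^2 * cc * (cos(ga) * cos(al) - cos(be))
  sqrt(V^2 / (s11 * h^2 + s22 * k^2 + s33 * l^2 +
                2 * s12 * h * k + 2 * s23 * k * l + 2 * s13 * h * l))
}

# independent re-implementation of the documented bin walk, used as the
# oracle for directional_limits' bin-edge semantics
walk_limit_oracle <- function(d, fsig, threshold = 3, n_bins = 10) {
  ord <- order(d, decreasing = TRUE)
  d <- d[ord]; fsig <- fsig[ord]
  n <- length(d); k <- min(n_bins, n)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  bin <- rep(seq_len(k), sizes)
  means <- tapply(fsig, bin, mean)
  if (means[1] < threshold) return(max(d))
  bad <- which(means < threshold)[1]
  if (is.na(bad)) return(min(d))
  min(d[bin == bad - 1])
}

# annotation table fixture covering the label vocabularies
write_annot_fixture <- function(path) {
  tab <- data.frame(
    entry_id = c("MEM1", "MEM2", "MEM3", "MON1"),
    is_membrane = c(TRUE, TRUE, TRUE, TRUE),
    fold = c("beta_barrel", "alpha_helical", "alpha_helical", "monotopic"),
    crystallization = c("detergent", "unknown", "bicelle", "unknown"),
    topology = c("embedded", "unknown", "extramembranous_domains", "unknown"),
    check.names = FALSE)
  tab[["function"]] <- c("transporter", "receptor", "atpase", "other")
  tab <- tab[, c("entry_id", "is_membrane", "fold", "crystallization",
                 "function", "topology")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random toy crystal in one of the supported space groups
random_crystal <- function(seed, max_atoms = 120) {
  set.seed(seed)
  sgs <- c("P1", "P21", "P212121")
  sg <- sample(sgs, 1)
  cell <- unit_cell(runif(1, 8, 25), runif(1, 8, 25), runif(1, 8, 25))
  n <- sample(3:max_atoms, 1)
  repeat {
    spec <- data.frame(element = sample(c("C", "N", "O", "S"), n, TRUE),
                       fx = runif(n, 0, 0.999), fy = runif(n, 0, 0.999),
                       fz = runif(n, 0, 0.999))
    toy <- tryCatch(gen_crystal(sg, cell, spec), error = function(e) NULL)
    if (!is.null(toy)) return(toy)
    n <- max(3, n - 5)  # overlapping draw: retry smaller
  }
}
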