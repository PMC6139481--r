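# Symmetry expansion, contact counting, Matthews/solvent.

one_atom_model <- function() {
  structure(list(atoms = data.frame(element = "C", x = 0, y = 0, z = 0,
                                    occ = 1, kind = "polymer", chain = "A"),
                 n_atoms_total = 1L), class = "structure_model")
}

test_that("symmetry expansion produces the expected copy counts", {
  m <- one_atom_model()
  cell <- unit_cell(20, 20, 20)
  expect_length(expand_symmetry(m, cell, space_group("P1"), shell = 1), 26)
  expect_length(expand_symmetry(m, cell, space_group("P212121"), shell = 1),
                4 * 27 - 1)
})

test_that("every symmetry copy is an isometry of the model", {
  set.seed(41)
  toy <- random_crystal(41, max_atoms = 20)
  d0 <- dist(as.matrix(toy$model$atoms[, c("x", "y", "z")]))
  copies <- expand_symmetry(toy$model, toy$cell, toy$sg, shell = 1)
  for (cp in copies[seq(1, length(copies), length.out = 8)]) {
    expect_equal(as.numeric(dist(cp)), as.numeric(d0), tolerance = 1e-6)
  }
})

test_that("single-atom P1 cells give the analytic contact counts", {
  m <- one_atom_model()
  # nearest images at 5 A > 4 A cutoff
  expect_equal(count_crystal_contacts(m, unit_cell(5, 5, 5),
                                      space_group("P1")), 0)
  # images at +/- a = 3.9 A within the 4.0 A cutoff
  expect_equal(count_crystal_contacts(m, unit_cell(3.9, 20, 20),
                                      space_group("P1")), 2)
})

test_that("intra-ASU pairs are not crystal contacts", {
  m <- structure(list(atoms = data.frame(
    element = c("C", "C"), x = c(10, 13), y = c(10, 10), z = c(10, 10),
    occ = 1, kind = "polymer", chain = "A"), n_atoms_total = 2L),
    class = "structure_model")
  expect_equal(count_crystal_contacts(m, unit_cell(40, 40, 40),
                                      space_group("P1")), 0)
})

test_that("grid contact count equals the exhaustive oracle on random crystals", {
  for (seed in 101:112) {
    toy <- random_crystal(seed)
    expect_equal(
      count_crystal_contacts(toy$model, toy$cell, toy$sg),
      toy$oracle_contacts,
      label = paste("crystal seed", seed, toy$sg$hm_symbol))
  }
})

test_that("contacts are invariant under lattice translation of the ASU", {
  toy <- random_crystal(55, max_atoms = 60)
  n0 <- count_crystal_contacts(toy$model, toy$cell, toy$sg)
  shifted <- toy$model
  tvec <- frac_to_cart(c(1, -2, 1), toy$cell)
  shifted$atoms$x <- shifted$atoms$x + tvec[1]
  shifted$atoms$y <- shifted$atoms$y + tvec[2]
  shifted$atoms$z <- shifted$atoms$z + tvec[3]
  expect_equal(count_crystal_contacts(shifted, toy$cell, toy$sg), n0)
})

test_that("contact count is non-decreasing in the cutoff", {
  toy <- random_crystal(66, max_atoms = 80)
  cuts <- c(2, 3, 4, 5)
  counts <- vapply(cuts, function(ct)
    count_crystal_contacts(toy$model, toy$cell, toy$sg, cutoff = ct), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("contacts ratio divides by the full atom count", {
  m <- one_atom_model()
  m$atoms <- m$atoms[rep(1, 100), ]
  m$n_atoms_total <- 100L
  expect_equal(contacts_ratio(50, m), 0.5)
  expect_equal(contacts_ratio(0, m), 0)
})

test_that("ASU mass sums polymer heavy atoms with the hydrogen factor", {
  m <- structure(list(atoms = data.frame(
    element = c("C", "C", "O"), x = 1:3, y = 1:3, z = 1:3, occ = 1,
    kind = c("polymer", "polymer", "water"), chain = "A"),
    n_atoms_total = 3L), class = "structure_model")
  expect_equal(asu_mass(m), 2 * 12.011 * 1.05)  # 25.2231 Da; water excluded
  waters <- m; waters$atoms$kind <- "water"
  expect_warning(mw <- asu_mass(waters), "no polymer")
  expect_equal(mw, 0)
  unk <- m; unk$atoms$element[1] <- "XQ"
  expect_error(asu_mass(unk), "XQ")
})

test_that("tripeptide mass approximates the sequence formula weight", {
  # glycine tripeptide backbone: 3x(N, CA, C, O) + terminal O = 13 heavy atoms
  el <- c(rep(c("N", "C", "C", "O"), 3), "O")
  m <- structure(list(atoms = data.frame(
    element = el, x = seq_along(el), y = 0, z = 0, occ = 1,
    kind = "polymer", chain = "A"), n_atoms_total = length(el)),
    class = "structure_model")
  seq_mass <- 3 * 75.07 - 2 * 18.02  # Gly-Gly-Gly with two waters lost
  expect_lt(abs(asu_mass(m) - seq_mass) / seq_mass, 0.06)
})

test_that("Matthews and solvent follow the standard closed forms", {
  # V_M = 1.23 exactly -> 0% solvent
  cell <- unit_cell(10, 10, 10)
  ms <- matthews_solvent(cell, space_group("P1"), 1000 / 1.23)
  expect_equal(ms$matthews, 1.23)
  expect_equal(ms$solvent_pct, 0)
  # V_cell = 100000, z = 4, mass = 10000 -> V_M = 2.5, solvent 50.8%
  cell2 <- unit_cell(100, 100, 10)
  ms2 <- matthews_solvent(cell2, space_group("P212121"), 10000)
  expect_equal(ms2$matthews, 2.5)
  expect_equal(ms2$solvent_pct, 100 * (1 - 1.23 / 2.5), tolerance = 1e-9)
  # doubling the mass halves V_M
  expect_equal(matthews_solvent(cell2, space_group("P212121"), 20000)$matthews,
               1.25)
  expect_error(matthews_solvent(cell, space_group("P1"), 0), "positive")
})

test_that("solvent content increases with Matthews coefficient", {
  masses <- c(5000, 8000, 12000, 20000)
  cell <- unit_cell(60, 60, 60)
  out <- t(vapply(masses, function(mm)
    unlist(matthews_solvent(cell, space_group("P1"), mm)), numeric(2)))
  expect_true(all(diff(out[, "matthews"]) < 0))
  expect_true(all(diff(out[, "solvent_pct"]) < 0))
})

test_that("packing_metrics assembles a coherent result", {
  toy <- random_crystal(77, max_atoms = 40)
  pm <- packing_metrics(toy$model, toy$cell, toy$sg)
  expect_equal(pm$n_contacts, toy$oracle_contacts)
  expect_equal(pm$contacts_ratio, pm$n_contacts / pm$n_atoms_total)
  expect_gt(pm$asu_mass, 0)
})
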