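# Structures, reactions, XYZ I/O, interpolation, bond-change classification.

test_that("structure invariants are enforced and distances behave", {
  s <- random_structure(6, seed = 1)
  dm <- distance_matrix(s)
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), rep(0, 6))
  expect_true(all(dm >= 0))
  expect_error(structure3d(integer(0), matrix(0, 0, 3)), "at least one atom")
  expect_error(structure3d(c(0L, 1L), matrix(0, 2, 3)), ">= 1")
  expect_error(structure3d(1L, matrix(c(1, Inf, 0), 1, 3)), "finite")
})

test_that("XYZ round trip preserves coordinates to 1e-6 A", {
  s <- random_structure(6, seed = 2)
  p <- withr::local_tempfile(fileext = ".xyz")
  write_structure_xyz(s, p)
  expect_error(read_reaction_xyz(p, frames = "RP"), "1")  # frame count
  r1 <- random_structure(5, seed = 4)
  r2 <- structure3d(r1$atomic_numbers, r1$coordinates + 0.37)
  ts <- structure3d(r1$atomic_numbers, r1$coordinates + 0.11)
  rxn <- reaction(r1, r2, ts_ref = ts, id = "rt",
                  properties = list(reactant = c(E = -1.5, S_vib = 0.2)))
  p2 <- withr::local_tempfile(fileext = ".xyz")
  frames <- write_reaction_xyz(rxn, p2)
  expect_identical(frames, "RTP")
  back <- read_reaction_xyz(p2, frames = "RTP", id = "rt")
  expect_lt(max(abs(back$reactant$coordinates - r1$coordinates)), 1e-6)
  expect_lt(max(abs(back$ts_ref$coordinates - ts$coordinates)), 1e-6)
  expect_equal(back$properties$reactant[["E"]], -1.5)
  expect_equal(back$properties$reactant[["S_vib"]], 0.2)
  # 2-frame file lacks ts_ref
  rxn2 <- reaction(r1, r2, id = "rp")
  p3 <- withr::local_tempfile(fileext = ".xyz")
  write_reaction_xyz(rxn2, p3)
  expect_null(read_reaction_xyz(p3, frames = "RP")$ts_ref)
  # single-atom structure is valid XYZ
  one <- structure3d(6L, matrix(c(0.1, 0.2, 0.3), 1, 3))
  p4 <- withr::local_tempfile(fileext = ".xyz")
  write_structure_xyz(one, p4)
  expect_match(readLines(p4)[1], "^1$")
})

test_that("XYZ parse errors are informative", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "c", "H 0 0 0", "C 1 0 0",
               "2", "c", "C 0 0 0", "H 1 0 0"), p)
  expect_error(read_reaction_xyz(p, frames = "RP"), "element sequence")
  writeLines(c("2", "c", "H 0 0 0", "C 1 zz 0",
               "2", "c", "H 0 0 0", "C 1 0 0"), p)
  expect_error(read_reaction_xyz(p, frames = "RP"), "line 4")
  writeLines(c("2", "c", "H 0 0 0", "C 1 0 0"), p)
  expect_error(read_reaction_xyz(p, frames = "RTP"), "3 frames")
})

test_that("manifest round trip reproduces the dataset", {
  rxns <- synthetic_reactions(3, n_atoms_range = c(3, 5), seed = 7)
  dir <- withr::local_tempdir()
  mp <- write_reactions(rxns, dir)
  back <- read_reactions(mp)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_identical(back[[k]]$id, rxns[[k]]$id)
    expect_lt(max(abs(back[[k]]$ts_ref$coordinates -
                      rxns[[k]]$ts_ref$coordinates)), 1e-6)
  }
})

test_that("interpolation hits its endpoints and midpoint", {
  r1 <- random_structure(5, seed = 10)
  r2 <- structure3d(r1$atomic_numbers, 2 * r1$coordinates + 1)
  rxn <- reaction(r1, r2, id = "i")
  expect_equal(interpolate_structure(rxn, 0)$coordinates, r1$coordinates)
  expect_equal(interpolate_structure(rxn, 1)$coordinates, r2$coordinates)
  one <- reaction(structure3d(1L, matrix(c(0, 0, 0), 1, 3)),
                  structure3d(1L, matrix(c(2, 0, 0), 1, 3)), id = "m")
  expect_equal(interpolate_structure(one, 0.5)$coordinates,
               matrix(c(1, 0, 0), 1, 3))
  expect_error(interpolate_structure(rxn, 1.2), "fraction")
  expect_identical(interpolate_structure(rxn, 0.5)$label, "interpolated")
})

test_that("interpolation is equivariant under a common rigid motion", {
  rxn <- synthetic_reactions(1, n_atoms_range = c(5, 5), seed = 3)[[1]]
  R <- random_rotation(seed = 8); t <- c(1, -2, 0.5)
  rot <- reaction(rigid_move(rxn$reactant, R, t),
                  rigid_move(rxn$product, R, t), id = "rot")
  a <- interpolate_structure(rot, 0.3)$coordinates
  b <- rigid_move(interpolate_structure(rxn, 0.3), R, t)$coordinates
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("bond-change classification follows the 156.6 pm rule", {
  z <- c(6L, 6L)
  mk <- function(d) structure3d(z, rbind(c(0, 0, 0), c(d, 0, 0)))
  # d_R = 100 pm, d_P = 300 pm -> breakage
  expect_equal(as.character(
    classify_pairs(reaction(mk(1.0), mk(3.0)))$category), "breakage")
  expect_equal(as.character(
    classify_pairs(reaction(mk(3.0), mk(1.0)))$category), "formation")
  expect_equal(as.character(
    classify_pairs(reaction(mk(2.0), mk(2.0)))$category), "none_none")
  expect_equal(as.character(
    classify_pairs(reaction(mk(1.0), mk(1.2)))$category), "bond_bond")
  # threshold is configurable
  expect_equal(as.character(
    classify_pairs(reaction(mk(2.0), mk(2.0)), theta_bond = 250)$category),
    "bond_bond")
})

test_that("classification covers all pairs and reversal swaps categories", {
  rxns <- synthetic_reactions(6, n_atoms_range = c(4, 7), seed = 21)
  for (r in rxns) {
    n <- n_atoms(r$reactant)
    cp <- classify_pairs(r)
    expect_identical(nrow(cp), as.integer(n * (n - 1) / 2))
    cr <- classify_pairs(reverse_reaction(r))
    swap <- c(none_none = "none_none", formation = "breakage",
              breakage = "formation", bond_bond = "bond_bond")
    expect_identical(as.character(cr$category),
                     unname(swap[as.character(cp$category)]))
  }
})

test_that("reaction reversal swaps roles, fixes ts_ref, and is an involution", {
  r <- synthetic_reactions(1, n_atoms_range = c(4, 4), seed = 5)[[1]]
  rev <- reverse_reaction(r)
  expect_identical(rev$reactant$coordinates, r$product$coordinates)
  expect_identical(rev$ts_ref$coordinates, r$ts_ref$coordinates)
  expect_identical(rev$properties$reactant, r$properties$product)
  expect_identical(reverse_reaction(rev)$reactant$coordinates,
                   r$reactant$coordinates)
  expect_error(reaction(structure3d(c(1L, 6L), matrix(0:5, 2, 3)),
                        structure3d(c(6L, 1L), matrix(0:5, 2, 3))),
               "element order")
})
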