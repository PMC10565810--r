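test_that("toy complexes match their designed coordination pattern", {
  for (bb in c("PNP", "SNS", "CNC", "PNN")) {
    tc <- make_toy_complex(bb)
    g <- perceive_bonds(tc$structure)
    expect_identical(g$edges, tc$graph$edges)
    expect_identical(coordination_number(g, tc$metal_index), 6L)
    expect_no_error(validate_annotation(tc$annotation, g))
  }
  expect_error(make_toy_complex("XYZ"), "unknown preset")
  # the alias preset
  expect_identical(make_toy_complex("octahedral_pincer")$backbone, "PNP")
})

test_that("toy complexes regenerate coordinate-identically", {
  a <- make_toy_complex("CNC")
  b <- make_toy_complex("CNC")
  expect_identical(a$structure$coords, b$structure$coords)
})

test_that("annotated donors and adduct are metal neighbors", {
  for (bb in c("PNP", "PNN")) {
    tc <- make_toy_complex(bb)
    g <- perceive_bonds(tc$structure)
    e <- g$edges[g$edges$class != "weak", ]
    nb <- sort(c(e$j[e$i == tc$metal_index], e$i[e$j == tc$metal_index]))
    expect_true(all(tc$annotation$donor_indices %in% nb))
    expect_true(all(tc$annotation$adduct_indices %in% nb))
  }
})

test_that("substituent fragments have sane perceived topology", {
  counts <- c(H = 0L, Br = 0L, CF3 = 3L, CH3 = 3L, OH = 1L,
              Ph = 11L, tBu = 12L, iPr = 9L, cy = 17L, OCH3 = 4L, OtBu = 13L)
  for (nm in names(counts)) {
    sub <- toy_substituent(nm)
    g <- perceive_bonds(sub$geometry)
    expect_identical(nrow(g$edges), counts[[nm]])
  }
  expect_error(toy_substituent("nope"), "unknown substituent")
})

test_that("an event-free script yields exactly one conformer", {
  tc <- make_toy_complex("PNP")
  sc <- event_script(list(), segment_energies_kcal = 0)
  traj <- make_trajectory(tc$structure, sc, 8L, jitter = 0.01, seed = 3L)
  expect_length(identify_conformers(traj)$records, 1L)
  # frame 0 equals the start structure exactly
  expect_identical(traj$frames[[1L]]$coords, tc$structure$coords)
})

test_that("trajectory generation is byte-identical for equal seeds", {
  tc <- make_toy_complex("SNS")
  arm <- tc$arms[[1L]]
  sc <- event_script(list(
    script_break_bond(3, tc$metal_index, arm$donor,
                      group = c(arm$donor, arm$r1),
                      mode = "pivot", pivot = arm$c1)
  ))
  p1 <- withr::local_tempfile(fileext = ".xyz")
  p2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(make_trajectory(tc$structure, sc, 6L, 0.02, 17L), p1)
  write_xyz_trajectory(make_trajectory(tc$structure, sc, 6L, 0.02, 17L), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("unrealizable scripts fail at generation time", {
  tc <- make_toy_complex("PNP")
  # breaking a bond that does not exist
  sc <- event_script(list(script_break_bond(2, tc$metal_index, tc$nh)))
  expect_error(make_trajectory(tc$structure, sc, 5L, 0.01, 1L),
               "absent bond")
  # scripts must fit within the frame budget and spare frame 0
  arm <- tc$arms[[1L]]
  st <- script_break_bond(9, tc$metal_index, arm$donor,
                          group = c(arm$donor, arm$r1),
                          mode = "pivot", pivot = arm$c1)
  expect_error(make_trajectory(tc$structure, event_script(list(st)), 5L,
                               0.01, 1L), "past n_frames")
  st$frame <- 0
  expect_error(make_trajectory(tc$structure, event_script(list(st)), 5L,
                               0.01, 1L), "frame 0")
})

test_that("segment energies are piecewise constant in the written units", {
  tc <- make_toy_complex("PNP")
  arm <- tc$arms[[1L]]
  sc <- event_script(list(
    script_break_bond(2, tc$metal_index, arm$donor,
                      group = c(arm$donor, arm$r1),
                      mode = "pivot", pivot = arm$c1)
  ), segment_energies_kcal = c(0, -7.5))
  traj <- make_trajectory(tc$structure, sc, 4L, 0.02, 19L,
                          base_energy = -5.0)
  e <- vapply(traj$frames, `[[`, numeric(1), "energy")
  expect_equal(e[1:2], rep(-5.0, 2L))
  expect_equal(e[3:4], rep(-5.0 - 7.5 / 627.509, 2L))
})

test_that("the fixture corpus covers the reaction families and validates", {
  corp <- make_fixture_corpus(seed = 4L)
  expect_gte(length(corp), 25L)
  final_labels <- lapply(corp, function(e)
    e$expected$segment_labels[[e$expected$n_conformers]])
  all_lab <- unlist(final_labels)
  expect_true(any(grepl("^-Mn-[NPSC]$", all_lab)))   # decoordination family
  expect_true("+C-O" %in% all_lab)                   # nucleophilic attack
  expect_true("+Mn-C" %in% all_lab && "-C-P" %in% all_lab)  # migration
  expect_true("+Mn-H" %in% all_lab)                  # agostic contacts
  # every trajectory already re-validated against its own script at
  # generation; spot-check the advertised determinism
  corp2 <- make_fixture_corpus(seed = 4L)
  expect_identical(corp$PNP_agostic$trajectory$frames[[5L]]$coords,
                   corp2$PNP_agostic$trajectory$frames[[5L]]$coords)
})

test_that("random trajectories are reproducible and well formed", {
  t1 <- random_trajectory(seed = 99L)
  t2 <- random_trajectory(seed = 99L)
  expect_identical(t1$frames[[2L]]$coords, t2$frames[[2L]]$coords)
  expect_true(length(t1$frames) <= 50L)
  expect_true(length(t1$frames[[1L]]$elements) <= 30L)
})
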