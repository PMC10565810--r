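test_that("identical frames collapse to a single conformer", {
  tc <- make_toy_complex("PNP")
  frames <- lapply(1:10, function(f) {
    xyz_frame(tc$structure$elements, tc$structure$coords, energy = -5.0,
              frame_index = f - 1L)
  })
  cs <- identify_conformers(xyz_trajectory(frames))
  expect_length(cs$records, 1L)
  expect_identical(cs$records[[1L]]$member_frames, 0:9)
  expect_identical(nrow(cs$records[[1L]]$changes), 0L)
  expect_identical(cs$records[[1L]]$delta_e, 0)
})

test_that("a scripted bond break splits the trajectory into two conformers", {
  tc <- make_toy_complex("PNP")
  arm <- tc$arms[[1L]]
  sc <- event_script(list(
    script_break_bond(5, tc$metal_index, arm$donor,
                      group = c(arm$donor, arm$r1),
                      mode = "pivot", pivot = arm$c1)
  ), segment_energies_kcal = c(0, -12))
  traj <- make_trajectory(tc$structure, sc, 10L, jitter = 0.02, seed = 5L)
  cs <- identify_conformers(traj)
  expect_length(cs$records, 2L)
  expect_identical(cs$records[[1L]]$member_frames, 0:4)
  expect_identical(cs$records[[2L]]$member_frames, 5:9)
  expect_identical(cs$records[[2L]]$changes$label, "-Mn-P")
  expect_equal(cs$records[[2L]]$delta_e, -12)
  expect_identical(oracle_conformer_partition(traj),
                   match(cs$assignments, unique(cs$assignments)))
})

test_that("frame order does not change the conformer partition", {
  tc <- make_toy_complex("SNS")
  arm <- tc$arms[[1L]]
  sc <- event_script(list(
    script_break_bond(4, tc$metal_index, arm$donor,
                      group = c(arm$donor, arm$r1),
                      mode = "pivot", pivot = arm$c1)
  ))
  traj <- make_trajectory(tc$structure, sc, 8L, jitter = 0.02, seed = 6L)
  a <- identify_conformers(traj)$assignments
  set.seed(9)
  perm <- c(1L, sample(2:8))  # frame 0 stays the reference
  traj2 <- xyz_trajectory(traj$frames[perm], energy_units = traj$energy_units)
  b <- identify_conformers(traj2)$assignments
  expect_identical(match(a[perm], unique(a[perm])), match(b, unique(b)))
})

test_that("energy bookkeeping uses the minimum member energy", {
  # piecewise profile with in-segment variation: hand-build a trajectory
  tc <- make_toy_complex("PNP")
  e <- c(-5.000, -4.999, -5.001)  # hartree
  frames <- lapply(seq_along(e), function(f)
    xyz_frame(tc$structure$elements, tc$structure$coords, energy = e[f],
              frame_index = f - 1L))
  cs <- identify_conformers(xyz_trajectory(frames))
  r <- cs$records[[1L]]
  expect_equal(r$e_min, -5.001 * 627.509)
  expect_equal(r$e_max, -4.999 * 627.509)
  expect_identical(r$delta_e, 0)
})

test_that("missing energies warn and propagate as NA", {
  frames <- list(h2o_frame(energy = -5), h2o_frame())
  expect_warning(cs <- identify_conformers(xyz_trajectory(frames)),
                 "missing energies")
  expect_true(is.na(cs$records[[1L]]$e_min))
})

test_that("positional diffs follow the set algebra of edges", {
  g <- random_molgraph(201L, n = 6L, p_edge = 0.5)
  expect_identical(nrow(diff_bonds(g, g)), 0L)

  # constructed 5-atom case: lose Mn-O, gain P-O
  els <- c("Mn", "O", "H", "P", "C")
  ref <- molgraph(els, data.frame(i = c(1L, 2L, 1L), j = c(2L, 3L, 4L),
                                  class = c("coordination", "covalent",
                                            "coordination")))
  conf <- molgraph(els, data.frame(i = c(2L, 1L, 2L), j = c(3L, 4L, 4L),
                                   class = c("covalent", "coordination",
                                             "covalent")))
  d <- diff_bonds(conf, ref)
  expect_setequal(d$label, c("-Mn-O", "+O-P"))
  expect_error(diff_bonds(g, random_molgraph(202L, n = 5L)), "atom sequence")
})

test_that("formed and broken swap under argument exchange", {
  for (seed in 211:218) {
    els <- c("Mn", "C", "O", "N", "H", "P")
    g1 <- random_molgraph(seed, n = 6L, p_edge = 0.4)
    g2 <- random_molgraph(seed + 50L, n = 6L, p_edge = 0.4)
    g2 <- molgraph(g1$elements, g2$edges)   # same atom sequence
    d12 <- diff_bonds(g1, g2)
    d21 <- diff_bonds(g2, g1)
    key <- function(d, s) sort(paste(d$i[d$sign == s], d$j[d$sign == s],
                                     d$class[d$sign == s]))
    expect_identical(key(d12, "formed"), key(d21, "broken"))
    expect_identical(key(d12, "broken"), key(d21, "formed"))
  }
})

test_that("coordination number counts non-weak metal edges", {
  tc <- make_toy_complex("CNC")
  expect_identical(coordination_number(tc$graph, tc$metal_index), 6L)
  e <- tc$graph$edges
  drop <- which((e$i == tc$metal_index | e$j == tc$metal_index) &
                  e$class == "coordination")[1L]
  expect_identical(coordination_number(molgraph(tc$graph$elements, e[-drop, ]),
                                       tc$metal_index), 5L)
  # degree oracle on random graphs
  for (seed in 221:226) {
    g <- random_molgraph(seed, n = 7L, p_edge = 0.5)
    m <- 1L
    manual <- sum((g$edges$i == m | g$edges$j == m) & g$edges$class != "weak")
    expect_identical(coordination_number(g, m), manual)
  }
})

test_that("event labels add side-arm and adduct semantics", {
  ann <- ref_annotation(1L, donor_indices = c(2L, 3L, 4L),
                        donor_roles = c("side_arm", "side_arm", "central"),
                        adduct_indices = 5L)
  ch <- function(sign, i, j, class, label) {
    data.frame(sign = sign, i = i, j = j, class = class, label = label,
               stringsAsFactors = FALSE)
  }
  expect_identical(label_events(ch(character(0), integer(0), integer(0),
                                   character(0), character(0)), ann),
                   character(0))
  # one side-arm loss
  d <- ch("broken", 1L, 2L, "coordination", "-Mn-P")
  expect_setequal(label_events(d, ann), c("-Mn-P", "-side arm"))
  # two side arms
  d <- rbind(ch("broken", 1L, 2L, "coordination", "-Mn-S"),
             ch("broken", 1L, 3L, "coordination", "-Mn-S"))
  expect_setequal(label_events(d, ann), c("-Mn-S(2)", "-side arm(2)"))
  # central donor loss is elemental only
  d <- ch("broken", 1L, 4L, "coordination", "-Mn-N")
  expect_setequal(label_events(d, ann), "-Mn-N")
  # adduct fully detached
  d <- ch("broken", 1L, 5L, "coordination", "-Mn-O")
  expect_setequal(label_events(d, ann), c("-Mn-O", "-adduct"))
})

test_that("hemilability flags only stabilizing donor decoordination", {
  tc <- make_toy_complex("PNN")
  arm <- tc$arms[[1L]]
  mk <- function(de) {
    sc <- event_script(list(
      script_break_bond(3, tc$metal_index, arm$donor,
                        group = c(arm$donor, arm$r1),
                        mode = "pivot", pivot = arm$c1)
    ), segment_energies_kcal = c(0, de))
    analyze_trajectory(make_trajectory(tc$structure, sc, 6L, 0.02, 31L),
                       tc$annotation)
  }
  expect_identical(detect_hemilability(mk(-12), tc$annotation), 2L)
  expect_identical(detect_hemilability(mk(5), tc$annotation), integer(0))
  # brute-force filter oracle over the records of both runs
  cs <- mk(-12)
  manual <- integer(0)
  for (r in cs$records) {
    br <- r$changes[r$changes$sign == "broken" & r$changes$class != "weak", ]
    others <- c(br$j[br$i == tc$metal_index], br$i[br$j == tc$metal_index])
    if (any(others %in% tc$annotation$donor_indices) && r$delta_e < 0) {
      manual <- c(manual, r$conformer_id)
    }
  }
  expect_identical(detect_hemilability(cs, tc$annotation), manual)
})

test_that("the evolution graph is a star with energy annotations", {
  tc <- make_toy_complex("PNP")
  arm1 <- tc$arms[[1L]]; arm2 <- tc$arms[[2L]]
  sc <- event_script(list(
    script_break_bond(3, tc$metal_index, arm1$donor,
                      group = c(arm1$donor, arm1$r1), mode = "pivot",
                      pivot = arm1$c1),
    script_break_bond(6, tc$metal_index, arm2$donor,
                      group = c(arm2$donor, arm2$r1), mode = "pivot",
                      pivot = arm2$c1)
  ))
  cs <- analyze_trajectory(make_trajectory(tc$structure, sc, 9L, 0.02, 12L),
                           tc$annotation)
  g <- build_evolution_graph(cs)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  deg <- igraph::degree(g)
  expect_equal(unname(deg[1L]), 2)               # reference is the hub
  expect_equal(igraph::V(g)$delta_e, c(0, -10, -20))

  # single-conformer degenerate case
  cs1 <- identify_conformers(xyz_trajectory(list(
    h2o_frame(energy = -5, frame_index = 0L))))
  g1 <- build_evolution_graph(cs1)
  expect_equal(igraph::vcount(g1), 1)
  expect_equal(igraph::ecount(g1), 0)
})

test_that("evolution graphs round-trip through GraphML", {
  tc <- make_toy_complex("SNS")
  arm <- tc$arms[[1L]]
  sc <- event_script(list(
    script_break_bond(4, tc$metal_index, arm$donor,
                      group = c(arm$donor, arm$r1), mode = "pivot",
                      pivot = arm$c1)
  ))
  cs <- analyze_trajectory(make_trajectory(tc$structure, sc, 8L, 0.02, 13L),
                           tc$annotation)
  g <- build_evolution_graph(cs)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_evolution_graph(g, path, format = "graphml")
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_equal(igraph::V(back)$delta_e, igraph::V(g)$delta_e)
  expect_identical(igraph::V(back)$members, igraph::V(g)$members)
  # DOT export exists and is non-empty
  dot <- withr::local_tempfile(fileext = ".dot")
  write_evolution_graph(g, dot, format = "dot")
  expect_gt(file.size(dot), 0)
})
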