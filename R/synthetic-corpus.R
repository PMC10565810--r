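# The shipped fixture corpus: scripted trajectories covering the three
# recurring reaction families (metal-donor decoordination, nucleophilic
# C-O bond formation onto a carbonyl, CF3-type group migration) plus
# agostic weak contacts, across all four toy backbones.

.corpus_entry <- function(name, traj, ann) {
  list(name = name, trajectory = traj, annotation = ann,
       expected = attr(traj, "expected"))
}

#' Generate the scripted fixture corpus
#'
#' Deterministically builds >= 25 scripted trajectories over the four toy
#' pincer backbones: single and double side-arm decoordination, central
#' donor decoordination, adduct loss, agostic metal-H contact formation,
#' CF3 migration from a donor to the metal, and nucleophilic attack of a
#' hydroxide adduct on a carbonyl carbon. Each entry carries the
#' annotation of its reference complex and the script-derived expectation
#' (conformer segmentation and cumulative bond-change labels), which the
#' generator itself has already verified against the emitted frames.
#'
#' @param seed Base seed; entry k uses `seed * 1000 + k`.
#' @param n_frames Frames per trajectory.
#' @param jitter Coordinate jitter in Angstrom (reduced automatically for
#'   fixtures whose target distances sit close to a perception threshold).
#' @return Named list of entries: `name`, `trajectory`, `annotation`,
#'   `expected`.
#' @export
make_fixture_corpus <- function(seed = 1L, n_frames = 10L, jitter = 0.02) {
  out <- list()
  k <- 0L
  add <- function(name, traj, ann) {
    k <<- k + 1L
    out[[name]] <<- .corpus_entry(name, traj, ann)
  }
  nseed <- function() as.integer(seed * 1000L + k + 1L)

  for (bb in names(.backbone_donors)) {
    tc <- make_toy_complex(bb)
    mn <- tc$metal_index
    arm1 <- tc$arms[[1L]]; arm2 <- tc$arms[[2L]]

    # single side-arm decoordination (hemilabile: more stable than ref)
    sc <- event_script(list(
      script_break_bond(5, mn, arm1$donor, group = c(arm1$donor, arm1$r1),
                        mode = "pivot", pivot = arm1$c1)
    ), segment_energies_kcal = c(0, -12))
    add(paste0(bb, "_arm1_decoord"),
        make_trajectory(tc$structure, sc, n_frames, jitter, nseed()),
        tc$annotation)

    sc <- event_script(list(
      script_break_bond(5, mn, arm2$donor, group = c(arm2$donor, arm2$r1),
                        mode = "pivot", pivot = arm2$c1)
    ), segment_energies_kcal = c(0, -8))
    add(paste0(bb, "_arm2_decoord"),
        make_trajectory(tc$structure, sc, n_frames, jitter, nseed()),
        tc$annotation)

    # double side-arm decoordination ("-side arm(2)")
    sc <- event_script(list(
      script_break_bond(3, mn, arm1$donor, group = c(arm1$donor, arm1$r1),
                        mode = "pivot", pivot = arm1$c1),
      script_break_bond(6, mn, arm2$donor, group = c(arm2$donor, arm2$r1),
                        mode = "pivot", pivot = arm2$c1)
    ), segment_energies_kcal = c(0, -6, -15))
    add(paste0(bb, "_both_arms_decoord"),
        make_trajectory(tc$structure, sc, n_frames, jitter, nseed()),
        tc$annotation)

    # adduct detachment (uphill: not hemilability)
    sc <- event_script(list(
      script_break_bond(5, mn, tc$adduct_site, group = tc$adduct_site)
    ), segment_energies_kcal = c(0, 7))
    add(paste0(bb, "_adduct_loss"),
        make_trajectory(tc$structure, sc, n_frames, jitter, nseed()),
        tc$annotation)

    # central donor decoordination (N-H rides along; backbone retained);
    # the folded CNC arms leave the central N no clean exit, so that
    # backbone instead contributes a compound side-arm + agostic fixture
    if (bb != "CNC") {
      sc <- event_script(list(
        script_break_bond(5, mn, tc$central_n, group = c(tc$central_n, tc$nh))
      ), segment_energies_kcal = c(0, -5))
      add(paste0(bb, "_central_decoord"),
          make_trajectory(tc$structure, sc, n_frames, jitter, nseed()),
          tc$annotation)
    } else {
      sc <- event_script(list(
        script_break_bond(3, mn, arm1$donor, group = c(arm1$donor, arm1$r1),
                          mode = "pivot", pivot = arm1$c1),
        script_form_bond(6, mn, arm2$r1[1L], group = arm2$r1[1L],
                         class = "weak", mode = "pivot", pivot = arm2$donor)
      ), segment_energies_kcal = c(0, -4, -11))
      add("CNC_arm_plus_agostic",
          make_trajectory(tc$structure, sc, n_frames, jitter = 0.005,
                          seed = nseed()),
          tc$annotation)
    }

    # agostic Mn...H contact: swing a ligand C-H into the weak window
    # (a backbone CH2 proton, except on CNC where the donor's R1 proton
    # has the cleaner approach)
    ag <- if (bb == "CNC") c(arm1$r1[1L], arm1$donor) else
      c(arm1$ch2_h[1L], arm1$c1)
    sc <- event_script(list(
      script_form_bond(5, mn, ag[1L], group = ag[1L], class = "weak",
                       mode = "pivot", pivot = ag[2L])
    ), segment_energies_kcal = c(0, -3))
    add(paste0(bb, "_agostic"),
        make_trajectory(tc$structure, sc, n_frames, jitter = 0.005,
                        seed = nseed()),
        tc$annotation)
  }

  # CF3 migration on PNP: side arm swings out, CF3 hops from P to Mn
  tc <- make_toy_complex("PNP")
  n0 <- length(tc$structure$elements)
  geo <- attach_substituent(tc$structure, tc$arms[[1L]]$r1[1L],
                            toy_substituent("CF3"))
  map <- attr(geo, "index_map")
  cf3 <- (n0 - 1L) + 1:4
  mn <- map[tc$metal_index]
  don <- map[tc$arms[[1L]]$donor]
  ann <- ref_annotation(
    metal_index = mn,
    donor_indices = map[tc$annotation$donor_indices],
    donor_roles = tc$annotation$donor_roles,
    adduct_indices = map[tc$adduct_site],
    features = list(backbone = "PNP", r1 = "CF3", r2 = "H", adduct = "H")
  )
  # the adduct leaves first; the CF3 then migrates into the vacated axial
  # site with its fluorines turned away from the metal
  vac <- .unit(geo$coords[map[tc$adduct_site], ] - geo$coords[mn, ])
  sc <- event_script(list(
    script_break_bond(3, mn, map[tc$adduct_site],
                      group = map[tc$adduct_site], target = 3.8),
    script_move_group(6, group = cf3, ref = cf3[1L],
                      at = geo$coords[mn, ] + 2.0 * vac,
                      orient = list(from = cf3[2:4], to = vac),
                      formed = list(c(mn, cf3[1L])),
                      broken = list(c(don, cf3[1L])))
  ), segment_energies_kcal = c(0, 6, -20))
  add("PNP_CF3_migration",
      make_trajectory(geo, sc, n_frames, jitter, nseed()), ann)

  # nucleophilic attack of an OH adduct on a carbonyl carbon (CNC)
  tc <- make_toy_complex("CNC")
  n0 <- length(tc$structure$elements)
  geo <- attach_substituent(tc$structure, tc$adduct_site, toy_substituent("OH"))
  map <- attr(geo, "index_map")
  oh <- (n0 - 1L) + 1:2
  mn <- map[tc$metal_index]
  co1c <- map[tc$co[[1L]][1L]]
  ann <- ref_annotation(
    metal_index = mn,
    donor_indices = map[tc$annotation$donor_indices],
    donor_roles = tc$annotation$donor_roles,
    adduct_indices = oh[1L],
    features = list(backbone = "CNC", r1 = "H", r2 = "H", adduct = "OH")
  )
  co1_pos <- geo$coords[co1c, ]
  sc <- event_script(list(
    script_move_group(5, group = oh, ref = oh[1L],
                      at = co1_pos + 1.40 * .unit(c(0, -0.1, -1)),
                      orient = list(from = oh[2L], to = c(0, -0.45, -0.9)),
                      formed = list(c(oh[1L], co1c)),
                      broken = list())
  ), segment_energies_kcal = c(0, -9))
  add("CNC_OH_carbonyl_attack",
      make_trajectory(geo, sc, n_frames, jitter, nseed()), ann)

  # event-free control: one conformer, empty diff
  tc <- make_toy_complex("PNP")
  sc <- event_script(list(), segment_energies_kcal = 0)
  add("PNP_no_event",
      make_trajectory(tc$structure, sc, n_frames, jitter, nseed()),
      tc$annotation)

  out
}
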