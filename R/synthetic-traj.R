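# Scripted trajectories: bond events realized as rigid group motions
# (translation along a bond axis, or pivot rotation about an atom), with
# per-frame Gaussian jitter and piecewise-constant energy segments.
# The generator validates itself: every emitted frame's perceived edge set
# must equal the edge set the script prescribes for that segment.

# bond class and perception threshold for an element pair
.pair_rule <- function(el_i, el_j, params, table) {
  ri <- table$covalent_radius[[el_i]]; rj <- table$covalent_radius[[el_j]]
  mi <- table$is_metal[[el_i]]; mj <- table$is_metal[[el_j]]
  if (!mi && !mj) {
    list(class = "covalent", threshold = params$covalent_scale * (ri + rj),
         natural = ri + rj)
  } else {
    list(class = "coordination", threshold = params$metal_scale * (ri + rj),
         natural = ri + rj)
  }
}

#' Scripted-event container for trajectory synthesis
#'
#' @param steps List of steps from [script_break_bond()],
#'   [script_form_bond()] or [script_move_group()], with strictly
#'   increasing `frame` fields (frame 0 is the unperturbed start).
#' @param segment_energies_kcal Relative energy of each conformer segment
#'   in kcal/mol (length `length(steps) + 1`, first entry 0 for the
#'   reference); defaults to a -10 kcal/mol staircase. Energies are
#'   piecewise constant per segment so energy bookkeeping downstream is
#'   analytic.
#' @return An object of class `event_script`.
#' @export
event_script <- function(steps, segment_energies_kcal = NULL) {
  frames <- vapply(steps, `[[`, numeric(1), "frame")
  if (length(frames) > 1L && any(diff(frames) <= 0)) {
    stop("step frames must be strictly increasing")
  }
  if (is.null(segment_energies_kcal)) {
    segment_energies_kcal <- seq(0, by = -10, length.out = length(steps) + 1L)
  }
  if (length(segment_energies_kcal) != length(steps) + 1L) {
    stop("need one segment energy per conformer segment (n_steps + 1)")
  }
  structure(list(steps = steps, segment_energies_kcal = segment_energies_kcal),
            class = "event_script")
}

#' Script a bond-breaking event
#'
#' At the given frame the atoms in `group` (which must contain `j` but not
#' `i`) move rigidly so that the i-j distance leaves the perception
#' threshold: either translated along the i->j axis (`mode =
#' "set_distance"`) or swung about a `pivot` atom, which preserves the
#' group's bond to the pivot (`mode = "pivot"`, the decoordination-arm
#' motion).
#'
#' @param frame Trajectory frame at which the event happens.
#' @param i,j Atom indices of the breaking bond (`i` stays put).
#' @param group Atom indices moved rigidly with `j`.
#' @param mode `"set_distance"`, `"pivot"`, or `"hinge"` (rotate the group
#'   about the axis through the two `axis` atoms - a ring-fold motion that
#'   preserves every group atom's distance to both hinge atoms).
#' @param pivot Pivot atom index (required for `mode = "pivot"`).
#' @param axis Two atom indices defining the hinge axis (for
#'   `mode = "hinge"`).
#' @param target Final i-j distance in Angstrom; defaults to 1.2x the
#'   perception threshold (and beyond the agostic window for metal-H).
#' @return A script step.
#' @export
script_break_bond <- function(frame, i, j, group = j,
                              mode = c("set_distance", "pivot", "hinge"),
                              pivot = NULL, axis = NULL, target = NULL) {
  mode <- match.arg(mode)
  list(frame = frame, kind = "break", i = i, j = j, group = group,
       mode = mode, pivot = pivot, axis = axis, target = target)
}

#' Script a bond-forming event
#'
#' The atoms in `group` move rigidly (translation along the i->j axis) so
#' the i-j distance enters the perception window for the requested bond
#' class.
#'
#' @inheritParams script_break_bond
#' @param class Bond class to form; `"weak"` places the distance inside
#'   the agostic metal-H window (beyond the coordination threshold),
#'   otherwise the class follows from the element pair.
#' @param mode `"set_distance"` (translate) or `"pivot"` (swing about
#'   `pivot`, preserving the group's bond to it).
#' @export
script_form_bond <- function(frame, i, j, group = j, class = NULL,
                             mode = c("set_distance", "pivot"),
                             pivot = NULL, target = NULL) {
  mode <- match.arg(mode)
  list(frame = frame, kind = "form", i = i, j = j, group = group,
       mode = mode, pivot = pivot, target = target, class = class)
}

#' Script an explicit group displacement
#'
#' For compound events (e.g. a migrating group that leaves one atom and
#' binds another): the group is translated by `vec` (or so that atom
#' `ref` lands at `at`), and the caller declares the bond changes this
#' motion is designed to produce.
#'
#' @param frame Trajectory frame.
#' @param group Atom indices moved rigidly.
#' @param vec Translation vector (3-vector), or `NULL` when using
#'   `ref`/`at`.
#' @param ref,at Alternative: translate so atom `ref` ends at position
#'   `at`.
#' @param orient Optional reorientation applied about `ref` before the
#'   translation: `list(from = <atom indices>, to = <3-vector>)` rotates
#'   the group so the mean direction from `ref` to the `from` atoms
#'   aligns with `to` (e.g. pointing a migrating group's substituents
#'   away from its destination).
#' @param formed,broken Lists of `c(i, j)` atom pairs (or `c(i, j, class)`)
#'   expected to form/break.
#' @export
script_move_group <- function(frame, group, vec = NULL, ref = NULL, at = NULL,
                              orient = NULL, formed = list(), broken = list()) {
  list(frame = frame, kind = "move", group = group, vec = vec,
       ref = ref, at = at, orient = orient, formed = formed, broken = broken)
}

# rotate `group` rows of coords about the axis through `pivot` point along
# unit vector `ax` by angle theta
.rotate_group <- function(coords, group, pivot_pos, ax, theta) {
  R <- .rotation_about(ax, theta)
  rel <- sweep(coords[group, , drop = FALSE], 2L, pivot_pos)
  coords[group, ] <- sweep(rel %*% t(R), 2L, pivot_pos, `+`)
  coords
}

# rotate `group` about a given axis (point + unit direction) until
# dist(anchor_pos, coords[ref,]) == target
.rotate_to_distance <- function(coords, group, pv, ax, anchor_pos, ref, target) {
  f <- function(theta) {
    cc <- .rotate_group(coords, group, pv, ax, theta)
    .vdist(anchor_pos, cc[ref, ]) - target
  }
  f0 <- f(0)
  dir <- if (f(0.05) - f0 >= 0) 1 else -1   # branch on which distance grows
  want <- if (f0 < 0) dir else -dir          # grow if below target else shrink
  th <- 0; step <- 0.05 * want; found <- NA
  while (abs(th) < pi) {
    th2 <- th + step
    if (sign(f(th2)) != sign(f0) || f(th2) == 0) { found <- th2; break }
    th <- th2
  }
  if (is.na(found)) stop("pivot cannot reach target distance ", target)
  root <- stats::uniroot(f, sort(c(th, found)), tol = 1e-10)$root
  .rotate_group(coords, group, pv, ax, root)
}

# swing `group` about `pivot` atom until dist(anchor_pos, coords[ref,]) ==
# target; rotation axis is perpendicular to the anchor/ref/pivot plane
.pivot_to_distance <- function(coords, group, pivot, anchor_pos, ref, target) {
  pv <- coords[pivot, ]
  ax <- .cross(coords[ref, ] - pv, anchor_pos - pv)
  nax <- sqrt(sum(ax^2))
  if (nax < 1e-8) stop("pivot axis degenerate (collinear atoms)")
  .rotate_to_distance(coords, group, pv, ax / nax, anchor_pos, ref, target)
}

# rotate `group` about the axis through two atoms (a hinge fold: every
# group atom keeps its distance to both hinge atoms)
.hinge_to_distance <- function(coords, group, axis_atoms, anchor_pos, ref,
                               target) {
  pv <- coords[axis_atoms[1L], ]
  ax <- coords[axis_atoms[2L], ] - pv
  nax <- sqrt(sum(ax^2))
  if (nax < 1e-8) stop("hinge axis degenerate")
  .rotate_to_distance(coords, group, pv, ax / nax, anchor_pos, ref, target)
}

.apply_step <- function(coords, elements, step, params, table) {
  if (step$kind == "move") {
    if (!is.null(step$orient)) {
      rp <- coords[step$ref, ]
      rel <- sweep(coords[step$orient$from, , drop = FALSE], 2L, rp)
      axis_now <- .unit(colSums(rel))
      R <- .rotation_align(axis_now, .unit(step$orient$to))
      g_rel <- sweep(coords[step$group, , drop = FALSE], 2L, rp)
      coords[step$group, ] <- sweep(g_rel %*% t(R), 2L, rp, `+`)
    }
    vec <- step$vec
    if (is.null(vec)) vec <- step$at - coords[step$ref, ]
    coords[step$group, ] <- sweep(coords[step$group, , drop = FALSE], 2L,
                                  vec, `+`)
    norm_pair <- function(p) {
      cl <- if (length(p) >= 3L) p[[3L]] else
        .pair_rule(elements[as.integer(p[[1L]])], elements[as.integer(p[[2L]])],
                   params, table)$class
      c(sort(as.integer(c(p[[1L]], p[[2L]]))), cl)
    }
    return(list(coords = coords,
                formed = lapply(step$formed, norm_pair),
                broken = lapply(step$broken, norm_pair)))
  }
  i <- step$i; j <- step$j
  rule <- .pair_rule(elements[i], elements[j], params, table)
  cls <- rule$class
  if (step$kind == "break") {
    target <- step$target
    if (is.null(target)) {
      target <- rule$threshold * 1.2
      # metal-H must also clear the agostic window
      if (cls == "coordination" && (elements[i] == "H" || elements[j] == "H")) {
        target <- max(target, params$weak_h_metal_max * 1.15)
      }
    }
  } else {
    if (identical(step$class, "weak")) {
      cls <- "weak"
      lo <- max(rule$threshold, params$weak_h_metal_min)
      target <- step$target %||% ((lo + params$weak_h_metal_max) / 2)
    } else {
      target <- step$target %||% min(rule$natural, 0.95 * rule$threshold)
    }
  }
  if (step$mode == "pivot") {
    coords <- .pivot_to_distance(coords, step$group, step$pivot,
                                 coords[i, ], j, target)
  } else if (step$mode == "hinge") {
    coords <- .hinge_to_distance(coords, step$group, step$axis,
                                 coords[i, ], j, target)
  } else {
    u <- .unit(coords[j, ] - coords[i, ])
    vec <- (coords[i, ] + target * u) - coords[j, ]
    coords[step$group, ] <- sweep(coords[step$group, , drop = FALSE], 2L,
                                  vec, `+`)
  }
  pair <- c(sort(c(i, j)), cls)
  if (step$kind == "break") {
    list(coords = coords, formed = list(), broken = list(pair))
  } else {
    list(coords = coords, formed = list(pair), broken = list())
  }
}

.edge_key <- function(edges) paste(edges$i, edges$j, edges$class)

#' Synthesize a trajectory with scripted bond events
#'
#' Builds an `n_frames` trajectory from a start structure: scripted group
#' motions are applied cumulatively at their frames, small Gaussian
#' coordinate jitter (seeded, frame 0 excluded) exercises the robustness
#' of the perception thresholds, and per-frame energies follow the
#' script's piecewise-constant segment profile. Before returning, the
#' generator re-perceives every emitted frame and verifies that its edge
#' set equals exactly the edge set prescribed by the script for that
#' segment - an unrealizable script fails loudly at generation time.
#'
#' @param start An [xyz_frame] (becomes frame 0, unjittered).
#' @param script An [event_script()].
#' @param n_frames Total frames; must exceed the last scripted frame.
#' @param jitter Per-coordinate Gaussian jitter, Angstrom.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param base_energy Reference energy in hartree for segment 0.
#' @param params,table Perception settings the script is realized against.
#' @return An [xyz_trajectory] (energies in hartree) with attribute
#'   `expected`: list with `assignments` (segment index per frame, 1-based),
#'   `n_conformers`, `segment_labels` (cumulative bond-change labels per
#'   segment), `segment_edges`.
#' @export
make_trajectory <- function(start, script, n_frames, jitter = 0.02, seed = 1L,
                            base_energy = -5.0, params = bond_params(),
                            table = element_table()) {
  stopifnot(inherits(start, "xyz_frame"), inherits(script, "event_script"))
  steps <- script$steps
  step_frames <- vapply(steps, `[[`, numeric(1), "frame")
  if (length(steps) > 0L && max(step_frames) >= n_frames) {
    stop("script extends past n_frames")
  }
  if (length(steps) > 0L && min(step_frames) < 1L) {
    stop("events cannot be scripted at frame 0 (the reference)")
  }
  ref_graph <- perceive_bonds(start, params = params, table = table)
  tab <- element_table()
  seg_edges <- list(ref_graph$edges)
  seg_labels <- list(character(0))
  coords <- start$coords
  base_coords <- list(coords)
  cum_changes <- list()
  for (s in seq_along(steps)) {
    res <- .apply_step(coords, start$elements, steps[[s]], params, table)
    coords <- res$coords
    prev <- seg_edges[[s]]
    key <- .edge_key(prev)
    for (b in res$broken) {
      k <- paste(b[1L], b[2L], b[3L])
      if (!(k %in% key)) stop("scripted break of absent bond: ", k)
      prev <- prev[key != k, , drop = FALSE]
      key <- .edge_key(prev)
      cum_changes[[length(cum_changes) + 1L]] <-
        paste0("-", .pair_label(start$elements[as.integer(b[1L])],
                                start$elements[as.integer(b[2L])], tab))
    }
    for (fm in res$formed) {
      k <- paste(fm[1L], fm[2L], fm[3L])
      if (k %in% key) stop("scripted formation of existing bond: ", k)
      prev <- rbind(prev, data.frame(i = as.integer(fm[1L]),
                                     j = as.integer(fm[2L]),
                                     class = fm[3L], stringsAsFactors = FALSE))
      prev <- prev[order(prev$i, prev$j), , drop = FALSE]
      rownames(prev) <- NULL
      key <- .edge_key(prev)
      cum_changes[[length(cum_changes) + 1L]] <-
        paste0("+", .pair_label(start$elements[as.integer(fm[1L])],
                                start$elements[as.integer(fm[2L])], tab))
    }
    seg_edges[[s + 1L]] <- prev
    seg_labels[[s + 1L]] <- sort(unlist(cum_changes))
    base_coords[[s + 1L]] <- coords
  }
  segment_of <- function(f) sum(step_frames <= f) + 1L   # f is 0-based
  set.seed(seed)
  frames <- vector("list", n_frames)
  e_seg <- base_energy + script$segment_energies_kcal / HARTREE_TO_KCAL
  for (f in seq_len(n_frames) - 1L) {
    seg <- segment_of(f)
    cc <- base_coords[[seg]]
    if (f > 0L && jitter > 0) {
      cc <- cc + matrix(stats::rnorm(length(cc), sd = jitter), nrow(cc), 3L)
    }
    frames[[f + 1L]] <- xyz_frame(start$elements, cc, energy = e_seg[seg],
                                  frame_index = f)
  }
  traj <- xyz_trajectory(frames, energy_units = "hartree")
  # self-validation: each frame's perceived edge set matches its segment
  for (f in seq_len(n_frames) - 1L) {
    g <- perceive_bonds(traj$frames[[f + 1L]], params = params, table = table)
    exp_e <- seg_edges[[segment_of(f)]]
    if (!identical(.edge_key(g$edges), .edge_key(exp_e))) {
      got <- .edge_key(g$edges); want <- .edge_key(exp_e)
      stop("script not geometrically realized at frame ", f,
           ": unexpected [", paste(setdiff(got, want), collapse = "; "),
           "] missing [", paste(setdiff(want, got), collapse = "; "), "]")
    }
  }
  attr(traj, "expected") <- list(
    assignments = vapply(seq_len(n_frames) - 1L, segment_of, integer(1)),
    n_conformers = length(seg_edges),
    segment_labels = seg_labels,
    segment_edges = seg_edges
  )
  traj
}

#' Random unscripted trajectory for stress testing
#'
#' A random-walk trajectory over a random small structure: organically
#' drifting geometry produces organically changing bond graphs with no
#' prescribed event structure. Used to compare the sequential conformer
#' identifier against brute-force all-pairs clustering.
#'
#' @param seed Integer seed.
#' @param n_atoms,n_frames Sizes (defaults drawn from the seed).
#' @param step_sd Random-walk step, Angstrom per coordinate per frame.
#' @return An [xyz_trajectory] with energies in hartree.
#' @export
random_trajectory <- function(seed, n_atoms = NULL, n_frames = NULL,
                              step_sd = 0.12) {
  set.seed(seed)
  if (is.null(n_atoms)) n_atoms <- sample(4:30, 1L)
  if (is.null(n_frames)) n_frames <- sample(5:50, 1L)
  pool <- c("H", "C", "N", "O", "P", "S", "Mn")
  els <- sample(pool, n_atoms, replace = TRUE)
  side <- max(4, 2.1 * n_atoms^(1 / 3))
  coords <- matrix(stats::runif(n_atoms * 3L, 0, side), n_atoms, 3L)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    frames[[f]] <- xyz_frame(els, coords,
                             energy = stats::runif(1, -5.05, -4.95),
                             frame_index = f - 1L)
    coords <- coords + matrix(stats::rnorm(n_atoms * 3L, sd = step_sd),
                              n_atoms, 3L)
  }
  xyz_trajectory(frames, energy_units = "hartree")
}
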