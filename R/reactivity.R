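# Trajectory reactivity analysis: unique-conformer identification by graph
# isomorphism, positional bond diffs against the reference frame, event
# labeling, hemilability detection and the evolution graph.

#' Reference-structure annotation
#'
#' Names the metal center, the donor atoms of the supporting ligand with
#' their roles (side-arm vs central), the adduct atoms bound to the metal,
#' and the categorical structural features of the complex. Atom indices are
#' 1-based positions into the reference structure.
#'
#' @param metal_index Index of the metal atom.
#' @param donor_indices Integer vector of ligand donor atoms.
#' @param donor_roles Character vector (same length), each `"side_arm"` or
#'   `"central"`.
#' @param adduct_indices Atoms of the adduct (X group) coordinated to the
#'   metal; typically the single donor atom of the anionic ligand.
#' @param features Named list/vector with entries `backbone`, `r1`, `r2`,
#'   `adduct` describing the complex.
#' @return An object of class `ref_annotation`.
#' @export
ref_annotation <- function(metal_index, donor_indices, donor_roles,
                           adduct_indices = integer(0), features = list()) {
  metal_index <- as.integer(metal_index)
  donor_indices <- as.integer(donor_indices)
  adduct_indices <- as.integer(adduct_indices)
  donor_roles <- as.character(donor_roles)
  stopifnot(
    length(metal_index) == 1L, metal_index >= 1L,
    length(donor_roles) == length(donor_indices),
    all(donor_roles %in% c("side_arm", "central"))
  )
  structure(
    list(metal_index = metal_index, donor_indices = donor_indices,
         donor_roles = donor_roles, adduct_indices = adduct_indices,
         features = as.list(features)),
    class = "ref_annotation"
  )
}

#' Check an annotation against a reference graph
#'
#' Donor and adduct atoms must actually be bonded (non-weak) neighbors of
#' the metal in the perceived reference graph.
#'
#' @param ann A [ref_annotation].
#' @param g The reference [molgraph].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_annotation <- function(ann, g) {
  stopifnot(inherits(ann, "ref_annotation"), inherits(g, "molgraph"))
  if (ann$metal_index > g$n_atoms) stop("metal_index out of range")
  e <- g$edges[g$edges$class != "weak", , drop = FALSE]
  nb <- c(e$j[e$i == ann$metal_index], e$i[e$j == ann$metal_index])
  for (d in c(ann$donor_indices, ann$adduct_indices)) {
    if (!(d %in% nb)) {
      stop("annotated atom ", d, " is not a metal neighbor in the reference graph")
    }
  }
  invisible(TRUE)
}

# element pair rendered metal-first, else alphabetically
.pair_label <- function(el_i, el_j, table = element_table()) {
  mi <- isTRUE(table$is_metal[[el_i]])
  mj <- isTRUE(table$is_metal[[el_j]])
  if (mj && !mi) {
    paste0(el_j, "-", el_i)
  } else if (mi && !mj) {
    paste0(el_i, "-", el_j)
  } else {
    paste(sort(c(el_i, el_j)), collapse = "-")
  }
}

#' Bond-change diff between a conformer and the reference
#'
#' Atoms are identity-tracked by position along a trajectory, so the diff
#' is positional: a bond present in the conformer but not in the reference
#' is formed (`"+"`); one present in the reference but not the conformer is
#' broken (`"-"`). Edge identity includes the bond class, so a contact that
#' changes class (e.g. coordination to weak) appears as one broken and one
#' formed change.
#'
#' @param conf,ref [molgraph] objects over the same atom sequence.
#' @return Data frame with columns `sign` (`"formed"`/`"broken"`), `i`,
#'   `j`, `class`, and `label` (`"+El-El"` / `"-El-El"`, metal element
#'   first where present).
#' @export
diff_bonds <- function(conf, ref) {
  stopifnot(inherits(conf, "molgraph"), inherits(ref, "molgraph"))
  if (conf$n_atoms != ref$n_atoms ||
      !identical(conf$elements, ref$elements)) {
    stop("graphs must share one atom sequence (positional diff)")
  }
  key <- function(g) paste(g$edges$i, g$edges$j, g$edges$class)
  kc <- key(conf); kr <- key(ref)
  formed <- conf$edges[!(kc %in% kr), , drop = FALSE]
  broken <- ref$edges[!(kr %in% kc), , drop = FALSE]
  tab <- element_table()
  mk <- function(e, sign, sym) {
    if (nrow(e) == 0L) {
      return(data.frame(sign = character(0), i = integer(0), j = integer(0),
                        class = character(0), label = character(0),
                        stringsAsFactors = FALSE))
    }
    lab <- vapply(seq_len(nrow(e)), function(k) {
      .pair_label(conf$elements[e$i[k]], conf$elements[e$j[k]], tab)
    }, character(1))
    data.frame(sign = sign, i = e$i, j = e$j, class = e$class,
               label = paste0(sym, lab), stringsAsFactors = FALSE)
  }
  out <- rbind(mk(formed, "formed", "+"), mk(broken, "broken", "-"))
  rownames(out) <- NULL
  out
}

#' Coordination number of the metal center
#'
#' Counts covalent and coordination edges at the metal; weak (agostic)
#' contacts do not contribute.
#'
#' @param g A [molgraph].
#' @param metal 1-based atom index of the metal center.
#' @return Integer coordination number.
#' @export
coordination_number <- function(g, metal) {
  stopifnot(inherits(g, "molgraph"), metal >= 1L, metal <= g$n_atoms)
  e <- g$edges[g$edges$class != "weak", , drop = FALSE]
  sum(e$i == metal | e$j == metal)
}

#' Render event labels from a bond-change diff
#'
#' Emits the elemental change labels (`"+El-El"` / `"-El-El"`, with a
#' `"(k)"` count suffix when the same change occurs k > 1 times) plus
#' derived labels: `"-side arm"` when a metal-donor bond to a side-arm
#' donor breaks (`"-side arm(2)"` for two side arms, and so on), and
#' `"-adduct"` when every metal-adduct bond is broken (adduct detachment).
#'
#' @param changes A diff from [diff_bonds()].
#' @param ann The reference [ref_annotation].
#' @return Sorted character vector of labels (a set).
#' @export
label_events <- function(changes, ann) {
  stopifnot(inherits(ann, "ref_annotation"))
  if (nrow(changes) == 0L) return(character(0))
  base <- table(changes$label)
  labels <- ifelse(base > 1L,
                   paste0(names(base), "(", as.integer(base), ")"),
                   names(base))
  m <- ann$metal_index
  broken <- changes[changes$sign == "broken", , drop = FALSE]
  other <- ifelse(broken$i == m, broken$j,
                  ifelse(broken$j == m, broken$i, NA_integer_))
  other <- other[!is.na(other) & broken$class != "weak"]
  side_arms <- ann$donor_indices[ann$donor_roles == "side_arm"]
  k <- length(unique(other[other %in% side_arms]))
  if (k == 1L) labels <- c(labels, "-side arm")
  if (k > 1L) labels <- c(labels, paste0("-side arm(", k, ")"))
  if (length(ann$adduct_indices) > 0L &&
      all(ann$adduct_indices %in% other)) {
    labels <- c(labels, "-adduct")
  }
  sort(unname(labels))
}

.empty_changes <- function() {
  data.frame(sign = character(0), i = integer(0), j = integer(0),
             class = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Identify unique conformers along a trajectory
#'
#' Scans frames in order; each frame's perceived graph is tested against
#' the conformers found so far (fingerprint prescreen, then exact labeled
#' isomorphism) and joins the first match, or founds a new conformer.
#' Frame 0 is the reference and always becomes conformer 1. Each conformer
#' records its member frames, the minimum and maximum member energy, and
#' its relative energy: the minimum member energy is taken as the
#' representative, and `delta_e` is that minimum minus the reference
#' conformer's minimum, in kcal/mol. The diff of each conformer's graph
#' against the reference graph is attached (positional bond diff).
#'
#' @param traj An [xyz_trajectory]; frame 0 is the reference structure.
#' @param params [bond_params()] used for perception.
#' @param table [element_table()].
#' @param weak_in_identity Whether weak (agostic) edges take part in the
#'   isomorphism identity. `TRUE` by default; set `FALSE` to avoid
#'   splitting conformers on transient contacts (diffs still include weak
#'   edges either way).
#' @return An object of class `conformer_set`: a list with `records` (one
#'   entry per conformer; see Details), `assignments` (conformer id per
#'   frame), `n_frames`, and `energy_units`.
#' @details Each record holds `conformer_id`, `member_frames` (0-based
#'   frame indices), `graph`, `e_min`, `e_max`, `delta_e` (kcal/mol; `NA`
#'   if any member energy is missing), and `changes` (diff vs reference).
#' @export
identify_conformers <- function(traj, params = bond_params(),
                                table = element_table(),
                                weak_in_identity = TRUE) {
  stopifnot(inherits(traj, "xyz_trajectory"))
  n <- length(traj$frames)
  graphs <- lapply(traj$frames, perceive_bonds, params = params, table = table)
  ident <- graphs
  if (!weak_in_identity) {
    ident <- lapply(graphs, function(g) {
      molgraph(g$elements, g$edges[g$edges$class != "weak", , drop = FALSE],
               source_frame = g$source_frame)
    })
  }
  fps <- vapply(ident, graph_fingerprint, character(1))
  assignments <- integer(n)
  conf_graph <- list()       # identity graph of each conformer
  conf_full <- list()        # full graph (incl. weak) of founding frame
  conf_fp <- character(0)
  members <- list()
  for (f in seq_len(n)) {
    cands <- which(conf_fp == fps[f])   # fingerprint prescreen
    hit <- 0L
    for (cid in cands) {   # discovery order: first match wins
      if (is_isomorphic(ident[[f]], conf_graph[[cid]])) { hit <- cid; break }
    }
    if (hit == 0L) {
      hit <- length(conf_graph) + 1L
      conf_graph[[hit]] <- ident[[f]]
      conf_full[[hit]] <- graphs[[f]]
      conf_fp[hit] <- fps[f]
      members[[hit]] <- integer(0)
    }
    assignments[f] <- hit
    members[[hit]] <- c(members[[hit]], f - 1L)
  }
  e_kcal <- .traj_energies_kcal(traj)
  if (anyNA(e_kcal)) {
    warning("frames with missing energies: conformer energies will be NA")
  }
  ref_graph <- graphs[[1L]]
  emin <- function(ids) {
    v <- e_kcal[ids + 1L]
    if (anyNA(v)) NA_real_ else min(v)
  }
  emax <- function(ids) {
    v <- e_kcal[ids + 1L]
    if (anyNA(v)) NA_real_ else max(v)
  }
  ref_e <- emin(members[[1L]])
  records <- lapply(seq_along(conf_graph), function(cid) {
    e_lo <- emin(members[[cid]])
    list(
      conformer_id = cid,
      member_frames = members[[cid]],
      graph = conf_full[[cid]],
      e_min = e_lo,
      e_max = emax(members[[cid]]),
      delta_e = e_lo - ref_e,
      changes = if (cid == 1L) .empty_changes() else
        diff_bonds(conf_full[[cid]], ref_graph)
    )
  })
  structure(
    list(records = records, assignments = assignments, n_frames = n,
         energy_units = traj$energy_units),
    class = "conformer_set"
  )
}

#' @export
print.conformer_set <- function(x, ...) {
  cat("<conformer_set> ", length(x$records), " conformers over ",
      x$n_frames, " frames\n", sep = "")
  for (r in x$records) {
    cat(sprintf("  C%-3d %3d frames  dE %8.2f  %s\n", r$conformer_id,
                length(r$member_frames),
                if (is.na(r$delta_e)) NA else r$delta_e,
                paste(unique(r$changes$label), collapse = " ")))
  }
  invisible(x)
}

#' Full trajectory analysis against an annotated reference
#'
#' Runs [identify_conformers()] and enriches each conformer record with
#' its event-label set ([label_events()]) and the coordination number of
#' the metal center in that conformer's graph.
#'
#' @inheritParams identify_conformers
#' @param ann A [ref_annotation] for the reference structure (frame 0);
#'   validated against the perceived reference graph.
#' @return A `conformer_set` whose records additionally carry
#'   `event_labels` and `cn_metal`, plus the annotation under `$annotation`.
#' @export
analyze_trajectory <- function(traj, ann, params = bond_params(),
                               table = element_table(),
                               weak_in_identity = TRUE) {
  cs <- identify_conformers(traj, params = params, table = table,
                            weak_in_identity = weak_in_identity)
  validate_annotation(ann, cs$records[[1L]]$graph)
  cs$records <- lapply(cs$records, function(r) {
    r$event_labels <- label_events(r$changes, ann)
    r$cn_metal <- coordination_number(r$graph, ann$metal_index)
    r
  })
  cs$annotation <- ann
  cs
}

#' Detect hemilabile decoordination events
#'
#' A conformer is flagged as evidence of hemilability when it has lost at
#' least one metal-donor bond relative to the reference AND sits lower in
#' energy than the reference (delta_e < 0): decoordination that leads to a
#' more stable structure.
#'
#' @param cs A `conformer_set` (from [analyze_trajectory()] or
#'   [identify_conformers()]).
#' @param ann A [ref_annotation].
#' @return Integer vector of flagged conformer ids.
#' @export
detect_hemilability <- function(cs, ann) {
  stopifnot(inherits(cs, "conformer_set"), inherits(ann, "ref_annotation"))
  m <- ann$metal_index
  out <- integer(0)
  for (r in cs$records) {
    if (is.na(r$delta_e)) stop("delta_e missing for conformer ", r$conformer_id)
    br <- r$changes[r$changes$sign == "broken" & r$changes$class != "weak", ,
                    drop = FALSE]
    other <- c(br$j[br$i == m], br$i[br$j == m])
    if (any(other %in% ann$donor_indices) && r$delta_e < 0) {
      out <- c(out, r$conformer_id)
    }
  }
  out
}

#' Evolution graph of conformers around the reference
#'
#' Star graph: one vertex per conformer, the reference conformer at the
#' center, one edge from the reference to every other conformer. Vertices
#' are annotated with member frames and energy bookkeeping. Sequential
#' edges between temporally adjacent conformers can be added on request
#' (an alternative reading of trajectory connectivity).
#'
#' @param cs A `conformer_set`.
#' @param sequential_edges Also connect conformers visited consecutively
#'   along the trajectory; default `FALSE` (pure star).
#' @return An `igraph` object with vertex attributes `name` (`"C<k>"`),
#'   `conformer_id`, `n_members`, `members` (comma-joined frame indices),
#'   `e_min`, `e_max`, `delta_e`.
#' @export
build_evolution_graph <- function(cs, sequential_edges = FALSE) {
  stopifnot(inherits(cs, "conformer_set"))
  m <- length(cs$records)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  igraph::V(g)$name <- paste0("C", seq_len(m))
  igraph::V(g)$conformer_id <- seq_len(m)
  igraph::V(g)$n_members <- vapply(cs$records, function(r)
    length(r$member_frames), integer(1))
  igraph::V(g)$members <- vapply(cs$records, function(r)
    paste(r$member_frames, collapse = ","), character(1))
  na2 <- function(v) ifelse(is.na(v), NaN, v)
  igraph::V(g)$e_min <- na2(vapply(cs$records, `[[`, numeric(1), "e_min"))
  igraph::V(g)$e_max <- na2(vapply(cs$records, `[[`, numeric(1), "e_max"))
  igraph::V(g)$delta_e <- na2(vapply(cs$records, `[[`, numeric(1), "delta_e"))
  if (m > 1L) {
    g <- igraph::add_edges(g, rbind(1L, 2:m))
  }
  if (sequential_edges && cs$n_frames > 1L) {
    a <- cs$assignments
    steps <- unique(t(apply(cbind(a[-length(a)], a[-1L]), 1L, sort)))
    steps <- steps[steps[, 1L] != steps[, 2L] & steps[, 1L] != 1L, ,
                   drop = FALSE]
    if (nrow(steps) > 0L) g <- igraph::add_edges(g, t(steps))
  }
  g$reference <- 1L
  g
}

#' Write an evolution graph to GraphML or DOT
#'
#' @param g An evolution graph from [build_evolution_graph()].
#' @param path Output file.
#' @param format `"graphml"` (round-trippable) or `"dot"`.
#' @return Invisibly, `path`.
#' @export
write_evolution_graph <- function(g, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Tabular summary of a conformer set
#'
#' One row per conformer with member count, energy bookkeeping and the
#' sorted label set (`"; "`-joined); the shape stored per trajectory in
#' the reactivity database.
#'
#' @param cs A `conformer_set` from [analyze_trajectory()].
#' @return A data frame.
#' @export
conformer_report <- function(cs) {
  stopifnot(inherits(cs, "conformer_set"))
  data.frame(
    conformer_id = vapply(cs$records, `[[`, integer(1), "conformer_id"),
    n_members = vapply(cs$records, function(r) length(r$member_frames),
                       integer(1)),
    e_min = vapply(cs$records, `[[`, numeric(1), "e_min"),
    e_max = vapply(cs$records, `[[`, numeric(1), "e_max"),
    delta_e = vapply(cs$records, `[[`, numeric(1), "delta_e"),
    cn_metal = vapply(cs$records, function(r)
      if (is.null(r$cn_metal)) NA_integer_ else r$cn_metal, integer(1)),
    labels = vapply(cs$records, function(r)
      if (is.null(r$event_labels)) "" else
        paste(r$event_labels, collapse = "; "), character(1)),
    stringsAsFactors = FALSE
  )
}
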