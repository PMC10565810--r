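# Labeled molecular graphs: bond perception from geometry, fingerprints,
# and exact isomorphism. Edges carry one of three bond classes:
#   covalent     - bond between two non-metal atoms
#   coordination - metal-ligand bond
#   weak         - close metal...H contact (agostic-type interaction)

BOND_CLASSES <- c("covalent", "coordination", "weak")

#' Bond perception parameters
#'
#' Distance criteria for turning Cartesian geometry into a labeled graph.
#' A pair of non-metal atoms is covalently bonded when its distance is at
#' most `covalent_scale` times the sum of covalent radii; a metal/non-metal
#' pair is coordination-bonded at up to `metal_scale` times the radius sum
#' (coordination bonds run systematically longer than covalent ones). A
#' metal-hydrogen pair that fails the coordination test but falls inside
#' `[weak_h_metal_min, weak_h_metal_max]` is recorded as a weak (agostic)
#' contact.
#'
#' @param covalent_scale Dimensionless factor on the covalent-radius sum;
#'   default 1.20, the common perception rule.
#' @param metal_scale Factor for metal-ligand pairs; default 1.30.
#' @param weak_h_metal_min,weak_h_metal_max Agostic window bounds in
#'   Angstrom; default \[1.6, 2.3\]. A geometric modeling choice, exposed
#'   for tuning.
#' @return An object of class `bond_params`.
#' @export
bond_params <- function(covalent_scale = 1.20, metal_scale = 1.30,
                        weak_h_metal_min = 1.6, weak_h_metal_max = 2.3) {
  stopifnot(
    covalent_scale > 0.5, covalent_scale < 2.0,
    metal_scale > 0.5, metal_scale < 2.0,
    weak_h_metal_min < weak_h_metal_max
  )
  structure(
    list(covalent_scale = covalent_scale, metal_scale = metal_scale,
         weak_h_metal_min = weak_h_metal_min,
         weak_h_metal_max = weak_h_metal_max),
    class = "bond_params"
  )
}

#' Construct a molecular graph directly
#'
#' Low-level constructor; most callers should use [perceive_bonds()].
#'
#' @param elements Element symbols (node labels, in atom order).
#' @param edges Data frame with integer columns `i`, `j` (1-based atom
#'   indices, `i < j`) and character column `class` drawn from
#'   `c("covalent", "coordination", "weak")`.
#' @param source_frame Optional originating frame index.
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(elements, edges, source_frame = NULL) {
  elements <- normalize_element(as.character(elements))
  n <- length(elements)
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) {
    edges <- data.frame(i = integer(0), j = integer(0),
                        class = character(0), stringsAsFactors = FALSE)
  }
  edges$i <- as.integer(edges$i)
  edges$j <- as.integer(edges$j)
  edges$class <- as.character(edges$class)
  if (nrow(edges) > 0L) {
    if (any(edges$i < 1L | edges$j > n | edges$i >= edges$j)) {
      stop("edge indices must satisfy 1 <= i < j <= n_atoms")
    }
    if (anyDuplicated(paste(edges$i, edges$j))) {
      stop("at most one edge per atom pair")
    }
    if (!all(edges$class %in% BOND_CLASSES)) {
      stop("bond class must be one of: ", paste(BOND_CLASSES, collapse = ", "))
    }
    # canonical order for reproducible diffs and printing
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(
    list(n_atoms = n, elements = elements, edges = edges,
         source_frame = source_frame),
    class = "molgraph"
  )
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$n_atoms, " atoms, ", nrow(x$edges), " edges (",
      paste(names(table(x$edges$class)), table(x$edges$class),
            sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Perceive bonds from 3D geometry
#'
#' Builds the labeled ("mixed") graph of a structure from interatomic
#' distances, covalent radii and the criteria in [bond_params()]. Hydrogen
#' atoms are restricted to their single nearest strong-bond partner when
#' several candidates pass the distance test, which suppresses spurious
#' H-H and H-C edges in sterically crowded groups; weak metal...H contacts
#' are exempt from this rule.
#'
#' The edge set depends on distances only, so the result is invariant under
#' any rigid rotation or translation of the coordinates.
#'
#' @param s An [xyz_frame].
#' @param params A [bond_params] object.
#' @param table An [element_table()].
#' @return A [molgraph] with `source_frame` taken from the structure.
#' @export
perceive_bonds <- function(s, params = bond_params(), table = element_table()) {
  stopifnot(inherits(s, "xyz_frame"))
  n <- length(s$elements)
  radii <- table$covalent_radius[s$elements]
  if (any(is.na(radii))) {
    stop("no covalent radius for element(s): ",
         paste(unique(s$elements[is.na(radii)]), collapse = ", "))
  }
  metal <- table$is_metal[s$elements]
  is_h <- s$elements == "H"

  ei <- integer(0); ej <- integer(0); ecl <- character(0)
  if (n >= 2L) {
    d <- as.matrix(stats::dist(s$coords))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dij <- d[i, j]
        rsum <- radii[i] + radii[j]
        nmetal <- metal[i] + metal[j]
        cls <- NA_character_
        if (nmetal == 0L) {
          if (dij <= params$covalent_scale * rsum) cls <- "covalent"
        } else {
          if (dij <= params$metal_scale * rsum) {
            cls <- "coordination"
          } else if (nmetal == 1L && (is_h[i] || is_h[j]) &&
                     dij >= params$weak_h_metal_min &&
                     dij <= params$weak_h_metal_max) {
            cls <- "weak"
          }
        }
        if (!is.na(cls)) {
          ei <- c(ei, i); ej <- c(ej, j); ecl <- c(ecl, cls)
        }
      }
    }
    # nearest-partner rule for H: among strong candidates incident to an H
    # atom keep only the closest; drop the rest.
    if (length(ei) > 0L && any(is_h)) {
      strong <- ecl != "weak"
      keep <- rep(TRUE, length(ei))
      for (h in which(is_h)) {
        inc <- which(strong & (ei == h | ej == h))
        if (length(inc) > 1L) {
          dd <- d[cbind(ei[inc], ej[inc])]
          keep[inc[-which.min(dd)]] <- FALSE
        }
      }
      ei <- ei[keep]; ej <- ej[keep]; ecl <- ecl[keep]
    }
  }
  molgraph(
    s$elements,
    data.frame(i = ei, j = ej, class = ecl, stringsAsFactors = FALSE),
    source_frame = s$frame_index
  )
}

# adjacency list of (neighbor, class) pairs; weak edges included
.adjacency <- function(g) {
  adj <- vector("list", g$n_atoms)
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges$i[k]; j <- g$edges$j[k]; cl <- g$edges$class[k]
    adj[[i]] <- rbind(adj[[i]], c(j, cl))
    adj[[j]] <- rbind(adj[[j]], c(i, cl))
  }
  adj
}

#' Order-invariant graph fingerprint
#'
#' Canonical text key computed by iterated neighborhood label refinement
#' (Weisfeiler-Lehman style) over element symbols and bond classes. The
#' fingerprint is invariant under atom reordering, so isomorphic graphs
#' always share a fingerprint, and graphs with different fingerprints are
#' guaranteed non-isomorphic. The converse does not hold: equal
#' fingerprints are a fast prescreen, certified by [is_isomorphic()].
#'
#' @param g A [molgraph].
#' @param n_iter Refinement rounds; 3 separates all molecular graphs of
#'   practical interest here.
#' @return A single character string.
#' @export
graph_fingerprint <- function(g, n_iter = 3L) {
  stopifnot(inherits(g, "molgraph"))
  labels <- g$elements
  if (nrow(g$edges) > 0L && n_iter > 0L) {
    adj <- .adjacency(g)
    for (t in seq_len(n_iter)) {
      new_labels <- character(g$n_atoms)
      for (v in seq_len(g$n_atoms)) {
        a <- adj[[v]]
        if (is.null(a)) {
          new_labels[v] <- labels[v]
        } else {
          nb <- paste0(a[, 2L], ":", labels[as.integer(a[, 1L])])
          new_labels[v] <- paste0(labels[v], "(", paste(sort(nb), collapse = ","), ")")
        }
      }
      labels <- new_labels
    }
  }
  paste0(g$n_atoms, "|", nrow(g$edges), "|",
         paste(sort(labels), collapse = ";"))
}

.mg_to_igraph <- function(g, elem_levels, class_levels = BOND_CLASSES) {
  ig <- igraph::make_empty_graph(n = g$n_atoms, directed = FALSE)
  if (nrow(g$edges) > 0L) {
    ig <- igraph::add_edges(ig, rbind(g$edges$i, g$edges$j))
  }
  list(
    graph = ig,
    vcol = match(g$elements, elem_levels),
    ecol = match(g$edges$class, class_levels)
  )
}

#' Exact labeled-graph isomorphism
#'
#' Tests whether a bijection of atoms exists that preserves element labels
#' and edge bond classes. Cheap invariants (atom count, element multiset,
#' per-class edge counts) and the refinement fingerprint screen out
#' non-matches; surviving pairs are certified with a color-aware VF2
#' matching. Bond classes are part of graph identity: a weak contact is
#' never interchangeable with a covalent or coordination bond.
#'
#' @param g1,g2 [molgraph] objects.
#' @return `TRUE` or `FALSE`.
#' @export
is_isomorphic <- function(g1, g2) {
  stopifnot(inherits(g1, "molgraph"), inherits(g2, "molgraph"))
  if (g1$n_atoms != g2$n_atoms) return(FALSE)
  if (nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  if (!identical(sort(g1$elements), sort(g2$elements))) return(FALSE)
  if (!identical(table(factor(g1$edges$class, BOND_CLASSES)),
                 table(factor(g2$edges$class, BOND_CLASSES)))) return(FALSE)
  if (!identical(graph_fingerprint(g1), graph_fingerprint(g2))) return(FALSE)
  elem_levels <- sort(unique(c(g1$elements, g2$elements)))
  a <- .mg_to_igraph(g1, elem_levels)
  b <- .mg_to_igraph(g2, elem_levels)
  igraph::isomorphic(
    a$graph, b$graph, method = "vf2",
    vertex.color1 = a$vcol, vertex.color2 = b$vcol,
    edge.color1 = a$ecol, edge.color2 = b$ecol
  )
}
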