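# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as naive nested loops, separate from any
# optimization or prescreen in the package code paths.

# all-pairs distance-threshold bond perception (no neighbor structures)
oracle_perceive_edges <- function(s, params = bond_params(),
                                  table = element_table()) {
  n <- length(s$elements)
  radius <- table$covalent_radius
  metal <- table$is_metal
  raw <- data.frame(i = integer(0), j = integer(0), class = character(0),
                    d = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- sqrt(sum((s$coords[i, ] - s$coords[j, ])^2))
      rsum <- radius[[s$elements[i]]] + radius[[s$elements[j]]]
      mi <- metal[[s$elements[i]]]; mj <- metal[[s$elements[j]]]
      cls <- NULL
      if (!mi && !mj) {
        if (d <= params$covalent_scale * rsum) cls <- "covalent"
      } else if (d <= params$metal_scale * rsum) {
        cls <- "coordination"
      } else if (xor(mi, mj) &&
                 (s$elements[i] == "H" || s$elements[j] == "H") &&
                 d >= params$weak_h_metal_min &&
                 d <= params$weak_h_metal_max) {
        cls <- "weak"
      }
      if (!is.null(cls)) {
        raw <- rbind(raw, data.frame(i = i, j = j, class = cls, d = d,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  # hydrogen keeps only its nearest strong partner
  drop <- rep(FALSE, nrow(raw))
  for (h in which(s$elements == "H")) {
    inc <- which(raw$class != "weak" & (raw$i == h | raw$j == h))
    if (length(inc) > 1L) {
      best <- inc[which.min(raw$d[inc])]
      drop[setdiff(inc, best)] <- TRUE
    }
  }
  e <- raw[!drop, c("i", "j", "class")]
  e <- e[order(e$i, e$j), , drop = FALSE]
  rownames(e) <- NULL
  e
}

# every permutation of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

edge_key_set <- function(edges) {
  sort(paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j), edges$class))
}

# factorial-time exact isomorphism (element labels + bond classes)
oracle_perm_iso <- function(g1, g2) {
  n <- g1$n_atoms
  if (n != g2$n_atoms || nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  k2 <- edge_key_set(g2$edges)
  for (p in all_perms(n)) {
    p <- unlist(p)
    if (!all(g2$elements[p] == g1$elements)) next
    mapped <- data.frame(i = p[g1$edges$i], j = p[g1$edges$j],
                         class = g1$edges$class)
    if (identical(edge_key_set(mapped), k2)) return(TRUE)
  }
  FALSE
}

# all-pairs isomorphism clustering of a trajectory's frame graphs,
# independent of the sequential first-match identifier
oracle_conformer_partition <- function(traj, params = bond_params()) {
  gs <- lapply(traj$frames, perceive_bonds, params = params)
  n <- length(gs)
  lab <- integer(n)
  for (i in seq_len(n)) {
    lab[i] <- i
    for (j in seq_len(i - 1L)) {
      if (is_isomorphic(gs[[i]], gs[[j]])) { lab[i] <- lab[j]; break }
    }
  }
  match(lab, unique(lab))
}

# random labeled molecular graph (not geometry-derived)
random_molgraph <- function(seed, n = NULL, p_edge = 0.3) {
  set.seed(seed)
  if (is.null(n)) n <- sample(2:8, 1L)
  els <- sample(c("H", "C", "N", "O", "Mn"), n, replace = TRUE)
  ei <- integer(0); ej <- integer(0); cl <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (stats::runif(1) < p_edge) {
      ei <- c(ei, i); ej <- c(ej, j)
      cl <- c(cl, sample(c("covalent", "coordination", "weak"), 1L))
    }
  }
  molgraph(els, data.frame(i = ei, j = ej, class = cl))
}

# relabel atoms of a graph by permutation p (old v becomes p[v])
permute_molgraph <- function(g, p) {
  els <- character(g$n_atoms)
  els[p] <- g$elements
  e <- g$edges
  i2 <- pmin(p[e$i], p[e$j]); j2 <- pmax(p[e$i], p[e$j])
  molgraph(els, data.frame(i = i2, j = j2, class = e$class))
}

random_rigid_motion <- function(coords, seed) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3L, 3L, byrow = TRUE)
  R <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  shift <- stats::rnorm(3, sd = 5)
  sweep(coords %*% t(R), 2L, shift, `+`)
}

# a tiny water structure used across io tests
h2o_frame <- function(energy = NULL, frame_index = NULL) {
  xyz_frame(c("O", "H", "H"),
            rbind(c(0, 0, 0), c(0.9572, 0, 0),
                  c(-0.2399872, 0.9266272, 0)),
            energy = energy, frame_index = frame_index)
}

random_frames <- function(seed, n_frames = 3L, n_atoms = 5L) {
  set.seed(seed)
  els <- sample(c("C", "H", "O", "N"), n_atoms, replace = TRUE)
  lapply(seq_len(n_frames), function(f) {
    xyz_frame(els, matrix(stats::runif(n_atoms * 3L, -8, 8), n_atoms, 3L),
              energy = stats::rnorm(1), frame_index = f - 1L)
  })
}
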