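# Deterministic synthetic fixtures: toy octahedral pincer complexes,
# substituent fragments, and trajectories with scripted bond events.
# These are topological test vehicles - geometries are schematic but
# chemically sensible, and every generated trajectory is validated
# against its own script (perceived edge set per frame must equal the
# scripted edge set) before it is returned.

.unit <- function(v) v / sqrt(sum(v^2))

.vdist <- function(a, b) sqrt(sum((a - b)^2))

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.any_perp <- function(v) {
  p <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(p - sum(p * v) * v)
}

# k open directions at a center given unit vectors to existing neighbors;
# tetrahedral-style split for k = 2, straight "away" direction for k = 1
.open_directions <- function(neigh, k) {
  avg <- -colSums(neigh)
  if (sqrt(sum(avg^2)) < 1e-6) avg <- c(0, 0, 1) else avg <- .unit(avg)
  if (k == 1L) return(rbind(avg))
  p <- if (nrow(neigh) >= 2L) .cross(neigh[1L, ], neigh[2L, ]) else .any_perp(avg)
  if (sqrt(sum(p^2)) < 1e-6) p <- .any_perp(avg)
  p <- p - sum(p * avg) * avg
  p <- .unit(p)
  ang <- 54.7 * pi / 180
  rbind(cos(ang) * avg + sin(ang) * p,
        cos(ang) * avg - sin(ang) * p)
}

# three sp3 directions at 109.47 deg from `axis`, fixed azimuths
.sp3_dirs <- function(axis) {
  axis <- .unit(axis)
  p <- .any_perp(axis)
  q <- .cross(axis, p)
  t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
    (-1 / 3) * axis + sqrt(8) / 3 * (cos(phi) * p + sin(phi) * q)
  }, numeric(3)))
}

# ---------------------------------------------------------------------------
# substituent fragments

.frag_methyl_at <- function(pos, axis_away) {
  h <- .sp3_dirs(-axis_away)   # H's point away from the bond we came from
  list(elements = "C", coords = rbind(pos),
       h_elements = rep("H", 3L),
       h_coords = sweep(1.09 * h, 2L, pos, `+`))
}

#' Built-in substituent fragment library
#'
#' Deterministic idealized geometries for the fragments used across the
#' toy catalyst library: H, CF3, CH3, iPr, tBu, cy (cyclohexyl), Ph, and
#' the adducts Br, OH, OCH3, OtBu. The attachment atom sits at the origin
#' with its open valence along +z (toward the future anchor), except where
#' ring geometry dictates otherwise.
#'
#' @param name Fragment name.
#' @return A [substituent].
#' @export
toy_substituent <- function(name) {
  z <- c(0, 0, 1)
  build <- switch(
    name,
    "H" = list(el = "H", xyz = rbind(c(0, 0, 0))),
    "Br" = list(el = "Br", xyz = rbind(c(0, 0, 0))),
    "CF3" = {
      d <- .sp3_dirs(z)
      list(el = c("C", rep("F", 3L)), xyz = rbind(c(0, 0, 0), 1.33 * d))
    },
    "CH3" = {
      d <- .sp3_dirs(z)
      list(el = c("C", rep("H", 3L)), xyz = rbind(c(0, 0, 0), 1.09 * d))
    },
    "iPr" = {
      d <- .sp3_dirs(z)
      els <- "C"; xyz <- rbind(c(0, 0, 0))
      for (k in 1:2) {
        m <- .frag_methyl_at(1.54 * d[k, ], d[k, ])
        els <- c(els, m$elements, m$h_elements)
        xyz <- rbind(xyz, m$coords, m$h_coords)
      }
      els <- c(els, "H"); xyz <- rbind(xyz, 1.09 * d[3L, ])
      list(el = els, xyz = xyz)
    },
    "tBu" = {
      d <- .sp3_dirs(z)
      els <- "C"; xyz <- rbind(c(0, 0, 0))
      for (k in 1:3) {
        m <- .frag_methyl_at(1.54 * d[k, ], d[k, ])
        els <- c(els, m$elements, m$h_elements)
        xyz <- rbind(xyz, m$coords, m$h_coords)
      }
      list(el = els, xyz = xyz)
    },
    "Ph" = {
      # regular hexagon, attachment carbon at origin, ring center at +y
      ctr <- c(0, 1.39, 0)
      ang <- seq(-pi / 2, by = pi / 3, length.out = 6L)
      ring <- t(vapply(ang, function(a) ctr + 1.39 * c(cos(a), sin(a), 0),
                       numeric(3)))
      els <- rep("C", 6L); xyz <- ring
      for (k in 2:6) {
        out <- .unit(ring[k, ] - ctr)
        els <- c(els, "H"); xyz <- rbind(xyz, ring[k, ] + 1.09 * out)
      }
      list(el = els, xyz = xyz, attach_vector = c(0, -1, 0))
    },
    "cy" = {
      # chair ring: alternating pucker, C-C = 1.54
      r <- sqrt(1.54^2 - 0.25); zp <- 0.25
      ang <- seq(0, by = pi / 3, length.out = 6L)
      ring <- t(vapply(seq_len(6L), function(k) {
        c(r * cos(ang[k]), r * sin(ang[k]), zp * (-1)^k)
      }, numeric(3)))
      ring <- sweep(ring, 2L, ring[1L, ])   # attachment C at origin
      els <- rep("C", 6L); xyz <- ring
      av <- NULL
      for (k in seq_len(6L)) {
        nb <- rbind(.unit(ring[if (k == 1L) 6L else k - 1L, ] - ring[k, ]),
                    .unit(ring[if (k == 6L) 1L else k + 1L, ] - ring[k, ]))
        d2 <- .open_directions(nb, 2L)
        if (k == 1L) {
          av <- d2[1L, ]                       # open valence
          els <- c(els, "H"); xyz <- rbind(xyz, ring[k, ] + 1.09 * d2[2L, ])
        } else {
          els <- c(els, "H", "H")
          xyz <- rbind(xyz, ring[k, ] + 1.09 * d2[1L, ],
                       ring[k, ] + 1.09 * d2[2L, ])
        }
      }
      list(el = els, xyz = xyz, attach_vector = av)
    },
    "OH" = {
      hd <- c(sin(104.5 * pi / 180), 0, cos(104.5 * pi / 180))
      list(el = c("O", "H"), xyz = rbind(c(0, 0, 0), 0.96 * hd))
    },
    "OCH3" = {
      cd <- c(sin(109.5 * pi / 180), 0, cos(109.5 * pi / 180))
      cpos <- 1.43 * cd
      m <- .sp3_dirs(-cd)
      list(el = c("O", "C", rep("H", 3L)),
           xyz = rbind(c(0, 0, 0), cpos, sweep(1.09 * m, 2L, cpos, `+`)))
    },
    "OtBu" = {
      cd <- c(sin(109.5 * pi / 180), 0, cos(109.5 * pi / 180))
      c0 <- 1.43 * cd
      els <- c("O", "C"); xyz <- rbind(c(0, 0, 0), c0)
      arms <- .sp3_dirs(-cd)
      for (k in 1:3) {
        m <- .frag_methyl_at(c0 + 1.54 * arms[k, ], arms[k, ])
        els <- c(els, m$elements, m$h_elements)
        xyz <- rbind(xyz, m$coords, m$h_coords)
      }
      list(el = els, xyz = xyz)
    },
    stop("unknown substituent preset: ", name)
  )
  av <- build$attach_vector %||% c(0, 0, 1)
  substituent(name, xyz_frame(build$el, build$xyz), attach_index = 1L,
              attach_vector = av)
}

# ---------------------------------------------------------------------------
# toy pincer complexes

.donor_spec <- list(
  # per-element: Mn-D bond length, D-C(backbone) bond length, R1 sites,
  # bridge carbons (short donor arms need a longer bridge to arc clear of
  # the metal)
  P = list(mn = 2.25, dc = 1.85, n_r1 = 2L, n_bridge = 2L),
  S = list(mn = 2.30, dc = 1.82, n_r1 = 1L, n_bridge = 2L),
  C = list(mn = 1.95, dc = 1.50, n_r1 = 1L, n_bridge = 3L),
  N = list(mn = 2.05, dc = 1.47, n_r1 = 2L, n_bridge = 3L)
)

.backbone_donors <- list(
  PNP = c("P", "P"), SNS = c("S", "S"), CNC = c("C", "C"), PNN = c("P", "N")
)

# place the n_c bridge carbons of one chelate arm, D-C1-...-Cn-N(central),
# keeping every carbon well clear of the metal and of non-bonded partners.
# Deterministic: fixed start, derivative-free local optimization.
.solve_bridge <- function(mn, D, Nc, b_dc, n_c, others) {
  hinge <- function(x) pmax(x, 0)
  bonds <- c(b_dc, rep(1.54, n_c - 1L), 1.47)
  obj <- function(par) {
    pts <- matrix(par, n_c, 3L, byrow = TRUE)
    chain <- rbind(D, pts, Nc)
    dd <- sqrt(rowSums((chain[-1L, , drop = FALSE] -
                          chain[-nrow(chain), , drop = FALSE])^2))
    err <- sum((dd - bonds)^2)
    pen <- 0
    for (k in seq_len(n_c)) {
      pen <- pen + hinge(3.05 - .vdist(pts[k, ], mn))^2
      if (k >= 2L) pen <- pen + hinge(2.45 - .vdist(pts[k, ], D))^2
      if (k <= n_c - 1L) pen <- pen + hinge(2.05 - .vdist(pts[k, ], Nc))^2
      if (k >= 3L) pen <- pen + hinge(2.15 - .vdist(pts[k, ], pts[k - 2L, ]))^2
      for (o in others) pen <- pen + hinge(2.2 - .vdist(pts[k, ], o))^2
    }
    err + 20 * pen
  }
  # start on an arc bowed outward (in the Mn equatorial sense) from the
  # straight D -> Nc line
  bow <- 0.45 * max(sum(bonds) - .vdist(D, Nc), 0.3)
  start <- numeric(0)
  for (k in seq_len(n_c)) {
    t <- k / (n_c + 1)
    base <- D + t * (Nc - D)
    start <- c(start, base + bow * .unit(base - mn))
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 10000L, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 10000L, reltol = 1e-14))
  # clearance hinges may bind at equality; accept residuals amounting to
  # bond-length deviations below ~0.01 A
  if (fit$value > 1e-4) {
    stop("bridge placement failed to converge (residual ", fit$value, ")")
  }
  matrix(fit$par, n_c, 3L, byrow = TRUE)
}

#' Build a toy octahedral pincer complex
#'
#' Constructs a schematic but topologically faithful Mn(I) pincer complex:
#' metal center, two side-arm donors trans to each other, a central amine
#' donor completing the tridentate ligand through two-carbon bridges, two
#' carbonyl ligands and an adduct placeholder, for an octahedral CN of 6.
#' Substitution sites (R1 on the donors, R2 on the backbone carbons
#' adjacent to the central donor, X at the adduct position) are explicit
#' placeholder H atoms. The perceived graph is verified against the
#' intended bonding pattern before the structure is returned, and repeated
#' calls are coordinate-identical.
#'
#' @param preset One of `"PNP"`, `"SNS"`, `"CNC"`, `"PNN"`, or
#'   `"octahedral_pincer"` (alias for `"PNP"`).
#' @param params,table Perception settings used for self-validation.
#' @return An object of class `toy_complex`: list with `structure`
#'   ([xyz_frame]), `annotation` ([ref_annotation]), `graph` (the expected
#'   [molgraph]), `r1_sites`, `r2_sites`, `adduct_site`, `arms` (per-arm
#'   atom bookkeeping: donor, bridge carbons, substituent placeholders).
#' @export
make_toy_complex <- function(preset = "octahedral_pincer",
                             params = bond_params(), table = element_table()) {
  if (preset == "octahedral_pincer") preset <- "PNP"
  donors <- .backbone_donors[[preset]]
  if (is.null(donors)) stop("unknown preset: ", preset)

  els <- character(0)
  xyz <- matrix(numeric(0), 0L, 3L)
  edges <- list()
  add_atom <- function(el, pos) {
    els <<- c(els, el)
    xyz <<- rbind(xyz, pos)
    length(els)
  }
  add_edge <- function(i, j, cl) {
    edges[[length(edges) + 1L]] <<- c(min(i, j), max(i, j), cl)
  }

  mn <- add_atom("Mn", c(0, 0, 0))
  d_pos <- list(c(1, 0, 0), c(-1, 0, 0))
  arm_donor <- integer(2)
  for (a in 1:2) {
    sp <- .donor_spec[[donors[a]]]
    arm_donor[a] <- add_atom(donors[a], sp$mn * d_pos[[a]])
    add_edge(mn, arm_donor[a], "coordination")
  }
  nc <- add_atom("N", c(0, 2.00, 0))
  add_edge(mn, nc, "coordination")
  co_c1 <- add_atom("C", c(0, -1.95, 0)); co_o1 <- add_atom("O", c(0, -3.10, 0))
  co_c2 <- add_atom("C", c(0, 0, 1.95));  co_o2 <- add_atom("O", c(0, 0, 3.10))
  add_edge(mn, co_c1, "coordination"); add_edge(co_c1, co_o1, "covalent")
  add_edge(mn, co_c2, "coordination"); add_edge(co_c2, co_o2, "covalent")
  x_site <- add_atom("H", c(0, 0, -1.60))
  add_edge(mn, x_site, "coordination")

  arms <- list()
  r1_sites <- integer(0); r2_sites <- integer(0)
  for (a in 1:2) {
    sp <- .donor_spec[[donors[a]]]
    D <- xyz[arm_donor[a], ]
    others <- list(xyz[co_c1, ], xyz[co_o1, ], xyz[co_c2, ], xyz[co_o2, ],
                   xyz[x_site, ])
    br <- .solve_bridge(c(0, 0, 0), D, xyz[nc, ], sp$dc, sp$n_bridge, others)
    cids <- integer(sp$n_bridge)
    for (b in seq_len(sp$n_bridge)) cids[b] <- add_atom("C", br[b, ])
    add_edge(arm_donor[a], cids[1L], "covalent")
    for (b in seq_len(sp$n_bridge - 1L)) add_edge(cids[b], cids[b + 1L], "covalent")
    add_edge(cids[sp$n_bridge], nc, "covalent")
    # CH2 hydrogens along the bridge; the central-side carbon carries one
    # plain H and one R2 placeholder
    chain <- rbind(D, br, xyz[nc, ])
    ch2_h <- integer(0); r2s <- NA_integer_; c2h <- NA_integer_
    for (b in seq_len(sp$n_bridge)) {
      hd <- .open_directions(rbind(.unit(chain[b, ] - br[b, ]),
                                   .unit(chain[b + 2L, ] - br[b, ])), 2L)
      ha <- add_atom("H", br[b, ] + 1.09 * hd[1L, ])
      hb <- add_atom("H", br[b, ] + 1.09 * hd[2L, ])
      add_edge(cids[b], ha, "covalent"); add_edge(cids[b], hb, "covalent")
      if (b == sp$n_bridge) { c2h <- ha; r2s <- hb } else {
        ch2_h <- c(ch2_h, ha, hb)
      }
    }
    r2_sites <- c(r2_sites, r2s)
    # R1 placeholders on the donor
    hb <- table$covalent_radius[[donors[a]]] + table$covalent_radius[["H"]]
    rd <- .open_directions(rbind(.unit(c(0, 0, 0) - D), .unit(br[1L, ] - D)),
                           sp$n_r1)
    arm_r1 <- integer(0)
    for (k in seq_len(sp$n_r1)) {
      s <- add_atom("H", D + hb * rd[k, ])
      add_edge(arm_donor[a], s, "covalent")
      arm_r1 <- c(arm_r1, s)
    }
    r1_sites <- c(r1_sites, arm_r1)
    arms[[a]] <- list(donor = arm_donor[a], c1 = cids[1L],
                      c2 = cids[sp$n_bridge], carbons = cids,
                      r1 = arm_r1, ch2_h = ch2_h, c2_h = c2h, r2 = r2s)
  }
  # N-H on the central donor: the in-plane directions are taken by Mn and
  # the two bridge carbons, so the proton points into the open axial
  # region, tilted away from the metal
  nh <- add_atom("H", xyz[nc, ] + 1.02 * .unit(c(0, 0.35, 0.94)))
  add_edge(nc, nh, "covalent")

  st <- xyz_frame(els, xyz)
  emat <- do.call(rbind, edges)
  expected <- molgraph(els, data.frame(i = as.integer(emat[, 1L]),
                                       j = as.integer(emat[, 2L]),
                                       class = emat[, 3L],
                                       stringsAsFactors = FALSE))
  got <- perceive_bonds(st, params = params, table = table)
  if (!identical(got$edges, expected$edges)) {
    stop("toy complex self-check failed: perceived graph differs from design")
  }
  ann <- ref_annotation(
    metal_index = mn,
    donor_indices = c(arm_donor, nc),
    donor_roles = c("side_arm", "side_arm", "central"),
    adduct_indices = x_site,
    features = list(backbone = preset, r1 = "H", r2 = "H", adduct = "H")
  )
  structure(
    list(structure = st, annotation = ann, graph = expected,
         r1_sites = r1_sites, r2_sites = r2_sites, adduct_site = x_site,
         metal_index = mn, central_n = nc, nh = nh,
         co = list(c(co_c1, co_o1), c(co_c2, co_o2)), arms = arms,
         backbone = preset),
    class = "toy_complex"
  )
}

#' Convert a toy complex into a scaffold for library generation
#'
#' @param tc A `toy_complex` from [make_toy_complex()].
#' @return A [scaffold].
#' @export
as_scaffold <- function(tc) {
  stopifnot(inherits(tc, "toy_complex"))
  scaffold(
    name = tc$backbone, geometry = tc$structure,
    r1_sites = tc$r1_sites, r2_sites = tc$r2_sites,
    adduct_site = tc$adduct_site, metal_index = tc$metal_index,
    donor_indices = tc$annotation$donor_indices,
    donor_roles = tc$annotation$donor_roles
  )
}
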