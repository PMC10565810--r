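# Combinatorial catalyst library generation: scaffold x R1 x R2 x adduct.
# Substitution sites are explicit placeholder atoms (dummy H by default)
# named in the scaffold annotation; attachment replaces the placeholder by
# a rigidly oriented substituent fragment. No force-field relaxation is
# applied: downstream graph analysis needs topologically correct,
# clash-free geometries, not refined ones.

#' Substituent fragment
#'
#' @param name Fragment name (e.g. `"CF3"`, `"tBu"`).
#' @param geometry An [xyz_frame] with the fragment coordinates.
#' @param attach_index 1-based index of the atom that forms the new bond.
#' @param attach_vector Direction (3-vector, normalized internally) from
#'   the attachment atom toward the future anchor atom — where the open
#'   valence points.
#' @return An object of class `substituent`.
#' @export
substituent <- function(name, geometry, attach_index, attach_vector) {
  stopifnot(inherits(geometry, "xyz_frame"))
  attach_index <- as.integer(attach_index)
  stopifnot(attach_index >= 1L, attach_index <= length(geometry$elements))
  v <- as.numeric(attach_vector)
  stopifnot(length(v) == 3L, all(is.finite(v)))
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) stop("attach_vector must be non-zero")
  structure(
    list(name = name, geometry = geometry, attach_index = attach_index,
         attach_vector = v / nv),
    class = "substituent"
  )
}

#' Catalyst scaffold with annotated substitution sites
#'
#' @param name Backbone name (e.g. `"PNP"`, `"SNS"`).
#' @param geometry An [xyz_frame] of the scaffold including placeholder
#'   atoms at every substitution site.
#' @param r1_sites Placeholder atom indices at the donor (first
#'   coordination sphere) positions.
#' @param r2_sites Placeholder atom indices at the backbone positions.
#' @param adduct_site Placeholder index for the anionic adduct X.
#' @param metal_index Index of the metal center.
#' @param donor_indices,donor_roles Ligand donor atoms and their roles
#'   (`"side_arm"`/`"central"`), as in [ref_annotation()].
#' @return An object of class `scaffold`.
#' @export
scaffold <- function(name, geometry, r1_sites, r2_sites, adduct_site,
                     metal_index, donor_indices, donor_roles) {
  stopifnot(inherits(geometry, "xyz_frame"))
  n <- length(geometry$elements)
  r1_sites <- as.integer(r1_sites)
  r2_sites <- as.integer(r2_sites)
  adduct_site <- as.integer(adduct_site)
  sites <- c(r1_sites, r2_sites, adduct_site)
  stopifnot(all(sites >= 1L), all(sites <= n), length(adduct_site) == 1L)
  if (anyDuplicated(sites)) stop("site index lists must be disjoint")
  structure(
    list(name = name, geometry = geometry, r1_sites = r1_sites,
         r2_sites = r2_sites, adduct_site = adduct_site,
         metal_index = as.integer(metal_index),
         donor_indices = as.integer(donor_indices),
         donor_roles = as.character(donor_roles)),
    class = "scaffold"
  )
}

#' Enumerate the combinatorial library
#'
#' Full Cartesian product backbone x R1 x R2 x X in deterministic
#' lexicographic order (backbone slowest, adduct fastest, each in input
#' order). Functionalization is symmetric: one R1 choice is applied to all
#' R1 sites of a scaffold, likewise R2, so one tuple fully determines a
#' library entry.
#'
#' @param backbones,r1_opts,r2_opts,adducts Character vectors of option
#'   names; each must be non-empty and duplicate-free.
#' @return Data frame with columns `backbone`, `r1`, `r2`, `adduct` and a
#'   unique `label` (`"backbone_r1_r2_adduct"`).
#' @examples
#' nrow(enumerate_combinations(
#'   c("PNP", "SNS", "CNC", "PNN"),
#'   c("H", "CF3", "cy", "iPr", "Ph", "tBu"),
#'   c("H", "CF3", "cy", "iPr", "Ph", "tBu"),
#'   c("Br", "OH", "OCH3", "OtBu")
#' ))  # 576
#' @export
enumerate_combinations <- function(backbones, r1_opts, r2_opts, adducts) {
  for (nm in list(backbones, r1_opts, r2_opts, adducts)) {
    if (length(nm) == 0L) stop("option lists must be non-empty")
    if (anyDuplicated(nm)) stop("duplicate option: ",
                                nm[duplicated(nm)][1L])
  }
  out <- expand.grid(adduct = adducts, r2 = r2_opts, r1 = r1_opts,
                     backbone = backbones, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[, c("backbone", "r1", "r2", "adduct")]
  out$label <- paste(out$backbone, out$r1, out$r2, out$adduct, sep = "_")
  rownames(out) <- NULL
  out
}

# Rodrigues rotation matrix: rotate by angle theta about unit axis k
.rotation_about <- function(k, theta) {
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3L, 3L, byrow = TRUE)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# minimal rotation taking unit vector a onto unit vector b
.rotation_align <- function(a, b) {
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(cr^2))
  co <- sum(a * b)
  if (s < 1e-10) {
    if (co > 0) return(diag(3L))
    # opposite vectors: rotate pi about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p <- p - sum(p * a) * a
    return(.rotation_about(p / sqrt(sum(p^2)), pi))
  }
  .rotation_about(cr / s, atan2(s, co))
}

#' Attach a substituent at a placeholder site
#'
#' Replaces the placeholder atom by the substituent fragment: the fragment
#' is rigidly rotated so its attachment direction lies along the
#' anchor-to-site axis, spun about that axis so its internal reference
#' perpendicular maps onto a canonical perpendicular (a deterministic
#' orientation rule chosen for reproducibility), and translated so the new
#' bond has the requested length. Fragment atoms are appended after the
#' remaining scaffold atoms.
#'
#' @param scaffold_geom [xyz_frame] of the host structure.
#' @param site Placeholder atom index; must have exactly one neighbor
#'   (its anchor) in the perceived graph.
#' @param sub A [substituent].
#' @param bond_length New anchor-attachment bond length in Angstrom;
#'   defaults to the sum of covalent radii of the two atoms.
#' @param clash_floor Minimum allowed distance (Angstrom) between any
#'   fragment atom and any retained scaffold atom other than the new bond
#'   itself; violations raise a clash error naming the offending pair.
#' @param params,table Perception settings used to locate the anchor.
#' @return The substituted [xyz_frame], with attribute `index_map`: an
#'   integer vector mapping old scaffold indices to new ones (`NA` for the
#'   removed placeholder).
#' @export
attach_substituent <- function(scaffold_geom, site, sub, bond_length = NULL,
                               clash_floor = 0.75, params = bond_params(),
                               table = element_table()) {
  stopifnot(inherits(scaffold_geom, "xyz_frame"), inherits(sub, "substituent"))
  n <- length(scaffold_geom$elements)
  site <- as.integer(site)
  stopifnot(site >= 1L, site <= n)
  g <- perceive_bonds(scaffold_geom, params = params, table = table)
  nb <- c(g$edges$j[g$edges$i == site], g$edges$i[g$edges$j == site])
  if (length(nb) != 1L) {
    stop("site ", site, " has ", length(nb),
         " neighbors; a placeholder must have exactly one")
  }
  anchor <- nb
  d <- scaffold_geom$coords[site, ] - scaffold_geom$coords[anchor, ]
  d <- d / sqrt(sum(d^2))
  att_el <- sub$geometry$elements[sub$attach_index]
  if (is.null(bond_length)) {
    bond_length <- table$covalent_radius[[scaffold_geom$elements[anchor]]] +
      table$covalent_radius[[att_el]]
  }
  # orient: attach_vector (attachment atom -> anchor) must map to -d
  R1 <- .rotation_align(sub$attach_vector, -d)
  local <- sweep(sub$geometry$coords, 2L,
                 sub$geometry$coords[sub$attach_index, ]) %*% t(R1)
  attach_pos <- scaffold_geom$coords[anchor, ] + bond_length * d
  # spin about the bond axis: scan a fixed grid of torsion angles and keep
  # the one maximizing the smallest fragment/scaffold contact distance
  # (deterministic; ties resolve to the smallest angle)
  keep_idx <- setdiff(seq_len(n), site)
  if (nrow(local) > 1L) {
    host <- scaffold_geom$coords[setdiff(keep_idx, anchor), , drop = FALSE]
    best_ang <- 0; best_clear <- -Inf
    for (ang in seq(0, 350, by = 10) * pi / 180) {
      frag_try <- sweep(local %*% t(.rotation_about(d, ang)), 2L,
                        attach_pos, `+`)
      clear <- min(vapply(seq_len(nrow(frag_try)), function(a) {
        min(sqrt(rowSums(sweep(host, 2L, frag_try[a, ])^2)))
      }, numeric(1)))
      if (clear > best_clear + 1e-9) { best_clear <- clear; best_ang <- ang }
    }
    local <- local %*% t(.rotation_about(d, best_ang))
  }
  frag <- sweep(local, 2L, attach_pos, `+`)

  keep <- keep_idx
  new_coords <- rbind(scaffold_geom$coords[keep, , drop = FALSE], frag)
  new_elems <- c(scaffold_geom$elements[keep], sub$geometry$elements)
  # clash check: fragment vs retained scaffold, excluding the new bond
  index_map <- rep(NA_integer_, n)
  index_map[keep] <- seq_along(keep)
  anchor_new <- index_map[anchor]
  attach_new <- length(keep) + sub$attach_index
  for (a in seq_len(nrow(frag))) {
    dd <- sqrt(rowSums(sweep(new_coords[seq_along(keep), , drop = FALSE],
                             2L, frag[a, ])^2))
    dd[anchor_new] <- if (a == sub$attach_index) Inf else dd[anchor_new]
    if (any(dd < clash_floor)) {
      w <- which.min(dd)
      stop(sprintf(
        "steric clash: fragment atom %d (%s) vs scaffold atom %d (%s) at %.2f A",
        a, sub$geometry$elements[a], w, new_elems[w], dd[w]))
    }
  }
  out <- xyz_frame(new_elems, new_coords,
                   energy = scaffold_geom$energy,
                   frame_index = scaffold_geom$frame_index)
  attr(out, "index_map") <- index_map
  out
}

# apply one substituent to several sites (given as original-scaffold
# indices, translated through the running index map); sites processed in
# decreasing index order so pending sites stay valid
.attach_at_sites <- function(geom, sites_orig, sub, ...) {
  for (s in sort(sites_orig, decreasing = TRUE)) {
    s_now <- geom$map[s]
    if (is.na(s_now)) stop("site ", s, " no longer present")
    new_geom <- attach_substituent(geom$frame, s_now, sub, ...)
    m <- attr(new_geom, "index_map")
    geom$map <- ifelse(is.na(geom$map), NA_integer_, m[geom$map])
    geom$frame <- new_geom
  }
  geom
}

#' Build the combinatorial catalyst library
#'
#' One geometry per enumerated (backbone, R1, R2, X) tuple: the named R1
#' substituent is attached at every R1 site, R2 at every R2 site and the
#' adduct at the adduct site. Entries that fail (steric clash, missing
#' fragment) are collected in a rejection report rather than silently
#' dropped, so `nrow(entries) + nrow(rejections)` always equals the
#' enumeration size.
#'
#' @param scaffolds Named list of [scaffold] objects (names are the
#'   backbone vocabulary).
#' @param substituents Named list of [substituent] fragments (the shared
#'   R1/R2 vocabulary).
#' @param adducts Named list of [substituent] fragments for X.
#' @param clash_floor,params,table Passed to [attach_substituent()].
#' @return List with `entries` (list of library entries: `backbone`, `r1`,
#'   `r2`, `adduct`, `label`, `geometry`, `annotation`) and `rejections`
#'   (data frame `label`, `reason`).
#' @export
build_library <- function(scaffolds, substituents, adducts,
                          clash_floor = 0.75, params = bond_params(),
                          table = element_table()) {
  combos <- enumerate_combinations(names(scaffolds), names(substituents),
                                   names(substituents), names(adducts))
  entries <- list()
  rej_label <- character(0); rej_reason <- character(0)
  for (k in seq_len(nrow(combos))) {
    sc <- scaffolds[[combos$backbone[k]]]
    res <- tryCatch({
      st <- list(frame = sc$geometry,
                 map = seq_along(sc$geometry$elements))
      st <- .attach_at_sites(st, sc$r1_sites, substituents[[combos$r1[k]]],
                             clash_floor = clash_floor, params = params,
                             table = table)
      st <- .attach_at_sites(st, sc$r2_sites, substituents[[combos$r2[k]]],
                             clash_floor = clash_floor, params = params,
                             table = table)
      ad <- adducts[[combos$adduct[k]]]
      n_before <- length(st$frame$elements)
      st <- .attach_at_sites(st, sc$adduct_site, ad,
                             clash_floor = clash_floor, params = params,
                             table = table)
      # adduct fragment is appended after placeholder removal, so its
      # coordinating (attachment) atom lands at a known final index
      adduct_atom <- (n_before - 1L) + ad$attach_index
      ann <- ref_annotation(
        metal_index = st$map[sc$metal_index],
        donor_indices = st$map[sc$donor_indices],
        donor_roles = sc$donor_roles,
        adduct_indices = adduct_atom,
        features = list(backbone = combos$backbone[k], r1 = combos$r1[k],
                        r2 = combos$r2[k], adduct = combos$adduct[k])
      )
      list(backbone = combos$backbone[k], r1 = combos$r1[k],
           r2 = combos$r2[k], adduct = combos$adduct[k],
           label = combos$label[k], geometry = st$frame, annotation = ann)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rej_label <- c(rej_label, combos$label[k])
      rej_reason <- c(rej_reason, conditionMessage(res))
    } else {
      entries[[length(entries) + 1L]] <- res
    }
  }
  list(
    entries = entries,
    rejections = data.frame(label = rej_label, reason = rej_reason,
                            stringsAsFactors = FALSE)
  )
}

#' Write a built library to disk
#'
#' One XYZ file per entry plus a CSV manifest (`label`, `backbone`, `r1`,
#' `r2`, `adduct`, `n_atoms`, `status`); rejected combinations appear in
#' the manifest with their failure reason.
#'
#' @param lib Result of [build_library()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (e in lib$entries) {
    write_xyz_trajectory(e$geometry, file.path(dir, paste0(e$label, ".xyz")))
    rows[[length(rows) + 1L]] <- data.frame(
      label = e$label, backbone = e$backbone, r1 = e$r1, r2 = e$r2,
      adduct = e$adduct, n_atoms = length(e$geometry$elements),
      status = "ok", stringsAsFactors = FALSE)
  }
  if (nrow(lib$rejections) > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      label = lib$rejections$label, backbone = NA, r1 = NA, r2 = NA,
      adduct = NA, n_atoms = NA,
      status = paste0("rejected: ", lib$rejections$reason),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
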