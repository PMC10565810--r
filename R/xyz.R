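# Structures and multi-frame XYZ trajectory I/O.

HARTREE_TO_KCAL <- 627.509

#' Single chemical structure (one XYZ frame)
#'
#' @param elements Character vector of element symbols (case-normalized and
#'   validated against the periodic table).
#' @param coords Numeric n x 3 matrix of Cartesian coordinates, Angstrom.
#' @param energy Optional scalar energy in the units declared by the
#'   enclosing trajectory; `NULL` when the frame carries no energy.
#' @param frame_index Optional non-negative integer position within a
#'   trajectory.
#' @return An object of class `xyz_frame`.
#' @export
xyz_frame <- function(elements, coords, energy = NULL, frame_index = NULL) {
  elements <- normalize_element(as.character(elements))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(elements) == 0L) stop("structure must contain at least one atom")
  if (nrow(coords) != length(elements) || ncol(coords) != 3L) {
    stop("coords must be an n x 3 matrix matching length(elements)")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.null(energy)) {
    energy <- as.numeric(energy)
    if (length(energy) != 1L || !is.finite(energy)) {
      stop("energy must be a finite scalar or NULL")
    }
  }
  if (!is.null(frame_index)) {
    frame_index <- as.integer(frame_index)
    if (frame_index < 0L) stop("frame_index must be non-negative")
  }
  dimnames(coords) <- NULL
  structure(
    list(elements = elements, coords = coords, energy = energy,
         frame_index = frame_index),
    class = "xyz_frame"
  )
}

#' @export
print.xyz_frame <- function(x, ...) {
  cat("<xyz_frame> ", length(x$elements), " atoms",
      if (!is.null(x$energy)) sprintf(", energy %.6f", x$energy) else "",
      "\n", sep = "")
  invisible(x)
}

#' Multi-frame trajectory container
#'
#' All frames must share one element sequence: atoms are identity-tracked
#' by position along the trajectory, which is what makes positional bond
#' diffs well defined downstream.
#'
#' @param frames List of [xyz_frame] objects.
#' @param energy_units `"hartree"` or `"kcal_per_mol"`; how the per-frame
#'   energies are to be interpreted.
#' @param source_path Optional provenance string.
#' @return An object of class `xyz_trajectory`.
#' @export
xyz_trajectory <- function(frames, energy_units = c("hartree", "kcal_per_mol"),
                           source_path = NA_character_) {
  energy_units <- match.arg(energy_units)
  if (length(frames) == 0L) stop("no frames")
  ref <- frames[[1L]]$elements
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!inherits(f, "xyz_frame")) stop("frames must be xyz_frame objects")
    if (!identical(f$elements, ref)) {
      stop("inconsistent element sequence at frame ", i - 1L)
    }
    frames[[i]]$frame_index <- i - 1L
  }
  structure(
    list(frames = frames, energy_units = energy_units,
         source_path = source_path),
    class = "xyz_trajectory"
  )
}

#' @export
print.xyz_trajectory <- function(x, ...) {
  cat("<xyz_trajectory> ", length(x$frames), " frames, ",
      length(x$frames[[1L]]$elements), " atoms, energies in ",
      x$energy_units, "\n", sep = "")
  invisible(x)
}

#' @export
length.xyz_trajectory <- function(x) length(x$frames)

# First parseable floating-point token of an XYZ comment line, NULL if none.
# Permissive by default: "Energy= -5.07", "-5.07 gnorm ...", bare numbers all
# parse. strict = TRUE accepts only a comment that is a single bare number.
.parse_comment_energy <- function(comment, strict = FALSE) {
  toks <- strsplit(trimws(comment), "[[:space:]=,]+")[[1L]]
  toks <- toks[nzchar(toks)]
  if (strict) {
    if (length(toks) != 1L) return(NULL)
    v <- suppressWarnings(as.numeric(toks))
    return(if (is.finite(v)) v else NULL)
  }
  for (t in toks) {
    v <- suppressWarnings(as.numeric(t))
    if (!is.na(v) && is.finite(v)) return(v)
  }
  NULL
}

#' Read a multi-frame XYZ trajectory
#'
#' Parses the standard XYZ stacking: an atom-count line, a comment line and
#' that many `El x y z` atom lines per frame. A frame energy is taken as the
#' first parseable floating-point token of the comment line (covering both
#' bare numbers and `Energy=`-style prefixes emitted by conformer-search
#' engines); frames whose comment holds no number carry no energy. Windows
#' line endings and trailing whitespace are tolerated.
#'
#' @param path Path to the XYZ file.
#' @param energy_units Units of the comment-line energies; defaults to
#'   hartree, the native unit of semiempirical and DFT engines.
#' @param strict_energy If `TRUE`, only a comment line consisting of a single
#'   bare number is read as an energy.
#' @return An [xyz_trajectory].
#' @export
read_xyz_trajectory <- function(path, energy_units = "hartree",
                                strict_energy = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  # drop trailing blank lines only
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) stop("no frames in ", path)
  frames <- list()
  pos <- 1L
  fidx <- 0L
  while (pos <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat <= 0L) {
      stop("frame ", fidx, ": bad atom-count header at line ", pos)
    }
    if (pos + 1L + nat > length(lines)) {
      stop("frame ", fidx, ": truncated block at line ", pos,
           " (expected ", nat, " atom lines)")
    }
    comment <- lines[pos + 1L]
    atom_lines <- lines[(pos + 2L):(pos + 1L + nat)]
    el <- character(nat)
    xyz <- matrix(NA_real_, nat, 3L)
    for (k in seq_len(nat)) {
      toks <- strsplit(trimws(atom_lines[k]), "[[:space:]]+")[[1L]]
      if (length(toks) < 4L) {
        stop("frame ", fidx, ": malformed atom line ", pos + 1L + k)
      }
      el[k] <- toks[1L]
      v <- suppressWarnings(as.numeric(toks[2:4]))
      if (any(!is.finite(v))) {
        stop("frame ", fidx, ": unparseable coordinate at line ", pos + 1L + k)
      }
      xyz[k, ] <- v
    }
    frames[[length(frames) + 1L]] <- xyz_frame(
      elements = el, coords = xyz,
      energy = .parse_comment_energy(comment, strict = strict_energy),
      frame_index = fidx
    )
    pos <- pos + 2L + nat
    fidx <- fidx + 1L
  }
  xyz_trajectory(frames, energy_units = energy_units, source_path = path)
}

#' Write a multi-frame XYZ trajectory
#'
#' Energies, where present, are written as the sole token of the comment
#' line with 12 significant digits so that a read/write round trip preserves
#' them to well below any chemically meaningful tolerance.
#'
#' @param traj An [xyz_trajectory] (or a single [xyz_frame], written as a
#'   one-frame file).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_xyz_trajectory <- function(traj, path) {
  if (inherits(traj, "xyz_frame")) {
    traj <- xyz_trajectory(list(traj))
  }
  if (!inherits(traj, "xyz_trajectory")) stop("not a trajectory")
  out <- character(0)
  for (f in traj$frames) {
    n <- length(f$elements)
    comment <- if (is.null(f$energy)) "" else sprintf("%.12g", f$energy)
    body <- sprintf("%-3s %18.10f %18.10f %18.10f",
                    f$elements, f$coords[, 1L], f$coords[, 2L], f$coords[, 3L])
    out <- c(out, as.character(n), comment, body)
  }
  writeLines(out, path)
  invisible(path)
}

#' Convert energies from hartree to kcal/mol
#'
#' @param e Numeric vector of energies in hartree.
#' @param factor Conversion constant; 1 hartree = 627.509 kcal/mol by
#'   default, overridable for callers needing more digits.
#' @return Energies in kcal/mol.
#' @examples
#' hartree_to_kcal(1)      # 627.509
#' hartree_to_kcal(-0.1)   # -62.7509
#' @export
hartree_to_kcal <- function(e, factor = HARTREE_TO_KCAL) {
  stopifnot(all(is.finite(e)))
  e * factor
}

# Energies of a trajectory in kcal/mol (NA where a frame has none).
.traj_energies_kcal <- function(traj) {
  e <- vapply(traj$frames, function(f) {
    if (is.null(f$energy)) NA_real_ else f$energy
  }, numeric(1))
  if (traj$energy_units == "hartree") e <- e * HARTREE_TO_KCAL
  e
}
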