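# Sidecar metadata files (simple "key: value" text) and per-trajectory
# analysis reports. Sidecars carry what an XYZ file cannot: atom roles,
# substitution sites and categorical structural features.

.write_kv <- function(kv, path) {
  lines <- vapply(names(kv), function(k) {
    paste0(k, ": ", paste(kv[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.read_kv <- function(path) {
  if (!file.exists(path)) stop("sidecar not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("\r$", "", lines))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed sidecar line: ", ln)
    kv[[trimws(m[2L])]] <- strsplit(m[3L], ",\\s*")[[1L]]
  }
  kv
}

#' Write/read a reference annotation sidecar
#'
#' @param ann A [ref_annotation].
#' @param path Sidecar file path.
#' @return `write_annotation` returns `path` invisibly; `read_annotation`
#'   returns a [ref_annotation].
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "ref_annotation"))
  .write_kv(list(
    metal_index = ann$metal_index,
    donor_indices = ann$donor_indices,
    donor_roles = ann$donor_roles,
    adduct_indices = ann$adduct_indices,
    backbone = ann$features$backbone %||% "",
    r1 = ann$features$r1 %||% "",
    r2 = ann$features$r2 %||% "",
    adduct = ann$features$adduct %||% ""
  ), path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  kv <- .read_kv(path)
  ref_annotation(
    metal_index = as.integer(kv$metal_index),
    donor_indices = as.integer(kv$donor_indices),
    donor_roles = kv$donor_roles,
    adduct_indices = if (is.null(kv$adduct_indices)) integer(0) else
      as.integer(kv$adduct_indices),
    features = list(backbone = kv$backbone, r1 = kv$r1, r2 = kv$r2,
                    adduct = kv$adduct)
  )
}

#' Write/read a scaffold as XYZ plus sidecar
#'
#' @param sc A [scaffold].
#' @param xyz_path,sidecar_path Paths for geometry and metadata.
#' @return `write_scaffold` returns the sidecar path invisibly;
#'   `read_scaffold` returns a [scaffold].
#' @export
write_scaffold <- function(sc, xyz_path, sidecar_path) {
  stopifnot(inherits(sc, "scaffold"))
  write_xyz_trajectory(sc$geometry, xyz_path)
  .write_kv(list(
    name = sc$name, metal_index = sc$metal_index,
    r1_sites = sc$r1_sites, r2_sites = sc$r2_sites,
    adduct_site = sc$adduct_site,
    donor_indices = sc$donor_indices, donor_roles = sc$donor_roles
  ), sidecar_path)
}

#' @rdname write_scaffold
#' @export
read_scaffold <- function(xyz_path, sidecar_path) {
  kv <- .read_kv(sidecar_path)
  geom <- read_xyz_trajectory(xyz_path)$frames[[1L]]
  scaffold(
    name = kv$name, geometry = geom,
    r1_sites = as.integer(kv$r1_sites), r2_sites = as.integer(kv$r2_sites),
    adduct_site = as.integer(kv$adduct_site),
    metal_index = as.integer(kv$metal_index),
    donor_indices = as.integer(kv$donor_indices),
    donor_roles = kv$donor_roles
  )
}

#' Write/read a substituent fragment as XYZ plus sidecar
#'
#' @param sub A [substituent].
#' @param xyz_path,sidecar_path Paths for geometry and metadata.
#' @return `write_substituent` returns the sidecar path invisibly;
#'   `read_substituent` returns a [substituent].
#' @export
write_substituent <- function(sub, xyz_path, sidecar_path) {
  stopifnot(inherits(sub, "substituent"))
  write_xyz_trajectory(sub$geometry, xyz_path)
  .write_kv(list(
    name = sub$name, attach_index = sub$attach_index,
    attach_vector = sprintf("%.10f", sub$attach_vector)
  ), sidecar_path)
}

#' @rdname write_substituent
#' @export
read_substituent <- function(xyz_path, sidecar_path) {
  kv <- .read_kv(sidecar_path)
  geom <- read_xyz_trajectory(xyz_path)$frames[[1L]]
  substituent(kv$name, geom, as.integer(kv$attach_index),
              as.numeric(kv$attach_vector))
}

#' Write a full trajectory analysis to disk
#'
#' Emits the per-trajectory conformer report as JSON (structural features
#' plus one record per conformer), the bond-change table as CSV and the
#' evolution graph as GraphML and DOT.
#'
#' @param cs A `conformer_set` from [analyze_trajectory()].
#' @param dir Output directory (created if needed).
#' @param name Basename for the emitted files.
#' @return Invisibly, the JSON path.
#' @export
write_analysis <- function(cs, dir, name = "analysis") {
  stopifnot(inherits(cs, "conformer_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  report <- conformer_report(cs)
  feats <- if (is.null(cs$annotation)) list() else cs$annotation$features
  json_path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(
    list(name = name, features = feats, n_frames = cs$n_frames,
         conformers = report),
    json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
    na = "null")
  changes <- do.call(rbind, lapply(cs$records, function(r) {
    if (nrow(r$changes) == 0L) return(NULL)
    cbind(conformer_id = r$conformer_id, r$changes)
  }))
  if (is.null(changes)) {
    changes <- data.frame(conformer_id = integer(0), sign = character(0),
                          i = integer(0), j = integer(0),
                          class = character(0), label = character(0))
  }
  utils::write.csv(changes, file.path(dir, paste0(name, "_changes.csv")),
                   row.names = FALSE)
  g <- build_evolution_graph(cs)
  write_evolution_graph(g, file.path(dir, paste0(name, ".graphml")),
                        "graphml")
  write_evolution_graph(g, file.path(dir, paste0(name, ".dot")), "dot")
  invisible(json_path)
}

#' Assemble the reactivity database from analysis report files
#'
#' Reads per-trajectory JSON reports written by [write_analysis()] and
#' flattens their non-reference conformers into the global database, in
#' the same shape as [reactivity_records()].
#'
#' @param paths Character vector of report JSON paths.
#' @return Database data frame.
#' @export
db_from_analysis_files <- function(paths) {
  rows <- list()
  for (p in paths) {
    rep <- jsonlite::read_json(p, simplifyVector = TRUE)
    conf <- rep$conformers
    if (is.null(conf) || nrow(conf) == 0L) next
    conf <- conf[conf$conformer_id != 1L, , drop = FALSE]
    if (nrow(conf) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      entry_label = rep$name,
      backbone = rep$features$backbone %||% NA_character_,
      r1 = rep$features$r1 %||% NA_character_,
      r2 = rep$features$r2 %||% NA_character_,
      adduct = rep$features$adduct %||% NA_character_,
      conformer_id = conf$conformer_id,
      delta_e = conf$delta_e,
      cn_metal = conf$cn_metal,
      labels = conf$labels,
      status = ifelse(is.na(conf$delta_e), "no_energy", "ok"),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) stop("no conformer records found")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the scripted fixture corpus to disk
#'
#' One XYZ trajectory, one annotation sidecar and one expected-result JSON
#' per corpus entry, for use outside R.
#'
#' @param corpus Result of [make_fixture_corpus()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_fixture_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in corpus) {
    write_xyz_trajectory(e$trajectory, file.path(dir, paste0(e$name, ".xyz")))
    write_annotation(e$annotation, file.path(dir, paste0(e$name, ".ann")))
    jsonlite::write_json(
      list(name = e$name,
           n_conformers = e$expected$n_conformers,
           assignments = e$expected$assignments,
           segment_labels = e$expected$segment_labels),
      file.path(dir, paste0(e$name, "_expected.json")),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
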