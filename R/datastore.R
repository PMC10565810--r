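# Global reactivity database: assembly, energy-window filtering,
# feature-correlation histograms and per-cluster reporting.

#' Assemble reactivity records from trajectory analyses
#'
#' Flattens a set of analyzed trajectories into the global database: one
#' row per non-reference conformer, carrying the structural features of
#' its reference complex (backbone, R1, R2, adduct), the conformer's
#' relative energy and metal coordination number, and its sorted event
#' labels joined with `"; "`. Conformers without a usable energy are kept
#' with `status = "no_energy"` so they can be excluded from energy-based
#' analyses without being lost.
#'
#' @param analyses Named list of `conformer_set` objects from
#'   [analyze_trajectory()]; names become `entry_label`.
#' @return Data frame with columns `entry_label`, `backbone`, `r1`, `r2`,
#'   `adduct`, `conformer_id`, `delta_e`, `cn_metal`, `labels`, `status`.
#' @export
reactivity_records <- function(analyses) {
  rows <- list()
  labs <- names(analyses)
  if (is.null(labs)) labs <- as.character(seq_along(analyses))
  for (t in seq_along(analyses)) {
    cs <- analyses[[t]]
    stopifnot(inherits(cs, "conformer_set"))
    feats <- cs$annotation$features
    for (r in cs$records) {
      if (r$conformer_id == 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        entry_label = labs[t],
        backbone = feats$backbone %||% NA_character_,
        r1 = feats$r1 %||% NA_character_,
        r2 = feats$r2 %||% NA_character_,
        adduct = feats$adduct %||% NA_character_,
        conformer_id = r$conformer_id,
        delta_e = r$delta_e,
        cn_metal = if (is.null(r$cn_metal)) NA_integer_ else r$cn_metal,
        labels = paste(r$event_labels, collapse = "; "),
        status = if (is.na(r$delta_e)) "no_energy" else "ok",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(entry_label = character(0), backbone = character(0),
                      r1 = character(0), r2 = character(0),
                      adduct = character(0), conformer_id = integer(0),
                      delta_e = numeric(0), cn_metal = integer(0),
                      labels = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Energy window
#'
#' Closed interval of relative energies (kcal/mol) used to restrict the
#' database to chemically credible species before classification; the
#' default \[-40, +25\] keeps structures near the reference and discards
#' collapse artifacts hundreds of kcal/mol downhill.
#'
#' @param lo,hi Window bounds, kcal/mol, `lo < hi`.
#' @return An object of class `energy_window`.
#' @export
energy_window <- function(lo = -40, hi = 25) {
  stopifnot(is.finite(lo), is.finite(hi), lo < hi)
  structure(list(lo = lo, hi = hi), class = "energy_window")
}

#' Filter records by an energy window
#'
#' Keeps records with `lo <= delta_e <= hi` (both endpoints included),
#' preserving input order. Missing `delta_e` is an error: callers must
#' drop or repair `no_energy` records explicitly first.
#'
#' @param records Database data frame ([reactivity_records()]).
#' @param w An [energy_window()].
#' @return The filtered data frame.
#' @export
filter_window <- function(records, w = energy_window()) {
  stopifnot(inherits(w, "energy_window"))
  if (anyNA(records$delta_e)) stop("records with missing delta_e")
  records[records$delta_e >= w$lo & records$delta_e <= w$hi, , drop = FALSE]
}

#' Feature-correlation histogram
#'
#' Cross-tabulates two record features: cell (a, b) counts the records
#' showing that combination, and the frequency of observed feature
#' combinations serves as the correlation measure. Row and column margins
#' (per-category totals) are returned alongside. `delta_e` may be used as
#' a feature; it is binned into fixed-width bins (5 kcal/mol by default)
#' aligned to the bin width. `cn_metal` is used as-is.
#'
#' @param records Database data frame.
#' @param feat_a,feat_b Column names among `backbone`, `r1`, `r2`,
#'   `adduct`, `cn_metal`, `delta_e`.
#' @param de_binwidth Bin width for `delta_e`, kcal/mol.
#' @return List with `counts` (matrix, rows = `feat_a` categories),
#'   `row_margin`, `col_margin`, `n`.
#' @export
correlation_histogram <- function(records, feat_a, feat_b, de_binwidth = 5) {
  get_feat <- function(f) {
    if (!f %in% names(records)) stop("unknown field: ", f)
    v <- records[[f]]
    if (f == "delta_e") {
      lo <- floor(min(v) / de_binwidth) * de_binwidth
      br <- seq(lo, max(v) + de_binwidth, by = de_binwidth)
      v <- as.character(cut(v, breaks = br, include.lowest = TRUE,
                            right = FALSE))
    }
    as.character(v)
  }
  a <- get_feat(feat_a)
  b <- get_feat(feat_b)
  counts <- table(a, b)
  counts <- unclass(counts)
  names(dimnames(counts)) <- c(feat_a, feat_b)
  rm <- rowSums(counts); cm <- colSums(counts)
  storage.mode(rm) <- "integer"; storage.mode(cm) <- "integer"
  list(counts = counts, row_margin = rm, col_margin = cm,
       n = nrow(records))
}

#' Encode record label sets as a binary matrix
#'
#' One column per distinct event label observed anywhere in the database
#' (sorted), one row per record; entry 1 when the record carries the
#' label. The vocabulary is attached for decoding.
#'
#' @param records Database data frame (column `labels`, `"; "`-joined).
#' @return Integer 0/1 matrix with `colnames` = vocabulary and attribute
#'   `vocabulary`.
#' @export
encode_labels <- function(records) {
  sets <- strsplit(records$labels, "; ", fixed = TRUE)
  sets <- lapply(sets, function(s) s[nzchar(s)])
  vocab <- sort(unique(unlist(sets)))
  m <- matrix(0L, nrow = length(sets), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (r in seq_along(sets)) m[r, match(sets[[r]], vocab)] <- 1L
  attr(m, "vocabulary") <- vocab
  m
}

#' Decode a binary label matrix back to label sets
#'
#' @param m Matrix from [encode_labels()].
#' @return Character vector of `"; "`-joined sorted label sets (the
#'   database `labels` representation).
#' @export
decode_labels <- function(m) {
  vocab <- colnames(m)
  apply(m, 1L, function(row) paste(vocab[row == 1L], collapse = "; "))
}

#' Per-cluster summary report
#'
#' Decodes each cluster center back to its label set and summarizes the
#' membership: count, delta-E range, and the composition of backbone, R1
#' and R2 features. Clusters are ordered by size, largest first (ties by
#' lower cluster id), matching the "top clusters" reading of the most
#' frequent interaction types.
#'
#' @param model A `kmodes_model` from [kmodes_cluster()].
#' @param records The database rows that were encoded and clustered, in
#'   the same order.
#' @return Data frame with one row per cluster: `cluster`, `size`,
#'   `center_labels`, `de_min`, `de_max`, `backbones`, `r1`, `r2`.
#' @export
cluster_report <- function(model, records) {
  stopifnot(inherits(model, "kmodes_model"),
            nrow(records) == length(model$assignments))
  comp <- function(v) {
    t <- sort(table(v), decreasing = TRUE)
    paste(paste0(names(t), ":", as.integer(t)), collapse = " ")
  }
  center_sets <- decode_labels(model$centers)
  rows <- lapply(seq_len(model$k), function(cid) {
    idx <- which(model$assignments == cid)
    data.frame(
      cluster = cid,
      size = length(idx),
      center_labels = center_sets[cid],
      de_min = if (length(idx)) min(records$delta_e[idx]) else NA_real_,
      de_max = if (length(idx)) max(records$delta_e[idx]) else NA_real_,
      backbones = comp(records$backbone[idx]),
      r1 = comp(records$r1[idx]),
      r2 = comp(records$r2[idx]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$size, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the database to CSV and JSON
#'
#' @param records Database data frame.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_database <- function(records, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(records, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(records, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(c(csv_path, json_path))
}
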