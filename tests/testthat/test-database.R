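# small synthetic database used across tests
fake_records <- function(n = 40L, seed = 1L) {
  set.seed(seed)
  labels_pool <- c("-Mn-N; -side arm", "+C-O", "-Mn-P; -side arm",
                   "+Mn-H", "-Mn-S(2); -side arm(2)", "")
  data.frame(
    entry_label = paste0("e", seq_len(n)),
    backbone = sample(c("PNP", "SNS", "CNC", "PNN"), n, TRUE),
    r1 = sample(c("H", "CF3", "tBu"), n, TRUE),
    r2 = sample(c("H", "Ph"), n, TRUE),
    adduct = sample(c("Br", "OH"), n, TRUE),
    conformer_id = sample(2:5, n, TRUE),
    delta_e = round(runif(n, -45, 30), 2),
    cn_metal = sample(4:6, n, TRUE),
    labels = sample(labels_pool, n, TRUE),
    status = "ok",
    stringsAsFactors = FALSE
  )
}

test_that("records flatten analyzed trajectories with their features", {
  corp <- make_fixture_corpus(seed = 2L)[1:3]
  analyses <- lapply(corp, function(e)
    analyze_trajectory(e$trajectory, e$annotation))
  names(analyses) <- names(corp)
  db <- reactivity_records(analyses)
  expect_true(all(db$conformer_id > 1L))
  expect_identical(db$backbone, rep("PNP", nrow(db)))
  expect_true(all(db$status == "ok"))
  expect_true(any(grepl("side arm", db$labels)))
})

test_that("energy-window filtering is closed, ordered and monotone", {
  db <- fake_records()
  db$delta_e[1L] <- -600  # collapse artifact
  db$delta_e[2L] <- 0
  w <- energy_window(-40, 25)
  kept <- filter_window(db, w)
  expect_false("e1" %in% kept$entry_label)
  expect_true("e2" %in% kept$entry_label)
  expect_true(all(kept$delta_e >= -40 & kept$delta_e <= 25))
  # endpoints included
  db$delta_e[3L] <- -40; db$delta_e[4L] <- 25
  kept <- filter_window(db, w)
  expect_true(all(c("e3", "e4") %in% kept$entry_label))
  # order preserved, idempotent, monotone under widening
  expect_identical(filter_window(kept, w), kept)
  inner <- filter_window(db, energy_window(-40, 0))
  expect_true(all(inner$entry_label %in% kept$entry_label))
  expect_error(filter_window(transform(db, delta_e = NA), w), "missing")
})

test_that("correlation histograms equal hand and nested-loop counts", {
  db <- data.frame(
    r1 = c("H", "H", "CF3", "CF3"),
    backbone = c("PNP", "SNS", "PNP", "PNP"),
    delta_e = c(-1, -2, -3, -4), cn_metal = c(6L, 6L, 5L, 6L),
    stringsAsFactors = FALSE
  )
  h <- correlation_histogram(db, "r1", "backbone")
  expect_identical(h$counts["CF3", "PNP"], 2L)
  expect_identical(h$counts["H", "SNS"], 1L)
  expect_identical(h$counts["CF3", "SNS"], 0L)
  expect_identical(sum(h$counts), 4L)
  expect_identical(unname(h$row_margin["CF3"]), 2L)

  big <- fake_records(60L, seed = 3L)
  for (pair in list(c("r1", "backbone"), c("backbone", "cn_metal"))) {
    h <- correlation_histogram(big, pair[1L], pair[2L])
    expect_identical(sum(h$counts), nrow(big))
    for (a in rownames(h$counts)) for (b in colnames(h$counts)) {
      manual <- 0L
      for (r in seq_len(nrow(big))) {
        if (as.character(big[[pair[1L]]][r]) == a &&
            as.character(big[[pair[2L]]][r]) == b) manual <- manual + 1L
      }
      expect_identical(unname(h$counts[a, b]), manual)
    }
    expect_equal(unname(h$row_margin), unname(as.integer(rowSums(h$counts))))
    expect_equal(unname(h$col_margin), unname(as.integer(colSums(h$counts))))
  }
  expect_error(correlation_histogram(big, "r1", "nope"), "unknown field")
})

test_that("delta_e histograms bin on a fixed-width grid", {
  db <- fake_records(30L, seed = 4L)
  h <- correlation_histogram(db, "r1", "delta_e", de_binwidth = 5)
  expect_identical(sum(h$counts), 30L)
  expect_true(all(grepl("^\\[", colnames(h$counts))))
})

test_that("label encoding is a faithful round trip", {
  db <- data.frame(labels = c("+A-B", "+A-B; -C-D", "", "-C-D"),
                   stringsAsFactors = FALSE)
  m <- encode_labels(db)
  expect_identical(colnames(m), c("+A-B", "-C-D"))
  expect_identical(as.vector(m), c(1L, 1L, 0L, 0L, 0L, 1L, 0L, 1L))
  expect_identical(decode_labels(m), db$labels)
  big <- fake_records(25L, seed = 6L)
  expect_identical(decode_labels(encode_labels(big)), big$labels)
})

test_that("cluster reports decode centers and conserve membership", {
  db <- fake_records(30L, seed = 8L)
  m <- encode_labels(db)
  fit <- kmodes_cluster(m, k = 3L, n_init = 5L, seed = 2L)
  rep <- cluster_report(fit, db)
  expect_identical(sum(rep$size), nrow(db))
  expect_identical(rep$size, sort(rep$size, decreasing = TRUE))
  # single cluster covers everything
  f1 <- kmodes_cluster(m, k = 1L, n_init = 1L, seed = 2L)
  r1 <- cluster_report(f1, db)
  expect_identical(nrow(r1), 1L)
  expect_identical(r1$size, nrow(db))
})

test_that("database writes to CSV and JSON", {
  db <- fake_records(5L)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_database(db, csv, js)
  back <- read.csv(csv, stringsAsFactors = FALSE)
  expect_identical(back$entry_label, db$entry_label)
  expect_equal(back$delta_e, db$delta_e)
  expect_length(jsonlite::read_json(js), 5L)
})
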