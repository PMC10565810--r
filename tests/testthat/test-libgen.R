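test_that("enumeration is the full Cartesian product with unique labels", {
  cmb <- enumerate_combinations("A", c("x", "y"), c("u", "v"), c("p", "q"))
  expect_identical(nrow(cmb), 8L)
  expect_identical(anyDuplicated(cmb$label), 0L)
  # lexicographic: backbone slowest, adduct fastest
  expect_identical(cmb$adduct[1:2], c("p", "q"))
  expect_identical(cmb$label[1L], "A_x_u_p")

  # matches a nested-loop count on random option sets
  set.seed(5)
  for (rep in 1:3) {
    opts <- lapply(1:4, function(k) paste0(letters[k], seq_len(sample(2:5, 1L))))
    cmb <- enumerate_combinations(opts[[1]], opts[[2]], opts[[3]], opts[[4]])
    manual <- 0L
    for (b in opts[[1]]) for (r1 in opts[[2]]) for (r2 in opts[[3]])
      for (x in opts[[4]]) manual <- manual + 1L
    expect_identical(nrow(cmb), manual)
    expect_identical(anyDuplicated(cmb$label), 0L)
  }
})

test_that("empty or duplicated option lists are rejected", {
  expect_error(enumerate_combinations(character(0), "a", "b", "c"), "non-empty")
  expect_error(enumerate_combinations("a", c("x", "x"), "b", "c"), "duplicate")
})

test_that("attaching a single H placeholder reproduces the bond length", {
  tc <- make_toy_complex("PNP")
  site <- tc$r1_sites[1L]
  out <- attach_substituent(tc$structure, site, toy_substituent("H"),
                            bond_length = 1.09)
  expect_identical(length(out$elements), length(tc$structure$elements))
  # topology unchanged
  expect_true(is_isomorphic(perceive_bonds(out), tc$graph))
  map <- attr(out, "index_map")
  anchor <- tc$arms[[1L]]$donor
  d <- sqrt(sum((out$coords[length(out$elements), ] -
                   out$coords[map[anchor], ])^2))
  expect_equal(d, 1.09, tolerance = 1e-6)
})

test_that("attaching CF3 adds exactly the expected covalent edges", {
  tc <- make_toy_complex("PNP")
  site <- tc$r1_sites[1L]
  g0 <- perceive_bonds(tc$structure)
  out <- attach_substituent(tc$structure, site, toy_substituent("CF3"))
  g1 <- perceive_bonds(out)
  expect_identical(length(out$elements), length(tc$structure$elements) + 3L)
  # diff against the placeholder-stripped reference graph
  n0 <- length(tc$structure$elements)
  cf3_c <- n0        # placeholder removed, fragment appended
  new_edges <- g1$edges[g1$edges$i >= cf3_c | g1$edges$j >= cf3_c, ]
  expect_identical(nrow(new_edges), 4L)
  expect_identical(sum(new_edges$j > cf3_c & new_edges$i == cf3_c), 3L)  # C-F
  expect_identical(nrow(g1$edges), nrow(g0$edges) - 1L + 4L)
})

test_that("attachment is deterministic and validates its preconditions", {
  tc <- make_toy_complex("SNS")
  site <- tc$r1_sites[1L]
  a <- attach_substituent(tc$structure, site, toy_substituent("Ph"))
  b <- attach_substituent(tc$structure, site, toy_substituent("Ph"))
  expect_identical(a$coords, b$coords)
  # a multi-neighbor atom is not a placeholder
  expect_error(
    attach_substituent(tc$structure, tc$metal_index, toy_substituent("H")),
    "neighbors")
})

test_that("steric clashes are reported with the offending pair", {
  # second placeholder site right next to the first: bulky fragment clashes
  s <- xyz_frame(c("C", "H", "N"),
                 rbind(c(0, 0, 0), c(1.05, 0, 0), c(1.8, 0.6, 0)))
  expect_error(attach_substituent(s, 2L, toy_substituent("tBu")),
               "clash.*atom")
})

test_that("library accounting is exact: entries + rejections = enumeration", {
  scafs <- lapply(c(PNP = "PNP", CNC = "CNC"),
                  function(b) as_scaffold(make_toy_complex(b)))
  subs <- lapply(c(H = "H", CF3 = "CF3", tBu = "tBu"), toy_substituent)
  adds <- lapply(c(Br = "Br", OH = "OH"), toy_substituent)
  lib <- build_library(scafs, subs, adds)
  expect_identical(length(lib$entries) + nrow(lib$rejections),
                   2L * 3L * 3L * 2L)
  labels <- vapply(lib$entries, `[[`, character(1), "label")
  expect_identical(anyDuplicated(c(labels, lib$rejections$label)), 0L)
})

test_that("accepted entries keep the metal-donor coordination shell", {
  scafs <- list(PNP = as_scaffold(make_toy_complex("PNP")))
  subs <- lapply(c(H = "H", CF3 = "CF3"), toy_substituent)
  adds <- list(OH = toy_substituent("OH"))
  lib <- build_library(scafs, subs, adds)
  expect_gt(length(lib$entries), 0L)
  for (e in lib$entries) {
    g <- perceive_bonds(e$geometry)
    expect_no_error(validate_annotation(e$annotation, g))
    expect_identical(coordination_number(g, e$annotation$metal_index), 6L)
  }
})

test_that("a built library round-trips through its on-disk manifest", {
  scafs <- list(SNS = as_scaffold(make_toy_complex("SNS")))
  subs <- list(H = toy_substituent("H"))
  adds <- list(Br = toy_substituent("Br"))
  lib <- build_library(scafs, subs, adds)
  dir <- withr::local_tempdir()
  write_library(lib, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), 1L)
  expect_identical(man$status, "ok")
  back <- read_xyz_trajectory(file.path(dir, paste0(man$label, ".xyz")))
  expect_identical(back$frames[[1L]]$elements, lib$entries[[1L]]$geometry$elements)
})
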