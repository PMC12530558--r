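test_that("SWC files round-trip through read and write", {
  rec <- y_recon()
  f1 <- withr::local_tempfile(fileext = ".swc")
  f2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(rec, f1)
  back <- read_swc(f1)
  write_swc(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(back$nodes[c("type", "x", "y", "z", "r")],
               renumbered <- spnmorph:::renumber_recon(rec)$nodes[
                 c("type", "x", "y", "z", "r")])
})

test_that("a minimal 3-node file parses to one root and one terminal", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# minimal", "1 1 0 0 0 5 -1", "2 3 5 0 0 0.4 1",
               "3 3 10 0 0 0.4 2"), f)
  rec <- read_swc(f)
  st <- spnmorph:::recon_structure(rec)
  expect_equal(st$n_primaries, 1L)
  expect_equal(st$n_terminals, 1L)
  expect_match(paste(rec$provenance, collapse = " "), "minimal")
})

test_that("structural defects are rejected with the offending id", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 5 0 0 0.4 2"), f)
  expect_error(read_swc(f), "2")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 5 0 0 0.4 9"), f)
  expect_error(read_swc(f), "orphan")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 5 0 0 -0.4 1"), f)
  expect_error(read_swc(f), "radius")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 5 0 0 0.4 3", "3 3 9 0 0 0.4 2"), f)
  expect_error(read_swc(f), "cycle|disconnected")
})

test_that("standardize collapses the soma, centres it and stretches z", {
  nodes <- data.frame(id = 1:4, type = c(1L, 1L, 3L, 3L),
                      x = c(1, -1, 3, 6), y = c(0, 0, 0, 0),
                      z = c(2, 2, 12, 22), r = c(1, 1, 0.3, 0.3),
                      parent = c(-1L, 1L, 1L, 3L))
  rec <- spn_recon(nodes)
  st <- standardize(rec, shrink_z = 1.7)
  soma <- st$nodes[st$nodes$type == 1L, ]
  expect_equal(nrow(soma), 1L)
  expect_equal(c(soma$x, soma$y, soma$z), c(0, 0, 0))
  expect_equal(soma$r, 1)                       # mean distance of (+-1,0,0)
  dend <- st$nodes[st$nodes$type == 3L, ]
  expect_equal(sort(dend$z), c(10, 20) * 1.7)   # z - soma z, times 1.7
  expect_equal(sort(dend$x), c(3, 6))           # x untouched beyond centring
  expect_error(standardize(rec, shrink_z = 0), "positive")
})

test_that("standardize with unit shrink on a centred sphere soma is identity", {
  rec <- straight_recon()
  st <- standardize(rec, shrink_z = 1)
  expect_equal(st$nodes[c("type", "x", "y", "z", "r")],
               rec$nodes[c("type", "x", "y", "z", "r")])
})

test_that("standardize preserves topology exactly", {
  rec <- binary_recon(depth = 3)
  st <- standardize(rec, shrink_z = 1.7)
  s0 <- spnmorph:::recon_structure(rec)
  s1 <- spnmorph:::recon_structure(st)
  expect_equal(s1$n_terminals, s0$n_terminals)
  expect_equal(s1$n_bifurcations, s0$n_bifurcations)
  expect_equal(s1$n_primaries, s0$n_primaries)
})

test_that("resample lays nodes at the requested spacing and keeps endpoints", {
  rec <- spn_recon(data.frame(id = 1:4, type = c(1L, 3L, 3L, 3L),
                              x = c(0, 0, 4, 9), y = 0, z = 0,
                              r = c(5, 0.3, 0.3, 0.3), parent = c(-1L, 1:3)))
  rs <- resample(rec, step = 3, upscale = 1)
  dend <- rs$nodes[rs$nodes$type == 3L, ]
  expect_equal(dend$x, c(0, 3, 6, 9))
  expect_error(resample(rec, step = 0), "positive")
})

test_that("resample of an exactly-sampled polyline with unit upscale is identity", {
  rec <- straight_recon(length_um = 9, n = 4)  # nodes at 0,3,6,9
  rs <- resample(rec, step = 3, upscale = 1)
  expect_equal(rs$nodes[c("x", "y", "z", "r")], rec$nodes[c("x", "y", "z", "r")],
               tolerance = 1e-12)
})

test_that("resampling a smooth curve changes total length by < 1.5%", {
  th <- seq(0, pi, length.out = 400)
  R <- 100
  nodes <- data.frame(id = 1:401, type = c(1L, rep.int(3L, 400)),
                      x = c(0, R * cos(th)), y = c(0, R * sin(th)), z = 0,
                      r = c(5, rep.int(0.3, 400)), parent = c(-1L, 1:400))
  rec <- spn_recon(nodes)
  L0 <- spnmorph:::total_dendritic_length(rec)
  rs <- resample(rec, step = 3, upscale = 1.01)
  L1 <- spnmorph:::total_dendritic_length(rs)
  expect_lt(spnmorph:::total_dendritic_length(resample(rec, 3, 1)), L0)
  expect_lt(abs(L1 - L0) / L0, 0.015)
})

test_that("resample preserves branch points and diameters interpolate", {
  rec <- binary_recon(depth = 2, seg_len = 17)
  rs <- resample(rec, step = 3, upscale = 1)
  s0 <- spnmorph:::recon_structure(rec)
  s1 <- spnmorph:::recon_structure(rs)
  expect_equal(s1$n_terminals, s0$n_terminals)
  expect_equal(s1$n_bifurcations, s0$n_bifurcations)
  expect_equal(range(rs$nodes$r[rs$nodes$type == 3L]), c(0.3, 0.3))
})

test_that("axons are read but dropped from analysis by default", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 5 0 0 0.4 1", "3 3 10 0 0 0.4 2",
               "4 2 -5 0 0 0.3 1", "5 2 -10 0 0 0.3 4"), f)
  rec <- read_swc(f)
  expect_false(any(rec$nodes$type == 2L))
  expect_equal(sum(rec$nodes$type == 3L), 2L)
  rec2 <- read_swc(f, drop_axon = FALSE)
  expect_equal(sum(rec2$nodes$type == 2L), 2L)
})
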