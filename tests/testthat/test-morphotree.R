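test_that("an unbranched primary dendrite is one segment, both primary and terminal", {
  segs <- partition_segments(straight_recon())
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$order, 1L)
  expect_equal(segs$breadth, 1L)
  expect_true(segs$is_primary && segs$is_terminal)
  expect_equal(segs$length_um, 100)
})

test_that("a Y tree decomposes into 3 segments with correct orders and breadths", {
  segs <- partition_segments(y_recon(stem = 30, arm = 50))
  expect_equal(sort(segs$order), c(1L, 2L, 2L))
  expect_equal(segs$breadth[segs$is_primary], 2L)
  expect_equal(sum(segs$is_terminal), 2L)
  expect_equal(sum(segs$length_um),
               spnmorph:::total_dendritic_length(y_recon(30, 50)))
})

test_that("a full binary tree of depth 3 has 7 segments and root breadth 4", {
  segs <- partition_segments(binary_recon(depth = 3))
  expect_equal(nrow(segs), 7L)
  expect_equal(segs$breadth[segs$is_primary], 4L)
  expect_equal(max(segs$order), 3L)
  expect_equal(sum(segs$is_terminal), 4L)
  # breadth of every segment equals the terminals distal to it
  expect_true(all(segs$breadth[segs$is_terminal] == 1L))
  expect_equal(sum(segs$breadth[segs$order == 2L]), 4L)
})

test_that("segment lengths conserve total dendritic length", {
  preset <- species_preset("human")
  for (seed in 1:5) {
    rec <- sample_morphology(preset, seed = seed)
    segs <- partition_segments(rec)
    expect_equal(sum(segs$length_um),
                 spnmorph:::total_dendritic_length(rec),
                 tolerance = 1e-9)
    # branch-root breadth equals that branch's terminal count
    for (b in unique(segs$branch_id)) {
      bs <- segs[segs$branch_id == b, ]
      expect_equal(bs$breadth[bs$is_primary], sum(bs$is_terminal))
    }
  }
})

test_that("branch morphometry computes the terminal length fraction", {
  # 4 terminals of 100 um and 3 internal segments of 20 um: 460 um total
  rec <- binary_recon(depth = 3, seg_len = 20)
  segs <- partition_segments(rec)
  # set lengths arithmetically: 3 internal x 20 um, 4 terminal x 100 um
  segs$length_um <- ifelse(segs$is_terminal, 100, 20)
  bm <- branch_morphometry(segs)
  expect_equal(bm$n_terminals, 4L)
  expect_equal(bm$total_length_um, 460)
  expect_equal(bm$terminal_length_fraction, 400 / 460, tolerance = 1e-12)
  # single-segment branch
  bm1 <- branch_morphometry(partition_segments(straight_recon()))
  expect_equal(bm1$terminal_length_fraction, 1.0)
  expect_error(branch_morphometry(partition_segments(straight_recon())[0, ]),
               "empty")
})

test_that("neuron morphometry counts primaries, terminals and bifurcations", {
  # two Y branches
  y <- y_recon()
  nd <- y$nodes
  second <- nd[nd$type == 3L, ]
  second$x <- -second$x
  second$id <- second$id + 100L
  second$parent <- ifelse(second$parent == 1L, 1L, second$parent + 100L)
  rec <- spn_recon(rbind(nd, second))
  nm <- neuron_morphometry(rec)
  expect_equal(nm$n_primaries, 2L)
  expect_equal(nm$n_terminals, 4L)
  expect_equal(nm$n_bifurcations, 2L)
  expect_equal(nm$mean_branching_ratio, 2)
})

test_that("binary-tree identity bifurcations = terminals - primaries holds on random cells", {
  preset <- species_preset("mouse")
  for (seed in seq(100, 119)) {
    nm <- neuron_morphometry(sample_morphology(preset, seed = seed))
    expect_equal(nm$n_bifurcations, nm$n_terminals - nm$n_primaries)
  }
})

test_that("Sholl profile of one radial dendrite crosses each sphere once", {
  rec <- straight_recon(length_um = 95, n = 96, soma_r = 0.5)
  sh <- sholl(rec, step = 10)
  expect_equal(sh$crossings[sh$radius_um <= 90], rep.int(1L, 9))
  expect_equal(sh$crossings[sh$radius_um == 100], 0L)
  expect_error(sholl(rec, step = 0), "positive")
})

test_that("Sholl crossings vanish beyond the most distal node", {
  rec <- sample_morphology(species_preset("mouse"), seed = 7)
  rad <- with(rec$nodes, sqrt(x^2 + y^2 + z^2))
  rmax <- max(rad[rec$nodes$type == 3L])
  sh <- sholl(rec, step = 10, max_radius = 10 * ceiling(rmax / 10) + 50)
  expect_true(all(sh$crossings[sh$radius_um > rmax] == 0L))
  expect_true(any(sh$crossings > 0L))
})

test_that("Sholl profile integral tracks total dendritic length on a cohort", {
  preset <- species_preset("mouse")
  co <- generate_cohort(preset, 10, seed = 21, spines = FALSE)
  tot <- vapply(co, function(cl)
    spnmorph:::total_dendritic_length(cl$recon), numeric(1))
  integ <- vapply(co, function(cl) {
    sh <- sholl(cl$recon, 10)
    sum(sh$crossings) * 10
  }, numeric(1))
  expect_gt(stats::cor(tot, integ, method = "spearman"), 0.7)
})

test_that("Z-scores are zero at the reference mean and unit for one SD", {
  ref <- data.frame(a = c(1, 2, 3), b = c(10, 20, 30))
  cand <- c(a = 2, b = 20)
  z <- zscore_features(cand, ref)
  expect_equal(unname(z$z), c(0, 0))
  cand2 <- c(a = 2 + stats::sd(ref$a), b = 20)
  expect_equal(unname(zscore_features(cand2, ref)$z[1]), 1)
  # zero-SD feature is flagged and excluded from the aggregate
  ref$c <- 5
  cand3 <- c(a = 3, b = 30, c = 7)
  z3 <- zscore_features(cand3, ref)
  expect_equal(z3$excluded, "c")
  expect_equal(z3$aggregate, abs(z3$z["a"]) + abs(z3$z["b"]),
               ignore_attr = TRUE)
})

test_that("group comparison: identical, monotone and separated samples", {
  same <- rep(2.5, 10)
  cg <- compare_groups(same, same)
  expect_equal(cg$welch$statistic, 0)
  expect_equal(cg$welch$p.value, 1)
  mono <- compare_groups(1:20, (1:20)^3, paired_xy = TRUE)
  expect_equal(mono$spearman$rho, 1)
  set.seed(42)
  sep <- compare_groups(rnorm(50), rnorm(50, mean = 1))
  expect_lt(sep$welch$p.value, 0.001)
  expect_error(compare_groups(1, 1:5), "at least 2")
})
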