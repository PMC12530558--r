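# Cohorts for the repair tests are small (the methods scale unchanged to
# larger ones); donors come from the same cohort as the damaged cell.

test_that("cut detection flags terminals near the top and nothing deeper", {
  rec <- straight_recon(length_um = 100, axis = c(0, 0, 1))
  det <- detect_cut_points(rec, z_threshold = 10)
  term_id <- rec$nodes$id[nrow(rec$nodes)]
  expect_equal(det$cut_node_ids, term_id)     # terminal exactly at z_max
  expect_equal(det$z_max, 100)
  # terminal far below z_max is not flagged
  rec2 <- y_recon(stem = 30, arm = 50)
  det2 <- detect_cut_points(rec2, z_threshold = 5)  # z_max on soma plane
  expect_length(det2$cut_node_ids,
                sum(rec2$nodes$z[spnmorph:::recon_structure(rec2)$terminal_rows]
                    >= det2$z_max - 5))
  expect_error(detect_cut_points(rec, -1), "positive")
})

test_that("donor pool excludes branches containing cut points", {
  preset <- species_preset("mouse")
  co <- generate_cohort(preset, 4, seed = 41, spines = FALSE)
  recs <- lapply(co, `[[`, "recon")
  sliced <- lapply(recs, slice_cut, slab_thickness = 300, soma_depth = 40)
  pool <- build_donor_pool(lapply(sliced, `[[`, "recon"),
                           preset$cut_z_threshold_um, preset$diam_bounds_um)
  n_intact <- sum(vapply(sliced, function(sl) {
    segs <- partition_segments(sl$recon)
    det <- detect_cut_points(sl$recon, preset$cut_z_threshold_um)
    cut_rows <- match(det$cut_node_ids, sl$recon$nodes$id)
    ends <- vapply(segs$path, function(p) p[length(p)], integer(1))
    length(setdiff(unique(segs$branch_id),
                   unique(segs$branch_id[ends %in% cut_rows])))
  }, integer(1)))
  expect_equal(length(pool$branches), n_intact)
  # every-branch-cut cohort gives an instructive error
  low <- straight_recon(length_um = 60, axis = c(0, 0, 1))
  expect_error(build_donor_pool(list(low), z_threshold = 100),
               "empty donor pool")
})

test_that("mirror prediction is exact for z-symmetric cells", {
  # two opposite straight dendrites along +z and -z
  up <- straight_recon(100, axis = c(0, 0, 1), start = 5)
  nd <- up$nodes
  dn <- nd[nd$type == 3L, ]
  dn$z <- -dn$z
  dn$id <- dn$id + 100L
  dn$parent <- ifelse(dn$parent == 1L, 1L, dn$parent + 100L)
  rec <- spn_recon(rbind(nd, dn))
  pred <- predict_morphometry(rec)
  truth <- neuron_morphometry(rec)
  expect_equal(pred$total_length_um, truth$total_length_um, tolerance = 1e-9)
  expect_equal(pred$n_terminals, truth$n_terminals)
  # single dendrite along -z doubles
  down <- straight_recon(100, axis = c(0, 0, -1), start = 5)
  expect_equal(predict_morphometry(down)$total_length_um, 200,
               tolerance = 1e-9)
  expect_error(predict_morphometry(up), "below z = 0")
})

test_that("mirror prediction tracks true morphometry on intact cells", {
  preset <- species_preset("mouse")
  co <- generate_cohort(preset, 12, seed = 51, spines = FALSE)
  nt <- cohort_neuron_features(co)
  sdl <- stats::sd(nt$total_length_um)
  z <- vapply(co, function(cl)
    (predict_morphometry(cl$recon)$total_length_um -
       neuron_morphometry(cl$recon)$total_length_um) / sdl, numeric(1))
  expect_gte(mean(abs(z) < 2), 0.9)
})

test_that("graft scales diameters for continuity and respects bounds", {
  preset <- species_preset("mouse")
  co <- generate_cohort(preset, 5, seed = 61, spines = FALSE)
  recs <- lapply(co, `[[`, "recon")
  sl <- slice_cut(recs[[1]], slab_thickness = 300, soma_depth = 40)
  pool <- build_donor_pool(recs[-1], preset$cut_z_threshold_um,
                           preset$diam_bounds_um)
  cut_id <- sl$cut_ids[1]
  set.seed(8)
  res <- NULL
  for (k in seq_along(pool$branches)) {
    res <- graft(sl$recon, cut_id, pool$branches[[k]], preset$diam_bounds_um)
    if (!is.null(res)) break
  }
  expect_s3_class(res, "spn_recon")
  scale <- attr(res, "graft_scale")
  # junction continuity: first grafted child of the cut node has the scaled
  # donor diameter, equal to the cut segment's mean diameter at scale time
  segs <- partition_segments(sl$recon)
  ends <- vapply(segs$path, function(p) p[length(p)], integer(1))
  cut_seg <- which(ends == match(cut_id, sl$recon$nodes$id))
  kids <- res$nodes[res$nodes$parent == cut_id &
                      !(res$nodes$id %in% sl$recon$nodes$id), ]
  expect_gt(nrow(kids), 0)
  # grafted terminal diameters inside the species bounds
  graft_ids <- setdiff(res$nodes$id, sl$recon$nodes$id)
  gn <- res$nodes[res$nodes$id %in% graft_ids, ]
  g_term <- gn[!(gn$id %in% res$nodes$parent), ]
  expect_true(all(2 * g_term$r >= preset$diam_bounds_um[1] - 1e-9))
  expect_true(all(2 * g_term$r <= preset$diam_bounds_um[2] + 1e-9))
  # intact nodes untouched
  expect_identical(res$nodes[seq_len(nrow(sl$recon$nodes)), ],
                   sl$recon$nodes)
  # a graft whose scaled tips fall below the lower bound is rejected
  bad <- pool$branches[[1]]
  tips <- !(bad$recon$nodes$id %in% bad$recon$nodes$parent)
  bad$recon$nodes$r[tips] <- 0.05   # 0.1 um tips: far under mouse bounds
  expect_null(graft(sl$recon, cut_id, bad, preset$diam_bounds_um))
})

test_that("repair restores cut cells and is deterministic under a seed", {
  preset <- species_preset("mouse")
  co <- generate_cohort(preset, 8, seed = 71, spines = FALSE)
  recs <- lapply(co, `[[`, "recon")
  nt <- cohort_neuron_features(recs)
  sl <- slice_cut(recs[[1]], slab_thickness = 300, soma_depth = 40)
  pool <- build_donor_pool(recs, preset$cut_z_threshold_um,
                           preset$diam_bounds_um)
  fix1 <- repair_reconstruction(sl$recon, pool, nt, n_candidates = 10,
                                seed = 2)
  fix2 <- repair_reconstruction(sl$recon, pool, nt, n_candidates = 10,
                                seed = 2)
  expect_identical(fix1$graft_log, fix2$graft_log)
  expect_identical(fix1$recon$nodes, fix2$recon$nodes)
  # recovered total length close to the unsliced truth
  t_true <- neuron_morphometry(recs[[1]])$total_length_um
  t_fix <- neuron_morphometry(fix1$recon)$total_length_um
  expect_lt(abs(t_fix - t_true) / t_true, 0.25)
  expect_gt(t_fix, neuron_morphometry(sl$recon)$total_length_um)
  # a reconstruction with an empty cut report is returned unchanged
  empty <- detect_cut_points(recs[[2]], 1e-6)
  empty$cut_node_ids <- integer(0)
  clean <- repair_reconstruction(recs[[2]], pool, nt, n_candidates = 5,
                                 seed = 3, cut_report = empty)
  expect_equal(clean$score, 0)
  expect_identical(clean$recon$nodes, recs[[2]]$nodes)
})

test_that("validate_repair returns zero Z when cohorts coincide", {
  preset <- species_preset("mouse")
  co <- generate_cohort(preset, 5, seed = 81, spines = FALSE)
  recs <- lapply(co, `[[`, "recon")
  bt <- cohort_branch_features(recs)
  v <- validate_repair(recs, bt)
  expect_true(all(abs(v$z) < 1e-9, na.rm = TRUE))
  expect_true(all(c("total_length_um", "n_terminals", "max_order",
                    "mean_terminal_length_um", "terminal_length_fraction")
                  %in% v$feature))
})
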