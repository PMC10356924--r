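test_that("scenes are reproducible and structurally consistent", {
  sp <- scene_spec(n_ftu = 5, image_shape = c(400, 400), seed = 101)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$truth_labels, b$truth_labels)
  expect_identical(a$annotations$annotations[[2]]$ring,
                   b$annotations$annotations[[2]]$ring)
  expect_equal(max(a$truth_labels), 5)
  cats <- vapply(a$annotations$annotations, `[[`, "", "category")
  expect_equal(sum(cats == "glomerulus"), 5)
  expect_equal(sum(cats == "cortex"), 1)
  expect_error(scene_spec(n_ftu = 5, seed = NULL), "seed")
})

test_that("truth label mask equals the rasterized annotations", {
  scn <- small_scene(seed = 55, n_ftu = 6)
  relab <- rasterize_set(scn$annotations)
  expect_identical(relab, scn$truth_labels)
})

test_that("planted glomeruli have in-range equivalent diameters", {
  scn <- generate_scene(scene_spec(n_ftu = 8, image_shape = c(600, 600),
                                   pixel_size_um = 4, seed = 77))
  px <- tabulate(scn$truth_labels[scn$truth_labels > 0],
                 nbins = max(scn$truth_labels))
  deq_um <- 2 * sqrt(px / pi) * 4
  expect_true(all(deq_um >= 100 - 4))   # +-1 px tolerance
  expect_true(all(deq_um <= 350 + 4))
})

test_that("instances never overlap and stay inside the cortex band", {
  scn <- small_scene(seed = 88, n_ftu = 8)
  lab <- scn$truth_labels
  # each label's pixels are a single connected component
  for (k in seq_len(max(lab)))
    expect_equal(max(label_components(lab == k, 8)), 1)
  cortex <- scn$annotations$annotations[[
    which(vapply(scn$annotations$annotations, `[[`, "", "category") ==
            "cortex")]]
  cm <- rasterize(cortex, dim(lab))
  expect_true(all(cm[lab > 0]))
})

test_that("packing failure raises a capacity error", {
  expect_error(generate_scene(scene_spec(n_ftu = 200,
                                         image_shape = c(300, 300),
                                         seed = 5)),
               "reduce n_ftu")
})

test_that("perturbation oracle: drops, additions and identity", {
  scn <- small_scene(seed = 120, n_ftu = 6)
  p0 <- perturb(scn, perturb_spec(seed = 1))
  tab <- match_instances(scn$truth_labels,
                         label_components(p0$prediction, 8))
  expect_true(all(tab$category == "TP"))
  expect_true(all(tab$dice == 1))

  p1 <- perturb(scn, perturb_spec(drop_n = 2, seed = 2))
  cc <- match_counts(match_instances(scn$truth_labels,
                                     label_components(p1$prediction, 8)))
  expect_equal(c(cc$tp, cc$fn, cc$fp), c(4, 2, 0))
  expect_equal(p1$expected$fn, 2)

  p2 <- perturb(scn, perturb_spec(add_n = 3, seed = 3))
  cc <- match_counts(match_instances(scn$truth_labels,
                                     label_components(p2$prediction, 8)))
  expect_equal(c(cc$tp, cc$fn, cc$fp), c(6, 0, 3))
})

test_that("merged pairs are restored by watershed separation", {
  scn <- generate_scene(scene_spec(n_ftu = 6, image_shape = c(500, 500),
                                   diameter_range_um = c(120, 180),
                                   seed = 131))
  pm <- perturb(scn, perturb_spec(merge_pairs = 1, seed = 4))
  n_merged <- max(label_components(pm$prediction, 8))
  expect_equal(n_merged, 5)   # six instances, one bridged pair
  sep <- watershed_separate(pm$prediction, separation_params(30))
  cc <- match_counts(match_instances(scn$truth_labels, sep))
  expect_equal(c(cc$tp, cc$fn, cc$fp), c(6, 0, 0))
})

test_that("small boundary jitter keeps all matches above threshold", {
  scn <- small_scene(seed = 140, n_ftu = 5)
  pj <- perturb(scn, perturb_spec(jitter_px = 2, seed = 6))
  tab <- match_instances(scn$truth_labels,
                         label_components(pj$prediction, 8))
  expect_true(all(tab$category == "TP"))
  expect_true(all(tab$dice >= 0.5 & tab$dice < 1))
})

test_that("cohorts are seeded, donor-consistent and density-accurate", {
  coh <- generate_cohort(n_donors = 2, scenes_per_donor = 2, seed = 900,
                         image_shape = c(512, 512), pixel_size_um = 8)
  expect_length(coh, 4)
  coh2 <- generate_cohort(n_donors = 2, scenes_per_donor = 2, seed = 900,
                          image_shape = c(512, 512), pixel_size_um = 8)
  expect_identical(coh[[3]]$scene$truth_labels,
                   coh2[[3]]$scene$truth_labels)
  # scenes of one donor share metadata
  expect_identical(coh[[1]]$donor$age, coh[[2]]$donor$age)
  expect_identical(coh[[1]]$donor$donor_id, coh[[2]]$donor$donor_id)
  for (e in coh) {
    rec <- ftu_density(e$scene$annotations, donor = as.list(e$donor))
    expect_lt(abs(rec$density_per_mm2 - e$planted_density) /
                e$planted_density, 0.02)
  }
})
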