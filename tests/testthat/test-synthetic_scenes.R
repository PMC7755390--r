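test_that("scenes are deterministic given the spec and seed", {
  sp <- scene_spec(frame_px = 192, n_somata = 2, soma_radius_um = c(3, 0.2),
                   boutons_per_soma = 6, seed = 3)
  s1 <- generate_scene(sp)
  s2 <- generate_scene(sp)
  for (ch in names(s1$images))
    expect_identical(s1$images[[ch]]$pixels, s2$images[[ch]]$pixels)
  expect_identical(s1$truth$boutons, s2$truth$boutons)

  s3 <- generate_scene(scene_spec(frame_px = 192, n_somata = 2,
                                  soma_radius_um = c(3, 0.2),
                                  boutons_per_soma = 6, seed = 4))
  expect_false(identical(s1$images$presyn_marker$pixels,
                         s3$images$presyn_marker$pixels))
})

test_that("an empty spec renders a blank scene with empty truth", {
  sp <- scene_spec(frame_px = 96, n_somata = 0, neuropil_texture = FALSE,
                   noise = FALSE, seed = 1)
  s <- generate_scene(sp)
  expect_equal(length(unique(as.numeric(s$images$surface_reporter$pixels))), 1)
  expect_equal(nrow(s$truth$soma), 0)
  expect_equal(nrow(s$truth$boutons), 0)
  expect_equal(sum(s$truth$soma_labels), 0)
})

test_that("planted geometry clears the detection and apposition minima", {
  sc <- small_scene()
  tr <- sc$truth
  expect_equal(nrow(tr$soma), 3)
  expect_equal(nrow(tr$boutons), 30)
  ## every planted bouton satisfies the contact criterion by construction
  expect_true(all(tr$boutons$structure_overlap_um2 >= 0.04))
  ## every planted punctum clears the strictest class minimum
  expect_true(all(pi * tr$boutons$r_um^2 >= 0.06))
  ## every planted pair clears the pairing criterion
  expect_true(all(tr$pairs$overlap_um2 >= 0.03))
  ## truth masks are consistent with the rendered pre-noise channels
  expect_true(all(sc$images$surface_reporter$pixels[tr$soma_labels > 0] > 60))
})

test_that("ground-truth areas and perimeters match the analytic disk", {
  sp <- scene_spec(frame_px = 256, n_somata = 2, soma_radius_um = c(5, 1e-9),
                   boutons_per_soma = 0, with_pairs = FALSE, noise = FALSE,
                   seed = 9)
  s <- generate_scene(sp)
  expect_equal(s$truth$soma$area_um2, rep(pi * 25, 2), tolerance = 0.05)
  expect_equal(s$truth$soma$perimeter_um, rep(2 * pi * 5, 2), tolerance = 0.05)
})

test_that("near-miss boutons fall below the contact criterion", {
  sp <- scene_spec(frame_px = 256, n_somata = 1, soma_radius_um = c(4, 1e-9),
                   boutons_per_soma = 6, bouton_count_dist = "fixed",
                   bouton_inside_frac = 0.5, near_miss_px = 4,
                   punctum_radius_um = c(0.2, 0.25), with_pairs = FALSE,
                   noise = FALSE, seed = 5)
  s <- generate_scene(sp)
  expect_true(all(s$truth$boutons$structure_overlap_um2 < 0.04))
})

test_that("noise-free pipeline recovers every planted contact and pair", {
  sc <- small_scene()
  somas <- segment_somata(sc$images$surface_reporter, 67, 30)
  expect_equal(nrow(somas$stats), 3)
  pun <- detect_puncta(sc$images$presyn_marker, 110, quant_params(), "GAD65")
  expect_equal(nrow(pun$stats), nrow(sc$truth$boutons))
  ct <- call_contacts(pun, somas)
  expect_equal(nrow(ct), nrow(sc$truth$boutons))
  ## per-structure counts match the planted ones
  planted <- table(sc$truth$boutons$structure)
  ## map segmented structure labels to planted somas by centroid
  seg2true <- vapply(seq_len(3), function(l) {
    i <- which(somas$stats$label == l)
    which.min((sc$truth$soma$centroid_x - somas$stats$centroid_x[i])^2 +
              (sc$truth$soma$centroid_y - somas$stats$centroid_y[i])^2)
  }, integer(1))
  recovered <- table(factor(seg2true[ct$structure], levels = 1:3))
  expect_equal(as.numeric(recovered), as.numeric(planted))

  post <- detect_puncta(sc$images$postsyn_marker, 110, quant_params(), "PSD95")
  prs <- pair_synapses(pun, post)
  expect_equal(nrow(prs), nrow(sc$truth$pairs))
})

test_that("cohorts are deterministic, validated, and carry the planted effect", {
  sp <- scene_spec(seed = 1)
  co <- generate_cohort(sp, c(control = 1, mutant = 0.6), n_animals = 4,
                        n_cells_per_animal = 10, seed = 11)
  expect_equal(nrow(co$measurements), 2 * 4 * 10)
  expect_equal(nrow(co$truth$animals), 8)
  co2 <- generate_cohort(sp, c(control = 1, mutant = 0.6), n_animals = 4,
                         n_cells_per_animal = 10, seed = 11)
  expect_identical(as.data.frame(co$measurements), as.data.frame(co2$measurements))

  ## the planted 40% reduction shows in the group means
  gm <- tapply(co$measurements$value, co$measurements$group_label, mean)
  expect_lt(gm["mutant"] / gm["control"], 0.8)

  expect_error(generate_cohort(sp, c(a = 1), 4, 10), "2 groups")
  expect_error(generate_cohort(sp, c(a = 1, b = -1), 4, 10), "positive")
  expect_error(generate_cohort(sp, c(1, 0.6), 4, 10), "named")

  ## a single animal per group surfaces the downstream precondition
  co1 <- generate_cohort(sp, c(control = 1, mutant = 0.6), n_animals = 1,
                         n_cells_per_animal = 5, seed = 2)
  expect_error(compare_groups(animal_means(co1$measurements)),
               "at least 2 animals")
})

test_that("rendered cohort cells carry exactly the planted bouton counts", {
  sp <- scene_spec(frame_px = 160, soma_radius_um = c(3.5, 0.3),
                   boutons_per_soma = 8, with_pairs = FALSE,
                   neuropil_texture = FALSE, noise = FALSE, seed = 1)
  co <- generate_cohort(sp, c(control = 1, mutant = 0.6), n_animals = 2,
                        n_cells_per_animal = 2, seed = 13, render = TRUE)
  expect_length(co$scenes, 8)
  for (cid in names(co$scenes)) {
    sc <- co$scenes[[cid]]
    expect_equal(nrow(sc$truth$soma), 1)
    ## planted count equals the measurement table's count / perimeter value
    v <- co$measurements$value[co$measurements$cell_id == cid]
    expect_equal(nrow(sc$truth$boutons) / (2 * pi * sc$truth$soma$radius_um),
                 v, tolerance = 1e-5)
  }
})
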