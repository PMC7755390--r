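test_that("overlap area is the exact pixel intersection", {
  a <- matrix(FALSE, 10, 10); a[1:5, 1:5] <- TRUE
  b <- matrix(FALSE, 10, 10); b[6:10, 6:10] <- TRUE
  expect_equal(overlap_area(a, b, pixel_size_um = 0.1), 0)

  ten <- matrix(FALSE, 10, 10); ten[3, 1:10] <- TRUE
  expect_equal(overlap_area(ten, ten, pixel_size_um = 0.1), 0.10)

  c4 <- matrix(FALSE, 10, 10); c4[3, 3:6] <- TRUE
  d4 <- matrix(FALSE, 10, 10); d4[3, 3:8] <- TRUE
  expect_equal(overlap_area(c4, d4, pixel_size_um = 0.1), 0.04)
  expect_equal(overlap_area(c4, d4, pixel_size_um = 0.1),
               overlap_area(d4, c4, pixel_size_um = 0.1))
  expect_error(overlap_area(a, matrix(FALSE, 9, 9)), "geometry")
})

test_that("overlap area matches brute-force enumeration on random masks", {
  set.seed(31)
  for (i in 1:25) {
    a <- rand_mask(24, runif(1, 0.05, 0.5))
    b <- rand_mask(24, runif(1, 0.05, 0.5))
    ps <- sample(c(0.05, 0.1, 0.2), 1)
    expect_identical(overlap_area(a, b, pixel_size_um = ps),
                     brute_overlap(a, b, ps))
  }
})

test_that("contact calls use the inclusive 0.04 um^2 criterion", {
  ## structure: left half-plane; punctum: 8-px bar crossing the boundary
  slab <- matrix(0L, 20, 20); slab[, 1:10] <- 1L
  soma <- structures_from_labels(slab)

  ## exactly 4 px (0.04 um^2) inside -> contact
  plab <- matrix(0L, 20, 20); plab[10, 7:14] <- 1L
  p <- puncta_from_labels(plab)
  ct <- call_contacts(p, soma)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$overlap_area_um2, 0.04)

  ## 3 px inside (0.03 um^2) -> no contact
  plab2 <- matrix(0L, 20, 20); plab2[10, 8:15] <- 1L
  expect_equal(nrow(call_contacts(puncta_from_labels(plab2), soma)), 0)

  ## punctum fully inside -> overlap equals punctum area
  plab3 <- matrix(0L, 20, 20); plab3[4:6, 3:5] <- 1L
  ct3 <- call_contacts(puncta_from_labels(plab3), soma)
  expect_equal(ct3$overlap_area_um2, 9 * 0.01)
})

test_that("each punctum contacts at most one structure, by overlap then label", {
  slab <- matrix(0L, 20, 30)
  slab[, 1:10] <- 1L; slab[, 21:30] <- 2L
  soma <- structures_from_labels(slab)
  ## punctum overlapping structure 1 by 5 px and structure 2 by 6 px
  plab <- matrix(0L, 20, 30); plab[10, 6:26] <- 1L
  plab[10, 11:20] <- 0L               # clear the gap
  plab[10, 6:10] <- 1L; plab[10, 21:26] <- 1L
  ## re-label as a single punctum
  plab[plab > 0] <- 1L
  ct <- call_contacts(puncta_from_labels(plab), soma)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$structure, 2)       # larger overlap wins

  ## equal overlaps -> lower structure label
  plab2 <- matrix(0L, 20, 30); plab2[10, 6:10] <- 1L; plab2[10, 21:25] <- 1L
  ct2 <- call_contacts(puncta_from_labels(plab2), soma)
  expect_equal(ct2$structure, 1)
})

test_that("contained clusters obey the same criterion against the soma", {
  slab <- matrix(0L, 20, 20); slab[5:15, 5:15] <- 1L
  soma <- structures_from_labels(slab)
  ## cluster straddling the boundary with 5 px (0.05 um^2) inside
  plab <- matrix(0L, 20, 20); plab[10, 3:9] <- 1L
  ct <- call_contained_clusters(puncta_from_labels(plab), soma)
  expect_equal(nrow(ct), 1)
  ## entirely outside -> not contained
  plab2 <- matrix(0L, 20, 20); plab2[2:3, 2:3] <- 1L
  expect_equal(nrow(call_contained_clusters(puncta_from_labels(plab2), soma)), 0)
  ## cluster equal to the soma mask -> overlap is the soma area
  ct3 <- call_contained_clusters(puncta_from_labels(slab), soma)
  expect_equal(ct3$overlap_area_um2, sum(slab > 0) * 0.01)
})

test_that("synapse pairing is inclusive at 0.03 um^2 and one-to-one greedy", {
  pre0 <- puncta_from_labels(matrix(0L, 16, 16))
  expect_equal(nrow(pair_synapses(pre0, pre0)), 0)

  ## 3-px overlap at 0.1 um/px = 0.03 um^2 -> one pair
  a <- matrix(0L, 16, 16); a[8, 3:8] <- 1L
  b <- matrix(0L, 16, 16); b[8, 6:11] <- 1L
  pr <- pair_synapses(puncta_from_labels(a), puncta_from_labels(b))
  expect_equal(nrow(pr), 1)
  expect_equal(pr$pair_overlap_um2, 0.03)
  ## one pixel less does not qualify
  b2 <- matrix(0L, 16, 16); b2[8, 7:12] <- 1L
  expect_equal(nrow(pair_synapses(puncta_from_labels(a), puncta_from_labels(b2))), 0)

  ## one pre over two posts (0.05 and 0.04): matched to the larger only
  pre <- matrix(0L, 16, 16); pre[8, 4:12] <- 1L
  post <- matrix(0L, 16, 16); post[8, 4:8] <- 1L; post[8, 9:12] <- 2L
  pr2 <- pair_synapses(puncta_from_labels(pre), puncta_from_labels(post))
  expect_equal(nrow(pr2), 1)
  expect_equal(pr2$post, 1)
  expect_equal(pr2$pair_overlap_um2, 0.05)
})

test_that("no punctum appears in two pairs on random scenes", {
  set.seed(41)
  for (i in 1:10) {
    pre <- label_components(rand_mask(32, 0.25))
    post <- label_components(rand_mask(32, 0.25))
    pr <- pair_synapses(puncta_from_labels(pre), puncta_from_labels(post),
                        min_overlap = 0.02)
    expect_false(anyDuplicated(pr$pre) > 0)
    expect_false(anyDuplicated(pr$post) > 0)
  }
})

test_that("axon-of-origin assignment filters pairs by process overlap", {
  a <- matrix(0L, 16, 16); a[8, 3:8] <- 1L     # pre, 6 px
  b <- matrix(0L, 16, 16); b[8, 6:11] <- 1L    # post
  pre <- puncta_from_labels(a); post <- puncta_from_labels(b)
  pairs <- pair_synapses(pre, post)

  empty <- matrix(FALSE, 16, 16)
  expect_equal(nrow(assign_pairs_to_process(pairs, pre, empty)), 0)

  full <- matrix(TRUE, 16, 16)   # pre fully inside: 0.06 >= 0.025
  kept <- assign_pairs_to_process(pairs, pre, full)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$process_overlap_um2, 0.06)

  ## 2-px overlap (0.02 um^2) -> dropped
  part <- matrix(FALSE, 16, 16); part[8, 3:4] <- TRUE
  expect_equal(nrow(assign_pairs_to_process(pairs, pre, part)), 0)

  ## union and either modes need the post set
  expect_error(assign_pairs_to_process(pairs, pre, full, mode = "union"),
               "post")
  u <- assign_pairs_to_process(pairs, pre, full, mode = "union", post = post)
  expect_equal(u$process_overlap_um2, sum((a > 0) | (b > 0)) * 0.01)
})

test_that("linear density divides counts by perimeter or length", {
  slab <- matrix(0L, 40, 40); slab[disk_mask(40, 20, 20, 10)] <- 1L
  soma <- structures_from_labels(slab)
  no <- linear_density(data.frame(punctum = integer(), structure = integer(),
                                  overlap_area_um2 = numeric()), soma)
  expect_equal(no$count, 0)
  expect_equal(no$density_per_um, 0)

  fake <- data.frame(punctum = 1:5, structure = 1L, overlap_area_um2 = 0.05)
  soma25 <- soma; soma25$stats$perimeter_um <- 25
  d <- linear_density(fake, soma25)
  expect_equal(d$density_per_um, 0.2)
  expect_equal(d$per_10um, 2)

  bad <- soma; bad$stats$perimeter_um <- 0
  expect_error(linear_density(fake, bad), "positive")
})

test_that("contact and pair counts are monotone in the overlap minima", {
  sc <- small_scene()
  somas <- segment_somata(sc$images$surface_reporter, 67, 30)
  pun <- detect_puncta(sc$images$presyn_marker, 110, quant_params(), "GAD65")
  post <- detect_puncta(sc$images$postsyn_marker, 110, quant_params(), "PSD95")
  n_ct <- vapply(c(0.01, 0.04, 0.08, 0.15),
                 function(m) nrow(call_contacts(pun, somas, m)), numeric(1))
  expect_false(is.unsorted(rev(n_ct)))
  n_pr <- vapply(c(0.01, 0.03, 0.06, 0.12),
                 function(m) nrow(pair_synapses(pun, post, m)), numeric(1))
  expect_false(is.unsorted(rev(n_pr)))
})
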