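test_that("gray-matter binarization uses an inclusive threshold", {
  vals <- array(0, dim = c(3, 3, 3))
  vals[1, 1, 1] <- 0.3
  vals[2, 1, 1] <- 0.29
  vals[3, 1, 1] <- 1
  mask <- binarize_gm(voxel_image(vals))
  expect_true(mask[1, 1, 1])
  expect_false(mask[2, 1, 1])
  expect_true(mask[3, 1, 1])

  bad <- voxel_image(array(1.5, dim = c(2, 2, 2)))
  expect_error(binarize_gm(bad), "\\[0, 1\\]")
})

test_that("an all-zero gray-matter map leaves no nodes", {
  labels <- make_two_region_labels()
  empty <- binarize_gm(voxel_image(array(0, dim = c(20, 20, 20))))
  ns <- select_nodes(labels, empty)
  expect_equal(sum(ns$nodes$included), 0)
  expect_true(all(ns$nodes$exclusion_reason == "gm_coverage"))
})

test_that("region centers sit at the voxel nearest the center of mass", {
  arr <- array(0L, dim = c(20, 20, 20))
  arr[11, 11, 11] <- 1L                    # single voxel at 0-based (10,10,10)
  expect_equal(region_center(label_image(arr), 1), c(10L, 10L, 10L))

  arr2 <- array(0L, dim = c(20, 20, 20))
  arr2[1:5, 1:5, 1:5] <- 2L                # 5^3 block, 0-based corner (0,0,0)
  expect_equal(region_center(label_image(arr2), 2), c(2L, 2L, 2L))

  expect_error(region_center(label_image(arr2), 9), "9")
})

test_that("L-shaped region center matches a brute-force enumeration", {
  arr <- array(0L, dim = c(20, 20, 20))
  arr[1:9, 1:3, 1:3] <- 1L
  arr[1:3, 4:9, 1:3] <- 1L                # an L in the x-y plane
  got <- region_center(label_image(arr), 1)

  vox <- which(arr == 1L, arr.ind = TRUE) - 1
  com <- colMeans(vox)
  cand <- as.matrix(expand.grid(0:19, 0:19, 0:19))
  d2 <- colSums((t(cand) - com)^2)
  keep <- which(d2 == min(d2))
  keep <- keep[order(cand[keep, 1], cand[keep, 2], cand[keep, 3])]
  expect_equal(got, unname(cand[keep[1], ]))
})

test_that("cube_voxels enumerates the centered block and flags bounds", {
  cube <- cube_voxels(c(5, 5, 5), 3, shape = c(20, 20, 20))
  expect_equal(nrow(cube), 27)
  expect_true(all(cube >= 4 & cube <= 6))
  expect_equal(unique(apply(cube, 1, paste, collapse = ",")) |> length(), 27)
  expect_false(any(attr(cube, "out_of_bounds")))

  single <- cube_voxels(c(7, 8, 9), 1)
  expect_equal(unname(single[1, ]), c(7L, 8L, 9L))
  expect_equal(nrow(single), 1)

  edge_cube <- cube_voxels(c(0, 5, 5), 3, shape = c(20, 20, 20))
  expect_true(any(attr(edge_cube, "out_of_bounds")))

  expect_error(cube_voxels(c(5, 5, 5), 4), "odd")
})

test_that("well-separated regions with full gray matter are all included", {
  labels <- make_two_region_labels()
  ns <- select_nodes(labels, full_gm())
  expect_true(all(ns$nodes$included))
  expect_true(all(ns$nodes$exclusion_reason == "none"))
})

test_that("overlapping cubes exclude both regions involved", {
  # centers 2 voxels apart: the two 3x3x3 cubes share a plane of voxels
  labels <- make_two_region_labels(centers = list(c(8, 8, 8), c(10, 8, 8)),
                                   half = 0L)
  ns <- select_nodes(labels, full_gm())
  expect_equal(sum(ns$nodes$included), 0)
  expect_true(all(ns$nodes$exclusion_reason == "overlap"))
})

test_that("a single sub-threshold gray-matter voxel excludes the node", {
  labels <- make_two_region_labels()
  gm <- voxel_image(array(1, dim = c(20, 20, 20)))
  gm$values[6, 6, 6] <- 0.2                # inside region 1's cube
  ns <- select_nodes(labels, gm)
  df <- as.data.frame(ns)
  expect_false(df$included[df$region_id == 1])
  expect_equal(df$exclusion_reason[df$region_id == 1], "gm_coverage")
  expect_true(df$included[df$region_id == 2])
})

test_that("selection is invariant to region relabeling", {
  base <- make_two_region_labels(
    centers = list(c(5, 5, 5), c(7, 5, 5), c(14, 14, 14)),
    half = 0L, ids = c(1L, 2L, 3L))
  swapped <- make_two_region_labels(
    centers = list(c(5, 5, 5), c(7, 5, 5), c(14, 14, 14)),
    half = 0L, ids = c(3L, 1L, 2L))
  ns1 <- as.data.frame(select_nodes(base, full_gm()))
  ns2 <- as.data.frame(select_nodes(swapped, full_gm()))
  # match by geometry: same center must get the same decision
  key1 <- paste(ns1$center_x, ns1$center_y, ns1$center_z)
  key2 <- paste(ns2$center_x, ns2$center_y, ns2$center_z)
  m <- match(key1, key2)
  expect_false(any(is.na(m)))
  expect_equal(ns1$included, ns2$included[m])
  expect_equal(ns1$exclusion_reason, ns2$exclusion_reason[m])
})

test_that("included cubes are pairwise disjoint on a crowded phantom", {
  set.seed(3)
  arr <- array(0L, dim = c(24, 24, 24))
  centers <- as.matrix(expand.grid(c(4, 8, 12, 16), c(6, 10), c(6, 12)))
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    arr[ctr[1]:(ctr[1] + 2), ctr[2]:(ctr[2] + 2), ctr[3]:(ctr[3] + 2)] <- i
  }
  ns <- select_nodes(label_image(arr), full_gm(c(24, 24, 24)))
  inc <- included_ids(ns)
  lin <- unlist(lapply(as.character(inc), function(id) {
    cube <- ns$cubes[[id]]
    cube[, 1] + 24 * (cube[, 2] + 24 * cube[, 3])
  }))
  expect_equal(anyDuplicated(lin), 0)
})

test_that("an explicit include list overrides rule-based selection", {
  labels <- make_two_region_labels()
  ns <- select_nodes(labels, full_gm(), node_config(include_list = 2L))
  df <- as.data.frame(ns)
  expect_equal(included_ids(ns), 2L)
  expect_equal(df$exclusion_reason, c("none", "none"))
})

test_that("profile extraction averages the 27 cube voxels", {
  labels <- make_two_region_labels()
  ns <- select_nodes(labels, full_gm())
  vals <- array(1, dim = c(20, 20, 20))
  vals[6, 6, 6] <- 2.35                    # one voxel of region 1's cube
  prof <- extract_profile(voxel_image(vals, suvr = TRUE), ns, "demo")
  expect_equal(prof$values[1], (26 * 1 + 2.35) / 27)
  expect_equal(prof$values[2], 1)
  expect_equal(prof$subject_id, "demo")

  vals[6, 6, 6] <- NaN
  expect_error(extract_profile(voxel_image(vals), ns), "node 1")
})

test_that("noise-free rendering recovers planted node values exactly", {
  atlas <- make_phantom_atlas(grid = c(40, 40, 40), k = 8, seed = 2)
  cohort <- simulate_profiles(
    atlas, sim_config(noise_sd = 0, baseline_sd = 0, seed = 4),
    severities = c(0.2, 0.9))
  profs <- cohort_profiles(cohort)
  ns <- select_nodes(atlas$labels, binarize_gm(atlas$gm_prob))
  for (p in profs) {
    img <- render_image(p, atlas, voxel_noise_sd = 0)
    got <- extract_profile(img, ns, p$subject_id)
    expect_equal(got$values, p$values)
  }
})

test_that("a non-2-mm grid triggers a warning but not an error", {
  labels <- make_two_region_labels()
  labels$grid_spacing <- c(1.5, 1.5, 1.5)
  expect_warning(select_nodes(labels, full_gm()), "2 mm")
})
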