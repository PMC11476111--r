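test_that("generate_dataset is seed-deterministic and respects the catalog", {
  cat3 <- tiny_catalog()
  a <- generate_dataset(cat3, 10, scene_spec(), seed = 1)
  b <- generate_dataset(cat3, 10, scene_spec(), seed = 1)
  expect_length(a, 10)
  expect_identical(lapply(a, `[[`, "image"), lapply(b, `[[`, "image"))
  expect_identical(lapply(a, `[[`, "boxes"), lapply(b, `[[`, "boxes"))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  labs <- unlist(lapply(a, `[[`, "labels"))
  expect_true(all(labs %in% c(0L, 1L, 2L)))
  c_ <- generate_dataset(cat3, 10, scene_spec(), seed = 2)
  expect_false(identical(a[[1]]$image, c_[[1]]$image))
})

test_that("every box lies inside the image and annotations are consistent", {
  for (sc in tiny_scenes()) {
    expect_equal(nrow(sc$boxes), length(sc$labels))
    expect_equal(length(sc$labels), length(sc$occluded))
    if (nrow(sc$boxes) > 0) {
      expect_true(all(sc$boxes[, 1] >= 0 & sc$boxes[, 2] >= 0))
      expect_true(all(sc$boxes[, 3] <= ncol(sc$image)))
      expect_true(all(sc$boxes[, 4] <= nrow(sc$image)))
      expect_true(all(sc$boxes[, 3] > sc$boxes[, 1]))
      expect_true(all(sc$boxes[, 4] > sc$boxes[, 2]))
    }
  }
})

test_that("empty-shot scenes have zero boxes", {
  empties <- generate_dataset(tiny_catalog(), 5, scene_spec(n_targets = 0),
                              seed = 3)
  expect_true(all(vapply(empties, function(s) nrow(s$boxes) == 0, logical(1))))
})

test_that("occluded targets overlap another target's box", {
  scenes <- generate_dataset(tiny_catalog(), 50,
                             scene_spec(n_targets = 3, occlusion_prob = 0.5),
                             seed = 5)
  for (sc in scenes) {
    for (i in which(sc$occluded)) {
      others <- setdiff(seq_len(nrow(sc$boxes)), i)
      ious <- vapply(others, function(j) {
        wildetect:::box_iou_pair(sc$boxes[i, ], sc$boxes[j, ])
      }, numeric(1))
      expect_gt(max(ious), 0)
    }
  }
})

test_that("occlusion flags follow the configured rate", {
  # 200 scenes x 3 targets at p = 0.5; observed fraction must fall inside
  # the exact binomial 99% interval for n = 600 draws
  scenes <- generate_dataset(tiny_catalog(), 200,
                             scene_spec(n_targets = 3, occlusion_prob = 0.5),
                             seed = 7)
  flags <- unlist(lapply(scenes, `[[`, "occluded"))
  n <- length(flags)
  ci <- qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(mean(flags), ci[1])
  expect_lte(mean(flags), ci[2])
})

test_that("split_dataset partitions with floor sizes and train remainder", {
  scenes <- as.list(seq_len(100))
  sp <- split_dataset(scenes, c(0.7, 0.15, 0.15), seed = 0)
  expect_equal(lengths(sp), c(train = 70, val = 15, test = 15))

  sp1 <- split_dataset(as.list(1), c(0.7, 0.15, 0.15), seed = 0)
  expect_equal(lengths(sp1), c(train = 1, val = 0, test = 0))

  sp2 <- split_dataset(as.list(1:10), c(0.5, 0.5, 0), seed = 3)
  expect_equal(lengths(sp2), c(train = 5, val = 5, test = 0))
  expect_setequal(unlist(sp2), 1:10)
  expect_length(intersect(unlist(sp2$train), unlist(sp2$val)), 0)

  expect_error(split_dataset(scenes, c(0.5, 0.4, 0.2)), "sum to 1")
  expect_identical(split_dataset(scenes, seed = 9), split_dataset(scenes, seed = 9))
})

test_that("invalid generator inputs are rejected", {
  expect_error(generate_dataset(list(), 5), "at least one species")
  expect_error(scene_spec(occlusion_prob = 1.2), "occlusion_prob")
  expect_error(scene_spec(lighting = 0), "lighting")
  expect_error(species_archetype(0, "x", "blob", c(0, 0, 0),
                                 size_range = c(2, 10)), ">= 4 px")
  expect_error(species_archetype(-1, "x", "blob", c(0, 0, 0)), "integer >= 0")
})
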