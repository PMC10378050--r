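test_that("label CSV reading validates grades and identifiers", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id_code,diagnosis", "a,0", "b,2", "c,4"), f)
  tab <- read_label_csv(f)
  expect_s3_class(tab, "am_label_table")
  expect_equal(tab$grade, c(0L, 2L, 4L))
  writeLines(c("id_code,diagnosis", "a,0", "b,7"), f)
  expect_error(read_label_csv(f), "row 2")
  writeLines(c("id_code,diagnosis", "a,0", "a,1"), f)
  expect_error(read_label_csv(f), "duplicate")
  writeLines(c("id,label", "a,0"), f)
  expect_error(read_label_csv(f), "missing column")
})

test_that("a written label table reads back identically", {
  tab <- data.frame(id = sprintf("img%02d", 1:8),
                    grade = c(0L, 0L, 1L, 2L, 3L, 4L, 2L, 0L))
  f <- tempfile(fileext = ".csv")
  write_label_csv(tab, f)
  back <- read_label_csv(f)
  expect_equal(back$id, tab$id)
  expect_equal(back$grade, tab$grade)
})

test_that("binary mapping collapses grades 1-4 to the DR class", {
  tab <- data.frame(id = letters[1:5], grade = 0:4)
  expect_equal(map_binary(tab)$grade, c(0L, 1L, 1L, 1L, 1L))
  tab0 <- data.frame(id = letters[1:3], grade = c(0L, 0L, 0L))
  expect_equal(map_binary(tab0)$grade, rep(0L, 3))
})

test_that("split counts reproduce the five-grade reference partition", {
  # class sizes of the five severity grades and the published per-part
  # counts of the 70/15/15 stratified split they induce
  sizes <- c(1805L, 370L, 999L, 193L, 295L)
  expected <- rbind(c(1263L, 271L, 271L),
                    c(259L, 56L, 55L),
                    c(699L, 150L, 150L),
                    c(135L, 29L, 29L),
                    c(207L, 44L, 44L))
  spec <- split_spec()
  for (k in 1:5) {
    expect_equal(unname(amcontrast:::split_counts_for_size(sizes[k], spec)),
                 expected[k, ])
  }
  # full splitter on a synthetic table of those sizes
  tab <- data.frame(id = as.character(seq_len(sum(sizes))),
                    grade = rep(0:4, times = sizes))
  sp <- stratified_split(tab, spec)
  expect_equal(unname(sp$counts), expected)
  # binary strata: the DR class pools grades 1-4
  spb <- stratified_split(tab, split_spec(seed = 1, task = "binary"))
  expect_equal(unname(spb$counts["1", ]),
               unname(amcontrast:::split_counts_for_size(sum(sizes[2:5]), spec)))
})

test_that("splits conserve counts, are seed-deterministic and partition rows", {
  set.seed(14)
  for (rep in 1:5) {
    sizes <- sample(3:40, 4)
    tab <- data.frame(id = as.character(seq_len(sum(sizes))),
                      grade = rep(c(0L, 1L, 2L, 4L), times = sizes))
    s1 <- stratified_split(tab, split_spec(seed = 5))
    expect_equal(unname(rowSums(s1$counts)), sizes)
    expect_equal(sum(s1$counts), nrow(tab))
    expect_false(anyNA(s1$assignment$split))
    expect_equal(sort(s1$assignment$id), sort(tab$id))
    # same seed: identical membership; different seed: identical counts
    s2 <- stratified_split(tab, split_spec(seed = 5))
    expect_identical(s1$assignment, s2$assignment)
    s3 <- stratified_split(tab, split_spec(seed = 6))
    expect_equal(s3$counts, s1$counts)
  }
  # degenerate class goes entirely to training with a warning
  tiny <- data.frame(id = c("a", "b", "c"), grade = c(0L, 0L, 1L))
  expect_warning(s <- stratified_split(tiny, split_spec(seed = 1)), "fewer than 2")
  expect_equal(unname(s$counts["1", ]), c(1L, 0L, 0L))
})

test_that("split manifest and part extraction are consistent", {
  tab <- synth_table()
  sp <- stratified_split(tab, split_spec(seed = 3))
  f <- tempfile(fileext = ".csv")
  write_split_manifest(sp, f)
  man <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(nrow(man), nrow(tab))
  tr <- split_part(tab, sp, "train")
  va <- split_part(tab, sp, "val")
  te <- split_part(tab, sp, "test")
  expect_equal(nrow(tr) + nrow(va) + nrow(te), nrow(tab))
  expect_length(intersect(tr$id, te$id), 0)
})

test_that("augmentation policies validate operators and parameters", {
  expect_error(augmentation_policy(list(op = "solarize")), "unknown")
  expect_error(augmentation_policy(list(op = "horizontal_flip", p = 1.4)),
               "probability")
  expect_error(augmentation_policy(list(op = "random_resized_crop",
                                        scale = c(0, 1.2))), "scale")
  pol <- default_augmentation_policy()
  expect_s3_class(pol, "am_aug_policy")
  expect_equal(vapply(pol, `[[`, "", "op"),
               c("random_resized_crop", "horizontal_flip", "vertical_flip"))
})

test_that("augmentation is deterministic and respects the identity policy", {
  img <- generate_fundus_like(2, synthetic_image_config(size = 48L), seed = 5)
  # empty policy resizes only
  plain <- apply_augmentation(img, augmentation_policy(), 32, seed = 1)
  expect_equal(dim(plain), c(32L, 32L, 3L))
  expect_equal(plain, amcontrast:::resize_image(img, 32))
  # deterministic repeat, bit-identical
  pol <- default_augmentation_policy()
  a <- apply_augmentation(img, pol, 32, seed = 9)
  b <- apply_augmentation(img, pol, 32, seed = 9)
  expect_identical(a, b)
  # horizontal flip at probability 1 is an involution
  flip <- augmentation_policy(list(op = "horizontal_flip", p = 1))
  once <- apply_augmentation(img, flip, 48, seed = 1)
  twice <- apply_augmentation(once, flip, 48, seed = 2)
  expect_equal(twice, apply_augmentation(img, augmentation_policy(), 48, seed = 1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("double-view batches pair sibling views with shared labels", {
  tab <- synth_table()
  rows <- tab[seq(1, 100, by = 13), ]
  batch <- make_double_view_batch(rows, size = 32L, seed = 4)
  n <- nrow(rows)
  expect_equal(dim(batch$images), c(32L, 32L, 3L, 2L * n))
  j <- batch$pairing
  expect_true(all(j[j] == seq_len(2 * n)) && all(j != seq_len(2 * n)))
  expect_equal(batch$labels[j], batch$labels)
  expect_equal(batch$labels[1:n], rows$grade)
  # binary task labels
  bb <- make_double_view_batch(rows, size = 32L, seed = 4, task = "binary")
  expect_true(all(bb$labels %in% 0:1))
  # determinism
  again <- make_double_view_batch(rows, size = 32L, seed = 4)
  expect_identical(batch$images, again$images)
  expect_error(make_double_view_batch(rows[1, , drop = FALSE]), "at least 2")
})
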