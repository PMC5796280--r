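# Shape descriptors (equivalent ellipse, min-area rectangle) and template
# derivation/rasterization.

disc_mask <- function(radius) {
  n <- 2 * radius + 1
  rr <- outer(seq_len(n) - radius - 1, rep(1, n))
  matrix(as.integer(rr^2 + t(rr)^2 <= radius^2), n)
}

test_that("equivalent ellipse recovers known shapes", {
  e <- equivalent_ellipse(disc_mask(20))
  expect_equal(e$major_axis, 40, tolerance = 1 / 40)
  expect_equal(e$minor_axis, 40, tolerance = 1 / 40)

  tpl <- render_template("ellipse", 158, 83)
  e2 <- equivalent_ellipse(tpl$mask)
  expect_lt(abs(e2$major_axis - 158), 2)
  expect_lt(abs(e2$minor_axis - 83), 2)
  expect_gte(e2$major_axis, e2$minor_axis)
})

test_that("both descriptors are rotation- and translation-invariant to within 2 px", {
  tpl <- render_template("ellipse", 101, 47)
  base_e <- equivalent_ellipse(tpl$mask)
  rect <- matrix(1L, 43, 33)
  base_r <- min_area_bounding_rectangle(rect)
  for (a in c(30, 45, 77, 120, 200)) {
    re <- equivalent_ellipse(rotate_mask(tpl$mask, a))
    expect_lt(abs(re$major_axis - base_e$major_axis), 2)
    expect_lt(abs(re$minor_axis - base_e$minor_axis), 2)
    rr <- min_area_bounding_rectangle(rotate_mask(rect, a))
    expect_lt(abs(rr$long_side - base_r$long_side), 2)
    expect_lt(abs(rr$short_side - base_r$short_side), 2)
  }
  # translation: embed at an offset
  big <- matrix(0L, 300, 300)
  big[100 + seq_len(nrow(tpl$mask)), 37 + seq_len(ncol(tpl$mask))] <- tpl$mask
  te <- equivalent_ellipse(big)
  expect_equal(te$major_axis, base_e$major_axis)
  expect_equal(te$minor_axis, base_e$minor_axis)
})

test_that("min-area rectangle matches exact and oracle answers", {
  r <- min_area_bounding_rectangle(matrix(1L, 43, 33))
  expect_equal(r$long_side, 43)
  expect_equal(r$short_side, 33)

  r30 <- min_area_bounding_rectangle(rotate_mask(matrix(1L, 43, 33), 30))
  expect_lt(abs(r30$long_side - 43), 1.01)
  expect_lt(abs(r30$short_side - 33), 1.01)

  # L-shaped particle vs dense orientation scan
  L <- matrix(0L, 30, 30); L[, 1:8] <- 1L; L[23:30, ] <- 1L
  impl <- min_area_bounding_rectangle(L)
  xy <- cbind(row = as.numeric(which(L == 1) - 1) %% 30,
              col = (which(L == 1) - 1) %/% 30)
  orc <- oracle_min_rect(xy)
  expect_equal(impl$long_side * impl$short_side, orc$area, tolerance = 1e-6)

  set.seed(31)
  for (k in 1:10) {
    blob <- matrix(as.integer(rbinom(100, 1, 0.4)), 10)
    if (sum(blob) < 2) next
    impl <- min_area_bounding_rectangle(blob)
    xy <- cbind(row = (which(blob == 1) - 1) %% 10,
                col = (which(blob == 1) - 1) %/% 10)
    orc <- oracle_min_rect(xy)
    expect_lte(impl$long_side * impl$short_side, orc$area + 1e-6)
  }
  expect_error(min_area_bounding_rectangle(matrix(c(1L), 1, 1)),
               class = "thermonest_input_error")
})

test_that("min-area rectangle never exceeds the axis-aligned bounding box", {
  set.seed(13)
  for (k in 1:20) {
    blob <- matrix(as.integer(rbinom(15 * 12, 1, 0.3)), 15)
    if (sum(blob) < 2) next
    xy <- which(blob == 1, arr.ind = TRUE)
    aabb <- prod(apply(xy, 2, function(v) diff(range(v)) + 1))
    r <- min_area_bounding_rectangle(blob)
    expect_lte(r$long_side * r$short_side, aabb + 1e-9)
  }
})

test_that("rendered templates have the analytic area and tight boxes", {
  tri <- render_template("triangle", 43, 33)
  expect_identical(dim(tri$mask), c(43L, 33L))
  expect_lt(abs(sum(tri$mask) - 43 * 33 / 2), 0.05 * 43 * 33 / 2)
  expect_true(all(rowSums(tri$mask) >= 1))
  expect_identical(sum(tri$mask[1, ]), 1L)         # apex
  expect_identical(sum(tri$mask[43, ]), 33L)       # full base row

  ell <- render_template("ellipse", 158, 83)
  expect_identical(dim(ell$mask), c(158L, 83L))
  expect_lt(abs(sum(ell$mask) - pi * 79 * 41.5), 0.05 * pi * 79 * 41.5)
  expect_true(all(c(rowSums(ell$mask)[c(1, 158)], colSums(ell$mask)[c(1, 83)]) >= 1))

  tiny <- render_template("triangle", 3, 3)
  expect_identical(dim(tiny$mask), c(3L, 3L))
  expect_true(all(rowSums(tiny$mask) >= 1))

  expect_error(render_template("triangle", 2, 5), class = "thermonest_input_error")
})

test_that("derive_template averages per-image descriptors (render/measure fixed point)", {
  # identical rendered blobs: template dims equal the blob's own dims
  tri <- render_template("triangle", 43, 33)
  big <- matrix(0L, 120, 120)
  big[30 + seq_len(43), 40 + seq_len(33)] <- tri$mask
  tpl <- derive_template(list(big, big, big), shift = 5)
  expect_identical(tpl$shape_kind, "triangle")
  expect_lte(abs(tpl$height - 43), 2)
  expect_lte(abs(tpl$base - 33), 2)

  ell <- render_template("ellipse", 158, 83)
  big2 <- matrix(0L, 300, 300)
  big2[50 + seq_len(158), 60 + seq_len(83)] <- ell$mask
  tpl2 <- derive_template(list(big2, big2), shift = 1)
  expect_identical(tpl2$shape_kind, "ellipse")
  expect_lte(abs(tpl2$height - 158), 2)
  expect_lte(abs(tpl2$base - 83), 2)

  # the largest particle is used: add a small distractor
  big[2:4, 2:4] <- 1L
  tpl3 <- derive_template(list(big), shift = 5)
  expect_lte(abs(tpl3$height - 43), 2)

  expect_error(derive_template(list(), 5), class = "thermonest_input_error")
})

test_that("render/measure is a fixed point within 2 px", {
  for (dims in list(c(43, 33), c(61, 41), c(158, 83))) {
    tri <- render_template("triangle", dims[1], dims[2])
    r <- min_area_bounding_rectangle(tri$mask)
    expect_lt(abs(r$long_side - dims[1]), 2)
    expect_lt(abs(r$short_side - dims[2]), 2)
    ell <- render_template("ellipse", dims[1], dims[2])
    e <- equivalent_ellipse(ell$mask)
    expect_lt(abs(e$major_axis - dims[1]), 2)
    expect_lt(abs(e$minor_axis - dims[2]), 2)
  }
})
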