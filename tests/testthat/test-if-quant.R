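# rasterized disk helper shared by the shape tests
.diskImage <- function(radius, value = 200, pad = 10) {
  n <- 2 * radius + 2 * pad + 1
  ctr <- radius + pad
  ii <- row(matrix(0, n, n)) - 1; jj <- col(matrix(0, n, n)) - 1
  m <- matrix(0, n, n)
  m[(ii - ctr)^2 + (jj - ctr)^2 <= radius^2] <- value
  m
}

test_that("preprocessing thresholds and rescales as a pixel-wise linear map", {
  img <- matrix(c(0, 49, 50, 150, 250, 300), 2, 3)
  out <- preprocessChannel(img, lower = 50, upper = 250)
  expect_equal(out[1, 1], 0)          # below lower -> 0
  expect_equal(out[2, 1], 0)
  expect_equal(out[1, 2], 0)          # lower maps to 0
  expect_equal(out[2, 2], round((150 - 50) * 255 / 200))  # midpoint
  expect_equal(out[1, 3], 255)        # upper maps to 255
  expect_equal(out[2, 3], 255)        # clipped
  # pure rescale preserves order
  img2 <- matrix(0:99, 10, 10)
  out2 <- preprocessChannel(img2, 0, 99)
  expect_true(all(diff(out2[order(img2)]) >= 0))
  expect_equal(max(out2), 255)
  # uniform image just below lower -> all zero
  expect_true(all(preprocessChannel(matrix(49, 3, 3), 50, 250) == 0))
  expect_error(preprocessChannel(img, 250, 50), "lower < upper")
})

test_that("particle analysis retains disks and rejects specks and bars", {
  disk <- .diskImage(10)
  cells <- detectCells(disk, 100)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$area_px, 317)
  expect_gt(cells$circularity, 0.85)
  expect_lte(cells$circularity, 1.1)
  expect_equal(cells$centroid_row, 20)   # symmetric disk, exact center
  expect_equal(cells$centroid_col, 20)

  # isolated pixel: area 1 <= 50, removed
  px <- matrix(0, 20, 20); px[10, 10] <- 200
  expect_equal(nrow(detectCells(px, 100)), 0L)

  # 3 x 60 bar: area 180 > 50 but circularity far below 0.3
  bar <- matrix(0, 30, 80); bar[14:16, 11:70] <- 200
  expect_equal(nrow(detectCells(bar, 100)), 0L)
  barKept <- detectCells(bar, 100, minCircularity = 0.1)
  expect_equal(nrow(barKept), 1L)
  expect_lt(barKept$circularity, 0.3)
})

test_that("area and circularity filters are strict inequalities", {
  sq <- matrix(0, 20, 20)
  sq[6:12, 6:12] <- 200            # 7x7 square: area 49
  expect_equal(nrow(detectCells(sq, 100, minArea = 48)), 1L)
  expect_equal(nrow(detectCells(sq, 100, minArea = 49)), 0L)
})

test_that("diagonal-touching components are a single 8-connected particle", {
  m <- matrix(0, 40, 40)
  m[5:15, 5:15] <- 200
  m[16:26, 16:26] <- 200   # touches the first square only at a corner
  cells <- detectCells(m, 100, minCircularity = 0)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$area_px, 2 * 121L)
})

test_that("disk circularity approaches 1 as the radius grows", {
  circ <- vapply(c(6, 12, 25, 50), function(r) {
    detectCells(.diskImage(r), 100)$circularity
  }, numeric(1))
  expect_true(all(circ > 0.85 & circ <= 1.1))
  expect_lt(abs(circ[4] - 1), 0.05)
  expect_lte(abs(circ[4] - 1), abs(circ[1] - 1))
})

test_that("elongating a rectangle strictly decreases circularity", {
  circOf <- function(w, h) {
    m <- matrix(0, h + 20, w + 20)
    m[11:(10 + h), 11:(10 + w)] <- 200
    detectCells(m, 100, minArea = 0, minCircularity = 0)$circularity
  }
  c1 <- circOf(12, 12); c2 <- circOf(24, 12); c3 <- circOf(48, 12)
  expect_gt(c1, c2)
  expect_gt(c2, c3)
})

test_that("detection is exactly translation-equivariant", {
  base <- .diskImage(8, pad = 15)
  shifted <- matrix(0, nrow(base), ncol(base))
  shifted[6:nrow(base), 4:ncol(base)] <-
    base[1:(nrow(base) - 5), 1:(ncol(base) - 3)]
  a <- detectCells(base, 100)
  b <- detectCells(shifted, 100)
  expect_equal(b$centroid_row, a$centroid_row + 5)
  expect_equal(b$centroid_col, a$centroid_col + 3)
  expect_equal(b$area_px, a$area_px)
  expect_equal(b$circularity, a$circularity)
})

test_that("crown and circle means match explicit pixel enumeration", {
  n <- 61; ctr <- c(30, 30); D <- 16
  uni <- matrix(7.5, n, n)
  expect_equal(as.numeric(crownLigandMean(uni, ctr, D)), 7.5)
  # signal strictly inside the inner circle never leaks into the crown
  inner <- matrix(0, n, n)
  ii <- row(inner) - 1; jj <- col(inner) - 1
  d <- sqrt((ii - 30)^2 + (jj - 30)^2)
  inner[d <= D / 2] <- 100
  expect_equal(as.numeric(crownLigandMean(inner, ctr, D)), 0)
  # half-plane: compare against direct enumeration over all pixels
  half <- matrix(0, n, n); half[, 31:n] <- 12    # columns >= 30 (0-based)
  sel <- d > D / 2 & d <= D
  expect_equal(as.numeric(crownLigandMean(half, ctr, D)),
               mean(half[sel]))
  expect_equal(as.numeric(innerCircleMean(half, ctr, D)),
               mean(half[d <= D / 2]))
})

test_that("off-image crowns error; partial crowns are flagged truncated", {
  img <- matrix(1, 40, 40)
  expect_error(crownLigandMean(img, c(200, 200), 16), "outside")
  v <- crownLigandMean(img, c(2, 20), 16)
  expect_true(attr(v, "truncated"))
  expect_equal(as.numeric(v), 1)
  v2 <- crownLigandMean(img, c(20, 20), 16)
  expect_false(attr(v2, "truncated"))
})

test_that("ifLR-score is the normalized geometric mean with hard bounds", {
  expect_equal(iflrScore(100, 64), 80 / 255)
  expect_equal(iflrScore(255, 255), 1)
  expect_equal(iflrScore(180, 0), 0)
  expect_error(iflrScore(-1, 10), "non-negative")
  expect_error(iflrScore(10, 300), "8-bit")
  # regularized alternative stays in [0, 1) and is monotone
  expect_lt(iflrScore(255, 255, method = "regularized"), 1)
})

test_that("positivity calls and the percentage handle edge cases", {
  cells <- data.frame(iflr_score = c(0.9, 0.2, 0.5, 0.3))
  out <- callPositives(cells, 0.3)
  expect_equal(out$cells$positive, c(TRUE, FALSE, TRUE, TRUE))  # inclusive
  expect_equal(out$percent_positive, 75)
  expect_equal(callPositives(cells, 0)$percent_positive, 100)
  expect_equal(callPositives(cells, 1)$percent_positive, 0)
  expect_true(is.na(callPositives(cells[0, , drop = FALSE],
                                  0.5)$percent_positive))
  # permutation-invariant
  expect_equal(callPositives(cells[4:1, , drop = FALSE],
                             0.3)$percent_positive, 75)
})

test_that("DSR grading uses left-closed bins anchored by the printed cutoffs", {
  expect_equal(dsrGrade(c(0, 4, 4.99)), c(0, 0, 0))
  expect_equal(dsrGrade(c(5, 10, 14.9)), c(1, 1, 1))
  expect_equal(dsrGrade(c(15, 40, 49.9)), c(2, 2, 2))
  expect_equal(dsrGrade(c(50, 60, 100)), c(3, 3, 3))
  expect_error(dsrGrade(101), "\\[0, 100\\]")
})

test_that("M2/M ratio flags high strictly above 0.5 and guards division", {
  r <- m2mRatio(0.4, 0.5)
  expect_equal(r$ratio, 0.8)
  expect_true(r$high)
  r2 <- m2mRatio(0.2, 0.5)
  expect_equal(r2$ratio, 0.4)
  expect_false(r2$high)
  expect_false(m2mRatio(0.25, 0.5)$high)   # exactly 0.5 is not high
  expect_true(is.na(m2mRatio(0.3, 0)$ratio))
})

test_that("channel TIFFs round-trip through 8-bit files", {
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  f <- withr::local_tempfile(fileext = ".tif")
  writeChannelTiff(img, f)
  back <- readChannelTiff(f)
  expect_equal(back, img, ignore_attr = TRUE)
})
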