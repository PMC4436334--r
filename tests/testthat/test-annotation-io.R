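# Dot-annotation and ROI input/output.

test_that("mask reading enumerates nonzero pixels regardless of bit depth", {
  m <- matrix(0L, 5, 5)
  expect_equal(nDots(readDotMask(m)), 0L)   # no marks means no eggs

  m[3, 4] <- 1L   # (2, 3) 0-based
  m[5, 1] <- 1L   # (4, 0)
  ann <- readDotMask(m)
  expect_equal(dots(ann), cbind(row = c(2L, 4L), col = c(3L, 0L)))

  # 8-bit export convention: 255 means the same as 1
  m255 <- m * 255L
  expect_equal(dots(readDotMask(m255)), dots(ann))

  # brute-force enumeration oracle on a random mask
  set.seed(11)
  mr <- matrix(rbinom(20 * 17, 1, 0.1) * sample(c(1L, 255L, 65535L),
                                                20 * 17, TRUE), 20, 17)
  annR <- readDotMask(mr)
  expected <- NULL
  for (r in 0:19) for (cc in 0:16)
    if (mr[r + 1, cc + 1] > 0) expected <- rbind(expected, c(r, cc))
  expect_equal(unname(dots(annR)), unname(expected))
  expect_error(readDotMask(array(0, c(3, 3, 3))), "2-D")
})

test_that("masks read identically from memory and from PNG files", {
  set.seed(8)
  m <- matrix(0L, 24, 18)
  m[sample.int(24 * 18, 15)] <- 1L
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(m * 1.0, f)   # 8-bit export: nonzero becomes 255
  ann <- readDotMask(f)
  expect_identical(dots(ann), dots(readDotMask(m)))
  expect_equal(imageId(ann), basename(tools::file_path_sans_ext(f)))
})

test_that("mask -> annotation -> mask is the identity", {
  set.seed(5)
  m <- matrix(0L, 30, 25)
  m[sample.int(30 * 25, 40)] <- 1L
  expect_identical(rasterizeDots(readDotMask(m)), m)
})

test_that("CSV dialect round-trips and reports malformed lines", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("row,col\n2,3\n4,0", f, sep = "\n")
  ann <- readDotsCsv(f, imageDim = c(5L, 5L))
  expect_equal(dots(ann), cbind(row = c(2L, 4L), col = c(3L, 0L)))

  # header-only file is an empty annotation
  writeLines("row,col", f)
  expect_equal(nDots(readDotsCsv(f, imageDim = c(5L, 5L))), 0L)

  # seeded round-trip on 1000 random in-bounds dots, duplicates included
  set.seed(21)
  d <- cbind(row = sample(0:199, 1000, TRUE), col = sample(0:149, 1000, TRUE))
  annIn <- DotAnnotation("rt", d, c(200L, 150L))
  writeDotsCsv(annIn, f)
  annOut <- readDotsCsv(f, imageDim = c(200L, 150L))
  expect_identical(dots(annOut), dots(annIn))

  writeLines(c("row,col", "3,4", "nope,7"), f)
  expect_error(readDotsCsv(f), "line 3")
})

test_that("ROI restriction uses half-open 0-based bounds", {
  ann <- DotAnnotation("x", cbind(c(2L, 4L), c(3L, 0L)), c(5L, 5L))
  expect_equal(unname(dots(dotsInRoi(ann, ROI(c(0, 0), 3, 5)))),
               unname(cbind(2L, 3L)))
  # whole-image ROI is the identity
  expect_equal(dots(dotsInRoi(ann, ROI(c(0, 0), 5, 5))), dots(ann))
  # a dot exactly on the lower boundary row r0 + h is excluded
  annB <- DotAnnotation("b", cbind(3L, 2L), c(6L, 6L))
  expect_equal(nDots(dotsInRoi(annB, ROI(c(0, 0), 3, 6))), 0L)
  expect_equal(nDots(dotsInRoi(annB, ROI(c(3, 0), 3, 6))), 1L)
  expect_error(dotsInRoi(ann, ROI(c(3, 3), 5, 5)), "beyond")
})

test_that("dot membership matches a brute-force oracle and tiles add up", {
  set.seed(31)
  d <- cbind(row = sample(0:39, 120, TRUE), col = sample(0:39, 120, TRUE))
  ann <- DotAnnotation("t", d, c(40L, 40L))
  roi <- ROI(c(7, 12), 15, 9)
  manual <- sum(d[, 1] >= 7 & d[, 1] < 22 & d[, 2] >= 12 & d[, 2] < 21)
  expect_equal(nDots(dotsInRoi(ann, roi)), manual)

  # four disjoint rectangles tiling the image partition the dots
  tiles <- list(ROI(c(0, 0), 20, 20), ROI(c(0, 20), 20, 20),
                ROI(c(20, 0), 20, 20), ROI(c(20, 20), 20, 20))
  expect_equal(sum(vapply(tiles, function(r) nDots(dotsInRoi(ann, r)),
                          numeric(1))),
               nDots(ann))
})

test_that("annotations reject out-of-bounds dots by name", {
  expect_error(DotAnnotation("x", cbind(5L, 2L), c(5L, 5L)), "dot 1")
  expect_error(DotAnnotation("x", cbind(c(1L, 2L), c(2L, 7L)), c(5L, 5L)),
               "dot 2")
})

test_that("annotation files are paired by basename and suffix", {
  dir <- withr::local_tempdir()
  file.create(file.path(dir, "vial_03.png"))
  writeDotsCsv(DotAnnotation("vial_03", cbind(1L, 1L), c(4L, 4L)),
               file.path(dir, "vial_03_dots.csv"))
  hit <- findAnnotationFile(file.path(dir, "vial_03.png"))
  expect_equal(basename(hit), "vial_03_dots.csv")
  expect_true(is.na(findAnnotationFile(file.path(dir, "vial_99.png"))))
})
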