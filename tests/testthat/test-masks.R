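# Intensity thresholding, NAWM complement, mode-derived ROIs and Dice.

arr3 <- function(x, dims = c(length(x), 1, 1)) array(x, dims)

test_that("the robust-range threshold rule selects hyperintense candidates", {
  # 1000 background voxels at 0 (excluded), WM at 100, lesions at 300,
  # CSF-like at 30: threshold = p2 + 0.30 (p98 - p2) of nonzero values
  vals <- c(rep(0, 500), rep(30, 200), rep(100, 500), rep(300, 100))
  wm <- c(rep(FALSE, 700), rep(TRUE, 600))
  class3 <- c(rep(FALSE, 500), rep(TRUE, 200), rep(FALSE, 500),
              rep(TRUE, 100))
  vol <- labeledVolume(arr3(vals), arr3(wm))
  nz <- vals[vals != 0]
  thr <- quantile(nz, 0.02, names = FALSE) +
    0.3 * diff(quantile(nz, c(0.02, 0.98), names = FALSE))
  expected <- arr3(class3 & wm & vals > thr)
  expect_identical(lesionMaskFromIntensities(vol, arr3(class3)),
                   expected)
  expect_identical(sum(expected), 100L)  # exactly the lesion voxels

  # degenerate intensities: nothing is strictly above the threshold
  flat <- labeledVolume(arr3(rep(5, 100)), arr3(rep(TRUE, 100)))
  expect_warning(m <- lesionMaskFromIntensities(flat,
                                                arr3(rep(TRUE, 100))),
                 "empty")
  expect_false(any(m))
})

test_that("NAWM is the WM complement of the lesion mask", {
  wm <- arr3(rep(TRUE, 1000))
  lesionIdx <- withr::with_seed(1, sample(1000, 137))
  lesion <- arr3(seq_len(1000) %in% lesionIdx)
  vol <- labeledVolume(arr3(runif(1000)), wm, lesion = lesion)
  nawm <- nawmMask(vol)
  expect_identical(sum(nawm), 863L)
  expect_false(any(nawm & lesion))
  expect_true(all(wm == (nawm | lesion)))

  empty <- labeledVolume(arr3(runif(10)), arr3(rep(TRUE, 10)),
                         lesion = arr3(rep(FALSE, 10)))
  expect_identical(nawmMask(empty), arr3(rep(TRUE, 10)))
  full <- labeledVolume(arr3(runif(10)), arr3(rep(TRUE, 10)),
                        lesion = arr3(rep(TRUE, 10)))
  expect_false(any(nawmMask(full)))
})

test_that("mode-derived ROIs use strict thresholds and stay disjoint", {
  vals <- c(0.02, 0.05, 0.10, 0.18, 0.22)
  vol <- labeledVolume(arr3(vals), arr3(rep(TRUE, 5)))
  rois <- roiFromModes(vol, 0.06, 0.17)
  expect_identical(which(rois$roiM1), 1:2)
  expect_identical(which(rois$roiM2), 4:5)
  expect_false(any(rois$roiM1 & rois$roiM2))

  expect_false(any(roiFromModes(vol, 0, 0.17)$roiM1))
  expect_false(any(roiFromModes(vol, 0.06, 0.22)$roiM2))
  expect_error(roiFromModes(vol, 0.2, 0.1), "exceed")

  # disjointness holds for random thresholds on random volumes
  withr::with_seed(2, {
    for (i in 1:10) {
      v <- labeledVolume(arr3(runif(200, 0, 0.4)),
                         arr3(runif(200) < 0.7))
      ms <- sort(runif(2, 0, 0.4))
      r <- roiFromModes(v, ms[1], ms[2])
      expect_false(any(r$roiM1 & r$roiM2))
      expect_true(all((r$roiM1 | r$roiM2) <= wmMask(v)))
    }
  })
})

test_that("Dice satisfies its axioms", {
  a <- arr3(c(TRUE, TRUE, FALSE, FALSE))
  b <- arr3(c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(diceCoefficient(a, b), 0.5)
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(diceCoefficient(a, arr3(c(FALSE, FALSE, TRUE, TRUE))), 0)
  expect_error(diceCoefficient(arr3(rep(FALSE, 4)), arr3(rep(FALSE, 4))),
               "undefined")
  expect_error(diceCoefficient(a, array(TRUE, c(2, 1, 1))), "grid")

  withr::with_seed(3, {
    for (i in 1:20) {
      x <- arr3(runif(100) < 0.4)
      y <- arr3(runif(100) < 0.4)
      if (!any(x) && !any(y)) next
      d <- diceCoefficient(x, y)
      expect_gte(d, 0)
      expect_lte(d, 1)
      expect_identical(d, diceCoefficient(y, x))            # symmetry
      expect_identical(d == 1, identical(x, y))             # 1 iff equal
      expect_identical(d == 0, !any(x & y))                 # 0 iff disjoint
    }
  })
})

test_that("group Dice comparison runs the Welch test on per-subject overlaps", {
  # subjects engineered so Dice(mask, roiM1) varies but equals
  # Dice(mask, roiM2): the Welch test must return t = 0, p = 1
  mkSubject <- function(nMask, nOverlap) {
    mask <- arr3(c(rep(TRUE, nMask), rep(FALSE, 100 - nMask)), c(100, 1, 1))
    roi <- arr3(c(rep(TRUE, nOverlap), rep(FALSE, 50 - nOverlap),
                  rep(TRUE, 10), rep(FALSE, 40)), c(100, 1, 1))
    list(mask = mask, roiM1 = roi, roiM2 = roi)
  }
  subjects <- list(mkSubject(20, 5), mkSubject(30, 10), mkSubject(40, 20))
  cmp <- compareDiceGroups(subjects, "lesion")
  expect_equal(cmp@tStat, 0)
  expect_equal(cmp@pValue, 1)
  expect_identical(cmp@diceM1, cmp@diceM2)

  # undefined-overlap subjects are excluded with a message
  degenerate <- list(mask = arr3(rep(FALSE, 100), c(100, 1, 1)),
                     roiM1 = arr3(rep(FALSE, 100), c(100, 1, 1)),
                     roiM2 = arr3(rep(FALSE, 100), c(100, 1, 1)))
  expect_message(cmp2 <- compareDiceGroups(c(subjects, list(degenerate)),
                                           "lesion"),
                 "excluded")
  expect_identical(cmp2@nExcluded, 1L)
  expect_error(compareDiceGroups(subjects[1:2], "lesion"), "3 subjects")
})
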