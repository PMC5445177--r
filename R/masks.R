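# Lesion/NAWM masks from intensity volumes, mode-derived ROIs and their
# Dice overlap.

#' Lesion mask from a FLAIR-like intensity volume
#'
#' Reproduces the intensity-threshold rule used to binarize white-matter
#' hyperintensities: candidate voxels are those of the third tissue class
#' (CSF plus lesions) that lie inside the WM mask; the robust intensity
#' range is the interval between the 2nd and 98th percentile of the
#' nonzero image, and only candidates with intensity strictly greater
#' than 30% of the way up that range,
#' \eqn{t = p_2 + 0.30 (p_{98} - p_2)}, are kept. Percentiles use linear
#' interpolation between order statistics.
#'
#' @param intensity a [LabeledVolume-class] whose values are intensities
#'   and whose `wm` slot is the white-matter mask.
#' @param class3 logical array, the third tissue class on the same grid.
#' @return Logical array, the binarized lesion mask (empty, with a
#'   warning, when there are no candidates above threshold).
#' @seealso [makeFlairLike()], [diceCoefficient()]
#' @export
lesionMaskFromIntensities <- function(intensity, class3) {
  stopifnot(is(intensity, "LabeledVolume"))
  if (!identical(dim(class3), dim(intensity@values)))
    stop("'class3' must share the grid of the intensity volume")
  vals <- intensity@values
  candidates <- class3 & intensity@wm
  nz <- vals[vals != 0]
  robust <- quantile(nz, c(0.02, 0.98), names = FALSE, type = 7)
  threshold <- robust[1] + 0.30 * (robust[2] - robust[1])
  mask <- candidates & (vals > threshold)
  if (!any(mask))
    warning("no candidate voxels above the robust-range threshold: ",
            "returning an empty lesion mask")
  mask
}

#' NAWM mask as the WM complement of the lesion mask
#'
#' Normal-appearing white matter is defined as every white-matter voxel
#' not in the lesion mask, so the two masks are mutually exclusive and
#' together partition WM.
#'
#' @param volume a [LabeledVolume-class] with `wm` and `lesion` labels.
#' @return Logical array, the NAWM mask.
#' @export
nawmMask <- function(volume) {
  stopifnot(is(volume, "LabeledVolume"))
  if (is.null(volume@lesion))
    stop("'volume' must carry a lesion label")
  if (any(volume@lesion & !volume@wm))
    stop("inconsistent labels: lesion mask extends outside the WM mask")
  volume@wm & !volume@lesion
}

#' Mode-derived regions of interest
#'
#' Interprets the fitted mixture spatially: `ROI[m1]` is the set of WM
#' voxels with MWF strictly below the low mode \eqn{m_1} (lesion-like),
#' and `ROI[m2]` the set with MWF strictly above the high mode
#' \eqn{m_2} (NAWM-like). Since \eqn{m_1 \le m_2} the two ROIs are
#' disjoint by construction; voxels exactly at a mode (measure zero for
#' continuous data) belong to neither.
#'
#' @param volume a [LabeledVolume-class] with MWF values and a WM mask.
#' @param m1,m2 the component modes, \eqn{0 \le m_1 \le m_2}.
#' @return A list with logical arrays `roiM1` and `roiM2`.
#' @export
roiFromModes <- function(volume, m1, m2) {
  stopifnot(is(volume, "LabeledVolume"))
  if (!is.finite(m1) || !is.finite(m2) || m1 < 0)
    stop("'m1' and 'm2' must be finite nonnegative MWF values")
  if (m1 > m2)
    stop("'m1' must not exceed 'm2'")
  list(roiM1 = volume@wm & (volume@values < m1),
       roiM2 = volume@wm & (volume@values > m2))
}

#' Dice overlap coefficient
#'
#' \eqn{Dice(A, B) = 2|A \cap B| / (|A| + |B|)}: 1 for identical
#' nonempty voxel sets, 0 for disjoint ones, symmetric in its arguments.
#'
#' @param a,b logical arrays on the same grid, at least one nonempty.
#' @return Overlap ratio in \eqn{[0, 1]}.
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
#' b <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1))
#' diceCoefficient(a, b)  # 0.5
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("'a' and 'b' must share a grid")
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0)
    stop("Dice undefined: both masks are empty")
  2 * sum(a & b) / (na + nb)
}

#' Group-level comparison of mask/ROI overlap
#'
#' For each subject, computes the Dice coefficient of a reference mask
#' (lesion or NAWM) with both mode-derived ROIs, then tests the
#' difference between the two per-subject Dice samples with a two-sided
#' Welch two-sample t-test (unequal variances, Welch--Satterthwaite
#' degrees of freedom). Subjects for whom a Dice value is undefined
#' (reference mask and ROI both empty) are excluded with a message.
#'
#' @param subjects a list; each element is a list with logical arrays
#'   `mask` (the reference mask), `roiM1` and `roiM2`.
#' @param reference `"lesion"` or `"nawm"`, recorded in the result.
#' @return A [DiceComparison-class].
#' @seealso [roiFromModes()], [welchT()]
#' @export
compareDiceGroups <- function(subjects, reference = c("lesion", "nawm")) {
  reference <- match.arg(reference)
  if (length(subjects) < 3L)
    stop("need at least 3 subjects")
  d1 <- numeric(0)
  d2 <- numeric(0)
  excluded <- 0L
  for (s in subjects) {
    pair <- tryCatch(
      c(diceCoefficient(s$mask, s$roiM1), diceCoefficient(s$mask, s$roiM2)),
      error = function(e) NULL)
    if (is.null(pair)) {
      excluded <- excluded + 1L
      next
    }
    d1 <- c(d1, pair[1])
    d2 <- c(d2, pair[2])
  }
  if (excluded > 0L)
    message(excluded, " subject(s) excluded: undefined Dice overlap")
  if (length(d1) < 3L)
    stop("fewer than 3 subjects with defined Dice overlap")
  wt <- welchT(d1, d2)
  new("DiceComparison", diceM1 = d1, diceM2 = d2, reference = reference,
      tStat = wt$t, df = wt$df, pValue = wt$p,
      direction = if (mean(d1) >= mean(d2)) "roiM1" else "roiM2",
      nExcluded = excluded)
}

setMethod("show", "DiceComparison", function(object) {
  cat(sprintf("DiceComparison (%s mask, %d subjects, %d excluded)\n",
              object@reference, length(object@diceM1), object@nExcluded))
  cat(sprintf("  mean Dice with ROI[m1]: %.3f, with ROI[m2]: %.3f\n",
              mean(object@diceM1), mean(object@diceM2)))
  cat(sprintf("  Welch t = %.3f, df = %.1f, two-sided p = %.3g\n",
              object@tStat, object@df, object@pValue))
  cat(sprintf("  larger overlap: %s\n", object@direction))
})
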