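# Synthetic MWF and FLAIR-like volumes with known ground truth.

#' MWF from water-compartment signal fractions
#'
#' The myelin water fraction of a voxel is the ratio of the myelin-water
#' signal to the total signal from all water compartments:
#' \eqn{MWF = c_{MW} / (c_{MW} + c_{CW} + c_{CSF})}, with
#' \eqn{c_{MW}} the myelin water, \eqn{c_{CW}} the intra/extra-cellular
#' water and \eqn{c_{CSF}} the cerebrospinal-fluid contribution.
#' Vectorized over voxels.
#'
#' @param cMW,cCW,cCSF nonnegative signal fractions (arbitrary units).
#' @return MWF ratio(s) in \eqn{[0, 1]}.
#' @examples
#' compartmentsToMWF(1, 1, 0)             # 0.5
#' compartmentsToMWF(0.1388, 0.8612, 0)   # 0.1388
#' @export
compartmentsToMWF <- function(cMW, cCW, cCSF) {
  if (any(cMW < 0 | cCW < 0 | cCSF < 0, na.rm = TRUE))
    stop("signal fractions must be nonnegative")
  total <- cMW + cCW + cCSF
  if (any(total <= 0, na.rm = TRUE))
    stop("invalid voxel: all water-compartment fractions are zero")
  cMW / total
}

#' Construct a labeled volume
#'
#' @param values 3D numeric array (MWF or intensity).
#' @param wm 3D logical white-matter mask on the same grid.
#' @param lesion,nawm,dirty optional 3D logical label volumes.
#' @param affine 4x4 voxel-to-world matrix.
#' @return A [LabeledVolume-class].
#' @export
labeledVolume <- function(values, wm, lesion = NULL, nawm = NULL,
                          dirty = NULL, affine = diag(4)) {
  new("LabeledVolume", values = values, wm = wm, lesion = lesion,
      nawm = nawm, dirty = dirty, affine = affine)
}

#' @rdname volume-accessors
#' @param object a [LabeledVolume-class].
#' @return `volumeValues`: the 3D array; `wmMask` / `lesionMask`: logical
#'   arrays; `wmValues`: the pooled vector of values inside the WM mask
#'   (the input to the mixture fit).
#' @export
setMethod("volumeValues", "LabeledVolume", function(object) object@values)

#' @rdname volume-accessors
#' @export
setMethod("wmMask", "LabeledVolume", function(object) object@wm)

#' @rdname volume-accessors
#' @export
setMethod("lesionMask", "LabeledVolume", function(object) object@lesion)

#' @rdname volume-accessors
#' @export
setMethod("wmValues", "LabeledVolume", function(object) {
  object@values[object@wm]
})

setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("LabeledVolume: %d x %d x %d grid, %d WM voxels\n",
              d[1], d[2], d[3], sum(object@wm)))
  if (!is.null(object@lesion))
    cat(sprintf("  lesion: %d voxels\n", sum(object@lesion)))
  if (!is.null(object@nawm))
    cat(sprintf("  NAWM:   %d voxels\n", sum(object@nawm)))
  if (!is.null(object@dirty))
    cat(sprintf("  dirty:  %d voxels (within NAWM)\n", sum(object@dirty)))
})

#' Specification for a synthetic MWF volume
#'
#' Defaults describe a desk-scale subject: a 64 x 64 x 32 grid whose
#' inscribed ellipsoidal WM mask holds about 60,000 voxels, spherical
#' lesions of radius 3--6 voxels with a 1-voxel dirty rim, and the
#' [referenceMixture()] as ground truth. With `nLesions = NA` (the
#' default) lesions are added until the low-MWF voxels (lesion plus
#' dirty rim) make up the mixture's \eqn{\lambda} fraction of WM, so the
#' pooled WM histogram matches the ground-truth mixture.
#'
#' @param gridShape voxel counts per axis.
#' @param wmFraction target fraction of the grid inside the WM mask.
#' @param nLesions lesion count, or `NA` to match \eqn{\lambda}.
#' @param lesionRadiusRange lesion radius range in voxels.
#' @param dirtyRimWidth dirty rim width in voxels.
#' @param mixture ground-truth [GammaMixtureModel-class].
#' @param dirtyOverlap fraction of dirty-rim voxels carrying the low
#'   component's largest realized draws (1 = the rim is exactly the upper
#'   tail, 0 = rim values exchangeable with lesion values). The pooled
#'   WM distribution is unaffected.
#' @param seed integer RNG seed.
#' @return A [VolumeSpec-class].
#' @seealso [makeMWFVolume()]
#' @export
volumeSpec <- function(gridShape = c(64L, 64L, 32L), wmFraction = 0.46,
                       nLesions = NA_integer_,
                       lesionRadiusRange = c(3, 6), dirtyRimWidth = 1,
                       mixture = referenceMixture(), dirtyOverlap = 0.5,
                       seed = 1L) {
  new("VolumeSpec", gridShape = as.integer(gridShape),
      wmFraction = wmFraction, nLesions = as.integer(nLesions),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      dirtyRimWidth = as.numeric(dirtyRimWidth), mixture = mixture,
      dirtyOverlap = dirtyOverlap, seed = as.integer(seed))
}

# Ellipsoidal norm of every voxel: 1 on the surface of the ellipsoid
# with the given semi-axes, centred in the grid.
ellipsoidNorm <- function(gridShape, semiAxes) {
  centre <- (gridShape + 1) / 2
  dx <- ((seq_len(gridShape[1]) - centre[1]) / semiAxes[1])^2
  dy <- ((seq_len(gridShape[2]) - centre[2]) / semiAxes[2])^2
  dz <- ((seq_len(gridShape[3]) - centre[3]) / semiAxes[3])^2
  sqrt(outer(outer(dx, dy, "+"), dz, "+"))
}

# Logical array of voxels within `radius` of `centre` (voxel units),
# computed on a bounding box for speed.
sphereMask <- function(gridShape, centre, radius) {
  out <- array(FALSE, gridShape)
  lo <- pmax(1L, floor(centre - radius))
  hi <- pmin(gridShape, ceiling(centre + radius))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  d2 <- outer(outer((xs - centre[1])^2, (ys - centre[2])^2, "+"),
              (zs - centre[3])^2, "+")
  out[xs, ys, zs] <- d2 <= radius^2
  out
}

# Split nLow draws from the low component between lesion core and dirty
# rim. A fraction `overlap` of the rim voxels takes the largest realized
# draws (the component's upper tail); the rest are exchangeable with the
# lesion draws. The pooled low-MWF sample is exactly nLow iid draws from
# the component, so the whole-WM histogram follows the ground-truth
# mixture for every value of `overlap`.
splitLowDraws <- function(comp, nLesion, nDirty, overlap) {
  draws <- rgamma(nLesion + nDirty, comp@shape, scale = comp@scale)
  if (nDirty == 0L)
    return(list(lesion = draws, dirty = numeric(0)))
  nTop <- round(overlap * nDirty)
  ord <- order(draws, decreasing = TRUE)
  top <- ord[seq_len(nTop)]
  rest <- if (nTop < length(draws)) sample(ord[-seq_len(nTop)]) else integer(0)
  dirtyIdx <- c(top, rest[seq_len(nDirty - nTop)])
  lesionIdx <- setdiff(seq_along(draws), dirtyIdx)
  list(lesion = draws[lesionIdx], dirty = sample(draws[dirtyIdx]))
}

#' Generate a synthetic MWF volume with known ground truth
#'
#' Builds one subject: an ellipsoidal white-matter mask occupying about
#' `wmFraction` of the grid, spherical lesions (centres uniform over WM
#' voxels where the lesion and its rim fit entirely inside WM), and MWF
#' values drawn from the ground-truth mixture -- lesion and dirty-rim
#' voxels jointly from the low-MWF component (with the rim biased toward
#' the component's upper tail, see `dirtyOverlap`) and the remaining WM
#' from the high-MWF component, so the pooled WM histogram follows the
#' ground-truth mixture exactly. Values are clipped to \eqn{[0, 1]} since MWF
#' is a signal fraction. The NAWM label is the WM complement of the
#' lesion label, so the dirty rim is part of NAWM, mirroring how lesion
#' masks miss dirty WM.
#'
#' With `nLesions = NA`, lesions are added until lesion-plus-rim voxels
#' reach the \eqn{\lambda} fraction of WM, so that the pooled WM
#' histogram approximates the ground-truth mixture.
#'
#' @param spec a [VolumeSpec-class].
#' @param maxAttempts placement attempts per lesion before giving up.
#' @return A [LabeledVolume-class] with `wm`, `lesion`, `nawm` and
#'   `dirty` labels.
#' @examples
#' vol <- makeMWFVolume(volumeSpec(gridShape = c(32, 32, 16), seed = 7))
#' vol
#' @export
makeMWFVolume <- function(spec, maxAttempts = 200L) {
  stopifnot(is(spec, "VolumeSpec"))
  validObject(spec)
  gs <- spec@gridShape
  # semi-axes scaled so the inscribed ellipsoid holds ~ wmFraction of
  # the grid (ellipsoid volume = 4/3 pi abc = 0.5236 of the bounding box)
  s <- (spec@wmFraction / (pi / 6))^(1 / 3)
  semi <- s * gs / 2
  rho <- ellipsoidNorm(gs, semi)
  wm <- rho <= 1
  nWM <- sum(wm)
  withSeed(spec@seed, {
    lesion <- array(FALSE, gs)
    rimAll <- array(FALSE, gs)
    autoFill <- is.na(spec@nLesions)
    target <- if (autoFill) round(mixingRatio(spec@mixture) * nWM) else NA
    nToPlace <- if (autoFill) 10000L else spec@nLesions
    placed <- 0L
    while (placed < nToPlace) {
      if (autoFill && sum(lesion | rimAll) >= target) break
      r <- runif(1, spec@lesionRadiusRange[1], spec@lesionRadiusRange[2])
      ok <- FALSE
      for (attempt in seq_len(maxAttempts)) {
        idx <- which(wm)[sample.int(nWM, 1)]
        centre <- arrayInd(idx, gs)[1, ]
        outerMask <- sphereMask(gs, centre, r + spec@dirtyRimWidth)
        if (all(wm[outerMask])) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place a lesion of radius ", round(r, 2),
             " inside the WM mask after ", maxAttempts, " attempts")
      lesion <- lesion | sphereMask(gs, centre, r)
      rimAll <- rimAll | outerMask
      placed <- placed + 1L
    }
    dirty <- rimAll & !lesion
    nawm <- wm & !lesion
    values <- array(0, gs)
    low <- lowComponent(spec@mixture)
    high <- highComponent(spec@mixture)
    nLes <- sum(lesion)
    nDirty <- sum(dirty)
    nHigh <- sum(nawm & !dirty)
    lowDraws <- splitLowDraws(low, nLes, nDirty, spec@dirtyOverlap)
    values[lesion] <- lowDraws$lesion
    values[dirty] <- lowDraws$dirty
    values[nawm & !dirty] <- rgamma(nHigh, high@shape, scale = high@scale)
    values[values > 1] <- 1
    labeledVolume(values, wm, lesion = lesion, nawm = nawm, dirty = dirty)
  })
}

#' Generate a FLAIR-like intensity volume from a labeled MWF volume
#'
#' Produces an intensity volume in which lesions are hyperintense over
#' the surrounding white matter by `lesionGain`, the dirty rim sits at an
#' intermediate level (40% of the gain), a cerebrospinal-fluid-like shell
#' outside the WM mask is dark, and Gaussian noise of SD `noiseSD` is
#' added everywhere. Alongside, a third-tissue-class mask is derived from
#' the noisy intensities (emulating an intensity-based segmentation whose
#' third class captures both CSF and lesions): brain voxels darker than
#' the CSF/WM midpoint or brighter than half the lesion gain above the WM
#' level.
#'
#' @param volume a [LabeledVolume-class] with `wm` and `lesion` labels.
#' @param lesionGain intensity offset of lesions over NAWM (arbitrary
#'   intensity units; WM sits at 100, CSF at 30).
#' @param noiseSD Gaussian noise SD, same units.
#' @param seed integer RNG seed.
#' @return A list with `intensity` (a [LabeledVolume-class] carrying the
#'   intensities and the same labels) and `class3` (logical array).
#' @examples
#' vol <- makeMWFVolume(volumeSpec(gridShape = c(32, 32, 16), seed = 7))
#' fl <- makeFlairLike(vol, lesionGain = 20, noiseSD = 5, seed = 7)
#' @export
makeFlairLike <- function(volume, lesionGain = 20, noiseSD = 5, seed = 1L) {
  stopifnot(is(volume, "LabeledVolume"))
  if (is.null(volume@lesion))
    stop("'volume' must carry a lesion label")
  gs <- dim(volume@values)
  wmLevel <- 100
  csfLevel <- 30
  # CSF-like shell just outside the WM ellipsoid
  s <- (mean(volume@wm) / (pi / 6))^(1 / 3)
  rho <- ellipsoidNorm(gs, s * gs / 2)
  csf <- !volume@wm & rho <= 1.10
  withSeed(seed, {
    intensity <- array(0, gs)
    intensity[volume@wm] <- wmLevel
    intensity[csf] <- csfLevel
    if (!is.null(volume@dirty))
      intensity[volume@dirty] <- wmLevel + 0.4 * lesionGain
    intensity[volume@lesion] <- wmLevel + lesionGain
    intensity <- intensity + rnorm(length(intensity), 0, noiseSD)
    brain <- volume@wm | csf
    class3 <- brain & (intensity < (csfLevel + wmLevel) / 2 |
                         intensity > wmLevel + lesionGain / 2)
    list(intensity = labeledVolume(intensity, volume@wm,
                                   lesion = volume@lesion,
                                   nawm = volume@nawm,
                                   dirty = volume@dirty,
                                   affine = volume@affine),
         class3 = class3)
  })
}
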