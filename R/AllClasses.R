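#' @import methods
NULL

#' RGBImage: an 8-bit RGB raster
#'
#' A thin S4 wrapper around a numeric `H x W x 3` array holding 8-bit channel
#' values in `[0, 255]` (red, green, blue plane order). It behaves like a plain
#' array (indexing, `dim()`), but carries a validity contract so every function
#' in the package can assume well-formed input.
#'
#' @slot .Data numeric array of dimension `H x W x 3` with whole values in
#'   `[0, 255]`.
#' @export
setClass("RGBImage", contains = "array", validity = function(object) {
  d <- dim(object)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L)
    return("image must have at least one row and one column")
  v <- as.numeric(object)
  if (anyNA(v) || any(v < 0) || any(v > 255))
    return("pixel values must lie in [0, 255]")
  if (any(v != round(v)))
    return("pixel values must be whole 8-bit numbers")
  TRUE
})

#' Construct an RGBImage from a pixel array
#'
#' @param pixels numeric or integer `H x W x 3` array with values in `[0, 255]`.
#' @return an [RGBImage-class] object.
#' @examples
#' img <- RGBImage(array(128, dim = c(32, 32, 3)))
#' dim(img)
#' @export
RGBImage <- function(pixels) {
  px <- array(as.numeric(pixels), dim = dim(pixels))
  new("RGBImage", px)
}

#' ClassAppearance: generative parameters of one synthetic tissue class
#'
#' Describes the color and texture statistics of one class of synthetic
#' H&E-like images: an eosin-like background hue/saturation, hematoxylin-like
#' nucleus blobs (hue, density, radius), a multiplicative texture field with a
#' stated correlation length, and per-channel sensor noise.
#'
#' @slot backgroundHue background hue in degrees, `[0, 360)`.
#' @slot backgroundSat background saturation fraction in `[0, 1]`.
#' @slot nucleusHue nucleus hue in degrees.
#' @slot nucleusDensity expected nucleus blobs per 10^4 px^2 (>= 0).
#' @slot nucleusRadius length-2 numeric: mean and sd of nucleus radius in px.
#' @slot textureGrain correlation length (px) of the multiplicative noise field.
#' @slot jitterSd per-channel Gaussian noise sd in 8-bit units.
#' @export
setClass("ClassAppearance",
  representation(
    backgroundHue  = "numeric",
    backgroundSat  = "numeric",
    nucleusHue     = "numeric",
    nucleusDensity = "numeric",
    nucleusRadius  = "numeric",
    textureGrain   = "numeric",
    jitterSd       = "numeric"
  ),
  validity = function(object) {
    if (object@backgroundHue < 0 || object@backgroundHue >= 360)
      return("backgroundHue must lie in [0, 360)")
    if (object@backgroundSat < 0 || object@backgroundSat > 1)
      return("backgroundSat must lie in [0, 1]")
    if (object@nucleusDensity < 0)
      return("nucleusDensity must be >= 0")
    if (length(object@nucleusRadius) != 2L || object@nucleusRadius[1] <= 0 ||
        object@nucleusRadius[2] < 0)
      return("nucleusRadius must be c(mean > 0, sd >= 0)")
    if (object@textureGrain <= 0)
      return("textureGrain must be strictly positive")
    if (object@jitterSd <= 0)
      return("jitterSd must be strictly positive")
    TRUE
  }
)

#' Construct a ClassAppearance
#'
#' @param backgroundHue background hue, degrees in `[0, 360)`.
#' @param backgroundSat background saturation fraction.
#' @param nucleusHue nucleus hue, degrees.
#' @param nucleusDensity nucleus blobs per 10^4 px^2.
#' @param nucleusRadius length-2 numeric `c(mean, sd)` of nucleus radius (px).
#' @param textureGrain correlation length in px of the texture field.
#' @param jitterSd per-channel noise sd in 8-bit units.
#' @return a [ClassAppearance-class] object.
#' @export
classAppearance <- function(backgroundHue = 330, backgroundSat = 0.25,
                            nucleusHue = 270, nucleusDensity = 25,
                            nucleusRadius = c(3, 0.8), textureGrain = 4,
                            jitterSd = 3) {
  new("ClassAppearance",
      backgroundHue = as.numeric(backgroundHue),
      backgroundSat = as.numeric(backgroundSat),
      nucleusHue = as.numeric(nucleusHue) %% 360,
      nucleusDensity = as.numeric(nucleusDensity),
      nucleusRadius = as.numeric(nucleusRadius),
      textureGrain = as.numeric(textureGrain),
      jitterSd = as.numeric(jitterSd))
}

#' HistoDataset: a labeled collection of RGB images
#'
#' Holds images together with two-class labels (1 = normal, 2 = malignant) and
#' free-text per-image tags (e.g. an emulated magnification).
#'
#' @slot images list of [RGBImage-class] objects.
#' @slot labels integer vector of class codes, each 1 or 2.
#' @slot tags character vector of per-image tags.
#' @export
setClass("HistoDataset",
  representation(images = "list", labels = "integer", tags = "character"),
  validity = function(object) {
    n <- length(object@images)
    if (length(object@labels) != n)
      return("labels must have one entry per image")
    if (length(object@tags) != n)
      return("tags must have one entry per image")
    if (n > 0 && !all(object@labels %in% c(1L, 2L)))
      return("labels must be drawn from the two-class code set {1, 2}")
    ok <- vapply(object@images, is, logical(1), class2 = "RGBImage")
    if (!all(ok)) return("all images must be RGBImage objects")
    TRUE
  }
)

#' Construct a HistoDataset
#'
#' @param images list of [RGBImage-class] objects.
#' @param labels integer class codes in `{1, 2}` (1 = normal, 2 = malignant).
#' @param tags optional character tags, recycled default `""`.
#' @return a [HistoDataset-class] object.
#' @export
HistoDataset <- function(images, labels, tags = NULL) {
  if (is.null(tags)) tags <- rep("", length(images))
  new("HistoDataset", images = images, labels = as.integer(labels),
      tags = as.character(tags))
}

#' AugmentSpec: the augmentation recipe
#'
#' Random horizontal/vertical flips, a random rotation within plus/minus
#' `maxRotation` degrees, and multiplicative brightness / contrast / saturation
#' jitter within the declared fractional deltas. Deterministic for a fixed
#' `seed`.
#'
#' @slot hflipProb,vflipProb flip probabilities in `[0, 1]`.
#' @slot maxRotation maximum absolute rotation angle in degrees (>= 0).
#' @slot brightnessDelta,contrastDelta,saturationDelta maximal fractional
#'   adjustment of each color property (>= 0).
#' @slot seed integer RNG seed.
#' @export
setClass("AugmentSpec",
  representation(hflipProb = "numeric", vflipProb = "numeric",
                 maxRotation = "numeric", brightnessDelta = "numeric",
                 contrastDelta = "numeric", saturationDelta = "numeric",
                 seed = "integer"),
  validity = function(object) {
    p <- c(object@hflipProb, object@vflipProb)
    if (any(p < 0 | p > 1)) return("flip probabilities must lie in [0, 1]")
    if (object@maxRotation < 0) return("maxRotation must be >= 0")
    d <- c(object@brightnessDelta, object@contrastDelta, object@saturationDelta)
    if (any(d < 0)) return("color deltas must be >= 0")
    TRUE
  }
)

#' Construct an AugmentSpec
#'
#' Defaults follow the common histopathology recipe: both flips at probability
#' 0.5, rotations within plus/minus 15 degrees, and 10% color jitter.
#'
#' @param hflipProb,vflipProb flip probabilities.
#' @param maxRotation maximum absolute rotation angle in degrees.
#' @param brightnessDelta,contrastDelta,saturationDelta max fractional changes.
#' @param seed integer RNG seed.
#' @return an [AugmentSpec-class] object.
#' @export
augmentSpec <- function(hflipProb = 0.5, vflipProb = 0.5, maxRotation = 15,
                        brightnessDelta = 0.1, contrastDelta = 0.1,
                        saturationDelta = 0.1, seed = 1L) {
  new("AugmentSpec", hflipProb = hflipProb, vflipProb = vflipProb,
      maxRotation = maxRotation, brightnessDelta = brightnessDelta,
      contrastDelta = contrastDelta, saturationDelta = saturationDelta,
      seed = as.integer(seed))
}

#' SplitSpec: train/validation/test partition specification
#'
#' @slot ratios length-3 numeric `(train, val, test)` summing to 1.
#' @slot stratify logical; preserve per-class ratios within one item.
#' @slot seed integer RNG seed for the shuffle.
#' @export
setClass("SplitSpec",
  representation(ratios = "numeric", stratify = "logical", seed = "integer"),
  validity = function(object) {
    if (length(object@ratios) != 3L) return("ratios must have length 3")
    if (any(object@ratios < 0)) return("each ratio must be >= 0")
    if (abs(sum(object@ratios) - 1) > 1e-9)
      return("ratios must sum to 1 within 1e-9")
    TRUE
  }
)

#' Construct a SplitSpec
#'
#' @param ratios `(train, val, test)` fractions summing to 1; default the
#'   standard 70/15/15 split.
#' @param stratify stratify by class label.
#' @param seed integer RNG seed.
#' @return a [SplitSpec-class] object.
#' @export
splitSpec <- function(ratios = c(0.70, 0.15, 0.15), stratify = TRUE, seed = 1L) {
  new("SplitSpec", ratios = as.numeric(ratios), stratify = isTRUE(stratify),
      seed = as.integer(seed))
}

#' BackboneConfig: architecture of the dual-branch cross-attention transformer
#'
#' @slot imageSize input side length in px (square input).
#' @slot patchSmall,patchLarge patch side lengths of the two branches.
#' @slot dimSmall,dimLarge token embedding widths of the two branches.
#' @slot depth encoder layers per branch.
#' @slot heads self-attention heads (must divide both dims).
#' @slot mlpRatio FFN expansion factor.
#' @slot nCrossRounds bidirectional cross-attention fusion rounds.
#' @slot nClasses number of output classes.
#' @export
setClass("BackboneConfig",
  representation(imageSize = "integer", patchSmall = "integer",
                 patchLarge = "integer", dimSmall = "integer",
                 dimLarge = "integer", depth = "integer", heads = "integer",
                 mlpRatio = "numeric", nCrossRounds = "integer",
                 nClasses = "integer"),
  validity = function(object) {
    if (object@imageSize %% object@patchSmall != 0L)
      return("imageSize must be divisible by patchSmall")
    if (object@imageSize %% object@patchLarge != 0L)
      return("imageSize must be divisible by patchLarge")
    if (object@dimSmall %% object@heads != 0L ||
        object@dimLarge %% object@heads != 0L)
      return("embedding dims must be divisible by heads")
    if (object@depth < 1L) return("depth must be >= 1")
    if (object@nCrossRounds < 0L) return("nCrossRounds must be >= 0")
    if (object@nClasses < 2L) return("nClasses must be >= 2")
    TRUE
  }
)

#' TrainHistory: per-epoch loss curves of a trained classifier
#'
#' @slot trainLoss per-epoch training cross-entropy.
#' @slot valLoss per-epoch validation cross-entropy.
#' @slot bestEpoch epoch index (1-based) minimizing validation loss.
#' @slot bestValLoss validation cross-entropy at `bestEpoch`.
#' @export
setClass("TrainHistory",
  representation(trainLoss = "numeric", valLoss = "numeric",
                 bestEpoch = "integer", bestValLoss = "numeric"),
  validity = function(object) {
    if (length(object@trainLoss) != length(object@valLoss))
      return("train and validation curves must have equal length")
    if (length(object@valLoss) > 0) {
      if (object@bestEpoch < 1L || object@bestEpoch > length(object@valLoss))
        return("bestEpoch out of range")
      if (abs(object@bestValLoss - min(object@valLoss)) > 1e-12)
        return("bestValLoss must equal the minimum of the validation curve")
      if (abs(object@valLoss[object@bestEpoch] - object@bestValLoss) > 1e-12)
        return("bestEpoch must index the best validation loss")
    }
    TRUE
  }
)

#' CrossViT model object
#'
#' Bundles a [BackboneConfig-class] with its parameter list (patch embeddings,
#' CLS tokens, positional encodings, encoder layers, cross-attention blocks,
#' final layer norms and the two classification heads).
#'
#' @slot config the architecture configuration.
#' @slot params named list of parameter tensors.
#' @export
setClass("CrossViT",
  representation(config = "BackboneConfig", params = "list"))

#' DeepFeatures: per-branch CLS feature vectors
#'
#' @slot small CLS vector of the small-patch branch.
#' @slot large CLS vector of the large-patch branch.
#' @export
setClass("DeepFeatures",
  representation(small = "numeric", large = "numeric"))

#' FusedFeatures: deep CLS features concatenated with the handcrafted vector
#'
#' Per branch the layout is deep CLS first, then the 818-dim handcrafted
#' vector; `combined` is small-branch then large-branch.
#'
#' @slot small,large per-branch fused vectors.
#' @slot combined concatenation of `small` and `large`.
#' @export
setClass("FusedFeatures",
  representation(small = "numeric", large = "numeric", combined = "numeric"),
  validity = function(object) {
    if (!identical(object@combined, c(object@small, object@large)))
      return("combined must equal c(small, large)")
    TRUE
  }
)

#' FusionANN: the feed-forward fusion classifier
#'
#' One (or, in per-branch mode, two) single-hidden-layer perceptrons with
#' rectified-linear activation and a 2-class softmax output, plus the
#' train-split standardization statistics they were fitted with.
#'
#' @slot nets list of parameter lists (`W1`, `b1`, `W2`, `b2`) per sub-network.
#' @slot inputDims integer input width per sub-network.
#' @slot inputOffsets integer start offset (0-based) of each sub-network's
#'   slice of the full feature vector.
#' @slot center,scale lists of per-feature standardization statistics.
#' @slot standardize logical; whether inputs are standardized.
#' @slot mode `"joint"` (one net on the combined vector) or `"perbranch"`.
#' @export
setClass("FusionANN",
  representation(nets = "list", inputDims = "integer",
                 inputOffsets = "integer", center = "list", scale = "list",
                 standardize = "logical", mode = "character"))
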