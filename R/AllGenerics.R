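#' Accessors for package classes
#'
#' `images()`, `imageLabels()` and `imageTags()` extract the components of a
#' [HistoDataset-class]; `trainLoss()`, `valLoss()`, `bestEpoch()` and
#' `bestValLoss()` read a [TrainHistory-class]; `deepSmall()`/`deepLarge()`
#' read a [DeepFeatures-class] or the branch slices of a
#' [FusedFeatures-class]; `combinedFeatures()` the full fused vector.
#'
#' @param object the object to access.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("images", function(object) standardGeneric("images"))
#' @rdname accessors
#' @export
setGeneric("imageLabels", function(object) standardGeneric("imageLabels"))
#' @rdname accessors
#' @export
setGeneric("imageTags", function(object) standardGeneric("imageTags"))
#' @rdname accessors
#' @export
setGeneric("trainLoss", function(object) standardGeneric("trainLoss"))
#' @rdname accessors
#' @export
setGeneric("valLoss", function(object) standardGeneric("valLoss"))
#' @rdname accessors
#' @export
setGeneric("bestEpoch", function(object) standardGeneric("bestEpoch"))
#' @rdname accessors
#' @export
setGeneric("bestValLoss", function(object) standardGeneric("bestValLoss"))
#' @rdname accessors
#' @export
setGeneric("deepSmall", function(object) standardGeneric("deepSmall"))
#' @rdname accessors
#' @export
setGeneric("deepLarge", function(object) standardGeneric("deepLarge"))
#' @rdname accessors
#' @export
setGeneric("combinedFeatures", function(object) standardGeneric("combinedFeatures"))

#' @rdname accessors
#' @export
setMethod("images", "HistoDataset", function(object) object@images)
#' @rdname accessors
#' @export
setMethod("imageLabels", "HistoDataset", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("imageTags", "HistoDataset", function(object) object@tags)
#' @rdname accessors
#' @export
setMethod("trainLoss", "TrainHistory", function(object) object@trainLoss)
#' @rdname accessors
#' @export
setMethod("valLoss", "TrainHistory", function(object) object@valLoss)
#' @rdname accessors
#' @export
setMethod("bestEpoch", "TrainHistory", function(object) object@bestEpoch)
#' @rdname accessors
#' @export
setMethod("bestValLoss", "TrainHistory", function(object) object@bestValLoss)
#' @rdname accessors
#' @export
setMethod("deepSmall", "DeepFeatures", function(object) object@small)
#' @rdname accessors
#' @export
setMethod("deepLarge", "DeepFeatures", function(object) object@large)
#' @rdname accessors
#' @export
setMethod("deepSmall", "FusedFeatures", function(object) object@small)
#' @rdname accessors
#' @export
setMethod("deepLarge", "FusedFeatures", function(object) object@large)
#' @rdname accessors
#' @export
setMethod("combinedFeatures", "FusedFeatures", function(object) object@combined)

#' Number of images in a dataset
#' @param x a [HistoDataset-class].
#' @return integer count.
#' @export
setMethod("length", "HistoDataset", function(x) length(x@images))

#' Subset a dataset
#' @param x a [HistoDataset-class].
#' @param i index vector.
#' @param j,...,drop ignored.
#' @return a [HistoDataset-class] with the selected images.
#' @export
setMethod("[", "HistoDataset", function(x, i, j, ..., drop = FALSE) {
  new("HistoDataset", images = x@images[i], labels = x@labels[i],
      tags = x@tags[i])
})

setMethod("show", "RGBImage", function(object) {
  d <- dim(object)
  cat(sprintf("RGBImage %d x %d, 8-bit RGB (range %d..%d)\n",
              d[1], d[2], min(object), max(object)))
})

setMethod("show", "HistoDataset", function(object) {
  n <- length(object)
  cat(sprintf("HistoDataset with %d images (%d normal, %d malignant)\n",
              n, sum(object@labels == 1L), sum(object@labels == 2L)))
  if (n > 0) {
    d <- dim(object@images[[1]])
    cat(sprintf("  first image: %d x %d\n", d[1], d[2]))
  }
})

setMethod("show", "ClassAppearance", function(object) {
  cat(sprintf(paste0("ClassAppearance: background hue %.1f deg (sat %.2f), ",
                     "nucleus hue %.1f deg,\n  density %.1f/10^4 px^2, radius ",
                     "%.1f +/- %.1f px, grain %.1f px, jitter sd %.1f\n"),
              object@backgroundHue, object@backgroundSat, object@nucleusHue,
              object@nucleusDensity, object@nucleusRadius[1],
              object@nucleusRadius[2], object@textureGrain, object@jitterSd))
})

setMethod("show", "BackboneConfig", function(object) {
  cat(sprintf(paste0("BackboneConfig: image %d, patches %d/%d, dims %d/%d,\n",
                     "  depth %d, heads %d, mlpRatio %.1f, crossRounds %d, ",
                     "classes %d\n"),
              object@imageSize, object@patchSmall, object@patchLarge,
              object@dimSmall, object@dimLarge, object@depth, object@heads,
              object@mlpRatio, object@nCrossRounds, object@nClasses))
})

setMethod("show", "CrossViT", function(object) {
  np <- sum(vapply(object@params, function(p) length(unlist(p)), numeric(1)))
  cat("CrossViT dual-branch cross-attention transformer\n")
  show(object@config)
  cat(sprintf("  parameters: %s values\n", format(np, big.mark = ",")))
})

setMethod("show", "TrainHistory", function(object) {
  cat(sprintf(paste0("TrainHistory: %d epochs, best validation cross-entropy ",
                     "%.6f at epoch %d\n"),
              length(object@valLoss), object@bestValLoss, object@bestEpoch))
})

setMethod("show", "DeepFeatures", function(object) {
  cat(sprintf("DeepFeatures: CLS dims (small %d, large %d)\n",
              length(object@small), length(object@large)))
})

setMethod("show", "FusedFeatures", function(object) {
  cat(sprintf("FusedFeatures: branch dims (%d, %d), combined %d\n",
              length(object@small), length(object@large),
              length(object@combined)))
})

setMethod("show", "FusionANN", function(object) {
  cat(sprintf("FusionANN (%s): %d sub-network(s), input dims %s\n",
              object@mode, length(object@nets),
              paste(object@inputDims, collapse = "/")))
})
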