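# Handcrafted feature fusion and batch extraction.

#' The 818-dimensional handcrafted feature vector
#'
#' Concatenates, in fixed order, the fuzzy color histogram (768), the LBP
#' histogram (26) and the GLCM statistics (24): positions 1..768 are FCH,
#' 769..794 LBP, 795..818 GLCM. Slicing the result at those ranges reproduces
#' the three extractor outputs bit-exactly.
#'
#' @param image an [RGBImage-class] valid for all three extractors.
#' @return named numeric vector of length 818.
#' @seealso [fchFeatures()], [lbpFeatures()], [glcmFeatures()]
#' @export
handcraftedVector <- function(image) {
  c(fchFeatures(image), lbpFeatures(image), glcmFeatures(image))
}

#' Handcrafted features for every image in a dataset
#'
#' @param dataset a [HistoDataset-class].
#' @return numeric matrix, one row per image, 818 named columns.
#' @export
handcraftedMatrix <- function(dataset) {
  stopifnot(is(dataset, "HistoDataset"))
  t(vapply(images(dataset), handcraftedVector, numeric(818)))
}

#' Write a per-image feature table
#'
#' One row per image with columns `path` (or a running id), `label`, and the
#' feature columns (`fch_000`..., `lbp_00`..., `glcm_00`..., plus any deep
#' feature columns when a backbone model is supplied).
#'
#' @param dataset a [HistoDataset-class].
#' @param file output CSV path.
#' @param model optional [CrossViT-class]; when given, per-branch fused
#'   vectors (deep CLS then handcrafted, small branch then large) are written
#'   instead of the handcrafted block alone.
#' @return invisibly, the feature data.frame.
#' @export
writeFeatureTable <- function(dataset, file, model = NULL) {
  stopifnot(is(dataset, "HistoDataset"))
  feat <- if (is.null(model)) handcraftedMatrix(dataset)
          else fusedMatrix(dataset, model)
  df <- data.frame(id = sprintf("img_%04d", seq_len(length(dataset))),
                   label = imageLabels(dataset), check.names = FALSE)
  df <- cbind(df, as.data.frame(feat, check.names = FALSE))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
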