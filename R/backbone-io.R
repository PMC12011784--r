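# Self-describing tensor archives (plain JSON) for backbone and classifier
# weights: a manifest of named tensors with explicit shapes, so archives can
# be inspected, diffed, and partially loaded by name.

.flattenTensors <- function(x, prefix = "") {
  if (is.list(x)) {
    out <- list()
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    for (i in seq_along(x)) {
      nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, .flattenTensors(x[[i]],
                                    if (nzchar(prefix)) paste0(prefix, ".", nm)
                                    else nm))
    }
    out
  } else {
    shape <- if (is.matrix(x)) dim(x) else length(x)
    stats::setNames(list(list(shape = as.integer(shape),
                              values = as.numeric(x))), prefix)
  }
}

.assignTensor <- function(params, path, value) {
  key <- path[1]
  if (grepl("^[0-9]+$", key)) key <- as.integer(key)
  if (length(path) == 1L) {
    params[[key]] <- value
    return(params)
  }
  params[[key]] <- .assignTensor(params[[key]], path[-1], value)
  params
}

#' Save backbone weights to a tensor archive
#'
#' Writes a plain-JSON archive (`format: histofuse-tensor-archive`) holding
#' every parameter as a named tensor with an explicit shape, plus the model
#' configuration.
#'
#' @param model a [CrossViT-class].
#' @param path output `.json` path.
#' @return invisibly, `path`.
#' @export
saveWeights <- function(model, path) {
  stopifnot(is(model, "CrossViT"))
  flat <- .flattenTensors(model@params)
  cfg <- model@config
  doc <- list(format = "histofuse-tensor-archive", version = 1L,
              config = list(imageSize = cfg@imageSize,
                            patchSmall = cfg@patchSmall,
                            patchLarge = cfg@patchLarge,
                            dimSmall = cfg@dimSmall, dimLarge = cfg@dimLarge,
                            depth = cfg@depth, heads = cfg@heads,
                            mlpRatio = cfg@mlpRatio,
                            nCrossRounds = cfg@nCrossRounds,
                            nClasses = cfg@nClasses),
              tensors = lapply(names(flat), function(nm)
                list(name = nm, shape = flat[[nm]]$shape,
                     values = flat[[nm]]$values)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load pretrained weights into a backbone
#'
#' Replaces every model parameter whose name and shape match a tensor in the
#' archive. Tensors present in the archive under names the model does not
#' have, and model tensors the archive lacks, are reported unmatched; a
#' matching name with a conflicting shape is an error naming the tensor.
#'
#' @param model a [CrossViT-class] to receive the weights.
#' @param path path to an archive written by [saveWeights()].
#' @return list with `model` (updated), `matched`, `unmatchedArchive`,
#'   `unmatchedModel` (character vectors of tensor names).
#' @export
loadPretrained <- function(model, path) {
  stopifnot(is(model, "CrossViT"))
  if (!file.exists(path)) stop("weight archive not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "histofuse-tensor-archive"))
    stop("not a histofuse tensor archive: ", path)
  flat <- .flattenTensors(model@params)
  params <- model@params
  matched <- character(0)
  unmatchedArchive <- character(0)
  for (tensor in doc$tensors) {
    nm <- tensor$name
    if (!nm %in% names(flat)) {
      unmatchedArchive <- c(unmatchedArchive, nm)
      next
    }
    want <- flat[[nm]]$shape
    got <- as.integer(tensor$shape)
    if (!identical(as.integer(want), got))
      stop("shape conflict for tensor '", nm, "': archive ",
           paste(got, collapse = "x"), ", model ",
           paste(want, collapse = "x"))
    value <- as.numeric(tensor$values)
    if (length(got) == 2L) value <- matrix(value, got[1], got[2])
    params <- .assignTensor(params, strsplit(nm, ".", fixed = TRUE)[[1]],
                            value)
    matched <- c(matched, nm)
  }
  list(model = new("CrossViT", config = model@config, params = params),
       matched = matched, unmatchedArchive = unmatchedArchive,
       unmatchedModel = setdiff(names(flat), matched))
}

#' Save a fusion classifier to a tensor archive
#'
#' @param model a [FusionANN-class].
#' @param path output `.json` path.
#' @return invisibly, `path`.
#' @export
saveFusionANN <- function(model, path) {
  stopifnot(is(model, "FusionANN"))
  flat <- .flattenTensors(list(nets = model@nets, center = model@center,
                               scale = model@scale))
  doc <- list(format = "histofuse-tensor-archive", version = 1L,
              meta = list(kind = "FusionANN", mode = model@mode,
                          standardize = model@standardize,
                          inputDims = model@inputDims,
                          inputOffsets = model@inputOffsets),
              tensors = lapply(names(flat), function(nm)
                list(name = nm, shape = flat[[nm]]$shape,
                     values = flat[[nm]]$values)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a fusion classifier from a tensor archive
#'
#' @param path archive written by [saveFusionANN()].
#' @return a [FusionANN-class].
#' @export
loadFusionANN <- function(path) {
  if (!file.exists(path)) stop("weight archive not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "histofuse-tensor-archive") ||
      !identical(doc$meta$kind, "FusionANN"))
    stop("not a FusionANN tensor archive: ", path)
  store <- list(nets = list(), center = list(), scale = list())
  nNets <- length(doc$meta$inputDims)
  store$nets <- replicate(nNets, list(), simplify = FALSE)
  store$center <- replicate(nNets, numeric(0), simplify = FALSE)
  store$scale <- replicate(nNets, numeric(0), simplify = FALSE)
  for (tensor in doc$tensors) {
    shape <- as.integer(tensor$shape)
    value <- as.numeric(tensor$values)
    if (length(shape) == 2L) value <- matrix(value, shape[1], shape[2])
    store <- .assignTensor(store, strsplit(tensor$name, ".",
                                           fixed = TRUE)[[1]], value)
  }
  new("FusionANN", nets = store$nets,
      inputDims = as.integer(doc$meta$inputDims),
      inputOffsets = as.integer(doc$meta$inputOffsets),
      center = store$center, scale = store$scale,
      standardize = isTRUE(doc$meta$standardize), mode = doc$meta$mode)
}
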