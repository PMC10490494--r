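# Checkpoints: models are serialized in R's native format with a JSON
# sidecar carrying the architecture hyperparameters (and, for cluster
# models, the centroids and class mapping) for backend-independent reuse.

specToList <- function(spec) {
  nms <- slotNames(class(spec))
  out <- lapply(nms, function(nm) slot(spec, nm))
  names(out) <- nms
  out
}

#' Save a model checkpoint
#'
#' Writes `<path>` (native serialization) and `<path>.json` (a sidecar
#' with the class, architecture and network specification).
#'
#' @param model a [CAEModel-class] or [SegModel-class].
#' @param path destination file (conventionally `.rds`).
#' @return invisibly, `path`.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "CAEModel") || is(model, "SegModel"))
  saveRDS(model, path)
  sidecar <- list(class = class(model)[1],
                  arch = if (is(model, "SegModel")) model@arch else "cae",
                  trained = model@trained,
                  spec = specToList(model@spec))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [saveModel()]
#'
#' @param path checkpoint file.
#' @return the model object.
#' @export
loadModel <- function(path) {
  if (!file.exists(path))
    stop("checkpoint not found: ", path, call. = FALSE)
  model <- readRDS(path)
  if (!(is(model, "CAEModel") || is(model, "SegModel")))
    stop("not a model checkpoint: ", path, call. = FALSE)
  model
}

#' Save a cluster model as JSON
#'
#' Centroids, inertia and the cluster-to-class mapping are plain numbers,
#' so the whole model round-trips through JSON.
#'
#' @param clusterModel a [ClusterModel-class].
#' @param path destination `.json`.
#' @return invisibly, `path`.
#' @export
saveClusterModel <- function(clusterModel, path) {
  stopifnot(is(clusterModel, "ClusterModel"))
  jsonlite::write_json(
    list(centroids = clusterModel@centroids,
         inertia = clusterModel@inertia,
         classOfCluster = clusterModel@classOfCluster),
    path, auto_unbox = TRUE, digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Load a cluster model saved by [saveClusterModel()]
#'
#' @param path `.json` file.
#' @return a [ClusterModel-class].
#' @export
loadClusterModel <- function(path) {
  if (!file.exists(path))
    stop("cluster model not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mapping <- as.integer(obj$classOfCluster)
  if (length(mapping) != 2L) mapping <- c(NA_integer_, NA_integer_)
  new("ClusterModel", centroids = matrix(obj$centroids, nrow = 2L),
      inertia = as.numeric(obj$inertia), classOfCluster = mapping)
}
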