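# Model serialization: both trained components round-trip through small
# JSON files so a reference built on one machine can be scored on another.

#' Write / read a fragment-length model
#'
#' The model is stored as its evaluator — the clamped, renormalized
#' per-length probabilities — together with the smoothing parameter and
#' support, so reloading reproduces `pf_eval()` exactly.
#'
#' @param model A `fraglen_model`.
#' @param path Output JSON path.
#' @return `write_fraglen_model()`: the path, invisibly.
#' @export
write_fraglen_model <- function(model, path) {
  stopifnot(inherits(model, "fraglen_model"))
  jsonlite::write_json(
    list(type = "fraglen_model", smoothing = model$smoothing,
         support = model$support, probs = model$probs),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_fraglen_model
#' @export
read_fraglen_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$type, "fraglen_model")) stop("not a fraglen_model file")
  m <- new_fraglen_model(x$probs, smoothing = x$smoothing)
  m
}

#' Write / read a binding-affinity model
#'
#' Stores the window width, architecture, weights and training metadata.
#'
#' @param model A `binding_model`.
#' @param path Output JSON path.
#' @return `write_binding_model()`: the path, invisibly.
#' @export
write_binding_model <- function(model, path) {
  stopifnot(inherits(model, "binding_model"))
  layers <- lapply(model$layers, function(l) {
    list(W = as.numeric(l$W), dim = dim(l$W), b = l$b)
  })
  jsonlite::write_json(
    list(type = "binding_model", W = model$W, metadata = model$metadata,
         layers = layers),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_binding_model
#' @export
read_binding_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(x$type, "binding_model")) stop("not a binding_model file")
  layers <- lapply(x$layers, function(l) {
    list(W = matrix(l$W, nrow = l$dim[1L], ncol = l$dim[2L]),
         b = as.numeric(l$b))
  })
  structure(list(layers = layers, W = as.integer(x$W), metadata = x$metadata),
            class = "binding_model")
}
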