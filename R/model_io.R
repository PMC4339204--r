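# JSON serialization of trained forests and feature descriptors.
#
# Numbers are written with 17 significant digits so thresholds and leaf
# statistics round-trip exactly; predictions after a save/load cycle are
# bit-identical to the original model's.

MODEL_FORMAT_VERSION <- "1.0"

descriptor_to_list <- function(d) {
  Filter(Negate(is.null), unclass(d))
}

descriptor_from_list <- function(l) {
  do.call(feature_descriptor, l)
}

node_to_list <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", mean = node$mean, var = node$var, n = node$n)
  } else {
    list(type = "split", descriptor = descriptor_to_list(node$descriptor),
         tau = node$tau, gain = node$gain,
         left = node_to_list(node$left), right = node_to_list(node$right))
  }
}

node_from_list <- function(l) {
  if (l$type == "leaf") {
    list(type = "leaf", mean = l$mean, var = l$var, n = l$n)
  } else {
    list(type = "split", descriptor = descriptor_from_list(l$descriptor),
         tau = l$tau, gain = l$gain,
         left = node_from_list(l$left), right = node_from_list(l$right))
  }
}

#' Write a trained forest as JSON
#' @export
write_forest <- function(forest, path) {
  stopifnot(inherits(forest, "age_forest"))
  obj <- list(format_version = MODEL_FORMAT_VERSION,
              hemisphere = forest$hemisphere,
              banks = forest$banks,
              hyperparams = unclass(forest$hp),
              trees = lapply(forest$trees, node_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = FALSE)
  invisible(path)
}

#' Read a trained forest from JSON
#'
#' Refuses models written with a different format version; a corrupted
#' file raises a parse error without producing a partial model.
#' @export
read_forest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format_version) ||
      !identical(obj$format_version, MODEL_FORMAT_VERSION))
    stop("model format version mismatch: file has ",
         if (is.null(obj$format_version)) "<none>" else obj$format_version,
         ", reader supports ", MODEL_FORMAT_VERSION)
  hp <- do.call(forest_hyperparams, obj$hyperparams[
    setdiff(names(obj$hyperparams), character(0))])
  structure(list(trees = lapply(obj$trees, node_from_list),
                 hp = hp,
                 hemisphere = obj$hemisphere,
                 banks = unlist(obj$banks),
                 format_version = obj$format_version),
            class = "age_forest")
}
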