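#' Serialize a trained SRPS model to a flat JSON file
#'
#' Version-stamped plain-text serialization of the classifier weights, the
#' baseline parameters and the training configuration.
#'
#' @param model An `srps_model`.
#' @param path Output path.
#' @export
write_srps_model <- function(model, path) {
  payload <- list(
    format = "srps_model",
    version = 1L,
    config = unclass(model$config),
    theta = model$theta,
    proteins = colnames(model$theta),
    b_c = model$b_c,
    baseline = if (!is.null(model$baseline)) lapply(model$baseline, unclass))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a serialized SRPS model
#'
#' @param path Path written by [write_srps_model()].
#' @return An `srps_model`.
#' @export
read_srps_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "srps_model")) stop("not an srps model file")
  cfg <- do.call(srps_config, p$config[setdiff(names(p$config), c("k", "d"))] |>
                   c(list(k = p$config$k, d = p$config$d)))
  theta <- matrix(unlist(p$theta), nrow = cfg$k, byrow = FALSE)
  if (!is.null(dim(p$theta))) theta <- p$theta
  colnames(theta) <- p$proteins
  baseline <- NULL
  if (!is.null(p$baseline)) {
    baseline <- p$baseline
    for (nm in c("W1", "W2", "W3")) baseline[[nm]] <- as.matrix(baseline[[nm]])
    baseline$b3 <- as.numeric(baseline$b3)
  }
  new_srps_model(theta, baseline, as.numeric(p$b_c), cfg)
}
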