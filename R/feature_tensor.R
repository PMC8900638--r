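#' Feature tensor
#'
#' A trials x windows x features numeric array with a named feature axis, as
#' produced by [extract_feature_set()]. Per-trial rows of window vectors are
#' the sequence input of the classifier.
#'
#' @param values numeric 3-d array, trials x windows x features.
#' @param feature_names character vector matching `dim(values)[3]`.
#' @param window_spec optional [window_spec()] provenance.
#' @param provenance optional named list of metadata (fs, weighting, flags...).
#' @return An object of class `feature_tensor`.
#' @export
feature_tensor <- function(values, feature_names, window_spec = NULL,
                           provenance = list()) {
  if (length(dim(values)) != 3L)
    stop_validation("`values` must be a trials x windows x features array")
  feature_names <- as.character(feature_names)
  if (dim(values)[3L] != length(feature_names))
    stop_validation("feature axis does not match the inventory length")
  if (anyDuplicated(feature_names))
    stop_validation("feature names must be unique")
  if (length(values) && !all(is.finite(values)))
    stop_validation("feature tensor contains non-finite values")
  dimnames(values) <- list(NULL, NULL, feature_names)
  structure(list(values = values, feature_names = feature_names,
                 window_spec = window_spec, provenance = provenance),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_tensor> %d trials x %d windows x %d features\n",
              d[1L], d[2L], d[3L]))
  cat("  features:", paste(head(x$feature_names, 6L), collapse = ", "),
      if (d[3L] > 6L) "..." else "", "\n")
  if (length(x$provenance$flags))
    cat(sprintf("  %d extraction flags\n", length(x$provenance$flags)))
  invisible(x)
}

#' @export
dim.feature_tensor <- function(x) dim(x$values)
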