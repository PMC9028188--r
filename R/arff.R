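#' Write a data frame to ARFF
#'
#' Numeric columns become numeric attributes; factor columns become nominal
#' attributes. Classification exports must carry a nominal `class` column.
#'
#' @param df Data frame to write.
#' @param path Output file path.
#' @param relation Relation name recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_gait_arff <- function(df, path, relation = "gait") {
  if (nrow(df) == 0) stopf("refusing to write empty ARFF file '%s'", path)
  ok <- tryCatch({
    foreign::write.arff(as.data.frame(df), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("failed to write ARFF '%s': %s", path,
                         conditionMessage(ok))
  # foreign::write.arff leaves the relation name empty; fill it in
  lines <- readLines(path)
  rel <- grep("^@relation", lines, ignore.case = TRUE)
  if (length(rel)) lines[rel[1]] <- paste("@relation", relation)
  writeLines(lines, path)
  invisible(path)
}

#' Read an ARFF dataset
#'
#' @param path ARFF file path.
#' @param require_class If `TRUE` (default), error unless the file declares a
#'   nominal `class` attribute.
#' @return A tibble; the `class` column (if present) is a factor.
#' @export
read_gait_arff <- function(path, require_class = TRUE) {
  if (!file.exists(path)) stopf("ARFF file not found: '%s'", path)
  df <- tryCatch(foreign::read.arff(path), error = function(e) {
    stopf("failed to parse ARFF '%s': %s", path, conditionMessage(e))
  })
  if (require_class && !"class" %in% names(df)) {
    stopf("ARFF file '%s' declares no 'class' attribute", path)
  }
  if (require_class && !is.factor(df$class)) {
    stopf("ARFF attribute 'class' in '%s' is not nominal", path)
  }
  tibble::as_tibble(df)
}
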