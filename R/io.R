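#' Write a dataset to plain CSV with a JSON sidecar
#'
#' The CSV holds columns `y` (and `w` when present); the sidecar
#' `<path>.json` records the family, generating parameters and seed so a
#' dataset is fully reproducible and reloadable.
#'
#' @param data an [eiv_data()] object.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  df <- data.frame(y = data$y)
  if (!is.null(data$w)) df$w <- data$w
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(family = data$family, n = data$n,
               true_theta = as.list(data$true_theta), seed = data$seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path CSV file path (the `<path>.json` sidecar is read if present).
#' @return an [eiv_data()] object.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  theta <- if (length(side$true_theta)) unlist(side$true_theta)
  eiv_data(df$y, if ("w" %in% names(df)) df$w,
           family = side$family, true_theta = theta, seed = side$seed)
}
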