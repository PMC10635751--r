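#' Read a one-column sample of positive reals from CSV
#'
#' The file must contain a single column of strictly positive numbers,
#' with or without a header line `value`.  Non-positive, missing, or
#' non-numeric entries are rejected with the offending row indices.
#'
#' @param path path to the CSV file.
#' @return a numeric vector.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("value", "1.5", "2", "0.3"), f)
#' read_sample_csv(f)
#' @export
read_sample_csv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(trimws(strsplit(
    first, ",", fixed = TRUE)[[1]][1]))))
  d <- utils::read.csv(path, header = has_header,
                       col.names = "value", colClasses = "character")
  v <- suppressWarnings(as.numeric(trimws(d$value)))
  bad <- which(is.na(v) | v <= 0)
  if (length(bad))
    stop(sprintf("non-positive or non-numeric sample values at data rows %s of '%s'",
                 paste(bad, collapse = ", "), path), call. = FALSE)
  v
}
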