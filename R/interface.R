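# Data access and plain-text sample input.

#' COVID-19 full-vaccination rates for 46 African countries
#'
#' The number of persons fully vaccinated against COVID-19 per 100
#' inhabitants in 46 African countries, recorded during the 2021 rollout.
#' Values range from 0.042 to 72.286 and the distribution is strongly
#' right-skewed (mean 9.80, median 3.17), which is what makes it a natural
#' test bed for heavy-tailed lifetime families.
#'
#' @return a numeric vector of length 46, sorted increasingly.
#' @examples
#' x <- covid_vaccination_africa()
#' length(x)   # 46
#' summary(x)
#' @export
covid_vaccination_africa <- function() {
  path <- system.file("extdata", "covid_vaccination_africa.txt",
                      package = "olinh", mustWork = TRUE)
  read_sample(path)
}

#' Read a univariate positive sample from a text file
#'
#' Parses one strictly positive real value per line (a single-column CSV
#' with an optional non-numeric header line is also accepted) and
#' preserves the input order.
#'
#' @param path path to the file, or the name of a packaged data set
#'   (currently `"covid_vaccination_africa"`).
#' @return numeric vector of the parsed values.
#' @export
read_sample <- function(path) {
  if (identical(path, "covid_vaccination_africa"))
    return(covid_vaccination_africa())
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  first_data <- 1L
  if (length(lines) && is.na(suppressWarnings(as.numeric(lines[1L]))) &&
      nzchar(lines[1L]))
    first_data <- 2L  # header line
  lines <- lines[seq.int(first_data, length.out = max(0L, length(lines) - first_data + 1L))]
  keep <- nzchar(lines)
  vals <- suppressWarnings(as.numeric(lines[keep]))
  line_no <- which(keep) + first_data - 1L
  bad <- which(is.na(vals) | vals <= 0)
  if (!length(vals))
    stop("no data values found in ", path, call. = FALSE)
  if (length(bad))
    stop(sprintf("invalid sample value at line %d of %s: '%s' (must be a positive number)",
                 line_no[bad[1L]], path, lines[keep][bad[1L]]), call. = FALSE)
  vals
}
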