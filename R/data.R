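#' Longitudinal binary dataset
#'
#' Validates and tags a long-format data frame of repeated binary outcomes:
#' one row per subject-occasion, a strictly 0/1 outcome column, and any number
#' of covariate columns.  Within a subject, occasion times must be distinct.
#'
#' @param data a data frame in long format.
#' @param id name of the subject-identifier column.
#' @param time name of the occasion-time column (months, round index, ...).
#' @param y name of the 0/1 outcome column.
#' @return an object of class `longData` (a data frame carrying `id_col`,
#'   `time_col` and `y_col` attributes).
#' @examples
#' d <- data.frame(id = c(1, 1, 2), time = c(0, 2, 0), y = c(0, 1, 1))
#' ld <- longData(d)
#' nSubjects(ld)
#' @export
longData <- function(data, id = "id", time = "time", y = "y") {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(id, time, y), names(data))
  if (length(missing_cols)) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "))
  }
  yv <- data[[y]]
  bad <- which(!(yv %in% c(0L, 1L)) | is.na(yv))
  if (length(bad)) {
    stop("outcome column '", y, "' must be exactly 0 or 1; offending row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "")
  }
  if (anyNA(data[[time]])) stop("missing values in time column '", time, "'")
  if (anyNA(data[[id]])) stop("missing values in id column '", id, "'")
  dup <- which(duplicated(data[, c(id, time)]))
  if (length(dup)) {
    stop("duplicate (id, time) pairs; offending row(s): ",
         paste(utils::head(dup, 10L), collapse = ", "))
  }
  data[[y]] <- as.integer(yv)
  structure(data,
            id_col = id, time_col = time, y_col = y,
            class = c("longData", "data.frame"))
}

#' @export
print.longData <- function(x, ...) {
  cat("Longitudinal binary dataset: ",
      nObs(x), " observations on ", nSubjects(x), " subjects\n", sep = "")
  cat("  id: '", attr(x, "id_col"), "'  time: '", attr(x, "time_col"),
      "'  outcome: '", attr(x, "y_col"), "'\n", sep = "")
  covs <- covariateNames(x)
  cat("  covariates: ",
      if (length(covs)) paste(covs, collapse = ", ") else "(none)", "\n",
      sep = "")
  cat("  outcome mean: ", signif(mean(outcomes(x)), 4), "\n", sep = "")
  invisible(x)
}

#' @rdname longData
#' @param x a `longData` object.
#' @export
nSubjects <- function(x) length(unique(subjectIds(x)))

#' @rdname longData
#' @export
nObs <- function(x) nrow(x)

#' @rdname longData
#' @export
subjectIds <- function(x) x[[attr(x, "id_col")]]

#' @rdname longData
#' @export
occasionTimes <- function(x) x[[attr(x, "time_col")]]

#' @rdname longData
#' @export
outcomes <- function(x) x[[attr(x, "y_col")]]

#' @rdname longData
#' @export
covariateNames <- function(x) {
  setdiff(names(x), c(attr(x, "id_col"), attr(x, "y_col")))
}

# subject index as consecutive integers in order of first appearance
subjectIndex <- function(x) {
  ids <- subjectIds(x)
  match(ids, unique(ids))
}

#' Read / write long-format CSV
#'
#' `readLongCSV()` reads a comma-separated long-format file (header required,
#' "." decimal) and validates it into a [longData] object; `writeLongCSV()`
#' writes one back out so that a read/write round trip is the identity.
#'
#' @param path file path.
#' @inheritParams longData
#' @return `readLongCSV()` a [longData]; `writeLongCSV()` the path, invisibly.
#' @export
readLongCSV <- function(path, id = "id", time = "time", y = "y") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  longData(df, id = id, time = time, y = y)
}

#' @rdname readLongCSV
#' @param data a [longData] (or plain data frame) to write.
#' @export
writeLongCSV <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
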