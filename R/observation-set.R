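#' Labelled univariate observations with an ordering flag
#'
#' The universal input of the package: a set of logically comparable
#' measurements (for example annual percentage compliance per hospital ward,
#' on the 0-100 scale), each carrying an opaque label, plus a flag stating
#' whether the records have an inherent order (a time series does; a set of
#' wards measured over the same year does not).  Stored as a tibble with
#' columns `label` and `value` and attributes `has_inherent_order` and
#' `unit_label`; row order is preserved everywhere and is treated as the
#' "original" ordering of the data.
#'
#' @param values Numeric vector of finite measurements, length >= 2.
#' @param labels Optional character vector of unique record identifiers;
#'   defaults to `obs_01`, `obs_02`, ...
#' @param ordered Logical; `TRUE` if the records carry an inherent order.
#' @param unit Free-text unit label, e.g. `"% compliance"`.
#' @return A tibble of class `observation_set` with columns `label`, `value`.
#' @examples
#' obs <- observation_set(c(10, 20, 30), c("w1", "w2", "w3"))
#' has_inherent_order(obs)
#' @export
observation_set <- function(values, labels = NULL, ordered = FALSE, unit = "") {
  if (!is.numeric(values)) {
    stop("non-numeric value: measurements must be numeric", call. = FALSE)
  }
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) {
    stop("insufficient data: need at least 2 observations", call. = FALSE)
  }
  if (anyNA(values)) stop("missing value in observations", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("non-numeric value: measurements must be finite", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- sprintf("obs_%0*d", max(2L, nchar(n)), seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("labels and values must have the same length", call. = FALSE)
  }
  if (anyDuplicated(labels) > 0) {
    stop("duplicate label: record identifiers must be unique", call. = FALSE)
  }
  out <- tibble::tibble(label = labels, value = values)
  class(out) <- c("observation_set", class(out))
  attr(out, "has_inherent_order") <- isTRUE(ordered)
  attr(out, "unit_label") <- unit
  out
}

#' @rdname observation_set
#' @param data An `observation_set`.
#' @export
has_inherent_order <- function(data) {
  isTRUE(attr(data, "has_inherent_order"))
}

#' @rdname observation_set
#' @export
unit_label <- function(data) {
  u <- attr(data, "unit_label")
  if (is.null(u)) "" else u
}

#' Read observations from a CSV file
#'
#' Expects a UTF-8 comma-separated file with header `label,value`, decimal
#' point `.`, one record per row.  File row order is preserved as the
#' original ordering of the data; reading never reorders rows.  Malformed
#' input is rejected with a distinct, identified failure: missing header,
#' blank/missing values, non-numeric values, duplicate labels, fewer than
#' two rows.
#'
#' @param path Path to a CSV file with columns `label,value`.
#' @param ordered Logical; do the records carry an inherent order?
#' @param unit Free-text unit label attached to the result.
#' @return An [observation_set()].
#' @seealso [write_observations()]
#' @export
read_observations <- function(path, ordered = FALSE, unit = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!identical(names(raw), c("label", "value"))) {
    stop("malformed CSV: expected header `label,value`", call. = FALSE)
  }
  v <- raw$value
  if (anyNA(v) || any(trimws(v) == "")) {
    stop("missing value at row(s) ",
      paste(which(is.na(v) | trimws(v) == ""), collapse = ", "),
      call. = FALSE
    )
  }
  num <- suppressWarnings(as.numeric(v))
  if (anyNA(num)) {
    stop("non-numeric value at row(s) ",
      paste(which(is.na(num)), collapse = ", "),
      call. = FALSE
    )
  }
  observation_set(num, raw$label, ordered = ordered, unit = unit)
}

#' Write observations to CSV
#'
#' Inverse of [read_observations()]: writes `label,value` rows in the
#' current row order, full precision.
#'
#' @param data An [observation_set()] (or any data frame with `label` and
#'   `value` columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(data, path) {
  readr::write_csv(tibble::tibble(
    label = obs_labels(data),
    value = obs_values(data)
  ), path)
  invisible(path)
}
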