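#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

# Classed conditions so callers (and tests) can distinguish bad inputs from
# malformed files and invalid simulator configurations.
stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "metscreen_input_error")
}
stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "metscreen_format_error")
}
stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "metscreen_config_error")
}

GROUP_LEVELS <- c("control", "case")

#' Coerce a group label vector to a case indicator
#'
#' Accepts `"case"`/`"control"` character or factor vectors, logical vectors
#' (`TRUE` = case), or 0/1 numeric vectors. Returns a logical vector with
#' `TRUE` for cases.
#'
#' @param labels group labels.
#' @return logical vector, `TRUE` for case samples.
#' @keywords internal
#' @noRd
case_indicator <- function(labels) {
  if (is.logical(labels)) {
    ind <- labels
  } else if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop_input("numeric labels must be 0/1 (1 = case)")
    }
    ind <- labels == 1
  } else {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), GROUP_LEVELS)
    if (length(bad) > 0) {
      stop_input("unknown group label(s): %s (expected 'case'/'control')",
                 paste(bad, collapse = ", "))
    }
    ind <- labels == "case"
  }
  if (anyNA(ind)) stop_input("group labels contain missing values")
  ind
}

require_both_classes <- function(labels) {
  ind <- case_indicator(labels)
  if (!any(ind) || all(ind)) {
    stop_input("both cases and controls are required (got %d cases / %d controls)",
               sum(ind), sum(!ind))
  }
  ind
}

# Columns in a cohort/Z-score tibble that are not metabolites.
ID_COLS <- c("sample_id", "group")

metabolite_ids <- function(data) setdiff(names(data), ID_COLS)

# Extract the numeric samples x metabolites matrix from a cohort tibble.
met_matrix <- function(data) {
  mets <- metabolite_ids(data)
  if (length(mets) == 0) stop_input("no metabolite columns found")
  m <- as.matrix(data[mets])
  if (!is.numeric(m)) stop_input("metabolite columns must be numeric")
  rownames(m) <- data$sample_id
  m
}

# round() in R is round-half-even; printed report tables use the conventional
# round-half-up at a fixed number of decimals.
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

check_probability <- function(p, what = "p-values") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_input("%s must be numeric values in [0, 1]", what)
  }
  invisible(p)
}

# Derive a stage seed from a global seed; keeps results independent across
# stages while remaining reproducible, and stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147480000L
}
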