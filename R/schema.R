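#' Declare a discrete clinical variable
#'
#' A variable spec names a variable, declares its role (ordinary attribute or
#' the class to be predicted), its ordered state labels (coded as consecutive
#' integers starting at 0), and, for variables measured on a continuous scale,
#' the interval edges used to discretize raw measurements.
#'
#' Intervals are half-open. With `closed = "left"` interval `j` is
#' `[edge_j, edge_{j+1})` and the last interval is closed on the right; with
#' `closed = "right"` interval `j` is `(edge_j, edge_{j+1}]` and the first
#' interval is closed on the left. The right-closed convention is what
#' clinical cutpoints such as "<= 400 mL" or "<= 10 months" require.
#'
#' @param name variable name (string).
#' @param states character vector of state labels, in code order; at least 2.
#' @param role `"attribute"` or `"class"`.
#' @param bins optional numeric vector of strictly increasing interval edges,
#'   of length `length(states) + 1`, for discretizing continuous values.
#' @param closed which side of each interior cutpoint belongs to the lower
#'   interval: `"left"` (default) or `"right"`; see Details.
#' @param units optional measurement units for `bins` (informational).
#'
#' @return An object of class `variable_spec`.
#' @seealso [discretize()], [hcc_schema()]
#' @export
variable_spec <- function(name, states, role = c("attribute", "class"),
                          bins = NULL, closed = c("left", "right"),
                          units = NULL) {
  role <- match.arg(role)
  closed <- match.arg(closed)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  states <- as.character(states)
  if (length(states) < 2L)
    stop("variable '", name, "' must have at least 2 states", call. = FALSE)
  if (anyDuplicated(states))
    stop("variable '", name, "' has duplicate state labels", call. = FALSE)
  if (!is.null(bins)) {
    bins <- as.numeric(bins)
    if (length(bins) != length(states) + 1L)
      stop("variable '", name, "': bins must have length(states)+1 edges",
           call. = FALSE)
    if (any(diff(bins) <= 0))
      stop("variable '", name, "': bin edges must be strictly increasing",
           call. = FALSE)
  }
  structure(
    list(name = name, role = role, states = states, bins = bins,
         closed = closed, units = units),
    class = "variable_spec"
  )
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s (%s), %d states: %s\n",
              x$name, x$role, length(x$states),
              paste(x$states, collapse = ", ")))
  if (!is.null(x$bins))
    cat(sprintf("  bins (%s, %s-closed): %s\n",
                if (is.null(x$units)) "unitless" else x$units,
                x$closed, paste(format(x$bins), collapse = " | ")))
  invisible(x)
}

#' Variable schema of the HCC hepatectomy cohort
#'
#' Returns the 16-variable schema used throughout the package: 15 clinical
#' attributes plus the binary survival-time class (state 0 = short survival,
#' at most 10 months; state 1 = survival beyond 10 months). Continuous
#' sources carry their discretization edges:
#' age 16-45 / 46-59 / 60-84 years, preoperative AFP 0-8 / 8.01-399.99 /
#' 400-121000 ng/mL, tumor size <2 / 2-4.9 / 5-9.9 / >=10 cm, intraoperative
#' blood loss cut at 400 mL, porta-hepatis clamping time (TCPH) cut at
#' 15 min, survival time cut at 10 months.
#'
#' @param age_bins `"table1"` for the 16-45/46-59/60-84 year intervals
#'   (default) or `"table4"` for the 16-45/45-60/60-84 variant, which moves
#'   the two interior cutpoints down by one year.
#'
#' @return A list of [variable_spec()] objects, class variable last.
#' @export
#' @examples
#' sch <- hcc_schema()
#' vapply(sch, function(v) length(v$states), integer(1))
hcc_schema <- function(age_bins = c("table1", "table4")) {
  age_bins <- match.arg(age_bins)
  age_edges <- if (age_bins == "table1") c(16, 46, 60, 84) else c(16, 45, 60, 84)
  yn <- c("N", "Y")
  list(
    variable_spec("sex", c("female", "male")),
    variable_spec("age", c("16-45", "46-59", "60-84"), bins = age_edges,
                  units = "years"),
    variable_spec("hbv", yn),
    variable_spec("hcv", yn),
    variable_spec("afp", c("0-8", "8.01-399.99", "400-121000"),
                  bins = c(0, 8.01, 400, 121000), units = "ng/mL"),
    variable_spec("liver_function", c("child_A", "child_B")),
    variable_spec("tumor_size", c("<2", "2-4.9", "5-9.9", ">=10"),
                  bins = c(0, 2, 5, 10, Inf), units = "cm"),
    variable_spec("tumor_number", c("single", "multiple")),
    variable_spec("pvtt", yn),
    variable_spec("operative_method", c("PAH", "ANH")),
    variable_spec("metastasis", yn),
    variable_spec("tcph", c("<=15", ">15"), bins = c(0, 15, Inf),
                  closed = "right", units = "min"),
    variable_spec("blood_loss", c("<=400", ">400"), bins = c(0, 400, Inf),
                  closed = "right", units = "mL"),
    variable_spec("complication", yn),
    variable_spec("tace", yn),
    variable_spec("survival_time", c("<=10m", ">10m"), role = "class",
                  bins = c(0, 10, 68), closed = "right", units = "months")
  )
}

#' Discretize a raw measurement into its coded state
#'
#' Maps raw continuous values onto the 0-based interval index declared in a
#' variable spec. Boundary handling follows the spec's `closed` convention
#' (see [variable_spec()]); the outermost interval on the far side is always
#' closed, so every value inside the covered range maps to exactly one state.
#'
#' @param raw_value numeric vector of raw measurements.
#' @param spec a [variable_spec()] with `bins`.
#'
#' @return Integer vector of state codes (0-based).
#' @export
#' @examples
#' afp <- hcc_schema()[[5]]
#' discretize(c(8, 181.4, 400), afp)  # 0 1 2
discretize <- function(raw_value, spec) {
  stopifnot(inherits(spec, "variable_spec"))
  if (is.null(spec$bins))
    stop("variable '", spec$name, "' has no bins; it is already discrete",
         call. = FALSE)
  raw_value <- as.numeric(raw_value)
  edges <- spec$bins
  lo <- edges[1L]; hi <- edges[length(edges)]
  bad <- !is.na(raw_value) & (raw_value < lo | raw_value > hi)
  if (any(bad))
    stop(sprintf("value %s outside the covered range [%s, %s] for '%s'",
                 format(raw_value[which(bad)[1L]]), format(lo), format(hi),
                 spec$name), call. = FALSE)
  if (anyNA(raw_value))
    stop("missing raw values cannot be discretized", call. = FALSE)
  if (spec$closed == "left") {
    idx <- findInterval(raw_value, edges, rightmost.closed = TRUE)
  } else {
    idx <- findInterval(raw_value, edges, left.open = TRUE)
    idx[raw_value == lo] <- 1L  # first interval closed on the left
  }
  as.integer(idx - 1L)
}

.schema_names <- function(schema) vapply(schema, `[[`, character(1), "name")

.class_index <- function(schema) {
  roles <- vapply(schema, `[[`, character(1), "role")
  idx <- which(roles == "class")
  if (length(idx) != 1L)
    stop("schema must declare exactly one class variable", call. = FALSE)
  idx
}

#' Assemble and validate a cohort table
#'
#' A cohort is a data frame of integer state codes, one row per patient and
#' one column per schema variable, carrying its schema as an attribute.
#' Every cell is checked against the declared state space; missing cells and
#' out-of-range codes are rejected rather than imputed.
#'
#' @param records data frame (or coercible) of integer state codes whose
#'   column names match the schema variable names.
#' @param schema list of [variable_spec()]s, e.g. [hcc_schema()].
#'
#' @return A validated `tan_cohort` data frame.
#' @export
cohort <- function(records, schema) {
  records <- as.data.frame(records)
  nms <- .schema_names(schema)
  missing_cols <- setdiff(nms, names(records))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records <- records[nms]
  if (nrow(records) == 0L) {
    for (v in nms) records[[v]] <- integer(0)
  } else {
    for (k in seq_along(schema)) {
      v <- schema[[k]]
      col <- records[[v$name]]
      if (anyNA(col))
        stop(sprintf("validation error: missing cell at row %d, column '%s'",
                     which(is.na(col))[1L], v$name), call. = FALSE)
      if (!is.numeric(col) || any(col != as.integer(col)))
        stop(sprintf("validation error: non-integer code in column '%s'",
                     v$name), call. = FALSE)
      col <- as.integer(col)
      bad <- col < 0L | col >= length(v$states)
      if (any(bad))
        stop(sprintf(
          "validation error: code %d at row %d, column '%s' outside 0..%d",
          col[which(bad)[1L]], which(bad)[1L], v$name,
          length(v$states) - 1L), call. = FALSE)
      records[[v$name]] <- col
    }
  }
  structure(records, schema = schema, class = c("tan_cohort", "data.frame"))
}

#' @export
print.tan_cohort <- function(x, ...) {
  schema <- attr(x, "schema")
  cat(sprintf("<tan_cohort> %d records x %d variables (class: %s)\n",
              nrow(x), length(schema),
              schema[[.class_index(schema)]]$name))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read a coded cohort CSV
#'
#' Reads a UTF-8 CSV with a header row of variable names and integer state
#' codes, then validates it against the schema. Rows with out-of-range or
#' missing codes abort with an error naming the offending row and column.
#'
#' @param path path to the CSV file.
#' @param schema list of [variable_spec()]s.
#' @return A validated `tan_cohort`.
#' @export
load_cohort <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "numeric")
  cohort(df, schema)
}

#' Write a cohort to CSV
#'
#' Inverse of [load_cohort()]: the written file reloads to an identical
#' table under the same schema.
#'
#' @param table a `tan_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "tan_cohort"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Tally the class variable
#'
#' @param table a `tan_cohort`.
#' @return Named integer vector of per-state counts of the class variable
#'   (all declared states, including unobserved ones); sums to `nrow(table)`.
#' @export
#' @examples
#' cc <- class_counts(replica_counts_cohort())
#' cc  # 150 short-survival, 149 long-survival
class_counts <- function(table) {
  schema <- attr(table, "schema")
  cls <- schema[[.class_index(schema)]]
  codes <- factor(table[[cls$name]], levels = seq_along(cls$states) - 1L,
                  labels = cls$states)
  tab <- table(codes)
  stats::setNames(as.integer(tab), names(tab))
}
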