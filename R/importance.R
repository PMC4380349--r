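#' Fussell-Vesely importance of one variable state
#'
#' The relative change in the short-survival probability when the variable
#' is fixed at the given state:
#' `(P(S=0) - P(S=0 | V=j)) / P(S=0)`.
#' Positive values mean the state lowers the short-survival probability
#' (protective); negative values mean it raises it. Unlike classical binary
#' reliability systems there is no designated "normal" state here, so signed
#' values are expected.
#'
#' @param prior marginal probability of the short-survival class state,
#'   in `(0, 1]`.
#' @param posterior posterior short-survival probability given the state,
#'   in `[0, 1]` (vectorized).
#' @return Signed importance value(s).
#' @export
#' @examples
#' fv_importance(0.5017, 0.84)  # -0.6743: PVTT present worsens prognosis
fv_importance <- function(prior, posterior) {
  if (any(prior <= 0))
    stop("prior short-survival probability must be positive", call. = FALSE)
  stopifnot(all(prior <= 1), all(posterior >= 0 & posterior <= 1))
  (prior - posterior) / prior
}

#' Composite importance of a multistate variable
#'
#' Aggregates the per-state Fussell-Vesely values of one variable into a
#' single nonnegative score: the sum of absolute state importances divided
#' by one less than the number of states,
#' `MFV = sum_j |FV_j| / (K - 1)`.
#' The divisor makes scores comparable across variables with different state
#' counts (binary variables divide by 1, three-state by 2, four-state by 3).
#'
#' @param fv_values numeric vector of the variable's per-state FV values,
#'   one per state (length at least 2).
#' @return Nonnegative composite importance; zero exactly when every state's
#'   FV is zero.
#' @export
#' @examples
#' composite_importance(c(0.0616, -0.6743))  # 0.7359 for PVTT
composite_importance <- function(fv_values) {
  k <- length(fv_values)
  if (k < 2L)
    stop("a variable needs at least 2 states for a composite importance",
         call. = FALSE)
  sum(abs(fv_values)) / (k - 1L)
}

#' Pearson correlation of two integer-coded variables
#'
#' Ordinary product-moment correlation on the integer state codes, used as a
#' conventional univariate benchmark against which the model-based
#' importance ranking is compared.
#'
#' @param x_codes,y_codes equal-length numeric/integer vectors, each with
#'   positive variance.
#' @return Coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x_codes, y_codes) {
  if (length(x_codes) != length(y_codes))
    stop("inputs must have equal length", call. = FALSE)
  if (stats::var(x_codes) == 0 || stats::var(y_codes) == 0)
    stop("undefined correlation: an input has zero variance", call. = FALSE)
  stats::cor(x_codes, y_codes)
}

# competition ranking of x, largest first: ties share the smaller rank,
# the next rank skips
.rank_desc <- function(x) vapply(x, function(v) sum(x > v) + 1L, integer(1))

#' Importance table of all prognostic factors
#'
#' For each attribute of a fitted model: the model-marginal prior of each
#' state, the exact posterior short-survival probability given that single
#' state as evidence, the per-state Fussell-Vesely value, the variable-level
#' composite importance (MFV) with its competition rank (rank 1 = most
#' important), and -- for comparison -- the Pearson correlation of the
#' integer-coded attribute with the class codes, ranked by absolute value.
#'
#' At a maximum-likelihood fit (`alpha = 0`) the single-evidence posteriors
#' equal the cohort's empirical conditional class frequencies, so the table
#' is fully reproducible from the training counts.
#'
#' @param model a fitted `tan_model`.
#' @param table the training `tan_cohort` (used for the Pearson column).
#' @return An `importance_table` data frame with one row per attribute
#'   state: `variable`, `state` (label), `code`, `prior`, `posterior`
#'   (short-survival), `fv`, and the per-variable `mfv`, `rank_mfv`, `pcc`,
#'   `rank_pcc` repeated on each of its rows.
#' @export
#' @examples
#' fit <- suppressWarnings(fit_tan(replica_counts_cohort()))
#' imp <- importance_table(fit, replica_counts_cohort())
#' unique(imp[imp$rank_mfv == 1, "variable"])  # "pvtt"
importance_table <- function(model, table) {
  stopifnot(inherits(model, "tan_model"), inherits(table, "tan_cohort"))
  schema <- model$schema
  nms <- .schema_names(schema)
  cls <- model$structure$class_var
  attrs <- model$structure$attributes
  prior_s0 <- unname(posterior(model, cls)[1L])

  per_var <- lapply(attrs, function(v) {
    states <- schema[[match(v, nms)]]$states
    prior_v <- posterior(model, v)
    post_s0 <- vapply(seq_along(states) - 1L, function(j)
      unname(posterior(model, cls, stats::setNames(j, v))[1L]), numeric(1))
    fv <- fv_importance(prior_s0, post_s0)
    data.frame(variable = v, state = states,
               code = seq_along(states) - 1L,
               prior = unname(prior_v), posterior = post_s0, fv = fv,
               mfv = composite_importance(fv),
               pcc = pearson_correlation(table[[v]], table[[cls]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_var)

  mfv_by_var <- vapply(per_var, function(d) d$mfv[1L], numeric(1))
  pcc_by_var <- vapply(per_var, function(d) d$pcc[1L], numeric(1))
  rk_mfv <- .rank_desc(mfv_by_var)
  rk_pcc <- .rank_desc(abs(pcc_by_var))
  out$rank_mfv <- rk_mfv[match(out$variable, attrs)]
  out$rank_pcc <- rk_pcc[match(out$variable, attrs)]
  out <- out[c("variable", "state", "code", "prior", "posterior", "fv",
               "mfv", "rank_mfv", "pcc", "rank_pcc")]
  class(out) <- c("importance_table", "data.frame")
  attr(out, "prior_short") <- prior_s0
  out
}

#' @export
print.importance_table <- function(x, digits = 4L, ...) {
  cat(sprintf("<importance_table> prior short-survival p = %.4f\n",
              attr(x, "prior_short")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1)) &
    !(names(df) %in% c("code", "rank_mfv", "rank_pcc"))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
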