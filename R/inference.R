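# Exact inference on a fitted TAN. Conditional on the class, the attributes
# form a tree (or forest), so evidence likelihoods are computed by a single
# upward message pass per class state; cost is linear in the number of
# attributes and quadratic in the largest state space.

.check_evidence <- function(model, evidence, allow_class = TRUE) {
  if (length(evidence) == 0L) return(stats::setNames(integer(0), character(0)))
  if (is.null(names(evidence)) || any(!nzchar(names(evidence))))
    stop("evidence must be a named vector of state codes", call. = FALSE)
  if (anyDuplicated(names(evidence)))
    stop("duplicate variable in evidence", call. = FALSE)
  nms <- .schema_names(model$schema)
  cls <- model$structure$class_var
  for (v in names(evidence)) {
    if (!(v %in% nms)) stop("unknown evidence variable '", v, "'",
                            call. = FALSE)
    if (v == cls && !allow_class)
      stop("class variable cannot appear in this evidence", call. = FALSE)
    k <- length(model$schema[[match(v, nms)]]$states)
    code <- evidence[[v]]
    if (is.na(code) || code != as.integer(code) || code < 0 || code >= k)
      stop(sprintf("invalid state code %s for '%s'", format(code), v),
           call. = FALSE)
  }
  stats::setNames(as.integer(evidence), names(evidence))
}

# P(S = s, attribute evidence) for every class state s, as a vector.
.class_joint <- function(model, evidence) {
  st <- model$structure
  ks <- length(model$prior)
  children <- split(st$edges$child, factor(st$edges$parent,
                                           levels = st$attributes))
  # process children before parents: reverse of a parent-first order
  ord <- character(0)
  queue <- st$roots
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    queue <- c(queue, children[[v]])
  }
  out <- numeric(ks)
  for (s in seq_len(ks)) {
    msgs <- list()
    total <- 1
    for (v in rev(ord)) {
      cpt <- model$cpts[[v]]$table
      kv <- dim(cpt)[1L]; ku <- dim(cpt)[3L]
      base <- rep(1, kv)
      if (v %in% names(evidence)) {
        base <- numeric(kv)
        base[evidence[[v]] + 1L] <- 1
      }
      for (ch in children[[v]]) base <- base * msgs[[ch]]
      m <- as.vector(crossprod(cpt[, s, , drop = FALSE][, 1L, ], base))
      if (is.na(model$cpts[[v]]$parent)) total <- total * m[1L]
      else msgs[[v]] <- m
    }
    out[s] <- model$prior[s] * total
  }
  names(out) <- names(model$prior)
  out
}

#' Joint probability of a complete assignment
#'
#' The product of the class prior entry and every attribute's CPT entry for
#' a complete assignment of the class and all attributes.
#'
#' @param model a `tan_model`.
#' @param assignment named vector of state codes covering the class variable
#'   and every attribute.
#' @return The joint probability (scalar).
#' @export
joint_probability <- function(model, assignment) {
  stopifnot(inherits(model, "tan_model"))
  assignment <- .check_evidence(model, assignment)
  st <- model$structure
  need <- c(st$class_var, st$attributes)
  missing <- setdiff(need, names(assignment))
  if (length(missing))
    stop("incomplete assignment (missing: ",
         paste(missing, collapse = ", "),
         "); use posterior() for partial evidence", call. = FALSE)
  s <- assignment[[st$class_var]] + 1L
  p <- model$prior[[s]]
  for (v in st$attributes) {
    pa <- model$cpts[[v]]$parent
    u <- if (is.na(pa)) 1L else assignment[[pa]] + 1L
    p <- p * model$cpts[[v]]$table[assignment[[v]] + 1L, s, u]
  }
  unname(p)
}

#' Exact posterior distribution of one variable
#'
#' Computes `P(query | evidence)` exactly by summing the model joint over all
#' unobserved variables; the sum is carried out by tree message passing,
#' which equals full enumeration on every model.
#'
#' @param model a `tan_model`.
#' @param query name of the query variable (class or attribute), not in the
#'   evidence.
#' @param evidence named vector of observed state codes (possibly empty).
#' @return Named probability vector over the query variable's states
#'   (a `PosteriorDistribution`), summing to 1.
#' @export
#' @examples
#' fit <- suppressWarnings(fit_tan(replica_counts_cohort()))
#' posterior(fit, "survival_time", c(pvtt = 1))  # 0.84 short survival
posterior <- function(model, query, evidence = integer(0)) {
  stopifnot(inherits(model, "tan_model"))
  evidence <- .check_evidence(model, evidence)
  if (query %in% names(evidence))
    stop("query variable is already in the evidence", call. = FALSE)
  cls <- model$structure$class_var
  nms <- .schema_names(model$schema)
  if (!(query %in% nms)) stop("unknown query variable '", query, "'",
                              call. = FALSE)

  class_mask <- function(joint) {
    if (cls %in% names(evidence)) {
      keep <- evidence[[cls]] + 1L
      joint[-keep] <- 0
    }
    joint
  }
  attr_ev <- evidence[setdiff(names(evidence), cls)]

  if (query == cls) {
    p <- .class_joint(model, attr_ev)
  } else {
    states <- model$schema[[match(query, nms)]]$states
    p <- vapply(seq_along(states) - 1L, function(x) {
      ev <- c(attr_ev, stats::setNames(x, query))
      sum(class_mask(.class_joint(model, ev)))
    }, numeric(1))
    names(p) <- states
  }
  if (query == cls) p <- class_mask(p)
  tot <- sum(p)
  if (tot <= 0)
    stop("evidence has zero probability under the model", call. = FALSE)
  p / tot
}

#' Classify one patient record
#'
#' The record is labelled long-survival exactly when the posterior
#' probability of the long-survival class state strictly exceeds the
#' threshold; a posterior equal to the threshold yields the short-survival
#' label.
#'
#' @param model a `tan_model` with a binary class.
#' @param record named vector of state codes for all attributes.
#' @param threshold decision threshold in `[0, 1]`; default 0.5.
#' @return List with `label` (class state label) and `probability`
#'   (posterior of the long-survival state, class state 1).
#' @export
classify <- function(model, record, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  cls <- model$structure$class_var
  missing <- setdiff(model$structure$attributes, names(record))
  if (length(missing))
    stop("record must assign every attribute (missing: ",
         paste(missing, collapse = ", "), ")", call. = FALSE)
  p <- posterior(model, cls, record)
  cls_states <- names(model$prior)
  p1 <- unname(p[[2L]])
  list(label = if (p1 > threshold) cls_states[2L] else cls_states[1L],
       probability = p1)
}

#' Predict class probabilities for a cohort
#'
#' @param object a fitted `tan_model`.
#' @param newdata a `tan_cohort` (its class column, if present, is ignored
#'   for prediction).
#' @param threshold decision threshold passed to [classify()].
#' @param ... unused.
#' @return Data frame with one row per record: `probability` (posterior of
#'   the long-survival class state) and `label`.
#' @export
predict.tan_model <- function(object, newdata, threshold = 0.5, ...) {
  attrs <- object$structure$attributes
  res <- lapply(seq_len(nrow(newdata)), function(r) {
    rec <- stats::setNames(as.integer(unlist(newdata[r, attrs])), attrs)
    classify(object, rec, threshold)
  })
  data.frame(probability = vapply(res, `[[`, numeric(1), "probability"),
             label = vapply(res, `[[`, character(1), "label"),
             stringsAsFactors = FALSE)
}

#' What-if scenario analysis under partial evidence
#'
#' Fixes a partial set of attribute states (for instance PVTT present and a
#' given operative method) and reports the class posterior alongside the
#' posterior of each requested free attribute under the same evidence -- the
#' machinery behind treatment-simulation tables.
#'
#' @param model a `tan_model`.
#' @param evidence named vector of observed attribute state codes.
#' @param targets names of unobserved attributes whose posteriors to report;
#'   defaults to all unobserved attributes.
#' @return List with `class`: posterior over class states, and `attributes`:
#'   named list of posterior vectors, one per target.
#' @export
scenario_query <- function(model, evidence = integer(0), targets = NULL) {
  evidence <- .check_evidence(model, evidence, allow_class = FALSE)
  free <- setdiff(model$structure$attributes, names(evidence))
  if (is.null(targets)) targets <- free
  if (length(bad <- setdiff(targets, free)))
    stop("target(s) not free attributes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  list(
    class = posterior(model, model$structure$class_var, evidence),
    attributes = stats::setNames(
      lapply(targets, function(v) posterior(model, v, evidence)), targets)
  )
}
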