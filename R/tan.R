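#' Class-conditional mutual information between two attributes
#'
#' Computes `I(X; Y | S)` in bits from the empirical cell frequencies of a
#' cohort, where `S` is the schema's class variable:
#' `sum over (x, y, s) of p(x,y,s) * log2( p(x,y|s) / (p(x|s) p(y|s)) )`.
#' Cells with zero joint count contribute zero. The value is always
#' nonnegative and symmetric in `x` and `y`; a degenerate single-state
#' attribute yields 0.
#'
#' @param x,y attribute names (distinct).
#' @param table a `tan_cohort`.
#' @return Nonnegative scalar, in bits.
#' @export
conditional_mutual_information <- function(x, y, table) {
  schema <- attr(table, "schema")
  nms <- .schema_names(schema)
  if (identical(x, y)) stop("x and y must be distinct attributes", call. = FALSE)
  if (!all(c(x, y) %in% nms)) stop("unknown attribute name", call. = FALSE)
  cls <- nms[.class_index(schema)]
  n <- nrow(table)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  kx <- length(schema[[match(x, nms)]]$states)
  ky <- length(schema[[match(y, nms)]]$states)
  ks <- length(schema[[match(cls, nms)]]$states)
  nxys <- table(factor(table[[x]], levels = 0:(kx - 1L)),
                factor(table[[y]], levels = 0:(ky - 1L)),
                factor(table[[cls]], levels = 0:(ks - 1L)))
  nxs <- apply(nxys, c(1L, 3L), sum)
  nys <- apply(nxys, c(2L, 3L), sum)
  ns <- apply(nxys, 3L, sum)
  cmi <- 0
  for (s in seq_len(ks)) {
    if (ns[s] == 0L) next
    for (i in seq_len(kx)) for (j in seq_len(ky)) {
      nij <- nxys[i, j, s]
      if (nij == 0L) next
      cmi <- cmi + (nij / n) * log2(nij * ns[s] / (nxs[i, s] * nys[j, s]))
    }
  }
  max(cmi, 0)  # clip tiny negative rounding residue
}

#' Learn the TAN attribute tree
#'
#' Builds the maximum-weight spanning tree over the attributes, with
#' class-conditional mutual information as edge weights (the Chow-Liu step
#' of the tree-augmented naive Bayes learner), then directs edges away from
#' the root. The class variable is implicitly a parent of every attribute.
#'
#' Determinism: candidate edges are sorted by weight (descending) and then
#' by the alphabetically ordered name pair (ascending); the tree is grown
#' greedily (Kruskal) and rooted at the first attribute in schema order, so
#' identical cohorts always yield the identical structure regardless of
#' record order.
#'
#' @param table a `tan_cohort` with at least two attributes.
#' @param cmi_threshold optional nonnegative pruning threshold: candidate
#'   edges with conditional mutual information at or below it are discarded
#'   before tree construction, which may yield a forest (attributes without
#'   an attribute parent keep the class as their only parent). `NULL`
#'   (default) keeps the strict spanning tree.
#' @return A `tan_structure`: class variable, attribute list, directed
#'   parent->child edges, and the root attribute(s).
#' @export
learn_tan_structure <- function(table, cmi_threshold = NULL) {
  schema <- attr(table, "schema")
  if (nrow(table) == 0L) stop("cannot learn structure from an empty table",
                              call. = FALSE)
  nms <- .schema_names(schema)
  cls <- nms[.class_index(schema)]
  attrs <- setdiff(nms, cls)
  if (length(attrs) < 2L)
    stop("need at least two attributes to build a tree", call. = FALSE)

  pairs <- utils::combn(attrs, 2L)
  w <- apply(pairs, 2L, function(p)
    conditional_mutual_information(p[1L], p[2L], table))
  a <- pmin(pairs[1L, ], pairs[2L, ])
  b <- pmax(pairs[1L, ], pairs[2L, ])
  ord <- order(-w, a, b)
  if (!is.null(cmi_threshold)) {
    keep <- w[ord] > cmi_threshold
    ord <- ord[keep]
  }

  # Kruskal with union-find
  parent <- stats::setNames(attrs, attrs)
  find <- function(v) { while (parent[[v]] != v) v <- parent[[v]]; v }
  chosen <- matrix(character(0), nrow = 2L)
  for (k in ord) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) {
      parent[[ra]] <- rb
      chosen <- cbind(chosen, c(a[k], b[k]))
      if (ncol(chosen) == length(attrs) - 1L) break
    }
  }

  # orient away from roots: BFS over undirected chosen edges, component by
  # component, seeding each component with its first attribute in schema order
  adj <- lapply(stats::setNames(vector("list", length(attrs)), attrs),
                function(x) character(0))
  if (ncol(chosen) > 0L) for (k in seq_len(ncol(chosen))) {
    adj[[chosen[1L, k]]] <- c(adj[[chosen[1L, k]]], chosen[2L, k])
    adj[[chosen[2L, k]]] <- c(adj[[chosen[2L, k]]], chosen[1L, k])
  }
  visited <- stats::setNames(rep(FALSE, length(attrs)), attrs)
  edges <- data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE)
  roots <- character(0)
  for (r in attrs) {
    if (visited[[r]]) next
    roots <- c(roots, r)
    queue <- r; visited[[r]] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in adj[[v]]) if (!visited[[u]]) {
        visited[[u]] <- TRUE
        edges <- rbind(edges, data.frame(parent = v, child = u,
                                         stringsAsFactors = FALSE))
        queue <- c(queue, u)
      }
    }
  }

  structure(list(class_var = cls, attributes = attrs, edges = edges,
                 roots = roots),
            class = "tan_structure")
}

#' @export
print.tan_structure <- function(x, ...) {
  cat(sprintf("<tan_structure> class '%s' -> all %d attributes\n",
              x$class_var, length(x$attributes)))
  cat(sprintf("  attribute tree (%d edge%s, root%s: %s)\n",
              nrow(x$edges), if (nrow(x$edges) == 1L) "" else "s",
              if (length(x$roots) > 1L) "s" else "",
              paste(x$roots, collapse = ", ")))
  if (nrow(x$edges))
    cat(paste0("    ", x$edges$parent, " -> ", x$edges$child, "\n"), sep = "")
  invisible(x)
}

.attr_parent <- function(structure, v) {
  hit <- structure$edges$parent[structure$edges$child == v]
  if (length(hit)) hit else NA_character_
}

#' Estimate conditional probability tables
#'
#' Fits the class prior and one CPT per attribute,
#' `P(V = v | S = s, parent(V) = u) = (n(v,s,u) + alpha) / (n(s,u) + alpha K)`
#' with `K` the number of states of `V`. `alpha = 0` is the
#' maximum-likelihood fit (empirical conditional frequencies); with
#' `alpha = 0` an unobserved conditioning context falls back to the uniform
#' distribution and a warning names it.
#'
#' @param structure a `tan_structure`.
#' @param table the training `tan_cohort`.
#' @param alpha nonnegative additive (Laplace) smoothing constant; default 0.
#' @return A `tan_model`: the structure, schema, class prior and per-attribute
#'   CPT arrays indexed `[state, class state, parent state]` (a singleton
#'   parent dimension for attributes whose only parent is the class).
#' @export
estimate_cpts <- function(structure, table, alpha = 0) {
  stopifnot(inherits(structure, "tan_structure"), alpha >= 0)
  schema <- attr(table, "schema")
  nms <- .schema_names(schema)
  if (!all(structure$attributes %in% nms))
    stop("structure attributes not all present in the cohort schema",
         call. = FALSE)
  cls <- structure$class_var
  ks <- length(schema[[match(cls, nms)]]$states)
  n <- nrow(table)
  if (n == 0L) stop("cannot fit on an empty table", call. = FALSE)

  cs <- tabulate(table[[cls]] + 1L, nbins = ks)
  prior <- (cs + alpha) / (n + alpha * ks)
  names(prior) <- schema[[match(cls, nms)]]$states

  cpts <- list()
  for (v in structure$attributes) {
    kv <- length(schema[[match(v, nms)]]$states)
    pa <- .attr_parent(structure, v)
    ku <- if (is.na(pa)) 1L else length(schema[[match(pa, nms)]]$states)
    pa_codes <- if (is.na(pa)) rep(0L, n) else table[[pa]]
    counts <- array(
      table(factor(table[[v]], levels = 0:(kv - 1L)),
            factor(table[[cls]], levels = 0:(ks - 1L)),
            factor(pa_codes, levels = 0:(ku - 1L))),
      dim = c(kv, ks, ku))
    cpt <- array(NA_real_, dim = dim(counts))
    for (s in seq_len(ks)) for (u in seq_len(ku)) {
      ctx <- sum(counts[, s, u])
      if (ctx + alpha * kv > 0) {
        cpt[, s, u] <- (counts[, s, u] + alpha) / (ctx + alpha * kv)
      } else {
        cpt[, s, u] <- 1 / kv
        warning(sprintf(
          "unobserved context for '%s' (class state %d%s): using uniform",
          v, s - 1L,
          if (is.na(pa)) "" else sprintf(", %s state %d", pa, u - 1L)),
          call. = FALSE)
      }
    }
    dimnames(cpt) <- list(schema[[match(v, nms)]]$states,
                          schema[[match(cls, nms)]]$states,
                          if (is.na(pa)) "." else
                            schema[[match(pa, nms)]]$states)
    cpts[[v]] <- list(parent = pa, table = cpt)
  }

  structure(list(structure = structure, schema = schema, prior = prior,
                 cpts = cpts, alpha = alpha),
            class = "tan_model")
}

#' Fit a TAN classifier in one call
#'
#' Convenience wrapper: [learn_tan_structure()] followed by
#' [estimate_cpts()].
#'
#' @inheritParams learn_tan_structure
#' @inheritParams estimate_cpts
#' @return A fitted `tan_model`.
#' @export
#' @examples
#' coh <- replica_counts_cohort()
#' fit <- suppressWarnings(fit_tan(coh))
#' round(posterior(fit, "survival_time", c(pvtt = 1))[">10m"], 2)
fit_tan <- function(table, alpha = 0, cmi_threshold = NULL) {
  estimate_cpts(learn_tan_structure(table, cmi_threshold), table, alpha)
}

#' @export
print.tan_model <- function(x, ...) {
  cat(sprintf("<tan_model> class '%s', %d attributes, alpha = %g\n",
              x$structure$class_var, length(x$structure$attributes), x$alpha))
  cat("  class prior:",
      paste(sprintf("%s=%.4f", names(x$prior), x$prior), collapse = ", "),
      "\n")
  invisible(x)
}

# ---- model serialization ----------------------------------------------------

.spec_to_list <- function(v)
  list(name = v$name, role = v$role, states = v$states,
       bins = v$bins, closed = v$closed, units = v$units)

.spec_from_list <- function(l)
  variable_spec(l$name, unlist(l$states), l$role,
                bins = if (length(l$bins)) unlist(l$bins) else NULL,
                closed = l$closed,
                units = if (length(l$units)) l$units else NULL)

#' Serialize a fitted model to JSON
#'
#' Writes structure, schema, class prior, and CPTs. Probabilities are stored
#' as 17-significant-digit decimal strings, which represent an IEEE double
#' exactly, so [read_tan_model()] restores a bit-identical model.
#'
#' @param model a `tan_model`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_tan_model <- function(model, path) {
  stopifnot(inherits(model, "tan_model"))
  num <- function(x) sprintf("%.17g", x)
  doc <- list(
    class_var = model$structure$class_var,
    attributes = model$structure$attributes,
    edges = model$structure$edges,
    roots = model$structure$roots,
    alpha = num(model$alpha),
    schema = lapply(model$schema, .spec_to_list),
    prior = as.list(stats::setNames(num(model$prior), names(model$prior))),
    cpts = lapply(model$cpts, function(c)
      list(parent = if (is.na(c$parent)) NULL else c$parent,
           dim = dim(c$table), values = num(as.vector(c$table))))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Restore a model written by [write_tan_model()]
#'
#' @param path path to the model JSON.
#' @return A `tan_model`.
#' @export
read_tan_model <- function(path) {
  doc <- jsonlite::read_json(path)
  schema <- lapply(doc$schema, .spec_from_list)
  nms <- .schema_names(schema)
  edges <- if (length(doc$edges))
    data.frame(parent = vapply(doc$edges, `[[`, character(1), "parent"),
               child = vapply(doc$edges, `[[`, character(1), "child"),
               stringsAsFactors = FALSE)
  else data.frame(parent = character(0), child = character(0),
                  stringsAsFactors = FALSE)
  str <- structure(list(class_var = doc$class_var,
                        attributes = unlist(doc$attributes),
                        edges = edges,
                        roots = unlist(doc$roots)),
                   class = "tan_structure")
  cls_states <- schema[[match(doc$class_var, nms)]]$states
  prior <- stats::setNames(vapply(doc$prior, as.numeric, numeric(1)),
                           names(doc$prior))
  cpts <- lapply(stats::setNames(names(doc$cpts), names(doc$cpts)),
                 function(v) {
    c <- doc$cpts[[v]]
    pa <- if (is.null(c$parent)) NA_character_ else c$parent
    tab <- array(vapply(c$values, as.numeric, numeric(1)),
                 dim = unlist(c$dim))
    dimnames(tab) <- list(schema[[match(v, nms)]]$states, cls_states,
                          if (is.na(pa)) "." else
                            schema[[match(pa, nms)]]$states)
    list(parent = pa, table = tab)
  })
  structure(list(structure = str, schema = schema, prior = prior,
                 cpts = cpts, alpha = as.numeric(doc$alpha)),
            class = "tan_model")
}
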