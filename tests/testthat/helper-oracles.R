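# Independent oracles and fixture builders. Everything here recomputes
# quantities by brute force (enumeration, triple loops, pairwise counts) and
# must stay independent of the package's own algorithms.

make_schema <- function(states_per_attr, class_states = 2L) {
  n <- length(states_per_attr)
  specs <- lapply(seq_len(n), function(i)
    variable_spec(paste0("v", i),
                  paste0("s", seq_len(states_per_attr[i]) - 1L)))
  c(specs, list(variable_spec("cls", paste0("c", seq_len(class_states) - 1L),
                              role = "class")))
}

# assemble a tan_model directly from parts (bypasses fitting)
build_model <- function(schema, edges, prior, cpts, alpha = 0) {
  nms <- vapply(schema, `[[`, character(1), "name")
  roles <- vapply(schema, `[[`, character(1), "role")
  cls <- nms[roles == "class"]
  attrs <- setdiff(nms, cls)
  parent_of <- function(v) {
    hit <- edges$parent[edges$child == v]
    if (length(hit)) hit else NA_character_
  }
  roots <- attrs[vapply(attrs, function(v) is.na(parent_of(v)), logical(1))]
  str <- structure(list(class_var = cls, attributes = attrs, edges = edges,
                        roots = roots), class = "tan_structure")
  structure(list(structure = str, schema = schema, prior = prior,
                 cpts = cpts, alpha = alpha), class = "tan_model")
}

rand_dist <- function(k) { p <- stats::rexp(k) + 0.05; p / sum(p) }

# random TAN over n_attr attributes: each non-root attribute gets a random
# earlier attribute as parent; CPTs are random strictly positive distributions
random_tan_model <- function(n_attr, max_states = 3L, seed = 1L,
                             tree = TRUE) {
  set.seed(seed)
  kst <- sample(2:max_states, n_attr, replace = TRUE)
  schema <- make_schema(kst)
  nms <- vapply(schema, `[[`, character(1), "name")
  attrs <- paste0("v", seq_len(n_attr))
  edges <- data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE)
  if (tree && n_attr >= 2L)
    for (i in 2:n_attr)
      edges <- rbind(edges, data.frame(
        parent = attrs[sample.int(i - 1L, 1L)], child = attrs[i],
        stringsAsFactors = FALSE))
  cls_states <- schema[[n_attr + 1L]]$states
  prior <- stats::setNames(rand_dist(2L), cls_states)
  cpts <- lapply(stats::setNames(seq_len(n_attr), attrs), function(i) {
    pa <- { hit <- edges$parent[edges$child == attrs[i]]
            if (length(hit)) hit else NA_character_ }
    ku <- if (is.na(pa)) 1L else kst[match(pa, attrs)]
    tab <- array(0, dim = c(kst[i], 2L, ku),
                 dimnames = list(schema[[i]]$states, cls_states,
                                 if (is.na(pa)) "." else
                                   schema[[match(pa, attrs)]]$states))
    for (s in 1:2) for (u in seq_len(ku)) tab[, s, u] <- rand_dist(kst[i])
    list(parent = pa, table = tab)
  })
  build_model(schema, edges, prior, cpts)
}

random_cohort <- function(n, states_per_attr, seed = 1L) {
  set.seed(seed)
  schema <- make_schema(states_per_attr)
  nms <- vapply(schema, `[[`, character(1), "name")
  df <- lapply(c(states_per_attr, 2L), function(k)
    sample.int(k, n, replace = TRUE) - 1L)
  names(df) <- nms
  cohort(as.data.frame(df), schema)
}

# ---- oracles ----------------------------------------------------------------

# CMI oracle: explicit triple loop over the contingency counts
cmi_oracle <- function(x, y, table) {
  sch <- attr(table, "schema")
  nms <- vapply(sch, `[[`, character(1), "name")
  cls <- nms[vapply(sch, `[[`, character(1), "role") == "class"]
  n <- nrow(table)
  total <- 0
  for (s in unique(table[[cls]]))
    for (a in unique(table[[x]]))
      for (b in unique(table[[y]])) {
        nabs <- sum(table[[x]] == a & table[[y]] == b & table[[cls]] == s)
        if (nabs == 0) next
        nas <- sum(table[[x]] == a & table[[cls]] == s)
        nbs <- sum(table[[y]] == b & table[[cls]] == s)
        ns <- sum(table[[cls]] == s)
        total <- total + (nabs / n) * log2((nabs / ns) / ((nas / ns) * (nbs / ns)))
      }
  total
}

# full-joint enumeration oracle for P(S = s, evidence) over all class states
enum_class_joint <- function(model, evidence) {
  sch <- model$schema
  nms <- vapply(sch, `[[`, character(1), "name")
  cls <- model$structure$class_var
  ks <- length(model$prior)
  grid <- expand.grid(lapply(stats::setNames(nms, nms), function(v)
    0:(length(sch[[match(v, nms)]]$states) - 1L)), KEEP.OUT.ATTRS = FALSE)
  for (v in names(evidence)) grid <- grid[grid[[v]] == evidence[[v]], ,
                                          drop = FALSE]
  p <- model$prior[grid[[cls]] + 1L]
  for (v in model$structure$attributes) {
    pa <- model$cpts[[v]]$parent
    u <- if (is.na(pa)) rep(1L, nrow(grid)) else grid[[pa]] + 1L
    p <- p * model$cpts[[v]]$table[cbind(grid[[v]] + 1L, grid[[cls]] + 1L, u)]
  }
  vapply(seq_len(ks) - 1L, function(s) sum(p[grid[[cls]] == s]), numeric(1))
}

enum_posterior <- function(model, query, evidence) {
  sch <- model$schema
  nms <- vapply(sch, `[[`, character(1), "name")
  k <- length(sch[[match(query, nms)]]$states)
  cls <- model$structure$class_var
  if (query == cls) {
    p <- enum_class_joint(model, evidence)
  } else {
    p <- vapply(0:(k - 1L), function(j)
      sum(enum_class_joint(model, c(evidence, stats::setNames(j, query)))),
      numeric(1))
  }
  names(p) <- sch[[match(query, nms)]]$states
  p / sum(p)
}

# all labeled spanning trees on n >= 2 nodes, via Pruefer sequences;
# returns list of 2-column matrices of node indices
all_spanning_trees <- function(n) {
  decode <- function(seq) {
    degree <- rep(1L, n)
    for (x in seq) degree[x] <- degree[x] + 1L
    edges <- matrix(0L, nrow = 0L, ncol = 2L)
    for (x in seq) {
      leaf <- min(which(degree == 1L))
      edges <- rbind(edges, c(leaf, x))
      degree[leaf] <- 0L
      degree[x] <- degree[x] - 1L
    }
    rbind(edges, which(degree == 1L))
  }
  if (n == 2L) return(list(matrix(c(1L, 2L), ncol = 2L)))
  seqs <- expand.grid(rep(list(1:n), n - 2L))
  lapply(seq_len(nrow(seqs)), function(i) decode(as.integer(seqs[i, ])))
}

# undirected edge set of a tan_structure as a sorted "a|b" character vector
undirected_edges <- function(structure) {
  if (nrow(structure$edges) == 0L) return(character(0))
  sort(paste(pmin(structure$edges$parent, structure$edges$child),
             pmax(structure$edges$parent, structure$edges$child), sep = "|"))
}

# AUC oracle: pairwise concordance with ties counted one half
auc_oracle <- function(prob, truth) {
  pos <- prob[truth]; neg <- prob[!truth]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
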