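test_that("conditional mutual information matches closed forms", {
  sch <- make_schema(c(2L, 2L))
  # X = Y, uniform binary within each class: I(X;Y|S) = H(X|S) = 1 bit
  df <- expand.grid(x = 0:1, s = 0:1)[rep(1:4, each = 5), ]
  coh <- cohort(data.frame(v1 = df$x, v2 = df$x, cls = df$s), sch)
  expect_equal(conditional_mutual_information("v1", "v2", coh), 1.0)
  # a constant attribute carries no information
  coh2 <- cohort(data.frame(v1 = rep(0L, 20), v2 = df$x, cls = df$s), sch)
  expect_equal(conditional_mutual_information("v1", "v2", coh2), 0)
})

test_that("CMI equals the brute-force triple-loop sum and is symmetric", {
  for (seed in 1:5) {
    coh <- random_cohort(20, c(2L, 3L, 2L), seed = seed)
    got <- conditional_mutual_information("v1", "v2", coh)
    expect_equal(got, cmi_oracle("v1", "v2", coh), tolerance = 1e-12)
    expect_equal(got, conditional_mutual_information("v2", "v1", coh))
    expect_gte(got, 0)
    expect_gte(conditional_mutual_information("v2", "v3", coh), 0)
  }
})

test_that("learned tree attains the maximum spanning-tree weight (exhaustive)", {
  for (case in list(list(k = c(2L, 2L, 2L, 2L, 2L), n = 60, seed = 11),
                    list(k = c(2L, 3L, 2L, 3L, 2L), n = 80, seed = 12),
                    list(k = c(3L, 2L, 2L), n = 40, seed = 13),
                    list(k = c(2L, 2L, 3L, 2L), n = 50, seed = 14))) {
    coh <- random_cohort(case$n, case$k, seed = case$seed)
    attrs <- paste0("v", seq_along(case$k))
    w <- matrix(0, length(attrs), length(attrs))
    for (i in seq_along(attrs)) for (j in seq_along(attrs))
      if (i < j) w[i, j] <- w[j, i] <-
          conditional_mutual_information(attrs[i], attrs[j], coh)
    best <- max(vapply(all_spanning_trees(length(attrs)), function(e)
      sum(w[e]), numeric(1)))
    st <- learn_tan_structure(coh)
    got <- sum(vapply(seq_len(nrow(st$edges)), function(r)
      w[match(st$edges$parent[r], attrs), match(st$edges$child[r], attrs)],
      numeric(1)))
    expect_equal(got, best, tolerance = 1e-12)
    expect_identical(nrow(st$edges), length(attrs) - 1L)
  }
})

test_that("structure learning recovers a generated chain given the class", {
  # ground truth: v1 -> v2 -> v3 with strong dependence given the class
  sch <- make_schema(c(2L, 2L, 2L))
  edges <- data.frame(parent = c("v1", "v2"), child = c("v2", "v3"),
                      stringsAsFactors = FALSE)
  copy_cpt <- function(stay = 0.9) {
    tab <- array(0, dim = c(2, 2, 2),
                 dimnames = list(c("s0", "s1"), c("c0", "c1"), c("s0", "s1")))
    for (s in 1:2) tab[, s, ] <- matrix(c(stay, 1 - stay, 1 - stay, stay), 2)
    tab
  }
  root_tab <- array(c(0.7, 0.3, 0.4, 0.6), dim = c(2, 2, 1),
                    dimnames = list(c("s0", "s1"), c("c0", "c1"), "."))
  truth <- build_model(
    sch, edges, prior = c(c0 = 0.5, c1 = 0.5),
    cpts = list(v1 = list(parent = NA_character_, table = root_tab),
                v2 = list(parent = "v1", table = copy_cpt()),
                v3 = list(parent = "v2", table = copy_cpt())))
  coh <- sample_cohort(truth, 2000, seed = 5)
  st <- learn_tan_structure(coh)
  expect_identical(undirected_edges(st), c("v1|v2", "v2|v3"))
  # exhaustive check on the same fixture: 3 spanning trees on 3 nodes
  w <- function(a, b) conditional_mutual_information(a, b, coh)
  weights <- c(w("v1", "v2") + w("v2", "v3"),
               w("v1", "v2") + w("v1", "v3"),
               w("v1", "v3") + w("v2", "v3"))
  expect_identical(which.max(weights), 1L)
})

test_that("equal weights fall back to the lexicographically first tree", {
  # all attributes mutually independent and identically distributed given the
  # class, sampled so that every empirical CMI is exactly equal (here: zero)
  sch <- make_schema(c(2L, 2L, 2L))
  grid <- expand.grid(v1 = 0:1, v2 = 0:1, v3 = 0:1, cls = 0:1)
  coh <- cohort(grid, sch)  # perfectly uniform table: all CMIs are 0
  st <- learn_tan_structure(coh)
  expect_identical(undirected_edges(st), c("v1|v2", "v1|v3"))
  expect_identical(st$roots, "v1")
})

test_that("structure learning is invariant to record order", {
  coh <- random_cohort(120, c(2L, 3L, 2L, 2L), seed = 21)
  sch <- attr(coh, "schema")
  shuffled <- cohort(as.data.frame(coh)[rev(seq_len(nrow(coh))), ], sch)
  expect_identical(learn_tan_structure(coh)$edges,
                   learn_tan_structure(shuffled)$edges)
})

test_that("CPT estimation matches empirical frequencies and smoothing rules", {
  sch <- make_schema(c(2L, 2L))
  coh <- cohort(data.frame(v1 = c(0, 0, 1, 0), v2 = c(0, 1, 1, 1),
                           cls = c(0, 0, 1, 1)), sch)
  st <- learn_tan_structure(coh)
  # (cls = 0, v1 = 1) is unobserved in this 4-record table, hence the warning
  expect_warning(fit0 <- estimate_cpts(st, coh, alpha = 0),
                 "unobserved context")
  expect_equal(unname(fit0$prior), c(0.5, 0.5))
  # ML: P(v1=0 | cls=0) = 2/2, P(v1=0 | cls=1) = 1/2 (v1 is the tree root)
  expect_identical(fit0$cpts$v1$parent, NA_character_)
  expect_equal(fit0$cpts$v1$table[1, 1, 1], 1.0)
  expect_equal(fit0$cpts$v1$table[1, 2, 1], 0.5)
  # Laplace: zero count with alpha = 1, binary variable, context count 3
  # gives (0 + 1) / (3 + 2) = 1/5
  coh3 <- cohort(data.frame(v1 = c(0, 0, 0, 1), v2 = c(1, 1, 1, 0),
                            cls = c(0, 0, 0, 1)), sch)
  st3 <- learn_tan_structure(coh3)
  fit1 <- estimate_cpts(st3, coh3, alpha = 1)
  # context (cls=0, parent v1=0) has 3 records, none with v2=0
  expect_equal(fit1$cpts$v2$table["s0", "c0", "s0"], 0.2)
  # unobserved contexts at alpha = 0 fall back to uniform with a warning each
  w <- capture_warnings(fit00 <- estimate_cpts(st3, coh3, alpha = 0))
  expect_match(w, "unobserved context", all = TRUE)
  expect_equal(unname(fit00$cpts$v2$table[, "c0", "s1"]), c(0.5, 0.5))
  # every CPT column is a distribution
  for (v in names(fit1$cpts)) {
    sums <- apply(fit1$cpts[[v]]$table, c(2, 3), sum)
    expect_equal(unname(sums), matrix(1, nrow(sums), ncol(sums)),
                 tolerance = 1e-9)
  }
})

test_that("ML fit preserves all class-attribute empirical marginals", {
  # Chow-Liu property at alpha = 0: model P(S, Vi) equals the empirical
  # joint for every attribute, checked by full-joint enumeration
  coh <- random_cohort(80, c(2L, 3L, 2L, 2L), seed = 31)
  fit <- suppressWarnings(fit_tan(coh))
  n <- nrow(coh)
  for (v in fit$structure$attributes) {
    k <- dim(fit$cpts[[v]]$table)[1L]
    for (j in 0:(k - 1L)) for (s in 0:1) {
      emp <- sum(coh[[v]] == j & coh$cls == s) / n
      mod <- enum_class_joint(fit, stats::setNames(j, v))[s + 1L]
      expect_equal(unname(mod), emp, tolerance = 1e-12)
    }
  }
})

test_that("model JSON serialization round-trips bit-exactly", {
  fit <- suppressWarnings(fit_tan(replica_counts_cohort(), alpha = 0.5))
  path <- withr::local_tempfile(fileext = ".json")
  write_tan_model(fit, path)
  back <- read_tan_model(path)
  expect_identical(back$prior, fit$prior)
  expect_identical(back$structure$edges, fit$structure$edges)
  expect_identical(back$alpha, fit$alpha)
  for (v in names(fit$cpts)) {
    expect_identical(back$cpts[[v]]$parent, fit$cpts[[v]]$parent)
    expect_identical(back$cpts[[v]]$table, fit$cpts[[v]]$table)
  }
  # restored model answers queries identically
  ev <- c(pvtt = 1L, tace = 0L)
  expect_identical(posterior(back, "survival_time", ev),
                   posterior(fit, "survival_time", ev))
})

test_that("CMI pruning yields a forest with class-only parents", {
  coh <- replica_counts_cohort()
  st <- learn_tan_structure(coh, cmi_threshold = Inf)
  expect_identical(nrow(st$edges), 0L)
  expect_identical(sort(st$roots), sort(st$attributes))
  fit <- fit_tan(coh, cmi_threshold = Inf)
  expect_true(all(vapply(fit$cpts, function(c) is.na(c$parent), logical(1))))
})
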