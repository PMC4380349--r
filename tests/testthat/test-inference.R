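uniform_model <- function(k_attr) {
  sch <- make_schema(rep(2L, k_attr))
  cpts <- lapply(stats::setNames(paste0("v", 1:k_attr), paste0("v", 1:k_attr)),
                 function(v) list(
    parent = NA_character_,
    table = array(0.5, dim = c(2, 2, 1),
                  dimnames = list(c("s0", "s1"), c("c0", "c1"), "."))))
  build_model(sch, data.frame(parent = character(0), child = character(0),
                              stringsAsFactors = FALSE),
              prior = c(c0 = 0.5, c1 = 0.5), cpts = cpts)
}

test_that("joint probability is the factorization product", {
  # all-uniform binary model with k attributes: every assignment has
  # probability 2^-(k+1), and the complete joint sums to one
  for (k in c(2L, 4L)) {
    m <- uniform_model(k)
    rec <- stats::setNames(rep(0L, k + 1L), c(paste0("v", 1:k), "cls"))
    expect_equal(joint_probability(m, rec), 2^-(k + 1L))
    grid <- expand.grid(rep(list(0:1), k + 1L))
    names(grid) <- c(paste0("v", 1:k), "cls")
    tot <- sum(vapply(seq_len(nrow(grid)), function(r)
      joint_probability(m, stats::setNames(as.integer(grid[r, ]),
                                           names(grid))), numeric(1)))
    expect_equal(tot, 1.0)
  }
  # random tree model: matches the term-by-term hand product
  m <- random_tan_model(4, seed = 7)
  rec <- c(v1 = 1L, v2 = 0L, v3 = 1L, v4 = 0L, cls = 1L)
  hand <- m$prior[[2]] *
    m$cpts$v1$table[2, 2, 1] *
    m$cpts$v2$table[1, 2, rec[[m$cpts$v2$parent]] + 1L] *
    m$cpts$v3$table[2, 2, rec[[m$cpts$v3$parent]] + 1L] *
    m$cpts$v4$table[1, 2, rec[[m$cpts$v4$parent]] + 1L]
  expect_equal(joint_probability(m, rec), hand)
  expect_error(joint_probability(m, c(v1 = 1L, cls = 0L)), "incomplete")
})

test_that("posterior with no evidence is the prior class marginal", {
  m <- random_tan_model(5, seed = 3)
  expect_equal(posterior(m, "cls"), m$prior / sum(m$prior))
})

test_that("tree message passing equals full-joint enumeration", {
  set.seed(99)
  for (i in 1:60) {
    n_attr <- sample(2:5, 1)
    m <- random_tan_model(n_attr, max_states = 3L, seed = 1000 + i,
                          tree = (i %% 3 != 0))  # include forests
    attrs <- m$structure$attributes
    n_ev <- sample(0:(n_attr - 1L), 1)
    ev_vars <- sample(attrs, n_ev)
    ev <- vapply(ev_vars, function(v)
      sample.int(dim(m$cpts[[v]]$table)[1L], 1) - 1L, integer(1))
    query <- sample(c(setdiff(attrs, ev_vars), "cls"), 1)
    expect_equal(posterior(m, query, ev), enum_posterior(m, query, ev),
                 tolerance = 1e-12)
  }
})

test_that("posterior is invariant to evidence order and rejects bad input", {
  m <- random_tan_model(4, seed = 17)
  ev <- c(v1 = 1L, v3 = 0L, v4 = 1L)
  expect_identical(posterior(m, "cls", ev), posterior(m, "cls", rev(ev)))
  expect_error(posterior(m, "cls", c(v1 = 1L, v1 = 0L)), "duplicate")
  expect_error(posterior(m, "v1", c(v1 = 1L)), "already in the evidence")
  expect_error(posterior(m, "cls", c(v1 = 5L)), "invalid state code")
  expect_error(posterior(m, "nope", c(v1 = 1L)), "unknown query")
})

test_that("contradictory evidence raises a zero-probability error", {
  sch <- make_schema(c(2L, 2L))
  # v2 deterministically copies v1, so v1 = 0 & v2 = 1 is impossible
  copy <- array(c(1, 0, 0, 1), dim = c(2, 2, 2))
  copy <- array(rep(c(1, 0, 0, 1), 2), dim = c(2, 2, 2),
                dimnames = list(c("s0", "s1"), c("c0", "c1"), c("s0", "s1")))
  copy[, 2, ] <- copy[, 1, ]
  m <- build_model(
    sch, data.frame(parent = "v1", child = "v2", stringsAsFactors = FALSE),
    prior = c(c0 = 0.5, c1 = 0.5),
    cpts = list(v1 = list(parent = NA_character_,
                          table = array(0.5, c(2, 2, 1),
                                        dimnames = list(c("s0", "s1"),
                                                        c("c0", "c1"), "."))),
                v2 = list(parent = "v1", table = copy)))
  expect_error(posterior(m, "cls", c(v1 = 0L, v2 = 1L)), "zero probability")
})

test_that("single-evidence posteriors at an ML fit are empirical frequencies", {
  for (seed in c(2, 8)) {
    coh <- generate_cohort(default_config(), n = 299, seed = seed)
    fit <- suppressWarnings(fit_tan(coh))
    cls <- "survival_time"
    for (v in c("pvtt", "afp", "tumor_size")) {
      for (j in unique(coh[[v]])) {
        emp <- sum(coh[[v]] == j & coh[[cls]] == 0L) / sum(coh[[v]] == j)
        got <- posterior(fit, cls, stats::setNames(j, v))[[1L]]
        expect_equal(got, emp, tolerance = 1e-12)
      }
    }
  }
})

test_that("classification threshold is strict", {
  m <- uniform_model(3)  # posterior long-survival is exactly 0.5 everywhere
  rec <- c(v1 = 0L, v2 = 1L, v3 = 0L)
  expect_identical(classify(m, rec, threshold = 0.5)$label, "c0")
  expect_identical(classify(m, rec, threshold = 0.49)$label, "c1")
  expect_identical(classify(m, rec, threshold = 0)$label, "c1")
  expect_equal(classify(m, rec)$probability, 0.5)
  expect_error(classify(m, c(v1 = 0L), 0.5), "missing")
})

test_that("labels change only at predicted-probability values", {
  coh <- generate_cohort(default_config(), n = 60, seed = 4)
  fit <- suppressWarnings(fit_tan(coh))
  probs <- predict(fit, coh)$probability
  for (t in c(0, sort(unique(probs)), 1)) {
    lab <- predict(fit, coh, threshold = t)$label
    expect_identical(lab == ">10m", probs > t)
  }
})

test_that("scenario_query is consistent with classify and enumeration", {
  m <- random_tan_model(4, seed = 23)
  rec <- c(v1 = 1L, v2 = 0L, v3 = 1L, v4 = 1L)
  sq <- scenario_query(m, rec)
  expect_equal(unname(sq$class[2L]), classify(m, rec)$probability)
  expect_identical(length(sq$attributes), 0L)
  partial <- c(v2 = 0L, v4 = 1L)
  sq2 <- scenario_query(m, partial, targets = c("v1", "v3"))
  expect_equal(sq2$class, enum_posterior(m, "cls", partial))
  expect_equal(sq2$attributes$v1, enum_posterior(m, "v1", partial))
  expect_equal(sq2$attributes$v3, enum_posterior(m, "v3", partial))
  expect_error(scenario_query(m, c(cls = 0L)), "class")
  expect_error(scenario_query(m, partial, targets = "v2"), "not free")
})
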