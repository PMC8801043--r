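# Corpus sampling, generation, splitting and scaling.

degenerate_ranges <- function() {
  rg <- scar_ranges()
  for (nm in varied_names(rg)) {
    rg[[nm]]$min <- rg[[nm]]$max <- rg[[nm]]$value
  }
  rg
}

test_that("degenerate ranges give a deterministic parameter set", {
  rg <- degenerate_ranges()
  p1 <- sample_params(rg, seed = 3L)
  p2 <- sample_params(rg, seed = 99L)
  for (nm in varied_names(rg)) {
    expect_identical(p1[[nm]], rg[[nm]]$value)
    expect_identical(p2[[nm]], p1[[nm]])
  }
  expect_identical(attr(p1, "rejections"), 0L)
})

test_that("ranges incompatible with stability raise a configuration error", {
  rg <- scar_ranges()
  # secretion range entirely above the largest possible decay threshold
  rg$k_c$min <- 1e-10
  rg$k_c$max <- 2e-10
  expect_error(sample_params(rg, seed = 1L, max_rejections = 200),
               "stability")
})

test_that("rejection sampling matches an independent Monte-Carlo acceptance estimate", {
  rg <- scar_ranges()
  n <- 300
  rejections <- vapply(seq_len(n), function(i) {
    attr(sample_params(rg, seed = 1000L + i), "rejections")
  }, 0L)
  attempts <- n + sum(rejections)
  p_emp <- n / attempts
  # independent estimate of P(k_c < delta_c rho_bar a_c_II) over the box
  set.seed(77)
  m <- 1e4
  kc <- runif(m, rg$k_c$min, rg$k_c$max)
  dc <- runif(m, rg$delta_c$min, rg$delta_c$max)
  rb <- runif(m, rg$rho_bar$min, rg$rho_bar$max)
  a2 <- runif(m, rg$a_c_II$min, rg$a_c_II$max)
  p_mc <- mean(kc < dc * rb * a2)
  se <- p_mc * sqrt((1 - p_mc) / n) + sqrt(p_mc * (1 - p_mc) / m)
  expect_lt(abs(p_emp - p_mc), 3 * se)
})

test_that("a generated corpus has the contracted shapes and admissible targets", {
  corp <- fixture_corpus()
  expect_equal(dim(corp$X), c(24, 25))
  expect_equal(dim(corp$Y), c(24, 365))
  expect_true(all(corp$Y > 0 & corp$Y <= 1))
  # every accepted row satisfies the stability inequality (post-hoc recheck)
  thr <- corp$X[, "delta_c"] * corp$X[, "rho_bar"] * corp$X[, "a_c_II"]
  expect_true(all(corp$X[, "k_c"] < thr))
})

test_that("corpora are reproducible from the master seed", {
  rg <- scar_ranges()
  c1 <- generate_corpus(3, rg, mesh = scar_mesh(10, 51), master_seed = 5L)
  c2 <- generate_corpus(3, rg, mesh = scar_mesh(10, 51), master_seed = 5L)
  expect_identical(c1$X, c2$X)
  expect_identical(c1$Y, c2$Y)
  c3 <- generate_corpus(3, rg, mesh = scar_mesh(10, 51), master_seed = 6L)
  expect_false(identical(c1$X, c3$X))
})

test_that("split, folds and Min-Max scaling satisfy their identities", {
  fake <- list(X = matrix(runif(10 * 25), 10, 25,
                          dimnames = list(NULL, varied_names(scar_ranges()))),
               Y = matrix(runif(10 * 20, 0.4, 1), 10, 20))
  sp <- split_and_scale(fake, train_fraction = 0.8, n_folds = 4, seed = 2L)
  expect_equal(nrow(sp$X_train), 8)
  expect_equal(nrow(sp$X_test), 2)
  # folds partition the training rows
  all_idx <- sort(unname(unlist(sp$folds)))
  expect_identical(all_idx, 1:8)
  for (i in seq_along(sp$folds)) {
    for (j in seq_len(i - 1)) {
      expect_length(intersect(sp$folds[[i]], sp$folds[[j]]), 0)
    }
  }
  # train and test rows are disjoint and cover the corpus
  expect_length(intersect(sp$idx_train, sp$idx_test), 0)
  expect_identical(sort(c(sp$idx_train, sp$idx_test)), 1:10)
  # Min-Max identity on the training block
  expect_equal(unname(apply(sp$Xs_train, 2, min)), rep(0, 25))
  expect_equal(unname(apply(sp$Xs_train, 2, max)), rep(1, 25))
  # the scaler depends on the training rows only
  refit <- fit_scaler(sp$X_train)
  expect_equal(refit$min, sp$scaler$min)
  expect_equal(refit$max, sp$scaler$max)
  expect_error(split_and_scale(fake, n_folds = 20), "folds")
})

test_that("a corpus round-trips through its directory container", {
  corp <- fixture_corpus()
  dir <- tempfile("corpus")
  write_corpus(corp, dir)
  expect_true(all(file.exists(file.path(dir, c("X.csv", "Y.csv",
                                               "seeds.csv", "meta.json")))))
  back <- read_corpus(dir)
  expect_equal(back$X, corp$X, tolerance = 1e-12)
  expect_equal(back$Y, corp$Y, tolerance = 1e-12)
  expect_identical(back$seeds, corp$seeds)
  expect_equal(back$control$days, corp$control$days)
})
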