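test_that("logistic loss matches its closed forms", {
  X <- matrix(c(1, 0, 0, 1), 2, 2)
  y <- c(1, -1)
  expect_equal(logistic_loss(rep(0, 2), 0, X, y), log(2))
  # single sample with margin log 3 -> loss log(4/3)
  expect_equal(logistic_loss(c(log(3), 0), 0,
                             matrix(c(1, 0), 1), 1, 1),
               log(4 / 3))
  # huge margins for every sample drive the loss to zero
  expect_equal(logistic_loss(c(500, -500), 0, X, y), 0)
  # weighted mean: weights scale sample contributions
  expect_equal(logistic_loss(c(1, 0), 0, X, y, w = c(3, 1)),
               (3 * log(1 + exp(-1)) + log(2)) / 4)
})

test_that("penalty combines L1 and weighted group norms", {
  g <- group_structure(data.frame(bit_index = 0:1, group = "g1",
                                  position = 1:2, char = "A"))
  g$weight <- 1
  expect_equal(penalty(c(0, 0), g, 1, 1), 0)
  expect_equal(penalty(c(3, 4), g, 0, 1), 5)
  expect_equal(penalty(c(1, -2), g, 1, 0), 3)
  g2 <- group_structure(data.frame(bit_index = 0:3,
                                   group = rep(c("a", "b"), each = 2),
                                   position = 1:4, char = "A"))
  expect_equal(penalty(c(3, 4, 1, 0), g2, 0.5, 2),
               0.5 * 8 + 2 * sqrt(2) * (5 + 1))
})

test_that("prox operator matches its spec examples", {
  g <- group_structure(data.frame(bit_index = 0:1, group = "g1",
                                  position = 1:2, char = "A"))
  g$weight <- 1
  z <- c(3, 4)
  expect_equal(prox_sgl(z, 1, 0, 0, g), z)                 # identity
  expect_equal(prox_sgl(z, 1, 0, 2.5, g), c(1.5, 2))       # block shrink
  expect_equal(prox_sgl(c(0.5, -0.2), 1, 1, 0.7, g), c(0, 0))
})

test_that("prox operator matches exhaustive enumeration on random instances", {
  worst <- 0
  withr::with_seed(99, {
    for (trial in 1:200) {
      d <- sample(1:6, 1)
      g <- random_groups(d, sample(1:min(3, d), 1))
      z <- rnorm(d, sd = 2)
      t <- runif(1, 0.1, 2)
      l1 <- runif(1)
      l2 <- runif(1)
      u <- prox_sgl(z, t, l1, l2, g)
      worst <- max(worst, max(abs(u - prox_oracle(z, t, l1, l2, g))))
    }
  })
  expect_lt(worst, 1e-6)
})

test_that("lambda_max agrees with a finite-difference gradient at zero", {
  prob <- make_logit_problem(30, 6, seed = 5)
  w <- rep(1, 30)
  c0 <- log(sum(prob$y == 1) / sum(prob$y == -1))
  eps <- 1e-6
  fd <- vapply(seq_len(6), function(j) {
    e <- numeric(6); e[j] <- eps
    (logistic_loss(e, c0, prob$X, prob$y, w) -
       logistic_loss(-e, c0, prob$X, prob$y, w)) / (2 * eps)
  }, numeric(1))
  expect_equal(lambda_max(prob$X, prob$y, w), max(abs(fd)),
               tolerance = 1e-6)
  # duplicated columns score identically, all-zero X scores 0
  X2 <- cbind(prob$X[, 1], prob$X[, 1])
  g2 <- matrix(c(1, 1), 1)
  expect_equal(lambda_max(matrix(0, 10, 3), rep(c(1, -1), 5)), 0)
})

test_that("unpenalized fit matches the IRLS logistic oracle", {
  prob <- make_logit_problem()
  m <- fit_sgl_logistic(prob$X, prob$y, groups = prob$groups,
                        lambda1 = 0, lambda2 = 0,
                        opts = fit_options(tol = 1e-13, max_iter = 50000))
  ref <- stats::glm.fit(cbind(1, prob$X), (prob$y + 1) / 2,
                        family = stats::binomial())
  expect_equal(m$beta, unname(ref$coefficients[-1]), tolerance = 1e-4)
  expect_equal(m$intercept, unname(ref$coefficients[1]), tolerance = 1e-4)
})

test_that("lambda1 = 1 gives the exact null model", {
  prob <- make_logit_problem()
  m <- fit_sgl_logistic(prob$X, prob$y, groups = prob$groups,
                        lambda1 = 1, lambda2 = 0)
  expect_identical(m$beta, rep(0, 10))
  expect_equal(m$intercept,
               log(sum(prob$y == 1) / sum(prob$y == -1)),
               tolerance = 1e-6)
})

test_that("objective is non-increasing over accepted iterates", {
  prob <- make_logit_problem()
  for (lam in list(c(0, 0), c(0.1, 0.1), c(0.05, 0.4), c(0.5, 0.05))) {
    m <- fit_sgl_logistic(prob$X, prob$y, groups = prob$groups,
                          lambda1 = lam[1], lambda2 = lam[2])
    expect_true(all(diff(m$objective) <= 1e-12),
                label = paste("lambda =", paste(lam, collapse = ",")))
  }
  p <- planted()
  m <- fit_sgl_logistic(p$enc$X, p$y, groups = p$groups)
  expect_true(all(diff(m$objective) <= 1e-12))
})

test_that("no_group_penalty reduces to the plain L1 logistic solution", {
  skip_if_not_installed("glmnet")
  prob <- make_logit_problem()
  m <- fit_sgl_logistic(prob$X, prob$y, groups = prob$groups,
                        lambda1 = 0.3, lambda2 = 0.9,
                        opts = fit_options(tol = 1e-13, max_iter = 50000,
                                           no_group_penalty = TRUE))
  lam_abs <- 0.3 * lambda_max(prob$X, prob$y)
  ref <- glmnet::glmnet(prob$X, factor(prob$y), family = "binomial",
                        lambda = lam_abs, standardize = FALSE,
                        thresh = 1e-14, maxit = 1e6)
  expect_equal(m$beta, as.numeric(ref$beta), tolerance = 1e-4)
  expect_equal(m$intercept, as.numeric(ref$a0), tolerance = 1e-4)
})

test_that("replicates as weights equal physically duplicated rows", {
  prob <- make_logit_problem(20, 5, seed = 21)
  reps <- withr::with_seed(8, sample(1:3, 20, replace = TRUE))
  Xdup <- prob$X[rep(seq_len(20), reps), ]
  ydup <- prob$y[rep(seq_len(20), reps)]
  g <- group_structure(data.frame(bit_index = 0:4, group = "g1",
                                  position = 1:5, char = "A"))
  opts <- fit_options(tol = 1e-14, max_iter = 100000)
  m1 <- fit_sgl_logistic(prob$X, prob$y, w = reps, groups = g,
                         lambda1 = 0.1, lambda2 = 0.1, opts = opts)
  m2 <- fit_sgl_logistic(Xdup, ydup, groups = g,
                         lambda1 = 0.1, lambda2 = 0.1, opts = opts)
  expect_equal(m1$beta, m2$beta, tolerance = 1e-8)
  expect_equal(m1$intercept, m2$intercept, tolerance = 1e-8)
})

test_that("group sparsity is non-increasing along the lambda2 ladder", {
  p <- planted()
  counts <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(l2) {
    n_groups_selected(fit_sgl_logistic(p$enc$X, p$y, groups = p$groups,
                                       lambda1 = 0.05, lambda2 = l2))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("solver validates inputs", {
  prob <- make_logit_problem()
  expect_error(fit_sgl_logistic(prob$X, rep(1, 40), groups = prob$groups),
               "one class empty")
  expect_error(fit_sgl_logistic(prob$X, prob$y, groups = prob$groups,
                                lambda1 = 1.5), "lambda")
  Xbad <- prob$X; Xbad[1, 1] <- NA
  expect_error(fit_sgl_logistic(Xbad, prob$y, groups = prob$groups),
               "non-finite")
})

test_that("group weight files load and apply", {
  dir <- withr::local_tempdir()
  gw <- file.path(dir, "gw.txt")
  writeLines(c("g1\t2.5", "g2\t0.5"), gw)
  w <- read_group_weights(gw)
  expect_equal(w, c(g1 = 2.5, g2 = 0.5))
  fm <- data.frame(bit_index = 0:3, group = rep(c("g1", "g2"), each = 2),
                   position = 1:4, char = "A")
  g <- group_structure(fm, w)
  expect_equal(g$weight, c(2.5, 0.5))
  expect_error(group_structure(fm, c(zz = 1)), "unknown group")
  writeLines(c("g1\t2.5", "g1\t1"), gw)
  expect_error(read_group_weights(gw), "duplicate")
})
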