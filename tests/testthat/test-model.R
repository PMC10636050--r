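test_that("leaky_relu follows max(0.01 x, x)", {
  expect_equal(leaky_relu(2.0), 2.0)
  expect_equal(leaky_relu(-1.0), -0.01)
  expect_equal(leaky_relu(0.0), 0.0)
  x <- seq(-3, 3, by = 0.25)
  expect_equal(leaky_relu(x), pmax(0.01 * x, x))
})

test_that("initialization is seed-reproducible and counts parameters", {
  cfg <- model_config(n_genes = 10, seed = 42)
  expect_identical(init_model(cfg)$theta, init_model(cfg)$theta)
  m10 <- init_model(model_config(n_genes = 10))
  m100 <- init_model(model_config(n_genes = 100))
  expect_equal(length(m100$theta) - length(m10$theta), 90L)
  # |G| + n_genes + 1 across a grid, for several widths
  for (h in c(1L, 4L, 32L)) for (g in c(1L, 7L, 50L, 691L)) {
    cfg <- model_config(n_genes = g, g_hidden_width = h)
    expect_equal(n_params(cfg), (13L * h + 1L) + g + 1L)
    expect_equal(length(init_model(cfg)$theta), n_params(cfg))
  }
})

test_that("flatten/unflatten round trip is the identity", {
  m <- init_model(model_config(n_genes = 6, g_hidden_width = 3, seed = 2))
  u <- unflatten_params(m)
  flat <- c(as.numeric(u$W1), u$b1, u$w2, u$b2, u$wf, u$bf)
  expect_identical(flat, flatten_params(m))
  expect_identical(set_theta(m, flatten_params(m))$theta, m$theta)
})

test_that("forward matches a hand-computed single-gene composition", {
  cfg <- model_config(n_genes = 1, g_hidden_width = 1, seed = 1)
  m <- init_model(cfg)
  W1 <- seq(-0.5, 0.5, length.out = 11); b1 <- 0.2
  w2 <- -1.5; b2 <- 0.1; wf <- 2.0; bf <- -0.3
  m <- set_theta(m, c(W1, b1, w2, b2, wf, bf))
  x <- matrix(c(3, 0, 1, 0, 0, 2, 0, 5, 0, -0.7, 4.2), ncol = 1)
  h1 <- max(0.01 * (sum(W1 * x) + b1), sum(W1 * x) + b1)
  s <- max(0.01 * (w2 * h1 + b2), w2 * h1 + b2)
  z <- wf * s + bf
  expect_equal(forward(m, x), 1 / (1 + exp(-z)), tolerance = 1e-12)
})

test_that("forward edge cases: zero parameters and eval determinism", {
  cfg <- model_config(n_genes = 4, g_hidden_width = 2)
  m <- set_theta(init_model(cfg), rep(0, n_params(cfg)))
  x <- matrix(rnorm(44), 11, 4)
  expect_equal(forward(m, x), 0.5)
  m2 <- init_model(cfg)
  expect_identical(forward(m2, x), forward(m2, x))
  co <- tiny_cohort(3, 3, n_genes = 4)
  expect_identical(predict_proba(m2, co), predict_proba(m2, co))
  expect_error(forward(m2, matrix(0, 11, 5)), "n_genes")
})

test_that("weight sharing: permuting genes and final weights together is a no-op", {
  cfg <- model_config(n_genes = 7, g_hidden_width = 5, seed = 3)
  m <- init_model(cfg)
  x <- matrix(abs(rnorm(77)), 11, 7)
  perm <- c(4, 1, 7, 2, 6, 3, 5)
  u <- unflatten_params(m)
  m_perm <- set_theta(m, c(as.numeric(u$W1), u$b1, u$w2, u$b2,
                           u$wf[perm], u$bf))
  expect_equal(forward(m, x), forward(m_perm, x[, perm]), tolerance = 1e-12)
})

test_that("bce_loss evaluates the cross-entropy formula", {
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(0.9, 0), -log(0.1))
  expect_lt(bce_loss(1 - 1e-12, 1), 1e-10)
  expect_lt(bce_loss(1e-12, 0), 1e-10)
  expect_true(is.finite(bce_loss(1, 1)))  # clamped
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(n_genes = 2, g_hidden_width = 3, seed = 11,
                      l2_lambda = 0.5, dropout_p = 0)
  m <- init_model(cfg)
  co <- tiny_cohort(4, 4, n_genes = 2, seed = 5)
  X <- aperm(co$tensor, c(2, 3, 1))
  g <- drop(fedgi:::cdk_grad_cpp(m$theta, X, as.numeric(co$labels),
                                 m$hidden, cfg$l2_lambda)$grad)
  eps <- 1e-6
  fd <- vapply(seq_along(m$theta), function(i) {
    up <- m$theta; up[i] <- up[i] + eps
    dn <- m$theta; dn[i] <- dn[i] - eps
    (fedgi:::penalized_loss(set_theta(m, up), co$tensor, co$labels, cfg$l2_lambda) -
     fedgi:::penalized_loss(set_theta(m, dn), co$tensor, co$labels, cfg$l2_lambda)) /
      (2 * eps)
  }, 0)
  expect_lt(max(rel_err(g, fd)), 1e-4)
})

test_that("training descends on separable data and is bit-reproducible", {
  co <- tiny_cohort(10, 10, n_genes = 8, effect = 3, seed = 21)
  cfg <- model_config(n_genes = 8, epochs = 50, seed = 13)
  m <- init_model(cfg)
  fit <- train_local(m, co, cfg)
  expect_length(fit$trace, 50)
  expect_lt(fit$trace[50], fit$trace[1])
  fit2 <- train_local(m, co, cfg)
  expect_identical(fit$model$theta, fit2$model$theta)
  expect_identical(fit$trace, fit2$trace)
})

test_that("strong L2 shrinks weights relative to no penalty", {
  co <- tiny_cohort(8, 8, n_genes = 5, seed = 31)
  base <- model_config(n_genes = 5, epochs = 40, seed = 17, dropout_p = 0)
  m <- init_model(base)
  free <- base; free$l2_lambda <- 0
  heavy <- base; heavy$l2_lambda <- 1000
  th_free <- train_local(m, co, free)$model$theta
  th_heavy <- train_local(m, co, heavy)$model$theta
  expect_lt(sqrt(sum(th_heavy^2)), 0.1 * sqrt(sum(th_free^2)))
})

test_that("single-class cohorts warn but train", {
  panel <- generate_panel(panel_spec(4), 1)
  co <- generate_center_cohort(center_spec("P", 6, 0, seed = 2), panel)
  cfg <- model_config(n_genes = 4, epochs = 3, seed = 1)
  expect_warning(fit <- train_local(init_model(cfg), co, cfg), "single-class")
  expect_length(fit$trace, 3)
})

test_that("checkpoints round-trip through disk", {
  cfg <- model_config(n_genes = 6, g_hidden_width = 4, seed = 8)
  co <- tiny_cohort(4, 4, n_genes = 6, seed = 3)
  cfg$epochs <- 5L
  m <- train_local(init_model(cfg), co, cfg)$model
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(m, path)
  back <- read_checkpoint(path)
  expect_identical(back$theta, m$theta)
  expect_equal(back$config$n_genes, 6L)
  x <- co$tensor[1, , ]
  expect_identical(forward(back, x), forward(m, x))
})
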