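test_that("single-batch global fit recovers mean, zero offset, ML variance", {
  set.seed(3)
  vals <- matrix(rnorm(8 * 12, 5, 2), 8, 12)
  Y <- meth_matrix(vals, scale = "M")
  sheet <- sample_sheet(colnames(Y), rep("only", 12))
  gp <- estimate_global_params(Y, build_design(sheet))
  expect_equal(unname(gp$global$alpha), rowMeans(vals))
  expect_equal(unname(gp$gamma_hat[, 1]), rep(0, 8))
  pop_var <- rowMeans((vals - rowMeans(vals))^2)  # divisor N, not N-1
  expect_equal(unname(gp$global$sigma2), pop_var)
})

test_that("two equal batches give the closed-form mean/offset decomposition", {
  vals <- rbind(c(1, 3, 5, 7), c(2, 4, 10, 14))  # two samples per batch
  Y <- meth_matrix(vals, scale = "M")
  sheet <- sample_sheet(colnames(Y), rep(c("a", "b"), each = 2))
  gp <- estimate_global_params(Y, build_design(sheet))
  mu1 <- rowMeans(vals[, 1:2]); mu2 <- rowMeans(vals[, 3:4])
  expect_equal(unname(gp$global$alpha), (mu1 + mu2) / 2)
  expect_equal(unname(gp$gamma_hat[, "a"]), (mu1 - mu2) / 2)
})

test_that("identifiability constraint holds and OLS matches lm oracle", {
  ds <- simulate_methylation("S1", 11)
  design <- build_design(ds$sheet)
  gp <- estimate_global_params(ds$Y, design)
  n_i <- design$n_per_batch
  expect_lt(max(abs(gp$gamma_hat %*% n_i)), 1e-9)

  # brute-force normal-equations oracle on a small instance, via lm()
  fx <- tiny_two_batch(G = 15, n1 = 14, n2 = 12)
  d <- build_design(fx$sheet)
  gp2 <- estimate_global_params(fx$Y, d)
  for (g in c(1, 7, 15)) {
    fit <- lm(unclass(fx$Y)[g, ] ~ 0 + d$X)
    th <- unname(coef(fit))
    w <- d$n_per_batch / sum(d$n_per_batch)
    alpha_o <- sum(w * th[1:2])
    expect_equal(unname(gp2$global$alpha[g]), alpha_o, tolerance = 1e-10)
    expect_equal(unname(gp2$gamma_hat[g, ]), th[1:2] - alpha_o,
                 tolerance = 1e-10)
    expect_equal(unname(gp2$global$beta_cov[g, ]), th[3:4],
                 tolerance = 1e-10)
    expect_equal(unname(gp2$global$sigma2[g]),
                 mean(residuals(fit)^2), tolerance = 1e-10)
  }
})

test_that("standardization divides centred residuals by sigma", {
  fx <- tiny_two_batch(G = 10)
  d <- build_design(fx$sheet)
  gp <- estimate_global_params(fx$Y, d)
  Z <- standardize_mvalues(fx$Y, gp$global, d$X_cov)
  # exact reconstruction: Y = alpha + X beta + sigma * Z
  rebuilt <- gp$global$alpha + gp$global$beta_cov %*% t(d$X_cov) +
    gp$global$sigma * Z
  expect_equal(rebuilt, unclass(fx$Y), ignore_attr = TRUE)
  # single batch: Z has per-site mean 0 and population variance 1
  set.seed(9)
  Y1 <- meth_matrix(matrix(rnorm(6 * 20, 3, 2), 6, 20), scale = "M")
  sh1 <- sample_sheet(colnames(Y1), rep("x", 20))
  d1 <- build_design(sh1)
  gp1 <- estimate_global_params(Y1, d1)
  Z1 <- standardize_mvalues(Y1, gp1$global, d1$X_cov)
  expect_equal(rowMeans(Z1), rep(0, 6), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rowMeans(Z1^2), rep(1, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero-variance sites are rejected or dropped per flag", {
  fx <- tiny_two_batch(G = 6)
  vals <- unclass(fx$Y)
  vals[4, ] <- 2.5
  Yc <- meth_matrix(vals, scale = "M")
  expect_error(combat_fit(Yc, fx$sheet), "zero-variance")
  fit <- suppressMessages(combat_fit(Yc, fx$sheet, drop_zero_variance = TRUE))
  expect_equal(nrow(fit$corrected), 5L)
})

test_that("hyperprior moment matching reproduces the printed identities", {
  # gamma side: constant offsets give tau2 = 0
  hp0 <- estimate_hyperpriors(rep(0.7, 50), seq(0.5, 1.5, length.out = 50))
  expect_equal(hp0$gamma_bar, 0.7)
  expect_equal(hp0$tau2_bar, 0)
  # a = 1, s2 = 0.5 closed forms: zeta = a^2/s2 + 2, theta = a (a^2/s2 + 1)
  hp <- estimate_hyperpriors(c(-1, 1), c(0.5, 1.5))
  expect_equal(hp$a, 1)
  expect_equal(hp$s2, 0.5)
  expect_equal(hp$zeta_bar, 1 / 0.5 + 2)
  expect_equal(hp$theta_bar, 1 * (1 / 0.5 + 1))
  # inverse-gamma mean/variance identities for an arbitrary positive vector
  set.seed(4)
  dh <- rexp(200) + 0.1
  hp2 <- estimate_hyperpriors(rnorm(200), dh)
  a <- mean(dh); s2 <- var(dh)
  expect_equal(hp2$theta_bar / (hp2$zeta_bar - 1), a, tolerance = 1e-8)
  expect_equal(hp2$theta_bar^2 / ((hp2$zeta_bar - 1)^2 * (hp2$zeta_bar - 2)),
               s2, tolerance = 1e-8)
  expect_error(estimate_hyperpriors(rnorm(10), rep(1, 10)), "degenerate")
})

test_that("EB estimates hit the fixed point and shrink between the limits", {
  fx <- tiny_two_batch(G = 60)
  d <- build_design(fx$sheet)
  gp <- estimate_global_params(fx$Y, d)
  Z <- standardize_mvalues(fx$Y, gp$global, d$X_cov)
  idx <- which(fx$sheet$batch == "A")
  Z_i <- Z[, idx]
  n_i <- length(idx)
  ghat <- rowMeans(Z_i)
  d2hat <- rowSums((Z_i - ghat)^2) / (n_i - 1)
  hp <- estimate_hyperpriors(ghat, d2hat)
  eb <- eb_batch_estimates(Z_i, hp, ghat, d2hat, tol = 1e-6)

  # substituting the converged solution back reproduces both equations
  g_up <- (n_i * hp$tau2_bar * ghat + eb$delta2_star * hp$gamma_bar) /
    (n_i * hp$tau2_bar + eb$delta2_star)
  sum2 <- rowSums((Z_i - g_up)^2)
  d_up <- (hp$theta_bar + sum2 / 2) / (n_i / 2 + hp$zeta_bar - 1)
  expect_lt(max(abs(g_up - eb$gamma_star) / pmax(abs(eb$gamma_star), 1e-12)),
            1e-4)
  expect_lt(max(abs(d_up - eb$delta2_star) / eb$delta2_star), 1e-4)

  # shrinkage geometry: gamma* lies between gamma_hat and gamma_bar
  expect_true(all(abs(eb$gamma_star - hp$gamma_bar) <=
                    abs(ghat - hp$gamma_bar) + 1e-12))
  expect_true(all(eb$delta2_star > 0))

  # limits of the location update
  hp_big <- hp; hp_big$tau2_bar <- 1e12
  eb_big <- eb_batch_estimates(Z_i, hp_big, ghat, d2hat)
  expect_equal(eb_big$gamma_star, ghat, tolerance = 1e-6)
  hp_zero <- hp; hp_zero$tau2_bar <- 0
  eb_zero <- eb_batch_estimates(Z_i, hp_zero, ghat, d2hat)
  expect_equal(unname(eb_zero$gamma_star),
               rep(hp$gamma_bar, length(ghat)), tolerance = 1e-8)
})

test_that("identity batch parameters leave the data unchanged", {
  fx <- tiny_two_batch(G = 12)
  d <- build_design(fx$sheet)
  gp <- estimate_global_params(fx$Y, d)
  Z <- standardize_mvalues(fx$Y, gp$global, d$X_cov)
  idm <- list(gamma_star = rep(0, 12), delta2_star = rep(1, 12))
  out <- apply_correction(Z, fx$sheet$batch,
                          list(A = idm, B = idm), gp$global, d$X_cov)
  expect_equal(unclass(out), unclass(fx$Y), tolerance = 1e-12)
  expect_error(apply_correction(Z, factor(rep("C", ncol(Z))),
                                list(A = idm), gp$global, d$X_cov),
               "no batch parameters")
})

test_that("correction removes an injected batch shift", {
  set.seed(21)
  G <- 80; n <- 800
  vals <- matrix(rnorm(G * 2 * n, 5, 1), G, 2 * n)
  vals[, (n + 1):(2 * n)] <- vals[, (n + 1):(2 * n)] + 5
  Y <- meth_matrix(vals, scale = "M")
  sheet <- sample_sheet(colnames(Y), rep(c("a", "b"), each = n))
  fit <- combat_fit(Y, sheet)
  corr <- unclass(fit$corrected)
  gap <- abs(rowMeans(corr[, 1:n]) - rowMeans(corr[, (n + 1):(2 * n)]))
  expect_lt(max(gap), 0.1)
})

test_that("full fit matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  ds <- simulate_methylation("S1", 23)
  fit <- combat_fit(ds$Y, ds$sheet)
  mod <- model.matrix(~ group + age, data = ds$sheet$covariates)
  ref <- suppressMessages(sva::ComBat(unclass(ds$Y),
                                      batch = ds$sheet$batch, mod = mod))
  # both solve the same fixed point to a 1e-4 relative stopping rule
  expect_lt(max(abs(unclass(fit$corrected) - ref)), 1e-3)
})

test_that("fitting is deterministic and the model is self-consistent", {
  fx <- tiny_two_batch()
  f1 <- combat_fit(fx$Y, fx$sheet)
  f2 <- combat_fit(fx$Y, fx$sheet)
  expect_identical(unclass(f1$corrected), unclass(f2$corrected))
  expect_identical(f1$model$batches$A$gamma_star, f2$model$batches$A$gamma_star)
  expect_equal(names(f1$model$batches), c("A", "B"))
  expect_equal(f1$model$global$n_total, ncol(fx$Y))
})

test_that("mean-only mode fixes delta at 1 and shifts only the means", {
  fx <- tiny_two_batch(G = 50)
  fit <- combat_fit(fx$Y, fx$sheet, mean_only = TRUE)
  expect_equal(unname(fit$model$batches$A$delta2_star), rep(1, 50))
  expect_equal(fit$model$batches$A$eb_iterations, 0L)
  # with delta* = 1 the correction reduces to Y - sigma_g * gamma*_ig: a
  # per-(site, batch) constant shift, so within-batch variances are intact
  raw <- unclass(fx$Y); corr <- unclass(fit$corrected)
  for (lab in c("A", "B")) {
    idx <- fx$sheet$batch == lab
    expect_equal(apply(corr[, idx], 1, var), apply(raw[, idx], 1, var),
                 tolerance = 1e-12)
    shift <- corr[, idx] - raw[, idx]
    expect_lt(max(apply(shift, 1, function(x) diff(range(x)))), 1e-12)
  }
  # single-sample batches are allowed only in mean-only mode
  Y1 <- fx$Y[, c(1:12, 13)]
  sh1 <- sample_sheet(colnames(Y1),
                      c(rep("A", 12), "solo"),
                      fx$sheet$covariates[c(1:12, 13), ])
  expect_error(combat_fit(Y1, sh1), "fewer than 2")
  fit1 <- combat_fit(Y1, sh1, mean_only = TRUE)
  expect_equal(unname(fit1$model$batches$solo$delta2_star), rep(1, 50))
})
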