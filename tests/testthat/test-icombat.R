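fit_existing_s1 <- function(seed = 31) {
  ds <- simulate_methylation("S1", seed)
  parts <- split_existing_new(ds)
  list(ds = ds, parts = parts,
       fit = combat_fit(parts$existing$Y, parts$existing$sheet))
}

test_that("a null new batch is corrected almost to identity", {
  set.seed(12)
  G <- 200; n_ex <- 80; n_new <- 40
  # existing: two batches with mild shifts; new: drawn from the global model
  vals <- matrix(rnorm(G * n_ex, 5, 1), G, n_ex)
  vals[, 41:80] <- vals[, 41:80] + 2
  group <- rep_len(c(0, 1), n_ex); age <- rnorm(n_ex, 50, 10)
  vals <- vals + outer(rep(0.4, G), group) + outer(rep(0.01, G), age)
  Y <- meth_matrix(vals, scale = "M")
  sheet <- sample_sheet(colnames(Y), rep(c("e1", "e2"), each = 40),
                        data.frame(group = group, age = age))
  fit <- combat_fit(Y, sheet)
  gl <- fit$model$global
  gnew <- rep_len(c(0, 1), n_new); anew <- rnorm(n_new, 50, 10)
  Xn <- cbind(group = gnew, age = anew)
  vnew <- gl$alpha + gl$beta_cov %*% t(Xn) +
    gl$sigma * matrix(rnorm(G * n_new), G, n_new)
  Yn <- meth_matrix(vnew, scale = "M", site_ids = rownames(Y),
                    sample_ids = paste0("n", seq_len(n_new)))
  shn <- sample_sheet(colnames(Yn), rep("newb", n_new),
                      data.frame(group = gnew, age = anew))
  res <- icombat_correct(Yn, shn, fit$model)
  bp <- res$model$batches$newb
  expect_lt(abs(mean(bp$gamma_star)), 0.1)
  expect_lt(abs(mean(bp$delta2_star) - 1), 0.2)
  expect_lt(mean(abs(unclass(res$corrected) - unclass(Yn))), 0.2)
})

test_that("incremental addition leaves every stored parameter untouched", {
  x <- fit_existing_s1()
  model_before <- x$fit$model
  res <- icombat_correct(x$parts$new[[1]]$Y, x$parts$new[[1]]$sheet,
                         model_before)
  expect_identical(res$model$global, model_before$global)
  expect_identical(res$model$batches[names(model_before$batches)],
                   model_before$batches)
  expect_equal(length(res$model$batches), length(model_before$batches) + 1L)
})

test_that("incremental and all-batch corrections agree to high correlation", {
  x <- fit_existing_s1()
  res <- icombat_correct(x$parts$new[[1]]$Y, x$parts$new[[1]]$sheet,
                         x$fit$model)
  icomb <- cbind(unclass(x$fit$corrected), unclass(res$corrected))
  icomb <- icomb[, colnames(x$ds$Y)]
  full <- combat_fit(x$ds$Y, x$ds$sheet)
  expect_gt(pairwise_correlation(icomb, unclass(full$corrected)), 0.98)
})

test_that("batches can be added in any order with identical results", {
  reg <- scenario_registry()
  ds <- simulate_methylation(reg$S8, 71)      # 6 existing + 3 new batches
  parts <- split_existing_new(ds)
  fit <- combat_fit(parts$existing$Y, parts$existing$sheet)
  many <- icombat_correct_many(parts$new, fit$model)
  # fold equivalence: same as separate sequential calls
  m <- fit$model
  for (k in seq_along(parts$new)) {
    r <- icombat_correct(parts$new[[k]]$Y, parts$new[[k]]$sheet, m)
    lab <- names(many$corrected)[k]
    expect_identical(unclass(r$corrected), unclass(many$corrected[[lab]]))
    m <- r$model
  }
  # order independence: B then C vs C then B
  rev_many <- icombat_correct_many(rev(parts$new), fit$model)
  for (lab in names(many$corrected))
    expect_identical(unclass(many$corrected[[lab]]),
                     unclass(rev_many$corrected[[lab]]))
  # earlier-added batches are untouched by later additions
  first <- icombat_correct(parts$new[[1]]$Y, parts$new[[1]]$sheet, fit$model)
  expect_identical(unclass(first$corrected),
                   unclass(many$corrected[[names(many$corrected)[1]]]))
})

test_that("model store round-trips bit-identically and is validated", {
  dir <- withr::local_tempdir()
  x <- fit_existing_s1()
  path <- file.path(dir, "model.icb")
  write_icombat_model(x$fit$model, path)
  model2 <- read_icombat_model(path)
  expect_identical(model2$global$alpha, x$fit$model$global$alpha)
  expect_identical(model2$global$sigma, x$fit$model$global$sigma)
  expect_identical(unname(model2$global$beta_cov),
                   unname(x$fit$model$global$beta_cov))
  for (lab in names(x$fit$model$batches)) {
    expect_identical(model2$batches[[lab]]$gamma_star,
                     x$fit$model$batches[[lab]]$gamma_star)
    expect_identical(model2$batches[[lab]]$delta2_star,
                     x$fit$model$batches[[lab]]$delta2_star)
    expect_equal(model2$batches[[lab]]$hyperpriors$zeta_bar,
                 x$fit$model$batches[[lab]]$hyperpriors$zeta_bar)
  }
  # correcting with the reloaded model is bit-identical
  nb <- x$parts$new[[1]]
  r_mem <- icombat_correct(nb$Y, nb$sheet, x$fit$model)
  r_disk <- icombat_correct(nb$Y, nb$sheet, model2)
  expect_identical(unclass(r_mem$corrected), unclass(r_disk$corrected))
  # tampering with the global block is caught by the checksum
  gfile <- file.path(path, "global.csv")
  lines <- readLines(gfile)
  writeLines(c(lines, lines[2]), gfile)
  expect_error(read_icombat_model(path), "checksum")
})

test_that("site alignment, labels and covariate levels are validated", {
  x <- fit_existing_s1()
  nb <- x$parts$new[[1]]
  # duplicate label
  bad_sheet <- sample_sheet(nb$sheet$sample_ids, rep("B1", 30),
                            nb$sheet$covariates)
  expect_error(icombat_correct(nb$Y, bad_sheet, x$fit$model),
               "already present")
  # two labels in the new sheet
  two <- sample_sheet(nb$sheet$sample_ids, rep(c("n1", "n2"), 15),
                      nb$sheet$covariates)
  expect_error(icombat_correct(nb$Y, two, x$fit$model), "exactly one")
  # missing model sites
  expect_error(icombat_correct(nb$Y[1:400, ], nb$sheet, x$fit$model),
               "absent from the new batch")
  # extra sites are rejected unless intersecting is requested
  extra_vals <- rbind(unclass(nb$Y), extra_site = rnorm(30))
  Yx <- meth_matrix(extra_vals, scale = "M")
  expect_error(icombat_correct(Yx, nb$sheet, x$fit$model), "unknown to the")
  ok <- suppressWarnings(icombat_correct(Yx, nb$sheet, x$fit$model,
                                         intersect_sites = TRUE))
  expect_equal(nrow(ok$corrected), 500L)
  # rows may arrive permuted; they are matched by ID
  perm <- sample(nrow(nb$Y))
  r1 <- icombat_correct(nb$Y[perm, ], nb$sheet, x$fit$model)
  r2 <- icombat_correct(nb$Y, nb$sheet, x$fit$model)
  expect_identical(unclass(r1$corrected), unclass(r2$corrected))
})
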