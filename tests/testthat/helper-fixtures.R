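# Small in-code fixtures shared across test files.

# Two clearly shifted batches with a binary group covariate; big enough for
# stable EB estimation, small enough to stay instant.
tiny_two_batch <- function(G = 40, n1 = 12, n2 = 10, shift = 3, seed = 7) {
  set.seed(seed)
  n <- n1 + n2
  group <- rep_len(c(0, 1), n)
  age <- rnorm(n, 50, 10)
  batch <- rep(c("A", "B"), c(n1, n2))
  vals <- matrix(rnorm(G * n, 5, 1), G, n) +
    outer(rep(0.5, G), group) + outer(rep(0.01, G), age)
  vals[, batch == "B"] <- vals[, batch == "B"] + shift
  Y <- meth_matrix(vals, scale = "M")
  sheet <- sample_sheet(colnames(Y), batch,
                        data.frame(group = group, age = age))
  list(Y = Y, sheet = sheet)
}

# A compact scenario for exercising the simulate/evaluate plumbing fast.
mini_scenario <- function(age_effect = 0.01) {
  sim_scenario("mini", "test scenario",
               existing_batches = list(batch_spec(20, 0, 1.0, 0.5),
                                       batch_spec(15, 1.5, 1.3, 0.5)),
               new_batches = list(batch_spec(12, -2, 1.6, 0.5)),
               G = 60, n_signal = 10, age_effect = age_effect)
}
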