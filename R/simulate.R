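#' Batch specification for the simulation generator
#'
#' @param n number of samples in the batch.
#' @param nu additive mean shift of the batch (applied inside the
#'   parenthesis of the generative model).
#' @param sigma multiplicative scale factor of the batch (applied to the
#'   whole parenthesis).
#' @param p probability that a sample of this batch is assigned to the
#'   treatment group.
#' @return a `batch_spec` list.
#' @export
batch_spec <- function(n, nu, sigma, p) {
  stopifnot(n >= 1, sigma > 0, p >= 0, p <= 1)
  structure(list(n = as.integer(n), nu = nu, sigma = sigma, p = p),
            class = "batch_spec")
}

#' Simulation scenario definition
#'
#' Defines one benchmark condition of the generative model
#' `Y = (mu_global + eps + nu_i + group * Delta_g + age * beta_g) * sigma_i`
#' with site-level noise `eps ~ N(0, sigma_global^2)`, a treatment effect
#' `Delta_g = delta_signal` on the first `n_signal` sites (0 elsewhere) and
#' an age effect `beta_g = age_effect` on every site.  Note that the batch
#' scale multiplies the whole parenthesis, so the realised group and age
#' contrasts are batch-scale dependent.
#'
#' @param id scenario identifier.
#' @param description short human-readable label.
#' @param existing_batches,new_batches lists of [batch_spec()]s; "existing"
#'   batches are corrected jointly, "new" batches incrementally.
#' @param G number of sites.
#' @param n_signal number of leading sites carrying the group effect.
#' @param delta_signal group effect size on signal sites.
#' @param age_effect per-site age coefficient.
#' @param mu_global,sigma_global global mean and noise SD.
#' @param age_mean,age_sd distribution of sampled ages.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(id, description, existing_batches, new_batches,
                         G = 500L, n_signal = 50L, delta_signal = 0.5,
                         age_effect = 0.01, mu_global = 5, sigma_global = 1,
                         age_mean = 50, age_sd = 10) {
  stopifnot(n_signal <= G, sigma_global > 0, age_sd > 0,
            length(existing_batches) >= 1)
  structure(list(id = id, description = description,
                 existing_batches = existing_batches,
                 new_batches = new_batches,
                 G = as.integer(G), n_signal = as.integer(n_signal),
                 delta_signal = delta_signal, age_effect = age_effect,
                 mu_global = mu_global, sigma_global = sigma_global,
                 age_mean = age_mean, age_sd = age_sd),
            class = "sim_scenario")
}

#' Registry of the 13 benchmark scenarios
#'
#' Thirteen conditions varying case/control imbalance, sample sizes, batch
#' counts and the strength of the age covariate.  All use 500 sites with a
#' group effect of 0.5 on sites 1-50, global mean 5, unit global noise SD,
#' and ages drawn from N(50, 10^2).  Each batch is parameterised by
#' `(n, nu, sigma, p)`: size, additive shift, scale factor, and treatment
#' probability.
#'
#' @return named list of [sim_scenario()]s, `S1` .. `S13`.
#' @export
scenario_registry <- function() {
  b <- function(n, nu, sigma, p) batch_spec(n, nu, sigma, p)
  s1_existing <- list(b(50, 0, 1.0, 0.5), b(30, 2.5, 1.5, 0.5),
                      b(40, -2, 1.2, 0.5))
  s1_new <- list(b(30, -4, 1.8, 0.5))
  s2_existing <- list(b(50, 0, 1.0, 0.3), b(30, 2.5, 1.5, 0.7),
                      b(40, -2, 1.2, 0.4))
  s2_new <- list(b(30, -4, 1.8, 0.6))
  list(
    S1 = sim_scenario("S1", "Baseline", s1_existing, s1_new),
    S2 = sim_scenario("S2", "Mild imbalance", s2_existing, s2_new),
    S3 = sim_scenario("S3", "Extreme imbalance",
                      list(b(50, 0, 1.0, 0.1), b(30, 2.5, 1.5, 0.9),
                           b(40, -2, 1.2, 0.2)),
                      list(b(30, -4, 1.8, 0.8))),
    S4 = sim_scenario("S4", "Small samples",
                      list(b(25, 0, 1.0, 0.5), b(15, 2.5, 1.5, 0.5),
                           b(20, -2, 1.2, 0.5)),
                      list(b(15, -4, 1.8, 0.5))),
    S5 = sim_scenario("S5", "Large samples",
                      list(b(250, 0, 1.0, 0.5), b(150, 2.5, 1.5, 0.5),
                           b(200, -2, 1.2, 0.5)),
                      list(b(150, -4, 1.8, 0.5))),
    S6 = sim_scenario("S6", "Mixed sizes",
                      list(b(200, 0, 1.0, 0.5), b(10, 2.5, 1.5, 0.5),
                           b(50, -2, 1.2, 0.5)),
                      list(b(100, -4, 1.8, 0.5))),
    S7 = sim_scenario("S7", "Few batches",
                      list(b(50, 0, 1.0, 0.5), b(30, 2.5, 1.5, 0.5)),
                      list(b(40, -2, 1.2, 0.5))),
    S8 = sim_scenario("S8", "Many batches",
                      list(b(20, 0, 1.0, 0.5), b(20, 0.5, 1.1, 0.5),
                           b(20, 1, 1.2, 0.5), b(20, -0.5, 1.1, 0.5),
                           b(20, -1, 1.2, 0.5), b(20, 1.5, 1.3, 0.5)),
                      list(b(15, -2, 1.4, 0.5), b(15, 2.5, 1.5, 0.5),
                           b(15, -3, 1.6, 0.5))),
    S9 = sim_scenario("S9", "Strong covariate", s1_existing, s1_new,
                      age_effect = 0.10),
    S10 = sim_scenario("S10", "Extremely strong covariate", s1_existing,
                       s1_new, age_effect = 1.00),
    S11 = sim_scenario("S11", "Imbalance + strong covariate", s2_existing,
                       s2_new, age_effect = 0.10),
    S12 = sim_scenario("S12", "Imbalance + strong covariate + small samples",
                       list(b(25, 0, 1.0, 0.3), b(15, 2.5, 1.5, 0.7),
                            b(20, -2, 1.2, 0.4)),
                       list(b(15, -4, 1.8, 0.6)), age_effect = 0.10),
    S13 = sim_scenario("S13",
                       "Imbalance + strong covariate + small samples + few batches",
                       list(b(25, 0, 1.0, 0.3), b(15, 2.5, 1.5, 0.7)),
                       list(b(20, -2, 1.2, 0.4)), age_effect = 0.10)
  )
}

#' Generate a simulated methylation dataset
#'
#' Draws one dataset from the scenario's generative model.  Per batch `i`,
#' group labels are independent Bernoulli(`p_i`), ages are per-sample
#' N(`age_mean`, `age_sd`^2), the noise is iid N(0, `sigma_global`^2) per
#' cell, and `Y = (mu_global + eps + nu_i + group * Delta_g +
#' age * beta_g) * sigma_i`.  Batches are laid out in order (existing, then
#' new); the first `n_signal` sites are the true positives.
#'
#' @param scenario a [sim_scenario()] (or a scenario id string looked up in
#'   [scenario_registry()]).
#' @param seed integer seed; the draw is fully reproducible given
#'   `(scenario, seed)`.
#' @return a `sim_dataset` list: `Y` (a `meth_matrix`), `sheet` (a
#'   [sample_sheet()] with covariates `group` and `age`), `truth_signal`
#'   (logical per site), `scenario`, `seed`.
#' @export
simulate_methylation <- function(scenario, seed) {
  if (is.character(scenario)) {
    reg <- scenario_registry()
    if (!scenario %in% names(reg)) stop("unknown scenario: ", scenario)
    scenario <- reg[[scenario]]
  }
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(as.integer(seed))
  G <- scenario$G
  delta <- c(rep(scenario$delta_signal, scenario$n_signal),
             rep(0, G - scenario$n_signal))
  beta_age <- rep(scenario$age_effect, G)
  specs <- c(scenario$existing_batches, scenario$new_batches)
  labels <- paste0("B", seq_along(specs))
  y_blocks <- vector("list", length(specs))
  groups <- ages <- batch_col <- ids <- NULL
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    group <- stats::rbinom(sp$n, 1L, sp$p)
    age <- stats::rnorm(sp$n, scenario$age_mean, scenario$age_sd)
    eps <- matrix(stats::rnorm(G * sp$n, 0, scenario$sigma_global), G, sp$n)
    y_blocks[[k]] <- (scenario$mu_global + eps + sp$nu +
                        outer(delta, group) + outer(beta_age, age)) * sp$sigma
    groups <- c(groups, group)
    ages <- c(ages, age)
    batch_col <- c(batch_col, rep(labels[k], sp$n))
    ids <- c(ids, sprintf("%s_s%02d", labels[k], seq_len(sp$n)))
  }
  Y <- meth_matrix(do.call(cbind, y_blocks), scale = "M",
                   site_ids = sprintf("cg%05d", seq_len(G)),
                   sample_ids = ids)
  sheet <- sample_sheet(ids, batch_col,
                        data.frame(group = as.numeric(groups), age = ages))
  structure(list(Y = Y, sheet = sheet,
                 truth_signal = seq_len(G) <= scenario$n_signal,
                 scenario = scenario, seed = as.integer(seed)),
            class = "sim_dataset")
}

subset_sim <- function(ds, sample_idx) {
  sheet <- ds$sheet
  list(Y = ds$Y[, sample_idx],
       sheet = sample_sheet(sheet$sample_ids[sample_idx],
                            droplevels(sheet$batch[sample_idx]),
                            sheet$covariates[sample_idx, , drop = FALSE],
                            coding = sheet$coding))
}

#' Partition a simulated dataset into existing and new batches
#'
#' Splits the samples by batch membership into the block corrected jointly
#' (the existing batches) and one view per incrementally added batch.  No
#' values are copied or altered beyond column subsetting.
#'
#' @param ds a `sim_dataset` from [simulate_methylation()].
#' @return list with `existing` (list of `Y`, `sheet`) and `new` (list of
#'   such lists, one per new batch, in scenario order).
#' @export
split_existing_new <- function(ds) {
  stopifnot(inherits(ds, "sim_dataset"))
  sc <- ds$scenario
  n_existing <- length(sc$existing_batches)
  labels <- paste0("B", seq_len(n_existing + length(sc$new_batches)))
  existing <- subset_sim(ds, which(ds$sheet$batch %in% labels[seq_len(n_existing)]))
  new <- lapply(labels[-seq_len(n_existing)], function(lab)
    subset_sim(ds, which(ds$sheet$batch == lab)))
  list(existing = existing, new = new)
}

# Deterministic child seed for replicate r (1-based) of scenario index s
# under a master seed; the attempt slot is used to resample degenerate
# draws without colliding with other replicates.  Always < 2^31.
child_seed <- function(master, scenario_index, rep, attempt = 0L) {
  (abs(as.integer(master)) %% 10000L) * 100000L +
    as.integer(scenario_index) * 5000L + (as.integer(rep) - 1L) * 50L +
    as.integer(attempt)
}
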