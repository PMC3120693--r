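#' Induction conditions for the tet-inducible reporter
#'
#' The five inducer (aTc) concentrations and the matching transcription
#' initiation rate constants k1. Induction enters the model only through
#' k1: stronger induction means more frequent initiation attempts. These
#' are the values used throughout the package's fitting and acceptance
#' runs; pass a modified data.frame to override them.
#'
#' @return data.frame with columns `aTc_ng_ml` and `k1` (s^-1).
#' @examples
#' tet_conditions()
#' @export
tet_conditions <- function() {
  data.frame(aTc_ng_ml = c(0, 0.1, 0.5, 1, 2),
             k1 = c(1.5e-4, 4.3e-4, 1.4e-3, 6.5e-3, 2.8e-2))
}

#' Parameters of the delayed gene-expression model
#'
#' The model is a single tet-repressible gene: transcription initiation
#' sequesters the promoter for the open-complex duration tau1 and emits a
#' ribosome binding site (the mRNA proxy) after the elongation delay tau2;
#' translation emits a mature GFP after tau3 (elongation + folding +
#' maturation); RNA and protein degrade with first-order rates. Variant 1
#' uses a constant tau1; variant 2 draws tau1 from a gamma distribution
#' with the same mean, making the open-complex duration variable from one
#' initiation to the next.
#'
#' @param k1 transcription initiation rate constant, s^-1.
#' @param variant 1 (constant tau1) or 2 (gamma tau1).
#' @param tau1_mean mean open-complex duration, seconds.
#' @param tau1_sd gamma standard deviation of tau1, seconds (variant 2).
#' @param k2 translation rate constant per RBS, s^-1.
#' @param k3,k4 RNA and protein degradation rate constants, s^-1.
#' @param tau2 transcription elongation delay, seconds.
#' @param tau3 translation + maturation delay, seconds.
#' @return an object of class `model_params`.
#' @export
model_params <- function(k1, variant = 1, tau1_mean = 19, tau1_sd = 400,
                         k2 = 0.19, k3 = 0.004, k4 = 2e-4,
                         tau2 = 2, tau3 = 420) {
  if (!variant %in% c(1, 2)) stop("variant must be 1 or 2")
  rates <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rate constants must be positive")
  if (tau1_mean <= 0) stop("tau1_mean must be positive")
  if (variant == 2 && (!is.finite(tau1_sd) || tau1_sd <= 0))
    stop("variant 2 requires tau1_sd > 0")
  tau1 <- if (variant == 1) delay_constant(tau1_mean)
          else delay_gamma(tau1_mean, tau1_sd)
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, tau1 = tau1,
                 tau2 = tau2, tau3 = tau3, variant = variant),
            class = "model_params")
}

#' Build the four-reaction delayed gene-expression system
#'
#' Constructs the reaction system
#' \preformatted{
#'   Pro --k1--> Pro(tau1) + RBS(tau2)   transcription initiation
#'   RBS --k2--> RBS + P(tau3)           translation
#'   RBS --k3--> 0                       RNA degradation
#'   P   --k4--> 0                       protein degradation
#' }
#' with a single promoter copy (Pro = 1) and no RNA or protein initially.
#' While an initiation's open complex is forming, the promoter sits on the
#' waiting list and cannot fire again, so tau1 sets a refractory period
#' between consecutive transcription events.
#'
#' @param params a [model_params()], or a k1 value combined with the other
#'   arguments, which are forwarded to [model_params()].
#' @param ... further arguments to [model_params()] when `params` is k1.
#' @return a [reaction_system()] with species Pro, RBS, P.
#' @examples
#' build_model(model_params(2.8e-2, variant = 2))
#' @export
build_model <- function(params, ...) {
  if (!inherits(params, "model_params")) params <- model_params(params, ...)
  p <- params
  reaction_system(list(
    reaction(p$k1, c(Pro = 1),
             list(product("Pro", delay = p$tau1),
                  product("RBS", delay = delay_constant(p$tau2)))),
    reaction(p$k2, c(RBS = 1),
             list(product("RBS"),
                  product("P", delay = delay_constant(p$tau3)))),
    reaction(p$k3, c(RBS = 1)),
    reaction(p$k4, c(P = 1))),
    initial_counts = c(Pro = 1, RBS = 0, P = 0),
    species = c("Pro", "RBS", "P"))
}

#' Closed-form steady-state means of the delayed model
#'
#' Independent analytic oracle for the simulator. Consecutive transcription
#' initiations are a renewal process: the promoter waits Exp(1/k1) to fire
#' and is then sequestered for the open-complex duration, so initiations
#' are separated on average by 1/k1 + mean(tau1) seconds regardless of the
#' delay's distribution. Balancing production against first-order decay
#' gives mean RNA = rate/(k3) and mean protein = mean RNA * k2/k4. Delay
#' distribution shape affects the noise, not these means.
#'
#' @param params a [model_params()] (or k1, forwarded).
#' @param ... further arguments to [model_params()] when `params` is k1.
#' @return named numeric vector `c(mean_rna =, mean_protein =)`.
#' @examples
#' steady_state_oracle(model_params(2.8e-2))
#' @export
steady_state_oracle <- function(params, ...) {
  if (!inherits(params, "model_params")) params <- model_params(params, ...)
  rate <- 1 / (1 / params$k1 + params$tau1$mean)
  mean_rna <- rate / params$k3
  c(mean_rna = mean_rna, mean_protein = mean_rna * params$k2 / params$k4)
}

#' Simulate a population of independent cells
#'
#' Runs `n_cells` independent simulations of the model from an empty
#' RNA/protein state and records the RNA (RBS) and protein (P) copy number
#' of each cell at `t_sample`. Each cell gets its own RNG stream seeded
#' with `master_seed + cell index`, so populations are reproducible and
#' individual cells can be re-simulated in isolation.
#'
#' @param params a [model_params()].
#' @param n_cells number of cells (>= 0).
#' @param t_sample sampling time in seconds; the default 25000 s (about
#'   5 protein lifetimes) is quasi-steady state.
#' @param master_seed integer master seed.
#' @param condition optional label stored with the sample.
#' @return a `population_sample` data.frame with columns `cell_id`,
#'   `condition`, `rna`, `protein`, `seed`; attributes `t_sample` and
#'   `master_seed`.
#' @export
simulate_population <- function(params, n_cells, t_sample = 25000,
                                master_seed = 1L, condition = NA) {
  stopifnot(inherits(params, "model_params"))
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (t_sample < 0) stop("t_sample must be >= 0")
  sys <- build_model(params)
  rbs_i <- match("RBS", sys$species)
  p_i <- match("P", sys$species)
  seeds <- (as.integer(master_seed) + seq_len(n_cells)) %% 2147483647L
  rna <- integer(n_cells)
  prot <- integer(n_cells)
  for (i in seq_len(n_cells)) {
    res <- run_simulation(sys, t_sample, seed = seeds[i])
    rna[i] <- res$final_counts[[rbs_i]]
    prot[i] <- res$final_counts[[p_i]]
  }
  out <- data.frame(cell_id = seq_len(n_cells),
                    condition = rep(condition, length.out = n_cells),
                    rna = rna, protein = prot, seed = seeds)
  attr(out, "t_sample") <- t_sample
  attr(out, "master_seed") <- master_seed
  class(out) <- c("population_sample", "data.frame")
  out
}

#' Simulate all induction conditions of one model variant
#'
#' @param conditions data.frame as [tet_conditions()].
#' @param variant model variant, 1 or 2.
#' @param n_cells cells per condition.
#' @param t_sample sampling time (seconds).
#' @param master_seed integer; each condition derives its own sub-seed.
#' @param tau1_sd gamma sd of the open-complex delay for variant 2.
#' @param ... further arguments to [model_params()].
#' @return list of `population_sample` objects, one per condition, named
#'   by aTc concentration.
#' @export
simulate_conditions <- function(conditions = tet_conditions(), variant = 1,
                                n_cells = 1000, t_sample = 25000,
                                master_seed = 1L, tau1_sd = 400, ...) {
  out <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    p <- model_params(conditions$k1[i], variant = variant,
                      tau1_sd = tau1_sd, ...)
    out[[i]] <- simulate_population(
      p, n_cells, t_sample,
      master_seed = (as.integer(master_seed) + 99991L * i) %% 2147483647L,
      condition = conditions$aTc_ng_ml[i])
  }
  names(out) <- as.character(conditions$aTc_ng_ml)
  out
}

#' Read or write population samples as CSV
#'
#' @param samples a `population_sample` or list of them.
#' @param path CSV path.
#' @return `write_population_csv` returns `path` invisibly;
#'   `read_population_csv` returns one data.frame with all rows.
#' @export
write_population_csv <- function(samples, path) {
  if (inherits(samples, "population_sample")) samples <- list(samples)
  df <- do.call(rbind, lapply(samples, function(s) {
    data.frame(cell_id = s$cell_id, condition_aTc_ng_ml = s$condition,
               rna_count = s$rna, protein_count = s$protein, seed = s$seed)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  utils::read.csv(path)
}
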