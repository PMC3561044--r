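#' Simulation configuration
#'
#' Kinetic and sampling parameters for the stochastic traffic simulation.
#' The translocation rate gamma has been measured at 35 s^-1 and is codon
#' independent; termination is taken comparably fast (beta = gamma by
#' default); a ribosome occludes 9 codons.
#'
#' @param gamma translocation rate, s^-1 (default 35).
#' @param beta termination rate, s^-1 (default `gamma`).
#' @param footprint ribosome footprint in codons, enforced as minimum
#'   A-site gap (default 9).
#' @param burn_in_time simulated seconds discarded before measuring
#'   (default 2000).
#' @param measure_time simulated seconds over which current and density
#'   are averaged (default 8000).
#' @param sample_interval seconds between density samples (default 1).
#' @param n_batches batches for Monte-Carlo standard errors (default 10).
#' @param seed RNG seed (default 1).
#' @param one_state if `TRUE`, run the collapsed single-step comparator
#'   in which a blocked ribosome effectively loses its captured tRNA
#'   (default `FALSE`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(gamma = 35, beta = gamma, footprint = 9,
                       burn_in_time = 2000, measure_time = 8000,
                       sample_interval = 1, n_batches = 10, seed = 1,
                       one_state = FALSE) {
  stopifnot(gamma > 0, beta > 0, footprint >= 1, burn_in_time >= 0,
            measure_time > 0, sample_interval > 0, n_batches >= 2)
  structure(list(gamma = gamma, beta = beta, footprint = as.integer(footprint),
                 burn_in_time = burn_in_time, measure_time = measure_time,
                 sample_interval = sample_interval,
                 n_batches = as.integer(n_batches), seed = as.integer(seed),
                 one_state = isTRUE(one_state)),
            class = "sim_config")
}

#' Simulate the steady state of ribosome traffic on one mRNA
#'
#' Exact continuous-time Monte Carlo (Gillespie) of the two-state
#' exclusion process: ribosomes enter at codon 1 at rate `alpha` when the
#' first `footprint` codons are clear, capture the cognate tRNA at the
#' codon-specific rate `k_i`, translocate at rate `gamma` when the next
#' codon's gap allows, and terminate from the tRNA-bound state at the last
#' codon at rate `beta`. A sterically blocked ribosome retains its
#' captured tRNA while it waits — the feature that distinguishes this
#' process from a plain codon-dependent TASEP.
#'
#' After `burn_in_time`, the current J is the number of terminations per
#' second of simulated time, and the density rho is the time average of
#' N/L sampled every `sample_interval` seconds. Standard errors come from
#' batch means.
#'
#' @param profile a `rate_profile`.
#' @param alpha initiation (on-)rate, s^-1, >= 0.
#' @param config a `sim_config`; its `seed` makes the run reproducible.
#' @return A `steady_state_estimate`: list with `J`, `rho`, `J_stderr`,
#'   `rho_stderr`, `n_terminations`, `init_rate` (accepted initiations per
#'   second, for flux checks) and `simulated_time`.
#' @export
#' @examples
#' prof <- structure(list(gene_id = "toy", codons = rep("AAA", 2),
#'                        k = c(8, 10)), class = "rate_profile")
#' simulate_steady_state(prof, alpha = 0.5,
#'                       sim_config(burn_in_time = 50, measure_time = 200))
simulate_steady_state <- function(profile, alpha, config = sim_config()) {
  stopifnot(inherits(profile, "rate_profile"), inherits(config, "sim_config"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0)
    stop("alpha must be a single number >= 0")
  if (length(profile$k) < 1) stop("rate profile must have length >= 1")
  res <- withr::with_seed(config$seed,
    gillespie_sim_cpp(profile$k, alpha, config$gamma, config$beta,
                      config$footprint, config$burn_in_time,
                      config$measure_time, config$sample_interval,
                      config$n_batches, config$one_state))
  structure(res, class = "steady_state_estimate", gene_id = profile$gene_id)
}

#' @export
print.steady_state_estimate <- function(x, ...) {
  cat("<steady_state_estimate> J = ", signif(x$J, 4), " +/- ",
      signif(x$J_stderr, 3), " s^-1, rho = ", signif(x$rho, 4), " +/- ",
      signif(x$rho_stderr, 3), " ribosomes/codon (",
      x$n_terminations, " terminations over ", x$simulated_time, " s)\n",
      sep = "")
  invisible(x)
}
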