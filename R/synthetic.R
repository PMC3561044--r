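## Synthetic fixtures: designed ORFs with known rate profiles and
## forward-simulated density tables with known ground-truth initiation
## rates, so the whole inference pipeline is testable without external
## sequence or polysome data.

#' Synthetic rate table with designated fast and slow codons
#'
#' Covers all 61 sense codons. The `slow_codons` (by default GCA and CCG,
#' each having a fast synonymous partner so that synonymous shuffling can
#' relocate bottlenecks) decode at `k_slow`; every other codon decodes at
#' `k_fast`. Clearly synthetic: rates are design parameters, not derived
#' from any tRNA census.
#'
#' @param k_fast background capture rate, s^-1 (default 20).
#' @param k_slow bottleneck capture rate, s^-1 (default 1); must be
#'   < `k_fast`.
#' @param slow_codons codons assigned `k_slow`.
#' @return A `rate_table`.
#' @export
synthetic_rate_table <- function(k_fast = 20, k_slow = 1,
                                 slow_codons = c("GCA", "CCG")) {
  stopifnot(k_slow < k_fast, k_slow > 0)
  rates <- setNames(rep(k_fast, length(sense_codons())), sense_codons())
  bad <- setdiff(slow_codons, names(rates))
  if (length(bad)) stop("not sense codons: ", paste(bad, collapse = ", "))
  rates[slow_codons] <- k_slow
  rate_table(rates)
}

# background codons all fast under synthetic_rate_table(): drawn from
# several amino-acid families for sequence diversity; GCU is the fast
# synonymous partner of the slow GCA
.fast_background <- c("GCU", "GAA", "AAA", "UUC", "GGU", "CUG", "GAU", "UCU")

#' Generate a synthetic ORF with a controlled bottleneck
#'
#' Builds a codon sequence whose capture-rate profile is `k_fast`
#' everywhere except over an optional bottleneck window, where it is
#' `k_slow`. Codon 1 is AUG; background codons are drawn uniformly from a
#' fast set; bottleneck positions carry the slow codon GCA. Deterministic
#' given `seed`.
#'
#' @param length ORF length L in codons (no stop codon).
#' @param k_fast background capture rate, s^-1 (default 20).
#' @param bottleneck `NULL` for a homogeneous profile, else
#'   `c(position, width)`: the window `[position, position + width - 1]`,
#'   which must lie within `[2, L]`.
#' @param k_slow bottleneck rate, s^-1 (default 1).
#' @param seed RNG seed.
#' @param gene_id identifier.
#' @return List with `codons`, `profile` (a `rate_profile`) and `table`
#'   (the `rate_table` the profile was built from).
#' @export
#' @examples
#' orf <- make_synthetic_orf(300, bottleneck = c(150, 5))
#' sum(orf$profile$k == 1)  # 5 slow positions
make_synthetic_orf <- function(length, k_fast = 20, bottleneck = NULL,
                               k_slow = 1, seed = 1, gene_id = "synth") {
  stopifnot(length >= 1)
  table <- synthetic_rate_table(k_fast = k_fast, k_slow = k_slow)
  codons <- withr::with_seed(seed,
    c("AUG", sample(.fast_background, length - 1, replace = TRUE)))
  if (!is.null(bottleneck)) {
    pos <- bottleneck[[1]]
    width <- bottleneck[[2]]
    if (pos < 2 || pos + width - 1 > length)
      stop("bottleneck window [", pos, ", ", pos + width - 1,
           "] must lie within [2, ", length, "]")
    codons[pos:(pos + width - 1)] <- "GCA"
  }
  list(codons = codons,
       profile = rate_profile(codons, table, gene_id = gene_id),
       table = table)
}

#' Forward-simulate densities with known ground-truth initiation rates
#'
#' For each profile, simulates the steady state at its true initiation
#' rate and records the resulting density — the synthetic analogue of an
#' experimental ribosome-density table — alongside a separate truth table
#' for recovery testing.
#'
#' @param profiles list of `rate_profile` objects.
#' @param alpha_true numeric vector of true initiation rates, one per
#'   profile, each >= 0 (a zero yields a zero-density row marked
#'   unusable for inversion).
#' @param config a `sim_config`; per-gene seeds derive from `config$seed`.
#' @param density_path,truth_path optional TSV output paths.
#' @return List of data frames `density` (`gene_id`, `rho_exp`, `usable`)
#'   and `truth` (`gene_id`, `alpha_true`).
#' @export
make_synthetic_density <- function(profiles, alpha_true,
                                   config = sim_config(),
                                   density_path = NULL, truth_path = NULL) {
  stopifnot(length(profiles) == length(alpha_true), all(alpha_true >= 0))
  rho <- vapply(seq_along(profiles), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed,
                            paste0(profiles[[i]]$gene_id, "/density"))
    simulate_steady_state(profiles[[i]], alpha_true[i], cfg)$rho
  }, 0)
  ids <- vapply(profiles, `[[`, "", "gene_id")
  density <- data.frame(gene_id = ids, rho_exp = rho, usable = rho > 0,
                        stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = ids, alpha_true = alpha_true,
                      stringsAsFactors = FALSE)
  if (!is.null(density_path)) write_density_tsv(density, density_path)
  if (!is.null(truth_path))
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  list(density = density, truth = truth)
}
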