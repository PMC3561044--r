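# Shared fixtures built in code. Simulation settings here are sized for
# unit-test scale: small lattices, short simulated times.

# a rate profile without going through a rate table
make_profile <- function(k, gene_id = "test") {
  structure(list(gene_id = gene_id, codons = rep("AAA", length(k)), k = k),
            class = "rate_profile")
}

quick_config <- function(seed = 1, ...) {
  sim_config(burn_in_time = 100, measure_time = 1000, sample_interval = 0.5,
             seed = seed, ...)
}

# analytic single-site current: renewal cycle 1/alpha + 1/k + 1/beta
single_site_J <- function(alpha, k, beta) 1 / (1 / alpha + 1 / k + 1 / beta)

# a synthetic response curve from closed-form series (no simulation)
analytic_curve <- function(gene_id, alpha, J, rho, window = 1) {
  response_curve(gene_id = gene_id, alpha = alpha, J_raw = J, rho_raw = rho,
                 smooth_window = window)
}

# toy tRNA table: one anticodon per amino-acid family needed by tests
toy_trna <- function() {
  trna_copy_table(
    anticodon = c("UUU", "GAU", "AGC", "UUC", "ACC", "CAG", "AUC", "UCU",
                  "CAU", "CCA", "UAC", "GAA", "AGA", "UGC", "AAU", "UAA",
                  "GUU", "UUG", "CUG", "GCU", "UGG", "GUG", "UAU", "CCC",
                  "GGU", "UCG", "CGU", "ACG", "CAA", "GCA", "AAC", "GGA",
                  "UGU", "AGG", "ACU", "UCC", "AGU", "GCC", "UGA", "CGA",
                  "CUU", "AAG", "GUA"),
    amino_acid = c("K", "I", "A", "E", "G", "L", "D", "R",
                   "M", "W", "V", "F", "S", "A", "I", "L",
                   "N", "Q", "Q", "S", "P", "H", "I", "G",
                   "T", "R", "T", "R", "L", "C", "V", "S",
                   "T", "P", "S", "G", "T", "G", "S", "S",
                   "K", "L", "Y"),
    copy_number = rep(4, 43))
}
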