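#' Derive a reproducible child seed from a master seed and a label
#'
#' Genome-scale runs simulate many genes and many grid points; each
#' stochastic unit gets its own seed derived deterministically from the
#' master seed and a string label (typically the gene id, possibly with a
#' grid index appended). Results are therefore independent of execution
#' order and of how work is distributed over workers.
#'
#' @param master integer master seed.
#' @param label character label identifying the stochastic unit.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "YPL106C")
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(label),
            length(label) == 1)
  # 31-bit polynomial rolling hash of the label, folded with the master seed
  mod <- 2147480009  # largest prime below 2^31 - 3000
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% mod
  as.integer((abs(master) + h) %% mod)
}
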