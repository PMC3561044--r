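#' Translation efficiency at the physiological initiation rate
#'
#' Te is the protein production rate at the operating point: the smoothed
#' current interpolated (piecewise-linearly) at `alpha_ph`.
#'
#' @param curve a `response_curve`.
#' @param alpha_ph initiation rate within the grid range, s^-1.
#' @return Te in proteins per second.
#' @export
translation_efficiency <- function(curve, alpha_ph) {
  stopifnot(inherits(curve, "response_curve"))
  a <- curve$alpha
  if (alpha_ph < a[1] || alpha_ph > a[length(a)])
    stop("alpha_ph = ", alpha_ph, " outside grid range")
  .interp_curve(curve, "J_smooth", alpha_ph)
}

#' Predict protein abundance from translation efficiency
#'
#' The steady-state abundance estimate is `P_est = Te * m` (production
#' rate times transcript copy number); when polysome-loaded fractions are
#' available, `P_est = Te * m * F` restricts the estimate to the
#' effective amount of transcript engaged in translation.
#'
#' @param records data frame with columns `gene_id`, `Te`, `m` and
#'   optionally `F` in `[0, 1]`.
#' @param use_polysome_fraction multiply by `F` (default `FALSE`).
#' @return The input with a `P_est` column appended.
#' @export
predict_abundance <- function(records, use_polysome_fraction = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("gene_id", "Te", "m") %in% names(records)))
  if (any(records$m < 0)) stop("mRNA abundances must be >= 0")
  if (use_polysome_fraction) {
    if (!"F" %in% names(records))
      stop("polysome fraction requested but column F is absent")
    if (any(records$F < 0 | records$F > 1)) stop("F must be in [0, 1]")
    records$P_est <- records$Te * records$m * records$F
  } else {
    records$P_est <- records$Te * records$m
  }
  records
}

#' Codon adaptation index weights from a reference gene set
#'
#' Relative synonymous codon usage of a (typically highly expressed)
#' reference set: `w_c = f_c / max f` over each synonymous family.
#' Codons unobserved in the reference receive a pseudo-count of 0.5
#' before normalisation, so no sense codon gets weight zero. Stop codons
#' carry no weight.
#'
#' @param reference_orfs list (or single vector) of sense-codon vectors.
#' @param reference_set_id label stored with the weights.
#' @return A `cai_weights` object: list with `w` (named numeric over the
#'   61 sense codons, in `(0, 1]`) and `reference_set_id`.
#' @export
cai_weights <- function(reference_orfs, reference_set_id = "reference") {
  if (!is.list(reference_orfs)) reference_orfs <- list(reference_orfs)
  if (length(reference_orfs) == 0) stop("reference set must be non-empty")
  codons <- unlist(lapply(reference_orfs, as_codons))
  codons <- codons[!Biostrings::RNA_GENETIC_CODE[codons] %in% "*"]
  counts <- table(factor(codons, levels = sense_codons()))
  counts <- pmax(as.numeric(counts), 0.5)
  names(counts) <- sense_codons()
  aa <- .codon_aa(sense_codons())
  w <- counts
  for (a in unique(aa)) {
    fam <- aa == a
    w[fam] <- counts[fam] / max(counts[fam])
  }
  structure(list(w = w, reference_set_id = reference_set_id),
            class = "cai_weights")
}

#' Codon adaptation index of a coding sequence
#'
#' Geometric mean of the reference weights over the sequence's codons,
#' excluding — per the standard definition — the single-codon amino acids
#' (AUG, UGG) and any stop codon.
#'
#' @param codons sense-codon vector or nucleotide string (a trailing stop
#'   codon is dropped).
#' @param weights a `cai_weights` object.
#' @return CAI score in `(0, 1]`.
#' @export
cai <- function(codons, weights) {
  stopifnot(inherits(weights, "cai_weights"))
  codons <- as_codons(codons)
  aa <- Biostrings::RNA_GENETIC_CODE[codons]
  if (length(codons) > 1 && aa[length(codons)] %in% "*") {
    codons <- codons[-length(codons)]
    aa <- aa[-length(aa)]
  }
  keep <- !codons %in% c("AUG", "UGG") & !aa %in% "*" & !is.na(aa)
  if (!any(keep)) stop("no codons eligible for CAI (all AUG/UGG/stop)")
  exp(mean(log(weights$w[codons[keep]])))
}

#' Mean tRNA-capture rate of a sequence (codon-usage summary)
#'
#' A composition-only comparator: invariant under synonymous shuffling,
#' unlike the simulated current.
#'
#' @param codons sense-codon vector.
#' @param table a `rate_table`.
#' @return Mean of the per-codon capture rates, s^-1.
#' @export
mean_capture_rate <- function(codons, table) {
  mean(rate_profile(codons, table)$k)
}
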