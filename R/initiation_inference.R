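#' Infer the physiological initiation rate from an observed density
#'
#' Inverts the simulated density response: finds the alpha at which the
#' smoothed rho(alpha) curve equals the experimentally observed ribosome
#' density, by root-finding on the piecewise-linear interpolant. When the
#' observed density exceeds every simulated value the gene is flagged
#' `SATURATED` (alpha pinned at the grid maximum); below the smallest
#' simulated value it is flagged `BELOW_GRID`. If Monte-Carlo noise leaves
#' several crossings after smoothing, the smallest root is returned and
#' the gene flagged ambiguous — a conservative choice reflecting the
#' low-alpha physiological prior.
#'
#' @param curve a `response_curve`.
#' @param rho_exp observed density, ribosomes per codon, > 0. May also be
#'   a `density_record` row (list/data.frame with `gene_id`, `rho_exp`).
#' @return An `initiation_estimate`: list with `gene_id`, `alpha_ph`,
#'   `status` (`"OK"`, `"SATURATED"`, `"BELOW_GRID"`), `ambiguous`
#'   (logical) and `bracket` (the grid interval containing the root).
#' @export
infer_alpha <- function(curve, rho_exp) {
  stopifnot(inherits(curve, "response_curve"))
  if (is.list(rho_exp)) rho_exp <- rho_exp$rho_exp
  if (!is.numeric(rho_exp) || length(rho_exp) != 1 || rho_exp <= 0)
    stop("rho_exp must be a single number > 0")
  a <- if (is.null(curve$alpha_s)) curve$alpha else curve$alpha_s
  r <- curve$rho_smooth
  n <- length(a)
  est <- list(gene_id = curve$gene_id, alpha_ph = NA_real_, status = "OK",
              ambiguous = FALSE, bracket = c(NA_real_, NA_real_))
  if (rho_exp > max(r)) {
    est$alpha_ph <- a[n]
    est$status <- "SATURATED"
  } else if (rho_exp < r[1]) {
    est$alpha_ph <- a[1]
    est$status <- "BELOW_GRID"
  } else {
    seg_lo <- pmin(r[-n], r[-1])
    seg_hi <- pmax(r[-n], r[-1])
    crossings <- which(rho_exp >= seg_lo & rho_exp <= seg_hi)
    if (length(crossings) == 0) {  # can only happen through noise dips at a[1]
      est$alpha_ph <- a[which.min(abs(r - rho_exp))]
      est$ambiguous <- TRUE
    } else {
      i <- crossings[1]
      if (length(crossings) > 1) {
        # distinct roots separated by a genuine excursion are ambiguous
        seg_alpha <- vapply(crossings, function(j) {
          if (r[j + 1] == r[j]) a[j]
          else a[j] + (rho_exp - r[j]) / (r[j + 1] - r[j]) * (a[j + 1] - a[j])
        }, 0)
        est$ambiguous <- diff(range(seg_alpha)) > .Machine$double.eps^0.5 * a[n]
      }
      est$alpha_ph <- if (r[i + 1] == r[i]) a[i] else
        a[i] + (rho_exp - r[i]) / (r[i + 1] - r[i]) * (a[i + 1] - a[i])
      est$bracket <- c(a[i], a[i + 1])
    }
  }
  structure(est, class = "initiation_estimate")
}

#' @export
print.initiation_estimate <- function(x, ...) {
  cat("<initiation_estimate> ", x$gene_id, ": alpha_ph = ",
      signif(x$alpha_ph, 4), " s^-1 [", x$status,
      if (x$ambiguous) ", AMBIGUOUS" else "", "]\n", sep = "")
  invisible(x)
}

#' Genome-wide inference of initiation rates and per-transcript summaries
#'
#' Joins response curves with density records by gene id and produces one
#' summary row per joined gene: the inferred physiological initiation
#' rate, translation efficiency Te = J(alpha_ph), gearing K, saturation
#' values and the traffic-class label from curve clustering. Genes
#' present on only one side are reported in the `unmatched` attribute,
#' never dropped silently.
#'
#' @param curves list of `response_curve` objects.
#' @param records a data frame with columns `gene_id`, `rho_exp`
#'   (ribosomes per codon) and optionally `F` (polysome-loaded fraction).
#' @param hybrid_band margin band passed to [classify_curves()].
#' @return A `data.frame` (one row per gene) with columns `gene_id`,
#'   `alpha_ph`, `status`, `ambiguous`, `Te`, `K`, `J_max`, `rho_max`,
#'   `class_label`; attribute `unmatched` lists ids missing a curve or a
#'   record.
#' @export
infer_genomewide <- function(curves, records, hybrid_band = 0.2) {
  stopifnot(is.list(curves), is.data.frame(records),
            all(c("gene_id", "rho_exp") %in% names(records)))
  curve_ids <- vapply(curves, `[[`, "", "gene_id")
  names(curves) <- curve_ids
  ids <- intersect(curve_ids, records$gene_id)
  if (length(ids) == 0) stop("no gene ids shared between curves and records")
  unmatched <- list(no_curve = setdiff(records$gene_id, curve_ids),
                    no_record = setdiff(curve_ids, records$gene_id))

  feats <- do.call(rbind, lapply(ids, function(id) {
    cv <- curves[[id]]
    as.data.frame(curve_features(cv, saturation_values(cv)))
  }))
  labels <- classify_curves(feats, band = hybrid_band)

  rows <- lapply(ids, function(id) {
    cv <- curves[[id]]
    rec <- records[match(id, records$gene_id), ]
    est <- infer_alpha(cv, rec$rho_exp)
    sat <- saturation_values(cv)
    data.frame(gene_id = id, alpha_ph = est$alpha_ph, status = est$status,
               ambiguous = est$ambiguous,
               Te = translation_efficiency(cv, est$alpha_ph),
               K = gearing_factor(cv, est$alpha_ph),
               J_max = sat$J_max, rho_max = sat$rho_max,
               class_label = labels[match(id, feats$gene_id)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "unmatched") <- unmatched
  out
}

#' Compare per-gene initiation rates between two conditions
#'
#' Mirrors re-running the inference on a density table from a second
#' (e.g. perturbed) condition: genes whose observed density is unchanged
#' get a delta of ~0.
#'
#' @param summary_a,summary_b transcript summaries from
#'   [infer_genomewide()] for the two conditions.
#' @return Data frame with `gene_id`, `alpha_ph_a`, `alpha_ph_b`,
#'   `delta_alpha_ph`.
#' @export
compare_conditions <- function(summary_a, summary_b) {
  ids <- intersect(summary_a$gene_id, summary_b$gene_id)
  a <- summary_a$alpha_ph[match(ids, summary_a$gene_id)]
  b <- summary_b$alpha_ph[match(ids, summary_b$gene_id)]
  data.frame(gene_id = ids, alpha_ph_a = a, alpha_ph_b = b,
             delta_alpha_ph = b - a, stringsAsFactors = FALSE)
}

#' Convert ribosomes-per-mRNA to ribosomes-per-codon
#'
#' Experimental density tables sometimes report ribosomes per transcript;
#' the model's density is ribosome count divided by ORF length in codons.
#'
#' @param ribosomes_per_mrna numeric vector.
#' @param length_codons ORF lengths in codons (stop codon excluded).
#' @return Densities in ribosomes per codon.
#' @export
density_per_codon <- function(ribosomes_per_mrna, length_codons) {
  stopifnot(all(length_codons >= 1))
  ribosomes_per_mrna / length_codons
}
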