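## Smooth / abrupt / hybrid classification of response curves.
##
## Abrupt transcripts carry rare-codon bottlenecks in the body of the ORF:
## above a sequence-specific initiation rate a ribosome queue forms, the
## density jumps and the current kinks into saturation. Smooth transcripts
## (bottleneck at the 5' edge, or none) saturate gradually because no
## queue can build upstream of codon 1. The classifier extracts
## shape features from the smoothed curves and 2-means-clusters them,
## holding back low-margin genes as hybrids.

#' Shape features of a response curve
#'
#' Computed on the smoothed series over the sub-saturation range (grid
#' points with `J_smooth < 0.95 * J_max`, plus one point):
#' \describe{
#'   \item{kink_score}{the height of the kink: `J / J_max` at the largest
#'     alpha where the windowed local slope dJ/dalpha still reaches
#'     `slope_threshold`. In the entry-limited regime every curve follows
#'     J ~ alpha (slope 1); an abrupt curve rides that line almost to its
#'     plateau and then clamps (score near 1, a sudden change of slope at
#'     high current), while a smooth curve leaves it early and bends
#'     gradually (small score). 0 for a curve with no entry-limited
#'     region on the grid (e.g. a constant).}
#'   \item{sat_sharpness}{width of the alpha interval over which J rises
#'     from 50% to 95% of `J_max`, normalised by the alpha at 95%; small
#'     for kinked curves, large for gradually saturating ones.}
#'   \item{rho_jump}{maximum single-step increase of the smoothed density,
#'     normalised by `rho_max`; picks up the density jump that accompanies
#'     queue formation behind a mid-body bottleneck.}
#' }
#'
#' @param curve a `response_curve` (smoothed).
#' @param sat its [saturation_values()]; `J_max` must be > 0.
#' @param slope_window half-window (in grid points) for the secant slopes
#'   (default 3).
#' @param slope_threshold slope (proteins/s per entering ribosome/s)
#'   above which the curve counts as still rising steeply (default 0.5,
#'   half the entry-limited slope).
#' @return A `curve_features` list with `gene_id` and the three features.
#' @export
curve_features <- function(curve, sat = saturation_values(curve),
                           slope_window = 3, slope_threshold = 0.5) {
  stopifnot(inherits(curve, "response_curve"))
  if (sat$J_max <= 0) stop("J_max = 0: untranslatable profile")
  a <- if (is.null(curve$alpha_s)) curve$alpha else curve$alpha_s
  J <- curve$J_smooth
  n <- length(a)

  i95 <- which(J >= 0.95 * sat$J_max)
  i95 <- if (length(i95)) min(i95) else n
  alpha95 <- a[i95]
  i50 <- which(J >= 0.50 * sat$J_max)
  alpha50 <- if (length(i50)) a[min(i50)] else alpha95
  sat_sharpness <- max((alpha95 - alpha50) / alpha95, .Machine$double.eps)

  # kink height: J/J_max at the last point whose windowed slope is still
  # above the threshold, within the sub-saturation range
  last <- min(i95 + 1L, n)
  kink <- 0
  w <- slope_window
  if (last >= 2 * w + 1) {
    for (i in (w + 1):(last - w)) {
      s <- (J[i + w] - J[i - w]) / (a[i + w] - a[i - w])
      if (s >= slope_threshold) kink <- max(kink, J[i] / sat$J_max)
    }
  }

  rho_jump <- if (sat$rho_max > 0)
    max(c(0, diff(curve$rho_smooth[seq_len(last)]))) / sat$rho_max else 0

  structure(list(gene_id = curve$gene_id, kink_score = max(kink, 0),
                 sat_sharpness = sat_sharpness, rho_jump = rho_jump),
            class = "curve_features")
}

#' @export
as.data.frame.curve_features <- function(x, ...) {
  data.frame(gene_id = x$gene_id, kink_score = x$kink_score,
             sat_sharpness = x$sat_sharpness, rho_jump = x$rho_jump,
             stringsAsFactors = FALSE)
}

#' Classify curves into SMOOTH / ABRUPT / HYBRID
#'
#' Standardises the features and runs 2-means clustering with a
#' deterministic initialisation (centres at the lowest- and
#' highest-kink genes); the cluster with the larger mean kink score is
#' labelled ABRUPT. Genes whose assignment margin — the relative
#' difference between the distances to the two centroids,
#' `(d_far - d_near) / (d_far + d_near)` — falls below `band` do not show
#' pronounced enough features for a call and are labelled HYBRID.
#'
#' @param features a data frame with columns `gene_id`, `kink_score`,
#'   `sat_sharpness`, `rho_jump` (e.g. rbind-ed [curve_features()] rows),
#'   or a single `curve_features` object.
#' @param band hybrid margin band in `[0, 1)` (default 0.2).
#' @param kink_threshold fixed threshold used for single-gene input,
#'   where clustering is impossible: `kink_score` above it is ABRUPT
#'   (default 0.5).
#' @param seed unused by the deterministic initialisation; kept so that
#'   alternative initialisations remain reproducible.
#' @return Character vector of labels, aligned with `features` rows.
#' @export
classify_curves <- function(features, band = 0.2, kink_threshold = 0.5,
                            seed = 1) {
  if (inherits(features, "curve_features"))
    features <- as.data.frame(features)
  stopifnot(is.data.frame(features),
            all(c("kink_score", "sat_sharpness", "rho_jump") %in% names(features)))
  if (band < 0 || band >= 1) stop("band must be in [0, 1)")
  n <- nrow(features)
  if (n == 1)
    return(if (features$kink_score[1] > kink_threshold) "ABRUPT" else "SMOOTH")

  x <- as.matrix(features[, c("kink_score", "sat_sharpness", "rho_jump")])
  sds <- apply(x, 2, sd)
  keep <- sds > 0
  if (!any(keep)) {
    warning("degenerate features (all genes identical): labelling all HYBRID")
    return(rep("HYBRID", n))
  }
  z <- scale(x[, keep, drop = FALSE])

  i_lo <- which.min(features$kink_score)
  i_hi <- which.max(features$kink_score)
  centres <- z[c(i_lo, i_hi), , drop = FALSE]
  km <- withr::with_seed(seed,
    kmeans(z, centers = centres, iter.max = 100, algorithm = "Lloyd"))

  abrupt_cluster <- which.max(tapply(features$kink_score, km$cluster, mean))
  d <- cbind(sqrt(rowSums(sweep(z, 2, km$centers[1, ])^2)),
             sqrt(rowSums(sweep(z, 2, km$centers[2, ])^2)))
  d_near <- pmin(d[, 1], d[, 2])
  d_far <- pmax(d[, 1], d[, 2])
  margin <- ifelse(d_far + d_near > 0, (d_far - d_near) / (d_far + d_near), 0)

  labels <- unname(ifelse(km$cluster == abrupt_cluster, "ABRUPT", "SMOOTH"))
  labels[margin < band] <- "HYBRID"
  labels
}
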