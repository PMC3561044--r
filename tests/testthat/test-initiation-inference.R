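# analytic density response rho(alpha) = rho_max * alpha / (K + alpha),
# built without simulation so inversion can be checked exactly
hyperbolic_curve <- function(gene_id = "g", rho_max = 0.1, K = 1,
                             alpha = exp(seq(log(0.01), log(5),
                                             length.out = 60))) {
  analytic_curve(gene_id, alpha, J = 10 * alpha / (K + alpha),
                 rho = rho_max * alpha / (K + alpha))
}

test_that("inversion recovers alpha from an analytic density curve", {
  cv <- hyperbolic_curve()          # rho(1) = 0.05
  est <- infer_alpha(cv, 0.05)
  expect_s3_class(est, "initiation_estimate")
  expect_equal(est$status, "OK")
  expect_false(est$ambiguous)
  expect_equal(est$alpha_ph, 1, tolerance = 0.01)  # linear interp error only
  expect_true(est$bracket[1] <= est$alpha_ph && est$alpha_ph <= est$bracket[2])
})

test_that("saturated and below-grid densities are flagged, not inverted", {
  cv <- hyperbolic_curve()
  sat <- infer_alpha(cv, 0.2)       # above rho_max = 0.1
  expect_equal(sat$status, "SATURATED")
  expect_equal(sat$alpha_ph, max(cv$alpha_s))
  low <- infer_alpha(cv, 1e-6)
  expect_equal(low$status, "BELOW_GRID")
  expect_equal(low$alpha_ph, min(cv$alpha_s))
  expect_error(infer_alpha(cv, -0.1), "> 0")
})

test_that("inferred alpha is monotone in the observed density", {
  cv <- hyperbolic_curve()
  rho_obs <- seq(0.005, 0.08, length.out = 15)  # all below rho at grid end
  alphas <- vapply(rho_obs, function(r) infer_alpha(cv, r)$alpha_ph, 0)
  expect_true(all(diff(alphas) > 0))
})

test_that("noise dips producing several crossings are flagged ambiguous", {
  a <- seq(0.1, 2, length.out = 20)
  r <- a / (1 + a)
  r[10] <- r[13]  # local excursion: values in (r[11], r[10]) cross three times
  cv <- analytic_curve("g", a, J = r, rho = r)
  target <- (r[11] + r[10]) / 2
  est <- infer_alpha(cv, target)
  expect_true(est$ambiguous)
  # smallest root is returned
  expect_lt(est$alpha_ph, a[11])
})

test_that("genome-wide inference joins curves and records, reports unmatched", {
  curves <- list(hyperbolic_curve("gA", K = 0.5),
                 hyperbolic_curve("gB", K = 1),
                 hyperbolic_curve("gC", K = 2))
  records <- data.frame(gene_id = c("gA", "gB", "gX"),
                        rho_exp = c(0.05, 0.05, 0.05),
                        stringsAsFactors = FALSE)
  out <- infer_genomewide(curves, records, hybrid_band = 0)
  expect_equal(sort(out$gene_id), c("gA", "gB"))
  un <- attr(out, "unmatched")
  expect_equal(un$no_curve, "gX")
  expect_equal(un$no_record, "gC")
  # same observed density, different K: gA (saturates earlier) needs
  # a smaller alpha to reach rho = rho_max/2
  expect_lt(out$alpha_ph[out$gene_id == "gA"],
            out$alpha_ph[out$gene_id == "gB"])
  expect_true(all(c("Te", "K", "J_max", "rho_max", "class_label") %in%
                    names(out)))
  expect_true(all(out$status == "OK"))
  expect_error(infer_genomewide(curves,
                                data.frame(gene_id = "zz", rho_exp = 0.1)),
               "no gene ids shared")
})

test_that("identical conditions give zero initiation-rate shifts", {
  curves <- list(hyperbolic_curve("gA"), hyperbolic_curve("gB", K = 2))
  rec <- data.frame(gene_id = c("gA", "gB"), rho_exp = c(0.04, 0.03))
  sa <- infer_genomewide(curves, rec, hybrid_band = 0)
  sb <- infer_genomewide(curves, rec, hybrid_band = 0)
  cmp <- compare_conditions(sa, sb)
  expect_equal(cmp$delta_alpha_ph, c(0, 0))
  # a density change in one condition moves only that gene
  rec2 <- rec; rec2$rho_exp[1] <- 0.06
  sc <- infer_genomewide(curves, rec2, hybrid_band = 0)
  cmp2 <- compare_conditions(sa, sc)
  expect_gt(cmp2$delta_alpha_ph[cmp2$gene_id == "gA"], 0)
  expect_equal(cmp2$delta_alpha_ph[cmp2$gene_id == "gB"], 0)
})

test_that("density unit conversion divides by ORF length", {
  expect_equal(density_per_codon(c(3, 10), c(300, 500)), c(0.01, 0.02))
  expect_error(density_per_codon(1, 0), ">= 1")
})
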