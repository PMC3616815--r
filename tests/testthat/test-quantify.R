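test_that("standard-curve closed forms hold exactly", {
  # perfect doubling chemistry: Ct spacing log10(10)/log10(2) per decade
  std <- tibble::tibble(q = 10^-(0:2), ct = 20 + (0:2) * (1 / log10(2)))
  suppressWarnings(curve <- fit_standard_curve(std, q, ct))
  g <- glance(curve)
  expect_equal(g$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(g$efficiency, 1, tolerance = 1e-9)
  expect_equal(g$r2, 1, tolerance = 1e-9)
  # direct evaluation: slope -3.5 -> E = 10^(1/3.5) - 1
  expect_equal(efficiency_from_slope(-3.5), 10^(1 / 3.5) - 1, tolerance = 1e-12)
  expect_equal(round(efficiency_from_slope(-3.5), 4), 0.9307)
})

test_that("efficiency and slope transforms are mutual inverses", {
  for (E in seq(0.55, 1.1, by = 0.05)) {
    expect_equal(efficiency_from_slope(slope_from_efficiency(E)), E, tolerance = 1e-10)
  }
  for (s in seq(-5, -3, by = 0.25)) {
    expect_equal(slope_from_efficiency(efficiency_from_slope(s)), s, tolerance = 1e-10)
  }
})

test_that("curve fitting validates its inputs and flags invalid slopes", {
  too_few <- tibble::tibble(q = c(1, 1, 0.1), ct = c(20, 20.1, 23))
  expect_error(fit_standard_curve(too_few, q, ct), class = "isoprime_value_error")
  cens <- tibble::tibble(q = 10^-(0:3), ct = c(20, 23, 26, 40),
                         censored = c(FALSE, FALSE, FALSE, TRUE))
  expect_error(fit_standard_curve(cens, q, ct), class = "isoprime_value_error")
  upward <- tibble::tibble(q = 10^-(0:3), ct = c(30, 27, 24, 21))
  expect_warning(cv <- fit_standard_curve(upward, q, ct), "invalid")
  expect_false(cv$valid)
  expect_error(quantity_from_ct(20, cv), class = "isoprime_value_error")
})

test_that("noisy curve fits recover the true efficiency within 0.05", {
  set.seed(61)
  for (E in c(0.85, 0.95, 1.05)) {
    q <- rep(10^-(0:5), each = 2)                  # 6 levels in duplicate
    ct <- 20 - log10(q) / log10(1 + E) + rnorm(length(q), 0, 0.2)
    cv <- fit_standard_curve(tibble::tibble(q = q, ct = ct), q, ct)
    expect_lt(abs(cv$efficiency - E), 0.05)
  }
})

test_that("quantities round-trip through the curve and normalize to A.U.", {
  std <- tibble::tibble(q = 10^-(0:5), ct = 19 - log10(10^-(0:5)) * 3.4)
  curve <- fit_standard_curve(std, q, ct)
  # ct = intercept -> quantity 1
  expect_equal(quantity_from_ct(curve$intercept, curve), 1, tolerance = 1e-9)
  for (q0 in c(0.004, 0.3, 2)) {
    ct0 <- curve$intercept + curve$slope * log10(q0)
    expect_equal(quantity_from_ct(ct0, curve), q0, tolerance = 1e-9)
  }
  expect_true(is.na(quantity_from_ct(35, curve, censored = TRUE)))
  expect_equal(normalize_expression(2, 0.5), 4)
  # A.U. invariant under common rescaling
  expect_equal(normalize_expression(2 * 7, 0.5 * 7), 4)
  expect_error(normalize_expression(1, 0), class = "isoprime_value_error")
})

test_that("the dCt-slope rule selects the quantification method", {
  # equal efficiencies: slope 0, ddCt permissible
  d <- tibble::tibble(q = 10^-(0:5), ct_t = 20 - log10(10^-(0:5)) * 3.32,
                      ct_r = 18 - log10(10^-(0:5)) * 3.32)
  r <- relative_efficiency_slope(d, q, ct_t, ct_r)
  expect_equal(r$slope, 0, tolerance = 1e-9)
  expect_equal(r$method, "ddct_permissible")
  # diverging efficiencies push the slope out of the band
  d2 <- tibble::tibble(q = 10^-(0:5), ct_t = 20 - log10(10^-(0:5)) * 3.6,
                       ct_r = 18 - log10(10^-(0:5)) * 3.32)
  expect_equal(relative_efficiency_slope(d2, q, ct_t, ct_r)$method,
               "standard_curve_required")
  expect_equal(ddct_method_check(c(-0.079, -0.206, 0.1, -0.101)),
               c("ddct_permissible", "standard_curve_required",
                 "ddct_permissible", "standard_curve_required"))
})

test_that("expression calls respect detection and the NTC guard", {
  # all censored -> not expressed
  expect_false(call_expressed(c(40, 40, 40), rep("s1", 3), censored = rep(TRUE, 3)))
  # clean triplicate with silent NTC -> expressed
  expect_true(call_expressed(c(24, 24, 24), rep("s1", 3), ntc_ct = numeric(0)))
  # Ct 38 with NTC at 39 fails the 3-cycle guard
  expect_false(call_expressed(c(38, 38, 38), rep("s1", 3), ntc_ct = 39))
  expect_true(call_expressed(c(35, 35, 35), rep("s1", 3), ntc_ct = 39))
  # one clean biological replicate is enough
  expect_true(call_expressed(c(40, 40, 40, 24, 24, 24),
                             rep(c("s1", "s2"), each = 3),
                             censored = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
})

test_that("reference candidates rank by cross-condition Ct stability", {
  grid <- tidyr::expand_grid(tissue = c("peel", "flesh"),
                             cultivar = c("c1", "c2"))
  mk <- function(assay, cts) {
    dplyr::mutate(grid, assay_id = assay, ct = cts,
                  sample_id = paste0(tissue, cultivar))
  }
  tab <- dplyr::bind_rows(mk("stable", c(20, 20, 20, 20)),
                          mk("mid", c(20, 20.2, 19.8, 20.1)),
                          mk("wobbly", c(18, 20, 22, 19)))
  rk <- reference_stability(tab)
  expect_equal(rk$assay_id, c("stable", "mid", "wobbly"))
  expect_equal(rk$sd_ct[1], 0)
  expect_equal(rk$rank, 1:3)
  # sample order permutation leaves the ranking unchanged
  rk2 <- reference_stability(tab[sample(nrow(tab)), ])
  expect_equal(rk2$assay_id, rk$assay_id)
})

test_that("replicate summaries and ANOVA match hand-computed values", {
  d <- tibble::tibble(assay_id = "g", tissue = "t", cultivar = "c",
                      au = c(3, 3, 3))
  s <- summarize_expression(d, au)
  expect_equal(s$au_sem, 0)
  expect_equal(s$au_mean, 3)

  # balanced 2x2, additive model: hand sum-of-squares
  dd <- tibble::tibble(gene = rep(c("g1", "g2"), each = 2),
                       tissue = rep(c("p", "f"), 2),
                       au = c(10, 6, 5, 0))
  out <- expression_anova(dd, response = "au", factors = c("gene", "tissue"))
  # gene means 8 / 2.5, grand 5.25: SS = 2*((8-5.25)^2 + (2.5-5.25)^2) = 30.25
  expect_equal(out$sumsq[out$term == "gene"], 30.25)
  # tissue means 7.5 / 3: SS = 2*((7.5-5.25)^2 + (3-5.25)^2) = 20.25
  expect_equal(out$sumsq[out$term == "tissue"], 20.25)
  expect_equal(out$df, c(1, 1, 1))
  # residual = total 50.75 - 30.25 - 20.25 = 0.25, so F_gene = 30.25/0.25
  expect_equal(out$statistic[out$term == "gene"], 121)
})

test_that("standard-curve output equals ddCt exactly at 100 % efficiencies", {
  assays <- tibble::tibble(assay_id = c("target", "actin"),
                           efficiency = c(1, 1), baseline_ct = c(21, 18))
  samples <- tidyr::expand_grid(sample_id = c("a_1", "b_1"),
                                assay_id = assays$assay_id)
  samples$tissue <- "peel"
  samples$cultivar <- ifelse(startsWith(samples$sample_id, "a"), "a", "b")
  samples$quantity <- ifelse(samples$assay_id == "actin", 0.02,
                             ifelse(samples$cultivar == "a", 0.12, 0.03))
  ct <- simulate_qpcr(assays, samples, noise_sd = 0, seed = 71)
  res <- suppressWarnings(quantify_expression(ct, "actin"))
  # standard-curve A.U. ratio between the two samples
  sc_ratio <- res$au_mean[res$cultivar == "a"] / res$au_mean[res$cultivar == "b"]
  # ddCt on the same wells
  m <- ct |>
    dplyr::filter(replicate_type == "technical") |>
    dplyr::group_by(cultivar, assay_id) |>
    dplyr::summarise(ct = mean(ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = assay_id, values_from = ct)
  dct <- m$target - m$actin
  ddct_ratio <- 2^-(dct[m$cultivar == "a"] - dct[m$cultivar == "b"])
  expect_equal(sc_ratio, ddct_ratio, tolerance = 1e-9)
  expect_equal(sc_ratio, 4, tolerance = 1e-9)
})

test_that("estimated expression ratios converge to truth as noise vanishes", {
  errs <- vapply(c(0.2, 0.05, 0), function(sd) {
    abs(ratio_experiment(seed = 81, ratio = 4, noise_sd = sd) - 4) / 4
  }, numeric(1))
  expect_equal(errs[3], 0, tolerance = 1e-9)
  expect_lt(errs[2], errs[1] + 1e-9)
})
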