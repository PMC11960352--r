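# Synthetic-data generator: parcellation geometry, cohort and expression
# ground truth, determinism, spatial autocorrelation sanity.

test_that("generated parcellations have the requested geometry", {
  parc <- make_parcellation(152, 156, seed = 1)
  expect_equal(n_regions(parc), 308)
  expect_equal(sum(parc$regions$hemisphere == "left"), 152)
  nrm <- sqrt(rowSums(centroids(parc)^2))
  expect_equal(nrm, setNames(rep(1, 308), region_ids(parc)),
               tolerance = 1e-12)
  # hemispheres separate along the x axis
  expect_true(all(centroids(parc)[1:152, 1] <= 0))
  expect_true(all(centroids(parc)[153:308, 1] >= 0))

  left_only <- make_parcellation(3, 0, seed = 1)
  expect_equal(n_regions(left_only), 3)
  expect_identical(make_parcellation(20, 20, seed = 9)$regions,
                   make_parcellation(20, 20, seed = 9)$regions)
})

test_that("simulated cohorts are deterministic with plausible manifests", {
  parc <- make_parcellation(15, 15, seed = 2)
  cfg <- sim_config(n_left = 15, n_right = 15, n_cases = 6, n_controls = 6,
                    n_effect_regions = 2, n_genes = 30, n_signal_genes = 4,
                    seed = 5)
  a <- simulate_cohort(parc, cfg)
  b <- simulate_cohort(parc, cfg)
  expect_identical(a$cohort$features, b$cohort$features)
  expect_identical(a$cohort$subjects, b$cohort$subjects)
  expect_identical(a$ground_truth, b$ground_truth)

  man <- a$cohort$subjects
  expect_true(all(man$age >= 16 & man$age <= 65))
  expect_true(all(is.na(man$disease_course[man$group == "control"])))
  expect_true(all(!is.na(man$disease_course[man$group == "case"])))
  expect_true(all(a$ground_truth$effect_regions %in% region_ids(parc)))
  expect_identical(sort(unique(man$group)), c("case", "control"))

  cfg_bad <- sim_config(n_left = 15, n_right = 15, n_cases = 6,
                        n_controls = 6, effect_regions = "nope", seed = 5)
  expect_error(simulate_cohort(parc, cfg_bad), "effect region not in")
})

test_that("config validation enforces minimum viable sizes", {
  expect_error(sim_config(n_left = 2), "at least 10")
  expect_error(sim_config(n_cases = 2), "at least 4 subjects")
  expect_error(sim_config(noise_sd = 0), "positive")
  expect_error(sim_config(n_genes = 10, n_signal_genes = 11), "exceeds")
})

test_that("smooth fields correlate more between neighbors than antipodes", {
  parc <- make_parcellation(80, 0, seed = 3)
  cen <- centroids(parc)
  d <- tcrossprod(cen)
  # closest and most antipodal pair of distinct regions
  diag(d) <- -Inf
  nb <- which(d == max(d), arr.ind = TRUE)[1, ]
  diag(d) <- Inf
  ap <- which(d == min(d), arr.ind = TRUE)[1, ]
  vals <- vapply(1:80, function(s)
    unname(simulate_smooth_map(parc, corr_length = 0.5, seed = 400 + s,
                               hemisphere = "left")[c(nb, ap)]),
    numeric(4))
  r_nb <- cor(vals[1, ], vals[2, ])
  r_ap <- cor(vals[3, ], vals[4, ])
  expect_gt(r_nb, r_ap)
  expect_gt(r_nb, 0.5)
})

test_that("expression matrices carry the planted structure", {
  parc <- make_parcellation(60, 0, seed = 4)
  cfg <- sim_config(n_left = 60, n_right = 0, n_genes = 120,
                    n_signal_genes = 10, expression_noise_sd = 0.2, seed = 6)
  y <- simulate_smooth_map(parc, seed = 91, hemisphere = "left")
  ex <- simulate_expression(parc, cfg, y)
  expect_identical(dim(ex$expression), c(60L, 120L))
  expect_equal(colMeans(ex$expression), setNames(rep(0, 120),
                                                 colnames(ex$expression)),
               tolerance = 1e-12)
  expect_equal(apply(ex$expression, 2, sd), setNames(rep(1, 120),
                                                     colnames(ex$expression)),
               tolerance = 1e-12)
  # determinism
  ex2 <- simulate_expression(parc, cfg, y)
  expect_identical(ex$expression, ex2$expression)
  # planted genes track the target with their recorded signs (low noise)
  gt <- ex$ground_truth
  rs <- vapply(seq_along(gt$signal_genes), function(j)
    cor(ex$expression[, gt$signal_genes[j]], y), numeric(1))
  expect_true(all(sign(rs) == gt$signal_signs))
  expect_true(all(abs(rs) > 0.8))
  # background genes share the anterior-posterior gradient on average
  bg <- setdiff(colnames(ex$expression), gt$signal_genes)
  ap <- scale(centroids(parc)[, 2])
  r_ap <- vapply(bg, function(g) cor(ex$expression[, g], ap), numeric(1))
  expect_gt(mean(r_ap), 0.3)

  expect_error(simulate_expression(parc, cfg, y[-1]), "does not match")
})

test_that("a null-effect cohort keeps case and control strengths exchangeable", {
  parc <- make_parcellation(20, 20, seed = 5)
  cfg <- sim_config(n_left = 20, n_right = 20, n_cases = 10, n_controls = 10,
                    effect_size = 0, seed = 8)
  sim <- simulate_cohort(parc, cfg)
  st <- cohort_strengths(sim$cohort)
  tm <- fit_region_glm(st$strengths, sim$cohort)
  # no region should show an extreme contrast under the null at this size
  expect_gt(min(tm$p), 1e-4)
})
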