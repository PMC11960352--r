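# PLS1 closed form, bootstrap Z, FDR selection, candidate analysis.

rand_pls_instance <- function(n = 20, g = 50, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * g), n, g,
              dimnames = list(sprintf("r%02d", 1:n), sprintf("G%03d", 1:g)))
  y <- setNames(rnorm(n), rownames(X))
  list(X = X, y = y)
}

test_that("pls1 weights equal the normalized X'y closed form", {
  for (seed in 1:5) {
    inst <- rand_pls_instance(seed = seed)
    fit <- pls1_fit(inst$X, inst$y)
    Xs <- scale(inst$X); ys <- as.numeric(scale(inst$y))
    w <- as.numeric(t(Xs) %*% ys)
    w <- w / sqrt(sum(w^2))
    if (cor(as.numeric(Xs %*% w), ys) < 0) w <- -w
    expect_equal(unname(fit$weights), w, tolerance = 1e-10)
    expect_equal(sqrt(sum(fit$weights^2)), 1, tolerance = 1e-12)
    expect_gte(cor(fit$scores, inst$y), 0)
  }
})

test_that("single- and two-gene degeneracies behave as the closed form says", {
  set.seed(3)
  g1 <- rnorm(15)
  y <- 2 * g1 + 1
  X <- cbind(GENE1 = g1)
  fit <- pls1_fit(X, y)
  expect_equal(unname(fit$scores), as.numeric(scale(g1)), tolerance = 1e-10)
  expect_equal(cor(fit$scores, y), abs(cor(g1, y)), tolerance = 1e-12)

  # an uncorrelated second gene gets exactly zero weight when y = gene 1
  g2 <- residuals(lm(rnorm(15) ~ g1))
  fit2 <- pls1_fit(cbind(GENE1 = g1, GENE2 = g2), g1)
  expect_equal(unname(fit2$weights), c(1, 0), tolerance = 1e-10)
})

test_that("pls1 is sign-equivariant and invariant to gene rescaling", {
  inst <- rand_pls_instance(seed = 7)
  fit <- pls1_fit(inst$X, inst$y)
  neg <- pls1_fit(inst$X, -inst$y)
  expect_equal(neg$weights, -fit$weights, tolerance = 1e-12)
  expect_equal(neg$scores, -fit$scores, tolerance = 1e-12)

  X2 <- inst$X
  X2[, 3] <- 100 * X2[, 3] - 7
  X2[, 10] <- 0.001 * X2[, 10] + 3
  fit2 <- pls1_fit(X2, inst$y)
  expect_equal(fit2$scores, fit$scores, tolerance = 1e-10)

  expect_error(pls1_fit(cbind(G1 = rep(2, 10)), rnorm(10)),
               "zero-variance gene")
  expect_error(pls1_fit(inst$X, rep(1, 20)), "zero-variance target")
})

test_that("pls1 behaves as a standard model object", {
  inst <- rand_pls_instance(seed = 2)
  fit <- pls1_fit(inst$X, inst$y)
  expect_s3_class(fit, "pls1")
  expect_equal(coef(fit), fit$weights)
  expect_equal(predict(fit), fit$scores)
  expect_equal(predict(fit, inst$X), fit$scores, tolerance = 1e-12)
  expect_equal(fitted(fit) + residuals(fit), fit$y, tolerance = 1e-12)
  expect_output(print(fit), "first PLS component")
})

test_that("bootstrap Z ranks a noiseless planted gene first, reproducibly", {
  set.seed(12)
  n <- 30; g <- 20
  X <- matrix(rnorm(n * g), n, g, dimnames = list(NULL, sprintf("G%02d", 1:g)))
  y <- 3 * X[, 7]                      # y is exactly gene 7
  z1 <- bootstrap_gene_z(X, y, n_boot = 150, seed = 4)
  expect_identical(z1$gene[which.max(abs(z1$z))], "G07")
  # determinism
  z2 <- bootstrap_gene_z(X, y, n_boot = 150, seed = 4)
  expect_identical(z1$z, z2$z)
  # sign coherence and rank validity
  ok <- z1$se > 0
  expect_true(all(sign(z1$z[ok]) == sign(z1$weight[ok])))
  expect_setequal(z1$rank, seq_len(g))
  # negating the target negates every z
  z3 <- bootstrap_gene_z(X, -y, n_boot = 150, seed = 4)
  expect_equal(z3$z, -z1$z, tolerance = 1e-10)
})

test_that("gene selection applies BH-FDR and hard Z cuts as stated", {
  res <- data.frame(gene = c("g1", "g2", "g3"),
                    weight = c(0.6, -0.5, 0.3),
                    se = c(0.1, 0.1, 0.1),
                    z = c(6.1, -5.2, 3.0), rank = c(1, 3, 2))
  sel <- select_genes(res, fdr_alpha = 0.005, z_cut = 5)
  expect_identical(sel$enrichment_pos, "g1")
  expect_identical(sel$enrichment_neg, "g2")

  # hand-checked BH at alpha 0.05: p = (0.001, 0.02, 0.9) rejects the
  # first two (thresholds 0.0167, 0.0333, 0.05)
  zz <- qnorm(1 - c(0.001, 0.02, 0.9) / 2)
  res2 <- data.frame(gene = c("a", "b", "c"), weight = c(1, 1, 1),
                     se = 1, z = zz, rank = 1:3)
  sel2 <- select_genes(res2, fdr_alpha = 0.05)
  expect_setequal(sel2$pls1_pos, c("a", "b"))
  expect_identical(sel2$pls1_neg, character(0))

  # all-null input selects nothing
  res3 <- data.frame(gene = letters[1:4], weight = 0, se = 1, z = 0,
                     rank = 1:4)
  sel3 <- select_genes(res3)
  expect_length(sel3$pls1_pos, 0)
  expect_length(sel3$enrichment_neg, 0)
})

test_that("BH selection is monotone in alpha and empty at alpha zero", {
  set.seed(31)
  res <- data.frame(gene = sprintf("g%02d", 1:40), weight = rnorm(40),
                    se = 1, z = rnorm(40, sd = 3), rank = 1:40)
  prev <- character(0)
  for (alpha in c(0, 0.001, 0.01, 0.05, 0.2)) {
    sel <- select_genes(res, fdr_alpha = alpha)
    cur <- c(sel$pls1_pos, sel$pls1_neg)
    expect_true(all(prev %in% cur))
    if (alpha == 0) expect_length(cur, 0)
    prev <- cur
  }
})

test_that("candidate overlap is case-normalized and order-preserving", {
  expect_identical(candidate_overlap(c("A", "B", "C"), c("B", "D")), "B")
  expect_identical(candidate_overlap(c("A", "B"), c("b", "a")), c("B", "A"))
  expect_warning(out <- candidate_overlap(c("A", "B"), "Z"), "no candidate")
  expect_length(out, 0)
})

test_that("candidate analysis flags planted genes and keeps nulls out", {
  parc <- make_parcellation(152, 0, seed = 8)
  spins <- generate_spins(parc, n_perm = 500, seed = 21, hemisphere = "left")
  y <- simulate_smooth_map(parc, seed = 50, hemisphere = "left")
  set.seed(51)
  noise <- vapply(1:3, function(k)
    unname(simulate_smooth_map(parc, sd = 0.5, seed = 60 + k,
                               hemisphere = "left")), numeric(152))
  X <- cbind(SELF = unname(y),
             PLANT = 0.6 * unname(y) + noise[, 1],
             NULL1 = noise[, 2] / 0.5, NULL2 = noise[, 3] / 0.5)
  rownames(X) <- names(y)
  res <- candidate_analysis(X, colnames(X), y, spins)
  expect_equal(res$r[res$gene == "SELF"], 1)
  expect_equal(res$p_spin[res$gene == "SELF"], 1 / 501)
  expect_true(res$significant_pre_fdr[res$gene == "PLANT"])
  expect_true(res$significant_post_fdr[res$gene == "PLANT"])
  # post-FDR implies pre-FDR everywhere
  expect_true(all(res$significant_pre_fdr | !res$significant_post_fdr))
  expect_error(candidate_analysis(X, "MISSING", y, spins), "not in expression")
})

test_that("enrichment lists export deterministically with provenance", {
  dir <- withr::local_tempdir()
  lists <- list(enrichment_pos = c("SMAD3", "PRR5"),
                enrichment_neg = character(0))
  p1 <- export_enrichment_lists(lists, dir, provenance = "seed: 1")
  expect_identical(read_gene_list(file.path(dir, "enrichment_pos.txt")),
                   c("SMAD3", "PRR5"))
  expect_length(read_gene_list(file.path(dir, "enrichment_neg.txt")), 0)
  before <- lapply(p1, readLines)
  p2 <- export_enrichment_lists(lists, dir, provenance = "seed: 1")
  expect_identical(lapply(p2, readLines), before)
})
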