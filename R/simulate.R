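# Synthetic parcellations, cohorts and expression matrices with known ground
# truth. The generator emulates the study design the pipeline targets: ~308
# parcels on a sphere split across two hemispheres, five morphometric features
# per region with spatially autocorrelated structure, a planted case-control
# effect in chosen regions, and an expression matrix with an
# anterior-posterior gradient plus planted signal genes tracking the effect
# map.

# internal feature model constants: three population spatial loading vectors
# (a rank-3 pattern, so regional profiles are heterogeneous and the cortical
# mean profile is well defined), subject-field loadings (lambda),
# covariate-pattern loadings (gamma), and realistic raw means / scales for
# (CT, GM, SA, GC, MC)
.feat <- list(
  names = c("CT", "GM", "SA", "GC", "MC"),
  beta1 = c(1.0, 0.8, 0.7, -0.5, -0.6),
  beta2 = c(-0.3, 0.6, -0.4, 0.8, 0.2),
  beta3 = c(0.4, -0.2, 0.6, 0.3, -0.7),
  pattern_weights = c(1, 0.5, 0.35),
  amp_skew = 0.7,
  lambda = c(0.30, 0.27, 0.33, 0.36, 0.30),
  gamma = c(0.3, -0.2, 0.4, 0.1, -0.3),
  mu = c(2.5, 550, 480, 0.14, 0.12),
  scale = c(0.25, 120, 90, 0.035, 0.025)
)

# Direction in feature space that increases a region's similarity to the
# cortical mean profile: the mean of the centered, normalized regional
# profiles of the column-z-scored population pattern. Shifting a region's
# feature vector along +d raises its correlation with the average region
# (hence its MSN strength); -d lowers it.
.mean_profile_direction <- function(pattern_std) {
  Z <- scale(pattern_std)
  Zc <- Z - rowMeans(Z)
  P <- Zc / sqrt(rowSums(Zc^2))
  m <- colMeans(P)
  nm <- sqrt(sum(m^2))
  if (nm < 1e-8) stop_msg("degenerate population pattern")
  m / nm
}

# Cholesky factor (upper) of the angular-distance covariance kernel
# K(i, j) = exp(-theta_ij / corr_length) on unit-sphere centroids
sphere_kernel_chol <- function(cen, corr_length) {
  cc <- tcrossprod(cen)
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  K <- exp(-acos(cc) / corr_length)
  chol(K + diag(1e-8, nrow(K)))
}

# one zero-mean unit-marginal-SD sample of the smooth field; consumes RNG
.smooth_field <- function(chol_upper) {
  as.numeric(crossprod(chol_upper, stats::rnorm(nrow(chol_upper))))
}

#' Simulate a spatially smooth map on the sphere
#'
#' Draws one sample of a Gaussian random field on the parcellation centroids
#' with covariance `exp(-angle / corr_length)`, the autocorrelation model the
#' spin-test calibration relies on.
#'
#' @param parcellation a [parcellation].
#' @param corr_length angular correlation length in radians, default 0.5.
#' @param sd marginal standard deviation, default 1.
#' @param seed integer seed.
#' @param hemisphere optional scope (`"left"`, `"right"`, `"both"`).
#' @return Named numeric map over the scoped regions.
#' @export
simulate_smooth_map <- function(parcellation, corr_length = 0.5, sd = 1,
                                seed = 1, hemisphere = "both") {
  scope <- parcellation_subset(parcellation, hemisphere)
  L <- sphere_kernel_chol(centroids(scope), corr_length)
  stats::setNames(sd * with_seed(seed, .smooth_field(L)), region_ids(scope))
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator with defaults matching
#' the emulated study: 308 regions (152 left / 156 right), 59 cases vs 61
#' controls, 8 effect regions (6 with increased and 2 with decreased regional
#' strength) at a standardized shift of 1.5, age/sex/eTIV covariate effects on
#' the features, and a 1000-gene expression matrix with 20 planted signal
#' genes at signal strength 0.8 over smooth noise of SD 0.5 on an
#' anterior-posterior gradient background.
#'
#' @param n_left,n_right regions per hemisphere (>= 10 when nonzero).
#' @param n_cases,n_controls subjects per group (>= 4).
#' @param n_effect_regions number of planted effect regions.
#' @param effect_regions optional character vector of region ids; when `NULL`
#'   regions are drawn at simulation time (split across hemispheres).
#' @param effect_signs +1 / -1 per effect region (recycled).
#' @param effect_size standardized shift delta of the planted effect.
#' @param feature_corr_length angular correlation length (radians) of the
#'   smooth fields underlying the features.
#' @param noise_sd SD of the white feature noise (standardized units).
#' @param covariate_effects named numeric vector of (age, sex, etiv) slopes
#'   modulating a second spatial pattern.
#' @param n_genes,n_signal_genes expression matrix size and planted signal
#'   genes.
#' @param signal_strength beta of the signal genes on the standardized target.
#' @param expression_noise_sd SD of the smooth noise on signal genes.
#' @param gradient_strength amplitude of the anterior-posterior background
#'   gradient.
#' @param subgroup_fraction fraction of cases carrying the optional subgroup
#'   label (emulating e.g. a lesion-positive subgroup); 0 disables it.
#' @param seed master seed; every generator output is a pure function of
#'   (config, seed).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_left = 152, n_right = 156,
                       n_cases = 59, n_controls = 61,
                       n_effect_regions = 8, effect_regions = NULL,
                       effect_signs = c(1, 1, 1, 1, 1, 1, -1, -1),
                       effect_size = 1.5,
                       feature_corr_length = 0.5, noise_sd = 0.5,
                       covariate_effects = c(age = 0.3, sex = 0.1,
                                             etiv = 0.2),
                       n_genes = 1000, n_signal_genes = 20,
                       signal_strength = 0.8, expression_noise_sd = 0.5,
                       gradient_strength = 1,
                       subgroup_fraction = 0.8,
                       seed = 1) {
  cfg <- list(n_left = n_left, n_right = n_right, n_cases = n_cases,
              n_controls = n_controls, n_effect_regions = n_effect_regions,
              effect_regions = effect_regions, effect_signs = effect_signs,
              effect_size = effect_size,
              feature_corr_length = feature_corr_length, noise_sd = noise_sd,
              covariate_effects = covariate_effects, n_genes = n_genes,
              n_signal_genes = n_signal_genes,
              signal_strength = signal_strength,
              expression_noise_sd = expression_noise_sd,
              gradient_strength = gradient_strength,
              subgroup_fraction = subgroup_fraction, seed = seed)
  if ((n_left > 0 && n_left < 10) || (n_right > 0 && n_right < 10)) {
    stop_msg("each represented hemisphere needs at least 10 regions")
  }
  if (n_left + n_right < 10) stop_msg("too few regions")
  if (n_cases < 4 || n_controls < 4) {
    stop_msg("each group needs at least 4 subjects")
  }
  if (noise_sd <= 0 || feature_corr_length <= 0) {
    stop_msg("noise_sd and feature_corr_length must be positive")
  }
  if (n_signal_genes > n_genes) stop_msg("n_signal_genes exceeds n_genes")
  structure(cfg, class = "sim_config")
}

#' Generate a quasi-uniform spherical parcellation
#'
#' Lays `n_left` regions on the x < 0 half of the unit sphere and `n_right`
#' on the x > 0 half using an area-uniform spiral (golden-angle azimuths),
#' adds a small seeded jitter and renormalizes. Region names follow
#' `lh_r###` / `rh_r###`.
#'
#' @param n_left,n_right regions per hemisphere (each 0 or >= 3).
#' @param seed integer seed for the jitter.
#' @return A [parcellation] with left regions first.
#' @export
make_parcellation <- function(n_left, n_right, seed = 1) {
  half_spiral <- function(n, side) {
    k <- seq_len(n)
    x <- side * (k - 0.5) / n        # area-uniform in the axis coordinate
    r <- sqrt(pmax(0, 1 - x^2))
    phi <- 2 * pi * k * (2 - (1 + sqrt(5)) / 2) # golden angle
    cbind(x, r * cos(phi), r * sin(phi))
  }
  cen <- NULL; ids <- character(0); hemi <- character(0)
  if (n_left > 0) {
    cen <- rbind(cen, half_spiral(n_left, -1))
    ids <- c(ids, sprintf("lh_r%03d", seq_len(n_left)))
    hemi <- c(hemi, rep("left", n_left))
  }
  if (n_right > 0) {
    cen <- rbind(cen, half_spiral(n_right, +1))
    ids <- c(ids, sprintf("rh_r%03d", seq_len(n_right)))
    hemi <- c(hemi, rep("right", n_right))
  }
  cen <- with_seed(seed, cen + 0.02 * matrix(stats::rnorm(length(cen)),
                                             ncol = 3))
  # jitter must not push a centroid across the hemisphere plane
  cen[hemi == "left", 1] <- -abs(cen[hemi == "left", 1])
  cen[hemi == "right", 1] <- abs(cen[hemi == "right", 1])
  cen <- cen / sqrt(rowSums(cen^2))
  parcellation(ids, hemisphere = hemi, centroids = cen)
}

# draw effect regions split across hemispheres roughly in proportion,
# restricted to regions with intermediate baseline mean-profile alignment
# (detectable headroom for planted change in either direction)
.draw_effect_regions <- function(parc, n_effect, seed, alignment,
                                 band = c(0.15, 0.85)) {
  df <- parc$regions
  qs <- rank(alignment) / length(alignment)
  eligible <- df$region_id[qs >= band[1] & qs <= band[2]]
  left <- intersect(df$region_id[df$hemisphere == "left"], eligible)
  right <- intersect(df$region_id[df$hemisphere == "right"], eligible)
  with_seed(seed, {
    if (length(left) && length(right)) {
      n_l <- max(1L, min(n_effect - 1L,
                         round(n_effect * length(left) / nrow(df))))
      c(sample(left, n_l), sample(right, n_effect - n_l))
    } else {
      sample(eligible, n_effect)
    }
  })
}

#' Simulate a case-control cohort of morphometric features
#'
#' Each subject's regions x 5 feature matrix is built, in standardized units,
#' as a shared smooth spatial pattern plus a subject-specific smooth latent
#' field, covariate-modulated spatial structure and white noise; the result
#' is mapped to realistic raw feature scales. For cases, every effect
#' region's feature vector is additionally shifted by `effect_size`
#' standardized units along the direction that increases its similarity to
#' the cortical mean morphometric profile (positive sign) or away from it
#' (negative sign), planting an increase or decrease of regional MSN
#' strength. The effect is planted on the features, not on strengths, so the
#' full MSN pipeline is exercised end to end.
#'
#' @param parcellation a [parcellation].
#' @param config a [sim_config]; `config$seed` drives all randomness through
#'   named per-stage streams.
#' @return List with `cohort` (an [msn_cohort]) and `ground_truth` (list with
#'   `effect_regions`, `effect_signs`, `effect_size`, `seed`).
#' @export
simulate_cohort <- function(parcellation, config = sim_config()) {
  ids <- region_ids(parcellation)
  n <- length(ids)
  L <- sphere_kernel_chol(centroids(parcellation),
                          config$feature_corr_length)
  g1 <- with_seed(derive_seed(config$seed, "pattern"), .smooth_field(L))
  g2p <- with_seed(derive_seed(config$seed, "patternB"), .smooth_field(L))
  g3 <- with_seed(derive_seed(config$seed, "patternC"), .smooth_field(L))
  g2 <- with_seed(derive_seed(config$seed, "pattern2"), .smooth_field(L))
  pw <- .feat$pattern_weights
  # the shared-profile amplitude is lognormal (all positive, right-skewed):
  # most regions align moderately with the cortical mean profile and a few
  # strongly, as in real cortex; this keeps the mean profile well defined
  # and the global strength mode stable across pattern draws
  amp <- exp(.feat$amp_skew * g1)
  pattern <- pw[1] * outer(amp, .feat$beta1) +
    pw[2] * outer(g2p, .feat$beta2) + pw[3] * outer(g3, .feat$beta3)
  m_hat <- .mean_profile_direction(pattern)
  col_sd <- apply(pattern, 2L, stats::sd)
  Z0 <- scale(pattern)
  Zc <- Z0 - rowMeans(Z0)
  rnorms <- sqrt(rowSums(Zc^2))
  alignment <- as.numeric(Zc %*% m_hat) / rnorms

  eff <- config$effect_regions
  if (is.null(eff)) {
    eff <- .draw_effect_regions(parcellation, config$n_effect_regions,
                                derive_seed(config$seed, "effects"),
                                alignment)
  }
  bad <- setdiff(eff, ids)
  if (length(bad)) {
    stop_msg("effect region not in parcellation: ", paste(bad, collapse = ", "))
  }
  signs <- rep_len(config$effect_signs, length(eff))
  eff_idx <- match(eff, ids)

  # planted shift, per effect region: a step of delta standardized units
  # (z-score space is per-column-SD units) toward a strongly expressed
  # target profile fully aligned with the cortical mean profile (sign +1)
  # or its opposite (sign -1), capped at arrival; mapped back to each
  # feature's across-region scale
  r90 <- stats::quantile(rnorms, 0.9, names = FALSE)
  shift_mat <- t(vapply(seq_along(eff), function(j) {
    z <- Zc[eff_idx[j], ]
    v <- signs[j] * r90 * m_hat - z
    nv <- sqrt(sum(v^2))
    step <- min(config$effect_size, nv)
    if (nv > 1e-8) v <- v / nv else v <- signs[j] * m_hat
    step * v * col_sd
  }, numeric(5L)))

  n_sub <- config$n_cases + config$n_controls
  man <- with_seed(derive_seed(config$seed, "subjects"), {
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n_sub)),
      group = c(rep("case", config$n_cases),
                rep("control", config$n_controls)),
      age = pmin(65, 16 + round(stats::rgamma(n_sub, shape = 2.2,
                                              scale = 5.5))),
      sex = sample(c("female", "male"), n_sub, replace = TRUE),
      etiv = round(stats::rnorm(n_sub, 1.49e6, 1.4e5)),
      disease_course = c(round(stats::rgamma(config$n_cases, shape = 1.4,
                                             scale = 5.5), 1),
                         rep(NA_real_, config$n_controls)),
      euler_number = round(stats::rnorm(n_sub, -75, 45)),
      stringsAsFactors = FALSE)
  })
  if (config$subgroup_fraction > 0) {
    man$subgroup <- with_seed(derive_seed(config$seed, "subgroup"), {
      sg <- rep(NA_character_, n_sub)
      is_case <- man$group == "case"
      sg[is_case] <- ifelse(stats::runif(sum(is_case)) <
                              config$subgroup_fraction, "yes", "no")
      sg
    })
  }

  ce <- config$covariate_effects
  age_c <- (man$age - 30) / 12
  sex01 <- as.numeric(man$sex == "male")
  etiv_c <- (man$etiv - 1.49e6) / 1.4e5
  cov_amp <- (ce[["age"]] %||% 0) * age_c + (ce[["sex"]] %||% 0) * sex01 +
    (ce[["etiv"]] %||% 0) * etiv_c

  feats <- with_seed(derive_seed(config$seed, "features"), {
    lapply(seq_len(n_sub), function(s) {
      u <- .smooth_field(L)
      eps <- matrix(stats::rnorm(n * 5L), nrow = n)
      std <- pattern + outer(u, .feat$lambda) +
        cov_amp[s] * outer(g2, .feat$gamma) + config$noise_sd * eps
      if (man$group[s] == "case") {
        std[eff_idx, ] <- std[eff_idx, ] + shift_mat
      }
      raw <- sweep(sweep(std, 2L, .feat$scale, "*"), 2L, .feat$mu, "+")
      dimnames(raw) <- list(ids, .feat$names)
      raw
    })
  })
  names(feats) <- man$subject_id
  list(cohort = msn_cohort(man, feats, parcellation),
       ground_truth = list(effect_regions = eff, effect_signs = signs,
                           effect_size = config$effect_size,
                           seed = config$seed))
}

#' Simulate a regions-by-genes expression matrix with planted signal genes
#'
#' Background genes share a fixed anterior-posterior gradient (the y centroid
#' coordinate, standardized) of amplitude `gradient_strength` plus
#' independent smooth spherical noise of unit SD, emulating the dominant
#' spatial mode of cortical expression. Signal genes are
#' `sign * signal_strength * standardized(target) + smooth noise` with
#' recorded random signs. All columns are standardized on output.
#'
#' @param parcellation a [parcellation]; the matrix covers its left
#'   hemisphere (the scope expression-linked analyses run in).
#' @param config a [sim_config].
#' @param target named numeric map on the left-hemisphere regions that the
#'   signal genes track (e.g. the true effect map).
#' @return List with `expression` (regions x genes matrix, genes named
#'   `G0001...`) and `ground_truth` (list with `signal_genes`,
#'   `signal_signs`).
#' @export
simulate_expression <- function(parcellation, config = sim_config(), target) {
  scope <- parcellation_subset(parcellation, "left")
  ids <- region_ids(scope)
  if (length(target) != length(ids) ||
      (!is.null(names(target)) && !identical(names(target), ids))) {
    stop_msg("target map does not match the left-hemisphere regions")
  }
  if (stats::sd(target) == 0) stop_msg("zero-variance target map")
  n <- length(ids)
  G <- config$n_genes
  genes <- sprintf("G%04d", seq_len(G))
  L <- sphere_kernel_chol(centroids(scope), config$feature_corr_length)
  ap <- as.numeric(scale(centroids(scope)[, 2])) # anterior-posterior axis = y
  t_std <- as.numeric(scale(target))
  out <- with_seed(derive_seed(config$seed, "expression"), {
    sig_idx <- sort(sample.int(G, config$n_signal_genes))
    sig_signs <- sample(c(-1, 1), config$n_signal_genes, replace = TRUE)
    noise <- crossprod(L, matrix(stats::rnorm(n * G), nrow = n))
    expr <- config$gradient_strength * ap + noise
    for (j in seq_along(sig_idx)) {
      expr[, sig_idx[j]] <- sig_signs[j] * config$signal_strength * t_std +
        config$expression_noise_sd * noise[, sig_idx[j]] /
          stats::sd(noise[, sig_idx[j]])
    }
    list(expr = expr, sig_idx = sig_idx, sig_signs = sig_signs)
  })
  expr <- apply(out$expr, 2L, scale)
  dimnames(expr) <- list(ids, genes)
  list(expression = expr,
       ground_truth = list(signal_genes = genes[out$sig_idx],
                           signal_signs = out$sig_signs))
}
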