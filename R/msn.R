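#' z-normalize morphometric features across regions
#'
#' Each feature column is centred and scaled to unit sample standard deviation
#' (denominator N-1) across regions, so that features measured on arbitrary
#' scales (mm of cortical thickness, mm^2 of surface area, curvature) become
#' comparable before region-by-region correlation. A constant feature column
#' is an error.
#'
#' @param fm numeric matrix, regions x features.
#' @return Matrix of the same shape with columns of mean 0 and sample SD 1.
#' @export
normalize_features <- function(fm) {
  fm <- as.matrix(fm)
  sds <- apply(fm, 2L, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    bad <- colnames(fm)[!is.finite(sds) | sds == 0] %||% which(sds == 0)
    stop_msg("constant feature: ", paste(bad, collapse = ", "))
  }
  out <- scale(fm, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  dimnames(out) <- dimnames(fm)
  out
}

#' Build a morphometric similarity network
#'
#' Computes the Pearson correlation of the (z-normalized) feature vectors of
#' every pair of regions, yielding a symmetric regions x regions similarity
#' matrix — the subject's morphometric similarity network. The diagonal is
#' defined as 0. With the default five features each correlation rests on five
#' points; at least three feature columns are required.
#'
#' @param fm numeric matrix, regions x features, typically the output of
#'   [normalize_features()].
#' @return Symmetric numeric matrix, regions x regions, zero diagonal, region
#'   ids as dimnames.
#' @export
build_msn <- function(fm) {
  fm <- as.matrix(fm)
  if (ncol(fm) < 3L) stop_msg("at least 3 features are required")
  rv <- apply(fm, 1L, stats::sd)
  if (any(rv == 0 | !is.finite(rv))) {
    bad <- rownames(fm)[rv == 0 | !is.finite(rv)] %||% which(rv == 0)
    stop_msg("zero across-feature variance for region: ",
             paste(bad, collapse = ", "))
  }
  m <- stats::cor(t(fm))
  diag(m) <- 0
  dimnames(m) <- list(rownames(fm), rownames(fm))
  m
}

#' Regional MSN strength
#'
#' The strength of a region is the signed sum of its correlations with all
#' other regions (row sum of the MSN, diagonal excluded). No absolute value
#' and no sparsification are applied by default; both are available as
#' documented options for sensitivity analyses.
#'
#' @param msn a symmetric MSN matrix with zero diagonal, as from [build_msn()].
#' @param absolute if `TRUE`, sum `|r|` instead of signed `r`.
#' @param threshold optional scalar; correlations with `|r|` below it are set
#'   to 0 before summing. `NULL` (default) applies no sparsification.
#' @return Named numeric vector of per-region strengths.
#' @export
regional_strength <- function(msn, absolute = FALSE, threshold = NULL) {
  m <- as.matrix(msn)
  if (!is.null(threshold)) m[abs(m) < threshold] <- 0
  if (absolute) m <- abs(m)
  rowSums(m)
}

#' Per-subject strengths and group mean maps for a cohort
#'
#' Runs z-normalization, MSN construction and strength summation for every
#' subject, returning a subjects x regions strength table plus per-group mean
#' strength maps.
#'
#' @param cohort an [msn_cohort].
#' @param absolute,threshold passed to [regional_strength()].
#' @return A list with `strengths` (subjects x regions matrix, subject ids as
#'   row names) and `group_means` (groups x regions matrix).
#' @export
cohort_strengths <- function(cohort, absolute = FALSE, threshold = NULL) {
  ids <- region_ids(cohort$parcellation)
  subs <- cohort$subjects$subject_id
  strengths <- matrix(NA_real_, nrow = length(subs), ncol = length(ids),
                      dimnames = list(subs, ids))
  for (sid in subs) {
    msn <- build_msn(normalize_features(cohort$features[[sid]]))
    strengths[sid, ] <- regional_strength(msn, absolute = absolute,
                                          threshold = threshold)
  }
  groups <- sort(unique(cohort$subjects$group))
  gm <- t(vapply(groups, function(g) {
    colMeans(strengths[cohort$subjects$subject_id[cohort$subjects$group == g], ,
                       drop = FALSE])
  }, numeric(length(ids))))
  rownames(gm) <- groups
  list(strengths = strengths, group_means = gm)
}
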