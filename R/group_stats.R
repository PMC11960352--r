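#' Region-wise covariate-adjusted case-control contrast
#'
#' Fits, for every region, an ordinary least squares model
#' `strength ~ group + covariates` (a Gaussian GLM with identity link) and
#' extracts the two-sided t statistic of the group coefficient with the sign
#' convention case minus control. Age, sex and estimated total intracranial
#' volume are the conventional covariates. All regions share one design
#' matrix, so the fit is vectorized through a single QR decomposition.
#'
#' @param strengths numeric matrix, subjects x regions (subject ids as row
#'   names), as from [cohort_strengths()].
#' @param subjects manifest data frame (or an [msn_cohort], whose manifest is
#'   used) with a `subject_id` column, the grouping column and any covariates.
#' @param covariates character vector of manifest columns to adjust for; may
#'   be empty. `sex` is encoded as a 0/1 indicator; the direction of that
#'   encoding does not affect the group t.
#' @param group_col,case,control names of the grouping column and its case /
#'   control levels.
#' @param contrast_label label recorded on the result.
#' @return A data frame of class `group_stat_map` with columns
#'   `region_id, t, p, significant` (`significant` is `NA` until
#'   [threshold_map()] is applied); attributes `contrast`, `df`, `covariates`.
#' @export
fit_region_glm <- function(strengths, subjects,
                           covariates = c("age", "sex", "etiv"),
                           group_col = "group", case = "case",
                           control = "control",
                           contrast_label = paste(case, "-", control)) {
  if (inherits(subjects, "msn_cohort")) subjects <- subjects$subjects
  man <- subjects[subjects[[group_col]] %in% c(case, control), , drop = FALSE]
  keep <- intersect(rownames(strengths), man$subject_id)
  man <- man[match(keep, man$subject_id), , drop = FALSE]
  Y <- strengths[keep, , drop = FALSE]
  g <- as.numeric(man[[group_col]] == case)
  if (sum(g == 1) < 2L || sum(g == 0) < 2L) {
    stop_msg("each group needs at least 2 subjects")
  }
  X <- cbind(`(Intercept)` = 1, group = g)
  for (cv in covariates) {
    v <- man[[cv]]
    if (is.null(v)) stop_msg("covariate not in manifest: ", cv)
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    if (anyNA(v)) stop_msg("missing values in covariate: ", cv)
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop_msg("rank-deficient design matrix")
  n <- nrow(X); p <- ncol(X); df <- n - p
  if (df < 1L) stop_msg("no residual degrees of freedom")
  beta <- qr.coef(qx, Y)
  resid <- Y - X %*% beta
  sigma2 <- colSums(resid^2) / df
  # qr() may pivot columns (rank-revealing); map (X'X)^-1 back to the
  # original column order before reading off the group-coefficient variance
  xtx_inv <- chol2inv(qr.R(qx))
  unpiv <- order(qx$pivot)
  xtx_inv <- xtx_inv[unpiv, unpiv, drop = FALSE]
  se <- sqrt(sigma2 * xtx_inv[2L, 2L])
  tval <- beta["group", ] / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  out <- data.frame(region_id = colnames(strengths), t = as.numeric(tval),
                    p = as.numeric(pval), significant = NA,
                    stringsAsFactors = FALSE)
  structure(out, class = c("group_stat_map", "data.frame"),
            contrast = contrast_label, df = df, covariates = covariates)
}

#' Flag significant regions at the exploratory 1/N threshold
#'
#' Marks a region significant iff `p < 1/n_regions` (strict), the
#' false-positive correction conventionally used for exploratory nodal
#' analyses: with N regions tested, fewer than one false positive is expected
#' under the global null.
#'
#' @param stats a `group_stat_map` from [fit_region_glm()].
#' @param n_regions the N of the 1/N rule; defaults to the number of rows.
#' @return The map with its `significant` column filled in and a `threshold`
#'   attribute recorded.
#' @export
threshold_map <- function(stats, n_regions = nrow(stats)) {
  stopifnot(n_regions >= 1)
  thr <- 1 / n_regions
  stats$significant <- stats$p < thr
  attr(stats, "threshold") <- thr
  stats
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat("group_stat_map: contrast", attr(x, "contrast"), "over", nrow(x),
      "regions (df =", attr(x, "df"), ")\n")
  if (!anyNA(x$significant)) {
    sig <- x[x$significant, , drop = FALSE]
    cat(" ", nrow(sig), "region(s) significant at p <",
        format(attr(x, "threshold"), digits = 4), "\n")
    if (nrow(sig)) {
      sig <- sig[order(-abs(sig$t)), ]
      for (i in seq_len(min(10, nrow(sig)))) {
        cat(sprintf("  %s  t = %.2f  p = %.3g\n",
                    sig$region_id[i], sig$t[i], sig$p[i]))
      }
    }
  }
  invisible(x)
}

#' Pearson correlation between two regional maps
#'
#' @param a,b numeric vectors on the same region set (names, when present,
#'   must agree in order).
#' @return A list with `r`, `df` (= n - 2) and the parametric two-sided `p`.
#'   For spatially smooth maps prefer the spin-test p from [spin_pvalue()].
#' @export
map_correlation <- function(a, b) {
  if (length(a) != length(b)) stop_msg("maps differ in length")
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b))) {
    stop_msg("maps are on different region sets")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop_msg("zero-variance map")
  r <- stats::cor(a, b)
  df <- length(a) - 2L
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tt), df = df))
}

#' Disease-course correlation in selected regions
#'
#' Pearson correlation between disease course (years) and regional MSN
#' strength across cases, per listed region, with a two-sided parametric p.
#' Used to probe whether strength changes in significant regions track how
#' long the disease has been present.
#'
#' @param strengths subjects x regions strength matrix.
#' @param cohort an [msn_cohort] (or manifest data frame) supplying `group`
#'   and `disease_course`.
#' @param regions character vector of region ids to test.
#' @return Data frame with columns `region_id, r, p`, one row per region.
#' @export
course_correlation <- function(strengths, cohort, regions) {
  man <- if (inherits(cohort, "msn_cohort")) cohort$subjects else cohort
  if (!length(regions)) stop_msg("no regions supplied")
  cases <- man$subject_id[man$group == "case" & !is.na(man$disease_course)]
  if (length(cases) < 3L) {
    stop_msg("fewer than 3 cases with disease-course data")
  }
  course <- man$disease_course[match(cases, man$subject_id)]
  if (stats::sd(course) == 0) stop_msg("zero-variance disease course")
  miss <- setdiff(regions, colnames(strengths))
  if (length(miss)) {
    stop_msg("region(s) not in strength table: ", paste(miss, collapse = ", "))
  }
  res <- lapply(regions, function(rg) {
    y <- strengths[cases, rg]
    if (stats::sd(y) == 0) stop_msg("zero-variance strength in region ", rg)
    ct <- stats::cor.test(course, y)
    data.frame(region_id = rg, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
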