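# PLS regression of a regional map on gene expression, bootstrap gene
# ranking, FDR selection and candidate-gene spatial analysis.

# first-component weights for a univariate response on standardized data:
# w proportional to X'y, normalized to unit Euclidean norm. Columns with zero
# variance (possible in bootstrap resamples) contribute weight 0.
.pls1_weights <- function(Xs, ys) {
  w <- as.numeric(crossprod(Xs, ys))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop_msg("degenerate fit: X'y is identically zero")
  w / nw
}

.standardize <- function(x, drop_constant = FALSE) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  sds <- sqrt(colSums(xc^2) / (nrow(x) - 1))
  if (drop_constant) {
    sds[sds == 0] <- Inf # column becomes all-zero, weight 0
  } else if (any(sds == 0)) {
    stop_msg("zero-variance gene: ",
             paste(colnames(x)[sds == 0], collapse = ", "))
  }
  sweep(xc, 2L, sds, "/")
}

#' First partial least squares component of expression on a regional map
#'
#' Fits the single-component PLS regression in which gene expression predicts
#' a regional map (for example a case-control t-map). With a univariate
#' response the first PLS weight vector has the exact closed form
#' `w = X'y / ||X'y||` after columnwise standardization of `X` and `y`, so no
#' iterative algorithm is needed and the fit is fully deterministic. The PLS1
#' score map is `X w`, the linear combination of gene expression most
#' covariant with the target; its sign is chosen so that the score-target
#' correlation is non-negative.
#'
#' @param X numeric matrix, regions x genes; genes with zero variance must be
#'   removed beforehand (they are an error here).
#' @param y numeric target map on the same regions.
#' @return An object of class `pls1` with components `weights` (unit-norm,
#'   per gene), `scores` (per region), `loadings` (gene-score correlations),
#'   `variance_explained` (squared score-target correlation),
#'   `sign_flipped`, `y`, standardization constants, and the usual
#'   `print`/`summary`/`coef`/`predict`/`fitted`/`residuals` methods.
#' @export
pls1_fit <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop_msg("at least 3 regions are required")
  if (nrow(X) != length(y)) stop_msg("X and y are on different region sets")
  if (!is.null(rownames(X)) && !is.null(names(y)) &&
      !identical(rownames(X), names(y))) {
    stop_msg("X and y region ids do not match")
  }
  if (stats::sd(y) == 0) stop_msg("zero-variance target map")
  x_center <- colMeans(X)
  x_scale <- apply(X, 2L, stats::sd)
  Xs <- .standardize(X)
  ys <- as.numeric(scale(y))
  w <- .pls1_weights(Xs, ys)
  scores <- as.numeric(Xs %*% w)
  flip <- stats::cor(scores, ys) < 0
  if (flip) {
    w <- -w
    scores <- -scores
  }
  loadings <- as.numeric(stats::cor(Xs, scores))
  structure(list(weights = stats::setNames(w, colnames(X)),
                 scores = stats::setNames(scores, rownames(X)),
                 loadings = stats::setNames(loadings, colnames(X)),
                 variance_explained = stats::cor(scores, ys)^2,
                 sign_flipped = flip,
                 x_center = x_center, x_scale = x_scale,
                 y = y, n_regions = nrow(X), n_genes = ncol(X),
                 call = match.call()),
            class = "pls1")
}

#' @export
print.pls1 <- function(x, ...) {
  cat("pls1: first PLS component,", x$n_genes, "genes over", x$n_regions,
      "regions\n")
  cat(sprintf("  score-target r = %.3f (variance explained %.1f%%)%s\n",
              sqrt(x$variance_explained), 100 * x$variance_explained,
              if (x$sign_flipped) ", sign-aligned to target" else ""))
  invisible(x)
}

#' @export
summary.pls1 <- function(object, n_top = 10L, ...) {
  print(object)
  ord <- order(-abs(object$weights))[seq_len(min(n_top, object$n_genes))]
  cat("  largest |weights|:\n")
  for (i in ord) {
    cat(sprintf("    %-12s %+0.4f\n", names(object$weights)[i],
                object$weights[i]))
  }
  invisible(object)
}

#' @export
coef.pls1 <- function(object, ...) object$weights

#' @export
#' @rdname pls1_fit
#' @param object a fitted `pls1`.
#' @param newdata optional regions x genes matrix on the same genes; scores
#'   are computed with the training standardization.
#' @param ... unused.
predict.pls1 <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  newdata <- as.matrix(newdata)
  Xs <- sweep(sweep(newdata, 2L, object$x_center, "-"), 2L,
              object$x_scale, "/")
  stats::setNames(as.numeric(Xs %*% object$weights), rownames(newdata))
}

#' @export
fitted.pls1 <- function(object, ...) {
  b <- stats::cov(object$y, object$scores) / stats::var(object$scores)
  mean(object$y) + b * object$scores
}

#' @export
residuals.pls1 <- function(object, ...) object$y - fitted(object)

#' Bootstrap gene Z scores for PLS1 weights
#'
#' Resamples regions with replacement, refits the first PLS component on each
#' resample, sign-aligns every replicate weight vector to the full fit (by
#' maximal cosine, i.e. the sign of their inner product) to avoid sign-flip
#' inflation of the spread, and takes each gene's bootstrap standard error as
#' the SD of its replicate weights. The gene ranking statistic is
#' `z = full-fit weight / bootstrap SE`. Resamples with fewer than 3 distinct
#' regions are redrawn (counted in the `redraws` attribute).
#'
#' @param X regions x genes expression matrix.
#' @param y target regional map.
#' @param n_boot number of bootstrap replicates (>= 100), default 1000.
#' @param seed integer seed; the result is deterministic given
#'   (X, y, n_boot, seed).
#' @return Data frame of class `gene_z` with columns `gene, weight, se, z,
#'   rank` (rank 1 = largest z, descending) ordered as the columns of `X`;
#'   attributes `n_boot`, `seed`, `redraws`.
#' @export
bootstrap_gene_z <- function(X, y, n_boot = 1000, seed = 1) {
  if (n_boot < 100) stop_msg("n_boot must be at least 100")
  fit <- pls1_fit(X, y)
  X <- as.matrix(X)
  n <- nrow(X)
  w_full <- fit$weights
  W <- matrix(NA_real_, nrow = ncol(X), ncol = n_boot)
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) >= 3L && stats::sd(y[idx]) > 0) break
        redraws <- redraws + 1L
      }
      Xs <- .standardize(X[idx, , drop = FALSE], drop_constant = TRUE)
      ys <- as.numeric(scale(y[idx]))
      wb <- .pls1_weights(Xs, ys)
      s <- sum(wb * w_full)
      if (s < 0) wb <- -wb
      W[, b] <- wb
    }
  })
  if (redraws > 0) {
    message("bootstrap_gene_z: ", redraws, " degenerate resample(s) redrawn")
  }
  se <- apply(W, 1L, stats::sd)
  z <- ifelse(se > 0, w_full / se,
              ifelse(w_full == 0, 0, sign(w_full) * Inf))
  out <- data.frame(gene = colnames(X), weight = as.numeric(w_full),
                    se = se, z = as.numeric(z),
                    rank = rank(-z, ties.method = "first"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("gene_z", "data.frame"),
            n_boot = n_boot, seed = seed, redraws = redraws)
}

#' @export
print.gene_z <- function(x, ...) {
  cat("gene_z:", nrow(x), "genes,", attr(x, "n_boot"),
      "bootstrap replicates (seed", paste0(attr(x, "seed"), ")"), "\n")
  top <- x[order(-abs(x$z)), ][seq_len(min(10L, nrow(x))), ]
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-12s w = %+0.4f  z = %+0.2f\n",
                top$gene[i], top$weight[i], top$z[i]))
  }
  invisible(x)
}

#' Select genes by FDR and by hard Z cuts
#'
#' Converts each gene's bootstrap Z to a two-sided p-value under the normal
#' approximation, applies Benjamini-Hochberg FDR control across all genes, and
#' splits the survivors by weight sign into the PLS1+ / PLS1- lists. A second,
#' harder selection by `|z|` cut-offs yields the lists conventionally uploaded
#' to enrichment platforms.
#'
#' @param results a `gene_z` data frame from [bootstrap_gene_z()].
#' @param fdr_alpha FDR level for the PLS1+/- lists, default 0.005 (5 per
#'   mille).
#' @param z_cut threshold for the enrichment lists (`z > z_cut`,
#'   `z < -z_cut`), default 5.
#' @return List with character vectors `pls1_pos`, `pls1_neg`,
#'   `enrichment_pos`, `enrichment_neg` and the augmented `table` (adds
#'   columns `p`, `q`, `category`).
#' @export
select_genes <- function(results, fdr_alpha = 0.005, z_cut = 5) {
  p <- 2 * stats::pnorm(-abs(results$z))
  q <- stats::p.adjust(p, method = "BH")
  sel <- q < fdr_alpha
  category <- rep("none", nrow(results))
  category[sel & results$z > 0] <- "PLS1+"
  category[sel & results$z < 0] <- "PLS1-"
  tab <- results
  class(tab) <- "data.frame"
  tab$p <- p
  tab$q <- q
  tab$category <- category
  list(pls1_pos = results$gene[sel & results$z > 0],
       pls1_neg = results$gene[sel & results$z < 0],
       enrichment_pos = results$gene[results$z > z_cut],
       enrichment_neg = results$gene[results$z < -z_cut],
       table = tab)
}

#' Overlap of a candidate panel with the gene universe
#'
#' Case-normalized set intersection; the original candidate order (and the
#' universe's spelling) is preserved. An empty overlap is a warning, not an
#' error.
#'
#' @param universe character vector of gene symbols present in the expression
#'   matrix.
#' @param candidates character vector of candidate symbols.
#' @return Character vector of overlapping symbols.
#' @export
candidate_overlap <- function(universe, candidates) {
  idx <- match(toupper(candidates), toupper(universe))
  out <- universe[idx[!is.na(idx)]]
  if (!length(out)) warning("no candidate genes overlap the universe")
  out
}

#' Spatial analysis of candidate genes against a regional map
#'
#' For each candidate gene, correlates its regional expression map with the
#' target map, computes a spin-test p-value, and applies Benjamini-Hochberg
#' FDR across the candidate set. Both the pre-FDR (`p_spin < alpha`) and
#' post-FDR (`q < alpha`) significance flags are reported.
#'
#' @param X regions x genes expression matrix.
#' @param candidates candidate symbols, a subset of `colnames(X)` (apply
#'   [candidate_overlap()] first).
#' @param y target regional map.
#' @param spins a `spin_set` on the same region scope.
#' @param alpha significance level, default 0.05.
#' @return Data frame of class `candidate_results` with columns
#'   `gene, r, p_spin, q, significant_pre_fdr, significant_post_fdr`.
#' @export
candidate_analysis <- function(X, candidates, y, spins, alpha = 0.05) {
  miss <- setdiff(candidates, colnames(X))
  if (length(miss)) {
    stop_msg("candidate(s) not in expression matrix: ",
             paste(miss, collapse = ", "))
  }
  res <- lapply(candidates, function(g) {
    sp <- spin_pvalue(X[, g], y, spins)
    data.frame(gene = g, r = sp$r, p_spin = sp$p_spin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p_spin, method = "BH")
  out$significant_pre_fdr <- out$p_spin < alpha
  out$significant_post_fdr <- out$q < alpha
  structure(out, class = c("candidate_results", "data.frame"),
            alpha = alpha, n_perm = spins$n_perm)
}

#' @export
print.candidate_results <- function(x, ...) {
  cat("candidate_results:", nrow(x), "genes, spin test with",
      attr(x, "n_perm"), "permutations\n")
  for (i in order(x$p_spin)) {
    cat(sprintf("  %-12s r = %+0.3f  p_spin = %.4g  q = %.4g%s\n",
                x$gene[i], x$r[i], x$p_spin[i], x$q[i],
                if (x$significant_post_fdr[i]) "  *" else ""))
  }
  invisible(x)
}

#' Export gene lists for external enrichment analysis
#'
#' Writes one plain-text symbol list per category with a `#` provenance
#' header; re-exporting the same inputs produces identical bytes.
#'
#' @param lists named list of character vectors (e.g. the `enrichment_pos` /
#'   `enrichment_neg` output of [select_genes()]).
#' @param out_dir output directory, created if needed.
#' @param provenance optional character vector appended to every header
#'   (thresholds, seed).
#' @return Character vector of the written file paths, invisibly.
#' @export
export_enrichment_lists <- function(lists, out_dir, provenance = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(lists), function(nm) {
    path <- file.path(out_dir, paste0(nm, ".txt"))
    write_gene_list(lists[[nm]], path,
                    header = c(paste0("list: ", nm),
                               paste0("n_genes: ", length(lists[[nm]])),
                               provenance))
    path
  }, character(1))
  invisible(paths)
}
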