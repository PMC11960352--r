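# Spin-permutation spatial nulls for parcellated hemisphere maps.
#
# Parcel-level spin test: draw a uniform random 3D rotation, rotate the parcel
# centroids on the sphere, and reassign every original parcel to the nearest
# rotated centroid. The permuted maps inherit the spatial autocorrelation of
# the original, which a naive parametric Pearson p ignores.

quat_to_rotmat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# nearest rotated-centroid reassignment: perm[i] is the source region whose
# rotated centroid is closest (max dot product = min chordal/geodesic distance)
# to original centroid i
spin_reassign <- function(cen, rot) {
  rotated <- cen %*% t(rot)
  sim <- cen %*% t(rotated)
  max.col(sim, ties.method = "first")
}

#' Generate a set of spin permutations
#'
#' Draws `n_perm` uniform random rotations of the sphere (normalized Gaussian
#' quaternions, which are uniform on SO(3)), applies each to the scoped
#' centroids and records the nearest-rotated-centroid reassignment as one
#' permutation of region indices. Duplicate assignments are permitted, as in
#' the canonical parcel-level spin procedure. When both hemispheres are in
#' scope the right hemisphere uses the x-mirrored image of the left
#' hemisphere's rotation and regions are reassigned within their own
#' hemisphere.
#'
#' @param parcellation a [parcellation].
#' @param n_perm number of permutations (>= 1), default 1000.
#' @param seed integer seed; the spin set is a pure function of
#'   (parcellation, n_perm, seed).
#' @param hemisphere scope: `"left"` (default), `"right"` or `"both"`.
#' @return An object of class `spin_set`: list with `perm` (n_perm x
#'   n_regions integer matrix; row k maps target region i to source region
#'   `perm[k, i]`), `region_ids`, `seed`, `hemisphere`.
#' @export
generate_spins <- function(parcellation, n_perm = 1000, seed = 1,
                           hemisphere = c("left", "right", "both")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(n_perm >= 1)
  scope <- parcellation_subset(parcellation, hemisphere)
  ids <- region_ids(scope)
  n <- length(ids)
  if (n < 3L) stop_msg("fewer than 3 regions in spin scope")
  cen <- centroids(scope)
  hemi <- scope$regions$hemisphere
  mirror <- diag(c(-1, 1, 1))
  quats <- with_seed(seed, matrix(stats::rnorm(4L * n_perm), nrow = n_perm))
  perm <- matrix(NA_integer_, nrow = n_perm, ncol = n)
  left_idx <- which(hemi == "left")
  right_idx <- which(hemi == "right")
  for (k in seq_len(n_perm)) {
    rot <- quat_to_rotmat(quats[k, ])
    if (length(left_idx)) {
      perm[k, left_idx] <-
        left_idx[spin_reassign(cen[left_idx, , drop = FALSE], rot)]
    }
    if (length(right_idx)) {
      rot_r <- mirror %*% rot %*% mirror
      perm[k, right_idx] <-
        right_idx[spin_reassign(cen[right_idx, , drop = FALSE], rot_r)]
    }
  }
  colnames(perm) <- ids
  structure(list(perm = perm, region_ids = ids, seed = seed,
                 hemisphere = hemisphere, n_perm = n_perm),
            class = "spin_set")
}

#' @export
print.spin_set <- function(x, ...) {
  cat("spin_set:", x$n_perm, "permutations over", length(x$region_ids),
      x$hemisphere, "regions (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Write / read a spin set
#'
#' The permutation index table is cached as a TSV with the seed and scope in
#' `#` header lines, so expensive spin sets can be reused across runs.
#'
#' @param spins a `spin_set`.
#' @param path file path.
#' @export
write_spin_set <- function(spins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# seed\t", spins$seed),
               paste0("# hemisphere\t", spins$hemisphere),
               paste(spins$region_ids, collapse = "\t")), con)
  utils::write.table(spins$perm, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spin_set
#' @export
read_spin_set <- function(path) {
  lines <- readLines(path, n = 3L)
  seed <- as.integer(strsplit(lines[1], "\t")[[1]][2])
  hemisphere <- strsplit(lines[2], "\t")[[1]][2]
  ids <- strsplit(lines[3], "\t")[[1]]
  perm <- as.matrix(utils::read.table(path, skip = 3L, sep = "\t"))
  colnames(perm) <- ids
  storage.mode(perm) <- "integer"
  structure(list(perm = perm, region_ids = ids, seed = seed,
                 hemisphere = hemisphere, n_perm = nrow(perm)),
            class = "spin_set")
}

#' Spin-test p-value for the correlation of two maps
#'
#' Observed statistic is the Pearson correlation of the two maps; the null
#' distribution is obtained by spinning map `a` with every permutation in the
#' set and re-correlating with `b`. The p-value is two-sided on `|r|` with the
#' add-one rule, so its minimum attainable value is `1/(n_perm + 1)`.
#'
#' @param a,b numeric maps on the spin scope (names, when present, must match
#'   the spin set's region order).
#' @param spins a `spin_set` from [generate_spins()].
#' @return List with `r` (observed Pearson r), `p_spin` and `n_perm`.
#' @export
spin_pvalue <- function(a, b, spins) {
  n <- length(spins$region_ids)
  if (length(a) != n || length(b) != n) {
    stop_msg("maps do not match the spin scope (", n, " regions)")
  }
  for (m in list(a, b)) {
    if (!is.null(names(m)) && !identical(names(m), spins$region_ids)) {
      stop_msg("map region order does not match the spin set")
    }
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop_msg("zero-variance map")
  r_obs <- stats::cor(a, b)
  a_perm <- matrix(a[spins$perm], nrow = spins$n_perm)
  am <- a_perm - rowMeans(a_perm)
  bc <- b - mean(b)
  r_null <- as.numeric(am %*% bc) /
    (sqrt(rowSums(am^2)) * sqrt(sum(bc^2)))
  p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (1 + spins$n_perm)
  list(r = r_obs, p_spin = p, n_perm = spins$n_perm)
}
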