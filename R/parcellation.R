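#' Cortical parcellation
#'
#' A parcellation is the index space every map and matrix in the package lives
#' in: an ordered set of cortical regions, each with a stable string id, a
#' hemisphere label and a centroid on the unit sphere. Region order is fixed at
#' construction and shared by every object derived from the parcellation, so
#' maps can never be silently misaligned.
#'
#' @param region_id character vector of unique region ids.
#' @param name human-readable region names (defaults to the ids).
#' @param hemisphere `"left"` or `"right"` per region.
#' @param centroids numeric matrix with one row per region and columns
#'   `cx, cy, cz`; each row must have unit Euclidean norm (tolerance `1e-9`).
#'
#' @return An object of class `parcellation`.
#' @examples
#' ids <- paste0("lh_r", 1:4)
#' cen <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0), c(0, 0, -1))
#' parcellation(ids, hemisphere = rep("left", 4), centroids = cen)
#' @export
parcellation <- function(region_id, name = region_id, hemisphere, centroids) {
  centroids <- as.matrix(centroids)
  stopifnot(length(region_id) == length(name),
            length(region_id) == length(hemisphere),
            nrow(centroids) == length(region_id), ncol(centroids) == 3L)
  df <- data.frame(region_id = as.character(region_id),
                   name = as.character(name),
                   hemisphere = as.character(hemisphere),
                   cx = as.numeric(centroids[, 1]),
                   cy = as.numeric(centroids[, 2]),
                   cz = as.numeric(centroids[, 3]),
                   stringsAsFactors = FALSE)
  validate_parcellation(df)
  structure(list(regions = df), class = "parcellation")
}

validate_parcellation <- function(df) {
  dup <- df$region_id[duplicated(df$region_id)]
  if (length(dup)) {
    stop_msg("duplicate region id: ", paste(unique(dup), collapse = ", "))
  }
  bad_hemi <- setdiff(unique(df$hemisphere), c("left", "right"))
  if (length(bad_hemi)) {
    stop_msg("unknown hemisphere label: ", paste(bad_hemi, collapse = ", "))
  }
  nrm <- sqrt(df$cx^2 + df$cy^2 + df$cz^2)
  if (any(abs(nrm - 1) > 1e-9)) {
    stop_msg("centroid not on the unit sphere for region: ",
             paste(df$region_id[abs(nrm - 1) > 1e-9], collapse = ", "))
  }
  for (h in unique(df$hemisphere)) {
    if (sum(df$hemisphere == h) < 3L) {
      stop_msg("hemisphere '", h, "' has fewer than 3 regions")
    }
  }
  invisible(df)
}

#' Read a parcellation table
#'
#' Reads a TSV with columns `region_id, name, hemisphere, cx, cy, cz`.
#' Centroids whose norm is within `1e-3` of 1 are renormalized to exact unit
#' length; anything farther off is an error.
#'
#' @param path path to the TSV file.
#' @return A [parcellation] in file row order.
#' @export
read_parcellation <- function(path) {
  df <- read_tsv(path)
  need <- c("region_id", "name", "hemisphere", "cx", "cy", "cz")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_msg("parcellation file lacks column(s): ", paste(miss, collapse = ", "))
  }
  for (col in c("cx", "cy", "cz")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stop_msg("non-numeric centroid coordinate in column ", col)
    df[[col]] <- v
  }
  nrm <- sqrt(df$cx^2 + df$cy^2 + df$cz^2)
  if (any(abs(nrm - 1) > 1e-3)) {
    stop_msg("non-normalizable centroid for region: ",
             paste(df$region_id[abs(nrm - 1) > 1e-3], collapse = ", "))
  }
  parcellation(df$region_id, df$name, df$hemisphere,
               cbind(df$cx, df$cy, df$cz) / nrm)
}

#' Write a parcellation table
#'
#' Inverse of [read_parcellation()]; coordinates are written with 17
#' significant digits so a read/write round trip reproduces them exactly.
#'
#' @param parc a [parcellation].
#' @param path output TSV path.
#' @export
write_parcellation <- function(parc, path) {
  df <- parc$regions
  out <- data.frame(region_id = df$region_id, name = df$name,
                    hemisphere = df$hemisphere,
                    cx = fmt_full(df$cx), cy = fmt_full(df$cy),
                    cz = fmt_full(df$cz), stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Restrict a parcellation to one hemisphere
#'
#' @param parc a [parcellation].
#' @param hemisphere `"left"`, `"right"` or `"both"`.
#' @return A [parcellation] containing the scoped regions, in original order.
#' @export
parcellation_subset <- function(parc, hemisphere = c("left", "right", "both")) {
  hemisphere <- match.arg(hemisphere)
  if (hemisphere == "both") return(parc)
  df <- parc$regions[parc$regions$hemisphere == hemisphere, , drop = FALSE]
  if (!nrow(df)) stop_msg("no regions in hemisphere '", hemisphere, "'")
  rownames(df) <- NULL
  structure(list(regions = df), class = "parcellation")
}

#' @rdname parcellation
#' @param parc,x a [parcellation].
#' @export
region_ids <- function(parc) parc$regions$region_id

#' @rdname parcellation
#' @export
n_regions <- function(parc) nrow(parc$regions)

#' @rdname parcellation
#' @export
centroids <- function(parc) {
  m <- as.matrix(parc$regions[, c("cx", "cy", "cz")])
  rownames(m) <- parc$regions$region_id
  m
}

#' @rdname parcellation
#' @param ... unused.
#' @export
print.parcellation <- function(x, ...) {
  tab <- table(x$regions$hemisphere)
  cat("parcellation:", nrow(x$regions), "regions (",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
  invisible(x)
}
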