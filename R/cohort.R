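#' Cohort container
#'
#' Bundles the subject manifest, one region-by-feature matrix per subject and
#' the parcellation they are bound to. Feature matrices are stored in
#' parcellation region order with region ids as row names.
#'
#' @param subjects data frame with columns `subject_id, group, age, sex, etiv`
#'   and optionally `disease_course, euler_number` (plus any extra label
#'   columns, e.g. a subgroup indicator).
#' @param features named list of numeric matrices (one per subject, names are
#'   subject ids), each `n_regions x n_features`.
#' @param parcellation the [parcellation] all matrices are bound to.
#' @return An object of class `msn_cohort`.
#' @export
msn_cohort <- function(subjects, features, parcellation) {
  stopifnot(is.data.frame(subjects), is.list(features))
  need <- c("subject_id", "group", "age", "sex", "etiv")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) {
    stop_msg("manifest lacks column(s): ", paste(miss, collapse = ", "))
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  if (anyDuplicated(subjects$subject_id)) {
    stop_msg("duplicate subject id: ",
             paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
                   collapse = ", "))
  }
  bad <- setdiff(unique(subjects$group), c("case", "control"))
  if (length(bad)) stop_msg("unknown group label: ", paste(bad, collapse = ", "))
  if (!setequal(names(features), subjects$subject_id)) {
    stop_msg("feature list does not match manifest subject ids")
  }
  ids <- region_ids(parcellation)
  for (sid in subjects$subject_id) {
    m <- features[[sid]]
    if (!is.matrix(m) || !identical(rownames(m), ids)) {
      stop_msg("feature matrix for subject ", sid,
               " is not aligned to the parcellation")
    }
    if (anyNA(m)) stop_msg("missing feature value for subject ", sid)
  }
  structure(list(subjects = subjects, features = features[subjects$subject_id],
                 parcellation = parcellation),
            class = "msn_cohort")
}

#' @export
print.msn_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat("msn_cohort:", nrow(x$subjects), "subjects (",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "),", n_regions(x$parcellation), "regions,",
      ncol(x$features[[1]]), "features\n")
  invisible(x)
}

#' Load a cohort from a manifest and per-subject feature files
#'
#' The manifest is a TSV with one row per subject; each subject has a feature
#' TSV `<subject_id>.tsv` in `features_dir`, with a `region_id` key column and
#' one numeric column per morphometric feature (default set: CT, GM, SA, GC,
#' MC). Rows may appear in any order; they are reordered to the parcellation.
#' A missing or extra region, a missing file or a non-numeric cell is an error.
#'
#' @param manifest_path path to the subject manifest TSV.
#' @param features_dir directory holding one feature TSV per subject.
#' @param parcellation the [parcellation] the features are bound to.
#' @return An [msn_cohort] with subjects in manifest order.
#' @export
read_subject_features <- function(manifest_path, features_dir, parcellation) {
  man <- read_tsv(manifest_path)
  man$subject_id <- as.character(man$subject_id)
  for (col in c("age", "etiv", "disease_course", "euler_number")) {
    if (col %in% names(man)) {
      v <- suppressWarnings(as.numeric(man[[col]]))
      if (any(is.na(v) & !(is.na(man[[col]]) | man[[col]] == "NA" | man[[col]] == ""))) {
        stop_msg("non-numeric value in manifest column ", col)
      }
      man[[col]] <- v
    }
  }
  ids <- region_ids(parcellation)
  feats <- lapply(man$subject_id, function(sid) {
    f <- file.path(features_dir, paste0(sid, ".tsv"))
    if (!file.exists(f)) stop_msg("missing feature file for subject ", sid, ": ", f)
    df <- read_tsv(f)
    if (!"region_id" %in% names(df)) {
      stop_msg("feature file for subject ", sid, " lacks a region_id column")
    }
    df$region_id <- as.character(df$region_id)
    miss <- setdiff(ids, df$region_id)
    if (length(miss)) {
      stop_msg("feature file for subject ", sid, " is missing region(s): ",
               paste(miss, collapse = ", "))
    }
    extra <- setdiff(df$region_id, ids)
    if (length(extra)) {
      stop_msg("feature file for subject ", sid, " has unknown region(s): ",
               paste(extra, collapse = ", "))
    }
    fcols <- setdiff(names(df), "region_id")
    if (length(fcols) < 3L) {
      stop_msg("feature file for subject ", sid,
               " has fewer than 3 feature columns")
    }
    m <- matrix(NA_real_, nrow = length(ids), ncol = length(fcols),
                dimnames = list(ids, fcols))
    for (col in fcols) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      if (anyNA(v)) stop_msg("non-numeric or missing value in feature '", col,
                             "' for subject ", sid)
      m[df$region_id, col] <- v
    }
    m
  })
  names(feats) <- man$subject_id
  msn_cohort(man, feats, parcellation)
}

#' Euler-number quality-control filter
#'
#' Removes subjects whose FreeSurfer Euler number is strictly lower than the
#' threshold (very negative Euler numbers flag poor surface reconstructions).
#' Subjects with a missing Euler number pass the filter; their count is
#' reported via a message.
#'
#' @param cohort an [msn_cohort].
#' @param threshold integer cut-off; a subject is excluded iff
#'   `euler_number < threshold`. Default `-200`.
#' @return A list with elements `cohort` (the kept subjects) and `excluded`
#'   (character vector of removed subject ids).
#' @export
qc_filter_euler <- function(cohort, threshold = -200) {
  man <- cohort$subjects
  eul <- if ("euler_number" %in% names(man)) man$euler_number else
    rep(NA_real_, nrow(man))
  n_missing <- sum(is.na(eul))
  if (n_missing > 0) {
    message("qc_filter_euler: ", n_missing,
            " subject(s) without an Euler number pass the filter")
  }
  drop <- !is.na(eul) & eul < threshold
  excluded <- man$subject_id[drop]
  kept <- man[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  out <- structure(list(subjects = kept,
                        features = cohort$features[kept$subject_id],
                        parcellation = cohort$parcellation),
                   class = "msn_cohort")
  list(cohort = out, excluded = excluded)
}

#' Write a cohort to manifest + per-subject feature files
#'
#' Emits exactly the layout [read_subject_features()] reads.
#'
#' @param cohort an [msn_cohort].
#' @param dir output directory; the manifest is written to
#'   `file.path(dir, "manifest.tsv")` and features under
#'   `file.path(dir, "features")`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "features"), recursive = TRUE, showWarnings = FALSE)
  write_tsv(cohort$subjects, file.path(dir, "manifest.tsv"))
  for (sid in cohort$subjects$subject_id) {
    m <- cohort$features[[sid]]
    df <- data.frame(region_id = rownames(m), stringsAsFactors = FALSE)
    for (col in colnames(m)) df[[col]] <- fmt_full(m[, col])
    write_tsv(df, file.path(dir, "features", paste0(sid, ".tsv")))
  }
  invisible(dir)
}
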