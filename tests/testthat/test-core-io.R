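# Domain types, readers/writers and manifest-level QC.

test_that("parcellation files load in order and round-trip exactly", {
  df <- data.frame(region_id = paste0("lh_a", 1:4), name = paste0("A", 1:4),
                   hemisphere = "left",
                   cx = c(0, 0, 1, 0), cy = c(0, 1, 0, 0),
                   cz = c(1, 0, 0, -1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_parcellation_file(df, f)
  p <- read_parcellation(f)
  expect_identical(region_ids(p), df$region_id)
  expect_equal(unname(centroids(p)), cbind(df$cx, df$cy, df$cz))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_parcellation(p, f2)
  p2 <- read_parcellation(f2)
  expect_equal(centroids(p2), centroids(p), tolerance = 1e-12)
  expect_identical(p2$regions$name, p$regions$name)
  expect_identical(p2$regions$hemisphere, p$regions$hemisphere)
})

test_that("centroids near the unit sphere are renormalized, others rejected", {
  df <- data.frame(region_id = paste0("lh_a", 1:3), name = "x",
                   hemisphere = "left", cx = 0, cy = 0,
                   cz = c(1.0005, 1, -1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_parcellation_file(df, f)
  p <- read_parcellation(f)
  expect_equal(unname(centroids(p)[1, ]), c(0, 0, 1), tolerance = 1e-15)

  df$cz[1] <- 1.5
  write_parcellation_file(df, f)
  expect_error(read_parcellation(f), "non-normalizable")
})

test_that("invalid parcellations are rejected with informative errors", {
  df <- data.frame(region_id = c("lh_a", "lh_a", "lh_b"), name = "x",
                   hemisphere = "left", cx = 0, cy = 0, cz = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_parcellation_file(df, f)
  expect_error(read_parcellation(f), "duplicate region id")

  df$region_id <- c("a", "b", "c")
  df$hemisphere <- c("left", "left", "middle")
  write_parcellation_file(df, f)
  expect_error(read_parcellation(f), "unknown hemisphere")

  expect_error(make_parcellation(3, 2), "fewer than 3 regions")
})

test_that("subject features load keyed by region, in any row order", {
  parc <- toy_parcellation(5)
  dir <- withr::local_tempdir()
  fd <- file.path(dir, "features")
  dir.create(fd)
  man <- data.frame(subject_id = c("S1", "S2"), group = c("case", "control"),
                    age = c(30, 40), sex = c("female", "male"),
                    etiv = c(1.4e6, 1.6e6))
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fm <- rand_features(5, 5, seed = 3, ids = region_ids(parc))
  for (s in man$subject_id) {
    df <- data.frame(region_id = rownames(fm), fm)
    write.table(df, file.path(fd, paste0(s, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  cohort <- read_subject_features(file.path(dir, "manifest.tsv"), fd, parc)
  expect_identical(cohort$subjects$subject_id, man$subject_id)
  expect_equal(cohort$features[["S1"]], fm, tolerance = 1e-12)

  # shuffling file rows must not change the loaded matrix
  df <- data.frame(region_id = rownames(fm), fm)
  write.table(df[c(3, 1, 5, 2, 4), ], file.path(fd, "S1.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cohort2 <- read_subject_features(file.path(dir, "manifest.tsv"), fd, parc)
  expect_equal(cohort2$features[["S1"]], cohort$features[["S1"]],
               tolerance = 0)

  # a missing region is reported by name
  write.table(df[-2, ], file.path(fd, "S1.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(
    read_subject_features(file.path(dir, "manifest.tsv"), fd, parc),
    region_ids(parc)[2])

  # missing file and non-numeric cells are errors
  file.remove(file.path(fd, "S1.tsv"))
  expect_error(
    read_subject_features(file.path(dir, "manifest.tsv"), fd, parc),
    "missing feature file")
  df2 <- data.frame(region_id = rownames(fm), fm)
  df2[2, 2] <- "oops"
  write.table(df2, file.path(fd, "S1.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(
    read_subject_features(file.path(dir, "manifest.tsv"), fd, parc),
    "non-numeric")
})

test_that("Euler QC removes strictly-below-threshold subjects and partitions", {
  parc <- toy_parcellation(5)
  man <- toy_manifest(3, 3)
  man$euler_number <- c(-250, -100, -200, NA, -201, -42)
  feats <- lapply(man$subject_id, function(s)
    rand_features(5, 5, seed = match(s, man$subject_id),
                  ids = region_ids(parc)))
  names(feats) <- man$subject_id
  cohort <- msn_cohort(man, feats, parc)

  expect_message(res <- qc_filter_euler(cohort), "1 subject")
  expect_identical(res$excluded, man$subject_id[c(1, 5)]) # -250, -201 out
  expect_identical(res$cohort$subjects$subject_id,
                   man$subject_id[-c(1, 5)])              # -200 exactly kept
  # partition and idempotence
  expect_setequal(c(res$cohort$subjects$subject_id, res$excluded),
                  man$subject_id)
  res2 <- suppressMessages(qc_filter_euler(res$cohort))
  expect_identical(res2$cohort$subjects, res$cohort$subjects)
  expect_length(res2$excluded, 0)
})

test_that("expression matrices are scoped to the left hemisphere and cleaned", {
  parc <- make_parcellation(4, 4, seed = 2)
  ids <- region_ids(parc)
  set.seed(8)
  m <- matrix(rnorm(8 * 3), nrow = 8,
              dimnames = list(ids, c("GENE1", "GENE2", "GENE3")))
  df <- data.frame(region_id = ids, m, check.names = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)

  x <- read_expression_matrix(f, parc)
  expect_identical(rownames(x), ids[1:4])   # left regions only
  expect_identical(colnames(x), colnames(m))
  expect_equal(unname(x), unname(m[1:4, ]), tolerance = 1e-12)

  # a gene with a missing value is dropped, with a logged count
  df$GENE2[2] <- NA
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(x2 <- read_expression_matrix(f, parc), "dropped 1")
  expect_identical(colnames(x2), c("GENE1", "GENE3"))

  # duplicate symbols and disjoint region sets are errors
  names(df)[4] <- "GENE1"
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_matrix(f, parc), "duplicate gene symbol")
  df2 <- data.frame(region_id = paste0("zz", 1:8), m, check.names = FALSE)
  write.table(df2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_matrix(f, parc), "no overlapping regions")
})

test_that("gene lists round-trip and skip comments", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# panel v1", "SMAD3", "", "IRF3  ", "PRR5 # mTORC2"), f)
  expect_identical(read_gene_list(f), c("SMAD3", "IRF3", "PRR5"))
  write_gene_list(c("A", "B"), f, header = "two genes")
  expect_identical(read_gene_list(f), c("A", "B"))
})
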