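make_group_fixture <- function(dir) {
  f1 <- file.path(dir, "sub-01.txt")
  f2 <- file.path(dir, "sub-02.txt")
  f3 <- file.path(dir, "sub-03.txt")
  write_review_fixture(f1, subject = "sub-01", censor_fraction = 0.05)
  write_review_fixture(f2, subject = "sub-02", censor_fraction = 0.2,
                       gcor_val = 0.21)
  # third subject: flipped, different software version, one label missing
  lines <- readLines(f1)
  lines <- sub("^subject ID.*", "subject ID : sub-03", lines)
  lines <- sub("NO_FLIP", "DO_FLIP", lines)
  lines <- sub("AFNI_23.1.10", "AFNI_24.0.01", lines)
  lines <- lines[!grepl("^TSNR average", lines)]
  writeLines(lines, f3)
  c(f1, f2, f3)
}

test_that("group tables take the label union with missing-cell markers", {
  dir <- withr::local_tempdir()
  files <- make_group_fixture(dir)
  tab <- build_group_table(files)
  expect_equal(tab$subject, c("sub-01", "sub-02", "sub-03"))
  expect_equal(tab[["global correlation (GCOR)"]][[1]], 0.0622461)
  expect_equal(tab[["TSNR average"]][[1]], 191.52)
  expect_null(tab[["TSNR average"]][[3]])          # missing cell
  expect_equal(tab[["fraction TRs censored"]][[2]], c(0.015, 0))
  # column order = first-seen order
  expect_equal(names(tab)[1:3], c("subject", "subject ID", "num runs found"))
})

test_that("numeric filters flag subjects via the review-table operators", {
  dir <- withr::local_tempdir()
  tab <- build_group_table(make_group_fixture(dir))
  ge <- report_outliers(tab, list(filter_spec("censor fraction", "GE", 0.1)))
  expect_equal(ge$subject, "sub-02")
  eq <- report_outliers(tab, list("'flip guess' EQ DO_FLIP"))
  expect_equal(eq$subject, "sub-03")
  lt <- report_outliers(tab, list("'TSNR average' LT 100"))
  expect_equal(nrow(lt), 0L)      # missing cells never satisfy LT
})

test_that("vector cells flag on ANY element", {
  dir <- withr::local_tempdir()
  tab <- build_group_table(make_group_fixture(dir))
  hit <- report_outliers(tab, list(filter_spec("fraction TRs censored",
                                               "GE", 0.01)))
  expect_equal(sort(hit$subject), c("sub-01", "sub-02", "sub-03"))
  none <- report_outliers(tab, list(filter_spec("fraction TRs censored",
                                                "GT", 0.5)))
  expect_equal(nrow(none), 0L)
})

test_that("VARY compares against the first subject and keepers inverts", {
  dir <- withr::local_tempdir()
  tab <- build_group_table(make_group_fixture(dir))
  v <- report_outliers(tab, list(filter_spec("AFNI version", "VARY")))
  expect_equal(v$subject, "sub-03")
  k <- report_outliers(tab, list(filter_spec("AFNI version", "VARY")),
                       keepers = TRUE)
  expect_equal(k$subject, c("sub-01", "sub-02"))
})

test_that("flagged and keeper sets partition the subjects for any filters", {
  dir <- withr::local_tempdir()
  tab <- build_group_table(make_group_fixture(dir))
  filter_sets <- list(
    list(filter_spec("censor fraction", "GE", 0.1)),
    list("'flip guess' EQ DO_FLIP", "'censor fraction' GE 0.1"),
    list(filter_spec("global correlation (GCOR)", "GT", 0.1),
         filter_spec("AFNI version", "VARY")))
  for (fs in filter_sets) {
    flagged <- report_outliers(tab, fs)$subject
    kept <- report_outliers(tab, fs, keepers = TRUE)$subject
    expect_setequal(c(flagged, kept), tab$subject)
    expect_length(intersect(flagged, kept), 0L)
  }
})

test_that("group tables survive a write/read cycle", {
  dir <- withr::local_tempdir()
  tab <- build_group_table(make_group_fixture(dir))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_group_table(tab, f)
  back <- read_group_table(f)
  expect_equal(names(back), names(tab))
  expect_equal(back$subject, tab$subject)
  expect_equal(back[["censor fraction"]][[2]], 0.2)
  expect_equal(back[["fraction TRs censored"]][[1]], c(0.015, 0))
  expect_null(back[["TSNR average"]][[3]])
  # idempotent: writing the re-read table reproduces the bytes
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_group_table(back, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("dataset scans report exactly the varying properties", {
  dir <- withr::local_tempdir()
  set.seed(70)
  arr <- array(runif(6 * 6 * 4 * 5, 100, 900), dim = c(6, 6, 4, 5))
  v1 <- volume_series(arr, voxdims = c(3, 3, 3), tr = 2.0)
  v2 <- volume_series(arr, voxdims = c(3, 3, 3), tr = 2.5)
  write_volume(v1, file.path(dir, "a.nii"))
  write_volume(v2, file.path(dir, "b.nii"))
  scan <- gtkyd_scan(file.path(dir, c("a.nii", "b.nii")))
  expect_equal(scan$varying, "TR")
  # the first dataset is the VARY reference, so only the second is flagged
  expect_equal(scan$variability$subject, "b")

  write_volume(v1, file.path(dir, "c.nii"))
  scan2 <- gtkyd_scan(file.path(dir, c("a.nii", "c.nii")))
  expect_length(scan2$varying, 0L)
  expect_equal(nrow(scan2$variability), 0L)
})

test_that("dataset scans carry the saturation flag", {
  dir <- withr::local_tempdir()
  arr <- array(runif(4^3, 0, 2000), dim = c(4, 4, 4))
  arr[1] <- 4095
  write_volume(volume_series(arr), file.path(dir, "sat.nii"))
  scan <- gtkyd_scan(file.path(dir, "sat.nii"))
  expect_equal(scan$properties[["saturation flag"]][[1]], "yes")
  expect_equal(scan$properties[["stored max"]][[1]], 4095)
})

test_that("unreadable datasets are skipped with a message", {
  dir <- withr::local_tempdir()
  arr <- array(1:64, dim = c(4, 4, 4))
  write_volume(volume_series(arr), file.path(dir, "good.nii"))
  bad <- file.path(dir, "bad.nii")
  writeLines("not a nifti", bad)
  expect_message(scan <- gtkyd_scan(file.path(dir, c("good.nii", "bad.nii"))),
                 "skipping")
  expect_equal(nrow(scan$properties), 1L)
})
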