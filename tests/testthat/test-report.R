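test_that("percentile display ranges follow the 90th/99th convention", {
  d <- c(5, 5, 4)
  mask <- array(TRUE, dim = d)
  const <- array(-7, dim = d)
  pr <- percentile_range(const, mask)
  expect_equal(pr$thr, 7); expect_equal(pr$vmax, 7)

  vals <- array(0, dim = c(10, 10, 1))
  vals[1:100] <- 1:100
  pr2 <- percentile_range(vals, array(TRUE, dim = c(10, 10, 1)))
  srt <- sort(abs(1:100))
  expect_equal(pr2$thr, stats::quantile(srt, 0.90, names = FALSE, type = 7))
  expect_equal(pr2$vmax, stats::quantile(srt, 0.99, names = FALSE, type = 7))

  zero <- percentile_range(array(0, dim = d), mask)
  expect_true(zero$degenerate)
  expect_equal(zero$thr, 0)
})

test_that("sub-threshold opacity falls off quadratically", {
  expect_equal(alpha_opacity(0.3, 0.3), 1)
  expect_equal(alpha_opacity(0.15, 0.3), 0.25)
  expect_equal(alpha_opacity(0, 0.3), 0)
  expect_equal(alpha_opacity(-0.3, 0.3), 1)       # two-sided
  expect_equal(alpha_opacity(10, 0.3), 1)
  expect_error(alpha_opacity(1, 0), "positive")
})

test_that("two-sided t thresholds satisfy their defining identity", {
  expect_equal(two_sided_t_threshold(1e9, 0.001), stats::qnorm(1 - 0.001 / 2),
               tolerance = 1e-5)
  expect_equal(stats::qnorm(1 - 0.001 / 2), 3.2905, tolerance = 1e-4)
  for (df in c(1, 5, 10, 50)) {
    thr <- two_sided_t_threshold(df, 0.001)
    expect_equal(stats::pt(thr, df) - stats::pt(-thr, df), 1 - 0.001,
                 tolerance = 1e-10)
  }
  # independent quantile oracle via root finding on the CDF
  thr10 <- two_sided_t_threshold(10, 0.001)
  root <- stats::uniroot(function(t) stats::pt(t, 10) - (1 - 0.001 / 2),
                         c(1, 100), tol = 1e-12)$root
  expect_equal(thr10, root, tolerance = 1e-8)
  expect_error(two_sided_t_threshold(0, 0.01))
})

test_that("montages pick slices inside the automask and composite overlays", {
  d <- c(12, 12, 15)
  u <- array(0, dim = d)
  u[3:10, 3:10, 6:10] <- 800            # signal only in the central third (z)
  img <- render_montage(u, plane = "axial", n_slices = 4)
  expect_true(all(img$slices >= 6 & img$slices <= 10))
  expect_equal(dim(img$raster)[3], 3L)

  img1 <- render_montage(u, plane = "axial", n_slices = 1)
  expect_equal(img1$slices, 8)          # midpoint of the automask range

  ov <- array(0, dim = d); ov[5:6, 5:6, 6:10] <- 5
  img2 <- render_montage(u, ov, plane = "axial", n_slices = 3, thr = 1, vmax = 5)
  expect_true(all(img2$raster >= 0 & img2$raster <= 1))
  # overlay actually changes pixels relative to the pure-underlay montage
  img3 <- render_montage(u, plane = "axial", n_slices = 3)
  expect_false(identical(img2$raster, img3$raster))
})

test_that("reports are self-contained, complete and deterministic", {
  rd <- review_dict("TSNR average" = 191.52, "flip guess" = "NO_FLIP",
                    "fraction TRs censored" = c(0.015, 0))
  u <- array(runif(12^3, 0, 100), dim = c(12, 12, 12))
  blocks <- list(
    qc_block("vorig", "original data",
             items = list("mean EPI" = render_montage(u, n_slices = 2))),
    qc_block("warns", "warnings", items = list("all clear"),
             warn = warn_level("severe", "planted")))
  out1 <- withr::local_tempdir()
  build_report(blocks, review = rd, outdir = out1, subject = "s1")
  html <- readLines(file.path(out1, "index.html"), warn = FALSE)
  page <- paste(html, collapse = "\n")
  for (lab in names(rd)) expect_match(page, lab, fixed = TRUE)
  expect_match(page, "191.52", fixed = TRUE)
  # menu lists every block and the severe block carries the severe color
  for (id in c("vorig", "warns", "qsumm"))
    expect_match(page, sprintf("href='#%s'", id), fixed = TRUE)
  expect_match(page, "#ff3333", fixed = TRUE)
  expect_true(file.exists(file.path(out1, "apqc_s1.rate.json")))
  expect_true(file.exists(file.path(out1, "extra_info", "out.ss_review.s1.json")))

  out2 <- withr::local_tempdir()
  build_report(blocks, review = rd, outdir = out2, subject = "s1")
  f1 <- sort(list.files(out1, recursive = TRUE))
  expect_identical(f1, sort(list.files(out2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readBin(file.path(out1, f), "raw", 5e6),
                     readBin(file.path(out2, f), "raw", 5e6))
  expect_error(build_report(list(), outdir = withr::local_tempdir()), "at least one")
})

test_that("commenting on an unrated block applies the 'other' rating", {
  st <- rating_store(c("vorig", "mot"))
  st <- ratings_update(st, "set_comment", "mot", "check slice 12")
  expect_equal(st$mot$rating, "?")
  expect_equal(st$mot$comment, "check slice 12")
  st <- ratings_update(st, "clear", "mot")
  expect_equal(st$mot, list(rating = "", comment = ""))
  expect_error(ratings_update(st, "set_rating", "nope", "+"), "unknown block")
})

test_that("rating cycling walks +, x, ?, and back", {
  st <- rating_store("vorig")
  seen <- character(4)
  for (k in 1:4) {
    st <- ratings_update(st, "cycle_rating", "vorig")
    seen[k] <- st$vorig$rating
  }
  expect_equal(seen, c("+", "x", "?", "+"))
})

test_that("ratings persist through JSON and normalize the multiplication sign", {
  st <- rating_store(c("vorig", "mot", "regr"))
  st <- ratings_update(st, "set_rating", "vorig", "+")
  st <- ratings_update(st, "set_comment", "mot", "ghosting?")
  st <- ratings_update(st, "set_rating", "FINAL", "x")
  f <- withr::local_tempfile(fileext = ".json")
  ratings_save(st, f)
  back <- ratings_load(f)
  expect_identical(unclass(back), unclass(st))
  # foreign "×" ratings are normalized on load
  raw <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  raw$regr$rating <- "×"
  jsonlite::write_json(raw, f, auto_unbox = TRUE)
  expect_equal(ratings_load(f)$regr$rating, "x")
})

test_that("comment implies rating after any action sequence", {
  set.seed(60)
  ids <- c("vorig", "mot", "regr", "warns")
  st <- rating_store(ids)
  actions <- c("set_rating", "cycle_rating", "set_comment", "clear")
  for (k in 1:200) {
    act <- sample(actions, 1)
    blk <- sample(names(st), 1)
    val <- switch(act,
                  set_rating = sample(c("+", "x", "?", ""), 1),
                  set_comment = sample(c("", "note", "bad coil"), 1),
                  "")
    st <- ratings_update(st, act, blk, val)
    for (e in st)
      expect_true(!nzchar(e$comment) || nzchar(e$rating))
  }
})
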