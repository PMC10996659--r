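#' Display range from in-mask percentiles
#'
#' Statistical overlays are windowed from the data itself: the display
#' threshold is the 90th percentile and the color-range maximum the 99th
#' percentile of the absolute in-mask values (linear-interpolation
#' percentiles).
#'
#' @param stat A [stat_volume()] or 3D array.
#' @param mask 3D binary mask.
#' @return List with `thr`, `vmax`, and `degenerate` (TRUE when the mask is
#'   all zeros so no meaningful window exists).
#' @export
percentile_range <- function(stat, mask) {
  v <- if (inherits(stat, "stat_volume")) stat$data else stat
  m <- as_mask(mask, dim(v))
  if (!any(m)) stop("mask is empty")
  av <- abs(v[m])
  q <- stats::quantile(av, c(0.90, 0.99), names = FALSE, type = 7)
  list(thr = q[1L], vmax = q[2L], degenerate = all(av == 0))
}

#' Quadratic sub-threshold opacity
#'
#' Transparent thresholding: voxels at or above the threshold are fully
#' opaque; below it the alpha channel falls off quadratically,
#' `(|v| / thr)^2`, so near-threshold structure stays faintly visible
#' instead of being hidden by a hard cut.
#'
#' @param v Numeric values (vectorized).
#' @param thr Positive threshold.
#' @return Opacities in \[0, 1\].
#' @export
alpha_opacity <- function(v, thr) {
  if (thr <= 0) stop("thr must be positive")
  pmin(1, (abs(v) / thr)^2)
}

#' Two-sided t threshold
#'
#' The t value whose two-sided tail mass equals `p` for the given degrees of
#' freedom; approaches `qnorm(1 - p/2)` (about 3.29 at p = 0.001) as df
#' grows.
#'
#' @param df Degrees of freedom (>= 1).
#' @param p Two-sided tail probability.
#' @return Positive threshold value.
#' @export
two_sided_t_threshold <- function(df, p = 0.001) {
  if (df < 1 || p <= 0 || p >= 1) stop("need df >= 1 and 0 < p < 1")
  stats::qt(1 - p / 2, df = df)
}

# Automask of an underlay: voxels above 10% of the robust (98th pct) max.
automask <- function(u) {
  hi <- stats::quantile(u[u > 0], 0.98, names = FALSE, type = 7)
  if (!is.finite(hi) || hi <= 0) return(array(FALSE, dim(u)))
  u > 0.1 * hi
}

# Map overlay values to RGB (warm positive / cool negative), range +-vmax.
overlay_rgb <- function(v, vmax) {
  s <- pmin(1, abs(v) / max(vmax, .Machine$double.eps))
  r <- ifelse(v >= 0, 1, 0.1)
  g <- ifelse(v >= 0, 0.2 + 0.8 * (1 - s) * 0.5 + 0.5 * s * 0.9, 0.4 * s)
  b <- ifelse(v >= 0, 0.05, 1)
  cbind(r, g, b)
}

#' Render a slice montage
#'
#' Selects `n_slices` evenly spaced slices within the bounding range of a
#' light automask of the underlay along the chosen plane axis (midpoint for
#' a single slice; full range when the automask is empty), window-levels the
#' underlay, and composites an optional statistical overlay using
#' [alpha_opacity()]; suprathreshold regions are outlined in black. Slice
#' indices are recorded for captioning.
#'
#' @param underlay 3D array or single-volume series.
#' @param overlay Optional [stat_volume()] or 3D array.
#' @param plane `"axial"` (3rd axis), `"sagittal"` (1st) or `"coronal"` (2nd).
#' @param n_slices Number of slices in the montage.
#' @param thr,vmax Overlay threshold and color range; defaults from
#'   [percentile_range()] over the automask.
#' @return An object of class `qc_image`: `raster` (H x W x 3 array in
#'   \[0,1\]), `slices` (indices used), `plane`.
#' @export
render_montage <- function(underlay, overlay = NULL,
                           plane = c("axial", "sagittal", "coronal"),
                           n_slices = 6L, thr = NULL, vmax = NULL) {
  plane <- match.arg(plane)
  u <- vol3d(underlay)
  ov <- if (is.null(overlay)) NULL
        else if (inherits(overlay, "stat_volume")) overlay$data else overlay
  if (!is.null(ov) && !identical(dim(ov), dim(u)))
    stop("overlay grid does not match underlay")
  ax <- switch(plane, sagittal = 1L, coronal = 2L, axial = 3L)
  am <- automask(u)
  rng <- if (any(am)) range(which(apply(am, ax, any))) else c(1L, dim(u)[ax])
  slices <- if (n_slices == 1L) round(mean(rng)) else
    unique(round(seq(rng[1L], rng[2L], length.out = n_slices)))
  lo <- stats::quantile(u, 0.02, names = FALSE)
  hi <- stats::quantile(u, 0.98, names = FALSE)
  if (hi <= lo) hi <- lo + 1
  if (!is.null(ov)) {
    if (is.null(thr) || is.null(vmax)) {
      pr <- percentile_range(ov, if (any(am)) am else array(TRUE, dim(u)))
      if (is.null(thr)) thr <- max(pr$thr, .Machine$double.eps)
      if (is.null(vmax)) vmax <- max(pr$vmax, thr)
    }
  }
  slice2d <- function(a, s) {
    switch(plane, sagittal = a[s, , ], coronal = a[, s, ], axial = a[, , s])
  }
  panes <- lapply(slices, function(s) {
    us <- slice2d(u, s)
    g <- pmin(1, pmax(0, (us - lo) / (hi - lo)))
    pane <- array(rep(g, 3L), dim = c(dim(us), 3L))
    if (!is.null(ov)) {
      os <- slice2d(ov, s)
      a <- alpha_opacity(os, thr)
      a[os == 0] <- 0
      rgb <- overlay_rgb(as.vector(os), vmax)
      for (ch in 1:3) {
        pane[, , ch] <- (1 - a) * pane[, , ch] +
          a * matrix(rgb[, ch], nrow = nrow(os))
      }
      supra <- abs(os) >= thr
      if (any(supra)) {
        edge <- supra & !(shift2(supra, 1, 0) & shift2(supra, -1, 0) &
                          shift2(supra, 0, 1) & shift2(supra, 0, -1))
        for (ch in 1:3) pane[, , ch][edge] <- 0
      }
    }
    pane
  })
  hgt <- dim(panes[[1L]])[2L]
  wid <- sum(vapply(panes, function(p) dim(p)[1L], integer(1L)))
  raster <- array(0, dim = c(hgt, wid, 3L))
  off <- 0L
  for (p in panes) {
    w <- dim(p)[1L]
    # array (x, y) -> image row/col: y runs bottom-to-top
    for (ch in 1:3) raster[, off + seq_len(w), ch] <- t(p[, rev(seq_len(dim(p)[2L])), ch])
    off <- off + w
  }
  structure(list(raster = raster, slices = slices, plane = plane),
            class = "qc_image")
}

# 2D logical shift with FALSE fill.
shift2 <- function(m, di, dj) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  si <- seq_len(nrow(m)) - di
  sj <- seq_len(ncol(m)) - dj
  ok_i <- si >= 1 & si <= nrow(m)
  ok_j <- sj >= 1 & sj <= ncol(m)
  out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
  out
}

#' Render a grayplot matrix to a raster image
#'
#' Grayscale carpet (black = -clip, white = +clip) with optional motion and
#' outlier-fraction strips on top.
#'
#' @param gp A `grayplot_matrix`.
#' @param max_rows Downsample to at most this many displayed rows.
#' @return A `qc_image`.
#' @export
render_grayplot <- function(gp, max_rows = 400L) {
  z <- gp$values
  if (nrow(z) > max_rows)
    z <- z[round(seq(1L, nrow(z), length.out = max_rows)), , drop = FALSE]
  g <- (z + gp$clip) / (2 * gp$clip)
  strips <- list()
  for (nm in c("enorm", "outliers")) {
    s <- gp[[nm]]
    if (!is.null(s)) {
      rng <- max(s, .Machine$double.eps)
      bar <- matrix(rep(1 - s / rng, each = 8L), nrow = 8L, byrow = FALSE)
      strips[[nm]] <- bar
    }
  }
  img <- do.call(rbind, c(strips, list(g)))
  raster <- array(rep(img, 3L), dim = c(dim(img), 3L))
  structure(list(raster = raster, slices = integer(0L), plane = "grayplot"),
            class = "qc_image")
}

#' Write a QC image as PNG
#' @param img A `qc_image`.
#' @param path Output PNG path.
#' @param scale Integer pixel-replication factor.
#' @return The path, invisibly.
#' @export
write_qc_image <- function(img, path, scale = 4L) {
  r <- img$raster
  if (scale > 1L) {
    r <- r[rep(seq_len(dim(r)[1L]), each = scale),
           rep(seq_len(dim(r)[2L]), each = scale), , drop = FALSE]
  }
  png::writePNG(r, path)
  invisible(path)
}

#' QC report block
#'
#' @param id Block id; the canonical order is vorig, vstat, mot, regr,
#'   radcor, warns, qsumm (extensible).
#' @param title Human-readable title.
#' @param items List of items: `qc_image` objects, tibbles/data.frames
#'   (rendered as tables), or character strings (rendered as text). Named
#'   items use the name as a caption.
#' @param warn A [warn_level()] for the block.
#' @return An object of class `qc_block`.
#' @export
qc_block <- function(id, title = id, items = list(), warn = warn_level("none")) {
  structure(list(id = id, title = title, items = items, warn = warn),
            class = "qc_block")
}

qc_block_order <- c("vorig", "vstat", "mot", "regr", "radcor", "warns", "qsumm")

warn_color <- c(none = "#e8f5e9", undecided = "#fff9c4", mild = "#ffd9e0",
                medium = "#ff94a8", severe = "#ff3333")

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

table_html <- function(df) {
  cells <- function(row, tag) paste0("<", tag, ">",
    vapply(row, function(c) html_escape(format(c, digits = 6)), character(1L)),
    "</", tag, ">", collapse = "")
  body <- vapply(seq_len(nrow(df)), function(r)
    paste0("<tr>", cells(as.list(df[r, ]), "td"), "</tr>"), character(1L))
  paste0("<table class='qc'><tr>", cells(as.list(names(df)), "th"), "</tr>",
         paste(body, collapse = "\n"), "</table>")
}

#' Assemble a static HTML QC report
#'
#' Writes a self-contained QC directory: `index.html`, a `media/`
#' subdirectory of PNGs, an (initially empty) ratings JSON, and an
#' `extra_info/` copy of the review dictionary as JSON for group tools. The
#' top menu lists the block ids, each colored by its block's maximum warning
#' level; a `qsumm` block showing the full review dictionary is appended
#' automatically when a review is supplied. Given identical inputs (and no
#' timestamp) the output is byte-identical, so rebuilds are verifiable.
#'
#' @param blocks List of [qc_block()] objects (at least one).
#' @param review Optional [review_dict()] rendered in the `qsumm` block and
#'   copied to `extra_info/`.
#' @param outdir Output directory (created; must be writable).
#' @param subject Subject identifier used in file names.
#' @param timestamp Optional character timestamp shown in the footer; leave
#'   `NULL` for deterministic output.
#' @return The path to `index.html`, invisibly.
#' @export
build_report <- function(blocks, review = NULL, outdir, subject = "subj",
                         timestamp = NULL) {
  if (length(blocks) == 0L) stop("need at least one QC block")
  if (!is.null(review)) {
    qs <- qc_block("qsumm", "quantitative summary",
                   items = list(review_table(review)))
    blocks <- c(blocks, list(qs))
  }
  ids <- vapply(blocks, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate block ids: ",
                               ids[duplicated(ids)][1L])
  ord <- order(match(ids, qc_block_order, nomatch = length(qc_block_order) + 1L))
  blocks <- blocks[ord]; ids <- ids[ord]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "media"), showWarnings = FALSE)
  dir.create(file.path(outdir, "extra_info"), showWarnings = FALSE)
  css <- paste(
    "body{font-family:sans-serif;background:#0b0b0b;color:#ddd;margin:0}",
    "nav{position:sticky;top:0;background:#222;padding:6px}",
    "nav a{margin-right:6px;padding:3px 8px;border-radius:4px;color:#111;",
    "text-decoration:none;font-weight:bold}",
    "section{padding:10px 16px;border-bottom:1px solid #333}",
    "img{max-width:100%;image-rendering:pixelated}",
    "table.qc{border-collapse:collapse;font-size:13px}",
    "table.qc td,table.qc th{border:1px solid #555;padding:2px 8px}",
    "h2{margin:4px 0}", ".cap{color:#999;font-size:12px}", sep = "\n")
  nav <- vapply(blocks, function(b) sprintf(
    "<a href='#%s' style='background:%s'>%s</a>",
    b$id, warn_color[[b$warn$level]], b$id), character(1L))
  body <- vapply(blocks, function(b) {
    items <- vapply(seq_along(b$items), function(k) {
      it <- b$items[[k]]
      cap <- names(b$items)[k]
      cap_html <- if (!is.null(cap) && nzchar(cap))
        sprintf("<div class='cap'>%s</div>", html_escape(cap)) else ""
      if (inherits(it, "qc_image")) {
        fn <- sprintf("media/%s_%s_%02d.png", subject, b$id, k)
        write_qc_image(it, file.path(outdir, fn))
        cap2 <- if (length(it$slices) > 0L)
          sprintf("<div class='cap'>%s slices: %s</div>", it$plane,
                  paste(it$slices, collapse = ", ")) else ""
        paste0(cap_html, sprintf("<img src='%s'>", fn), cap2)
      } else if (is.data.frame(it)) {
        paste0(cap_html, table_html(it))
      } else {
        paste0(cap_html, "<p>", html_escape(as.character(it)), "</p>")
      }
    }, character(1L))
    sprintf("<section id='%s'><h2 style='color:%s'>%s: %s</h2>%s</section>",
            b$id, warn_color[[b$warn$level]], b$id, html_escape(b$title),
            paste(items, collapse = "\n"))
  }, character(1L))
  foot <- if (is.null(timestamp)) "" else
    sprintf("<footer class='cap'>generated %s</footer>", html_escape(timestamp))
  html <- paste0("<!DOCTYPE html><html><head><meta charset='utf-8'>",
                 "<title>QC: ", html_escape(subject), "</title>",
                 "<style>", css, "</style></head><body><nav>",
                 paste(nav, collapse = ""), "</nav>\n",
                 paste(body, collapse = "\n"), foot, "</body></html>")
  index <- file.path(outdir, "index.html")
  writeLines(html, index)
  store <- rating_store(ids)
  ratings_save(store, file.path(outdir, sprintf("apqc_%s.rate.json", subject)))
  if (!is.null(review))
    write_review(review, file.path(outdir, "extra_info",
                                   sprintf("out.ss_review.%s.json", subject)),
                 format = "json")
  invisible(index)
}

# Review dictionary as a two-column data frame for HTML rendering.
review_table <- function(rd) {
  tibble::tibble(
    label = names(rd),
    value = vapply(rd, function(v)
      if (is.numeric(v)) paste(fmt_num(v), collapse = " ") else as.character(v),
      character(1L)))
}

#' Ratings and comments store
#'
#' Per-block rating (`"+"` good, `"x"` bad, `"?"` other, `""` unset) and
#' free-text comment, plus an overall `"FINAL"` entry. The invariant that a
#' nonempty comment implies a nonempty rating is enforced by every action:
#' commenting on an unrated block auto-applies the "other" rating.
#'
#' @param block_ids Character vector of block ids.
#' @return An object of class `rating_store`.
#' @export
rating_store <- function(block_ids) {
  ids <- unique(c(block_ids, "FINAL"))
  entries <- stats::setNames(
    lapply(ids, function(i) list(rating = "", comment = "")), ids)
  structure(entries, class = "rating_store")
}

rating_cycle <- c("+", "x", "?")

#' Update a ratings store
#'
#' @param store A [rating_store()].
#' @param action One of `"set_rating"`, `"cycle_rating"`, `"set_comment"`,
#'   `"clear"`.
#' @param block Block id (must exist in the store).
#' @param value Rating (for `set_rating`; `"×"` is normalized to `"x"`) or
#'   comment text (for `set_comment`).
#' @return The updated store.
#' @export
ratings_update <- function(store, action = c("set_rating", "cycle_rating",
                                             "set_comment", "clear"),
                           block, value = "") {
  action <- match.arg(action)
  if (!block %in% names(store)) stop("unknown block id: ", block)
  e <- store[[block]]
  if (action == "set_rating") {
    v <- normalize_rating(value)
    e$rating <- v
    if (v == "") e$comment <- ""   # keep comment => rating invariant
  } else if (action == "cycle_rating") {
    cur <- match(e$rating, rating_cycle)
    e$rating <- if (is.na(cur)) rating_cycle[1L]
                else rating_cycle[cur %% length(rating_cycle) + 1L]
  } else if (action == "set_comment") {
    e$comment <- as.character(value)
    if (nzchar(e$comment) && e$rating == "") e$rating <- "?"
  } else {
    e$rating <- ""
    e$comment <- ""
  }
  store[[block]] <- e
  store
}

normalize_rating <- function(v) {
  v <- as.character(v)
  if (v == "×") v <- "x"
  if (!v %in% c("+", "x", "?", "")) stop("invalid rating: '", v, "'")
  v
}

#' Save / load a ratings store as JSON
#' @param store A [rating_store()].
#' @param path JSON path.
#' @return `ratings_save` returns the path invisibly; `ratings_load` the
#'   store (with `"×"` ratings normalized to `"x"`).
#' @export
ratings_save <- function(store, path) {
  jsonlite::write_json(unclass(store), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname ratings_save
#' @export
ratings_load <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(obj, function(e) {
    r <- normalize_rating(if (is.null(e$rating)) "" else e$rating)
    cm <- if (is.null(e$comment)) "" else as.character(e$comment)
    if (nzchar(cm) && r == "") r <- "?"
    list(rating = r, comment = cm)
  })
  structure(out, class = "rating_store")
}
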