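#' Build a cross-subject table of review quantities
#'
#' Reads a set of per-subject review files (colon text or JSON) into one
#' table: one row per subject, one column per label in first-seen order
#' (the union over subjects). Cells keep their review types — numbers,
#' numeric vectors, strings — as list-column entries; a label absent for a
#' subject is a missing cell (`NULL`).
#'
#' @param paths Review file paths (at least one readable).
#' @param subjects Optional subject ids (default: `"subject ID"` entry if
#'   present, else the file's base name).
#' @return A tibble of class `group_table`: column `subject` plus one
#'   list-column per review label.
#' @export
build_group_table <- function(paths, subjects = NULL) {
  if (length(paths) == 0L) stop("no input files")
  dicts <- lapply(paths, read_review)
  if (is.null(subjects)) {
    subjects <- vapply(seq_along(paths), function(i) {
      sid <- dicts[[i]][["subject ID"]]
      if (!is.null(sid) && is.character(sid)) sid
      else sub("\\.(txt|json)$", "", basename(paths[i]))
    }, character(1L))
  }
  if (anyDuplicated(subjects)) subjects <- make.unique(subjects)
  labels <- character(0L)
  for (d in dicts) labels <- union(labels, names(d))
  out <- tibble::tibble(subject = subjects)
  for (lab in labels) {
    out[[lab]] <- lapply(dicts, function(d) d[[lab]])
  }
  class(out) <- c("group_table", class(out))
  out
}

#' Write / read a group table as TSV or CSV
#'
#' Vector cells are flattened space-separated; missing cells are written as
#' empty fields and read back as missing.
#'
#' @param table A `group_table`.
#' @param path Output path.
#' @param sep Field separator (`"\t"` or `","`).
#' @return The path (write) or a `group_table` (read).
#' @export
write_group_table <- function(table, path, sep = "\t") {
  flat <- vapply(names(table), function(cn) "", character(1L))
  rows <- vapply(seq_len(nrow(table)), function(r) {
    cells <- vapply(names(table), function(cn) {
      v <- table[[cn]][[r]] %||% table[[cn]][r]
      v <- if (is.list(v)) v[[1L]] else v
      if (is.null(v) || (length(v) == 1L && is.na(v))) ""
      else if (is.numeric(v)) paste(fmt_num(v), collapse = " ")
      else as.character(v)
    }, character(1L))
    paste(cells, collapse = sep)
  }, character(1L))
  writeLines(c(paste(names(table), collapse = sep), rows), path)
  invisible(path)
}

#' @rdname write_group_table
#' @export
read_group_table <- function(path, sep = "\t") {
  lines <- readLines(path, warn = FALSE)
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  out <- tibble::tibble(subject = character(length(lines) - 1L))
  cells <- lapply(lines[-1L], function(l) strsplit(l, sep, fixed = TRUE)[[1L]])
  cells <- lapply(cells, function(cc) c(cc, rep("", length(header) - length(cc))))
  out$subject <- vapply(cells, `[[`, character(1L), 1L)
  for (ci in seq_along(header)[-1L]) {
    out[[header[ci]]] <- lapply(cells, function(cc) {
      v <- cc[[ci]]
      if (!nzchar(v)) NULL else parse_review_value(v)
    })
  }
  class(out) <- c("group_table", class(out))
  out
}

#' Filter specification for group-table triage
#'
#' Comparisons follow the review-table DSL: `VARY` flags subjects whose
#' value differs from the first subject's; `EQ` tests string or numeric
#' equality; `GT`, `LT`, `GE`, `LE` compare numerically. For vector cells a
#' subject is flagged when ANY element satisfies the comparison. Missing
#' cells never satisfy a comparison except `VARY`, which treats missing as
#' differing.
#'
#' @param label Review label the filter applies to.
#' @param op One of `"VARY"`, `"EQ"`, `"GT"`, `"LT"`, `"GE"`, `"LE"`.
#' @param value Operand (required except for `VARY`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(label, op = c("VARY", "EQ", "GT", "LT", "GE", "LE"),
                        value = NULL) {
  op <- match.arg(op)
  if (op != "VARY" && is.null(value)) stop("operator ", op, " needs an operand")
  structure(list(label = label, op = op, value = value), class = "filter_spec")
}

#' Parse a filter from DSL text
#'
#' Accepts strings like `"'censor fraction' GE 0.1"` or
#' `"'flip guess' EQ DO_FLIP"` (label quoting optional for single words).
#'
#' @param text One filter expression.
#' @return A [filter_spec()].
#' @export
parse_filter <- function(text) {
  m <- regmatches(text, regexec(
    "^\\s*(?:'([^']+)'|\"([^\"]+)\"|(\\S+))\\s+(VARY|EQ|GT|LT|GE|LE)\\s*(.*)$",
    text))[[1L]]
  if (length(m) == 0L) stop("cannot parse filter: ", text)
  label <- m[2:4][nzchar(m[2:4])][1L]
  op <- m[5L]
  rest <- trimws(m[6L])
  value <- if (op == "VARY") NULL else {
    num <- suppressWarnings(as.numeric(rest))
    if (!is.na(num)) num else rest
  }
  filter_spec(label, op, value)
}

cell_matches <- function(v, op, operand, ref = NULL) {
  if (op == "VARY") {
    if (is.null(v) || is.null(ref)) return(!identical(v, ref))
    return(!identical(as.character(v), as.character(ref)))
  }
  if (is.null(v) || (length(v) == 1L && is.na(v))) return(FALSE)
  if (op == "EQ") {
    if (is.numeric(v) && is.numeric(operand))
      return(any(abs(v - operand) <=
                   1e-9 * pmax(abs(v), abs(operand), 1e-300) |
                 v == operand))
    return(any(as.character(v) == as.character(operand)))
  }
  if (!is.numeric(v) || !is.numeric(operand)) {
    warning("skipping non-numeric comparison for operator ", op)
    return(FALSE)
  }
  fn <- switch(op, GT = `>`, LT = `<`, GE = `>=`, LE = `<=`)
  any(fn(v, operand))
}

#' Flag subjects failing (or passing) group-table filters
#'
#' Applies a set of [filter_spec()] comparisons to a group table and returns
#' the subjects for which at least one comparison is true, together with the
#' triggering columns and any requested show-columns. With `keepers = TRUE`
#' the set is inverted: subjects with no true comparison are returned.
#'
#' @param table A `group_table`.
#' @param filters List of [filter_spec()] objects (or DSL strings).
#' @param show_labels Extra columns appended to the output.
#' @param keepers Invert the selection.
#' @return A tibble subset of `table` (subject column plus filter and show
#'   columns).
#' @export
report_outliers <- function(table, filters, show_labels = character(0L),
                            keepers = FALSE) {
  filters <- lapply(filters, function(f)
    if (is.character(f)) parse_filter(f) else f)
  n <- nrow(table)
  hit <- rep(FALSE, n)
  used_labels <- character(0L)
  for (f in filters) {
    used_labels <- union(used_labels, f$label)
    col <- table[[f$label]]
    if (is.null(col)) { hit <- hit | (f$op == "VARY"); next }
    ref <- if (f$op == "VARY") col[[1L]] else NULL
    for (r in seq_len(n))
      hit[r] <- hit[r] || cell_matches(col[[r]], f$op, f$value, ref)
  }
  sel <- if (keepers) !hit else hit
  cols <- c("subject", intersect(c(used_labels, show_labels), names(table)))
  out <- table[sel, cols, drop = FALSE]
  class(out) <- setdiff(class(out), "group_table")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan raw datasets for basic-property consistency
#'
#' "Getting to know your data": reads only the headers/intensities of a set
#' of NIfTI datasets and builds a per-dataset dictionary of basic
#' properties — matrix dimensions, voxel sizes, TR, number of time points,
#' storage datum type, orientation, stored min/max (with the 12-bit
#' saturation flag), and slice-timing presence — then reports every
#' property that varies across the set (a `VARY` filter on each property).
#' Unreadable datasets are skipped with a message.
#'
#' @param paths NIfTI dataset paths.
#' @return List with `properties` (a `group_table`, one row per dataset),
#'   `varying` (character vector of property labels that vary), and
#'   `variability` (the flagged-subject subtable).
#' @export
gtkyd_scan <- function(paths) {
  if (length(paths) == 0L) stop("no datasets given")
  dicts <- list(); ids <- character(0L)
  for (p in paths) {
    rd <- tryCatch(dataset_properties(p), error = function(e) {
      message("skipping unreadable dataset ", p, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(rd)) next
    dicts[[length(dicts) + 1L]] <- rd
    ids <- c(ids, sub("\\.nii(\\.gz)?$", "", basename(p)))
  }
  if (length(dicts) == 0L) stop("no readable datasets")
  tmp <- tempfile("gtkyd"); dir.create(tmp)
  files <- vapply(seq_along(dicts), function(i) {
    f <- file.path(tmp, paste0(ids[i], ".txt"))
    write_review(dicts[[i]], f, "colon"); f
  }, character(1L))
  tab <- build_group_table(files, subjects = make.unique(ids))
  unlink(tmp, recursive = TRUE)
  props <- setdiff(names(tab), "subject")
  varying <- character(0L)
  for (lab in props) {
    vals <- lapply(tab[[lab]], function(v) paste(as.character(v), collapse = " "))
    if (length(unique(unlist(vals))) > 1L) varying <- c(varying, lab)
  }
  variability <- report_outliers(tab, lapply(varying, filter_spec, op = "VARY"))
  list(properties = tab, varying = varying, variability = variability)
}

dataset_properties <- function(path) {
  hdr <- suppressWarnings(RNifti::niftiHeader(path))
  img <- suppressWarnings(RNifti::readNifti(path))
  nd <- hdr$dim[1L]
  dims <- hdr$dim[2:(1 + min(nd, 3L))]
  ntime <- if (nd >= 4L) hdr$dim[5L] else 1L
  rng <- suppressWarnings(range(as.array(img), na.rm = TRUE))
  slope <- hdr$scl_slope
  raw <- if (is.finite(slope) && slope != 0) (rng - hdr$scl_inter) / slope else rng
  review_dict(
    "matrix dims" = as.numeric(dims),
    "voxel sizes" = as.numeric(abs(hdr$pixdim[2:4])),
    "TR" = if (nd >= 4L) hdr$pixdim[5L] else 0,
    "n_time" = as.numeric(ntime),
    "datum" = as.character(hdr$datatype),
    "orientation" = RNifti::orientation(img),
    "stored min" = raw[1L],
    "stored max" = raw[2L],
    "saturation flag" = if (raw[2L] == 4095) "yes" else "no",
    "slice timing" = if (!is.null(hdr$slice_code) && hdr$slice_code > 0)
      "yes" else "no"
  )
}
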