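#' Read a whitespace-separated numeric column file ("1D" format)
#'
#' Motion parameters, censor vectors and ideal-response regressors are
#' exchanged as plain text: whitespace-separated numeric columns, with lines
#' starting in `#` treated as comments.
#'
#' @param path Path to the text file.
#' @return Numeric matrix (rows x columns).
#' @export
read_table_1d <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data rows in ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L)
    stop("inconsistent column count in ", path, ": ",
         paste(unique(ncols), collapse = ", "))
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- unlist(toks)[is.na(vals)][1L]
    stop("non-numeric token in ", path, ": '", bad, "'")
  }
  matrix(vals, nrow = length(lines), ncol = ncols[1L], byrow = TRUE)
}

#' Write a numeric matrix as a 1D column file
#'
#' @param x Numeric matrix or vector.
#' @param path Output path.
#' @param comments Optional character vector written as `#` header lines.
#' @return The path, invisibly.
#' @export
write_table_1d <- function(x, path, comments = NULL) {
  x <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  writeLines(apply(x, 1L, function(r) paste(fmt_num(r), collapse = " ")), con)
  invisible(path)
}

# Shortest decimal representation that round-trips through as.numeric().
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    if (v == round(v) && abs(v) < 1e15) return(format(v, scientific = FALSE))
    for (d in 6:17) {
      s <- trimws(formatC(v, digits = d, format = "g"))
      if (as.numeric(s) == v) return(s)
    }
    trimws(formatC(v, digits = 17, format = "g"))
  }, character(1L))
}

#' Review dictionary: ordered label -> value map of QC quantities
#'
#' The per-subject quantitative review is an ordered dictionary mapping a
#' label (e.g. `"TSNR average"`) to a number, a numeric vector (one entry per
#' run or per stimulus), or a verbatim string. It serializes either as
#' colon-separated text (`label : value`) or as JSON.
#'
#' @param ... Named values (numbers, numeric vectors, or strings), or a single
#'   named list.
#' @return An object of class `review_dict` (an ordered named list).
#' @export
review_dict <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1L]]) && is.null(names(entries)[1L]))
    entries <- entries[[1L]]
  entries <- entries[!vapply(entries, is.null, logical(1L))]
  labs <- names(entries)
  if (is.null(labs) || any(!nzchar(labs)))
    stop("all review entries must be named")
  if (anyDuplicated(labs)) stop("duplicate review label: ",
                                labs[duplicated(labs)][1L])
  structure(entries, class = "review_dict")
}

#' @export
print.review_dict <- function(x, ...) {
  for (lab in names(x)) {
    v <- x[[lab]]
    vs <- if (is.numeric(v)) paste(fmt_num(v), collapse = " ") else as.character(v)
    cat(sprintf("%-34s : %s\n", lab, vs))
  }
  invisible(x)
}

#' Merge review dictionaries
#' @param ... `review_dict` objects or named lists; later entries override.
#' @return A `review_dict`.
#' @export
review_merge <- function(...) {
  out <- list()
  for (rd in list(...)) for (lab in names(rd)) out[[lab]] <- rd[[lab]]
  review_dict(out)
}

#' Read a review dictionary (colon text or JSON, auto-detected)
#'
#' Colon format: one `label : value` per line. A value whose whitespace-split
#' tokens all parse as numbers becomes a numeric scalar or vector; anything
#' else is kept as a verbatim string (version strings, dataset names, ...).
#'
#' @param path Path to a colon-separated text or JSON object file.
#' @return A [review_dict()].
#' @export
read_review <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  first <- trimws(txt[nzchar(trimws(txt))][1L])
  if (!is.na(first) && startsWith(first, "{")) {
    obj <- jsonlite::fromJSON(paste(txt, collapse = "\n"),
                              simplifyVector = TRUE, simplifyDataFrame = FALSE)
    return(review_dict(obj))
  }
  lines <- txt[nzchar(trimws(txt)) & !grepl("^\\s*#", txt)]
  out <- list()
  for (ln in lines) {
    pos <- regexpr(":", ln, fixed = TRUE)
    if (pos < 0L) stop("unparseable review line (no ':'): '", ln, "'")
    lab <- trimws(substr(ln, 1L, pos - 1L))
    val <- trimws(substr(ln, pos + 1L, nchar(ln)))
    if (!nzchar(lab)) stop("empty label in review line: '", ln, "'")
    if (!is.null(out[[lab]])) stop("duplicate review label: ", lab)
    out[[lab]] <- parse_review_value(val)
  }
  review_dict(out)
}

parse_review_value <- function(val) {
  if (!nzchar(val)) return("")
  toks <- strsplit(val, "\\s+")[[1L]]
  nums <- suppressWarnings(as.numeric(toks))
  if (!anyNA(nums)) nums else val
}

#' Write a review dictionary
#'
#' @param rd A [review_dict()].
#' @param path Output path.
#' @param format `"colon"` (tab-padded `label : value` lines) or `"json"`.
#'   Numeric values keep full (round-trippable) precision.
#' @return The path, invisibly.
#' @export
write_review <- function(rd, path, format = c("colon", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(rd, "review_dict"))
  if (format == "json") {
    jsonlite::write_json(unclass(rd), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    lines <- vapply(names(rd), function(lab) {
      v <- rd[[lab]]
      vs <- if (is.numeric(v)) paste(fmt_num(v), collapse = " ") else as.character(v)
      paste0(lab, " : ", vs)
    }, character(1L))
    writeLines(lines, path)
  }
  invisible(path)
}
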