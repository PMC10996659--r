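#' Degrees-of-freedom cost of temporal bandpassing
#'
#' Bandpassing a length-`n_t` series sampled at `tr_s` removes every discrete
#' Fourier frequency bin `k / (n_t * tr_s)`, `k = 0..floor(n_t/2)`, outside
#' `[f_low_hz, f_high_hz]`. Each interior bin carries 2 degrees of freedom
#' (sine and cosine); the `k = 0` bin and, for even `n_t`, the Nyquist bin
#' carry 1. The popular 0.01-0.1 Hz "low frequency fluctuation" band removes
#' roughly 60% of the DFs at TR = 2 s and roughly 80% at TR = 1 s.
#'
#' @param n_t Number of time points.
#' @param tr_s Repetition time, s.
#' @param f_low_hz,f_high_hz Passband edges, Hz (`0 <= f_low < f_high <=`
#'   Nyquist).
#' @return List with `df_removed` (integer) and `frac_removed`
#'   (`df_removed / n_t`).
#' @export
bandpass_df <- function(n_t, tr_s, f_low_hz, f_high_hz) {
  nyq <- 1 / (2 * tr_s)
  if (f_low_hz < 0 || f_high_hz <= f_low_hz || f_high_hz > nyq + 1e-12)
    stop("band must satisfy 0 <= f_low < f_high <= Nyquist (", signif(nyq, 6), " Hz)")
  k <- 0:(n_t %/% 2L)
  freq <- k / (n_t * tr_s)
  df_per_bin <- ifelse(k == 0L | (n_t %% 2L == 0L & k == n_t %/% 2L), 1L, 2L)
  removed <- freq < f_low_hz - 1e-12 | freq > f_high_hz + 1e-12
  df_removed <- sum(df_per_bin[removed])
  list(df_removed = as.integer(df_removed), frac_removed = df_removed / n_t)
}

#' Design matrix for regression bookkeeping
#'
#' @param columns T x P numeric matrix of regressors.
#' @param labels Unique column labels (default `X1..XP`).
#' @param groups Per-column group: `"baseline"` (slow drift), `"motion"`, or
#'   `"interest"`.
#' @return An object of class `design_matrix`.
#' @export
design_matrix <- function(columns, labels = NULL, groups = NULL) {
  columns <- as.matrix(columns)
  p <- ncol(columns)
  if (p < 1L) stop("design matrix needs at least one column")
  if (is.null(labels)) labels <- paste0("X", seq_len(p))
  if (length(labels) != p || anyDuplicated(labels))
    stop("labels must be unique and match the number of columns")
  if (is.null(groups)) groups <- rep("interest", p)
  groups <- match.arg(groups, c("baseline", "motion", "interest"),
                      several.ok = TRUE)
  if (length(groups) == 1L) groups <- rep(groups, p)
  if (length(groups) != p) stop("groups must have one entry per column")
  structure(list(columns = columns, labels = labels, groups = groups),
            class = "design_matrix")
}

#' Degrees-of-freedom ledger for a subject-level regression
#'
#' Accounts for every time point consumed by the model: censoring, slow-drift
#' (baseline) regressors, motion regressors, bandpass projection, and any
#' other regressors of interest. The identity
#' `df_used = n_censored + df_drift + df_motion + df_bandpass + df_other`
#' and `df_left = n_total - df_used` always holds; a negative `df_left` is
#' reported as a severe warning rather than an error.
#'
#' @param n_total Total number of acquired volumes.
#' @param censor Optional `censor_vector` (or an integer count of censored
#'   volumes).
#' @param design Optional [design_matrix()]; its `baseline`, `motion` and
#'   `interest` column counts populate the drift/motion/other slots.
#' @param bandpass Optional list `(tr_s, f_low_hz, f_high_hz)` passed to
#'   [bandpass_df()].
#' @param intercepts Number of per-run constant baseline terms counted into
#'   the drift slot in addition to the design's baseline columns.
#' @return An object of class `df_ledger` with fields `n_total`,
#'   `n_censored`, `df_drift`, `df_motion`, `df_bandpass`, `df_other`,
#'   `df_used`, `df_left`, `frac_left`, and `warn` (a [warn_level()]).
#' @export
df_ledger <- function(n_total, censor = NULL, design = NULL, bandpass = NULL,
                      intercepts = 0L) {
  n_censored <- if (is.null(censor)) 0L
                else if (inherits(censor, "censor_vector")) sum(censor$keep == 0L)
                else as.integer(censor)
  df_drift <- df_motion <- df_other <- 0L
  if (!is.null(design)) {
    if (inherits(design, "design_matrix")) {
      df_drift <- sum(design$groups == "baseline")
      df_motion <- sum(design$groups == "motion")
      df_other <- sum(design$groups == "interest")
    } else {
      df_other <- as.integer(design)   # plain regressor count
    }
  }
  df_drift <- df_drift + as.integer(intercepts)
  df_bandpass <- if (is.null(bandpass)) 0L else
    bandpass_df(n_total - n_censored, bandpass$tr_s,
                bandpass$f_low_hz, bandpass$f_high_hz)$df_removed
  df_used <- n_censored + df_drift + df_motion + df_bandpass + df_other
  df_left <- n_total - df_used
  structure(list(n_total = as.integer(n_total), n_censored = n_censored,
                 df_drift = df_drift, df_motion = df_motion,
                 df_bandpass = df_bandpass, df_other = df_other,
                 df_used = as.integer(df_used), df_left = as.integer(df_left),
                 frac_left = df_left / n_total,
                 warn = if (df_left < 0) warn_level("severe",
                        "model uses more degrees of freedom than acquired")
                        else if (df_left < 0.3 * n_total) warn_level("medium",
                        "fewer than 30% of degrees of freedom remain")
                        else warn_level("none")),
            class = "df_ledger")
}

#' @export
print.df_ledger <- function(x, ...) {
  cat(sprintf(paste0("<df_ledger> %d TRs: censored %d, drift %d, motion %d, ",
                     "bandpass %d, other %d -> used %d, left %d (%.6g)\n"),
              x$n_total, x$n_censored, x$df_drift, x$df_motion, x$df_bandpass,
              x$df_other, x$df_used, x$df_left, x$frac_left))
  invisible(x)
}

#' Review-dictionary entries for a DF ledger
#' @param ledger A `df_ledger`.
#' @return A [review_dict()] with the standard labels
#'   (`"degrees of freedom used"`, `"degrees of freedom left"`,
#'   `"final DF fraction"` rounded to 6 decimals).
#' @export
review_from_ledger <- function(ledger) {
  review_dict(
    "degrees of freedom used" = ledger$df_used - ledger$n_censored,
    "degrees of freedom left" = ledger$df_left,
    "final DF fraction" = round(ledger$frac_left, 6)
  )
}

#' Design-matrix collinearity diagnostics
#'
#' Pairwise |Pearson r| between mean-removed regressor columns (computed on
#' kept time points when a censor is supplied), graded mild / medium /
#' severe at configurable thresholds; plus the condition number of the
#' column-normalized matrix, flagged severe when numerically rank-deficient.
#' Zero-variance columns get their own warning row.
#'
#' @param design A [design_matrix()].
#' @param censor Optional `censor_vector`; correlations use kept indices only.
#' @param thresholds Named vector `c(mild=, medium=, severe=)` on |r|.
#' @return A tibble with columns `type` (`"pair"`, `"cond"`, `"zero_var"`),
#'   `label1`, `label2`, `value`, `level`.
#' @export
collinearity_check <- function(design, censor = NULL,
                               thresholds = c(mild = 0.4, medium = 0.6,
                                              severe = 0.8)) {
  x <- design$columns
  if (!is.null(censor)) x <- x[censor$keep == 1L, , drop = FALSE]
  if (nrow(x) <= ncol(x))
    stop("need more (kept) time points than regressors")
  labs <- design$labels
  sds <- apply(x, 2L, stats::sd)
  rows <- list()
  for (j in which(sds == 0))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      type = "zero_var", label1 = labs[j], label2 = NA_character_,
      value = 0, level = "severe")
  ok <- which(sds > 0)
  if (length(ok) >= 2L) {
    r <- stats::cor(x[, ok, drop = FALSE])
    for (a in seq_along(ok)[-length(ok)]) for (b in (a + 1L):length(ok)) {
      v <- abs(r[a, b])
      lev <- grade_level(v, thresholds)
      if (lev != "none")
        rows[[length(rows) + 1L]] <- tibble::tibble(
          type = "pair", label1 = labs[ok[a]], label2 = labs[ok[b]],
          value = v, level = lev)
    }
  }
  xn <- sweep(x, 2L, sqrt(colSums(x^2)), `/`)
  xn <- xn[, colSums(is.finite(xn)) == nrow(xn), drop = FALSE]
  if (ncol(xn) >= 1L) {
    sv <- svd(xn, nu = 0L, nv = 0L)$d
    rank_def <- sv[length(sv)] < max(sv) * max(dim(xn)) * .Machine$double.eps
    cond <- if (rank_def) Inf else sv[1L] / sv[length(sv)]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      type = "cond", label1 = NA_character_, label2 = NA_character_,
      value = cond,
      level = if (rank_def) "severe" else if (cond > 1e3) "medium" else "none")
  }
  if (length(rows) == 0L)
    return(tibble::tibble(type = character(), label1 = character(),
                          label2 = character(), value = numeric(),
                          level = character()))
  do.call(rbind, rows)
}

# Map a nonnegative value onto graded warning labels.
grade_level <- function(v, thresholds) {
  if (v >= thresholds[["severe"]]) "severe"
  else if (v >= thresholds[["medium"]]) "medium"
  else if (v >= thresholds[["mild"]]) "mild"
  else "none"
}

#' Per-stimulus censored-response fractions
#'
#' For each stimulus, the response interval is the set of time points where
#' its idealized response regressor is nonzero; the fraction is the share of
#' those time points that are censored (reported rounded to 3 decimals).
#' Removing too much of any stimulus class's response interval undermines
#' its effect estimate.
#'
#' @param ideal T x S matrix of idealized response regressors (one column per
#'   stimulus), or a length-T vector for a single stimulus.
#' @param censor A `censor_vector`.
#' @param labels Optional stimulus names.
#' @return A tibble with columns `label`, `n_resp`, `n_censored`, `fraction`
#'   (NA with a `flag` of `"empty_regressor"` when a regressor is all zero).
#' @export
stim_censor_fraction <- function(ideal, censor, labels = NULL) {
  ideal <- as.matrix(ideal)
  if (nrow(ideal) != length(censor$keep))
    stop("ideal regressors and censor vector lengths differ")
  s <- ncol(ideal)
  if (is.null(labels)) labels <- paste0("stim", seq_len(s))
  cens <- censor$keep == 0L
  out <- lapply(seq_len(s), function(j) {
    resp <- abs(ideal[, j]) > 0
    n_resp <- sum(resp)
    if (n_resp == 0L)
      return(tibble::tibble(label = labels[j], n_resp = 0L, n_censored = 0L,
                            fraction = NA_real_, flag = "empty_regressor"))
    nc <- sum(resp & cens)
    tibble::tibble(label = labels[j], n_resp = n_resp, n_censored = nc,
                   fraction = round(nc / n_resp, 3), flag = "")
  })
  do.call(rbind, out)
}

#' Detect pre-steady-state volumes
#'
#' MRI volumes acquired before longitudinal magnetization reaches steady
#' state have elevated intensity. For each run, leading volumes whose
#' mask-mean intensity strictly exceeds `(1 + rel_excess)` times the run's
#' median mask-mean are flagged, scanning from the run start until the first
#' non-flagged volume (at most `max_check` per run).
#'
#' @param vol A [volume_series()].
#' @param mask 3D binary mask.
#' @param rel_excess Relative excess over the run median, default 0.02.
#' @param max_check Maximum leading volumes inspected per run.
#' @return Integer vector of flagged (1-based, global) volume indices;
#'   empty on steady data.
#' @export
pre_steady_check <- function(vol, mask, rel_excess = 0.02, max_check = 4L) {
  y <- masked_matrix(vol, mask)
  means <- colMeans(y)
  flagged <- integer(0L)
  off <- 0L
  for (rl in vol$run_lengths) {
    run_means <- means[off + seq_len(rl)]
    thr <- (1 + rel_excess) * stats::median(run_means)
    for (t in seq_len(min(max_check, rl))) {
      if (run_means[t] > thr) flagged <- c(flagged, off + t) else break
    }
    off <- off + rl
  }
  flagged
}
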