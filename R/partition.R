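#' Cap per-position duplicate counts
#'
#' Limits the duplicate contribution of every position to at most `cap`
#' duplicates (the handful of extreme pile-ups at single positions are
#' overwhelmingly amplification artifacts; most in-peak positions carry five
#' or fewer duplicates). Adds a `capped_duplicates = min(duplicates, cap)`
#' column; tallies are otherwise untouched.
#'
#' @param tallies Tally data.frame from [mark_duplicates()].
#' @param cap Maximum duplicates retained per (position, strand) key
#'   (default 5).
#' @return The tallies with a `capped_duplicates` column.
#' @export
cap_position_duplicates <- function(tallies, cap = 5L) {
  if (cap < 0L) stop("cap must be non-negative")
  tallies$capped_duplicates <- pmin(tallies$duplicates, as.integer(cap))
  tallies
}

#' Robust locally weighted regression evaluated at the data points
#'
#' Locally weighted linear regression with tricube weights and bisquare
#' robustifying iterations (`stats::lowess`), evaluated at each input `x`
#' and returned in input order. By default every point is fit exactly
#' (`delta = 0`, no interpolation shortcut) because downstream allocation
#' reads the fit at each peak's own enrichment level. Fitted values are
#' clipped at zero (a duplicate level cannot be negative).
#'
#' @param x,y Numeric vectors of equal length (>= 10).
#' @param span Smoother span, the fraction of points in each local window
#'   (default 2/3).
#' @param iterations Robustifying iterations (default 3).
#' @param delta Interpolation shortcut distance passed to `stats::lowess`
#'   (default 0 = exact evaluation everywhere).
#' @return Numeric vector of fitted values aligned with the input order.
#' @export
lowess_fit <- function(x, y, span = 2/3, iterations = 3L, delta = 0) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10L) stop("need at least 10 points for the local fit")
  if (diff(range(x)) == 0) stop("degenerate x: all values equal")
  fit <- stats::lowess(x, y, f = span, iter = iterations, delta = delta)
  out <- numeric(length(x))
  out[order(x)] <- fit$y
  pmax(0, out)
}

#' Per-peak duplicate and enrichment levels
#'
#' Builds the per-peak level table feeding the signal/noise allocation:
#' nonredundant reads per kb (the target enrichment level, the predictor),
#' and raw and capped duplicates per kb. Reads are assigned to peaks by
#' their duplicate-key coordinate.
#'
#' @param peaks GRanges of blacklist-filtered peaks.
#' @param marking `"dup_marking"` for the library.
#' @param cap Per-position duplicate cap (default 5).
#' @return data.frame with one row per peak: `peak_id`, `length_kb`,
#'   `n_nondup`, `n_dup_raw`, `n_dup_capped`, `nondup_per_kb`,
#'   `dup_per_kb_raw`, `dup_per_kb_capped`, plus `p_value` when present on
#'   the peaks.
#' @export
peak_levels <- function(peaks, marking, cap = 5L) {
  tallies <- cap_position_duplicates(marking$tallies, cap)
  pos <- tally_positions(tallies)
  ov <- GenomicRanges::findOverlaps(pos, peaks, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  agg <- function(v) {
    out <- rep(0L, length(peaks))
    if (length(qh)) {
      s <- tapply(v[qh], sh, sum)
      out[as.integer(names(s))] <- as.integer(s)
    }
    out
  }
  kb <- GenomicRanges::width(peaks) / 1e3
  out <- data.frame(
    peak_id = if (!is.null(peaks$name)) as.character(peaks$name)
      else paste0("peak_", seq_along(peaks)),
    length_kb = kb,
    n_nondup = agg(rep(1L, nrow(tallies))),
    n_dup_raw = agg(tallies$duplicates),
    n_dup_capped = agg(tallies$capped_duplicates),
    stringsAsFactors = FALSE)
  out$nondup_per_kb <- out$n_nondup / kb
  out$dup_per_kb_raw <- out$n_dup_raw / kb
  out$dup_per_kb_capped <- out$n_dup_capped / kb
  if (!is.null(peaks$p_value)) out$p_value <- peaks$p_value
  out
}

#' Allocate in-peak duplicates between signal and noise
#'
#' The core partition: fit the capped duplicate level (duplicates per kb)
#' against the target enrichment level (nonredundant reads per kb) with
#' robust local regression, set each peak's natural-duplicate level to the
#' observed or predicted level, whichever is smaller, and integerize into
#' `S` signal duplicates (round half to even, clamped into
#' `[0, capped count]`) and `N = capped - S` noise duplicates. Peaks with
#' zero nonredundant reads are excluded from the fit and get predicted
#' level 0.
#'
#' @param levels Level table from [peak_levels()].
#' @param span,iterations,delta Local-regression controls, see
#'   [lowess_fit()].
#' @return data.frame of class `"dup_partition"`: per peak `peak_id`,
#'   `predicted_level`, `signal_level`, `S`, `N`, plus the input level
#'   columns. Attributes: `library_signal_fraction` (sum of S over sum of
#'   capped duplicates) and, when the levels carry `p_value`,
#'   `top_signal_fraction` (same fraction over the top 10% most confident
#'   peaks).
#' @export
allocate_signal <- function(levels, span = 2/3, iterations = 3L, delta = 0) {
  if (nrow(levels) < 10L) {
    stop("fewer than 10 peaks; pool peaks (e.g. across replicates) ",
         "before fitting the local regression")
  }
  fit_ok <- levels$n_nondup > 0L
  pred <- numeric(nrow(levels))
  if (sum(fit_ok) >= 10L) {
    pred[fit_ok] <- lowess_fit(levels$nondup_per_kb[fit_ok],
                               levels$dup_per_kb_capped[fit_ok],
                               span = span, iterations = iterations,
                               delta = delta)
  } else {
    stop("fewer than 10 peaks with nonredundant reads")
  }
  out <- levels
  out$predicted_level <- pred
  out$signal_level <- pmin(out$dup_per_kb_capped, pred)
  S <- round(out$signal_level * out$length_kb)
  out$S <- as.integer(pmin(pmax(S, 0), out$n_dup_capped))
  out$N <- out$n_dup_capped - out$S
  attr(out, "library_signal_fraction") <-
    if (sum(out$n_dup_capped) > 0) sum(out$S) / sum(out$n_dup_capped)
    else NA_real_
  if (!is.null(out$p_value)) {
    k <- max(1L, ceiling(0.10 * nrow(out)))
    top <- out[order(out$p_value), ][seq_len(k), ]
    attr(out, "top_signal_fraction") <-
      if (sum(top$n_dup_capped) > 0) sum(top$S) / sum(top$n_dup_capped)
      else NA_real_
  }
  class(out) <- c("dup_partition", class(out))
  out
}

#' @export
print.dup_partition <- function(x, ...) {
  cat("Signal/noise duplicate partition over", nrow(x), "peaks\n")
  cat("  capped duplicates:", sum(x$n_dup_capped),
      " signal (S):", sum(x$S), " noise (N):", sum(x$N), "\n")
  cat(sprintf("  library signal fraction: %.3f\n",
              attr(x, "library_signal_fraction")))
  invisible(x)
}

#' One-call partition of in-peak duplicates
#'
#' Convenience wrapper chaining [peak_levels()] and [allocate_signal()].
#'
#' @inheritParams peak_levels
#' @inheritParams allocate_signal
#' @return See [allocate_signal()].
#' @export
partition_duplicates <- function(peaks, marking, cap = 5L, span = 2/3,
                                 iterations = 3L, delta = 0) {
  allocate_signal(peak_levels(peaks, marking, cap = cap), span = span,
                  iterations = iterations, delta = delta)
}
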