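#' Match flow-based breaths to valid neural breaths
#'
#' Each flow-based breath is linked to the nearest valid neural breath
#' whose envelope peak lies in the window from Tbreath/2 before to 0.5 s
#' after the volume peak (neural activation physiologically precedes or
#' coincides with the flow-based breath). Matching is one-to-one: pairs
#' are accepted greedily in order of increasing absolute lag, and a neural
#' breath is used at most once.
#'
#' @param flow_breaths data.frame from \code{\link{detect_flow_breaths}}
#'   (only included breaths are matched).
#' @param neural_breaths data.frame from \code{\link{assess_quality}}
#'   (only valid breaths are eligible).
#' @param tbreath median inter-breath time, s (> 0).
#' @param after late limit of the window, s (default 0.5).
#' @return data.frame with one row per matched pair: \code{flow_time},
#'   \code{tv}, \code{neural_time}, \code{etpdi}, \code{lag}
#'   (neural peak time - flow peak time, s), plus the row indices
#'   \code{flow_row}, \code{neural_row} into the input tables.
#' @export
match_breaths <- function(flow_breaths, neural_breaths, tbreath,
                          after = 0.5) {
  stopifnot(tbreath > 0)
  fi <- which(flow_breaths$included)
  ni <- which(neural_breaths$valid)
  if (!length(fi) || !length(ni)) return(empty_matches())
  ft <- flow_breaths$peak_time[fi]
  nt <- neural_breaths$peak_time[ni]
  cand <- do.call(rbind, lapply(seq_along(fi), function(a) {
    lag <- nt - ft[a]
    ok <- lag >= -tbreath / 2 & lag <= after
    if (!any(ok)) return(NULL)
    data.frame(a = a, b = which(ok), lag = lag[ok])
  }))
  if (is.null(cand)) return(empty_matches())
  cand <- cand[order(abs(cand$lag), cand$a), ]
  used_f <- logical(length(fi))
  used_n <- logical(length(ni))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    a <- cand$a[r]; b <- cand$b[r]
    if (!used_f[a] && !used_n[b]) {
      keep[r] <- TRUE
      used_f[a] <- TRUE
      used_n[b] <- TRUE
    }
  }
  cand <- cand[keep, ]
  out <- data.frame(
    flow_time = ft[cand$a],
    tv = flow_breaths$tv[fi[cand$a]],
    neural_time = nt[cand$b],
    etpdi = neural_breaths$etpdi[ni[cand$b]],
    lag = cand$lag,
    flow_row = fi[cand$a],
    neural_row = ni[cand$b])
  out <- out[order(out$flow_time), ]
  rownames(out) <- NULL
  out
}

empty_matches <- function() {
  data.frame(flow_time = numeric(0), tv = numeric(0),
             neural_time = numeric(0), etpdi = numeric(0),
             lag = numeric(0), flow_row = integer(0),
             neural_row = integer(0))
}

#' Trial validity: the 10 percent rule
#'
#' A PS-trial enters the analysis only if, at every PS level, the number
#' of valid neural breaths is at least 10 percent of the number of
#' flow-based breaths at that level. A level with zero flow-based breaths
#' invalidates the trial.
#'
#' @param level_counts data.frame with columns \code{ps_level},
#'   \code{n_valid_neural}, \code{n_flow}.
#' @param min_fraction validity fraction (default 0.10).
#' @return logical scalar with attribute \code{per_level} (logical vector
#'   of per-level verdicts).
#' @export
check_trial_validity <- function(level_counts, min_fraction = 0.10) {
  stopifnot(all(c("ps_level", "n_valid_neural", "n_flow") %in%
                names(level_counts)),
            all(level_counts$n_valid_neural >= 0),
            all(level_counts$n_flow >= 0))
  per <- level_counts$n_flow > 0 &
    level_counts$n_valid_neural >= min_fraction * level_counts$n_flow
  out <- all(per) && nrow(level_counts) > 0
  attr(out, "per_level") <- per
  out
}

#' Tukey-fence outlier exclusion on breath pairs
#'
#' Removes a (ETPdi, TV) pair if either variable lies outside its own
#' Tukey fences, Q1 - 1.5 IQR to Q3 + 1.5 IQR, with quartiles computed on
#' the input pair set by the shared linear-interpolation percentile
#' (\code{\link{pctl}}). With fewer than four pairs no exclusion is done
#' (a warning is raised) since quartiles are not meaningful.
#'
#' @param pairs data.frame with columns \code{etpdi} and \code{tv}.
#' @param k fence multiplier (default 1.5).
#' @return the retained rows, with attribute \code{n_removed}.
#' @export
tukey_exclude <- function(pairs, k = 1.5) {
  stopifnot(all(c("etpdi", "tv") %in% names(pairs)))
  if (nrow(pairs) < 4L) {
    warning("fewer than 4 pairs: no outlier exclusion performed")
    attr(pairs, "n_removed") <- 0L
    return(pairs)
  }
  inside <- function(x) {
    q1 <- pctl(x, 25); q3 <- pctl(x, 75)
    iqr <- q3 - q1
    x >= q1 - k * iqr & x <= q3 + k * iqr
  }
  keep <- inside(pairs$etpdi) & inside(pairs$tv)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Neuro-ventilatory coupling of a pair set
#'
#' NVC is 100 times the squared Pearson correlation between breath-by-
#' breath ETPdi and tidal volume. If either variable has zero variance the
#' coupling is reported as 0 and flagged degenerate (constant TV is the
#' physiological signature of passive, uncoupled breathing). With fewer
#' than \code{min_pairs} pairs the result is undefined (NA), not zero.
#'
#' @param pairs data.frame with columns \code{etpdi} and \code{tv}
#'   (typically after \code{\link{tukey_exclude}}).
#' @param min_pairs minimum pair count (default 5).
#' @return list: \code{nvc} (percent, or NA if undefined), \code{n_pairs},
#'   \code{degenerate}, \code{undefined}.
#' @export
compute_nvc <- function(pairs, min_pairs = 5) {
  n <- nrow(pairs)
  if (n < min_pairs)
    return(list(nvc = NA_real_, n_pairs = n, degenerate = FALSE,
                undefined = TRUE))
  if (stats::var(pairs$etpdi) == 0 || stats::var(pairs$tv) == 0)
    return(list(nvc = 0, n_pairs = n, degenerate = TRUE,
                undefined = FALSE))
  r <- stats::cor(pairs$etpdi, pairs$tv)
  list(nvc = 100 * r^2, n_pairs = n, degenerate = FALSE,
       undefined = FALSE)
}

#' Per-level NVC with outlier exclusion
#'
#' Applies the Tukey-fence exclusion and the NVC computation per PS level
#' of a matched-breath table. This is the unit at which coupling is
#' reported; a trial-level summary is the median over its levels.
#'
#' @param matched data.frame of matched pairs with columns \code{etpdi},
#'   \code{tv} and \code{ps_level}.
#' @param min_pairs minimum pair count per level (default 5).
#' @param k fence multiplier (default 1.5).
#' @return data.frame: \code{ps_level}, \code{nvc}, \code{n_pairs},
#'   \code{n_outliers_removed}, \code{degenerate}, \code{undefined}.
#' @export
nvc_by_level <- function(matched, min_pairs = 5, k = 1.5) {
  stopifnot(all(c("etpdi", "tv", "ps_level") %in% names(matched)))
  levels <- sort(unique(matched$ps_level), decreasing = TRUE)
  out <- lapply(levels, function(l) {
    sub <- matched[matched$ps_level == l, c("etpdi", "tv")]
    kept <- if (nrow(sub) >= 4L) tukey_exclude(sub, k = k) else sub
    n_rm <- if (nrow(sub) >= 4L) attr(kept, "n_removed") else 0L
    r <- compute_nvc(kept, min_pairs = min_pairs)
    data.frame(ps_level = l, nvc = r$nvc, n_pairs = r$n_pairs,
               n_outliers_removed = n_rm, degenerate = r$degenerate,
               undefined = r$undefined)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
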