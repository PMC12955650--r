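#' Discretize continuous confidence into ordinal levels
#'
#' Replaces a continuous confidence scale with per-subject quantile levels:
#' cutpoints are placed at the `i/n_levels` quantiles (type-7, linearly
#' interpolated) of each subject's own confidence values and trials are
#' mapped to levels 1 (lowest confidence) .. n (highest). A value exactly on
#' a cutpoint goes to the lower level. Confidence scales that are already
#' ordinal should be used as-is, not re-discretized.
#'
#' @param trials Data frame with columns `subject` and `confidence`
#'   (continuous).
#' @param n_levels Number of levels `n >= 2` (tertiles when 3).
#' @return `trials` with `confidence` replaced by integer levels 1..n.
#' @export
discretize_confidence <- function(trials, n_levels) {
  n_levels <- as.integer(n_levels)
  stopifnot(is.data.frame(trials), n_levels >= 2L)
  if (!all(c("subject", "confidence") %in% names(trials))) {
    stop("trials need `subject` and `confidence` columns", call. = FALSE)
  }
  out <- trials
  for (id in unique(trials$subject)) {
    sel <- trials$subject == id
    conf <- trials$confidence[sel]
    if (length(unique(conf)) < n_levels) {
      stop("subject `", id, "` has fewer distinct confidence values (",
           length(unique(conf)), ") than levels (", n_levels, ")",
           call. = FALSE)
    }
    cuts <- stats::quantile(conf, probs = seq_len(n_levels - 1L) / n_levels,
                            type = 7, names = FALSE)
    # ties at a cutpoint fall to the lower level
    out$confidence[sel] <- 1L + rowSums(outer(conf, cuts, ">"))
  }
  out$confidence <- as.integer(out$confidence)
  out
}

#' Bin response times into quantile-based evidence strengths
#'
#' Discretizes each subject's RTs into `n_bins` quantile bins (type-7
#' cutpoints at `i/n_bins`), treating a faster response as a stronger
#' indication of the choice made: the fastest bin is strength `n_bins`, the
#' slowest is strength 1. An RT exactly on a cutpoint goes to the slower
#' (weaker) bin. Under `scheme = "pooled"` (default) cutpoints are computed
#' over all of a subject's trials on a common clock; `"within_response"`
#' computes them separately for yes and no responses.
#'
#' @param trials Data frame with columns `subject`, `response` and `rt`.
#' @param n_bins Number of bins `>= 2`.
#' @param scheme `"pooled"` or `"within_response"`.
#' @param degenerate What to do when a subject has fewer distinct RTs than
#'   bins: `"error"` (default) or `"collapse"` (assign all trials the middle
#'   strength).
#' @return `trials` with an integer `rt_strength` column (1 = weakest /
#'   slowest, `n_bins` = strongest / fastest).
#' @export
bin_rt <- function(trials, n_bins, scheme = c("pooled", "within_response"),
                   degenerate = c("error", "collapse")) {
  scheme <- match.arg(scheme)
  degenerate <- match.arg(degenerate)
  n_bins <- as.integer(n_bins)
  stopifnot(is.data.frame(trials), n_bins >= 2L)
  if (!all(c("subject", "response", "rt") %in% names(trials))) {
    stop("trials need `subject`, `response` and `rt` columns", call. = FALSE)
  }
  assign_bins <- function(rt, id) {
    if (length(rt) < n_bins || length(unique(rt)) < n_bins) {
      if (degenerate == "error") {
        stop("subject `", id, "` has too few distinct RTs (",
             length(unique(rt)), ") for ", n_bins, " bins", call. = FALSE)
      }
      return(rep((n_bins + 1L) %/% 2L, length(rt)))
    }
    cuts <- stats::quantile(rt, probs = seq_len(n_bins - 1L) / n_bins,
                            type = 7, names = FALSE)
    # bin index 1 = fastest; an RT equal to a cutpoint joins the slower bin
    bin <- 1L + rowSums(outer(rt, cuts, ">="))
    n_bins + 1L - bin
  }
  out <- trials
  out$rt_strength <- NA_integer_
  for (id in unique(trials$subject)) {
    sel <- which(trials$subject == id)
    if (scheme == "pooled") {
      out$rt_strength[sel] <- assign_bins(trials$rt[sel], id)
    } else {
      for (r in 0:1) {
        sub <- sel[trials$response[sel] == r]
        if (length(sub)) out$rt_strength[sub] <- assign_bins(trials$rt[sub], id)
      }
    }
  }
  out$rt_strength <- as.integer(out$rt_strength)
  out
}

#' Build padded per-subject rating tables
#'
#' Convenience wrapper running, per subject, the rating-dimension
#' preparation ([bin_rt()] for `evidence = "rt"`; [discretize_confidence()]
#' for continuous confidence), [build_table()] and [pad_table()].
#'
#' @param trials Trial data frame (`subject`, `stimulus`, `response`, `rt`,
#'   optional `confidence`).
#' @param n_levels Rating levels per response.
#' @param evidence `"rt"` or `"confidence"`.
#' @param scheme RT binning scheme, see [bin_rt()].
#' @param discretize If `TRUE`, treat `confidence` as continuous and
#'   discretize it; if `FALSE` (default) `confidence` is used as ordinal
#'   levels 1..n as-is.
#' @return Named list of padded [rating_table()]s, one per subject.
#' @export
prepare_tables <- function(trials, n_levels,
                           evidence = c("rt", "confidence"),
                           scheme = c("pooled", "within_response"),
                           discretize = FALSE) {
  evidence <- match.arg(evidence)
  scheme <- match.arg(scheme)
  if (evidence == "rt") {
    trials <- bin_rt(trials, n_levels, scheme = scheme)
  } else if (discretize) {
    trials <- discretize_confidence(trials, n_levels)
  }
  ids <- unique(trials$subject)
  tables <- lapply(ids, function(id) {
    pad_table(build_table(trials[trials$subject == id, , drop = FALSE],
                          n_levels, evidence = evidence))
  })
  names(tables) <- as.character(ids)
  tables
}

#' Screen subjects for below-chance performance
#'
#' Flags subjects whose overall yes/no performance is not above chance:
#' using the ROC midpoint rates (yes responses collapsed over strength
#' levels), a subject with `z(hit) - z(fa) <= 0` is excluded from fitting.
#' The boundary `hit = fa` counts as excluded.
#'
#' @param tables Named list of padded per-subject [rating_table()]s.
#' @return A `"preprocess_report"`: a data frame with one row per subject
#'   (`subject`, `hit_rate`, `fa_rate`, `d_prime_midpoint`, `below_chance`)
#'   and exclusion counts in attributes.
#' @export
exclude_below_chance <- function(tables) {
  stopifnot(is.list(tables), length(tables) > 0L)
  rows <- lapply(names(tables), function(id) {
    tab <- tables[[id]]
    stopifnot(inherits(tab, "rating_table"))
    n <- tab$n_levels
    yes <- rowSums(tab$freq[, seq_len(n), drop = FALSE]) / rowSums(tab$freq)
    dp <- stats::qnorm(yes[["present"]]) - stats::qnorm(yes[["absent"]])
    data.frame(subject = id, hit_rate = yes[["present"]],
               fa_rate = yes[["absent"]], d_prime_midpoint = dp,
               below_chance = dp <= 0, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(report,
            n_input_subjects = nrow(report),
            n_below_chance_excluded = sum(report$below_chance),
            n_final = sum(!report$below_chance),
            class = c("preprocess_report", "data.frame"))
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(
    "Preprocessing screen: %d subjects, %d excluded as below chance, %d kept\n",
    attr(x, "n_input_subjects"), attr(x, "n_below_chance_excluded"),
    attr(x, "n_final")))
  print.data.frame(x, ...)
  invisible(x)
}
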