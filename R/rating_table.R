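#' Response-frequency rating table
#'
#' A 2 x 2n table crossing stimulus class (absent, present) with the `2n`
#' ordered response categories of an `n`-level rating scheme: "yes" with
#' strength n (highest confidence / fastest RT bin) down to "yes" with
#' strength 1, then "no" with strength 1 up to "no" with strength n. This
#' table is the sufficient statistic for rating-model maximum likelihood.
#'
#' @param freq A 2 x 2n matrix of nonnegative frequencies; rows are
#'   (absent, present), columns ordered as above. Unpadded tables must hold
#'   integer counts.
#' @param padded Logical; whether the 1/N stabilizing constant has already
#'   been added (see [pad_table()]).
#' @return An object of class `"rating_table"` with elements `freq`,
#'   `n_levels` and `padded`.
#' @examples
#' rating_table(rbind(c(1, 2, 10, 7), c(9, 6, 4, 1)))
#' @export
rating_table <- function(freq, padded = FALSE) {
  freq <- as.matrix(freq)
  if (nrow(freq) != 2L || ncol(freq) < 4L || ncol(freq) %% 2L != 0L) {
    stop("`freq` must be a 2 x 2n matrix with n >= 2", call. = FALSE)
  }
  if (any(!is.finite(freq)) || any(freq < 0)) {
    stop("frequencies must be finite and nonnegative", call. = FALSE)
  }
  if (!padded && any(abs(freq - round(freq)) > 1e-8)) {
    stop("unpadded frequencies must be integer counts", call. = FALSE)
  }
  if (any(rowSums(freq) <= 0)) {
    stop("each stimulus class must contain at least one trial", call. = FALSE)
  }
  n <- ncol(freq) %/% 2L
  dimnames(freq) <- list(c("absent", "present"),
                         c(paste0("yes", n:1), paste0("no", 1:n)))
  structure(
    list(freq = freq, n_levels = n, padded = isTRUE(padded)),
    class = "rating_table"
  )
}

#' @export
n_levels.rating_table <- function(x) x$n_levels

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf("Rating table: %d levels, N = %.4g%s\n", x$n_levels,
              sum(x$freq), if (x$padded) " (padded)" else ""))
  print(x$freq, ...)
  invisible(x)
}

#' Tabulate trials into a rating table
#'
#' Sorts trial records into the 2 x 2n response-frequency table for one
#' subject, using either the ordinal confidence level or the RT-bin strength
#' as the rating dimension. A "yes" with strength `s` lands in column
#' `n - s + 1`, a "no" with strength `s` in column `n + s`, so columns run
#' from the strongest "yes" evidence to the strongest "no" evidence.
#'
#' @param trials A data frame of trials with columns `stimulus` (0/1),
#'   `response` (0/1) and the rating column named by `evidence`:
#'   `confidence` (ordinal 1..n, see [discretize_confidence()]) or
#'   `rt_strength` (see [bin_rt()]).
#' @param n_levels Number of rating levels `n >= 2`.
#' @param evidence `"confidence"` or `"rt"`.
#' @return An unpadded [rating_table()].
#' @export
build_table <- function(trials, n_levels, evidence = c("confidence", "rt")) {
  evidence <- match.arg(evidence)
  n_levels <- as.integer(n_levels)
  stopifnot(is.data.frame(trials), n_levels >= 2L)
  col <- if (evidence == "confidence") "confidence" else "rt_strength"
  if (!col %in% names(trials)) {
    stop("trials lack the ordinal column `", col, "`; run ",
         if (evidence == "rt") "bin_rt()" else "discretize_confidence()",
         " first", call. = FALSE)
  }
  strength <- trials[[col]]
  if (any(is.na(strength)) || any(strength < 1L) || any(strength > n_levels)) {
    stop("`", col, "` must be integers in 1..n_levels", call. = FALSE)
  }
  if (length(unique(trials$stimulus)) < 2L) {
    stop("both stimulus classes (present and absent) are required",
         call. = FALSE)
  }
  category <- ifelse(trials$response == 1L,
                     n_levels + 1L - strength,
                     n_levels + strength)
  freq <- matrix(0, 2L, 2L * n_levels)
  for (s in 0:1) {
    tab <- tabulate(category[trials$stimulus == s], nbins = 2L * n_levels)
    freq[s + 1L, ] <- tab
  }
  rating_table(freq, padded = FALSE)
}

#' Add the 1/N stabilizing constant
#'
#' Adds `1/N` to every cell of an unpadded rating table, where `N` is the
#' table's grand total of trials. Padding keeps every cumulative hit and
#' false-alarm rate strictly inside (0, 1), which the z-transform and the
#' likelihood surface require, while perturbing the rates only at order 1/N.
#'
#' @param table An unpadded [rating_table()].
#' @return The padded table (`padded = TRUE`).
#' @export
pad_table <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  if (table$padded) {
    stop("table is already padded; padding twice would bias the rates",
         call. = FALSE)
  }
  n_total <- sum(table$freq)
  rating_table(table$freq + 1 / n_total, padded = TRUE)
}
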