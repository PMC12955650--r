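# roc_curve objects: data.frame of (fa, hit[, criterion]) points ordered from
# most conservative (bottom-left) to most lenient, plus source metadata.
new_roc_curve <- function(points, source, n_levels = NA_integer_) {
  structure(
    list(points = points, source = source, n_levels = n_levels),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Type-1 ROC (%s, %d points)\n", x$source, nrow(x$points)))
  if (nrow(x$points) <= 12L) print(x$points, ...) else
    print(utils::head(x$points, 6L), ...)
  invisible(x)
}

#' @export
as.data.frame.roc_curve <- function(x, ...) x$points

#' Empirical type-1 ROC from a rating table
#'
#' Builds the cumulative (false-alarm, hit) operating points: point `k`
#' treats the `k` strongest-"yes" response categories as "yes", for
#' `k = 1 .. 2n - 1`. The leftmost point counts only the strongest yes
#' responses (highest confidence / fastest RT bin); the midpoint
#' (`k = n`) is determined solely by yes/no responses; the omitted
#' `k = 2n` point is the trivial anchor (1, 1).
#'
#' @param table A [rating_table()] (padded or unpadded; rates use row
#'   totals).
#' @return A `"roc_curve"` with `2n - 1` points and `source = "empirical"`.
#' @export
empirical_roc <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  n2 <- 2L * table$n_levels
  cum <- t(apply(table$freq / rowSums(table$freq), 1, cumsum))
  k <- seq_len(n2 - 1L)
  pts <- data.frame(fa = cum["absent", k], hit = cum["present", k])
  rownames(pts) <- NULL
  new_roc_curve(pts, source = "empirical", n_levels = table$n_levels)
}

#' z-transformed ROC and descriptive slope
#'
#' Applies the standard-normal quantile transform to both coordinates of an
#' ROC curve. Under the bi-Gaussian model the zROC is a straight line with
#' slope `1/sigma` and intercept `mu/sigma`; the ordinary least-squares line
#' through the points is returned as a descriptive estimate (the maximum-
#' likelihood fit, [fit_uvsdt()], is authoritative for sigma).
#'
#' @param curve A `"roc_curve"` whose rates lie strictly inside (0, 1)
#'   (pad the table first).
#' @return A list of class `"zroc"`: `points` (columns `z_fa`, `z_hit`),
#'   `slope`, `intercept`, and the implied `sigma_hat = 1/slope`,
#'   `mu_hat = intercept/slope`.
#' @export
zroc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  check_rates(curve$points$hit, curve$points$fa)
  pts <- data.frame(z_fa = stats::qnorm(curve$points$fa),
                    z_hit = stats::qnorm(curve$points$hit))
  slope <- intercept <- NA_real_
  if (nrow(pts) >= 2L && stats::sd(pts$z_fa) > 0) {
    fit <- stats::lm.fit(cbind(1, pts$z_fa), pts$z_hit)
    intercept <- fit$coefficients[[1L]]
    slope <- fit$coefficients[[2L]]
  }
  structure(
    list(points = pts, slope = slope, intercept = intercept,
         sigma_hat = 1 / slope, mu_hat = intercept / slope),
    class = "zroc"
  )
}

#' @export
print.zroc <- function(x, ...) {
  cat(sprintf(
    "zROC: slope %.4f, intercept %.4f (sigma_hat %.4f, mu_hat %.4f)\n",
    x$slope, x$intercept, x$sigma_hat, x$mu_hat))
  invisible(x)
}

#' Trapezoidal area under an ROC curve
#'
#' Model-free AUC: the trapezoidal area under the curve's points with the
#' (0, 0) and (1, 1) anchors appended (the most lenient cumulative point of
#' a rating table maps to (1, 1)).
#'
#' @param curve A `"roc_curve"`.
#' @return The area, in \[0, 1\] for monotone curves.
#' @export
empirical_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  ord <- order(curve$points$fa, curve$points$hit)
  fa <- c(0, curve$points$fa[ord], 1)
  hit <- c(0, curve$points$hit[ord], 1)
  sum(diff(fa) * (utils::head(hit, -1L) + utils::tail(hit, -1L)) / 2)
}
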