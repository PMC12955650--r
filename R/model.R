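#' Unequal-variance SDT model parameters
#'
#' Bundles the parameters of the unequal-variance Gaussian signal detection
#' model: the target-present distribution N(`mu`, `sigma`) (target-absent
#' fixed at N(0, 1)) and `2n - 1` strictly increasing decision/rating
#' criteria partitioning the evidence axis for an `n`-level rating scheme.
#' The middle criterion (position `n`) is the yes/no decision criterion.
#'
#' @param mu Mean of the target-present evidence distribution.
#' @param sigma SD of the target-present distribution; must be > 0.
#' @param criteria Strictly increasing numeric vector of odd length
#'   `2n - 1`, `n >= 2`.
#' @return An object of class `"uvsdt_params"`.
#' @examples
#' uvsdt_params(1.5, 1.5, c(-1, 0, 1))
#' @export
uvsdt_params <- function(mu, sigma, criteria) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single finite value > 0", call. = FALSE)
  }
  criteria <- as.numeric(criteria)
  if (length(criteria) < 3L || length(criteria) %% 2L == 0L) {
    stop("`criteria` must have odd length 2n - 1 with n >= 2", call. = FALSE)
  }
  if (any(!is.finite(criteria)) || any(diff(criteria) <= 0)) {
    stop("`criteria` must be finite and strictly increasing", call. = FALSE)
  }
  structure(
    list(mu = mu, sigma = sigma, criteria = criteria),
    class = "uvsdt_params"
  )
}

#' @export
print.uvsdt_params <- function(x, ...) {
  n <- n_levels(x)
  cat("Unequal-variance SDT parameters (", n, " rating levels)\n", sep = "")
  cat(sprintf("  mu = %.4f, sigma = %.4f (d_a = %.4f)\n",
              x$mu, x$sigma, d_a(x$mu, x$sigma)))
  cat("  criteria:", paste(sprintf("%.4f", x$criteria), collapse = " "), "\n")
  invisible(x)
}

#' Number of rating levels
#'
#' Returns `n`, the number of rating (confidence or RT-bin) levels per
#' response, for a parameter set or a rating table.
#'
#' @param x An `"uvsdt_params"` or `"rating_table"` object.
#' @return Integer number of levels.
#' @export
n_levels <- function(x) UseMethod("n_levels")

#' @export
n_levels.uvsdt_params <- function(x) (length(x$criteria) + 1L) %/% 2L

#' Predicted response-category probabilities
#'
#' For each stimulus class, returns the model-implied probabilities of the
#' `2n` ordered response categories (columns ordered from strongest "yes" —
#' highest confidence or fastest RT bin — to strongest "no"). Each
#' probability is the Gaussian mass between consecutive criteria (with
#' infinite end caps): the target-absent row uses N(0, 1) and the
#' target-present row uses N(mu, sigma). Each row sums to 1.
#'
#' @param params An [uvsdt_params()] object.
#' @return A 2 x 2n numeric matrix with rows `"absent"` and `"present"`.
#' @examples
#' cell_probabilities(uvsdt_params(0, 1, c(-1, 0, 1)))
#' @export
cell_probabilities <- function(params) {
  stopifnot(inherits(params, "uvsdt_params"))
  cuts <- c(-Inf, params$criteria, Inf)
  # diff() of the CDF walks the evidence axis left (strong no) to right
  # (strong yes); rev() puts strongest "yes" in column 1
  absent  <- rev(diff(stats::pnorm(cuts)))
  present <- rev(diff(stats::pnorm(cuts, mean = params$mu, sd = params$sigma)))
  p <- rbind(absent = absent, present = present)
  n <- n_levels(params)
  colnames(p) <- c(paste0("yes", n:1), paste0("no", 1:n))
  p
}

#' Multinomial log-likelihood of a rating table
#'
#' Computes `sum(freq * log(p))` where `p` are the model-predicted cell
#' probabilities, i.e. the log of the product of each cell's predicted
#' probability raised to its observed frequency. Predicted probabilities are
#' floored at `prob_floor` so the optimizer stays finite; hitting the floor
#' raises a warning.
#'
#' @param table A [rating_table()] (padding recommended before fitting).
#' @param params An [uvsdt_params()] object with `2n - 1` criteria matching
#'   the table's `n` levels.
#' @param prob_floor Lower bound applied to predicted probabilities inside
#'   the log (default `1e-300`).
#' @return A single numeric log-likelihood.
#' @export
uvsdt_loglik <- function(table, params, prob_floor = 1e-300) {
  stopifnot(inherits(table, "rating_table"), inherits(params, "uvsdt_params"))
  if (n_levels(table) != n_levels(params)) {
    stop("table and params disagree on the number of rating levels",
         call. = FALSE)
  }
  p <- cell_probabilities(params)
  if (any(p < prob_floor)) {
    warning("predicted cell probabilities floored at ", prob_floor,
            call. = FALSE)
    p <- pmax(p, prob_floor)
  }
  sum(table$freq * log(p))
}

#' Model-implied type-1 ROC curve
#'
#' Sweeps a decision criterion `k` over a dense grid (augmented with the
#' parameter set's own criteria) and returns the ROC points
#' `(FA, hit) = (1 - Phi(k), 1 - Phi((k - mu) / sigma))`, ordered from most
#' conservative (bottom-left) to most lenient (top-right).
#'
#' @param params An [uvsdt_params()] object.
#' @param n_grid Number of grid criteria (default 512).
#' @return A `"roc_curve"` object (see [empirical_roc()]) with
#'   `source = "model"` and a `criterion` column.
#' @examples
#' model_roc(uvsdt_params(1.5, 1.5, c(-1, 0, 1)))
#' @export
model_roc <- function(params, n_grid = 512L) {
  stopifnot(inherits(params, "uvsdt_params"))
  # restrict the sweep to criteria where both rates stay inside
  # [1e-8, 1 - 1e-8]: beyond that the rates are numerically saturated and
  # the curve is indistinguishable from its (0,0)/(1,1) anchors
  zmax <- -stats::qnorm(1e-8)
  lo <- max(-zmax, params$mu - zmax * params$sigma)
  hi <- min(zmax, params$mu + zmax * params$sigma)
  if (lo >= hi) {
    lo <- -zmax
    hi <- zmax
  }
  crit <- params$criteria[params$criteria > lo & params$criteria < hi]
  k <- sort(unique(c(seq(lo, hi, length.out = n_grid), crit)),
            decreasing = TRUE)
  pts <- data.frame(
    fa = stats::pnorm(k, lower.tail = FALSE),
    hit = stats::pnorm((k - params$mu) / params$sigma, lower.tail = FALSE),
    criterion = k
  )
  new_roc_curve(pts, source = "model", n_levels = n_levels(params))
}

#' Model-implied area under the type-1 ROC
#'
#' Numerically integrates the model ROC, `hit(FA)`, over FA in \[0, 1\].
#' Under the bi-Gaussian model this area equals `pnorm(d_a / sqrt(2))`,
#' which provides an internal consistency check on the fitted model.
#'
#' @param params An [uvsdt_params()] object.
#' @param rel_tol Relative tolerance passed to [stats::integrate()].
#' @return The area under the curve, in \[0, 1\].
#' @export
model_auc <- function(params, rel_tol = 1e-10) {
  stopifnot(inherits(params, "uvsdt_params"))
  mu <- params$mu
  sigma <- params$sigma
  f <- function(fa) 1 - stats::pnorm((stats::qnorm(1 - fa) - mu) / sigma)
  stats::integrate(f, 0, 1, rel.tol = rel_tol, abs.tol = rel_tol)$value
}
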