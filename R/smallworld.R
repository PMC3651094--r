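#' Small-world indices
#'
#' \eqn{\gamma = Cp / Cp_{rand}}, \eqn{\lambda = Lp / Lp_{rand}},
#' \eqn{\sigma = \gamma / \lambda}. A network is called small-world when its
#' clustering far exceeds degree-matched nulls (\eqn{\gamma \gg 1}) while
#' its characteristic path length stays comparable (\eqn{\lambda \approx 1}),
#' i.e. \eqn{\sigma > 1}.
#'
#' @param Cp,Cp_rand,Lp,Lp_rand positive reals (observed vs null-mean)
#' @return list with `gamma`, `lam`, `sigma`
#' @export
small_world_indices <- function(Cp, Cp_rand, Lp, Lp_rand) {
  v <- c(Cp = Cp, Cp_rand = Cp_rand, Lp = Lp, Lp_rand = Lp_rand)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all inputs must be positive and finite")
  gamma <- Cp / Cp_rand
  lam <- Lp / Lp_rand
  list(gamma = gamma, lam = lam, sigma = gamma / lam)
}

#' Geometric mean
#'
#' \eqn{\exp(\mathrm{mean}(\ln v))}; the natural average for ratio-type
#' quantities swept across thresholds.
#'
#' @param values positive numeric vector
#' @return geometric mean
#' @export
geometric_mean <- function(values) {
  if (length(values) < 1L) stop("need at least one value")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("geometric mean requires positive finite values")
  exp(mean(log(values)))
}

#' Empirical degree distribution
#'
#' p(k) is the fraction of ALL nodes having degree k, tabulated over the
#' observed degrees k >= 1. Isolated nodes are excluded from the support
#' (log-log fitting needs k >= 1), so the probabilities sum to the fraction
#' of non-isolated nodes.
#'
#' @param degrees integer vector of node degrees
#' @return data.frame with columns `k` and `pk`; zero rows (with a warning)
#'   when every node is isolated
#' @export
degree_distribution <- function(degrees) {
  if (length(degrees) < 1L) stop("need at least one node")
  n <- length(degrees)
  pos <- degrees[degrees >= 1L]
  if (!length(pos)) {
    warning("all nodes are isolated; empty degree distribution")
    return(data.frame(k = integer(), pk = numeric()))
  }
  tab <- table(pos)
  data.frame(k = as.integer(names(tab)), pk = as.numeric(tab) / n)
}

#' Fit a power law to a degree distribution
#'
#' Default method: ordinary least squares of \eqn{\log_{10} p(k)} on
#' \eqn{\log_{10} k} over the observed support (zero-count bins are absent
#' by construction), mirroring the conventional straight-line fit on a
#' log-log plot; the reported `exponent` is the positive decay rate
#' \eqn{\gamma} in \eqn{p(k) \sim c\,k^{-\gamma}} and `prefactor` is c.
#' `method = "mle"` instead maximizes the exact discrete power-law
#' likelihood (zeta-function normalization over k >= k_min), which is
#' statistically preferable and essentially unbiased; OLS remains the
#' default because binned log-log fitting is what the exponent is usually
#' read from, and the two can differ noticeably. In particular the plain
#' OLS estimate is pulled toward shallower slopes by sparsely populated
#' tail bins (where p(k) sits on a flat 1/n floor); `min_count` restricts
#' the fit to bins holding at least that many nodes, the usual remedy when
#' reading an exponent off an empirical log-log plot.
#'
#' @param dist a data.frame from [degree_distribution()], or a raw degree
#'   vector (tabulated internally)
#' @param method `"ols"` (default) or `"mle"`
#' @param min_count OLS only: keep bins with at least this many underlying
#'   nodes (default 1 = all occupied bins); needs the bin node counts, so
#'   values > 1 require raw degrees as input
#' @return object of class `degree_fit`: `exponent`, `prefactor`,
#'   `k_values`, `pk`, `method`
#' @export
fit_power_law <- function(dist, method = c("ols", "mle"), min_count = 1L) {
  method <- match.arg(method)
  degrees <- NULL
  if (!is.data.frame(dist)) {
    degrees <- dist
    dist <- degree_distribution(dist)
  }
  keep <- dist$k >= 1 & dist$pk > 0
  dist <- dist[keep, , drop = FALSE]
  if (method == "ols" && min_count > 1L) {
    if (is.null(degrees)) stop("min_count > 1 requires raw degrees as input")
    cnt <- table(degrees[degrees >= 1L])
    ok <- dist$k %in% as.integer(names(cnt)[cnt >= min_count])
    dist <- dist[ok, , drop = FALSE]
  }
  if (nrow(dist) < 3L) stop("need at least 3 support points with k >= 1")
  if (method == "ols") {
    fit <- stats::lm(log10(pk) ~ log10(k), data = dist)
    co <- stats::coef(fit)
    exponent <- -as.numeric(co[2L])
    prefactor <- 10^as.numeric(co[1L])
  } else {
    # exact discrete MLE: minimize n log Z(a) + a sum(log k), with the
    # normalization Z(a) = sum_{k >= kmin} k^-a evaluated by direct
    # summation plus an integral tail correction
    if (is.null(degrees)) {
      kk <- dist$k
      wt <- dist$pk / sum(dist$pk)
      n <- 1
      slog <- sum(wt * log(kk))
      kmin <- min(kk)
    } else {
      kk <- degrees[degrees >= 1L]
      n <- length(kk)
      slog <- sum(log(kk))
      kmin <- min(kk)
    }
    zeta_from <- function(a, k0) {
      ks <- k0:(k0 + 9999L)
      sum(ks^(-a)) + (k0 + 10000)^(1 - a) / (a - 1)
    }
    nll <- function(a) n * log(zeta_from(a, kmin)) + a * slog
    exponent <- stats::optimize(nll, c(1.05, 20))$minimum
    prefactor <- NA_real_
  }
  structure(list(exponent = exponent, prefactor = prefactor,
                 k_values = dist$k, pk = dist$pk, method = method),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("degree_fit (%s): p(k) ~ c k^-gamma with gamma = %.3f\n",
              x$method, x$exponent))
  invisible(x)
}

#' Hub nodes by the mean-plus-one-SD degree rule
#'
#' Node i is a hub iff \eqn{k_i > \bar{k} + sd(k)} (sample standard
#' deviation over all nodes, isolated nodes included).
#'
#' @param degrees integer vector of node degrees (length >= 2)
#' @return logical vector, TRUE for hubs
#' @export
hub_mask <- function(degrees) {
  if (length(degrees) < 2L) stop("need at least 2 nodes")
  thr <- mean(degrees) + stats::sd(degrees)
  degrees > thr
}
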