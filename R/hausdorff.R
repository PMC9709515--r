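#' Mean-standardize a trait axis
#'
#' Divides a vector by its mean, so the output has mean exactly 1.
#' Applied to the `z`-axis of each landscape before Hausdorff
#' distancing so that traits measured on different scales (days of
#' lifespan vs egg counts) are compared without scale effects.
#'
#' @param z numeric vector with non-zero mean.
#' @return `z / mean(z)`.
#' @examples
#' mean_standardize(c(1, 2, 3))
#' @export
mean_standardize <- function(z) {
  if (!is.numeric(z) || !all(is.finite(z))) stop("z must be finite numeric")
  m <- mean(z)
  if (m == 0)
    stop("degenerate scale: mean of z is zero; mean-standardization undefined")
  z / m
}

.as_pointset <- function(p, arg = "point set") {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 1)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (nrow(p) == 0) stop(arg, " is empty")
  if (!all(is.finite(p))) stop(arg, " contains non-finite coordinates")
  p
}

#' Directed Hausdorff distance between point sets
#'
#' \eqn{\vec d(A, B) = \sup_{a \in A} \inf_{b \in B} \|a - b\|}: the
#' smallest expansion of `B` that swallows every point of `A`. It is
#' asymmetric: for `A = {1, 2}` and `B = {1, 2, 3, 4}`,
#' `d(A, B) = 0` (A is a subset of B) but `d(B, A) = 2`.
#'
#' @param A,B point sets: matrices with one row per point and the same
#'   number of columns, or plain numeric vectors (treated as 1-D
#'   sets). Computed exactly (early-break scan over all pairs).
#' @return Non-negative scalar.
#' @examples
#' directed_hausdorff(c(1, 2), c(1, 2, 3, 4))   # 0
#' directed_hausdorff(c(1, 2, 3, 4), c(1, 2))   # 2
#' @export
directed_hausdorff <- function(A, B) {
  A <- .as_pointset(A, "A"); B <- .as_pointset(B, "B")
  if (ncol(A) != ncol(B))
    stop("dimension mismatch: A has ", ncol(A), " columns, B has ", ncol(B))
  .directed_hausdorff_cpp(A, B)
}

#' Hausdorff distance between landscapes or point sets
#'
#' The symmetric Hausdorff distance
#' \eqn{d_H(S_m, S_n) = \inf\{\epsilon \ge 0 : S_m \subseteq S_n^\epsilon
#' \text{ and } S_n \subseteq S_m^\epsilon\}}, i.e. the maximum of the
#' two directed distances. It is zero iff the two sets coincide, which
#' makes it a genuine metric on landscapes viewed as 3-D point sets
#' and a global measure of how different two performance landscapes
#' are.
#'
#' For two [landscape_grid()]s the grids must share the same `(x, y)`
#' template; each landscape's 3-D points are formed with the nutrient
#' axes min-max standardized to `[0, 1]^2` (so no axis dominates by
#' units) and the `z`-axis mean-standardized per landscape
#' ([mean_standardize()]).
#'
#' @param m,n two landscapes ([landscape_grid()]) or two point sets
#'   (matrices / numeric vectors, compared raw).
#' @param ... unused.
#' @return Non-negative scalar with attribute `"directed"`, the named
#'   vector of the two directed distances.
#' @examples
#' hausdorff_distance(c(1, 2), c(1, 2, 3, 4))   # 2
#' @export
hausdorff_distance <- function(m, n, ...) UseMethod("hausdorff_distance")

#' @export
hausdorff_distance.default <- function(m, n, ...) {
  d_mn <- directed_hausdorff(m, n)
  d_nm <- directed_hausdorff(n, m)
  structure(max(d_mn, d_nm), directed = c(mn = d_mn, nm = d_nm))
}

# shared (x,y) template check + standardized 3-D point clouds
.grid_points3d <- function(m, n) {
  stopifnot(inherits(m, "landscape_grid"), inherits(n, "landscape_grid"))
  if (!identical(m$x, n$x) || !identical(m$y, n$y))
    stop("landscape grids do not share the same (x, y) template; ",
         "re-grid both surfaces with predict_grid() over one domain")
  xy <- expand.grid(x = m$x, y = m$y, KEEP.OUT.ATTRS = FALSE)
  xs <- if (diff(range(xy$x)) > 0) minmax_standardize(xy$x) else xy$x
  ys <- if (diff(range(xy$y)) > 0) minmax_standardize(xy$y) else xy$y
  list(m = cbind(xs, ys, mean_standardize(as.vector(m$z))),
       n = cbind(xs, ys, mean_standardize(as.vector(n$z))))
}

#' @export
hausdorff_distance.landscape_grid <- function(m, n, ...) {
  pts <- .grid_points3d(m, n)
  hausdorff_distance.default(pts$m, pts$n)
}

#' Bootstrap confidence interval for the Hausdorff distance
#'
#' Grid nodes are resampled with replacement — the same node indices
#' applied to both landscapes, preserving their pairing and shared
#' domain — and the Hausdorff distance is recomputed on each resample
#' (via [boot::boot()]). Standardization (nutrient axes to
#' `[0, 1]^2`, `z` by its mean) happens once on the full grids before
#' resampling, so the resampled statistic is a pure function of the
#' node subset.
#'
#' @inheritParams hausdorff_distance
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed (required; resampling is random).
#' @return A `hausdorff_result`: list with the full-grid point
#'   estimate `d_H`, its `directed` components, bootstrap `mean`,
#'   `sd`, percentile `lwr95`/`upr95`, `n_boot`, `seed`, and the
#'   vector of resampled distances `t`.
#' @examples
#' flat <- canonical_flat(n = 11)
#' saddle <- canonical_saddle(n = 11)
#' hausdorff_bootstrap(flat, saddle, n_boot = 50, seed = 1)
#' @export
hausdorff_bootstrap <- function(m, n, n_boot = 1000, seed) {
  if (missing(seed)) stop("seed is required: bootstrap resampling is random")
  stopifnot(is.numeric(n_boot), length(n_boot) == 1, n_boot >= 2)
  pts <- .grid_points3d(m, n)
  point <- hausdorff_distance.default(pts$m, pts$n)
  stat <- function(data, idx) {
    a <- pts$m[idx, , drop = FALSE]
    b <- pts$n[idx, , drop = FALSE]
    max(directed_hausdorff(a, b), directed_hausdorff(b, a))
  }
  set.seed(as.integer(seed))
  bt <- boot::boot(data = seq_len(nrow(pts$m)), statistic = stat, R = n_boot)
  t <- as.vector(bt$t)
  structure(
    list(d_H = as.numeric(point), directed = attr(point, "directed"),
         mean = mean(t), sd = sd(t),
         lwr95 = as.numeric(quantile(t, 0.025, names = FALSE)),
         upr95 = as.numeric(quantile(t, 0.975, names = FALSE)),
         n_boot = n_boot, seed = as.integer(seed), t = t,
         comparison = paste(m$trait, n$trait, sep = "-")),
    class = "hausdorff_result"
  )
}

#' @export
print.hausdorff_result <- function(x, ...) {
  cat(sprintf(paste0("<hausdorff_result> %s\n",
                     "  d_H = %.4g (directed %.4g / %.4g)\n",
                     "  bootstrap (n = %d): mean %.4g, sd %.4g, ",
                     "95%% CI [%.4g, %.4g]\n"),
              x$comparison, x$d_H, x$directed[["mn"]], x$directed[["nm"]],
              x$n_boot, x$mean, x$sd, x$lwr95, x$upr95))
  invisible(x)
}
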