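#' Min-max standardization to the unit interval
#'
#' `(v - min(v)) / (max(v) - min(v))`. Used to put the nutrient axes
#' of different experiments on the common domain `[0, 1]^2` so that
#' landscapes are comparable.
#'
#' @param values numeric vector with at least two distinct finite
#'   values.
#' @return Numeric vector in `[0, 1]`; the minimum maps to 0, the
#'   maximum to 1, order is preserved.
#' @examples
#' minmax_standardize(c(2, 4, 6))
#' @export
minmax_standardize <- function(values) {
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("values must be finite numeric")
  rng <- range(values)
  if (diff(rng) == 0)
    stop("degenerate scale: all values are equal (", rng[1],
         "); min-max standardization undefined")
  (values - rng[1]) / diff(rng)
}

#' A nutrient-intake domain
#'
#' The rectangle `[0, x_max] x [0, y_max]` over which a landscape is
#' evaluated: from zero to the maximum protein (`x`) and carbohydrate
#' (`y`) intakes. All landscapes compared with each other must share
#' one domain.
#'
#' @param x_max,y_max positive upper intake limits.
#' @return An object of class `nutrient_domain`: a named numeric
#'   vector `c(x_max, y_max)`.
#' @examples
#' nutrient_domain(1, 1)
#' @export
nutrient_domain <- function(x_max = 1, y_max = 1) {
  if (!is.numeric(x_max) || !is.numeric(y_max) ||
      length(x_max) != 1 || length(y_max) != 1 ||
      !is.finite(x_max) || !is.finite(y_max) || x_max <= 0 || y_max <= 0)
    stop("domain limits must be positive finite scalars")
  structure(c(x_max = x_max, y_max = y_max), class = "nutrient_domain")
}

.as_domain <- function(domain) {
  if (inherits(domain, "nutrient_domain")) return(domain)
  if (is.numeric(domain) && length(domain) == 2)
    return(nutrient_domain(domain[[1]], domain[[2]]))
  stop("domain must be a nutrient_domain() or a length-2 numeric ",
       "c(x_max, y_max)")
}

#' Fit the quadratic landscape model to GF data
#'
#' Ordinary-least-squares fit of
#' \eqn{z = a x^2 + b y^2 + c x + d y + e x y + z_0}
#' for one performance trait, the response-surface model whose closed
#' form makes curvature and surface-area computations analytic. An
#' intercept is included: it shifts the landscape height only and has
#' no effect on gradients, curvature or area.
#'
#' @param data a data frame with numeric columns `x` (protein intake),
#'   `y` (carbohydrate intake) and one column per trait, e.g. from
#'   [read_nutritional_data()] or [simulate_gf_experiment()].
#' @param trait name of the trait column to fit.
#' @return A [quadratic_surface()] with the fitted coefficients, plus
#'   `$trait` and `$fit` (the underlying `lm` object, so residuals and
#'   standard errors remain available).
#' @examples
#' d <- expand.grid(x = 0:4, y = 0:4)
#' d$size <- d$x * d$y            # a pure saddle
#' fit_quadratic(d, "size")$coefficients
#' @export
fit_quadratic <- function(data, trait) {
  stopifnot(is.data.frame(data))
  if (!all(c("x", "y") %in% names(data)))
    stop("data must contain columns 'x' and 'y'")
  if (!trait %in% names(data)) stop("no trait column '", trait, "' in data")
  df <- data.frame(x = data$x, y = data$y, z = data[[trait]])
  if (!all(vapply(df, is.numeric, logical(1))) || !all(is.finite(as.matrix(df))))
    stop("x, y and trait values must be finite numeric")
  if (nrow(df) < 6)
    stop("need at least 6 records to identify the 6 quadratic ",
         "coefficients; got ", nrow(df))
  fit <- lm(z ~ I(x^2) + I(y^2) + x + y + I(x * y), data = df,
            singular.ok = TRUE)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("singular design: collinear columns ",
         paste(names(cf)[is.na(cf)], collapse = ", "),
         "; the diets do not span the quadratic model")
  s <- quadratic_surface(a = cf[["I(x^2)"]], b = cf[["I(y^2)"]],
                         c = cf[["x"]], d = cf[["y"]],
                         e = cf[["I(x * y)"]],
                         intercept = cf[["(Intercept)"]])
  s$trait <- trait
  s$fit <- fit
  s
}

#' Build the prediction grid for a landscape
#'
#' Evaluates a surface on a square, axis-aligned `n x n` grid from 0
#' to the maximum intakes. Every trait of an experiment is predicted
#' on the *same* `(x, y)` template so that curvature fields, areas and
#' Hausdorff distances are computed over coinciding domains.
#'
#' @param surface a [surface_patch()] (typically a fitted
#'   [quadratic_surface()]).
#' @param domain a [nutrient_domain()] or `c(x_max, y_max)`.
#' @param n nodes per axis (default 101; both endpoints included).
#' @param trait optional trait label; defaults to the surface's.
#' @return A `landscape_grid`: a list with axis vectors `x`, `y`
#'   (length `n`, spanning `[0, max]`), the `n x n` height matrix `z`
#'   (`z[i, j]` at `(x[i], y[j])`), the generating `surface`, and
#'   `trait`. `as.data.frame()` yields long format, `x` varying
#'   fastest.
#' @examples
#' g <- predict_grid(quadratic_surface(e = 1), c(1, 1), n = 3)
#' g$z                       # z = xy on the 3 x 3 grid
#' @export
predict_grid <- function(surface, domain, n = 101, trait = NULL) {
  stopifnot(inherits(surface, "surface_patch"))
  domain <- .as_domain(domain)
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n))
    stop("n must be an integer >= 2")
  xs <- seq(0, domain[["x_max"]], length.out = n)
  ys <- seq(0, domain[["y_max"]], length.out = n)
  z <- outer(xs, ys, surface$height)
  if (!all(is.finite(z))) stop("surface is non-finite on the grid")
  structure(
    list(x = xs, y = ys, z = z, surface = surface,
         trait = trait %||% surface$trait %||% surface$name,
         domain = domain),
    class = "landscape_grid"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> '%s': %d x %d nodes on [0, %g] x [0, %g]\n",
              x$trait, length(x$x), length(x$y),
              max(x$x), max(x$y)))
  invisible(x)
}

#' @export
as.data.frame.landscape_grid <- function(x, ...) {
  out <- expand.grid(x = x$x, y = x$y, KEEP.OUT.ATTRS = FALSE)
  out$z <- as.vector(x$z)
  out
}

#' Root-mean-square error
#'
#' \eqn{\sqrt{\mathrm{mean}((\hat z - z)^2)}}, the model-performance
#' measure used to compare landscape fits. The mean (rather than sum)
#' convention keeps the statistic comparable across sample sizes;
#' at fixed `n` the two differ by a constant factor only, so model
#' rankings are unaffected.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return Non-negative scalar.
#' @examples
#' rmse(c(3, 4), c(0, 0))   # sqrt(25 / 2)
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed lengths differ (",
         length(predicted), " vs ", length(observed), ")")
  if (length(predicted) == 0) stop("empty vectors")
  sqrt(mean((predicted - observed)^2))
}

# cap a smoother basis dimension by the covariate's unique-value count
.cap_k <- function(v, kmax) max(3, min(kmax, length(unique(v)) - 1))

#' Benchmark the quadratic model against spline smoothers
#'
#' Checks the quadratic-landscape assumption: the data are split once
#' into training and testing sets (default 60/40), bootstrap resamples
#' are drawn from the training set, and on each resample three models
#' are fitted: (i) the quadratic linear model of [fit_quadratic()],
#' (ii) an additive smoother `z ~ s(x) + s(y)`, and (iii) a thin-plate
#' spline `z ~ s(x, y)` (both via [mgcv::gam()] with default
#' smoothness selection). Train RMSE is evaluated on the resample,
#' test RMSE on the held-out set. If the quadratic model's test error
#' tracks the smoothers', the landscape is adequately described by the
#' closed-form polynomial.
#'
#' @inheritParams fit_quadratic
#' @param split training fraction (default 0.6).
#' @param n_resamples bootstrap resamples of the training set
#'   (default 200).
#' @param seed integer seed; the split and every resample are
#'   deterministic given the seed.
#' @return A `model_comparison`: a data frame with columns `model`,
#'   `trait`, `resample`, `rmse_train`, `rmse_test`. Attributes record
#'   `seed`, `split`, `n_resamples`, the mgcv version, and any
#'   `warnings` from smoother fits that failed (those resamples carry
#'   `NA` rather than being dropped silently).
#' @examples
#' d <- simulate_gf_experiment(gf_design(
#'   true_surface = list(size = quadratic_surface(-1, -1, 2, 2, 0.5)),
#'   noise_sd = c(size = 0.1), seed = 1))
#' cmp <- compare_models(d, "size", n_resamples = 10, seed = 42)
#' aggregate(cbind(rmse_train, rmse_test) ~ model, cmp, median)
#' @export
compare_models <- function(data, trait, split = 0.6, n_resamples = 200,
                           seed) {
  stopifnot(is.data.frame(data), split > 0, split < 1, n_resamples >= 1)
  if (missing(seed)) stop("seed is required: the split and resamples are random")
  df <- data.frame(x = data$x, y = data$y, z = data[[trait]])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  set.seed(as.integer(seed))
  n <- nrow(df)
  idx_train <- sort(sample.int(n, size = round(split * n)))
  train <- df[idx_train, , drop = FALSE]
  test <- df[-idx_train, , drop = FALSE]
  if (nrow(train) < 6) stop("training set too small for a full-rank quadratic fit")

  models <- c("quadratic-LM", "additive-smoother", "thin-plate-spline")
  res <- vector("list", n_resamples * length(models))
  warns <- character(0)
  row <- 0L
  for (b in seq_len(n_resamples)) {
    boot_idx <- sample.int(nrow(train), replace = TRUE)
    tr <- train[boot_idx, , drop = FALSE]
    fits <- list(
      `quadratic-LM` = function()
        lm(z ~ I(x^2) + I(y^2) + x + y + I(x * y), data = tr),
      `additive-smoother` = function()
        mgcv::gam(z ~ s(x, k = .cap_k(tr$x, 10)) + s(y, k = .cap_k(tr$y, 10)),
                  data = tr),
      `thin-plate-spline` = function()
        mgcv::gam(z ~ s(x, y, k = .cap_k(paste(tr$x, tr$y), 30)), data = tr)
    )
    for (m in models) {
      row <- row + 1L
      rt <- tryCatch({
        fit <- fits[[m]]()
        c(rmse(predict(fit, tr), tr$z), rmse(predict(fit, test), test$z))
      }, error = function(e) {
        warns <<- c(warns, sprintf("resample %d, %s: %s", b, m,
                                   conditionMessage(e)))
        c(NA_real_, NA_real_)
      })
      res[[row]] <- data.frame(model = m, trait = trait, resample = b,
                               rmse_train = rt[1], rmse_test = rt[2],
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "split") <- split
  attr(out, "n_resamples") <- n_resamples
  attr(out, "backend") <- c(mgcv = as.character(packageVersion("mgcv")))
  attr(out, "warnings") <- warns
  if (length(warns))
    warning(length(warns), " smoother fit(s) failed; see attr(, 'warnings')")
  class(out) <- c("model_comparison", class(out))
  out
}
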