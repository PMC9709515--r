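#' Canonical validation landscapes
#'
#' The two reference landscapes used to validate the toolchain:
#' the flat landscape `(x, y, 1)` (constant height; both curvatures
#' zero everywhere, surface-area ratio exactly 1) and the saddle
#' `(x, y, xy)` (Gauss curvature -1 at the origin, mean curvature 0
#' there, and a quadrant-antisymmetric mean-curvature field).
#'
#' @param domain a [nutrient_domain()] or `c(x_max, y_max)`
#'   (default the unit square).
#' @param n nodes per axis (default 101).
#' @return A [landscape_grid()] carrying its generating
#'   [quadratic_surface()].
#' @examples
#' area_ratio(canonical_flat(n = 11))$ratio
#' curvature_field(grid = canonical_saddle(n = 11))[1, ]
#' @export
canonical_flat <- function(domain = c(1, 1), n = 101) {
  predict_grid(quadratic_surface(intercept = 1), domain, n, trait = "flat")
}

#' @rdname canonical_flat
#' @export
canonical_saddle <- function(domain = c(1, 1), n = 101) {
  predict_grid(quadratic_surface(e = 1), domain, n, trait = "saddle")
}

#' Design of a simulated geometric-framework experiment
#'
#' Real GF experiments explore the nutrient plane along *rails* —
#' lines of fixed protein:carbohydrate ratio — with diets of several
#' dilutions (total intake levels) on each rail and several animals
#' per diet. This constructor records such a layout together with the
#' true quadratic landscape and noise level of each simulated trait.
#'
#' Defaults mirror a classic fly GF layout: six rails from P:C 1:16 to
#' 2:1, four dilutions spanning an eight-fold intake range, five
#' replicates per diet. Intakes get multiplicative log-normal jitter
#' (sd 0.1 on the log scale) around their rail targets, mimicking the
#' scatter of realized intakes around target diets.
#'
#' @param rails numeric vector of P:C ratios, one per rail.
#' @param dilutions numeric vector of total-intake levels (x + y).
#' @param replicates animals per diet (>= 1).
#' @param true_surface named list of [quadratic_surface()]s, one per
#'   simulated trait.
#' @param noise_sd named numeric vector of additive Gaussian trait
#'   noise sds (same names as `true_surface`); 0 allowed.
#' @param jitter_sd sd of the log-normal intake jitter (0 = diets
#'   exactly on the rails).
#' @param seed integer seed (required; simulation is random).
#' @return An object of class `gf_design`.
#' @examples
#' d <- gf_design(true_surface = list(lifespan =
#'         quadratic_surface(-2e-4, -1e-4, 0.1, 0.08, 2e-4, 20)),
#'      noise_sd = c(lifespan = 2), seed = 7)
#' head(simulate_gf_experiment(d))
#' @export
gf_design <- function(rails = c(1 / 16, 1 / 8, 1 / 4, 1 / 2, 1, 2),
                      dilutions = c(30, 60, 120, 240),
                      replicates = 5,
                      true_surface,
                      noise_sd,
                      jitter_sd = 0.1,
                      seed) {
  if (length(rails) == 0) stop("empty rails: need at least one P:C ratio")
  stopifnot(all(rails > 0), all(dilutions > 0),
            length(dilutions) >= 1, replicates >= 1,
            is.numeric(jitter_sd), jitter_sd >= 0)
  if (missing(seed)) stop("seed is required")
  if (!is.list(true_surface) || is.null(names(true_surface)) ||
      !all(vapply(true_surface, inherits, logical(1), "quadratic_surface")))
    stop("true_surface must be a named list of quadratic_surface objects")
  if (!all(names(true_surface) %in% names(noise_sd)))
    stop("noise_sd must name every trait in true_surface")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  structure(
    list(rails = rails, dilutions = dilutions, replicates = replicates,
         true_surface = true_surface,
         noise_sd = noise_sd[names(true_surface)],
         jitter_sd = jitter_sd, seed = as.integer(seed)),
    class = "gf_design"
  )
}

#' @export
print.gf_design <- function(x, ...) {
  cat(sprintf(paste0("<gf_design> %d rails x %d dilutions x %d replicates ",
                     "(%d animals), traits: %s\n"),
              length(x$rails), length(x$dilutions), x$replicates,
              length(x$rails) * length(x$dilutions) * x$replicates,
              paste(names(x$true_surface), collapse = ", ")))
  invisible(x)
}

#' Simulate a geometric-framework experiment
#'
#' Places one animal per replicate on each rail-by-dilution diet. A
#' diet on rail `r` (P:C ratio) at dilution `t` targets intakes
#' `x = t r / (1 + r)`, `y = t / (1 + r)`; realized intakes multiply
#' the targets by independent log-normal jitter. Each trait is the
#' true quadratic landscape evaluated at the realized intakes plus
#' additive Gaussian noise. Deterministic given the design's seed.
#'
#' @param design a [gf_design()].
#' @return A data frame of class `nutritional_dataset`: columns
#'   `rail`, `dilution`, `x`, `y`, then one column per trait.
#' @export
simulate_gf_experiment <- function(design) {
  stopifnot(inherits(design, "gf_design"))
  set.seed(design$seed)
  diets <- expand.grid(rail = design$rails, dilution = design$dilutions,
                       rep = seq_len(design$replicates),
                       KEEP.OUT.ATTRS = FALSE)
  x0 <- diets$dilution * diets$rail / (1 + diets$rail)
  y0 <- diets$dilution / (1 + diets$rail)
  m <- nrow(diets)
  x <- x0 * exp(rnorm(m, 0, design$jitter_sd))
  y <- y0 * exp(rnorm(m, 0, design$jitter_sd))
  out <- data.frame(rail = diets$rail, dilution = diets$dilution,
                    x = x, y = y)
  for (trait in names(design$true_surface)) {
    s <- design$true_surface[[trait]]
    out[[trait]] <- s$height(x, y) + rnorm(m, 0, design$noise_sd[[trait]])
  }
  class(out) <- c("nutritional_dataset", class(out))
  out
}
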