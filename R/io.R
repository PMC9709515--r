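#' Read a GF dataset from CSV
#'
#' Expects a header row with columns `x` (protein intake), `y`
#' (carbohydrate intake) and at least one trait column. Rows with
#' missing or non-finite values in `x`, `y` or a requested trait are
#' dropped, with the count reported via `message()`.
#'
#' @param path CSV file path.
#' @param traits character vector of trait columns to keep; `NULL`
#'   (default) keeps every non-coordinate column.
#' @return A data frame of class `nutritional_dataset` with columns
#'   `x`, `y` and the traits.
#' @export
read_nutritional_data <- function(path, traits = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, header = TRUE)
  missing_cols <- setdiff(c("x", "y"), names(raw))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(traits)) traits <- setdiff(names(raw),
                                         c("x", "y", "rail", "dilution"))
  missing_tr <- setdiff(traits, names(raw))
  if (length(missing_tr))
    stop("schema error: missing trait column(s): ",
         paste(missing_tr, collapse = ", "))
  if (length(traits) == 0) stop("no trait columns found")
  keep <- c("x", "y", traits)
  df <- raw[keep]
  for (cl in keep) df[[cl]] <- as.numeric(df[[cl]])
  ok <- rowSums(!is.finite(as.matrix(df))) == 0
  dropped <- sum(!ok)
  if (dropped > 0)
    message("dropped ", dropped, " row(s) with missing/non-finite values")
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop("no usable rows after filtering")
  if (any(df$x < 0) || any(df$y < 0))
    stop("negative nutrient intakes in x/y; intakes must be >= 0")
  rownames(df) <- NULL
  class(df) <- c("nutritional_dataset", class(df))
  df
}

#' Export a curvature field as CSV
#'
#' Long-format CSV with columns `x`, `y`, `z`, `K`, `H`,
#' `region_class`, one row per grid node.
#'
#' @param field a [curvature_field()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curvature_field <- function(field, path) {
  stopifnot(inherits(field, "curvature_field"))
  write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}

#' Run the full landscape-characterization pipeline
#'
#' For each requested trait: fit the quadratic landscape
#' ([fit_quadratic()]), predict it on a shared grid over
#' `[0, x_max] x [0, y_max]` ([predict_grid()]), compute its curvature
#' field and surface-area ratio. A flat reference landscape
#' `(x, y, 1)` is added on the same grid (the constant is arbitrary:
#' it affects neither curvature nor area, and mean-standardization
#' removes it from Hausdorff distances). Hausdorff distances with
#' bootstrap CIs are computed for every trait against the flat
#' landscape and for every trait pair.
#'
#' @param data a `nutritional_dataset` (or data frame with columns
#'   `x`, `y`, traits), or a CSV path passed to
#'   [read_nutritional_data()].
#' @param traits trait columns to analyse; default all.
#' @param n grid nodes per axis (default 101).
#' @param domain landscape domain; default `[0, max(x)] x [0, max(y)]`
#'   of the data.
#' @param class_tol zero-curvature classification tolerance.
#' @param area_tol quadrature tolerance for surface areas.
#' @param n_boot Hausdorff bootstrap resamples (default 1000).
#' @param seed integer seed (required).
#' @param out_dir if non-`NULL`, reports are written there:
#'   `coefficients.csv`, `curvature_<trait>.csv`, `area.csv`,
#'   `hausdorff.csv` and `manifest.json`.
#' @return Invisibly, a list with elements `surfaces`, `grids`,
#'   `curvature`, `area` (data frame), `hausdorff` (data frame shaped
#'   like a pairwise comparison table: comparison, point estimate,
#'   bootstrap mean, sd, 95% CI), and `manifest`.
#' @examples
#' d <- simulate_gf_experiment(gf_design(
#'   true_surface = list(size = quadratic_surface(-1, -1, 2, 2, 0.5)),
#'   noise_sd = c(size = 0.1), seed = 1))
#' res <- run_pipeline(d, n = 21, n_boot = 50, seed = 2)
#' res$area
#' @export
run_pipeline <- function(data, traits = NULL, n = 101, domain = NULL,
                         class_tol = 1e-8, area_tol = 1e-8,
                         n_boot = 1000, seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is required")
  if (is.character(data)) data <- read_nutritional_data(data, traits)
  stopifnot(is.data.frame(data))
  if (is.null(traits))
    traits <- setdiff(names(data), c("x", "y", "rail", "dilution"))
  if (length(traits) == 0) stop("stage 'fit': no trait columns")
  if (is.null(domain)) domain <- nutrient_domain(max(data$x), max(data$y))
  domain <- .as_domain(domain)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  surfaces <- stage("fit", lapply(setNames(traits, traits),
                                  function(tr) fit_quadratic(data, tr)))
  grids <- stage("grid", lapply(surfaces, predict_grid,
                                domain = domain, n = n))
  flat <- predict_grid(quadratic_surface(intercept = 1), domain, n,
                       trait = "flat")
  curvature <- stage("curvature",
                     lapply(grids, function(g)
                       curvature_field(grid = g, tol = class_tol)))
  area <- stage("area", do.call(rbind, lapply(grids, function(g) {
    r <- area_ratio(g, tol = area_tol)
    data.frame(trait = g$trait, domain_x_max = r$domain[["x_max"]],
               domain_y_max = r$domain[["y_max"]], area = r$area,
               flat_area = r$flat_area, ratio = r$ratio, tol = area_tol)
  })))
  rownames(area) <- NULL

  pairs <- c(lapply(traits, function(tr) c(tr, "flat")),
             if (length(traits) >= 2) utils::combn(traits, 2, simplify = FALSE))
  all_grids <- c(grids, list(flat = flat))
  seeds <- seed + seq_along(pairs)
  hd <- stage("hausdorff", do.call(rbind, lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    h <- hausdorff_bootstrap(all_grids[[pr[1]]], all_grids[[pr[2]]],
                             n_boot = n_boot, seed = seeds[i])
    data.frame(comparison = paste(pr, collapse = "-"),
               d_H = h$d_H, mean = h$mean, sd = h$sd,
               lwr95 = h$lwr95, upr95 = h$upr95, n_boot = n_boot)
  })))

  manifest <- list(
    package = as.character(packageVersion("nutrigeom")),
    r_version = as.character(getRversion()),
    n_records = nrow(data), traits = traits,
    grid_n = n, domain = as.list(unclass(domain)),
    class_tol = class_tol, area_tol = area_tol,
    n_boot = n_boot, seed = as.integer(seed)
  )

  res <- list(surfaces = surfaces, grids = grids, flat = flat,
              curvature = curvature, area = area, hausdorff = hd,
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    coefs <- do.call(rbind, lapply(traits, function(tr)
      data.frame(trait = tr, t(surfaces[[tr]]$coefficients))))
    write.csv(coefs, file.path(out_dir, "coefficients.csv"),
              row.names = FALSE)
    for (tr in traits)
      write_curvature_field(curvature[[tr]],
                            file.path(out_dir,
                                      paste0("curvature_", tr, ".csv")))
    write.csv(area, file.path(out_dir, "area.csv"), row.names = FALSE)
    write.csv(hd, file.path(out_dir, "hausdorff.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(res)
}
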