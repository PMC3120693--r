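#' Fano factor of a sample
#'
#' Variance divided by mean, the standard measure of count (or intensity)
#' dispersion: 1 for a Poisson process, larger for super-Poissonian noise.
#' The sample variance uses the n - 1 denominator.
#'
#' @param values numeric vector of at least two non-negative values with a
#'   positive mean.
#' @return the Fano factor, in the units of `values`.
#' @examples
#' fano(rpois(1000, 10))  # ~1
#' @export
fano <- function(values) {
  if (length(values) < 2L) stop("fano needs at least two values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("fano is undefined for mean <= 0")
  stats::var(values) / m
}

#' Fano factor from summary statistics
#'
#' @param mean,sd sample mean and standard deviation.
#' @return `sd^2 / mean` (vectorised).
#' @export
fano_from_summary <- function(mean, sd) {
  if (any(mean <= 0)) stop("fano is undefined for mean <= 0")
  sd^2 / mean
}

#' Means normalised by the largest mean
#'
#' @param means positive numeric vector (or a list of summaries carrying a
#'   `mean` column).
#' @return dimensionless vector in (0, 1]; the maximum maps to exactly 1.
#' @export
relative_means <- function(means) {
  if (is.data.frame(means)) means <- means$mean
  if (!length(means)) stop("no means supplied")
  if (any(means <= 0)) stop("means must be positive")
  means / max(means)
}

#' Binned probability distribution
#'
#' Bins values into half-open bins [lo, hi) (the last bin is closed) and
#' returns the fraction of values per bin, i.e. probabilities that sum
#' to 1.
#'
#' @param values numeric vector (at least one value).
#' @param bins either a single bin count (equal-width bins spanning the
#'   data range) or a vector of bin edges.
#' @return a `binned_distribution`: list with `edges` and `probability`.
#' @export
bin_distribution <- function(values, bins = 30) {
  if (!length(values)) stop("no values to bin")
  edges <- if (length(bins) == 1L) {
    rng <- range(values)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    seq(rng[1], rng[2], length.out = bins + 1L)
  } else sort(bins)
  inside <- values >= edges[1] & values <= edges[length(edges)]
  if (!any(inside)) stop("all values fall outside the bin edges")
  v <- values[inside]
  idx <- findInterval(v, edges, rightmost.closed = TRUE, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(edges = edges, probability = counts / sum(counts)),
            class = "binned_distribution")
}

#' Squared-difference distance between Fano-factor vectors
#'
#' The fit distance D between the measured and modelled Fano factors,
#' summed over induction conditions: D = sum_i (Fano(E)_i - Fano(M)_i)^2.
#'
#' @param fano_measured,fano_model equal-length numeric vectors.
#' @return the scalar distance D (>= 0).
#' @export
fit_distance_D <- function(fano_measured, fano_model) {
  if (length(fano_measured) != length(fano_model))
    stop("Fano vectors must have equal length")
  if (!length(fano_measured)) stop("empty Fano vectors")
  sum((fano_measured - fano_model)^2)
}

#' Fluorescence-per-protein calibration factor
#'
#' Measurements report arbitrary fluorescence units while the model counts
#' molecules; Fano factors scale linearly under multiplication, so a single
#' conversion factor phi (a.u. per GFP molecule) links the two. phi is the
#' least-squares proportionality constant through the origin:
#' phi = sum(measured * model) / sum(model^2). A per-condition phi would
#' trivially equalise the means; physically the factor is a fixed optical
#' property, and the spread of the per-condition ratios (see
#' [calibration_ratios()]) checks that assumption.
#'
#' @param measured_means positive vector of measured means (a.u.).
#' @param model_means positive vector of model means (molecules), same
#'   length.
#' @return phi in a.u. per molecule.
#' @export
calibration_factor <- function(measured_means, model_means) {
  if (length(measured_means) != length(model_means))
    stop("mean vectors must have equal length")
  if (any(measured_means <= 0) || any(model_means <= 0))
    stop("means must be positive")
  sum(measured_means * model_means) / sum(model_means^2)
}

#' @rdname calibration_factor
#' @return `calibration_ratios` returns the per-condition ratios
#'   measured/model, whose coefficient of variation should be small if a
#'   single phi is adequate.
#' @export
calibration_ratios <- function(measured_means, model_means) {
  if (any(measured_means <= 0) || any(model_means <= 0))
    stop("means must be positive")
  measured_means / model_means
}

#' Summarise per-cell values into population statistics
#'
#' @param values per-cell values (counts or intensities).
#' @param condition condition label.
#' @return one-row data.frame: `condition`, `n_cells`, `mean`, `sd`,
#'   `fano`.
#' @export
summarize_population <- function(values, condition = NA) {
  data.frame(condition = condition, n_cells = length(values),
             mean = mean(values), sd = stats::sd(values),
             fano = fano(values))
}

#' Combine condition summaries and add relative means
#'
#' @param summaries list of one-row summaries from
#'   [summarize_population()], or a data.frame of them.
#' @return data.frame with an added `relative_mean` column (max = 1),
#'   in the input order.
#' @export
summarize_conditions <- function(summaries) {
  df <- if (is.data.frame(summaries)) summaries else do.call(rbind, summaries)
  df$relative_mean <- relative_means(df$mean)
  rownames(df) <- NULL
  df
}

#' Bundled single-cell GFP measurement summary
#'
#' Per-condition summary statistics (cell count, mean and standard
#' deviation of total GFP fluorescence in arbitrary units) of the
#' single-cell measurements of the tet-inducible GFP reporter at five aTc
#' induction levels, shipped with the package as the measured reference for
#' model fitting. Fano factors and relative means are recomputed from the
#' mean/SD columns.
#'
#' @return data.frame with columns `aTc_ng_ml`, `n_cells`, `mean`, `sd`,
#'   `fano`, `relative_mean`.
#' @export
measured_gfp_summary <- function() {
  path <- system.file("extdata", "measured_gfp_summary.csv",
                      package = "tetnoise", mustWork = TRUE)
  df <- utils::read.csv(path)
  df$fano <- fano_from_summary(df$mean, df$sd)
  df$relative_mean <- relative_means(df$mean)
  df
}
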