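#' 2x2 lower-median filter
#'
#' Even-window median filtering used to remove single-pixel noise spikes
#' before projection. The window is anchored top-left: output(i, j) is the
#' lower median (second-smallest) of the 2x2 neighbourhood
#' \{(i, j), (i+1, j), (i, j+1), (i+1, j+1)\}, with edge rows/columns
#' replicated. The lower-median convention makes the even-sized window
#' deterministic and suppresses isolated hot pixels exactly.
#'
#' @param x numeric matrix.
#' @return filtered matrix of the same dimensions.
#' @export
median_filter_2x2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  rs <- if (h > 1L) c(2:h, h) else 1L
  cs <- if (w > 1L) c(2:w, w) else 1L
  a <- x
  b <- x[rs, , drop = FALSE]
  cc <- x[, cs, drop = FALSE]
  d <- x[rs, cs, drop = FALSE]
  m1 <- pmin(a, b); M1 <- pmax(a, b)
  m2 <- pmin(cc, d); M2 <- pmax(cc, d)
  out <- pmin(pmax(m1, m2), pmin(M1, M2))   # 2nd-smallest of the four
  dim(out) <- c(h, w)
  out
}

#' Median-filter a z-stack and form its sum projection
#'
#' Each slice is filtered with [median_filter_2x2()]; `i_sum` is the
#' pixelwise sum of the filtered slices and is the image used for
#' segmentation (cells are visible in it regardless of which slice is in
#' focus).
#'
#' @param stack 3-D array, height x width x slices (at least one slice).
#' @return list with `filtered` (array like `stack`) and `i_sum` (matrix).
#' @export
preprocess_stack <- function(stack) {
  if (length(dim(stack)) != 3L || dim(stack)[3] < 1L)
    stop("stack must be a height x width x slices array with >= 1 slice")
  filtered <- stack
  for (s in seq_len(dim(stack)[3]))
    filtered[, , s] <- median_filter_2x2(stack[, , s])
  list(filtered = filtered, i_sum = rowSums(filtered, dims = 2L))
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so components
# touching only diagonally are merged afterwards.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  if (max(lab) < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(max(lab))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_along(parent), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  relabel(lab)
}

relabel <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

# replace isolated hot pixels by their 3x3 neighbourhood median; unlike a
# median filter this leaves diffraction-limited spot integrals intact
despike <- function(x) {
  mx <- max(x)
  if (mx <= 0) return(x)
  med <- as.matrix(EBImage::medianFilter(EBImage::Image(x / mx), size = 1)) * mx
  spike <- x > med + 8 * sqrt(pmax(med, 1))
  x[spike] <- med[spike]
  x
}

# extended-maxima seeds of one cluster: local maxima of the smoothed
# intensity at least h above the segmentation threshold (h a fraction of
# the cluster's dynamic range), strongest first, mutually >= 5 px apart,
# at most k of them
cluster_seeds <- function(smooth, rows, cols, k, threshold, h_frac) {
  v <- smooth[cbind(rows, cols)]
  hmin <- threshold + h_frac * (max(v) - threshold)
  sub <- matrix(-Inf, nrow(smooth), ncol(smooth))
  sub[cbind(rows, cols)] <- v
  is_max <- vapply(seq_along(rows), function(i) {
    r <- rows[i]; c <- cols[i]
    v[i] >= max(sub[max(1, r - 1):min(nrow(sub), r + 1),
                    max(1, c - 1):min(ncol(sub), c + 1)]) && v[i] >= hmin
  }, logical(1))
  cand <- order(v, decreasing = TRUE)
  cand <- cand[is_max[cand]]
  seeds <- matrix(numeric(0), 0, 2)
  for (i in cand) {
    p <- c(rows[i], cols[i])
    if (!nrow(seeds) ||
        all((seeds[, 1] - p[1])^2 + (seeds[, 2] - p[2])^2 >= 25))
      seeds <- rbind(seeds, p)
    if (nrow(seeds) == k) break
  }
  seeds
}

# solidity = pixel area / area of the convex hull of the pixel squares
object_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2L) return(1)
  pts <- cbind(c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5),
               c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5))
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  k <- nrow(hp)
  area <- abs(sum(hp[, 1] * hp[c(2:k, 1), 2] - hp[c(2:k, 1), 1] * hp[, 2])) / 2
  min(1, n / area)
}

# moment eccentricity of the equivalent second-moment ellipse
object_eccentricity <- function(rows, cols) {
  if (length(rows) <= 1L) return(0)
  mrr <- stats::var(rows) * (length(rows) - 1) / length(rows) + 1 / 12
  mcc <- stats::var(cols) * (length(cols) - 1) / length(cols) + 1 / 12
  mrc <- stats::cov(rows, cols) * (length(rows) - 1) / length(rows)
  common <- sqrt(((mrr - mcc) / 2)^2 + mrc^2)
  l1 <- (mrr + mcc) / 2 + common
  l2 <- (mrr + mcc) / 2 - common
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

#' Segment cells from a sum-projection image
#'
#' Pipeline: (1) threshold `i_sum` with a permissively small value (by
#' default a fraction of Otsu's threshold, so dim cells survive);
#' (2) morphological opening with a disk of the given radius to drop noise
#' specks; (3) label 8-connected objects; (4) objects whose solidity is
#' below `solidity_min` or whose eccentricity is below `ecc_min` are
#' treated as clusters of touching cells (rod-shaped bacteria are convex
#' and elongated) and split using the fact that cell centres are brighter
#' than cell borders: extended maxima of the smoothed cluster intensity
#' (local maxima at least `split_h_frac` of the cluster's dynamic range
#' above the threshold) seed individual cells, the seed count is capped by
#' the cluster's area relative to the typical single-cell area, and every
#' cluster pixel is assigned to its nearest seed; (5) objects touching the
#' image border or with area outside `area_range` are removed; (6) labels
#' are renumbered consecutively.
#'
#' @param i_sum sum-projection matrix from [preprocess_stack()].
#' @param threshold absolute threshold; overrides `threshold_frac`.
#' @param threshold_frac fraction of Otsu's threshold used as the small
#'   initial threshold (default 0.1).
#' @param opening_radius disk radius (pixels) of the opening element.
#' @param solidity_min,ecc_min cluster-detection cutoffs.
#' @param split_h_frac extended-maxima height `h` as a fraction of the
#'   cluster's intensity range above the threshold; shallower maxima do
#'   not seed cells.
#' @param area_range admissible object area in pixels (pre-statistics
#'   noise filter).
#' @param exclude integer labels (after splitting/renumbering of the first
#'   pass) to drop, the batch equivalent of manual exclusion.
#' @return a `cell_mask`: list with `labels` (integer matrix, 0 =
#'   background), `n_cells`, and the per-object `solidity`/`eccentricity`
#'   table of the pre-split objects.
#' @export
segment_cells <- function(i_sum, threshold = NULL, threshold_frac = 0.1,
                          opening_radius = 2, solidity_min = 0.9,
                          ecc_min = 0.7, split_h_frac = 0.1,
                          area_range = c(30, 5000), exclude = integer(0)) {
  if (diff(range(i_sum)) == 0) stop("i_sum is constant; nothing to segment")
  rng <- range(i_sum)
  norm <- (i_sum - rng[1]) / diff(rng)
  if (is.null(threshold)) {
    # permissively small threshold: a fraction of the way from the
    # background level (the image median; most pixels are background) up
    # to Otsu's threshold, so dim cells survive and an offset background
    # (camera floor) does not defeat the fraction
    ot <- rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng)
    bg <- stats::median(i_sum)
    threshold <- bg + threshold_frac * max(ot - bg, 0)
  }
  mask <- i_sum > threshold
  if (!any(mask)) {
    warning("no foreground after thresholding; empty mask")
    return(structure(list(labels = matrix(0L, nrow(i_sum), ncol(i_sum)),
                          n_cells = 0L, objects = NULL),
                     class = "cell_mask"))
  }
  brush <- EBImage::makeBrush(2L * opening_radius + 1L, shape = "disc")
  mask <- EBImage::opening(EBImage::Image(mask * 1), brush) > 0.5
  lab <- label_components(mask)

  n_obj <- max(lab)
  obj <- NULL
  if (n_obj > 0L) {
    px <- which(lab > 0L, arr.ind = TRUE)
    ids <- lab[lab > 0L]
    obj <- data.frame(label = seq_len(n_obj), area = tabulate(ids, n_obj),
                      solidity = NA_real_, eccentricity = NA_real_)
    for (o in seq_len(n_obj)) {
      sel <- ids == o
      obj$solidity[o] <- object_solidity(px[sel, 1], px[sel, 2])
      obj$eccentricity[o] <- object_eccentricity(px[sel, 1], px[sel, 2])
    }
    obj$cluster <- obj$solidity < solidity_min | obj$eccentricity < ecc_min
    # typical single-cell area, taken from the well-formed objects; used
    # to cap the number of cells a cluster may be split into (with no
    # well-formed object to calibrate on, the extended maxima alone
    # decide)
    est_area <- stats::median(obj$area[!obj$cluster])
    smooth <- as.matrix(EBImage::gblur(EBImage::Image(i_sum), sigma = 1.5))

    out <- matrix(0L, nrow(lab), ncol(lab))
    next_id <- 0L
    for (o in seq_len(n_obj)) {
      sel <- ids == o
      rows <- px[sel, 1]; cols <- px[sel, 2]
      if (is.na(est_area)) {
        k <- Inf
      } else {
        ratio <- obj$area[o] / est_area
        k <- max(1L, round(ratio))
        if (obj$cluster[o] && ratio > 1.35 && k < 2L) k <- 2L
      }
      if (!obj$cluster[o] || identical(k, 1L) || obj$area[o] <= 1L) {
        next_id <- next_id + 1L
        out[cbind(rows, cols)] <- next_id
        next
      }
      seeds <- cluster_seeds(smooth, rows, cols, k, threshold, split_h_frac)
      if (nrow(seeds) < 2L) {
        next_id <- next_id + 1L
        out[cbind(rows, cols)] <- next_id
        next
      }
      d2 <- vapply(seq_len(nrow(seeds)), function(s)
        (rows - seeds[s, 1])^2 + (cols - seeds[s, 2])^2,
        numeric(length(rows)))
      assign <- max.col(-d2, ties.method = "first")
      for (s in seq_len(nrow(seeds))) {
        next_id <- next_id + 1L
        w <- assign == s
        out[cbind(rows[w], cols[w])] <- next_id
      }
    }
    lab <- relabel(out)
  }

  # border / area / manual-exclusion removal
  n_obj <- max(lab)
  if (n_obj > 0L) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    areas <- tabulate(lab[lab > 0L], n_obj)
    drop <- unique(c(border[border > 0L],
                     which(areas < area_range[1] | areas > area_range[2]),
                     as.integer(exclude)))
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabel(lab)
  }
  structure(list(labels = lab, n_cells = max(lab), objects = obj),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("cell_mask: %d cells on a %d x %d image\n", x$n_cells,
              nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Measure one cell's total fluorescence
#'
#' For the cell's pixels, computes each slice's total intensity and selects
#' the in-focus slice as the one with the highest total. If the maximum is
#' attained at the first or last slice only, the cell is flagged
#' `discarded_slice` (its focal plane was probably outside the acquired
#' range); among tied maxima the lowest interior slice index wins.
#'
#' @param stack_filtered filtered z-stack from [preprocess_stack()].
#' @param mask a `cell_mask` (or integer label matrix).
#' @param label cell label to measure.
#' @return one-row data.frame: `label`, `area`, `chosen_slice` (1-based),
#'   `total_intensity`, `flag_discarded_slice`.
#' @export
measure_cell <- function(stack_filtered, mask, label) {
  lab <- if (inherits(mask, "cell_mask")) mask$labels else mask
  px <- which(lab == label, arr.ind = TRUE)
  if (!nrow(px)) stop("label ", label, " not present in the mask")
  ns <- dim(stack_filtered)[3]
  totals <- vapply(seq_len(ns), function(s)
    sum(stack_filtered[, , s][px]), numeric(1))
  cand <- which(totals == max(totals))
  interior <- cand[cand > 1L & cand < ns]
  if (length(interior)) {
    chosen <- min(interior); flag <- FALSE
  } else {
    # single-plane images have no z-series, so the first/last-slice
    # discard rule does not apply to them
    chosen <- min(cand); flag <- ns > 1L
  }
  data.frame(label = label, area = nrow(px), chosen_slice = chosen,
             total_intensity = totals[chosen], flag_discarded_slice = flag)
}

#' Measure all cells of a mask
#'
#' @inheritParams measure_cell
#' @return data.frame of [measure_cell()] rows (one per label) with
#'   outlier flag columns initialised to `FALSE` and
#'   `corrected_intensity = NA` until [subtract_background()] is applied.
#' @export
measure_cells <- function(stack_filtered, mask) {
  lab <- if (inherits(mask, "cell_mask")) mask$labels else mask
  n <- max(lab)
  recs <- do.call(rbind, lapply(seq_len(n), function(l)
    measure_cell(stack_filtered, lab, l)))
  if (is.null(recs))
    recs <- data.frame(label = integer(0), area = integer(0),
                       chosen_slice = integer(0), total_intensity = numeric(0),
                       flag_discarded_slice = logical(0))
  recs$flag_outlier_intensity <- FALSE
  recs$flag_outlier_area <- FALSE
  recs$corrected_intensity <- NA_real_
  recs
}

#' Flag intensity and area outliers
#'
#' Applies the two population-level filters: the `floor(0.025 n)` cells of
#' highest total intensity are flagged (`n` counts the records not already
#' flagged on entry), then cells whose area is strictly below 0.5x or
#' strictly above 1.5x the median area (median over cells surviving the
#' intensity rule) are flagged. Records are returned, never deleted, so
#' the filter trail is auditable.
#'
#' @param records data.frame from [measure_cells()].
#' @return the records with `flag_outlier_intensity` / `flag_outlier_area`
#'   set.
#' @export
remove_outliers <- function(records) {
  prior <- records$flag_discarded_slice
  ok <- which(!prior)
  if (!length(ok)) stop("no unflagged records to filter")
  n <- length(ok)
  k <- floor(0.025 * n)
  if (k > 0L) {
    ord <- ok[order(records$total_intensity[ok], decreasing = TRUE)]
    records$flag_outlier_intensity[ord[seq_len(k)]] <- TRUE
  }
  keep <- ok[!records$flag_outlier_intensity[ok]]
  med <- stats::median(records$area[keep])
  bad <- keep[records$area[keep] < 0.5 * med | records$area[keep] > 1.5 * med]
  records$flag_outlier_area[bad] <- TRUE
  records
}

#' Fit the autofluorescence-versus-size background model
#'
#' Cellular autofluorescence (measured on cells without the reporter)
#' grows linearly with cell size; the ordinary least-squares line of total
#' autofluorescence on area is used to predict, and subtract, the
#' background of reporter cells.
#'
#' @param area cell areas in pixels (>= 2 distinct values), or a
#'   data.frame with columns `area` and `autofluorescence`.
#' @param autofluorescence total autofluorescence per cell (a.u.).
#' @return a `background_model`: list with `slope` (a.u./pixel) and
#'   `intercept` (a.u.).
#' @export
fit_background <- function(area, autofluorescence = NULL) {
  if (is.data.frame(area)) {
    autofluorescence <- area$autofluorescence
    area <- area$area
  }
  if (length(unique(area)) < 2L)
    stop("background fit needs at least two distinct areas")
  fit <- stats::lm(autofluorescence ~ area)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1])),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: autofluorescence = %.4g * area + %.4g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Subtract predicted autofluorescence from cell intensities
#'
#' `corrected = total - (slope * area + intercept)`. Negative corrected
#' values are retained (clipping would bias the population mean and Fano
#' factor upward for dim cells).
#'
#' @param records data.frame from [measure_cells()].
#' @param model a `background_model` from [fit_background()].
#' @return records with `corrected_intensity` filled in.
#' @export
subtract_background <- function(records, model) {
  stopifnot(inherits(model, "background_model"))
  records$corrected_intensity <-
    records$total_intensity - (model$slope * records$area + model$intercept)
  records
}

#' Count MS2-GFP-tagged RNA from fluorescent spots
#'
#' Tagged transcripts appear as diffraction-limited spots whose integrated
#' intensity is an integer multiple of the intensity of one tagged RNA.
#' The image is segmented (mean-intensity threshold plus opening) unless a
#' mask is supplied; spots are enhanced with a difference-of-Gaussian
#' kernel-density response, segmented by Otsu's threshold on the enhanced
#' image, and each spot's background-corrected intensity (the cell's
#' median non-spot intensity is the local background) is divided by the
#' unit intensity and rounded to an RNA count of at least 1. The unit
#' intensity defaults to the first mode of the spot-intensity
#' distribution.
#'
#' @param image 2-D intensity matrix.
#' @param mask optional `cell_mask` or label matrix; segmented from
#'   `image` when `NULL`.
#' @param unit_intensity a.u. of a single tagged RNA; estimated from the
#'   spot-intensity distribution when `NULL`.
#' @param spot_sigma spot scale in pixels for the enhancement kernel.
#' @param opening_radius disk radius for segmentation when `mask` is
#'   `NULL`.
#' @param area_range admissible cell area (segmentation only).
#' @param exclude labels to exclude (manual-exclusion list).
#' @return list with `spots` (data.frame: `cell`, `spot`, `intensity`,
#'   `rna_count`), `per_cell` (data.frame: `label`, `rna_count`, zero for
#'   spotless cells), `unit_intensity`, and `labels`, the cell label
#'   matrix the counts refer to.
#' @export
count_rna <- function(image, mask = NULL, unit_intensity = NULL,
                      spot_sigma = 1.5, opening_radius = 2,
                      area_range = c(30, 5000), exclude = integer(0)) {
  image <- despike(image)   # hot pixels break Otsu and spot integrals
  if (is.null(mask)) {
    bw <- image > mean(image)
    brush <- EBImage::makeBrush(2L * opening_radius + 1L, shape = "disc")
    bw <- EBImage::opening(EBImage::Image(bw * 1), brush) > 0.5
    lab <- label_components(bw)
    n <- max(lab)
    if (n > 0L) {
      areas <- tabulate(lab[lab > 0L], n)
      drop <- unique(c(which(areas < area_range[1] | areas > area_range[2]),
                       as.integer(exclude)))
      if (length(drop)) lab[lab %in% drop] <- 0L
      lab <- relabel(lab)
    }
  } else {
    lab <- if (inherits(mask, "cell_mask")) mask$labels else mask
    if (length(exclude)) {
      lab[lab %in% as.integer(exclude)] <- 0L
      lab <- relabel(lab)
    }
  }
  n_cells <- max(lab)
  per_cell <- data.frame(label = seq_len(n_cells),
                         rna_count = integer(n_cells))
  empty <- list(spots = data.frame(cell = integer(0), spot = integer(0),
                                   intensity = numeric(0),
                                   rna_count = integer(0)),
                per_cell = per_cell, unit_intensity = unit_intensity,
                labels = lab)
  if (n_cells == 0L) return(empty)

  # difference-of-Gaussian density response: keeps spot-scale structure;
  # the cell interior (eroded mask) is used so the response of the cell
  # boundary itself cannot masquerade as a spot
  img <- EBImage::Image(image)
  enh <- EBImage::gblur(img, sigma = spot_sigma) -
    EBImage::gblur(img, sigma = 3 * spot_sigma)
  enh <- pmax(as.matrix(enh), 0)
  interior <- EBImage::erode(EBImage::Image((lab > 0L) * 1),
                             EBImage::makeBrush(5, "disc")) > 0.5
  enh[!interior] <- 0
  if (max(enh) <= 0) return(empty)

  # Otsu over the log-compressed cell-interior response: the split is
  # then diffuse-cytoplasm ripple vs spot cores, and dim single-RNA spots
  # are neither drowned out by the empty background nor by spots an order
  # of magnitude brighter
  v <- log1p(enh[interior])
  thr <- expm1(EBImage::otsu(EBImage::Image(matrix(v / max(v), nrow = 1)),
                             range = c(0, 1)) * max(v))
  spot_mask <- enh > thr & interior
  spot_lab <- label_components(spot_mask)
  if (max(spot_lab) == 0L) return(empty)

  # split components carrying several resolvable spots: local maxima of
  # the response at least 4 sigma apart each seed one spot
  comp <- spot_lab
  spot_lab <- matrix(0L, nrow(comp), ncol(comp))
  next_spot <- 0L
  sep2 <- (4 * spot_sigma)^2
  for (co in seq_len(max(comp))) {
    px <- which(comp == co, arr.ind = TRUE)
    rows <- px[, 1]; cols <- px[, 2]
    vv <- enh[px]
    sub <- matrix(-Inf, nrow(comp), ncol(comp))
    sub[px] <- vv
    is_max <- vapply(seq_along(rows), function(i) {
      r <- rows[i]; c <- cols[i]
      vv[i] >= max(sub[max(1, r - 1):min(nrow(sub), r + 1),
                       max(1, c - 1):min(ncol(sub), c + 1)])
    }, logical(1))
    cand <- order(vv, decreasing = TRUE)
    cand <- cand[is_max[cand]]
    seeds <- matrix(numeric(0), 0, 2)
    for (i in cand) {
      p <- c(rows[i], cols[i])
      if (!nrow(seeds) ||
          all((seeds[, 1] - p[1])^2 + (seeds[, 2] - p[2])^2 >= sep2))
        seeds <- rbind(seeds, p)
    }
    if (nrow(seeds) <= 1L) {
      next_spot <- next_spot + 1L
      spot_lab[px] <- next_spot
    } else {
      d2 <- vapply(seq_len(nrow(seeds)), function(s)
        (rows - seeds[s, 1])^2 + (cols - seeds[s, 2])^2,
        numeric(length(rows)))
      assign <- max.col(-d2, ties.method = "first")
      for (s in seq_len(nrow(seeds))) {
        next_spot <- next_spot + 1L
        w <- assign == s
        spot_lab[cbind(rows[w], cols[w])] <- next_spot
      }
    }
  }
  n_spots <- max(spot_lab)
  if (n_spots == 0L) return(empty)

  spots <- data.frame(cell = integer(n_spots), spot = seq_len(n_spots),
                      intensity = NA_real_, rna_count = NA_integer_)
  # diffuse cytoplasmic level per cell: median over pixels clear of the
  # (dilated) spot mask, so spot tails do not inflate the estimate and
  # pixel noise does not bias it downward
  win <- ceiling(2 * spot_sigma)
  clear <- !(EBImage::dilate(EBImage::Image(spot_mask * 1),
                             EBImage::makeBrush(2L * win + 1L, "disc")) > 0.5)
  cell_bg <- vapply(seq_len(n_cells), function(l) {
    v <- image[lab == l & clear]
    if (!length(v)) v <- image[lab == l & spot_lab == 0L]
    if (!length(v)) 0 else stats::median(v)
  }, numeric(1))
  for (s in seq_len(n_spots)) {
    px <- which(spot_lab == s, arr.ind = TRUE)
    owner <- lab[px]
    owner <- owner[owner > 0L]
    cell <- as.integer(names(sort(table(owner), decreasing = TRUE))[1])
    spots$cell[s] <- cell
    # integrate over a fixed window around the intensity centroid so the
    # measured intensity stays proportional to the spot's RNA content
    w <- enh[px]
    cr <- sum(px[, 1] * w) / sum(w); cc <- sum(px[, 2] * w) / sum(w)
    rows <- max(1, round(cr) - win):min(nrow(image), round(cr) + win)
    cols <- max(1, round(cc) - win):min(ncol(image), round(cc) + win)
    g <- expand.grid(r = rows, c = cols)
    keep <- (g$r - cr)^2 + (g$c - cc)^2 <= win^2
    wpx <- cbind(g$r[keep], g$c[keep])
    spots$intensity[s] <- max(0, sum(image[wpx] - cell_bg[cell]))
  }
  if (is.null(unit_intensity)) {
    unit_intensity <- estimate_unit_intensity(spots$intensity)
    if (is.na(unit_intensity))
      stop("unit intensity could not be estimated; supply unit_intensity")
  }
  # detections well under the single-RNA intensity are noise, not spots
  spots <- spots[spots$intensity >= 0.3 * unit_intensity, , drop = FALSE]
  if (nrow(spots)) {
    spots$spot <- seq_len(nrow(spots))
    spots$rna_count <- pmax(1L, as.integer(round(spots$intensity / unit_intensity)))
    agg <- tapply(spots$rna_count, spots$cell, sum)
    per_cell$rna_count[as.integer(names(agg))] <- as.integer(agg)
  }
  list(spots = spots, per_cell = per_cell, unit_intensity = unit_intensity,
       labels = lab)
}

# first mode of the spot-intensity distribution: intensity-distribution
# slicing assumes the single-RNA peak is the lowest-lying mode
estimate_unit_intensity <- function(intensities) {
  intensities <- intensities[intensities > 0]
  if (!length(intensities)) return(NA_real_)
  # sub-single-RNA junk detections would otherwise seed a spurious first
  # mode well below the unit intensity
  intensities <- intensities[intensities > 0.3 * stats::median(intensities)]
  if (length(intensities) < 5L) return(stats::median(intensities))
  # bandwidth well under the unit spacing, so consecutive multiples of
  # the unit intensity stay resolved as separate modes
  d <- stats::density(intensities, bw = 0.1 * stats::median(intensities),
                      from = 0)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  peaks <- peaks[y[peaks] > 0.1 * max(y)]
  if (!length(peaks)) return(stats::median(intensities))
  d$x[peaks[1]]
}

#' Read or write z-stacks as multi-page 32-bit TIFF
#'
#' Intensities are divided by 2^24 before writing (32-bit float TIFF
#' stores [0, 1]); the power-of-two scaling is exact in float arithmetic,
#' so the round trip preserves intensities below 2^24 a.u. to single
#' float precision (about seven significant digits).
#'
#' @param stack height x width x slices array (a matrix is treated as one
#'   slice).
#' @param path TIFF path.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns the array.
#' @export
write_stack_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  slices <- lapply(seq_len(dim(stack)[3]), function(s) stack[, , s] / 2^24)
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(slices[[1]])[1:2], length(slices)))
  for (s in seq_along(slices)) arr[, , s] <- slices[[s]] * 2^24
  arr
}

#' Write a label mask as a 16-bit PNG or TIFF
#'
#' @param mask `cell_mask` or label matrix.
#' @param path output path ending in .png or .tif/.tiff.
#' @return `path`, invisibly.
#' @export
write_mask_image <- function(mask, path) {
  lab <- if (inherits(mask, "cell_mask")) mask$labels else mask
  img <- lab / 65535
  if (grepl("\\.png$", path, ignore.case = TRUE))
    png::writePNG(img, path)
  else tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}
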