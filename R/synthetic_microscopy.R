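#' Configuration of the synthetic microscopy generator
#'
#' Defaults emulate the measured data's qualitative features: rod-shaped
#' bacteria rendered as blurred capsules, brightest in an interior z-slice
#' (so in-focus slice selection is meaningful), cellular autofluorescence
#' linear in cell area, a camera floor whose shot noise gives a background
#' coefficient of variation of about 10%, occasional hot pixels (removed
#' by the median filter), and diffraction-limited RNA spots whose
#' integrated intensity is an integer multiple of a unit intensity.
#'
#' @param n_cells number of cells in a scene.
#' @param cluster_fraction fraction of cells placed touching a neighbour.
#' @param cell_length,cell_width rod length/width ranges in pixels.
#' @param psf_sigma lateral Gaussian blur sigma in pixels.
#' @param photons_per_au Poisson shot-noise scale (0 disables shot noise).
#' @param read_noise_sd additive Gaussian read noise sd in a.u.
#' @param hot_pixel_rate per-pixel-per-slice probability of a hot pixel.
#' @param phi fluorescence units per protein molecule.
#' @param bg_slope,bg_intercept autofluorescence model: total cell
#'   autofluorescence = slope * area + intercept (a.u.).
#' @param floor camera background level in a.u. (every pixel).
#' @param unit_intensity integrated a.u. of a single tagged RNA.
#' @param spot_sigma RNA spot Gaussian sigma in pixels.
#' @param ms2_background diffuse cytoplasmic MS2-GFP level per cell pixel.
#' @param n_slices number of z-slices (>= 3 so interior slices exist).
#' @param axial_sigma Gaussian width of the axial intensity profile, in
#'   slices.
#' @param img_size image height and width in pixels.
#' @param margin minimum distance of cell centres from the border.
#' @param seed integer seed for scene generation.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_cells = 40, cluster_fraction = 0,
                             cell_length = c(14, 22), cell_width = c(5, 7),
                             psf_sigma = 1, photons_per_au = 1,
                             read_noise_sd = 2, hot_pixel_rate = 1e-4,
                             phi = 53, bg_slope = 2, bg_intercept = 200,
                             floor = 100, unit_intensity = 400,
                             spot_sigma = 1.2, ms2_background = 30,
                             n_slices = 5, axial_sigma = 1.2,
                             img_size = c(192, 192), margin = 16,
                             seed = 1L) {
  cfg <- as.list(environment())
  num <- unlist(cfg[c("n_cells", "cluster_fraction", "psf_sigma",
                      "photons_per_au", "read_noise_sd", "hot_pixel_rate",
                      "phi", "floor", "unit_intensity", "spot_sigma",
                      "n_slices", "axial_sigma")])
  if (any(num < 0)) stop("generator_config values must be non-negative")
  if (cluster_fraction > 1) stop("cluster_fraction must be in [0, 1]")
  if (n_slices < 3) stop("n_slices must be >= 3")
  structure(cfg, class = "generator_config")
}

capsule_pixels <- function(cx, cy, theta, len, wid, img_size) {
  half <- (len - wid) / 2           # half-length of the capsule axis
  r <- wid / 2
  pad <- ceiling(len / 2 + r + 1)
  rows <- max(1, floor(cx - pad)):min(img_size[1], ceiling(cx + pad))
  cols <- max(1, floor(cy - pad)):min(img_size[2], ceiling(cy + pad))
  g <- expand.grid(row = rows, col = cols)
  dx <- g$row - cx
  dy <- g$col - cy
  u <- dx * cos(theta) + dy * sin(theta)    # along the axis
  v <- -dx * sin(theta) + dy * cos(theta)   # across
  uc <- pmax(abs(u) - half, 0)              # distance to the axis segment
  d <- sqrt(uc^2 + v^2)
  inside <- d <= r
  list(row = g$row[inside], col = g$col[inside], d = d[inside], r = r)
}

#' Generate a ground-truthed synthetic scene of rod-shaped cells
#'
#' Places `n_cells` rods at random positions and orientations; a
#' `cluster_fraction` of them is placed touching an already-placed cell so
#' the cluster-splitting stage can be exercised. Per-cell protein and RNA
#' copy numbers can be supplied (e.g. from [simulate_population()]) or are
#' drawn from wide log-normal defaults.
#'
#' @param config a [generator_config()].
#' @param protein_counts,rna_counts optional integer vectors of length
#'   `n_cells`.
#' @param positions optional data.frame (`cx`, `cy`, `theta`, `length`,
#'   `width`) overriding random placement; extra cells beyond its rows are
#'   placed randomly.
#' @return a `synthetic_scene`: list with `truth` (per-cell data.frame:
#'   `cell_id`, `cx`, `cy`, `theta`, `length`, `width`, `area`,
#'   `protein`, `rna`, `clustered`, `center_slice`, `autofluorescence`)
#'   and the `config`. Rendering is done by [render_stack()] /
#'   [render_spot_image()].
#' @export
synthetic_scene <- function(config = generator_config(),
                            protein_counts = NULL, rna_counts = NULL,
                            positions = NULL) {
  set.seed(config$seed)
  n <- config$n_cells
  if (is.null(protein_counts))
    protein_counts <- as.integer(round(stats::rlnorm(n, log(2000), 0.5)))
  if (is.null(rna_counts))
    rna_counts <- stats::rpois(n, 3)
  stopifnot(length(protein_counts) == n, length(rna_counts) == n)

  H <- config$img_size[1]; W <- config$img_size[2]
  occupied <- matrix(FALSE, H, W)
  gap <- 4   # clearance in px between independent cells (blur-proof)
  truth <- data.frame(cell_id = integer(0))
  pix <- vector("list", n)
  n_clustered <- round(config$cluster_fraction * n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in 1:300) {
      if (!is.null(positions) && i <= nrow(positions)) {
        cx <- positions$cx[i]; cy <- positions$cy[i]
        th <- positions$theta[i]
        len <- positions$length[i]; wid <- positions$width[i]
        clustered <- FALSE
      } else {
        len <- stats::runif(1, config$cell_length[1], config$cell_length[2])
        wid <- stats::runif(1, config$cell_width[1], config$cell_width[2])
        clustered <- i > 1 && (i - 1) > (n - n_clustered) - 1
        if (clustered && nrow(truth)) {
          # grow a V-shaped pair: the new rod starts at one end of a
          # previous rod and leaves at an angle, so the merged object is
          # non-convex (low solidity) and carries two intensity maxima
          j <- sample.int(nrow(truth), 1)
          bend <- sample(c(-1, 1), 1) * stats::runif(1, 0.6, 1.1)
          end <- sample(c(-1, 1), 1)
          half_j <- (truth$length[j] - truth$width[j]) / 2
          jx <- truth$cx[j] + end * half_j * cos(truth$theta[j])
          jy <- truth$cy[j] + end * half_j * sin(truth$theta[j])
          th <- truth$theta[j] + bend
          half <- (len - wid) / 2
          cx <- jx + end * half * cos(th)
          cy <- jy + end * half * sin(th)
        } else {
          cx <- stats::runif(1, config$margin, H - config$margin)
          cy <- stats::runif(1, config$margin, W - config$margin)
          th <- stats::runif(1, 0, pi)
        }
      }
      cp <- capsule_pixels(cx, cy, th, len, wid, c(H, W))
      if (!length(cp$row)) next
      idx <- cbind(cp$row, cp$col)
      if (!clustered && is.null(positions)) {
        # enforce a clearance band so independent cells stay separable
        wide <- capsule_pixels(cx, cy, th, len + 2 * gap, wid + 2 * gap,
                               c(H, W))
        if (any(occupied[cbind(wide$row, wide$col)])) next
      } else {
        # cells cannot interpenetrate: contested pixels stay with the
        # earlier cell, so a touching pair keeps two distinct maxima
        keep <- !occupied[idx]
        if (sum(keep) < 0.6 * length(cp$row)) next
        cp$row <- cp$row[keep]; cp$col <- cp$col[keep]; cp$d <- cp$d[keep]
        idx <- idx[keep, , drop = FALSE]
      }
      occupied[idx] <- TRUE
      area <- length(cp$row)
      truth <- rbind(truth, data.frame(
        cell_id = i, cx = cx, cy = cy, theta = th, length = len,
        width = wid, area = area, protein = protein_counts[i],
        rna = rna_counts[i], clustered = clustered,
        center_slice = sample(2:(config$n_slices - 1), 1),
        autofluorescence = config$bg_slope * area + config$bg_intercept))
      pix[[i]] <- cp
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place cell ", i, "; scene overcrowded")
  }
  structure(list(truth = truth, pixels = pix, config = config),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d cells on %d x %d (%d clustered)\n",
              nrow(x$truth), x$config$img_size[1], x$config$img_size[2],
              sum(x$truth$clustered)))
  invisible(x)
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(matrix(1, 1, 1))
  r <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

# circular-boundary convolution conserves the image integral exactly
blur_conserve <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  as.matrix(EBImage::filter2(EBImage::Image(mat), gaussian_kernel(sigma),
                             boundary = "circular"))
}

apply_camera_noise <- function(mat, config) {
  if (config$photons_per_au > 0)
    mat <- stats::rpois(length(mat), pmax(mat, 0) * config$photons_per_au) /
      config$photons_per_au
  if (config$read_noise_sd > 0)
    mat <- mat + stats::rnorm(length(mat), sd = config$read_noise_sd)
  mat
}

#' Render a scene as a fluorescence z-stack
#'
#' Each cell's total signal is `phi * protein` a.u., distributed over its
#' pixels with a bright-centre radial profile and over slices with a
#' Gaussian axial profile centred on the cell's (interior) `center_slice`.
#' Autofluorescence (`bg_slope * area + bg_intercept`) is spread uniformly
#' over the cell's pixels and slices, the camera `floor` covers every
#' pixel, slices are blurred with an integral-conserving Gaussian PSF, and
#' Poisson/read noise plus hot pixels are applied last (hot pixels are
#' single-pixel spikes at 20x the pre-noise maximum).
#'
#' @param scene a [synthetic_scene()].
#' @param noise apply the camera noise model (`FALSE` renders the clean
#'   expectation).
#' @return the scene with a `stack` element (height x width x slices).
#' @export
render_stack <- function(scene, noise = TRUE) {
  cfg <- scene$config
  H <- cfg$img_size[1]; W <- cfg$img_size[2]; NS <- cfg$n_slices
  stack <- array(cfg$floor, c(H, W, NS))
  for (i in seq_len(nrow(scene$truth))) {
    tr <- scene$truth[i, ]
    cp <- scene$pixels[[tr$cell_id]]
    wpix <- 1.5 - (cp$d / cp$r)^2            # brighter centre
    wpix <- wpix / sum(wpix)
    az <- stats::dnorm(seq_len(NS), mean = tr$center_slice,
                       sd = cfg$axial_sigma)
    az <- az / sum(az)
    total <- cfg$phi * tr$protein
    auto_per <- tr$autofluorescence / (length(cp$row) * NS)
    for (s in seq_len(NS)) {
      idx <- cbind(cp$row, cp$col, s)
      stack[idx] <- stack[idx] + total * wpix * az[s] + auto_per
    }
  }
  for (s in seq_len(NS)) stack[, , s] <- blur_conserve(stack[, , s],
                                                       cfg$psf_sigma)
  if (noise) {
    set.seed(cfg$seed + 7L)
    hot_value <- 20 * max(stack)
    for (s in seq_len(NS)) {
      m <- apply_camera_noise(stack[, , s], cfg)
      nhot <- stats::rbinom(1, H * W, cfg$hot_pixel_rate)
      if (nhot > 0) m[sample.int(H * W, nhot)] <- hot_value
      stack[, , s] <- m
    }
  }
  scene$stack <- stack
  scene
}

#' Render a scene as an MS2-GFP RNA spot image
#'
#' Cells carry a diffuse cytoplasmic MS2-GFP level; each cell's RNA
#' molecules are grouped into spots (by default a random partition with
#' 1-3 RNA per spot) rendered as Gaussians whose integrated intensity is
#' `rna_in_spot * unit_intensity`. Spot centres are kept inside the cell
#' and apart from each other so spots are diffraction-limited and
#' disjoint.
#'
#' @param scene a [synthetic_scene()].
#' @param spots_per_rna `"random"` (1-3 RNA per spot), `"singles"` (one
#'   spot per RNA) or `"one_spot"` (all of a cell's RNA in one spot).
#' @param noise apply the camera noise model.
#' @return the scene with `spot_image` (matrix) and `spot_truth`
#'   (data.frame: `cell_id`, `spot`, `x`, `y`, `rna`) elements.
#' @export
render_spot_image <- function(scene, spots_per_rna = c("random", "singles",
                                                       "one_spot"),
                              noise = TRUE) {
  spots_per_rna <- match.arg(spots_per_rna)
  cfg <- scene$config
  H <- cfg$img_size[1]; W <- cfg$img_size[2]
  set.seed(cfg$seed + 13L)
  img <- matrix(cfg$floor, H, W)
  spot_truth <- data.frame(cell_id = integer(0), spot = integer(0),
                           x = numeric(0), y = numeric(0), rna = integer(0))
  for (i in seq_len(nrow(scene$truth))) {
    tr <- scene$truth[i, ]
    cp <- scene$pixels[[tr$cell_id]]
    img[cbind(cp$row, cp$col)] <- img[cbind(cp$row, cp$col)] +
      cfg$ms2_background
    if (tr$rna < 1) next
    sizes <- switch(spots_per_rna,
      singles = rep(1L, tr$rna),
      one_spot = tr$rna,
      random = {
        left <- tr$rna; out <- integer(0)
        while (left > 0) {
          s <- min(left, sample.int(3L, 1))
          out <- c(out, s); left <- left - s
        }
        out
      })
    interior <- cp$d <= 0.6 * cp$r
    cand <- cbind(cp$row[interior], cp$col[interior])
    if (!nrow(cand)) cand <- cbind(cp$row, cp$col)
    centres <- matrix(numeric(0), 0, 2)
    cell_rows <- integer(0)
    for (k in seq_along(sizes)) {
      ok <- rep(TRUE, nrow(cand))
      if (nrow(centres))
        ok <- apply(cand, 1, function(p)
          all(sqrt(rowSums((centres - matrix(p, nrow(centres), 2,
                                             byrow = TRUE))^2)) >
                5.5 * cfg$spot_sigma))
      pool <- which(ok)
      if (!length(pool)) {
        # no room for another resolvable spot: the RNA co-localises with
        # an existing spot (diffraction-limited merging, kept in truth)
        j <- cell_rows[sample.int(length(cell_rows), 1)]
        spot_truth$rna[j] <- spot_truth$rna[j] + sizes[k]
        next
      }
      pick <- cand[pool[sample.int(length(pool), 1)], ]
      centres <- rbind(centres, pick)
      spot_truth <- rbind(spot_truth, data.frame(
        cell_id = tr$cell_id, spot = nrow(centres), x = pick[1],
        y = pick[2], rna = sizes[k]))
      cell_rows <- c(cell_rows, nrow(spot_truth))
    }
  }
  # render all spots as integral-normalised Gaussians
  if (nrow(spot_truth)) {
    r <- max(1L, ceiling(4 * cfg$spot_sigma))
    for (s in seq_len(nrow(spot_truth))) {
      st <- spot_truth[s, ]
      rows <- max(1, st$x - r):min(H, st$x + r)
      cols <- max(1, st$y - r):min(W, st$y + r)
      g <- outer(stats::dnorm(rows, st$x, cfg$spot_sigma),
                 stats::dnorm(cols, st$y, cfg$spot_sigma))
      img[rows, cols] <- img[rows, cols] +
        st$rna * cfg$unit_intensity * g / sum(g)
    }
  }
  if (noise) {
    img <- matrix(apply_camera_noise(img, cfg), H, W)
    nhot <- stats::rbinom(1, H * W, cfg$hot_pixel_rate)
    if (nhot > 0) img[sample.int(H * W, nhot)] <- 20 * max(img)
  }
  scene$spot_image <- img
  scene$spot_truth <- spot_truth
  scene
}

#' Per-cell fluorescence table bridging model counts to imaging
#'
#' Converts simulated protein counts into the fluorescence a population
#' summary would see: `phi * protein` signal plus size-dependent
#' autofluorescence plus optional Gaussian measurement noise, with the
#' decomposition kept so tests know the ground truth.
#'
#' @param samples a `population_sample` or list of them (one per
#'   condition), e.g. from [simulate_conditions()].
#' @param config a [generator_config()]; `phi`, `bg_slope`,
#'   `bg_intercept` and `seed` are used.
#' @param noise_cv Gaussian measurement noise, as a coefficient of
#'   variation of each cell's total fluorescence (0 = none).
#' @return data.frame: `condition`, `cell_id`, `protein`, `rna`, `area`,
#'   `signal`, `background`, `fluorescence`.
#' @export
generate_population_counts <- function(samples, config = generator_config(),
                                       noise_cv = 0) {
  if (inherits(samples, "population_sample")) samples <- list(samples)
  set.seed(config$seed + 23L)
  out <- do.call(rbind, lapply(samples, function(s) {
    n <- nrow(s)
    len <- stats::runif(n, config$cell_length[1], config$cell_length[2])
    wid <- stats::runif(n, config$cell_width[1], config$cell_width[2])
    area <- round((len - wid) * wid + pi * (wid / 2)^2)  # capsule area
    signal <- config$phi * s$protein
    background <- config$bg_slope * area + config$bg_intercept
    fl <- signal + background
    if (noise_cv > 0) fl <- fl + stats::rnorm(n, sd = noise_cv * fl)
    data.frame(condition = s$condition, cell_id = s$cell_id,
               protein = s$protein, rna = s$rna, area = area,
               signal = signal, background = background, fluorescence = fl)
  }))
  rownames(out) <- NULL
  out
}
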