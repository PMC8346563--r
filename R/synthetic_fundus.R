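#' Configuration for the synthetic fundus generator
#'
#' Describes a fundus-like scene: a bright circular retina disc on a black
#' background, optional dark vessels and a bright optic disc as confounders,
#' and a number of compact bright lesions ("hard exudates") whose pixels are
#' recorded in a ground-truth mask. Intensities are on the 0-255 scale.
#'
#' Defaults emulate, at reduced scale, heterogeneous screening photographs:
#' an 880x660 frame (not a multiple of the 224 tile, so black-border padding
#' is exercised), lesions of 3-18 px semi-axis with additive gain 40-90
#' above the local background, clustered as exudate rings are, and mild
#' sensor noise.
#'
#' @param width,height Image size in pixels; both must be at least 224.
#' @param fundus_radius_frac Fundus disc radius as a fraction of
#'   `min(width, height) / 2`; in `(0, 1]`.
#' @param n_lesions Integer range `c(min, max)`; the lesion count is drawn
#'   uniformly from it. Use `c(0, 0)` for a healthy image.
#' @param lesion_radius Range of the lesion major semi-axis in pixels.
#' @param lesion_gain Range of additive intensity above local background.
#' @param n_artifacts Integer range of bright streak artifacts (emulating
#'   reflections and imaging artifacts, classic false-positive sources);
#'   drawn with lesion-range gains but high eccentricity and never recorded
#'   in the ground-truth mask.
#' @param cluster_frac Lesions are placed inside a random cluster circle of
#'   radius `cluster_frac * fundus_radius` (exudates typically cluster in
#'   rings around a leakage site rather than spreading over the whole
#'   retina); `1` spreads them over the full disc.
#' @param n_vessels Number of dark vessel arcs.
#' @param include_optic_disc Draw a bright optic disc (a classic false-positive
#'   source for exudate detectors).
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise.
#' @param separate_lesions If `TRUE` (default) lesions are rejection-placed so
#'   their supports do not touch and the mask has exactly one connected
#'   component per lesion; if `FALSE`, overlapping lesions merge into a single
#'   mask component, i.e. a single ground-truth object.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A `synth_config` list.
#' @export
synth_config <- function(width = 880, height = 660,
                         fundus_radius_frac = 0.94,
                         n_lesions = c(2, 6),
                         lesion_radius = c(3, 18),
                         lesion_gain = c(40, 90),
                         cluster_frac = 0.3,
                         n_artifacts = c(0, 2),
                         n_vessels = 4,
                         include_optic_disc = TRUE,
                         noise_sigma = 4,
                         separate_lesions = TRUE,
                         seed = 1L) {
  if (length(n_lesions) == 1) n_lesions <- c(n_lesions, n_lesions)
  if (length(n_artifacts) == 1) n_artifacts <- c(n_artifacts, n_artifacts)
  if (length(lesion_radius) == 1) lesion_radius <- rep(lesion_radius, 2)
  if (length(lesion_gain) == 1) lesion_gain <- rep(lesion_gain, 2)
  cfg <- list(width = as.integer(width), height = as.integer(height),
              fundus_radius_frac = fundus_radius_frac,
              n_lesions = as.integer(n_lesions),
              lesion_radius = as.numeric(lesion_radius),
              lesion_gain = as.numeric(lesion_gain),
              cluster_frac = as.numeric(cluster_frac),
              n_artifacts = as.integer(n_artifacts),
              n_vessels = as.integer(n_vessels),
              include_optic_disc = isTRUE(include_optic_disc),
              noise_sigma = as.numeric(noise_sigma),
              separate_lesions = isTRUE(separate_lesions),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$width < 224 || cfg$height < 224) {
    abort("`width` and `height` must be at least 224")
  }
  if (cfg$fundus_radius_frac <= 0 || cfg$fundus_radius_frac > 1) {
    abort("`fundus_radius_frac` must be in (0, 1]")
  }
  if (any(cfg$n_lesions < 0) || cfg$n_lesions[2] < cfg$n_lesions[1]) {
    abort("`n_lesions` must be a non-negative, non-decreasing range")
  }
  if (any(cfg$lesion_radius <= 0) || cfg$lesion_radius[2] < cfg$lesion_radius[1]) {
    abort("`lesion_radius` must be a positive, non-decreasing range")
  }
  if (any(cfg$lesion_gain < 0) || any(cfg$noise_sigma < 0)) {
    abort("`lesion_gain` and `noise_sigma` must be non-negative")
  }
  if (cfg$cluster_frac <= 0 || cfg$cluster_frac > 1) {
    abort("`cluster_frac` must be in (0, 1]")
  }
  if (any(cfg$n_artifacts < 0) || cfg$n_artifacts[2] < cfg$n_artifacts[1]) {
    abort("`n_artifacts` must be a non-negative, non-decreasing range")
  }
  r_fundus <- cfg$fundus_radius_frac * min(cfg$width, cfg$height) / 2
  if (cfg$lesion_radius[2] + 6 >= r_fundus) {
    abort("lesion radius range exceeds the fundus radius: shrink `lesion_radius`")
  }
  invisible(cfg)
}

#' Generate a synthetic fundus image with per-pixel exudate ground truth
#'
#' Renders a radial-gradient orange-red retina disc on a black background,
#' optionally with dark vessel arcs and a bright optic disc, then places
#' soft-edged bright elliptical lesions strictly inside the disc. The binary
#' mask marks exactly the lesion ellipse pixels.
#'
#' @param config A [synth_config()].
#' @return A `fundus_sample`: list with `image` (`H x W x 3`, 0-255), `mask`
#'   (`H x W` 0/1 matrix), `lesions` (tibble: `center_x`, `center_y`, `a`,
#'   `b`, `theta`, `gain`), `label` (`TRUE` when the mask has at least one
#'   on-pixel) and the generating `config`.
#' @examples
#' s <- generate_fundus(synth_config(seed = 7))
#' s$label
#' @export
generate_fundus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  with_seed(config$seed, render_fundus(config))
}

render_fundus <- function(cfg) {
  w <- cfg$width; h <- cfg$height
  cx <- w / 2; cy <- h / 2
  r_fundus <- cfg$fundus_radius_frac * min(w, h) / 2

  xs <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  rr <- sqrt((xs - cx)^2 + (ys - cy)^2)
  inside <- rr <= r_fundus
  t_rad <- rr / r_fundus
  t_rad[t_rad > 1] <- 1

  ch_r <- (190 - 50 * t_rad)
  ch_g <- (110 - 40 * t_rad)
  ch_b <- (40 - 15 * t_rad)

  # vessels: dark arcs radiating from the disc centre region
  if (cfg$n_vessels > 0) {
    for (v in seq_len(cfg$n_vessels)) {
      th0 <- runif(1, 0, 2 * pi)
      curv <- runif(1, -0.8, 0.8)
      width_v <- runif(1, 1.2, 2.4)
      tt <- seq(0.05, 0.92, length.out = 400)
      px <- cx + tt * r_fundus * cos(th0 + curv * tt)
      py <- cy + tt * r_fundus * sin(th0 + curv * tt)
      for (k in seq_along(tt)) {
        c0 <- max(1, floor(px[k] - width_v)); c1 <- min(w, ceiling(px[k] + width_v))
        r0 <- max(1, floor(py[k] - width_v)); r1 <- min(h, ceiling(py[k] + width_v))
        if (c0 > c1 || r0 > r1) next
        ch_r[r0:r1, c0:c1] <- ch_r[r0:r1, c0:c1] - 45 / 9
        ch_g[r0:r1, c0:c1] <- ch_g[r0:r1, c0:c1] - 40 / 9
      }
    }
  }

  # optic disc: bright soft circle off-centre
  if (cfg$include_optic_disc) {
    od_r <- 0.13 * r_fundus
    od_th <- runif(1, -pi / 6, pi / 6) + sample(c(0, pi), 1)
    od_cx <- cx + 0.55 * r_fundus * cos(od_th)
    od_cy <- cy + 0.55 * r_fundus * sin(od_th)
    od_d <- sqrt((xs - od_cx)^2 + (ys - od_cy)^2) / od_r
    od_w <- pmin(1, pmax(0, (1.15 - od_d) / 0.3))
    ch_r <- ch_r + 65 * od_w
    ch_g <- ch_g + 60 * od_w
    ch_b <- ch_b + 35 * od_w
  }

  # lesions: soft-edged bright ellipses strictly inside the fundus
  n_les <- if (cfg$n_lesions[2] > cfg$n_lesions[1]) {
    sample(cfg$n_lesions[1]:cfg$n_lesions[2], 1)
  } else cfg$n_lesions[1]
  lesions <- tibble(center_x = numeric(), center_y = numeric(),
                    a = numeric(), b = numeric(),
                    theta = numeric(), gain = numeric())
  mask <- matrix(0L, h, w)
  gain_map <- matrix(0, h, w)
  # lesions cluster inside a circle of radius cluster_frac * r_fundus whose
  # centre is itself random within the disc
  r_cluster <- cfg$cluster_frac * r_fundus
  off_max <- max(0, r_fundus - r_cluster - cfg$lesion_radius[2] - 6)
  off_r <- runif(1, 0, off_max); off_a <- runif(1, 0, 2 * pi)
  ccx <- cx + off_r * cos(off_a); ccy <- cy + off_r * sin(off_a)
  placed <- 0L; tries <- 0L
  while (placed < n_les && tries < 4000L) {
    tries <- tries + 1L
    a <- runif(1, cfg$lesion_radius[1], cfg$lesion_radius[2])
    b <- a * runif(1, 0.6, 1)
    theta <- runif(1, 0, pi)
    gain <- runif(1, cfg$lesion_gain[1], cfg$lesion_gain[2])
    margin <- a + 4
    rad <- runif(1, 0, 1)
    ang <- runif(1, 0, 2 * pi)
    lx <- ccx + sqrt(rad) * max(0, r_cluster - margin) * cos(ang)
    ly <- ccy + sqrt(rad) * max(0, r_cluster - margin) * sin(ang)
    if (sqrt((lx - cx)^2 + (ly - cy)^2) > r_fundus - margin) next
    if (cfg$separate_lesions && nrow(lesions) > 0) {
      d <- sqrt((lesions$center_x - lx)^2 + (lesions$center_y - ly)^2)
      if (any(d < lesions$a + a + 5)) next
    }
    lesions <- bind_rows(lesions, tibble(center_x = lx, center_y = ly,
                                         a = a, b = b, theta = theta,
                                         gain = gain))
    placed <- placed + 1L
  }
  if (placed < n_les) {
    abort("could not place the requested lesions without overlap; reduce `n_lesions` or `lesion_radius`")
  }
  for (i in seq_len(nrow(lesions))) {
    li <- lesions[i, ]
    ext <- ceiling(li$a * 1.1) + 2
    c0 <- max(1, floor(li$center_x - ext)); c1 <- min(w, ceiling(li$center_x + ext))
    r0 <- max(1, floor(li$center_y - ext)); r1 <- min(h, ceiling(li$center_y + ext))
    sub_x <- xs[r0:r1, c0:c1] - li$center_x
    sub_y <- ys[r0:r1, c0:c1] - li$center_y
    u <- (sub_x * cos(li$theta) + sub_y * sin(li$theta)) / li$a
    v <- (-sub_x * sin(li$theta) + sub_y * cos(li$theta)) / li$b
    rho <- sqrt(u^2 + v^2)
    soft <- pmin(1, pmax(0, (1.08 - rho) / 0.2))
    gain_map[r0:r1, c0:c1] <- gain_map[r0:r1, c0:c1] + li$gain * soft
    mask[r0:r1, c0:c1][rho <= 1] <- 1L
  }

  # bright streak artifacts: lesion-like gains, highly eccentric, not in
  # the ground-truth mask (emulate reflections / imaging artifacts)
  n_art <- if (cfg$n_artifacts[2] > cfg$n_artifacts[1]) {
    sample(cfg$n_artifacts[1]:cfg$n_artifacts[2], 1)
  } else cfg$n_artifacts[1]
  for (k in seq_len(n_art)) {
    a <- runif(1, 12, 35)
    b <- a * runif(1, 0.12, 0.3)
    theta <- runif(1, 0, pi)
    gain <- runif(1, max(30, cfg$lesion_gain[1]), max(40, cfg$lesion_gain[2]))
    margin <- a + 4
    rad <- runif(1, 0, 1); ang <- runif(1, 0, 2 * pi)
    axx <- cx + sqrt(rad) * (r_fundus - margin) * cos(ang)
    ayy <- cy + sqrt(rad) * (r_fundus - margin) * sin(ang)
    ext <- ceiling(a * 1.1) + 2
    c0 <- max(1, floor(axx - ext)); c1 <- min(w, ceiling(axx + ext))
    r0 <- max(1, floor(ayy - ext)); r1 <- min(h, ceiling(ayy + ext))
    sub_x <- xs[r0:r1, c0:c1] - axx
    sub_y <- ys[r0:r1, c0:c1] - ayy
    u <- (sub_x * cos(theta) + sub_y * sin(theta)) / a
    v <- (-sub_x * sin(theta) + sub_y * cos(theta)) / b
    rho <- sqrt(u^2 + v^2)
    soft <- pmin(1, pmax(0, (1.08 - rho) / 0.25))
    gain_map[r0:r1, c0:c1] <- gain_map[r0:r1, c0:c1] + gain * soft
  }

  ch_r <- ch_r + gain_map
  ch_g <- ch_g + 0.95 * gain_map
  ch_b <- ch_b + 0.35 * gain_map

  if (cfg$noise_sigma > 0) {
    ch_r <- ch_r + rnorm(h * w, sd = cfg$noise_sigma)
    ch_g <- ch_g + rnorm(h * w, sd = cfg$noise_sigma)
    ch_b <- ch_b + rnorm(h * w, sd = cfg$noise_sigma)
  }

  image <- array(0, dim = c(h, w, 3))
  image[, , 1] <- clip255(ch_r * inside)
  image[, , 2] <- clip255(ch_g * inside)
  image[, , 3] <- clip255(ch_b * inside)
  mask[!inside] <- 0L

  out <- list(image = image, mask = mask, lesions = lesions,
              label = any(mask > 0), config = cfg)
  class(out) <- "fundus_sample"
  out
}

#' @export
print.fundus_sample <- function(x, ...) {
  cat(sprintf("<fundus_sample> %dx%d, %d lesion(s), label=%s\n",
              ncol(x$mask), nrow(x$mask), nrow(x$lesions),
              if (x$label) "exudates" else "healthy"))
  invisible(x)
}

#' Generate a synthetic dataset of fundus images on disk
#'
#' Writes `n_images` samples (image and mask PNGs) plus a manifest CSV. The
#' number of positive-labelled samples is `round(n_images *
#' positive_fraction)`; the remaining samples are healthy (lesion-free).
#' Each sample gets its own seed derived from `config$seed` so the dataset is
#' reproducible row by row.
#'
#' @param config Base [synth_config()]; its lesion settings apply to the
#'   positive samples.
#' @param n_images Number of images to generate (`>= 1`).
#' @param positive_fraction Fraction of images that contain lesions.
#' @param dir Output directory (created if needed).
#' @return Manifest tibble with columns `image_path`, `mask_path`, `label`
#'   (`"exudates"` / `"healthy"`), `seed`; also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
generate_dataset <- function(config, n_images, positive_fraction, dir) {
  stopifnot(inherits(config, "synth_config"), n_images >= 1)
  stop_if_not_scalar_frac(positive_fraction, "positive_fraction")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", dir))
  }
  n_pos <- round(n_images * positive_fraction)
  labels <- c(rep("exudates", n_pos), rep("healthy", n_images - n_pos))
  rows <- map(seq_len(n_images), function(i) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, paste0("sample", i))
    if (labels[i] == "healthy") cfg_i$n_lesions <- c(0L, 0L)
    s <- generate_fundus(cfg_i)
    ip <- file.path(dir, sprintf("img_%03d.png", i))
    mp <- file.path(dir, sprintf("mask_%03d.png", i))
    write_image_png(s$image, ip)
    png::writePNG(s$mask + 0, mp)
    tibble(image_path = ip, mask_path = mp, label = labels[i],
           seed = cfg_i$seed)
  })
  manifest <- list_rbind(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read or write a generator configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_synth_config()` returns a [synth_config()];
#'   `write_synth_config()` returns `path` invisibly.
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(synth_config, y)
}

#' @rdname read_synth_config
#' @param config A [synth_config()] to serialise.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
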