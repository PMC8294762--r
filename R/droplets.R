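#' Configuration for the synthetic droplet-field generator
#'
#' Two-channel fields of non-overlapping circular condensates on a uniform
#' dilute-phase background, optionally Gaussian-blurred and with additive
#' Gaussian noise. Images are synthesized pre-segmentation: the purpose is
#' recovery of planted partition ratios, not optical realism.
#'
#' @param field_size_um field size `c(width, height)` in micrometres.
#' @param pixel_size_um pixel size in micrometres.
#' @param n_droplets number of droplets to place (may be 0).
#' @param radius_um_range droplet radius range in micrometres.
#' @param channel_inside_mean,channel_outside_mean named per-channel mean
#'   intensity inside droplets / in the dilute phase; the planted partition
#'   ratio per channel is inside/outside.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 = none).
#' @param seed integer seed.
#' @return a list of class `sim_droplet_config`.
#' @export
sim_droplet_config <- function(field_size_um = c(60, 60), pixel_size_um = 0.2,
                               n_droplets = 12L, radius_um_range = c(1.5, 3),
                               channel_inside_mean = c(scaffold = 400, client = 350),
                               channel_outside_mean = c(scaffold = 100, client = 100),
                               noise_sd = 5, blur_sigma_px = 1, seed = 1L) {
  check_pair(field_size_um, "field_size_um", positive = TRUE, ordered = FALSE)
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_scalar(n_droplets, "n_droplets", nonneg = TRUE, integerish = TRUE)
  check_pair(radius_um_range, "radius_um_range", positive = TRUE)
  if (is.null(names(channel_inside_mean)) ||
      !identical(sort(names(channel_inside_mean)), sort(names(channel_outside_mean))))
    stop("invalid configuration field 'channel_inside_mean': ",
         "inside/outside means must share channel names", call. = FALSE)
  if (any(channel_inside_mean <= 0) || any(channel_outside_mean <= 0))
    stop("invalid configuration field 'channel_outside_mean': means must be > 0",
         call. = FALSE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(blur_sigma_px, "blur_sigma_px", nonneg = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(field_size_um = field_size_um, pixel_size_um = pixel_size_um,
                 n_droplets = as.integer(n_droplets),
                 radius_um_range = radius_um_range,
                 channel_inside_mean = channel_inside_mean,
                 channel_outside_mean = channel_outside_mean,
                 noise_sd = noise_sd, blur_sigma_px = blur_sigma_px,
                 seed = as.integer(seed)),
            class = "sim_droplet_config")
}

#' Simulate a two-channel condensate field with known partition ratios
#'
#' Places `n_droplets` non-overlapping disks fully inside the field by
#' rejection sampling (at most `10 * n_droplets` attempts), paints each
#' channel at its inside/outside mean, then applies blur and noise. Negative
#' noise excursions are clamped at zero.
#'
#' @param cfg a [sim_droplet_config()].
#' @return list with `image` (an [image_raster()]) and `truth` (data frame
#'   with one row per droplet: `droplet`, `center_row_px`, `center_col_px`,
#'   `radius_um`, and one `true_ratio_<channel>` column per channel).
#' @export
simulate_droplet_field <- function(cfg) {
  if (!inherits(cfg, "sim_droplet_config")) cfg <- do.call(sim_droplet_config, cfg)
  set.seed(cfg$seed)
  px <- cfg$pixel_size_um
  n_r <- round(cfg$field_size_um[2] / px)
  n_c <- round(cfg$field_size_um[1] / px)
  margin <- 2
  centers <- matrix(numeric(0), 0, 2)
  radii_px <- numeric(0)
  attempts <- 0L
  while (length(radii_px) < cfg$n_droplets) {
    if (attempts >= 10L * cfg$n_droplets)
      stop("droplet placement failed after ", attempts,
           " attempts; request fewer or smaller droplets", call. = FALSE)
    attempts <- attempts + 1L
    r <- runif(1, cfg$radius_um_range[1], cfg$radius_um_range[2]) / px
    row <- runif(1, r + margin, n_r - r - margin)
    col <- runif(1, r + margin, n_c - r - margin)
    if (length(radii_px) == 0 ||
        all(sqrt((centers[, 1] - row)^2 + (centers[, 2] - col)^2) >
            radii_px + r + 2)) {
      centers <- rbind(centers, c(row, col))
      radii_px <- c(radii_px, r)
    }
  }
  channels <- lapply(stats::setNames(nm = names(cfg$channel_inside_mean)), function(ch) {
    m <- matrix(cfg$channel_outside_mean[[ch]], n_r, n_c)
    for (i in seq_along(radii_px))
      m <- paint_disk(m, centers[i, 1], centers[i, 2], radii_px[i],
                      cfg$channel_inside_mean[[ch]])
    m <- gaussian_blur(m, cfg$blur_sigma_px)
    if (cfg$noise_sd > 0)
      m <- pmax(m + matrix(rnorm(n_r * n_c, 0, cfg$noise_sd), n_r, n_c), 0)
    m
  })
  truth <- data.frame(droplet = seq_along(radii_px),
                      center_row_px = if (length(radii_px)) round(centers[, 1]) else numeric(0),
                      center_col_px = if (length(radii_px)) round(centers[, 2]) else numeric(0),
                      radius_um = radii_px * px)
  for (ch in names(cfg$channel_inside_mean))
    truth[[paste0("true_ratio_", ch)]] <-
      rep(cfg$channel_inside_mean[[ch]] / cfg$channel_outside_mean[[ch]],
          length(radii_px))
  list(image = image_raster(channels, px), truth = truth)
}

#' Subtract a protein-free blank image
#'
#' Per-pixel, per-channel subtraction of a buffer-only blank, clamped at
#' zero. Removes static background artifacts before quantification.
#'
#' @param image,blank [image_raster()]s with identical channels and shapes.
#' @return blank-corrected [image_raster()].
#' @export
subtract_blank <- function(image, blank) {
  stopifnot(inherits(image, "image_raster"), inherits(blank, "image_raster"))
  if (!identical(sort(names(image$channels)), sort(names(blank$channels))))
    stop("image and blank must share channel names", call. = FALSE)
  if (!identical(dim(image$channels[[1]]), dim(blank$channels[[1]])))
    stop("image and blank shapes differ", call. = FALSE)
  out <- lapply(stats::setNames(nm = names(image$channels)), function(ch)
    pmax(image$channels[[ch]] - blank$channels[[ch]], 0))
  image_raster(out, image$pixel_size_um)
}

#' Segment droplets from a binary mask with shape filtering
#'
#' Labels 8-connected components, computes area, equivalent radius
#' (`sqrt(area/pi)`), perimeter (marching squares with corner correction) and
#' circularity (`4*pi*A/P^2`, clamped at 1.0 before filtering), and keeps
#' components with `equivalent_radius_um > min_radius_um` and circularity in
#' `circ_range` (inclusive).
#'
#' @param mask logical matrix (e.g. from [otsu_mask()]).
#' @param pixel_size_um pixel size in micrometres.
#' @param min_radius_um minimum equivalent radius (default 1.0, strict).
#' @param circ_range inclusive circularity gate (default `c(0.5, 1.0)`).
#' @return data frame of droplet records (`label`, `area_um2`,
#'   `equivalent_radius_um`, `circularity`, `centroid_row`, `centroid_col`),
#'   with the full label matrix as attribute `labels`; may be empty.
#' @export
segment_droplets <- function(mask, pixel_size_um, min_radius_um = 1.0,
                             circ_range = c(0.5, 1.0)) {
  stopifnot(is.matrix(mask), is.logical(mask))
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_pair(circ_range, "circ_range")
  labels <- label_components(mask, 8L)
  st <- component_stats(labels, pixel_size_um)
  st$circularity <- pmin(st$circularity, 1.0)
  keep <- st$equivalent_radius_um > min_radius_um &
    st$circularity >= circ_range[1] & st$circularity <= circ_range[2]
  rec <- st[keep, c("label", "area_um2", "equivalent_radius_um", "circularity",
                    "centroid_row", "centroid_col")]
  rownames(rec) <- NULL
  attr(rec, "labels") <- labels
  attr(rec, "pixel_size_um") <- pixel_size_um
  rec
}

#' Mean background intensity from droplet-free circular ROIs
#'
#' Places `n_roi` circular regions of interest (default diameter 5 um) at
#' seeded random positions such that no ROI pixel overlaps the droplet mask,
#' and returns the average of the ROI means. Averaging several ROIs reduces
#' the variance of the manual single-ROI convention.
#'
#' @param channel numeric intensity matrix.
#' @param mask logical droplet mask to avoid.
#' @param pixel_size_um pixel size in micrometres.
#' @param roi_diameter_um ROI diameter (default 5).
#' @param n_roi number of ROIs averaged (default 5).
#' @param seed optional integer seed for ROI placement.
#' @param max_attempts placement attempts before giving up (default 10000).
#' @return mean background intensity (scalar).
#' @export
background_mean <- function(channel, mask, pixel_size_um, roi_diameter_um = 5,
                            n_roi = 5L, seed = NULL, max_attempts = 10000L) {
  stopifnot(is.matrix(channel), is.matrix(mask),
            identical(dim(channel), dim(mask)))
  check_scalar(roi_diameter_um, "roi_diameter_um", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  r_px <- roi_diameter_um / 2 / pixel_size_um
  off <- disk_offsets(r_px)
  n <- nrow(channel); m <- ncol(channel)
  means <- numeric(0)
  attempts <- 0L
  while (length(means) < n_roi) {
    if (attempts >= max_attempts)
      stop("background error: no droplet-free ROI found after ", max_attempts,
           " attempts", call. = FALSE)
    attempts <- attempts + 1L
    row <- sample.int(n, 1); col <- sample.int(m, 1)
    rr <- row + off$dr; cc <- col + off$dc
    if (any(rr < 1 | rr > n | cc < 1 | cc > m)) next
    px <- cbind(rr, cc)
    if (any(mask[px])) next
    means <- c(means, mean(channel[px]))
  }
  mean(means)
}

#' Partition-enrichment ratios of a client channel
#'
#' Per droplet, the ratio of the mean client-channel intensity inside the
#' droplet's segmented component to the droplet-free background mean.
#'
#' @param image an [image_raster()].
#' @param droplets droplet records from [segment_droplets()] (carrying the
#'   label matrix).
#' @param channel client channel name to measure.
#' @param background background mean intensity (> 0), from
#'   [background_mean()].
#' @return a list of class `enrichment_result`: `ratios` (data frame `label`,
#'   `mean_intensity`, `ratio`), `mean_ratio`, `background_mean`,
#'   `n_droplets`.
#' @export
enrichment_ratios <- function(image, droplets, channel, background) {
  stopifnot(inherits(image, "image_raster"))
  if (!channel %in% names(image$channels))
    stop("unknown channel '", channel, "'", call. = FALSE)
  if (!is.numeric(background) || background <= 0)
    stop("background mean must be > 0", call. = FALSE)
  labels <- attr(droplets, "labels")
  if (is.null(labels)) stop("droplet records carry no label matrix", call. = FALSE)
  ch <- image$channels[[channel]]
  mi <- vapply(droplets$label, function(id) mean(ch[labels == id]), numeric(1))
  ratios <- data.frame(label = droplets$label, mean_intensity = mi,
                       ratio = mi / background)
  structure(list(ratios = ratios,
                 mean_ratio = if (nrow(ratios)) mean(ratios$ratio) else NA_real_,
                 background_mean = background, n_droplets = nrow(ratios)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment:", x$n_droplets, "droplets, mean ratio =",
      format(x$mean_ratio, digits = 3),
      "(background =", format(x$background_mean, digits = 4), ")\n")
  invisible(x)
}

#' End-to-end droplet partition quantification
#'
#' Chains the full in-vitro partitioning analysis: optional blank
#' subtraction, Otsu mask on the scaffold channel, radius/circularity
#' particle filtering, droplet-free background estimation on the client
#' channel, and per-droplet enrichment ratios.
#'
#' @param image an [image_raster()] with scaffold and client channels.
#' @param blank optional blank [image_raster()] to subtract.
#' @param scaffold,client channel names (defaults `"scaffold"`, `"client"`).
#' @param min_radius_um,circ_range particle filter, see [segment_droplets()].
#' @param roi_diameter_um,n_roi background ROIs, see [background_mean()].
#' @param seed seed for ROI placement.
#' @return list with `droplets` (records), `enrichment`
#'   (an `enrichment_result`), `threshold` (Otsu threshold on the scaffold).
#' @export
quantify_droplets <- function(image, blank = NULL, scaffold = "scaffold",
                              client = "client", min_radius_um = 1.0,
                              circ_range = c(0.5, 1.0), roi_diameter_um = 5,
                              n_roi = 5L, seed = NULL) {
  stopifnot(inherits(image, "image_raster"))
  if (!is.null(blank)) image <- subtract_blank(image, blank)
  for (ch in c(scaffold, client))
    if (!ch %in% names(image$channels))
      stop("unknown channel '", ch, "'", call. = FALSE)
  mask <- otsu_mask(image$channels[[scaffold]])
  rec <- segment_droplets(mask, image$pixel_size_um, min_radius_um, circ_range)
  bg <- background_mean(image$channels[[client]], unclass(mask),
                        image$pixel_size_um, roi_diameter_um, n_roi, seed)
  enr <- enrichment_ratios(image, rec, client, bg)
  list(droplets = rec, enrichment = enr, threshold = attr(mask, "threshold"))
}
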