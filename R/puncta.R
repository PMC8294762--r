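#' Configuration for the synthetic axon-image generator
#'
#' Models the axon as a straight horizontal corridor of configurable width
#' (geometry is irrelevant to a per-length density statistic). Channel-1
#' puncta are planted at `round(puncta_per_100um[1] * axon_length_um / 100)`
#' disk-shaped spots inside the corridor; a configured fraction receives a
#' fully covering channel-2 partner (`full`), a fraction receives an offset
#' partner overlapping roughly 40% of its area (`partial`), and the rest have
#' none (`negative`). An optional second entry of `puncta_per_100um` plants
#' additional independent channel-2 puncta.
#'
#' @param axon_length_um axon length (um).
#' @param puncta_per_100um channel-1 puncta density per 100 um (scalar), or
#'   `c(ch1, ch2_extra)`.
#' @param punctum_area_um2_range punctum area range (um^2).
#' @param overlap_full_frac,overlap_partial_frac fractions of channel-1
#'   puncta planted as `full` / `partial`; their sum must be <= 1.
#' @param corridor_width_um corridor width (um, default 2).
#' @param pixel_size_um pixel size (um, default 0.1).
#' @param amplitude,background punctum peak and background intensity.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return a list of class `sim_axon_config`.
#' @export
sim_axon_config <- function(axon_length_um = 100, puncta_per_100um = 20,
                            punctum_area_um2_range = c(0.15, 0.4),
                            overlap_full_frac = 0.2, overlap_partial_frac = 0.4,
                            corridor_width_um = 2, pixel_size_um = 0.1,
                            amplitude = 1, background = 0.05,
                            noise_sd = 0.02, seed = 1L) {
  check_scalar(axon_length_um, "axon_length_um", positive = TRUE)
  if (length(puncta_per_100um) == 1L) puncta_per_100um <- c(puncta_per_100um, 0)
  if (!is.numeric(puncta_per_100um) || length(puncta_per_100um) != 2L ||
      any(puncta_per_100um < 0))
    stop("invalid configuration field 'puncta_per_100um': ",
         "must be one or two non-negative densities", call. = FALSE)
  check_pair(punctum_area_um2_range, "punctum_area_um2_range", positive = TRUE)
  check_scalar(overlap_full_frac, "overlap_full_frac", min = 0, max = 1)
  check_scalar(overlap_partial_frac, "overlap_partial_frac", min = 0, max = 1)
  if (overlap_full_frac + overlap_partial_frac > 1)
    stop("invalid configuration field 'overlap_partial_frac': ",
         "overlap fractions must sum to <= 1", call. = FALSE)
  check_scalar(corridor_width_um, "corridor_width_um", positive = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_scalar(amplitude, "amplitude", positive = TRUE)
  check_scalar(background, "background", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  max_r <- sqrt(punctum_area_um2_range[2] / pi)
  if (max_r > corridor_width_um / 2)
    stop("invalid configuration field 'punctum_area_um2_range': ",
         "largest punctum (radius ", round(max_r, 2),
         " um) exceeds the axon corridor half-width", call. = FALSE)
  structure(list(axon_length_um = axon_length_um,
                 puncta_per_100um = puncta_per_100um,
                 punctum_area_um2_range = punctum_area_um2_range,
                 overlap_full_frac = overlap_full_frac,
                 overlap_partial_frac = overlap_partial_frac,
                 corridor_width_um = corridor_width_um,
                 pixel_size_um = pixel_size_um, amplitude = amplitude,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_axon_config")
}

#' Simulate a two-channel axon image with planted puncta
#'
#' @param cfg a [sim_axon_config()].
#' @return list with `image` (an [image_raster()] with channels `ch1`,
#'   `ch2`), `truth` (data frame: `punctum`, `channel`, `center_row_px`,
#'   `center_col_px`, `radius_um`, `area_um2`, `class` for channel-1 puncta),
#'   and `axon` (an [axon_trace()] along the corridor centreline).
#' @export
simulate_axon_image <- function(cfg) {
  if (!inherits(cfg, "sim_axon_config")) cfg <- do.call(sim_axon_config, cfg)
  set.seed(cfg$seed)
  px <- cfg$pixel_size_um
  margin_um <- 1
  n_c <- round(cfg$axon_length_um / px)
  n_r <- round((cfg$corridor_width_um + 2 * margin_um) / px)
  mid <- (n_r + 1) / 2
  half_w <- cfg$corridor_width_um / 2 / px
  n1 <- round(cfg$puncta_per_100um[1] * cfg$axon_length_um / 100)
  n2x <- round(cfg$puncta_per_100um[2] * cfg$axon_length_um / 100)
  radii <- sqrt(runif(n1, cfg$punctum_area_um2_range[1],
                      cfg$punctum_area_um2_range[2]) / pi) / px
  # non-overlapping channel-1 placements inside the corridor
  centers <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  for (i in seq_len(n1)) {
    repeat {
      if (attempts > 200L * max(n1, 1))
        stop("punctum placement failed; lower the density or punctum size",
             call. = FALSE)
      attempts <- attempts + 1L
      col <- runif(1, radii[i] + 1, n_c - radii[i] - 1)
      row <- mid + runif(1, -(half_w - radii[i]), half_w - radii[i])
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - row)^2 + (centers[, 2] - col)^2) >
              radii[seq_len(nrow(centers))] + radii[i] + 2)) break
    }
    centers <- rbind(centers, c(row, col))
  }
  n_full <- round(cfg$overlap_full_frac * n1)
  n_part <- round(cfg$overlap_partial_frac * n1)
  cls <- rep("negative", n1)
  if (n1 > 0) {
    ord <- sample.int(n1)
    cls[ord[seq_len(n_full)]] <- "full"
    if (n_part > 0) cls[ord[n_full + seq_len(n_part)]] <- "partial"
  }
  ch1 <- matrix(cfg$background, n_r, n_c)
  ch2 <- matrix(cfg$background, n_r, n_c)
  for (i in seq_len(n1))
    ch1 <- paint_disk(ch1, centers[i, 1], centers[i, 2], radii[i], cfg$amplitude)
  truth2 <- NULL
  for (i in seq_len(n1)) {
    if (cls[i] == "full") {
      ch2 <- paint_disk(ch2, centers[i, 1], centers[i, 2], radii[i] + 2,
                        cfg$amplitude)
    } else if (cls[i] == "partial") {
      off <- centers[i, 2] + radii[i] * sample(c(-1, 1), 1)
      ch2 <- paint_disk(ch2, centers[i, 1], off, radii[i], cfg$amplitude)
    }
  }
  # independent channel-2 puncta away from channel-1 spots
  if (n2x > 0) {
    r2 <- sqrt(runif(n2x, cfg$punctum_area_um2_range[1],
                     cfg$punctum_area_um2_range[2]) / pi) / px
    placed <- 0L; tries <- 0L
    rows2 <- cols2 <- numeric(0)
    while (placed < n2x && tries < 200L * n2x) {
      tries <- tries + 1L
      r <- r2[placed + 1L]
      col <- runif(1, r + 1, n_c - r - 1)
      row <- mid + runif(1, -(half_w - r), half_w - r)
      if (n1 == 0 ||
          all(sqrt((centers[, 1] - row)^2 + (centers[, 2] - col)^2) >
              radii + r + 4)) {
        placed <- placed + 1L
        rows2 <- c(rows2, row); cols2 <- c(cols2, col)
        ch2 <- paint_disk(ch2, row, col, r, cfg$amplitude)
      }
    }
    if (placed)
      truth2 <- data.frame(punctum = n1 + seq_len(placed), channel = "ch2",
                           center_row_px = round(rows2),
                           center_col_px = round(cols2),
                           radius_um = r2[seq_len(placed)] * px,
                           area_um2 = pi * (r2[seq_len(placed)] * px)^2,
                           class = NA_character_, stringsAsFactors = FALSE)
  }
  if (cfg$noise_sd > 0) {
    ch1 <- pmax(ch1 + matrix(rnorm(n_r * n_c, 0, cfg$noise_sd), n_r, n_c), 0)
    ch2 <- pmax(ch2 + matrix(rnorm(n_r * n_c, 0, cfg$noise_sd), n_r, n_c), 0)
  }
  truth1 <- data.frame(punctum = seq_len(n1), channel = rep("ch1", n1),
                       center_row_px = if (n1) round(centers[, 1]) else numeric(0),
                       center_col_px = if (n1) round(centers[, 2]) else numeric(0),
                       radius_um = radii * px, area_um2 = pi * (radii * px)^2,
                       class = cls, stringsAsFactors = FALSE)
  axon <- axon_trace(data.frame(x_um = c(0, cfg$axon_length_um),
                                y_um = rep(mid * px, 2)))
  list(image = image_raster(list(ch1 = ch1, ch2 = ch2), px),
       truth = rbind(truth1, truth2), axon = axon)
}

#' Axon trace polyline
#'
#' @param points data frame with columns `x_um`, `y_um`: ordered vertices of
#'   the axon centreline in physical coordinates.
#' @return a list of class `axon_trace` with `points` and `length_um` (sum of
#'   segment lengths).
#' @export
axon_trace <- function(points) {
  stopifnot(is.data.frame(points), all(c("x_um", "y_um") %in% names(points)),
            nrow(points) >= 2)
  seg <- sqrt(diff(points$x_um)^2 + diff(points$y_um)^2)
  structure(list(points = points, length_um = sum(seg)), class = "axon_trace")
}

#' Detect puncta in an intensity channel
#'
#' Otsu threshold, 8-connected component labelling, and removal of
#' components below `min_area_um2`. An automated stand-in for manual spot
#' counting.
#'
#' @param channel numeric intensity matrix (non-constant).
#' @param pixel_size_um pixel size (um).
#' @param min_area_um2 minimum component area kept (um^2; default 0.05, the
#'   lower PLA gate).
#' @return data frame of punctum records (`label`, `centroid_row`,
#'   `centroid_col`, `area_um2`, `mean_intensity`) with the label matrix as
#'   attribute `labels`.
#' @export
detect_puncta <- function(channel, pixel_size_um, min_area_um2 = 0.05) {
  stopifnot(is.matrix(channel))
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  mask <- otsu_mask(channel)
  labels <- label_components(mask, 8L)
  st <- component_stats(labels, pixel_size_um)
  keep <- st$area_um2 >= min_area_um2
  mi <- vapply(st$label, function(id) mean(channel[labels == id]), numeric(1))
  rec <- data.frame(label = st$label, centroid_row = st$centroid_row,
                    centroid_col = st$centroid_col, area_um2 = st$area_um2,
                    mean_intensity = mi)[keep, ]
  rownames(rec) <- NULL
  attr(rec, "labels") <- labels
  attr(rec, "pixel_size_um") <- pixel_size_um
  rec
}

#' Size-gate puncta by area
#'
#' Keeps records with `lo_um2 <= area_um2 <= hi_um2` (inclusive bounds); the
#' defaults are the PLA quantification gate 0.05-3.00 um^2.
#'
#' @param puncta data frame with an `area_um2` column.
#' @param lo_um2,hi_um2 inclusive area bounds.
#' @return filtered data frame (attributes preserved).
#' @export
size_gate <- function(puncta, lo_um2 = 0.05, hi_um2 = 3.00) {
  stopifnot(is.data.frame(puncta), "area_um2" %in% names(puncta))
  if (lo_um2 > hi_um2)
    stop("invalid configuration field 'lo_um2': gate bounds out of order",
         call. = FALSE)
  keep <- puncta$area_um2 >= lo_um2 & puncta$area_um2 <= hi_um2
  out <- puncta[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("labels", "pixel_size_um"))
    attr(out, a) <- attr(puncta, a)
  out
}

#' Linear puncta density along an axon
#'
#' Counts puncta whose centroid lies within `corridor_um` of the axon
#' polyline and expresses the count per 100 um of axon length.
#'
#' @param puncta punctum records (from [detect_puncta()] or a planted truth
#'   table with centroid columns); centroids in pixel coordinates.
#' @param axon an [axon_trace()].
#' @param corridor_um maximum centroid-to-polyline distance counted
#'   (default 1, i.e. a 2-um-wide corridor).
#' @param pixel_size_um pixel size; taken from the records' attribute when
#'   omitted.
#' @return puncta per 100 um.
#' @export
linear_density <- function(puncta, axon, corridor_um = 1,
                           pixel_size_um = NULL) {
  stopifnot(inherits(axon, "axon_trace"))
  if (axon$length_um <= 0) stop("zero-length axon", call. = FALSE)
  px <- pixel_size_um %||% attr(puncta, "pixel_size_um")
  if (is.null(px)) stop("pixel_size_um required", call. = FALSE)
  rows <- puncta$centroid_row %||% puncta$center_row_px
  cols <- puncta$centroid_col %||% puncta$center_col_px
  if (length(rows) == 0) return(0)
  x <- cols * px; y <- rows * px
  d <- dist_to_polyline(x, y, axon$points$x_um, axon$points$y_um)
  100 * sum(d <= corridor_um) / axon$length_um
}

# minimum distance from points (x, y) to a polyline
dist_to_polyline <- function(x, y, vx, vy) {
  d <- rep(Inf, length(x))
  for (i in seq_len(length(vx) - 1)) {
    ax <- vx[i]; ay <- vy[i]; bx <- vx[i + 1]; by <- vy[i + 1]
    lx <- bx - ax; ly <- by - ay
    len2 <- lx^2 + ly^2
    t <- if (len2 > 0) pmin(pmax(((x - ax) * lx + (y - ay) * ly) / len2, 0), 1) else 0
    d <- pmin(d, sqrt((x - (ax + t * lx))^2 + (y - (ay + t * ly))^2))
  }
  d
}

#' Classify channel-1 puncta by overlap with a channel-2 mask
#'
#' The overlap fraction of each punctum is the share of its pixels falling
#' inside the channel-2 mask. Classes: `full` when the fraction is at least
#' `thresholds["full"]` (default 0.80), `negative` when at most
#' `thresholds["negative"]` (default 0.05), otherwise `partial`. The
#' thresholds are conventions exposed for tuning — published image panels
#' define full/partial only pictorially.
#'
#' @param puncta records from [detect_puncta()] (carrying the label matrix).
#' @param mask logical channel-2 mask (e.g. [otsu_mask()] of the second
#'   channel).
#' @param thresholds named vector with entries `full` and `negative`.
#' @return the records with `overlap_fraction` and `class` columns added.
#' @export
classify_overlap <- function(puncta, mask,
                             thresholds = c(full = 0.80, negative = 0.05)) {
  labels <- attr(puncta, "labels")
  if (is.null(labels)) stop("punctum records carry no label matrix", call. = FALSE)
  stopifnot(is.matrix(mask), identical(dim(mask), dim(labels)))
  frac <- vapply(puncta$label, function(id) mean(mask[labels == id]), numeric(1))
  puncta$overlap_fraction <- frac
  puncta$class <- ifelse(frac >= thresholds[["full"]], "full",
                         ifelse(frac <= thresholds[["negative"]], "negative",
                                "partial"))
  puncta
}

#' Normalized group summary of per-axon densities
#'
#' Scales every axon's density by `100 / mean(control densities)` so the
#' control group averages 100, and reports per-group mean +/- SEM. A
#' Kruskal-Wallis p-value across groups is attached when there are at least
#' two groups.
#'
#' @param densities data frame with columns `group` and `density` (one row
#'   per axon); an optional `experiment` column is carried through.
#' @param control control group label (default `"control"`).
#' @return data frame with `group`, `mean_normalized`, `sem`, `n`;
#'   per-axon normalized values as attribute `per_axon`, Kruskal-Wallis p as
#'   attribute `kruskal_p`.
#' @export
summarize_by_group <- function(densities, control = "control") {
  stopifnot(is.data.frame(densities),
            all(c("group", "density") %in% names(densities)))
  ctl <- densities$density[densities$group == control]
  if (length(ctl) == 0)
    stop("control group '", control, "' not found", call. = FALSE)
  m <- mean(ctl)
  if (!is.finite(m) || m <= 0)
    stop("control mean density must be > 0", call. = FALSE)
  densities$normalized <- densities$density * 100 / m
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  smry <- do.call(rbind, lapply(split(densities, densities$group), function(d)
    data.frame(group = d$group[1], mean_normalized = mean(d$normalized),
               sem = sem(d$normalized), n = nrow(d))))
  rownames(smry) <- NULL
  attr(smry, "per_axon") <- densities
  if (length(unique(densities$group)) >= 2)
    attr(smry, "kruskal_p") <-
      kruskal.test(densities$density, factor(densities$group))$p.value
  smry
}
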