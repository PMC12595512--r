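# Oxidative-stress staining quantified as the percentage of mycelial plug
# area fluorescing, from grayscale plug images (DHE for superoxide,
# H2DCFDA for hydrogen peroxide).
#
# Images are numeric matrices with intensities in [0, 1] (PNG/TIFF readers
# scale 8- and 16-bit data into this range). Thresholding is Otsu's
# criterion on a 256-level histogram of the pixels inside the plug mask,
# or a fixed intensity; pixels outside the mask never enter the
# computation.

ROS_CHANNELS <- c("DHE", "H2DCFDA")

#' Read a grayscale plug image
#'
#' Reads PNG or TIFF; multi-channel images are averaged to grayscale.
#'
#' @param path image file path (.png, .tif or .tiff).
#' @return numeric matrix of intensities in [0, 1].
#' @export
readPlugImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  stopifnot(is.matrix(img))
  img
}

#' Segment the plug disc of an image
#'
#' Returns the provided disc as a logical mask, or, when no disc is given,
#' a centred disc whose diameter covers \code{fraction} of the image's
#' shorter dimension (plugs are cut with a fixed-diameter borer and imaged
#' roughly centred).
#'
#' @param image numeric intensity matrix, both dimensions >= 16.
#' @param disc optional list/vector with \code{cx}, \code{cy}, \code{r}
#'   (centre column, centre row, radius, in pixels).
#' @param fraction fraction of the shorter dimension covered by the default
#'   disc diameter (default 0.9).
#' @return logical matrix of the same dimension, TRUE inside the disc.
#' @examples
#' m <- matrix(0, 100, 100)
#' sum(segmentPlug(m))  # ~ pi * 45^2
#' @export
segmentPlug <- function(image, disc = NULL, fraction = 0.9) {
  stopifnot(is.matrix(image))
  if (any(dim(image) < 16L))
    stop("image too small: both dimensions must be >= 16 pixels")
  if (is.null(disc)) {
    r <- fraction * min(dim(image)) / 2
    cy <- (nrow(image) + 1) / 2
    cx <- (ncol(image) + 1) / 2
  } else {
    disc <- as.list(disc)
    stopifnot(all(c("cx", "cy", "r") %in% names(disc)))
    r <- as.numeric(disc$r); cx <- as.numeric(disc$cx)
    cy <- as.numeric(disc$cy)
    stopifnot(r > 0)
  }
  row_d <- (seq_len(nrow(image)) - cy)^2
  col_d <- (seq_len(ncol(image)) - cx)^2
  outer(row_d, col_d, "+") <= r^2
}

#' Otsu threshold of a set of intensities
#'
#' Maximises the between-class variance over a 256-level histogram of
#' intensities in [0, 1]; returns the upper edge value separating the two
#' classes (pixels strictly above it are foreground).
#'
#' @param values numeric vector of intensities in [0, 1].
#' @param levels histogram resolution (default 256, 8-bit granularity).
#' @return threshold intensity, or \code{NA} when the values are uniform
#'   (degenerate histogram).
#' @export
otsuThreshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  stopifnot(length(values) > 0, all(values >= 0), all(values <= 1))
  if (diff(range(values)) == 0) return(NA_real_)
  bins <- pmin(floor(values * levels), levels - 1L)  # 0 .. levels-1
  counts <- tabulate(bins + 1L, nbins = levels)
  p <- counts / sum(counts)
  midpoints <- (seq_len(levels) - 0.5) / levels
  omega <- cumsum(p)
  mu <- cumsum(p * midpoints)
  mu_total <- mu[levels]
  # between-class variance for thresholds after each bin t = 1..levels-1
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, levels)
  sigma_b[valid] <- (mu_total * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  t_bin <- which.max(sigma_b[-levels])
  t_bin / levels  # upper edge of bin t_bin; foreground: value > threshold
}

#' Percent of plug area stained
#'
#' percent = 100 * (masked pixels with intensity > threshold) / (masked
#' pixels). The threshold is Otsu's criterion on the masked intensities or
#' a fixed value. A uniform masked region is a degenerate case for Otsu and
#' returns 0 percent with the threshold reported as \code{NA}.
#'
#' @param image numeric intensity matrix in [0, 1].
#' @param mask logical matrix of the same dimension (see [segmentPlug()]);
#'   must select at least one pixel.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param threshold fixed intensity threshold in [0, 1] (required for
#'   \code{method = "fixed"}).
#' @param strain_id,channel,replicate optional metadata copied to the
#'   result row.
#' @return One-row data.frame: \code{strain_id}, \code{channel},
#'   \code{replicate}, \code{percent_area}, \code{threshold_used},
#'   \code{method}, \code{n_pixels}.
#' @export
percentStainedArea <- function(image, mask, method = c("otsu", "fixed"),
                               threshold = NULL, strain_id = NA_character_,
                               channel = NA_character_, replicate = NA_integer_) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), is.logical(mask),
            identical(dim(image), dim(mask)))
  vals <- image[mask]
  if (length(vals) == 0L) stop("mask selects no pixels")
  if (method == "fixed") {
    stopifnot(!is.null(threshold), threshold >= 0, threshold <= 1)
    thr <- threshold
  } else {
    thr <- otsuThreshold(vals)
  }
  pct <- if (is.na(thr)) 0 else 100 * mean(vals > thr)
  data.frame(strain_id = strain_id, channel = channel,
             replicate = replicate, percent_area = pct,
             threshold_used = thr, method = method,
             n_pixels = length(vals), stringsAsFactors = FALSE)
}

#' Quantify a batch of plug images from a sidecar table
#'
#' @param sidecar data.frame with columns \code{strain_id}, \code{channel},
#'   \code{replicate}, \code{filename} and optionally \code{cx}, \code{cy},
#'   \code{r} for a known plug disc.
#' @param image_dir directory containing the image files.
#' @param method,threshold passed to [percentStainedArea()].
#' @return data.frame of per-image measurements.
#' @export
measureRosBatch <- function(sidecar, image_dir, method = "otsu",
                            threshold = NULL) {
  sidecar <- as.data.frame(sidecar)
  req <- c("strain_id", "channel", "replicate", "filename")
  stopifnot(all(req %in% names(sidecar)))
  if (!all(sidecar$channel %in% ROS_CHANNELS))
    stop("unknown channel(s): ",
         paste(setdiff(sidecar$channel, ROS_CHANNELS), collapse = ", "))
  has_disc <- all(c("cx", "cy", "r") %in% names(sidecar))
  out <- lapply(seq_len(nrow(sidecar)), function(i) {
    row <- sidecar[i, ]
    img <- readPlugImage(file.path(image_dir, row$filename))
    disc <- if (has_disc && is.finite(row$r))
      list(cx = row$cx, cy = row$cy, r = row$r) else NULL
    mask <- segmentPlug(img, disc)
    percentStainedArea(img, mask, method = method, threshold = threshold,
                       strain_id = row$strain_id, channel = row$channel,
                       replicate = row$replicate)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise ROS measurements per strain and channel
#'
#' @param measurements data.frame from [percentStainedArea()] /
#'   [measureRosBatch()].
#' @return data.frame with one row per (strain_id, channel): \code{mean},
#'   \code{sd} (\code{NA} for a single replicate), \code{n}. Feeds
#'   [anovaFromSummary()] for strain comparisons.
#' @export
summarizeRos <- function(measurements) {
  measurements <- as.data.frame(measurements)
  stopifnot(all(c("strain_id", "channel", "percent_area") %in%
                  names(measurements)))
  if (nrow(measurements) == 0L) stop("missing data: no ROS measurements")
  groups <- split(measurements,
                  list(measurements$strain_id, measurements$channel),
                  drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) data.frame(
    strain_id = g$strain_id[1], channel = g$channel[1],
    mean = mean(g$percent_area),
    sd = if (nrow(g) > 1L) stats::sd(g$percent_area) else NA_real_,
    n = nrow(g), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$strain_id, out$channel), , drop = FALSE]
}
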