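# Hemocyte spreading, phagocytosis and relative F-actin fluorescence.

# perimeter of an object from its ordered contour: the pixel staircase is
# smoothed with a short circular moving average before summing segment
# lengths (removing digitization noise that would bias disk circularity
# above 1), then offset-corrected by 2*pi*0.5 because the object boundary
# runs half a pixel outside the boundary-pixel centres (a closed curve
# offset outward by h gains 2*pi*h in length). Accurate for object radii
# of about 8 px and above; pseudopod arms survive the smoothing.
.chain_perimeter <- function(contour, k = 2) {
  n <- nrow(contour)
  if (n < 5) return(max(4, n))
  sm <- apply(contour, 2, function(v) {
    f <- stats::filter(c(v[(n - k + 1):n], v, v[1:k]),
                       rep(1 / (2 * k + 1), 2 * k + 1))
    as.numeric(f[(k + 1):(k + n)])
  })
  d <- rbind(diff(sm), sm[1, ] - sm[n, ])
  sum(sqrt(rowSums(d^2))) + pi
}

# count radial "arms" on an object's ordered contour: contiguous runs of
# contour points whose distance from the centroid exceeds 1.15x the median
# distance. A disk has none; a star silhouette has one run per arm. Serves
# as the convexity-defect count for spreading classification.
.count_arms <- function(contour) {
  ctr <- colMeans(contour)
  r <- sqrt((contour[, 1] - ctr[1])^2 + (contour[, 2] - ctr[2])^2)
  if (length(r) < 8) return(0L)
  # light circular smoothing against pixel jaggies
  k <- 5
  rs <- stats::filter(c(tail(r, k), r, head(r, k)), rep(1 / (2 * k + 1), 2 * k + 1))
  rs <- rs[(k + 1):(k + length(r))]
  rs[is.na(rs)] <- r[is.na(rs)]
  high <- rs > 1.15 * stats::median(rs)
  if (!any(high)) return(0L)
  if (all(high)) return(1L)
  runs <- sum(diff(c(high[length(high)], high)) == 1)
  as.integer(runs)
}

#' Segment hemocytes and compute per-cell morphology features
#'
#' Thresholds the cell-body (DIC-like) channel, labels nuclei as seeds, and
#' partitions the cell mask among the seeds with a Voronoi-style
#' propagation, so touching cells with separate nuclei are split. For each
#' cell it computes area, perimeter, circularity `4*pi*area/perimeter^2`
#' and a convexity-defect (arm) count from the radial profile of the
#' object contour.
#'
#' @param dic_channel,nuclei_channel Registered numeric matrices of equal
#'   dimensions.
#' @param config An [assay_config()]; `cell_threshold` and
#'   `nucleus_threshold` set the two masks.
#' @return A list with `records`, a data frame (`cell_id, center_row,
#'   center_col, area, perimeter, circularity, defects`), and `labels`, the
#'   labelled cell mask (used by [count_engulfed()]). An empty field gives
#'   zero rows, not an error.
#' @export
extract_cell_features <- function(dic_channel, nuclei_channel,
                                  config = assay_config()) {
  if (!all(dim(dic_channel) == dim(nuclei_channel)))
    stop("channels must have identical dimensions")
  cell_mask <- dic_channel > config$cell_threshold
  seeds <- EBImage::bwlabel(nuclei_channel > config$nucleus_threshold)
  empty <- list(records = data.frame(
    cell_id = integer(0), center_row = numeric(0), center_col = numeric(0),
    area = numeric(0), perimeter = numeric(0), circularity = numeric(0),
    defects = integer(0)), labels = matrix(0L, nrow(dic_channel), ncol(dic_channel)))
  if (!any(cell_mask) || max(seeds) == 0) return(empty)
  labels <- EBImage::propagate(dic_channel, seeds, mask = cell_mask)
  labels <- EBImage::imageData(labels)
  shape <- EBImage::computeFeatures.shape(labels)
  if (is.null(shape) || nrow(shape) == 0) return(empty)
  moments <- EBImage::computeFeatures.moment(labels)
  contours <- EBImage::ocontour(labels)
  ids <- as.integer(rownames(shape))
  px_area <- shape[, "s.area"] * config$pixel_size^2
  perim <- vapply(ids, function(i) .chain_perimeter(contours[[i]]),
                  numeric(1)) * config$pixel_size
  records <- data.frame(
    cell_id = ids,
    center_row = moments[, "m.cx"], center_col = moments[, "m.cy"],
    area = px_area, perimeter = perim,
    circularity = 4 * pi * px_area / perim^2,
    defects = vapply(ids, function(i) .count_arms(contours[[i]]), integer(1)))
  rownames(records) <- NULL
  list(records = records, labels = labels)
}

#' Classify cells as spread or round
#'
#' A cell is called spread when it has lost the compact disk morphology:
#' circularity below `circularity_max` or at least `defects_min` pseudopod
#' arms (convexity defects). Both thresholds live in [assay_config()].
#'
#' @param records Per-cell data frame with `circularity` and `defects`
#'   columns (e.g. from [extract_cell_features()]).
#' @param config An [assay_config()].
#' @return The records with a logical `spread` column added; rows missing
#'   either feature are dropped with a warning.
#' @export
classify_spread <- function(records, config = assay_config()) {
  ok <- is.finite(records$circularity) & is.finite(records$defects)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) missing morphology features; skipped")
    records <- records[ok, ]
  }
  records$spread <- records$circularity < config$circularity_max |
    records$defects >= config$defects_min
  records
}

#' Percentage of spreading hemocytes
#'
#' The number of spread plasmatocytes plus spread granulocytes divided by
#' the total plasmatocytes plus granulocytes, times 100. Cells typed
#' `"other"` (e.g. lysed oenocytoids) are excluded from both numerator and
#' denominator. If the records carry no `type` column, every cell is
#' treated as eligible.
#'
#' @param records Data frame with a logical `spread` column and optionally
#'   a `type` column.
#' @return Percentage in `[0, 100]`.
#' @export
spreading_percentage <- function(records) {
  if (is.null(records$spread)) stop("records need a 'spread' column")
  eligible <- if (is.null(records$type)) rep(TRUE, nrow(records)) else
    records$type %in% c("plasmatocyte", "granulocyte")
  if (!any(eligible))
    stop("no plasmatocytes or granulocytes: spreading percentage undefined")
  100 * sum(records$spread[eligible]) / sum(eligible)
}

#' Count engulfed bacteria per cell
#'
#' Detects bright spots in the bacteria channel (connected components above
#' `spot_threshold`) and assigns each spot to the cell whose mask contains
#' the spot centroid; spots outside every cell mask are counted for no
#' cell. Engulfment is scored by 2D containment, matching
#' fluorescence-microscopy counting of ingested labelled bacteria.
#'
#' @param features Output of [extract_cell_features()] (needs `records`
#'   and `labels`).
#' @param bacteria_channel Numeric matrix registered with the segmented
#'   channels.
#' @param config An [assay_config()].
#' @return The records data frame with integer `engulfed_count` and logical
#'   `phagocytic` (`engulfed_count >= 1`) columns added. A saturated
#'   channel (more than half the pixels above threshold) triggers a
#'   warning; counts are still computed.
#' @export
count_engulfed <- function(features, bacteria_channel,
                           config = assay_config()) {
  records <- features$records; labels <- features$labels
  if (!all(dim(bacteria_channel) == dim(labels)))
    stop("bacteria channel must match the segmented image dimensions")
  spot_mask <- bacteria_channel > config$spot_threshold
  if (mean(spot_mask) > 0.5)
    warning("bacteria channel looks saturated; spot counts may be unreliable")
  records$engulfed_count <- 0L
  if (any(spot_mask) && nrow(records) > 0) {
    spots <- EBImage::bwlabel(spot_mask)
    n_spots <- max(spots)
    idx <- which(spots > 0, arr.ind = TRUE)
    cr <- round(tapply(idx[, 1], spots[spots > 0], mean))
    cc <- round(tapply(idx[, 2], spots[spots > 0], mean))
    owner <- labels[cbind(cr, cc)]
    hits <- table(owner[owner > 0])
    m <- match(records$cell_id, as.integer(names(hits)))
    records$engulfed_count <- ifelse(is.na(m), 0L, as.integer(hits)[m])
  }
  records$phagocytic <- records$engulfed_count >= 1L
  records
}

#' Percentage of phagocytic hemocytes
#'
#' The fraction of cells that have engulfed at least one labelled
#' bacterium, times 100. Counts beyond the first bacterium do not change
#' the percentage.
#'
#' @param records Data frame with an `engulfed_count` column.
#' @return Percentage in `[0, 100]`.
#' @export
phagocytosis_percentage <- function(records) {
  if (is.null(records$engulfed_count) || nrow(records) == 0)
    stop("records with an engulfed_count column are required")
  100 * mean(records$engulfed_count >= 1)
}

#' Relative F-actin fluorescence per group
#'
#' Divides each treated reading by the blank (saline) intensity and reports
#' the per-group mean and standard error of the ratio. If `blank` is not
#' given it is taken as the mean intensity of the rows with group
#' `"blank"`.
#'
#' @param samples Data frame with `group` and `intensity` columns, e.g.
#'   from [generate_factin_readings()] or [read_assay_table()].
#' @param blank Positive blank intensity; defaults to the mean of the
#'   `"blank"` rows.
#' @return A list with `per_sample` (the non-blank rows with a
#'   `relative_intensity` column) and `per_group` (data frame `group, n,
#'   mean_relative, se_relative`).
#' @export
relative_fluorescence <- function(samples, blank = NULL) {
  if (is.null(samples$group) || is.null(samples$intensity))
    stop("samples need 'group' and 'intensity' columns")
  if (is.null(blank)) {
    b <- samples$intensity[samples$group == "blank"]
    if (length(b) == 0) stop("no blank given and no 'blank' rows present")
    blank <- mean(b)
  }
  if (!is.finite(blank) || blank <= 0) stop("blank intensity must be positive")
  per_sample <- samples[samples$group != "blank", , drop = FALSE]
  per_sample$relative_intensity <- per_sample$intensity / blank
  agg <- split(per_sample$relative_intensity, per_sample$group)
  per_group <- data.frame(
    group = names(agg),
    n = vapply(agg, length, integer(1)),
    mean_relative = vapply(agg, mean, numeric(1)),
    se_relative = vapply(agg, function(x)
      if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_, numeric(1)))
  rownames(per_group) <- NULL
  list(per_sample = per_sample, per_group = per_group)
}
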