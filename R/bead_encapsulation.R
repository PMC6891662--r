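# Capsule geometry measurement and the encapsulation grading/index.
#
# The two grade schemes bin the capsule's angular coverage fraction
# A = covered degrees / 360 into five grades (0-4) and the capsule
# thickness ratio T = (sqrt(Area/pi) - R) / R into seven grades (0-6),
# where Area is the total bead-plus-capsule footprint and R the bead
# radius. The encapsulation index of a cohort is
# sum_g P_area(g) * g + sum_g P_thickness(g) * g with P the fraction of
# beads at each grade, which algebraically equals
# mean(area_grade) + mean(thickness_grade) and so lies in [0, 10].

# number of TRUE 8-neighbours of each pixel in a logical matrix
.neighbor_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- mask
  s <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) if (dr != 0 || dc != 0)
    s <- s + p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  s
}

#' Segment the bead in a single-bead image
#'
#' Thresholds at the bead intensity band, keeps the largest connected
#' component, and fits the equivalent circle: the centre is the component
#' centroid and the radius is `sqrt(area / pi)`. Because the bead band is
#' brighter than the capsule band, the fitted radius is the inner (bead)
#' radius even when a full annulus surrounds it.
#'
#' @param image Numeric matrix, intensities in `[0, 1]`.
#' @param config An [assay_config()]; `bead_threshold` separates bead from
#'   capsule, `pixel_size` calibrates the reported radius.
#' @param min_area Minimum component size in px^2 below which no bead is
#'   reported.
#' @return A list with `center` (`c(row, col)`), `radius_px` and
#'   `radius_um`.
#' @export
segment_bead <- function(image, config = assay_config(), min_area = 50) {
  mask <- image > config$bead_threshold
  if (!any(mask)) stop("no bead found: no pixels above bead_threshold")
  labels <- EBImage::bwlabel(mask)
  areas <- tabulate(labels[labels > 0])
  if (max(areas) < min_area) stop("no bead found: largest component below minimum size")
  best <- which.max(areas)
  idx <- which(labels == best, arr.ind = TRUE)
  center <- colMeans(idx)
  radius <- sqrt(areas[best] / pi)
  list(center = c(row = unname(center[1]), col = unname(center[2])),
       radius_px = radius, radius_um = radius * config$pixel_size)
}

#' Measure capsule angular coverage
#'
#' Scans the full circle from the bead centre at 1-degree resolution: a
#' degree is covered when capsule-band pixels exist beyond the bead radius
#' within that 1-degree sector. Sector membership is decided by
#' pixel-centre angle, which resolves ties at sector boundaries. Capsule
#' pixels with no capsule-classified 8-neighbour are discarded first, so an
#' isolated noise pixel cannot mark a stray degree while even a one-pixel
#' thin capsule arc (whose pixels adjoin each other) is kept intact.
#'
#' @param image Numeric matrix.
#' @param bead A [segment_bead()] result (or a list with `center` and
#'   `radius_px`).
#' @param config An [assay_config()]; the capsule band is
#'   `(capsule_low, bead_threshold]`.
#' @return Integer count of covered degrees in `[0, 360]`, with attribute
#'   `partial = TRUE` (and a warning) when the bead touches the image
#'   border and part of the circle is unobservable.
#' @export
measure_coverage_angle <- function(image, bead, config = assay_config()) {
  ctr <- bead$center; R <- bead$radius_px
  rows <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  cols <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)
  dx <- cols - ctr["col"]
  dy <- ctr["row"] - rows
  d <- sqrt(dx^2 + dy^2)
  capsule <- image > config$capsule_low & image <= config$bead_threshold &
    d > R
  capsule <- capsule & .neighbor_count(capsule) >= 1
  covered <- if (!any(capsule)) 0L else {
    ang <- (atan2(dy[capsule], dx[capsule]) * 180 / pi) %% 360
    bins <- tabulate(floor(ang) + 1, nbins = 360) > 0
    # close single-degree gaps: near the axes a thin annulus can skip one
    # 1-degree sector purely through pixel quantization (adjacent pixel
    # columns/rows there sit more than 1 degree apart)
    prv <- c(bins[360], bins[-360]); nxt <- c(bins[-1], bins[1])
    sum(bins | (prv & nxt))
  }
  partial <- ctr["row"] - R < 1 || ctr["row"] + R > nrow(image) ||
    ctr["col"] - R < 1 || ctr["col"] + R > ncol(image)
  if (partial) {
    warning("bead touches the image border; coverage measurement is partial")
    attr(covered, "partial") <- TRUE
  }
  covered
}

#' Measure the total bead-plus-capsule footprint area
#'
#' Counts pixels above the capsule-band lower threshold (bead and capsule
#' both exceed it) and converts to um^2 with the pixel calibration.
#'
#' @param image Numeric matrix.
#' @param config An [assay_config()]; `pixel_size` must be set.
#' @return Footprint area in um^2.
#' @export
measure_total_area <- function(image, config = assay_config()) {
  if (is.null(config$pixel_size) || !is.finite(config$pixel_size) ||
      config$pixel_size <= 0)
    stop("pixel_size calibration missing from config")
  sum(image > config$capsule_low) * config$pixel_size^2
}

#' Angular coverage fraction
#'
#' `A = coverage_deg / 360`, the fraction of the bead circumference covered
#' by capsule.
#'
#' @param coverage_deg Degrees in `[0, 360]`.
#' @return Fraction in `[0, 1]`.
#' @export
area_fraction <- function(coverage_deg) {
  if (any(coverage_deg < 0 | coverage_deg > 360))
    stop("coverage_deg must lie in [0, 360]")
  coverage_deg / 360
}

#' Capsule thickness ratio
#'
#' `T = (sqrt(total_area / pi) - R) / R`: the equivalent-circle radius of
#' the total bead-plus-capsule footprint, expressed as the excess over the
#' bead radius in units of the bead radius. Floored at 0 so that
#' segmentation jitter on a bare bead cannot produce a negative thickness.
#'
#' @param total_area Footprint area (bead plus capsule), same length unit
#'   squared as `radius`.
#' @param radius Bead radius, `> 0`.
#' @return Thickness ratio `>= 0`.
#' @export
thickness_ratio <- function(total_area, radius) {
  if (any(total_area < 0)) stop("total_area must be >= 0")
  if (any(radius <= 0)) stop("radius must be positive")
  pmax(0, sqrt(total_area / pi) / radius - 1)
}

#' Assign a capsule grade
#'
#' Bins a coverage fraction `A` into five grades (0-4, bin width 0.25) or a
#' thickness ratio `T` into seven grades (0-6; bin width 0.2 up to 1.0,
#' then a single bin for 1.0-2.0). Grade 0 is reserved for exactly 0 (no
#' capsule); the remaining bins are lower-exclusive/upper-inclusive, so
#' e.g. `A` in (0.25, 0.5] is grade 2. Thickness values beyond 2.0 clamp to
#' grade 6, keeping the index bounded at 10.
#'
#' @param value Nonnegative measurement(s); area values must not exceed 1.
#' @param scheme_part `"area"` or `"thickness"`.
#' @return Integer grade(s): 0-4 for area, 0-6 for thickness.
#' @examples
#' assign_grade(1/3, "area")       # grade 2
#' assign_grade(0.5, "thickness")  # grade 3
#' @export
assign_grade <- function(value, scheme_part = c("area", "thickness")) {
  scheme_part <- match.arg(scheme_part)
  if (any(!is.finite(value)) || any(value < 0))
    stop("grade values must be finite and >= 0")
  eps <- 1e-9
  if (scheme_part == "area") {
    if (any(value > 1 + eps)) stop("area fraction cannot exceed 1")
    g <- ceiling(pmin(value, 1) / 0.25 - eps)
  } else {
    g <- ifelse(value <= 1 + eps, ceiling(pmin(value, 1) / 0.2 - eps), 6L)
  }
  as.integer(pmax(g, 0))
}

#' Summarize a graded bead cohort: encapsulation index and rate
#'
#' Computes the grade distributions `P_area` (grades 0-4) and `P_thickness`
#' (grades 0-6) as fractions, the encapsulation index
#' `sum(P_thickness * grade) + sum(P_area * grade)` (range 0-10), and the
#' encapsulation rate, reported here as the fraction of beads showing any
#' capsule (area grade >= 1).
#'
#' @param measurements Data frame with integer columns `area_grade` (0-4)
#'   and `thickness_grade` (0-6), one row per bead.
#' @return An object of class `cohort_summary`: a list with `n_beads`,
#'   `P_area`, `P_thickness`, `encapsulation_index`, `encapsulation_rate`.
#' @examples
#' encapsulation_index(data.frame(area_grade = c(4, 2),
#'                                thickness_grade = c(6, 2)))
#' @export
encapsulation_index <- function(measurements) {
  if (!is.data.frame(measurements) || nrow(measurements) == 0)
    stop("measurements must be a nonempty data frame")
  a <- measurements$area_grade; t <- measurements$thickness_grade
  if (is.null(a) || is.null(t))
    stop("measurements needs area_grade and thickness_grade columns")
  if (any(a < 0 | a > 4) || any(t < 0 | t > 6) ||
      any(a != round(a)) || any(t != round(t)))
    stop("grades must be integers in 0-4 (area) and 0-6 (thickness)")
  P_area <- tabulate(a + 1, nbins = 5) / length(a)
  P_thickness <- tabulate(t + 1, nbins = 7) / length(t)
  structure(list(
    n_beads = nrow(measurements),
    P_area = stats::setNames(P_area, 0:4),
    P_thickness = stats::setNames(P_thickness, 0:6),
    encapsulation_index = sum(P_thickness * 0:6) + sum(P_area * 0:4),
    encapsulation_rate = mean(a >= 1)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Bead cohort summary (", x$n_beads, " beads)\n", sep = "")
  cat("  encapsulation index:", round(x$encapsulation_index, 3), "(0-10)\n")
  cat("  encapsulation rate: ", round(x$encapsulation_rate, 3), "\n")
  cat("  P(area grade 0-4):  ", paste(round(x$P_area, 3), collapse = " "), "\n")
  cat("  P(thick grade 0-6): ", paste(round(x$P_thickness, 3), collapse = " "), "\n")
  invisible(x)
}

#' Run the full bead-scoring pipeline on a cohort of images
#'
#' For each single-bead image: segment the bead, measure angular coverage
#' and total footprint area, derive `A`, `T` and the two grades, then
#' summarize the cohort with [encapsulation_index()]. An image that fails
#' (e.g. no bead found) contributes a flagged row instead of aborting the
#' cohort.
#'
#' @param images A list of numeric matrices, or of `list(image = ...)`
#'   pairs as returned by [generate_bead_cohort()].
#' @param config An [assay_config()].
#' @return A list with `per_bead` (data frame: `bead_id, ok, error,
#'   radius_um, coverage_deg, total_area, A, T, area_grade,
#'   thickness_grade`) and `summary` (a `cohort_summary` over the
#'   successfully graded beads).
#' @export
analyze_bead_cohort <- function(images, config = assay_config()) {
  if (length(images) == 0) stop("at least one image is required")
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    if (is.list(img)) img <- img$image
    tryCatch({
      bead <- segment_bead(img, config)
      cov <- measure_coverage_angle(img, bead, config)
      area <- measure_total_area(img, config)
      A <- area_fraction(cov)
      T <- thickness_ratio(area, bead$radius_um)
      data.frame(bead_id = i, ok = TRUE, error = NA_character_,
                 radius_um = bead$radius_um, coverage_deg = cov,
                 total_area = area, A = A, T = T,
                 area_grade = assign_grade(A, "area"),
                 thickness_grade = assign_grade(T, "thickness"))
    }, error = function(e) {
      data.frame(bead_id = i, ok = FALSE, error = conditionMessage(e),
                 radius_um = NA, coverage_deg = NA, total_area = NA,
                 A = NA, T = NA, area_grade = NA, thickness_grade = NA)
    })
  })
  per_bead <- do.call(rbind, rows)
  graded <- per_bead[per_bead$ok, ]
  summary <- if (nrow(graded) > 0) encapsulation_index(graded) else NULL
  list(per_bead = per_bead, summary = summary)
}
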