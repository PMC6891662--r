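# Seeded generators for synthetic bead and hemocyte imagery with exact
# ground truth. All randomness is local to the call: generators restore the
# caller's RNG state, so the same (parameters, seed) always gives the same
# output regardless of surrounding code.

# intensity bands used by the renderers; assay_config() thresholds sit
# between them
.bands <- list(background = 0.05, capsule = 0.45, cell = 0.70,
               bead = 0.90, nucleus = 0.90, spot = 1.00)

#' Ground-truth description of one encapsulated bead
#'
#' Parameters for a synthetic congo-red-stained chromatography bead
#' (rendered as a bright disk) partially surrounded by a hemocyte capsule
#' (an annular arc in a distinct intensity band). The capsule subtends
#' `coverage_deg` degrees and extends from the bead radius `R` out to
#' `R * (1 + thickness_ratio)`.
#'
#' @param bead_radius Bead radius in pixels (beads are < 150 um across; at
#'   the default 1 um/px calibration the default radius of 40 px emulates an
#'   80 um bead).
#' @param coverage_deg Angular extent of the capsule arc, degrees in
#'   `[0, 360]`.
#' @param thickness_ratio Capsule thickness as a fraction of the bead
#'   radius, `>= 0`.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise on
#'   the `[0, 1]` intensity scale (0.05 = 5% of full scale).
#' @param pixel_size Calibration in um per pixel.
#' @param arc_start_deg Angle at which the capsule arc begins, degrees
#'   counter-clockwise from +x.
#' @param seed Integer seed controlling the noise field.
#' @return An object of class `bead_truth`.
#' @seealso [generate_bead_image()], [bead_truth_measurement()]
#' @export
bead_truth <- function(bead_radius = 40, coverage_deg = 0,
                       thickness_ratio = 0, noise_sd = 0,
                       pixel_size = 1, arc_start_deg = 0, seed = 1L) {
  if (!is.numeric(coverage_deg) || coverage_deg < 0 || coverage_deg > 360)
    stop("coverage_deg must lie in [0, 360]")
  if (thickness_ratio < 0) stop("thickness_ratio must be >= 0")
  if (bead_radius <= 0) stop("bead_radius must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(bead_radius = bead_radius, coverage_deg = coverage_deg,
                 thickness_ratio = thickness_ratio, noise_sd = noise_sd,
                 pixel_size = pixel_size, arc_start_deg = arc_start_deg,
                 seed = as.integer(seed)),
            class = "bead_truth")
}

#' Render a synthetic bead image
#'
#' Draws the bead as a disk at intensity 0.90 and the capsule as a
#' concentric annular arc at intensity 0.45 on a 0.05 background, then adds
#' seeded Gaussian noise clipped to `[0, 1]`. A pixel belongs to a structure
#' when its centre falls inside the analytic region, so measured pixel areas
#' track the analytic disk/annulus areas to within rasterization error
#' (about 2% for radii of 20 px and above).
#'
#' @param truth A [bead_truth()] object.
#' @param image_size Optional `c(rows, cols)`; defaults to a square canvas
#'   2.4 times the capsule outer radius. Must be at least 2.2 times the
#'   outer radius `bead_radius * (1 + thickness_ratio)`.
#' @param bead_center Optional `c(row, col)` centre; defaults to the canvas
#'   centre. The full capsule footprint must fit inside the canvas.
#' @return A list with elements `image` (numeric matrix) and `truth`.
#' @examples
#' b <- generate_bead_image(bead_truth(bead_radius = 30, coverage_deg = 180,
#'                                     thickness_ratio = 0.5))
#' dim(b$image)
#' @export
generate_bead_image <- function(truth, image_size = NULL, bead_center = NULL) {
  stopifnot(inherits(truth, "bead_truth"))
  r_out <- truth$bead_radius * (1 + truth$thickness_ratio)
  if (is.null(image_size)) {
    side <- ceiling(2.4 * r_out)
    image_size <- c(side, side)
  }
  if (any(image_size < 2.2 * r_out))
    stop("image_size too small: each dimension must be >= 2.2 * outer radius")
  if (is.null(bead_center)) bead_center <- (image_size + 1) / 2
  if (bead_center[1] - r_out < 1 || bead_center[1] + r_out > image_size[1] ||
      bead_center[2] - r_out < 1 || bead_center[2] + r_out > image_size[2])
    stop("bead footprint extends beyond the canvas")

  rows <- matrix(seq_len(image_size[1]), image_size[1], image_size[2])
  cols <- matrix(seq_len(image_size[2]), image_size[1], image_size[2],
                 byrow = TRUE)
  dx <- cols - bead_center[2]
  dy <- bead_center[1] - rows            # y up
  d <- sqrt(dx^2 + dy^2)

  img <- matrix(.bands$background, image_size[1], image_size[2])
  if (truth$coverage_deg > 0 && truth$thickness_ratio > 0) {
    ang <- (atan2(dy, dx) * 180 / pi) %% 360
    offset <- (ang - truth$arc_start_deg) %% 360
    capsule <- d > truth$bead_radius & d <= r_out &
      offset <= truth$coverage_deg
    img[capsule] <- .bands$capsule
  }
  img[d <= truth$bead_radius] <- .bands$bead

  if (truth$noise_sd > 0) {
    img <- withr::with_seed(truth$seed, {
      img + matrix(rnorm(length(img), 0, truth$noise_sd),
                   nrow(img), ncol(img))
    })
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  list(image = img, truth = truth)
}

#' Analytic ground-truth measurement for a bead truth
#'
#' Computes, without rasterization, the quantities the image pipeline
#' estimates: angular coverage fraction `A = coverage_deg / 360`, the total
#' bead-plus-capsule footprint area, the capsule thickness ratio
#' `T = sqrt(Area / pi) / R - 1` derived from that footprint, and the two
#' grades. Used as the exact oracle when validating the pipeline.
#'
#' @param truth A [bead_truth()] object.
#' @return A one-row data frame with columns `A`, `T`, `total_area`
#'   (um^2), `area_grade`, `thickness_grade`.
#' @export
bead_truth_measurement <- function(truth) {
  stopifnot(inherits(truth, "bead_truth"))
  R <- truth$bead_radius * truth$pixel_size
  A <- truth$coverage_deg / 360
  r_out <- R * (1 + truth$thickness_ratio)
  area <- pi * R^2 + A * pi * (r_out^2 - R^2)
  T <- thickness_ratio(area, R)
  data.frame(A = A, T = T, total_area = area,
             area_grade = assign_grade(A, "area"),
             thickness_grade = assign_grade(T, "thickness"))
}

# draw n values from a small distribution spec:
#   list(dist = "uniform", min =, max =)
#   list(dist = "fixed", value =)
#   list(dist = "discrete", values =, probs = NULL)
.draw_dist <- function(spec, n) {
  if (!is.list(spec) || is.null(spec$dist))
    stop("distribution spec must be a list with a 'dist' element")
  switch(spec$dist,
    uniform = {
      if (is.null(spec$min) || is.null(spec$max) || spec$min > spec$max)
        stop("uniform spec needs min <= max")
      runif(n, spec$min, spec$max)
    },
    fixed = {
      if (is.null(spec$value)) stop("fixed spec needs a value")
      rep(spec$value, n)
    },
    discrete = {
      if (is.null(spec$values)) stop("discrete spec needs values")
      sample(spec$values, n, replace = TRUE, prob = spec$probs)
    },
    stop("unknown distribution '", spec$dist, "'")
  )
}

#' Generate a cohort of synthetic bead images
#'
#' Draws per-bead coverage and thickness independently from the given
#' distribution specs and renders each bead with [generate_bead_image()].
#' Emulates the assay setup of ten chromatography beads per tube.
#'
#' @param n_beads Number of beads, `>= 1`.
#' @param coverage_dist,thickness_dist Distribution specs: a list with
#'   `dist = "uniform"` (`min`, `max`), `dist = "fixed"` (`value`) or
#'   `dist = "discrete"` (`values`, optional `probs`).
#' @param seed Master seed; per-bead noise seeds are derived from it.
#' @param bead_radius,noise_sd,pixel_size Passed to [bead_truth()].
#' @return A list of length `n_beads` of `list(image, truth)` pairs.
#' @examples
#' cohort <- generate_bead_cohort(3,
#'   coverage_dist  = list(dist = "uniform", min = 90, max = 360),
#'   thickness_dist = list(dist = "fixed", value = 0.5), seed = 7)
#' length(cohort)
#' @export
generate_bead_cohort <- function(n_beads, coverage_dist, thickness_dist,
                                 seed = 1L, bead_radius = 40, noise_sd = 0,
                                 pixel_size = 1) {
  if (!is.numeric(n_beads) || n_beads < 1)
    stop("n_beads must be >= 1")
  n_beads <- as.integer(n_beads)
  draws <- withr::with_seed(as.integer(seed), {
    list(coverage = .draw_dist(coverage_dist, n_beads),
         thickness = .draw_dist(thickness_dist, n_beads),
         seeds = sample.int(.Machine$integer.max, n_beads))
  })
  if (any(draws$coverage < 0 | draws$coverage > 360))
    stop("coverage_dist produced values outside [0, 360]")
  if (any(draws$thickness < 0))
    stop("thickness_dist produced negative values")
  lapply(seq_len(n_beads), function(i) {
    generate_bead_image(bead_truth(
      bead_radius = bead_radius, coverage_deg = draws$coverage[i],
      thickness_ratio = draws$thickness[i], noise_sd = noise_sd,
      pixel_size = pixel_size, seed = draws$seeds[i]))
  })
}

#' Ground-truth description of a hemocyte field
#'
#' Parameters for a synthetic field of attached hemocytes: a controllable
#' fraction of spread (pseudopod-bearing, star-silhouette) versus round
#' cells, a mixture of cell types, and a controllable fraction of
#' phagocytic cells carrying labelled-bacteria spots.
#'
#' @param n_cells Number of cells to place.
#' @param spread_fraction Probability that a cell is rendered spread.
#' @param type_mix Named fractions for `plasmatocyte`, `granulocyte`,
#'   `other`; must sum to 1.
#' @param phagocytic_fraction Probability that a cell has engulfed at least
#'   one bacterium.
#' @param mean_spots Expected engulfed bacteria per phagocytic cell; counts
#'   are drawn as `1 + Poisson(mean_spots - 1)` so every phagocytic cell
#'   carries at least one spot.
#' @param noise_sd Additive Gaussian noise sd on the `[0, 1]` scale.
#' @param seed Integer seed.
#' @return An object of class `field_truth`.
#' @export
field_truth <- function(n_cells = 100, spread_fraction = 0.5,
                        type_mix = c(plasmatocyte = 0.45,
                                     granulocyte = 0.45, other = 0.10),
                        phagocytic_fraction = 0, mean_spots = 2,
                        noise_sd = 0, seed = 1L) {
  if (spread_fraction < 0 || spread_fraction > 1)
    stop("spread_fraction must lie in [0, 1]")
  if (phagocytic_fraction < 0 || phagocytic_fraction > 1)
    stop("phagocytic_fraction must lie in [0, 1]")
  if (abs(sum(type_mix) - 1) > 1e-9)
    stop("type_mix must sum to 1")
  if (!all(c("plasmatocyte", "granulocyte", "other") %in% names(type_mix)))
    stop("type_mix needs plasmatocyte, granulocyte and other entries")
  if (mean_spots < 1) stop("mean_spots must be >= 1")
  structure(list(n_cells = as.integer(n_cells),
                 spread_fraction = spread_fraction,
                 type_mix = type_mix,
                 phagocytic_fraction = phagocytic_fraction,
                 mean_spots = mean_spots, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "field_truth")
}

# star silhouette radius at angle theta (radians)
.star_radius <- function(theta, r0, arms, amp, phase) {
  r0 * (1 + amp * cos(arms * theta + phase))
}

# (row, col) index matrix of the pixels inside one silhouette, for painting
# by direct assignment (avoids copying the full canvas per cell)
.cell_pixels <- function(dim_img, cr, cc, r0, arms, amp, phase) {
  rmax <- ceiling(r0 * (1 + amp)) + 1
  rr <- max(1, floor(cr - rmax)):min(dim_img[1], ceiling(cr + rmax))
  cc2 <- max(1, floor(cc - rmax)):min(dim_img[2], ceiling(cc + rmax))
  dx <- outer(rep(1, length(rr)), cc2 - cc)
  dym <- outer(cr - rr, rep(1, length(cc2)))
  d <- sqrt(dx^2 + dym^2)
  th <- atan2(dym, dx)
  inside <- d <= .star_radius(th, r0, arms, amp, phase)
  cbind(rep(rr, length(cc2))[inside],
        rep(cc2, each = length(rr))[inside])
}

#' Generate a synthetic hemocyte field with ground truth
#'
#' Places non-overlapping cells at random positions and renders three
#' registered channels: a DIC-like cell-body channel (spread cells as
#' star/ramified silhouettes with low circularity, round cells as disks), a
#' nuclei channel (one bright nucleus per cell, used as watershed seeds
#' downstream), and a bacteria channel with bright spots inside phagocytic
#' cells. Spots are placed fully inside the silhouette and at least 4 px
#' apart; in the rare case a drawn count cannot be placed without merging,
#' the record reports the count actually rendered, keeping the ground truth
#' exact.
#'
#' @param truth A [field_truth()] object.
#' @param image_size Optional `c(rows, cols)`; defaults to a square sized so
#'   the requested number of cells places comfortably.
#' @return A list with `dic_channel`, `nuclei_channel`, `bacteria_channel`
#'   (numeric matrices) and `records`, a data frame with one row per cell:
#'   `cell_id, type, center_row, center_col, radius, arms, spread,
#'   phagocytic, engulfed_count`.
#' @export
generate_hemocyte_field <- function(truth, image_size = NULL) {
  stopifnot(inherits(truth, "field_truth"))
  n <- truth$n_cells
  if (is.null(image_size)) {
    side <- max(128L, ceiling(sqrt(n) * 75))
    image_size <- c(side, side)
  }

  res <- withr::with_seed(truth$seed, {
    spread <- runif(n) < truth$spread_fraction
    type <- sample(names(truth$type_mix), n, replace = TRUE,
                   prob = truth$type_mix)
    phago <- runif(n) < truth$phagocytic_fraction
    r0 <- ifelse(spread, runif(n, 10, 14), runif(n, 8, 12))
    arms <- ifelse(spread, sample(4:6, n, replace = TRUE), 0L)
    amp <- ifelse(spread, 0.55, 0)
    phase <- runif(n, 0, 2 * pi)
    reff <- r0 * (1 + amp)

    # sequential random placement with bounded retries
    cr <- numeric(n); cc <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(300)) {
        cand_r <- runif(1, reff[i] + 2, image_size[1] - reff[i] - 1)
        cand_c <- runif(1, reff[i] + 2, image_size[2] - reff[i] - 1)
        if (i == 1 || all(sqrt((cr[seq_len(i - 1)] - cand_r)^2 +
                               (cc[seq_len(i - 1)] - cand_c)^2) >
                          reff[seq_len(i - 1)] + reff[i] + 2)) {
          cr[i] <- cand_r; cc[i] <- cand_c; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("field too crowded: could not place cell ", i,
             " after 300 attempts; enlarge image_size or reduce n_cells")
    }

    dic <- matrix(.bands$background, image_size[1], image_size[2])
    nuc <- matrix(.bands$background, image_size[1], image_size[2])
    bac <- matrix(0.02, image_size[1], image_size[2])
    engulfed <- integer(n)
    spot_r <- 1.2

    dims <- dim(dic)
    for (i in seq_len(n)) {
      dic[.cell_pixels(dims, cr[i], cc[i], r0[i], arms[i], amp[i],
                       phase[i])] <- .bands$cell
      nuc[.cell_pixels(dims, cr[i], cc[i], 3.5, 0, 0, 0)] <- .bands$nucleus
      if (phago[i]) {
        k <- 1L + rpois(1, truth$mean_spots - 1)
        sr <- numeric(0); sc <- numeric(0)
        for (s in seq_len(k)) {
          for (try in seq_len(60)) {
            a <- runif(1, 0, 2 * pi)
            u <- sqrt(runif(1)) * r0[i] * (1 - amp[i])
            pr <- cr[i] - u * sin(a); pc <- cc[i] + u * cos(a)
            # spot must sit fully inside the silhouette, clear of others
            edge <- .star_radius(a, r0[i], arms[i], amp[i], phase[i])
            if (u + spot_r + 1 <= edge &&
                (length(sr) == 0 ||
                 all(sqrt((sr - pr)^2 + (sc - pc)^2) >= 4))) {
              sr <- c(sr, pr); sc <- c(sc, pc)
              break
            }
          }
        }
        for (s in seq_along(sr))
          bac[.cell_pixels(dims, sr[s], sc[s], spot_r, 0, 0, 0)] <- .bands$spot
        engulfed[i] <- length(sr)
      }
    }

    if (truth$noise_sd > 0) {
      addn <- function(x) {
        x <- x + matrix(rnorm(length(x), 0, truth$noise_sd),
                        nrow(x), ncol(x))
        x[x < 0] <- 0; x[x > 1] <- 1; x
      }
      dic <- addn(dic); nuc <- addn(nuc); bac <- addn(bac)
    }

    list(dic_channel = dic, nuclei_channel = nuc, bacteria_channel = bac,
         records = data.frame(
           cell_id = seq_len(n), type = type,
           center_row = cr, center_col = cc, radius = r0, arms = arms,
           spread = spread, phagocytic = engulfed >= 1L,
           engulfed_count = engulfed))
  })
  res$truth <- truth
  res
}

#' Generate replicate fluorometer readings around group means
#'
#' Emulates bound-phalloidin fluorescence readings: positive lognormal
#' replicates with the requested mean and coefficient of variation per
#' treatment group, plus blank (saline) rows used downstream as the
#' denominator of relative fluorescence. Four biological replicates per
#' group is the assay's standard design.
#'
#' @param group_means Named (or unnamed) vector of positive group mean
#'   intensities, in arbitrary fluorescence units.
#' @param cv Coefficient of variation of the readings, in `[0, 1)`; `cv = 0`
#'   gives readings exactly equal to the group mean.
#' @param n_per_group Replicates per group (default 4).
#' @param blank_mean Positive mean of the blank readings.
#' @param seed Integer seed.
#' @return A data frame with columns `group`, `replicate`, `intensity`;
#'   blank rows carry group `"blank"`.
#' @export
generate_factin_readings <- function(group_means, cv = 0.1, n_per_group = 4,
                                     blank_mean, seed = 1L) {
  if (any(group_means <= 0) || blank_mean <= 0)
    stop("group_means and blank_mean must be positive")
  if (cv < 0 || cv >= 1) stop("cv must lie in [0, 1)")
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  gnames <- names(group_means)
  if (is.null(gnames)) gnames <- paste0("group", seq_along(group_means))
  means <- c(group_means, blank_mean)
  labels <- c(gnames, "blank")
  withr::with_seed(as.integer(seed), {
    out <- lapply(seq_along(means), function(i) {
      x <- if (cv == 0) rep(means[i], n_per_group) else {
        sdlog <- sqrt(log(1 + cv^2))
        rlnorm(n_per_group, log(means[i]) - sdlog^2 / 2, sdlog)
      }
      data.frame(group = labels[i], replicate = seq_len(n_per_group),
                 intensity = x)
    })
    do.call(rbind, out)
  })
}

#' Generate a synthetic docking pose table
#'
#' Per ligand, draws `n_conformers` binding energies uniformly within that
#' ligand's range (kcal/mol), emulating the repeated-conformer output of a
#' docking engine from which the lowest-energy pose is selected. The default
#' of ten conformers matches standard docking practice.
#'
#' @param ligands Character vector of ligand names.
#' @param n_conformers Conformers per ligand, `>= 1` (default 10).
#' @param energy_ranges A list of `c(lo, hi)` per ligand (recycled if a
#'   single range is given); finite, in kcal/mol.
#' @param seed Integer seed.
#' @return A data frame `ligand, conformer, binding_energy_kcal_mol`, with
#'   attribute `"truth"`: a data frame of each ligand's minimum energy.
#' @export
generate_docking_table <- function(ligands, n_conformers = 10,
                                   energy_ranges, seed = 1L) {
  if (length(ligands) == 0) stop("ligand list must be nonempty")
  if (n_conformers < 1) stop("n_conformers must be >= 1")
  if (!is.list(energy_ranges)) energy_ranges <- list(energy_ranges)
  if (length(energy_ranges) == 1)
    energy_ranges <- rep(energy_ranges, length(ligands))
  if (length(energy_ranges) != length(ligands))
    stop("energy_ranges must have one range per ligand")
  if (!all(vapply(energy_ranges,
                  function(r) length(r) == 2 && all(is.finite(r)) &&
                    r[1] <= r[2], logical(1))))
    stop("each energy range must be a finite c(lo, hi)")
  tab <- withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(seq_along(ligands), function(i) {
      r <- energy_ranges[[i]]
      data.frame(ligand = ligands[i], conformer = seq_len(n_conformers),
                 binding_energy_kcal_mol = runif(n_conformers, r[1], r[2]))
    }))
  })
  truth <- aggregate(binding_energy_kcal_mol ~ ligand, tab, min)
  names(truth)[2] <- "best_energy"
  attr(tab, "truth") <- truth
  tab
}
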