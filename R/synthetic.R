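# Procedural generator of labelled plant-like point clouds. The geometry is
# deliberately minimal — a planar ground patch, a thin near-vertical stem and
# curved drooping leaf sheets — but reproduces the two properties that make
# real scans hard to segment: severe class imbalance (stem is a few percent
# of points) and thin-sheet leaf surfaces adjacent to the stem.

#' Recipe for one synthetic plant
#'
#' Defaults emulate an early-growth-stage crop scan at desk scale: a stem
#' share of 5.5 % of points (the minority-class share observed in maize
#' training scans), ground and leaf splitting the remainder roughly evenly,
#' and metric lengths of the order of a young maize plant.
#'
#' @param n_points_target total number of points to draw.
#' @param ground_extent side length of the square ground patch (m).
#' @param stem_height stem height (m).
#' @param stem_radius stem radius (m); all stem points lie within this
#'   distance of the stem axis before noise.
#' @param n_leaves number of leaves (>= 1).
#' @param leaf_length,leaf_width leaf blade dimensions (m).
#' @param droop_angle how far the leaf tip bends down along the blade (rad).
#' @param stem_fraction target fraction of stem points, in (0, 0.5).
#' @param noise_sd Gaussian coordinate noise added to every point (m).
#' @param whorl add a cluster of short leaves at the stem tip, mimicking
#'   stems surrounded by leaves; off by default.
#' @param seed RNG seed; generation is fully deterministic given the recipe.
#' @return an object of class `plant_recipe`.
#' @export
plant_recipe <- function(n_points_target = 20000L, ground_extent = 0.30,
                         stem_height = 0.50, stem_radius = 0.005,
                         n_leaves = 6L, leaf_length = 0.25, leaf_width = 0.06,
                         droop_angle = 0.7, stem_fraction = 0.055,
                         noise_sd = 0.001, whorl = FALSE, seed = 1L) {
  r <- list(n_points_target = as.integer(n_points_target),
            ground_extent = ground_extent, stem_height = stem_height,
            stem_radius = stem_radius, n_leaves = as.integer(n_leaves),
            leaf_length = leaf_length, leaf_width = leaf_width,
            droop_angle = droop_angle, stem_fraction = stem_fraction,
            noise_sd = noise_sd, whorl = isTRUE(whorl), seed = as.integer(seed))
  stopifnot(r$n_points_target >= 10L, r$n_leaves >= 1L,
            r$ground_extent > 0, r$stem_height > 0, r$stem_radius > 0,
            r$leaf_length > 0, r$leaf_width > 0, r$noise_sd >= 0)
  if (r$stem_fraction <= 0 || r$stem_fraction >= 0.5)
    stop("stem_fraction must lie in (0, 0.5)")
  structure(r, class = "plant_recipe")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# Points on one leaf blade: a rectangular sheet bent downwards along its
# length (midrib arc of total angle `droop`) with a shallow transverse fold.
leaf_points <- function(n, attach, azimuth, length, width, droop,
                        elev0 = 0.95) {
  s <- sqrt(stats::runif(n))               # denser towards the tip, like scans
  w <- stats::runif(n, -1, 1)
  if (droop > 1e-9) {
    h <- (sin(elev0) - sin(elev0 - droop * s)) / droop
    v <- (cos(elev0 - droop * s) - cos(elev0)) / droop
  } else {
    h <- s * cos(elev0)
    v <- s * sin(elev0)
  }
  dirx <- cos(azimuth); diry <- sin(azimuth)
  half <- width / 2
  fold <- 0.25 * half * w^2                # transverse midrib fold
  cbind(attach[1L] + length * h * dirx - w * half * diry,
        attach[2L] + length * h * diry + w * half * dirx,
        attach[3L] + length * v + fold)
}

#' Generate one labelled synthetic plant
#'
#' Ground points (label 0) sample a plane patch at z = 0, stem points
#' (label 1) a solid, slightly curved vertical cylinder, and leaf points
#' (label 2) curved blades attached at distinct stem heights. Organ point
#' counts are drawn from a multinomial at the target class fractions
#' (ground and leaf split `1 - stem_fraction` evenly), so realised fractions
#' fluctuate like scanner density does. Leaves are kept clear of the ground
#' plane by construction.
#'
#' @param recipe a [plant_recipe()].
#' @param plant_id,day metadata for the returned cloud.
#' @return a semantic `point_cloud` with labels in `{0, 1, 2}`.
#' @export
generate_plant <- function(recipe, plant_id = NULL, day = 0L) {
  stopifnot(inherits(recipe, "plant_recipe"))
  r <- recipe
  if (is.null(plant_id)) plant_id <- sprintf("synthetic-%d", r$seed)
  with_seed(r$seed, {
    f_stem <- r$stem_fraction
    f_ground <- (1 - f_stem) / 2
    f_leaf <- 1 - f_stem - f_ground
    counts <- as.vector(stats::rmultinom(1L, r$n_points_target,
                                         c(f_ground, f_stem, f_leaf)))
    n_g <- counts[1L]; n_s <- counts[2L]; n_l <- counts[3L]

    half <- r$ground_extent / 2
    ground <- cbind(stats::runif(n_g, -half, half),
                    stats::runif(n_g, -half, half),
                    rep(0, n_g))

    t_s <- stats::runif(n_s)
    bend <- 0.8 * r$stem_radius            # subtle axis curvature
    ax <- bend * sin(pi * t_s)
    theta <- stats::runif(n_s, 0, 2 * pi)
    rad <- r$stem_radius * sqrt(stats::runif(n_s))
    stem <- cbind(ax + rad * cos(theta), rad * sin(theta),
                  t_s * r$stem_height)

    n_lv <- r$n_leaves + if (r$whorl) 3L else 0L
    per_leaf <- as.vector(stats::rmultinom(1L, n_l, rep(1, n_lv)))
    blades <- vector("list", n_lv)
    for (k in seq_len(n_lv)) {
      if (per_leaf[k] == 0L) next
      if (k <= r$n_leaves) {
        frac <- if (r$n_leaves == 1L) 0.6
                else 0.30 + 0.60 * (k - 1L) / (r$n_leaves - 1L)
        attach_z <- frac * r$stem_height
        len <- r$leaf_length
        droop <- r$droop_angle
      } else {                              # whorl: short leaves at the tip
        attach_z <- 0.97 * r$stem_height
        len <- 0.35 * r$leaf_length
        droop <- 0.5 * r$droop_angle
      }
      azim <- (k - 1L) * 137.5 * pi / 180
      pts <- leaf_points(per_leaf[k],
                         c(bend * sin(pi * attach_z / r$stem_height), 0,
                           attach_z),
                         azim, len, r$leaf_width, droop)
      clearance <- 2.5 * r$stem_radius      # keep blades off the ground plane
      lowest <- min(pts[, 3L])
      if (lowest < clearance) pts[, 3L] <- pts[, 3L] + (clearance - lowest)
      blades[[k]] <- pts
    }
    leaf <- do.call(rbind, blades[!vapply(blades, is.null, TRUE)])

    coords <- rbind(ground, stem, leaf)
    labels <- c(rep(0L, n_g), rep(1L, n_s), rep(2L, nrow(leaf)))
    if (r$noise_sd > 0)
      coords <- coords + matrix(stats::rnorm(length(coords), 0, r$noise_sd),
                                ncol = 3L)
    perm <- sample.int(nrow(coords))        # interleave organs like a scan
    point_cloud(coords[perm, , drop = FALSE], labels[perm],
                semantic_classes(), plant_id, day,
                sprintf("synthetic(seed=%d)", r$seed))
  })
}

#' Generate a growth series of one plant
#'
#' Day `t` (0-based) scales stem height, leaf length and the point budget by
#' `(1 + growth_rate)^t`, emulating the growing cloud sizes of daily scans.
#' Per-day seeds derive from the base seed, so the series is reproducible.
#'
#' @param base a [plant_recipe()] describing day 0.
#' @param n_days number of days (>= 1).
#' @param growth_rate per-day multiplicative growth (>= 0).
#' @param plant_id plant id shared by all days.
#' @return a `dataset_bundle` of `n_days` clouds.
#' @export
generate_growth_series <- function(base, n_days, growth_rate,
                                   plant_id = NULL) {
  stopifnot(inherits(base, "plant_recipe"), n_days >= 1L, growth_rate >= 0)
  if (is.null(plant_id)) plant_id <- sprintf("synthetic-%d", base$seed)
  clouds <- lapply(seq_len(n_days) - 1L, function(t) {
    f <- (1 + growth_rate)^t
    r <- base
    r$stem_height <- base$stem_height * f
    r$leaf_length <- base$leaf_length * f
    r$n_points_target <- as.integer(round(base$n_points_target * f))
    r$seed <- base$seed + t
    generate_plant(r, plant_id = plant_id, day = t)
  })
  dataset_bundle(clouds,
                 stats::setNames("train", plant_id),
                 sprintf("synthetic growth series (base seed %d)", base$seed))
}
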