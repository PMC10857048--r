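#' Synthetic thermal-scene parameters
#'
#' Ground truth for one simulated 8x8 sensor reading: a warm elliptical
#' human silhouette over a cooler uniform background. The silhouette is
#' an axis-aligned ellipse whose vertical (row) semi-axis is larger for
#' standing than for sitting and whose apparent size scales inversely
#' with the sensor-to-person distance; per-pixel body coverage blends
#' each pixel between background and body temperature.
#'
#' @param posture `"standing"`, `"sitting"` or `"none"` (empty scene).
#' @param distance sensor-to-person distance in metres, in (0, 1.5\].
#' @param background_temp background temperature in degrees Celsius.
#' @param body_temp apparent body surface temperature in degrees Celsius;
#'   must exceed `background_temp`.
#' @param thermistor_temp ambient temperature the device reports.
#' @param noise_sd standard deviation of additive i.i.d. Gaussian pixel
#'   noise in degrees Celsius (>= 0). The default 0.3 sits inside the
#'   sensor's stated 0.5-1.0 degree accuracy band.
#' @param center_col column coordinate of the silhouette centroid in the
#'   grid frame \[0, 8\]; default 4 (grid centre). Lateral sway scenes
#'   displace it.
#' @param seed optional integer seed; when set, [render_frame()] is
#'   deterministic in isolation, otherwise it draws from the current RNG
#'   stream.
#'
#' @details Default temperatures (background 13, body 31, ambient 18)
#'   are calibration choices, not physics claims: they are picked so the
#'   closed-form posture rule separates the two postures at the default
#'   distance. Reference geometry at 0.5 m: standing semi-axes 3.2 x 1.4
#'   pixels, sitting 1.25 x 0.8; both axes scale by `0.5 / distance`.
#'   The sitting geometry is sized against the detector's actual
#'   statistic — the interpolated-grid mean, which up-weights interior
#'   pixels relative to the raw frame mean under the align-corners
#'   resampling — so that at the default temperatures the noiseless
#'   postures fall on opposite sides of the standing threshold.
#' @return An object of class `scene_params` (a list of the above).
#' @export
scene_params <- function(posture = c("standing", "sitting", "none"),
                         distance = 0.5, background_temp = 13,
                         body_temp = 31, thermistor_temp = 18,
                         noise_sd = 0.3, center_col = 4, seed = NULL) {
  posture <- match.arg(posture)
  if (!(distance > 0 && distance <= 1.5)) {
    stop("'distance' must lie in (0, 1.5] metres", call. = FALSE)
  }
  if (body_temp <= background_temp) {
    stop("'body_temp' must exceed 'background_temp'", call. = FALSE)
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(
    list(posture = posture, distance = distance,
         background_temp = background_temp, body_temp = body_temp,
         thermistor_temp = thermistor_temp, noise_sd = noise_sd,
         center_col = center_col, seed = seed),
    class = "scene_params"
  )
}

# Reference silhouette semi-axes (rows, cols) in pixel units at the
# 0.5 m reference distance.
.silhouette_axes <- list(standing = c(3.2, 1.4), sitting = c(1.25, 0.8))
.reference_distance <- 0.5

# Fraction of each 8x8 pixel covered by the silhouette ellipse,
# midpoint-subsampled on an n_sub x n_sub grid per pixel. Deterministic.
coverage_matrix <- function(posture, distance, center_col = 4,
                            n_sub = 15L) {
  if (posture == "none") return(matrix(0, 8, 8))
  ax <- .silhouette_axes[[posture]] * (.reference_distance / distance)
  cr <- 4  # centroid row, grid coordinates [0, 8], (0,0) top-left
  cc <- center_col
  # subpixel midpoints along one axis of the full grid
  u <- (seq_len(8L * n_sub) - 0.5) / n_sub
  inside <- outer(((u - cr) / ax[1])^2, ((u - cc) / ax[2])^2, "+") <= 1
  # average n_sub x n_sub blocks down to 8 x 8
  block <- matrix(0, 8, 8)
  idx <- rep(seq_len(8L), each = n_sub)
  rs <- rowsum(inside + 0, idx)
  block <- t(rowsum(t(rs), idx)) / n_sub^2
  block
}

with_scene_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render one synthetic thermal frame
#'
#' Produces an 8x8 [thermal_frame()] from a [scene_params()] scene: each
#' pixel is blended from background towards body temperature by its
#' silhouette coverage fraction, additive Gaussian noise is applied, and
#' values are clamped to the sensor range \[-20, 80\] degrees Celsius.
#'
#' @param scene a [scene_params()].
#' @param timestamp timestamp attached to the frame, seconds.
#' @return A [thermal_frame()].
#' @examples
#' fr <- render_frame(scene_params("standing", noise_sd = 0, seed = 1))
#' mean(fr$pixels)
#' @export
render_frame <- function(scene, timestamp = 0) {
  stopifnot(inherits(scene, "scene_params"))
  cov <- coverage_matrix(scene$posture, scene$distance, scene$center_col)
  px <- scene$background_temp +
    cov * (scene$body_temp - scene$background_temp)
  px <- with_scene_seed(scene$seed, {
    if (scene$noise_sd > 0) px + stats::rnorm(64, 0, scene$noise_sd) else px
  })
  px <- pmin(pmax(px, -20), 80)
  thermal_frame(px, thermistor = scene$thermistor_temp,
                timestamp = timestamp)
}

#' Build a straight-line trajectory
#'
#' A trajectory is an ordered list of scenes with a shared noise stream;
#' its motion label derives from the distance sequence: strictly
#' decreasing distances mean the person approaches the sensor, strictly
#' increasing means they recede, constant means still.
#'
#' @param d_from,d_to start and end distances in metres.
#' @param n number of steps (frames).
#' @param posture posture held throughout.
#' @param ... further arguments to [scene_params()] (temperatures,
#'   noise, ...).
#' @param seed integer seed for the trajectory's noise stream.
#' @return An object of class `trajectory`: a list with `scenes` (list of
#'   [scene_params()]), `motion` label and `seed`.
#' @export
make_trajectory <- function(d_from, d_to, n, posture = "standing", ...,
                            seed = NULL) {
  stopifnot(n >= 1)
  d <- seq(d_from, d_to, length.out = n)
  motion <- if (n > 1 && all(diff(d) < 0)) "approaching"
            else if (n > 1 && all(diff(d) > 0)) "receding"
            else "still"
  scenes <- lapply(d, function(di) {
    scene_params(posture = posture, distance = di, ..., seed = NULL)
  })
  structure(list(scenes = scenes, motion = motion, seed = seed),
            class = "trajectory")
}

#' Simulate a labeled frame sequence from a trajectory
#'
#' Renders each scene of the trajectory in order under a single seeded
#' noise stream, attaching posture and motion ground-truth labels. In the
#' noiseless case a strictly decreasing distance sequence yields strictly
#' increasing frame means (hence a strictly increasing difference
#' factor), which is what grounds the detector's motion rule.
#'
#' @param traj a [make_trajectory()] trajectory.
#' @return A list with `frames` (list of [thermal_frame()]), `posture`
#'   (character vector) and `motion` (single ground-truth label).
#' @export
simulate_sequence <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$scenes) == 0L) stop("empty trajectory", call. = FALSE)
  render_all <- function() {
    lapply(seq_along(traj$scenes), function(i) {
      render_frame(traj$scenes[[i]],
                   timestamp = (i - 1) * 0.625)
    })
  }
  frames <- with_scene_seed(traj$seed, render_all())
  list(frames = frames,
       posture = vapply(traj$scenes, `[[`, "", "posture"),
       motion = traj$motion)
}

# Per-frame scene schedule for one state of the labeled dataset.
# Swing states oscillate with a 16-frame period (10 s at the 0.625 s
# sampling period): forward-backward sway modulates distance (apparent
# size), lateral sway modulates the centroid column.
state_schedule <- function(state, i, distance) {
  phase <- 2 * pi * (i - 1) / 16
  switch(state,
    standing = list(posture = "standing", distance = distance, center_col = 4),
    sitting  = list(posture = "sitting", distance = distance, center_col = 4),
    none     = list(posture = "none", distance = distance, center_col = 4),
    swingfb  = list(posture = "standing",
                    distance = 0.32 + 0.06 * sin(phase), center_col = 4),
    swinglr  = list(posture = "standing", distance = 0.45,
                    center_col = 4 + 1.5 * sin(phase)),
    stop("unknown state '", state, "'", call. = FALSE)
  )
}

.known_states <- c("standing", "sitting", "swingfb", "swinglr", "none")

#' Generate a labeled synthetic dataset
#'
#' Simulates `n_per_state` frames for each requested state and merges
#' them into the canonical 65-column tabular form: 64 pixel columns
#' `p00`..`p63` (row-major from the 8x8 grid) plus a `state` label
#' column. Each state's block is generated from an independent seeded
#' substream, so the dataset is reproducible and states can be
#' regenerated in isolation.
#'
#' Recognized states: `"standing"` and `"sitting"` (still postures at
#' the given distance), `"swingfb"` (continuous forward-backward sway:
#' the apparent silhouette size oscillates), `"swinglr"` (lateral sway:
#' the silhouette centroid column oscillates) and `"none"` (empty room).
#'
#' @param n_per_state frames per state (>= 1).
#' @param states character vector of state names.
#' @param background_temp,body_temp,thermistor_temp,noise_sd,distance
#'   scene parameters shared by all states; see [scene_params()].
#' @param seed integer master seed.
#' @return A data frame with `n_per_state * length(states)` rows and 65
#'   columns.
#' @examples
#' d <- generate_dataset(5, c("standing", "sitting"), seed = 1)
#' dim(d)  # 10 65
#' @export
generate_dataset <- function(n_per_state,
                             states = c("standing", "sitting",
                                        "swingfb", "swinglr"),
                             background_temp = 13, body_temp = 31,
                             thermistor_temp = 18, noise_sd = 0.3,
                             distance = 0.5, seed = 42) {
  if (n_per_state < 1) stop("'n_per_state' must be >= 1", call. = FALSE)
  unknown <- setdiff(states, .known_states)
  if (length(unknown)) {
    stop("unknown state(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  blocks <- lapply(seq_along(states), function(s) {
    rows <- with_scene_seed(seed + s, {
      lapply(seq_len(n_per_state), function(i) {
        sch <- state_schedule(states[s], i, distance)
        fr <- render_frame(
          scene_params(posture = sch$posture, distance = sch$distance,
                       background_temp = background_temp,
                       body_temp = body_temp,
                       thermistor_temp = thermistor_temp,
                       noise_sd = noise_sd, center_col = sch$center_col),
          timestamp = (i - 1) * 0.625)
        frame_to_row(fr)
      })
    })
    m <- do.call(rbind, rows)
    df <- as.data.frame(m)
    names(df) <- sprintf("p%02d", 0:63)
    df$state <- states[s]
    df
  })
  do.call(rbind, c(blocks, list(make.row.names = FALSE)))
}

#' Convert dataset rows back to thermal frames
#'
#' Rebuilds [thermal_frame()] objects from the 64 pixel columns of a
#' labeled dataset, attaching a common thermistor temperature (the
#' canonical CSV layout does not carry one).
#'
#' @param dataset a 65-column labeled dataset (or any data frame with
#'   pixel columns `p00`..`p63`).
#' @param thermistor_temp ambient temperature to attach to every frame.
#' @param sample_period seconds between consecutive rows, used for
#'   timestamps.
#' @return A list of [thermal_frame()] objects, with the dataset's
#'   `state` column (if present) as a `labels` attribute.
#' @export
dataset_to_frames <- function(dataset, thermistor_temp = 18,
                              sample_period = 0.625) {
  pcols <- sprintf("p%02d", 0:63)
  if (!all(pcols %in% names(dataset))) {
    stop("dataset lacks the 64 pixel columns p00..p63", call. = FALSE)
  }
  frames <- lapply(seq_len(nrow(dataset)), function(i) {
    thermal_frame(as.numeric(dataset[i, pcols]),
                  thermistor = thermistor_temp,
                  timestamp = (i - 1) * sample_period)
  })
  if ("state" %in% names(dataset)) {
    attr(frames, "labels") <- as.character(dataset$state)
  }
  frames
}
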