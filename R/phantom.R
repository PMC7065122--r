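#' Digital neck phantom for the MESE simulator
#'
#' Builds a 2D software phantom standing in for an axial neck slice:
#' a bulk "neck" ellipse of muscle, two circular vessel-wall annuli
#' with dark lumens (a dark-lumen surrogate for black-blood flow
#' suppression), a subcutaneous fat rim, and a labelled mobile "throat"
#' structure whose in-plane displacement models swallowing.
#'
#' The y axis (first array dimension) is the anteroposterior
#' phase-encode direction, so throat displacement and ghosting are
#' both along y.
#'
#' Tissue labels: 0 background, 1 muscle, 2 vessel wall, 3 lumen,
#' 4 throat, 5 fat rim.
#'
#' @param grid_shape integer length-2 `(ny, nx)`, at least `(64, 64)`.
#' @param rng_seed integer seed; the same seed gives identical maps.
#' @param config named list overriding tissue parameters; see
#'   [phantom_config()].
#' @return A `phantom_model` object with fields `proton_density`
#'   (arbitrary units, >= 0), `t2_map` (ms, > 0 where there is signal),
#'   `tissue_labels`, `grid_shape`, and `config`.
#' @examples
#' ph <- make_phantom(c(96, 96), rng_seed = 0)
#' table(ph$tissue_labels)
#' @export
make_phantom <- function(grid_shape = c(192L, 192L), rng_seed = 0L,
                         config = phantom_config()) {
  ny <- as.integer(grid_shape[1L]); nx <- as.integer(grid_shape[2L])
  if (ny < 64L || nx < 64L) {
    stop("grid too small to contain the vessel geometry (need >= 64 x 64)")
  }
  set.seed(rng_seed)
  cfg <- utils::modifyList(phantom_config(), config)

  # normalised coordinates in [-1, 1]; y anterior at low index
  y <- matrix(rep(seq(-1, 1, length.out = ny), nx), ny, nx)
  x <- matrix(rep(seq(-1, 1, length.out = nx), each = ny), ny, nx)

  labels <- matrix(0L, ny, nx)
  # bulk neck ellipse
  neck <- (y / 0.72)^2 + (x / 0.85)^2 <= 1
  labels[neck] <- 1L
  # fat rim: thin outer band of the neck ellipse
  rim <- neck & ((y / 0.72)^2 + (x / 0.85)^2 > 0.88)
  labels[rim] <- 5L

  # two carotid vessels, left/right of midline, slightly anterior
  vr_out <- cfg$wall_outer_radius   # in normalised units
  vr_in <- cfg$lumen_radius
  for (cx in c(-0.38, 0.38)) {
    r2 <- (y - (-0.12))^2 + (x - cx)^2
    labels[r2 <= vr_out^2] <- 2L
    labels[r2 <= vr_in^2] <- 3L
  }

  # mobile throat structure: anterior midline blob (tongue base/airway
  # wall); this is the component translated during swallowing events
  throat <- ((y - (-0.42)) / 0.20)^2 + (x / 0.24)^2 <= 1
  labels[throat & labels != 2L & labels != 3L] <- 4L

  pd_of <- c(cfg$pd_muscle, cfg$pd_wall, cfg$pd_lumen, cfg$pd_throat, cfg$pd_fat)
  t2_of <- c(cfg$t2_muscle_ms, cfg$t2_wall_ms, cfg$t2_lumen_ms,
             cfg$t2_throat_ms, cfg$t2_fat_ms)
  pd <- matrix(0, ny, nx)
  t2 <- matrix(1, ny, nx)  # positive everywhere; background has pd = 0
  for (lab in 1:5) {
    pd[labels == lab] <- pd_of[lab]
    t2[labels == lab] <- t2_of[lab]
  }
  # mild smooth texture so the object is not piecewise constant
  tex <- 1 + cfg$texture_amplitude *
    (sin(3.1 * pi * y + 0.7) * cos(2.3 * pi * x - 0.4))
  pd <- pd * tex

  structure(list(
    proton_density = pd,
    t2_map = t2,
    tissue_labels = labels,
    grid_shape = c(ny = ny, nx = nx),
    config = cfg
  ), class = "phantom_model")
}

#' Default phantom tissue parameters
#'
#' Proton densities are arbitrary units; T2 values are milliseconds and
#' bracket neck tissue at 3T (muscle ~35 ms, vessel wall ~50 ms, fat
#' ~80 ms).  The lumen proton density is ~0 to emulate black-blood
#' flow suppression.
#'
#' @return named list of parameters.
#' @export
phantom_config <- function() {
  list(
    pd_muscle = 0.80, t2_muscle_ms = 35,
    pd_wall = 1.00, t2_wall_ms = 50,
    pd_lumen = 0.002, t2_lumen_ms = 200,
    pd_throat = 0.90, t2_throat_ms = 60,
    pd_fat = 0.95, t2_fat_ms = 80,
    texture_amplitude = 0.06,
    wall_outer_radius = 0.10,
    lumen_radius = 0.055
  )
}

# image-domain component of the phantom that moves during events
# (throat label), and the static remainder
phantom_components <- function(phantom) {
  thr <- phantom$tissue_labels == 4L
  list(static = phantom$proton_density * !thr,
       throat = phantom$proton_density * thr,
       throat_mask = thr)
}

#' Smooth complex coil sensitivity maps
#'
#' Places `ncoils` Gaussian receive lobes around the object perimeter
#' with smooth per-coil phase (constant + linear + quadratic terms),
#' emulating a phased-array surface coil.  Maps are bandlimited by
#' construction and their root-sum-of-squares is strictly positive on
#' every pixel.
#'
#' @param phantom a [make_phantom()] result (defines the grid).
#' @param ncoils number of channels (default 10).
#' @param rng_seed integer seed for the small random perturbations of
#'   lobe positions/widths.
#' @param uniform if `TRUE`, return all-ones maps (single uniform
#'   "body coil"), useful for tests.
#' @return A `coil_profiles` object with `sensitivities`, a complex
#'   array `(ncoils, ny, nx)`, and `ncoils`.
#' @export
make_coil_profiles <- function(phantom, ncoils = 10L, rng_seed = 0L,
                               uniform = FALSE) {
  if (ncoils < 1L) stop("ncoils must be >= 1")
  ny <- phantom$grid_shape[["ny"]]; nx <- phantom$grid_shape[["nx"]]
  sens <- array(0 + 0i, dim = c(ncoils, ny, nx))
  if (uniform) {
    sens[] <- 1 + 0i
    return(structure(list(sensitivities = sens, ncoils = as.integer(ncoils)),
                     class = "coil_profiles"))
  }
  set.seed(rng_seed)
  y <- matrix(rep(seq(-1, 1, length.out = ny), nx), ny, nx)
  x <- matrix(rep(seq(-1, 1, length.out = nx), each = ny), ny, nx)
  ang <- seq(0, 2 * pi, length.out = ncoils + 1L)[seq_len(ncoils)] +
    stats::rnorm(ncoils, sd = 0.05)
  for (c in seq_len(ncoils)) {
    cy <- 1.05 * sin(ang[c]); cx <- 1.05 * cos(ang[c])
    width <- 0.55 * (1 + stats::rnorm(1, sd = 0.05))
    mag <- exp(-((y - cy)^2 + (x - cx)^2) / (2 * width^2))
    # smooth phase: slowly varying, keeps maps bandlimited
    ph <- stats::runif(1, -pi, pi) +
      0.6 * stats::rnorm(1) * y + 0.6 * stats::rnorm(1) * x +
      0.3 * stats::rnorm(1) * (y^2 - x^2)
    sens[c, , ] <- mag * exp(1i * ph)
  }
  structure(list(sensitivities = sens, ncoils = as.integer(ncoils)),
            class = "coil_profiles")
}

#' Root-sum-of-squares of coil sensitivities
#'
#' @param coils a [make_coil_profiles()] result.
#' @return `ny x nx` nonnegative matrix.
#' @export
coil_rss <- function(coils) {
  s <- coils$sensitivities
  sqrt(apply(abs(s)^2, c(2, 3), sum))
}
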