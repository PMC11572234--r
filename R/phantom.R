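#' @name phantoms
#' @title Synthetic ventricle and lesion phantoms
#'
#' @description
#' Stand-ins for clinical segmentations: paired elongated ventricle lobes
#' and star-convex lesions with a tunable irregularity parameter kappa.
#' kappa = 0 digitizes an exact ellipsoid; larger kappa adds band-limited
#' radial perturbations that lower solidity/convexity and raise concavity
#' index and fractal dimension, giving a controlled irregularity axis along
#' which marker behaviour can be validated.
NULL

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

voxel_centers_mm <- function(geometry) {
  lapply(1:3, function(ax)
    geometry$origin[ax] + (seq_len(geometry$dims[ax]) - 1) * geometry$spacing[ax])
}

#' Phantom specification
#'
#' @param geometry Grid the phantom is rendered on. The default
#'   96 x 96 x 48 at 1 x 1 x 2 mm keeps phantom tests fast; pass a
#'   0.86 x 0.86 x 3.0 mm geometry for protocol-like fixtures.
#' @param ventricle_semi_axes Semi-axes (mm) of each ventricle lobe,
#'   elongated along the second (anterior-posterior) axis by default.
#' @param ventricle_separation Centre-to-centre distance (mm) of the two
#'   lobes along the first axis; 0 fuses them into one body.
#' @param lesions List of lesion specs, each a list with \code{center_mm},
#'   \code{semi_axes_mm}, \code{kappa}, \code{seed}.
#' @return Object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(geometry = vol_geom(c(96, 96, 48), c(1, 1, 2)),
                         ventricle_semi_axes = c(5, 28, 7),
                         ventricle_separation = 18,
                         lesions = list()) {
  if (ventricle_separation < 0) stop("ventricle_separation must be >= 0")
  if (any(ventricle_semi_axes <= 0)) stop("ventricle semi-axes must be > 0")
  structure(list(geometry = geometry,
                 ventricle_semi_axes = as.numeric(ventricle_semi_axes),
                 ventricle_separation = as.numeric(ventricle_separation),
                 lesions = lesions),
            class = "phantom_spec")
}

#' Lesion specification helper
#'
#' @param center_mm Lesion centre in mm.
#' @param semi_axes_mm Base ellipsoid semi-axes in mm.
#' @param kappa Irregularity in [0, 1]; 0 = exact digitized ellipsoid.
#' @param seed Integer seed for the radial perturbation field.
#' @return A lesion spec list.
#' @export
lesion_spec <- function(center_mm, semi_axes_mm, kappa = 0, seed = 1L) {
  if (kappa < 0 || kappa > 1) stop("kappa must be in [0, 1]")
  if (any(semi_axes_mm <= 0)) stop("semi-axes must be > 0")
  list(center_mm = as.numeric(center_mm),
       semi_axes_mm = as.numeric(semi_axes_mm),
       kappa = as.numeric(kappa), seed = as.integer(seed))
}

voxelize_ellipsoid <- function(geometry, center_mm, semi_axes_mm) {
  cs <- voxel_centers_mm(geometry)
  ux <- (cs[[1]] - center_mm[1]) / semi_axes_mm[1]
  uy <- (cs[[2]] - center_mm[2]) / semi_axes_mm[2]
  uz <- (cs[[3]] - center_mm[3]) / semi_axes_mm[3]
  q <- outer(outer(ux^2, uy^2, `+`), uz^2, `+`)
  array(q <= 1, dim = geometry$dims)
}

#' Render the paired ventricle lobes
#'
#' Two disjoint elongated ellipsoidal lobes mimicking the lateral
#' ventricles, centred in the grid and separated along the first axis.
#' Deterministic (no randomness is involved in the template).
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return A \code{binary_mask}.
#' @export
make_ventricles <- function(spec) {
  g <- spec$geometry
  centre <- (g$dims - 1) / 2 * g$spacing + g$origin
  half <- spec$ventricle_separation / 2
  sa <- spec$ventricle_semi_axes
  extent_ok <- all(centre - c(half, 0, 0) - sa >= g$origin - g$spacing / 2) &&
    all(centre + c(half, 0, 0) + sa <=
          g$origin + (g$dims - 0.5) * g$spacing)
  if (!extent_ok) stop("ventricle lobes exceed the grid extent")
  left <- voxelize_ellipsoid(g, centre - c(half, 0, 0), sa)
  right <- voxelize_ellipsoid(g, centre + c(half, 0, 0), sa)
  m <- binary_mask(left | right, g)
  if (n_voxels(m) == 0L) stop("ventricle template rendered empty on this grid")
  m
}

# band-limited zero-mean directional noise: sum of random plane-wave
# harmonics over the unit sphere with a 1/sqrt(f) spectrum (multi-scale
# roughness), normalized to unit standard deviation. Returns a function of
# an n x 3 matrix of unit directions.
radial_noise_field <- function(seed, n_harmonics = 60, freq_range = c(3, 20)) {
  with_seed(seed, {
    dirs <- matrix(rnorm(3 * n_harmonics), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    freq <- exp(runif(n_harmonics, log(freq_range[1]), log(freq_range[2])))
    phase <- runif(n_harmonics, 0, 2 * pi)
    amp <- rnorm(n_harmonics) / sqrt(freq)
    amp <- amp / sqrt(sum(amp^2) / 2)
  })
  function(u) {
    g <- numeric(nrow(u))
    for (i in seq_len(n_harmonics))
      g <- g + amp[i] * cos(freq[i] * (u %*% dirs[i, ])[, 1] + phase[i])
    g
  }
}

#' Render one star-convex lesion
#'
#' The lesion radius along direction u is the ellipsoid radius times
#' \code{1 + kappa * amplitude * g(u)} (clipped to \code{clip}), where g is
#' a fixed band-limited zero-mean multi-scale noise field drawn from the
#' lesion seed, and the base semi-axes grow with kappa by
#' \code{1 + growth * kappa}. The extent coupling mirrors how irregular
#' confluent lesions present in cohort data - larger and more sprawling,
#' not merely rougher at fixed size - and is what lets the box-counting
#' fractal dimension rise along the irregularity axis while solidity and
#' convexity fall. Star-convexity keeps every lesion connected; kappa = 0
#' reproduces the exact digitized ellipsoid.
#'
#' @param geometry Grid to render on.
#' @param center_mm,semi_axes_mm,kappa,seed See \code{\link{lesion_spec}}.
#' @param growth Relative semi-axis growth per unit kappa.
#' @param amplitude Radial perturbation amplitude per unit kappa (in units
#'   of the local ellipsoid radius).
#' @param clip Lower/upper bounds of the radial multiplier; the upper bound
#'   caps outward spikes so the lesion envelope stays near its ellipsoid.
#' @return A \code{binary_mask} with attribute \code{clipped} (TRUE when the
#'   lesion support reached the grid boundary).
#' @export
make_lesion <- function(geometry, center_mm, semi_axes_mm, kappa = 0,
                        seed = 1L, growth = 2.4, amplitude = 0.36,
                        clip = c(0.45, 1.2)) {
  if (kappa < 0 || kappa > 1) stop("kappa must be in [0, 1]")
  g <- geometry
  cs <- voxel_centers_mm(g)
  semi <- semi_axes_mm * (1 + growth * kappa)
  rmax <- max(semi) * clip[2]
  rng <- lapply(1:3, function(ax)
    which(cs[[ax]] >= center_mm[ax] - rmax & cs[[ax]] <= center_mm[ax] + rmax))
  if (any(vapply(rng, length, integer(1)) == 0L))
    stop("lesion rendered empty: support lies outside the grid")
  grid <- as.matrix(expand.grid(x = cs[[1]][rng[[1]]],
                                y = cs[[2]][rng[[2]]],
                                z = cs[[3]][rng[[3]]]))
  v <- sweep(grid, 2, center_mm)
  r <- sqrt(rowSums(v^2))
  inside <- r == 0
  nz <- which(r > 0)
  u <- v[nz, , drop = FALSE] / r[nz]
  # ellipsoid radius along u
  r_ell <- 1 / sqrt((u[, 1] / semi[1])^2 +
                    (u[, 2] / semi[2])^2 +
                    (u[, 3] / semi[3])^2)
  radius <- if (kappa > 0) {
    gfun <- radial_noise_field(seed)
    r_ell * pmin(pmax(1 + kappa * amplitude * gfun(u), clip[1]), clip[2])
  } else r_ell
  inside[nz] <- r[nz] <= radius
  arr <- array(FALSE, dim = g$dims)
  sub <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  arr[sub[inside, , drop = FALSE]] <- TRUE
  if (!any(arr)) stop("lesion rendered empty on this grid")
  clipped <- any(vapply(1:3, function(ax) {
    ix <- sub[inside, ax]
    min(ix) == 1L || max(ix) == g$dims[ax]
  }, logical(1)))
  m <- binary_mask(arr, g)
  attr(m, "clipped") <- clipped
  m
}

#' Render a full participant phantom with ground truth
#'
#' Renders the ventricles and every lesion of the spec, builds the WMH mask
#' as the union of lesions minus ventricle voxels, and records per lesion
#' the intended type under the 3/10 mm distance rule together with its
#' margin to those decision boundaries. The truth labels come from each
#' lesion's own voxel distances to the ventricle surface, independently of
#' the component-based classifier they are used to validate.
#'
#' @param spec A \code{\link{phantom_spec}} with at least the geometry set.
#' @param radii The classification radii (mm) used for the truth labels.
#' @return List: \code{ventricles}, \code{wmh} (binary masks), and
#'   \code{truth} (data frame: lesion, type, d_min_mm, d_max_mm, margin_mm,
#'   n_voxels, clipped).
#' @export
make_participant_images <- function(spec, radii = c(3, 10)) {
  g <- spec$geometry
  vent <- make_ventricles(spec)
  dfield <- distance_field(vent)$values
  wmh <- array(FALSE, dim = g$dims)
  rows <- vector("list", length(spec$lesions))
  for (i in seq_along(spec$lesions)) {
    ls <- spec$lesions[[i]]
    lm <- make_lesion(g, ls$center_mm, ls$semi_axes_mm, ls$kappa, ls$seed)
    keep <- lm$data & !vent$data
    wmh <- wmh | keep
    dv <- dfield[keep]
    if (length(dv) == 0L) {
      rows[[i]] <- data.frame(lesion = i, type = NA_character_,
                              d_min_mm = NA_real_, d_max_mm = NA_real_,
                              margin_mm = NA_real_, n_voxels = 0L,
                              clipped = attr(lm, "clipped"))
      next
    }
    dmin <- min(dv); dmax <- max(dv)
    if (dmin > radii[1]) {
      type <- "deep"; margin <- dmin - radii[1]
    } else if (dmax > radii[2]) {
      type <- "confluent"; margin <- min(radii[1] - dmin, dmax - radii[2])
    } else {
      type <- "periventricular"; margin <- min(radii[1] - dmin, radii[2] - dmax)
    }
    rows[[i]] <- data.frame(lesion = i, type = type, d_min_mm = dmin,
                            d_max_mm = dmax, margin_mm = margin,
                            n_voxels = sum(keep),
                            clipped = attr(lm, "clipped"))
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lesion = integer(0), type = character(0),
               d_min_mm = numeric(0), d_max_mm = numeric(0),
               margin_mm = numeric(0), n_voxels = integer(0),
               clipped = logical(0))
  list(ventricles = vent, wmh = binary_mask(wmh, g), truth = truth)
}
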