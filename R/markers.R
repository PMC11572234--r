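#' @name shape-markers
#' @title Per-lesion 3D shape markers
#'
#' @description
#' Five markers describe lesion shape. For periventricular/confluent WMH:
#' solidity (V / V_hull), convexity (hull surface area / lesion surface
#' area), concavity index (a composite of the convexity and solidity
#' deficits) and box-counting fractal dimension; lower solidity/convexity
#' and higher concavity index / fractal dimension mean a more irregular
#' lesion. For deep WMH: eccentricity (principal-axis anisotropy; higher =
#' more elongated) and fractal dimension.
NULL

component_array <- function(x, pad = 1L) {
  # crop a lesion to its padded bounding box; returns logical array + spacing
  if (inherits(x, "lesion_component")) {
    vox <- x$voxels
    spacing <- x$geometry$spacing
  } else if (inherits(x, "binary_mask")) {
    idx <- which(x$data)
    if (length(idx) == 0L) stop("empty component")
    vox <- arrayInd(idx, x$geometry$dims)
    spacing <- x$geometry$spacing
  } else stop("expected a lesion_component or binary_mask")
  if (nrow(vox) == 0L) stop("empty component")
  lo <- apply(vox, 2, min) - pad
  hi <- apply(vox, 2, max) + pad
  dm <- hi - lo + 1L
  arr <- array(FALSE, dim = dm)
  arr[cbind(vox[, 1] - lo[1] + 1L, vox[, 2] - lo[2] + 1L, vox[, 3] - lo[3] + 1L)] <- TRUE
  list(arr = arr, spacing = spacing, offset = lo)
}

#' Lesion surface area
#'
#' Area (mm^2) of a sub-voxel isosurface extracted at level 0.5 from the
#' binary occupancy field. By default the field is first regularized with a
#' small Gaussian (sigma in voxel units) so that the piecewise-linear surface
#' tracks the underlying smooth boundary rather than the voxel staircase;
#' voxel-face counting, which overestimates oblique smooth surfaces by up to
#' about 1.5x, is available for sensitivity checks. For very small lesions
#' where smoothing would erase the object the sigma is halved until the
#' surface survives (sigma 0 = raw binary field, vertices at edge midpoints).
#'
#' @param x A \code{lesion_component} or \code{binary_mask}.
#' @param method \code{"isosurface"} (default) or \code{"voxel_faces"}.
#' @param smooth_sigma Gaussian sigma in voxels for the isosurface field.
#' @return Surface area in mm^2.
#' @export
surface_area <- function(x, method = c("isosurface", "voxel_faces"),
                         smooth_sigma = 0.7) {
  method <- match.arg(method)
  ca <- component_array(x, pad = if (method == "isosurface")
    max(2L, as.integer(ceiling(3 * smooth_sigma))) else 1L)
  arr <- ca$arr
  sp <- ca$spacing
  if (method == "voxel_faces") {
    area <- 0
    shift <- function(a, ax, by) {
      out <- array(FALSE, dim = dim(a))
      idx <- lapply(dim(a), seq_len)
      src <- idx; dst <- idx
      n <- dim(a)[ax]
      if (by == 1) { src[[ax]] <- 1:(n - 1); dst[[ax]] <- 2:n }
      else { src[[ax]] <- 2:n; dst[[ax]] <- 1:(n - 1) }
      out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
      out
    }
    face <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
    for (ax in 1:3) for (by in c(-1, 1))
      area <- area + face[ax] * sum(arr & !shift(arr, ax, by))
    return(area)
  }
  field <- array(as.numeric(arr), dim = dim(arr))
  sig <- smooth_sigma
  repeat {
    sm <- if (sig > 0)
      array(.gauss_smooth3d(field, dim(arr), sig), dim = dim(arr))
    else field
    if (max(sm) > 0.5 || sig == 0) break
    sig <- if (sig > 0.25) sig / 2 else 0
  }
  .isosurface_area(as.numeric(sm), dim(arr), sp, 0.5)
}

#' Convex hull volume and surface area
#'
#' Hull of the corner points of the lesion's surface voxels in physical mm,
#' so even a single voxel has positive hull volume (its own box).
#'
#' @param x A \code{lesion_component} or \code{binary_mask}.
#' @return List with \code{volume} (mm^3, \code{V_H}) and \code{area}
#'   (mm^2, \code{S_H}).
#' @export
convex_hull_metrics <- function(x) {
  ca <- component_array(x, pad = 1L)
  arr <- ca$arr
  sp <- ca$spacing
  d <- dim(arr)
  # surface voxels: at least one 6-neighbour is background
  idx <- which(arr)
  vox <- arrayInd(idx, d)
  interior <- rep(TRUE, nrow(vox))
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    nb <- vox
    nb[, ax] <- nb[, ax] + by
    interior <- interior & arr[nb]
  }
  surf <- vox[!interior, , drop = FALSE]
  if (nrow(surf) == 0L) surf <- vox
  # corner points: voxel i spans (i-1, i) in padded-grid units
  nxc <- d[1] + 1L; nyc <- d[2] + 1L
  corners <- integer(0)
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    key <- (surf[, 1] - 1L + ox) +
      (surf[, 2] - 1L + oy) * nxc +
      (surf[, 3] - 1L + oz) * nxc * nyc
    corners <- c(corners, key)
  }
  corners <- unique(corners)
  cx <- corners %% nxc
  cy <- (corners %/% nxc) %% nyc
  cz <- corners %/% (nxc * nyc)
  pts <- cbind(cx * sp[1], cy * sp[2], cz * sp[3])
  h <- .hull3d_metrics(pts)
  list(volume = h$volume, area = h$area)
}

#' Solidity: lesion volume over convex hull volume
#'
#' @param x A \code{lesion_component} or \code{binary_mask}, or a
#'   precomputed metrics list from \code{\link{component_shape_metrics}}.
#' @return Solidity in (0, 1]; 1 for convex bodies, lower = more irregular.
#' @export
solidity <- function(x) {
  m <- if (is.list(x) && !is.null(x$V) && !is.null(x$V_H)) x else
    component_shape_metrics(x, markers = "none")
  if (m$V_H <= 0) stop("degenerate hull: V_H = 0")
  min(m$V / m$V_H, 1)
}

#' Convexity: hull surface area over lesion surface area
#'
#' @inheritParams solidity
#' @return Convexity ratio; near 1 for smooth convex bodies (slightly above
#'   1 can occur because the meshed lesion surface is a smoothed estimate),
#'   lower for irregular surfaces.
#' @export
convexity <- function(x) {
  m <- if (is.list(x) && !is.null(x$S) && !is.null(x$S_H)) x else
    component_shape_metrics(x, markers = "none")
  if (m$S <= 0) stop("degenerate surface: S = 0")
  m$S_H / m$S
}

#' Concavity index
#'
#' Composite irregularity score combining the convexity deficit and the
#' solidity deficit. The default strategy is
#' \code{(2 - convexity) + (1 - solidity)}: 1.0 for an ideal convex body and
#' strictly increasing as either ratio falls. The formula is a named,
#' swappable strategy so an alternative composite can be substituted without
#' touching callers.
#'
#' @param convexity,solidity Marker values.
#' @param formula Strategy name (\code{"deficit_sum"}) or a
#'   \code{function(convexity, solidity)}.
#' @return Concavity index (dimensionless, >= ~1, higher = more irregular).
#' @export
concavity_index <- function(convexity, solidity, formula = "deficit_sum") {
  f <- if (is.function(formula)) formula else
    switch(formula,
           deficit_sum = function(cvx, sol) (2 - cvx) + (1 - sol),
           stop("unknown concavity formula: ", formula))
  f(convexity, solidity)
}

box_count_sizes <- function(max_side) {
  if (max_side < 2L) return(integer(0))
  s_all <- 2L^(0:floor(log2(max_side)))
  s_half <- s_all[s_all <= max_side / 2]
  if (length(s_half) >= 3L) s_half else s_all[seq_len(min(3L, length(s_all)))]
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes on a geometric ladder of cubic box sizes (powers of
#' two in voxel units, anchored at the lesion bounding-box corner) and
#' returns the least-squares slope of log N(s) against log(1/s), clamped to
#' [0, 3]. Counting is done in index space at the native grid, so a solid
#' cube of side 2^k gives exactly 3, a one-voxel-thick plane 2, a straight
#' line 1 whenever the box sizes divide the side. The ladder runs up to half
#' the bounding-box max side, extended to a minimum of three scales (never
#' beyond the side itself) for small lesions.
#'
#' @param x A \code{lesion_component} or \code{binary_mask}.
#' @return Fractal dimension, or \code{NA} (with a warning suppressed at
#'   aggregation level) when fewer than two usable scales exist.
#' @export
fractal_dimension <- function(x) {
  ca <- component_array(x, pad = 0L)
  vox <- arrayInd(which(ca$arr), dim(ca$arr)) - 1L  # 0-based, bbox-anchored
  max_side <- max(dim(ca$arr))
  sizes <- box_count_sizes(max_side)
  if (length(sizes) < 2L)
    stop("fractal dimension needs at least 2 usable box scales (component too small)")
  counts <- vapply(sizes, function(s) {
    b <- vox %/% s
    nb <- apply(b, 2, max) + 1L
    length(unique(b[, 1] + b[, 2] * nb[1] + b[, 3] * nb[1] * nb[2]))
  }, numeric(1))
  slope <- unname(coef(lm(log(counts) ~ I(log(1 / sizes))))[2])
  min(max(slope, 0), 3)
}

#' Eccentricity from second central moments
#'
#' Eigenvalues lambda1 >= lambda2 >= lambda3 of the covariance of the
#' lesion's voxel-centre coordinates (mm), with each voxel contributing its
#' own box moment (spacing^2 / 12) so that thin structures keep a positive
#' minor axis. Eccentricity is \code{sqrt(1 - lambda3/lambda1)}: 0 for an
#' isotropic body, approaching 1 for a needle. A single voxel is defined as
#' eccentricity 0 (for isotropic spacing; in general its box anisotropy).
#'
#' @param x A \code{lesion_component} or \code{binary_mask}.
#' @return Eccentricity in [0, 1).
#' @export
eccentricity <- function(x) {
  ca <- component_array(x, pad = 0L)
  vox <- arrayInd(which(ca$arr), dim(ca$arr))
  pts <- sweep(vox, 2, ca$spacing, `*`)
  cv <- if (nrow(pts) > 1) stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
        else matrix(0, 3, 3)
  cv <- cv + diag(ca$spacing^2 / 12)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  sqrt(max(0, 1 - ev[3] / ev[1]))
}

#' All geometric metrics and markers of one lesion
#'
#' @param x A \code{lesion_component} or \code{binary_mask}.
#' @param markers \code{"all"} or \code{"none"} (geometry only).
#' @param concavity_formula Passed to \code{\link{concavity_index}}.
#' @param surface_method,smooth_sigma Passed to \code{\link{surface_area}}.
#' @return List with V, S, V_H, S_H (mm^3 / mm^2) and, for
#'   \code{markers = "all"}, solidity, convexity, concavity_index,
#'   fractal_dimension, eccentricity.
#' @export
component_shape_metrics <- function(x, markers = "all",
                                    concavity_formula = "deficit_sum",
                                    surface_method = "isosurface",
                                    smooth_sigma = 0.7) {
  ca <- component_array(x, pad = 0L)
  spacing <- ca$spacing
  V <- sum(ca$arr) * prod(spacing)
  S <- surface_area(x, method = surface_method, smooth_sigma = smooth_sigma)
  h <- convex_hull_metrics(x)
  out <- list(V = V, S = S, V_H = h$volume, S_H = h$area)
  if (identical(markers, "none")) return(out)
  out$solidity <- solidity(out)
  out$convexity <- convexity(out)
  out$concavity_index <- concavity_index(out$convexity, out$solidity,
                                         formula = concavity_formula)
  out$fractal_dimension <- fractal_dimension(x)
  out$eccentricity <- eccentricity(x)
  out
}

#' Per-participant averaged shape markers
#'
#' Unweighted arithmetic mean of per-lesion markers over the lesions of each
#' type: solidity, convexity, concavity index and fractal dimension for
#' periventricular/confluent lesions; eccentricity and fractal dimension for
#' deep lesions. Lesions smaller than \code{min_voxels} are skipped (their
#' count is reported); a type with no scoreable lesion yields \code{NA}
#' markers, and such participants are later excluded case-wise from that
#' type's association models.
#'
#' @param typed A \code{typed_wmh} from \code{\link{merge_pv_confluent}}.
#' @param min_voxels Minimum lesion size for shape scoring (default 2: a
#'   single voxel has no usable box-counting scale).
#' @param ... Passed to \code{\link{component_shape_metrics}}.
#' @return One-row data frame: n_pvc, n_deep, n_skipped, solidity,
#'   convexity, concavity_index, fd_pvc, eccentricity, fd_deep.
#' @export
participant_markers <- function(typed, min_voxels = 2L, ...) {
  score <- function(comps) {
    comps <- Filter(function(c) c$n_voxels >= min_voxels, comps)
    lapply(comps, component_shape_metrics, ...)
  }
  pvc_all <- typed$pv_confluent
  deep_all <- typed$deep
  pvc <- score(pvc_all)
  deep <- score(deep_all)
  n_skipped <- (length(pvc_all) - length(pvc)) + (length(deep_all) - length(deep))
  avg <- function(ms, field) {
    if (length(ms) == 0L) return(NA_real_)
    mean(vapply(ms, function(m) m[[field]], numeric(1)))
  }
  data.frame(
    n_pvc = length(pvc), n_deep = length(deep), n_skipped = n_skipped,
    solidity = avg(pvc, "solidity"),
    convexity = avg(pvc, "convexity"),
    concavity_index = avg(pvc, "concavity_index"),
    fd_pvc = avg(pvc, "fractal_dimension"),
    eccentricity = avg(deep, "eccentricity"),
    fd_deep = avg(deep, "fractal_dimension")
  )
}
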