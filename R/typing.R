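#' Inflate a mask by a physical radius
#'
#' Thresholds the exact Euclidean distance field at \code{radius_mm}
#' (inclusive), which is exact under anisotropic spacing where iterated
#' structuring elements are not. Boundary voxels at exactly the radius are
#' inside the inflated mask. Radius 0 returns the input mask.
#'
#' @param mask A nonempty \code{binary_mask}.
#' @param radius_mm Non-negative inflation radius in millimetres.
#' @return A \code{binary_mask}.
#' @export
inflate_mask <- function(mask, radius_mm) {
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  if (n_voxels(mask) == 0L) stop("cannot inflate an empty mask")
  if (radius_mm == 0) return(mask)
  df <- distance_field(mask)
  out <- binary_mask(df$values <= radius_mm, mask$geometry)
  attr(out, "nifti_ref") <- attr(mask, "nifti_ref")
  out
}

new_lesion_component <- function(id, voxels, geometry, type = NA_character_) {
  structure(list(id = id,
                 voxels = voxels,  # n x 3 integer matrix of 1-based indices
                 n_voxels = nrow(voxels),
                 volume_ml = nrow(voxels) * voxel_volume_mm3(geometry) / 1000,
                 type = type,
                 geometry = geometry),
            class = "lesion_component")
}

#' @export
print.lesion_component <- function(x, ...) {
  cat(sprintf("<lesion_component> id %d, type %s, %d voxels (%.4g ml)\n",
              x$id, x$type, x$n_voxels, x$volume_ml))
  invisible(x)
}

components_as_list <- function(cc) {
  idx <- which(cc$labels > 0L)
  if (length(idx) == 0L) return(list())
  co <- arrayInd(idx, cc$geometry$dims)
  lab <- cc$labels[idx]
  ord <- order(lab)
  splits <- split(seq_along(idx)[ord], lab[ord])
  lapply(seq_len(cc$n), function(k) {
    rows <- splits[[as.character(k)]]
    new_lesion_component(k, co[rows, , drop = FALSE], cc$geometry)
  })
}

#' Classify WMH components by ventricle distance
#'
#' Applies the 3 mm / 10 mm rule per connected component: a component is
#' \emph{deep} if it has no voxel within 3 mm of the ventricles (no overlap
#' with the 3 mm-inflated ventricle mask), otherwise \emph{confluent} if it
#' extends beyond 10 mm from the ventricular wall, and \emph{periventricular}
#' if it stays within 10 mm.
#'
#' @param wmh A \code{labeled_components} of the WMH mask.
#' @param vent3,vent10 Ventricle masks inflated by the two radii;
#'   \code{vent3} must be a subset of \code{vent10}.
#' @return A list of \code{lesion_component} objects with type labels set.
#' @export
classify_components <- function(wmh, vent3, vent10) {
  stop_if_geom_mismatch(wmh$geometry, vent3$geometry, "WMH and 3 mm ventricle masks")
  stop_if_geom_mismatch(wmh$geometry, vent10$geometry, "WMH and 10 mm ventricle masks")
  if (any(vent3$data & !vent10$data))
    stop("the 3 mm inflated mask must be contained in the 10 mm inflated mask")
  comps <- components_as_list(wmh)
  lapply(comps, function(comp) {
    in3 <- vent3$data[comp$voxels]
    comp$type <- if (!any(in3)) {
      "deep"
    } else if (any(!vent10$data[comp$voxels])) {
      "confluent"
    } else {
      "periventricular"
    }
    comp
  })
}

#' Merge periventricular and confluent components
#'
#' Periventricular and confluent lesions overlap spatially and are analysed
#' as one category; deep lesions are kept separate.
#'
#' @param components List of classified \code{lesion_component}s.
#' @return Object of class \code{typed_wmh}: lists \code{pv_confluent} and
#'   \code{deep} plus per-type total volumes (ml).
#' @export
merge_pv_confluent <- function(components) {
  types <- vapply(components, function(x) x$type, character(1))
  if (anyNA(types)) stop("components must be classified before merging")
  pvc <- components[types %in% c("periventricular", "confluent")]
  deep <- components[types == "deep"]
  structure(list(
    pv_confluent = pvc,
    deep = deep,
    volume_pvc_ml = sum(vapply(pvc, function(x) x$volume_ml, numeric(1))),
    volume_deep_ml = sum(vapply(deep, function(x) x$volume_ml, numeric(1)))
  ), class = "typed_wmh")
}

#' @export
print.typed_wmh <- function(x, ...) {
  cat(sprintf("<typed_wmh> %d periventricular/confluent (%.4g ml), %d deep (%.4g ml)\n",
              length(x$pv_confluent), x$volume_pvc_ml,
              length(x$deep), x$volume_deep_ml))
  invisible(x)
}

#' Full WMH typing stage
#'
#' Convenience wrapper: optionally intersects the WMH mask with a brain mask
#' (to correct oversegmentation outside the brain), removes WMH voxels lying
#' inside the ventricles themselves (segmentation spill-in: lesion shape
#' should not include CSF space), labels connected components, inflates the
#' ventricle mask by the two radii, and classifies every component.
#'
#' @param wmh_mask,ventricle_mask Co-registered \code{binary_mask}s.
#' @param radii Two increasing inflation radii in mm (default 3 and 10).
#' @param connectivity Component connectivity (default 26).
#' @param brain_mask Optional \code{binary_mask}; WMH voxels outside it are
#'   dropped before typing.
#' @return List with \code{components} (classified list), \code{typed}
#'   (\code{\link{merge_pv_confluent}} result), \code{type_codes} (integer
#'   array: 1 periventricular, 2 confluent, 3 deep), \code{cc},
#'   \code{vent3}, \code{vent10}, and a \code{table} data frame (one row per
#'   component: id, type, n_voxels, volume_ml).
#' @export
classify_wmh <- function(wmh_mask, ventricle_mask, radii = c(3, 10),
                         connectivity = 26, brain_mask = NULL) {
  if (length(radii) != 2L || radii[1] >= radii[2] || any(radii < 0))
    stop("radii must be two increasing non-negative values (mm)")
  stop_if_geom_mismatch(wmh_mask$geometry, ventricle_mask$geometry,
                        "WMH and ventricle masks")
  dat <- wmh_mask$data
  if (!is.null(brain_mask)) {
    stop_if_geom_mismatch(wmh_mask$geometry, brain_mask$geometry,
                          "WMH and brain masks")
    dat <- dat & brain_mask$data
  }
  dat <- dat & !ventricle_mask$data
  wmh <- binary_mask(dat, wmh_mask$geometry)
  cc <- connected_components(wmh, connectivity)
  df <- distance_field(ventricle_mask)
  vent3 <- binary_mask(df$values <= radii[1], wmh_mask$geometry)
  vent10 <- binary_mask(df$values <= radii[2], wmh_mask$geometry)
  comps <- classify_components(cc, vent3, vent10)

  codes <- c(periventricular = 1L, confluent = 2L, deep = 3L)
  type_codes <- array(0L, dim = wmh_mask$geometry$dims)
  for (comp in comps) type_codes[comp$voxels] <- codes[[comp$type]]

  tab <- data.frame(
    id = vapply(comps, function(x) x$id, integer(1)),
    type = vapply(comps, function(x) x$type, character(1)),
    n_voxels = vapply(comps, function(x) x$n_voxels, integer(1)),
    volume_ml = vapply(comps, function(x) x$volume_ml, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(components = comps, typed = merge_pv_confluent(comps),
       type_codes = type_codes, cc = cc, vent3 = vent3, vent10 = vent10,
       table = tab)
}
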