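#' Extract per-participant shape markers from one mask pair
#'
#' Runs typing (\code{\link{classify_wmh}}) and marker aggregation
#' (\code{\link{participant_markers}}) for one participant.
#'
#' @param wmh_mask,ventricle_mask Co-registered \code{binary_mask}s.
#' @param radii Inflation radii in mm.
#' @param connectivity Component connectivity.
#' @param min_voxels Minimum lesion size for shape scoring.
#' @param ... Passed to \code{\link{component_shape_metrics}}.
#' @return One-row data frame: lesion counts, the six markers, and
#'   \code{wmh_volume_ml}.
#' @export
extract_markers <- function(wmh_mask, ventricle_mask, radii = c(3, 10),
                            connectivity = 26, min_voxels = 2L, ...) {
  cls <- classify_wmh(wmh_mask, ventricle_mask, radii = radii,
                      connectivity = connectivity)
  mk <- participant_markers(cls$typed, min_voxels = min_voxels, ...)
  mk$wmh_volume_ml <- mask_volume_ml(wmh_mask)
  mk$volume_pvc_ml <- cls$typed$volume_pvc_ml
  mk$volume_deep_ml <- cls$typed$volume_deep_ml
  mk
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory for all run artifacts.
#' @param stages Stages to execute, in order, from
#'   \code{c("simulate", "classify", "extract", "associate")}.
#' @param n_participants Phantom cohort size for the simulate stage.
#' @param geometry Phantom grid.
#' @param radii Inflation radii (mm), strictly increasing.
#' @param connectivity 6 or 26.
#' @param min_voxels Minimum lesion size for shape scoring.
#' @param mean_lesions Mean lesion count per participant (Poisson + 1).
#' @param at_risk_only,invert_scope Statistics options, see
#'   \code{\link{run_association}}.
#' @param seed Master seed; per-participant seeds are derived from it.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(out_dir,
                       stages = c("simulate", "classify", "extract",
                                  "associate"),
                       n_participants = 20,
                       geometry = vol_geom(c(96, 96, 48), c(1, 1, 2)),
                       radii = c(3, 10), connectivity = 26,
                       min_voxels = 2L, mean_lesions = 5,
                       at_risk_only = TRUE, invert_scope = "logistic",
                       seed = 1L) {
  if (length(radii) != 2L || radii[1] >= radii[2])
    stop("radii must be strictly increasing")
  structure(list(out_dir = out_dir, stages = stages,
                 n_participants = as.integer(n_participants),
                 geometry = geometry, radii = radii,
                 connectivity = connectivity, min_voxels = min_voxels,
                 mean_lesions = mean_lesions, at_risk_only = at_risk_only,
                 invert_scope = invert_scope, seed = as.integer(seed)),
            class = "run_config")
}

config_fingerprint <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "out_dir")]),
             collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 997)) %% .Machine$integer.max)
}

participant_ids <- function(n) sprintf("P%03d", seq_len(n))

simulate_stage <- function(config, log_line) {
  g <- config$geometry
  img_dir <- file.path(config$out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- participant_ids(config$n_participants)
  extent <- (g$dims - 1) * g$spacing
  centre <- extent / 2
  truth_all <- list()
  kappa <- numeric(length(ids))
  wmh_vol <- numeric(length(ids))
  for (i in seq_along(ids)) {
    pseed <- config$seed * 1000L + i
    spec <- with_seed(pseed, {
      kap <- runif(1, 0.05, 0.8)
      nles <- 1L + rpois(1, config$mean_lesions)
      lesions <- lapply(seq_len(nles), function(j) {
        # mix of periventricular (near-surface) and deep placements
        deepish <- runif(1) < 0.5
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        offset <- if (deepish) runif(1, 18, 28) else runif(1, 6, 10)
        ctr <- pmin(pmax(centre + dir * offset, 8), extent - 8)
        lesion_spec(ctr, semi_axes_mm = sort(runif(3, 2.5, 6),
                                             decreasing = TRUE),
                    kappa = kap, seed = pseed + j)
      })
      phantom_spec(geometry = g, lesions = lesions)
    })
    kappa[i] <- spec$lesions[[1]]$kappa
    imgs <- make_participant_images(spec, radii = config$radii)
    write_mask(imgs$ventricles, file.path(img_dir, paste0(ids[i], "_vent.nii.gz")))
    write_mask(imgs$wmh, file.path(img_dir, paste0(ids[i], "_wmh.nii.gz")))
    tr <- imgs$truth
    tr$id <- ids[i]
    truth_all[[i]] <- tr
    wmh_vol[i] <- mask_volume_ml(imgs$wmh)
  }
  truth <- do.call(rbind, truth_all)
  write.csv(truth, file.path(config$out_dir, "truth.csv"), row.names = FALSE)

  # covariates and outcomes driven by the irregularity level
  cov_tab <- with_seed(config$seed * 1000L + 999L, {
    n <- length(ids)
    zk <- as.vector(scale(kappa))
    age <- rnorm(n, 74.5, 4.7)
    sex <- rbinom(n, 1, 0.61)
    delta <- 2 + 2 * zk + rnorm(n, 0, 2)
    icv0 <- rnorm(n, 1500, 140)
    df <- data.frame(id = ids, age = age, sex = sex, kappa = kappa,
                     wmh_volume_baseline = wmh_vol,
                     wmh_volume_followup = wmh_vol + delta,
                     icv_baseline = icv0,
                     icv_followup = icv0 + rnorm(n, -5, 8))
    prev <- c(subcortical_infarct = 0.1, microbleed = 0.25, epvs = 0.1,
              cerebellar_infarct = 0.15, cortical_infarct = 0.12)
    for (oc in names(prev)) {
      df[[paste0(oc, "_baseline")]] <- rbinom(n, 1, prev[[oc]])
      df[[paste0(oc, "_new")]] <-
        rbinom(n, 1, plogis(qlogis(prev[[oc]]) + 0.6 * zk))
    }
    df
  })
  write.csv(cov_tab, file.path(config$out_dir, "cohort.csv"),
            row.names = FALSE)
  log_line(sprintf("simulate: %d participants, %d lesions, %.2f ml total WMH",
                   length(ids), nrow(truth), sum(wmh_vol)))
  list(n_participants = length(ids), n_lesions = nrow(truth))
}

classify_stage <- function(config, log_line) {
  img_dir <- file.path(config$out_dir, "images")
  ids <- participant_ids(config$n_participants)
  rows <- list()
  for (id in ids) {
    wf <- file.path(img_dir, paste0(id, "_wmh.nii.gz"))
    vf <- file.path(img_dir, paste0(id, "_vent.nii.gz"))
    if (!file.exists(wf)) stop("participant ", id, ": missing WMH file ", wf)
    if (!file.exists(vf)) stop("participant ", id, ": missing ventricle file ", vf)
    wmh <- read_mask(wf)
    vent <- read_mask(vf)
    cls <- classify_wmh(wmh, vent, radii = config$radii,
                        connectivity = config$connectivity)
    write_mask(cls$type_codes, file.path(img_dir, paste0(id, "_types.nii.gz")),
               geometry = wmh$geometry, reference = wmh)
    tab <- cls$table
    if (nrow(tab)) tab$id <- id
    rows[[id]] <- tab
  }
  comp <- do.call(rbind, rows[vapply(rows, nrow, integer(1)) > 0])
  write.csv(comp, file.path(config$out_dir, "components.csv"),
            row.names = FALSE)
  log_line(sprintf("classify: %d components (%d pv, %d confluent, %d deep)",
                   nrow(comp), sum(comp$type == "periventricular"),
                   sum(comp$type == "confluent"), sum(comp$type == "deep")))
  list(n_components = nrow(comp))
}

extract_stage <- function(config, log_line) {
  img_dir <- file.path(config$out_dir, "images")
  ids <- participant_ids(config$n_participants)
  rows <- lapply(ids, function(id) {
    wmh <- read_mask(file.path(img_dir, paste0(id, "_wmh.nii.gz")))
    vent <- read_mask(file.path(img_dir, paste0(id, "_vent.nii.gz")))
    mk <- extract_markers(wmh, vent, radii = config$radii,
                          connectivity = config$connectivity,
                          min_voxels = config$min_voxels)
    cbind(data.frame(id = id), mk)
  })
  mk <- do.call(rbind, rows)
  write.csv(mk, file.path(config$out_dir, "markers.csv"), row.names = FALSE)
  log_line(sprintf("extract: %d participants scored, %d lesions skipped as too small",
                   nrow(mk), sum(mk$n_skipped)))
  list(n_scored = nrow(mk), n_skipped = sum(mk$n_skipped))
}

associate_stage <- function(config, log_line) {
  mk <- read.csv(file.path(config$out_dir, "markers.csv"),
                 stringsAsFactors = FALSE)
  cov_tab <- read.csv(file.path(config$out_dir, "cohort.csv"),
                      stringsAsFactors = FALSE)
  cohort <- merge(cov_tab, mk, by = "id")
  cohort <- derive_volumes(cohort)
  predictors <- c(pvc_markers, deep_markers, "wmh_volume_baseline")
  lin <- transform_predictors(cohort, predictors,
                              invert = config$invert_scope == "both")
  logi <- transform_predictors(cohort, predictors,
                               invert = config$invert_scope != "none")
  outcomes <- c("subcortical_infarct", "microbleed", "epvs",
                "cerebellar_infarct", "cortical_infarct")
  res <- list()
  skipped <- character(0)
  for (p in predictors) {
    res[[length(res) + 1L]] <- tryCatch(fit_linear(lin, p), error = function(e) {
      skipped <<- c(skipped, paste0(p, "/delta_wmh: ", conditionMessage(e)))
      NULL
    })
    for (oc in outcomes) {
      res[[length(res) + 1L]] <- tryCatch(
        fit_logistic(logi, p, paste0(oc, "_new"),
                     at_risk_only = config$at_risk_only),
        error = function(e) {
          skipped <<- c(skipped, paste0(p, "/", oc, ": ", conditionMessage(e)))
          NULL
        })
    }
  }
  res <- do.call(rbind, res)
  write.csv(res, file.path(config$out_dir, "results.csv"), row.names = FALSE)
  tab <- build_results_table(res)
  writeLines(c(attr(tab, "direction_note"), "",
               utils::capture.output(print(tab, quote = FALSE))),
             file.path(config$out_dir, "report.txt"))
  log_line(sprintf("associate: %d model fits, %d skipped", nrow(res),
                   length(skipped)))
  list(n_fits = nrow(res), n_skipped_fits = length(skipped),
       skipped = skipped)
}

#' Run the end-to-end phantom pipeline
#'
#' Executes the selected stages in order (simulate, classify, extract,
#' associate) under \code{out_dir} and writes a JSON manifest capturing the
#' configuration fingerprint, seed, per-stage counts and warnings. Identical
#' config and seed produce identical artifacts.
#'
#' @param config A \code{\link{run_config}}.
#' @return The manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  unlink(log_path)
  log_line <- function(msg) cat(msg, "\n", sep = "", file = log_path,
                                append = TRUE)
  stage_fns <- list(simulate = simulate_stage, classify = classify_stage,
                    extract = extract_stage, associate = associate_stage)
  bad <- setdiff(config$stages, names(stage_fns))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  manifest <- list(
    config_fingerprint = config_fingerprint(config),
    seed = config$seed,
    radii_mm = config$radii,
    connectivity = config$connectivity,
    min_voxels = config$min_voxels,
    invert_scope = config$invert_scope,
    at_risk_only = config$at_risk_only,
    stages = list()
  )
  for (st in config$stages) {
    out <- tryCatch(stage_fns[[st]](config, log_line), error = function(e) {
      stop("stage '", st, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[st]] <- out
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
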