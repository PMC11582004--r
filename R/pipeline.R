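#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis in one serialisable
#' object. Defaults are the values the analysis is calibrated to: striatal
#' mask at 2.0 x the occipital reference, cluster-defining p < 0.001 with
#' family-wise alpha 0.05, frame scrubbing at FD > 0.5 mm, putaminal
#' z cutoff -2.5, 0.01-0.08 Hz band-pass, 5 mm smoothing FWHM and 5 mm seed
#' radius.
#'
#' @param input_dir,output_dir study directories (see [simulate_study()] and
#'   [run_pipeline()]).
#' @param seed root RNG seed for all stochastic stages.
#' @param n_perm permutations for cluster inference.
#' @param mask_threshold local-SBR threshold of the DaTStriatum mask.
#' @param cdt_p cluster-defining one-sided p.
#' @param alpha family-wise significance level.
#' @param fd_threshold scrubbing threshold, mm.
#' @param z_cutoff putaminal z dichotomization cutoff.
#' @param bandpass_low,bandpass_high band-pass edges, Hz.
#' @param smoothing_fwhm Gaussian smoothing FWHM, mm.
#' @param seed_radius connectivity seed sphere radius, mm.
#' @param pi_variant performance-index parse (see [compute_pi()]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = NULL, seed = 1L,
                            n_perm = 5000L, mask_threshold = 2.0,
                            cdt_p = 0.001, alpha = 0.05, fd_threshold = 0.5,
                            z_cutoff = -2.5, bandpass_low = 0.01,
                            bandpass_high = 0.08, smoothing_fwhm = 5,
                            seed_radius = 5,
                            pi_variant = c("exp_shift", "exp_minus_one")) {
  pi_variant <- match.arg(pi_variant)
  stopifnot(mask_threshold > 0, cdt_p > 0, cdt_p < 1, alpha > 0, alpha < 1,
            fd_threshold > 0, bandpass_high > bandpass_low,
            smoothing_fwhm >= 0, seed_radius > 0, n_perm >= 100)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 seed = as.integer(seed), n_perm = as.integer(n_perm),
                 mask_threshold = mask_threshold, cdt_p = cdt_p,
                 alpha = alpha, fd_threshold = fd_threshold,
                 z_cutoff = z_cutoff, bandpass_low = bandpass_low,
                 bandpass_high = bandpass_high,
                 smoothing_fwhm = smoothing_fwhm, seed_radius = seed_radius,
                 pi_variant = pi_variant),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `path` / the restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[!vapply(vals, is.null, logical(1))])
}

#' Write a synthetic study directory
#'
#' Materialises a generated cohort as the on-disk layout [run_pipeline()]
#' consumes: `clinical.csv`, `keystrokes.csv`, `occipital_mask.nii.gz`,
#' one `volumes/<subject>.nii.gz` per subject and, optionally, normative
#' resting-state runs `rsfmri/run<k>.nii.gz` with motion files.
#'
#' @param dir output directory (created).
#' @param spec a [cohort_spec()].
#' @param n_rsfmri_runs number of normative resting-state runs to write
#'   (0 = skip the connectivity inputs).
#' @param rsfmri_frames frames per resting-state run.
#' @param rsfmri_center MNI centre of the resting-state phantom grid
#'   (placed over the posterior putamen by default so DaT-derived seeds fall
#'   inside it).
#' @return the cohort list from [gen_cohort()], invisibly.
#' @export
simulate_study <- function(dir, spec, n_rsfmri_runs = 0L,
                           rsfmri_frames = 400L,
                           rsfmri_center = c(-26, -14, 8)) {
  dir.create(file.path(dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  cohort <- gen_cohort(spec)
  utils::write.csv(cohort$records, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, cohort$logs),
                   file.path(dir, "keystrokes.csv"), row.names = FALSE)
  write_volume(cohort$regions$occipital,
               file.path(dir, "occipital_mask.nii.gz"))
  for (id in names(cohort$volumes)) {
    write_volume(cohort$volumes[[id]],
                 file.path(dir, "volumes", paste0(id, ".nii.gz")))
  }
  if (n_rsfmri_runs > 0L) {
    dir.create(file.path(dir, "rsfmri"), showWarnings = FALSE)
    layout <- rsfmri_layout(center_mm = rsfmri_center)
    for (k in seq_len(n_rsfmri_runs)) {
      run <- gen_rsfmri(layout, n_frames = rsfmri_frames,
                        seed = spec$seed + 20000L + k)
      base <- file.path(dir, "rsfmri", sprintf("run%02d", k))
      RNifti::writeNifti(
        RNifti::`sform<-`(RNifti::asNifti(run$data),
                          structure(layout$geom$affine, code = 4L)),
        paste0(base, ".nii.gz"))
      write_motion(run$motion, paste0(base, "_motion.txt"))
    }
    write_volume(layout$wm_mask, file.path(dir, "rsfmri", "wm_mask.nii.gz"))
    write_volume(layout$csf_mask, file.path(dir, "rsfmri", "csf_mask.nii.gz"))
  }
  invisible(cohort)
}

read_bold_run <- function(nii_path, motion_path, tr = 0.72) {
  img <- RNifti::readNifti(nii_path)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  new_bold_run(array(as.numeric(img), dim = dim(img)),
               aff, tr = tr, motion = read_motion(motion_path))
}

stage_msg <- function(log, stage, msg) {
  log[[length(log) + 1L]] <- list(stage = stage, message = msg,
                                  time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  log
}

#' Run the full analysis pipeline on a study directory
#'
#' Stages, in order: behavioural scoring (per-block curves and
#' online/offline learning measures), occipital rescaling to local SBR,
#' DaTStriatum mask construction (restricted to the task-contralateral left
#' hemisphere), right-to-left mirroring for left-hand trainers, striatal
#' summary metrics, voxelwise regression with cluster-level permutation FWE
#' for the UES (negative direction) and online-learning (positive
#' direction) covariates, peak-seed extraction, and - when resting-state
#' inputs are present - seed-based normative connectivity with group
#' inference and the binary overlap of the two networks. Outputs (CSV
#' tables, NIfTI maps, a provenance log) are written under
#' `config$output_dir`. Reruns with an identical config are bit-identical.
#'
#' @param config a [pipeline_config()] with `input_dir` and `output_dir`
#'   set.
#' @return list with the behavioural table, mask, cluster sets, seeds and
#'   (optionally) connectivity results; invisibly.
#' @export
run_pipeline <- function(config) {
  ind <- config$input_dir
  outd <- config$output_dir
  if (is.null(ind) || !dir.exists(ind)) stop("input_dir does not exist: ", ind)
  needed <- c("clinical.csv", "keystrokes.csv", "occipital_mask.nii.gz")
  missing_in <- needed[!file.exists(file.path(ind, needed))]
  if (length(missing_in)) {
    stop("missing input file(s): ", paste(missing_in, collapse = ", "))
  }
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  log <- list()

  ## --- behaviour ---------------------------------------------------------
  records <- utils::read.csv(file.path(ind, "clinical.csv"),
                             stringsAsFactors = FALSE)
  keys <- read_keystroke_log(file.path(ind, "keystrokes.csv"))
  behav <- do.call(rbind, lapply(records$subject_id, function(id) {
    sub <- keys[keys$subject == id, ]
    tr <- score_session(sub, "training", pi_variant = config$pi_variant)
    re <- score_session(sub, "retest", pi_variant = config$pi_variant)
    learning_metrics(tr, re)
  }))
  behav <- merge(records, behav, by.x = "subject_id", by.y = "subject",
                 sort = FALSE)
  utils::write.csv(behav, file.path(outd, "behaviour.csv"), row.names = FALSE)
  log <- stage_msg(log, "behaviour", sprintf("scored %d subjects", nrow(behav)))

  ## --- local SBR + mask --------------------------------------------------
  occ <- read_volume(file.path(ind, "occipital_mask.nii.gz"))
  occ <- new_mask(occ$data > 0.5, occ$affine, "occipital reference (input)")
  vols <- lapply(records$subject_id, function(id) {
    read_volume(file.path(ind, "volumes", paste0(id, ".nii.gz")))
  })
  names(vols) <- records$subject_id
  vols <- lapply(vols, rescale_local_sbr, occipital_mask = occ)
  if (!is.null(records$hand)) {
    for (i in which(records$hand == "left")) {
      vols[[i]] <- mirror_volume(vols[[i]])
    }
  }
  mask <- build_datstriatum_mask(vols, config$mask_threshold)
  xs <- array(voxel_grid_mni(mask)[, 1], dim(mask$data))
  mask <- new_mask(mask$data & xs < 0, mask$affine,
                   provenance = paste0(mask$provenance,
                                       "; restricted to left hemisphere"))
  write_volume(mask, file.path(outd, "datstriatum_mask.nii.gz"))
  summ <- striatal_summary_table(vols, mask)
  utils::write.csv(summ, file.path(outd, "striatal_summary.csv"),
                   row.names = FALSE)
  log <- stage_msg(log, "local_sbr",
                   sprintf("mask extent %d voxels", sum(mask$data)))

  ## --- voxelwise inference -----------------------------------------------
  contrasts <- list(
    ues = list(covariate = behav$ues, direction = "negative"),
    online = list(covariate = behav$online, direction = "positive"))
  cluster_sets <- list()
  seeds <- list()
  for (nm in names(contrasts)) {
    cs <- permutation_fwe(vols, contrasts[[nm]]$covariate, mask,
                          direction = contrasts[[nm]]$direction,
                          cdt_p = config$cdt_p, alpha = config$alpha,
                          n_perm = config$n_perm,
                          seed = config$seed, covariate_name = nm)
    cluster_sets[[nm]] <- cs
    write_cluster_table(cs, file.path(outd, sprintf("clusters_%s.csv", nm)))
    glm <- voxelwise_regression(vols, contrasts[[nm]]$covariate, mask,
                                direction = contrasts[[nm]]$direction,
                                covariate_name = nm)
    tm <- glm$t_map
    tm$data[is.na(tm$data)] <- 0
    write_volume(tm, file.path(outd, sprintf("tmap_%s.nii.gz", nm)))
    write_volume(significance_mask(cs),
                 file.path(outd, sprintf("sigmask_%s.nii.gz", nm)))
    if (any(cs$clusters$significant)) {
      seeds[[nm]] <- peak_seed(cs, config$seed_radius)
    }
    log <- stage_msg(log, paste0("voxelwise_", nm),
                     sprintf("%d cluster(s), %d significant",
                             nrow(cs$clusters), sum(cs$clusters$significant)))
  }

  ## --- normative connectivity (when inputs present) ----------------------
  connectivity <- NULL
  rsdir <- file.path(ind, "rsfmri")
  run_files <- if (dir.exists(rsdir)) {
    sort(list.files(rsdir, pattern = "^run[0-9]+\\.nii(\\.gz)?$",
                    full.names = TRUE))
  } else character(0)
  if (length(run_files) >= 3L && length(seeds) > 0L) {
    wm <- read_volume(file.path(rsdir, "wm_mask.nii.gz"))
    wm <- new_mask(wm$data > 0.5, wm$affine)
    csf <- read_volume(file.path(rsdir, "csf_mask.nii.gz"))
    csf <- new_mask(csf$data > 0.5, csf$affine)
    runs <- lapply(run_files, function(f) {
      read_bold_run(f, sub("\\.nii(\\.gz)?$", "_motion.txt", f))
    })
    prep <- lapply(runs, function(r) {
      r <- scrub_run(r, config$fd_threshold)
      r <- nuisance_regress(r, wm, csf)
      bandpass_run(r, config$bandpass_low, config$bandpass_high)
    })
    nets <- list()
    for (nm in names(seeds)) {
      ## seeds come from the SPECT analysis; both grids share MNI space
      geom_rs <- run_geometry(prep[[1L]])
      if (length(seed_voxels(geom_rs, seeds[[nm]])) == 0L) {
        log <- stage_msg(log, paste0("connectivity_", nm),
                         "seed outside resting-state grid; skipped")
        next
      }
      maps <- lapply(seq_along(prep), function(i) {
        seed_map(prep[[i]], seeds[[nm]], fwhm = config$smoothing_fwhm,
                 subject_id = sprintf("run%02d", i))
      })
      nets[[nm]] <- group_connectivity(maps, cdt_p = config$cdt_p,
                                       alpha = config$alpha,
                                       n_perm = min(config$n_perm, 2000L),
                                       seed = config$seed)
      write_cluster_table(nets[[nm]],
                          file.path(outd, sprintf("connectivity_%s.csv", nm)))
      log <- stage_msg(log, paste0("connectivity_", nm),
                       sprintf("%d significant cluster(s)",
                               sum(nets[[nm]]$clusters$significant)))
    }
    if (length(nets) == 2L) {
      ov <- overlap_map(nets[[1L]], nets[[2L]], config$alpha)
      write_volume(ov, file.path(outd, "connectivity_overlap.nii.gz"))
    }
    connectivity <- nets
  }

  ## --- provenance ---------------------------------------------------------
  inputs <- c(file.path(ind, needed),
              file.path(ind, "volumes",
                        paste0(records$subject_id, ".nii.gz")))
  prov <- list(config = unclass(config),
               input_md5 = as.list(tools::md5sum(inputs)),
               stages = log)
  yaml::write_yaml(prov, file.path(outd, "provenance.yaml"))

  invisible(list(behaviour = behav, mask = mask, clusters = cluster_sets,
                 seeds = seeds, connectivity = connectivity,
                 summary = summ))
}

#' Recompute every statistic derivable from the packaged cohort table
#'
#' Correlations of UES with caudate and putamen SBR, the putaminal-z
#' dichotomization with per-group demographics, the Mann-Whitney comparison
#' of UES between the DaT groups, and the mean levodopa-equivalent dose of
#' the medicated participants.
#'
#' @return named list of results.
#' @export
reproduce_table1 <- function() {
  d <- load_table1()
  grp <- dichotomize_dat(d)
  mw <- mann_whitney_u(d$ues[grp$labels == "DaT-"],
                       d$ues[grp$labels == "DaT+"])
  list(r_ues_putamen = pearson_cor(d$ues, d$sbr_putamen),
       r_ues_caudate = pearson_cor(d$ues, d$sbr_caudate),
       dichotomization = grp$summary,
       mann_whitney_ues = mw,
       mean_ledd_medicated = mean(d$ledd[d$ledd > 0]),
       n_medicated = sum(d$ledd > 0))
}
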