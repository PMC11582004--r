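#' Coarse MNI-like phantom geometry
#'
#' A 4 mm isotropic grid spanning roughly the MNI head volume, symmetric
#' about x = 0 (so right-to-left mirroring is exact), with room for both
#' striata and an occipital reference slab.
#'
#' @param voxel_mm isotropic voxel size (default 4 mm).
#' @return a `dat_volume` of zeros fixing dims and affine.
#' @export
phantom_geometry <- function(voxel_mm = 4) {
  dims <- c(24L, 30L, 20L)
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- c(-voxel_mm * (dims[1] - 1) / 2, -92, -30)
  new_volume(array(0, dims), affine)
}

#' Anatomical regions of the striatal phantom
#'
#' Striatal ellipsoids (left centred at (-26, -2, 4) mm, semi-axes
#' 9 x 19 x 9 mm; right mirrored), an occipital reference slab
#' (y <= -70 mm), the posterior putaminal sub-region where the
#' learning-related depletion component lives, and the left half-space used
#' to restrict group analysis to the task-contralateral striatum.
#'
#' @param geom geometry volume from [phantom_geometry()].
#' @return list of `dat_mask`s: `occipital`, `striatum_left`,
#'   `striatum_right`, `striatum`, `posterior_left`, `left_halfspace`, plus
#'   numeric arrays `postfrac` (antero-posterior position, 0 anterior tip to
#'   1 posterior tip) and `posterior_weight` (ramp, 1 in the posterior
#'   putamen).
#' @export
phantom_regions <- function(geom) {
  xyz <- voxel_grid_mni(geom)
  d <- dim(geom$data)
  x <- array(xyz[, 1], d)
  y <- array(xyz[, 2], d)
  z <- array(xyz[, 3], d)
  ell <- function(cx) ((x - cx) / 9)^2 + ((y + 2) / 19)^2 + ((z - 4) / 9)^2 <= 1
  sl <- ell(-26)
  sr <- ell(26)
  occ <- y <= -70 & abs(x) <= 38 & z >= -22 & z <= 18
  postfrac <- pmin(pmax((17 - y) / 38, 0), 1)   # anterior tip y=17, posterior y=-21
  latfrac <- pmin(pmax((abs(x) - 17) / 18, 0), 1)  # medial edge |x|=17, lateral |x|=35
  pw <- pmin(pmax((-4 - y) / 10, 0), 1)         # 0 at y>=-4, 1 at y<=-14
  mk <- function(a, what) new_mask(a, geom$affine, provenance = what)
  list(occipital = mk(occ, "phantom occipital slab"),
       striatum_left = mk(sl, "phantom left striatum"),
       striatum_right = mk(sr, "phantom right striatum"),
       striatum = mk(sl | sr, "phantom striatum"),
       posterior_left = mk(sl & pw > 0, "phantom posterior left putamen (support of the posterior-specific depletion component)"),
       left_halfspace = mk(x < 0, "x < 0"),
       postfrac = postfrac,
       latfrac = latfrac,
       posterior_weight = pw)
}

#' Generate one synthetic DaT-SPECT volume
#'
#' Non-striatal tissue (including the occipital reference) has intensity ~1;
#' striatal voxels carry `1 + (base_sbr - 1) * (1 - loss)`, where the loss
#' combines a global-deficit component graded along the antero-posterior
#' and medio-lateral axes (strongest in the posterior lateral putamen, so
#' that with rising deficit the surviving maximum-intensity voxel shifts
#' medially and anteriorly) and an independent posterior-specific component
#' confined to the posterior putamen. Gaussian voxel noise is added
#' everywhere.
#'
#' @param geom geometry from [phantom_geometry()].
#' @param deficit global dopaminergic deficit in `[0, 1]`.
#' @param posterior_deficit posterior-specific deficit in `[0, 1]`.
#' @param base_sbr healthy striatal SBR plateau.
#' @param depletion_gradient maximum fractional loss (of specific binding)
#'   per unit global deficit at the posterior tip.
#' @param posterior_amplitude maximum fractional loss per unit posterior
#'   deficit.
#' @param noise_sd Gaussian voxel noise SD.
#' @param seed RNG seed; required when `noise_sd > 0`.
#' @param regions optional precomputed [phantom_regions()] (saves rebuilding
#'   in cohort loops).
#' @return a `dat_volume`.
#' @export
gen_striatal_volume <- function(geom = phantom_geometry(), deficit,
                                posterior_deficit = 0, base_sbr = 3,
                                depletion_gradient = 0.6,
                                posterior_amplitude = 0.75, noise_sd = 0.1,
                                seed = NULL, regions = phantom_regions(geom)) {
  if (deficit < 0 || deficit > 1) stop("deficit must lie in [0, 1]")
  if (posterior_deficit < 0 || posterior_deficit > 1) {
    stop("posterior_deficit must lie in [0, 1]")
  }
  d <- dim(geom$data)
  arr <- array(1, d)
  stri <- regions$striatum$data
  ## global loss grows toward the posterior lateral putamen
  gweight <- 0.4 + 0.3 * regions$postfrac + 0.3 * regions$latfrac
  loss <- deficit * depletion_gradient * gweight +
    posterior_deficit * posterior_amplitude * regions$posterior_weight
  arr[stri] <- 1 + (base_sbr - 1) * pmax(1 - loss[stri], 0)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0")
    arr <- arr + withr::with_seed(seed, array(stats::rnorm(prod(d), 0, noise_sd), d))
    arr <- pmax(arr, 0.05)
  }
  new_volume(arr, geom$affine)
}

#' Generate a full keystroke log for one subject
#'
#' Emulates the sequential finger-tapping task: 18 training + 14 retest
#' blocks, each terminated after exactly 60 presses. The per-block
#' correct-sequence duration follows an exponential approach to an
#' asymptote, `csd(b) = asymptote + (start - asymptote) * exp(-learning_rate
#' * (b - 1))`; inter-press intervals are Gamma-distributed around csd/4,
#' and each press is replaced by a random wrong key with probability
#' `error_rate`.
#'
#' @param start_csd,asymptote_csd training start / asymptotic CSD (seconds).
#' @param learning_rate exponential rate per block (> 0).
#' @param error_rate per-press error probability in `[0, 1)`.
#' @param retest_start_csd,retest_asymptote_csd retest curve (defaults:
#'   start above the training asymptote, emulating partial offline
#'   forgetting).
#' @param jitter_shape Gamma shape of the interval jitter (larger =
#'   steadier tapping).
#' @param template practised key sequence.
#' @param subject subject label written into the log.
#' @param seed RNG seed (mandatory; identical seeds give bit-identical
#'   logs).
#' @return keystroke data.frame (see [read_keystroke_log()]).
#' @export
gen_keystroke_log <- function(start_csd = 3, asymptote_csd = 1.5,
                              learning_rate = 0.35, error_rate = 0.04,
                              retest_start_csd = asymptote_csd * 1.35,
                              retest_asymptote_csd = asymptote_csd * 0.95,
                              jitter_shape = 40,
                              template = DEFAULT_SEQUENCE,
                              subject = "sim", seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(start_csd > 0, asymptote_csd > 0, learning_rate > 0,
            error_rate >= 0, error_rate < 1)
  csd_curve <- function(start, asym, n) {
    asym + (start - asym) * exp(-learning_rate * (seq_len(n) - 1))
  }
  blocks <- rbind(
    data.frame(session = "training", block = 1:18,
               csd = csd_curve(start_csd, asymptote_csd, 18)),
    data.frame(session = "retest", block = 1:14,
               csd = csd_curve(retest_start_csd, retest_asymptote_csd, 14)))
  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(blocks)), function(i) {
      keys <- rep(template, 12L)
      err <- stats::runif(60L) < error_rate
      if (any(err)) {
        keys[err] <- vapply(keys[err], function(k) {
          sample(setdiff(1:4, k), 1L)
        }, integer(1))
      }
      gaps <- stats::rgamma(60L, shape = jitter_shape,
                            rate = jitter_shape / (blocks$csd[i] / 4))
      data.frame(subject = subject, session = blocks$session[i],
                 block = blocks$block[i], t = cumsum(gaps), key = keys)
    })
    do.call(rbind, out)
  })
}

#' Cohort specification for the synthetic study
#'
#' Bundles the generative parameters of the synthetic cohort: how strongly
#' global striatal deficit drives motor symptoms (`ues_effect`, UES points
#' per unit deficit), how strongly posterior-putaminal specific binding
#' drives online learning (`learning_effect`, PI units per unit local SBR),
#' the spatial depletion gradients, and the per-channel noise levels.
#'
#' @param n_subjects cohort size (>= 3).
#' @param base_sbr healthy striatal SBR plateau.
#' @param depletion_gradient,posterior_amplitude spatial loss amplitudes
#'   (see [gen_striatal_volume()]).
#' @param ues_effect UES points per unit global deficit.
#' @param learning_effect online-learning PI units per unit posterior local
#'   SBR above the non-specific level.
#' @param noise_sd list with per-channel Gaussian SDs: `volume`, `ues`,
#'   `learning`.
#' @param error_rate mean per-press error probability.
#' @param left_hand_prop proportion of left-hand trainers (mirrored in the
#'   imaging pipeline).
#' @param seed root RNG seed (mandatory; all randomness derives from it).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 40L, base_sbr = 3.5, depletion_gradient = 0.5,
                        posterior_amplitude = 0.75, ues_effect = 12,
                        learning_effect = 4,
                        noise_sd = list(volume = 0.1, ues = 1,
                                        learning = 1.5),
                        error_rate = 0.04, left_hand_prop = 16 / 38, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_subjects < 3L) stop("n_subjects must be >= 3")
  stopifnot(all(unlist(noise_sd) >= 0))
  structure(list(n_subjects = as.integer(n_subjects), base_sbr = base_sbr,
                 depletion_gradient = depletion_gradient,
                 posterior_amplitude = posterior_amplitude,
                 ues_effect = ues_effect, learning_effect = learning_effect,
                 noise_sd = noise_sd, error_rate = error_rate,
                 left_hand_prop = left_hand_prop, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a complete synthetic cohort
#'
#' Draws, per subject, an independent global deficit (uniform on `[0, 1]`)
#' and a posterior-specific deficit that follows the mixed clinical makeup
#' of a DaT-SPECT referral cohort: about half the subjects are
#' parkinsonian-type, with substantial posterior-putaminal depletion
#' (uniform on `[0.4, 1]`), while the tremor-type remainder have none.
#' The phantom volumes are built from both components; UES derives from the
#' global deficit (rounded and clipped to 0-16) and the online-learning
#' target from the noise-free posterior-putaminal local SBR, realised
#' through keystroke simulation. The two deficit components are independent
#' so that motor-symptom severity and learning ability dissociate
#' spatially: the global component loads on the whole striatum, the
#' posterior component only on the posterior putamen.
#'
#' @param spec a [cohort_spec()].
#' @return list with `records` (clinical table), `logs` (named list of
#'   keystroke data.frames), `volumes` (named list of `dat_volume`s),
#'   `geom`, `regions`, and `truth` (latent deficits and generative
#'   targets).
#' @export
gen_cohort <- function(spec) {
  n <- spec$n_subjects
  geom <- phantom_geometry()
  regions <- phantom_regions(geom)
  lat <- withr::with_seed(spec$seed, {
    list(d_global = stats::runif(n),
         pd_type = stats::runif(n) < 0.5,
         d_post_raw = stats::runif(n, 0.4, 1),
         ues_noise = stats::rnorm(n, 0, spec$noise_sd$ues),
         learn_noise = stats::rnorm(n, 0, spec$noise_sd$learning),
         bot_pi = pmin(pmax(stats::rnorm(n, 5, 1), 2.5), 9),
         offline = stats::rnorm(n, -4, 2),
         err = stats::runif(n, 0.5, 1.5) * spec$error_rate,
         left_hand = stats::runif(n) < spec$left_hand_prop,
         age = round(stats::runif(n, 46, 76)),
         female = stats::runif(n) < 0.4)
  })
  lat$d_post <- ifelse(lat$pd_type, lat$d_post_raw, 0)
  ids <- sprintf("sub%02d", seq_len(n))

  post_lin <- which(regions$posterior_left$data)
  ant_lin <- which(regions$striatum_left$data & regions$posterior_weight < 0.5)
  volumes <- vector("list", n)
  post_sbr <- ant_sbr <- numeric(n)
  for (i in seq_len(n)) {
    clean <- gen_striatal_volume(geom, lat$d_global[i], lat$d_post[i],
                                 base_sbr = spec$base_sbr,
                                 depletion_gradient = spec$depletion_gradient,
                                 posterior_amplitude = spec$posterior_amplitude,
                                 noise_sd = 0, regions = regions)
    post_sbr[i] <- mean(clean$data[post_lin])
    ant_sbr[i] <- mean(clean$data[ant_lin])
    volumes[[i]] <- gen_striatal_volume(geom, lat$d_global[i], lat$d_post[i],
                                        base_sbr = spec$base_sbr,
                                        depletion_gradient = spec$depletion_gradient,
                                        posterior_amplitude = spec$posterior_amplitude,
                                        noise_sd = spec$noise_sd$volume,
                                        seed = spec$seed + i,
                                        regions = regions)
  }
  names(volumes) <- ids

  ## motor symptoms track the global deficit, with a posterior contribution
  ## (bradykinesia/rigidity follow posterior-putaminal depletion)
  symptom_load <- 0.7 * lat$d_global + 0.3 * lat$d_post
  ues <- as.integer(pmin(pmax(round(spec$ues_effect * symptom_load +
                                      lat$ues_noise), 0), 16))
  online_target <- pmax(1 + spec$learning_effect * (post_sbr - 1) +
                          lat$learn_noise, 0.3)

  logs <- vector("list", n)
  for (i in seq_len(n)) {
    acc_exp <- (1 - lat$err[i])^5
    pi_to_csd <- function(pi) pmax((acc_exp - 1) - log(pi / 100), 0.2)
    bot <- lat$bot_pi[i]
    eot <- bot + online_target[i]
    bor <- pmax(eot + lat$offline[i], 1)
    logs[[i]] <- gen_keystroke_log(
      start_csd = pi_to_csd(bot), asymptote_csd = pi_to_csd(eot),
      retest_start_csd = pi_to_csd(bor),
      retest_asymptote_csd = pi_to_csd(bor) * 0.95,
      error_rate = lat$err[i], subject = ids[i], seed = spec$seed + 10000L + i)
  }
  names(logs) <- ids

  ## clinical-style SBR summaries from the noise-free model, with synthetic
  ## age-adjusted z on an arbitrary but monotone scale
  records <- data.frame(
    subject_id = ids, age = lat$age,
    sex = ifelse(lat$female, "F", "M"),
    ues = ues,
    sbr_caudate = ant_sbr, sbr_putamen = post_sbr,
    z_caudate = (ant_sbr - mean(spec$base_sbr)) / 0.35,
    z_putamen = (post_sbr - spec$base_sbr) / 0.35,
    ledd = 0,
    diagnosis = ifelse(lat$pd_type, "PD", "ET"),
    hand = ifelse(lat$left_hand, "left", "right"))

  list(records = records, logs = logs, volumes = volumes, geom = geom,
       regions = regions,
       truth = list(d_global = lat$d_global, d_post = lat$d_post,
                    post_sbr = post_sbr, online_target = online_target,
                    planted_learning = regions$posterior_left,
                    planted_symptom = regions$striatum_left))
}

#' Layout for the resting-state phantom
#'
#' Small centred grid with a seed blob, a distant target blob, and
#' white-matter / CSF slabs used as nuisance regions.
#'
#' @param dims grid dimensions (default 12 x 12 x 10).
#' @param voxel_mm isotropic voxel size.
#' @param center_mm MNI coordinate at the grid centre; shift it to place the
#'   phantom over a region of interest (e.g. a striatal seed).
#' @return list: `geom`, `wm_mask`, `csf_mask`, `seed_region`,
#'   `target_region` (linear indices), `seed` (a `seed_spec` centred on the
#'   seed blob), `planted` (`dat_mask` of all signal-carrying voxels).
#' @export
rsfmri_layout <- function(dims = c(12L, 12L, 10L), voxel_mm = 4,
                          center_mm = c(0, 0, 0)) {
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- center_mm - voxel_mm * (dims - 1) / 2
  geom <- new_volume(array(0, dims), affine)
  xyz <- voxel_grid_mni(geom)
  d2 <- function(c0) (xyz[, 1] - c0[1])^2 + (xyz[, 2] - c0[2])^2 +
    (xyz[, 3] - c0[3])^2
  ## blob centres sit on grid points; the target is network-sized (10 mm
  ## radius) so that recovered clusters are dominated by true support, not
  ## by the smoothing halo at the blob surface
  seed_c <- center_mm + c(-10, -10, 2)
  targ_c <- center_mm + c(10, 10, 2)
  seed_region <- which(d2(seed_c) <= 6^2)
  target_region <- which(d2(targ_c) <= 10^2)
  arr <- array(FALSE, dims)
  arr[c(seed_region, target_region)] <- TRUE
  x <- array(xyz[, 1], dims)
  wm <- array(FALSE, dims)
  wm[1, , ] <- TRUE
  csf <- array(FALSE, dims)
  csf[dims[1], , ] <- TRUE
  list(geom = geom,
       wm_mask = new_mask(wm, affine, "phantom WM slab"),
       csf_mask = new_mask(csf, affine, "phantom CSF slab"),
       seed_region = seed_region, target_region = target_region,
       seed = seed_spec(seed_c, 5),
       planted = new_mask(arr, affine, "planted seed + target blobs"))
}

#' Generate a synthetic resting-state BOLD run
#'
#' Voxels in the seed and target regions share a band-limited latent signal
#' (scaled by `snr` relative to unit i.i.d. Gaussian noise); all other
#' voxels are independent noise. The effective amplitude varies
#' log-normally from run to run (`snr_sd_log`), emulating inter-individual
#' differences in connectivity strength. Motion parameters drift slowly;
#' optional spikes exceed the scrubbing threshold at given frames.
#'
#' @param layout from [rsfmri_layout()].
#' @param n_frames number of frames (default 400).
#' @param tr repetition time, seconds.
#' @param snr amplitude of the shared signal relative to the noise SD.
#' @param snr_sd_log SD of the log-normal run-level amplitude jitter.
#' @param motion_spike_frames frames at which a 0.6 mm translation step is
#'   planted.
#' @param spike_mm size of the planted step.
#' @param seed RNG seed (mandatory).
#' @return a `bold_run`.
#' @export
gen_rsfmri <- function(layout = rsfmri_layout(), n_frames = 400L, tr = 0.72,
                       snr = 0.6, snr_sd_log = 0.3,
                       motion_spike_frames = integer(0),
                       spike_mm = 0.6, seed) {
  if (missing(seed)) stop("seed is required")
  if (snr <= 0) stop("snr must be > 0")
  dims <- dim(layout$geom$data)
  nv <- prod(dims)
  withr::with_seed(seed, {
    fs <- 1 / tr
    bf <- signal::butter(2, c(0.01, 0.08) / (fs / 2), type = "pass")
    latent <- signal::filtfilt(bf, stats::rnorm(n_frames + 100L))
    latent <- latent[51:(50 + n_frames)]
    latent <- latent / stats::sd(latent)
    M <- matrix(stats::rnorm(n_frames * nv), n_frames, nv)
    sig <- c(layout$seed_region, layout$target_region)
    amp <- snr * exp(stats::rnorm(1, 0, snr_sd_log))
    M[, sig] <- M[, sig] + amp * latent
    trans <- apply(matrix(stats::rnorm(n_frames * 3, 0, 0.01), n_frames), 2L, cumsum)
    rot <- apply(matrix(stats::rnorm(n_frames * 3, 0, 2e-4), n_frames), 2L, cumsum)
    for (k in motion_spike_frames) {
      trans[k:n_frames, 1] <- trans[k:n_frames, 1] + spike_mm
    }
    new_bold_run(array(t(M), c(dims, n_frames)), layout$geom$affine, tr = tr,
                 motion = cbind(trans, rot))
  })
}

#' Load the packaged DaT-SPECT cohort table
#'
#' The 38-row clinical/imaging characteristics table shipped with the
#' package: per participant age, sex, MDS-UPDRS III total, UES, caudate and
#' putamen SBR, age-adjusted z-values, levodopa-equivalent dose and
#' clinical diagnosis (values for the striatum contralateral to the
#' task-performing hand). A `dat_group` column (DaT- iff putaminal
#' z < -2.5) is appended on load. Column sums are verified against frozen
#' checksums so silent fixture corruption is caught.
#'
#' @return data.frame with 38 rows.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_dat_spect_cohort.csv",
                      package = "datmotor", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect <- c(n = 38, ues = 174, updrs3_total = 680, sbr_caudate = 79.01,
              sbr_putamen = 66.4, ledd = 1707)
  got <- c(n = nrow(d), ues = sum(d$ues), updrs3_total = sum(d$updrs3_total),
           sbr_caudate = round(sum(d$sbr_caudate), 2),
           sbr_putamen = round(sum(d$sbr_putamen), 2), ledd = sum(d$ledd))
  if (!isTRUE(all.equal(expect, got, tolerance = 1e-9))) {
    stop("cohort table fixture failed checksum verification")
  }
  d$dat_group <- ifelse(d$z_putamen < -2.5, "DaT-", "DaT+")
  d
}

#' Dice coefficient between two voxel sets
#'
#' @param a,b `dat_mask`s on one grid, or vectors of linear indices.
#' @return `2 |A intersect B| / (|A| + |B|)`; 0 when both empty.
#' @export
dice_coefficient <- function(a, b) {
  la <- if (inherits(a, "dat_mask")) which(a$data) else a
  lb <- if (inherits(b, "dat_mask")) which(b$data) else b
  if (length(la) + length(lb) == 0L) return(0)
  2 * length(intersect(la, lb)) / (length(la) + length(lb))
}
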