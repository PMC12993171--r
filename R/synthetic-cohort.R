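# Tissue-class labels emitted by the phantom generator, in a fixed order so
# that random draws are reproducible. "background" is outside the brain.
phantom_classes <- c("background", "normal_brain", "fluid", "core",
                     "necrosis", "arterial", "flairpos_stable",
                     "flairpos_rec", "flairneg_stable", "flairneg_rec")

#' Specification of a synthetic multi-contrast phantom case
#'
#' Defines the geometry and tissue parameters of a co-registered phantom:
#' an ellipsoidal brain containing a spherical enhancing core with necrotic
#' interior, a one-sided FLAIR-hyperintense halo, a recurrence lobe
#' contiguous with the core that straddles the FLAIR boundary, fluid-filled
#' ventricles (one abutting the peri-enhancing rim), and vertical arterial
#' vessels feeding the slice-wise AIF estimation. Per-tissue ADC means are
#' in 1e-6 mm^2/s; CBV values are unitless. Geometry defaults are stated for
#' a 96-voxel grid and scale proportionally with `grid_shape`.
#'
#' The recurrence lobe's polar angle (relative to the FLAIR boundary plane)
#' is solved numerically per case so that the outside-FLAIR share of the
#' rim's recurrence tissue matches `fraction_recurrence_outside_flair`; its
#' azimuth is free and randomised across cases.
#'
#' @param grid_shape integer triple (default `c(96, 96, 96)`;
#'   `c(256, 256, 220)` supported).
#' @param core_radius_mm,necrosis_radius_mm radii of the enhancing core and
#'   its necrotic interior.
#' @param flair_halo_thickness_mm maximal distance from the core surface
#'   reached by the FLAIR-hyperintense halo.
#' @param flair_plane_offset_mm signed offset of the plane bounding the
#'   FLAIR halo (halo exists where the coordinate along the plane normal
#'   exceeds this offset from the core centre).
#' @param recurrence_radius_mm radius of the recurrence lobe, centred on the
#'   core surface.
#' @param fraction_recurrence_outside_flair target share of rim recurrence
#'   tissue in FLAIR-normal regions (default 1/3).
#' @param pez_width_voxels rim width used when solving the lobe angle.
#' @param adc_means,adc_between_sd named per-class ADC means and
#'   between-subject SDs.
#' @param adc_noise_sd within-tissue voxel noise SD for ADC.
#' @param cbv_means,cbv_between_sd named per-class CBV values and
#'   between-subject SDs.
#' @param subject_corr length-2 named vector: within-patient correlation of
#'   compartment means induced by a shared subject offset, per modality.
#' @param adc_cbv_coupling correlation of the ADC and CBV case-level draws
#'   (negative: cases with lower ADC have higher CBV).
#' @param between_subject_scale multiplies all between-subject SDs (0 gives
#'   a cohort of identical-mean cases).
#' @param dsc_params list: `te_s`, `dt_s`, `n_timepoints`, `s0`,
#'   `bolus_t0_s`, `bolus_tp_s`, `bolus_alpha`, `conc_peak`,
#'   `baseline_window`.
#' @param signal_noise_sd additive Gaussian noise SD on the DSC signal.
#' @param with_dsc synthesize the 4D DSC series (default `TRUE`); set
#'   `FALSE` for diffusion-only cohorts.
#' @param null_effect set the recurrence-prone class means equal to the
#'   stable ones (ground-truth contrasts exactly zero).
#' @param radius_jitter relative jitter of the geometric radii across cohort
#'   cases (default 0.1).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         core_radius_mm = NULL,
                         necrosis_radius_mm = NULL,
                         flair_halo_thickness_mm = NULL,
                         flair_plane_offset_mm = NULL,
                         recurrence_radius_mm = NULL,
                         fraction_recurrence_outside_flair = 1 / 3,
                         pez_width_voxels = 5,
                         adc_means = NULL, adc_between_sd = NULL,
                         adc_noise_sd = 150,
                         cbv_means = NULL, cbv_between_sd = NULL,
                         subject_corr = c(adc = 0.5, rcbv = 0.1),
                         adc_cbv_coupling = -0.6,
                         between_subject_scale = 1,
                         dsc_params = list(),
                         signal_noise_sd = 10,
                         with_dsc = TRUE,
                         null_effect = FALSE,
                         radius_jitter = 0.1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("'grid_shape' must be three integers >= 16")
  s <- min(grid_shape) / 96  # geometry reference scale

  if (is.null(core_radius_mm)) core_radius_mm <- 12 * s
  if (is.null(necrosis_radius_mm)) necrosis_radius_mm <- 6 * s
  if (is.null(flair_halo_thickness_mm)) flair_halo_thickness_mm <- 10 * s
  if (is.null(flair_plane_offset_mm)) flair_plane_offset_mm <- -3 * s
  if (is.null(recurrence_radius_mm)) recurrence_radius_mm <- 9 * s
  for (r in c(core_radius_mm, necrosis_radius_mm, flair_halo_thickness_mm,
              recurrence_radius_mm))
    if (!is.numeric(r) || r <= 0) stop("all radii must be positive")
  if (necrosis_radius_mm >= core_radius_mm)
    stop("'necrosis_radius_mm' must be smaller than 'core_radius_mm'")

  default_adc <- c(background = 0, normal_brain = 800, fluid = 3000,
                   core = 900, necrosis = 900, arterial = 1000,
                   flairpos_stable = 1291, flairpos_rec = 1192,
                   flairneg_stable = 971, flairneg_rec = 987)
  default_adc_sd <- c(background = 0, normal_brain = 80, fluid = 150,
                      core = 120, necrosis = 120, arterial = 80,
                      flairpos_stable = 162, flairpos_rec = 188,
                      flairneg_stable = 102, flairneg_rec = 131)
  default_cbv <- c(background = 0, normal_brain = 0.35, fluid = 0.02,
                   core = 0.8, necrosis = 0.05, arterial = 1.0,
                   flairpos_stable = 0.29, flairpos_rec = 0.33,
                   flairneg_stable = 0.35, flairneg_rec = 0.36)
  default_cbv_sd <- c(background = 0, normal_brain = 0.05, fluid = 0.005,
                      core = 0.1, necrosis = 0.01, arterial = 0.05,
                      flairpos_stable = 0.07, flairpos_rec = 0.08,
                      flairneg_stable = 0.05, flairneg_rec = 0.08)
  merge_named <- function(user, default) {
    if (is.null(user)) return(default)
    out <- default
    out[names(user)] <- user
    out
  }
  adc_means <- merge_named(adc_means, default_adc)
  adc_between_sd <- merge_named(adc_between_sd, default_adc_sd)
  cbv_means <- merge_named(cbv_means, default_cbv)
  cbv_between_sd <- merge_named(cbv_between_sd, default_cbv_sd)
  if (!all(phantom_classes %in% names(adc_means)) ||
      !all(phantom_classes %in% names(cbv_means)))
    stop("class mean tables must cover every emitted voxel label")

  if (null_effect) {
    adc_means["flairpos_rec"] <- adc_means["flairpos_stable"]
    adc_means["flairneg_rec"] <- adc_means["flairneg_stable"]
    cbv_means["flairpos_rec"] <- cbv_means["flairpos_stable"]
    cbv_means["flairneg_rec"] <- cbv_means["flairneg_stable"]
    adc_between_sd["flairpos_rec"] <- adc_between_sd["flairpos_stable"]
    adc_between_sd["flairneg_rec"] <- adc_between_sd["flairneg_stable"]
    cbv_between_sd["flairpos_rec"] <- cbv_between_sd["flairpos_stable"]
    cbv_between_sd["flairneg_rec"] <- cbv_between_sd["flairneg_stable"]
  }

  dsc_defaults <- list(te_s = 0.029, dt_s = 1.8, n_timepoints = 60,
                       s0 = 1000, bolus_t0_s = 18, bolus_tp_s = 9,
                       bolus_alpha = 3, conc_peak = 25,
                       baseline_window = 1:5)
  dsc_defaults[names(dsc_params)] <- dsc_params
  if (dsc_defaults$n_timepoints < 3L)
    stop("'n_timepoints' must be at least 3")

  structure(
    list(grid_shape = grid_shape,
         core_radius_mm = core_radius_mm,
         necrosis_radius_mm = necrosis_radius_mm,
         flair_halo_thickness_mm = flair_halo_thickness_mm,
         flair_plane_offset_mm = flair_plane_offset_mm,
         recurrence_radius_mm = recurrence_radius_mm,
         fraction_recurrence_outside_flair =
           fraction_recurrence_outside_flair,
         pez_width_voxels = pez_width_voxels,
         adc_means = adc_means, adc_between_sd = adc_between_sd,
         adc_noise_sd = adc_noise_sd,
         cbv_means = cbv_means, cbv_between_sd = cbv_between_sd,
         subject_corr = subject_corr,
         adc_cbv_coupling = adc_cbv_coupling,
         between_subject_scale = between_subject_scale,
         dsc_params = dsc_defaults,
         signal_noise_sd = signal_noise_sd,
         with_dsc = with_dsc,
         null_effect = null_effect,
         radius_jitter = radius_jitter),
    class = "phantom_spec"
  )
}

# gamma-variate bolus, peak value 1 at t = t0 + tp
gamma_variate_bolus <- function(t, t0, tp, alpha) {
  g <- numeric(length(t))
  up <- t > t0
  tau <- (t[up] - t0) / tp
  g[up] <- tau^alpha * exp(alpha * (1 - tau))
  g
}

#' Generate one phantom case
#'
#' Builds the co-registered volume set of a synthetic case: tissue-class
#' label grid, ADC map (class mean plus i.i.d. Gaussian noise), binary masks
#' (core, FLAIR, recurrence, brain), and optionally a 4D DSC series whose
#' voxel signal follows `S(t) = S0 * exp(-TE * C(t)) + noise` with
#' `C(t) = conc_peak * CBV_class * bolus(t)` and a gamma-variate bolus.
#' Arterial voxels (CBV 1) carry the highest-amplitude curves, so the
#' slice-wise AIF selection recovers them. Ground truth (labels, per-case
#' class means, true CBV ratios, rim recurrence share outside FLAIR) is
#' recorded alongside the volumes.
#'
#' @param spec `phantom_spec`.
#' @param seed integer seed; the same spec and seed give bit-identical
#'   volumes.
#' @param case_id identifier stored on the volumes.
#' @return An object of class `phantom_case`: list with `volumes`
#'   (`case_volumes`) and `truth`.
#' @export
generate_case <- function(spec, seed = 1L, case_id = sprintf("case%03d", seed)) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  set.seed(seed)
  dims <- spec$grid_shape
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  c0 <- (dims + 1) / 2
  n <- min(dims)

  ax <- seq_len(nx); ay <- seq_len(ny); az <- seq_len(nz)

  # squared normalized ellipsoid coordinates, built separably
  ell2 <- function(center, semi) {
    qx <- ((ax - center[1]) / semi[1])^2
    qy <- ((ay - center[2]) / semi[2])^2
    qz <- ((az - center[3]) / semi[3])^2
    outer(outer(qx, qy, `+`), qz, `+`)
  }
  sphere2 <- function(center) {
    qx <- (ax - center[1])^2
    qy <- (ay - center[2])^2
    qz <- (az - center[3])^2
    outer(outer(qx, qy, `+`), qz, `+`)
  }

  brain_q <- ell2(c0, c(0.46, 0.46, 0.44) * n)
  brain <- brain_q <= 1
  # subarachnoid CSF shell (outer ~6% of the ellipsoid radius, ~15% of the
  # intracranial volume): keeps the whole-brain upper-percentile anchor
  # inside the fluid distribution, as in real heads
  csf_shell <- brain & brain_q > 0.94^2

  core_c <- c0 + c(0.15 * n, 0, 0)
  d2core <- sphere2(core_c)
  core <- d2core <= spec$core_radius_mm^2 & brain
  if (!any(core)) stop("core construction produced an empty mask")
  necrosis <- d2core <= spec$necrosis_radius_mm^2 & brain
  dist_core <- sqrt(distance_squared_to_mask(core))

  # one ventricle abuts the rim on the core's medial side; a second sits
  # centrally for fluid volume
  v1_c <- c(core_c[1] - spec$core_radius_mm - 3, c0[2], c0[3])
  v2_c <- c(c0[1] - 0.17 * n, c0[2] - 0.08 * n, c0[3])
  ventricles <- ((ell2(v1_c, c(0.05, 0.12, 0.06) * n) <= 1 |
                  ell2(v2_c, c(0.05, 0.13, 0.07) * n) <= 1) & brain) |
    csf_shell

  # four vertical arterial vessels; large enough that arterial voxels exceed
  # the top-2% peak percentile on every slice crossing the rim
  vr <- 0.042 * n
  vx <- c(-1, -1, 1, 1) * 0.25 * n + c0[1]
  vy <- c(-1, 1, -1, 1) * 0.25 * n + c0[2]
  vessel2d <- matrix(FALSE, nx, ny)
  for (k in 1:4)
    vessel2d <- vessel2d |
      outer((ax - vx[k])^2, (ay - vy[k])^2, `+`) <= vr^2
  arterial <- array(vessel2d, dim = dims) & brain

  # FLAIR halo: shell around the core cut by a plane with +y normal
  Yrel <- array(rep(ay - core_c[2], each = nx), dim = dims)
  halo <- dist_core > 0 & dist_core <= spec$flair_halo_thickness_mm & brain
  flair <- halo & (Yrel >= spec$flair_plane_offset_mm)

  rim <- dist_core > 0 & dist_core <= spec$pez_width_voxels & brain

  # recurrence lobe: sphere centred on the core surface; polar angle solved
  # so the outside-FLAIR share of rim recurrence hits the target
  psi <- stats::runif(1, 0, 2 * pi)
  lobe_centre <- function(phi) {
    u <- c(sin(phi) * cos(psi), cos(phi), sin(phi) * sin(psi))
    core_c + spec$core_radius_mm * u
  }
  lobe_at <- function(phi) {
    sphere2(lobe_centre(phi)) <= spec$recurrence_radius_mm^2 & brain
  }
  # during the angle search only rim voxels matter: evaluate the lobe on
  # their coordinates rather than the whole grid
  rim_idx <- which(rim)
  rim_xyz <- arrayInd(rim_idx, dims)
  rim_out <- !flair[rim_idx]
  frac_out <- function(phi) {
    ctr <- lobe_centre(phi)
    inlobe <- (rim_xyz[, 1] - ctr[1])^2 + (rim_xyz[, 2] - ctr[2])^2 +
      (rim_xyz[, 3] - ctr[3])^2 <= spec$recurrence_radius_mm^2
    m <- sum(inlobe)
    if (m == 0L) return(NA_real_)
    sum(rim_out[inlobe]) / m
  }
  lo <- 0.05; hi <- pi - 0.05
  flo <- frac_out(lo); fhi <- frac_out(hi)
  target <- spec$fraction_recurrence_outside_flair
  if (is.na(flo) || is.na(fhi) || flo > target || fhi < target) {
    phi <- if (!is.na(fhi) && fhi < target) hi else lo
  } else {
    for (i in 1:8) {
      phi <- (lo + hi) / 2
      f <- frac_out(phi)
      if (is.na(f)) break
      if (f < target) lo <- phi else hi <- phi
    }
    phi <- (lo + hi) / 2
  }
  recurrence <- lobe_at(phi)
  if (!any(recurrence & dist_core <= 1))
    stop("recurrence lobe is not contiguous with the core")

  # label assignment, highest priority first
  label <- array(1L, dim = dims)             # background
  label[brain] <- 2L                         # normal_brain
  peri <- brain & !core & !arterial & !ventricles &
    (dist_core <= spec$flair_halo_thickness_mm | recurrence)
  label[peri & !flair & !recurrence] <- 9L   # flairneg_stable
  label[peri & !flair & recurrence] <- 10L   # flairneg_rec
  label[peri & flair & !recurrence] <- 7L    # flairpos_stable
  label[peri & flair & recurrence] <- 8L     # flairpos_rec
  label[ventricles & !core & !arterial] <- 3L # fluid
  label[arterial & !core] <- 6L              # arterial
  label[core] <- 4L                          # core
  label[necrosis] <- 5L                      # necrosis

  # per-case class means: shared subject offset + class-specific deviation,
  # with ADC/CBV draws coupled (negatively, by default) across modalities
  ncls <- length(phantom_classes)
  kappa <- spec$adc_cbv_coupling
  z_case_a <- rnorm(1)
  z_case_b <- kappa * z_case_a + sqrt(1 - kappa^2) * rnorm(1)
  e_a <- rnorm(ncls)
  e_b <- kappa * e_a + sqrt(1 - kappa^2) * rnorm(ncls)
  rho_a <- spec$subject_corr[["adc"]]
  rho_b <- spec$subject_corr[["rcbv"]]
  sc <- spec$between_subject_scale
  adc_case <- spec$adc_means[phantom_classes] +
    sc * spec$adc_between_sd[phantom_classes] *
    (sqrt(rho_a) * z_case_a + sqrt(1 - rho_a) * e_a)
  cbv_case <- spec$cbv_means[phantom_classes] +
    sc * spec$cbv_between_sd[phantom_classes] *
    (sqrt(rho_b) * z_case_b + sqrt(1 - rho_b) * e_b)
  adc_case["background"] <- 0
  cbv_case["background"] <- 0
  cbv_case <- pmax(cbv_case, 0.01)
  cbv_case["background"] <- 0

  # ADC field
  adc_data <- array(0, dim = dims)
  inbrain <- which(brain)
  adc_data[inbrain] <- adc_case[label[inbrain]]
  if (spec$adc_noise_sd > 0)
    adc_data[inbrain] <- adc_data[inbrain] +
      rnorm(length(inbrain), 0, spec$adc_noise_sd)

  mk_mask <- function(m) voxel_grid(m * 1, kind = "binary_mask")
  adc_grid <- voxel_grid(adc_data, kind = "parametric_map",
                         units = "1e-6 mm^2/s")

  dsc <- NULL
  if (spec$with_dsc) {
    dp <- spec$dsc_params
    tt <- (seq_len(dp$n_timepoints) - 1) * dp$dt_s
    bolus <- gamma_variate_bolus(tt, dp$bolus_t0_s, dp$bolus_tp_s,
                                 dp$bolus_alpha)
    # class x time signal curves; voxel signal looked up by label
    curves <- dp$s0 * exp(-dp$te_s * dp$conc_peak *
                            outer(cbv_case, bolus))
    sig <- curves[as.vector(label), ]
    if (spec$signal_noise_sd > 0)
      # noise only where it is ever read: the analysis masks out background
      sig[inbrain, ] <- sig[inbrain, ] +
        rnorm(length(inbrain) * dp$n_timepoints, 0, spec$signal_noise_sd)
    dim(sig) <- c(dims, dp$n_timepoints)
    dsc <- dsc_series(sig, te_s = dp$te_s, dt_s = dp$dt_s,
                      baseline_window = dp$baseline_window)
  }

  vols <- case_volumes(
    adc = adc_grid, dsc = dsc,
    core_mask = mk_mask(core),
    flair_mask = mk_mask(flair),
    recurrence_mask = mk_mask(recurrence),
    brain_mask = mk_mask(brain),
    case_id = case_id
  )

  rim_rec <- rim & recurrence
  truth <- list(
    labels = label,
    class_names = phantom_classes,
    adc_class_means = adc_case,
    cbv_class_means = cbv_case,
    cbv_ratio_flairpos = unname(cbv_case["flairpos_rec"] /
                                  cbv_case["flairpos_stable"]),
    fraction_recurrence_outside_flair =
      if (any(rim_rec)) sum(rim_rec & !flair) / sum(rim_rec) else NA_real_,
    lobe_polar_angle = phi,
    lobe_azimuth = psi,
    # compartment truth counted on the label grid (fluid/arterial rim voxels
    # belong to their own classes, matching the pipeline's fluid exclusion)
    compartment_voxels = c(
      t1pos_flairpos = sum(rim & label == 8L),
      t1neg_flairpos = sum(rim & label == 7L),
      t1pos_flairneg = sum(rim & label == 10L),
      t1neg_flairneg = sum(rim & label == 9L)
    )
  )
  structure(list(volumes = vols, truth = truth, spec = spec, seed = seed),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case %s> grid %s, seed %d\n", x$volumes$case_id,
              paste(x$volumes$adc$shape, collapse = "x"), x$seed))
  invisible(x)
}

# per-case plan: derived seeds and jittered geometry, all drawn from the
# cohort seed so that streaming and list-based generation agree exactly
cohort_case_plan <- function(n_cases, spec, seed) {
  if (!is.numeric(n_cases) || n_cases < 1)
    stop("'n_cases' must be at least 1")
  n_cases <- as.integer(n_cases)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  jit <- matrix(stats::runif(4L * n_cases, 1 - spec$radius_jitter,
                             1 + spec$radius_jitter),
                nrow = n_cases)
  lapply(seq_len(n_cases), function(i) {
    sp <- spec
    sp$core_radius_mm <- spec$core_radius_mm * jit[i, 1]
    sp$necrosis_radius_mm <- spec$necrosis_radius_mm * jit[i, 2]
    sp$flair_halo_thickness_mm <- spec$flair_halo_thickness_mm * jit[i, 3]
    sp$recurrence_radius_mm <- spec$recurrence_radius_mm * jit[i, 4]
    list(spec = sp, seed = case_seeds[i],
         case_id = sprintf("case%03d", i))
  })
}

#' Generate a phantom cohort
#'
#' Cases receive derived seeds and independently jittered geometry (radii
#' scaled by +/- `radius_jitter`, free lobe azimuth) plus between-subject
#' variation of the tissue-class means. For large grids with DSC prefer
#' [analyze_phantom_cohort()], which streams cases instead of holding the
#' whole cohort in memory.
#'
#' @param n_cases number of cases (>= 1).
#' @param spec `phantom_spec`.
#' @param seed cohort seed.
#' @return List of `phantom_case` objects.
#' @export
generate_cohort <- function(n_cases, spec, seed = 1L) {
  plan <- cohort_case_plan(n_cases, spec, seed)
  lapply(plan, function(p) generate_case(p$spec, p$seed, p$case_id))
}
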