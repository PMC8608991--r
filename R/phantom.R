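#' Specification of the synthetic head phantom
#'
#' The phantom lives directly in a common world space (RAS mm, grid centred
#' on the origin): bilateral centromedian (CM) and parafascicular (Pf)
#' thalamic nuclei around the stereotactic target (X = +/-9, Y = -9, Z = 0),
#' a brain sphere with a grey-matter shell and white-matter core, and a
#' six-region parcellation (brainstem/cerebellum, pre/postcentral, SMA,
#' middle and superior frontal) laid out at fixed world coordinates.
#'
#' @param grid_shape voxels per axis (positive integers). The default 64 mm
#'   field of view is the minimum that contains the region layout.
#' @param voxel_size isotropic voxel edge in mm.
#' @param target_coord list with \code{right}/\code{left} world-mm targets.
#' @param nucleus_radii named mm radii for the \code{cm} and \code{pf}
#'   spheres (> 0).
#' @param region_labels name -> integer map for the parcellation (unique,
#'   nonzero, must include the six canonical regions).
#' @param seed master integer PRNG seed; each generator draws from its own
#'   named substream so generators never perturb one another.
#' @param bundle_spread mm SD of the planted bundle's waypoint scatter
#'   around the CM centre.
#' @param distractor_margin mm added to the nucleus radii to define the
#'   CM/Pf neighbourhood that distractor streamlines must avoid.
#' @param curve_points vertices per generated streamline (odd, so the
#'   waypoint itself is a vertex).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L), voxel_size = 1,
                         target_coord = list(right = c(9, -9, 0),
                                             left = c(-9, -9, 0)),
                         nucleus_radii = c(cm = 3, pf = 2),
                         region_labels = c(brainstem_cerebellum = 1L,
                                           postcentral = 2L, precentral = 3L,
                                           SMA = 4L, middle_frontal = 5L,
                                           superior_frontal = 6L),
                         seed = 42L, bundle_spread = 2.5,
                         distractor_margin = 1, curve_points = 41L) {
  if (any(grid_shape <= 0)) stop("grid_shape must be positive")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (any(nucleus_radii <= 0))
    stop("geometry error: nucleus radii must be > 0")
  if (anyDuplicated(region_labels) || any(region_labels == 0))
    stop("spec error: region labels must be unique and nonzero")
  req <- c("brainstem_cerebellum", "postcentral", "precentral", "SMA",
           "middle_frontal", "superior_frontal")
  if (!all(req %in% names(region_labels)))
    stop("spec error: region_labels must include ",
         paste(setdiff(req, names(region_labels)), collapse = ", "))
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
    target_coord = target_coord, nucleus_radii = nucleus_radii,
    region_labels = region_labels, seed = as.integer(seed),
    bundle_spread = bundle_spread, distractor_margin = distractor_margin,
    curve_points = as.integer(curve_points)), class = "phantom_spec")
  half <- grid_shape * voxel_size / 2
  for (nm in names(phantom_layout(spec))) {
    s <- phantom_layout(spec)[[nm]]
    if (any(abs(s$centre) + s$radius > half))
      stop(sprintf("geometry error: sphere '%s' extends outside the grid", nm))
  }
  spec
}

# deterministic substream seed derived from the master seed and a name
substream_seed <- function(seed, name) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# world-mm sphere layout: nuclei plus parcellation regions
phantom_layout <- function(spec) {
  tc <- spec$target_coord
  r <- spec$nucleus_radii
  pf_off <- function(t) c(-4 * sign(t[1]), -1, 0)   # Pf medial-posterior to CM
  list(
    cm_right = list(centre = tc$right, radius = r[["cm"]]),
    cm_left = list(centre = tc$left, radius = r[["cm"]]),
    pf_right = list(centre = tc$right + pf_off(tc$right), radius = r[["pf"]]),
    pf_left = list(centre = tc$left + pf_off(tc$left), radius = r[["pf"]]),
    brainstem_cerebellum = list(centre = c(0, -10, -18), radius = 7),
    postcentral = list(centre = c(0, -14, 24), radius = 6),
    precentral = list(centre = c(0, 0, 24), radius = 6),
    SMA = list(centre = c(0, 13, 22), radius = 5),
    superior_frontal = list(centre = c(0, 24, 14), radius = 5),
    middle_frontal = list(centre = c(0, 26, 0), radius = 4))
}

empty_grid <- function(spec) {
  label_volume(array(0, spec$grid_shape), spec$voxel_size)
}

#' Generate the head phantom volumes
#'
#' @param spec a \code{phantom_spec}.
#' @return list of three co-registered \code{label_volume}s:
#'   \code{tissue} (0 CSF/background, 1 GM, 2 WM), \code{nuclei}
#'   (1 CM right, 2 CM left, 3 Pf right, 4 Pf left; names in the
#'   \code{nucleus_labels} attribute) and \code{parcellation} (labels per
#'   \code{spec$region_labels}).
#' @export
make_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lay <- phantom_layout(spec)
  tmpl <- empty_grid(spec)
  half <- min(spec$grid_shape * spec$voxel_size) / 2
  brain_r <- 0.875 * half
  d2 <- dist2_from_point(tmpl, c(0, 0, 0))
  tissue <- array(0L, spec$grid_shape)
  tissue[d2 <= brain_r^2] <- 1L                       # GM shell
  tissue[d2 <= (brain_r - 4)^2] <- 2L                 # WM core

  nuclei <- array(0L, spec$grid_shape)
  nuc_names <- c("cm_right", "cm_left", "pf_right", "pf_left")
  for (i in seq_along(nuc_names)) {
    s <- lay[[nuc_names[i]]]
    m <- rasterize_sphere(tmpl, s$centre, s$radius)
    nuclei[m] <- i
    tissue[m] <- 1L                                   # nuclei are grey matter
  }

  parc <- array(0L, spec$grid_shape)
  for (nm in names(spec$region_labels)) {
    s <- lay[[nm]]
    m <- rasterize_sphere(tmpl, s$centre, s$radius)
    parc[m] <- spec$region_labels[[nm]]
    tissue[m] <- 1L      # parcellated regions are grey-matter structures
  }

  tis <- label_volume(tissue, spec$voxel_size)
  nuc <- label_volume(nuclei, spec$voxel_size)
  attr(nuc, "nucleus_labels") <- stats::setNames(seq_along(nuc_names),
                                                 nuc_names)
  prc <- label_volume(parc, spec$voxel_size)
  attr(prc, "region_labels") <- spec$region_labels
  list(tissue = tis, nuclei = nuc, parcellation = prc)
}

# uniform points inside a sphere, n x 3
runif_sphere <- function(n, centre, radius) {
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * runif(n)^(1 / 3)
  sweep(u * r, 2, centre, "+")
}

# quadratic Bezier curves through control points; A,C,B are n x 3; returns
# coords ((n*m) x 3, streamline-major) for m parameter values
bezier_points <- function(A, C, B, m) {
  t <- seq(0, 1, length.out = m)
  w0 <- (1 - t)^2; w1 <- 2 * t * (1 - t); w2 <- t^2
  n <- nrow(A)
  out <- matrix(0, n * m, 3)
  for (co in 1:3) {
    # n x m matrix of coordinate `co`
    M <- outer(A[, co], w0) + outer(C[, co], w1) + outer(B[, co], w2)
    out[, co] <- as.numeric(t(M))
  }
  out
}

min_dist2_to_centres <- function(pts, centres) {
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(centres))) {
    d2 <- (pts[, 1] - centres[i, 1])^2 + (pts[, 2] - centres[i, 2])^2 +
      (pts[, 3] - centres[i, 3])^2
    best <- pmin(best, d2)
  }
  best
}

#' Generate a whole-brain synthetic tractogram with a planted bundle
#'
#' A fraction of streamlines forms the planted thalamo-brainstem bundle:
#' smooth curves from a sensorimotor cortical region (precentral,
#' postcentral or SMA), through a waypoint scattered around the CM centre of
#' one hemisphere, down to the brainstem/cerebellum region. The remainder
#' are distractors: random smooth curves inside the brain, rejected if any
#' vertex enters the CM/Pf neighbourhood (nucleus radius +
#' \code{distractor_margin}), so the ground truth is clean.
#'
#' @param spec a \code{phantom_spec}.
#' @param n_streamlines total streamline count (default 200,000, the
#'   whole-brain connectome scale).
#' @param bundle_fraction proportion of streamlines in the planted bundle.
#' @return list with \code{tractogram} (labels 1 = bundle, 0 = distractor)
#'   and \code{truth} (list: \code{bundle} indices, \code{labels},
#'   \code{bundle_fraction}).
#' @export
make_tractogram <- function(spec, n_streamlines = 200000,
                            bundle_fraction = 0.04) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_streamlines < 1) stop("n_streamlines must be >= 1")
  if (bundle_fraction < 0 || bundle_fraction > 1)
    stop("bundle_fraction must be in [0, 1]")
  set.seed(substream_seed(spec$seed, "tractogram"))
  lay <- phantom_layout(spec)
  m <- spec$curve_points
  n_b <- round(bundle_fraction * n_streamlines)
  n_d <- n_streamlines - n_b
  half <- min(spec$grid_shape * spec$voxel_size) / 2
  brain_r <- 0.875 * half

  pieces <- list(); labels <- integer(0)
  if (n_b > 0) {
    hemi <- sample(c("right", "left"), n_b, replace = TRUE)
    cort <- sample(c("precentral", "postcentral", "SMA"), n_b, replace = TRUE)
    A <- matrix(0, n_b, 3)
    for (rg in c("precentral", "postcentral", "SMA")) {
      k <- which(cort == rg)
      if (length(k))
        A[k, ] <- runif_sphere(length(k), lay[[rg]]$centre, lay[[rg]]$radius)
    }
    B <- runif_sphere(n_b, lay$brainstem_cerebellum$centre,
                      lay$brainstem_cerebellum$radius)
    W <- matrix(0, n_b, 3)
    for (h in c("right", "left")) {
      k <- which(hemi == h)
      if (length(k))
        W[k, ] <- matrix(lay[[paste0("cm_", h)]]$centre, length(k), 3,
                         byrow = TRUE) +
          matrix(rnorm(3 * length(k), sd = spec$bundle_spread), length(k), 3)
    }
    Ctrl <- 2 * W - (A + B) / 2      # curve passes through W at t = 0.5
    pieces <- c(pieces, list(bezier_points(A, Ctrl, B, m)))
    labels <- c(labels, rep(1L, n_b))
  }
  if (n_d > 0) {
    excl <- rbind(lay$cm_right$centre, lay$cm_left$centre,
                  lay$pf_right$centre, lay$pf_left$centre)
    excl_r2 <- (c(spec$nucleus_radii[["cm"]], spec$nucleus_radii[["cm"]],
                  spec$nucleus_radii[["pf"]], spec$nucleus_radii[["pf"]]) +
                  spec$distractor_margin)^2
    keep <- vector("list", 0)
    got <- 0L
    while (got < n_d) {
      nb <- max(1000L, ceiling((n_d - got) * 1.25))
      A <- runif_sphere(nb, c(0, 0, 0), 0.95 * brain_r)
      B <- runif_sphere(nb, c(0, 0, 0), 0.95 * brain_r)
      Ctrl <- runif_sphere(nb, c(0, 0, 0), 0.95 * brain_r)
      pts <- bezier_points(A, Ctrl, B, m)
      bad <- rep(FALSE, nb)
      for (q in seq_len(nrow(excl))) {
        d2 <- (pts[, 1] - excl[q, 1])^2 + (pts[, 2] - excl[q, 2])^2 +
          (pts[, 3] - excl[q, 3])^2
        # coords are streamline-major: row i of the nb x m matrix holds
        # streamline i's vertices
        bad <- bad | rowSums(matrix(d2 <= excl_r2[q], nb, m,
                                    byrow = TRUE)) > 0
      }
      ok <- which(!bad)
      take <- ok[seq_len(min(length(ok), n_d - got))]
      if (length(take)) {
        sel <- unlist(lapply(take, function(i) ((i - 1) * m + 1):(i * m)))
        keep[[length(keep) + 1L]] <- pts[sel, , drop = FALSE]
        got <- got + length(take)
      }
    }
    pieces <- c(pieces, keep)
    labels <- c(labels, rep(0L, n_d))
  }
  coords <- do.call(rbind, pieces)
  # geometry closure: clamp inside the grid
  half3 <- spec$grid_shape * spec$voxel_size / 2
  for (co in 1:3)
    coords[, co] <- pmin(pmax(coords[, co], -half3[co] + 1e-6),
                         half3[co] - 1e-6)
  tract <- tractogram(list(coords = coords,
                           offsets = c(1L, 1L + cumsum(rep(m, length(labels))))),
                      labels = labels)
  truth <- list(bundle = which(labels > 0L), labels = labels,
                bundle_fraction = bundle_fraction)
  list(tractogram = tract, truth = truth)
}

#' Corridor mask of the planted bundle
#'
#' Rasterizes the bundle streamlines' vertices and dilates by one voxel,
#' giving the label volume the bundle was generated through (useful as a
#' stand-in tract atlas for overlap checks).
#' @param spec a \code{phantom_spec}.
#' @param tract a \code{tractogram} with bundle labels.
#' @return binary \code{label_volume}.
#' @export
bundle_corridor <- function(spec, tract) {
  tmpl <- empty_grid(spec)
  ids <- point_ids(tract)
  pts <- tract$coords[tract$labels[ids] > 0L, , drop = FALSE]
  m <- array(FALSE, spec$grid_shape)
  li <- linear_index(tmpl, world_to_voxel(tmpl, pts))
  m[li[!is.na(li)]] <- TRUE
  dilate_mask(label_volume(m, spec$voxel_size), spec$voxel_size)
}

#' Generate a synthetic DBS patient cohort
#'
#' Each patient receives bilateral lead placements at the stereotactic
#' target plus Gaussian jitter, a monopolar stimulation setting (integer
#' amplitude 1..5 V at 60 Hz / 90 us, one random active contact), and a VTA
#' from the analytic field model at the 0.2 V/mm threshold. The planted
#' connectivity is the count of bundle streamlines traversing the patient's
#' unioned bilateral VTA, and the seizure-frequency improvement at the
#' 24-month endpoint is \code{effect * connectivity + N(0, noise_sd^2)},
#' truncated to [-100, 100]. Earlier follow-ups ramp towards that endpoint
#' with their own (half-SD) noise; baseline improvement is 0 by definition.
#'
#' @param spec a \code{phantom_spec}.
#' @param n_patients cohort size (>= 3).
#' @param jitter_sd mm SD of the isotropic placement jitter.
#' @param effect improvement units per unit planted connectivity.
#' @param noise_sd improvement-unit noise SD (>= 0).
#' @param tract,truth optional tractogram + ground truth from
#'   \code{\link{make_tractogram}}; generated at 2000 streamlines from the
#'   same spec when omitted.
#' @param impedance_ohm access impedance for the V-to-I conversion.
#' @param threshold VTA activation threshold in V/mm.
#' @return list with \code{cohort} (class \code{dbs_cohort}: \code{table}
#'   data.frame as per the CSV interface, \code{placements}, \code{stim},
#'   \code{vtas} (unioned per patient), \code{improvement} matrix,
#'   \code{outcome} = 24-month column, \code{connectivity}) and \code{truth}.
#' @export
make_cohort <- function(spec, n_patients = 10, jitter_sd = 1.75, effect = 5,
                        noise_sd = 5, tract = NULL, truth = NULL,
                        impedance_ohm = 1000, threshold = 0.2) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_patients < 3) stop("n_patients must be >= 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(tract)) {
    tg <- make_tractogram(spec, n_streamlines = 2000)
    tract <- tg$tractogram; truth <- tg$truth
  }
  force(truth)   # promises may run other generators; settle them before
  force(tract)   # seeding the cohort substream
  set.seed(substream_seed(spec$seed, "cohort"))
  lead <- build_lead("medtronic3389")
  grid <- empty_grid(spec)
  rs <- resample_points(tract, spec$voxel_size / 2)
  bundle_ids <- truth$bundle

  timepoints <- c("baseline", "m3", "m6", "m12", "m18", "m24", "last")
  ramp <- c(baseline = 0, m3 = 0.5, m6 = 0.85, m12 = 0.95, m18 = 0.97,
            m24 = 1, last = 0.95)
  placements <- vector("list", n_patients)
  stim <- vector("list", n_patients)
  vtas <- vector("list", n_patients)
  connectivity <- numeric(n_patients)
  rows <- list()
  for (p in seq_len(n_patients)) {
    per_hemi <- list()
    union_mask <- array(FALSE, spec$grid_shape)
    for (h in c("right", "left")) {
      tgt <- spec$target_coord[[h]]
      jit <- rnorm(3, sd = jitter_sd)
      tilt <- c(rnorm(2, sd = 0.05), 1)
      dirn <- tilt / sqrt(sum(tilt^2))
      k <- sample(0:3, 1)
      amp <- sample(1:5, 1)
      off <- lead$tip_to_first_contact +
        k * (lead$contact_length + lead$intercontact_gap)
      tip <- tgt + jit - off * dirn
      pl <- lead_placement(tip, dirn, h)
      st <- stim_config(k, amp)
      fld <- efield_analytic(st, pl, lead, sigma = 0.33, grid,
                             impedance_ohm = impedance_ohm)
      v <- binarize_vta(fld, threshold)
      union_mask <- union_mask | v$mask$data
      per_hemi[[h]] <- list(placement = pl, stim = st, vta = v)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("P%02d", p), hemisphere = h,
        tip_x = tip[1], tip_y = tip[2], tip_z = tip[3],
        dir_x = dirn[1], dir_y = dirn[2], dir_z = dirn[3],
        active_contacts = paste0("C", k), amplitude_V = amp,
        frequency_Hz = st$frequency, pulse_us = st$pulse_width)
    }
    placements[[p]] <- lapply(per_hemi, `[[`, "placement")
    stim[[p]] <- lapply(per_hemi, `[[`, "stim")
    uvol <- label_volume(union_mask, spec$voxel_size)
    vtas[[p]] <- structure(list(mask = uvol, threshold_used = threshold,
                                volume_mm3 = sum(union_mask) *
                                  spec$voxel_size^3),
                           class = "vta_mask")
    li <- linear_index(uvol, world_to_voxel(uvol, rs$coords))
    inside <- !is.na(li) & union_mask[ifelse(is.na(li), 1L, li)]
    conn_ids <- unique(rs$ids[inside])
    connectivity[p] <- sum(conn_ids %in% bundle_ids)
  }
  final <- pmin(100, pmax(-100, effect * connectivity +
                            rnorm(n_patients, sd = noise_sd)))
  imp <- sapply(timepoints, function(tp) {
    if (tp == "baseline") return(rep(0, n_patients))
    extra <- if (tp == "m24") 0 else rnorm(n_patients, sd = noise_sd / 2)
    pmin(100, pmax(-100, ramp[[tp]] * final + extra))
  })
  rownames(imp) <- sprintf("P%02d", seq_len(n_patients))
  tab <- do.call(rbind, rows)
  for (tp in timepoints)
    tab[[paste0("improvement_pct_", tp)]] <- imp[tab$patient_id, tp]
  cohort <- structure(list(table = tab, placements = placements, stim = stim,
                           vtas = vtas, improvement = imp,
                           outcome = imp[, "m24"],
                           connectivity = connectivity,
                           timepoints = timepoints),
                      class = "dbs_cohort")
  truth_out <- list(effect = effect, noise_sd = noise_sd,
                    connectivity = connectivity, tract_truth = truth)
  list(cohort = cohort, truth = truth_out)
}

#' @export
print.dbs_cohort <- function(x, ...) {
  cat(sprintf("<dbs_cohort> %d patients, outcome (24 mo) mean %.1f%%\n",
              length(x$outcome), mean(x$outcome)))
  invisible(x)
}

#' Generate a normative resting-state fMRI cohort
#'
#' Each subject's voxel time series is unit-variance AR(1) noise plus a
#' shared AR(1) latent signal loaded onto the planted network (the dilated
#' CM/Pf seed neighbourhood, brainstem/cerebellum, and the sensorimotor
#' regions). The loading is chosen so the expected seed-network correlation
#' approximates \code{coupling}. All other grey-matter voxels carry a weak
#' positive loading (default 15% of \code{coupling}), emulating the broad
#' cortical projection of an arousal network, so that expected connectivity
#' is nonnegative everywhere at nonnegative coupling; white matter and CSF
#' carry none (they feed the nuisance regressors).
#'
#' @param spec a \code{phantom_spec}; a 3 mm grid
#'   (\code{phantom_spec(grid_shape = c(22L,22L,22L), voxel_size = 3)})
#'   matches the normative acquisition resolution.
#' @param n_subjects number of subjects.
#' @param n_timepoints frames per series (>= 20; default 124).
#' @param TR repetition time in seconds (default 3).
#' @param coupling target seed-network correlation, in (-1, 1).
#' @param background_fraction background loading as a fraction of
#'   \code{coupling}.
#' @param ar_phi lag-1 autocorrelation of noise and latent signal.
#' @param subjects subject indices to generate (defaults to all); each
#'   subject has its own seed substream, so any subset reproduces the same
#'   series as the full call.
#' @return list of \code{fmri_series} objects; attributes \code{network}
#'   and \code{seed} carry the binary \code{label_volume}s of the planted
#'   network and the seed neighbourhood.
#' @export
make_normative_fmri <- function(spec, n_subjects = 20, n_timepoints = 124,
                                TR = 3, coupling = 0.6,
                                background_fraction = 0.15, ar_phi = 0.3,
                                subjects = seq_len(n_subjects)) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_timepoints < 20) stop("n_timepoints must be >= 20")
  if (abs(coupling) >= 1) stop("coupling must be inside (-1, 1)")
  vols <- make_head_phantom(spec)
  seed_mask <- dilate_mask(label_volume(vols$nuclei$data > 0,
                                        spec$voxel_size), 2)
  rl <- spec$region_labels
  net <- seed_mask$data |
    vols$parcellation$data %in% rl[c("brainstem_cerebellum", "precentral",
                                     "postcentral", "SMA")]
  gm_bg <- vols$tissue$data == 1 & !net
  lam_net <- coupling / sqrt(1 - coupling^2)
  bg <- background_fraction * coupling
  lam_bg <- bg / sqrt(1 - bg^2)
  nvox <- prod(spec$grid_shape)
  innov_sd <- sqrt(1 - ar_phi^2)

  ar1 <- function(n_series, T) {
    e <- matrix(rnorm(T * n_series, sd = innov_sd), T, n_series)
    x <- matrix(0, T, n_series)
    x[1, ] <- rnorm(n_series)            # stationary start, unit variance
    for (t in 2:T) x[t, ] <- ar_phi * x[t - 1, ] + e[t, ]
    x
  }

  out <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    set.seed(substream_seed(spec$seed, paste0("fmri", subjects[si])))
    s <- ar1(1, n_timepoints)[, 1]
    Y <- ar1(nvox, n_timepoints)
    Y[, net] <- Y[, net] + outer(s, rep(lam_net, sum(net)))
    if (lam_bg != 0)
      Y[, gm_bg] <- Y[, gm_bg] + outer(s, rep(lam_bg, sum(gm_bg)))
    out[[si]] <- fmri_series(array(t(Y), c(spec$grid_shape, n_timepoints)),
                             TR = TR, voxel_size = spec$voxel_size,
                             origin = -spec$grid_shape * spec$voxel_size / 2)
  }
  attr(out, "network") <- label_volume(net, spec$voxel_size)
  attr(out, "seed") <- seed_mask
  attr(out, "tissue") <- vols$tissue
  out
}
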