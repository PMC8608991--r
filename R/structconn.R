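#' Streamlines traversing a binary mask
#'
#' Streamlines are resampled to at most \code{step} mm spacing (default half
#' the mask voxel size) and selected iff any resampled vertex falls inside
#' the mask; an optional dilation radius relaxes strict traversal to
#' proximity.
#'
#' @param tract a \code{tractogram}.
#' @param mask a \code{vta_mask} or binary \code{label_volume} (nonempty).
#' @param step resample step in mm.
#' @param dilate_mm optional mask dilation radius before selection.
#' @param resampled optional precomputed \code{resample_points(tract, step)}
#'   (reused across patients for speed).
#' @return sorted integer indices of selected streamlines.
#' @export
connected_fibers <- function(tract, mask, step = NULL, dilate_mm = 0,
                             resampled = NULL) {
  vol <- if (inherits(mask, "vta_mask")) mask$mask else mask
  if (sum(vol$data != 0) == 0L) stop("mask is empty")
  if (dilate_mm > 0) vol <- dilate_mask(vol, dilate_mm)
  if (n_streamlines(tract) == 0L) return(integer(0))
  if (is.null(step)) step <- vol$voxel_size / 2
  rs <- if (is.null(resampled)) resample_points(tract, step) else resampled
  li <- linear_index(vol, world_to_voxel(vol, rs$coords))
  inside <- !is.na(li) & vol$data[ifelse(is.na(li), 1L, li)] != 0
  sort(unique(rs$ids[inside]))
}

#' Terminal parcellation labels of every streamline
#'
#' @param tract a \code{tractogram}.
#' @param parcellation integer \code{label_volume}; endpoints outside every
#'   region (or outside the grid) get label 0.
#' @return data.frame with \code{start_label} and \code{end_label}.
#' @export
terminal_regions <- function(tract, parcellation) {
  n <- n_streamlines(tract)
  starts <- tract$coords[tract$offsets[-length(tract$offsets)], ,
                         drop = FALSE]
  ends <- tract$coords[tract$offsets[-1L] - 1L, , drop = FALSE]
  data.frame(start_label = as.integer(sample_volume(parcellation, starts)),
             end_label = as.integer(sample_volume(parcellation, ends)))
}

#' Regional fiber-count profile of a VTA
#'
#' Counts streamlines traversing the VTA whose far endpoint (the endpoint
#' farther from the VTA centroid) lies in each parcellation region.
#' Normalized counts are raw / (total streamlines x region voxel count); raw
#' counts are always reported alongside.
#'
#' @param tract a \code{tractogram}.
#' @param vta a \code{vta_mask} (a patient's unioned bilateral VTA).
#' @param parcellation integer \code{label_volume} with a
#'   \code{region_labels} attribute (name -> label).
#' @param resampled optional precomputed resampling (see
#'   \code{\link{connected_fibers}}).
#' @return object of class \code{regional_profile}: data.frame with
#'   \code{region}, \code{label}, \code{raw_count}, \code{normalized_count};
#'   attribute \code{flag} is \code{"empty_vta"} for an all-zero profile
#'   from an empty VTA.
#' @export
regional_profile <- function(tract, vta, parcellation, resampled = NULL) {
  rl <- attr(parcellation, "region_labels")
  if (is.null(rl)) {
    labs <- sort(unique(parcellation$data[parcellation$data != 0]))
    rl <- stats::setNames(as.integer(labs), paste0("region_", labs))
  }
  vox_count <- vapply(rl, function(l) sum(parcellation$data == l), numeric(1))
  n_tot <- n_streamlines(tract)
  empty <- sum(vta$mask$data != 0) == 0L
  if (empty) {
    sel <- integer(0)
  } else {
    sel <- connected_fibers(tract, vta, resampled = resampled)
  }
  raw <- stats::setNames(numeric(length(rl)), names(rl))
  if (length(sel)) {
    starts <- tract$coords[tract$offsets[sel], , drop = FALSE]
    ends <- tract$coords[tract$offsets[sel + 1L] - 1L, , drop = FALSE]
    ctr <- mask_centroid(vta$mask)
    d_start <- rowSums(sweep(starts, 2, ctr)^2)
    d_end <- rowSums(sweep(ends, 2, ctr)^2)
    # each selected streamline contributes its farther endpoint exactly once
    far_pts <- rbind(ends, starts)[c(which(d_end >= d_start),
                                     nrow(ends) + which(d_end < d_start)), ,
                                   drop = FALSE]
    far_lab <- as.integer(sample_volume(parcellation, far_pts))
    for (nm in names(rl)) raw[nm] <- sum(far_lab == rl[[nm]])
  }
  out <- data.frame(region = names(rl), label = as.integer(rl),
                    raw_count = as.numeric(raw),
                    normalized_count = as.numeric(raw) / (n_tot * vox_count),
                    row.names = NULL)
  structure(out, class = c("regional_profile", "data.frame"),
            flag = if (empty) "empty_vta" else NA_character_,
            n_selected = length(sel))
}

#' Per-region association between fiber counts and clinical outcome
#'
#' Pearson correlation (with two-sided p) between each region's raw fiber
#' count across patients and the seizure-frequency improvement.
#'
#' @param profiles list of per-patient \code{regional_profile}s.
#' @param outcomes numeric improvement percentages, one per patient (>= 3).
#' @param use \code{"raw_count"} or \code{"normalized_count"}.
#' @return data.frame with \code{region}, \code{r}, \code{p}, \code{flag}
#'   (\code{"zero_variance"} where r is undefined).
#' @export
profile_outcome_association <- function(profiles, outcomes,
                                        use = "raw_count") {
  if (length(profiles) != length(outcomes))
    stop("one profile per outcome required")
  if (length(outcomes) < 3) stop("need >= 3 patients")
  regions <- profiles[[1]]$region
  counts <- sapply(profiles, function(p) p[[use]])  # regions x patients
  res <- lapply(seq_along(regions), function(i) {
    x <- counts[i, ]
    if (var(x) == 0 || var(outcomes) == 0)
      return(data.frame(region = regions[i], r = NA_real_, p = NA_real_,
                        flag = "zero_variance"))
    fit <- pearson_regression(x, outcomes)
    data.frame(region = regions[i], r = fit$r, p = fit$p,
               flag = NA_character_)
  })
  do.call(rbind, res)
}

#' Overlap of selected streamlines with a tract atlas
#'
#' For each atlas label, the fraction of all selected streamline points
#' lying inside that label (fractions need not sum to 1).
#'
#' @param tract a \code{tractogram}.
#' @param selected streamline indices.
#' @param atlas integer \code{label_volume}.
#' @return data.frame with \code{label} and \code{fraction}; attribute
#'   \code{flag} = \code{"empty_selection"} when no streamlines are given.
#' @export
bundle_atlas_overlap <- function(tract, selected, atlas) {
  labs <- sort(unique(atlas$data[atlas$data != 0]))
  if (length(selected) == 0L) {
    return(structure(data.frame(label = as.integer(labs),
                                fraction = rep(0, length(labs))),
                     flag = "empty_selection"))
  }
  ids <- point_ids(tract)
  pts <- tract$coords[ids %in% selected, , drop = FALSE]
  v <- sample_volume(atlas, pts)
  structure(data.frame(label = as.integer(labs),
                       fraction = vapply(labs, function(l) mean(v == l),
                                         numeric(1))),
            flag = NA_character_)
}
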