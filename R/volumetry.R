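# Semi-automated fluid volumetry: seeded region-growing segmentation of the
# hyperintense fluid signal, voxel-count volume quantification with the
# perilymph-containment rule, hydrops classification, and the reliability
# analyses (per-ear TV deviations, dose/delay association).

#' Segment hyperintense fluid by seeded region growing
#'
#' Thresholds the image and keeps the 26-connected component(s) of
#' supra-threshold voxels reachable from the user-supplied seed voxels. This
#' is the semi-automated step: seed placement is the operator input,
#' everything downstream is automatic.
#'
#' @param volume 3D numeric array of intensities.
#' @param seeds a single xyz triple or a list of triples (1-based voxel
#'   coordinates).
#' @param threshold_policy `"fraction"` (default; threshold =
#'   `fraction * robust max`, where the robust max is the 99th intensity
#'   percentile), `"fixed"` (threshold = `value`), or `"otsu"` (Otsu's
#'   threshold within `roi`, or the whole volume if `roi` is `NULL`).
#' @param fraction fraction of the robust max for the `"fraction"` policy.
#' @param value threshold for the `"fixed"` policy.
#' @param roi optional list of ranges `list(x = c(lo, hi), ...)` restricting
#'   the Otsu histogram.
#' @return logical 3D array (the segmentation mask) with attributes
#'   `threshold` and `n_voxels`.
#' @export
segment_fluid <- function(volume, seeds,
                          threshold_policy = c("fraction", "fixed", "otsu"),
                          fraction = 0.5, value = NULL, roi = NULL) {
  threshold_policy <- match.arg(threshold_policy)
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  if (!is.list(seeds)) seeds <- list(seeds)
  if (length(seeds) < 1L) stop("at least one seed is required", call. = FALSE)
  d <- dim(volume)
  for (s in seeds) {
    if (length(s) != 3L || any(s < 1L) || any(s > d)) {
      stop("seed outside the image grid", call. = FALSE)
    }
  }
  thr <- switch(threshold_policy,
    fraction = fraction * stats::quantile(volume, 0.99, names = FALSE),
    fixed = {
      if (is.null(value)) stop("fixed policy requires `value`", call. = FALSE)
      value
    },
    otsu = {
      vals <- if (is.null(roi)) as.numeric(volume) else {
        as.numeric(volume[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2], roi$z[1]:roi$z[2]])
      }
      otsu_threshold(vals)
    })
  binary <- volume >= thr
  seed_lin <- vapply(seeds, function(s) {
    s[1] + (s[2] - 1L) * d[1] + (s[3] - 1L) * d[1] * d[2]
  }, numeric(1))
  if (any(!binary[seed_lin])) {
    stop("seed outside fluid: seed voxel intensity is below the threshold",
         call. = FALSE)
  }
  mask <- grow_from_seeds(binary, as.integer(seed_lin))
  if (!any(mask)) stop("empty mask after region growing", call. = FALSE)
  attr(mask, "threshold") <- thr
  attr(mask, "n_voxels") <- sum(mask)
  mask
}

# Breadth-first flood fill over a binary array with 26-connectivity,
# vectorized over the frontier.
grow_from_seeds <- function(binary, seed_lin) {
  d <- dim(binary)
  visited <- array(FALSE, d)
  visited[seed_lin] <- TRUE
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  frontier <- seed_lin
  while (length(frontier) > 0) {
    co <- arrayInd(frontier, d)
    nb_x <- rep(co[, 1], times = nrow(off)) + rep(off[, 1], each = nrow(co))
    nb_y <- rep(co[, 2], times = nrow(off)) + rep(off[, 2], each = nrow(co))
    nb_z <- rep(co[, 3], times = nrow(off)) + rep(off[, 3], each = nrow(co))
    ok <- nb_x >= 1L & nb_x <= d[1] & nb_y >= 1L & nb_y <= d[2] &
      nb_z >= 1L & nb_z <= d[3]
    lin <- nb_x[ok] + (nb_y[ok] - 1L) * d[1] + (nb_z[ok] - 1L) * d[1] * d[2]
    lin <- unique(lin)
    lin <- lin[binary[lin] & !visited[lin]]
    visited[lin] <- TRUE
    frontier <- lin
  }
  visited
}

#' Quantify fluid compartment volumes from a mask pair
#'
#' Converts the total-fluid (STIR-channel) and perilymph (FLAIR-channel)
#' segmentation masks into compartment volumes. The perilymph mask is first
#' intersected with the total-fluid mask (the containment rule), so that
#' `EV = TV - PV >= 0` holds by construction; perilymph voxels falling
#' outside the total-fluid mask are clipped with a warning.
#'
#' @param stir_mask logical 3D array: total fluid.
#' @param flair_mask logical 3D array: perilymph.
#' @param voxel_size isotropic voxel edge, mm.
#' @param structure `"cochlea"` or `"vestibule"` (carried through).
#' @return an object of class `fluid_volumes`: list with `structure`, `tv`,
#'   `pv`, `ev` (uL) and `ep_ratio`, plus `n_clipped` (perilymph voxels
#'   removed by the containment rule).
#' @export
#' @examples
#' m <- array(FALSE, c(10, 10, 10)); m[2:9, 2:9, 2:9] <- TRUE
#' p <- m; p[4:6, 4:6, 4:6] <- FALSE   # endolymph hole
#' quantify_volumes(m, p, voxel_size = 0.5)
quantify_volumes <- function(stir_mask, flair_mask, voxel_size,
                             structure = c("vestibule", "cochlea")) {
  structure <- match.arg(structure)
  stopifnot(identical(dim(stir_mask), dim(flair_mask)), voxel_size > 0)
  clipped <- flair_mask & !stir_mask
  n_clipped <- sum(clipped)
  if (n_clipped > 0) {
    warning(sprintf("%d perilymph voxels outside the total-fluid mask were clipped",
                    n_clipped), call. = FALSE)
  }
  pv_vox <- sum(flair_mask & stir_mask)
  tv_vox <- sum(stir_mask)
  if (pv_vox == 0) stop("no perilymph detected: E/P ratio undefined", call. = FALSE)
  vv <- voxel_size^3
  ev_vox <- tv_vox - pv_vox
  structure(list(structure = structure,
                 tv = tv_vox * vv, pv = pv_vox * vv, ev = ev_vox * vv,
                 ep_ratio = ev_vox / pv_vox, n_clipped = n_clipped),
            class = "fluid_volumes")
}

#' @export
print.fluid_volumes <- function(x, ...) {
  cat(sprintf("%s fluid volumes: TV %.2f uL, PV %.2f uL, EV %.2f uL, E/P %.3f\n",
              x$structure, x$tv, x$pv, x$ev, x$ep_ratio))
  invisible(x)
}

#' Classify endolymphatic hydrops from an E/P ratio
#'
#' Flags hydrops when the E/P ratio strictly exceeds the threshold. The
#' original determination was a radiologist's read of expanded hypointense
#' endolymph space; this numeric rule is the package's operational stand-in.
#'
#' @param fv a `fluid_volumes` object or a numeric E/P ratio.
#' @param threshold positive E/P cut-off (default 0.50 for the vestibule).
#' @return logical.
#' @export
classify_hydrops <- function(fv, threshold = 0.50) {
  stopifnot(threshold > 0)
  ep <- if (inherits(fv, "fluid_volumes")) fv$ep_ratio else as.numeric(fv)
  ep > threshold
}

#' Per-ear total-volume deviations from the ear mean
#'
#' Reliability diagnostic: deviations of each visit's TV from the ear's mean
#' TV. Deviations sum to zero per ear.
#'
#' @param tv numeric vector of TV measurements for one ear (>= 1 visit).
#' @return numeric vector of deviations.
#' @export
tv_deviations <- function(tv) {
  stopifnot(is.numeric(tv), length(tv) >= 1L)
  tv - mean(tv)
}

#' Association of contrast dose and delay time with perilymph volume
#'
#' Checks whether gadolinium dose or post-contrast delay time predicts the
#' measured perilymph volume: for each predictor, a simple linear regression
#' of PV on the predictor, reported as Pearson r, slope, and two-sided
#' p-value.
#'
#' @param cohort data frame with columns `vest_pv` (or `pv`), `dose`, and
#'   `delay_h`.
#' @return data frame with one row per predictor: `predictor`, `r`, `slope`,
#'   `p`.
#' @export
dose_delay_association <- function(cohort) {
  pv <- cohort$vest_pv %||% cohort$pv
  if (is.null(pv)) stop("cohort must contain a perilymph volume column", call. = FALSE)
  out <- lapply(c("dose", "delay_h"), function(nm) {
    x <- cohort[[nm]]
    if (is.null(x)) stop(sprintf("cohort lacks column '%s'", nm), call. = FALSE)
    keep <- is.finite(x) & is.finite(pv)
    x <- x[keep]; y <- pv[keep]
    if (length(x) < 3L) stop("need >= 3 instances", call. = FALSE)
    if (stats::sd(x) == 0) stop(sprintf("degenerate predictor '%s' (constant)", nm),
                                call. = FALSE)
    fit <- stats::lm(y ~ x)
    ct <- suppressWarnings(stats::cor.test(x, y))
    data.frame(predictor = nm, r = unname(ct$estimate),
               slope = unname(stats::coef(fit)[2]),
               p = summary(fit)$coefficients[2, 4])
  })
  do.call(rbind, out)
}

#' Dice overlap between two masks
#'
#' @param a,b logical arrays of equal dimension.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Run full volumetry on a phantom or image pair
#'
#' Segments both channels (the STIR-like channel from the fluid seed, the
#' FLAIR-like channel from the perilymph seed) and quantifies TV, PV, EV and
#' the E/P ratio.
#'
#' @param phantom an `ear_phantom`, or a list with `stir`, `flair`,
#'   `voxel_size` plus explicit `seeds`.
#' @param seeds optional list with elements `fluid` and `perilymph`
#'   overriding `phantom$seeds`.
#' @param ... passed to [segment_fluid()].
#' @return a `fluid_volumes` object.
#' @export
measure_phantom <- function(phantom, seeds = NULL, ...) {
  seeds <- seeds %||% phantom$seeds
  if (is.null(seeds)) stop("seeds are required", call. = FALSE)
  stir_mask <- segment_fluid(phantom$stir, seeds$fluid, ...)
  flair_mask <- segment_fluid(phantom$flair, seeds$perilymph, ...)
  st <- if (!is.null(phantom$spec)) phantom$spec$structure else "vestibule"
  quantify_volumes(stir_mask, flair_mask, phantom$voxel_size, structure = st)
}
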