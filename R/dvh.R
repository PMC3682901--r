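# Dose sampling, DVH computation and descriptive dose statistics of a masked
# region against a dose grid.

#' Sample a dose grid over a fractional mask
#'
#' For every occupied mask voxel the dose is trilinearly interpolated at the
#' voxel center mapped through `transform` (identity when the mask already
#' lives on the dose frame). Voxels mapping outside the dose grid are never
#' silently zeroed: they are returned with `defined = FALSE` and their volume
#' is carried through to the statistics as a separate "dose undefined"
#' volume.
#'
#' @param dose an [image_volume()] in Gy.
#' @param mask a [voxel_mask()].
#' @param transform a [rigid_transform()] mapping mask-frame points into the
#'   dose frame, or `NULL` for identity.
#' @return A data frame with columns `dose_gy`, `volume_ml`, `defined`.
#' @export
sample_dose <- function(dose, mask, transform = NULL) {
  occ <- as.vector(mask$occupancy)
  keep <- occ > 0
  if (!any(keep)) stop("mask has no occupied voxels")
  centers <- voxel_centers(mask)[keep, , drop = FALSE]
  if (!is.null(transform)) centers <- rt_apply(transform, centers)
  dval <- interp_volume(dose, centers, "linear", fill = NA_real_)
  defined <- !attr(dval, "outside")
  vol <- occ[keep] * voxel_volume_ml(mask)
  undef_frac <- sum(vol[!defined]) / sum(vol)
  if (undef_frac > 0.5)
    stop(sprintf(
      "%.0f%% of the masked volume maps outside the dose grid (grid mismatch)",
      100 * undef_frac))
  data.frame(dose_gy = as.numeric(dval), volume_ml = vol, defined = defined)
}

#' Dose-volume histogram of dose samples
#'
#' Volume-weighted histogram on uniform dose bins. The cumulative form is the
#' reverse cumulative sum: volume receiving at least each bin-edge dose; its
#' value at 0 Gy is the total (defined) volume.
#'
#' @param samples data frame from [sample_dose()].
#' @param bin_width bin width in Gy.
#' @param kind `"cumulative"` or `"differential"`.
#' @return An object of class `DVH` with fields `kind`, `dose_edges`,
#'   `volume_ml`, `total_volume_ml`, `bin_width`.
#' @export
compute_dvh <- function(samples, bin_width = 0.1,
                        kind = c("cumulative", "differential")) {
  kind <- match.arg(kind)
  def <- samples[samples$defined, , drop = FALSE]
  if (nrow(def) == 0L) stop("no defined dose samples")
  total <- sum(def$volume_ml)
  n_bins <- max(1L, ceiling(max(def$dose_gy) / bin_width + 1e-9))
  idx <- pmin(pmax(floor(def$dose_gy / bin_width) + 1L, 1L), n_bins)
  per_bin <- vapply(split(def$volume_ml, factor(idx, levels = seq_len(n_bins))),
                    sum, numeric(1))
  names(per_bin) <- NULL
  if (kind == "differential") {
    structure(list(kind = kind,
                   dose_edges = (seq_len(n_bins) - 1L) * bin_width,
                   volume_ml = per_bin,
                   total_volume_ml = total, bin_width = bin_width),
              class = "DVH")
  } else {
    cum <- rev(cumsum(rev(per_bin)))   # volume in bins k..n = dose >= edge k
    structure(list(kind = kind,
                   dose_edges = (seq_len(n_bins + 1L) - 1L) * bin_width,
                   volume_ml = c(cum, 0),
                   total_volume_ml = total, bin_width = bin_width),
              class = "DVH")
  }
}

#' @export
print.DVH <- function(x, ...) {
  cat(sprintf("<DVH> %s, %d bins of %.3g Gy, total volume %.2f ml\n",
              x$kind, length(x$volume_ml), x$bin_width, x$total_volume_ml))
  invisible(x)
}

#' @export
as.data.frame.DVH <- function(x, ...) {
  data.frame(dose_gy = x$dose_edges, volume_ml = x$volume_ml)
}

#' @export
plot.DVH <- function(x, ..., xlab = "Dose [Gy]", ylab = "Volume [ml]",
                     type = "s") {
  graphics::plot(x$dose_edges, x$volume_ml, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Export a DVH as two-column CSV
#'
#' Header comment lines state the kind, bin width and the structure/plan the
#' histogram belongs to, so exported curves remain self-describing.
#'
#' @param dvh a `DVH`.
#' @param path output file.
#' @param structure,plan labels written into the header.
#' @export
write_dvh_csv <- function(dvh, path, structure = "", plan = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# kind=%s bin_width_gy=%g structure=%s plan=%s",
            dvh$kind, dvh$bin_width, structure, plan),
    "dose_gy,volume_ml"), con)
  utils::write.table(
    data.frame(format(dvh$dose_edges, trim = TRUE),
               format(dvh$volume_ml, trim = TRUE)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# volume-weighted quantile with linear interpolation between spanning samples
weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w)
  total <- cw[length(cw)]
  pos <- (cw - w / 2) / total
  if (p <= pos[1L]) return(x[1L])
  if (p >= pos[length(pos)]) return(x[length(x)])
  stats::approx(pos, x, xout = p, ties = "ordered")$y
}

#' Descriptive dose statistics of a masked region
#'
#' Min/max over occupied voxels with defined dose, volume-weighted median
#' with linear interpolation across the spanning sample, and the masked
#' volume receiving at least the isodose threshold. Dose-undefined voxels are
#' excluded from min/max/median (a silent zero would corrupt the minimum) but
#' reported as `undefined_vol_ml`.
#'
#' @param samples data frame from [sample_dose()].
#' @param isodose_threshold_gy absolute threshold in Gy for the
#'   volume-in-isodose statistic.
#' @return An object of class `DoseStats`.
#' @export
dose_stats <- function(samples, isodose_threshold_gy = NA_real_) {
  def <- samples[samples$defined, , drop = FALSE]
  if (nrow(def) == 0L) stop("no defined dose samples")
  vol_iso <- if (is.na(isodose_threshold_gy)) NA_real_
             else sum(def$volume_ml[def$dose_gy >= isodose_threshold_gy])
  structure(list(
    min_gy = min(def$dose_gy),
    max_gy = max(def$dose_gy),
    median_gy = weighted_quantile(def$dose_gy, def$volume_ml, 0.5),
    vol_in_isodose_ml = vol_iso,
    isodose_threshold_gy = isodose_threshold_gy,
    recurrence_vol_ml = sum(samples$volume_ml),
    undefined_vol_ml = sum(samples$volume_ml[!samples$defined])
  ), class = "DoseStats")
}

#' @export
print.DoseStats <- function(x, ...) {
  cat(sprintf("<DoseStats> volume %.2f ml: min %.2f / median %.2f / max %.2f Gy\n",
              x$recurrence_vol_ml, x$min_gy, x$median_gy, x$max_gy))
  if (!is.na(x$vol_in_isodose_ml))
    cat(sprintf("  volume at >= %.2f Gy: %.2f ml\n",
                x$isodose_threshold_gy, x$vol_in_isodose_ml))
  if (x$undefined_vol_ml > 0)
    cat(sprintf("  dose-undefined volume: %.2f ml\n", x$undefined_vol_ml))
  invisible(x)
}
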