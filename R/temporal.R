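#' Aggregate EGCI points into temporal centroids
#'
#' Groups timestamped HxC points (the output of [egci_batch()]) and returns
#' per-group centroids with dispersion: arithmetic means of H, J, C, sample
#' standard deviations of H and C, and normal-approximation 95% confidence
#' half-widths (`1.96 * sd / sqrt(n)`). Dispersion fields are 0 for
#' single-point groups. These are the plane centroids plotted per hour of
#' day in soundscape characterizations.
#'
#' @param points data frame with columns `H`, `J`, `C` and a `timestamp`
#'   column of `POSIXct` values (no missing timestamps).
#' @param by grouping granularity: `"hour"` (hour of day, 0-23),
#'   `"half_hour"` (decimal hour 0, 0.5, ..., 23.5), `"day"` (calendar
#'   date), or a function `(POSIXct) -> labels`.
#' @param tz time zone used to extract local hour (default `"UTC"`; field
#'   sites use fixed offsets, so no DST handling is applied).
#' @return data frame of class `egci_centroids`, sorted by group key:
#'   columns `key`, `n`, `mean_H`, `mean_J`, `mean_C`, `sd_H`, `sd_C`,
#'   `ci_H`, `ci_C`.
#' @export
aggregate_points <- function(points, by = "hour", tz = "UTC") {
  stopifnot(is.data.frame(points))
  for (cn in c("H", "J", "C", "timestamp"))
    if (is.null(points[[cn]]))
      stop("`points` must have column `", cn, "`", call. = FALSE)
  bad <- which(is.na(points$timestamp))
  if (length(bad) > 0)
    stop("untimestamped points at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  ts <- as.POSIXct(points$timestamp, tz = tz)
  lt <- as.POSIXlt(ts, tz = tz)
  key <- if (is.function(by)) {
    by(ts)
  } else {
    switch(match.arg(by, c("hour", "half_hour", "day")),
           hour = lt$hour,
           half_hour = lt$hour + ifelse(lt$min >= 30, 0.5, 0),
           day = format(ts, "%Y-%m-%d", tz = tz))
  }
  groups <- split(seq_len(nrow(points)), key)
  rows <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    n <- length(idx)
    sdv <- function(v) if (n > 1) stats::sd(v) else 0
    sH <- sdv(points$H[idx]); sC <- sdv(points$C[idx])
    data.frame(key = k, n = n,
               mean_H = mean(points$H[idx]),
               mean_J = mean(points$J[idx]),
               mean_C = mean(points$C[idx]),
               sd_H = sH, sd_C = sC,
               ci_H = if (n > 1) 1.96 * sH / sqrt(n) else 0,
               ci_C = if (n > 1) 1.96 * sC / sqrt(n) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keynum <- suppressWarnings(as.numeric(out$key))
  out <- out[order(if (all(!is.na(keynum))) keynum else out$key), ]
  rownames(out) <- NULL
  class(out) <- c("egci_centroids", "data.frame")
  out
}

#' Daily soundscape fingerprint
#'
#' The half-hour profile of the complexity index pooled across all recorded
#' days: 48 bins of mean H, J, C with confidence intervals. Bins without any
#' segment are present but flagged (`n = 0`, means `NA`), never
#' interpolated — duty-cycled or interrupted deployments simply leave gaps.
#' A stable soundscape reproduces this curve from day to day; diel activity
#' peaks (dawn/dusk choruses) appear as complexity maxima.
#'
#' @param points data frame as in [aggregate_points()].
#' @param tz time zone for local hour extraction.
#' @return data frame of class `egci_fingerprint`: 48 rows with `key`
#'   (decimal hour: 0, 0.5, ..., 23.5) and the centroid columns.
#' @export
fingerprint <- function(points, tz = "UTC") {
  agg <- aggregate_points(points, by = "half_hour", tz = tz)
  bins <- data.frame(key = sprintf("%g", seq(0, 23.5, by = 0.5)),
                     stringsAsFactors = FALSE)
  agg$key <- sprintf("%g", as.numeric(agg$key))
  out <- merge(bins, agg, by = "key", all.x = TRUE, sort = FALSE)
  out$n[is.na(out$n)] <- 0L
  out <- out[order(as.numeric(out$key)), ]
  out$key <- as.numeric(out$key)
  rownames(out) <- NULL
  class(out) <- c("egci_fingerprint", "data.frame")
  out
}

#' Stratify EGCI points by arbitrary labels
#'
#' Partitions plane points by an external label — month, season, or an event
#' interval such as a rain shower — and returns both the per-label centroid
#' and the raw point cloud for plane overlays. Seasonal change appears as
#' centroid displacement; a rain interval pulls its centroid toward the
#' low-entropy end of the colored-noise curve.
#'
#' @param points data frame as in [aggregate_points()].
#' @param labels character/factor vector of length `nrow(points)`, or a
#'   function `(POSIXct) -> labels`. `NA` labels are an error.
#' @return list with `centroids` (one [aggregate_points()] row per label)
#'   and `clouds` (named list of the per-label point subsets).
#' @export
stratify <- function(points, labels) {
  stopifnot(is.data.frame(points))
  lab <- if (is.function(labels)) labels(as.POSIXct(points$timestamp)) else
    labels
  if (length(lab) != nrow(points))
    stop("`labels` must provide one label per point", call. = FALSE)
  if (any(is.na(lab)))
    stop("unknown (NA) labels at rows: ",
         paste(utils::head(which(is.na(lab)), 10), collapse = ", "),
         call. = FALSE)
  cent <- aggregate_points(points, by = function(ts) lab)
  clouds <- split(points, lab)
  list(centroids = cent, clouds = clouds)
}
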