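#' Growth parameters from OD time series
#'
#' Per well: the curve is smoothed with a centered 3-point running median
#' (endpoints kept), then carrying capacity = max smoothed OD, AUC = the
#' trapezoidal integral over the observation window, and maximum growth
#' rate = the largest forward difference per hour. Wells with fewer than 3
#' timepoints are marked unusable.
#'
#' @param series long data.frame with columns `well`, `hour`, `od` (one
#'   strain/plate/wavelength at a time).
#' @return data.frame: `well`, `carrying_capacity`, `auc`, `max_rate`,
#'   `usable`.
#' @export
fit_growth <- function(series) {
  wells <- unique(series$well)
  out <- lapply(wells, function(wl) {
    s <- series[series$well == wl, ]
    s <- s[order(s$hour), ]
    if (any(diff(s$hour) <= 0)) stop("timepoints must be strictly increasing")
    if (any(s$od < 0)) stop("OD must be non-negative")
    if (nrow(s) < 3)
      return(data.frame(well = wl, carrying_capacity = NA_real_, auc = NA_real_,
                        max_rate = NA_real_, usable = FALSE))
    sm <- stats::runmed(s$od, 3, endrule = "keep")
    auc <- sum(diff(s$hour) * (utils::head(sm, -1) + sm[-1]) / 2)
    max_rate <- max(diff(sm) / diff(s$hour))
    data.frame(well = wl, carrying_capacity = max(sm), auc = auc,
               max_rate = max(0, max_rate), usable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Flag wells with abiotic dye reduction
#'
#' Default heuristic: a well whose OD at the first timepoint exceeds the
#' plate median first-timepoint OD by more than 3 MADs is excluded.
#'
#' @param series long data.frame (`well`, `hour`, `od`) for one plate.
#' @param n_mad MAD multiplier (default 3).
#' @return character vector of excluded wells.
#' @export
exclude_dye_wells <- function(series, n_mad = 3) {
  t0 <- min(series$hour)
  od0 <- series$od[series$hour == t0]
  names(od0) <- series$well[series$hour == t0]
  med <- stats::median(od0)
  mad0 <- stats::mad(od0)
  if (mad0 == 0) mad0 <- 1e-9
  names(od0)[od0 > med + n_mad * mad0]
}

#' Normalize growth parameters by the A1 negative control and scale per strain
#'
#' Each well's parameter is reduced by the A1 value (so A1 maps exactly to
#' 0), then positive values are scaled by `100 / max` and negative values by
#' `100 / |min|` independently, giving values in [-100, 100] with 0
#' preserved.
#'
#' @param params named numeric vector of one growth parameter per well
#'   (must contain `"A1"`).
#' @return named numeric vector of scaled values in [-100, 100].
#' @export
normalize_and_scale <- function(params) {
  if (!("A1" %in% names(params))) stop("A1 negative control missing or excluded")
  v <- params - params[["A1"]]
  pos <- max(v, na.rm = TRUE)
  neg <- min(v, na.rm = TRUE)
  out <- v
  if (pos > 0) out[v > 0] <- v[v > 0] * 100 / pos
  if (neg < 0) out[v < 0] <- v[v < 0] * 100 / abs(neg)
  out
}

#' Activity index (AV) from scaled utilization values
#'
#' Exact univariate k-means over the pooled scaled values of one
#' wavelength; clusters are ordered by center and labeled 1 (lowest
#' utilization) to `k` (highest, default 9). AV is monotone in the scaled
#' value by construction.
#'
#' @param scaled numeric vector of scaled values (possibly across wells and
#'   strains).
#' @param k number of activity levels (default 9; reduced with a warning
#'   when there are fewer distinct values).
#' @return integer vector of AV labels aligned with `scaled`.
#' @export
activity_index <- function(scaled, k = 9) {
  km <- kmeans_1d(scaled, k)
  km$cluster  # kmeans_1d labels clusters in ascending center order
}

#' Full Phenotype MicroArray scoring pipeline
#'
#' For every strain x plate x wavelength: excludes dye-reduction wells, fits
#' growth parameters, normalizes by A1 and scales to [-100, 100]; then pools
#' scaled values per wavelength across strains and assigns the 1-9 activity
#' index. A strain/wavelength whose A1 well is excluded is dropped with a
#' warning.
#'
#' @param pm long data.frame: `strain`, `plate`, `well`, `wavelength`,
#'   `hour`, `od` (optionally `substrate`).
#' @param param which growth parameter feeds the AV
#'   (`"auc"` default, `"carrying_capacity"`, or `"max_rate"`).
#' @param k number of AV levels (default 9).
#' @param exclude_dye apply [exclude_dye_wells()] (default TRUE).
#' @return data.frame: `strain`, `plate`, `wavelength`, `well`, parameter
#'   columns, `scaled`, `av`.
#' @export
pm_pipeline <- function(pm, param = c("auc", "carrying_capacity", "max_rate"),
                        k = 9, exclude_dye = TRUE) {
  param <- match.arg(param)
  groups <- unique(pm[, c("strain", "plate", "wavelength")])
  res <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    s <- pm[pm$strain == g$strain & pm$plate == g$plate &
              pm$wavelength == g$wavelength, ]
    excl <- if (exclude_dye) exclude_dye_wells(s) else character(0)
    if ("A1" %in% excl) {
      warning("A1 excluded for dye reduction; strain ", g$strain,
              " unusable at ", g$wavelength, " nm")
      next
    }
    s <- s[!(s$well %in% excl), ]
    fit <- fit_growth(s)
    fit <- fit[fit$usable, ]
    vals <- stats::setNames(fit[[param]], fit$well)
    scaled <- normalize_and_scale(vals)
    res[[length(res) + 1L]] <- data.frame(
      strain = g$strain, plate = g$plate, wavelength = g$wavelength,
      well = fit$well, carrying_capacity = fit$carrying_capacity,
      auc = fit$auc, max_rate = fit$max_rate,
      scaled = unname(scaled[fit$well]), stringsAsFactors = FALSE)
  }
  if (length(res) == 0) stop("no usable strain/wavelength combination")
  out <- do.call(rbind, res)
  out$av <- NA_integer_
  for (wv in unique(out$wavelength)) {
    rows <- out$wavelength == wv
    out$av[rows] <- activity_index(out$scaled[rows], k = k)
  }
  out
}
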