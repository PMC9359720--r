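#' @include synth-growth.R
NULL

#' Configuration of synthetic survival endpoints
#'
#' Endpoint rules for a simulated cohort: a mouse reaches its event when any
#' of its tumors first exceeds the endpoint volume, and is censored at the
#' follow-up cap otherwise. The default endpoint volume is the
#' sphere-equivalent of a 1.5 cm diameter, `(4/3) * pi * 7.5^3 ~ 1767 mm^3`;
#' the default cap is 180 days.
#'
#' @param endpoint_volume volume threshold in mm^3 (> 0).
#' @param max_followup_days censoring horizon in days from enrollment (> 0).
#' @param seed integer seed (kept for interface symmetry; the endpoint rule
#'   itself is deterministic given a cohort).
#' @return A list of class `SurvivalSimConfig`.
#' @export
survivalSimConfig <- function(endpoint_volume = 4 / 3 * pi * 7.5^3,
                              max_followup_days = 180, seed = 1L) {
  .checkPositiveScalar(endpoint_volume, "endpoint_volume")
  .checkPositiveScalar(max_followup_days, "max_followup_days")
  structure(list(endpoint_volume = endpoint_volume,
                 max_followup_days = max_followup_days,
                 seed = as.integer(seed)),
            class = "SurvivalSimConfig")
}

# First crossing day of one tumor's volume trajectory over a threshold,
# interpolating linearly on the cube-root scale between observation days.
.firstCrossing <- function(day, volume, threshold) {
  o <- order(day)
  day <- day[o]
  y <- volume[o]^(1 / 3)
  thr <- threshold^(1 / 3)
  if (y[1L] >= thr) return(day[1L])
  idx <- which(y >= thr)
  if (!length(idx)) return(NA_real_)
  i <- idx[1L]
  # linear interpolation on the cube-root scale within the bracketing segment
  day[i - 1L] + (thr - y[i - 1L]) / (y[i] - y[i - 1L]) * (day[i] - day[i - 1L])
}

#' Simulate survival endpoints from a volume cohort
#'
#' Per mouse, the event time is the first day (linearly interpolated on the
#' cube-root volume scale between observation days) at which any of its
#' tumors crosses the endpoint volume; mice whose tumors never cross are
#' censored at `max_followup_days`.
#'
#' @param cohort data.frame with mouse_id, tumor_id, arm, day, volume_mm3
#'   (e.g. from [simulateGrowthCohort()]).
#' @param config a [survivalSimConfig()].
#' @return data.frame with columns mouse_id, group (arm), time_days, event
#'   (1 = endpoint reached, 0 = censored).
#' @export
simulateSurvival <- function(cohort, config = survivalSimConfig()) {
  if (!inherits(config, "SurvivalSimConfig"))
    stop("'config' must come from survivalSimConfig()")
  if (is.null(cohort) || !nrow(cohort)) stop("cohort is empty")
  need <- c("mouse_id", "tumor_id", "day", "volume_mm3")
  if (!all(need %in% names(cohort)))
    stop("cohort must provide columns ", paste(need, collapse = ", "))
  grp_col <- if ("arm" %in% names(cohort)) "arm" else "true_group"
  mice <- unique(cohort[c("mouse_id", grp_col)])
  times <- vapply(mice$mouse_id, function(m) {
    sub <- cohort[cohort$mouse_id == m, , drop = FALSE]
    xs <- vapply(split(sub, sub$tumor_id), function(s)
      .firstCrossing(s$day, s$volume_mm3, config$endpoint_volume), numeric(1))
    if (all(is.na(xs))) NA_real_ else min(xs, na.rm = TRUE)
  }, numeric(1))
  event <- as.integer(!is.na(times) & times <= config$max_followup_days)
  time_days <- ifelse(event == 1L, times, config$max_followup_days)
  data.frame(mouse_id = mice$mouse_id, group = mice[[grp_col]],
             time_days = time_days, event = event,
             row.names = NULL, stringsAsFactors = FALSE)
}
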