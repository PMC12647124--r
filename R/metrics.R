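# Mucus area ratio and mucus contact ratio.
#
# Per cross-section: the area ratio is the fraction of the airway lumen
# (air + mucus) occupied by mucus; the contact ratio is the fraction of the
# airway wall covered by mucus, with the wall operationalised as the lumen
# voxels having a 6-neighbour outside the airway interior.  Ratios are kept
# as fractions internally; summaries report percent.

#' Mucus area ratio of cross-section records
#'
#' @param cs a `cs_records` table (or any data.frame with `n_mucus`,
#'   `n_lumen`).
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
area_ratio <- function(cs) {
  if (any(cs$n_lumen < 1L)) stop("empty lumen in cross-section record")
  cs$n_mucus / cs$n_lumen
}

#' Mucus contact ratio of cross-section records
#'
#' @param cs a `cs_records` table (or any data.frame with
#'   `n_perimeter_mucus`, `n_perimeter`).
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
contact_ratio <- function(cs) {
  if (any(cs$n_perimeter < 1L)) stop("empty perimeter in cross-section record")
  cs$n_perimeter_mucus / cs$n_perimeter
}

#' Ratio records from cross-section records
#'
#' @param records a `cs_records` table from one extraction method.
#' @return data.table `method, branch_id, station, area_ratio, contact_ratio,
#'   n_lumen, n_perimeter`.
#' @export
compute_ratios <- function(records) {
  if (!nrow(records))
    return(data.table(method = character(), branch_id = integer(), station = integer(),
                      area_ratio = numeric(), contact_ratio = numeric(),
                      n_lumen = integer(), n_perimeter = integer()))
  # a geodesic bin can (rarely) contain only interior voxels; its contact
  # ratio is undefined and recorded as NA rather than dropping the record
  contact <- ifelse(records$n_perimeter > 0L,
                    records$n_perimeter_mucus / pmax(records$n_perimeter, 1L),
                    NA_real_)
  data.table(method = records$method, branch_id = records$branch_id,
             station = records$station, area_ratio = area_ratio(records),
             contact_ratio = contact,
             n_lumen = records$n_lumen, n_perimeter = records$n_perimeter)
}

#' Ordered per-branch ratio profiles
#'
#' Stations are ordered proximal to distal; stations absent from the input
#' (e.g. skipped bifurcations) are preserved as missing rows.
#'
#' @param ratios output of [compute_ratios()], single method.
#' @return data.table `branch_id, station, area_ratio, contact_ratio` with
#'   `NA` for missing stations.
#' @export
branch_profile <- function(ratios) {
  r <- as.data.table(ratios)
  if (!nrow(r)) return(data.table(branch_id = integer(), station = integer(),
                                  area_ratio = numeric(), contact_ratio = numeric()))
  if (length(unique(r$method)) > 1L)
    stop("branch_profile expects records from a single method")
  full <- r[, .(station = seq(min(station), max(station))), by = branch_id]
  out <- merge(full, r[, .(branch_id, station, area_ratio, contact_ratio)],
               by = c("branch_id", "station"), all.x = TRUE, sort = TRUE)
  out[]
}

#' Per-sample summary of mucus ratios
#'
#' Unweighted mean over cross-section records (switch to per-branch means
#' with `mean_over = "branches"`), reported in percent.
#'
#' @param ratios output of [compute_ratios()].
#' @param sample_id sample identifier.
#' @param mean_over average over `"stations"` (default, every record counts
#'   once) or `"branches"` (branch means first, then across branches).
#' @return one-row data.table `sample_id, method, mean_area_ratio,
#'   mean_contact_ratio, n_cross_sections` (percent scale).
#' @export
sample_summary <- function(ratios, sample_id, mean_over = c("stations", "branches")) {
  mean_over <- match.arg(mean_over)
  r <- as.data.table(ratios)
  if (!nrow(r)) stop("cannot summarise zero ratio records")
  by_method <- function(rr) {
    if (mean_over == "branches") {
      bm <- rr[, .(a = mean(area_ratio), c = mean(contact_ratio, na.rm = TRUE)),
               by = branch_id]
      data.table(mean_area_ratio = 100 * mean(bm$a), mean_contact_ratio = 100 * mean(bm$c),
                 n_cross_sections = nrow(rr))
    } else {
      data.table(mean_area_ratio = 100 * mean(rr$area_ratio),
                 mean_contact_ratio = 100 * mean(rr$contact_ratio, na.rm = TRUE),
                 n_cross_sections = nrow(rr))
    }
  }
  out <- r[, by_method(.SD), by = method]
  out[, sample_id := sample_id]
  setcolorder(out, c("sample_id", "method", "mean_area_ratio", "mean_contact_ratio",
                     "n_cross_sections"))
  out[]
}

#' Correlation and regression between mean area and mean contact ratios
#'
#' Pearson r of per-sample (mean area %, mean contact %) pairs and the
#' ordinary least squares fit of contact on area, per method.
#'
#' @param summaries table of [sample_summary()] rows (>= 3 samples per
#'   method).
#' @return data.table `method, r, slope, intercept, r_squared, p_value, n`.
#' @export
correlate_summaries <- function(summaries) {
  s <- as.data.table(summaries)
  one <- function(ss) {
    if (nrow(ss) < 3L) stop("correlate_summaries needs >= 3 samples")
    fit <- simple_linreg(ss$mean_area_ratio, ss$mean_contact_ratio)
    data.table(r = fit$r, slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, p_value = fit$p_value, n = fit$n)
  }
  out <- s[, one(.SD), by = method]
  out[]
}
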