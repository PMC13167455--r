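#' Select candidate range-shift events from a directed overlap panel
#'
#' Scans every forward period pair (t, t+i), i >= 1, within each unordered
#' dyad and keeps events where (a) the directed overlap in at least one
#' direction rises from below 0.25 to above 0.45 (both comparisons strict,
#' exactly as printed) and (b) the net change in relative group size --
#' `(size_a - size_b)` at t+i minus the same difference at t -- has absolute
#' value of at least 5 individuals. The group whose relative size grew is
#' recorded as the one that `became_larger`. Dyads with zero overlap in every
#' period never qualify (the thresholds require a nonzero-overlap period).
#'
#' @param records directed dyad table (double-entered) with columns
#'   `focal_id`, `neighbour_id`, `dyad_id`, `period`, `po`, `focal_size`,
#'   `neighbour_size`; `period` must be sortable (year or year-season label).
#' @param po_low,po_high overlap thresholds (strict `<` and `>`).
#' @param min_size_change minimum absolute net relative-size change (`>=`).
#' @return data.frame of shift events: dyad, periods, overlap before/after,
#'   `size_change_net` (signed toward the dyad's first-listed group) and
#'   `grew_id` / `shrank_id`.
#' @export
select_shift_events <- function(records, po_low = 0.25, po_high = 0.45,
                                min_size_change = 5) {
  need <- c("focal_id", "neighbour_id", "dyad_id", "period", "po",
            "focal_size", "neighbour_size")
  stopifnot(all(need %in% names(records)))
  out <- list()
  for (dy in unique(records$dyad_id)) {
    sub <- records[records$dyad_id == dy, ]
    ids <- strsplit(dy, ":", fixed = TRUE)[[1]]
    a <- ids[1]; b <- ids[2]
    periods <- sort(unique(sub$period))
    if (length(periods) < 2) next
    for (i in seq_along(periods)) for (j in seq_along(periods)) {
      if (j <= i) next
      t0 <- sub[sub$period == periods[i], ]
      t1 <- sub[sub$period == periods[j], ]
      # overlap criterion: either direction passes strictly
      po_pass <- any(vapply(ids, function(f) {
        p0 <- t0$po[t0$focal_id == f]; p1 <- t1$po[t1$focal_id == f]
        length(p0) == 1 && length(p1) == 1 && p0 < po_low && p1 > po_high
      }, NA))
      if (!isTRUE(po_pass)) next
      rel0 <- rel_size(t0, a); rel1 <- rel_size(t1, a)
      if (anyNA(c(rel0, rel1))) next
      net <- rel1 - rel0
      if (abs(net) < min_size_change) next
      out[[length(out) + 1L]] <- data.frame(
        dyad_id = dy, period_t = periods[i], period_ti = periods[j],
        po_before = max(t0$po), po_after = max(t1$po),
        size_change_net = net,
        grew_id = if (net > 0) a else b, shrank_id = if (net > 0) b else a)
    }
  }
  if (length(out) == 0)
    return(data.frame(dyad_id = character(0), period_t = character(0),
                      period_ti = character(0), po_before = numeric(0),
                      po_after = numeric(0), size_change_net = numeric(0),
                      grew_id = character(0), shrank_id = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

rel_size <- function(rows, a) {
  fa <- rows[rows$focal_id == a, ]
  if (nrow(fa) != 1) return(NA_real_)
  fa$focal_size - fa$neighbour_size
}

#' Classify which group drove an overlap increase
#'
#' Given the signed centroid-distance changes ([delta_d()]) of the two groups
#' in a shift event, the group with the larger magnitude of change is deemed
#' the driver. The event is labelled `became_larger` if the driver is the
#' group whose relative size grew, `became_smaller` otherwise, and
#' `indeterminate` on an exact magnitude tie (ties are excluded from the
#' driver-proportion summary).
#'
#' @param event one row of [select_shift_events()] output.
#' @param dd_grew,dd_shrank [delta_d()] for the growing and shrinking group.
#' @return the event row with `delta_d_grew`, `delta_d_shrank`, `driver_id`,
#'   `driver` columns added.
#' @export
classify_driver <- function(event, dd_grew, dd_shrank) {
  stopifnot(is.finite(dd_grew), is.finite(dd_shrank))
  event$delta_d_grew <- dd_grew
  event$delta_d_shrank <- dd_shrank
  if (abs(dd_grew) == abs(dd_shrank)) {
    event$driver_id <- NA_character_
    event$driver <- "indeterminate"
  } else if (abs(dd_grew) > abs(dd_shrank)) {
    event$driver_id <- event$grew_id
    event$driver <- "became_larger"
  } else {
    event$driver_id <- event$shrank_id
    event$driver <- "became_smaller"
  }
  event
}

#' Proportion of shift events driven by the group that became larger
#'
#' Fraction of non-indeterminate classified events with
#' `driver == "became_larger"`, with an exact (Clopper-Pearson) binomial
#' confidence interval.
#'
#' @param events data.frame of classified events (see [classify_driver()]).
#' @param conf confidence level.
#' @return list: `proportion`, `n`, `n_larger`, `ci` (length-2).
#' @export
driver_proportion <- function(events, conf = 0.95) {
  ev <- events[events$driver != "indeterminate", , drop = FALSE]
  if (nrow(ev) == 0) stop("no non-indeterminate events")
  k <- sum(ev$driver == "became_larger")
  bt <- stats::binom.test(k, nrow(ev), conf.level = conf)
  list(proportion = k / nrow(ev), n = nrow(ev), n_larger = k,
       ci = as.numeric(bt$conf.int))
}
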