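# Rates of change along environmental transitions: the OLS slope of
# dissimilarity-to-head-site (or abundance difference) against water transit
# time, computed per transition and sampling date.

#' Construct a transition series
#'
#' The ordered sites of one environmental transition on one sampling date,
#' with the cumulative water transit time (hours) from the head site.
#'
#' @param transition_id Identifier of the transition.
#' @param date Sampling-date label.
#' @param site_ids Ordered site-date ids (head first); must match the row
#'   ids of the category matrices and band table.
#' @param transit_times_h Hours from the head site: starts at 0, strictly
#'   increasing, one value per site.
#' @return Object of class `transition_series`.
#' @export
transition_series <- function(transition_id, date, site_ids, transit_times_h) {
  site_ids <- as.character(site_ids)
  transit_times_h <- as.numeric(transit_times_h)
  if (length(site_ids) < 2L) {
    stop("a transition needs at least 2 sites", call. = FALSE)
  }
  if (length(site_ids) != length(transit_times_h)) {
    stop("site_ids and transit_times_h lengths differ", call. = FALSE)
  }
  if (transit_times_h[1] != 0) {
    stop("transit time of the head site must be 0", call. = FALSE)
  }
  if (any(diff(transit_times_h) <= 0)) {
    stop("transit times must be strictly increasing", call. = FALSE)
  }
  structure(list(transition_id = transition_id, date = date,
                 site_ids = site_ids, transit_times_h = transit_times_h),
            class = "transition_series")
}

#' @export
print.transition_series <- function(x, ...) {
  cat(sprintf("transition_series %s / %s: %d sites, 0-%g h\n",
              x$transition_id, x$date, length(x$site_ids),
              max(x$transit_times_h)))
  invisible(x)
}

#' Dissimilarity-to-head series of a transition
#'
#' Looks up, for each site of a transition, its dissimilarity to the head
#' site, paired with its transit time.  The head contributes the anchoring
#' point (0 h, 0 dissimilarity).
#'
#' @param d Square dissimilarity matrix with site-date ids as dimnames
#'   (see [euclidean_distance_matrix()]).
#' @param t A [transition_series()].
#' @return Data frame with columns `hours` and `dissimilarity`, one row per
#'   site in transition order.
#' @export
head_dissimilarity_series <- function(d, t) {
  stopifnot(inherits(t, "transition_series"))
  missing <- setdiff(t$site_ids, rownames(d))
  if (length(missing)) {
    stop("site(s) absent from dissimilarity matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  head_id <- t$site_ids[1]
  data.frame(hours = t$transit_times_h,
             dissimilarity = d[head_id, t$site_ids])
}

#' Rate of change: OLS slope of a value-versus-time series
#'
#' Ordinary least squares with a free intercept; the slope, in value per
#' hour, is the rate-of-change statistic.  Use `through_origin = TRUE` to
#' force the fit through (0, 0) instead.
#'
#' @param series Data frame or list with components `hours` (or first
#'   column) and a value column.
#' @param through_origin Force a zero intercept (default `FALSE`).
#' @return List with `slope` (per hour), `r_squared` (`NA` for a constant
#'   series) and `n` (points used).
#' @export
rate_of_change <- function(series, through_origin = FALSE) {
  series <- as.data.frame(series)
  hours <- as.numeric(series[[1]])
  value <- as.numeric(series[[2]])
  ok <- is.finite(hours) & is.finite(value)
  hours <- hours[ok]; value <- value[ok]
  n <- length(hours)
  if (n < 2L) stop("need at least 2 points for a rate", call. = FALSE)
  if (length(unique(hours)) < 2L) {
    stop("degenerate design: all transit times equal", call. = FALSE)
  }
  fit <- if (through_origin) {
    stats::lm(value ~ 0 + hours)
  } else {
    stats::lm(value ~ hours)
  }
  slope <- unname(stats::coef(fit)[["hours"]])
  r2 <- if (stats::var(value) == 0) NA_real_ else summary(fit)$r.squared
  list(slope = slope, r_squared = r2, n = n)
}

# Head-relative series carry a deterministic self-comparison (0 h, 0) at the
# head site.  Because dissimilarities are non-negative, anchoring a
# free-intercept OLS at that exact zero biases slopes upward under pure
# noise; the "auto" policy therefore drops the self-pair whenever at least
# two downstream points remain, and keeps it for 2-site transitions where
# the slope is the finite difference.
apply_anchor_policy <- function(series, include_anchor) {
  include_anchor <- match.arg(include_anchor, c("auto", "always", "never"))
  if (include_anchor == "always") return(series)
  if (include_anchor == "never" || nrow(series) >= 3L) {
    series[-1, , drop = FALSE]
  } else {
    series
  }
}

#' Rate of change in abundance
#'
#' Abundance is a single variable, so instead of a multivariate
#' dissimilarity the rate uses the actual difference in abundance from the
#' head site, regressed on transit time.
#'
#' @param abundances Abundance per site, in transition order (native units,
#'   e.g. cells per ml).
#' @param t A [transition_series()].
#' @param include_anchor Policy for the head's deterministic (0 h, 0)
#'   self-comparison: `"auto"` (default; dropped when at least two
#'   downstream sites remain), `"always"` or `"never"`.
#' @inheritParams rate_of_change
#' @return As [rate_of_change()]; slope in abundance units per hour.
#' @export
abundance_rate <- function(abundances, t, through_origin = FALSE,
                           include_anchor = "auto") {
  stopifnot(inherits(t, "transition_series"))
  abundances <- as.numeric(abundances)
  if (length(abundances) != length(t$site_ids)) {
    stop("one abundance per site required", call. = FALSE)
  }
  series <- data.frame(hours = t$transit_times_h,
                       value = abundances - abundances[1])
  rate_of_change(apply_anchor_policy(series, include_anchor),
                 through_origin = through_origin)
}

#' Rates of change in diversity and in banding pattern
#'
#' From the band table of one transition: the OLS slope of (i) the
#' difference in Shannon diversity H' from the head lane and (ii) the number
#' of presence-absence band changes relative to the head lane, both against
#' transit time.  These two descriptive rates are reported alongside the six
#' category rates but are excluded from path modeling.
#'
#' @param bands Band-intensity matrix (rows: site-date ids; columns: bands).
#' @param t A [transition_series()].
#' @param presence_threshold Passed to [band_turnover()].
#' @inheritParams abundance_rate
#' @inheritParams rate_of_change
#' @return List with `H_rate` and `banding_rate`, each as returned by
#'   [rate_of_change()].
#' @export
diversity_and_banding_rates <- function(bands, t, presence_threshold = 0,
                                        through_origin = FALSE,
                                        include_anchor = "auto") {
  stopifnot(inherits(t, "transition_series"))
  missing <- setdiff(t$site_ids, rownames(bands))
  if (length(missing)) {
    stop("site(s) absent from band table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lanes <- bands[t$site_ids, , drop = FALSE]
  H <- apply(lanes, 1, function(r) shannon_index(relative_intensities(r)))
  head_lane <- lanes[1, ]
  changed <- apply(lanes, 1, function(r) {
    band_turnover(head_lane, r, presence_threshold)[["n_changed"]]
  })
  list(
    H_rate = rate_of_change(
      apply_anchor_policy(data.frame(t$transit_times_h, H - H[1]),
                          include_anchor),
      through_origin = through_origin),
    banding_rate = rate_of_change(
      apply_anchor_policy(data.frame(t$transit_times_h, changed),
                          include_anchor),
      through_origin = through_origin)
  )
}

# Standardize one category matrix through the normalize -> standardize ->
# distance chain, dropping constant columns (they carry no dissimilarity
# information) with a message.
category_dissimilarity <- function(cm, transform_map = list()) {
  if (cm_stage(cm) == "raw" && length(transform_map)) {
    cm <- normalize_columns(cm, transform_map)
  }
  x <- unclass(cm)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    message("dropping ", sum(sds == 0), " constant column(s) from category ",
            cm_category(cm))
    x <- x[, sds > 0, drop = FALSE]
    cm <- category_matrix(x, cm_category(cm), stage = cm_stage(cm))
  }
  if (cm_stage(cm) != "standardized") cm <- standardize_columns(cm)
  euclidean_distance_matrix(cm)
}

#' Build the full rate table
#'
#' For every transition and sampling date, computes the rate of change of
#' each category: RES, SCC, PS and BCM (and the band-derived BCC) through
#' the standardize-then-Euclidean dissimilarity chain and
#' [head_dissimilarity_series()]; BA through [abundance_rate()]; plus the
#' descriptive H' and banding-pattern rates.  Standardization pools all
#' site-dates into one global z-space so rates are comparable across
#' transitions.
#'
#' @param categories Named list of raw [category_matrix()] objects; must
#'   contain `RES`, `SCC`, `PS`, `BCM` and `BA` (BA with a single column).
#' @param bands Band-intensity matrix covering all site-dates (used for the
#'   BCC rate and the descriptive diversity/banding rates).
#' @param transitions List of [transition_series()].
#' @param single_resource Optional variable name within the RES category
#'   (e.g. `"DOC"`): adds a rate column of that name computed from the
#'   one-variable dissimilarity of that resource alone.
#' @param transform_maps Optional named list (by category) of
#'   `transform_map`s for [normalize_columns()].
#' @param through_origin Force rate regressions through the origin.
#' @param presence_threshold Passed to [band_turnover()].
#' @inheritParams abundance_rate
#' @return Object of class `rate_table`: a data frame with one row per
#'   transition-date, columns `transition`, `date`, the six rate variables,
#'   `H_prime`, `banding` and any single-resource column, plus a
#'   `provenance` attribute (data frame of per-slope `n` and `r_squared`).
#' @export
build_rate_table <- function(categories, bands, transitions,
                             single_resource = NULL, transform_maps = list(),
                             through_origin = FALSE, presence_threshold = 0,
                             include_anchor = "auto") {
  needed <- c("RES", "SCC", "PS", "BCM", "BA")
  missing <- setdiff(needed, names(categories))
  if (length(missing)) {
    stop("categories list lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  # global dissimilarity matrices (one z-space pooled over all site-dates)
  diss <- list()
  for (cat in c("RES", "SCC", "PS", "BCM")) {
    diss[[cat]] <- category_dissimilarity(categories[[cat]],
                                          transform_maps[[cat]] %||% list())
  }
  # BCC: relative band intensities, standardized like any other matrix
  rel <- t(apply(bands, 1, relative_intensities))
  dimnames(rel) <- dimnames(bands)
  diss[["BCC"]] <- category_dissimilarity(
    category_matrix(rel, "BCC", stage = "raw"), list())

  if (!is.null(single_resource)) {
    res_raw <- unclass(categories[["RES"]])
    if (!single_resource %in% colnames(res_raw)) {
      stop("RES category has no variable '", single_resource, "'",
           call. = FALSE)
    }
    res_map <- transform_maps[["RES"]] %||% list()
    res_map <- res_map[intersect(names(res_map), single_resource)]
    diss[[single_resource]] <- category_dissimilarity(
      category_matrix(res_raw[, single_resource, drop = FALSE], "RES",
                      stage = "raw"),
      res_map)
  }

  ba <- unclass(categories[["BA"]])
  if (ncol(ba) != 1L) stop("BA category must have exactly one column",
                           call. = FALSE)

  rate_cols <- c(rate_variables(), "H_prime", "banding", single_resource)
  rows <- vector("list", length(transitions))
  prov <- vector("list", length(transitions))
  for (i in seq_along(transitions)) {
    t <- transitions[[i]]
    all_ids <- t$site_ids
    absent <- setdiff(all_ids, rownames(ba))
    if (length(absent)) {
      stop("site(s) missing from BA table: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    vals <- stats::setNames(numeric(length(rate_cols)), rate_cols)
    pr <- list()
    for (cat in c("RES", "BCC", "SCC", "PS", "BCM", single_resource)) {
      series <- apply_anchor_policy(head_dissimilarity_series(diss[[cat]], t),
                                    include_anchor)
      r <- rate_of_change(series, through_origin = through_origin)
      vals[[cat]] <- r$slope
      pr[[cat]] <- c(n = r$n, r_squared = r$r_squared)
    }
    r_ba <- abundance_rate(ba[all_ids, 1], t, through_origin = through_origin,
                           include_anchor = include_anchor)
    vals[["BA"]] <- r_ba$slope
    pr[["BA"]] <- c(n = r_ba$n, r_squared = r_ba$r_squared)
    db <- diversity_and_banding_rates(bands, t,
                                      presence_threshold = presence_threshold,
                                      through_origin = through_origin,
                                      include_anchor = include_anchor)
    vals[["H_prime"]] <- db$H_rate$slope
    vals[["banding"]] <- db$banding_rate$slope
    pr[["H_prime"]] <- c(n = db$H_rate$n, r_squared = db$H_rate$r_squared)
    pr[["banding"]] <- c(n = db$banding_rate$n,
                         r_squared = db$banding_rate$r_squared)
    rows[[i]] <- data.frame(transition = t$transition_id, date = t$date,
                            as.list(vals), check.names = FALSE,
                            stringsAsFactors = FALSE)
    pr_df <- do.call(rbind, pr)
    prov[[i]] <- data.frame(transition = t$transition_id, date = t$date,
                            column = rownames(pr_df), pr_df, row.names = NULL,
                            stringsAsFactors = FALSE)
  }
  rt <- do.call(rbind, rows)
  rownames(rt) <- NULL
  structure(rt, provenance = do.call(rbind, prov),
            class = c("rate_table", "data.frame"))
}

#' Cross-rate regression (distance-decay style)
#'
#' OLS regression of one rate column on another, optionally after log10
#' transformation of both (the presentation used for the cross-rate
#' scatterplots).  Under log10, rows where either rate is non-positive are
#' excluded and counted.
#'
#' @param rt Rate table.
#' @param x,y Column names (predictor, response).
#' @param log10 Log10-transform both columns (default `TRUE`).
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n_used`,
#'   `n_excluded`.
#' @export
rate_regression <- function(rt, x, y, log10 = TRUE) {
  rt <- as.data.frame(rt)
  if (!all(c(x, y) %in% names(rt))) {
    stop("rate table lacks column(s): ",
         paste(setdiff(c(x, y), names(rt)), collapse = ", "), call. = FALSE)
  }
  xv <- rt[[x]]; yv <- rt[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  n_excluded <- 0L
  if (log10) {
    pos <- ok & xv > 0 & yv > 0
    n_excluded <- sum(ok) - sum(pos)
    xv <- log10(xv[pos]); yv <- log10(yv[pos])
  } else {
    xv <- xv[ok]; yv <- yv[ok]
  }
  if (length(xv) < 3L) {
    stop("fewer than 3 usable rows for regression of ", y, " on ", x,
         call. = FALSE)
  }
  fit <- stats::lm(yv ~ xv)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n_used = length(xv), n_excluded = n_excluded)
}
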