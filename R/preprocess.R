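# Feature-level preprocessing ahead of trajectory modeling. Fixed order:
# additive field-strength bias correction -> three-sigma outlier removal ->
# min-max normalization -> orientation flip. Every parameter used is stored
# in a normalization record so the transform is reproducible and invertible
# on retained points.

#' Additive field-strength bias correction
#'
#' Regional features extracted from 3T acquisitions are systematically offset
#' relative to 1.5T. Within each diagnosis group and region, 3T values are
#' shifted by (mean of 1.5T values - mean of 3T values) so that the
#' post-correction per-group means are equal across field strengths; 1.5T
#' values are untouched. A group observed at a single field strength is left
#' unchanged (with a message).
#'
#' @param visits visit table with `group`, `field_strength` and region
#'   columns.
#' @param regions character vector of region column names; defaults to every
#'   column starting with none of the metadata names.
#' @return A list with `visits` (corrected table) and `shifts` (data.frame
#'   `group`, `region`, `shift` applied to 3T rows).
#' @export
additive_bias_correction <- function(visits, regions = region_columns(visits)) {
  if (!"field_strength" %in% names(visits))
    stop("visit table has no 'field_strength' column", call. = FALSE)
  if (!"group" %in% names(visits))
    stop("visit table has no 'group' column", call. = FALSE)
  if (!all(visits$field_strength %in% c(1.5, 3.0)))
    stop("field_strength values must be 1.5 or 3.0", call. = FALSE)
  shifts <- expand.grid(group = unique(visits$group), region = regions,
                        stringsAsFactors = FALSE)
  shifts$shift <- 0
  for (g in unique(visits$group)) {
    in_g <- visits$group == g
    is3 <- in_g & visits$field_strength == 3.0
    is15 <- in_g & visits$field_strength == 1.5
    if (!any(is3) || !any(is15)) {
      message("group '", g, "' observed at a single field strength; ",
              "no correction applied")
      next
    }
    for (r in regions) {
      d <- mean(visits[[r]][is15]) - mean(visits[[r]][is3])
      visits[[r]][is3] <- visits[[r]][is3] + d
      shifts$shift[shifts$group == g & shifts$region == r] <- d
    }
  }
  list(visits = visits, shifts = shifts)
}

region_columns <- function(visits) {
  meta <- c("subject_id", "age_years", "group", "field_strength",
            "is_duplicate")
  setdiff(names(visits), meta)
}

#' Three-sigma outlier rule
#'
#' Flags observations further than three standard deviations from the mean,
#' both computed once on all values of that region within the cohort (plain
#' mean and sd, single pass, no iteration). With zero spread nothing is
#' removed.
#'
#' @param x numeric vector of one region's values within one cohort.
#' @return A list with `keep` (logical vector) and `removed` (integer
#'   indices of discarded observations).
#' @export
three_sigma_filter <- function(x) {
  if (sum(!is.na(x)) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    message("zero spread: no outliers removed")
    return(list(keep = !is.na(x), removed = integer(0)))
  }
  keep <- !is.na(x) & abs(x - m) <= 3 * s
  list(keep = keep, removed = which(!keep & !is.na(x)))
}

#' Min-max normalization with optional orientation flip
#'
#' Scales to [0, 1] by the observed (post-outlier-removal) minimum and
#' maximum; if the feature decreases over time (cortical thickness, regional
#' volumes), applies the rotation `x -> 1 - x` so the normalized feature is
#' increasing, as logistic modeling requires.
#'
#' @param x numeric vector of retained values.
#' @param decreasing logical: flip after scaling.
#' @param lo,hi optional externally supplied min/max (for applying a stored
#'   record); default to `min(x)`/`max(x)`.
#' @param region region name used in error messages.
#' @return Numeric vector in [0, 1] (for values inside `[lo, hi]`).
#' @export
minmax_flip <- function(x, decreasing = FALSE, lo = min(x), hi = max(x),
                        region = "feature") {
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("degenerate range for region '", region,
         "': max must exceed min", call. = FALSE)
  y <- (x - lo) / (hi - lo)
  if (decreasing) y <- 1 - y
  y
}

# Pooled within-subject slope of value on age (each subject centred), used
# to decide per region whether the feature decreases over time.
pooled_slope <- function(value, age, subject) {
  ca <- age - stats::ave(age, subject)
  cv <- value - stats::ave(value, subject)
  den <- sum(ca^2)
  if (den == 0) return(0)
  sum(ca * cv) / den
}

#' Preprocess a visit table for trajectory modeling
#'
#' Runs the fixed pipeline: additive field-strength bias correction, then a
#' single-pass three-sigma outlier removal per region, then min-max
#' normalization on the retained values, then an orientation flip for
#' regions whose pooled within-subject slope is negative. Rows in which a
#' region was flagged as an outlier get `NA` for that region (the row is
#' kept for the other regions).
#'
#' @param visits visit table in the cohort dialect.
#' @param regions region column names.
#' @param bias_correction,normalize,flip stage toggles; `flip = NA` (the
#'   default) decides per region from the data, `TRUE`/`FALSE` forces it.
#' @param record an existing normalization record to re-apply (makes the
#'   transform idempotent/reproducible on new data).
#' @return A list with `visits` (processed table) and `record` (class
#'   `normalization_record`: per-region min/max, flip flags, removed row
#'   indices, bias shifts).
#' @export
preprocess_visits <- function(visits, regions = region_columns(visits),
                              bias_correction = TRUE, normalize = TRUE,
                              flip = NA, record = NULL) {
  stopifnot(length(regions) > 0)
  if (!is.null(record)) {
    # re-apply a stored transform
    for (g in unique(visits$group)) for (r in regions) {
      s <- record$shifts$shift[record$shifts$group == g &
                                 record$shifts$region == r]
      if (length(s) == 1 && s != 0) {
        is3 <- visits$group == g & visits$field_strength == 3.0
        visits[[r]][is3] <- visits[[r]][is3] + s
      }
    }
    for (r in regions) {
      if (!isTRUE(record$normalized[[r]])) next
      visits[[r]] <- minmax_flip(visits[[r]], record$flipped[[r]],
                                 record$min[[r]], record$max[[r]], region = r)
    }
    return(list(visits = visits, record = record))
  }

  shifts <- data.frame(group = character(0), region = character(0),
                       shift = numeric(0))
  if (bias_correction) {
    bc <- additive_bias_correction(visits, regions)
    visits <- bc$visits
    shifts <- bc$shifts
  }
  rec <- list(shifts = shifts, min = list(), max = list(), flipped = list(),
              normalized = list(), removed = list())
  for (r in regions) {
    f <- three_sigma_filter(visits[[r]])
    rec$removed[[r]] <- f$removed
    visits[[r]][!f$keep] <- NA
    x <- visits[[r]]
    ok <- !is.na(x)
    dec <- if (is.na(flip)) {
      pooled_slope(x[ok], visits$age_years[ok], visits$subject_id[ok]) < 0
    } else flip
    rec$flipped[[r]] <- dec
    rec$normalized[[r]] <- normalize
    if (normalize) {
      rec$min[[r]] <- min(x, na.rm = TRUE)
      rec$max[[r]] <- max(x, na.rm = TRUE)
      visits[[r]][ok] <- minmax_flip(x[ok], dec, rec$min[[r]], rec$max[[r]],
                                     region = r)
    } else if (dec) {
      rec$min[[r]] <- NA_real_
      rec$max[[r]] <- NA_real_
      visits[[r]][ok] <- 1 - x[ok]
    }
  }
  class(rec) <- "normalization_record"
  list(visits = visits, record = rec)
}

#' Invert a stored normalization on one region
#'
#' @param y normalized values.
#' @param record a `normalization_record`.
#' @param region region name.
#' @return Values on the original (bias-corrected) scale.
#' @export
invert_normalization <- function(y, record, region) {
  if (!isTRUE(record$normalized[[region]]))
    stop("region '", region, "' was not normalized", call. = FALSE)
  if (record$flipped[[region]]) y <- 1 - y
  y * (record$max[[region]] - record$min[[region]]) + record$min[[region]]
}

#' @export
write_normalization_record <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
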