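#' Validate a long-format intake table
#'
#' An intake table records, per subject, recall day and food group, the
#' consumed mass in grams/day. Combinations absent from the table are
#' treated as nil consumption (amount 0), which is the natural encoding
#' for episodically consumed groups.
#'
#' @param intake data.frame with columns `subject_id`, `day` (1 or 2),
#'   `food_group`, `amount` (grams/day, non-negative).
#' @param require_both_days if `TRUE`, every subject must appear on both
#'   recall days (complete-case contract).
#' @return The intake table with the full subject x day x food-group grid
#'   completed (implicit zeros made explicit), columns in canonical order.
#' @export
validate_intake <- function(intake, require_both_days = TRUE) {
  needed <- c("subject_id", "day", "food_group", "amount")
  miss <- setdiff(needed, names(intake))
  if (length(miss)) {
    stop("intake table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(intake) == 0L) stop("intake table is empty")
  if (!all(intake$day %in% c(1L, 2L))) {
    stop("day must be 1 or 2")
  }
  if (any(is.na(intake$amount)) || any(intake$amount < 0)) {
    stop("amounts must be non-negative and non-missing")
  }
  key <- paste(intake$subject_id, intake$day, intake$food_group, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, day, food_group) records present")
  }
  subjects <- unique(intake$subject_id)
  if (require_both_days) {
    d1 <- unique(intake$subject_id[intake$day == 1L])
    d2 <- unique(intake$subject_id[intake$day == 2L])
    bad <- c(setdiff(subjects, d1), setdiff(subjects, d2))
    if (length(bad)) {
      stop("subject(s) missing a recall day: ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "")
    }
  }
  groups <- unique(intake$food_group)
  days <- sort(unique(intake$day))
  grid <- expand.grid(subject_id = subjects, day = days,
                      food_group = groups, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  gkey <- paste(grid$subject_id, grid$day, grid$food_group, sep = "\r")
  grid$amount <- intake$amount[match(gkey, key)]
  grid$amount[is.na(grid$amount)] <- 0
  grid[order(grid$subject_id, grid$day, grid$food_group), , drop = FALSE]
}

#' Exclude food groups with near-universal nil consumption
#'
#' Food groups whose fraction of person-days with zero intake reaches the
#' threshold carry almost no information about habitual consumption and
#' are removed before pattern modelling. The boundary counts as rare:
#' a group nil on exactly 95% of person-days is excluded at the default
#' threshold.
#'
#' @param intake validated intake table (see [validate_intake()]).
#' @param nil_threshold proportion in (0, 1]; groups with nil fraction
#'   `>= nil_threshold` are excluded. Default 0.95.
#' @return list with `intake` (retained groups only) and `exclusions`, a
#'   data.frame of every food group with its nil fraction and whether it
#'   was excluded.
#' @export
filter_rare_food_groups <- function(intake, nil_threshold = 0.95) {
  stopifnot(nil_threshold > 0, nil_threshold <= 1)
  intake <- validate_intake(intake)
  nilfrac <- tapply(intake$amount == 0, intake$food_group, mean)
  report <- data.frame(food_group = names(nilfrac),
                       nil_fraction = as.numeric(nilfrac),
                       excluded = as.numeric(nilfrac) >= nil_threshold,
                       stringsAsFactors = FALSE)
  row.names(report) <- NULL
  keep <- report$food_group[!report$excluded]
  if (length(keep) == 0L) {
    stop("all food groups excluded at nil threshold ", nil_threshold,
         "; nothing left to model")
  }
  list(intake = intake[intake$food_group %in% keep, , drop = FALSE],
       exclusions = report)
}

#' Average the two recall days per subject
#'
#' Collapses the two recall days into a single pseudo-day holding the
#' arithmetic mean intake per food group. This is the input to the
#' latent class branch of the analysis (the latent transition branch
#' keeps both days).
#'
#' @param intake validated intake table with both days per subject.
#' @return intake table with a single day (day = 1) of per-subject means.
#' @export
average_days <- function(intake) {
  intake <- validate_intake(intake, require_both_days = TRUE)
  agg <- stats::aggregate(amount ~ subject_id + food_group, data = intake,
                          FUN = mean)
  out <- data.frame(subject_id = agg$subject_id, day = 1L,
                    food_group = agg$food_group, amount = agg$amount,
                    stringsAsFactors = FALSE)
  out[order(out$subject_id, out$food_group), , drop = FALSE]
}

#' Code intakes into three ordinal categories
#'
#' Each food group is coded 0 (nil), 1 (positive but at or below the
#' consumer median) or 2 (above the consumer median). The median is
#' computed per group over all records with positive amount, pooling the
#' recall days so that day-1 and day-2 indicators share one cutoff (a
#' requirement for measurement invariance across days). Ties at the
#' median code as category 1.
#'
#' @param intake validated intake table, rare groups already excluded.
#' @param median_map optional named numeric vector of per-group medians
#'   (grams/day) to reuse on new data; if `NULL`, medians are computed
#'   from `intake`.
#' @return list with `ordinal` (data.frame `subject_id`, `day`, `item`,
#'   `category`) and `median_map`.
#' @export
categorize_intake <- function(intake, median_map = NULL) {
  intake <- validate_intake(intake, require_both_days = FALSE)
  groups <- sort(unique(intake$food_group))
  if (is.null(median_map)) {
    median_map <- vapply(groups, function(g) {
      a <- intake$amount[intake$food_group == g & intake$amount > 0]
      if (length(a) == 0L) {
        stop("food group '", g, "' has no positive amounts; ",
             "it should have been excluded as rare")
      }
      stats::median(a)
    }, numeric(1))
  } else {
    miss <- setdiff(groups, names(median_map))
    if (length(miss)) {
      stop("median_map lacks entries for: ", paste(miss, collapse = ", "))
    }
  }
  med <- median_map[intake$food_group]
  category <- ifelse(intake$amount == 0, 0L,
                     ifelse(intake$amount <= med, 1L, 2L))
  ordinal <- data.frame(subject_id = intake$subject_id, day = intake$day,
                        item = intake$food_group, category = category,
                        stringsAsFactors = FALSE)
  list(ordinal = ordinal, median_map = median_map)
}

#' Intra-class correlation of intake across the two recall days
#'
#' One-way random-effects ANOVA ICC per food group with two measurements
#' per subject: `(MSB - MSW) / (MSB + MSW)`, floored at 0. Low values
#' indicate high day-to-day (within-person) variability relative to
#' between-person differences.
#'
#' @param intake validated intake table with both days per subject.
#' @return data.frame `food_group`, `icc` (NA with a warning for groups
#'   with zero total variance).
#' @export
compute_icc <- function(intake) {
  intake <- validate_intake(intake, require_both_days = TRUE)
  groups <- sort(unique(intake$food_group))
  icc <- vapply(groups, function(g) {
    sub <- intake[intake$food_group == g, ]
    wide <- stats::reshape(sub[, c("subject_id", "day", "amount")],
                           idvar = "subject_id", timevar = "day",
                           direction = "wide")
    x1 <- wide$amount.1
    x2 <- wide$amount.2
    n <- length(x1)
    grand <- mean(c(x1, x2))
    m <- (x1 + x2) / 2
    ssb <- 2 * sum((m - grand)^2)
    ssw <- sum((x1 - m)^2 + (x2 - m)^2)
    if (ssb + ssw == 0) return(NA_real_)
    msb <- ssb / (n - 1)
    msw <- ssw / n
    max(0, (msb - msw) / (msb + msw))
  }, numeric(1))
  if (anyNA(icc)) {
    warning("ICC undefined (zero total variance) for: ",
            paste(groups[is.na(icc)], collapse = ", "))
  }
  data.frame(food_group = groups, icc = as.numeric(icc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Validate a covariate table
#'
#' @param covariates data.frame with `subject_id`, `age` (years), `sex`
#'   (0/1; the reference category is 0 throughout).
#' @param age_bounds permitted age range, default 18-84 years.
#' @return the covariate table, one row per subject.
#' @export
validate_covariates <- function(covariates, age_bounds = c(18, 84)) {
  needed <- c("subject_id", "age", "sex")
  miss <- setdiff(needed, names(covariates))
  if (length(miss)) {
    stop("covariate table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(covariates$subject_id)) {
    stop("covariate table has duplicated subjects")
  }
  if (any(covariates$age < age_bounds[1] | covariates$age > age_bounds[2])) {
    stop("age outside configured bounds [", age_bounds[1], ", ",
         age_bounds[2], "]")
  }
  if (!all(covariates$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  covariates
}
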