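#' The 16 food-frequency-questionnaire items
#'
#' Column-name stems used throughout the package. Rating columns are named
#' `ffq_<item>` (integers 1-7), recoded weekly-frequency columns
#' `weekly_<item>` (0-14 times/week).
#'
#' @return Character vector of 16 item names.
#' @export
ffqItems <- function() {
  c(
    "dark_bread", "sweet_pastry", "biscuits_cookies", "ice_cream",
    "sugary_juice_drink", "sugary_soft_drink", "sweets_chocolate", "pizza",
    "hamburger_hotdog", "milk_sourmilk", "cooked_vegetables",
    "fresh_vegetables", "fruit_berries", "juice", "salty_snacks", "water"
  )
}

#' Default rating-to-weekly-frequency mapping
#'
#' Maps the 7-point rating scale (1 = not at all ... 7 = several times a day)
#' to weekly consumption frequencies on the 0-14 times/week scale. The
#' endpoints (1 -> 0, 7 -> 14) are fixed by the scale definition; interior
#' values are a documented, overridable convention.
#'
#' @return Numeric vector of length 7, named "1".."7".
#' @export
defaultFfqMapping <- function() {
  setNames(c(0, 0.5, 1, 2.5, 5.5, 7, 14), as.character(1:7))
}

.checkMapping <- function(mapping) {
  if (length(mapping) != 7 || any(!is.finite(mapping))) {
    stop("mapping must give a finite frequency for each rating 1..7", call. = FALSE)
  }
  if (is.null(names(mapping))) names(mapping) <- as.character(1:7)
  mapping <- mapping[as.character(1:7)]
  if (any(is.na(mapping))) {
    stop("mapping must be named by ratings 1..7", call. = FALSE)
  }
  if (any(diff(mapping) < 0)) {
    stop("mapping must be monotone non-decreasing in the rating", call. = FALSE)
  }
  if (mapping[1] != 0 || mapping[7] != 14) {
    stop("mapping must anchor rating 1 at 0 and rating 7 at 14 times/week", call. = FALSE)
  }
  mapping
}

#' Recode FFQ ratings to weekly consumption frequencies
#'
#' Element-wise lookup of the 1-7 ratings into times/week; missing ratings
#' stay missing. Accepts a data.frame of `ffq_<item>` columns (or any integer
#' rating columns) or a bare vector/matrix.
#'
#' @param ratings data.frame, matrix or vector of integer ratings in 1..7
#'   (NA allowed).
#' @param mapping named numeric vector, ratings "1".."7" to times/week;
#'   must be monotone with `mapping[1]` = 0 and `mapping[7]` = 14.
#' @return Object of the same shape with frequencies in \[0, 14\]; data.frame
#'   column names have any `ffq_` prefix replaced by `weekly_`.
#' @examples
#' recodeFfq(c(1, 4, 7, NA)) # 0 2.5 14 NA
#' @export
recodeFfq <- function(ratings, mapping = defaultFfqMapping()) {
  mapping <- .checkMapping(mapping)
  recode1 <- function(x) {
    bad <- !is.na(x) & !(x %in% 1:7)
    if (any(bad)) {
      stop("ratings must be integers in 1..7 or NA", call. = FALSE)
    }
    unname(mapping[as.character(x)])
  }
  if (is.data.frame(ratings)) {
    out <- as.data.frame(lapply(ratings, recode1))
    names(out) <- sub("^ffq_", "weekly_", names(ratings))
    rownames(out) <- rownames(ratings)
    out
  } else if (is.matrix(ratings)) {
    out <- matrix(recode1(as.vector(ratings)),
      nrow = nrow(ratings),
      dimnames = dimnames(ratings)
    )
    colnames(out) <- sub("^ffq_", "weekly_", colnames(out))
    out
  } else {
    recode1(ratings)
  }
}

.sumIndex <- function(weekly, items, index_name) {
  if (!is.data.frame(weekly)) stop("weekly must be a data.frame", call. = FALSE)
  # accept either weekly_<item> or bare <item> column names
  cols <- ifelse(paste0("weekly_", items) %in% names(weekly),
    paste0("weekly_", items), items
  )
  unknown <- items[!cols %in% names(weekly)]
  if (length(unknown)) {
    stop(
      index_name, ": unknown item(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  m <- as.matrix(weekly[, cols, drop = FALSE])
  # any missing component makes the index missing
  rowSums(m)
}

#' Plant consumption index (PCI)
#'
#' Weekly consumption frequency summed over the plant items (cooked
#' vegetables, fresh and grated vegetables, fruit and berries). Missing any
#' component makes the index missing.
#'
#' @param weekly data.frame with `weekly_<item>` (or bare item) columns.
#' @param items character, the component items.
#' @return Numeric vector, times/week.
#' @export
plantConsumptionIndex <- function(weekly,
                                  items = c(
                                    "cooked_vegetables",
                                    "fresh_vegetables",
                                    "fruit_berries"
                                  )) {
  .sumIndex(weekly, items, "plant consumption index")
}

#' Sweet treat index (STI)
#'
#' Weekly consumption frequency summed over the six sugary items (sweet
#' pastry, biscuits and cookies, ice cream, sugary juice drink, sugary soft
#' drink, sweets and chocolate). Missing any component makes the index missing.
#'
#' @inheritParams plantConsumptionIndex
#' @return Numeric vector, times/week.
#' @export
sweetTreatIndex <- function(weekly,
                            items = c(
                              "sweet_pastry", "biscuits_cookies", "ice_cream",
                              "sugary_juice_drink", "sugary_soft_drink",
                              "sweets_chocolate"
                            )) {
  .sumIndex(weekly, items, "sweet treat index")
}

#' Default per-item FFQ weekly means
#'
#' Target mean weekly consumption frequencies the synthetic cohort generator
#' is calibrated to (times/week); values chosen to resemble a Finnish
#' school-aged cohort (milk ~10.5/week, pizza ~0.55/week, ...).
#'
#' @return Named numeric vector over [ffqItems()].
#' @export
defaultFfqWeeklyMeans <- function() {
  setNames(
    c(
      4.8, 1.15, 1.8, 2.0, 2.25, 1.4, 1.4, 0.55,
      0.6, 10.5, 1.7, 5.65, 4.55, 3.5, 1.0, 9.8
    ),
    ffqItems()
  )
}

#' Rating probabilities matching a target weekly mean
#'
#' For each item, rating probabilities over 1..7 are taken from the
#' exponential family p_k proportional to exp(theta * w_k), where w is the
#' rating-to-weekly mapping, with theta solved so the implied mean weekly
#' frequency equals the target. This gives a smooth, deterministic
#' distribution family fully determined by the target means.
#'
#' @param means named numeric vector of target weekly means (0 < mean < 14).
#' @param mapping as in [recodeFfq()].
#' @return Matrix items x 7 of rating probabilities (rows sum to 1).
#' @export
ffqRatingProbabilities <- function(means = defaultFfqWeeklyMeans(),
                                   mapping = defaultFfqMapping()) {
  mapping <- .checkMapping(mapping)
  w <- unname(mapping)
  if (any(means <= 0 | means >= 14)) {
    stop("target weekly means must lie strictly inside (0, 14)", call. = FALSE)
  }
  tilt_mean <- function(theta) {
    p <- exp(theta * w - max(theta * w))
    p <- p / sum(p)
    sum(p * w)
  }
  probs <- t(vapply(means, function(m) {
    theta <- uniroot(function(t) tilt_mean(t) - m,
      interval = c(-10, 10), tol = 1e-10
    )$root
    p <- exp(theta * w - max(theta * w))
    p / sum(p)
  }, numeric(7)))
  dimnames(probs) <- list(names(means), as.character(1:7))
  probs
}
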