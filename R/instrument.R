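#' The Q-Genie item set
#'
#' The instrument contains 11 items, each rated on a 7-point Likert scale
#' anchored by "poor" (1) and "excellent" (7). Item 3 asks the rater to
#' assess the description of comparison groups and is therefore only
#' applicable to studies with a control group; for studies without one
#' (e.g. quantitative-trait studies) it is dropped from the total score.
#'
#' @return A data frame with one row per item and columns `item_id`,
#'   `stem`, `theme`, and `requires_control_group` (TRUE only for item 3).
#' @examples
#' items <- qgenie_items()
#' nrow(items)                                # 11
#' items$item_id[items$requires_control_group] # 3
#' @export
qgenie_items <- function() {
  stems <- c(
    "Please rate the study on the adequacy of the presented hypothesis and rationale.",
    "Please rate the study on the classification of the outcome (e.g. disease status or quantitative trait).",
    "Please rate the study on the description of comparison groups (e.g. cases and controls).",
    "Please rate the study on the technical classification of the exposure (i.e. the genetic variant).",
    "Please rate the study on the non-technical classification of the exposure (i.e. the genetic variant).",
    "Please rate the study on the disclosure and discussion of sources of bias.",
    "Please rate whether the study was adequately powered.",
    "Please rate the study on description of planned analyses.",
    "Please rate the study on the statistical methods.",
    "Please rate the study on the description and test of all assumptions and inferences.",
    "Please rate the study on whether conclusions drawn by the authors were supported by the results and appropriate methods."
  )
  themes <- c(
    "scientific basis for the research question",
    "classification of the outcome",
    "ascertainment of comparison groups",
    "technical classification of the genetic variant",
    "non-technical classification of the genetic variant",
    "sources of bias",
    "appropriateness of sample size",
    "description of planned statistical analyses",
    "statistical methods",
    "testing of assumptions in genetic studies",
    "interpretation of results"
  )
  data.frame(
    item_id = 1:11,
    stem = stems,
    theme = themes,
    requires_control_group = 1:11 == 3L,
    stringsAsFactors = FALSE
  )
}

#' Likert-scale bounds of the instrument
#' @keywords internal
#' @noRd
.likert_range <- c(1L, 7L)

.assert_likert <- function(value, item_id) {
  bad <- !is.finite(value) | value < 1 | value > 7 | value != round(value)
  if (any(bad)) {
    stop(sprintf("invalid rating for item %s: ratings must be integers in 1..7",
                 paste(item_id[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a single study's rating record
#'
#' A `study_rating` holds the responses of one rater to one study: a named
#' set of integer ratings in 1..7 covering all 11 items, together with the
#' study's control-group status. For studies without a control group,
#' item 3 may be omitted; if present it is ignored for scoring (with a
#' warning at scoring time).
#'
#' @param study_id Study identifier (scalar).
#' @param responses Named numeric vector or list mapping item ids (as names
#'   or via `item_id` attribute) to integer ratings in 1..7. Names are
#'   coerced to integers 1..11.
#' @param has_control_group Logical scalar; does the study have a control
#'   group (so that item 3 applies)?
#' @return An object of class `study_rating`.
#' @examples
#' r <- study_rating("s1", setNames(rep(5, 11), 1:11), has_control_group = TRUE)
#' total_score(r)
#' @export
study_rating <- function(study_id, responses, has_control_group = TRUE) {
  stopifnot(length(study_id) == 1L, length(has_control_group) == 1L,
            is.logical(has_control_group), !is.na(has_control_group))
  responses <- unlist(responses)
  ids <- suppressWarnings(as.integer(names(responses)))
  if (length(responses) == 0L || anyNA(ids)) {
    stop("responses must be named by item_id (1..11)", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicated item_id in responses", call. = FALSE)
  if (!all(ids %in% 1:11)) {
    stop(sprintf("unknown item_id: %s",
                 paste(setdiff(ids, 1:11), collapse = ", ")), call. = FALSE)
  }
  required <- if (has_control_group) 1:11 else setdiff(1:11, 3L)
  missing_ids <- setdiff(required, ids)
  if (length(missing_ids) > 0L) {
    stop(sprintf("missing response for item %s (study %s)",
                 paste(missing_ids, collapse = ", "), study_id), call. = FALSE)
  }
  .assert_likert(as.numeric(responses), ids)
  out <- list(study_id = as.character(study_id),
              responses = stats::setNames(as.integer(responses), ids),
              has_control_group = has_control_group)
  class(out) <- "study_rating"
  out
}

#' @export
print.study_rating <- function(x, ...) {
  cat(sprintf("Q-Genie rating for study '%s' (%s control group)\n",
              x$study_id, if (x$has_control_group) "with" else "without"))
  print(x$responses)
  invisible(x)
}

#' Total Q-Genie score for one study
#'
#' Sums the 11 item responses; for studies without a control group item 3
#' is excluded, giving a 10-item total. The achievable range is 11-77 with
#' a control group and 10-70 without.
#'
#' @param rating A [study_rating()] object.
#' @return Integer total score.
#' @examples
#' total_score(study_rating("s", setNames(rep(7, 11), 1:11), TRUE))  # 77
#' @export
total_score <- function(rating) {
  stopifnot(inherits(rating, "study_rating"))
  resp <- rating$responses
  if (!rating$has_control_group && "3" %in% names(resp)) {
    warning(sprintf("study %s has no control group: ignoring item 3 response",
                    rating$study_id), call. = FALSE)
    resp <- resp[names(resp) != "3"]
  }
  sum(resp)
}

#' Cut-point schemes for quality classification
#'
#' A scheme holds the two boundary scores separating low from moderate and
#' moderate from high quality. The published schemes are 35/45 for studies
#' with a control group (11-item total, range 11-77) and 32/40 for studies
#' without one (10-item total, range 10-70); `derive_cutpoints()` can
#' produce alternatives from new rating data.
#'
#' @param variant `"with_control"` or `"without_control"`.
#' @param low_max Highest score still classified as low quality.
#' @param moderate_max Highest score still classified as moderate quality.
#' @return An object of class `cutpoint_scheme`.
#' @examples
#' cutpoint_scheme("with_control")            # default 35/45
#' cutpoint_scheme("without_control")         # default 32/40
#' cutpoint_scheme("with_control", 30, 50)    # custom boundaries
#' @export
cutpoint_scheme <- function(variant = c("with_control", "without_control"),
                            low_max = NULL, moderate_max = NULL) {
  variant <- match.arg(variant)
  defaults <- list(with_control = c(35L, 45L), without_control = c(32L, 40L))
  if (is.null(low_max)) low_max <- defaults[[variant]][1]
  if (is.null(moderate_max)) moderate_max <- defaults[[variant]][2]
  low_max <- as.integer(low_max); moderate_max <- as.integer(moderate_max)
  rng <- score_range(variant)
  if (low_max >= moderate_max) {
    stop("low_max must be strictly below moderate_max", call. = FALSE)
  }
  if (low_max < rng[1] || moderate_max > rng[2]) {
    stop(sprintf("cut-points must lie within the achievable range %d..%d",
                 rng[1], rng[2]), call. = FALSE)
  }
  structure(list(variant = variant, low_max = low_max,
                 moderate_max = moderate_max),
            class = "cutpoint_scheme")
}

#' @export
print.cutpoint_scheme <- function(x, ...) {
  cat(sprintf("Cut-point scheme (%s): low <= %d < moderate <= %d < high\n",
              x$variant, x$low_max, x$moderate_max))
  invisible(x)
}

#' Achievable total-score range for a scoring variant
#'
#' @param variant `"with_control"` (11 items, 11-77) or `"without_control"`
#'   (10 items, 10-70).
#' @return Integer vector `c(min, max)`.
#' @export
score_range <- function(variant = c("with_control", "without_control")) {
  variant <- match.arg(variant)
  if (variant == "with_control") c(11L, 77L) else c(10L, 70L)
}

#' Classify a total score as low, moderate, or high quality
#'
#' Scores at or below `low_max` are low; above `low_max` and at or below
#' `moderate_max` are moderate; above `moderate_max` are high. Under the
#' published with-control scheme, a score of 35 is low and 46 is high.
#'
#' @param score Integer total score(s) within the variant's achievable range.
#' @param scheme A [cutpoint_scheme()].
#' @return Ordered factor with levels `low < moderate < high`.
#' @examples
#' sch <- cutpoint_scheme("with_control")
#' classify(c(35, 36, 45, 46), sch)
#' @export
classify <- function(score, scheme = cutpoint_scheme("with_control")) {
  stopifnot(inherits(scheme, "cutpoint_scheme"))
  rng <- score_range(scheme$variant)
  if (any(!is.finite(score)) || any(score < rng[1] | score > rng[2])) {
    stop(sprintf("score outside achievable range %d..%d for variant '%s'",
                 rng[1], rng[2], scheme$variant), call. = FALSE)
  }
  lab <- ifelse(score <= scheme$low_max, "low",
                ifelse(score <= scheme$moderate_max, "moderate", "high"))
  factor(lab, levels = c("low", "moderate", "high"), ordered = TRUE)
}

#' Score and classify a batch of study ratings
#'
#' Computes each rating's total score and quality class under the scheme
#' matching its control-group status, and attaches a class-distribution
#' summary (count and percent per class).
#'
#' @param ratings A list of [study_rating()] objects. `study_id`s must be
#'   unique: scores from several raters of the same study are classified
#'   per rater by default, so pass one rater's ratings at a time (or
#'   pre-average them into one `study_rating` per study).
#' @param scheme_with,scheme_without [cutpoint_scheme()]s used for studies
#'   with / without a control group.
#' @return A data frame with columns `study_id`, `variant`, `score`,
#'   `quality`; attribute `"summary"` holds the class distribution
#'   (a data frame of `quality`, `n`, `percent`), absent when `ratings`
#'   is empty.
#' @examples
#' rs <- lapply(1:3, function(i)
#'   study_rating(paste0("s", i), setNames(rep(2 + i, 11), 1:11), TRUE))
#' batch_score(rs)
#' @export
batch_score <- function(ratings,
                        scheme_with = cutpoint_scheme("with_control"),
                        scheme_without = cutpoint_scheme("without_control")) {
  if (length(ratings) == 0L) {
    return(data.frame(study_id = character(), variant = character(),
                      score = integer(),
                      quality = factor(character(),
                                       levels = c("low", "moderate", "high"),
                                       ordered = TRUE)))
  }
  stopifnot(all(vapply(ratings, inherits, logical(1), "study_rating")))
  ids <- vapply(ratings, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate study_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  has_cg <- vapply(ratings, `[[`, logical(1), "has_control_group")
  scores <- vapply(ratings, total_score, numeric(1))
  variant <- ifelse(has_cg, "with_control", "without_control")
  quality <- factor(rep("low", length(ids)),
                    levels = c("low", "moderate", "high"), ordered = TRUE)
  if (any(has_cg)) quality[has_cg] <- classify(scores[has_cg], scheme_with)
  if (any(!has_cg)) quality[!has_cg] <- classify(scores[!has_cg], scheme_without)
  out <- data.frame(study_id = ids, variant = variant,
                    score = as.integer(scores), quality = quality,
                    stringsAsFactors = FALSE)
  tab <- table(out$quality)
  attr(out, "summary") <- data.frame(
    quality = factor(names(tab), levels = c("low", "moderate", "high"),
                     ordered = TRUE),
    n = as.integer(tab),
    percent = 100 * as.integer(tab) / nrow(out)
  )
  out
}
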