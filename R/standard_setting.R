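# Borderline-groups regression standard setting: raters answer a single
# global-impression question ("rate overall quality of the study", 1-7);
# its grade bands anchor a regression of instrument total scores on the
# grade, and cut scores are read at the half-grade boundaries.

#' Map a global-impression rating to a quality grade
#'
#' Ratings of 1-2 on the global impression question are graded low (1),
#' 3-4 moderate (2), and 5-7 high (3). The global question is used only to
#' establish cut-points; it is not part of the instrument itself.
#'
#' @param rating Integer rating(s) in 1..7.
#' @return Integer grade(s) 1 (low), 2 (moderate), 3 (high).
#' @examples
#' map_global_to_grade(c(2, 4, 7))  # 1 2 3
#' @export
map_global_to_grade <- function(rating) {
  .assert_likert(rating, seq_along(rating))
  ifelse(rating <= 2, 1L, ifelse(rating <= 4, 2L, 3L))
}

# round-half-up, since published cut scores are integers
.round_half_up <- function(x) floor(x + 0.5)

#' Derive quality cut-points by borderline-groups regression
#'
#' Fits the ordinary least-squares line `score = a + b * grade` with the
#' grade coded 1/2/3 and reads the cut scores as the fitted values at the
#' borderline grades 1.5 and 2.5, rounded half-up to integers. A valid
#' scheme requires a positive slope (total scores must increase with the
#' global grade) and distinct cut-points.
#'
#' @param score Numeric total scores (for the `without_control` variant,
#'   totals recomputed with item 3 excluded).
#' @param grade Integer grades 1/2/3 (from [map_global_to_grade()]), one
#'   per score; at least two distinct grades must be present.
#' @param variant Scoring variant the derived scheme applies to.
#' @return Object of class `borderline_fit`: list with `intercept`,
#'   `slope`, `r_squared`, `cut_low` / `cut_high` (unrounded fitted values
#'   at grades 1.5 / 2.5), `scheme` (a [cutpoint_scheme()] with the
#'   rounded cut-points), and the `(grade, score)` data for plotting.
#' @examples
#' derive_cutpoints(score = c(30, 30, 40, 40, 50, 50),
#'                  grade = c(1, 1, 2, 2, 3, 3))  # cuts 35 and 45
#' @export
derive_cutpoints <- function(score, grade,
                             variant = c("with_control", "without_control")) {
  variant <- match.arg(variant)
  stopifnot(length(score) == length(grade))
  if (length(score) < 3L) stop("need at least 3 (score, grade) pairs",
                               call. = FALSE)
  if (!all(grade %in% 1:3)) stop("grades must be coded 1, 2, 3", call. = FALSE)
  if (length(unique(grade)) < 2L) {
    stop("cannot derive cut-points: all observations carry the same grade",
         call. = FALSE)
  }
  gbar <- mean(grade); sbar <- mean(score)
  sxx <- sum((grade - gbar)^2)
  slope <- sum((grade - gbar) * (score - sbar)) / sxx
  intercept <- sbar - slope * gbar
  if (slope <= 0) {
    stop("invalid scheme: total score does not increase with the global grade",
         call. = FALSE)
  }
  fitted <- intercept + slope * grade
  ss_res <- sum((score - fitted)^2)
  ss_tot <- sum((score - sbar)^2)
  r_squared <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  cut_low <- intercept + slope * 1.5
  cut_high <- intercept + slope * 2.5
  lo <- .round_half_up(cut_low); hi <- .round_half_up(cut_high)
  if (lo >= hi) {
    stop("invalid scheme: rounded cut-points coincide", call. = FALSE)
  }
  rng <- score_range(variant)
  lo <- min(max(lo, rng[1]), rng[2]); hi <- min(max(hi, rng[1]), rng[2])
  out <- list(intercept = intercept, slope = slope, r_squared = r_squared,
              cut_low = cut_low, cut_high = cut_high,
              scheme = cutpoint_scheme(variant, lo, hi),
              data = data.frame(grade = grade, score = score))
  class(out) <- "borderline_fit"
  out
}

#' @export
print.borderline_fit <- function(x, ...) {
  cat(sprintf("Borderline-groups regression: score = %.2f + %.2f * grade (R^2 = %.3f)\n",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("Cut scores at grades 1.5 / 2.5: %.2f / %.2f -> scheme %d/%d\n",
              x$cut_low, x$cut_high, x$scheme$low_max, x$scheme$moderate_max))
  invisible(x)
}

#' Plot-ready table for a borderline-groups fit
#'
#' @param fit A `borderline_fit`.
#' @return List of data frames: `points` (grade, score), `line` (grade grid
#'   and fitted score), `cuts` (the two cut scores).
#' @export
borderline_plot_table <- function(fit) {
  stopifnot(inherits(fit, "borderline_fit"))
  grid <- seq(1, 3, by = 0.1)
  list(points = fit$data,
       line = data.frame(grade = grid,
                         fitted = fit$intercept + fit$slope * grid),
       cuts = data.frame(boundary = c("low/moderate", "moderate/high"),
                         grade = c(1.5, 2.5),
                         cut_score = c(fit$scheme$low_max,
                                       fit$scheme$moderate_max)))
}
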