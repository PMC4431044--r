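# Item discrimination and internal consistency over a studies x items
# matrix of ratings (typically mean-over-rater ratings for one rater group).

.check_item_matrix <- function(m, min_items = 2L, min_studies = 3L) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("rating matrix must be numeric", call. = FALSE)
  if (ncol(m) < min_items) {
    stop(sprintf("need at least %d items", min_items), call. = FALSE)
  }
  if (nrow(m) < min_studies) {
    stop(sprintf("need at least %d studies", min_studies), call. = FALSE)
  }
  if (anyNA(m)) stop("rating matrix contains missing values", call. = FALSE)
  m
}

.resolve_item <- function(m, item_id) {
  nm <- colnames(m)
  j <- if (!is.null(nm) && as.character(item_id) %in% nm) {
    match(as.character(item_id), nm)
  } else {
    as.integer(item_id)
  }
  if (is.na(j) || j < 1L || j > ncol(m)) {
    stop(sprintf("unknown item '%s'", item_id), call. = FALSE)
  }
  j
}

#' Item-total correlation
#'
#' Measures item discrimination: how well an item separates good from bad
#' studies. The corrected (item-rest) form, the default, is the Pearson
#' correlation between the item's ratings and the total of the *remaining*
#' items; the uncorrected form correlates the item with the full total
#' (itself included), which inflates the coefficient.
#'
#' @param m Numeric studies x items matrix (rows = studies; entries are
#'   typically each study's mean rating over a group's raters).
#' @param item_id Column to evaluate: an integer index or a column name.
#' @param corrected Use the item-rest correlation (default TRUE).
#' @return Pearson correlation in \[-1, 1\].
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(2, 3, 4))
#' item_total_correlation(m, "a")  # parallel items: 1
#' @export
item_total_correlation <- function(m, item_id, corrected = TRUE) {
  m <- .check_item_matrix(m)
  j <- .resolve_item(m, item_id)
  item <- m[, j]
  total <- if (corrected) rowSums(m[, -j, drop = FALSE]) else rowSums(m)
  if (stats::var(item) == 0) {
    stop(sprintf("item '%s' has zero variance: item-total correlation undefined",
                 item_id), call. = FALSE)
  }
  if (stats::var(total) == 0) {
    stop(sprintf("%s has zero variance: item-total correlation undefined",
                 if (corrected) "rest-total" else "total"), call. = FALSE)
  }
  stats::cor(item, total)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = k/(k-1) (1 - \sum_j s^2_j / s^2_{total})}
#' where \eqn{s^2_j} are the item variances and \eqn{s^2_{total}} the
#' variance of the total score over studies.
#'
#' @inheritParams item_total_correlation
#' @return Alpha (at most 1; can be negative for incoherent item sets).
#' @examples
#' cronbach_alpha(cbind(c(1, 2, 3), c(2, 3, 4)))  # parallel items: 1
#' @export
cronbach_alpha <- function(m) {
  m <- .check_item_matrix(m)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    stop("total-score variance is zero: alpha undefined", call. = FALSE)
  }
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Cronbach's alpha with one item deleted
#'
#' Alpha recomputed on the matrix with the named item removed; a higher
#' alpha-if-deleted than the full-scale alpha marks an item that weakens
#' internal consistency. Requires at least 3 items (deleting one from a
#' 2-item scale leaves a single item, for which alpha is undefined).
#'
#' @inheritParams item_total_correlation
#' @export
alpha_if_deleted <- function(m, item_id) {
  m <- .check_item_matrix(m, min_items = 3L)
  j <- .resolve_item(m, item_id)
  cronbach_alpha(m[, -j, drop = FALSE])
}

#' Endorsement rate of an item
#'
#' Fraction of ratings of 6 or 7 on the 7-point scale. High endorsement
#' suggests an item on which nearly all studies perform well and which
#' therefore carries little discriminative information.
#'
#' @param ratings Numeric vector of Likert ratings (pooled over studies and
#'   raters for one item).
#' @return Proportion in \[0, 1\].
#' @examples
#' endorsement_rate(c(5, 6, 7, 6))  # 0.75
#' @export
endorsement_rate <- function(ratings) {
  if (length(ratings) == 0L) stop("empty rating set", call. = FALSE)
  .assert_likert(ratings, seq_along(ratings))
  mean(ratings >= 6)
}

#' Per-item discrimination statistics
#'
#' Computes, for every item, the (corrected) item-total correlation, alpha
#' if the item is deleted, the endorsement rate, and a flag marking items
#' outside the informative band: item-total correlations below 0.2
#' (`uninformative_low`) or above 0.9 (`uninformative_high`) mark items
#' that are candidates for exclusion from the instrument.
#'
#' @inheritParams item_total_correlation
#' @param raw_ratings Optional long data frame (`item_id`, `rating`) of the
#'   unaveraged per-rater ratings used for endorsement rates; when NULL,
#'   endorsement is computed from `m` itself (sensible only if `m` holds
#'   integer ratings of a single rater).
#' @param itc_low,itc_high Informative band for the item-total correlation.
#' @return Data frame (`item_id`, `item_total_correlation`,
#'   `alpha_if_deleted`, `endorsement_rate`, `flag`) with the full-scale
#'   alpha as attribute `"alpha"`.
#' @export
item_stats <- function(m, raw_ratings = NULL, corrected = TRUE,
                       itc_low = 0.2, itc_high = 0.9) {
  m <- .check_item_matrix(m, min_items = 3L)
  ids <- colnames(m)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(m)))
  itc <- vapply(seq_len(ncol(m)),
                function(j) item_total_correlation(m, j, corrected = corrected),
                numeric(1))
  aid <- vapply(seq_len(ncol(m)), function(j) alpha_if_deleted(m, j),
                numeric(1))
  endo <- if (is.null(raw_ratings)) {
    vapply(seq_len(ncol(m)), function(j) mean(m[, j] >= 6), numeric(1))
  } else {
    stopifnot(all(c("item_id", "rating") %in% names(raw_ratings)))
    vapply(ids, function(id) {
      endorsement_rate(raw_ratings$rating[as.character(raw_ratings$item_id) == id])
    }, numeric(1))
  }
  flag <- ifelse(itc < itc_low, "uninformative_low",
                 ifelse(itc > itc_high, "uninformative_high", "ok"))
  out <- data.frame(item_id = ids, item_total_correlation = itc,
                    alpha_if_deleted = aid, endorsement_rate = unname(endo),
                    flag = flag, stringsAsFactors = FALSE)
  attr(out, "alpha") <- cronbach_alpha(m)
  out
}

#' Items flagged for exclusion review
#'
#' @param stats A data frame from [item_stats()].
#' @return The subset of rows with `flag != "ok"` (possibly empty).
#' @export
flag_items <- function(stats) {
  stopifnot(is.data.frame(stats), "flag" %in% names(stats))
  stats[stats$flag != "ok", , drop = FALSE]
}
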