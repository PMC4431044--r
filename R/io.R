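# CSV readers/writers for the rating, metadata, global-impression, impact
# and effect tables, plus the end-to-end pipeline that chains scoring,
# item analysis, reliability, standard setting, validity and the
# meta-analysis sensitivity stage.

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a long-format ratings table
#'
#' The long dialect requires the header
#' `study_id,rater_id,item_id,rating`; the wide dialect requires
#' `study_id,rater_id` plus one `item_<id>` column per item and is
#' reshaped to long. Every rating must be an integer in 1-7; malformed
#' rows are reported with their file line numbers.
#'
#' @param path CSV file path.
#' @param format `"long"` (default) or `"wide"`.
#' @return Data frame `study_id, rater_id, item_id, rating`.
#' @export
read_ratings <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  d <- .read_csv(path)
  if (format == "wide") {
    need <- c("study_id", "rater_id")
    if (!all(need %in% names(d))) {
      stop("wide ratings file must have columns study_id, rater_id, item_<id>...",
           call. = FALSE)
    }
    item_cols <- grep("^item_[0-9]+$", names(d), value = TRUE)
    if (length(item_cols) == 0L) {
      stop("wide ratings file has no item_<id> columns", call. = FALSE)
    }
    d <- stats::reshape(d[c(need, item_cols)], direction = "long",
                        varying = item_cols, v.names = "rating",
                        timevar = "item_id",
                        times = as.integer(sub("^item_", "", item_cols)),
                        idvar = need)
    rownames(d) <- NULL
    d <- d[c("study_id", "rater_id", "item_id", "rating")]
  } else {
    need <- c("study_id", "rater_id", "item_id", "rating")
    if (!all(need %in% names(d))) {
      stop("long ratings file must have header study_id,rater_id,item_id,rating",
           call. = FALSE)
    }
    d <- d[need]
  }
  bad <- which(!is.finite(d$rating) | d$rating < 1 | d$rating > 7 |
                 d$rating != round(d$rating))
  if (length(bad) > 0L) {
    stop(sprintf("ratings outside 1..7 at data row(s) %s of %s",
                 paste(utils::head(bad, 5), collapse = ", "), path),
         call. = FALSE)
  }
  d$rating <- as.integer(d$rating)
  d$study_id <- as.character(d$study_id)
  d$rater_id <- as.character(d$rater_id)
  d
}

#' Write a ratings table or array as long-format CSV
#'
#' @param x A long data frame (`study_id, rater_id, item_id, rating`) or a
#'   [rating_array()].
#' @param path Output CSV path.
#' @export
write_ratings <- function(x, path) {
  if (inherits(x, "rating_array") || (is.array(x) && length(dim(x)) == 3L)) {
    x <- ratings_to_long(x)
  }
  stopifnot(all(c("study_id", "rater_id", "item_id", "rating") %in% names(x)))
  utils::write.csv(x[c("study_id", "rater_id", "item_id", "rating")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a rating array to a long table
#' @param arr A [rating_array()] or plain 3-way array.
#' @return Long data frame `study_id, rater_id, item_id, rating`.
#' @export
ratings_to_long <- function(arr) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  dn <- dimnames(arr)
  if (is.null(dn)) {
    dn <- list(sprintf("study_%02d", seq_len(dim(arr)[1])),
               sprintf("rater_%d", seq_len(dim(arr)[2])),
               as.character(seq_len(dim(arr)[3])))
  }
  g <- expand.grid(study_id = dn[[1]], rater_id = dn[[2]], item_id = dn[[3]],
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$rating <- as.vector(arr)
  g$item_id <- as.integer(g$item_id)
  g[order(g$study_id, g$rater_id, g$item_id), , drop = FALSE]
}

#' Assemble a long ratings table into a crossed rating array
#'
#' Checks that the design is fully crossed (every study x rater x item
#' cell present exactly once); missing cells are listed in the error.
#'
#' @param long Data frame `study_id, rater_id, item_id, rating`.
#' @return A [rating_array()] with dimnames from the table.
#' @export
ratings_to_array <- function(long) {
  stopifnot(all(c("study_id", "rater_id", "item_id", "rating") %in% names(long)))
  studies <- sort(unique(long$study_id))
  raters <- sort(unique(long$rater_id))
  items <- sort(unique(as.integer(long$item_id)))
  key <- paste(long$study_id, long$rater_id, long$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (study, rater, item) cells in ratings table",
         call. = FALSE)
  }
  full <- expand.grid(study_id = studies, rater_id = raters, item_id = items,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full_key <- paste(full$study_id, full$rater_id, full$item_id, sep = "\r")
  miss <- !full_key %in% key
  if (any(miss)) {
    ex <- full[miss, , drop = FALSE][seq_len(min(5, sum(miss))), ]
    stop(sprintf("ratings are not fully crossed; %d missing cell(s), e.g. %s",
                 sum(miss),
                 paste(sprintf("(%s, %s, item %s)", ex$study_id, ex$rater_id,
                               ex$item_id), collapse = "; ")),
         call. = FALSE)
  }
  arr <- array(NA_real_, dim = c(length(studies), length(raters), length(items)),
               dimnames = list(studies, raters, as.character(items)))
  arr[cbind(match(long$study_id, studies), match(long$rater_id, raters),
            match(as.integer(long$item_id), items))] <- long$rating
  rating_array(arr)
}

#' Read the study metadata table
#'
#' Expected header: `study_id,has_control_group,year,impact_factor,
#' total_citations,self_citations` (impact columns may be absent when only
#' scoring is needed).
#'
#' @param path CSV file path.
#' @return Data frame with `has_control_group` as logical.
#' @export
read_study_metadata <- function(path) {
  d <- .read_csv(path)
  if (!all(c("study_id", "has_control_group") %in% names(d))) {
    stop("metadata file must have at least study_id and has_control_group",
         call. = FALSE)
  }
  d$study_id <- as.character(d$study_id)
  d$has_control_group <- as.logical(d$has_control_group)
  if (anyNA(d$has_control_group)) {
    stop("has_control_group must be TRUE/FALSE for every study", call. = FALSE)
  }
  if (all(c("total_citations", "self_citations") %in% names(d)) &&
      any(d$self_citations > d$total_citations)) {
    stop("self_citations cannot exceed total_citations", call. = FALSE)
  }
  d
}

#' Score a long ratings table study by study
#'
#' Computes each (study, rater) total under the variant implied by the
#' study's control-group status and classifies it. With
#' `aggregate = "mean"` the per-rater totals are averaged per study
#' before classification instead (per-rater classification is the
#' default).
#'
#' @param long Ratings table from [read_ratings()].
#' @param metadata Data frame from [read_study_metadata()].
#' @param scheme_with,scheme_without Cut-point schemes per variant.
#' @param aggregate `"per_rater"` or `"mean"`.
#' @return Data frame `study_id, rater_id, variant, score, quality`
#'   (rater_id is `"mean"` under aggregation) with the class-distribution
#'   summary as attribute `"summary"`.
#' @export
score_table <- function(long, metadata,
                        scheme_with = cutpoint_scheme("with_control"),
                        scheme_without = cutpoint_scheme("without_control"),
                        aggregate = c("per_rater", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("study_id", "rater_id", "item_id", "rating") %in% names(long)))
  meta_cg <- stats::setNames(metadata$has_control_group, metadata$study_id)
  unknown <- setdiff(unique(long$study_id), names(meta_cg))
  if (length(unknown) > 0L) {
    stop("studies missing from metadata: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  has_cg <- meta_cg[long$study_id]
  keep <- has_cg | long$item_id != 3L
  if (any(!keep)) {
    warning(sprintf("%d item-3 rating(s) on studies without a control group ignored",
                    sum(!keep)), call. = FALSE)
  }
  d <- long[keep, , drop = FALSE]
  # completeness per (study, rater): 11 items with control, 10 without
  cnt <- stats::aggregate(item_id ~ study_id + rater_id, data = d, FUN = length)
  need <- ifelse(meta_cg[cnt$study_id], 11L, 10L)
  short <- cnt$item_id < need
  if (any(short)) {
    ex <- cnt[short, ][1, ]
    stop(sprintf("incomplete ratings: study %s, rater %s has %d of %d items",
                 ex$study_id, ex$rater_id, ex$item_id,
                 ifelse(meta_cg[ex$study_id], 11L, 10L)), call. = FALSE)
  }
  tot <- stats::aggregate(rating ~ study_id + rater_id, data = d, FUN = sum)
  names(tot)[3] <- "score"
  if (aggregate == "mean") {
    tot <- stats::aggregate(score ~ study_id, data = tot, FUN = mean)
    tot$rater_id <- "mean"
  }
  tot$variant <- ifelse(meta_cg[tot$study_id], "with_control",
                        "without_control")
  tot$quality <- factor(NA, levels = c("low", "moderate", "high"),
                        ordered = TRUE)
  wc <- tot$variant == "with_control"
  if (any(wc)) tot$quality[wc] <- classify(tot$score[wc], scheme_with)
  if (any(!wc)) tot$quality[!wc] <- classify(tot$score[!wc], scheme_without)
  out <- tot[c("study_id", "rater_id", "variant", "score", "quality")]
  out <- out[order(out$study_id, out$rater_id), , drop = FALSE]
  rownames(out) <- NULL
  tab <- table(out$quality)
  attr(out, "summary") <- data.frame(
    quality = factor(names(tab), levels = c("low", "moderate", "high"),
                     ordered = TRUE),
    n = as.integer(tab), percent = 100 * as.integer(tab) / nrow(out))
  out
}

#' Read an analysis configuration file (JSON or YAML)
#'
#' @param path Configuration file; `.json` parsed with jsonlite,
#'   `.yml`/`.yaml` with the yaml package (if installed).
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.write_report <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  jsonlite::write_json(x, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
  if (is.data.frame(x)) {
    utils::write.csv(x, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Chains the stages of the instrument's validation workflow in order:
#' scoring and classification, per-group item statistics, G-theory
#' reliability, cut-point derivation from global impressions, construct
#' validity, and the quality-stratified meta-analysis sensitivity stage.
#' Stages whose inputs are absent are skipped; any stage failure aborts
#' with the stage name.
#'
#' @param ratings Long ratings table (data frame) or CSV path.
#' @param metadata Study metadata (data frame or CSV path).
#' @param rater_groups Named character vector or data frame
#'   (`rater_id, group`) mapping raters to user-status groups; `NULL`
#'   treats all raters as one group (reliability and per-group item
#'   statistics are then computed for that single group and the
#'   inter-user coefficient is skipped).
#' @param global Global-impression table (`study_id, rater_id, rating`) or
#'   path; `NULL` skips cut-point derivation.
#' @param impact Impact table or path; `NULL` skips the validity stage.
#' @param effects Meta-analysis effects table (`study_id, log_or, se` or
#'   `study_id, a, b, c, d`, optional `quality`) or path; `NULL` skips the
#'   meta stage. When `quality` is absent it is joined from the scoring
#'   stage (mean-over-rater totals).
#' @param analysis_year Year for citations-per-year (default: current).
#' @param scheme_with,scheme_without Cut-point schemes used for
#'   classification.
#' @param out_dir Directory for JSON/CSV reports (created if needed);
#'   `NULL` returns the bundle without writing.
#' @param quiet Suppress progress messages (stderr).
#' @return Invisible list of class `qgenie_pipeline` with one element per
#'   stage (`scores`, `item_stats`, `reliability`, `cutpoints`,
#'   `validity`, `meta`) plus `log` (parameters and timestamps).
#' @export
run_pipeline <- function(ratings, metadata, rater_groups = NULL,
                         global = NULL, impact = NULL, effects = NULL,
                         analysis_year = as.integer(format(Sys.Date(), "%Y")),
                         scheme_with = cutpoint_scheme("with_control"),
                         scheme_without = cutpoint_scheme("without_control"),
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.character(ratings)) ratings <- read_ratings(ratings)
  if (is.character(metadata)) metadata <- read_study_metadata(metadata)
  if (is.character(global)) global <- .read_csv(global)
  if (is.character(impact)) impact <- .read_csv(impact)
  if (is.character(effects)) effects <- .read_csv(effects)
  if (is.data.frame(rater_groups)) {
    rater_groups <- stats::setNames(as.character(rater_groups$group),
                                    rater_groups$rater_id)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  bundle <- list()

  say("stage: scoring")
  scores <- stage("scoring", score_table(ratings, metadata,
                                         scheme_with, scheme_without))
  bundle$scores <- scores
  say(sprintf("  scheme with control: <=%d / <=%d; without: <=%d / <=%d",
              scheme_with$low_max, scheme_with$moderate_max,
              scheme_without$low_max, scheme_without$moderate_max))
  .write_report(scores, out_dir, "scores")
  .write_report(attr(scores, "summary"), out_dir, "class_distribution")

  say("stage: item statistics")
  arr <- stage("item statistics", ratings_to_array(ratings))
  groups <- if (is.null(rater_groups)) {
    stats::setNames(rep("all", dim(arr)[2]), dimnames(arr)[[2]])
  } else rater_groups[dimnames(arr)[[2]]]
  if (anyNA(groups)) {
    stop("pipeline stage 'item statistics' failed: rater_groups misses raters ",
         paste(dimnames(arr)[[2]][is.na(groups)], collapse = ", "),
         call. = FALSE)
  }
  istats <- stage("item statistics", {
    lapply(split(seq_along(groups), groups), function(idx) {
      sub <- arr[, idx, , drop = FALSE]
      m <- apply(sub, c(1, 3), mean)   # mean over the group's raters
      raw <- ratings[ratings$rater_id %in% dimnames(arr)[[2]][idx], ]
      item_stats(m, raw_ratings = raw)
    })
  })
  bundle$item_stats <- istats
  for (g in names(istats)) .write_report(istats[[g]], out_dir,
                                         paste0("item_stats_", g))

  if (length(unique(groups)) >= 1 && all(table(groups) >= 2)) {
    say("stage: reliability")
    bundle$reliability <- stage("reliability", {
      if (length(unique(groups)) >= 2) reliability_suite(arr, groups)
      else {
        vc <- estimate_variance_components(arr)
        n_r <- dim(arr)[2]; n_i <- dim(arr)[3]
        list(per_group = data.frame(
          group = unique(groups),
          internal_consistency = phi_coefficient(vc, "items",
                                                 n_prime = c(items = n_i),
                                                 n_fixed = c(raters = n_r)),
          inter_rater = phi_coefficient(vc, "raters",
                                        n_prime = c(raters = n_r),
                                        n_fixed = c(items = n_i)),
          overall = phi_coefficient(vc, c("raters", "items"),
                                    n_prime = c(raters = n_r,
                                                items = n_i))),
          inter_user = NA_real_)
      }
    })
    rel <- bundle$reliability
    .write_report(list(per_group = rel$per_group,
                       inter_user = rel$inter_user),
                  out_dir, "reliability")
  }

  if (!is.null(global)) {
    say("stage: cut-points")
    bundle$cutpoints <- stage("cut-points", {
      if (!"grade" %in% names(global)) {
        global$grade <- map_global_to_grade(global$rating)
      }
      per_rater <- scores[scores$rater_id != "mean", ]
      merged <- merge(per_rater, global, by = c("study_id", "rater_id"))
      if (nrow(merged) < 3L) {
        stop("too few matched (score, global impression) pairs")
      }
      lapply(c(with_control = "with_control",
               without_control = "without_control"), function(v) {
        sub <- merged[merged$variant == v, ]
        if (nrow(sub) < 3L || length(unique(sub$grade)) < 2L) return(NULL)
        derive_cutpoints(sub$score, sub$grade, variant = v)
      })
    })
    for (v in names(bundle$cutpoints)) {
      fit <- bundle$cutpoints[[v]]
      if (is.null(fit)) next
      .write_report(list(variant = v, intercept = fit$intercept,
                         slope = fit$slope, r_squared = fit$r_squared,
                         cut_low = fit$cut_low, cut_high = fit$cut_high,
                         scheme = unclass(fit$scheme)),
                    out_dir, paste0("cutpoints_", v))
      .write_report(borderline_plot_table(fit)$line, out_dir,
                    paste0("cutpoints_", v, "_line"))
    }
  }

  if (!is.null(impact)) {
    say("stage: validity")
    mean_scores <- stats::aggregate(
      score ~ study_id, data = scores[c("study_id", "score")], FUN = mean)
    bundle$validity <- stage("validity",
                             validity_table(mean_scores, impact,
                                            analysis_year))
    .write_report(bundle$validity, out_dir, "validity")
  }

  if (!is.null(effects)) {
    say("stage: meta sensitivity")
    bundle$meta <- stage("meta sensitivity", {
      if (!all(c("log_or", "se") %in% names(effects))) {
        if (!all(c("a", "b", "c", "d") %in% names(effects))) {
          stop("effects need either log_or/se or 2x2 counts a,b,c,d")
        }
        est <- Map(effect_from_2x2, effects$a, effects$b, effects$c,
                   effects$d)
        effects$log_or <- vapply(est, `[[`, numeric(1), "log_or")
        effects$se <- vapply(est, `[[`, numeric(1), "se")
      }
      if (!"quality" %in% names(effects)) {
        mean_scores <- score_table(ratings, metadata, scheme_with,
                                   scheme_without, aggregate = "mean")
        effects <- merge(effects,
                         mean_scores[c("study_id", "quality")],
                         by = "study_id")
      }
      sensitivity_by_quality(effects)
    })
    mres <- function(r) list(pooled_or = r$pooled_or, ci_low = r$ci_low,
                             ci_high = r$ci_high, tau2 = r$tau2, k = r$k,
                             heterogeneity = r$heterogeneity)
    .write_report(list(all = mres(bundle$meta$all),
                       excluding_low = mres(bundle$meta$excluding_low),
                       n_excluded = bundle$meta$n_excluded),
                  out_dir, "meta")
    .write_report(bundle$meta$forest, out_dir, "forest_table")
  }

  bundle$log <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("qgenie")),
    scheme_with = unclass(scheme_with),
    scheme_without = unclass(scheme_without),
    analysis_year = analysis_year,
    stages = setdiff(names(bundle), "log")
  )
  .write_report(bundle$log, out_dir, "run_log")
  class(bundle) <- "qgenie_pipeline"
  invisible(bundle)
}
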