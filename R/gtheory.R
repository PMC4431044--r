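# Generalizability theory for the fully crossed study x rater x item
# design (the G-study behind the instrument's reliability analysis) and
# the nested rater-within-group design used for inter-user reliability.
#
# The object of measurement is the study (facet "p"); raters and items are
# random facets. Variance components come from the three-way ANOVA mean
# squares through the expected-mean-square equations for a balanced
# crossed random-effects design; absolute-error dependability
# coefficients (Phi) follow, with any facet optionally held fixed.

#' Construct a fully crossed rating array
#'
#' @param values Numeric 3-way array or vector reshaped to
#'   `c(n_study, n_rater, n_item)`, indexed study x rater x item. No
#'   missing cells are allowed (balanced designs only).
#' @param dimnames Optional dimnames (study, rater, item ids).
#' @return A `rating_array` (a numeric 3-way array subclass).
#' @examples
#' arr <- rating_array(array(4, dim = c(5, 2, 3)))
#' dim(arr)
#' @export
rating_array <- function(values, dimnames = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a 3-way array (study x rater x item)", call. = FALSE)
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)
    stop(sprintf("missing cells (first at study %d, rater %d, item %d); only fully crossed designs are supported",
                 idx[1, 1], idx[1, 2], idx[1, 3]), call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (!is.null(dimnames)) dimnames(values) <- dimnames
  class(values) <- c("rating_array", class(values))
  values
}

.check_rating_array <- function(arr, min_dim = 2L) {
  if (!is.array(arr) || length(dim(arr)) != 3L) {
    stop("expected a 3-way rating array", call. = FALSE)
  }
  if (anyNA(arr)) stop("rating array has missing cells", call. = FALSE)
  if (any(dim(arr) < min_dim)) {
    stop(sprintf("each dimension needs at least %d levels (got %s)",
                 min_dim, paste(dim(arr), collapse = " x ")), call. = FALSE)
  }
  invisible(arr)
}

#' Estimate variance components of the crossed study x rater x item design
#'
#' Decomposes the rating variance into the seven components of the fully
#' crossed two-facet random design: study (`p`, the universe-score
#' variance), rater (`r`), item (`i`), their pairwise interactions and the
#' confounded three-way interaction plus error (`pri_e`). Mean squares
#' from the three-way ANOVA are converted by the expected-mean-square
#' equations, e.g. \eqn{\sigma^2_{pri,e} = MS_{pri}},
#' \eqn{\sigma^2_{pr} = (MS_{pr} - MS_{pri}) / n_i},
#' \eqn{\sigma^2_p = (MS_p - MS_{pr} - MS_{pi} + MS_{pri}) / (n_r n_i)}.
#' Negative moment estimates are truncated to zero and flagged.
#'
#' @param arr A [rating_array()] (or plain 3-way array), study x rater x
#'   item, fully crossed, each dimension of size at least 2.
#' @return An object of class `variance_components`: list with `components`
#'   (named vector `p, r, i, pr, pi, ri, pri_e`, truncated), `raw`
#'   (pre-truncation estimates), `truncated` (logical flags),
#'   `mean_squares`, and the design sizes `n_p`, `n_r`, `n_i`.
#' @examples
#' set.seed(1)
#' arr <- simulate_ratings(sim_config(n_studies = 50), seed = 1)$ratings
#' estimate_variance_components(arr)
#' @export
estimate_variance_components <- function(arr) {
  .check_rating_array(arr)
  d <- dim(arr); n_p <- d[1]; n_r <- d[2]; n_i <- d[3]
  m <- mean(arr)
  m_p <- apply(arr, 1, mean); m_r <- apply(arr, 2, mean); m_i <- apply(arr, 3, mean)
  m_pr <- apply(arr, c(1, 2), mean)
  m_pi <- apply(arr, c(1, 3), mean)
  m_ri <- apply(arr, c(2, 3), mean)

  ss <- c(
    p  = n_r * n_i * sum((m_p - m)^2),
    r  = n_p * n_i * sum((m_r - m)^2),
    i  = n_p * n_r * sum((m_i - m)^2),
    pr = n_i * sum((m_pr - outer(m_p, m_r, "+") + m)^2),
    pi = n_r * sum((m_pi - outer(m_p, m_i, "+") + m)^2),
    ri = n_p * sum((m_ri - outer(m_r, m_i, "+") + m)^2)
  )
  resid <- arr
  resid <- sweep(resid, c(1, 2), m_pr)
  resid <- sweep(resid, c(1, 3), m_pi)
  resid <- sweep(resid, c(2, 3), m_ri)
  resid <- sweep(resid, 1, m_p, "+")
  resid <- sweep(resid, 2, m_r, "+")
  resid <- sweep(resid, 3, m_i, "+")
  ss <- c(ss, pri = sum((resid - m)^2))

  df <- c(p = n_p - 1, r = n_r - 1, i = n_i - 1,
          pr = (n_p - 1) * (n_r - 1), pi = (n_p - 1) * (n_i - 1),
          ri = (n_r - 1) * (n_i - 1),
          pri = (n_p - 1) * (n_r - 1) * (n_i - 1))
  ms <- ss / df

  raw <- c(
    p     = (ms[["p"]] - ms[["pr"]] - ms[["pi"]] + ms[["pri"]]) / (n_r * n_i),
    r     = (ms[["r"]] - ms[["pr"]] - ms[["ri"]] + ms[["pri"]]) / (n_p * n_i),
    i     = (ms[["i"]] - ms[["pi"]] - ms[["ri"]] + ms[["pri"]]) / (n_p * n_r),
    pr    = (ms[["pr"]] - ms[["pri"]]) / n_i,
    pi    = (ms[["pi"]] - ms[["pri"]]) / n_r,
    ri    = (ms[["ri"]] - ms[["pri"]]) / n_p,
    pri_e = ms[["pri"]]
  )
  truncated <- raw < 0
  out <- list(components = pmax(raw, 0), raw = raw, truncated = truncated,
              mean_squares = ms, n_p = n_p, n_r = n_r, n_i = n_i)
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, digits = 4, ...) {
  cat(sprintf("Variance components, crossed %d x %d x %d (study x rater x item)\n",
              x$n_p, x$n_r, x$n_i))
  tab <- data.frame(component = names(x$components),
                    estimate = round(unname(x$components), digits),
                    truncated = unname(x$truncated))
  print(tab, row.names = FALSE)
  invisible(x)
}

# Facet sets (excluding the object of measurement p) of each component.
.facets_of <- list(r = "raters", i = "items", pr = "raters", pi = "items",
                   ri = c("raters", "items"), pri_e = c("raters", "items"))
# Components that include the object of measurement p.
.with_p <- c("pr", "pi", "pri_e")

#' Dependability (absolute-error) coefficient Phi
#'
#' Computes \eqn{\Phi = \sigma^2_\tau / (\sigma^2_\tau + \sigma^2_\Delta)},
#' the absolute-error G-coefficient of the D-study in which the facets in
#' `generalize_over` are random (sampled anew, with `n_prime` conditions
#' averaged) and any remaining facet is fixed. Universe-score variance
#' \eqn{\sigma^2_\tau} is \eqn{\sigma^2_p} plus, for every fixed facet f,
#' \eqn{\sigma^2_{pf}/n_f} (the mixed-design convention: the fixed facet's
#' interaction with the study becomes part of the measured attribute).
#' Absolute error \eqn{\sigma^2_\Delta} sums every component involving a
#' random facet — main effects included, which is what distinguishes
#' absolute from relative error — divided by the number of conditions
#' averaged over: `n_prime` for each random facet involved and the design
#' size `n_fixed` for a fixed facet involved.
#'
#' @param vc A `variance_components` object (or a named numeric vector with
#'   elements `p, r, i, pr, pi, ri, pri_e`).
#' @param generalize_over Character subset of `c("raters","items")`: the
#'   random facets of the D-study.
#' @param n_prime Named counts of conditions for the random facets (e.g.
#'   `c(raters = 2, items = 11)`); defaults to the G-study design sizes
#'   when `vc` carries them.
#' @param n_fixed Named counts for fixed facets; same default.
#' @param type `"absolute"` (Phi, default) or `"relative"` (the
#'   generalizability coefficient, whose error term keeps only components
#'   crossing the study with a random facet).
#' @return Coefficient in \[0, 1\].
#' @examples
#' vc <- c(p = 1, r = 0, i = 0, pr = 0, pi = 0, ri = 0, pri_e = 1)
#' phi_coefficient(vc, n_prime = c(raters = 1, items = 1))  # 0.5
#' @export
phi_coefficient <- function(vc, generalize_over = c("raters", "items"),
                            n_prime = NULL, n_fixed = NULL,
                            type = c("absolute", "relative")) {
  type <- match.arg(type)
  comps <- if (inherits(vc, "variance_components")) vc$components else vc
  needed <- c("p", "r", "i", "pr", "pi", "ri", "pri_e")
  if (!all(needed %in% names(comps))) {
    stop("vc must provide components ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(comps[needed] < 0)) stop("variance components must be nonnegative",
                                   call. = FALSE)
  generalize_over <- match.arg(generalize_over, c("raters", "items"),
                               several.ok = TRUE)
  fixed <- setdiff(c("raters", "items"), generalize_over)
  design_n <- if (inherits(vc, "variance_components")) {
    c(raters = vc$n_r, items = vc$n_i)
  } else c(raters = NA_real_, items = NA_real_)
  if (is.null(n_prime)) n_prime <- design_n[generalize_over]
  if (is.null(n_fixed)) n_fixed <- design_n[fixed]
  if (length(generalize_over) &&
      (anyNA(n_prime[generalize_over]) || any(n_prime[generalize_over] <= 0))) {
    stop("n_prime must give a positive count for every random facet",
         call. = FALSE)
  }
  if (length(fixed) && (anyNA(n_fixed[fixed]) || any(n_fixed[fixed] <= 0))) {
    stop("n_fixed must give a positive count for every fixed facet",
         call. = FALSE)
  }

  tau <- comps[["p"]]
  for (f in fixed) {
    pf <- if (f == "raters") "pr" else "pi"
    tau <- tau + comps[[pf]] / n_fixed[[f]]
  }

  delta <- 0
  for (comp in names(.facets_of)) {
    facets <- .facets_of[[comp]]
    rand <- intersect(facets, generalize_over)
    if (length(rand) == 0L) next                  # fixed-only: no error
    if (type == "relative" && !comp %in% .with_p) next
    divisor <- prod(vapply(facets, function(f) {
      if (f %in% generalize_over) n_prime[[f]] else n_fixed[[f]]
    }, numeric(1)))
    delta <- delta + comps[[comp]] / divisor
  }

  if (tau + delta == 0) {
    stop("all relevant variance components are zero: coefficient undefined",
         call. = FALSE)
  }
  unname(tau / (tau + delta))
}

# ---- nested design: study x (rater : group), on item-summed scores ----

#' Variance components of the nested study x (rater : group) design
#'
#' Used for inter-user reliability: raters are nested in user-status
#' groups, and each rater's 11 item ratings are first summed to a total
#' score per study, giving a balanced two-way layout of studies by raters
#' nested in groups. Components are estimated by the nested-design
#' expected-mean-square equations and truncated at zero.
#'
#' @param scores Numeric array study x rater x group (raters within group),
#'   or a study x rater matrix plus `groups` giving each rater column's
#'   group label (groups must be balanced).
#' @param groups Optional group label per rater column when `scores` is a
#'   matrix.
#' @return List of class `nested_components` with `components` (named
#'   `p, g, r_g, pg, pr_g_e`), `raw`, `truncated`, `mean_squares`, and
#'   sizes `n_p`, `n_g`, `n_r`.
#' @export
nested_variance_components <- function(scores, groups = NULL) {
  if (is.matrix(scores)) {
    if (is.null(groups) || length(groups) != ncol(scores)) {
      stop("groups must label every rater column", call. = FALSE)
    }
    groups <- as.factor(groups)
    sizes <- table(groups)
    if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
    if (length(unique(sizes)) != 1L) {
      stop("unequal raters per group: only balanced designs are supported",
           call. = FALSE)
    }
    n_r <- unname(sizes[1])
    arr <- array(NA_real_, dim = c(nrow(scores), n_r, length(sizes)))
    for (gi in seq_along(levels(groups))) {
      arr[, , gi] <- scores[, groups == levels(groups)[gi], drop = FALSE]
    }
    scores <- arr
  }
  if (!is.array(scores) || length(dim(scores)) != 3L || anyNA(scores)) {
    stop("scores must be a complete study x rater x group array", call. = FALSE)
  }
  d <- dim(scores); n_p <- d[1]; n_r <- d[2]; n_g <- d[3]
  if (n_p < 2L || n_r < 1L || n_g < 2L) {
    stop("need >= 2 studies, >= 1 rater per group, >= 2 groups", call. = FALSE)
  }
  m <- mean(scores)
  m_p <- apply(scores, 1, mean)
  m_g <- apply(scores, 3, mean)
  m_rg <- apply(scores, c(2, 3), mean)   # rater-within-group means
  m_pg <- apply(scores, c(1, 3), mean)

  ss_p <- n_g * n_r * sum((m_p - m)^2)
  ss_g <- n_p * n_r * sum((m_g - m)^2)
  ss_rg <- n_p * sum(sweep(m_rg, 2, m_g)^2)
  ss_pg <- n_r * sum((m_pg - outer(m_p, m_g, "+") + m)^2)
  resid <- scores
  resid <- sweep(resid, c(1, 3), m_pg)
  resid <- sweep(resid, c(2, 3), m_rg)
  resid <- sweep(resid, 3, m_g, "+")
  ss_prg <- sum(resid^2)

  df <- c(p = n_p - 1, g = n_g - 1, r_g = n_g * (n_r - 1),
          pg = (n_p - 1) * (n_g - 1), pr_g = (n_p - 1) * n_g * (n_r - 1))
  if (df[["pr_g"]] == 0) {
    stop("design too small to separate the residual (single rater per group)",
         call. = FALSE)
  }
  ms <- c(p = ss_p, g = ss_g, r_g = ss_rg, pg = ss_pg, pr_g = ss_prg) / df

  raw <- c(
    p      = (ms[["p"]] - ms[["pg"]]) / (n_g * n_r),
    g      = (ms[["g"]] - ms[["pg"]] - ms[["r_g"]] + ms[["pr_g"]]) / (n_p * n_r),
    r_g    = (ms[["r_g"]] - ms[["pr_g"]]) / n_p,
    pg     = (ms[["pg"]] - ms[["pr_g"]]) / n_r,
    pr_g_e = ms[["pr_g"]]
  )
  truncated <- raw < 0
  out <- list(components = pmax(raw, 0), raw = raw, truncated = truncated,
              mean_squares = ms, n_p = n_p, n_g = n_g, n_r = n_r)
  class(out) <- "nested_components"
  out
}

#' Nested-design dependability coefficient from components
#'
#' \eqn{\Phi = \sigma^2_p / (\sigma^2_p + \sigma^2_g/n_g + \sigma^2_{pg}/n_g
#' + \sigma^2_{r:g}/(n_g n_r) + \sigma^2_{pr:g,e}/(n_g n_r))}: the
#' dependability of a study's mean score over all groups and raters, with
#' group and rater-within-group effects both treated as random.
#'
#' @param vc A `nested_components` object or named vector
#'   (`p, g, r_g, pg, pr_g_e`).
#' @param n_g,n_r Numbers of groups and of raters per group averaged over;
#'   default to the design sizes when `vc` carries them.
#' @return Coefficient in \[0, 1\].
#' @export
phi_nested <- function(vc, n_g = NULL, n_r = NULL) {
  comps <- if (inherits(vc, "nested_components")) vc$components else vc
  needed <- c("p", "g", "r_g", "pg", "pr_g_e")
  if (!all(needed %in% names(comps))) {
    stop("vc must provide components ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(n_g)) n_g <- if (inherits(vc, "nested_components")) vc$n_g else
    stop("n_g required", call. = FALSE)
  if (is.null(n_r)) n_r <- if (inherits(vc, "nested_components")) vc$n_r else
    stop("n_r required", call. = FALSE)
  delta <- comps[["g"]] / n_g + comps[["pg"]] / n_g +
    comps[["r_g"]] / (n_g * n_r) + comps[["pr_g_e"]] / (n_g * n_r)
  if (comps[["p"]] + delta == 0) {
    stop("all relevant variance components are zero: coefficient undefined",
         call. = FALSE)
  }
  unname(comps[["p"]] / (comps[["p"]] + delta))
}

#' Inter-user dependability from a grouped rating array
#'
#' Quantifies how far a rating from one user-status group (e.g. raters
#' familiar with genetic association studies) generalizes to the other:
#' item ratings are summed to a total score per study and rater, raters
#' are nested in their groups, and the nested-design Phi is computed with
#' both group and rater facets random.
#'
#' @param arr A [rating_array()] study x rater x item.
#' @param rater_groups Group label per rater (length `dim(arr)[2]`); groups
#'   must have equal numbers of raters.
#' @return List with `phi`, the `nested_components`, and the group labels.
#' @export
inter_user_phi <- function(arr, rater_groups) {
  .check_rating_array(arr, min_dim = 1L)
  if (length(rater_groups) != dim(arr)[2]) {
    stop("rater_groups must label every rater", call. = FALSE)
  }
  totals <- apply(arr, c(1, 2), sum)   # item-summed score per study x rater
  vc <- nested_variance_components(totals, groups = rater_groups)
  list(phi = phi_nested(vc), components = vc,
       groups = levels(as.factor(rater_groups)))
}

#' Reliability suite for grouped raters
#'
#' Reproduces the layout of the instrument's reliability table: for each
#' rater group, internal consistency (generalizing over items, raters
#' fixed at the design size), inter-rater reliability (generalizing over
#' raters, items fixed), and overall reliability (generalizing over both);
#' plus a single inter-user coefficient from the nested design pooling all
#' raters.
#'
#' @param arr A [rating_array()] study x rater x item covering all raters.
#' @param rater_groups Group label per rater (e.g. `"user"`/`"non-user"`);
#'   equal group sizes required for the inter-user coefficient.
#' @return Object of class `g_report`: list with `per_group` (data frame of
#'   group, internal_consistency, inter_rater, overall), `inter_user`, and
#'   the per-group `variance_components`.
#' @examples
#' set.seed(7)
#' sim <- simulate_ratings(sim_config(n_studies = 30), seed = 7)
#' reliability_suite(sim$ratings, sim$rater_groups)
#' @export
reliability_suite <- function(arr, rater_groups) {
  .check_rating_array(arr)
  rater_groups <- as.factor(rater_groups)
  if (length(rater_groups) != dim(arr)[2]) {
    stop("rater_groups must label every rater", call. = FALSE)
  }
  groups <- levels(rater_groups)
  per <- lapply(groups, function(g) {
    sub <- arr[, rater_groups == g, , drop = FALSE]
    if (dim(sub)[2] < 2L) {
      stop(sprintf("group '%s' needs at least 2 raters", g), call. = FALSE)
    }
    vc <- estimate_variance_components(sub)
    n_r <- dim(sub)[2]; n_i <- dim(sub)[3]
    data.frame(
      group = g,
      internal_consistency = phi_coefficient(vc, "items",
                                             n_prime = c(items = n_i),
                                             n_fixed = c(raters = n_r)),
      inter_rater = phi_coefficient(vc, "raters",
                                    n_prime = c(raters = n_r),
                                    n_fixed = c(items = n_i)),
      overall = phi_coefficient(vc, c("raters", "items"),
                                n_prime = c(raters = n_r, items = n_i)),
      stringsAsFactors = FALSE
    )
  })
  vcs <- lapply(groups, function(g) {
    estimate_variance_components(arr[, rater_groups == g, , drop = FALSE])
  })
  names(vcs) <- groups
  iu <- if (length(groups) >= 2L &&
            length(unique(table(rater_groups))) == 1L) {
    inter_user_phi(arr, rater_groups)$phi
  } else NA_real_
  out <- list(per_group = do.call(rbind, per), inter_user = iu,
              variance_components = vcs)
  class(out) <- "g_report"
  out
}

#' @export
print.g_report <- function(x, digits = 2, ...) {
  cat("G-coefficients of reliability (absolute error), by rater group\n")
  tab <- x$per_group
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Inter-user (all raters, nested in groups): %s\n",
              if (is.na(x$inter_user)) "not estimable" else
                format(round(x$inter_user, digits))))
  invisible(x)
}
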