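# Seeded generators for every input the analysis modules consume, with
# the generating parameters returned alongside the data so recovery tests
# can compare estimates against known truth.
#
# The default configuration mirrors the validation study's design: 30
# studies rated by 4 raters (2 user-status groups of 2) on 11 items of a
# 1-7 Likert scale.

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate
#' the instrument's validation design: 30 studies, 4 raters in 2
#' user-status groups, 11 items, a grand mean of 4.5 on the 7-point
#' scale, and variance components dominated by true study differences
#' with a sizeable residual — the pattern expected when raters broadly
#' agree on which studies are strong.
#'
#' @param n_studies,n_raters,n_items,n_groups Design sizes; `n_raters`
#'   must be divisible by `n_groups`.
#' @param mu Grand mean on the 1-7 scale.
#' @param components Named variances (score-scale squared) of the crossed
#'   random effects: `p, r, i, pr, pi, ri, pri_e`.
#' @param discretize `"round_clip"` (round to integers, clip to 1-7;
#'   default), `"threshold"` (graded thresholds on the latent scale,
#'   which avoids the shrinkage that rounding-plus-clipping induces near
#'   the scale ends), or `"none"` (return the continuous latent ratings,
#'   used by recovery tests where unbiasedness is asserted).
#' @param global_noise_sd Rating noise of the global-impression question.
#' @param impact_link_weight,impact_noise_sd Strength of the monotone
#'   latent-quality to log-impact link and its noise.
#' @param citation_scale Multiplier from impact to expected citations.
#' @param self_fraction Expected fraction of citations that are
#'   self-citations.
#' @param year_range Publication-year range for impact records.
#' @param meta_k,meta_theta,meta_tau2,meta_se_range,meta_frac_low,meta_bias_low
#'   Meta-analysis generator: number of studies, true pooled log odds
#'   ratio, between-study variance, per-study standard-error range,
#'   fraction of studies labelled low quality, and the upward log-OR bias
#'   added to those studies.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_studies = 30, n_raters = 4, n_items = 11,
                       n_groups = 2, mu = 4.5,
                       components = c(p = 1.0, r = 0.1, i = 0.2, pr = 0.3,
                                      pi = 0.2, ri = 0.05, pri_e = 0.8),
                       discretize = c("round_clip", "threshold", "none"),
                       global_noise_sd = 0.5,
                       impact_link_weight = 0.5, impact_noise_sd = 0.3,
                       citation_scale = 10, self_fraction = 0.1,
                       year_range = c(2005, 2013),
                       meta_k = 7, meta_theta = log(1.15), meta_tau2 = 0,
                       meta_se_range = c(0.08, 0.25),
                       meta_frac_low = 2 / 7, meta_bias_low = 0.5) {
  discretize <- match.arg(discretize)
  needed <- c("p", "r", "i", "pr", "pi", "ri", "pri_e")
  if (!all(needed %in% names(components)) || any(components[needed] < 0)) {
    stop("components must be nonnegative and named ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  stopifnot(n_studies >= 2, n_raters >= 2, n_items >= 2, n_groups >= 1,
            n_raters %% n_groups == 0, mu >= 1, mu <= 7,
            global_noise_sd >= 0, impact_noise_sd >= 0,
            meta_k >= 2, meta_tau2 >= 0,
            meta_frac_low >= 0, meta_frac_low < 1,
            length(meta_se_range) == 2, all(meta_se_range > 0))
  cfg <- list(n_studies = n_studies, n_raters = n_raters, n_items = n_items,
              n_groups = n_groups, mu = mu,
              components = components[needed], discretize = discretize,
              global_noise_sd = global_noise_sd,
              impact_link_weight = impact_link_weight,
              impact_noise_sd = impact_noise_sd,
              citation_scale = citation_scale,
              self_fraction = self_fraction, year_range = year_range,
              meta_k = meta_k, meta_theta = meta_theta,
              meta_tau2 = meta_tau2, meta_se_range = meta_se_range,
              meta_frac_low = meta_frac_low, meta_bias_low = meta_bias_low)
  class(cfg) <- "sim_config"
  cfg
}

.discretize <- function(y, how) {
  if (how == "round_clip") {
    y[] <- pmin(7, pmax(1, round(y)))
  } else if (how == "threshold") {
    # graded thresholds at half-integers around the scale midpoint
    y[] <- as.numeric(cut(y, breaks = c(-Inf, 1.5:6.5, Inf), labels = FALSE))
  }
  y
}

#' Simulate a crossed study x rater x item rating array
#'
#' Generates `y[p, r, i] = mu + p + r + i + pr + pi + ri + e` with
#' independent zero-mean normal effects at the configured variances, then
#' discretizes to the 1-7 scale (unless `discretize = "none"`). The same
#' seed always yields the identical array.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (required for reproducibility; `NULL` uses the
#'   current RNG state).
#' @return List with `ratings` (a [rating_array()]), `rater_groups`
#'   (labels, `"user"`/`"non_user"` for two groups), and `truth` (the
#'   configured components, grand mean, and the drawn study effects
#'   `latent_quality`).
#' @examples
#' sim <- simulate_ratings(sim_config(n_studies = 10), seed = 42)
#' dim(sim$ratings)
#' @export
simulate_ratings <- function(cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(seed, {
    n_p <- cfg$n_studies; n_r <- cfg$n_raters; n_i <- cfg$n_items
    v <- cfg$components
    p_eff <- stats::rnorm(n_p, 0, sqrt(v[["p"]]))
    r_eff <- stats::rnorm(n_r, 0, sqrt(v[["r"]]))
    i_eff <- stats::rnorm(n_i, 0, sqrt(v[["i"]]))
    pr_eff <- matrix(stats::rnorm(n_p * n_r, 0, sqrt(v[["pr"]])), n_p, n_r)
    pi_eff <- matrix(stats::rnorm(n_p * n_i, 0, sqrt(v[["pi"]])), n_p, n_i)
    ri_eff <- matrix(stats::rnorm(n_r * n_i, 0, sqrt(v[["ri"]])), n_r, n_i)
    e_eff <- array(stats::rnorm(n_p * n_r * n_i, 0, sqrt(v[["pri_e"]])),
                   dim = c(n_p, n_r, n_i))
    y <- cfg$mu + e_eff
    y <- sweep(y, 1, p_eff, "+")
    y <- sweep(y, 2, r_eff, "+")
    y <- sweep(y, 3, i_eff, "+")
    y <- sweep(y, c(1, 2), pr_eff, "+")
    y <- sweep(y, c(1, 3), pi_eff, "+")
    y <- sweep(y, c(2, 3), ri_eff, "+")
    y <- .discretize(y, cfg$discretize)

    groups <- if (cfg$n_groups == 2) c("user", "non_user") else
      paste0("group", seq_len(cfg$n_groups))
    rater_groups <- rep(groups, each = cfg$n_raters / cfg$n_groups)
    study_ids <- sprintf("study_%02d", seq_len(n_p))
    dimnames(y) <- list(study_ids,
                        sprintf("rater_%d", seq_len(n_r)),
                        as.character(seq_len(n_i)))
    list(ratings = rating_array(y),
         rater_groups = rater_groups,
         truth = list(components = v, mu = cfg$mu,
                      latent_quality = stats::setNames(p_eff, study_ids),
                      discretize = cfg$discretize))
  })
}

#' Simulate global-impression ratings from latent study quality
#'
#' Studies are ranked by latent quality and anchored at a base global
#' rating of 2, 4 or 6 by latent-quality tercile; rater noise is added and
#' the result rounded and clipped to 1-7. With zero noise the derived
#' grades exactly partition the studies into their latent terciles.
#'
#' @param latent_quality Named numeric vector of per-study latent quality
#'   (from `simulate_ratings()$truth`).
#' @param n_raters Number of raters answering the global question.
#' @param noise_sd Rating noise standard deviation.
#' @param seed Integer seed.
#' @return Data frame with `study_id`, `rater_id`, `rating` (1-7), and
#'   `grade` (1/2/3 via [map_global_to_grade()]).
#' @export
simulate_global_impressions <- function(latent_quality, n_raters = 4,
                                        noise_sd = 0.5, seed = NULL) {
  stopifnot(length(latent_quality) >= 3, n_raters >= 1, noise_sd >= 0)
  .with_seed(seed, {
    n <- length(latent_quality)
    ids <- names(latent_quality)
    if (is.null(ids)) ids <- sprintf("study_%02d", seq_len(n))
    tercile <- ceiling(3 * rank(latent_quality, ties.method = "first") / n)
    base <- c(2, 4, 6)[tercile]
    out <- do.call(rbind, lapply(seq_len(n_raters), function(r) {
      rating <- pmin(7, pmax(1, round(base + stats::rnorm(n, 0, noise_sd))))
      data.frame(study_id = ids, rater_id = sprintf("rater_%d", r),
                 rating = as.integer(rating), stringsAsFactors = FALSE)
    }))
    out$grade <- map_global_to_grade(out$rating)
    out
  })
}

#' Simulate journal-impact records from latent study quality
#'
#' Impact factor is a log-linear monotone function of latent quality plus
#' noise; citation counts are Poisson draws around a multiple of the
#' impact factor, with a binomial share of self-citations; publication
#' years are uniform over the configured range.
#'
#' @inheritParams simulate_global_impressions
#' @param cfg A [sim_config()] (uses the `impact_*`, `citation_scale`,
#'   `self_fraction`, `year_range` fields).
#' @return Data frame with `study_id`, `impact_factor`, `total_citations`,
#'   `self_citations`, `year`.
#' @export
simulate_impact <- function(latent_quality, cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), length(latent_quality) >= 1)
  .with_seed(seed, {
    n <- length(latent_quality)
    ids <- names(latent_quality)
    if (is.null(ids)) ids <- sprintf("study_%02d", seq_len(n))
    z <- as.numeric(scale(latent_quality))
    if (any(!is.finite(z))) z <- rep(0, n)  # constant latent quality
    log_if <- log(3) + cfg$impact_link_weight * z +
      stats::rnorm(n, 0, cfg$impact_noise_sd)
    impact <- exp(log_if)
    total <- stats::rpois(n, cfg$citation_scale * impact)
    self <- stats::rbinom(n, total, cfg$self_fraction)
    years <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n,
                    replace = TRUE)
    data.frame(study_id = ids, impact_factor = impact,
               total_citations = total, self_citations = self,
               year = years, stringsAsFactors = FALSE)
  })
}

#' Simulate a meta-analysis dataset with known truth
#'
#' Study-level true log odds ratios are drawn from
#' `Normal(meta_theta, meta_tau2)`; a configured fraction of studies is
#' labelled low quality and receives an additional upward bias
#' (`meta_bias_low`), emulating the situation where poorly conducted
#' studies inflate the pooled effect and drive heterogeneity. Observed
#' effects are drawn around the (possibly biased) study truths at
#' standard errors uniform over `meta_se_range`.
#'
#' @param cfg A [sim_config()] (uses the `meta_*` fields).
#' @param seed Integer seed.
#' @return Data frame of study effects (`study_id`, `log_or`, `se`,
#'   `quality`) with attribute `"truth"` (theta, tau2, bias, and the
#'   per-study true effects).
#' @export
simulate_meta <- function(cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(seed, {
    k <- cfg$meta_k
    n_low <- round(cfg$meta_frac_low * k)
    quality <- rep("moderate", k)
    if (n_low > 0) quality[seq_len(n_low)] <- "low"
    theta_i <- stats::rnorm(k, cfg$meta_theta, sqrt(cfg$meta_tau2))
    bias <- ifelse(quality == "low", cfg$meta_bias_low, 0)
    se <- stats::runif(k, cfg$meta_se_range[1], cfg$meta_se_range[2])
    y <- stats::rnorm(k, theta_i + bias, se)
    out <- data.frame(study_id = sprintf("study_%d", seq_len(k)),
                      log_or = y, se = se, quality = quality,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(theta = cfg$meta_theta, tau2 = cfg$meta_tau2,
                               bias_low = cfg$meta_bias_low,
                               true_effects = theta_i)
    out
  })
}
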