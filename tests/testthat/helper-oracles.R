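# Independent definitional oracles used to cross-check the package's
# implementations. Each recomputes a statistic from first principles by a
# different route than the package code takes.

# Cronbach's alpha in covariance-matrix form: k/(k-1) * (1 - tr(C)/sum(C))
alpha_cov_oracle <- function(m) {
  C <- cov(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# corrected item-total correlation as ranks-free Pearson from raw sums
itc_sum_oracle <- function(m, j) {
  x <- m[, j]
  y <- rowSums(m[, -j, drop = FALSE])
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# corrected item-total correlation in centered covariance form
itc_cov_oracle <- function(m, j) {
  x <- m[, j]
  y <- rowSums(m[, -j, drop = FALSE])
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# crossed p x r x i variance components via stats::lm/anova mean squares
# (sums of squares computed by R's linear-model machinery, then the EMS
# equations applied to those mean squares)
vc_aov_oracle <- function(arr) {
  d <- dim(arr)
  dat <- expand.grid(P = factor(seq_len(d[1])), R = factor(seq_len(d[2])),
                     I = factor(seq_len(d[3])))
  dat$y <- as.vector(arr)
  an <- anova(lm(y ~ P + R + I + P:R + P:I + R:I, data = dat))
  ms <- setNames(an[["Mean Sq"]], rownames(an))
  n_p <- d[1]; n_r <- d[2]; n_i <- d[3]
  c(p = (ms[["P"]] - ms[["P:R"]] - ms[["P:I"]] + ms[["Residuals"]]) / (n_r * n_i),
    r = (ms[["R"]] - ms[["P:R"]] - ms[["R:I"]] + ms[["Residuals"]]) / (n_p * n_i),
    i = (ms[["I"]] - ms[["P:I"]] - ms[["R:I"]] + ms[["Residuals"]]) / (n_p * n_r),
    pr = (ms[["P:R"]] - ms[["Residuals"]]) / n_i,
    pi = (ms[["P:I"]] - ms[["Residuals"]]) / n_r,
    ri = (ms[["R:I"]] - ms[["Residuals"]]) / n_p,
    pri_e = ms[["Residuals"]])
}

# nested p x (r : g) variance components via lm/anova on study x rater
# totals; RTR labels are unique per rater so RTR after G is rater-within-group
vc_nested_oracle <- function(scores_mat, groups) {
  n_p <- nrow(scores_mat)
  n_rtot <- ncol(scores_mat)
  groups <- factor(groups)
  n_g <- nlevels(groups)
  n_r <- n_rtot / n_g
  dat <- expand.grid(P = factor(seq_len(n_p)), RTR = factor(seq_len(n_rtot)))
  dat$G <- groups[as.integer(dat$RTR)]
  dat$y <- as.vector(scores_mat)
  an <- anova(lm(y ~ P + G + RTR + P:G, data = dat))
  ms <- setNames(an[["Mean Sq"]], rownames(an))
  c(p = (ms[["P"]] - ms[["P:G"]]) / (n_g * n_r),
    g = (ms[["G"]] - ms[["P:G"]] - ms[["RTR"]] + ms[["Residuals"]]) / (n_p * n_r),
    r_g = (ms[["RTR"]] - ms[["Residuals"]]) / n_p,
    pg = (ms[["P:G"]] - ms[["Residuals"]]) / n_r,
    pr_g_e = ms[["Residuals"]])
}

# absolute / relative coefficient by explicit enumeration of all seven
# components and their divisors
phi_enum_oracle <- function(vc, random, nprime, nfixed,
                            type = c("absolute", "relative")) {
  type <- match.arg(type)
  facets <- list(p = character(), r = "raters", i = "items",
                 pr = "raters", pi = "items",
                 ri = c("raters", "items"), pri_e = c("raters", "items"))
  has_p <- c("p", "pr", "pi", "pri_e")
  fixed <- setdiff(c("raters", "items"), random)
  tau <- vc[["p"]]
  if ("raters" %in% fixed) tau <- tau + vc[["pr"]] / nfixed[["raters"]]
  if ("items" %in% fixed) tau <- tau + vc[["pi"]] / nfixed[["items"]]
  delta <- 0
  for (nm in setdiff(names(facets), "p")) {
    fs <- facets[[nm]]
    if (!any(fs %in% random)) next
    if (type == "relative" && !nm %in% has_p) next
    div <- 1
    for (f in fs) div <- div * (if (f %in% random) nprime[[f]] else nfixed[[f]])
    delta <- delta + vc[[nm]] / div
  }
  tau / (tau + delta)
}

# Spearman rho by explicit midrank construction + raw-sum Pearson formula
spearman_midrank_oracle <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt((n * sum(rx^2) - sum(rx)^2) * (n * sum(ry^2) - sum(ry)^2))
  num / den
}

# build a complete rating list: one study_rating per study, all items at
# the given value(s)
uniform_rating <- function(study_id, value, has_control = TRUE) {
  items <- if (has_control) 1:11 else setdiff(1:11, 3)
  study_rating(study_id, setNames(rep(value, length(items)), items),
               has_control_group = has_control)
}

# random valid variance-component vector for property tests
random_vc <- function() {
  v <- runif(7, 0, 2)
  names(v) <- c("p", "r", "i", "pr", "pi", "ri", "pri_e")
  v
}
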