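# Construct validity: higher-quality studies should appear in
# higher-impact journals and be cited more often, so instrument totals are
# correlated (Spearman) with impact factor, citations per year, and total
# citations, optionally excluding self-citations by the first and senior
# authors.

#' Average citations per year
#'
#' Citation counts divided by the number of calendar years the study has
#' been citable, counted inclusively with a floor of one year so that a
#' study published in the analysis year is not divided by zero.
#'
#' @param total_citations,self_citations Nonnegative counts;
#'   `self_citations <= total_citations`.
#' @param publication_year,analysis_year Calendar years,
#'   `publication_year <= analysis_year`.
#' @param exclude_self Subtract self-citations first?
#' @return Citations per year (vectorized).
#' @examples
#' citations_per_year(20, 4, 2011, 2014, exclude_self = TRUE)  # 4
#' @export
citations_per_year <- function(total_citations, self_citations = 0,
                               publication_year, analysis_year,
                               exclude_self = FALSE) {
  stopifnot(all(total_citations >= 0), all(self_citations >= 0),
            all(self_citations <= total_citations),
            all(publication_year <= analysis_year))
  n <- if (exclude_self) total_citations - self_citations else total_citations
  n / pmax(1, analysis_year - publication_year + 1)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of midranks (average ranks for ties), with a
#' two-sided p-value from the t approximation on n - 2 degrees of freedom.
#' For small samples an exact permutation p-value is available
#' (`exact = TRUE`, full enumeration, n <= 8).
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param exact Compute the p-value by enumerating all permutations of the
#'   ranks of `y` (two-sided, by |rho|). Only supported for n <= 8.
#' @return List with `rho`, `p_value`, `n`, and `method`.
#' @examples
#' spearman(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not supported", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("zero rank variance: Spearman correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8L) {
      stop("exact permutation p-value supported only for n <= 8", call. = FALSE)
    }
    perms <- .permutations(n)
    rho_perm <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# all permutations of 1..n, one per row (n small)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Construct-validity correlation table
#'
#' Correlates per-study instrument totals with impact factor, average
#' citations per year (with and without self-citations), and total
#' citations, producing one row per construct.
#'
#' @param scores Data frame with `study_id` and `score` (one total per
#'   study, e.g. a rater group's mean or one rater's totals).
#' @param impact Data frame with `study_id`, `impact_factor`,
#'   `total_citations`, `self_citations`, `year` (publication year).
#' @param analysis_year Year the citation counts were retrieved.
#' @return Data frame with `construct`, `rho`, `p_value`, `n`.
#' @export
validity_table <- function(scores, impact, analysis_year) {
  stopifnot(all(c("study_id", "score") %in% names(scores)),
            all(c("study_id", "impact_factor", "total_citations",
                  "self_citations", "year") %in% names(impact)))
  d <- merge(scores, impact, by = "study_id")
  if (nrow(d) < 4L) stop("need at least 4 studies with both score and impact data",
                         call. = FALSE)
  cpy <- citations_per_year(d$total_citations, d$self_citations,
                            d$year, analysis_year, exclude_self = FALSE)
  cpy_ns <- citations_per_year(d$total_citations, d$self_citations,
                               d$year, analysis_year, exclude_self = TRUE)
  constructs <- list(
    impact_factor = d$impact_factor,
    citations_per_year = cpy,
    citations_per_year_no_self = cpy_ns,
    total_citations = d$total_citations
  )
  rows <- lapply(names(constructs), function(nm) {
    s <- spearman(d$score, constructs[[nm]])
    data.frame(construct = nm, rho = s$rho, p_value = s$p_value, n = s$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
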