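# Condition-level aggregation and nonparametric comparisons: quartile
# summaries with histograms, pulling-velocity series, and two-sample
# Wilcoxon rank-sum tests (exact enumeration for small samples, tie-corrected
# normal approximation otherwise).

#' Summarize a pooled rupture-force population
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the histogram covers `[0, max]` with fixed
#' bin width (default 10 pN, matching the granularity at which rupture-force
#' histograms are conventionally drawn).  An empty dataset yields an `n = 0`
#' sentinel with no quantiles.
#'
#' @param data a `condition_dataset` (see [pool_condition()]) or a numeric
#'   vector of rupture forces, pN
#' @param bin_width histogram bin width, pN
#' @return object of class `condition_summary`: labels, `n`, `q25`, `median`,
#'   `q75` (pN) and `histogram` (list with `breaks`, `counts`)
#' @export
summarize_forces <- function(data, bin_width = 10) {
  stopifnot(bin_width > 0)
  if (inherits(data, "condition_dataset")) {
    forces <- data$rupture_forces
    labs <- data[c("condition_label", "treatment_label", "velocity_v")]
  } else {
    forces <- as.numeric(data)
    labs <- list(condition_label = NA_character_,
                 treatment_label = NA_character_, velocity_v = NA_real_)
  }
  if (length(forces) == 0) {
    return(structure(c(labs, list(n = 0L, q25 = NA_real_, median = NA_real_,
                                  q75 = NA_real_,
                                  histogram = list(breaks = numeric(0),
                                                   counts = integer(0)),
                                  bin_width = bin_width)),
                     class = "condition_summary"))
  }
  q <- unname(stats::quantile(forces, c(0.25, 0.5, 0.75), type = 7))
  breaks <- seq(0, bin_width * ceiling(max(forces) / bin_width), by = bin_width)
  if (length(breaks) < 2) breaks <- c(0, bin_width)
  h <- graphics::hist(forces, breaks = breaks, plot = FALSE)
  structure(c(labs, list(n = length(forces), q25 = q[1], median = q[2],
                         q75 = q[3],
                         histogram = list(breaks = h$breaks, counts = h$counts),
                         bin_width = bin_width)),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  if (x$n == 0) {
    cat("<condition_summary> empty (n = 0)\n")
  } else {
    cat(sprintf("<condition_summary> %s / %s @ %s um/s: n = %d, median %.2f pN (q25 %.2f, q75 %.2f)\n",
                x$condition_label, x$treatment_label,
                format(x$velocity_v), x$n, x$median, x$q25, x$q75))
  }
  invisible(x)
}

#' Median rupture force versus pulling velocity
#'
#' Least-squares line through the (velocity, median) pairs plus their
#' Spearman rank correlation, capturing the monotone (approximately linear
#' over the measured range) growth of rupture force with pulling rate.
#'
#' @param velocities pulling velocities, um/s (>= 3 values)
#' @param medians median rupture forces, pN
#' @return object of class `velocity_series`: `velocities`, `medians`,
#'   `slope` (pN per um/s), `intercept` (pN), `spearman_rho`
#' @export
velocity_trend <- function(velocities, medians) {
  stopifnot(length(velocities) == length(medians))
  if (length(velocities) < 3)
    stop("velocity_trend: need at least 3 velocities")
  fit <- stats::lm.fit(cbind(1, velocities), medians)
  rho <- stats::cor(velocities, medians, method = "spearman")
  structure(list(velocities = velocities, medians = medians,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 spearman_rho = rho,
                 residuals = unname(fit$residuals)),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("<velocity_series> %d velocities, slope %.2f pN/(um/s), spearman rho %.3f\n",
              length(x$velocities), x$slope, x$spearman_rho))
  invisible(x)
}

.stars <- function(p) ifelse(p < 0.005, "**", ifelse(p < 0.05, "*", ""))

# exact two-sided rank-sum p-value by full enumeration of the
# choose(n_a + n_b, n_a) assignments of the pooled midranks to group a.
.ranksum_exact <- function(ra, n_a, ranks) {
  combos <- utils::combn(length(ranks), n_a)
  sums <- colSums(matrix(ranks[combos], nrow = n_a))
  tol <- 1e-9
  p_le <- mean(sums <= ra + tol)
  p_ge <- mean(sums >= ra - tol)
  min(1, 2 * min(p_le, p_ge))
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Compares two independent rupture-force populations.  When the smaller
#' sample has at most `exact_max` observations the two-sided p-value is
#' computed by full enumeration of the permutation null of the rank sum
#' (midranks, so ties are handled exactly); otherwise a tie-corrected normal
#' approximation with continuity correction is used.  Significance stars
#' follow the convention `*` for p < 0.05 and `**` for p < 0.005.
#'
#' @param a,b numeric vectors of rupture forces (pN), or `condition_dataset`
#'   objects
#' @param exact_max largest min(n) for which the exact enumeration is used
#' @param label_a,label_b labels carried into the result
#' @return object of class `comparison_result`: `U` (Mann-Whitney U for
#'   sample a), `p_value`, `stars`, `method`, sample sizes
#' @export
wilcoxon_ranksum <- function(a, b, exact_max = 10,
                             label_a = deparse(substitute(a)),
                             label_b = deparse(substitute(b))) {
  force(label_a); force(label_b)
  if (inherits(a, "condition_dataset")) {
    label_a <- paste(a$condition_label, a$treatment_label, sep = "/")
    a <- a$rupture_forces
  }
  if (inherits(b, "condition_dataset")) {
    label_b <- paste(b$condition_label, b$treatment_label, sep = "/")
    b <- b$rupture_forces
  }
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0 || n_b == 0)
    stop("wilcoxon_ranksum: both samples must be non-empty")
  pooled <- c(a, b)
  ranks <- rank(pooled)          # midranks
  ra <- sum(ranks[seq_len(n_a)])
  U <- ra - n_a * (n_a + 1) / 2

  n_min <- min(n_a, n_b)
  feasible <- choose(n_a + n_b, n_min) <= 5e6   # enumeration stays desk-scale
  if (n_min <= exact_max && feasible) {
    if (n_a <= n_b) {
      p <- .ranksum_exact(ra, n_a, ranks)
    } else {                     # enumerate the smaller group instead
      rb <- sum(ranks[n_a + seq_len(n_b)])
      p <- .ranksum_exact(rb, n_b, ranks)
    }
    method <- "exact enumeration"
  } else {
    N <- n_a + n_b
    mu <- n_a * (N + 1) / 2
    ties <- table(pooled)
    sigma2 <- n_a * n_b / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (abs(ra - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation (tie-corrected)"
  }
  structure(list(label_a = label_a, label_b = label_b,
                 n_a = n_a, n_b = n_b, U = U,
                 p_value = p, stars = .stars(p), method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s: U = %g, p = %.4g %s (%s)\n",
              x$label_a, x$label_b, x$U, x$p_value, x$stars, x$method))
  invisible(x)
}

#' Assemble condition summaries into a long-format table
#'
#' One row per summary with columns `condition`, `treatment`, `velocity_um_s`,
#' `n`, `q25_pN`, `median_pN`, `q75_pN`, deterministically ordered by
#' (condition, treatment, velocity).
#'
#' @param summaries list of `condition_summary` objects
#' @return data frame
#' @export
build_summary_table <- function(summaries) {
  cols <- c("condition", "treatment", "velocity_um_s", "n",
            "q25_pN", "median_pN", "q75_pN")
  if (length(summaries) == 0) {
    tab <- as.data.frame(stats::setNames(list(character(0), character(0),
                                              numeric(0), integer(0),
                                              numeric(0), numeric(0),
                                              numeric(0)), cols))
    return(tab)
  }
  tab <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(condition = s$condition_label, treatment = s$treatment_label,
               velocity_um_s = s$velocity_v, n = s$n,
               q25_pN = s$q25, median_pN = s$median, q75_pN = s$q75,
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$condition, tab$treatment, tab$velocity_um_s), ]
  rownames(tab) <- NULL
  tab
}

#' Control / vehicle / drug pairwise comparisons
#'
#' Runs [wilcoxon_ranksum()] on the three pairs (control, vehicle),
#' (vehicle, drug) and (control, drug) -- the layout used to separate a drug
#' effect from its DMSO vehicle.
#'
#' @param control,dmso,drug `condition_dataset` objects or force vectors
#' @param ... passed to [wilcoxon_ranksum()]
#' @return named list of three `comparison_result` objects:
#'   `control_vs_dmso`, `dmso_vs_drug`, `control_vs_drug`
#' @export
compare_treatments <- function(control, dmso, drug, ...) {
  list(control_vs_dmso = wilcoxon_ranksum(control, dmso,
                                          label_a = "control", label_b = "dmso", ...),
       dmso_vs_drug = wilcoxon_ranksum(dmso, drug,
                                       label_a = "dmso", label_b = "drug", ...),
       control_vs_drug = wilcoxon_ranksum(control, drug,
                                          label_a = "control", label_b = "drug", ...))
}
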