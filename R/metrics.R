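#' Dice score coefficient between two binary masks
#'
#' 2|A intersect B| / (|A| + |B|). Two empty masks score 1 (with a warning),
#' matching the convention that an absent structure correctly predicted
#' absent is a perfect overlap.
#'
#' @param A,B `binary_mask`s on the same grid.
#' @return Dice score in [0, 1].
#' @export
dice <- function(A, B) {
  if (!same_grid(A$grid, B$grid))
    stop_resectr("masks are on different grids", "resectr_grid_mismatch")
  na <- sum(A$values)
  nb <- sum(B$values)
  if (na + nb == 0L) {
    warning("both masks are empty; Dice defined as 1")
    return(1)
  }
  2 * sum(A$values * B$values) / (na + nb)
}

#' Threshold a probability volume into a binary mask
#'
#' A voxel is positive iff its value is greater than or equal to the
#' threshold (ties count as positive).
#'
#' @param probabilities A `scalar_volume`.
#' @param t Threshold, default 0.5.
#' @return A `binary_mask`.
#' @export
threshold_prediction <- function(probabilities, t = 0.5) {
  binary_mask(probabilities$values >= t, probabilities$grid)
}

#' Keep only the largest connected component
#'
#' Components use 26-connectivity; among equally sized components the one
#' containing the lowest linear voxel index is kept. An empty mask is
#' returned unchanged.
#'
#' @param mask A `binary_mask`.
#' @return A `binary_mask` with at most one component.
#' @export
keep_largest_component <- function(mask) {
  lab <- label_components_cpp(as.logical(mask$values), mask$grid$shape)
  if (all(lab == 0L)) return(mask)
  sizes <- tabulate(lab)
  best <- which.max(sizes) # first-voxel order breaks ties at the lowest index
  binary_mask(array(as.integer(lab == best), dim = mask$grid$shape), mask$grid)
}

# Exact null distribution of the Mann-Whitney U statistic: number of
# arrangements with U = u for sample sizes m, n (no ties), by the standard
# counting recurrence.
u_distribution <- function(m, n) {
  maxu <- m * n
  counts <- c(1, rep(0, maxu)) # f(u) for m' = 0
  # recurrence over adding each of the m x-observations
  # f_{m,n}(u) = f_{m-1,n}(u - n) + f_{m,n-1}(u) is awkward; use the
  # generating function: prod_{i=1}^{m} (1 - q^(n+i)) / (1 - q^i)
  # implemented as iterative polynomial updates.
  poly <- 1
  counts <- rep(0, maxu + 1)
  counts[1] <- 1
  for (i in seq_len(m)) {
    # multiply by (1 + q + ... + q^(n)) restricted appropriately via
    # divide by (1 - q^i), multiply by (1 - q^(n+i))
    # divide: prefix sums with stride i
    for (u in seq_len(maxu + 1 - i)) counts[u + i] <- counts[u + i] + counts[u]
    # multiply by (1 - q^(n+i))
    if (n + i <= maxu) {
      for (u in rev(seq_len(maxu + 1 - (n + i))))
        counts[u + n + i] <- counts[u + n + i] - counts[u]
    }
  }
  counts # counts[u + 1] = #arrangements with U = u
}

#' One-tailed Mann-Whitney U test
#'
#' U counts, over all pairs, how often an `xs` observation exceeds a `ys`
#' observation (ties count half). The one-tailed p-value is exact (by
#' enumeration of the null U distribution) when n1 * n2 <= 400 and there are
#' no ties across samples, and otherwise uses the normal approximation with
#' tie correction and continuity correction.
#'
#' @param xs,ys Numeric samples.
#' @param alternative `"less"` tests whether `xs` is stochastically smaller
#'   than `ys`; `"greater"` the reverse. There is no default: the direction
#'   must be stated explicitly.
#' @return List with `U` (for `xs`), `p.value`, and `method`.
#' @export
mann_whitney_one_tailed <- function(xs, ys, alternative) {
  alternative <- match.arg(alternative, c("less", "greater"))
  if (length(xs) == 0L || length(ys) == 0L)
    stop_resectr("samples must be non-empty", "resectr_empty_sample")
  m <- length(xs)
  n <- length(ys)
  r <- rank(c(xs, ys))
  u_x <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(c(xs, ys)) > 0L
  if (!has_ties && m * n <= 400) {
    counts <- u_distribution(m, n)
    total <- sum(counts)
    p <- if (alternative == "less")
      sum(counts[seq_len(u_x + 1)]) / total          # P(U <= u_x)
    else
      sum(counts[(u_x + 1):(m * n + 1)]) / total     # P(U >= u_x)
    method <- "exact"
  } else {
    mu <- m * n / 2
    tie_sizes <- table(c(xs, ys))
    tie_term <- sum(tie_sizes^3 - tie_sizes) / ((m + n) * (m + n - 1))
    sigma <- sqrt(m * n / 12 * ((m + n + 1) - tie_term))
    z <- if (alternative == "less") (u_x - mu + 0.5) / sigma
         else (u_x - mu - 0.5) / sigma
    p <- if (alternative == "less") stats::pnorm(z) else
      stats::pnorm(z, lower.tail = FALSE)
    method <- "normal approximation"
  }
  list(U = u_x, p.value = p, method = method)
}

#' Bonferroni-style significance threshold for n experiments
#'
#' alpha / (n * (n - 1)): the correction uses the count of ordered
#' experiment pairs. `conventional = TRUE` instead divides by the number of
#' unordered comparisons n * (n - 1) / 2.
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param n Number of experiments (>= 2).
#' @param conventional Use the unordered-pair denominator.
#' @return Corrected per-test threshold.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n, conventional = FALSE) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_resectr("alpha must be in (0, 1)", "resectr_bad_alpha_level")
  n <- as.integer(n)
  if (is.na(n) || n < 2L)
    stop_resectr("n must be >= 2", "resectr_bad_alpha_level")
  denom <- if (conventional) n * (n - 1) / 2 else n * (n - 1)
  alpha / denom
}

#' Median and interquartile range of a sample
#'
#' Quantiles use linear interpolation (R's default type 7).
#'
#' @param values Non-empty numeric sample.
#' @return A `summary_stat` with fields `median` and `iqr`.
#' @export
median_iqr <- function(values) {
  if (length(values) == 0L || anyNA(values))
    stop_resectr("sample must be non-empty and complete", "resectr_empty_sample")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(median = q[2], iqr = q[3] - q[1]), class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("%.1f (%.1f)\n", x$median, x$iqr))
  invisible(x)
}

#' Per-case Dice evaluation table
#'
#' Convenience wrapper reproducing the evaluation protocol: threshold the
#' prediction at 0.5, optionally keep only the largest connected component,
#' and report the Dice score against the reference.
#'
#' @param pred A `scalar_volume` of probabilities or a `binary_mask`.
#' @param truth Reference `binary_mask`.
#' @param threshold Probability threshold.
#' @param largest_component Apply largest-component postprocessing.
#' @return The Dice score.
#' @export
evaluate_segmentation <- function(pred, truth, threshold = 0.5,
                                  largest_component = FALSE) {
  mask <- if (inherits(pred, "binary_mask")) pred
          else threshold_prediction(pred, threshold)
  if (largest_component) mask <- keep_largest_component(mask)
  dice(mask, truth)
}
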