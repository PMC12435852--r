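#' Distance-binned enrichment profile across the DZ-LZ boundary
#'
#' Bins cells by signed boundary distance into `bin_width`-micrometre
#' increments over `range` (default -100 um, DZ side, to +100 um, LZ side;
#' 20 bins) and computes the mean of a per-cell value in each bin. Bins are
#' half-open `[lo, hi)` except the last, which is closed at the upper range
#' limit. With the default 0/1 subtype indicator the bin mean is the subtype
#' fraction. Cells outside the range are excluded; empty bins are recorded
#' with `n = 0` and skipped by the regression.
#'
#' @param distances signed boundary distances in micrometres.
#' @param values per-cell enrichment value, same length (0/1 indicator or a
#'   continuous score).
#' @param range two-element numeric range.
#' @param bin_width bin width in micrometres.
#' @return an `enrichment_profile`: list with `bin_edges`, `bin_centers`,
#'   `bin_means` (NA for empty bins), `bin_n`, `range`, `bin_width`.
#' @export
enrichment_profile <- function(distances, values = rep(1, length(distances)),
                               range = c(-100, 100), bin_width = 10) {
  if (length(distances) != length(values))
    stop("distances and values must be aligned")
  edges <- seq(range[1], range[2], by = bin_width)
  n_bins <- length(edges) - 1
  bin <- bin_index(distances, range, bin_width)
  keep <- !is.na(bin)
  if (!any(keep)) stop("no cells fall inside the profiling range")
  bin_n <- tabulate(bin[keep], n_bins)
  sums <- rep(0, n_bins)
  agg <- tapply(values[keep], bin[keep], sum)
  sums[as.integer(names(agg))] <- agg
  means <- ifelse(bin_n > 0, sums / bin_n, NA_real_)
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 bin_means = means, bin_n = bin_n,
                 range = range, bin_width = bin_width),
            class = "enrichment_profile")
}

# half-open [lo, hi) bins, last bin closed at range[2]; NA outside range
bin_index <- function(d, range, bin_width) {
  n_bins <- as.integer(round(diff(range) / bin_width))
  idx <- floor((d - range[1]) / bin_width) + 1
  idx[d == range[2]] <- n_bins
  idx[d < range[1] | d > range[2]] <- NA
  as.integer(idx)
}

#' Fit the enrichment-versus-distance slope
#'
#' Unweighted ordinary least squares of the bin means on the bin centers
#' (micrometres), over non-empty bins only.
#'
#' @param profile an [enrichment_profile].
#' @return list with `slope` (enrichment per um), `intercept` and
#'   `n_bins_used`.
#' @export
fit_slope <- function(profile) {
  ok <- profile$bin_n > 0
  if (sum(ok) < 2)
    stop("need at least 2 non-empty bins to fit a slope (have ", sum(ok), ")")
  fit <- stats::lm.fit(cbind(1, profile$bin_centers[ok]),
                       profile$bin_means[ok])
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       n_bins_used = sum(ok))
}

#' Monte-Carlo null envelope for the enrichment slope
#'
#' Simulates complete spatial randomness for a subtype of fixed size: in
#' each of `n_sim` replicates the subtype label is assigned to a uniformly
#' random subset of the observed cell positions (total count fixed), the
#' binned indicator profile is recomputed and its slope refitted. The
#' `(alpha/2, 1 - alpha/2)` percentiles of the null slopes form the
#' confidence envelope used by [call_trend].
#'
#' @param distances signed boundary distances of ALL cells inside the
#'   profiling range (out-of-range cells are dropped here).
#' @param subtype_count number of subtype cells (fixed across replicates).
#' @param n_sim number of Monte-Carlo replicates (>= 100; default 10000).
#' @param seed integer seed.
#' @param alpha envelope level (default 0.05 for a 95% envelope).
#' @param range,bin_width as in [enrichment_profile].
#' @return list with `null_slopes`, `ci_low`, `ci_high`, `alpha`, `n_sim`.
#' @export
mc_envelope <- function(distances, subtype_count, n_sim = 10000, seed = 1,
                        alpha = 0.05, range = c(-100, 100), bin_width = 10) {
  bin <- bin_index(distances, range, bin_width)
  bin <- bin[!is.na(bin)]
  n <- length(bin)
  if (subtype_count <= 0) stop("subtype_count must be positive")
  if (subtype_count > n)
    stop("subtype_count (", subtype_count, ") exceeds the ", n,
         " cells inside the range")
  if (n_sim < 100) stop("n_sim must be at least 100")
  n_bins <- as.integer(round(diff(range) / bin_width))
  bin_n <- tabulate(bin, n_bins)
  ok <- bin_n > 0
  if (sum(ok) < 2) stop("fewer than 2 non-empty bins")
  x <- ((seq_len(n_bins) - 0.5) * bin_width + range[1])[ok]
  xc <- x - mean(x)
  # slope = sum(coef * subtype counts per non-empty bin); closed-form OLS
  coef <- (xc / sum(xc^2)) / bin_n[ok]
  null_slopes <- withr::with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      cnt <- tabulate(bin[sample.int(n, subtype_count)], n_bins)
      sum(coef * cnt[ok])
    }, numeric(1))
  })
  ci <- stats::quantile(null_slopes, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  list(null_slopes = null_slopes, ci_low = ci[1], ci_high = ci[2],
       alpha = alpha, n_sim = n_sim)
}

#' Three-way trend call against the Monte-Carlo envelope
#'
#' @param slope observed enrichment slope.
#' @param envelope a [mc_envelope] result.
#' @return `"increasing"` (slope above the upper envelope limit: enrichment
#'   rises from DZ into LZ), `"decreasing"` (below the lower limit) or
#'   `"random"` (inside the envelope).
#' @export
call_trend <- function(slope, envelope) {
  if (slope > envelope$ci_high) "increasing"
  else if (slope < envelope$ci_low) "decreasing"
  else "random"
}

#' Full enrichment-trend analysis for one subtype
#'
#' Convenience wrapper: profiles the subtype indicator across the boundary,
#' fits the observed slope, builds the Monte-Carlo envelope and calls the
#' trend.
#'
#' @param distances signed boundary distances for all cells.
#' @param is_subtype logical/0-1 subtype membership per cell.
#' @param n_sim,seed,alpha,range,bin_width see [mc_envelope].
#' @return list with `profile`, `slope`, `intercept`, `envelope`, `trend`
#'   and `n_subtype_in_range`.
#' @export
enrichment_trend <- function(distances, is_subtype, n_sim = 10000, seed = 1,
                             alpha = 0.05, range = c(-100, 100),
                             bin_width = 10) {
  inside <- distances >= range[1] & distances <= range[2]
  if (!any(inside)) stop("no cells fall inside the profiling range")
  d <- distances[inside]
  ind <- as.numeric(is_subtype)[inside]
  if (sum(ind) == 0) stop("no subtype cells inside the profiling range")
  prof <- enrichment_profile(d, ind, range = range, bin_width = bin_width)
  fit <- fit_slope(prof)
  env <- mc_envelope(d, sum(ind), n_sim = n_sim, seed = seed, alpha = alpha,
                     range = range, bin_width = bin_width)
  list(profile = prof, slope = fit$slope, intercept = fit$intercept,
       envelope = env, trend = call_trend(fit$slope, env),
       n_subtype_in_range = sum(ind))
}

# nearest-neighbor distance from each row of a to the rows of b
nn_dist <- function(a, b) {
  out <- rep(Inf, nrow(a))
  chunk <- 1024L
  for (s in seq(1L, nrow(b), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(b))
    d2 <- outer(a[, 1], b[idx, 1], "-")^2 + outer(a[, 2], b[idx, 2], "-")^2
    out <- pmin(out, apply(d2, 1, min))
  }
  sqrt(out)
}

#' Nearest-neighbor immune-exclusion test
#'
#' Compares the observed nearest-neighbor distances from each A cell to the
#' B cells against randomized controls: the A/B labels are permuted over the
#' pooled observed positions (group sizes fixed) `n_rand` times, the
#' nearest-neighbor distances recomputed and pooled into the null sample.
#' Observed and null distances are compared with a two-sided Wilcoxon
#' rank-sum test. Direction is `"excluded"` when the observed median exceeds
#' the null median with `p < alpha` (A cells sit farther from B cells than
#' chance allows), `"attracted"` for the opposite significant shift, and
#' `"neutral"` otherwise.
#'
#' @param points_a,points_b two-column matrices or data.frames of x/y
#'   positions in micrometres.
#' @param n_rand number of label permutations (default 100).
#' @param seed integer seed.
#' @param alpha significance level for the direction call.
#' @return an `exclusion_result`: list with `observed_nn`, `null_nn`,
#'   `p_value`, `direction`, `median_observed`, `median_null`, `n_rand`.
#' @export
#' @examples
#' nn_exclusion_test(cbind(0, 0), cbind(3, 4), n_rand = 100)$observed_nn
nn_exclusion_test <- function(points_a, points_b, n_rand = 100, seed = 1,
                              alpha = 0.05) {
  a <- as.matrix(points_a); b <- as.matrix(points_b)
  if (!nrow(a)) stop("points_a is empty")
  if (!nrow(b)) stop("points_b is empty")
  observed <- nn_dist(a, b)
  pool <- rbind(a, b)
  na <- nrow(a); np <- nrow(pool)
  null_nn <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_rand), function(r) {
      ia <- sample.int(np, na)
      nn_dist(pool[ia, , drop = FALSE], pool[-ia, , drop = FALSE])
    }))
  })
  # exact enumeration for small samples, normal approximation with
  # continuity correction otherwise (wilcox.test default switch)
  p <- suppressWarnings(
    stats::wilcox.test(observed, null_nn, correct = TRUE)$p.value)
  if (!is.finite(p)) p <- 1  # zero-variance rank statistic (all ties)
  med_o <- stats::median(observed); med_n <- stats::median(null_nn)
  direction <- if (p < alpha && med_o > med_n) "excluded"
  else if (p < alpha && med_o < med_n) "attracted"
  else "neutral"
  structure(list(observed_nn = observed, null_nn = null_nn, p_value = p,
                 direction = direction, median_observed = med_o,
                 median_null = med_n, n_rand = n_rand),
            class = "exclusion_result")
}

#' Right-continuous empirical cumulative distribution function
#'
#' @param values numeric vector with at least one finite value.
#' @return a step function (as from [stats::ecdf]); evaluated at
#'   `max(values)` it returns 1.
#' @export
empirical_cdf <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("empirical_cdf needs at least one finite value")
  stats::ecdf(values)
}
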