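#' Normalize a count matrix for signature scoring
#'
#' Per-cell total-count scaling to the median library size, `log1p`
#' transform, then per-gene z-scaling (mean 0, SD 1 across cells). Genes that
#' are constant across cells map to 0.
#'
#' @param ct a [cell_table] (QC-filtered; a zero-total cell is an error).
#' @return dense cells-by-genes matrix of z-scaled log expression, with
#'   dimnames carried over from the counts.
#' @export
normalize_cells <- function(ct) {
  totals <- Matrix::rowSums(ct$counts)
  if (any(totals == 0))
    stop(sum(totals == 0), " cell(s) have zero total counts; run qc_filter first")
  target <- stats::median(totals)
  scaled <- as.matrix(ct$counts / totals * target)
  lg <- log1p(scaled)
  mu <- colMeans(lg)
  sd <- apply(lg, 2, stats::sd)
  z <- sweep(lg, 2, mu, "-")
  z <- sweep(z, 2, ifelse(sd > 0, sd, 1), "/")
  z[, sd == 0] <- 0
  dimnames(z) <- dimnames(ct$counts)
  z
}

# match signature genes against matrix columns (case-sensitive exact symbols);
# unmatched genes are reported and skipped
match_signature <- function(normalized, signature) {
  hit <- signature$genes %in% colnames(normalized)
  if (!any(hit))
    stop("no gene of signature '", signature$name,
         "' is present in the expression matrix")
  if (any(!hit))
    message("signature '", signature$name, "': ", sum(!hit), " of ",
            length(hit), " genes absent from the matrix (",
            round(100 * mean(!hit), 1), "%), skipped")
  signature$genes[hit]
}

#' Score a gene signature per cell
#'
#' Default method `"mean_z"`: the score is the mean of the z-scaled
#' expression values over the signature genes present in the matrix. Method
#' `"ctrl_bins"` subtracts, for each signature gene, the mean of `n_ctrl`
#' control genes drawn from the same average-expression bin (of `n_bins`
#' bins), the control-gene practice common in single-cell module scoring;
#' the draw is seeded and deterministic.
#'
#' @param normalized matrix from [normalize_cells] (cells x genes).
#' @param signature a [gene_signature].
#' @param method `"mean_z"` or `"ctrl_bins"`.
#' @param n_bins,n_ctrl control-bin parameters for `"ctrl_bins"`.
#' @param seed seed for the control-gene draw.
#' @return numeric score per cell (named by cell id).
#' @export
score_signature <- function(normalized, signature,
                            method = c("mean_z", "ctrl_bins"),
                            n_bins = 25, n_ctrl = 50, seed = 1) {
  method <- match.arg(method)
  genes <- match_signature(normalized, signature)
  if (method == "mean_z")
    return(rowMeans(normalized[, genes, drop = FALSE]))
  avg <- colMeans(normalized)
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bins) <- colnames(normalized)
  ctrl_means <- withr::with_seed(seed, {
    vapply(genes, function(g) {
      pool <- setdiff(names(bins)[bins == bins[g]], g)
      if (!length(pool)) pool <- g
      ctrl <- sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
      rowMeans(normalized[, ctrl, drop = FALSE])
    }, numeric(nrow(normalized)))
  })
  rowMeans(normalized[, genes, drop = FALSE] - ctrl_means)
}

#' Classify cells by the combined DZ-LZ score
#'
#' The combined score is `dz_score - lz_score`. A highly positive combined
#' score (> `upper`, default 0.3) yields a DZ phenotype, a highly negative one
#' (< `lower`, default -0.3) an LZ phenotype, and everything in between the
#' intermediate (INT) phenotype.
#'
#' @param dz_score,lz_score numeric per-cell signature scores, equal length.
#' @param upper,lower classification thresholds on the combined score.
#' @return a `zone_annotation` data.frame with columns `dz_score`,
#'   `lz_score`, `dzlz_score`, `phenotype` (`"DZ"`, `"LZ"`, `"INT"`) and
#'   `region` (initialised to `"unassigned"`, filled by [iterative_smooth]).
#' @export
#' @examples
#' classify_cells(c(0.8, 0.1, 0), c(0.3, 0.1, 0.31))$phenotype
classify_cells <- function(dz_score, lz_score, upper = 0.3, lower = -0.3) {
  if (length(dz_score) != length(lz_score))
    stop("dz_score and lz_score must have equal length")
  if (!all(is.finite(dz_score)) || !all(is.finite(lz_score)))
    stop("scores must be finite")
  if (upper <= lower) stop("upper threshold must exceed lower threshold")
  dzlz <- dz_score - lz_score
  phenotype <- ifelse(dzlz > upper, "DZ", ifelse(dzlz < lower, "LZ", "INT"))
  ann <- data.frame(dz_score = dz_score, lz_score = lz_score,
                    dzlz_score = dzlz, phenotype = phenotype,
                    region = "unassigned", stringsAsFactors = FALSE)
  if (!is.null(names(dz_score))) rownames(ann) <- names(dz_score)
  class(ann) <- c("zone_annotation", "data.frame")
  ann
}

#' Stratify bulk samples into DZ-like, LZ-like and intermediate groups
#'
#' Per-sample signature scores are means of per-gene z-scores (computed
#' across samples) over the signature genes. The default `"tertile"` rule
#' ranks samples by `dz_score - lz_score` and assigns the top third to
#' DZ-like, the bottom third to LZ-like and the remainder to intermediate;
#' `"kmeans"` clusters the combined score into three groups ordered by their
#' centers.
#'
#' @param expr genes-by-samples numeric matrix (log scale or otherwise
#'   comparable across samples).
#' @param dz_sig,lz_sig [gene_signature] objects.
#' @param rule `"tertile"` or `"kmeans"`.
#' @param seed seed for the k-means initialisation.
#' @return a `bulk_stratification` data.frame with per-sample `dz_score`,
#'   `lz_score`, `dzlz_score` and `group`; the grouping rule and cut points
#'   are stored in the `grouping_rule` attribute.
#' @export
stratify_bulk <- function(expr, dz_sig, lz_sig,
                          rule = c("tertile", "kmeans"), seed = 1) {
  rule <- match.arg(rule)
  if (ncol(expr) < 2) stop("bulk stratification needs at least 2 samples")
  z <- t(scale(t(expr)))
  z[is.na(z)] <- 0  # constant genes
  sample_score <- function(sig) {
    genes <- sig$genes[sig$genes %in% rownames(z)]
    if (!length(genes))
      stop("no gene of signature '", sig$name, "' is present in the matrix")
    colMeans(z[genes, , drop = FALSE])
  }
  dz <- sample_score(dz_sig)
  lz <- sample_score(lz_sig)
  dzlz <- dz - lz
  n <- ncol(expr)
  if (rule == "tertile") {
    if (n < 3) stop("tertile rule needs at least 3 samples")
    k <- floor(n / 3)
    r <- rank(dzlz, ties.method = "first")
    group <- rep("intermediate", n)
    group[r <= k] <- "LZ-like"
    group[r > n - k] <- "DZ-like"
    rule_meta <- list(rule = "tertile", group_size = k,
                      cuts = c(sort(dzlz)[k], sort(dzlz)[n - k]))
  } else {
    km <- withr::with_seed(seed, stats::kmeans(dzlz, centers = 3, nstart = 10))
    ord <- order(km$centers)  # ascending: LZ-like, intermediate, DZ-like
    lab <- character(3)
    lab[ord] <- c("LZ-like", "intermediate", "DZ-like")
    group <- lab[km$cluster]
    rule_meta <- list(rule = "kmeans", centers = sort(as.numeric(km$centers)))
  }
  out <- data.frame(sample = colnames(expr), dz_score = dz, lz_score = lz,
                    dzlz_score = dzlz, group = group,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "grouping_rule") <- rule_meta
  class(out) <- c("bulk_stratification", "data.frame")
  out
}
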