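#' Subtype specification for the synthetic generator
#'
#' Describes one cell subtype to be planted in a synthetic germinal center:
#' either carrying a logistic enrichment gradient across the DZ-LZ boundary
#' (probability of membership follows `plogis(alpha + beta * d)` in the signed
#' boundary distance `d`, with `alpha` calibrated so the expected subtype size
#' equals `n_cells`) or spatially uniform (complete spatial randomness, drawn
#' exactly as `n_cells` cells).
#'
#' @param name subtype label written into the cell metadata.
#' @param n_cells target number of subtype cells.
#' @param gradient_beta logistic slope per micrometre of signed boundary
#'   distance (positive = enrichment increasing from DZ into LZ). Ignored for
#'   `gradient_type = "uniform"`.
#' @param gradient_type `"logistic"` or `"uniform"`.
#' @return a `subtype_spec` list.
#' @export
subtype_spec <- function(name, n_cells, gradient_beta = 0,
                         gradient_type = c("logistic", "uniform")) {
  gradient_type <- match.arg(gradient_type)
  stopifnot(is.character(name), length(name) == 1, n_cells > 0,
            is.finite(gradient_beta))
  structure(list(name = name, n_cells = as.integer(n_cells),
                 gradient_beta = gradient_beta,
                 gradient_type = gradient_type), class = "subtype_spec")
}

#' Configuration for the synthetic germinal-center generator
#'
#' The generator emulates the tissue structure assumed by the zonation
#' pipeline: cells uniform in a disc, a straight chord boundary splitting the
#' disc into a dark-zone and a light-zone side, zone-shifted negative-binomial
#' expression for signature genes, and planted T-cell-like subtypes with known
#' spatial gradients.
#'
#' @param n_cells number of cells in the disc.
#' @param gc_radius disc radius in micrometres.
#' @param boundary_angle direction of the boundary chord, radians.
#' @param dz_fraction fraction of the disc area on the DZ side; the chord
#'   offset from the center is solved from this (0.5 puts the chord through
#'   the center).
#' @param signature_effect natural-log fold change applied to the zone mean of
#'   in-zone signature genes; with the default dispersion this is
#'   approximately the shift in per-gene log-expression SD units.
#' @param label_noise proportion of cells whose expression is drawn from the
#'   opposite zone's profile (their geometric zone stays in the truth table),
#'   emulating imperfect zone phenotypes. Must be in [0, 0.5).
#' @param subtypes list of [subtype_spec] objects.
#' @param n_dz_genes,n_lz_genes,n_background_genes gene-panel composition.
#' @param base_mean baseline negative-binomial mean per gene.
#' @param gene_mean_sdlog lognormal SD of per-gene baseline means around
#'   `base_mean` (0 for identical genes).
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed; variance is `mu + mu^2 / dispersion`).
#' @param seed integer seed; generation is fully reproducible given the seed.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_cells = 2000, gc_radius = 150,
                             boundary_angle = 0, dz_fraction = 0.5,
                             signature_effect = 1.5, label_noise = 0,
                             subtypes = list(), n_dz_genes = 50,
                             n_lz_genes = 50, n_background_genes = 100,
                             base_mean = 4, gene_mean_sdlog = 0.25,
                             dispersion = 1, seed = 1) {
  cfg <- list(n_cells = as.integer(n_cells), gc_radius = gc_radius,
              boundary_angle = boundary_angle, dz_fraction = dz_fraction,
              signature_effect = signature_effect, label_noise = label_noise,
              subtypes = subtypes, n_dz_genes = as.integer(n_dz_genes),
              n_lz_genes = as.integer(n_lz_genes),
              n_background_genes = as.integer(n_background_genes),
              base_mean = base_mean, gene_mean_sdlog = gene_mean_sdlog,
              dispersion = dispersion, seed = as.integer(seed))
  num <- unlist(cfg[c("n_cells", "gc_radius", "boundary_angle", "dz_fraction",
                      "signature_effect", "label_noise", "base_mean",
                      "gene_mean_sdlog", "dispersion")])
  if (!all(is.finite(num))) stop("non-finite configuration parameter")
  if (cfg$n_cells <= 0) stop("n_cells must be positive")
  if (cfg$gc_radius <= 0 || cfg$dispersion <= 0 || cfg$base_mean <= 0)
    stop("gc_radius, dispersion and base_mean must be positive")
  if (cfg$dz_fraction <= 0 || cfg$dz_fraction >= 1)
    stop("dz_fraction must lie strictly inside (0, 1)")
  if (cfg$label_noise < 0 || cfg$label_noise >= 0.5)
    stop("label_noise must lie in [0, 0.5)")
  if (!all(vapply(subtypes, inherits, TRUE, "subtype_spec")))
    stop("subtypes must be a list of subtype_spec objects")
  if (length(subtypes) &&
      sum(vapply(subtypes, `[[`, 1L, "n_cells")) > cfg$n_cells)
    stop("subtype cell counts exceed n_cells")
  class(cfg) <- "synthetic_config"
  cfg
}

# chord offset (along the boundary normal) at which the fraction of disc area
# on the negative side equals `fraction`; circular-segment area inverted by
# uniroot
chord_offset <- function(fraction, radius) {
  if (abs(fraction - 0.5) < 1e-12) return(0)
  area_below <- function(c) {
    seg_above <- radius^2 * acos(pmin(pmax(c / radius, -1), 1)) -
      c * sqrt(pmax(radius^2 - c^2, 0))
    1 - seg_above / (pi * radius^2)
  }
  stats::uniroot(function(c) area_below(c) - fraction,
                 c(-radius + 1e-9, radius - 1e-9), tol = 1e-10)$root
}

#' Generate a synthetic germinal center with known zone structure
#'
#' Cells are placed uniformly in a disc of `gc_radius`. A straight chord with
#' direction `boundary_angle`, offset so that `dz_fraction` of the disc area
#' lies on its DZ side, defines the true zone of every cell (negative signed
#' distance = DZ). Counts are negative-binomial; DZ-signature genes have their
#' mean multiplied by `exp(signature_effect)` in DZ cells and LZ-signature
#' genes in LZ cells. Subtype membership is sampled over the generated cells
#' (so subtypes inherit the tissue geometry): logistic subtypes by independent
#' Bernoulli draws with probability `plogis(alpha + beta * d)` calibrated to
#' the target size, uniform (CSR) subtypes as an exact-size simple random
#' sample.
#'
#' @param config a [synthetic_config].
#' @return a list with elements:
#'   \describe{
#'     \item{cells}{a [cell_table] with a `subtype` metadata column
#'       (`"none"` for unassigned cells).}
#'     \item{truth}{data.frame with `cell_id`, `true_zone`, `true_distance`
#'       (signed micrometres from the analytic boundary, negative = DZ),
#'       `subtype`, `noise_flipped`.}
#'     \item{boundary_true}{analytic boundary: list(angle, offset, normal,
#'       point) where `point` is a point on the line and `normal` the unit
#'       normal pointing into the LZ.}
#'     \item{signatures}{list of [gene_signature] `DZ` and `LZ` matching the
#'       generated panel.}
#'     \item{gradient_params}{per-subtype data.frame of the beta/alpha used
#'       and realized sizes.}
#'     \item{config}{the configuration, echoed.}
#'   }
#' @export
#' @examples
#' sim <- generate_gc(synthetic_config(n_cells = 300, seed = 7))
#' table(sim$truth$true_zone)
generate_gc <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_gc_impl(config))
}

generate_gc_impl <- function(cfg) {
  n <- cfg$n_cells
  r <- cfg$gc_radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  x <- r * cos(th); y <- r * sin(th)

  u <- c(cos(cfg$boundary_angle), sin(cfg$boundary_angle))  # chord direction
  nrm <- c(-u[2], u[1])                                     # unit normal (LZ side)
  off <- chord_offset(cfg$dz_fraction, cfg$gc_radius)
  d_true <- x * nrm[1] + y * nrm[2] - off
  true_zone <- ifelse(d_true < 0, "DZ", "LZ")

  flipped <- stats::runif(n) < cfg$label_noise
  expr_zone <- ifelse(flipped, ifelse(true_zone == "DZ", "LZ", "DZ"), true_zone)

  gene_ids <- c(sprintf("DZS%03d", seq_len(cfg$n_dz_genes)),
                sprintf("LZS%03d", seq_len(cfg$n_lz_genes)),
                sprintf("BG%04d", seq_len(cfg$n_background_genes)))
  n_genes <- length(gene_ids)
  base_mu <- cfg$base_mean *
    exp(stats::rnorm(n_genes, 0, cfg$gene_mean_sdlog) - cfg$gene_mean_sdlog^2 / 2)
  is_dz_gene <- seq_len(n_genes) <= cfg$n_dz_genes
  is_lz_gene <- seq_len(n_genes) > cfg$n_dz_genes &
    seq_len(n_genes) <= cfg$n_dz_genes + cfg$n_lz_genes

  mu <- matrix(base_mu, n, n_genes, byrow = TRUE)
  in_dz <- expr_zone == "DZ"
  shift <- exp(cfg$signature_effect)
  mu[in_dz, is_dz_gene] <- mu[in_dz, is_dz_gene] * shift
  mu[!in_dz, is_lz_gene] <- mu[!in_dz, is_lz_gene] * shift
  counts <- matrix(stats::rnbinom(n * n_genes, mu = mu, size = cfg$dispersion),
                   n, n_genes)

  subtype <- rep("none", n)
  grad <- data.frame(name = character(), beta = numeric(), alpha = numeric(),
                     target_n = integer(), realized_n = integer(),
                     gradient_type = character(), stringsAsFactors = FALSE)
  for (sp in cfg$subtypes) {
    free <- which(subtype == "none")
    if (sp$n_cells > length(free))
      stop("subtype '", sp$name, "' requests ", sp$n_cells,
           " cells but only ", length(free), " remain unassigned")
    if (sp$gradient_type == "uniform" || sp$gradient_beta == 0) {
      take <- sample(free, sp$n_cells)
      alpha <- NA_real_
    } else {
      d <- d_true[free]
      expected <- function(a) sum(stats::plogis(a + sp$gradient_beta * d))
      lo <- -50; hi <- 50
      alpha <- stats::uniroot(function(a) expected(a) - sp$n_cells,
                              c(lo, hi), tol = 1e-8)$root
      p <- stats::plogis(alpha + sp$gradient_beta * d)
      take <- free[stats::runif(length(free)) < p]
    }
    subtype[take] <- sp$name
    grad <- rbind(grad, data.frame(
      name = sp$name, beta = sp$gradient_beta, alpha = alpha,
      target_n = sp$n_cells, realized_n = length(take),
      gradient_type = sp$gradient_type, stringsAsFactors = FALSE))
  }

  cell_ids <- sprintf("cell_%05d", seq_len(n))
  cells <- cell_table(cell_ids, x, y, counts, gene_ids,
                      metadata = data.frame(subtype = subtype,
                                            stringsAsFactors = FALSE))
  truth <- data.frame(cell_id = cell_ids, true_zone = true_zone,
                      true_distance = d_true, subtype = subtype,
                      noise_flipped = flipped, stringsAsFactors = FALSE)
  sigs <- list(
    DZ = gene_signature("DZ", gene_ids[is_dz_gene], "DZ_up"),
    LZ = gene_signature("LZ", gene_ids[is_lz_gene], "LZ_up"))
  list(cells = cells, truth = truth,
       boundary_true = list(angle = cfg$boundary_angle, offset = off,
                            normal = nrm, point = off * nrm),
       signatures = sigs, gradient_params = grad, config = cfg)
}

#' Write a synthetic germinal center to disk
#'
#' Writes the cell table (MTX + cells.csv + genes.tsv), the truth table
#' (`truth.csv`) and the configuration (`config.json`) into `dir`.
#'
#' @param sim result of [generate_gc].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_synthetic <- function(sim, dir) {
  write_cell_table(sim$cells, dir)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- sim$config
  cfg$subtypes <- lapply(cfg$subtypes, unclass)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a bulk expression cohort with DZ-like and LZ-like classes
#'
#' Genes-by-samples Gaussian log-expression with two latent classes: class 1
#' (DZ-like) has DZ-signature genes shifted up and LZ-signature genes shifted
#' down by `effect` SD units; class 2 is the mirror image. Used to validate
#' bulk stratification.
#'
#' @param n_samples number of samples.
#' @param effect class shift in SD units of per-gene expression.
#' @param class_fraction fraction of samples in class 1 (DZ-like).
#' @param dz_genes,lz_genes,background_genes gene symbol vectors.
#' @param seed integer seed.
#' @return list with `expr` (genes x samples matrix), `class` (1 = DZ-like,
#'   2 = LZ-like per sample), and the signatures used.
#' @export
simulate_bulk_cohort <- function(n_samples = 60, effect = 1,
                                 class_fraction = 0.5,
                                 dz_genes = sprintf("DZS%03d", 1:50),
                                 lz_genes = sprintf("LZS%03d", 1:50),
                                 background_genes = sprintf("BG%04d", 1:100),
                                 seed = 1) {
  withr::with_seed(seed, {
    genes <- c(dz_genes, lz_genes, background_genes)
    cls <- rep(2L, n_samples)
    cls[sample(n_samples, round(class_fraction * n_samples))] <- 1L
    expr <- matrix(stats::rnorm(length(genes) * n_samples),
                   length(genes), n_samples,
                   dimnames = list(genes, sprintf("sample_%03d", 1:n_samples)))
    half <- effect / 2
    expr[dz_genes, cls == 1] <- expr[dz_genes, cls == 1] + half
    expr[dz_genes, cls == 2] <- expr[dz_genes, cls == 2] - half
    expr[lz_genes, cls == 2] <- expr[lz_genes, cls == 2] + half
    expr[lz_genes, cls == 1] <- expr[lz_genes, cls == 1] - half
    list(expr = expr, class = cls,
         signatures = list(DZ = gene_signature("DZ", dz_genes, "DZ_up"),
                           LZ = gene_signature("LZ", lz_genes, "LZ_up")))
  })
}
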