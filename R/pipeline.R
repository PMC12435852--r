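#' Run the full germinal-center zonation pipeline on one tissue
#'
#' Executes, in order: QC filtering, normalization, DZ and LZ signature
#' scoring, phenotype classification by the combined DZ-LZ score, spatial
#' graph construction, iterative neighbor-based region formation, the
#' per-region purity check, boundary extraction, signed boundary distances,
#' and the distance-binned enrichment trend (profile + Monte-Carlo envelope)
#' for every requested cell subtype. Any stage failure aborts with the stage
#' name and the cell count at failure.
#'
#' @param cells a [cell_table] for one (pre-cropped) germinal center.
#' @param dz_sig,lz_sig [gene_signature] objects; default the packaged
#'   synthetic stand-in lists from [gc_signatures].
#' @param subtype_col metadata column holding subtype labels (`"none"` marks
#'   unassigned cells); `NULL` skips the enrichment stage.
#' @param subtypes subtype labels to profile; default all labels present
#'   except `"none"`.
#' @param qc apply [qc_filter] first.
#' @param max_features,min_counts QC thresholds.
#' @param score_method [score_signature] method.
#' @param upper,lower combined-score classification thresholds.
#' @param neighbor_radius,dissimilar_fraction,max_iter graph and smoothing
#'   parameters.
#' @param min_purity per-region purity requirement.
#' @param range,bin_width,n_sim,alpha enrichment-profile parameters.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return a `gczone_report` list with `annotation` (per-cell data.frame:
#'   coordinates, scores, phenotype, region, signed distance, subtype),
#'   `purity`, `boundary`, `trends` (per-subtype [enrichment_trend]
#'   results), `n_cells_in`, `n_cells_qc` and `manifest` (parameters, seed,
#'   software version, timestamp).
#' @export
run_gc_pipeline <- function(cells, dz_sig = NULL, lz_sig = NULL,
                            subtype_col = "subtype", subtypes = NULL,
                            qc = TRUE, max_features = 3000, min_counts = 400,
                            score_method = "mean_z",
                            upper = 0.3, lower = -0.3,
                            neighbor_radius = 30, dissimilar_fraction = 0.5,
                            max_iter = 100, min_purity = 0.70,
                            range = c(-100, 100), bin_width = 10,
                            n_sim = 10000, alpha = 0.05, seed = 1) {
  if (is.null(dz_sig) || is.null(lz_sig)) {
    sigs <- gc_signatures()
    if (is.null(dz_sig)) dz_sig <- sigs$DZ
    if (is.null(lz_sig)) lz_sig <- sigs$LZ
  }
  n_in <- n_cells(cells)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed with ", n_cells(cells),
           " cells: ", conditionMessage(e), call. = FALSE))
  }
  if (qc)
    cells <- stage("qc_filter",
                   qc_filter(cells, max_features = max_features,
                             min_counts = min_counts))
  norm <- stage("normalize", normalize_cells(cells))
  dz_score <- stage("score_signature",
                    score_signature(norm, dz_sig, method = score_method,
                                    seed = seed))
  lz_score <- stage("score_signature",
                    score_signature(norm, lz_sig, method = score_method,
                                    seed = seed + 1L))
  ann <- stage("classify_cells",
               classify_cells(dz_score, lz_score, upper = upper,
                              lower = lower))
  graph <- stage("build_graph", build_graph(cells, neighbor_radius))
  result <- stage("iterative_smooth",
                  iterative_smooth(graph, ann, dissimilar_fraction, max_iter))
  purity <- check_purity(result, min_purity)
  boundary <- stage("extract_boundary",
                    extract_boundary(graph, result, min_purity))
  dist <- stage("signed_distance", signed_distance(cells, boundary, result))

  annotation <- data.frame(cell_id = cells$cell_ids, x = cells$x, y = cells$y,
                           dz_score = dz_score, lz_score = lz_score,
                           dzlz_score = ann$dzlz_score,
                           phenotype = ann$phenotype, region = result$region,
                           boundary_distance = dist,
                           stringsAsFactors = FALSE, row.names = NULL)
  trends <- list()
  if (!is.null(subtype_col) && subtype_col %in% names(cells$metadata)) {
    labels <- cells$metadata[[subtype_col]]
    annotation$subtype <- labels
    if (is.null(subtypes)) subtypes <- setdiff(unique(labels), "none")
    for (k in seq_along(subtypes)) {
      st <- subtypes[k]
      trends[[st]] <- stage(
        paste0("enrichment_trend[", st, "]"),
        enrichment_trend(dist, labels == st, n_sim = n_sim,
                         seed = seed + 100L + k, alpha = alpha,
                         range = range, bin_width = bin_width))
    }
  }
  manifest <- list(
    command = "run_gc_pipeline",
    parameters = list(qc = qc, max_features = max_features,
                      min_counts = min_counts, score_method = score_method,
                      upper = upper, lower = lower,
                      neighbor_radius = neighbor_radius,
                      dissimilar_fraction = dissimilar_fraction,
                      max_iter = max_iter, min_purity = min_purity,
                      range = range, bin_width = bin_width, n_sim = n_sim,
                      alpha = alpha),
    seed = seed,
    software_version = as.character(utils::packageVersion("gczone")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  structure(list(annotation = annotation, purity = purity,
                 boundary = boundary, trends = trends,
                 smoothing = list(n_iterations = result$n_iterations,
                                  converged = result$converged,
                                  changes_per_sweep = result$changes_per_sweep),
                 n_cells_in = n_in, n_cells_qc = n_cells(cells),
                 manifest = manifest),
            class = "gczone_report")
}

#' @export
print.gczone_report <- function(x, ...) {
  cat("<gczone_report> ", x$n_cells_qc, "/", x$n_cells_in,
      " cells after QC; ", x$purity$message, "\n", sep = "")
  for (nm in names(x$trends))
    cat(sprintf("  %s: slope %.3g, trend %s\n", nm, x$trends[[nm]]$slope,
                x$trends[[nm]]$trend))
  invisible(x)
}

# JSON-serializable view of a report (null slope samples summarised)
report_record <- function(report) {
  trends <- lapply(report$trends, function(tr) {
    list(slope = tr$slope, intercept = tr$intercept,
         trend = tr$trend, n_subtype_in_range = tr$n_subtype_in_range,
         bin_centers = tr$profile$bin_centers,
         bin_means = tr$profile$bin_means, bin_n = tr$profile$bin_n,
         ci_low = tr$envelope$ci_low, ci_high = tr$envelope$ci_high,
         alpha = tr$envelope$alpha, n_sim = tr$envelope$n_sim)
  })
  list(annotation = report$annotation,
       purity = report$purity[c("pass", "purity_dz", "purity_lz",
                                "min_purity")],
       boundary_vertices = unname(apply(report$boundary$vertices, 1,
                                        as.numeric, simplify = FALSE)),
       trends = trends, smoothing = report$smoothing,
       n_cells_in = report$n_cells_in, n_cells_qc = report$n_cells_qc,
       manifest = report$manifest)
}

#' Write and read pipeline result reports
#'
#' `write_report` serialises a [run_gc_pipeline] report to JSON (per-cell
#' annotation table, purities, boundary vertices, per-subtype profiles with
#' envelope limits, smoothing diagnostics and the run manifest);
#' `read_report` loads it back as the same record structure.
#'
#' @param report a `gczone_report`.
#' @param path JSON path.
#' @return `write_report`: invisibly, the path; `read_report`: the report
#'   record (a named list).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_record(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
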