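#' Build the spatial cell graph
#'
#' Nodes are cells; an undirected edge joins every pair of cells whose
#' Euclidean distance is at most `neighbor_radius` micrometres. Neighbor
#' search uses spatial grid bucketing, so the full pairwise distance matrix
#' is never formed.
#'
#' @param cells a [cell_table], or any list/data.frame with numeric `x` and
#'   `y` components in micrometres.
#' @param neighbor_radius edge threshold in micrometres (default 30,
#'   roughly 2-3 cell diameters).
#' @return a `spatial_graph`: list with `x`, `y`, `edges` (two-column integer
#'   matrix, `i < j`), `dist` (edge lengths), `radius` and `n`. Isolated
#'   nodes are permitted; their indices are in attribute `isolated`.
#' @export
#' @examples
#' g <- build_graph(data.frame(x = c(0, 10, 40), y = c(0, 0, 0)),
#'                  neighbor_radius = 15)
#' g$edges
build_graph <- function(cells, neighbor_radius = 30) {
  x <- cells$x; y <- cells$y
  if (length(x) < 2) stop("need at least 2 cells to build a graph")
  if (neighbor_radius <= 0) stop("neighbor_radius must be positive")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite cell coordinates")
  n <- length(x)
  r <- neighbor_radius
  bx <- floor(x / r); by <- floor(y / r)
  key <- paste(bx, by)
  buckets <- split(seq_len(n), key)
  bucket_of <- function(kx, ky) buckets[[paste(kx, ky)]]
  ei <- integer(0); ej <- integer(0)
  # each unordered bucket pair visited once: self, E, NW, N, NE
  offsets <- list(c(1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))
  for (k in names(buckets)) {
    a <- buckets[[k]]
    kk <- as.integer(strsplit(k, " ", fixed = TRUE)[[1]])
    # within-bucket pairs
    if (length(a) > 1) {
      pr <- utils::combn(a, 2)
      ei <- c(ei, pr[1, ]); ej <- c(ej, pr[2, ])
    }
    for (off in offsets) {
      b <- bucket_of(kk[1] + off[1], kk[2] + off[2])
      if (!is.null(b)) {
        ei <- c(ei, rep(a, each = length(b)))
        ej <- c(ej, rep(b, times = length(a)))
      }
    }
  }
  d2 <- (x[ei] - x[ej])^2 + (y[ei] - y[ej])^2
  keep <- d2 <= r^2
  ei <- ei[keep]; ej <- ej[keep]; d <- sqrt(d2[keep])
  swap <- ei > ej
  tmp <- ei[swap]; ei[swap] <- ej[swap]; ej[swap] <- tmp
  ord <- order(ei, ej)
  g <- structure(list(x = x, y = y,
                      edges = cbind(i = ei[ord], j = ej[ord]),
                      dist = d[ord], radius = r, n = n),
                 class = "spatial_graph")
  attr(g, "isolated") <- setdiff(seq_len(n), unique(c(ei, ej)))
  g
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("<spatial_graph> ", x$n, " cells, ", nrow(x$edges),
      " edges (radius ", x$radius, " um)\n", sep = "")
  invisible(x)
}

# symmetric sparse adjacency pattern of a spatial_graph
graph_adjacency <- function(graph) {
  e <- graph$edges
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(graph$n, graph$n))
}

#' Iterative neighbor-based region formation
#'
#' Runs synchronous sweeps over the spatial graph until a fixpoint: cells
#' with the intermediate (INT) phenotype take the majority phenotype among
#' their DZ/LZ neighbors (current labels, so assignments propagate inward
#' over sweeps), and a DZ or LZ cell flips when the fraction of its
#' neighbors holding the opposite phenotype among the ORIGINAL calls
#' strictly exceeds `dissimilar_fraction` — a cleanup of isolated
#' misclassified cells that, unlike a flip rule on current labels, cannot
#' erode a genuine region front. Ties and neighbor-less cells keep their
#' current label. Updates within a sweep are simultaneous (Jacobi style), so
#' the result does not depend on cell order. Region purities are computed
#' against the ORIGINAL phenotype calls, which is what makes the purity
#' condition informative.
#'
#' @param graph a [build_graph] result.
#' @param annotation a [classify_cells] result (or any data.frame with a
#'   `phenotype` column of `"DZ"`, `"LZ"`, `"INT"`).
#' @param dissimilar_fraction flip threshold on the opposite-phenotype
#'   neighbor fraction (strict; default 0.5).
#' @param max_iter sweep limit; non-convergence within it is an error.
#' @return a `region_result`: list with `region` (per-cell `"DZ_region"`,
#'   `"LZ_region"` or `"unassigned"` for residual INT cells), `purity_dz`,
#'   `purity_lz`, `n_iterations` (sweeps executed, including the one that
#'   confirms the fixpoint), `converged`, `changes_per_sweep` and
#'   `annotation` (input annotation with the `region` column filled).
#' @export
iterative_smooth <- function(graph, annotation, dissimilar_fraction = 0.5,
                             max_iter = 100) {
  orig <- annotation$phenotype
  if (length(orig) != graph$n)
    stop("annotation has ", length(orig), " cells but the graph has ", graph$n)
  if (!all(orig %in% c("DZ", "LZ", "INT")))
    stop("phenotype labels must be DZ, LZ or INT")
  if (!any(orig == "DZ") || !any(orig == "LZ"))
    stop("need at least one DZ and one LZ cell to form two regions")
  adj <- graph_adjacency(graph)
  deg <- Matrix::rowSums(adj)
  # opposite-phenotype neighbor fractions against the original calls; the
  # flip rule is evaluated on these, not on the evolving labels
  orig_dz_frac <- as.numeric(adj %*% (orig == "DZ")) / pmax(deg, 1)
  orig_lz_frac <- as.numeric(adj %*% (orig == "LZ")) / pmax(deg, 1)
  lab <- orig
  changes <- integer(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    n_dz <- as.numeric(adj %*% (lab == "DZ"))
    n_lz <- as.numeric(adj %*% (lab == "LZ"))
    new <- lab
    is_int <- lab == "INT"
    new[is_int & n_dz > n_lz] <- "DZ"
    new[is_int & n_lz > n_dz] <- "LZ"
    flip_dz <- lab == "DZ" & deg > 0 & orig_lz_frac > dissimilar_fraction
    flip_lz <- lab == "LZ" & deg > 0 & orig_dz_frac > dissimilar_fraction
    new[flip_dz] <- "LZ"
    new[flip_lz] <- "DZ"
    changes <- c(changes, sum(new != lab))
    lab <- new
    if (changes[iter] == 0) { converged <- TRUE; break }
  }
  if (!converged)
    stop("iterative_smooth did not converge within ", max_iter,
         " sweeps (last sweep changed ", changes[length(changes)], " labels)")
  region <- c(DZ = "DZ_region", LZ = "LZ_region", INT = "unassigned")[lab]
  names(region) <- NULL
  purity <- function(reg, phen) {
    inside <- region == reg
    if (!any(inside)) return(NA_real_)
    mean(orig[inside] == phen)
  }
  annotation$region <- region
  structure(list(region = region,
                 purity_dz = purity("DZ_region", "DZ"),
                 purity_lz = purity("LZ_region", "LZ"),
                 n_iterations = length(changes), converged = converged,
                 changes_per_sweep = changes, annotation = annotation),
            class = "region_result")
}

#' Check the per-region purity condition
#'
#' The DZ region must contain at least `min_purity` originally-DZ cells and
#' the LZ region at least `min_purity` originally-LZ cells (default 70%).
#' Boundary extraction refuses to run when the check fails.
#'
#' @param result a [iterative_smooth] result.
#' @param min_purity minimum fraction (inclusive) of same-phenotype cells.
#' @return list with `pass`, `purity_dz`, `purity_lz`, `min_purity` and a
#'   human-readable `message`.
#' @export
check_purity <- function(result, min_purity = 0.70) {
  pd <- result$purity_dz; pl <- result$purity_lz
  if (is.na(pd) || is.na(pl)) {
    empty <- c("DZ", "LZ")[c(is.na(pd), is.na(pl))]
    return(list(pass = FALSE, purity_dz = pd, purity_lz = pl,
                min_purity = min_purity,
                message = paste0("empty region(s): ",
                                 paste(empty, collapse = ", "))))
  }
  pass <- pd >= min_purity && pl >= min_purity
  list(pass = pass, purity_dz = pd, purity_lz = pl, min_purity = min_purity,
       message = sprintf("DZ purity %.3f, LZ purity %.3f (minimum %.2f): %s",
                         pd, pl, min_purity, if (pass) "pass" else "fail"))
}

#' Extract the DZ-LZ boundary polyline
#'
#' Boundary vertices are the midpoints of all graph edges joining a
#' DZ-region cell to an LZ-region cell, ordered by their projection onto the
#' first principal axis of the midpoint cloud (sign fixed for determinism).
#'
#' @param graph a [build_graph] result.
#' @param result a [iterative_smooth] result.
#' @param min_purity purity gate applied via [check_purity] before
#'   extraction; set `enforce_purity = FALSE` to skip.
#' @param enforce_purity logical.
#' @return a `gc_boundary`: list with `vertices` (ordered two-column matrix,
#'   micrometres) and `meta` (radius, iterations, purities).
#' @export
extract_boundary <- function(graph, result, min_purity = 0.70,
                             enforce_purity = TRUE) {
  if (enforce_purity) {
    chk <- check_purity(result, min_purity)
    if (!chk$pass)
      stop("purity condition not met, refusing to extract boundary: ",
           chk$message)
  }
  e <- graph$edges
  reg <- result$region
  cross <- (reg[e[, 1]] == "DZ_region" & reg[e[, 2]] == "LZ_region") |
    (reg[e[, 1]] == "LZ_region" & reg[e[, 2]] == "DZ_region")
  if (!any(cross))
    stop("no edge joins the DZ and LZ regions; regions are not adjacent ",
         "at radius ", graph$radius, " um")
  mid <- cbind(x = (graph$x[e[cross, 1]] + graph$x[e[cross, 2]]) / 2,
               y = (graph$y[e[cross, 1]] + graph$y[e[cross, 2]]) / 2)
  if (nrow(mid) < 2)
    stop("fewer than 2 boundary vertices; boundary is degenerate")
  ctr <- colMeans(mid)
  sweep_mid <- sweep(mid, 2, ctr)
  sv <- svd(sweep_mid, nu = 0, nv = 1)
  axis <- sv$v[, 1]
  nz <- which(abs(axis) > 1e-12)[1]
  if (!is.na(nz) && axis[nz] < 0) axis <- -axis  # deterministic orientation
  proj <- as.numeric(sweep_mid %*% axis)
  ord <- order(proj)
  structure(list(vertices = mid[ord, , drop = FALSE],
                 meta = list(radius = graph$radius,
                             n_iterations = result$n_iterations,
                             purity_dz = result$purity_dz,
                             purity_lz = result$purity_lz)),
            class = "gc_boundary")
}

#' @export
print.gc_boundary <- function(x, ...) {
  cat("<gc_boundary> ", nrow(x$vertices), " vertices\n", sep = "")
  invisible(x)
}

#' Write a boundary as GeoJSON
#'
#' Exports the boundary polyline as a GeoJSON LineString in micrometre
#' coordinates.
#'
#' @param boundary a [extract_boundary] result.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_boundary_geojson <- function(boundary, path) {
  gj <- list(type = "Feature",
             geometry = list(type = "LineString",
                             coordinates = unname(
                               lapply(seq_len(nrow(boundary$vertices)),
                                      function(i) boundary$vertices[i, ]))),
             properties = boundary$meta)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Signed distance of cells to the DZ-LZ boundary
#'
#' The magnitude is the Euclidean distance to the nearest boundary vertex.
#' The sign follows the region of the nearest region-labeled cell: negative
#' on the DZ side, positive on the LZ side (matching the -100 um DZ to
#' +100 um LZ profiling convention). Cells lying exactly on a vertex get 0.
#'
#' @param cells a [cell_table] or list with `x`, `y`.
#' @param boundary a [extract_boundary] result.
#' @param result a [iterative_smooth] result aligned with `cells`.
#' @return numeric signed distances in micrometres.
#' @export
signed_distance <- function(cells, boundary, result) {
  v <- boundary$vertices
  if (is.null(v) || nrow(v) < 2 || !all(is.finite(v)))
    stop("invalid boundary")
  x <- cells$x; y <- cells$y
  n <- length(x)
  dmin <- rep(Inf, n)
  # nearest-vertex distance, chunked over vertices to bound memory
  chunk <- 512L
  for (s in seq(1L, nrow(v), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(v))
    d2 <- outer(x, v[idx, 1], "-")^2 + outer(y, v[idx, 2], "-")^2
    dmin <- pmin(dmin, sqrt(apply(d2, 1, min)))
  }
  reg <- result$region
  labeled <- which(reg != "unassigned")
  if (!length(labeled)) stop("no region-labeled cells to determine the side")
  sign_of <- integer(n)
  own <- reg != "unassigned"
  sign_of[own] <- ifelse(reg[own] == "DZ_region", -1L, 1L)
  todo <- which(!own)
  if (length(todo)) {
    nd <- rep(Inf, length(todo)); nearest <- integer(length(todo))
    for (s in seq(1L, length(labeled), by = chunk)) {
      idx <- labeled[s:min(s + chunk - 1L, length(labeled))]
      d2 <- outer(x[todo], x[idx], "-")^2 + outer(y[todo], y[idx], "-")^2
      best <- apply(d2, 1, which.min)
      bd <- d2[cbind(seq_along(todo), best)]
      upd <- bd < nd
      nd[upd] <- bd[upd]; nearest[upd] <- idx[best[upd]]
    }
    sign_of[todo] <- ifelse(reg[nearest] == "DZ_region", -1L, 1L)
  }
  out <- sign_of * dmin
  out[dmin == 0] <- 0
  out
}
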