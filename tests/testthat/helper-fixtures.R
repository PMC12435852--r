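# small in-code fixtures shared across test files

# 3 cells x 2 genes with known entries
toy_cell_table <- function() {
  counts <- matrix(c(5, 0, 0,
                     0, 0, 2), nrow = 3,
                   dimnames = list(NULL, c("g1", "g2")))
  cell_table(c("a", "b", "c"), x = c(0, 10, 20), y = c(0, 0, 0),
             counts = counts, gene_ids = c("g1", "g2"),
             metadata = data.frame(subtype = c("T", "none", "T")))
}

# write the toy table's MTX triplet to a temp dir, returning the paths
toy_mtx_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_cell_table(toy_cell_table(), dir)
}

# a region_result-like list for boundary/purity units that bypass smoothing
manual_region_result <- function(region, purity_dz = 1, purity_lz = 1) {
  structure(list(region = region, purity_dz = purity_dz,
                 purity_lz = purity_lz, n_iterations = 1L, converged = TRUE,
                 changes_per_sweep = 0L),
            class = "region_result")
}

# brute-force radius graph: reference oracle for build_graph
brute_force_edges <- function(x, y, radius) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  idx <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  unname(cbind(idx[, 1], idx[, 2]))
}
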