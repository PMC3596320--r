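#' Ward hierarchical clustering of half-life profiles
#'
#' Agglomerative clustering of per-gene half-life profiles across growth
#' conditions using Ward's minimum-variance criterion on Euclidean
#' distances, with a flat cut at a requested number of clusters. Cluster
#' labels are assigned deterministically in order of first appearance in the
#' input, so permuting rows changes labels only up to relabeling.
#'
#' Distances are computed on raw half-lives in minutes (all coordinates
#' share units); set `log_scale = TRUE` to cluster log half-lives instead.
#'
#' @param profiles A tibble with a `gene` column and one numeric column per
#'   condition; no missing values (genes lacking any condition must be
#'   excluded upstream).
#' @param n_clusters Number of flat clusters (1..number of profiles).
#' @param log_scale Cluster `log(t_half)` instead of raw minutes.
#' @return An object of class `ward_clustering`: `assignments` (tibble:
#'   gene, cluster), `heights` (merge heights in agglomeration order),
#'   `hclust` (the full merge tree), `profiles`.
#' @examples
#' p <- tibble::tibble(gene = c("a", "b", "c", "d"),
#'                     h1 = c(5, 6, 50, 52), h2 = c(8, 9, 60, 61))
#' ward_cluster(p, n_clusters = 2)$assignments
#' @export
ward_cluster <- function(profiles, n_clusters, log_scale = FALSE) {
  stopifnot("gene" %in% names(profiles), n_clusters >= 1)
  mat <- as.matrix(profiles[, setdiff(names(profiles), "gene")])
  if (anyNA(mat)) stop("profiles contain missing values")
  if (n_clusters > nrow(mat)) {
    stop("n_clusters exceeds the number of profiles")
  }
  if (log_scale) mat <- log(mat)
  rownames(mat) <- profiles$gene
  # ward.D2 is Ward's minimum-variance criterion for Euclidean (not squared)
  # distances
  hc <- hclust(dist(mat, method = "euclidean"), method = "ward.D2")
  labels <- cutree(hc, k = n_clusters)
  structure(
    list(
      assignments = tibble::tibble(gene = profiles$gene,
                                   cluster = unname(labels)),
      heights = hc$height,
      hclust = hc,
      n_clusters = n_clusters,
      profiles = profiles
    ),
    class = "ward_clustering"
  )
}

#' @export
print.ward_clustering <- function(x, ...) {
  sizes <- table(x$assignments$cluster)
  cat(sprintf("<ward_clustering> %d profiles in %d clusters (sizes: %s)\n",
              nrow(x$assignments), x$n_clusters,
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Export a Ward merge tree as newick text
#'
#' @param clustering A [ward_cluster()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_tree <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' Per-cluster mean half-life profiles with confidence intervals
#'
#' Summarizes each cluster's half-life profile as the per-condition member
#' mean with a two-sided t-interval. With the default `confidence = 0.05`
#' this is the 95% interval. Singleton clusters have no dispersion and their
#' interval is reported as NA.
#'
#' @param clustering A [ward_cluster()] result (or pass `profiles` and
#'   `assignments` explicitly).
#' @param confidence Two-sided error rate (interval level is
#'   `1 - confidence`).
#' @param profiles,assignments Override the tibbles stored in `clustering`.
#' @return A tibble: `cluster`, `condition`, `n`, `mean`, `ci_lo`, `ci_hi`.
#' @export
cluster_summary <- function(clustering = NULL, confidence = 0.05,
                            profiles = clustering$profiles,
                            assignments = clustering$assignments) {
  stopifnot(!is.null(profiles), !is.null(assignments))
  if (!all(profiles$gene %in% assignments$gene)) {
    stop("assignments do not cover all profiles")
  }
  long <- profiles |>
    dplyr::left_join(assignments, by = "gene") |>
    tidyr::pivot_longer(
      cols = -c("gene", "cluster"),
      names_to = "condition", values_to = "t_half"
    )
  long |>
    dplyr::group_by(.data$cluster, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$t_half),
      half_width = if (dplyr::n() > 1) {
        qt(1 - confidence / 2, dplyr::n() - 1) *
          sd(.data$t_half) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(ci_lo = .data$mean - .data$half_width,
                  ci_hi = .data$mean + .data$half_width) |>
    dplyr::select("cluster", "condition", "n", "mean", "ci_lo", "ci_hi")
}
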