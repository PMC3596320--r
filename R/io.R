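# All tables are TSV with a header row; provenance is carried in leading
# "#"-prefixed comment lines; missing values are written as "ND" (the
# convention used for not-determined half-lives in stability tables).

ND <- "ND"

provenance_header <- function(meta = list()) {
  meta <- c(list(written_by = paste0("ratechase ",
                                     as.character(utils::packageVersion("ratechase")))),
            meta)
  sprintf("# %s: %s", names(meta),
          vapply(meta, function(x) paste(format(x), collapse = " "),
                 character(1)))
}

write_tsv_prov <- function(x, path, meta = list()) {
  writeLines(provenance_header(meta), path)
  readr::write_tsv(x, path, na = ND, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_prov <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", na = c("ND", "NA", ""),
                  col_types = col_types, show_col_types = FALSE)
}

#' Read and write intensity matrices
#'
#' Long-format TSV with columns `gene`, `time_min`, `bio_rep`, `tech_rep`,
#' `batch`, `intensity`; the same format the synthetic generator writes and
#' the decay fitter reads. Writers prepend `#`-prefixed provenance lines
#' (package version, seed, any supplied metadata); readers skip them.
#'
#' @param intensities Intensity tibble.
#' @param path TSV file.
#' @param meta Named list of provenance fields to record.
#' @return The tibble (readers) or `path` invisibly (writers).
#' @export
write_intensity_tsv <- function(intensities, path, meta = list()) {
  check_intensity_cols(intensities)
  write_tsv_prov(intensities, path, meta)
}

#' @rdname write_intensity_tsv
#' @export
read_intensity_tsv <- function(path) {
  out <- read_tsv_prov(path, col_types = readr::cols(
    gene = readr::col_character(),
    time_min = readr::col_double(),
    batch = readr::col_character(),
    intensity = readr::col_double(),
    .default = readr::col_guess()
  ))
  check_intensity_cols(out)
  out
}

#' Read and write per-gene decay-fit tables
#'
#' TSV with columns `gene`, `k`, `sigma_k_pct`, `t_half_min`, `n_points`,
#' `status`; undefined half-lives (not-determined or extremely stable fits)
#' are encoded as `ND`.
#'
#' @param fits Fit tibble from [fit_decay()].
#' @param path TSV file.
#' @param meta Named list of provenance fields.
#' @export
write_fits_tsv <- function(fits, path, meta = list()) {
  thr <- attr(fits, "thresholds")
  if (!is.null(thr)) {
    meta <- c(meta, as.list(thr),
              list(sigma_k_definition = attr(fits, "sigma_k_definition")))
  }
  write_tsv_prov(fits, path, meta)
}

#' @rdname write_fits_tsv
#' @export
read_fits_tsv <- function(path) {
  read_tsv_prov(path, col_types = readr::cols(
    gene = readr::col_character(),
    status = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' Read a pipeline configuration file
#'
#' YAML with fields `seed`, `output_dir`, `conditions` (list of label / mu /
#' culture_mode), `thresholds` (`sigma_reliable`, `sigma_stable`,
#' `rho_epsilon`, `dilution_ratio`), and either `simulate` (synthetic-run
#' parameters) or `inputs` (per-condition intensity TSV paths), plus
#' optional `cluster: {n_clusters: ...}`.
#'
#' @param path YAML file.
#' @return A validated config list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

default_thresholds <- function() {
  list(sigma_reliable = 30, sigma_stable = 70, rho_epsilon = 0.05,
       dilution_ratio = 10)
}

validate_config <- function(config) {
  stopifnot(is.list(config))
  config$thresholds <- modifyList(default_thresholds(),
                                  config$thresholds %||% list())
  thr <- unlist(config$thresholds)
  if (any(thr < 0 | thr > 100)) {
    stop("thresholds must lie in [0, 100]")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  labels <- vapply(config$conditions, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("condition labels must be unique")
  }
  if (is.null(config$simulate)) {
    paths <- vapply(config$inputs, `[[`, character(1), "path")
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    }
  }
  config
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages in dependency order: simulate (or load) per-
#' condition chase intensities, normalize and fit decay, estimate initial
#' levels, compute pairwise regulation coefficients between consecutive
#' conditions, cluster half-life profiles of genes reliable in every
#' condition, and write a text report. Every output table carries provenance
#' headers (config hash, seed, thresholds); a rerun with an identical config
#' is bit-identical for the deterministic stages.
#'
#' @param config A config list ([read_config()]) or path to a YAML file.
#' @return The output directory, invisibly; artifacts are written under it
#'   (`<label>_fits.tsv`, `regulation_<a>_vs_<b>.tsv`,
#'   `regulation_summary.tsv`, `cluster_labels.tsv`, `report.txt`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  out_dir <- config$output_dir %||% stop("config needs output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$thresholds
  # hash the analysis-relevant config only: where outputs land must not
  # change what they contain
  hash_cfg <- config[setdiff(names(config), "output_dir")]
  prov <- c(list(config_hash = rlang::hash(hash_cfg), seed = config$seed),
            thr)

  labels <- vapply(config$conditions, `[[`, character(1), "label")
  mus <- vapply(config$conditions, `[[`, numeric(1), "mu")

  intensity_sets <- load_or_simulate(config, labels, mus, out_dir, prov)

  per_cond <- purrr::map2(intensity_sets, labels, function(ints, lab) {
    norm <- normalize_to_reference(ints)
    fits <- fit_decay(norm, sigma_reliable = thr$sigma_reliable,
                      sigma_stable = thr$sigma_stable)
    write_fits_tsv(fits, file.path(out_dir, paste0(lab, "_fits.tsv")),
                   meta = c(prov, list(condition = lab)))
    # levels from raw membranes: cross-condition comparisons need the
    # common raw scale, not per-condition normalized units
    list(fits = fits, levels = initial_levels(ints))
  })
  names(per_cond) <- labels

  if (length(labels) >= 2) {
    summaries <- list()
    for (i in seq_len(length(labels) - 1)) {
      a <- reliable_state(per_cond[[i]])
      b <- reliable_state(per_cond[[i + 1]])
      reg <- regulation_coefficients(a, b, epsilon = thr$rho_epsilon)
      pair <- paste0(labels[i], "_vs_", labels[i + 1])
      write_tsv_prov(reg, file.path(out_dir,
                                    paste0("regulation_", pair, ".tsv")),
                     meta = c(prov, list(pair = pair)))
      summaries[[pair]] <- summarize_regulation(reg) |>
        dplyr::mutate(pair = pair, .before = 1)
    }
    write_tsv_prov(dplyr::bind_rows(summaries),
                   file.path(out_dir, "regulation_summary.tsv"), meta = prov)
  }

  n_clusters <- config$cluster$n_clusters %||% 4
  profiles <- halflife_profiles(per_cond)
  if (nrow(profiles) >= n_clusters) {
    cl <- ward_cluster(profiles, n_clusters = n_clusters)
    write_tsv_prov(cl$assignments,
                   file.path(out_dir, "cluster_labels.tsv"), meta = prov)
    export_tree(cl, file.path(out_dir, "cluster_tree.nwk"))
  }

  report <- c(
    provenance_header(prov),
    vapply(labels, function(lab) {
      s <- summarize_halflives(per_cond[[lab]]$fits)$stats
      sprintf("%s: %d reliable fits, mean t1/2 %.2f +/- %.2f min, median %.2f",
              lab, s$n, s$mean, s$se, s$median)
    }, character(1))
  )
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

reliable_state <- function(cond) {
  cond$fits |>
    dplyr::filter(.data$status == "reliable") |>
    dplyr::select("gene", "k") |>
    dplyr::inner_join(cond$levels, by = "gene")
}

halflife_profiles <- function(per_cond) {
  tabs <- purrr::imap(per_cond, function(cond, lab) {
    cond$fits |>
      dplyr::filter(.data$status == "reliable") |>
      dplyr::select("gene", !!lab := "t_half_min")
  })
  purrr::reduce(tabs, dplyr::inner_join, by = "gene")
}

load_or_simulate <- function(config, labels, mus, out_dir, prov) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    base <- synth_params(
      n_genes = sim$n_genes %||% 500,
      mu = mus[1],
      noise_sd_ln = sim$noise_sd_ln %||% 0.1,
      frac_extremely_stable = sim$frac_extremely_stable %||% 0.05,
      seed = config$seed
    )
    sets <- purrr::map(seq_along(labels), function(i) {
      p <- base
      p$mu <- mus[i]
      p$seed <- base$seed + i - 1L
      d <- generate_chase(p)
      write_intensity_tsv(
        d$intensities,
        file.path(out_dir, paste0(labels[i], "_intensities.tsv")),
        meta = c(prov, list(condition = labels[i], mu = mus[i]))
      )
      write_tsv_prov(d$truth,
                     file.path(out_dir, paste0(labels[i], "_truth.tsv")),
                     meta = c(prov, list(condition = labels[i])))
      d$intensities
    })
  } else {
    sets <- purrr::map(config$inputs, ~ read_intensity_tsv(.x$path))
  }
  sets
}
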