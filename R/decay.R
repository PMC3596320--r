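#' Normalize chase intensities to the pre-arrest reference membrane
#'
#' Each membrane (one hybridization at one time point) belongs to a batch that
#' was processed together with its own pre-arrest (t = 0) reference membrane.
#' Every intensity in a batch is divided by the scalar mean intensity of that
#' batch's reference membrane(s), so that membranes become comparable while
#' within-gene decay slopes are untouched (a per-batch scalar only shifts the
#' log-intercept).
#'
#' @param intensities A tibble with columns `gene`, `time_min`, `batch`,
#'   `intensity` (strictly positive), and optionally replicate identifiers.
#'   Rows with `time_min == 0` are the reference measurements.
#' @return A tibble with the same columns, `intensity` replaced by its
#'   batch-normalized value.
#' @examples
#' d <- generate_chase(synth_params(n_genes = 20, seed = 1))
#' norm <- normalize_to_reference(d$intensities)
#' @export
normalize_to_reference <- function(intensities) {
  check_intensity_cols(intensities)
  ref_means <- intensities |>
    dplyr::filter(.data$time_min == 0) |>
    dplyr::group_by(.data$batch) |>
    dplyr::summarise(.ref_mean = mean(.data$intensity), .groups = "drop")
  missing <- setdiff(unique(intensities$batch), ref_means$batch)
  if (length(missing) > 0) {
    stop("batch(es) without a t = 0 reference membrane: ",
         paste(missing, collapse = ", "))
  }
  intensities |>
    dplyr::left_join(ref_means, by = "batch") |>
    dplyr::mutate(intensity = .data$intensity / .data$.ref_mean) |>
    dplyr::select(-".ref_mean")
}

check_intensity_cols <- function(x) {
  needed <- c("gene", "time_min", "batch", "intensity")
  miss <- setdiff(needed, names(x))
  if (length(miss) > 0) {
    stop("intensity table lacks column(s): ", paste(miss, collapse = ", "))
  }
  invisible(x)
}

#' Fit per-gene first-order decay from a chase time course
#'
#' After transcription arrest each transcript decays exponentially, so its
#' log-intensity is linear in time with slope -k. All replicate membranes are
#' pooled into a single ordinary least-squares regression of ln(intensity) on
#' time per gene; `k = -slope` and `sigma_k` is the relative standard error of
#' the slope in percent, `100 * SE(slope) / |slope|`.
#'
#' Fits are classified by `sigma_k`:
#' \describe{
#'   \item{reliable}{`sigma_k <= sigma_reliable` (default 30); only these
#'     genes get a half-life `t_half = ln 2 / k`.}
#'   \item{extremely_stable}{flat or rising series (`slope >= 0`) or
#'     `sigma_k >= sigma_stable` (default 70): the chase window is too short
#'     to resolve the decay of these transcripts.}
#'   \item{not_determined}{everything in between, or fewer than 3 usable
#'     time points.}
#' }
#'
#' @param intensities A (typically normalized) intensity tibble; see
#'   [normalize_to_reference()]. Non-positive intensities are dropped per
#'   point with a warning; a gene needs at least 3 surviving distinct time
#'   points.
#' @param sigma_reliable,sigma_stable Classification thresholds on `sigma_k`,
#'   in percent.
#' @return A tibble with one row per gene: `gene`, `k` (min^-1), `sigma_k_pct`,
#'   `t_half_min` (NA unless reliable), `n_points`, `status`.
#' @examples
#' d <- generate_chase(synth_params(n_genes = 50, seed = 1))
#' fits <- fit_decay(normalize_to_reference(d$intensities))
#' @export
fit_decay <- function(intensities, sigma_reliable = 30, sigma_stable = 70) {
  check_intensity_cols(intensities)
  if (any(intensities$intensity <= 0, na.rm = TRUE) ||
      anyNA(intensities$intensity)) {
    warning("dropping non-positive or missing intensities before log fit")
    intensities <- dplyr::filter(
      intensities, !is.na(.data$intensity), .data$intensity > 0
    )
  }
  fits <- intensities |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(~ fit_one_gene(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      status = classify_fit(.data$slope, .data$sigma_k_pct, .data$n_points,
                            sigma_reliable, sigma_stable),
      k = -.data$slope,
      t_half_min = dplyr::if_else(
        .data$status == "reliable", log(2) / .data$k, NA_real_
      )
    ) |>
    dplyr::select("gene", "k", "sigma_k_pct", "t_half_min", "n_points",
                  "status")
  attr(fits, "sigma_k_definition") <-
    "relative standard error of pooled-regression slope, percent"
  attr(fits, "thresholds") <-
    c(sigma_reliable = sigma_reliable, sigma_stable = sigma_stable)
  fits
}

fit_one_gene <- function(df) {
  n_t <- dplyr::n_distinct(df$time_min)
  if (n_t < 3) {
    return(tibble::tibble(
      slope = NA_real_, sigma_k_pct = NA_real_, n_points = nrow(df)
    ))
  }
  fit <- lm(log(intensity) ~ time_min, data = df)
  est <- summary(fit)$coefficients
  tibble::tibble(
    slope = est["time_min", "Estimate"],
    sigma_k_pct = 100 * est["time_min", "Std. Error"] /
      abs(est["time_min", "Estimate"]),
    n_points = nrow(df)
  )
}

classify_fit <- function(slope, sigma_k_pct, n_points,
                         sigma_reliable, sigma_stable) {
  dplyr::case_when(
    is.na(slope)                ~ "not_determined",
    slope >= 0                  ~ "extremely_stable",
    sigma_k_pct >= sigma_stable ~ "extremely_stable",
    sigma_k_pct <= sigma_reliable ~ "reliable",
    TRUE                        ~ "not_determined"
  )
}

#' Half-life from a first-order rate constant
#'
#' `t_half = ln 2 / k`. The same relation applied to a growth rate gives the
#' culture doubling time; see [doubling_time()].
#'
#' @param k Degradation rate constant(s), min^-1; must be strictly positive.
#' @return Half-life in minutes.
#' @examples
#' half_life(log(2)) # 1 minute
#' @export
half_life <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("half_life() requires k > 0; flat or rising fits have no half-life")
  }
  log(2) / k
}

#' Doubling time from a specific growth rate
#'
#' @param mu Growth rate(s) in h^-1, strictly positive.
#' @return Doubling time in hours, `ln 2 / mu`.
#' @examples
#' doubling_time(c(0.11, 0.51)) # 6.30 h and 1.36 h
#' @export
doubling_time <- function(mu) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("doubling_time() requires mu > 0")
  }
  log(2) / mu
}

#' Per-gene pre-arrest mRNA levels
#'
#' The initial (pre-rifampicin) concentration of each transcript, taken as
#' the mean intensity over the t = 0 reference membranes. This is the
#' concentration the regulation analysis pairs with the decay constant.
#'
#' Pass raw (un-normalized) intensities when the levels will be compared
#' across conditions: per-batch reference normalization rescales every
#' condition by its own average transcript level, which cancels out of decay
#' slopes but would shift every between-condition log concentration change
#' by a constant. Raw intensities share a scale across conditions when the
#' same amount of RNA is hybridized per membrane, as in the assay this
#' emulates.
#'
#' @param intensities An intensity tibble (raw for cross-condition use).
#' @return A tibble: `gene`, `mrna`.
#' @export
initial_levels <- function(intensities) {
  check_intensity_cols(intensities)
  intensities |>
    dplyr::filter(.data$time_min == 0) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(mrna = mean(.data$intensity), .groups = "drop")
}

#' Summarize half-lives across a fit table
#'
#' Reports the mean with its standard error, the median, per-status counts,
#' histogram bins and a rolling average over the sorted half-lives (the
#' smoothed overall tendency used when overlaying distributions from several
#' growth rates).
#'
#' @param fits A decay-fit tibble from [fit_decay()].
#' @param status Which fit status to summarize (default `"reliable"`, the only
#'   status with defined half-lives).
#' @param bin_width Histogram bin width in minutes.
#' @param window Rolling-average window size (number of genes).
#' @return A list with elements `stats` (tibble: n, mean, se, median),
#'   `counts` (tibble: status, n), `histogram` (tibble: bin midpoint, count)
#'   and `rolling` (tibble: rank, t_half_min, rolling_mean).
#' @export
summarize_halflives <- function(fits, status = "reliable", bin_width = 2,
                                window = 25) {
  counts <- fits |>
    dplyr::count(.data$status, name = "n")
  th <- fits$t_half_min[fits$status == status & !is.na(fits$t_half_min)]
  if (length(th) == 0) {
    return(list(
      stats = tibble::tibble(n = 0L, mean = NA_real_, se = NA_real_,
                             median = NA_real_),
      counts = counts,
      histogram = tibble::tibble(mid = numeric(), count = integer()),
      rolling = tibble::tibble(rank = integer(), t_half_min = numeric(),
                               rolling_mean = numeric())
    ))
  }
  se <- if (length(th) > 1) sd(th) / sqrt(length(th)) else 0
  breaks <- seq(0, max(th) + bin_width, by = bin_width)
  hist_counts <- table(cut(th, breaks = breaks, include.lowest = TRUE))
  th_sorted <- sort(th)
  w <- min(window, length(th_sorted))
  roll <- as.numeric(stats::filter(th_sorted, rep(1 / w, w), sides = 2))
  list(
    stats = tibble::tibble(n = length(th), mean = mean(th), se = se,
                           median = median(th)),
    counts = counts,
    histogram = tibble::tibble(
      mid = utils::head(breaks, -1) + bin_width / 2,
      count = as.integer(hist_counts)
    ),
    rolling = tibble::tibble(
      rank = seq_along(th_sorted),
      t_half_min = th_sorted,
      rolling_mean = roll
    )
  )
}
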