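#' Growth condition descriptor
#'
#' @param label Condition label.
#' @param mu Growth rate in h^-1 (>= 0).
#' @param culture_mode `"chemostat"` or `"batch_phase"`.
#' @return A tibble row with `label`, `mu`, `culture_mode` and the derived
#'   `doubling_time_h` (`ln 2 / mu`, NA when mu = 0).
#' @examples
#' growth_condition("low", 0.11)
#' @export
growth_condition <- function(label, mu, culture_mode = c("chemostat",
                                                         "batch_phase")) {
  culture_mode <- match.arg(culture_mode)
  stopifnot(mu >= 0)
  tibble::tibble(
    label = label, mu = mu, culture_mode = culture_mode,
    doubling_time_h = ifelse(mu > 0, log(2) / mu, NA_real_)
  )
}

#' Transcription rate implied by steady state
#'
#' At steady state, synthesis balances loss by degradation and by dilution
#' through growth: `V_T = (mu/60 + k) * [mRNA]`, with mu converted from h^-1
#' to min^-1 so both loss terms share units. Genome-wide transcription rates
#' are not measured directly; this derived value is reported for diagnostics.
#'
#' @param mrna mRNA concentration (arbitrary units, >= 0).
#' @param k Degradation rate constant, min^-1 (>= 0).
#' @param mu Growth rate, h^-1 (>= 0).
#' @return Transcription rate in units min^-1.
#' @examples
#' infer_transcription_rate(10, 0.1, 0) # 1.0
#' @export
infer_transcription_rate <- function(mrna, k, mu) {
  if (any(mrna < 0) || any(k < 0) || any(mu < 0)) {
    stop("mrna, k and mu must all be non-negative")
  }
  (per_hour_to_per_min(mu) + k) * mrna
}

#' Is dilution by growth negligible against degradation?
#'
#' Generation times are usually much longer than mRNA half-lives, so the
#' dilution term mu/60 can be dropped from the turnover balance when the
#' decay constant dominates it by a comfortable margin.
#'
#' @param k Degradation rate constant, min^-1 (> 0).
#' @param mu Growth rate, h^-1 (>= 0).
#' @param ratio_threshold How many times larger than mu/60 the decay constant
#'   must be (default 10).
#' @return Logical: `k >= ratio_threshold * mu / 60`.
#' @examples
#' dilution_negligible(k = log(2) / 6, mu = 0.51) # TRUE, ratio ~ 13.6
#' @export
dilution_negligible <- function(k, mu, ratio_threshold = 10) {
  stopifnot(all(k > 0), all(mu >= 0))
  k >= ratio_threshold * per_hour_to_per_min(mu)
}

#' Regulation coefficients between two steady states
#'
#' For each gene present in both conditions, the change in mRNA level is
#' decomposed into a degradational and a transcriptional contribution:
#' `rho_d = -d ln k / d ln[mRNA]` (the opposite slope of the
#' double-logarithmic plot of k versus initial concentration) and
#' `rho_t = 1 - rho_d`. Genes whose concentration change is smaller than
#' `epsilon` in absolute log units are reported `undetermined` rather than
#' forced into a bin.
#'
#' @param a,b Tibbles with columns `gene`, `mrna`, `k` (both positive;
#'   typically the reliable subset of a fit table joined with pre-arrest
#'   concentrations). Ordered: the change is b relative to a.
#' @param epsilon Guard on `|d ln mrna|` below which rho_d is not computed.
#' @param mode_tolerance Band used by [classify_mode()] for calling the exact
#'   modes I (rho_d = 1) and II (rho_d = 0).
#' @return A tibble with one row per shared gene: `gene`, `d_ln_mrna`,
#'   `d_ln_k`, `rho_d`, `rho_t`, `mode` (I..V or undetermined) and `bin`
#'   (mainly_transcriptional / shared / mainly_degradational / undetermined).
#' @examples
#' a <- tibble::tibble(gene = "x", mrna = 1, k = 0.1)
#' b <- tibble::tibble(gene = "x", mrna = 2, k = 0.1)
#' regulation_coefficients(a, b) # rho_d = 0: purely transcriptional
#' @export
regulation_coefficients <- function(a, b, epsilon = 0.05,
                                    mode_tolerance = 0.05) {
  for (tab in list(a, b)) {
    stopifnot(all(c("gene", "mrna", "k") %in% names(tab)))
    if (any(tab$mrna <= 0) || any(tab$k <= 0)) {
      stop("regulation coefficients require mrna > 0 and k > 0 in both conditions")
    }
  }
  res <- dplyr::inner_join(
    a |> dplyr::select("gene", mrna_a = "mrna", k_a = "k"),
    b |> dplyr::select("gene", mrna_b = "mrna", k_b = "k"),
    by = "gene"
  ) |>
    dplyr::mutate(
      d_ln_mrna = log(.data$mrna_b / .data$mrna_a),
      d_ln_k = log(.data$k_b / .data$k_a),
      rho_d = dplyr::if_else(abs(.data$d_ln_mrna) < epsilon, NA_real_,
                             -.data$d_ln_k / .data$d_ln_mrna),
      rho_t = 1 - .data$rho_d
    )
  cls <- classify_mode(res$rho_d, tolerance = mode_tolerance)
  res |>
    dplyr::mutate(mode = cls$mode, bin = cls$bin) |>
    dplyr::select("gene", "d_ln_mrna", "d_ln_k", "rho_d", "rho_t",
                  "mode", "bin")
}

#' Classify a degradation regulation coefficient
#'
#' Five regulation patterns are distinguished: I, control solely by
#' degradation (rho_d = 1); II, control solely by transcription (rho_d = 0);
#' III, shared control (0 < rho_d < 1); IV, mainly degradational control
#' with antagonistic transcription (rho_d > 1); V, mainly transcriptional
#' control with antagonistic degradation (rho_d < 0). The exact modes I and
#' II are called within a tolerance band; the headline bins use closed/open
#' edges: rho_d <= 0 mainly transcriptional, 0 < rho_d < 1 shared,
#' rho_d >= 1 mainly degradational.
#'
#' @param rho_d Numeric vector (NA allowed: reported undetermined).
#' @param tolerance Half-width of the band for exact modes I/II.
#' @return A tibble with factor columns `mode` and `bin` aligned to `rho_d`.
#' @examples
#' classify_mode(c(-0.5, 0.5, 1.3))
#' @export
classify_mode <- function(rho_d, tolerance = 0.05) {
  mode <- dplyr::case_when(
    is.na(rho_d)               ~ "undetermined",
    abs(rho_d - 1) <= tolerance ~ "I",
    abs(rho_d) <= tolerance     ~ "II",
    rho_d > 0 & rho_d < 1       ~ "III",
    rho_d > 1                   ~ "IV",
    TRUE                        ~ "V"
  )
  bin <- dplyr::case_when(
    is.na(rho_d)          ~ "undetermined",
    rho_d <= 0            ~ "mainly_transcriptional",
    rho_d < 1             ~ "shared",
    TRUE                  ~ "mainly_degradational"
  )
  tibble::tibble(
    mode = factor(mode, levels = c("I", "II", "III", "IV", "V",
                                   "undetermined")),
    bin = factor(bin, levels = c("mainly_transcriptional", "shared",
                                 "mainly_degradational", "undetermined"))
  )
}

#' Summarize regulation bins across genes
#'
#' Produces the per-bin gene counts and percentages for a pairwise condition
#' comparison. Percentages are computed over genes with a determinate bin;
#' rounding is left to display.
#'
#' @param results Output of [regulation_coefficients()].
#' @return A tibble: `bin`, `n`, `pct` (NA for the undetermined row).
#' @export
summarize_regulation <- function(results) {
  counts <- results |>
    dplyr::count(.data$bin, name = "n", .drop = FALSE)
  n_det <- sum(counts$n[counts$bin != "undetermined"])
  counts |>
    dplyr::mutate(
      pct = dplyr::if_else(.data$bin == "undetermined", NA_real_,
                           if (n_det > 0) 100 * .data$n / n_det else 0)
    )
}
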