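#' Parameters for a synthetic transcription-arrest chase experiment
#'
#' Bundles the design of a simulated rifampicin-chase time course. Defaults
#' emulate the macroarray design the pipeline targets: sampling through a
#' 20-minute window after the arrest, 2 biological x 2 technical replicate
#' series, and a decay-rate distribution calibrated so the median half-life
#' is 5.8 min (the fast-growth condition, mu = 0.80 h^-1).
#'
#' @param n_genes Number of genes.
#' @param time_points Sampling times in minutes post-arrest; must be sorted
#'   ascending with the pre-arrest reference at 0.
#' @param n_bio_reps,n_tech_reps Biological and technical replicate counts;
#'   each (bio, tech) pair is one membrane series, i.e. one batch.
#' @param mu Growth rate in h^-1 (converted to min^-1 internally wherever it
#'   meets a decay constant).
#' @param halflife_median Median half-life in minutes for the decaying genes.
#' @param halflife_log_sd Standard deviation of ln k across genes.
#' @param frac_extremely_stable Fraction of genes simulated with k exactly 0
#'   (transcripts whose decay the chase window cannot resolve).
#' @param noise_sd_ln SD of additive Gaussian noise on ln intensity
#'   (equivalently multiplicative log-normal noise).
#' @param batch_gain_sd_ln SD of the per-batch log gain (overall membrane
#'   exposure/labelling differences, removed by reference normalization).
#' @param seed Integer seed; identical parameters and seed give a
#'   bit-identical dataset.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_genes = 2000,
                         time_points = c(0, 1, 2, 4, 6, 10, 15, 20),
                         n_bio_reps = 2,
                         n_tech_reps = 2,
                         mu = 0.80,
                         halflife_median = 5.8,
                         halflife_log_sd = 0.5,
                         frac_extremely_stable = 0.05,
                         noise_sd_ln = 0.1,
                         batch_gain_sd_ln = 0.15,
                         seed = 1L) {
  p <- list(
    n_genes = as.integer(n_genes), time_points = as.numeric(time_points),
    n_bio_reps = as.integer(n_bio_reps), n_tech_reps = as.integer(n_tech_reps),
    mu = mu, halflife_median = halflife_median,
    halflife_log_sd = halflife_log_sd,
    frac_extremely_stable = frac_extremely_stable,
    noise_sd_ln = noise_sd_ln, batch_gain_sd_ln = batch_gain_sd_ln,
    seed = as.integer(seed)
  )
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  stopifnot(
    "n_genes must be positive" = p$n_genes > 0,
    "time_points must be non-empty" = length(p$time_points) > 0,
    "time_points must start at 0 and increase" =
      p$time_points[1] == 0 && !is.unsorted(p$time_points, strictly = TRUE),
    "replicate counts must be positive" =
      p$n_bio_reps > 0 && p$n_tech_reps > 0,
    "mu must be non-negative" = p$mu >= 0,
    "halflife_median must be positive" = p$halflife_median > 0,
    "frac_extremely_stable must be in [0,1]" =
      p$frac_extremely_stable >= 0 && p$frac_extremely_stable <= 1,
    "noise_sd_ln must be non-negative" = p$noise_sd_ln >= 0
  )
  invisible(p)
}

# Draw per-gene ground truth: k (min^-1), initial concentration and the
# transcription rate implied by steady state, V_T = (mu/60 + k) * mrna0.
draw_truth <- function(p) {
  gene <- sprintf("g%04d", seq_len(p$n_genes))
  k <- exp(rnorm(p$n_genes, mean = log(log(2) / p$halflife_median),
                 sd = p$halflife_log_sd))
  n_stable <- round(p$frac_extremely_stable * p$n_genes)
  if (n_stable > 0) {
    k[sample.int(p$n_genes, n_stable)] <- 0
  }
  mrna0 <- exp(rnorm(p$n_genes, mean = log(100), sd = 1))
  tibble::tibble(
    gene = gene, k = k, mrna0 = mrna0,
    v_t = (per_hour_to_per_min(p$mu) + k) * mrna0,
    t_half_min = ifelse(k > 0, log(2) / k, NA_real_),
    extremely_stable = k == 0
  )
}

#' Simulate a rifampicin-chase dataset with known ground truth
#'
#' After the arrest at t = 0 each transcript decays exponentially, so the
#' expected intensity of gene g on a membrane at time t is
#' `mrna0_g * exp(-k_g * t)`, scaled by a per-batch gain; the observed ln
#' intensity adds Gaussian noise with SD `noise_sd_ln`. A fraction of genes
#' is simulated as extremely stable with k exactly 0, giving an unambiguous
#' truth class for the sigma_k filter.
#'
#' @param params A [synth_params()] object.
#' @param truth Optional per-gene truth tibble (columns `gene`, `k`, `mrna0`)
#'   to use instead of drawing one; used by [generate_paired_conditions()] to
#'   impose exact regulation coefficients.
#' @return A list of class `chase_dataset`: `intensities` (tibble: gene,
#'   time_min, bio_rep, tech_rep, batch, intensity), `truth` (per-gene k,
#'   mrna0, v_t, t_half_min, extremely_stable), `params`.
#' @examples
#' d <- generate_chase(synth_params(n_genes = 100, seed = 7))
#' head(d$intensities)
#' @export
generate_chase <- function(params, truth = NULL) {
  validate_synth_params(params)
  set.seed(params$seed)
  if (is.null(truth)) {
    truth <- draw_truth(params)
  } else {
    stopifnot(all(c("gene", "k", "mrna0") %in% names(truth)),
              nrow(truth) == params$n_genes)
    truth <- truth |>
      dplyr::mutate(
        v_t = (per_hour_to_per_min(params$mu) + .data$k) * .data$mrna0,
        t_half_min = ifelse(.data$k > 0, log(2) / .data$k, NA_real_),
        extremely_stable = .data$k == 0
      )
  }

  design <- tidyr::expand_grid(
    bio_rep = seq_len(params$n_bio_reps),
    tech_rep = seq_len(params$n_tech_reps),
    time_min = params$time_points
  ) |>
    dplyr::mutate(batch = sprintf("b%d.t%d", .data$bio_rep, .data$tech_rep))

  batches <- unique(design$batch)
  gains <- setNames(
    exp(rnorm(length(batches), 0, params$batch_gain_sd_ln)), batches
  )

  obs <- tidyr::expand_grid(
    truth |> dplyr::select("gene", "k", "mrna0"),
    design
  ) |>
    dplyr::mutate(
      ln_expected = log(.data$mrna0) - .data$k * .data$time_min +
        log(unname(gains[.data$batch])),
      intensity = exp(.data$ln_expected +
                        rnorm(dplyr::n(), 0, params$noise_sd_ln))
    ) |>
    dplyr::select("gene", "time_min", "bio_rep", "tech_rep", "batch",
                  "intensity")

  structure(
    list(intensities = obs, truth = truth, params = params),
    class = "chase_dataset"
  )
}

#' @export
print.chase_dataset <- function(x, ...) {
  cat(sprintf(
    "<chase_dataset> %d genes x %d membranes (mu = %.2f h^-1, seed = %d)\n",
    nrow(x$truth), dplyr::n_distinct(x$intensities$batch) *
      length(x$params$time_points), x$params$mu, x$params$seed
  ))
  invisible(x)
}

#' Simulate two growth conditions with prescribed regulation coefficients
#'
#' Builds a pair of chase datasets over the same gene set in which the truth
#' of condition b is solved from condition a so that the degradation
#' regulation coefficient `rho_d = -d ln k / d ln[mRNA]` equals a requested
#' per-gene target exactly: given a concentration change `d_ln_mrna`,
#' `k_b = k_a * exp(-rho_d * d_ln_mrna)` and
#' `mrna_b = mrna_a * exp(d_ln_mrna)`. Transcription rates are recomputed
#' from the steady-state balance in each condition.
#'
#' @param params_a,params_b [synth_params()] for the two conditions (same
#'   `n_genes`; growth rates may differ).
#' @param rho_d_targets Numeric vector of per-gene target rho_d values.
#' @param d_ln_mrna Optional per-gene log concentration changes; by default
#'   magnitudes are drawn uniformly in [0.5, 1.5] with random sign. Must be
#'   bounded away from 0: a finite rho_d target with no concentration change
#'   is rejected.
#' @return A list of class `paired_chase`: `condition_a`, `condition_b`
#'   (both `chase_dataset`), and `truth` (per-gene k/mrna0 in both conditions
#'   plus `d_ln_mrna`, `rho_d`, `rho_t`).
#' @export
generate_paired_conditions <- function(params_a, params_b, rho_d_targets,
                                       d_ln_mrna = NULL) {
  validate_synth_params(params_a)
  validate_synth_params(params_b)
  stopifnot(params_a$n_genes == params_b$n_genes,
            length(rho_d_targets) == params_a$n_genes)

  set.seed(params_a$seed)
  truth_a <- draw_truth(params_a)
  if (is.null(d_ln_mrna)) {
    d_ln_mrna <- sample(c(-1, 1), params_a$n_genes, replace = TRUE) *
      runif(params_a$n_genes, 0.5, 1.5)
  }
  finite <- is.finite(rho_d_targets)
  if (any(finite & d_ln_mrna == 0)) {
    stop("a finite rho_d target requires a non-zero d_ln_mrna")
  }

  truth_b <- truth_a |>
    dplyr::mutate(
      k = ifelse(.data$k > 0 & finite,
                 .data$k * exp(-rho_d_targets * d_ln_mrna), .data$k),
      mrna0 = .data$mrna0 * exp(d_ln_mrna)
    ) |>
    dplyr::select("gene", "k", "mrna0")

  cond_a <- generate_chase(params_a, truth = truth_a)
  cond_b <- generate_chase(params_b, truth = truth_b)

  truth <- dplyr::inner_join(
    cond_a$truth |> dplyr::select("gene", k_a = "k", mrna_a = "mrna0"),
    cond_b$truth |> dplyr::select("gene", k_b = "k", mrna_b = "mrna0"),
    by = "gene"
  ) |>
    dplyr::mutate(
      d_ln_mrna = d_ln_mrna,
      rho_d = ifelse(.data$k_a > 0, rho_d_targets, NA_real_),
      rho_t = 1 - .data$rho_d
    )

  structure(
    list(condition_a = cond_a, condition_b = cond_b, truth = truth),
    class = "paired_chase"
  )
}

#' Simulate a feature table with known half-life determinants
#'
#' Generates per-gene sequence/expression features across several growth
#' rates together with a log half-life response built from a known linear
#' model: dominant growth-rate level effects plus small coefficients on
#' standardized quantitative features, with Gaussian noise. Used to validate
#' the covariance-model selection machinery against a known truth.
#'
#' The default effect sizes follow the structure seen in determinant analyses
#' of bacterial mRNA stability: negative effects of mRNA concentration and
#' gene length, positive effects of CAI and upstream folding energy |dG|, and
#' growth-rate level effects an order of magnitude larger than any
#' gene-specific feature. GC content, tAI and gene position are generated as
#' pure noise features so that selection has something to reject. The noise
#' SD default (0.55) puts the full-model R^2 near 0.6.
#'
#' @param n_genes Genes per growth rate (each gene contributes one
#'   observation per growth rate).
#' @param mu_levels Growth-rate levels in h^-1.
#' @param coefs Named coefficients on the z-scored quantitative features
#'   (names among `ln_mrna`, `length`, `abs_dg`, `cai`, `tai`, `gc`,
#'   `position`).
#' @param mu_effects Named per-level effects on ln half-life (names =
#'   formatted mu levels; must be as long as `mu_levels`).
#' @param noise_sd Residual SD on ln half-life.
#' @param seed Integer seed.
#' @return A tibble (class `determinants_sim`) with columns `gene`,
#'   `mu_level`, the raw features, and `ln_thalf`; the generative
#'   coefficients are stored in `attr(, "truth")`.
#' @export
generate_feature_table <- function(n_genes = 486,
                                   mu_levels = c(0.80, 0.51, 0.11),
                                   coefs = c(ln_mrna = -0.065,
                                             length = -0.059,
                                             abs_dg = 0.06, cai = 0.06),
                                   mu_effects = c(`0.8` = -0.952,
                                                  `0.51` = 0.189,
                                                  `0.11` = 0.763),
                                   noise_sd = 0.55,
                                   seed = 1L) {
  stopifnot(n_genes > 1, length(mu_levels) == length(mu_effects))
  set.seed(as.integer(seed))
  gene <- sprintf("g%04d", seq_len(n_genes))
  per_gene <- tibble::tibble(
    gene = gene,
    length = round(exp(rnorm(n_genes, log(900), 0.5))),
    cai = runif(n_genes, 0.2, 0.9),
    tai = runif(n_genes, 0.2, 0.9),
    gc = rnorm(n_genes, 0.36, 0.03),
    abs_dg = rgamma_shifted(n_genes),
    position = runif(n_genes, 1, 2.4e6),
    motif_class = factor(sample(c("0", "1", "2+"), n_genes, replace = TRUE,
                                prob = c(0.6, 0.3, 0.1)),
                         levels = c("0", "1", "2+"))
  )
  data <- tidyr::expand_grid(per_gene, mu_level = as.character(mu_levels)) |>
    dplyr::mutate(
      mu_level = factor(.data$mu_level, levels = as.character(mu_levels)),
      ln_mrna = rnorm(dplyr::n(), 4, 1)
    )
  quant <- intersect(names(coefs),
                     c("ln_mrna", "length", "abs_dg", "cai", "tai", "gc",
                       "position"))
  zmat <- vapply(quant, function(v) as.numeric(scale(data[[v]])),
                 numeric(nrow(data)))
  signal <- drop(zmat %*% coefs[quant]) +
    unname(mu_effects[as.character(data$mu_level)])
  data$ln_thalf <- signal + rnorm(nrow(data), 0, noise_sd)
  attr(data, "truth") <- list(coefs = coefs, mu_effects = mu_effects,
                              noise_sd = noise_sd, seed = as.integer(seed))
  class(data) <- c("determinants_sim", class(data))
  data
}

rgamma_shifted <- function(n) stats::rgamma(n, shape = 4, scale = 3)
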