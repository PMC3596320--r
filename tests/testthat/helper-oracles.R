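# Independent oracles used across tests. These deliberately re-derive
# results from first principles (textbook formulas, explicit enumeration)
# and never call the package functions they check.

# Closed-form simple linear regression: slope, its standard error and the
# intercept, from the textbook sums.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  list(slope = slope, intercept = intercept, se = se)
}

# Brute-force reimplementation of the regulation mode and bin rules,
# written as plain nested conditionals.
brute_force_modes <- function(rho_d, tolerance = 0.05) {
  mode <- character(length(rho_d))
  bin <- character(length(rho_d))
  for (i in seq_along(rho_d)) {
    r <- rho_d[i]
    if (is.na(r)) {
      mode[i] <- "undetermined"
      bin[i] <- "undetermined"
      next
    }
    if (abs(r - 1) <= tolerance) {
      mode[i] <- "I"
    } else if (abs(r) <= tolerance) {
      mode[i] <- "II"
    } else if (r > 0 && r < 1) {
      mode[i] <- "III"
    } else if (r > 1) {
      mode[i] <- "IV"
    } else {
      mode[i] <- "V"
    }
    if (r <= 0) {
      bin[i] <- "mainly_transcriptional"
    } else if (r < 1) {
      bin[i] <- "shared"
    } else {
      bin[i] <- "mainly_degradational"
    }
  }
  list(mode = mode, bin = bin)
}

geom_mean <- function(x) exp(mean(log(x)))

# A noise-free chase series for one gene laid out as the fitter expects.
toy_series <- function(times, ln_values, gene = "g1", batch = "b1") {
  tibble::tibble(
    gene = gene, time_min = times, bio_rep = 1L, tech_rep = 1L,
    batch = batch, intensity = exp(ln_values)
  )
}

# Decay fits + initial levels joined into the state table the regulation
# functions take, for one simulated condition.
condition_state <- function(dataset) {
  fits <- suppressWarnings(
    fit_decay(normalize_to_reference(dataset$intensities))
  )
  fits |>
    dplyr::filter(status == "reliable") |>
    dplyr::select(gene, k) |>
    dplyr::inner_join(initial_levels(dataset$intensities), by = "gene")
}

# Noise-free paired-condition parameter sets used by several tests.
noiseless_params <- function(n_genes, mu = 0.80, seed = 1) {
  synth_params(
    n_genes = n_genes, mu = mu, noise_sd_ln = 0, batch_gain_sd_ln = 0,
    frac_extremely_stable = 0, seed = seed
  )
}
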