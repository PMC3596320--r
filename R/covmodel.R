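#' Fit the AIC-selected covariance model of half-life determinants
#'
#' Models log half-life as a linear function of quantitative gene features
#' (z-scored before fitting, so coefficients are comparable across features)
#' and qualitative factors (growth-rate level, functional category, motif
#' class). Starting from the full candidate model, terms are added/removed by
#' bidirectional stepwise search on the Akaike Information Criterion until no
#' move lowers the AIC; ties break toward the smaller model (a removal is
#' preferred to an equal-AIC stay).
#'
#' @param data A tibble with one row per gene x growth rate; must contain
#'   `response` and every candidate column. Rows with missing candidate
#'   values are dropped with a message.
#' @param response Response column name (default `ln_thalf`; pass half-lives
#'   through `log()` upstream).
#' @param quantitative Character vector of quantitative candidate columns
#'   (z-scored internally).
#' @param qualitative Character vector of factor candidate columns.
#' @return An object of class `covmodel_fit` with [tidy()] and [glance()]
#'   methods; fields include the selected `lm` fit, `aic`, `full_aic`,
#'   `r_squared`, `selected_terms` and `dropped_terms` (rank-deficient
#'   candidates removed before selection).
#' @examples
#' sim <- generate_feature_table(n_genes = 120, seed = 3)
#' fit <- fit_covariance_model(sim)
#' glance(fit)
#' @export
fit_covariance_model <- function(data,
                                 response = "ln_thalf",
                                 quantitative = intersect(
                                   c("ln_mrna", "length", "abs_dg", "cai",
                                     "tai", "gc", "position"), names(data)
                                 ),
                                 qualitative = intersect(
                                   c("mu_level", "category", "motif_class"),
                                   names(data)
                                 )) {
  terms_all <- c(quantitative, qualitative)
  stopifnot(length(terms_all) > 0, response %in% names(data))
  missing_cols <- setdiff(terms_all, names(data))
  if (length(missing_cols) > 0) {
    stop("candidate column(s) not in data: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data[, c(response, terms_all)]
  complete <- stats::complete.cases(df)
  if (!all(complete)) {
    message(sum(!complete), " row(s) with missing candidate values dropped")
    df <- df[complete, ]
  }
  df <- as.data.frame(df)
  for (v in quantitative) df[[v]] <- as.numeric(scale(df[[v]]))
  for (v in qualitative) df[[v]] <- droplevels(factor(df[[v]]))

  # Single-level factors and aliased (rank-deficient) terms cannot enter the
  # search; drop them up front and report.
  dropped <- qualitative[vapply(df[qualitative], nlevels, integer(1)) < 2]
  terms_use <- setdiff(terms_all, dropped)
  full_formula <- stats::reformulate(terms_use, response = response)
  full <- lm(full_formula, data = df)
  if (anyNA(coef(full))) {
    na_coef <- names(coef(full))[is.na(coef(full))]
    aliased <- terms_use[vapply(terms_use, function(tm) {
      any(startsWith(na_coef, tm))
    }, logical(1))]
    dropped <- c(dropped, aliased)
    terms_use <- setdiff(terms_use, aliased)
    full <- lm(stats::reformulate(terms_use, response = response), data = df)
  }
  if (length(dropped) > 0) {
    message("dropped rank-deficient/constant term(s): ",
            paste(dropped, collapse = ", "))
  }

  selected <- step(full, direction = "both",
                   scope = list(lower = ~1, upper = stats::formula(full)),
                   trace = 0)
  sm <- summary(selected)
  structure(
    list(
      model = selected,
      full_model = full,
      data = tibble::as_tibble(df),
      response = response,
      quantitative = quantitative,
      qualitative = setdiff(qualitative, dropped),
      dropped_terms = dropped,
      selected_terms = attr(stats::terms(selected), "term.labels"),
      aic = stats::AIC(selected),
      full_aic = stats::AIC(full),
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared
    ),
    class = "covmodel_fit"
  )
}

#' @export
print.covmodel_fit <- function(x, ...) {
  cat("<covmodel_fit> response:", x$response, "\n")
  cat("  selected terms:",
      if (length(x$selected_terms)) paste(x$selected_terms, collapse = ", ")
      else "(intercept only)", "\n")
  cat(sprintf("  R^2 = %.3f, AIC = %.1f (full model AIC = %.1f)\n",
              x$r_squared, x$aic, x$full_aic))
  if (length(x$dropped_terms) > 0) {
    cat("  dropped before selection:",
        paste(x$dropped_terms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname fit_covariance_model
#' @param x A `covmodel_fit` object.
#' @param ... Unused.
#' @method tidy covmodel_fit
#' @export
tidy.covmodel_fit <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"],
    significant = cf[, "Pr(>|t|)"] <= 0.05
  )
}

#' @rdname fit_covariance_model
#' @method glance covmodel_fit
#' @export
glance.covmodel_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    AIC = x$aic,
    AIC.full = x$full_aic,
    n = nrow(x$data),
    df.residual = x$model$df.residual,
    n.terms = length(x$selected_terms)
  )
}

#' Per-growth-rate models without the growth-rate term
#'
#' Quantifies how much of the half-life variance is explained by gene
#' features alone once growth rate no longer varies: the same candidate set
#' minus the growth-rate factor is fitted (with the same AIC selection)
#' within each growth-rate level separately, and each within-condition R^2
#' is reported. A large pooled R^2 collapsing to near zero here indicates
#' growth rate is the dominant determinant.
#'
#' @inheritParams fit_covariance_model
#' @param mu_col Growth-rate factor column (default `mu_level`).
#' @return A tibble: `mu_level`, `r_squared`, `n`, `n_terms`.
#' @export
growth_rate_only_r2 <- function(data,
                                response = "ln_thalf",
                                quantitative = intersect(
                                  c("ln_mrna", "length", "abs_dg", "cai",
                                    "tai", "gc", "position"), names(data)
                                ),
                                qualitative = intersect(
                                  c("category", "motif_class"), names(data)
                                ),
                                mu_col = "mu_level") {
  stopifnot(mu_col %in% names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(mu_col))) |>
    dplyr::group_map(~ {
      fit <- fit_covariance_model(
        .x, response = response,
        quantitative = quantitative,
        qualitative = setdiff(qualitative, mu_col)
      )
      tibble::tibble(
        mu_level = as.character(.y[[mu_col]]),
        r_squared = fit$r_squared,
        n = nrow(fit$data),
        n_terms = length(fit$selected_terms)
      )
    }) |>
    dplyr::bind_rows()
}
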