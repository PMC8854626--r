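# Logistic modelling of haematuria risk for heterozygous COL4A3/COL4A4
# Gly missense carriers.

#' Logistic regression of haematuria on molecular features
#'
#' Maximum-likelihood logistic fit (IRLS via `stats::glm`, gradient
#' tolerance 1e-8) of a binary outcome on the requested feature columns,
#' with per-term Wald tests, model and null log-likelihoods, and
#' McFadden's pseudo-R².  Perfect separation and constant feature columns
#' are rejected.
#'
#' @param cohort data.frame with an `outcome` column (0/1 or logical) and
#'   the feature columns.
#' @param terms character vector of feature column names (the intercept is
#'   always included).
#' @return list of class `logistic_result`: data.frame `terms` (term,
#'   estimate, se, z, p_wald), `ll_model`, `ll_null`, `pseudo_r2`,
#'   `n`, `n_cases`, underlying `fit`.
#' @export
logistic_fit <- function(cohort, terms) {
  d <- as.data.frame(cohort)
  if (!"outcome" %in% names(d))
    col4gly_error("schema_error", "cohort missing column: outcome")
  y <- as.integer(as.logical(d$outcome))
  if (any(is.na(y))) col4gly_error("input_error", "outcome must be binary with no NA")
  if (sum(y) == 0L || sum(y) == length(y))
    col4gly_error("input_error", "cohort needs at least one case and one control")
  for (tm in terms) {
    v <- d[[tm]]
    if (is.null(v)) col4gly_error("schema_error", paste("missing feature column:", tm))
    if (length(unique(v)) < 2L)
      col4gly_error("degenerate_error", sprintf("feature '%s' is constant", tm))
  }
  d$outcome <- y
  form <- stats::as.formula(paste("outcome ~",
                                  if (length(terms)) paste(terms, collapse = " + ") else "1"))
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = d,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  # perfect separation: fitted probabilities pinned at 0/1 that classify exactly
  eps <- 1e-8
  pinned <- fit$fitted.values < eps | fit$fitted.values > 1 - eps
  if (length(terms) && any(pinned) &&
      all(round(fit$fitted.values[pinned]) == y[pinned]) &&
      max(abs(stats::coef(fit)[-1])) > 10)
    col4gly_error("separation_error",
                  "perfect separation: a feature completely predicts the outcome")
  sm <- summary(fit)$coefficients
  terms_df <- data.frame(term = rownames(sm),
                         estimate = sm[, "Estimate"],
                         se = sm[, "Std. Error"],
                         z = sm[, "z value"],
                         p_wald = sm[, "Pr(>|z|)"],
                         row.names = NULL, stringsAsFactors = FALSE)
  ll_model <- as.numeric(stats::logLik(fit))
  null_fit <- stats::glm(outcome ~ 1, family = stats::binomial(), data = d)
  ll_null <- as.numeric(stats::logLik(null_fit))
  structure(list(terms = terms_df, ll_model = ll_model, ll_null = ll_null,
                 pseudo_r2 = mcfadden_pseudo_r2(ll_model, ll_null),
                 n = length(y), n_cases = sum(y), fit = fit),
            class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("Logistic fit: n=%d (%d cases), McFadden pseudo-R2 = %.3f\n",
              x$n, x$n_cases, x$pseudo_r2))
  print(x$terms, digits = 3)
  invisible(x)
}

#' McFadden's pseudo-R-squared
#'
#' `1 - ll_model / ll_null` for a fitted logistic model against the
#' intercept-only model.
#'
#' @param ll_model,ll_null log-likelihoods (both negative,
#'   `ll_model >= ll_null`).
#' @return numeric in `[0, 1)`.
#' @export
mcfadden_pseudo_r2 <- function(ll_model, ll_null) {
  if (!is.finite(ll_model) || !is.finite(ll_null) || ll_null >= 0)
    col4gly_error("input_error", "log-likelihoods must be finite and negative")
  if (ll_model < ll_null - 1e-9)
    col4gly_error("ordering_error", "ll_model must be >= ll_null")
  1 - ll_model / ll_null
}

#' Drop carriers of named variants (sensitivity analysis)
#'
#' Removes every individual carrying any of the listed variant labels
#' (matched against the cohort's `protein_hgvs` column) and reports the
#' removed count.  Labels absent from the cohort trigger a warning only.
#'
#' @param cohort data.frame with a `protein_hgvs` column.
#' @param variant_labels character vector (e.g. `c("Gly695Arg",
#'   "Gly1277Ser")`).
#' @return the reduced cohort, with attribute `n_removed`.
#' @export
sensitivity_exclude <- function(cohort, variant_labels) {
  d <- as.data.frame(cohort)
  if (length(variant_labels) == 0L) {
    attr(d, "n_removed") <- 0L
    return(d)
  }
  if (!"protein_hgvs" %in% names(d))
    col4gly_error("schema_error", "cohort missing column: protein_hgvs")
  canon <- function(x) vapply(x, function(s)
    tryCatch(format_protein(parse_protein(s)), error = function(e) as.character(s)),
    character(1))
  lbl <- canon(variant_labels)
  have <- canon(d$protein_hgvs)
  missing_lbl <- setdiff(lbl, have)
  if (length(missing_lbl))
    col4gly_warning("label_warning",
                    paste("variant label(s) not present in cohort:",
                          paste(missing_lbl, collapse = ", ")))
  drop <- have %in% lbl
  out <- d[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Local-region subgroup of a haematuria cohort
#'
#' Drops all non-collagenous boundary carriers and swaps the boundary
#' indicator for amino-end / carboxyl-end indicators (central variants are
#' the reference), for the subgroup refit.
#'
#' @param cohort annotated data.frame with a `position_class` column.
#' @return list with `cohort` (subgroup, with `amino_end` and
#'   `carboxyl_end` indicator columns added) and `terms` (suggested model
#'   terms for the refit).
#' @export
subgroup_local_region <- function(cohort) {
  d <- as.data.frame(cohort)
  if (!"position_class" %in% names(d))
    col4gly_error("schema_error", "cohort missing column: position_class")
  sub <- d[d$position_class != "nc_boundary", , drop = FALSE]
  if (nrow(sub) == 0L)
    col4gly_error("input_error", "no individuals remain after excluding boundary carriers")
  sub$amino_end <- as.integer(sub$position_class == "amino_end")
  sub$carboxyl_end <- as.integer(sub$position_class == "carboxyl_end")
  list(cohort = sub,
       terms = c("is_carboxyl_block", "amino_end", "carboxyl_end", "is_high_destab"))
}
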