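# Record extraction, family aggregation, and time-to-event analysis of
# kidney failure and hearing-loss diagnosis ages.

.endpoint_keywords <- list(
  kidney  = c("renal", "failure", "ESRD", "ESRF", "ESKD", "ESKF",
              "transplant", "dialysis"),
  hearing = c("hearing", "hypoacusia", "deaf", "sensorineural", "audio"))

#' Filter individual records by endpoint keywords
#'
#' Keeps records whose free-text phenotype contains any of the endpoint's
#' keywords, case-insensitively.  Kidney-failure keywords: renal, failure,
#' ESRD, ESRF, ESKD, ESKF, transplant, dialysis.  Hearing keywords:
#' hearing, hypoacusia, deaf, sensorineural, audio.
#'
#' @param records data.frame with a `phenotype_text` column.
#' @param endpoint `"kidney"` or `"hearing"`.
#' @return the filtered data.frame.
#' @export
phenotype_keyword_filter <- function(records, endpoint) {
  if (!endpoint %in% names(.endpoint_keywords))
    col4gly_error("domain_error",
                  sprintf("unknown endpoint '%s' (use 'kidney' or 'hearing')", endpoint))
  if (!"phenotype_text" %in% names(records))
    col4gly_error("schema_error", "records missing column: phenotype_text")
  kw <- .endpoint_keywords[[endpoint]]
  pat <- paste(kw, collapse = "|")
  keep <- grepl(pat, records$phenotype_text, ignore.case = TRUE)
  records[keep, , drop = FALSE]
}

#' Aggregate one family's records into a single survival observation
#'
#' Each family enters the analysis once.  Affected males with an event
#' contribute their event age (a reported age range contributes its
#' midpoint); multiple affected males are averaged (mean).  If no male in
#' the family has had the event, the family is censored at the latest
#' last-seen age among its males.  Families with no male records yield an
#' extraction error (families with only affected females are excluded).
#'
#' @param records data.frame of one family's individuals, columns
#'   `family_id`, `sex` (`"M"`/`"F"`), `event_age`, `event_age_low`,
#'   `event_age_high`, `last_seen_age` (ages in years; `NA` when absent).
#' @return list with `family_id`, `time` (years), `event` (logical).
#' @export
aggregate_family <- function(records) {
  r <- as.data.frame(records)
  fam <- unique(r$family_id)
  if (length(fam) != 1L)
    col4gly_error("input_error", "aggregate_family expects records of a single family")
  males <- r[toupper(substr(r$sex, 1, 1)) == "M", , drop = FALSE]
  if (nrow(males) == 0L)
    col4gly_error("extraction_error",
                  sprintf("family %s has no male records (female-only families are excluded)", fam))
  num <- function(x) suppressWarnings(as.numeric(x))
  ev <- ifelse(!is.na(num(males$event_age)), num(males$event_age),
               ifelse(!is.na(num(males$event_age_low)) & !is.na(num(males$event_age_high)),
                      (num(males$event_age_low) + num(males$event_age_high)) / 2,
                      NA_real_))
  if (any(!is.na(ev))) {
    t <- mean(ev[!is.na(ev)])
    if (!is.finite(t) || t <= 0)
      col4gly_error("extraction_error",
                    sprintf("family %s: non-positive aggregated event age", fam))
    return(list(family_id = fam, time = t, event = TRUE))
  }
  cens <- num(males$last_seen_age)
  if (all(is.na(cens)))
    col4gly_error("extraction_error",
                  sprintf("family %s has no usable event or last-seen age", fam))
  t <- max(cens, na.rm = TRUE)
  if (t <= 0)
    col4gly_error("extraction_error",
                  sprintf("family %s: non-positive censoring age", fam))
  list(family_id = fam, time = t, event = FALSE)
}

#' Build the per-family observation table from a registry
#'
#' Applies the endpoint keyword filter, drops multi-variant carriers and
#' female-only families, and aggregates each remaining family with
#' [aggregate_family()].
#'
#' @param registry data.frame, one row per individual, columns
#'   `family_id`, `sex`, `phenotype_text`, age columns as in
#'   [aggregate_family()], optional `n_variants` (individuals with more
#'   than one COL4A3-COL4A5 variant are excluded), plus any per-family
#'   covariate columns (carried through from the first male record).
#' @param endpoint `"kidney"` or `"hearing"`.
#' @param covariates character vector of covariate column names to carry.
#' @return data.frame with `family_id`, `time`, `event` and the covariate
#'   columns; attribute `exclusions` holds a named count vector.
#' @export
build_family_observations <- function(registry, endpoint = "kidney",
                                      covariates = character(0)) {
  reg <- as.data.frame(registry)
  n_read <- nrow(reg)
  kept <- phenotype_keyword_filter(reg, endpoint)
  n_keyword_dropped <- n_read - nrow(kept)
  if ("n_variants" %in% names(kept)) {
    multi <- !is.na(kept$n_variants) & kept$n_variants > 1
    n_multi <- sum(multi)
    kept <- kept[!multi, , drop = FALSE]
  } else n_multi <- 0L
  fams <- split(kept, kept$family_id)
  obs <- list(); n_female_only <- 0L; n_no_age <- 0L
  for (f in fams) {
    o <- tryCatch(aggregate_family(f), col4gly_error = function(e) e)
    if (inherits(o, "error")) {
      if (grepl("no male records", conditionMessage(o))) n_female_only <- n_female_only + 1L
      else n_no_age <- n_no_age + 1L
      next
    }
    males <- f[toupper(substr(f$sex, 1, 1)) == "M", , drop = FALSE]
    for (cv in covariates) o[[cv]] <- males[[cv]][1L]
    obs[[length(obs) + 1L]] <- as.data.frame(o, stringsAsFactors = FALSE)
  }
  out <- if (length(obs)) do.call(rbind, obs) else
    data.frame(family_id = character(0), time = numeric(0), event = logical(0))
  attr(out, "exclusions") <- c(read = n_read,
                               keyword_filtered = n_keyword_dropped,
                               multi_variant = n_multi,
                               female_only = n_female_only,
                               no_usable_age = n_no_age,
                               analyzed_families = nrow(out))
  out
}

#' Kaplan-Meier fit of family observations
#'
#' Product-limit estimate with Greenwood variance and log-transformed
#' pointwise 95% confidence bounds (the survival package's `conf.type =
#' "log"`).  The median is the smallest time at which the estimate falls
#' to 0.5 or below; an unreached median or CI bound is reported as `NA`
#' ("ND" in tabulations).
#'
#' @param observations data.frame with `time` and `event`.
#' @return list of class `km_curve`: `times`, `survival`, `ci_low`,
#'   `ci_high`, `median`, `median_ci`, `n`, `n_events`, and the underlying
#'   `survfit` object as `fit`.
#' @export
km_fit <- function(observations) {
  obs <- as.data.frame(observations)
  if (nrow(obs) < 1L) col4gly_error("input_error", "no observations")
  if (any(!is.finite(obs$time)) || any(obs$time <= 0))
    col4gly_error("input_error", "observation times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = obs,
                           conf.type = "log")
  s <- summary(fit)
  med_tab <- summary(fit)$table
  med <- unname(med_tab["median"])
  med_ci <- c(unname(med_tab["0.95LCL"]), unname(med_tab["0.95UCL"]))
  structure(list(times = fit$time, survival = fit$surv,
                 ci_low = fit$lower, ci_high = fit$upper,
                 median = med, median_ci = med_ci,
                 n = nrow(obs), n_events = sum(obs$event), fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "ND", format(v, digits = 4))
  cat(sprintf("Kaplan-Meier: n=%d, events=%d, median %s (95%% CI %s, %s)\n",
              x$n, x$n_events, fmt(x$median),
              fmt(x$median_ci[1]), fmt(x$median_ci[2])))
  invisible(x)
}

#' Log-rank test across groups
#'
#' @param group factor/vector of group labels, one per observation.
#' @param observations data.frame with `time` and `event`.
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(group, observations) {
  obs <- as.data.frame(observations)
  g <- factor(group)
  if (nlevels(g) < 2L || any(table(g) == 0L))
    col4gly_error("input_error", "log-rank test needs >= 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(obs$time, obs$event) ~ g)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation with Efron handling of tied event
#' times.  Reports per-covariate hazard ratios with 95% Wald intervals and
#' p-values, and the overall likelihood-ratio test against the null model.
#'
#' @param observations data.frame with `time`, `event` and covariate
#'   columns.
#' @param covariates character vector of covariate column names.
#' @return list of class `cox_result`: data.frame `terms` (term, coef,
#'   hr, ci_low, ci_high, se, p_wald), `lr_chisq`, `lr_df`, `lr_p`,
#'   `n`, `n_events`, underlying `fit`.
#' @export
cox_fit <- function(observations, covariates) {
  obs <- as.data.frame(observations)
  if (sum(obs$event) < 2L)
    col4gly_error("input_error", "Cox model needs at least 2 events")
  for (cv in covariates) {
    v <- obs[[cv]]
    if (is.null(v)) col4gly_error("schema_error", paste("missing covariate column:", cv))
    if (length(unique(v[!is.na(v)])) < 2L)
      col4gly_error("degenerate_covariate_error",
                    sprintf("covariate '%s' does not vary", cv))
  }
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(form, data = obs, ties = "efron"),
    warning = function(w) {
      if (grepl("did not converge|infinite", conditionMessage(w)))
        col4gly_error("convergence_error",
                      paste("Cox fit did not converge:", conditionMessage(w)))
      suppressWarnings(survival::coxph(form, data = obs, ties = "efron"))
    })
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- data.frame(term = rownames(co),
                      coef = co[, "coef"],
                      hr = exp(co[, "coef"]),
                      ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                      ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                      se = co[, "se(coef)"],
                      p_wald = co[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  lr <- sm$logtest
  structure(list(terms = terms,
                 lr_chisq = unname(lr["test"]), lr_df = unname(lr["df"]),
                 lr_p = unname(lr["pvalue"]),
                 n = nrow(obs), n_events = sum(obs$event), fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH (Efron ties): n=%d, events=%d, LR p=%.4g\n",
              x$n, x$n_events, x$lr_p))
  print(x$terms, digits = 3)
  invisible(x)
}

#' Survival subgroup excluding boundary variants
#'
#' Drops families whose variant hits a non-collagenous boundary Gly and
#' returns the remaining observations together with the local-region
#' covariate set (`amino_end`, `carboxyl_end`; central is the reference),
#' mirroring the main-analysis aggregation unchanged.
#'
#' @param observations data.frame with `position_class` among its columns.
#' @return list with `observations` (subgroup) and `covariates`
#'   (character vector for the refit).
#' @export
survival_subgroup_local_region <- function(observations) {
  obs <- as.data.frame(observations)
  if (!"position_class" %in% names(obs))
    col4gly_error("schema_error", "observations missing column: position_class")
  sub <- obs[obs$position_class != "nc_boundary", , drop = FALSE]
  if (nrow(sub) == 0L) col4gly_error("input_error", "subgroup is empty")
  sub$amino_end <- as.integer(sub$position_class == "amino_end")
  sub$carboxyl_end <- as.integer(sub$position_class == "carboxyl_end")
  list(observations = sub, covariates = c("amino_end", "carboxyl_end"))
}
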