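# End-to-end orchestration: file readers/writers, the splice-exclusion
# step, and a manifest that reconciles every record in and out.

#' Read a tab-separated variant/registry/cohort table
#'
#' Tab-separated with a header; `#`-prefixed lines are comments.
#' `required` columns are checked and a schema error names any missing
#' column.
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @return data.frame.
#' @export
read_variant_table <- function(path, required = "protein_hgvs") {
  if (!file.exists(path))
    col4gly_error("io_error", paste("no such file:", path))
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    col4gly_error("schema_error",
                  paste("table missing required column(s):",
                        paste(miss, collapse = ", ")))
  tab
}

#' Write a table as tab-separated text
#'
#' Lossless round trip with [read_variant_table()] for all declared
#' columns.
#'
#' @param table data.frame.
#' @param path file path.
#' @export
write_variant_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a structured JSON report
#'
#' @param report named list.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# splice screen over an annotated table: flag rows whose cDNA position is
# within 3 bases of an internal junction and whose mutant window scores
# >15% below wild type under the supplied models and context sequence.
# Without cDNA or context, near-junction candidacy alone is not an
# exclusion (flag stays FALSE) unless conservative = TRUE.
splice_flag_table <- function(arch, tab, cds = NULL, donor_model = NULL,
                              threshold = 0.15, conservative = FALSE) {
  n <- nrow(tab)
  flag <- rep(FALSE, n)
  has_cdna <- "cdna_hgvs" %in% names(tab)
  for (i in seq_len(n)) {
    if (!has_cdna || is.na(tab$cdna_hgvs[i]) || !nzchar(tab$cdna_hgvs[i])) next
    v <- tryCatch(parse_cdna(tab$cdna_hgvs[i]), error = function(e) NULL)
    if (is.null(v)) next
    cds_len <- arch$exon_map$cdna_end[nrow(arch$exon_map)]
    if (v$cdna_position > cds_len) next
    if (!near_splice_site(arch, v$cdna_position)) next
    if (is.null(donor_model) || is.null(cds)) {
      flag[i] <- conservative
      next
    }
    # donor window: last 3 exonic bases + 6 intronic; intronic context is
    # unavailable from a CDS alone, so fill with the canonical GTAAGT and
    # score the exonic part of the window (documented "context
    # unavailable" fill).
    em <- arch$exon_map
    ex_end <- em$cdna_end[findInterval(v$cdna_position, em$cdna_start)]
    seqv <- strsplit(toupper(cds), "")[[1]]
    wt_ex <- seqv[(ex_end - 2L):ex_end]
    mut_ex <- wt_ex
    off <- v$cdna_position - (ex_end - 2L) + 1L
    if (off >= 1L && off <= 3L) {
      if (wt_ex[off] != v$ref_base) next   # ref mismatch: leave unflagged
      mut_ex[off] <- v$alt_base
      fill <- c("G", "T", "A", "A", "G", "T")
      wt <- score_site(donor_model, paste(c(wt_ex, fill), collapse = ""))
      mu <- score_site(donor_model, paste(c(mut_ex, fill), collapse = ""))
      flag[i] <- assess_splice_effect(wt, mu, threshold)$affected
    }
  }
  flag
}

#' Run the full analysis pipeline on file inputs
#'
#' Executes annotate -> splice screen -> requested stages and returns a
#' manifest whose record counts reconcile: `read = analyzed +
#' sum(exclusions)` for each stage input.
#'
#' @param config named list with elements:
#'   * `architecture`: list(`segment_file`, `exon_file`) or a
#'     `chain_architecture`;
#'   * `registry_file` (optional): per-individual registry table;
#'   * `cohort_file` (optional): case-control table;
#'   * `allele_file` (optional) + `male_total`/`female_total`;
#'   * `rate_table_file` (optional; default internal table);
#'   * `cds_file` (optional FASTA or plain text, for the population stage);
#'   * `endpoint` (`"kidney"`/`"hearing"`, default kidney);
#'   * `splice_threshold` (default 0.15), `splice_conservative`
#'     (default TRUE: near-junction variants are excluded when no
#'     intronic context is available);
#'   * `out_dir` (optional: reports are written there as JSON/TSV).
#' @param seed seed for any stochastic step (none in analysis stages;
#'   recorded in the manifest).
#' @return list of class `run_manifest` with per-stage reports and counts.
#' @export
run_pipeline <- function(config, seed = 1L) {
  arch <- config$architecture
  if (!inherits(arch, "chain_architecture")) {
    if (is.null(arch$segment_file) || !file.exists(arch$segment_file) ||
        !file.exists(arch$exon_file %||% ""))
      col4gly_error("io_error", "architecture files not found")
    arch <- read_architecture(arch$segment_file, arch$exon_file)
  }
  for (f in c("registry_file", "cohort_file", "allele_file", "cds_file")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      col4gly_error("io_error", paste("missing input:", config[[f]]))
  }
  rate_tab <- if (!is.null(config$rate_table_file))
    read_rate_table(config$rate_table_file) else make_rate_table()
  thr <- config$splice_threshold %||% 0.15
  conservative <- config$splice_conservative %||% TRUE
  manifest <- list(seed = seed, chain = arch$chain_id, stages = list())
  reports <- list()

  screen_and_annotate <- function(tab, label) {
    n_read <- nrow(tab)
    ann <- annotate_table(arch, tab)
    bad <- !is.na(ann$annotation_error)
    flag <- splice_flag_table(arch, ann, conservative = conservative,
                              threshold = thr)
    ann$splice_flagged <- flag
    keep <- ann[!bad & !flag, , drop = FALSE]
    manifest$stages[[label]] <<- list(
      read = n_read,
      excluded_splice = sum(flag & !bad),
      excluded_annotation = sum(bad),
      analyzed = nrow(keep),
      exclusion_reasons = c(splice_predicted = sum(flag & !bad),
                            annotation_failed = sum(bad)))
    keep
  }

  if (!is.null(config$registry_file)) {
    reg <- read_variant_table(config$registry_file,
                              required = c("family_id", "sex", "phenotype_text",
                                           "protein_hgvs"))
    reg <- screen_and_annotate(reg, "survival")
    covs <- c("is_carboxyl_block", "is_nc_boundary", "is_high_destab")
    if (!all(covs %in% names(reg))) {
      reg$is_carboxyl_block <- as.integer(!reg$is_amino_block)
      reg$is_nc_boundary <- as.integer(reg$position_class == "nc_boundary")
      reg$is_high_destab <- as.integer(reg$destab_class == "high")
    }
    obs <- build_family_observations(reg, endpoint = config$endpoint %||% "kidney",
                                     covariates = c(covs, "position_class"))
    km <- km_fit(obs)
    cox <- tryCatch(cox_fit(obs, covs), col4gly_error = function(e) e)
    reports$survival <- list(
      n_families = nrow(obs), n_events = sum(obs$event),
      km_median = km$median, km_median_ci = km$median_ci,
      exclusions = as.list(attr(obs, "exclusions")),
      cox = if (inherits(cox, "cox_result"))
        list(terms = cox$terms, lr_p = cox$lr_p) else
        list(error = conditionMessage(cox)))
  }

  if (!is.null(config$cohort_file)) {
    coh <- read_variant_table(config$cohort_file,
                              required = c("outcome", "protein_hgvs"))
    coh <- screen_and_annotate(coh, "haematuria")
    coh$is_carboxyl_block <- as.integer(!coh$is_amino_block)
    coh$is_nc_boundary <- as.integer(coh$position_class == "nc_boundary")
    coh$is_high_destab <- as.integer(coh$destab_class == "high")
    fit <- logistic_fit(coh, c("is_carboxyl_block", "is_nc_boundary",
                               "is_high_destab"))
    reports$haematuria <- list(n = fit$n, n_cases = fit$n_cases,
                               terms = fit$terms, pseudo_r2 = fit$pseudo_r2)
  }

  if (!is.null(config$allele_file)) {
    alle <- read_allele_table(config$allele_file)
    n_read <- nrow(alle)
    ann <- annotate_table(arch, alle)
    bad <- !is.na(ann$annotation_error)
    ok <- ann[!bad, , drop = FALSE]
    manifest$stages$population <- list(read = n_read, excluded_splice = 0L,
                                       excluded_annotation = sum(bad),
                                       analyzed = nrow(ok),
                                       exclusion_reasons = c(annotation_failed = sum(bad)))
    k <- sum(ok$position_class == "nc_boundary")
    n <- nrow(ok)
    pop <- list(observed_boundary = k, n_variants = n,
                observed_fraction = if (n > 0) k / n else NA_real_)
    if (!is.null(config$cds_file)) {
      cds <- read_cds(config$cds_file)
      expct <- expected_boundary_fraction(arch, cds, rate_tab)
      pop$expected_fraction <- expct
      pop$binomial_p_greater <- exact_binomial(k, n, expct, "greater")
      pop$binomial_p_two_sided <- exact_binomial(k, n, expct, "two_sided")
    }
    if (!is.null(config$male_total) && !is.null(config$female_total)) {
      prev <- carrier_prevalence(ok[ok$position_class == "nc_boundary", ,
                                    drop = FALSE],
                                 config$male_total, config$female_total)
      pop$prevalence <- prev
    }
    reports$population <- pop
  }

  manifest$reports <- reports
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(manifest, file.path(config$out_dir, "report.json"))
  }
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest (chain %s, seed %d)\n", x$chain, x$seed))
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %s: read %d, analyzed %d, excluded %d (splice %d, annotation %d)\n",
                nm, s$read, s$analyzed, s$read - s$analyzed,
                s$excluded_splice, s$excluded_annotation))
  }
  invisible(x)
}

#' Read a coding sequence from FASTA or plain text
#'
#' A `>`-headed file is parsed as single-record FASTA; otherwise the file
#' body (minus comments and whitespace) is the sequence.
#'
#' @param path file path.
#' @return character scalar (uppercase).
#' @export
read_cds <- function(path) {
  if (!file.exists(path)) col4gly_error("io_error", paste("no such file:", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) && startsWith(lines[1], ">")) lines <- lines[-1L]
  s <- toupper(gsub("\\s", "", paste(lines, collapse = "")))
  if (!nzchar(s) || grepl("[^ACGTN]", s))
    col4gly_error("input_error", "CDS contains non-nucleotide characters")
  s
}

#' Write a coding sequence as FASTA
#' @param cds character scalar.
#' @param path file path.
#' @param name FASTA record name.
#' @export
write_cds <- function(cds, path, name = "cds") {
  chunks <- substring(cds, seq(1, nchar(cds), 60),
                      pmin(seq(60, nchar(cds) + 59, 60), nchar(cds)))
  writeLines(c(paste0(">", name), chunks), path)
  invisible(path)
}
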