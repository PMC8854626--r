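# Observed vs expected proportions of boundary-Gly missense variants under
# a neighbour-dependent nucleotide substitution-rate model, and carrier
# prevalence from allele-count tables.

#' Build a neighbour-dependent substitution rate table
#'
#' A rate table maps every context `(left, ref, alt, right)` — 12
#' substitution types x 16 flanking contexts — to a strictly positive
#' relative rate.  `make_rate_table()` builds one from a transition /
#' transversion ratio and a CpG transition multiplier (applied to G>A with
#' a C on the left and C>T with a G on the right, i.e. deamination of
#' methylated CpG on either strand), the dominant context effects of the
#' human germline mutation spectrum.
#'
#' @param titv transition:transversion rate ratio (default 4).
#' @param cpg_multiplier extra multiplier for CpG transitions (default 10).
#' @return data.frame of class `rate_table` with columns `left`, `ref`,
#'   `alt`, `right`, `rate`.
#' @export
make_rate_table <- function(titv = 4, cpg_multiplier = 10) {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(left = b, ref = b, alt = b, right = b,
                   stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, ]
  is_ts <- (g$ref == "A" & g$alt == "G") | (g$ref == "G" & g$alt == "A") |
           (g$ref == "C" & g$alt == "T") | (g$ref == "T" & g$alt == "C")
  rate <- ifelse(is_ts, titv, 1)
  cpg <- (g$ref == "G" & g$alt == "A" & g$left == "C") |
         (g$ref == "C" & g$alt == "T" & g$right == "G")
  rate[cpg & is_ts] <- rate[cpg & is_ts] * cpg_multiplier
  out <- data.frame(g, rate = rate, row.names = NULL)
  class(out) <- c("rate_table", "data.frame")
  out
}

.rate_key <- function(left, ref, alt, right) paste(left, ref, alt, right, sep = "|")

revcomp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Read a rate table file
#'
#' Tab-separated columns `left`, `ref`, `alt`, `right`, `rate`; `#` lines
#' are comments.  Unless the file carries a `#stranded` directive the
#' table is strand-symmetrized at load: each context's rate is averaged
#' with its reverse complement.
#'
#' @param path file path.
#' @return a `rate_table`.
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) col4gly_error("io_error", paste("no such file:", path))
  lines <- readLines(path)
  stranded <- any(grepl("^#\\s*stranded", lines))
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  need <- c("left", "ref", "alt", "right", "rate")
  if (!all(need %in% names(tab)))
    col4gly_error("schema_error",
                  paste("rate table missing column(s):",
                        paste(setdiff(need, names(tab)), collapse = ", ")))
  if (any(tab$rate <= 0))
    col4gly_error("input_error", "rates must be strictly positive")
  if (!stranded) {
    rc_key <- .rate_key(revcomp_base(tab$right), revcomp_base(tab$ref),
                        revcomp_base(tab$alt), revcomp_base(tab$left))
    idx <- match(rc_key, .rate_key(tab$left, tab$ref, tab$alt, tab$right))
    if (any(is.na(idx)))
      col4gly_error("completeness_error",
                    "cannot strand-symmetrize: reverse-complement contexts missing")
    tab$rate <- (tab$rate + tab$rate[idx]) / 2
  }
  class(tab) <- c("rate_table", "data.frame")
  tab
}

#' Write a rate table file
#' @param table a `rate_table`.
#' @param path file path.
#' @param stranded emit a `#stranded` directive so the table is not
#'   re-symmetrized on load.
#' @export
write_rate_table <- function(table, path, stranded = TRUE) {
  con <- file(path, "w"); on.exit(close(con))
  if (stranded) writeLines("#stranded", con)
  utils::write.table(as.data.frame(table)[, c("left", "ref", "alt", "right", "rate")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up a context-dependent substitution rate
#'
#' @param table a `rate_table`.
#' @param left,ref,alt,right single bases; `ref != alt`.
#' @return numeric rate(s).
#' @export
context_rate <- function(table, left, ref, alt, right) {
  if (any(ref == alt))
    col4gly_error("input_error", "ref and alt bases must differ")
  ok <- c(left, ref, alt, right) %in% c("A", "C", "G", "T")
  if (!all(ok)) col4gly_error("input_error", "bases must be one of A, C, G, T")
  idx <- match(.rate_key(left, ref, alt, right),
               .rate_key(table$left, table$ref, table$alt, table$right))
  if (any(is.na(idx)))
    col4gly_error("completeness_error", "context missing from rate table")
  table$rate[idx]
}

#' Expected fraction of Gly missense SNVs hitting boundary residues
#'
#' Enumerates every single-base substitution in every collagenous-Gly
#' codon of the CDS that yields a missense change (non-Gly, non-stop),
#' weights each by its neighbour-dependent rate (flanking bases taken from
#' the CDS; at a sequence edge the single available neighbour is used for
#' both sides), and returns the rate mass on non-collagenous boundary Gly
#' over the rate mass on all collagenous Gly.  The result is invariant
#' under global rescaling of the rate table, and reduces to the raw SNV
#' count fraction for a uniform table.
#'
#' @param arch a `chain_architecture`.
#' @param cds character scalar, coding sequence of length `3 * L`, whose
#'   Gly codons coincide with the architecture's Gly slots.
#' @param table a `rate_table`.
#' @param exclude_splice drop substitutions within 3 bases of an internal
#'   exon junction (the splice screen's candidate set); default `FALSE`.
#' @return proportion in `[0, 1]`.
#' @export
expected_boundary_fraction <- function(arch, cds, table, exclude_splice = FALSE) {
  stopifnot(inherits(arch, "chain_architecture"))
  cds <- toupper(cds)
  if (nchar(cds) != 3L * arch$length)
    col4gly_error("consistency_error",
                  sprintf("CDS length %d does not match 3 x chain length (%d)",
                          nchar(cds), 3L * arch$length))
  seqv <- strsplit(cds, "")[[1]]
  gp <- gly_positions(arch)
  if (nrow(gp) == 0L) col4gly_error("input_error", "architecture has no Gly slots")
  cls <- classify_position(arch, gp$residue)
  bases <- c("A", "C", "G", "T")
  mass_boundary <- 0; mass_total <- 0
  for (i in seq_len(nrow(gp))) {
    res <- gp$residue[i]
    cpos <- 3L * (res - 1L) + 1:3
    codon <- paste(seqv[cpos], collapse = "")
    if (translate_codon(codon) != "G")
      col4gly_error("consistency_error",
                    sprintf("CDS codon at residue %d is %s, not Gly", res, codon))
    for (k in 1:3) {
      p <- cpos[k]
      if (exclude_splice && near_splice_site(arch, p)) next
      ref <- seqv[p]
      left <- if (p > 1L) seqv[p - 1L] else seqv[p + 1L]
      right <- if (p < length(seqv)) seqv[p + 1L] else seqv[p - 1L]
      for (alt in setdiff(bases, ref)) {
        mut <- codon
        substr(mut, k, k) <- alt
        aa <- translate_codon(mut)
        if (aa == "G" || aa == "*") next
        r <- context_rate(table, left, ref, alt, right)
        mass_total <- mass_total + r
        if (cls[i] == "nc_boundary") mass_boundary <- mass_boundary + r
      }
    }
  }
  if (mass_total == 0)
    col4gly_error("input_error", "no missense substitutions to weight")
  mass_boundary / mass_total
}

#' Exact binomial test by direct tail summation
#'
#' One-sided tails sum the binomial mass directly; the two-sided p-value
#' sums the mass of every outcome whose probability does not exceed that
#' of the observed count (the standard exact two-sided definition).
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials.
#' @param p0 null proportion in (0, 1).
#' @param alternative `"greater"`, `"less"` or `"two_sided"`.
#' @return p-value.
#' @export
exact_binomial <- function(k, n, p0, alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    col4gly_error("domain_error", "p0 must lie strictly between 0 and 1")
  k <- as.integer(k); n <- as.integer(n)
  if (is.na(k) || is.na(n) || k < 0L || n < 1L || k > n)
    col4gly_error("domain_error", "need 0 <= k <= n")
  mass <- stats::dbinom(0:n, n, p0)
  p <- switch(alternative,
              greater = sum(mass[(k + 1L):(n + 1L)]),
              less = sum(mass[1L:(k + 1L)]),
              two_sided = sum(mass[mass <= mass[k + 1L] * (1 + 1e-7)]))
  min(1, p)
}

#' Total allele count for an X-linked variant
#'
#' Hemizygous males carry one allele, heterozygous females one,
#' homozygous females two: `hem + het + 2 * hom`.
#'
#' @param hem,het,hom non-negative integer counts.
#' @return integer allele total(s).
#' @export
allele_total <- function(hem, het, hom) {
  v <- cbind(hem, het, hom)
  if (any(is.na(v)) || any(v < 0) || any(v != floor(v)))
    col4gly_error("domain_error", "counts must be non-negative integers")
  as.integer(hem + het + 2L * hom)
}

#' Carrier prevalence from allele-count records
#'
#' Each individual carrying at least one allele counts once (hemizygous
#' males, heterozygous and homozygous females), summed across variants
#' under the rare-variant approximation of no co-occurrence, over the
#' sampled population.
#'
#' @param records data.frame with columns `hem`, `het`, `hom`.
#' @param male_total,female_total sampled individuals by sex.
#' @return list with `carrier_count`, `population_size`, `prevalence`,
#'   `one_in` (rounded reciprocal; `NA` when prevalence is 0).
#' @export
carrier_prevalence <- function(records, male_total, female_total) {
  if (male_total <= 0 || female_total <= 0)
    col4gly_error("domain_error", "population totals must be positive")
  r <- as.data.frame(records)
  if (nrow(r) > 0L && (any(is.na(c(r$hem, r$het, r$hom))) ||
                       any(c(r$hem, r$het, r$hom) < 0)))
    col4gly_error("domain_error", "counts must be non-negative integers")
  carriers <- if (nrow(r) == 0L) 0L else sum(r$hem + r$het + r$hom)
  pop <- male_total + female_total
  if (carriers > pop)
    col4gly_error("consistency_error", "more carriers than sampled individuals")
  prev <- carriers / pop
  list(carrier_count = as.integer(carriers), population_size = pop,
       prevalence = prev,
       one_in = if (prev > 0) round(1 / prev) else NA_integer_)
}

#' Read an allele-count table
#'
#' Tab-separated with header; columns `variant`, `hem`, `het`, `hom`
#' (gnomAD-style counts) plus optional passthrough columns; `#` lines are
#' comments.  A `total_alleles` column, when absent, is computed with
#' [allele_total()].
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_allele_table <- function(path) {
  if (!file.exists(path)) col4gly_error("io_error", paste("no such file:", path))
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("variant", "hem", "het", "hom")
  if (!all(need %in% names(tab)))
    col4gly_error("schema_error",
                  paste("allele table missing column(s):",
                        paste(setdiff(need, names(tab)), collapse = ", ")))
  if (!"total_alleles" %in% names(tab))
    tab$total_alleles <- allele_total(tab$hem, tab$het, tab$hom)
  tab
}
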