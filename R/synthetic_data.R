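# Synthetic-data generators: chain architectures, coding sequences, family
# registries, case-control cohorts, allele tables and splice training sets
# with known ground truth.  Every generator is a pure function of its
# arguments and seed (byte-identical reruns).
#
# Defaults emulate the scale of the source cohorts: a collagen IV
# alpha-5-like chain (23 local collagenous regions, ~460 Gly), boundary
# carrier frequency ~15%, haematuria model coefficients (intercept -2.41,
# boundary -1.25, highly destabilising +0.94) and marginal prevalence
# ~15.8%.

#' Generate a synthetic chain architecture
#'
#' Builds a chain with an amino terminus, `n_regions` local collagenous
#' regions separated by short non-collagenous interruptions, and a
#' carboxyl terminus.  Region lengths (in triplets) and interruption
#' lengths are drawn from the supplied ranges.
#'
#' @param n_regions number of local collagenous regions (default 23, the
#'   collagen IV alpha-5 count).
#' @param triplet_range integer range of Gly-Xaa-Yaa triplets per region
#'   (default 8--32, mean 20, giving ~460 Gly per chain).
#' @param interruption_range integer range of interruption lengths in
#'   residues (default 2--12).
#' @param amino_nc,carboxyl_nc lengths of the non-collagenous termini
#'   (defaults 41 and 229 residues).
#' @param seed RNG seed.
#' @return a `chain_architecture`.  Exons: the CDS is tiled into
#'   `n_exons` (default 53) exons of near-equal codon-multiple length.
#' @param n_exons number of exons in the synthetic exon map.
#' @export
gen_architecture <- function(n_regions = 23L, triplet_range = c(8L, 32L),
                             interruption_range = c(2L, 12L),
                             amino_nc = 41L, carboxyl_nc = 229L,
                             n_exons = 53L, seed = 1L) {
  if (n_regions < 1L || any(triplet_range < 1L) || any(interruption_range < 1L) ||
      amino_nc < 1L || carboxyl_nc < 1L)
    col4gly_error("config_error", "architecture dimensions must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  trips <- sample(seq.int(triplet_range[1], triplet_range[2]), n_regions, replace = TRUE)
  ints <- if (n_regions > 1L)
    sample(seq.int(interruption_range[1], interruption_range[2]),
           n_regions - 1L, replace = TRUE) else integer(0)
  kind <- c("amino_terminus",
            utils::head(as.vector(rbind(rep("collagenous", n_regions),
                                        rep("interruption", n_regions))),
                        2L * n_regions - 1L),
            "carboxyl_terminus")
  len <- c(amino_nc,
           utils::head(as.vector(rbind(3L * trips, c(ints, 0L))),
                       2L * n_regions - 1L),
           carboxyl_nc)
  end <- cumsum(len)
  start <- end - len + 1L
  seg <- data.frame(kind = kind, start = start, end = end)
  L <- end[length(end)]
  cds_len <- 3L * L
  # exon map: near-equal exon sizes, each a multiple of 3 except adjusted last
  base_len <- (cds_len %/% n_exons)
  sizes <- rep(base_len, n_exons)
  sizes[n_exons] <- cds_len - sum(sizes[-n_exons])
  e_end <- cumsum(sizes)
  exo <- data.frame(exon = seq_len(n_exons),
                    cdna_start = e_end - sizes + 1L, cdna_end = e_end)
  build_architecture(seg, exo, chain_id = sprintf("synthetic_chain_seed%d", seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

GLY_CODONS <- c("GGA", "GGC", "GGG", "GGT")

# sense, non-Gly, non-stop codons
NONGLY_SENSE_CODONS <- local({
  all <- names(GENETIC_CODE_TABLE)
  all[!GENETIC_CODE_TABLE %in% c("G", "*")]
})

#' Generate a coding sequence matching an architecture
#'
#' Gly slots receive a random Gly codon (GGA/GGC/GGG/GGT); all other
#' positions receive random sense non-Gly codons, so the translation has
#' Gly exactly at the architecture's Gly slots and no internal stops.
#'
#' @param arch a `chain_architecture`.
#' @param seed RNG seed.
#' @return character scalar of length `3 * L`.
#' @export
gen_cds <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "chain_architecture"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gly <- gly_positions(arch)$residue
  codons <- sample(NONGLY_SENSE_CODONS, arch$length, replace = TRUE)
  codons[1L] <- "ATG"
  codons[gly] <- sample(GLY_CODONS, length(gly), replace = TRUE)
  paste(codons, collapse = "")
}

# sample n Gly missense variants uniformly over the chain's Gly slots,
# returning their annotation fields as an n-row data.frame (vectorized:
# the simulation-heavy tests draw hundreds of thousands of these)
.sample_gly_variants <- function(arch, n, gp = gly_positions(arch)) {
  cls_all <- classify_position(arch, gp$residue)
  ex_all <- exon_location(arch, 3L * (gp$residue - 1L) + 1L)
  reach <- lapply(GLY_CODONS, reachable_substitutions)
  names(reach) <- GLY_CODONS
  i <- sample.int(nrow(gp), n, replace = TRUE)
  codon <- sample(GLY_CODONS, n, replace = TRUE)
  alt <- vapply(codon, function(cd) sample(reach[[cd]], 1L), character(1))
  res <- gp$residue[i]
  cls <- cls_all[i]
  data.frame(residue = res,
             protein_hgvs = sprintf("Gly%d%s", res, alt),
             position_class = cls,
             is_nc_boundary = as.integer(cls == "nc_boundary"),
             is_carboxyl_block = as.integer(!ex_all$is_amino_block[i]),
             is_high_destab = as.integer(destabilisation_class(alt) == "high"),
             region = gp$region[i],
             stringsAsFactors = FALSE)
}

#' Generate a family registry under a proportional-hazards model
#'
#' Each family carries one collagenous Gly variant (sampled uniformly over
#' the chain's Gly slots) and 1--3 affected males.  One family-level event
#' age is drawn from an exponential proportional-hazards model,
#' `T ~ Exp(baseline_hazard * exp(x . log_hr))` with `x` the family's
#' feature vector (`is_carboxyl_block`, `is_nc_boundary`,
#' `is_high_destab`); an independent uniform last-seen age censors it.
#' Event families have their phenotype text stamped with endpoint
#' keywords.
#'
#' @param arch a `chain_architecture`.
#' @param n_families number of families (default 157, kidney-failure
#'   cohort scale).
#' @param baseline_hazard exponential baseline hazard per year (default
#'   `log(2)/26`: median 26 years at covariate reference, the observed
#'   overall median age at kidney failure).
#' @param log_hr named numeric: log hazard ratios for
#'   `is_carboxyl_block`, `is_nc_boundary`, `is_high_destab` (defaults
#'   0.1, -0.8, 0.7: direction and scale of the fitted clinical models).
#' @param censor_max last-seen ages are Uniform(5, `censor_max`) years
#'   (default 90).
#' @param endpoint keyword set stamped on event families.
#' @param seed RNG seed.
#' @return data.frame, one row per individual, with registry columns and
#'   (ground-truth) feature columns.
#' @export
gen_registry <- function(arch, n_families = 157L,
                         baseline_hazard = log(2) / 26,
                         log_hr = c(is_carboxyl_block = 0.1,
                                    is_nc_boundary = -0.8,
                                    is_high_destab = 0.7),
                         censor_max = 90, endpoint = "kidney", seed = 1L) {
  stopifnot(inherits(arch, "chain_architecture"))
  if (baseline_hazard <= 0 || censor_max <= 5)
    col4gly_error("config_error", "invalid hazard or censoring configuration")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gp <- gly_positions(arch)
  kw <- list(kidney = c("ESRD at age", "kidney failure", "started dialysis aged",
                        "renal transplant at"),
             hearing = c("sensorineural hearing loss diagnosed",
                         "deafness noted at", "abnormal audiogram at"))[[endpoint]]
  kw_censored <- list(kidney = "chronic renal disease, no kidney failure to date",
                      hearing = "audiometry normal to date")[[endpoint]]
  v <- .sample_gly_variants(arch, n_families, gp)
  eta <- v$is_carboxyl_block * log_hr[["is_carboxyl_block"]] +
    v$is_nc_boundary * log_hr[["is_nc_boundary"]] +
    v$is_high_destab * log_hr[["is_high_destab"]]
  lambda <- baseline_hazard * exp(eta)
  t_event <- pmax(stats::rexp(n_families, lambda), 0.5)  # ages >= 6 months
  t_cens <- stats::runif(n_families, 5, censor_max)
  event <- t_event <= t_cens
  n_males <- sample.int(3L, n_families, replace = TRUE)
  fam_id <- sprintf("FAM%04d", seq_len(n_families))
  txt <- ifelse(event,
                sprintf("%s %.0f", sample(kw, n_families, replace = TRUE),
                        round(t_event)),
                kw_censored)
  rep_i <- rep.int(seq_len(n_families), n_males)
  out <- data.frame(
    family_id = fam_id[rep_i],
    individual_id = sprintf("%s_M%d", fam_id[rep_i],
                            sequence(n_males)),
    sex = "M",
    phenotype_text = txt[rep_i],
    event_age = ifelse(event, round(t_event, 1), NA_real_)[rep_i],
    event_age_low = NA_real_, event_age_high = NA_real_,
    last_seen_age = ifelse(event, NA_real_, round(t_cens, 1))[rep_i],
    n_variants = 1L,
    protein_hgvs = v$protein_hgvs[rep_i],
    position_class = v$position_class[rep_i],
    is_carboxyl_block = v$is_carboxyl_block[rep_i],
    is_nc_boundary = v$is_nc_boundary[rep_i],
    is_high_destab = v$is_high_destab[rep_i],
    true_event_age = round(ifelse(event, t_event, t_cens), 1)[rep_i],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate a case-control haematuria cohort under a logistic model
#'
#' Individuals carry one heterozygous Gly missense variant each (sampled
#' uniformly over the chain's Gly slots) and an outcome drawn
#' `Bernoulli(plogis(intercept + x . coef))` on the three molecular
#' features.
#'
#' @param arch a `chain_architecture`.
#' @param n number of individuals (default 304, the case-control cohort
#'   scale).
#' @param intercept,coef logistic intercept and named coefficients for
#'   `is_carboxyl_block`, `is_nc_boundary`, `is_high_destab` (defaults
#'   -2.41 and (0.24, -1.25, 0.94), the fitted haematuria model).
#' @param genes gene labels assigned round-robin.
#' @param seed RNG seed.
#' @return data.frame, one row per individual, with `outcome`, feature
#'   columns and variant labels.
#' @export
gen_cohort <- function(arch, n = 304L, intercept = -2.41,
                       coef = c(is_carboxyl_block = 0.24,
                                is_nc_boundary = -1.25,
                                is_high_destab = 0.94),
                       genes = c("COL4A3", "COL4A4"), seed = 1L) {
  stopifnot(inherits(arch, "chain_architecture"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gp <- gly_positions(arch)
  v <- .sample_gly_variants(arch, n, gp)
  eta <- intercept + v$is_carboxyl_block * coef[["is_carboxyl_block"]] +
    v$is_nc_boundary * coef[["is_nc_boundary"]] +
    v$is_high_destab * coef[["is_high_destab"]]
  out <- data.frame(
    individual_id = sprintf("IND%05d", seq_len(n)),
    gene = genes[(seq_len(n) - 1L) %% length(genes) + 1L],
    outcome = stats::rbinom(n, 1, stats::plogis(eta)),
    protein_hgvs = v$protein_hgvs,
    position_class = v$position_class,
    is_carboxyl_block = v$is_carboxyl_block,
    is_nc_boundary = v$is_nc_boundary,
    is_high_destab = v$is_high_destab,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate a gnomAD-like allele-count table
#'
#' Samples `n_variants` distinct Gly missense SNV sites with probability
#' proportional to their neighbour-dependent substitution rates, then
#' draws hemizygote / heterozygote / homozygote counts for a declared
#' male/female sample under a per-variant allele frequency.
#'
#' @param arch a `chain_architecture`.
#' @param cds matching coding sequence (see [gen_cds()]).
#' @param table a `rate_table`.
#' @param n_variants number of distinct variant sites (default 45).
#' @param male_total,female_total sampled individuals (defaults 67000 /
#'   74000, gnomAD v2-like exome scale).
#' @param freq_range per-variant allele frequencies are drawn
#'   log-uniformly over this range (default `c(1e-5, 5e-3)`).
#' @param seed RNG seed.
#' @return data.frame with `variant`, `cdna_hgvs`, `protein_hgvs`,
#'   `position_class`, `hem`, `het`, `hom` and the sample totals as
#'   attributes `male_total` / `female_total`.
#' @export
gen_allele_table <- function(arch, cds, table, n_variants = 45L,
                             male_total = 67000L, female_total = 74000L,
                             freq_range = c(1e-5, 5e-3), seed = 1L) {
  stopifnot(inherits(arch, "chain_architecture"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  snvs <- enumerate_gly_missense(arch, cds, table)
  if (n_variants > nrow(snvs))
    col4gly_error("config_error", "n_variants exceeds the number of possible Gly missense SNVs")
  pick <- sample.int(nrow(snvs), n_variants, prob = snvs$rate)
  sel <- snvs[pick, , drop = FALSE]
  af <- exp(stats::runif(n_variants, log(freq_range[1]), log(freq_range[2])))
  hem <- stats::rbinom(n_variants, male_total, af)
  het <- stats::rbinom(n_variants, female_total, 2 * af * (1 - af))
  hom <- stats::rbinom(n_variants, female_total, af^2)
  out <- data.frame(variant = sel$protein_hgvs,
                    cdna_hgvs = sel$cdna_hgvs,
                    protein_hgvs = sel$protein_hgvs,
                    position_class = sel$position_class,
                    hem = hem, het = het, hom = hom,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "male_total") <- male_total
  attr(out, "female_total") <- female_total
  out
}

#' Enumerate all Gly missense SNVs of a chain with their context rates
#'
#' Support table for the population stage and its generators: one row per
#' (Gly codon position, alternate base) missense combination, with the
#' resulting protein change, position class and neighbour-dependent rate.
#'
#' @inheritParams expected_boundary_fraction
#' @return data.frame with columns `residue`, `cdna_position`, `ref`,
#'   `alt`, `cdna_hgvs`, `protein_hgvs`, `position_class`, `rate`.
#' @export
enumerate_gly_missense <- function(arch, cds, table) {
  stopifnot(inherits(arch, "chain_architecture"))
  cds <- toupper(cds)
  if (nchar(cds) != 3L * arch$length)
    col4gly_error("consistency_error", "CDS length does not match chain length")
  seqv <- strsplit(cds, "")[[1]]
  gp <- gly_positions(arch)
  cls <- classify_position(arch, gp$residue)
  bases <- c("A", "C", "G", "T")
  n_max <- 9L * nrow(gp)
  o_res <- integer(n_max); o_pos <- integer(n_max)
  o_ref <- character(n_max); o_alt <- character(n_max)
  o_aa <- character(n_max); o_cls <- character(n_max)
  o_left <- character(n_max); o_right <- character(n_max)
  m <- 0L
  for (i in seq_len(nrow(gp))) {
    res <- gp$residue[i]
    cpos <- 3L * (res - 1L) + 1:3
    codon <- paste(seqv[cpos], collapse = "")
    for (k in 1:3) {
      p <- cpos[k]
      ref <- seqv[p]
      left <- if (p > 1L) seqv[p - 1L] else seqv[p + 1L]
      right <- if (p < length(seqv)) seqv[p + 1L] else seqv[p - 1L]
      for (alt in bases) {
        if (alt == ref) next
        mut <- codon
        substr(mut, k, k) <- alt
        aa <- translate_codon(mut)
        if (aa == "G" || aa == "*") next
        m <- m + 1L
        o_res[m] <- res; o_pos[m] <- p
        o_ref[m] <- ref; o_alt[m] <- alt
        o_aa[m] <- aa; o_cls[m] <- cls[i]
        o_left[m] <- left; o_right[m] <- right
      }
    }
  }
  idx <- seq_len(m)
  data.frame(residue = o_res[idx], cdna_position = o_pos[idx],
             ref = o_ref[idx], alt = o_alt[idx],
             cdna_hgvs = sprintf("%d%s>%s", o_pos[idx], o_ref[idx], o_alt[idx]),
             protein_hgvs = sprintf("Gly%d%s", o_res[idx],
                                    unname(AA3[o_aa[idx]])),
             position_class = o_cls[idx],
             rate = context_rate(table, o_left[idx], o_ref[idx],
                                 o_alt[idx], o_right[idx]),
             stringsAsFactors = FALSE)
}

#' Generate aligned splice-site training windows from a known PWM
#'
#' Draws windows from a declared per-position weight matrix (columns =
#' positions, rows = A,C,G,T); the matrix is returned as the ground-truth
#' distribution for trainer validation.
#'
#' @param n number of windows.
#' @param pwm 4 x L matrix of per-position base probabilities; default a
#'   donor-like 9-mer matrix with a strong GT core.
#' @param seed RNG seed.
#' @return list with `windows` (character vector) and `pwm`.
#' @export
gen_splice_training <- function(n = 500L, pwm = NULL, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(pwm)) {
    # donor-like consensus (c)AG | GTRAGT
    pwm <- matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
    strong <- function(base, w = 0.85) {
      p <- rep((1 - w) / 3, 4); names(p) <- c("A", "C", "G", "T")
      p[base] <- w; p
    }
    pwm[, 1] <- strong("C", 0.4); pwm[, 2] <- strong("A", 0.6)
    pwm[, 3] <- strong("G", 0.8); pwm[, 4] <- strong("G", 0.95)
    pwm[, 5] <- strong("T", 0.95); pwm[, 6] <- c(0.5, 0.05, 0.4, 0.05)
    pwm[, 7] <- strong("A", 0.7); pwm[, 8] <- strong("G", 0.8)
    pwm[, 9] <- strong("T", 0.5)
  }
  pwm <- sweep(pwm, 2, colSums(pwm), "/")
  L <- ncol(pwm)
  windows <- vapply(seq_len(n), function(i)
    paste(vapply(seq_len(L), function(j)
      sample(c("A", "C", "G", "T"), 1L, prob = pwm[, j]), character(1)),
      collapse = ""), character(1))
  list(windows = windows, pwm = pwm)
}
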