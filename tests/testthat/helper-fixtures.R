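# Shared fixtures and independent brute-force oracles.  The oracles are
# written directly from first principles and never call the package's own
# implementation of the quantity they check.

toy_arch <- function() {
  build_architecture(
    data.frame(kind = c("amino_terminus", "collagenous", "carboxyl_terminus"),
               start = c(1, 11, 41), end = c(10, 40, 50)),
    data.frame(exon = 1:2, cdna_start = c(1, 91), cdna_end = c(90, 150)),
    chain_id = "toy")
}

col4a5_like_arch <- function() {
  read_architecture(
    system.file("extdata", "col4a5_synthetic_segments.tsv", package = "col4gly"),
    system.file("extdata", "col4a5_synthetic_exons.tsv", package = "col4gly"),
    chain_id = "COL4A5_synthetic")
}

# random small architecture for property tests
random_arch <- function(n_regions = sample(1:10, 1)) {
  trips <- sample(1:8, n_regions, replace = TRUE)
  ints <- if (n_regions > 1) sample(1:6, n_regions - 1, replace = TRUE) else integer(0)
  kind <- c("amino_terminus",
            head(as.vector(rbind(rep("collagenous", n_regions),
                                 rep("interruption", n_regions))), 2 * n_regions - 1),
            "carboxyl_terminus")
  len <- c(sample(2:10, 1),
           head(as.vector(rbind(3 * trips, c(ints, 0))), 2 * n_regions - 1),
           sample(2:10, 1))
  end <- cumsum(len); start <- end - len + 1
  L <- end[length(end)]
  exo <- data.frame(exon = 1:2, cdna_start = c(1, 3 * L %/% 2 + 1),
                    cdna_end = c(3 * L %/% 2, 3 * L))
  build_architecture(data.frame(kind = kind, start = start, end = end), exo)
}

# --- oracle: residue classification, written straight from the feature
# definitions: list the Gly slots per uninterrupted collagenous stretch;
# boundary = first/last Gly; carboxyl end = two before the last; amino
# end = ordinals 2-3 (boundary excluded); carboxyl wins overlaps; all
# other Gly central; non-Gly collagenous and non-collagenous otherwise.
oracle_classify <- function(segments, residue) {
  seg <- segments[order(segments$start), ]
  for (i in seq_len(nrow(seg))) {
    if (residue >= seg$start[i] && residue <= seg$end[i]) {
      if (seg$kind[i] != "collagenous") return("non_collagenous")
      glys <- seq(seg$start[i], seg$end[i], by = 3)
      if (!(residue %in% glys)) return("collagenous_non_gly")
      n <- length(glys)
      ord <- which(glys == residue)
      if (ord == 1 || ord == n) return("nc_boundary")
      if (ord %in% c(n - 1, n - 2)) return("carboxyl_end")
      if (ord %in% c(2, 3)) return("amino_end")
      return("central")
    }
  }
  stop("residue outside chain")
}

# --- oracle: product-limit estimator computed by hand
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(times = ut, surv = surv,
       median = if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_)
}

# --- oracle: binomial tail by explicit log-space summation
oracle_binom_tail <- function(k, n, p, upper = TRUE) {
  ks <- if (upper) k:n else 0:k
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

# --- oracle: expected boundary fraction by exhaustive SNV enumeration
# over the whole CDS (every position x every alternate base), keeping
# substitutions that land in a Gly codon of the architecture and change
# Gly to another (non-stop) residue.
oracle_expected_fraction <- function(arch, cds, rate_table) {
  code <- getFromNamespace("GENETIC_CODE_TABLE", "col4gly")
  seqv <- strsplit(toupper(cds), "")[[1]]
  gly_res <- gly_positions(arch)$residue
  cls <- classify_position(arch, gly_res)
  names(cls) <- gly_res
  num <- 0; den <- 0
  for (p in seq_along(seqv)) {
    res <- (p + 2) %/% 3
    if (!(res %in% gly_res)) next
    cpos <- (3 * (res - 1) + 1):(3 * res)
    codon <- paste(seqv[cpos], collapse = "")
    for (alt in setdiff(c("A", "C", "G", "T"), seqv[p])) {
      mut_seq <- seqv; mut_seq[p] <- alt
      mut <- paste(mut_seq[cpos], collapse = "")
      aa <- unname(code[mut])
      if (aa %in% c("G", "*")) next
      left <- if (p > 1) seqv[p - 1] else seqv[p + 1]
      right <- if (p < length(seqv)) seqv[p + 1] else seqv[p - 1]
      r <- rate_table$rate[rate_table$left == left & rate_table$ref == seqv[p] &
                           rate_table$alt == alt & rate_table$right == right]
      den <- den + r
      if (cls[as.character(res)] == "nc_boundary") num <- num + r
    }
  }
  num / den
}

# --- oracle: exact logistic log-likelihood and brute-force maximizer
oracle_logistic_ll <- function(beta, X, y) {
  eta <- as.vector(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

oracle_logistic_mle <- function(X, y) {
  fit <- optim(rep(0, ncol(X)), function(b) -oracle_logistic_ll(b, X, y),
               method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}
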