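# Maximum-entropy splice-site scoring.
#
# A splice model here is a maximum-entropy distribution over fixed-length
# windows (9 nt for 5' donors: last 3 exonic + first 6 intronic bases;
# 23 nt for 3' acceptors: last 20 intronic + first 3 exonic bases),
# constrained to match the first-order (per-position) and adjacent-pair
# marginals of a training set of true sites.  With adjacent-pair
# constraints the distribution factorises over a chain, so marginals are
# computed exactly by forward-backward passes over 4-state transfer
# matrices and the model is fitted by iterative proportional scaling.

BASES <- c("A", "C", "G", "T")

.window_length <- c(donor_5prime = 9L, acceptor_3prime = 23L)

seq_to_idx <- function(s) {
  x <- match(strsplit(toupper(s), "")[[1]], BASES)
  if (anyNA(x)) col4gly_error("input_error", "window contains a non-ACGT base")
  x
}

# pair marginals of a chain model given log factor tables.
# factors: list of (L-1) 4x4 matrices (non-log scale).
chain_pair_marginals <- function(factors) {
  L <- length(factors) + 1L
  fwd <- vector("list", L)   # fwd[[i]]: unnormalized marginal message into i
  fwd[[1]] <- rep(1, 4)
  for (i in seq_len(L - 1L)) fwd[[i + 1L]] <- as.vector(fwd[[i]] %*% factors[[i]])
  bwd <- vector("list", L)
  bwd[[L]] <- rep(1, 4)
  for (i in rev(seq_len(L - 1L))) bwd[[i]] <- as.vector(factors[[i]] %*% bwd[[i + 1L]])
  Z <- sum(fwd[[1]] * bwd[[1]])
  lapply(seq_len(L - 1L), function(i) {
    m <- (fwd[[i]] %o% bwd[[i + 1L]]) * factors[[i]] / Z
    m
  })
}

#' Train a maximum-entropy splice-site model
#'
#' Fits, by iterative proportional scaling, the maximum-entropy
#' distribution over windows that reproduces the per-position and
#' adjacent-pair base frequencies of a set of aligned true-site windows.
#' A pseudocount can be added to the pair counts to keep probabilities
#' strictly positive.
#'
#' @param site_kind `"donor_5prime"` (9-mers) or `"acceptor_3prime"`
#'   (23-mers).  Any other uniform window length is accepted for toy
#'   models, with `site_kind = "custom"`.
#' @param training_windows character vector of at least 50 equal-length
#'   ACGT windows.
#' @param background per-position background base probabilities: `"uniform"`
#'   (default), or a 4 x L matrix of probabilities (rows A,C,G,T).
#' @param pseudocount added to each adjacent-pair count cell before
#'   normalisation (default 0.5; use 0 only when every cell is observed).
#' @param tol convergence tolerance on the maximum absolute deviation of
#'   fitted from target marginals (default 1e-6).
#' @param max_iter iteration cap (default 10000).
#' @return object of class `splice_model` with the fitted chain factors,
#'   target marginals, background and window length.
#' @export
train_maxent <- function(site_kind, training_windows, background = "uniform",
                         pseudocount = 0.5, tol = 1e-6, max_iter = 10000L) {
  if (length(training_windows) < 50L)
    col4gly_error("input_error", "at least 50 training windows are required")
  lens <- unique(nchar(training_windows))
  if (length(lens) != 1L)
    col4gly_error("input_error", "training windows have inconsistent lengths")
  L <- lens
  if (site_kind %in% names(.window_length) && L != .window_length[[site_kind]])
    col4gly_error("input_error",
                  sprintf("%s model requires %d-base windows, got %d",
                          site_kind, .window_length[[site_kind]], L))
  idx <- t(vapply(training_windows, seq_to_idx, integer(L)))
  n <- nrow(idx)
  # target adjacent-pair marginals (with pseudocount smoothing)
  targets <- lapply(seq_len(L - 1L), function(i) {
    tab <- matrix(pseudocount, 4, 4, dimnames = list(BASES, BASES))
    for (r in seq_len(n)) tab[idx[r, i], idx[r, i + 1L]] <- tab[idx[r, i], idx[r, i + 1L]] + 1
    tab / sum(tab)
  })
  factors <- lapply(targets, function(t) t + 0)   # IPS init at targets
  # cyclic iterative proportional scaling: overlapping cliques must be
  # updated one at a time, with marginals recomputed between updates
  dev <- Inf
  for (it in seq_len(max_iter)) {
    for (i in seq_along(factors)) {
      cur_i <- chain_pair_marginals(factors)[[i]]
      factors[[i]] <- factors[[i]] * targets[[i]] / pmax(cur_i, 1e-300)
      factors[[i]] <- factors[[i]] / sum(factors[[i]])
    }
    cur <- chain_pair_marginals(factors)
    dev <- max(vapply(seq_along(targets),
                      function(i) max(abs(cur[[i]] - targets[[i]])), numeric(1)))
    if (dev < tol) break
  }
  if (dev >= tol)
    col4gly_error("convergence_error",
                  sprintf("iterative scaling did not reach tol %g in %d iterations (deviation %g)",
                          tol, max_iter, dev))
  if (identical(background, "uniform")) {
    bg <- matrix(0.25, 4, L, dimnames = list(BASES, NULL))
  } else {
    bg <- as.matrix(background)
    if (!all(dim(bg) == c(4, L)) || any(bg <= 0))
      col4gly_error("input_error", "background must be a positive 4 x L matrix")
    bg <- sweep(bg, 2, colSums(bg), "/")
    rownames(bg) <- BASES
  }
  structure(list(site_kind = site_kind, window_length = L,
                 factors = factors, targets = targets, background = bg,
                 iterations = it),
            class = "splice_model")
}

#' @export
print.splice_model <- function(x, ...) {
  cat(sprintf("splice_model (%s): %d-base windows, chain maxent fitted in %d IPS iterations\n",
              x$site_kind, x$window_length, x$iterations))
  invisible(x)
}

# probability of one window under the chain maxent model
maxent_probability <- function(model, window) {
  x <- seq_to_idx(window)
  if (length(x) != model$window_length)
    col4gly_error("input_error",
                  sprintf("window length %d, model expects %d",
                          length(x), model$window_length))
  fwd <- rep(1, 4)
  for (f in model$factors) fwd <- as.vector(fwd %*% f)
  Z <- sum(fwd)
  p <- 1
  for (i in seq_along(model$factors))
    p <- p * model$factors[[i]][x[i], x[i + 1L]]
  p / Z
}

background_probability <- function(model, window) {
  x <- seq_to_idx(window)
  prod(model$background[cbind(x, seq_along(x))])
}

#' Score a splice-site window
#'
#' The score is the log-odds (base 2) of the window under the fitted
#' maximum-entropy distribution against the background model:
#' `log2(P_maxent(window) / P_background(window))`.
#'
#' @param model a `splice_model`.
#' @param window character scalar, ACGT, of the model's window length.
#' @return numeric log2-odds score.
#' @export
score_site <- function(model, window) {
  stopifnot(inherits(model, "splice_model"))
  p <- maxent_probability(model, window)
  q <- background_probability(model, window)
  log2(p / q)
}

#' Is a CDS position within 3 bases of a splice site?
#'
#' True iff the position lies in the 3 terminal exonic bases on either side
#' of an internal exon junction (positions `end-2..end` of every exon but
#' the last; `start..start+2` of every exon but the first).  The CDS
#' termini are not splice junctions.
#'
#' @param arch a `chain_architecture` (its exon map is used).
#' @param cdna_position CDS position(s).
#' @return logical vector.
#' @export
near_splice_site <- function(arch, cdna_position) {
  stopifnot(inherits(arch, "chain_architecture"))
  em <- arch$exon_map
  p <- as.integer(cdna_position)
  cds_len <- em$cdna_end[nrow(em)]
  if (any(is.na(p)) || any(p < 1L) || any(p > cds_len))
    col4gly_error("bounds_error", "cDNA position outside CDS")
  hit <- rep(FALSE, length(p))
  n <- nrow(em)
  for (i in seq_len(n)) {
    if (i < n) hit <- hit | (p >= em$cdna_end[i] - 2L & p <= em$cdna_end[i])
    if (i > 1L) hit <- hit | (p >= em$cdna_start[i] & p <= em$cdna_start[i] + 2L)
  }
  hit
}

#' Assess a predicted splice effect from wild-type and mutant scores
#'
#' A variant is flagged as affecting splicing when the mutant score is more
#' than 15% lower than the wild-type score (strict inequality).  The
#' relative drop is `(wt - mut)/|wt|`; for `wt == 0` it is defined as
#' `Inf` when the mutant score is negative and `0` otherwise, keeping the
#' rule directional.
#'
#' @param wt_score,mut_score finite numeric scores.
#' @param threshold relative-drop threshold (default 0.15).
#' @return list with `wt_score`, `mut_score`, `relative_drop`, `affected`.
#' @export
assess_splice_effect <- function(wt_score, mut_score, threshold = 0.15) {
  if (!is.finite(wt_score) || !is.finite(mut_score))
    col4gly_error("input_error", "splice scores must be finite")
  drop <- if (wt_score != 0) (wt_score - mut_score) / abs(wt_score)
          else if (mut_score < 0) Inf else 0
  list(wt_score = wt_score, mut_score = mut_score,
       relative_drop = drop, affected = drop > threshold)
}

#' Write / read splice model parameters as a plain-text key-value table
#'
#' The file stores the chain factor tables as lines
#' `pair <i> <base_i> <base_i+1> <log_factor>` plus `background` lines and
#' a header describing the site kind and window length.
#'
#' @param model a `splice_model`.
#' @param path file path.
#' @export
write_splice_model <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# site_kind %s", model$site_kind), con)
  writeLines(sprintf("# window_length %d", model$window_length), con)
  for (i in seq_along(model$factors)) {
    f <- model$factors[[i]]
    for (a in BASES) for (b in BASES)
      writeLines(sprintf("pair\t%d\t%s\t%s\t%.17g", i, a, b, log(f[a, b])), con)
  }
  for (j in seq_len(model$window_length)) for (a in BASES)
    writeLines(sprintf("background\t%d\t%s\t.\t%.17g", j, a,
                       log(model$background[a, j])), con)
  invisible(path)
}

#' @rdname write_splice_model
#' @export
read_splice_model <- function(path) {
  if (!file.exists(path)) col4gly_error("io_error", paste("no such file:", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kind <- sub("^# site_kind ", "", hdr[grepl("site_kind", hdr)])
  L <- as.integer(sub("^# window_length ", "", hdr[grepl("window_length", hdr)]))
  body <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                     stringsAsFactors = FALSE)
  pr <- body[body$V1 == "pair", ]
  factors <- lapply(seq_len(L - 1L), function(i) {
    f <- matrix(NA_real_, 4, 4, dimnames = list(BASES, BASES))
    rows <- pr[pr$V2 == i, ]
    f[cbind(rows$V3, rows$V4)] <- exp(rows$V5)
    f
  })
  bgr <- body[body$V1 == "background", ]
  bg <- matrix(NA_real_, 4, L, dimnames = list(BASES, NULL))
  bg[cbind(match(bgr$V3, BASES), as.integer(bgr$V2))] <- exp(bgr$V5)
  structure(list(site_kind = kind, window_length = L, factors = factors,
                 targets = NULL, background = bg, iterations = NA_integer_),
            class = "splice_model")
}
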