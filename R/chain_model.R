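#' Collagen IV chain architecture
#'
#' A collagen IV alpha chain consists of a short non-collagenous amino
#' terminus, a long collagenous domain of Gly-Xaa-Yaa triplet repeats broken
#' by 21--26 short non-collagenous interruptions, and a large non-collagenous
#' carboxyl (NC1) terminus.  Each uninterrupted Gly-Xaa-Yaa stretch flanked
#' by two non-collagenous regions or termini is a "local collagenous region"
#' with its own amino and carboxyl ends.  `build_architecture()` validates a
#' segment table describing one chain and attaches the exon map of its
#' reference transcript.
#'
#' @param segment_table data.frame with columns `kind` (one of
#'   `"amino_terminus"`, `"collagenous"`, `"interruption"`,
#'   `"carboxyl_terminus"`), `start`, `end` (1-based inclusive protein
#'   residue indices).  Segments must tile residues `1..L` contiguously,
#'   start with the amino terminus and end with the carboxyl terminus, and
#'   every collagenous segment must have length divisible by 3 (the first
#'   residue of each triplet is the Gly slot).
#' @param exon_table data.frame with columns `exon`, `cdna_start`,
#'   `cdna_end`: 1-based inclusive CDS coordinates (position 1 = A of the
#'   initiator ATG) tiling the CDS contiguously.
#' @param chain_id label for the chain (e.g. `"COL4A5"`).
#' @return An object of class `chain_architecture` with elements
#'   `chain_id`, `segments`, `exon_map`, `n_exons`, `length` (chain length
#'   in residues).
#' @export
build_architecture <- function(segment_table, exon_table, chain_id = "chain") {
  seg <- as.data.frame(segment_table)
  exo <- as.data.frame(exon_table)
  if (nrow(seg) == 0L || nrow(exo) == 0L)
    col4gly_error("input_error", "segment and exon tables must be non-empty")
  need <- c("kind", "start", "end")
  if (!all(need %in% names(seg)))
    col4gly_error("schema_error",
                  paste("segment table missing column(s):",
                        paste(setdiff(need, names(seg)), collapse = ", ")))
  kinds <- c("amino_terminus", "collagenous", "interruption", "carboxyl_terminus")
  if (!all(seg$kind %in% kinds))
    col4gly_error("input_error", paste("unknown segment kind:",
                  paste(setdiff(seg$kind, kinds), collapse = ", ")))
  seg$start <- as.integer(seg$start)
  seg$end <- as.integer(seg$end)
  if (any(is.na(seg$start)) || any(is.na(seg$end)) ||
      any(seg$start < 1L) || any(seg$end < seg$start))
    col4gly_error("input_error", "segment coordinates must be positive with start <= end")
  seg <- seg[order(seg$start), , drop = FALSE]
  # contiguity: segment i+1 starts where segment i ended + 1
  if (seg$start[1] != 1L)
    col4gly_error("structural_error",
                  sprintf("segments must start at residue 1 (gap at residues 1-%d)",
                          seg$start[1] - 1L))
  if (nrow(seg) > 1L) {
    brk <- which(seg$start[-1L] != seg$end[-nrow(seg)] + 1L)
    if (length(brk)) {
      i <- brk[1L]
      col4gly_error("structural_error",
                    sprintf("gap/overlap between segments at residues %d-%d",
                            seg$end[i] + 1L, seg$start[i + 1L]))
    }
  }
  if (seg$kind[1] != "amino_terminus" || seg$kind[nrow(seg)] != "carboxyl_terminus" ||
      sum(seg$kind == "amino_terminus") != 1L || sum(seg$kind == "carboxyl_terminus") != 1L)
    col4gly_error("structural_error",
                  "exactly one amino_terminus (first) and one carboxyl_terminus (last) segment required")
  col_len <- seg$end - seg$start + 1L
  bad3 <- which(seg$kind == "collagenous" & col_len %% 3L != 0L)
  if (length(bad3))
    col4gly_error("triplet_error",
                  sprintf("collagenous segment %d-%d has length %d, not divisible by 3",
                          seg$start[bad3[1]], seg$end[bad3[1]], col_len[bad3[1]]))
  # local region ordinal for collagenous segments, amino -> carboxyl
  seg$region <- NA_integer_
  is_col <- seg$kind == "collagenous"
  seg$region[is_col] <- seq_len(sum(is_col))

  need_e <- c("exon", "cdna_start", "cdna_end")
  if (!all(need_e %in% names(exo)))
    col4gly_error("schema_error",
                  paste("exon table missing column(s):",
                        paste(setdiff(need_e, names(exo)), collapse = ", ")))
  exo$exon <- as.integer(exo$exon)
  exo$cdna_start <- as.integer(exo$cdna_start)
  exo$cdna_end <- as.integer(exo$cdna_end)
  exo <- exo[order(exo$cdna_start), , drop = FALSE]
  if (exo$cdna_start[1] != 1L ||
      (nrow(exo) > 1L && any(exo$cdna_start[-1L] != exo$cdna_end[-nrow(exo)] + 1L)))
    col4gly_error("structural_error", "exon map must tile the CDS contiguously from position 1")
  if (any(exo$cdna_end < exo$cdna_start))
    col4gly_error("input_error", "exon cdna_end must be >= cdna_start")

  structure(list(chain_id = chain_id,
                 segments = seg[, c("kind", "start", "end", "region")],
                 exon_map = exo[, c("exon", "cdna_start", "cdna_end")],
                 n_exons = nrow(exo),
                 length = seg$end[nrow(seg)]),
            class = "chain_architecture")
}

#' @export
print.chain_architecture <- function(x, ...) {
  ncol_reg <- sum(x$segments$kind == "collagenous")
  nint <- sum(x$segments$kind == "interruption")
  cat(sprintf("chain_architecture '%s': %d residues, %d local collagenous regions, %d interruptions, %d exons\n",
              x$chain_id, x$length, ncol_reg, nint, x$n_exons))
  invisible(x)
}

#' Read a chain architecture from segment and exon map files
#'
#' Both files are tab-separated with a header and `#` comment lines:
#' the segment file has columns `kind`/`start`/`end`, the exon map has
#' `exon`/`cdna_start`/`cdna_end`.
#'
#' @param segment_file,exon_file paths.
#' @inheritParams build_architecture
#' @return A `chain_architecture`.
#' @export
read_architecture <- function(segment_file, exon_file, chain_id = NULL) {
  if (!file.exists(segment_file) || !file.exists(exon_file))
    col4gly_error("io_error", "architecture file not found")
  seg <- utils::read.delim(segment_file, comment.char = "#",
                           stringsAsFactors = FALSE)
  exo <- utils::read.delim(exon_file, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (is.null(chain_id))
    chain_id <- sub("\\..*$", "", basename(segment_file))
  build_architecture(seg, exo, chain_id = chain_id)
}

#' Enumerate the Gly slots of a chain
#'
#' Lists the first residue of every Gly-Xaa-Yaa triplet of every local
#' collagenous region, amino to carboxyl.
#'
#' @param arch a `chain_architecture`.
#' @return data.frame with columns `residue` (1-based index),
#'   `region` (local collagenous region ordinal) and `gly_ordinal`
#'   (1-based position of the Gly within its region).
#' @export
gly_positions <- function(arch) {
  stopifnot(inherits(arch, "chain_architecture"))
  seg <- arch$segments[arch$segments$kind == "collagenous", , drop = FALSE]
  if (nrow(seg) == 0L)
    return(data.frame(residue = integer(0), region = integer(0),
                      gly_ordinal = integer(0)))
  out <- lapply(seq_len(nrow(seg)), function(i) {
    res <- seq.int(seg$start[i], seg$end[i], by = 3L)
    data.frame(residue = res, region = seg$region[i],
               gly_ordinal = seq_along(res))
  })
  do.call(rbind, out)
}

#' Classify a residue position by collagenous context
#'
#' Every residue belongs to exactly one class: `nc_boundary` (first or last
#' Gly of a local collagenous region, i.e. adjacent to a non-collagenous
#' interruption or terminus), `amino_end` (Gly ordinals 2-3 of the region,
#' not counting the boundary Gly), `carboxyl_end` (the two Gly immediately
#' before the last), `central` (all other Gly), `collagenous_non_gly`
#' (Xaa/Yaa positions) or `non_collagenous`.  In short regions where the
#' ordinal windows overlap, precedence is
#' `nc_boundary > carboxyl_end > amino_end > central` (trimerisation starts
#' at the carboxyl terminus, and boundary status is the primary stratifier);
#' regions with one or two Gly are all boundary.
#'
#' @param arch a `chain_architecture`.
#' @param residue_index 1-based protein position(s).
#' @return character vector of classes.
#' @seealso [boundary_side()] for the amino/carboxyl side annotation.
#' @export
classify_position <- function(arch, residue_index) {
  stopifnot(inherits(arch, "chain_architecture"))
  residue_index <- as.integer(residue_index)
  if (any(is.na(residue_index)) || any(residue_index < 1L) ||
      any(residue_index > arch$length))
    col4gly_error("bounds_error",
                  sprintf("residue index out of range 1..%d", arch$length))
  seg <- arch$segments
  vapply(residue_index, function(r) {
    i <- which(seg$start <= r & seg$end >= r)[1L]
    if (seg$kind[i] != "collagenous") return("non_collagenous")
    off <- r - seg$start[i]
    if (off %% 3L != 0L) return("collagenous_non_gly")
    g <- off %/% 3L + 1L                      # Gly ordinal in region
    n <- (seg$end[i] - seg$start[i] + 1L) %/% 3L  # Gly count in region
    if (g == 1L || g == n) return("nc_boundary")
    if (g >= n - 2L) return("carboxyl_end")   # n-1, n-2 (boundary already out)
    if (g <= 3L) return("amino_end")          # 2, 3
    "central"
  }, character(1))
}

#' Side annotation for boundary Gly residues
#'
#' A boundary Gly at the amino end of its local collagenous region sits on
#' the amino side of that region; one at the carboxyl end sits on the
#' carboxyl side.  Non-boundary positions and single-Gly regions (where both
#' ends coincide) return `NA`.
#'
#' @inheritParams classify_position
#' @return character vector: `"amino"`, `"carboxyl"` or `NA`.
#' @export
boundary_side <- function(arch, residue_index) {
  stopifnot(inherits(arch, "chain_architecture"))
  seg <- arch$segments
  vapply(as.integer(residue_index), function(r) {
    i <- which(seg$start <= r & seg$end >= r)[1L]
    if (is.na(i) || seg$kind[i] != "collagenous") return(NA_character_)
    off <- r - seg$start[i]
    if (off %% 3L != 0L) return(NA_character_)
    g <- off %/% 3L + 1L
    n <- (seg$end[i] - seg$start[i] + 1L) %/% 3L
    if (n == 1L) return(NA_character_)
    if (g == 1L) return("amino")
    if (g == n) return("carboxyl")
    NA_character_
  }, character(1))
}

#' Locate a CDS position in the exon map
#'
#' @param arch a `chain_architecture`.
#' @param cdna_position 1-based CDS coordinate(s).
#' @return data.frame with `exon` and `is_amino_block` (`TRUE` iff the exon
#'   index is at most 20 — the chain's amino exon block).
#' @export
exon_location <- function(arch, cdna_position) {
  stopifnot(inherits(arch, "chain_architecture"))
  em <- arch$exon_map
  cds_len <- em$cdna_end[nrow(em)]
  cdna_position <- as.integer(cdna_position)
  if (any(is.na(cdna_position)) || any(cdna_position < 1L) ||
      any(cdna_position > cds_len))
    col4gly_error("bounds_error",
                  sprintf("cDNA position out of CDS range 1..%d", cds_len))
  idx <- findInterval(cdna_position, em$cdna_start)
  data.frame(exon = em$exon[idx], is_amino_block = em$exon[idx] <= 20L)
}
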