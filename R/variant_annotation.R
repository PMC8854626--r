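# Parsing of HGVS-like SNV notations and derivation of the molecular
# feature vector used throughout the analysis stages.

#' Parse a cDNA HGVS-like SNV description
#'
#' Accepts forms like `"2858G>T"` or `"c.1871G>A"` (case-insensitive).
#' Non-SNV descriptions (del/ins/dup) and intronic offsets (`"+5"`, `"-3"`)
#' are rejected: only exonic single-nucleotide substitutions are in scope.
#'
#' @param text character scalar.
#' @return list with `cdna_position`, `ref_base`, `alt_base`.
#' @export
parse_cdna <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    col4gly_error("parse_error", "empty cDNA description")
  s <- toupper(gsub("\\s", "", text))
  s <- sub("^C\\.", "", s)
  if (grepl("DEL|INS|DUP", s))
    col4gly_error("parse_error",
                  sprintf("'%s': only single-nucleotide substitutions are supported", text))
  if (grepl("^[0-9]+[+-][0-9]+", s))
    col4gly_error("parse_error",
                  sprintf("'%s': intronic offset positions are not supported", text))
  m <- regmatches(s, regexec("^([0-9]+)([ACGT])>([ACGT])$", s))[[1]]
  if (length(m) != 4L)
    col4gly_error("parse_error", sprintf("cannot parse cDNA change '%s'", text))
  if (m[3] == m[4])
    col4gly_error("parse_error", sprintf("'%s': ref and alt bases are identical", text))
  list(cdna_position = as.integer(m[2]), ref_base = m[3], alt_base = m[4])
}

#' Format a parsed cDNA variant back to its canonical string
#' @param v list as returned by [parse_cdna()].
#' @export
format_cdna <- function(v) {
  sprintf("%d%s>%s", v$cdna_position, v$ref_base, v$alt_base)
}

#' Parse a protein HGVS-like missense description
#'
#' Accepts `"Gly953Val"`, `"p.Gly953Val"` and one-letter `"G953V"`
#' (case-insensitive); output is normalized to 3-letter codes.
#'
#' @param text character scalar.
#' @return list with `residue_index`, `ref_residue`, `alt_residue`
#'   (3-letter codes).
#' @export
parse_protein <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    col4gly_error("parse_error", "empty protein description")
  s <- gsub("\\s", "", text)
  s <- sub("^[pP]\\.", "", s)
  m <- regmatches(s, regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z]{1,3})$", s))[[1]]
  if (length(m) != 4L)
    col4gly_error("parse_error", sprintf("cannot parse protein change '%s'", text))
  ref <- normalize_aa(m[2]); alt <- normalize_aa(m[4])
  if (is.na(ref) || is.na(alt))
    col4gly_error("parse_error", sprintf("unknown residue code in '%s'", text))
  if (ref == alt)
    col4gly_error("parse_error", sprintf("'%s': ref and alt residues identical", text))
  list(residue_index = as.integer(m[3]), ref_residue = ref, alt_residue = alt)
}

#' Format a parsed protein variant back to its canonical 3-letter string
#' @param v list as returned by [parse_protein()].
#' @export
format_protein <- function(v) {
  sprintf("%s%d%s", v$ref_residue, v$residue_index, v$alt_residue)
}

#' Map a CDS coordinate to its codon
#'
#' @param cdna_position 1-based CDS position(s) (position 1 = A of ATG).
#' @return data.frame with `residue` (= `ceiling(position/3)`) and
#'   `codon_offset` (1..3).
#' @export
codon_of <- function(cdna_position) {
  p <- as.integer(cdna_position)
  if (any(is.na(p)) || any(p < 1L))
    col4gly_error("input_error", "cDNA position must be a positive integer")
  res <- (p + 2L) %/% 3L
  data.frame(residue = res, codon_offset = p - 3L * (res - 1L))
}

#' Amino acids reachable from a Gly codon by one nucleotide change
#'
#' Enumerates the nine single-base neighbours of the codon and keeps
#' missense changes only (no synonymous, no stop).
#'
#' @param gly_codon one of `"GGA"`, `"GGC"`, `"GGG"`, `"GGT"`.
#' @return character vector of 3-letter residue codes.
#' @export
reachable_substitutions <- function(gly_codon) {
  codon <- toupper(gly_codon)
  if (length(codon) != 1L || is.na(translate_codon(codon)) ||
      translate_codon(codon) != "G")
    col4gly_error("domain_error", sprintf("'%s' is not a Gly codon", gly_codon))
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      aa <- translate_codon(mut)
      if (aa != "G" && aa != "*") out <- c(out, AA3[aa])
    }
  }
  sort(unique(unname(out)))
}

#' Destabilisation class of a Gly-substituting residue
#'
#' Gly is the only residue small enough to pack in the triple-helix core;
#' the eight residues reachable from a Gly codon by a single nucleotide
#' change are split into mildly destabilising (Ala, Ser, Cys) and highly
#' destabilising (Arg, Val, Glu, Asp, Trp) replacements.
#'
#' @param alt_residue residue code(s), 1- or 3-letter.
#' @return character vector, `"mild"` or `"high"`.
#' @export
destabilisation_class <- function(alt_residue) {
  aa <- normalize_aa(alt_residue)
  if (any(is.na(aa)))
    col4gly_error("domain_error", "unknown residue code")
  out <- ifelse(aa %in% c("Ala", "Ser", "Cys"), "mild",
         ifelse(aa %in% c("Arg", "Val", "Glu", "Asp", "Trp"), "high",
                NA_character_))
  if (any(is.na(out)))
    col4gly_error("domain_error",
                  sprintf("residue(s) %s not reachable from a Gly codon by one nucleotide change",
                          paste(aa[is.na(out)], collapse = ", ")))
  out
}

#' Annotate a Gly missense variant with the molecular feature vector
#'
#' Derives, for one variant: the position class within the chain
#' architecture, the boundary side, the exon and amino-block flag, the
#' destabilisation class of the replacing residue, and the local
#' collagenous region ordinal.  When no cDNA change is given the exon is
#' derived from the first base of the codon.
#'
#' @param arch a `chain_architecture`.
#' @param protein list from [parse_protein()] (or a string, parsed here);
#'   `ref_residue` must be Gly.
#' @param cdna optional list from [parse_cdna()] (or a string); when given,
#'   its codon must agree with `protein$residue_index`.
#' @return list of class `variant_annotation` with fields `gene`,
#'   `protein`, `cdna`, `position_class`, `boundary_side`, `exon`,
#'   `is_amino_block`, `destab_class`, `region`.
#' @param gene gene label carried through to the annotation.
#' @export
annotate_variant <- function(arch, protein, cdna = NULL, gene = arch$chain_id) {
  if (is.character(protein)) protein <- parse_protein(protein)
  if (length(cdna) == 1L && (is.na(cdna) || identical(unname(cdna), "")))
    cdna <- NULL
  if (is.character(cdna)) cdna <- parse_cdna(cdna)
  if (protein$ref_residue != "Gly")
    col4gly_error("classification_error",
                  sprintf("%s: reference residue is not Gly", format_protein(protein)))
  if (!is.null(cdna)) {
    co <- codon_of(cdna$cdna_position)
    if (co$residue != protein$residue_index)
      col4gly_error("consistency_error",
                    sprintf("cDNA position %d maps to residue %d, not %d",
                            cdna$cdna_position, co$residue, protein$residue_index))
  }
  cls <- classify_position(arch, protein$residue_index)
  if (!cls %in% c("nc_boundary", "amino_end", "carboxyl_end", "central"))
    col4gly_error("classification_error",
                  sprintf("residue %d is not a collagenous Gly slot (%s)",
                          protein$residue_index, cls))
  side <- boundary_side(arch, protein$residue_index)
  seg <- arch$segments
  i <- which(seg$start <= protein$residue_index & seg$end >= protein$residue_index)[1L]
  cdna_pos <- if (!is.null(cdna)) cdna$cdna_position else 3L * (protein$residue_index - 1L) + 1L
  ex <- exon_location(arch, cdna_pos)
  structure(list(gene = gene,
                 protein = protein,
                 cdna = cdna,
                 position_class = cls,
                 boundary_side = side,
                 exon = ex$exon,
                 is_amino_block = ex$is_amino_block,
                 destab_class = destabilisation_class(protein$alt_residue),
                 region = seg$region[i]),
            class = "variant_annotation")
}

#' @export
print.variant_annotation <- function(x, ...) {
  cat(sprintf("%s %s: %s (side %s), exon %d (%s), %s destabilising, region %d\n",
              x$gene, format_protein(x$protein), x$position_class,
              x$boundary_side %||% NA, x$exon,
              if (x$is_amino_block) "exons 1-20" else "exons 21+",
              x$destab_class, x$region))
  invisible(x)
}

#' Annotate a variant table
#'
#' Applies [annotate_variant()] to every row of a variant table (columns
#' `gene`, `protein_hgvs`, optional `cdna_hgvs`; passthrough columns kept)
#' and appends the annotation columns.  Rows that fail annotation are
#' returned with `annotation_error` filled instead of failing the batch.
#'
#' @param arch a `chain_architecture`.
#' @param variants data.frame.
#' @return the input with columns `position_class`, `boundary_side`,
#'   `exon`, `is_amino_block`, `destab_class`, `region`,
#'   `annotation_error` appended.
#' @export
annotate_table <- function(arch, variants) {
  v <- as.data.frame(variants)
  if (!"protein_hgvs" %in% names(v))
    col4gly_error("schema_error", "variant table missing column: protein_hgvs")
  n <- nrow(v)
  out <- data.frame(position_class = character(n), boundary_side = character(n),
                    exon = integer(n), is_amino_block = logical(n),
                    destab_class = character(n), region = integer(n),
                    annotation_error = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    res <- tryCatch(
      annotate_variant(arch, v$protein_hgvs[i],
                       cdna = if ("cdna_hgvs" %in% names(v)) v$cdna_hgvs[i] else NULL,
                       gene = if ("gene" %in% names(v)) v$gene[i] else arch$chain_id),
      col4gly_error = function(e) e)
    if (inherits(res, "variant_annotation")) {
      out$position_class[i] <- res$position_class
      out$boundary_side[i] <- res$boundary_side %||% NA_character_
      out$exon[i] <- res$exon
      out$is_amino_block[i] <- res$is_amino_block
      out$destab_class[i] <- res$destab_class
      out$region[i] <- res$region
    } else {
      out[i, c("position_class", "destab_class")] <- NA_character_
      out$exon[i] <- NA_integer_; out$region[i] <- NA_integer_
      out$is_amino_block[i] <- NA
      out$annotation_error[i] <- conditionMessage(res)
    }
  }
  cbind(v, out)
}
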