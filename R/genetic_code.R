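# Amino-acid code tables and the standard genetic code (DNA alphabet).

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")
AA1 <- structure(names(AA3), names = AA3)

# standard genetic code, DNA alphabet, stop = "*"
GENETIC_CODE_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste0, collapse = "")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  structure(aas, names = codons)
})

translate_codon <- function(codon) {
  unname(GENETIC_CODE_TABLE[toupper(codon)])
}

normalize_aa <- function(x) {
  x <- as.character(x)
  up <- toupper(x)
  three <- paste0(substr(up, 1, 1), tolower(substr(up, 2, 3)))
  out <- ifelse(nchar(x) == 1L & up %in% names(AA3), AA3[up],
         ifelse(nchar(x) == 3L & three %in% AA3, three, NA_character_))
  unname(out)
}

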