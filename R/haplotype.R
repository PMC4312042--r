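# HVR-I haplotypes in motif notation.
#
# A haplotype is the set of its differences from the reference window
# 16024-16384 (361 sites, 1-based rCRS coordinates).  All downstream
# statistics depend only on symmetric differences between variant sets,
# so reference bases are needed only for FASTA round-trips.

HVR1_START <- 16024L
HVR1_END   <- 16384L
HVR1_LEN   <- 361L

#' Construct an HVR-I haplotype from variant positions and bases
#'
#' A haplotype is represented as a set of `(position, base)` variants
#' relative to the reference window 16024--16384.  The empty set denotes
#' the reference (CRS) haplotype.
#'
#' @param positions Integer vector of 1-based rCRS positions, each within
#'   `[16024, 16384]`.
#' @param bases Character vector of the same length, each one of
#'   `"A"`, `"C"`, `"G"`, `"T"`.
#' @return An object of class `"haplotype"`: a character vector of bases
#'   named by position, sorted by position.
#' @examples
#' haplotype(c(16284, 16294), c("G", "T"))
#' haplotype()                     # the CRS reference haplotype
#' @export
haplotype <- function(positions = integer(), bases = character()) {
  positions <- as.integer(positions)
  bases <- toupper(as.character(bases))
  if (length(positions) != length(bases))
    stop("positions and bases must have equal length", call. = FALSE)
  if (length(positions)) {
    if (any(positions < HVR1_START | positions > HVR1_END))
      stop(sprintf("variant position outside window [%d,%d]",
                   HVR1_START, HVR1_END), call. = FALSE)
    if (anyDuplicated(positions))
      stop("duplicate variant position: ",
           positions[duplicated(positions)][1L], call. = FALSE)
    if (!all(bases %in% c("A", "C", "G", "T")))
      stop("bases must be one of A, C, G, T", call. = FALSE)
    o <- order(positions)
    positions <- positions[o]
    bases <- bases[o]
  }
  structure(stats::setNames(bases, positions), class = "haplotype")
}

#' @export
print.haplotype <- function(x, ...) {
  cat("<haplotype> ", format_motif(x), "\n", sep = "")
  invisible(x)
}

#' Parse a motif string into a haplotype
#'
#' Motif notation lists each variant as three digits (the rCRS position
#' minus 16000) followed by the variant base, e.g. `"284G 294T"`.  The
#' string `"CRS"` denotes the reference haplotype (no variants).
#'
#' @param motif A single motif string.
#' @return A [haplotype()].
#' @examples
#' parse_motif("284G 294T")
#' parse_motif("CRS")
#' @export
parse_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif))
    stop("motif must be a single string", call. = FALSE)
  motif <- trimws(motif)
  if (toupper(motif) == "CRS") return(haplotype())
  tokens <- strsplit(motif, "[[:space:]]+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stop("empty motif string", call. = FALSE)
  ok <- grepl("^[0-9]{3}[ACGTacgt]$", tokens)
  if (!all(ok))
    stop("malformed motif token: '", tokens[!ok][1L], "'", call. = FALSE)
  pos <- 16000L + as.integer(substr(tokens, 1L, 3L))
  base <- toupper(substr(tokens, 4L, 4L))
  if (any(bad <- pos < HVR1_START | pos > HVR1_END))
    stop("motif token outside window [16024,16384]: '",
         tokens[bad][1L], "'", call. = FALSE)
  if (anyDuplicated(pos))
    stop("duplicate position in motif: '",
         tokens[duplicated(pos)][1L], "'", call. = FALSE)
  haplotype(pos, base)
}

#' Format a haplotype as a motif string
#'
#' Inverse of [parse_motif()]: tokens sorted by position, the empty
#' variant set rendered as `"CRS"`.
#'
#' @param h A [haplotype()].
#' @return A single motif string.
#' @export
format_motif <- function(h) {
  stopifnot(inherits(h, "haplotype"))
  if (!length(h)) return("CRS")
  pos <- as.integer(names(h))
  paste0(sprintf("%03d", pos - 16000L), unname(h), collapse = " ")
}

# Canonical key for haplotype identity (distinctness, hashing).
haplotype_key <- function(h) {
  if (!length(h)) return("CRS")
  paste0(names(h), unname(h), collapse = ";")
}

#' Number of pairwise sequence differences between two haplotypes
#'
#' Counts positions at which the two sequences differ: positions carried
#' by exactly one haplotype, plus positions carried by both but with
#' different variant bases (one difference, not two).
#'
#' @param a,b Objects of class `"haplotype"` over the same window.
#' @return A non-negative integer.
#' @examples
#' pairwise_difference(parse_motif("069T 126C"), parse_motif("069T 126C 153A"))
#' @export
pairwise_difference <- function(a, b) {
  stopifnot(inherits(a, "haplotype"), inherits(b, "haplotype"))
  pa <- names(a); pb <- names(b)
  only_a <- sum(!(pa %in% pb))
  only_b <- sum(!(pb %in% pa))
  shared <- intersect(pa, pb)
  diff_shared <- sum(a[shared] != b[shared])
  as.integer(only_a + only_b + diff_shared)
}
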