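# Labelled sets of HVR-I sequences with a sampling age in generations.

#' Construct a population sample
#'
#' A population sample bundles an ordered set of sequences sharing one
#' sampling age: 0 generations for modern samples, 55 for the medieval
#' sample (1375 years at 25 years per generation).
#'
#' @param label Population label.
#' @param age_generations Non-negative integer sampling age.
#' @param sample_id Character vector of unique sequence identifiers.
#' @param haplotypes List of [haplotype()] objects, one per sequence.
#' @param haplogroup Optional character vector of haplogroup labels
#'   (read from published tables, never computed here).
#' @param site Optional character vector of site/locality labels.
#' @return An object of class `"population_sample"`.
#' @export
population_sample <- function(label, age_generations, sample_id, haplotypes,
                              haplogroup = NULL, site = NULL) {
  n <- length(sample_id)
  if (length(haplotypes) != n)
    stop("sample_id and haplotypes must have equal length", call. = FALSE)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         sample_id[duplicated(sample_id)][1L], call. = FALSE)
  age_generations <- as.integer(age_generations)
  if (length(age_generations) != 1L || is.na(age_generations) ||
      age_generations < 0L)
    stop("age_generations must be a single non-negative integer",
         call. = FALSE)
  ok <- vapply(haplotypes, inherits, logical(1), "haplotype")
  if (!all(ok)) stop("all members must be haplotype objects", call. = FALSE)
  structure(list(
    label = as.character(label),
    age_generations = age_generations,
    sample_id = as.character(sample_id),
    haplotypes = haplotypes,
    haplogroup = if (is.null(haplogroup)) rep(NA_character_, n)
                 else as.character(haplogroup),
    site = if (is.null(site)) rep(NA_character_, n) else as.character(site)
  ), class = "population_sample")
}

#' @export
length.population_sample <- function(x) length(x$sample_id)

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("<population_sample> %s: n = %d, age = %d generations\n",
              x$label, length(x), x$age_generations))
  invisible(x)
}

#' @export
as.data.frame.population_sample <- function(x, ...) {
  data.frame(
    sample_id = x$sample_id,
    motif = vapply(x$haplotypes, format_motif, character(1)),
    haplogroup = x$haplogroup,
    site = x$site,
    stringsAsFactors = FALSE
  )
}

motifs_to_population <- function(label, age_generations, sample_id, motifs,
                                 haplogroup = NULL, site = NULL) {
  population_sample(label, age_generations, sample_id,
                    lapply(motifs, parse_motif), haplogroup, site)
}

#' Read a population sample from a motif table or FASTA file
#'
#' Two formats are supported.  A delimited table (tab or comma separated,
#' header row) must contain columns `sample_id` and `motif`, and may
#' contain `haplogroup` and `site`.  A FASTA file must contain records of
#' exactly 361 bases, which are diffed against the packaged reference
#' window to produce variant sets.
#'
#' @param path Path to the input file.
#' @param label Population label.
#' @param age_generations Sampling age in generations.
#' @param format `"auto"` (default: FASTA when the first non-blank
#'   character is `>`), `"table"` or `"fasta"`.
#' @param reference Character vector of 361 reference bases used for the
#'   FASTA route; defaults to the packaged window.
#' @return A [population_sample()].
#' @export
load_population <- function(path, label, age_generations,
                            format = c("auto", "table", "fasta"),
                            reference = hvr1_reference()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(trimws(first), ">"))
      "fasta" else "table"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    if (!length(seqs)) stop("empty FASTA file: ", path, call. = FALSE)
    if (any(Biostrings::width(seqs) != HVR1_LEN))
      stop("FASTA records must be exactly ", HVR1_LEN, " bases", call. = FALSE)
    haps <- lapply(seq_along(seqs), function(i) {
      bases <- strsplit(as.character(seqs[[i]]), "")[[1L]]
      idx <- which(toupper(bases) != toupper(reference))
      haplotype(HVR1_START + idx - 1L, bases[idx])
    })
    population_sample(label, age_generations, names(seqs), haps)
  } else {
    # motifs contain spaces, so the delimiter must be tab or comma
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("sample_id", "motif") %in% names(df)))
      df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                     error = function(e) df)
    if (!all(c("sample_id", "motif") %in% names(df)))
      stop("motif table must contain columns 'sample_id' and 'motif'",
           call. = FALSE)
    motifs_to_population(label, age_generations, df$sample_id, df$motif,
                         haplogroup = df[["haplogroup"]],
                         site = df[["site"]])
  }
}

#' Write a population sample as a tab-delimited motif table
#'
#' @param x A [population_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population <- function(x, path) {
  stopifnot(inherits(x, "population_sample"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged reference window
#'
#' Returns the 361 reference bases for window 16024--16384 used by the
#' FASTA reader/writer.  The packaged file is a synthetic stand-in (all
#' statistics in this package depend only on sequence differences, never
#' on the actual reference bases), shipped so FASTA round-trips are
#' well defined offline.
#'
#' @return Character vector of 361 bases named by position.
#' @export
hvr1_reference <- function() {
  path <- system.file("extdata", "hvr1_reference_synthetic.fasta",
                      package = "serialabc", mustWork = TRUE)
  s <- Biostrings::readDNAStringSet(path)
  bases <- strsplit(as.character(s[[1L]]), "")[[1L]]
  stats::setNames(bases, HVR1_START:HVR1_END)
}

#' Write a population sample as FASTA against the reference window
#'
#' @param x A [population_sample()].
#' @param path Output path.
#' @param reference Reference bases, defaults to the packaged window.
#' @return `path`, invisibly.
#' @export
write_population_fasta <- function(x, path, reference = hvr1_reference()) {
  stopifnot(inherits(x, "population_sample"))
  seqs <- vapply(x$haplotypes, function(h) {
    bases <- unname(reference)
    if (length(h))
      bases[as.integer(names(h)) - HVR1_START + 1L] <- unname(h)
    paste0(bases, collapse = "")
  }, character(1))
  set <- Biostrings::DNAStringSet(stats::setNames(seqs, x$sample_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' The 28 medieval HVR-I sequences
#'
#' Returns the packaged medieval sample: 28 sequences from five
#' early-medieval burial sites in Piedmont (Rivoli Corso Levi, Rivoli La
#' Perosa, Mombello Monferrato, Collegno, Centallo San Gervasio), each
#' given as its published motif over window 16024--16384 together with
#' its published haplogroup label.  Sampling age is 55 generations
#' (about 1375 years at 25 years per generation).
#'
#' @return A [population_sample()] of 28 members.
#' @examples
#' med <- medieval_fixture()
#' haplotype_count(med)    # 18 distinct haplotypes
#' @export
medieval_fixture <- function() {
  path <- system.file("extdata", "medieval_hvr1.tsv",
                      package = "serialabc", mustWork = TRUE)
  load_population(path, label = "medieval", age_generations = 55L,
                  format = "table")
}
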