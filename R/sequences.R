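#' Construct an oligonucleotide sequence with per-position 5mC flags
#'
#' An `oligo_seq` holds an explicit DNA sequence over the alphabet
#' \{A, C, G, T\} together with a logical methylation flag per position
#' (`TRUE` marks a 5-methylcytosine).  Methylation flags are only legal on
#' cytosines.
#'
#' @param bases Character scalar (e.g. `"GGGGCC"`) or character vector of
#'   single bases.
#' @param methyl Logical vector of the same length as the sequence, or `NULL`
#'   for an unmethylated oligo.
#' @param name Free-text label.
#' @return An object of class `oligo_seq` with elements `bases` (character
#'   vector of single letters), `methyl` (logical vector) and `name`.
#' @examples
#' oligo_seq("GGGGCCGGGG", name = "toy")
#' @export
oligo_seq <- function(bases, methyl = NULL, name = "") {
  if (length(bases) == 1L && nchar(bases) > 1L)
    bases <- strsplit(bases, "")[[1]]
  bases <- toupper(as.character(bases))
  if (length(bases) < 1L)
    stop("sequence must have length >= 1")
  bad <- setdiff(unique(bases), c("A", "C", "G", "T"))
  if (length(bad))
    stop("invalid alphabet: sequence contains non-ACGT character(s): ",
         paste(bad, collapse = ", "))
  if (is.null(methyl)) methyl <- rep(FALSE, length(bases))
  stopifnot(is.logical(methyl), length(methyl) == length(bases))
  if (any(methyl & bases != "C"))
    stop("methylation flag set on a non-cytosine position")
  structure(list(bases = bases, methyl = methyl, name = name),
            class = "oligo_seq")
}

#' @export
print.oligo_seq <- function(x, ...) {
  cat(sprintf("<oligo_seq> %s (%d nt, %d x 5mC)\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              length(x$bases), sum(x$methyl)))
  cat(" ", paste(x$bases, collapse = ""), "\n")
  invisible(x)
}

#' @export
length.oligo_seq <- function(x) length(x$bases)

#' @export
as.character.oligo_seq <- function(x, ...) paste(x$bases, collapse = "")

#' Expand repeat notation into an explicit oligo sequence
#'
#' Expands run-length repeat notation such as `(GGGGCC)3 + "GGGG"` into an
#' explicit sequence: the repeat unit concatenated `n` times, followed by an
#' optional suffix.  The C9orf72 repeat oligos used throughout this package
#' are written this way, e.g. the 22-mer `(G4C2)3GGGG` and the 48-mer
#' `(G4C2)8`.
#'
#' @param unit Repeat unit, e.g. `"GGGGCC"`.
#' @param n Number of repeats (>= 0).
#' @param suffix Bases appended after the repeats (may be `""`).
#' @param name Label for the resulting oligo.
#' @return An [oligo_seq], of length `n * nchar(unit) + nchar(suffix)`.
#' @examples
#' expand_repeat("GGGGCC", 3, "GGGG", name = "C9-22mer")  # 22 nt
#' expand_repeat("GGGGCC", 8, name = "C9-48mer")          # 48 nt
#' @export
expand_repeat <- function(unit, n, suffix = "", name = "") {
  stopifnot(length(n) == 1L, n >= 0, n == round(n))
  if (n * nchar(unit) + nchar(suffix) < 1L)
    stop("expansion is empty: need n >= 1 or a non-empty suffix")
  seq <- paste0(strrep(unit, n), suffix)
  oligo_seq(seq, name = name)
}

#' Locate CpG dinucleotides
#'
#' Scans the given strand for cytosines immediately followed (3' direction)
#' by a guanine.  Only the given strand is scanned; positions refer to the C
#' of each CpG.
#'
#' @param seq An [oligo_seq] (or a string coercible to one).
#' @param base Index base of the returned positions: 0 (default) or 1.
#' @return Integer vector of CpG positions, ascending.
#' @examples
#' find_cpg_sites(expand_repeat("GGGGCC", 3, "GGGG"))  # 5, 11, 17
#' @export
find_cpg_sites <- function(seq, base = 0L) {
  if (!inherits(seq, "oligo_seq")) seq <- oligo_seq(seq)
  stopifnot(base %in% c(0L, 1L))
  b <- seq$bases
  n <- length(b)
  if (n < 2L) return(integer(0))
  i <- which(b[-n] == "C" & b[-1L] == "G")
  i + base - 1L
}

#' Set 5-methylcytosine flags at given positions
#'
#' Marks the cytosines at `positions` as 5mC.  The base letters are
#' unchanged; only flags are set.  Flagging a non-cytosine is an error.
#'
#' @param seq An [oligo_seq].
#' @param positions Positions of cytosines to methylate (same index base as
#'   `base`).
#' @param base Index base of `positions`: 0 (default) or 1.
#' @return The methylated [oligo_seq].
#' @examples
#' s <- expand_repeat("GGGGCC", 3, "GGGG", name = "C9-22mer")
#' apply_methylation(s, find_cpg_sites(s))
#' @export
apply_methylation <- function(seq, positions, base = 0L) {
  stopifnot(inherits(seq, "oligo_seq"), base %in% c(0L, 1L))
  if (length(positions) == 0L) return(seq)
  idx <- as.integer(positions) - base + 1L
  if (any(idx < 1L | idx > length(seq$bases)))
    stop("invalid site: position out of range")
  if (any(seq$bases[idx] != "C"))
    stop("invalid site: methylation position does not index a cytosine")
  seq$methyl[idx] <- TRUE
  seq
}

#' Write an oligo to FASTA plus a methylation sidecar
#'
#' IUPAC has no code for 5-methylcytosine, so the sequence is written as
#' plain FASTA and the methylated positions to a JSON sidecar
#' (`{"name":..., "methylated_positions":[...]}`, 0-based).
#'
#' @param seq An [oligo_seq].
#' @param fasta_path,json_path Output paths.  `json_path` defaults to
#'   `fasta_path` with extension `.methyl.json`.
#' @return Invisibly, the two paths.
#' @export
write_oligo <- function(seq, fasta_path,
                        json_path = sub("\\.[^.]*$", ".methyl.json", fasta_path)) {
  stopifnot(inherits(seq, "oligo_seq"))
  nm <- if (nzchar(seq$name)) seq$name else "oligo"
  seqinr::write.fasta(list(seq$bases), names = nm, file.out = fasta_path)
  jsonlite::write_json(
    list(name = nm, methylated_positions = which(seq$methyl) - 1L),
    json_path, auto_unbox = TRUE)
  invisible(c(fasta = fasta_path, json = json_path))
}

#' Read an oligo from FASTA (optionally with methylation sidecar)
#'
#' @param fasta_path FASTA file with a single record.
#' @param json_path Optional sidecar JSON written by [write_oligo()].
#' @return An [oligo_seq].
#' @export
read_oligo <- function(fasta_path, json_path = NULL) {
  fa <- seqinr::read.fasta(fasta_path, seqtype = "DNA", forceDNAtolower = FALSE)
  if (length(fa) != 1L)
    stop("expected exactly one FASTA record, found ", length(fa))
  s <- oligo_seq(toupper(as.character(fa[[1]])), name = attr(fa[[1]], "name"))
  if (!is.null(json_path)) {
    side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    s <- apply_methylation(s, side$methylated_positions, base = 0L)
  }
  s
}
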