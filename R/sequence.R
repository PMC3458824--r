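# Peptide charge / hydrophobicity profiling of OMP terminal fragments.
#
# The classification alphabet is frozen:
#   negative    D, E
#   positive    K, R, H   (His counted as positive)
#   hydrophobic A, V, L, I, M, F, W, Y  (Gly, Pro, Thr excluded)
# This is the unique assignment consistent with the per-fragment counts used
# throughout the analysis (e.g. 7 charged / 8 hydrophobic for the OmpC
# N-terminal 20-mer vs 3 charged / 11 hydrophobic for its C-terminal 21-mer)
# and it must not be changed silently; see the methods vignette.

.AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.AA_NEGATIVE <- c("D", "E")
.AA_POSITIVE <- c("K", "R", "H")
.AA_HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "Y")

#' Construct a peptide sequence
#'
#' A light container for a one-letter amino-acid string with a short label.
#' Residue indexing is 1-based within the fragment, matching the convention
#' used for labels such as Glu2 or Asp18.
#'
#' @param id short label, e.g. `"OmpC_N"`.
#' @param residues one-letter string or character vector of canonical codes.
#' @return object of class `peptide_sequence` with fields `id`, `residues`
#'   (character vector) and `indexing_base` (always 1).
#' @examples
#' peptide_sequence("OmpC_N", "AEVYNKDGNKLDLYGKVDGL")
#' @export
peptide_sequence <- function(id, residues) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(residues)
  if (length(residues) < 1L) stop("peptide must contain at least one residue")
  bad <- which(!residues %in% .AA_CANONICAL)
  if (length(bad) > 0L)
    stop(sprintf("non-canonical residue code '%s' at position %d in '%s'",
                 residues[bad[1]], bad[1], id))
  structure(list(id = as.character(id), residues = residues,
                 indexing_base = 1L),
            class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(sprintf("<peptide %s> %d aa: %s\n", x$id, length(x$residues),
              paste(x$residues, collapse = "")))
  invisible(x)
}

as_peptide <- function(x, id = "peptide") {
  if (inherits(x, "peptide_sequence")) x else peptide_sequence(id, x)
}

#' Classify peptide residues by charge and hydrophobicity
#'
#' Counts negatively charged (D, E), positively charged (K, R, H) and
#' hydrophobic (A, V, L, I, M, F, W, Y) residues and records the position,
#' code and sign of every charged residue.
#'
#' @param seq a [peptide_sequence()] or one-letter string.
#' @return object of class `peptide_profile`: list with `id`, `length`,
#'   `n_negative`, `n_positive`, `n_charged`, `n_hydrophobic` and
#'   `charge_positions` (data.frame with columns `position`, `residue`,
#'   `sign` where sign is `"+"` or `"-"`).
#' @examples
#' p <- classify_residues("AEVYNKDGNKLDLYGKVDGL")
#' p$n_charged      # 7
#' p$n_hydrophobic  # 8
#' @export
classify_residues <- function(seq) {
  seq <- as_peptide(seq)
  res <- seq$residues
  neg <- which(res %in% .AA_NEGATIVE)
  pos <- which(res %in% .AA_POSITIVE)
  hyd <- which(res %in% .AA_HYDROPHOBIC)
  idx <- sort(c(neg, pos))
  charge_positions <- data.frame(
    position = idx,
    residue = res[idx],
    sign = ifelse(res[idx] %in% .AA_NEGATIVE, "-", "+"),
    stringsAsFactors = FALSE)
  structure(list(
    id = seq$id,
    length = length(res),
    n_negative = length(neg),
    n_positive = length(pos),
    n_charged = length(neg) + length(pos),
    n_hydrophobic = length(hyd),
    charge_positions = charge_positions),
    class = "peptide_profile")
}

#' @export
print.peptide_profile <- function(x, ...) {
  cat(sprintf("<profile %s> length %d | %d charged (%d-, %d+) | %d hydrophobic\n",
              x$id, x$length, x$n_charged, x$n_negative, x$n_positive,
              x$n_hydrophobic))
  if (nrow(x$charge_positions) > 0)
    cat("  charges:",
        paste0(x$charge_positions$residue, x$charge_positions$position,
               "(", x$charge_positions$sign, ")", collapse = " "), "\n")
  invisible(x)
}

#' Replace every charged residue by a neutral one
#'
#' Produces the charge-neutralized mutant of a peptide: every D, E, K, R or H
#' is replaced by the given neutral residue (Ala or Asn), as in
#' charge-ablation control constructs. Idempotent; length preserved.
#'
#' @param seq a [peptide_sequence()] or one-letter string.
#' @param replacement `"A"` or `"N"`.
#' @return a new `peptide_sequence` with `_<replacement>mut` appended to the id.
#' @examples
#' neutralize_charges("AEVYNKDGNKLDLYGKVDGL", "A")
#' @export
neutralize_charges <- function(seq, replacement = c("A", "N")) {
  replacement <- match.arg(replacement)
  seq <- as_peptide(seq)
  res <- seq$residues
  res[res %in% c(.AA_NEGATIVE, .AA_POSITIVE)] <- replacement
  peptide_sequence(paste0(seq$id, "_", replacement, "mut"), res)
}

#' Compare the charge content of two termini
#'
#' Orders two fragment profiles (typically the N- and C-terminal fragments of
#' one OMP) by total charged-residue count, the quantity that separates
#' cavity-entering from non-entering fragments.
#'
#' @param n_profile,c_profile `peptide_profile` objects from
#'   [classify_residues()] (same classification scheme by construction).
#' @return list with `verdict` (`"N>C"`, `"C>N"` or `"tie"`) and
#'   `difference` (`n_profile$n_charged - c_profile$n_charged`).
#' @examples
#' n <- classify_residues(peptide_sequence("N", "AEVYNKDGNKLDLYGKVDGL"))
#' c <- classify_residues(peptide_sequence("C", "FTRDAGINTDNIVALGLVYQF"))
#' compare_termini(n, c) # N>C by 4
#' @export
compare_termini <- function(n_profile, c_profile) {
  stopifnot(inherits(n_profile, "peptide_profile"),
            inherits(c_profile, "peptide_profile"))
  d <- n_profile$n_charged - c_profile$n_charged
  verdict <- if (d > 0) "N>C" else if (d < 0) "C>N" else "tie"
  list(verdict = verdict, difference = d)
}

#' Read peptide sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return list of [peptide_sequence()] objects named by FASTA id.
#' @export
read_peptides_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             set.attributes = FALSE)
  out <- lapply(names(recs), function(nm)
    peptide_sequence(nm, toupper(unlist(recs[[nm]]))))
  names(out) <- names(recs)
  out
}

#' Write peptide sequences to a FASTA file
#'
#' @param peptides list of [peptide_sequence()] objects (or a single one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peptides_fasta <- function(peptides, path) {
  if (inherits(peptides, "peptide_sequence")) peptides <- list(peptides)
  seqinr::write.fasta(lapply(peptides, `[[`, "residues"),
                      names = vapply(peptides, `[[`, "", "id"),
                      file.out = path)
  invisible(path)
}

#' Tabulate peptide profiles
#'
#' Batch-classifies peptides into a characteristics table (one row per
#' fragment: id, length, hydrophobic count, charged count, with the +/- split).
#'
#' @param peptides list of [peptide_sequence()] objects or one-letter strings.
#' @return data.frame with columns `id`, `length`, `n_hydrophobic`,
#'   `n_charged`, `n_negative`, `n_positive`.
#' @export
profile_table <- function(peptides) {
  if (inherits(peptides, "peptide_sequence")) peptides <- list(peptides)
  rows <- lapply(peptides, function(p) {
    pr <- classify_residues(p)
    data.frame(id = pr$id, length = pr$length,
               n_hydrophobic = pr$n_hydrophobic, n_charged = pr$n_charged,
               n_negative = pr$n_negative, n_positive = pr$n_positive,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(), length = integer(),
                      n_hydrophobic = integer(), n_charged = integer(),
                      n_negative = integer(), n_positive = integer())
  rownames(out) <- NULL
  out
}
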