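#' Define a peptic peptide
#'
#' Constructs the peptide descriptor used by every downstream stage: the
#' 1-letter sequence, its residue span in the parent protein, the observed
#' charge state and the number of backbone amides observable in a deuterium
#' exchange experiment.
#'
#' @param sequence Amino-acid sequence, 1-letter codes, standard 20 residues.
#' @param start,end 1-based, inclusive residue indices in the parent protein.
#'   Must satisfy \code{end - start + 1 == nchar(sequence)}.
#' @param charge Positive integer charge state.
#' @param n_exchangeable Number of exchange-competent backbone amides. Defaults
#'   to [count_exchangeable()] applied to \code{sequence}; override per peptide
#'   if a different convention is wanted.
#'
#' @return An object of class \code{"hdx_peptide"}: a list with fields
#'   \code{sequence}, \code{start}, \code{end}, \code{charge},
#'   \code{n_exchangeable}.
#' @examples
#' pep <- hdx_peptide("ALIYGAPRAATVKAKTNVKL", start = 202, end = 221, charge = 2)
#' pep$n_exchangeable  # 17
#' @export
hdx_peptide <- function(sequence, start = 1L, end = start + nchar(sequence) - 1L,
                        charge = 1L, n_exchangeable = count_exchangeable(sequence)) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  if (end - start + 1L != nchar(sequence)) {
    stop("end - start + 1 must equal the sequence length", call. = FALSE)
  }
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer", call. = FALSE)
  n_exchangeable <- as.integer(n_exchangeable)
  if (n_exchangeable < 0L || n_exchangeable > nchar(sequence) - 1L) {
    stop("n_exchangeable must be in [0, length - 1]", call. = FALSE)
  }
  .peptide_formula(sequence)  # validates residues
  structure(list(sequence = sequence, start = as.integer(start),
                 end = as.integer(end), charge = charge,
                 n_exchangeable = n_exchangeable),
            class = "hdx_peptide")
}

#' @export
print.hdx_peptide <- function(x, ...) {
  cat(sprintf("<hdx_peptide> %d-%d %s (+%d), %d exchangeable amides\n",
              x$start, x$end, x$sequence, x$charge, x$n_exchangeable))
  invisible(x)
}

#' Count exchange-competent backbone amides
#'
#' Number of backbone amide hydrogens whose exchange is observable in a
#' peptide-level HDX-MS experiment, under the common convention: the first two
#' residues are excluded (their amides back-exchange too fast to retain label
#' through analysis) and prolines beyond position 2 are excluded (no amide
#' hydrogen). That is, \code{nchar(sequence) - 2 - #prolines at positions
#' 3..length}.
#'
#' @param sequence Amino-acid sequence (1-letter codes), length >= 2.
#' @return Integer count, in \code{[0, length - 2]}.
#' @examples
#' count_exchangeable("ALIYGAPRAATVKAKTNVKL")  # 17
#' count_exchangeable("APPA")                  # 0
#' @export
count_exchangeable <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < 2L) stop("sequence must have length >= 2", call. = FALSE)
  aa <- strsplit(sequence, "")[[1]]
  internal_pro <- if (n >= 3L) sum(aa[3:n] == "P") else 0L
  as.integer(n - 2L - internal_pro)
}
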