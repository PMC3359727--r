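# Sequence-derived predictor features: monomer molecular weight, average
# hydropathy (GRAVY) and the longest contiguous stretch of disordered
# residues.

# Average (not monoisotopic) residue masses, Da: amino acid minus water,
# as used for purified-protein MW estimates.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

WATER_MASS <- 18.01528

# Kyte & Doolittle (1982) hydropathy scale.
KD_HYDROPATHY <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Per-residue disorder propensity (TOP-IDP-style scale: positive values
# promote disorder) used only by the labelled fallback heuristic.
DISORDER_PROPENSITY <- c(
  W = -0.884, F = -0.697, Y = -0.510, I = -0.486, M = -0.397,
  L = -0.326, V = -0.121, N = 0.007,  C = 0.020,  T = 0.059,
  A = 0.060,  G = 0.166,  R = 0.180,  D = 0.192,  H = 0.303,
  Q = 0.318,  S = 0.341,  K = 0.586,  E = 0.736,  P = 0.987)

splitResidues <- function(seq) {
  if (is(seq, "SequenceRecord")) seq <- seq@residues
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

checkResidues <- function(chars) {
  bad <- which(!chars %in% c(names(AA_RESIDUE_MASS), "X"))
  if (length(bad))
    stop(sprintf("illegal residue '%s' at position %d", chars[bad[1]], bad[1]))
  invisible(chars)
}

#' Create a sequence record
#'
#' @param residues one-letter amino-acid string (upper/lowercase accepted);
#'   the 20 standard letters plus `X`.
#' @param id identifier.
#' @param disorderCalls optional logical vector of per-residue disorder calls
#'   (e.g. precomputed by an external predictor); length must equal the
#'   sequence length.
#' @return a [SequenceRecord-class].
#' @export
sequenceRecord <- function(residues, id = "seq", disorderCalls = NULL) {
  residues <- toupper(gsub("[[:space:]*]", "", residues))
  checkResidues(splitResidues(residues))
  if (!is.null(disorderCalls)) disorderCalls <- as.logical(disorderCalls)
  new("SequenceRecord", id = id, residues = residues,
      disorderCalls = disorderCalls,
      disorderSource = if (is.null(disorderCalls)) "none" else "user")
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a list of
#' [SequenceRecord-class] objects.
#'
#' @param path FASTA file.
#' @return list of [SequenceRecord-class].
#' @export
readFastaSequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  lapply(seq_along(aa), function(i)
    sequenceRecord(as.character(aa[[i]]), id = names(aa)[i]))
}

#' Read per-residue disorder calls
#'
#' Two-column CSV (position, call-or-probability).  Probabilities are
#' thresholded at `threshold`; 0/1 and TRUE/FALSE columns pass through.
#'
#' @param path CSV file with columns position, call.
#' @param length sequence length; positions absent from the file are FALSE.
#' @param threshold probability cutoff for a disordered call.
#' @return logical vector of length `length`.
#' @export
readDisorderCalls <- function(path, length, threshold = 0.5) {
  tab <- read.csv(path, header = TRUE)
  if (ncol(tab) < 2L) stop("disorder-call file needs two columns")
  pos <- as.integer(tab[[1]])
  val <- tab[[2]]
  if (is.logical(val)) call <- val else call <- as.numeric(val) >= threshold
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > length))
    stop("disorder-call positions out of sequence range")
  out <- rep(FALSE, length)
  out[pos] <- call
  out
}

#' Monomer molecular weight from sequence
#'
#' Sum of average residue masses plus one water mass.  `X` contributes the
#' mean of the 20 standard residue masses.
#'
#' @param seq a [SequenceRecord-class] or a plain residue string.
#' @return molecular weight in Da.
#' @examples
#' monomerMW("G")   # 75.07
#' @export
monomerMW <- function(seq) {
  chars <- checkResidues(splitResidues(seq))
  if (length(chars) == 0L) stop("empty sequence")
  masses <- AA_RESIDUE_MASS[chars]
  masses[chars == "X"] <- mean(AA_RESIDUE_MASS)
  sum(masses) + WATER_MASS
}

#' Average hydropathy (GRAVY)
#'
#' Mean of per-residue Kyte--Doolittle hydropathy values over the whole
#' sequence (no sliding window).  `X` residues are excluded from the mean.
#'
#' @param seq a [SequenceRecord-class] or a plain residue string.
#' @return dimensionless GRAVY value in `[-4.5, 4.5]`.
#' @export
avgHydropathy <- function(seq) {
  chars <- checkResidues(splitResidues(seq))
  chars <- chars[chars != "X"]
  if (length(chars) == 0L) stop("no scoreable residues (empty or all-X)")
  mean(KD_HYDROPATHY[chars])
}

#' Longest contiguous stretch of disordered residues
#'
#' @param calls logical vector of per-residue disorder calls.
#' @return length (residues) of the maximal run of consecutive TRUE values.
#' @export
longestDisorderStretch <- function(calls) {
  calls <- as.logical(calls)
  if (length(calls) == 0L) return(0L)
  r <- rle(calls)
  runs <- r$lengths[r$values]
  if (length(runs) == 0L) 0L else as.integer(max(runs))
}

#' Fallback per-residue disorder heuristic
#'
#' Deterministic stand-in used only when no externally computed disorder
#' calls are supplied: a per-residue disorder-propensity score (TOP-IDP-style
#' scale in which charged and structure-breaking residues promote disorder
#' and hydrophobics oppose it) is smoothed with a centered `window`-residue
#' moving average and thresholded.  The result is labelled
#' `"fallback, not DisEMBL"` in its `source` attribute; user-supplied calls
#' always take precedence everywhere in the package.
#'
#' @param seq a [SequenceRecord-class] or plain residue string.
#' @param threshold smoothed-propensity cutoff for a disordered call.
#' @param window smoothing window (odd number of residues).
#' @return logical vector with attribute `source = "fallback, not DisEMBL"`.
#' @export
fallbackDisorder <- function(seq, threshold = 0.30, window = 15L) {
  chars <- checkResidues(splitResidues(seq))
  if (length(chars) == 0L) stop("empty sequence")
  prop <- DISORDER_PROPENSITY[chars]
  prop[chars == "X"] <- mean(DISORDER_PROPENSITY)
  sm <- movingAverage(unname(prop), window)
  structure(sm > threshold, source = "fallback, not DisEMBL")
}

disorderCallsFor <- function(rec) {
  if (!is.null(rec@disorderCalls)) rec@disorderCalls
  else fallbackDisorder(rec)
}

#' Sequence feature bundle
#'
#' Computes the three sequence-level features in one call: monomer molecular
#' weight, GRAVY, and the longest disorder stretch (from user-supplied calls
#' when present, otherwise from [fallbackDisorder()]).
#'
#' @param seq a [SequenceRecord-class] or plain residue string.
#' @return named list with `mw_mono` (Da), `gravy`, `l_dis` (residues) and
#'   `disorder_source`.
#' @export
sequenceFeatures <- function(seq) {
  if (!is(seq, "SequenceRecord")) seq <- sequenceRecord(seq)
  calls <- disorderCallsFor(seq)
  list(mw_mono = monomerMW(seq),
       gravy = avgHydropathy(seq),
       l_dis = longestDisorderStretch(calls),
       disorder_source = if (is.null(seq@disorderCalls))
         "fallback, not DisEMBL" else "user")
}

setMethod("show", "SequenceRecord", function(object) {
  cat(sprintf("SequenceRecord '%s': %d residues, disorder calls: %s\n",
              object@id, nchar(object@residues), object@disorderSource))
})
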