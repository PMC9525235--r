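# Monoisotopic mass and fragment-ion chemistry for peptidoforms.
#
# Residue masses and modification deltas are derived from elemental
# composition and monoisotopic atomic masses rather than hard-coded, so the
# printed search-engine deltas (amidation -0.98402 Da, pyroGlu from E
# -18.01057 Da, pyroGlu from Q -17.02655 Da, Met oxidation +15.99491 Da)
# fall out of first principles.

# IUPAC monoisotopic atomic masses (Da)
.atomic_mono <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

# Residue (i.e. dehydrated amino-acid) elemental formulas, counts of C,H,N,O,S
.residue_formulas <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)

.formula_mass <- function(counts) {
  sum(counts * .atomic_mono[c("C", "H", "N", "O", "S")])
}

#' Monoisotopic mass table
#'
#' Builds the table of monoisotopic residue masses, the mass of water and of
#' a proton, and the signed deltas of the post-translational modifications
#' used throughout the package. All values are computed from elemental
#' formulas and IUPAC monoisotopic atomic masses.
#'
#' The four modification deltas follow from simple chemistry:
#' * `c_amidation`: the C-terminal OH is replaced by NH2 (`+NH2 -OH`),
#'   a loss of 0.98402 Da;
#' * `pyroglu_from_E`: N-terminal glutamate cyclizes with loss of H2O;
#' * `pyroglu_from_Q`: N-terminal glutamine cyclizes with loss of NH3;
#' * `met_oxidation`: addition of one oxygen.
#'
#' @return An object of class `mass_table`: a list with `residue_masses`
#'   (named numeric, the 20 canonical residues), `water`, `proton`, and
#'   `mod_deltas` (named numeric, signed Da).
#' @examples
#' t <- mass_table()
#' t$mod_deltas[["c_amidation"]]  # ~ -0.98402
#' @export
mass_table <- function() {
  masses <- vapply(.residue_formulas, .formula_mass, numeric(1))
  H <- .atomic_mono[["H"]]
  N <- .atomic_mono[["N"]]
  O <- .atomic_mono[["O"]]
  structure(list(
    residue_masses = masses,
    water  = 2 * H + O,
    proton = 1.00727646688,
    mod_deltas = c(
      c_amidation    = (N + 2 * H) - (O + H),  # -OH +NH2
      pyroglu_from_E = -(2 * H + O),           # -H2O
      pyroglu_from_Q = -(N + 3 * H),           # -NH3
      met_oxidation  = O                       # +O
    )
  ), class = "mass_table")
}

#' Signed mass delta of a supported modification
#'
#' @param mod_name One of `"c_amidation"`, `"pyroglu_from_E"`,
#'   `"pyroglu_from_Q"`, `"met_oxidation"`.
#' @param t A [mass_table()].
#' @return Signed monoisotopic delta in Da.
#' @export
modification_delta <- function(mod_name, t = mass_table()) {
  if (length(mod_name) != 1L || !mod_name %in% names(t$mod_deltas)) {
    stop("unsupported modification: ", paste(mod_name, collapse = ", "),
         " (supported: ", paste(names(t$mod_deltas), collapse = ", "), ")")
  }
  unname(t$mod_deltas[[mod_name]])
}

#' Construct a peptidoform
#'
#' A mature peptide together with its modification state: optional
#' C-terminal amide, optional N-terminal pyroglutamate (only valid when the
#' first residue is Q or E) and a set of oxidized methionine positions.
#'
#' @param sequence Character scalar over the 20 canonical amino-acid letters.
#' @param c_amidated Logical, C-terminal amidation.
#' @param n_pyroglu Logical, N-terminal pyroglutamation.
#' @param oxidized_positions Integer vector of 0-based positions; each must
#'   hold an M residue.
#' @param precursor_id Optional identifier of the parent precursor.
#' @param span Optional length-2 integer vector, 0-based half-open interval
#'   in precursor coordinates.
#' @return An object of class `peptidoform`.
#' @export
peptidoform <- function(sequence, c_amidated = FALSE, n_pyroglu = FALSE,
                        oxidized_positions = integer(0),
                        precursor_id = NA_character_, span = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, names(.residue_formulas))
  if (length(bad)) {
    stop("non-canonical residue(s) in sequence: ", paste(unique(bad), collapse = ", "))
  }
  if (isTRUE(n_pyroglu) && !chars[1] %in% c("Q", "E")) {
    stop("n_pyroglu requires the first residue to be Q or E, got ", chars[1])
  }
  oxidized_positions <- as.integer(oxidized_positions)
  if (length(oxidized_positions)) {
    if (any(oxidized_positions < 0L | oxidized_positions >= length(chars))) {
      stop("oxidized_positions out of bounds")
    }
    if (any(chars[oxidized_positions + 1L] != "M")) {
      stop("oxidized_positions must all hold M residues")
    }
  }
  if (!is.null(span)) {
    span <- as.integer(span)
    stopifnot(length(span) == 2L, span[2] - span[1] == length(chars))
  }
  structure(list(
    sequence = sequence,
    c_amidated = isTRUE(c_amidated),
    n_pyroglu = isTRUE(n_pyroglu),
    oxidized_positions = oxidized_positions,
    precursor_id = precursor_id,
    span = span
  ), class = "peptidoform")
}

#' @export
print.peptidoform <- function(x, ...) {
  mods <- c(
    if (x$c_amidated) "C-amide",
    if (x$n_pyroglu) "pyroGlu",
    if (length(x$oxidized_positions))
      paste0("ox@", paste(x$oxidized_positions, collapse = ","))
  )
  cat("<peptidoform> ", x$sequence,
      if (length(mods)) paste0(" [", paste(mods, collapse = "; "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Neutral monoisotopic mass of a peptidoform
#'
#' Sum of residue masses plus water plus the signed deltas of all
#' modifications carried by the peptidoform.
#'
#' @param p A [peptidoform()].
#' @param t A [mass_table()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass(peptidoform("IGSDIKLVPGAGGNPW", c_amidated = TRUE))
#' @export
monoisotopic_mass <- function(p, t = mass_table()) {
  stopifnot(inherits(p, "peptidoform"))
  chars <- strsplit(p$sequence, "")[[1]]
  missing <- setdiff(chars, names(t$residue_masses))
  if (length(missing)) {
    stop("residue(s) absent from mass table: ", paste(unique(missing), collapse = ", "))
  }
  m <- sum(t$residue_masses[chars]) + t$water
  if (p$c_amidated) m <- m + t$mod_deltas[["c_amidation"]]
  if (p$n_pyroglu) {
    m <- m + t$mod_deltas[[if (chars[1] == "E") "pyroglu_from_E" else "pyroglu_from_Q"]]
  }
  m + length(p$oxidized_positions) * t$mod_deltas[["met_oxidation"]]
}

#' Construct a fragment spectrum
#'
#' @param mz Numeric vector of m/z values (Da).
#' @param intensity Non-negative numeric vector, recycled to `length(mz)`.
#' @param precursor_charge Positive integer.
#' @param label Optional per-peak annotation (e.g. ion names).
#' @return An object of class `fragment_spectrum` with peaks sorted by m/z.
#' @export
fragment_spectrum <- function(mz, intensity = 1, precursor_charge = 1L,
                              label = NULL) {
  stopifnot(all(intensity >= 0), precursor_charge >= 1L)
  intensity <- rep_len(intensity, length(mz))
  ord <- order(mz)
  peaks <- data.frame(mz = mz[ord], intensity = intensity[ord])
  if (!is.null(label)) peaks$label <- rep_len(label, length(mz))[ord]
  structure(list(peaks = peaks, precursor_charge = as.integer(precursor_charge)),
            class = "fragment_spectrum")
}

#' Theoretical b- and y-ion spectrum of a peptidoform
#'
#' Generates singly- up to `charge`-charged b and y ions (indices 1..n-1).
#' The C-terminal amide shifts only the y series; N-terminal pyroglutamate
#' shifts only the b series; oxidized methionines shift whichever series
#' contains them. All peaks carry unit intensity.
#'
#' @param p A [peptidoform()].
#' @param t A [mass_table()].
#' @param charge Maximum fragment charge (>= 1).
#' @return A `fragment_spectrum` whose peak labels name each ion, e.g.
#'   `"b3^1"`, `"y5^2"`.
#' @export
by_fragments <- function(p, t = mass_table(), charge = 1L) {
  stopifnot(inherits(p, "peptidoform"), charge >= 1L)
  chars <- strsplit(p$sequence, "")[[1]]
  n <- length(chars)
  res <- unname(t$residue_masses[chars])
  ox <- rep(0, n)
  ox[p$oxidized_positions + 1L] <- t$mod_deltas[["met_oxidation"]]
  res <- res + ox

  pyro_delta <- if (p$n_pyroglu) {
    t$mod_deltas[[if (chars[1] == "E") "pyroglu_from_E" else "pyroglu_from_Q"]]
  } else 0
  amide_delta <- if (p$c_amidated) t$mod_deltas[["c_amidation"]] else 0

  if (n < 2L) {
    return(fragment_spectrum(numeric(0), numeric(0), precursor_charge = charge))
  }
  idx <- seq_len(n - 1L)
  b_neutral <- cumsum(res)[idx] + pyro_delta                    # prefix residues
  y_neutral <- rev(cumsum(rev(res)))[idx + 1L] + t$water + amide_delta  # suffixes

  mz <- c()
  lab <- c()
  for (z in seq_len(charge)) {
    mz <- c(mz, (b_neutral + z * t$proton) / z, (y_neutral + z * t$proton) / z)
    lab <- c(lab,
             paste0("b", idx, "^", z),
             paste0("y", rev(idx), "^", z))
  }
  fragment_spectrum(mz, 1, precursor_charge = charge, label = lab)
}

#' Cosine similarity between two fragment spectra
#'
#' Peaks are matched greedily: among all cross-spectrum peak pairs within
#' `tol` Da, the closest pair is matched first (ties broken toward lower
#' m/z), then the next closest among unmatched peaks, and so on. The score
#' is the cosine of the intensity vectors aligned by that matching;
#' unmatched peaks contribute zero to the numerator but remain in the norms.
#' The procedure is symmetric in its two arguments.
#'
#' @param observed,theoretical `fragment_spectrum` objects.
#' @param tol Match tolerance in Da (> 0); the default mirrors a 0.3 Da
#'   fragment tolerance.
#' @return Similarity in \[0, 1\]. An empty spectrum yields 0 with a warning.
#' @export
spectral_similarity <- function(observed, theoretical, tol = 0.3) {
  stopifnot(inherits(observed, "fragment_spectrum"),
            inherits(theoretical, "fragment_spectrum"), tol > 0)
  a <- observed$peaks
  b <- theoretical$peaks
  if (nrow(a) == 0L || nrow(b) == 0L) {
    warning("empty spectrum; similarity defined as 0")
    return(0)
  }
  d <- abs(outer(a$mz, b$mz, "-"))
  cand <- which(d <= tol, arr.ind = TRUE)
  num <- 0
  if (nrow(cand)) {
    dist <- d[cand]
    lo <- pmin(a$mz[cand[, 1]], b$mz[cand[, 2]])
    hi <- pmax(a$mz[cand[, 1]], b$mz[cand[, 2]])
    ord <- order(dist, lo, hi)
    used_a <- rep(FALSE, nrow(a))
    used_b <- rep(FALSE, nrow(b))
    for (k in ord) {
      i <- cand[k, 1]
      j <- cand[k, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE
        used_b[j] <- TRUE
        num <- num + a$intensity[i] * b$intensity[j]
      }
    }
  }
  den <- sqrt(sum(a$intensity^2)) * sqrt(sum(b$intensity^2))
  if (den == 0) return(0)
  min(1, num / den)
}
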