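#' Construct a peptide with positional modifications and provenance
#'
#' A peptide is a protein subsequence plus a list of positional mass
#' modifications (e.g. carbamidomethyl on Cys) and provenance coordinates on
#' its parent protein (1-based inclusive).
#'
#' @param sequence peptide sequence over the 20 one-letter codes
#' @param mods data.frame with columns `position` (1-based), `delta` (Da),
#'   `name`, or NULL for none
#' @param protein parent protein id (may be NA)
#' @param start,end 1-based inclusive coordinates on the parent; must satisfy
#'   `end - start + 1 == nchar(sequence)`
#' @return object of class `xl_peptide`
#' @export
#' @examples
#' peptide("TETTGEKGK")
#' peptide("ACDK", mods = data.frame(position = 2, delta = 57.02146,
#'                                   name = "cam"))
peptide <- function(sequence, mods = NULL, protein = NA_character_,
                    start = 1L, end = start + nchar(sequence) - 1L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("peptide sequence must be a non-empty string")
  aa <- strsplit(sequence, "")[[1]]
  mc <- mass_constants()
  bad <- which(!aa %in% names(mc$residue_mono))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]))
  if (is.null(mods))
    mods <- data.frame(position = integer(), delta = numeric(),
                       name = character(), stringsAsFactors = FALSE)
  stopifnot(all(c("position", "delta", "name") %in% names(mods)))
  if (nrow(mods) && (any(mods$position < 1L) ||
                     any(mods$position > nchar(sequence))))
    stop("modification position outside peptide")
  if (end - start + 1L != nchar(sequence))
    stop("provenance range does not match sequence length")
  structure(list(sequence = sequence, mods = mods,
                 protein = protein, start = as.integer(start),
                 end = as.integer(end)),
            class = "xl_peptide")
}

#' Apply fixed carbamidomethylation to every cysteine of a peptide
#'
#' @param p an `xl_peptide`
#' @return the peptide with a +57.02146 Da `cam` modification on each Cys
#' @export
with_cam <- function(p) {
  stopifnot(inherits(p, "xl_peptide"))
  pos <- which(strsplit(p$sequence, "")[[1]] == "C")
  if (!length(pos)) return(p)
  mc <- mass_constants()
  add <- data.frame(position = pos, delta = mc$cam_delta, name = "cam",
                    stringsAsFactors = FALSE)
  p$mods <- rbind(p$mods, add)
  p
}

#' Neutral mass of a peptide
#'
#' Sum of residue masses on the chosen scale, plus water, plus all
#' modification deltas.
#'
#' @param p an `xl_peptide`
#' @param scale `"mono"` (monoisotopic) or `"average"`
#' @return mass in Da
#' @export
#' @examples
#' peptide_mass(peptide("TETTGEKGK"))  # 949.4716 Da
peptide_mass <- function(p, scale = c("mono", "average")) {
  stopifnot(inherits(p, "xl_peptide"))
  scale <- match.arg(scale)
  mc <- mass_constants()
  tab <- if (scale == "mono") mc$residue_mono else mc$residue_avg
  water <- if (scale == "mono") mc$water else mc$water_avg
  aa <- strsplit(p$sequence, "")[[1]]
  sum(tab[aa]) + water + sum(p$mods$delta)
}

#' Construct a cross-linked peptide pair
#'
#' Two peptides joined by a linker bridging residue `linkA` of `peptideA`
#' and `linkB` of `peptideB`.  Linked residues must be lysines, or position 1
#' when the peptide starts at its protein N-terminus (the free alpha-amine is
#' BS3-reactive).
#'
#' @param peptideA,peptideB `xl_peptide` objects
#' @param linkA,linkB 1-based linked positions
#' @param linker_delta mass added by the intact bridge (Da); default the BS3
#'   delta 138.06808
#' @return object of class `xl_pair`
#' @export
xl_pair <- function(peptideA, peptideB, linkA, linkB,
                    linker_delta = mass_constants()$bs3_xlink_delta) {
  stopifnot(inherits(peptideA, "xl_peptide"), inherits(peptideB, "xl_peptide"),
            linker_delta > 0)
  check_site <- function(p, pos, which) {
    if (pos < 1L || pos > nchar(p$sequence))
      stop(sprintf("link position %d outside peptide %s", pos, which))
    res <- substr(p$sequence, pos, pos)
    nterm_ok <- pos == 1L && !is.na(p$start) && p$start == 1L
    if (res != "K" && !nterm_ok)
      stop(sprintf(
        "linked residue of peptide %s must be K (or a protein N-terminus), got '%s' at %d",
        which, res, pos))
  }
  check_site(peptideA, linkA, "A")
  check_site(peptideB, linkB, "B")
  structure(list(peptideA = peptideA, peptideB = peptideB,
                 linkA = as.integer(linkA), linkB = as.integer(linkB),
                 linker_delta = linker_delta),
            class = "xl_pair")
}

#' Neutral mass of a cross-linked pair
#'
#' @param x an `xl_pair`
#' @param scale `"mono"` or `"average"`
#' @return mass(A) + mass(B) + linker_delta, in Da
#' @export
pair_mass <- function(x, scale = c("mono", "average")) {
  stopifnot(inherits(x, "xl_pair"))
  scale <- match.arg(scale)
  peptide_mass(x$peptideA, scale) + peptide_mass(x$peptideB, scale) +
    x$linker_delta
}

#' m/z of an ion from its neutral mass and charge
#'
#' @param mass neutral mass in Da
#' @param z positive integer charge
#' @param digits if non-NULL, round the result to this many decimals
#' @return m/z = (mass + z * proton) / z
#' @export
#' @examples
#' precursor_mz(3562.7072, z = 4, digits = 2)  # 891.68
precursor_mz <- function(mass, z, digits = NULL) {
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z))
    stop("charge z must be a positive integer")
  mz <- (mass + z * mass_constants()$proton) / z
  if (!is.null(digits)) mz <- round(mz, digits)
  mz
}

# Cumulative modified residue masses of one chain (monoisotopic), used by
# the fragment ladder.  Returns the per-position residue mass including any
# positional modification deltas.
.residue_masses <- function(p) {
  mc <- mass_constants()
  aa <- strsplit(p$sequence, "")[[1]]
  m <- unname(mc$residue_mono[aa])
  if (nrow(p$mods))
    for (k in seq_len(nrow(p$mods)))
      m[p$mods$position[k]] <- m[p$mods$position[k]] + p$mods$delta[k]
  m
}

#' Theoretical b/y fragment ions of a cross-linked pair
#'
#' Enumerates the b- and y-series ions of both chains.  Any fragment whose
#' residue span contains that chain's linked residue carries the bridge: its
#' mass includes `linker_delta` plus the full modified mass of the intact
#' partner peptide (the appendage).  Chains are labelled "A" and "B";
#' labels read e.g. `"A.y9.+1"`.
#'
#' @param x an `xl_pair`
#' @param series character subset of `c("b", "y")`
#' @param max_fragment_charge fragment charges 1..max_fragment_charge
#' @return data.frame with columns label, chain, series, index, z, mz,
#'   carries_link, sorted by chain, series, index, z
#' @export
fragment_ions <- function(x, series = c("b", "y"), max_fragment_charge = 1L) {
  stopifnot(inherits(x, "xl_pair"), max_fragment_charge >= 1L)
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  mc <- mass_constants()
  chain_rows <- function(p, link_pos, partner, chain) {
    n <- nchar(p$sequence)
    res <- .residue_masses(p)
    appendage <- x$linker_delta + peptide_mass(partner)
    prefix <- cumsum(res)
    out <- list()
    for (ser in series) {
      if (ser == "b") {
        if (n < 2L) next
        i <- seq_len(n - 1L)                 # b ion: residue sum
        neutral <- prefix[i]
        carries <- link_pos <= i
      } else {
        i <- seq_len(n)
        neutral <- prefix[n] - c(0, prefix)[n - i + 1L] + mc$water
        carries <- link_pos >= n - i + 1L
      }
      neutral <- neutral + ifelse(carries, appendage, 0)
      for (z in seq_len(max_fragment_charge)) {
        out[[length(out) + 1L]] <- data.frame(
          label = sprintf("%s.%s%d.+%d", chain, ser, i, z),
          chain = chain, series = ser, index = i, z = z,
          mz = (neutral + z * mc$proton) / z,
          carries_link = carries, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }
  out <- rbind(
    chain_rows(x$peptideA, x$linkA, x$peptideB, "A"),
    chain_rows(x$peptideB, x$linkB, x$peptideA, "B")
  )
  out <- out[order(out$chain, out$series, out$index, out$z), ]
  rownames(out) <- NULL
  out
}
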