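#' Digestion parameters
#'
#' Defaults follow the search settings used throughout this workflow:
#' trypsin, up to 4 missed cleavages, peptide length 6-50.
#'
#' @param enzyme cleavage rule id; only `"trypsin"` (cleave C-terminal to
#'   K/R, suppressed before P) is implemented
#' @param max_missed maximum missed cleavage sites (>= 0)
#' @param min_len,max_len retained peptide length range
#' @return list of class `digest_params`
#' @export
digest_params <- function(enzyme = "trypsin", max_missed = 4L,
                          min_len = 6L, max_len = 50L) {
  stopifnot(identical(enzyme, "trypsin"), max_missed >= 0L,
            min_len >= 1L, min_len <= max_len)
  structure(list(enzyme = enzyme, max_missed = as.integer(max_missed),
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "digest_params")
}

# 1-based positions after which trypsin cleaves: K or R not followed by P.
# The protein C-terminus is always a peptide boundary.
.cleavage_sites <- function(aa) {
  n <- length(aa)
  pos <- which(aa %in% c("K", "R"))
  pos[pos == n | aa[pmin(pos + 1L, n)] != "P"]
}

#' In-silico tryptic digestion
#'
#' Returns every tryptic peptide of the protein with 0..`max_missed` missed
#' cleavages, filtered to the configured length range, with 1-based inclusive
#' provenance coordinates.
#'
#' @param id protein identifier recorded in the provenance
#' @param sequence protein sequence
#' @param params a [digest_params()] object
#' @return data.frame with columns protein, sequence, start, end, n_missed
#' @export
#' @examples
#' digest("toy", "KAKR", digest_params(max_missed = 1, min_len = 1))
digest <- function(id, sequence, params = digest_params()) {
  stopifnot(inherits(params, "digest_params"), nzchar(sequence))
  aa <- strsplit(sequence, "")[[1]]
  mc <- mass_constants()
  bad <- which(!aa %in% names(mc$residue_mono))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]))
  n <- length(aa)
  bounds <- unique(c(.cleavage_sites(aa), n))   # peptide end positions
  starts <- c(1L, head(bounds, -1L) + 1L)
  starts <- starts[starts <= n]
  out <- list()
  for (si in seq_along(starts)) {
    for (mm in 0:params$max_missed) {
      ei <- si + mm
      if (ei > length(bounds)) break
      s <- starts[si]; e <- bounds[ei]
      len <- e - s + 1L
      if (len < params$min_len || len > params$max_len) next
      out[[length(out) + 1L]] <- data.frame(
        protein = id, sequence = substr(sequence, s, e),
        start = s, end = e, n_missed = mm, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(protein = character(), sequence = character(),
                      start = integer(), end = integer(),
                      n_missed = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a decoy sequence
#'
#' Same length and residue composition as the input; `"reversed"` is
#' deterministic, `"randomized"` is a seeded permutation reproducible across
#' runs.
#'
#' @param sequence protein sequence
#' @param mode `"reversed"` or `"randomized"`
#' @param seed integer seed, required for `"randomized"`
#' @return decoy sequence string
#' @export
make_decoy <- function(sequence, mode = c("reversed", "randomized"),
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(nzchar(sequence))
  aa <- strsplit(sequence, "")[[1]]
  if (mode == "reversed") return(paste(rev(aa), collapse = ""))
  if (is.null(seed)) stop("randomized decoys require a seed")
  aa <- withr::with_seed(as.integer(seed), sample(aa))
  paste(aa, collapse = "")
}

#' Read a FASTA file into a named character vector
#'
#' Multi-record, wrapped lines; the record id is the first
#' whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Build a target+decoy peptide database
#'
#' Digests each target protein and one decoy per requested protein, tagging
#' decoy peptides.  Decoy proteins are named `<id>_decoy`.
#'
#' @param targets named character vector of protein sequences
#' @param decoy_of character vector of target ids to build decoys for
#'   (default: all targets)
#' @param decoy_mode `"reversed"` or `"randomized"`
#' @param seed seed for randomized decoys
#' @param params [digest_params()]
#' @return data.frame of peptides (protein, sequence, start, end, n_missed,
#'   is_decoy) with an attribute `proteins` holding the full database
#' @export
build_database <- function(targets, decoy_of = names(targets),
                           decoy_mode = "reversed", seed = NULL,
                           params = digest_params()) {
  stopifnot(length(targets) >= 1L, !is.null(names(targets)))
  decoys <- vapply(targets[decoy_of], make_decoy, "", mode = decoy_mode,
                   seed = seed)
  names(decoys) <- paste0(decoy_of, "_decoy")
  all_prot <- c(targets, decoys)
  peps <- do.call(rbind, lapply(names(all_prot), function(id)
    digest(id, all_prot[[id]], params)))
  peps$is_decoy <- peps$protein %in% names(decoys)
  attr(peps, "proteins") <- all_prot
  peps
}
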