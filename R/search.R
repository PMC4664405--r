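#' Search parameters for cross-linked peptide-spectrum matching
#'
#' @param precursor_tol precursor tolerance in ppm
#' @param fragment_tol fragment tolerance in Da
#' @param charge_list charges assumed when a spectrum's charge is
#'   undetermined; the search rule drops 1 from this list for undetermined
#'   spectra (only spectra declared singly charged are searched at 1+)
#' @param linker_delta intact bridge delta (Da), default BS3
#' @param digest a [digest_params()] object
#' @param n_perm permutation count for the pp2 abundance score
#' @param perm_seed mandatory integer seed for the pp2 permutations
#' @param min_score,min_pp,min_pp2 report thresholds; matches below any of
#'   them are discarded from the PSM table (never asserted to be the
#'   published engine's internal cutoffs — configure per analysis)
#' @return list of class `search_params`
#' @export
search_params <- function(precursor_tol = 10, fragment_tol = 0.02,
                          charge_list = c(1L, 2L, 3L),
                          linker_delta = mass_constants()$bs3_xlink_delta,
                          digest = digest_params(),
                          n_perm = 1000L, perm_seed = 1L,
                          min_score = 5, min_pp = 2, min_pp2 = 0) {
  stopifnot(precursor_tol > 0, fragment_tol > 0, length(charge_list) >= 1L,
            linker_delta > 0, n_perm >= 1L, !is.null(perm_seed))
  structure(list(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
                 charge_list = as.integer(charge_list),
                 linker_delta = linker_delta, digest = digest,
                 n_perm = as.integer(n_perm),
                 perm_seed = as.integer(perm_seed),
                 min_score = min_score, min_pp = min_pp, min_pp2 = min_pp2),
            class = "search_params")
}

#' Eligible cross-link sites of a peptide
#'
#' BS3 bridges lysine side chains and free protein N-terminal alpha-amines.
#' A lysine at the peptide's C-terminal boundary is not an eligible site
#' unless it is the protein C-terminus: a BS3-blocked lysine is not cleaved
#' by trypsin, so an internal link implies a missed cleavage.
#'
#' @param sequence peptide sequence
#' @param start,end provenance on the parent protein (1-based inclusive)
#' @param protein_length parent protein length
#' @return integer vector of eligible 1-based positions within the peptide
#' @export
eligible_link_sites <- function(sequence, start, end, protein_length) {
  n <- nchar(sequence)
  aa <- strsplit(sequence, "")[[1]]
  kpos <- which(aa == "K")
  kpos <- kpos[kpos < n | end == protein_length]
  if (start == 1L && !1L %in% kpos) kpos <- c(1L, kpos)
  sort(unique(kpos))
}

#' Index a peptide database for pair searching
#'
#' Adds the fixed-modification (CAM on Cys) monoisotopic mass and the
#' eligible link sites of each peptide, dropping peptides with no eligible
#' site.
#'
#' @param db peptide data.frame from [build_database()] (needs its
#'   `proteins` attribute for protein lengths)
#' @return the peptide table with added columns `mass` and list-column
#'   `sites`, rows without sites removed
#' @export
index_peptides <- function(db) {
  prot <- attr(db, "proteins")
  stopifnot(!is.null(prot))
  plen <- nchar(prot)
  mc <- mass_constants()
  ncys <- vapply(strsplit(db$sequence, ""), function(a) sum(a == "C"), 0L)
  resmass <- vapply(strsplit(db$sequence, ""),
                    function(a) sum(mc$residue_mono[a]), 0)
  db$mass <- resmass + mc$water + ncys * mc$cam_delta
  db$sites <- Map(eligible_link_sites, db$sequence, db$start, db$end,
                  plen[db$protein])
  keep <- lengths(db$sites) > 0L
  out <- db[keep, ]
  attr(out, "proteins") <- prot
  rownames(out) <- NULL
  out
}

#' Enumerate candidate cross-linked pairs at a precursor mass
#'
#' All unordered peptide pairs (self-pairs allowed) from an indexed database
#' whose bridged pair mass lies within the ppm tolerance of the precursor
#' mass.  Both peptides must carry at least one eligible link site (enforced
#' by [index_peptides()]).
#'
#' @param idx indexed peptide table from [index_peptides()]
#' @param precursor_mass neutral precursor mass (Da)
#' @param tol_ppm tolerance in ppm
#' @param linker_delta intact bridge delta (Da)
#' @return data.frame with columns iA, iB (row indices into `idx`, iA <= iB)
#'   and pair_mass
#' @export
candidate_pairs <- function(idx, precursor_mass, tol_ppm,
                            linker_delta = mass_constants()$bs3_xlink_delta) {
  stopifnot(precursor_mass > 0, tol_ppm >= 0)
  m <- idx$mass
  ord <- order(m)
  ms <- m[ord]
  tol <- precursor_mass * tol_ppm * 1e-6
  target <- precursor_mass - linker_delta
  out <- list()
  for (a in seq_along(ms)) {
    lo <- target - tol - ms[a]
    hi <- target + tol - ms[a]
    if (hi < ms[a]) break                     # partners are >= ms[a] (b >= a)
    j1 <- findInterval(lo, ms, left.open = TRUE) + 1L
    j2 <- findInterval(hi, ms)
    j1 <- max(j1, a)
    if (j2 < j1) next
    out[[length(out) + 1L]] <- data.frame(
      iA = ord[a], iB = ord[j1:j2],
      pair_mass = ms[a] + ms[j1:j2] + linker_delta)
  }
  if (!length(out))
    return(data.frame(iA = integer(), iB = integer(), pair_mass = numeric()))
  res <- do.call(rbind, out)
  swap <- res$iA > res$iB
  tmp <- res$iA[swap]; res$iA[swap] <- res$iB[swap]; res$iB[swap] <- tmp
  res <- unique(res)
  rownames(res) <- NULL
  res
}

#' Charges assumed for a spectrum
#'
#' A declared charge is used as-is; spectra declared singly charged are
#' searched only at 1+; spectra with undetermined charge are searched at
#' every charge of `charge_list` except 1 (by default, as doubly and triply
#' charged).
#'
#' @param s an [spectrum_record()]
#' @param params a [search_params()]
#' @return integer vector of assumed charges
#' @export
assumed_charges <- function(s, params = search_params()) {
  if (!is.na(s$charge)) return(s$charge)
  z <- setdiff(params$charge_list, 1L)
  if (!length(z)) z <- params$charge_list
  z
}

# Build an xl_pair from two rows of an indexed db, with fixed CAM mods.
.pair_from_rows <- function(idx, iA, iB, sA, sB,
                            linker_delta = mass_constants()$bs3_xlink_delta) {
  mk <- function(i) with_cam(peptide(idx$sequence[i], protein = idx$protein[i],
                                     start = idx$start[i], end = idx$end[i]))
  xl_pair(mk(iA), mk(iB), sA, sB, linker_delta)
}

# Canonical id string of a pair, order-independent.
.pair_id <- function(idx, iA, iB, sA, sB) {
  a <- sprintf("%s:%s:%d", idx$protein[iA], idx$sequence[iA], sA)
  b <- sprintf("%s:%s:%d", idx$protein[iB], idx$sequence[iB], sB)
  paste(sort(c(a, b)), collapse = "--")
}

#' Score a cross-linked pair against a spectrum
#'
#' Three scores are computed.  `score` is the number of theoretical b/y ions
#' (both chains, fragment charges 1..max(1, min(z-1, 2))) matched by an
#' observed peak within `fragment_tol`.  `pp` answers whether that many
#' matched product ions could be a random occurrence: it is the -log10
#' upper-tail binomial probability of >= `score` matches out of the
#' theoretical ion count when each ion independently hits a peak with
#' probability `n_peaks * 2 * fragment_tol / span(m/z)`.  `pp2` answers
#' whether the matched total abundance could be random: the -log10
#' permutation probability (seeded, `n_perm` draws) that a random peak
#' subset of the same size reaches the matched summed intensity.
#'
#' @param s an [spectrum_record()]
#' @param x an [xl_pair()]
#' @param z assumed precursor charge
#' @param params a [search_params()]
#' @return list with components score, pp, pp2, n_theoretical, n_peaks
#' @export
match_spectrum <- function(s, x, z, params = search_params()) {
  peaks <- s$peaks
  zmax <- max(1L, min(z - 1L, 2L))
  theo <- fragment_ions(x, max_fragment_charge = zmax)
  N <- nrow(theo)
  if (!nrow(peaks))
    return(list(score = 0L, pp = 0, pp2 = 0, n_theoretical = N, n_peaks = 0L))
  pmz <- peaks$mz
  hit_idx <- integer(0)
  i <- findInterval(theo$mz, pmz)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(pmz))
  d_lo <- abs(theo$mz - pmz[lo])
  d_hi <- abs(theo$mz - pmz[hi])
  nearest <- ifelse(d_lo <= d_hi, lo, hi)
  matched <- abs(theo$mz - pmz[nearest]) <= params$fragment_tol
  score <- sum(matched)
  span <- max(pmz) - min(pmz)
  p_rand <- if (span > 0)
    min(1, nrow(peaks) * 2 * params$fragment_tol / span) else 1
  pp <- if (score == 0L) 0 else
    -stats::pbinom(score - 1L, N, p_rand, lower.tail = FALSE,
                   log.p = TRUE) / log(10)
  hit_idx <- unique(nearest[matched])
  m <- length(hit_idx)
  pp2 <- 0
  if (m > 0L && m < nrow(peaks)) {
    t_obs <- sum(peaks$intensity[hit_idx])
    ge <- withr::with_seed(params$perm_seed, {
      sum(vapply(seq_len(params$n_perm), function(k)
        sum(peaks$intensity[sample.int(nrow(peaks), m)]) >= t_obs, NA))
    })
    pp2 <- -log10((1 + ge) / (params$n_perm + 1))
  }
  list(score = as.integer(score), pp = pp, pp2 = pp2,
       n_theoretical = N, n_peaks = nrow(peaks))
}

#' Search spectra against a target+decoy peptide database
#'
#' For each spectrum, every candidate pair and link-site combination at every
#' assumed charge is scored; the single highest-scoring match is retained
#' (ties broken by higher pp, then lexicographic pair id).  Matches below the
#' configured thresholds are discarded.  A PSM is flagged decoy when either
#' constituent protein is a decoy.
#'
#' @param spectra list of [spectrum_record()] objects
#' @param db peptide database from [build_database()]
#' @param params a [search_params()]
#' @return data.frame of PSMs (one best per passing spectrum) with columns
#'   spectrum_id, proteinA, pepA, posA, proteinB, pepB, posB, z, score, pp,
#'   pp2, decoy, pair_id; a `report` attribute carries run counts and
#'   parameters
#' @export
run_search <- function(spectra, db, params = search_params()) {
  idx <- index_peptides(db)
  mc <- mass_constants()
  rows <- list()
  n_no_candidate <- 0L; n_below <- 0L; n_skipped <- 0L
  for (s in spectra) {
    if (!inherits(s, "xl_spectrum")) { n_skipped <- n_skipped + 1L; next }
    best <- NULL
    for (z in assumed_charges(s, params)) {
      pmass <- s$precursor_mz * z - z * mc$proton
      cands <- candidate_pairs(idx, pmass, params$precursor_tol,
                               params$linker_delta)
      if (!nrow(cands)) next
      for (r in seq_len(nrow(cands))) {
        iA <- cands$iA[r]; iB <- cands$iB[r]
        for (sA in idx$sites[[iA]]) for (sB in idx$sites[[iB]]) {
          pair <- .pair_from_rows(idx, iA, iB, sA, sB, params$linker_delta)
          sc <- match_spectrum(s, pair, z, params)
          cand <- list(iA = iA, iB = iB, sA = sA, sB = sB, z = z,
                       score = sc$score, pp = sc$pp, pp2 = sc$pp2,
                       id = .pair_id(idx, iA, iB, sA, sB))
          if (is.null(best) ||
              cand$score > best$score ||
              (cand$score == best$score && cand$pp > best$pp) ||
              (cand$score == best$score && cand$pp == best$pp &&
               cand$id < best$id))
            best <- cand
        }
      }
    }
    if (is.null(best)) { n_no_candidate <- n_no_candidate + 1L; next }
    if (best$score < params$min_score || best$pp < params$min_pp ||
        best$pp2 < params$min_pp2) { n_below <- n_below + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      spectrum_id = s$id,
      proteinA = idx$protein[best$iA], pepA = idx$sequence[best$iA],
      posA = best$sA,
      proteinB = idx$protein[best$iB], pepB = idx$sequence[best$iB],
      posB = best$sB,
      z = best$z, score = best$score, pp = best$pp, pp2 = best$pp2,
      decoy = idx$is_decoy[best$iA] || idx$is_decoy[best$iB],
      pair_id = best$id, stringsAsFactors = FALSE)
  }
  psms <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spectrum_id = character(), proteinA = character(),
               pepA = character(), posA = integer(), proteinB = character(),
               pepB = character(), posB = integer(), z = integer(),
               score = integer(), pp = numeric(), pp2 = numeric(),
               decoy = logical(), pair_id = character(),
               stringsAsFactors = FALSE)
  psms <- psms[order(psms$spectrum_id), ]
  rownames(psms) <- NULL
  attr(psms, "report") <- list(
    n_spectra = length(spectra), n_psm = nrow(psms),
    n_no_candidate = n_no_candidate, n_below_threshold = n_below,
    n_skipped = n_skipped,
    params = unclass(params)[c("precursor_tol", "fragment_tol",
                               "linker_delta", "n_perm", "perm_seed",
                               "min_score", "min_pp", "min_pp2")])
  psms
}

#' Target-decoy FDR table
#'
#' For each candidate score cutoff, counts target and decoy PSMs at or above
#' the cutoff and estimates FDR as #decoy / #target.
#'
#' @param psms PSM table from [run_search()] (columns score, decoy)
#' @param cutoffs score cutoffs to tabulate (default: the sorted unique PSM
#'   scores)
#' @return data.frame with columns cutoff, n_target, n_decoy, fdr (NA where
#'   no targets survive); attribute `no_decoys` flags an all-target input
#' @export
decoy_fdr <- function(psms, cutoffs = sort(unique(psms$score))) {
  stopifnot(all(c("score", "decoy") %in% names(psms)))
  if (!any(psms$decoy))
    warning("no decoy PSMs: estimated FDR is 0 everywhere")
  out <- do.call(rbind, lapply(cutoffs, function(cut) {
    keep <- psms$score >= cut
    nt <- sum(keep & !psms$decoy); nd <- sum(keep & psms$decoy)
    data.frame(cutoff = cut, n_target = nt, n_decoy = nd,
               fdr = if (nt > 0) nd / nt else NA_real_)
  }))
  attr(out, "no_decoys") <- !any(psms$decoy)
  out
}

#' Write a PSM table to TSV
#' @param psms PSM table from [run_search()]
#' @param path output path
#' @export
write_psm_tsv <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a search run report to JSON
#' @param psms PSM table from [run_search()] (its `report` attribute is used)
#' @param path output path
#' @export
write_search_report <- function(psms, path) {
  jsonlite::write_json(attr(psms, "report"), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
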