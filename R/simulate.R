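#' Build a structure fixture with lysine anchors at specified distances
#'
#' Places one lysine residue per requested anchor so that the pairwise NZ-NZ
#' distances reproduce a target distance matrix (classical multidimensional
#' scaling into 3-D), then attaches a CA atom next to each NZ so the model
#' is a valid coarse structure.  Distance sets that are not realizable in
#' 3-D are rejected; triangle-inequality violations are reported with the
#' offending triple.
#'
#' @param anchors data.frame with columns chain, resno (one row per anchor)
#' @param dmat symmetric matrix of target distances (Angstrom), zero diagonal
#' @param tol placement tolerance (Angstrom)
#' @return an `xl_structure` with LYS residues carrying NZ and CA atoms
#' @export
make_structure_fixture <- function(anchors, dmat, tol = 0.01) {
  k <- nrow(anchors)
  stopifnot(k >= 1L, nrow(dmat) == k, ncol(dmat) == k,
            isSymmetric(unname(dmat)), all(diag(dmat) == 0), all(dmat >= 0))
  if (k >= 3L)
    for (i in 1:(k - 2)) for (j in (i + 1):(k - 1)) for (l in (j + 1):k)
      if (dmat[i, j] > dmat[i, l] + dmat[j, l] + 1e-9 ||
          dmat[i, l] > dmat[i, j] + dmat[j, l] + 1e-9 ||
          dmat[j, l] > dmat[i, j] + dmat[i, l] + 1e-9)
        stop(sprintf("triangle inequality violated by anchors (%d, %d, %d)",
                     i, j, l))
  pts <- if (k == 1L) matrix(0, 1, 3) else {
    # realization is verified against dmat below, so MDS eigenvalue warnings
    # on non-Euclidean input are redundant
    cm <- suppressWarnings(stats::cmdscale(stats::as.dist(dmat),
                                           k = min(3L, k - 1L)))
    cbind(cm, matrix(0, k, 3L - ncol(cm)))
  }
  realized <- as.matrix(stats::dist(pts))
  if (max(abs(realized - dmat)) > tol)
    stop(sprintf("distance set not realizable in 3-D (max error %.3f A)",
                 max(abs(realized - dmat))))
  rows <- lapply(seq_len(k), function(i) data.frame(
    chain = rep(anchors$chain[i], 2L), resno = rep(anchors$resno[i], 2L),
    resname = "LYS", atom = c("CA", "NZ"),
    x = c(pts[i, 1] + 1.5, pts[i, 1]),
    y = c(pts[i, 2], pts[i, 2]),
    z = c(pts[i, 3], pts[i, 3]), stringsAsFactors = FALSE))
  structure_model(do.call(rbind, rows))
}

#' Simulate a docking pose ensemble with a planted satisfying fraction
#'
#' Generates `n` ligand poses around a receptor: exactly `floor(f * n)` of
#' them satisfy every evidence restraint by construction (each ligand anchor
#' placed within the cap of its receptor anchor); the rest violate every
#' evidence restraint (placed beyond the cap).  Which pose indices satisfy
#' is a seeded random draw.
#'
#' @param receptor an `xl_structure` containing the receptor anchors
#' @param evidence list of [xl_restraint()] objects whose `anchor1` is on the
#'   receptor and whose `anchor2` names the ligand chain/residue to create
#' @param n number of poses
#' @param f fraction of satisfying poses (0..1); count is floor(f * n)
#' @param seed integer seed
#' @param margin minimum clearance (Angstrom) from the cap on either side
#' @param spread width of the violating-distance band beyond the cap
#' @return list with `pose_set` (a [pose_set()]) and `truth` (data.frame
#'   pose_id, satisfying)
#' @export
make_pose_ensemble <- function(receptor, evidence, n = 100L, f = 0.07,
                               seed = 1L, margin = 1, spread = 40) {
  stopifnot(f >= 0, f <= 1, n >= 1L, length(evidence) >= 1L)
  n_sat <- floor(f * n)
  withr::with_seed(as.integer(seed), {
    sat <- rep(FALSE, n)
    sat[sample.int(n, n_sat)] <- TRUE
    poses <- vector("list", n)
    for (p in seq_len(n)) {
      rows <- lapply(evidence, function(r) {
        anchor <- .resolve_anchor(receptor, r$anchor1)$xyz
        rr <- if (sat[p]) stats::runif(1, margin, r$cap - margin) else
          stats::runif(1, r$cap + margin, r$cap + margin + spread)
        u <- drop(.rand_units(1L))
        pos <- anchor + rr * u
        data.frame(chain = rep(r$anchor2$chain, 2L),
                   resno = rep(r$anchor2$resno, 2L),
                   resname = "LYS", atom = c("CA", "NZ"),
                   x = c(pos[1] + 1.5, pos[1]), y = c(pos[2], pos[2]),
                   z = c(pos[3], pos[3]), stringsAsFactors = FALSE)
      })
      poses[[p]] <- structure_model(do.call(rbind, rows))
    }
    names(poses) <- sprintf("pose_%03d", seq_len(n))
    list(pose_set = pose_set(receptor, poses),
         truth = data.frame(pose_id = names(poses), satisfying = sat,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate MS/MS spectra of known cross-linked pairs
#'
#' For each pair, emits a spectrum containing a stated fraction of its
#' theoretical b/y ions (cross-link-carrying ions included) at exact m/z
#' plus uniformly placed noise peaks, with log-normal intensities (signal
#' drawn above noise on average).  The precursor m/z is computed from the
#' pair mass at the chosen charge.  Byte-identical output for a fixed seed.
#'
#' @param pairs list of [xl_pair()] objects
#' @param coverage fraction of theoretical ions present (0..1)
#' @param n_noise number of noise peaks per spectrum
#' @param charge precursor charge used for all spectra
#' @param declare_charge write the charge into the spectrum (TRUE) or leave
#'   it undetermined (FALSE)
#' @param scan_range m/z window for noise peaks (the acquisition window)
#' @param signal_meanlog,signal_sdlog log-normal intensity model for signal
#' @param noise_meanlog,noise_sdlog log-normal intensity model for noise
#' @param max_fragment_charge fragment charges included
#' @param seed integer seed
#' @return list with `spectra` (list of [spectrum_record()]) and `truth`
#'   (data.frame spectrum_id, pepA, posA, pepB, posB, pair_mass, z)
#' @export
make_xl_spectra <- function(pairs, coverage = 0.8, n_noise = 50L,
                            charge = 4L, declare_charge = FALSE,
                            scan_range = c(300, 1650),
                            signal_meanlog = log(1e5), signal_sdlog = 0.5,
                            noise_meanlog = log(1e3), noise_sdlog = 1,
                            max_fragment_charge = 2L, seed = 1L) {
  stopifnot(coverage >= 0, coverage <= 1, n_noise >= 0L, charge >= 1L)
  withr::with_seed(as.integer(seed), {
    spectra <- list(); truth <- list()
    for (k in seq_along(pairs)) {
      x <- pairs[[k]]
      theo <- fragment_ions(x, max_fragment_charge = max_fragment_charge)
      n_sig <- floor(coverage * nrow(theo))
      keep <- if (n_sig > 0L) sort(sample.int(nrow(theo), n_sig)) else
        integer(0)
      sig <- data.frame(
        mz = theo$mz[keep],
        intensity = stats::rlnorm(length(keep), signal_meanlog, signal_sdlog))
      noise <- data.frame(
        mz = stats::runif(n_noise, scan_range[1], scan_range[2]),
        intensity = stats::rlnorm(n_noise, noise_meanlog, noise_sdlog))
      peaks <- rbind(sig, noise)
      id <- sprintf("sim_%03d", k)
      spectra[[k]] <- spectrum_record(
        id, precursor_mz(pair_mass(x), charge),
        charge = if (declare_charge) charge else NA_integer_, peaks = peaks)
      truth[[k]] <- data.frame(
        spectrum_id = id, pepA = x$peptideA$sequence, posA = x$linkA,
        pepB = x$peptideB$sequence, posB = x$linkB,
        pair_mass = pair_mass(x), z = charge, stringsAsFactors = FALSE)
    }
    list(spectra = spectra, truth = do.call(rbind, truth))
  })
}

#' Default densitometry conditions
#'
#' The stated world of the bound/input simulator: three co-expression
#' conditions with the group mean ratios reported for the Flag pull-down
#' comparison (1.08, 0.74, 0.76) and per-replicate SDs back-computed from
#' the reported SEMs at n = 3 (SD = SEM * sqrt(3)).
#'
#' @return data.frame with columns construct, partner, true_mean, true_sd, n
#' @export
densitometry_conditions <- function() {
  data.frame(
    construct = c("alpha", "beta", "alphabeta"),
    partner   = "PDI-WT",
    true_mean = c(1.08, 0.74, 0.76),
    true_sd   = c(0.13, 0.02, 0.06) * sqrt(3),
    n         = 3L, stringsAsFactors = FALSE)
}

#' Simulate replicate bound/input densitometry
#'
#' Per replicate, the true ratio is drawn Normal(true_mean, true_sd)
#' truncated at zero (redrawn while negative); the input signal is
#' log-normal and bound = ratio * input, so [bound_over_input()] recovers
#' the planted ratios exactly.
#'
#' @param conditions data.frame with columns construct, partner, true_mean,
#'   true_sd, n (default [densitometry_conditions()])
#' @param input_meanlog,input_sdlog log-normal model of the input signal
#' @param seed integer seed
#' @return list with `table` (construct, partner, replicate, bound, input)
#'   and `truth` (the conditions table)
#' @export
make_densitometry <- function(conditions = densitometry_conditions(),
                              input_meanlog = log(100), input_sdlog = 0.3,
                              seed = 1L) {
  stopifnot(all(conditions$n >= 2L), all(conditions$true_sd >= 0))
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(nrow(conditions)), function(i) {
      n <- conditions$n[i]
      ratio <- stats::rnorm(n, conditions$true_mean[i], conditions$true_sd[i])
      while (any(ratio < 0))
        ratio[ratio < 0] <- stats::rnorm(sum(ratio < 0),
                                         conditions$true_mean[i],
                                         conditions$true_sd[i])
      input <- stats::rlnorm(n, input_meanlog, input_sdlog)
      data.frame(construct = conditions$construct[i],
                 partner = conditions$partner[i], replicate = seq_len(n),
                 bound = ratio * input, input = input,
                 stringsAsFactors = FALSE)
    })
    list(table = do.call(rbind, rows), truth = conditions)
  })
}

#' Random lysine-rich protein sequence
#'
#' Seeded generator of a synthetic protein sequence with lysine and arginine
#' enriched (roughly tryptic-peptide-sized fragments), used to build toy
#' search databases.
#'
#' @param n sequence length
#' @param seed integer seed
#' @return a sequence string
#' @export
random_protein_seq <- function(n, seed) {
  withr::with_seed(as.integer(seed), {
    alphabet <- c(strsplit("ACDEFGHILMNPQSTVWY", "")[[1]],
                  rep("K", 4), rep("R", 2))
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
  })
}

#' The worked-example cross-linked pair
#'
#' The inter-subunit BS3 pair used throughout the documentation and tests:
#' a 21-mer (two carbamidomethylated cysteines, bridged at its internal
#' lysine, position 13) linked to TETTGEKGK (bridged at position 7).
#'
#' @return an [xl_pair()]
#' @export
example_xl_pair <- function() {
  pepA <- with_cam(peptide("YCLFGNNVTLANKFESCSVPR", protein = "sGC_alpha",
                           start = 594L, end = 614L))
  pepB <- peptide("TETTGEKGK", protein = "sGC_beta", start = 553L,
                  end = 561L)
  xl_pair(pepA, pepB, linkA = 13L, linkB = 7L)
}
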