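#' Specify a missing C-terminal tail to sample
#'
#' A coarse-grained (one bead per residue, Calpha level) description of
#' residues absent from a deposited model: grown from the last resolved
#' residue with a fixed virtual bond length and a hard-sphere clash radius
#' against the resolved Calpha atoms.
#'
#' @param chain chain id of the anchor residue
#' @param anchor_resno last resolved residue number (must have a CA atom)
#' @param residues one-letter identities of the added residues, in order
#' @param bond_length Calpha-Calpha virtual bond length (Angstrom)
#' @param clash_radius hard-sphere exclusion radius (Angstrom)
#' @return list of class `tail_spec`
#' @export
tail_spec <- function(chain, anchor_resno, residues, bond_length = 3.8,
                      clash_radius = 4.0) {
  stopifnot(length(residues) >= 1L, bond_length > 0, clash_radius >= 0)
  structure(list(chain = as.character(chain),
                 anchor_resno = as.integer(anchor_resno),
                 residues = residues, bond_length = bond_length,
                 clash_radius = clash_radius),
            class = "tail_spec")
}

# Uniform random unit vectors, n x 3.
.rand_units <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Sample self-avoiding conformers of a missing tail
#'
#' Grows `n` conformers bead by bead from the anchor Calpha: each step takes
#' a uniformly random direction at fixed bond length and is rejected if the
#' new bead clashes (within `clash_radius`) with any resolved Calpha of the
#' model or any earlier bead of the same conformer, excluding the bead it is
#' bonded to.  A conformer that exhausts its per-step retry budget is
#' discarded and counted; reproducible from the seed.
#'
#' @param m an `xl_structure` providing the clash context and the anchor
#' @param spec a [tail_spec()]
#' @param n number of conformers to attempt
#' @param seed integer seed (mandatory)
#' @param max_retry per-step retry budget
#' @return list of class `tail_ensemble`: spec, seed, n_failed, and
#'   `coords`, an array of dim (kept conformers, residues, 3)
#' @export
sample_tail <- function(m, spec, n, seed, max_retry = 50L) {
  stopifnot(inherits(spec, "tail_spec"), n >= 1L, !is.null(seed))
  anchor_row <- m[m$chain == spec$chain & m$resno == spec$anchor_resno &
                    m$atom == "CA", ]
  if (!nrow(anchor_row))
    stop(sprintf("anchor residue %s/%d has no CA atom", spec$chain,
                 spec$anchor_resno))
  anchor <- c(anchor_row$x[1], anchor_row$y[1], anchor_row$z[1])
  ca <- m[m$atom == "CA", c("x", "y", "z")]
  context <- as.matrix(ca)
  L <- length(spec$residues)
  keep <- list(); n_failed <- 0L
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(n)) {
      chain <- matrix(NA_real_, nrow = L, ncol = 3)
      prev <- anchor
      ok <- TRUE
      for (i in seq_len(L)) {
        placed <- FALSE
        for (try in seq_len(max_retry)) {
          cand <- prev + spec$bond_length * drop(.rand_units(1L))
          # clash context: resolved CAs + earlier beads, minus the bonded
          # predecessor (the anchor for i == 1, bead i-1 otherwise)
          ctx <- context
          if (i == 1L) {
            drop_row <- which(colSums(abs(t(ctx) - anchor)) < 1e-9)
            if (length(drop_row)) ctx <- ctx[-drop_row[1], , drop = FALSE]
            if (i > 1L) ctx <- rbind(ctx, chain[seq_len(i - 1L), , drop = FALSE])
          } else {
            beads <- chain[seq_len(i - 1L), , drop = FALSE]
            beads <- beads[-(i - 1L), , drop = FALSE]  # exclude bonded bead
            ctx <- rbind(ctx, beads)
          }
          if (!nrow(ctx) ||
              min(sqrt(colSums((t(ctx) - cand)^2))) >= spec$clash_radius) {
            chain[i, ] <- cand
            prev <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) keep[[length(keep) + 1L]] <- chain else
        n_failed <- n_failed + 1L
    }
  })
  if (!length(keep))
    stop("tail sampling failed for every conformer")
  coords <- array(NA_real_, dim = c(length(keep), L, 3))
  for (k in seq_along(keep)) coords[k, , ] <- keep[[k]]
  structure(list(spec = spec, seed = as.integer(seed), anchor = anchor,
                 n_failed = n_failed, coords = coords),
            class = "tail_ensemble")
}

# Index of a residue number within a tail ensemble's added residues.
.tail_index <- function(e, resno) {
  idx <- resno - e$spec$anchor_resno
  if (idx < 1L || idx > dim(e$coords)[2])
    stop(sprintf("residue %d is not part of the sampled tail (%d..%d)",
                 resno, e$spec$anchor_resno + 1L,
                 e$spec$anchor_resno + dim(e$coords)[2]))
  idx
}

#' Closest achievable distance between two tail residues
#'
#' Minimum, over all sampled conformer pairs, of the distance between the
#' named residue of ensemble A and the named residue of ensemble B: a
#' sampling estimator (and upper bound) of the geometric minimum separation
#' the two flexible tails can achieve.
#'
#' @param eA,eB `tail_ensemble` objects
#' @param residueA,residueB author residue numbers within the respective
#'   tails
#' @return minimum distance in Angstrom
#' @export
closest_pair_distance <- function(eA, residueA, eB, residueB) {
  stopifnot(inherits(eA, "tail_ensemble"), inherits(eB, "tail_ensemble"))
  iA <- .tail_index(eA, residueA)
  iB <- .tail_index(eB, residueB)
  A <- eA$coords[, iA, , drop = FALSE]; dim(A) <- c(dim(eA$coords)[1], 3)
  B <- eB$coords[, iB, , drop = FALSE]; dim(B) <- c(dim(eB$coords)[1], 3)
  best <- Inf
  chunk <- 256L
  for (s in seq(1L, nrow(A), by = chunk)) {
    rows <- s:min(s + chunk - 1L, nrow(A))
    # squared cross-distances block: |a|^2 + |b|^2 - 2 a.b
    G <- A[rows, , drop = FALSE] %*% t(B)
    d2 <- outer(rowSums(A[rows, , drop = FALSE]^2), rowSums(B^2), "+") - 2 * G
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Export a tail ensemble as a multi-model PDB
#'
#' @param e a `tail_ensemble`
#' @param path output path
#' @param max_models cap on exported conformers
#' @export
write_tail_ensemble_pdb <- function(e, path, max_models = 100L) {
  n <- min(dim(e$coords)[1], max_models)
  if (file.exists(path)) file.remove(path)
  for (k in seq_len(n)) {
    atoms <- data.frame(
      chain = e$spec$chain,
      resno = e$spec$anchor_resno + seq_len(dim(e$coords)[2]),
      resname = "GLY", atom = "CA",
      x = e$coords[k, , 1], y = e$coords[k, , 2], z = e$coords[k, , 3],
      stringsAsFactors = FALSE)
    write_pdb(structure_model(atoms), path, model = k, append = k > 1L)
  }
  invisible(path)
}

#' Summarise a tail-sampling run
#'
#' @param e a `tail_ensemble`
#' @return data.frame with n kept, n failed, and the span (Angstrom) from
#'   anchor to the last residue across conformers (min/median/max)
#' @export
summarize_tail_ensemble <- function(e) {
  L <- dim(e$coords)[2]
  last <- e$coords[, L, , drop = FALSE]; dim(last) <- c(dim(e$coords)[1], 3)
  span <- sqrt(colSums((t(last) - e$anchor)^2))
  data.frame(n = dim(e$coords)[1], n_failed = e$n_failed,
             span_min = min(span), span_median = stats::median(span),
             span_max = max(span))
}
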