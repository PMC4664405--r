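#' Specify a cross-link anchor on a structure
#'
#' An anchor is the atom chosen to represent a cross-linked residue when
#' measuring restraint distances.  The default preference order is the
#' lysine side-chain amine nitrogen (NZ), falling back to CB then CA when the
#' side chain is not resolved; fallbacks are reported in the resolution.
#'
#' @param chain chain id
#' @param resno author residue number
#' @param atoms atom-name preference order
#' @return list of class `anchor_spec`
#' @export
anchor_spec <- function(chain, resno, atoms = c("NZ", "CB", "CA")) {
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 atoms = atoms),
            class = "anchor_spec")
}

# Resolve an anchor to coordinates; returns list(xyz, atom) or error.
.resolve_anchor <- function(m, a) {
  stopifnot(inherits(m, "xl_structure"), inherits(a, "anchor_spec"))
  sub <- m[m$chain == a$chain & m$resno == a$resno, ]
  for (at in a$atoms) {
    hit <- which(sub$atom == at)
    if (length(hit)) {
      r <- sub[hit[1], ]
      return(list(xyz = c(r$x, r$y, r$z), atom = at,
                  fallback = at != a$atoms[1]))
    }
  }
  stop(sprintf("anchor %s/%d unresolvable (tried %s)", a$chain, a$resno,
               paste(a$atoms, collapse = ",")))
}

#' Distance between two anchors
#'
#' @param m an `xl_structure`
#' @param a,b [anchor_spec()] objects
#' @return Euclidean distance in Angstrom
#' @export
anchor_distance <- function(m, a, b) {
  pa <- .resolve_anchor(m, a)
  pb <- .resolve_anchor(m, b)
  sqrt(sum((pa$xyz - pb$xyz)^2))
}

#' Define a cross-link distance restraint
#'
#' The cap (default 15 Angstrom) is the acceptance rule: lysine side-chain
#' reach plus the BS3 spacer.  The spacer length (11.3 Angstrom) is carried
#' as metadata.  Role `"control"` marks a receptor-internal cross-link used
#' as an internal control of a structural model; `"evidence"` marks a
#' receptor-ligand cross-link under test.
#'
#' @param anchor1,anchor2 [anchor_spec()] objects
#' @param cap acceptance distance cap (Angstrom)
#' @param spacer linker spacer length (Angstrom), metadata
#' @param label restraint label
#' @param role `"evidence"` or `"control"`
#' @return list of class `xl_restraint`
#' @export
xl_restraint <- function(anchor1, anchor2, cap = 15, spacer = 11.3,
                         label = NULL, role = c("evidence", "control")) {
  role <- match.arg(role)
  if (is.null(label))
    label <- sprintf("%s%d-%s%d", anchor1$chain, anchor1$resno,
                     anchor2$chain, anchor2$resno)
  structure(list(anchor1 = anchor1, anchor2 = anchor2, cap = cap,
                 spacer = spacer, label = label, role = role),
            class = "xl_restraint")
}

#' Read a restraint table from TSV
#'
#' Expected columns: label, chain1, res1, chain2, res2, cap, role (missing
#' cap defaults to 15, missing role to "evidence").
#'
#' @param path TSV path
#' @param atoms anchor atom preference order
#' @return list of [xl_restraint()] objects
#' @export
read_restraints_tsv <- function(path, atoms = c("NZ", "CB", "CA")) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "chain1", "res1", "chain2", "res2") %in% names(tb)))
  if (is.null(tb$cap)) tb$cap <- 15
  tb$cap <- as.numeric(tb$cap)
  if (is.null(tb$role)) tb$role <- "evidence"
  lapply(seq_len(nrow(tb)), function(i)
    xl_restraint(anchor_spec(tb$chain1[i], tb$res1[i], atoms),
                 anchor_spec(tb$chain2[i], tb$res2[i], atoms),
                 cap = tb$cap[i], label = tb$label[i], role = tb$role[i]))
}

#' Write restraints to TSV
#' @param restraints list of [xl_restraint()] objects
#' @param path output path
#' @export
write_restraints_tsv <- function(restraints, path) {
  tb <- do.call(rbind, lapply(restraints, function(r) data.frame(
    label = r$label, chain1 = r$anchor1$chain, res1 = r$anchor1$resno,
    chain2 = r$anchor2$chain, res2 = r$anchor2$resno, cap = r$cap,
    role = r$role, stringsAsFactors = FALSE)))
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Evaluate cross-link restraints on a structure
#'
#' A restraint is satisfied when its anchor distance is less than or equal
#' to the cap (a distance exactly at the cap satisfies, per the "15 Angstrom
#' or less" acceptance rule).  Unresolvable restraints are marked
#' unevaluable, never silently dropped.
#'
#' @param m an `xl_structure`
#' @param restraints list of [xl_restraint()] objects
#' @return data.frame with columns label, role, cap, distance, satisfied,
#'   evaluable, anchor_atoms
#' @export
evaluate_restraints <- function(m, restraints) {
  do.call(rbind, lapply(restraints, function(r) {
    res <- tryCatch({
      pa <- .resolve_anchor(m, r$anchor1)
      pb <- .resolve_anchor(m, r$anchor2)
      d <- sqrt(sum((pa$xyz - pb$xyz)^2))
      data.frame(label = r$label, role = r$role, cap = r$cap, distance = d,
                 satisfied = d <= r$cap, evaluable = TRUE,
                 anchor_atoms = paste(pa$atom, pb$atom, sep = "-"),
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(label = r$label, role = r$role, cap = r$cap,
                 distance = NA_real_, satisfied = NA, evaluable = FALSE,
                 anchor_atoms = NA_character_, stringsAsFactors = FALSE))
    res
  }))
}

#' Can one ligand molecule bridge two receptor sites?
#'
#' Each cross-link allows its ligand anchor to sit at most `cap` from its
#' receptor anchor.  `"paper"` mode treats the two ligand anchors as
#' colocated, so a single ligand molecule can engage both receptor sites
#' only if the receptor anchors are within `2 * cap` of each other (the
#' 30 Angstrom bound at the default 15 Angstrom cap).  `"triangle"` mode
#' uses the ligand's own anchor separation: placement is possible only if
#' `|d_receptor - d_ligand| <= 2 * cap` (a necessary condition from the
#' triangle inequality).
#'
#' @param d_receptor distance between the two receptor anchors (Angstrom)
#' @param d_ligand distance between the two ligand anchors (Angstrom);
#'   required in triangle mode
#' @param cap per-cross-link distance cap (Angstrom)
#' @param mode `"paper"` or `"triangle"`
#' @return list with components feasible (logical), bound (the numeric bound
#'   applied), mode
#' @export
bridging_feasibility <- function(d_receptor, d_ligand = NULL, cap = 15,
                                 mode = c("paper", "triangle")) {
  mode <- match.arg(mode)
  stopifnot(d_receptor >= 0, cap >= 0)
  if (mode == "paper") {
    bound <- 2 * cap
    feasible <- d_receptor <= bound
  } else {
    stopifnot(!is.null(d_ligand), d_ligand >= 0)
    bound <- 2 * cap
    feasible <- abs(d_receptor - d_ligand) <= bound
  }
  list(feasible = feasible, bound = bound, mode = mode)
}
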