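#' Read a PDB coordinate file
#'
#' Parses ATOM/HETATM records into a flat atom table.  Alternate locations
#' are resolved to the highest-occupancy copy of each (chain, residue, atom).
#' Optionally keeps only the first instance of each chain id, mirroring the
#' usual treatment of multi-copy crystals.
#'
#' @param path path to a PDB-format file
#' @param first_chain_instance if TRUE, when a chain id reappears after other
#'   chains (multiple models/copies), later instances are dropped
#' @return object of class `xl_structure`: a data.frame with columns chain,
#'   resno, resname, atom, altloc, occ, x, y, z
#' @export
read_pdb <- function(path, first_chain_instance = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  sel <- which(substr(lines, 1, 6) %in% c("ATOM  ", "HETATM"))
  if (!length(sel)) stop("no ATOM records in ", path)
  ln <- lines[sel]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(ln, from, to)))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed ATOM record (bad %s) at line %d", what,
                   sel[bad[1]]))
    v
  }
  atoms <- data.frame(
    chain   = trimws(substr(ln, 22, 22)),
    resno   = as.integer(num(23, 26, "residue number")),
    resname = trimws(substr(ln, 18, 20)),
    atom    = trimws(substr(ln, 13, 16)),
    altloc  = trimws(substr(ln, 17, 17)),
    occ     = {
      o <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
      ifelse(is.na(o), 1, o)
    },
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    stringsAsFactors = FALSE)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates in ", path)
  if (first_chain_instance) {
    runs <- rle(atoms$chain)
    first <- !duplicated(runs$values)
    atoms <- atoms[rep(first, runs$lengths), ]
  }
  # altloc: keep the highest-occupancy copy per (chain, resno, atom)
  key <- paste(atoms$chain, atoms$resno, atoms$atom, sep = "\r")
  atoms <- atoms[order(key, -atoms$occ), ]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$atom,
                                   sep = "\r")), ]
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                       atoms$resno), ]
  rownames(atoms) <- NULL
  class(atoms) <- c("xl_structure", "data.frame")
  atoms
}

#' Build a structure model from an atom table
#'
#' @param atoms data.frame with columns chain, resno, resname, atom, x, y, z
#'   (altloc and occ optional)
#' @return an `xl_structure`
#' @export
structure_model <- function(atoms) {
  req <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  stopifnot(all(req %in% names(atoms)))
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("coordinates must be finite")
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  atoms <- atoms[, c("chain", "resno", "resname", "atom", "altloc", "occ",
                     "x", "y", "z")]
  atoms$resno <- as.integer(atoms$resno)
  class(atoms) <- c("xl_structure", "data.frame")
  atoms
}

#' Write a structure model to PDB
#'
#' @param m an `xl_structure`
#' @param path output path
#' @param model if non-NULL, wrap the coordinates in MODEL/ENDMDL with this
#'   model number (for multi-model files, append = TRUE)
#' @param append append to an existing file
#' @export
write_pdb <- function(m, path, model = NULL, append = FALSE) {
  stopifnot(inherits(m, "xl_structure"))
  # contiguous chains (first-appearance order) so readers applying the
  # one-instance-per-chain rule never split a chain into apparent copies
  m <- m[order(match(m$chain, unique(m$chain)), m$resno), ]
  an <- ifelse(nchar(m$atom) < 4L, paste0(" ", m$atom), m$atom)
  recs <- sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                  seq_len(nrow(m)), an, m$resname, m$chain, m$resno,
                  m$x, m$y, m$z, m$occ, 0)
  if (!is.null(model)) recs <- c(sprintf("MODEL     %4d", model), recs,
                                 "ENDMDL")
  con <- file(path, if (append) "a" else "w"); on.exit(close(con))
  writeLines(recs, con)
  if (is.null(model)) writeLines("END", con)
  invisible(path)
}

#' Merge two structure models
#'
#' Used to place a docking-pose ligand in the receptor frame; chain ids must
#' be disjoint.
#'
#' @param receptor,ligand `xl_structure` objects
#' @return combined `xl_structure`
#' @export
merge_structures <- function(receptor, ligand) {
  overlap <- intersect(unique(receptor$chain), unique(ligand$chain))
  if (length(overlap))
    stop("ligand chain ids collide with receptor: ",
         paste(overlap, collapse = ", "))
  structure_model(rbind(as.data.frame(receptor), as.data.frame(ligand)))
}

#' Apply a rigid transform to a structure
#'
#' @param m an `xl_structure`
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 numeric
#' @return transformed `xl_structure`
#' @export
transform_structure <- function(m, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(as.data.frame(m)[, c("x", "y", "z")]) %*% t(rotation)
  m$x <- xyz[, 1] + translation[1]
  m$y <- xyz[, 2] + translation[2]
  m$z <- xyz[, 3] + translation[3]
  m
}
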