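#' Bundle a receptor and an ensemble of docking poses
#'
#' Each pose is a ligand model already expressed in the receptor coordinate
#' frame (the usual output of rigid-body docking).  Ligand chain ids must be
#' disjoint from receptor chain ids.
#'
#' @param receptor an `xl_structure`
#' @param poses named list of ligand `xl_structure` objects (names are pose
#'   ids; unnamed lists get `pose_1..n`)
#' @return list of class `pose_set`
#' @export
pose_set <- function(receptor, poses) {
  stopifnot(inherits(receptor, "xl_structure"), length(poses) >= 1L)
  if (is.null(names(poses)) || any(!nzchar(names(poses))))
    names(poses) <- sprintf("pose_%d", seq_along(poses))
  rc <- unique(receptor$chain)
  for (p in poses)
    if (length(intersect(unique(p$chain), rc)))
      stop("ligand chain ids must be disjoint from receptor chain ids")
  structure(list(receptor = receptor, poses = poses), class = "pose_set")
}

#' Screen docking poses against cross-link restraints
#'
#' Each pose is merged with the receptor and all restraints are evaluated on
#' the composite.  A pose is accepted iff every evidence restraint is
#' satisfied (distance <= cap) and every receptor-internal control restraint
#' passes the control rule.  The default control rule is the same cap;
#' `control_rule = "spacer"` applies the stricter `<= spacer + slack` test
#' motivated by a control cross-link observed essentially at the linker's
#' spacer length.
#'
#' @param ps a [pose_set()]
#' @param restraints list of [xl_restraint()] objects (roles `"evidence"`
#'   and/or `"control"`)
#' @param control_rule `"cap"` or `"spacer"`
#' @param control_slack slack (Angstrom) added to the spacer under
#'   `control_rule = "spacer"`
#' @return list with `evaluations` (data.frame: pose_id, restraint label,
#'   role, distance, satisfied), `verdicts` (data.frame: pose_id, verdict,
#'   reasons) and `summary` (accepted / rejected / unevaluable counts)
#' @export
screen_poses <- function(ps, restraints, control_rule = c("cap", "spacer"),
                         control_slack = 1) {
  stopifnot(inherits(ps, "pose_set"), length(restraints) >= 1L)
  control_rule <- match.arg(control_rule)
  evals <- list(); verdicts <- list()
  for (id in names(ps$poses)) {
    comp <- merge_structures(ps$receptor, ps$poses[[id]])
    ev <- evaluate_restraints(comp, restraints)
    if (control_rule == "spacer") {
      ctrl <- ev$role == "control" & ev$evaluable
      spacers <- vapply(restraints, function(r) r$spacer, 0)
      ev$satisfied[ctrl] <-
        ev$distance[ctrl] <= spacers[ctrl] + control_slack
    }
    ev <- cbind(pose_id = id, ev, stringsAsFactors = FALSE)
    evals[[id]] <- ev
    if (any(!ev$evaluable)) {
      verdict <- "unevaluable"
      reasons <- paste("unresolvable:",
                       paste(ev$label[!ev$evaluable], collapse = ","))
    } else if (all(ev$satisfied)) {
      verdict <- "accepted"; reasons <- ""
    } else {
      verdict <- "rejected"
      reasons <- paste("violated:",
                       paste(ev$label[!ev$satisfied], collapse = ","))
    }
    verdicts[[id]] <- data.frame(pose_id = id, verdict = verdict,
                                 reasons = reasons, stringsAsFactors = FALSE)
  }
  evaluations <- do.call(rbind, evals); rownames(evaluations) <- NULL
  verdicts <- do.call(rbind, verdicts); rownames(verdicts) <- NULL
  list(evaluations = evaluations, verdicts = verdicts,
       summary = c(accepted = sum(verdicts$verdict == "accepted"),
                   rejected = sum(verdicts$verdict == "rejected"),
                   unevaluable = sum(verdicts$verdict == "unevaluable")))
}

#' Single-ligand bridging (mutual-exclusivity) report
#'
#' Given the separation of the two receptor cross-link anchors (measured
#' directly or estimated by tail sampling) and the separation of the two
#' ligand anchors, decides whether one ligand molecule can satisfy both
#' cross-links at once, in both the colocated-anchor ("paper") bound and the
#' triangle-inequality bound.
#'
#' @param d_receptor receptor anchor separation (Angstrom)
#' @param d_ligand ligand anchor separation (Angstrom)
#' @param cap per-cross-link cap (Angstrom)
#' @return list of class `exclusivity_report`: distances, both mode results,
#'   and a human-readable verdict string
#' @export
exclusivity_report <- function(d_receptor, d_ligand, cap = 15) {
  paper <- bridging_feasibility(d_receptor, cap = cap, mode = "paper")
  tri <- bridging_feasibility(d_receptor, d_ligand, cap = cap,
                              mode = "triangle")
  verdict <- if (!paper$feasible)
    sprintf(paste0("infeasible: receptor anchors %.1f A apart exceed the ",
                   "%.0f A single-ligand bound (2 x %.0f A cap); ",
                   "simultaneous engagement of both sites by one ligand ",
                   "molecule is excluded"),
            d_receptor, paper$bound, cap)
  else if (!tri$feasible)
    sprintf(paste0("infeasible by anchor geometry: |%.1f - %.1f| A exceeds ",
                   "2 x %.0f A"), d_receptor, d_ligand, cap)
  else
    sprintf("feasible: both bounds met (receptor %.1f A, ligand %.1f A, cap %.0f A)",
            d_receptor, d_ligand, cap)
  structure(list(d_receptor = d_receptor, d_ligand = d_ligand, cap = cap,
                 paper = paper, triangle = tri, verdict = verdict),
            class = "exclusivity_report")
}

#' @export
print.exclusivity_report <- function(x, ...) {
  cat("Single-ligand bridging feasibility\n")
  cat(sprintf("  receptor anchor separation: %.2f A\n", x$d_receptor))
  cat(sprintf("  ligand anchor separation:   %.2f A\n", x$d_ligand))
  cat(sprintf("  per-link cap:               %.2f A\n", x$cap))
  cat(sprintf("  colocated-anchor bound:     %.2f A -> %s\n", x$paper$bound,
              if (x$paper$feasible) "feasible" else "infeasible"))
  cat(sprintf("  triangle bound:             %.2f A -> %s\n", x$triangle$bound,
              if (x$triangle$feasible) "feasible" else "infeasible"))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Write pose screening results to TSV + JSON summary
#'
#' @param screen result of [screen_poses()]
#' @param tsv_path path for the per-restraint evaluation table
#' @param json_path optional path for the JSON summary
#' @export
write_screen_results <- function(screen, tsv_path, json_path = NULL) {
  utils::write.table(screen$evaluations, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.list(screen$summary), json_path,
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(tsv_path)
}
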