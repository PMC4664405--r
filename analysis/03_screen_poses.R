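#!/usr/bin/env Rscript
# Stage 3: screen the simulated docking ensemble against the cross-link
# restraints.  Each pose must satisfy the receptor-ligand evidence restraint
# (<= 15 A between lysine anchors, the lysine side-chain reach plus BS3
# spacer) and the receptor-internal control cross-link.

suppressPackageStartupMessages(library(xlmapr))
simdir <- "results/sim"
out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rec <- read_pdb(file.path(simdir, "receptor.pdb"))
truth <- read.delim(file.path(simdir, "pose_truth.tsv"))
poses <- lapply(truth$pose_id, function(id)
  read_pdb(file.path(simdir, paste0(id, ".pdb"))))
names(poses) <- truth$pose_id

restraints <- list(
  xl_restraint(anchor_spec("B", 615), anchor_spec("L", 370), cap = 15,
               label = "b615-l370"),
  xl_restraint(anchor_spec("A", 606), anchor_spec("B", 559), cap = 15,
               label = "ctrl-a606-b559", role = "control"))

sc <- screen_poses(pose_set(rec, poses), restraints)
write_screen_results(sc, file.path(out, "evaluations.tsv"),
                     file.path(out, "summary.json"))

accepted <- sc$verdicts$pose_id[sc$verdicts$verdict == "accepted"]
cat(sprintf("poses screened: %d\n", nrow(sc$verdicts)))
print(sc$summary)
cat(sprintf("accepted set matches planted truth: %s\n",
            identical(sort(accepted), sort(truth$pose_id[truth$satisfying]))))
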