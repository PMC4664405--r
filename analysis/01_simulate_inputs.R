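#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream stages consume,
# with known ground truth, under results/sim/.
#
# The stated world: a two-chain receptor whose C-terminal tail lysines sit
# 61.3 A apart with an internal-control lysine pair at 11.2 A; a 100-pose
# docking ensemble with a 7% planted satisfying fraction; MS/MS spectra of
# 10 known BS3 cross-linked peptide pairs at 80% fragment coverage with 40
# noise peaks each; and bound/input densitometry with group mean ratios
# 1.08 / 0.74 / 0.76 at n = 3.

suppressPackageStartupMessages(library(xlmapr))
seed <- 1L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## receptor with the four anchors of interest (distances from explicit 3-D
## points so the matrix is realizable; control pair pinned at 11.2 A)
pts <- rbind(c(0, 0, 0), c(61.3, 0, 0), c(20, 15, 0), c(25.6, 15, 9.7))
u <- (pts[4, ] - pts[3, ]) / sqrt(sum((pts[4, ] - pts[3, ])^2))
pts[4, ] <- pts[3, ] + 11.2 * u
rec <- make_structure_fixture(
  data.frame(chain = c("A", "B", "A", "B"),
             resno = c(672L, 615L, 606L, 559L)),
  as.matrix(dist(pts)))
write_pdb(rec, file.path(out, "receptor.pdb"))

## 100-pose ensemble, 7 satisfying by construction
ev <- list(xl_restraint(anchor_spec("B", 615), anchor_spec("L", 370),
                        cap = 15, label = "b615-l370"))
pe <- make_pose_ensemble(rec, ev, n = 100, f = 0.07, seed = seed)
for (id in names(pe$pose_set$poses))
  write_pdb(pe$pose_set$poses[[id]], file.path(out, paste0(id, ".pdb")))
write.table(pe$truth, file.path(out, "pose_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## target database + 10 planted cross-linked pairs -> MGF
targets <- c(protX = random_protein_seq(120, seed + 10L),
             protY = random_protein_seq(120, seed + 11L))
write_fasta(targets, file.path(out, "targets.fasta"))
db <- build_database(targets, params = digest_params())
idx <- index_peptides(db)
tgt <- idx[!idx$is_decoy, ]
pairs <- withr::with_seed(seed + 1L, {
  pick <- sample(nrow(tgt), 20L)
  lapply(1:10, function(k) {
    i <- pick[2 * k - 1]; j <- pick[2 * k]
    xl_pair(with_cam(peptide(tgt$sequence[i], protein = tgt$protein[i],
                             start = tgt$start[i], end = tgt$end[i])),
            with_cam(peptide(tgt$sequence[j], protein = tgt$protein[j],
                             start = tgt$start[j], end = tgt$end[j])),
            tgt$sites[[i]][1], tgt$sites[[j]][1])
  })
})
sim <- make_xl_spectra(pairs, coverage = 0.8, n_noise = 40, charge = 4L,
                       declare_charge = TRUE, seed = seed + 2L)
write_mgf(sim$spectra, file.path(out, "spectra.mgf"))
write.table(sim$truth, file.path(out, "spectra_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## densitometry replicates
dens <- make_densitometry(seed = seed + 3L)
write.table(dens$table, file.path(out, "densitometry.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("simulated inputs written to", out, "\n")
cat(sprintf("  poses: %d (%d satisfying)\n", nrow(pe$truth),
            sum(pe$truth$satisfying)))
cat(sprintf("  spectra: %d planted pairs\n", nrow(sim$truth)))
cat(sprintf("  densitometry: %d rows\n", nrow(dens$table)))
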