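#!/usr/bin/env Rscript
# Stage 2 — drive the stochastic neuron model with the generated input
# sets. Produces:
#   * granule-cell (GC) recording sets for all eleven 10 Hz Poisson sets,
#   * GC recordings of input sets A and B,
#   * a paired control/disinhibition (GC vs GC+gzn) pair on the 0.76 set,
#   * one recording set per celltype preset on the 0.76 set.
# Run analysis/01_generate_inputs.R first.

library(patsep)

set.seed(20260929L)
dir.create("results/recordings", recursive = TRUE, showWarnings = FALSE)

p10 <- read_trains("results/inputs/p10hz_sets.csv")
set_a <- read_trains("results/inputs/set_a.csv")$set_a
set_b <- read_trains("results/inputs/set_b.csv")$set_b

gc <- celltype_preset("GC")

gc_recs <- lapply(p10, simulate_recording_set, model = gc, celltype = "GC",
                  condition = "aCSF")
names(gc_recs) <- names(p10)
empties <- vapply(gc_recs, function(r) {
  sum(vapply(r$sweeps, is_empty_train, TRUE))
}, 0L)
cat(sprintf("GC recordings: %d sets x 50 sweeps; empty sweeps per set: %s\n",
            length(gc_recs), paste(empties, collapse = "/")))
write_trains(gc_recs, "results/recordings/gc_p10hz.csv")

rec_a <- simulate_recording_set(set_a, gc, celltype = "GC",
                                condition = "aCSF")
rec_b <- simulate_recording_set(set_b, gc, celltype = "GC",
                                condition = "aCSF")
write_trains(list(set_a = rec_a, set_b = rec_b),
             "results/recordings/gc_sets_ab.csv")
cat("GC recordings of input sets A and B written\n")

# paired disinhibition experiment on the reference 0.76 set
ref_set <- p10$p10hz_r076
paired <- list(
  gc_ctrl = simulate_recording_set(ref_set, celltype_preset("GC"),
                                   celltype = "GC", condition = "aCSF"),
  gc_gzn = simulate_recording_set(ref_set, celltype_preset("GC+gzn"),
                                  celltype = "GC", condition = "gzn"))
write_trains(paired, "results/recordings/gzn_pair.csv")
cat(sprintf("disinhibition pair: p(Burst) %.3f (aCSF) vs %.3f (gzn)\n",
            p_burst(paired$gc_ctrl), p_burst(paired$gc_gzn)))

# one recording set per celltype on the same input set
celltypes <- c("GC", "FS", "HMC", "CA3", "GC+gzn")
ct_recs <- lapply(celltypes, function(ct) {
  simulate_recording_set(ref_set, celltype_preset(ct), celltype = ct,
                         condition = if (ct %in% c("CA3", "GC+gzn"))
                           "gzn" else "aCSF")
})
names(ct_recs) <- sub("\\+", "_", celltypes)
write_trains(ct_recs, "results/recordings/celltypes.csv")
cat("celltype battery written:", paste(celltypes, collapse = ", "), "\n")
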