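#!/usr/bin/env Rscript
# Sequence-level disorder metrics for the bundled Cnidoin-related
# peptides: amino-acid composition, charge-hydropathy (Uversky)
# classification, and the GXGQQ elastic-motif scan.

suppressPackageStartupMessages(library(nanospring))
dir.create("results", showWarnings = FALSE)

recs <- read_fasta_records(system.file("extdata", "cnidoin_peptides.fasta",
                                       package = "nanospring"))

rows <- lapply(recs, function(r) {
  m <- uversky_metrics(r)
  hits <- scan_motif(r, "GXGQQ")
  data.frame(id = r$id, length = nchar(r$residues),
             mean_hydropathy = round(m$mean_hydropathy, 4),
             mean_net_charge = round(m$mean_net_charge, 4),
             boundary_charge = round(m$boundary_charge, 4),
             classification = m$classification,
             motif_hits = paste(hits, collapse = ","))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/sequence_disorder.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

comp <- aa_composition(recs[[1]])
write.table(data.frame(residue = names(comp), fraction = round(comp, 4)),
            "results/repeat_unit_composition.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Charge-hydropathy classification of the peptides:\n")
print(tab, row.names = FALSE)
cat(sprintf(paste0(
  "\nDespite classifying on the folded side of the charge-hydropathy\n",
  "boundary (low net charge, high hydropathy), the repeat unit is\n",
  "%.0f%% Gly + %.0f%% Gln + %.0f%% Met -- a composition that cannot\n",
  "form a hydrophobic core; the GXGQQ motif (GCGQQ here) sits at\n",
  "position %d of both repeat units.\n"),
  100 * comp["G"], 100 * comp["Q"], 100 * comp["M"],
  scan_motif(recs[[1]], "GXGQQ")[1]))
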