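#!/usr/bin/env Rscript
# Step 4 — chemical novelty of the hit compounds.
#
# Profiles a synthetic hit set against a synthetic reference set of known
# binders: Tanimoto similarity (dissimilar below 0.7), physicochemical
# descriptors (TPSA, hydrogen-bond donors/acceptors) and scaffold classes.
# Both sets are generated from fragment templates, so scaffold ground truth
# is known; real reference sets (e.g. curated RNA-binder databases) can be
# supplied as SMILES files via read_smiles().

library(ribotriage)
dir.create("results", showWarnings = FALSE)

hits <- gen_compounds(12, seed = 11)$compounds
refs <- gen_compounds(12, templates = c(furan = "c1ccoc1",
                                        pyrrole = "c1cc[nH]c1",
                                        cyclopentane = "C1CCCC1"),
                      seed = 12)$compounds

fh <- compound_fingerprints(setNames(hits$smiles, hits$compound_id))
fr <- compound_fingerprints(setNames(refs$smiles, refs$compound_id))
nov <- novelty_vs_reference(fh, fr, threshold = 0.7)
cat(sprintf("novelty vs reference: mean Tanimoto %.2f +/- %.2f; %d/%d dissimilar (<0.7)\n",
            attr(nov, "mean_of_means"), attr(nov, "sd_of_means"),
            sum(nov$dissimilar), nrow(nov)))
write.csv(nov, "results/novelty.csv", row.names = FALSE)

dh <- compound_descriptors(setNames(hits$smiles, hits$compound_id))
dr <- compound_descriptors(setNames(refs$smiles, refs$compound_id))
cat(sprintf("descriptors: hit TPSA median %.1f vs reference %.1f\n",
            median(dh$tpsa), median(dr$tpsa)))
write.csv(rbind(cbind(set = "hit", dh), cbind(set = "reference", dr)),
          "results/descriptors.csv", row.names = FALSE)

sc <- scaffold_classes(setNames(hits$smiles, hits$compound_id))
cat(sprintf("scaffolds: %d frameworks in %d shape classes among %d hits\n",
            attr(sc, "n_scaffolds"), attr(sc, "n_classes"), nrow(sc)))
write.csv(sc, "results/scaffolds.csv", row.names = FALSE)
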