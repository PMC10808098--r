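#!/usr/bin/env Rscript
# Pairwise Rst distances with 10,000-permutation tests, Bonferroni
# correction at alpha = 0.05, and a 2-D classical MDS of the distance
# matrix.
#
# Reads:  results/data/haplotypes.tsv
# Writes: results/rst_matrix.tsv (+ .pvalues.tsv), results/mds_coordinates.tsv

library(ystrtrace)

survey <- read_haplotype_table("results/data/haplotypes.tsv",
                               normalized = TRUE)
rst <- rst_matrix(survey, n_permutations = 10000L, seed = 2609L,
                  alpha = 0.05)
write_distance_matrix(rst, "results/rst_matrix.tsv")
print(rst)
cat(sprintf("Bonferroni per-test threshold: %.4f (alpha 0.05, m = %d)\n",
            rst$threshold$display, rst$threshold$m))
cat(sprintf("%d of %d pairs significant after correction\n",
            sum(rst$significant[upper.tri(rst$significant)]),
            rst$threshold$m))

mds <- classical_mds(rst, k = 2)
write_mds_embedding(mds, "results/mds_coordinates.tsv")
print(mds)
cat("coordinates:\n")
print(round(mds$coordinates, 4))
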