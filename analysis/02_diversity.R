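#!/usr/bin/env Rscript
# Per-population diversity of the synthetic survey: Nei average gene
# diversity, Vp (mean microsatellite variance), haplotype reiteration and
# cross-population sharing. Under the serial-founder design both diversity
# measures should decay along the colonization chain.
#
# Reads:  results/data/haplotypes.tsv
# Writes: results/diversity_summary.tsv, results/haplotype_sharing.tsv

library(ystrtrace)

survey <- read_haplotype_table("results/data/haplotypes.tsv",
                               normalized = TRUE)
div <- diversity_summary(survey)
write_diversity_summary(div, "results/diversity_summary.tsv")

sh <- haplotype_sharing_summary(survey)
ystrtrace:::utf8_write_tsv(
  data.frame(Population = rownames(sh$sharing), sh$sharing,
             check.names = FALSE),
  "results/haplotype_sharing.tsv")

print(div, digits = 3)
ord <- match(c("Mainland", "Strait", "NearIsle", "MidIsle", "FarIsle"),
             div$population)
cat("\nGD along the chain: ", paste(round(div$nei_gd[ord], 3),
                                    collapse = " -> "), "\n")
cat("Vp along the chain: ", paste(round(div$vp[ord], 3),
                                  collapse = " -> "), "\n")
shared <- sh$sharing; diag(shared) <- 0L
cat("haplotypes shared between at least two populations:",
    sum(shared > 0) / 2, "population pairs\n")
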