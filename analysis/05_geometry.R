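#!/usr/bin/env Rscript
# Reconstitution geometry: v-SNARE surface densities of the three nanodisc
# preparations and the fractional lipid contribution of fused t-SNARE
# vesicles to the planar membrane.

suppressPackageStartupMessages(library(fusepore))
dir.create("results", showWarnings = FALSE)

nd <- data.frame(
  prep = c("ND3S", "ND3L", "ND9L"),
  copies = c(3, 3, 9),
  diameter_nm = c(13, 30, 30)
)
nd$density_per_nm2 <- nd_surface_density(nd$copies, nd$diameter_nm)
print(transform(nd, density_per_nm2 = signif(density_per_nm2, 2)))

frac <- blm_lipid_fraction(vesicles = 40, vesicle_diameter_nm = 50,
                           aperture_diameter_um = 150)
cat(sprintf("BLM lipid fraction from 40 fused 50-nm vesicles: %.4f%%\n", frac))

write.table(nd, "results/geometry_nd_density.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(list(nd_density = nd,
                          blm_lipid_fraction_percent = frac),
                     "results/geometry.json", auto_unbox = TRUE, digits = NA,
                     pretty = TRUE)
cat("written: results/geometry.json, results/geometry_nd_density.tsv\n")
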