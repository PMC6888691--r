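#!/usr/bin/env Rscript
# Stage 5: platinum shell thickness from XPS overlayer attenuation,
# T = L_film * cos(theta) * ln(1 + R), at normal emission with overlayer
# parameter R = 3, for both tabulated attenuation lengths (Au 4f: 1.02 nm;
# Pt: 1.05 nm).

library(npdamage)
dir.create("results", showWarnings = FALSE)

tab <- data.frame(
  photoelectron = c("Au 4f", "Pt"),
  l_film_nm = c(1.02, 1.05),
  theta_deg = 0,
  r_overlayer = 3
)
tab$thickness_nm <- mapply(shell_thickness, tab$l_film_nm, tab$theta_deg,
                           tab$r_overlayer)
print(tab, digits = 4, row.names = FALSE)
cat(sprintf("\nPt shell thickness (Au-4f attenuation): %.1f nm\n",
            round(tab$thickness_nm[1], 1)))
write.csv(tab, "results/shell_thickness.csv", row.names = FALSE)
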