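#!/usr/bin/env Rscript
# Free-ammonia speciation for the enrichment reactor conditions: the
# unionized NH3 fraction of total ammonium nitrogen at thermophilic pH and
# temperature, the variable implicated in suppressing acetoclastic
# methanogens.

suppressMessages(library(saoflux))

conditions <- data.frame(
  label = c("inoculum medium", "steady-state reactor"),
  tan_g_l = c(1.7, 1.6),
  ph = c(7.5, 8.0),
  temp_k = 328.15)
conditions$nh3_g_l <- free_ammonia(conditions$tan_g_l, conditions$ph,
                                   conditions$temp_k)

dir.create("results", showWarnings = FALSE)
utils::write.table(conditions, "results/free_ammonia.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (i in seq_len(nrow(conditions)))
  cat(sprintf("%s: TAN %.1f g N/L, pH %.1f, %.0f K -> %.0f mg NH3-N/L\n",
              conditions$label[i], conditions$tan_g_l[i], conditions$ph[i],
              conditions$temp_k[i], conditions$nh3_g_l[i] * 1000))
cat("(thermophilic acetoclastic inhibition is reported at 200-500 mg NH3-N/L)\n")
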