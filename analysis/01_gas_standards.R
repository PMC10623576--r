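#!/usr/bin/env Rscript
# Gas-standard design: what stock solutions and flows deliver the gas-phase
# set points used throughout the suppression experiments.

suppressMessages(library(sesisuppress))
dir.create("results", showWarnings = FALSE)

flows <- flow_config() # 8 L/min dilution over 5 mL/min chamber flow
cat(sprintf("Mixing-chamber dilution factor: %g\n", dilution_factor(flows)))

# Stock molarities behind the lowest crossover set points, and full
# half-logarithmic ladders up to 1000x
set_points <- data.frame(
  compound = c("acetone", "d6-acetone", "d3-acoh", "pyridine"),
  target_ppm = c(1.1e-2, 1.1e-2, 7.0e-4, 2.7e-4)
)
set_points$stock_molarity <- vapply(seq_len(nrow(set_points)), function(i)
  required_stock(set_points$target_ppm[i],
                 get_compound(set_points$compound[i]), flows), numeric(1))
set_points$check_ppm <- vapply(seq_len(nrow(set_points)), function(i)
  outlet_ppm(set_points$stock_molarity[i],
             get_compound(set_points$compound[i]), flows), numeric(1))
print(set_points, digits = 4)

ladders <- do.call(rbind, lapply(seq_len(nrow(set_points)), function(i) {
  lad <- concentration_ladder(set_points$target_ppm[i], 3, 0.5)
  data.frame(compound = set_points$compound[i], step = seq_along(lad),
             ppm = as.numeric(lad))
}))
write.table(set_points, "results/gas_standard_set_points.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ladders, "results/concentration_ladders.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/gas_standard_set_points.tsv and",
    "results/concentration_ladders.tsv\n")
cat(sprintf(
  "Finding: a %.3g M acetone stock yields %.3g ppm at the outlet; the\n",
  set_points$stock_molarity[1], set_points$check_ppm[1]))
cat("half-log ladder spans 1000x in 7 steps, as in the titration design.\n")
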