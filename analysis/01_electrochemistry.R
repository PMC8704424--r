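#!/usr/bin/env Rscript
# Electrochemical characterisation of the synthetic SIROF-like electrodes:
# charge storage capacity (CSC) from slow cyclic voltammetry, charge
# injection capacity (CIC) from biphasic voltage transients, and the
# resulting per-electrode charge budgets for 10/20/30 um disks.
#
# Usage: Rscript analysis/01_electrochemistry.R [--seed N]

suppressPackageStartupMessages(library(stimlimit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
out_dir <- "results/electrochemistry"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

circ <- sirof_circuit_preset()
limits <- electrochem_limits()

## CSC per diameter: densities should be diameter-invariant
csc_rows <- lapply(c(10, 20, 30), function(d) {
  g <- electrode_geometry(d)
  scan <- gen_cv_trace(circ, g, seed = substream_seed(seed, paste0("cv", d)))
  csc <- compute_csc(scan, g, limits)
  data.frame(diameter_um = d,
             csc_anodic_mC_cm2 = csc$csc_anodic_mC_cm2,
             csc_cathodic_mC_cm2 = csc$csc_cathodic_mC_cm2)
})
csc_tab <- do.call(rbind, csc_rows)
write.csv(csc_tab, file.path(out_dir, "csc_by_diameter.csv"), row.names = FALSE)

truth <- designed_csc(circ, limits)
cat(sprintf("CSC (designed %.1f / %.1f mC/cm^2):\n",
            truth$csc_anodic_mC_cm2, truth$csc_cathodic_mC_cm2))
print(csc_tab, row.names = FALSE)

## CIC from an increasing-current transient family (1 ms phases)
cic_rows <- lapply(c(10, 20, 30), function(d) {
  g <- electrode_geometry(d)
  q_ref <- max_injectable_charge(g, designed_cic(circ, limits)) * 1e-9
  fam <- gen_transient_family(circ, g,
                              currents_A = seq(0.3, 1.6, by = 0.1) * q_ref / 1e-3,
                              seed = substream_seed(seed, paste0("vt", d)))
  cic <- compute_cic(fam, g, limits)
  data.frame(diameter_um = d, cic_mC_cm2 = cic$cic_mC_cm2,
             binding = cic$binding,
             qmax_nC = max_injectable_charge(g, cic$cic_mC_cm2),
             qmax_2sf_nC = max_injectable_charge(g, cic$cic_mC_cm2, signif = 2),
             i_cic_1ms_uA = max_injectable_charge(g, cic$cic_mC_cm2) * 1e-9 / 1e-3 * 1e6)
})
cic_tab <- do.call(rbind, cic_rows)
write.csv(cic_tab, file.path(out_dir, "cic_charge_limits.csv"), row.names = FALSE)

cat(sprintf("\nCIC (designed %.2f mC/cm^2, anodic limit binds):\n",
            designed_cic(circ, limits)))
print(cic_tab, row.names = FALSE)
cat(sprintf("\nCharge budget scales as d^2 (ratios %s relative to 10 um).\n",
            paste(round(cic_tab$qmax_nC / cic_tab$qmax_nC[1], 2), collapse = " : ")))

## full report for downstream stages
jsonlite::write_json(
  list(csc_anodic_mC_cm2 = mean(csc_tab$csc_anodic_mC_cm2),
       csc_cathodic_mC_cm2 = mean(csc_tab$csc_cathodic_mC_cm2),
       cic_mC_cm2 = mean(cic_tab$cic_mC_cm2),
       per_electrode = lapply(seq_len(nrow(cic_tab)), function(r)
         list(diameter_um = cic_tab$diameter_um[r], qmax_nC = cic_tab$qmax_nC[r]))),
  file.path(out_dir, "electrochem_report.json"), auto_unbox = TRUE, digits = NA)
cat("\nwrote", out_dir, "\n")
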