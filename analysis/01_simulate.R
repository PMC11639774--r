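#!/usr/bin/env Rscript
# Stage 1: generate the ground-truthed synthetic study.
#
# Emulates the study design: 66 grape varieties in four berry-color classes
# (17 white / 16 pink / 16 red / 17 purple), three biological replicates
# each, a compound library spanning modified flavonoids, oleanane
# triterpenoids and background metabolite classes, positive-mode MS2 spectra
# at 5 ppm mass error, and a color-structured abundance matrix with purple
# enrichment of acylated flavonoid glycosides and triterpenoids.

suppressPackageStartupMessages(library(vitimet))

seed <- 20241L
n_compounds <- 400L
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
lib <- generate_library(n_compounds, cfg)
truth <- library_truth(lib)
write.csv(truth, file.path(out, "library_truth.csv"), row.names = FALSE)

spectra <- simulate_spectra(lib, cfg)
write_mgf(spectra, file.path(out, "spectra.mgf"))

qt <- simulate_abundance_matrix(lib, cfg)
write_quant_csv(qt, file.path(out, "quant.csv"))
inj <- attr(qt, "truth")$injection_factors
write.csv(data.frame(sample_id = names(inj), injection_factor = inj),
          file.path(out, "injection_factors.csv"), row.names = FALSE)

cat(sprintf("simulated %d compounds (%d ladder-class flavonoids, %d triterpenoids)\n",
            n_compounds,
            sum(truth$compound_class %in% c("simple_flavonoid", "mono_glycoside",
                                            "di_glycoside", "acylated_glycoside")),
            sum(truth$compound_class == "triterpenoid")))
cat(sprintf("%d spectra -> %s\n", length(spectra), file.path(out, "spectra.mgf")))
cat(sprintf("%d x %d abundance matrix (incl. internal standard) -> %s\n",
            nrow(qt$values), ncol(qt$values), file.path(out, "quant.csv")))
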