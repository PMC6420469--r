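#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study.
#
# One hemisphere is emulated by a 2,562-vertex sphere (radius 30 mm) carved
# into 91 geodesic-Voronoi areas; 4 widely spaced areas play the role of
# primary sensory-motor cortex. A connectivity-distance gradient anchored at
# their borders is planted in both data modalities: 10 subjects x 2 scans x
# 250 timepoints of correlated series, and 29 retrograde tracer injections
# with Poisson labeled-neuron counts. The heavyweight time series are not
# written to disk — later stages regenerate them deterministically from the
# same seed; this stage records everything else.

library(geograd)

cfg <- simulation_config()          # seed = 1; defaults are the study design
out <- "results/dataset"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_dataset(cfg, with_timeseries = FALSE)
write_surface_csv(sim$mesh, file.path(out, "vertices.csv"),
                  file.path(out, "faces.csv"))
write_gifti_surface(sim$mesh, file.path(out, "surface.surf.gii"))
write_labels_csv(sim$parc, file.path(out, "labels.csv"),
                 file.path(out, "label_names.csv"))
write_tracer_csv(sim$records, file.path(out, "tracer_counts.csv"),
                 file.path(out, "injection_sites.csv"))
write_map_csv(sim$dist_primary, file.path(out, "dist_primary.csv"))
jsonlite::write_json(sim$ground_truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)
write_manifest(file.path(out, "manifest.json"), "simulate",
               params = unclass(cfg), seed = cfg$seed)

areas <- table(sim$parc$labels)
message("mesh: ", sim$mesh$n_vertices, " vertices, ",
        nrow(sim$mesh$faces), " faces")
message("parcellation: ", length(areas), " areas, ",
        min(areas), "-", max(areas), " vertices each")
message("primary areas: ", paste(sim$parc$names[as.character(sim$primary)],
                                 collapse = ", "))
message("distance from primary: 0-", round(max(sim$dist_primary), 1), " mm")
message("tracer injections: ", length(sim$records), "; median extrinsic ",
        "neurons per injection: ",
        median(vapply(sim$records, function(r) sum(r$counts), numeric(1))))
message("written to ", out)
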