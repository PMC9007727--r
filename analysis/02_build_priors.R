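#!/usr/bin/env Rscript
# Stage 2 — fMRI spatial priors.
#
# Generates the synthetic SPM{T}-like volume (two valid blobs at the true
# dipole locations plus one invalid right-frontal blob), thresholds it
# into clusters, projects each cluster onto the cortical mesh (Voronoi
# assignment), smooths with the mesh Green's function and forms rank-one
# covariance components.  Also builds the 512-patch MSP library.

suppressPackageStartupMessages(library(pebmeg))

seed <- 1
out <- "results"
geo <- readRDS(file.path(out, "geometry.rds"))
mesh <- geo$geometry$mesh
cfg <- study_config(seed = seed)

pspec <- synthetic_prior_spec()
vol <- make_synthetic_statmap(pspec)
write_stat_volume(vol, file.path(out, "synthetic_spmT.nii.gz"))

clusters <- threshold_statmap(vol, cfg$height_T, cfg$extent_k)
message(sprintf("thresholding at T > %.1f, k >= %d: %d clusters (sizes %s)",
                cfg$height_T, cfg$extent_k, length(clusters),
                paste(vapply(clusters, `[[`, 0, "size"), collapse = ", ")))
write_cluster_labels(clusters, vol, file.path(out, "clusters.nii.gz"))

spec <- smoothing_spec(mesh$adjacency, cfg$sigma, cfg$truncation_order)
fmri <- build_prior_set(vol, mesh, cfg$height_T, cfg$extent_k, spec)
is_valid <- classify_priors(fmri, mesh, pspec$valid_centers)
message(sprintf("%d fMRI components (%d valid, %d invalid)",
                length(fmri), sum(is_valid), sum(!is_valid)))

msp <- build_msp_library(mesh, cfg$n_patches, spec, seed = seed + 1)
message(sprintf("MSP library: %d Green's-function patches (sigma = %.1f)",
                length(msp), cfg$sigma))

saveRDS(list(fmri = fmri, is_valid = is_valid, msp = msp, spec_sigma = cfg$sigma),
        file.path(out, "priors.rds"))
write_run_manifest(list(stage = "build_priors", seed = seed,
                        height_T = cfg$height_T, extent_k = cfg$extent_k,
                        sigma = cfg$sigma),
                   c(file.path(out, "synthetic_spmT.nii.gz"),
                     file.path(out, "clusters.nii.gz")),
                   file.path(out, "manifest_priors.json"))
message("stage 2 complete")
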