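#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs — a toy atlas, a
# two-group calcium cohort with planted regional effects, and per-larva
# tail-angle traces with planted movement events.

suppressMessages(library(kinesia))
dir.create("results", showWarnings = FALSE)
seed <- 1L

atlas <- generate_toy_atlas(n_regions = 10, seed = seed)
cat(sprintf("toy atlas: %d masks (%d base regions) on a %s grid\n",
            length(atlas$masks),
            sum(atlas$manifest$class == "base"),
            paste(atlas$grid$shape, collapse = "x")))

spec <- cohort_spec(n_control = 10, n_deficient = 10,
                    neurons_per_larva = 300,
                    effect_active_neurons = 0.30,
                    effect_firing_rate = -0.25,
                    affected_region_labels = c("region02", "region05",
                                               "region08"),
                    duration_s = 300, seed = seed)
cohort <- generate_calcium_cohort(spec, atlas = atlas)
gt <- cohort$ground_truth$neurons
gt$affected_region <- gt$region %in% spec$affected_region_labels
per_larva <- aggregate(cbind(active = active,
                             spikes = true_spike_count) ~
                         larva + group + affected_region, gt, mean)
write.csv(per_larva, "results/01_ground_truth_summary.csv",
          row.names = FALSE)
print(aggregate(active ~ group + affected_region, gt, mean))
cat("planted: +30% active neurons and -25% rate in 3 of 10 regions\n")

plan <- tail_event_plan(rep(c("swim", "struggle", "right_flip",
                              "left_flip"), 4), spacing_s = 17)
gen <- generate_tail_trace(plan, frame_rate = 200, duration_s = 300,
                           seed = seed)
lowres <- resample_to_imaging(remove_baseline(fill_nans(gen$trace)))
write.csv(data.frame(t_s = seq_along(lowres$angle_deg),
                     angle_deg = lowres$angle_deg),
          "results/01_tail_trace_demo_1hz.csv", row.names = FALSE)
cat(sprintf("tail trace demo: %d planted events over %.0f s at 200 Hz\n",
            nrow(plan), 300))
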