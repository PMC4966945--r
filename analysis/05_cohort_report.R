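#!/usr/bin/env Rscript
# Cohort report: produced metrical levels per stimulus, movement-type
# contrast on beat-level counts (rank-sum), regularity summaries weighted by
# response count, and the poor-synchronizer profile clustering.

suppressPackageStartupMessages(library(beatsync))

seed <- 20260927L
trials <- read.delim("results/trial_results.tsv")
parts <- read.delim("results/participants.tsv")
profiles <- read.delim("results/success_profiles.tsv")

## produced metrical levels ------------------------------------------------
tab <- level_distribution_table(trials)
write.table(tab$counts, "results/level_distribution.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Participants per produced level (rows = stimuli):\n")
print(tab$counts, row.names = FALSE)
cat("\nColumn medians (halves rounded to even):\n")
print(tab$medians)

rs <- rank_sum_test(tab$counts$bounce_beat, tab$counts$clap_beat)
cat(sprintf("\nBeat-level counts, bouncing vs clapping: U = %.2f, p = %.4g\n",
            rs$U, rs$p))

## regularity in normal synchronizers --------------------------------------
normals <- parts$participant_id[parts$group == "normal_synchronizer"]
sr_tab <- trials[trials$participant_id %in% normals &
                   trials$trial_class == "normal",
                 c("participant_id", "movement_type", "stimulus_name",
                   "sr", "n_events")]
names(sr_tab)[names(sr_tab) == "n_events"] <- "n"
cs <- condition_summary(sr_tab)
write.table(cs$by_condition, "results/sr_by_condition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nWeighted mean regularity (SR): clapping %.2f vs bouncing %.2f\n",
            cs$by_movement[["clap"]], cs$by_movement[["bounce"]]))
cat(sprintf("Participants with clap SR > bounce SR: %d of %d\n",
            sum(cs$clap_minus_bounce > 0, na.rm = TRUE),
            sum(!is.na(cs$clap_minus_bounce))))

## poor-synchronizer profiles ----------------------------------------------
poor_ids <- parts$participant_id[parts$group == "poor_synchronizer"]
pp <- profiles[profiles$participant_id %in% poor_ids, ]
cl <- cluster_profiles(pp, k_range = 2:6, seed = seed)
cat(sprintf("\nPoor-synchronizer profile clustering: k = %d chosen by silhouette\n",
            cl$k))
cat("Cluster centroids (success proportions):\n")
cent <- data.frame(cluster = seq_len(nrow(cl$centroids)),
                   round(cl$centroids, 3),
                   n = as.integer(table(cl$assignments)))
print(cent, row.names = FALSE)
write.table(cent, "results/poor_profile_centroids.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
assign_df <- data.frame(participant_id = names(cl$assignments),
                        cluster = unname(cl$assignments))
write.table(assign_df, "results/poor_profile_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

arch <- unique(trials[trials$group_truth == "poor",
                      c("participant_id", "trial_mode")])  # not informative
truth <- read.delim("results/cohort_plan.tsv")
truth <- unique(truth[truth$group_truth == "poor",
                      c("participant_id", "archetype")])
merged <- merge(assign_df, truth, by = "participant_id")
cat("\nCluster vs generating archetype:\n")
print(table(merged$cluster, merged$archetype))
cat("\nWrote level_distribution.tsv, sr_by_condition.tsv,",
    "poor_profile_centroids.tsv, poor_profile_clusters.tsv\n")
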