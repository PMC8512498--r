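#!/usr/bin/env Rscript
# Step 5 -- pooled scatter and Bland-Altman figures.
#
# Pools all mean temporal parameters per cohort and per environment and
# draws (a) A1-vs-A2 scatter with the OLS regression line and (b) the
# Bland-Altman plot with mean difference and 1.96-SD limits of agreement.
# Plot data are also written as CSVs so the figures are reproducible
# without rerunning the study.

library(imugait)
library(ggplot2)

master_seed <- 20240901
fig_dir <- "results/figures"
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

study <- suppressWarnings(run_study(master_seed = master_seed))
subjects <- do.call(rbind, lapply(names(study$cells), function(nm) {
  cbind(cell = nm, study$cells[[nm]]$subjects)
}))
mean_vals <- subjects[subjects$statistic == "mean", ]
wide <- reshape(mean_vals[, c("cell", "subject_id", "parameter",
                              "algorithm", "value_s")],
                idvar = c("cell", "subject_id", "parameter"),
                timevar = "algorithm", direction = "wide")
names(wide)[names(wide) == "value_s.A1"] <- "a1"
names(wide)[names(wide) == "value_s.A2"] <- "a2"
wide <- wide[complete.cases(wide[, c("a1", "a2")]), ]
wide$cohort <- sub("_.*", "", wide$cell)
wide$environment <- sub(".*_", "", wide$cell)
write.csv(wide, file.path(fig_dir, "pooled_mean_parameters.csv"),
          row.names = FALSE)

plot_group <- function(data, by, file_stem) {
  sc <- ggplot(data, aes(a1, a2)) +
    geom_point(alpha = 0.5, size = 1) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "darkgreen", linewidth = 0.6) +
    facet_wrap(by, scales = "free") +
    labs(x = "A1, lower back (s)", y = "A2, shank (s)",
         title = "Pooled mean temporal parameters") +
    theme_bw()
  ggsave(file.path(fig_dir, paste0(file_stem, "_scatter.pdf")), sc,
         width = 9, height = 4)

  data$mid <- (data$a1 + data$a2) / 2
  data$diff <- data$a1 - data$a2
  stats <- do.call(rbind, lapply(split(data, data[[by]]), function(d) {
    ba <- bland_altman(d$a1, d$a2)
    data.frame(g = d[[by]][1], mean_diff = ba$mean_diff,
               lo = ba$loa_lower, hi = ba$loa_upper)
  }))
  names(stats)[1] <- by
  ba <- ggplot(data, aes(mid, diff)) +
    geom_point(alpha = 0.5, size = 1) +
    geom_hline(data = stats, aes(yintercept = mean_diff), colour = "purple") +
    geom_hline(data = stats, aes(yintercept = lo), colour = "purple",
               linetype = 2) +
    geom_hline(data = stats, aes(yintercept = hi), colour = "purple",
               linetype = 2) +
    facet_wrap(by, scales = "free") +
    labs(x = "Mean of methods (s)", y = "A1 - A2 (s)",
         title = "Bland-Altman, pooled mean temporal parameters") +
    theme_bw()
  ggsave(file.path(fig_dir, paste0(file_stem, "_bland_altman.pdf")), ba,
         width = 9, height = 4)
  write.csv(stats, file.path(fig_dir, paste0(file_stem, "_loa.csv")),
            row.names = FALSE)
}

plot_group(wide[wide$environment == "indoor", ], "cohort", "by_cohort")
plot_group(wide[wide$cohort == "YA", ], "environment", "by_environment")

cat("Figures and plot-data CSVs written under", fig_dir, "\n")
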