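#!/usr/bin/env Rscript
# Fit the logarithmic accuracy-vs-image-count model to the simulated ladders
# (both deposition regimes) and solve for the minimum number of images
# reaching the 95% accuracy limit; also evaluate the published regression
# coefficients for both strategies. Writes results/accuracy_model.csv.

library(diatomLD)

dir.create("results", showWarnings = FALSE)

fit_ladder <- function(file, label) {
  if (!file.exists(file)) stop("run analysis/02_acquisition_experiment.R first")
  ladder <- read.csv(file)
  do.call(rbind, lapply(split(ladder, ladder$strategy), function(d) {
    curve <- fit_log_curve(data.frame(n_images = d$n_images,
                                      accuracy_pct = d$mean_accuracy_pct),
                           strategy = d$strategy[1])
    data.frame(source = label, strategy = curve$strategy,
               a = curve$a, b = curve$b,
               images_needed_95 = images_needed(curve, 95))
  }))
}

tab <- rbind(
  fit_ladder("results/experiment_csr.csv", "simulated ladder (CSR)"),
  fit_ladder("results/experiment_clustered.csv", "simulated ladder (clustered)"),
  do.call(rbind, lapply(
    list(accuracy_curve(6.5832, 66.32, strategy = "transect"),
         accuracy_curve(4.3587, 77.99, strategy = "scatter")),
    function(cv) data.frame(source = "published coefficients",
                            strategy = cv$strategy, a = cv$a, b = cv$b,
                            images_needed_95 = images_needed(cv, 95))
  ))
)
rownames(tab) <- NULL
print(tab, digits = 4)
write.csv(tab, "results/accuracy_model.csv", row.names = FALSE)

pub <- tab[tab$source == "published coefficients", ]
clu <- tab[tab$source == "simulated ladder (clustered)", ]
cat(sprintf(
  paste0(
    "\nThe published coefficients require %d transect images but only %d scatter\n",
    "images to reach 95%% accuracy. The simulated ladders show where that gap\n",
    "comes from: under complete spatial randomness the strategies are nearly\n",
    "equivalent at equal image counts, but under clustered deposition the\n",
    "scatter threshold (%d images) undercuts the transect threshold (%d) by far,\n",
    "because scattered fields decorrelate from individual clusters while a\n",
    "transect repeatedly samples the same ones.\n"
  ),
  pub$images_needed_95[pub$strategy == "transect"],
  pub$images_needed_95[pub$strategy == "scatter"],
  clu$images_needed_95[clu$strategy == "scatter"],
  clu$images_needed_95[clu$strategy == "transect"]
))
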