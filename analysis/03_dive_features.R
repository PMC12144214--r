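#!/usr/bin/env Rscript
# Step 3: derive the four model features per dive (maximum depth,
# bottom time, dive time, post-dive surface interval), apply the
# standard exclusions (first 24 h, <= 10 m, transmission gaps), and
# fit the pooled log + range transform.

suppressPackageStartupMessages(library(tdrstates))

dives <- read.csv("results/dives_split.csv", stringsAsFactors = FALSE)
feats <- extract_features(dives)

dep_start <- tapply(dives$start_time, dives$individual_id, min)
exc <- apply_exclusions(feats, dep_start, dive_config())
cat("exclusions:", paste(names(exc$counts), exc$counts, collapse = ", "),
    "\n")
feats <- exc$features

tr <- fit_transform(feats)
out <- cbind(feats, as.data.frame(tr$X) |>
               stats::setNames(paste0("t_", colnames(tr$X))))
write.csv(out, "results/features.csv", row.names = FALSE)
jsonlite::write_json(
  list(log_features = tr$spec$log_features,
       range_min = as.list(tr$spec$range_min),
       range_max = as.list(tr$spec$range_max),
       epsilon = tr$spec$epsilon),
  "results/transform_spec.json", auto_unbox = TRUE, digits = NA)
cat(sprintf("wrote %d feature rows -> results/features.csv\n", nrow(out)))
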