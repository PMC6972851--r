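#!/usr/bin/env Rscript
# Stage 2: consensus honey-bee LD50s.
#
# Standardizes the raw toxicity records (unit conversion to ug/bee and the
# four selection criteria) and applies the six-tier consensus ladder to
# produce one contact and one oral LD50 per compound.

suppressPackageStartupMessages(library(beetoxload))
suppressPackageStartupMessages(library(dplyr))

tox <- read_toxicity_table("results/data/toxicity.csv")
use <- read_use_table("results/data/use.csv")

std <- standardize_toxicity_records(tox)
rej <- attr(std, "rejections")
cat(sprintf(
  "Standardization kept %d of %d records; rejections by reason:\n",
  nrow(std), nrow(tox)
))
print(table(rej$reason))

moa <- distinct(select(default_compound_catalog(), compound, moa_group))
cons <- consensus_table(std, unique(use$compound), moa, standardized = TRUE)
readr::write_csv(cons, "results/consensus_ld50.csv")

cat("Consensus tier usage (1 = regulatory point ... 6 = global median):\n")
print(table(cons$tier))
cat(sprintf(
  "Oral LD50 range: %.4f-%.1f ug/bee; most potent compound: %s.\n",
  min(cons$ld50_ug_per_bee[cons$route == "oral"]),
  max(cons$ld50_ug_per_bee[cons$route == "oral"]),
  cons$compound[cons$route == "oral"][
    which.min(cons$ld50_ug_per_bee[cons$route == "oral"])
  ]
))
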