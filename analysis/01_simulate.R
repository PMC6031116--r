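#!/usr/bin/env Rscript
# Stage 1: generate the synthetic SIP study.
#
# Builds the full input set for the downstream stages: a labeled
# "rhizosphere" treatment gradient and an unlabeled "bulk" control over the
# same soil community, a low-GC focal genome (GC 49.95%, true AFE 0.85)
# with imposed replication strand bias, per-fraction genome coverages, and
# the ground-truth record used to judge recovery.

suppressPackageStartupMessages(library(sipscope))

seed <- 42L
out <- "results/fixture"
fx <- make_study_fixture(out, seed = seed)

message("fixture written to ", out)
message("true focal AFE:         ", fx$truth$focal_afe)
message("true focal band centre: ", round(fx$truth$focal_band_centre, 4),
        " g/mL")
message("true origin / terminus: ", fx$truth$ori_true, " / ",
        fx$truth$ter_true, " bp")
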