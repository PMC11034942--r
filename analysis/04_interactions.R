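#!/usr/bin/env Rscript
# Stage 4: community-level antagonism intensity and the taxon-by-taxon
# comparison of the warming x drought and warming x wet scenarios.

suppressMessages(library(qsipgrowth))

calls <- read.delim("results/calls.tsv")
wd <- calls[calls$scenario == "WxD", ]
ww <- calls[calls$scenario == "WxW", ]

antag <- vapply(split(calls$type, calls$scenario), community_antagonism, 1)
comp <- compare_scenarios(wd, ww)

summary <- data.frame(
  scenario = names(antag),
  n_calls = as.vector(table(calls$scenario)[names(antag)]),
  community_antagonism = as.vector(antag))
write.table(summary, "results/interaction_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(as.data.frame(comp$cross_tab), "results/scenario_crosstab.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("Community antagonism: W x D = %.2f, W x W = %.2f (scale -1..3).",
                antag["WxD"], antag["WxW"]))
message(sprintf("%d incorporators classified in both scenarios; %d with higher antagonism under W x W.",
                comp$n_shared, comp$n_higher_in_ww))
message(sprintf("%d taxa shift weak-antagonistic (W x D) -> neutralizing (W x W).",
                comp$cross_tab["weak_antagonistic", "neutralizing"]))
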