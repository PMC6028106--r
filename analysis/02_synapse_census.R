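#!/usr/bin/env Rscript
# Synapse density census: counting-brick stereology on the simulated
# stacks (from 01) and the published per-animal table, with group
# summaries, t-tests and the E/I ratio.

library(neuropilr)

# --- published per-animal table -------------------------------------------
t1 <- load_table1()
rep1 <- census_report(t1)
write.csv(rep1$groups, "results/census_groups_published.csv",
          row.names = FALSE)
write.csv(rep1$tests, "results/census_tests_published.csv",
          row.names = FALSE)

dens <- t1$n_included / t1$volume_um3
for (g in c("adult", "aged")) {
  gs <- group_summary(dens[t1$group == g], g)
  cat(sprintf("%s total density: %.3f +/- %.3f per um^3 (n = %d)\n",
              g, gs$mean, gs$sem, gs$n))
}
ei <- c(adult = mean(ei_ratio(t1[t1$group == "adult", ])),
        aged = mean(ei_ratio(t1[t1$group == "aged", ])))
cat(sprintf("E/I ratio: adult %.3f, aged %.3f (%.1f%% decrease)\n",
            ei["adult"], ei["aged"], percent_change(ei["adult"], ei["aged"])))

# --- simulated stacks ------------------------------------------------------
for (grp in c("adult", "aged")) {
  gen <- readRDS(sprintf("results/simulated_%s.rds", grp))
  cen <- density_census(gen$stack$markers, gen$stack$brick)
  write.csv(cen, sprintf("results/census_simulated_%s.csv", grp),
            row.names = FALSE)
  msb <- msb_census(gen$stack$markers, gen$stack$brick)
  write.csv(msb, sprintf("results/msb_simulated_%s.csv", grp),
            row.names = FALSE)
  cat(sprintf(
    "[sim %s] measured density %.3f vs programmed %.3f; %d MSBs in brick\n",
    grp, cen$total, sum(gen$ground_truth$density), sum(msb$count)))
}
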