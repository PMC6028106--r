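#!/usr/bin/env Rscript
# Generate one synthetic adult and one synthetic aged dataset under the
# study conditions: a 10-um annotated stack of synapse markers and a
# densely reconstructed 5-um sub-volume each. Writes the annotation tables,
# a sample of contact meshes as OBJ, and the construction ground truth.

library(neuropilr)

dir.create("results", showWarnings = FALSE)

for (grp in c("adult", "aged")) {
  cfg <- neuropil_config(group = grp)
  seed <- if (grp == "adult") 101L else 201L
  gen <- generate_neuropil(cfg, seed = seed)

  write.csv(gen$stack$markers,
            sprintf("results/markers_%s.csv", grp), row.names = FALSE)
  contacts <- lapply(gen$sub$contacts[seq_len(min(20, length(gen$sub$contacts)))],
                     `[[`, "mesh")
  write_obj(contacts, sprintf("results/contacts_%s_sample.obj", grp))

  gt <- gen$ground_truth
  cat(sprintf(
    "[%s] %d markers (programmed density %.3f/um^3), %d contacts,\n",
    grp, nrow(gen$stack$markers), sum(gt$density), gt$n_contacts),
    sprintf("  axon length density %.2f um/um^3 (target %.2f), %d perforated contacts\n",
            gt$axon_length_density, cfg$axon_length_density,
            gt$n_perforated))

  saveRDS(gen, sprintf("results/simulated_%s.rds", grp))
}
cat("wrote results/markers_{adult,aged}.csv, contact OBJ samples, RDS scenes\n")
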