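#!/usr/bin/env Rscript
# Step 3: PRE profiles. Forward-models transverse PREs from the ensemble's
# recorded spin-label distances via Solomon-Bloembergen <r^-6> averaging,
# adds measurement noise, applies the three-pass trimmed threshold, and
# checks that the significant set recovers the planted contact face.
# Also demonstrates the apo-vs-bound delta-Gamma2 contrast by re-simulating
# the ensemble at a lower compact population (the "bound" condition).

suppressMessages(library(domcross))
seed <- 1L
out <- "results"
cfg <- default_config(seed)

pre_profile <- function(p_compact, seed) {
  ens <- gen_two_state_ensemble(p_compact = p_compact,
                                n_frames = cfg$ensemble$n_frames, seed = seed)
  b_res <- ens$ranges$PPIASE[1]:ens$ranges$PPIASE[2]
  g2 <- vapply(as.character(b_res), function(r)
    ensemble_gamma2(ens$truth$label_distances[, r], cfg$pre$tau_c_ns * 1e-9),
    numeric(1))
  noisy <- g2 + stats::rnorm(length(g2), 0, cfg$pre$noise_sd)
  list(ens = ens,
       tab = data.frame(residue = b_res, gamma2 = noisy,
                        sigma = cfg$pre$noise_sd, status = "QUANTIFIED",
                        stringsAsFactors = FALSE))
}

set.seed(seed)
apo <- pre_profile(cfg$ensemble$p_compact, seed + 2L)
thr <- twice_filtered_threshold(apo$tab$gamma2)
sig <- classify_significant(apo$tab, thr)
write_results(sig, file.path(out, "pre_profile.tsv"))
hits <- sig$residue[sig$significance == "significant"]
cat(sprintf("threshold M3 + 2 SD = %.3f rad/s; significant residues: %s\n",
            thr$upper, paste(hits, collapse = ", ")))
cat(sprintf("planted contact face: %s -> %s\n",
            paste(apo$ens$truth$face_residues, collapse = ", "),
            if (setequal(hits, apo$ens$truth$face_residues)) "recovered" else "MISMATCH"))

# "substrate-bound" condition: domains spend less time compact, PREs drop
bound <- pre_profile(p_compact = 0.2, seed + 2L)
dg <- delta_gamma2(apo$tab, bound$tab)
sig_dg <- classify_significant(
  data.frame(residue = dg$delta$residue, gamma2 = dg$delta$delta_gamma2,
             status = "QUANTIFIED"), dg$threshold, two_sided = TRUE)
write_results(sig_dg, file.path(out, "pre_delta.tsv"))
cat(sprintf("delta-Gamma2 bounds [%.3f, %.3f]; residues losing contact: %s\n",
            dg$threshold$lower, dg$threshold$upper,
            paste(sig_dg$residue[sig_dg$significance == "significant" &
                                   sig_dg$gamma2 > 0], collapse = ", ")))
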