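#!/usr/bin/env Rscript
# Full-scale study sweep (opt-in; several hours on one CPU).
#
# Runs the complete LN reduction for every included variant of both model
# classes across the three background-noise regimes and five synaptic
# weights, scores all working points on the stepped-Poisson test at full
# population size, and reports the proportion of conditions reaching
# Er_opt >= 0.8 per class, plus the k-means model grouping.
#
#   Rscript scripts/full_sweep.R --seed 1 --out results/full_sweep
#
# Problem sizes follow the full protocol: 20 working points, 1024
# transfer-function trials, 60 fit starts, 4096 neurons, 5 seeds.

suppressPackageStartupMessages(library(lnspike))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(name, default = NULL) {
  i <- which(args == paste0("--", name))
  if (length(i) && i < length(args)) args[i + 1L] else default
}
seed <- as.integer(get_arg("seed", 1))
out <- get_arg("out", "results/full_sweep")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

weights <- list(izhikevich = c(0.1, 0.25, 0.5, 0.6, 0.75),
                amat = c(100, 300, 500, 700, 900))

all_opt <- list()
all_fits <- list()
k <- 0L
for (cls in c("amat", "izhikevich")) {
  for (lab in model_variants(cls)) {
    for (nz in c("none", "balanced", "biased")) {
      for (w in weights[[cls]]) {
        k <- k + 1L
        message(sprintf("[%s %s %s w=%s]", cls, lab, nz, w))
        res <- tryCatch(
          run_ln_pipeline(model_spec(cls, lab), noise_preset(nz, cls), w = w,
                          seed = seed + k),
          error = function(e) {
            message("  failed: ", conditionMessage(e))
            NULL
          })
        er <- if (is.null(res)) NA_real_ else res$er_opt
        all_opt[[k]] <- data.frame(class = cls, model = lab, noise = nz,
                                   w = w, er_opt = er)
        if (!is.null(res) && !is.null(res$fits))
          all_fits[[length(all_fits) + 1L]] <- res$fits
        message(sprintf("  er_opt = %.3f", er))
      }
    }
  }
}
opt <- do.call(rbind, all_opt)
fits <- do.call(rbind, all_fits)
utils::write.csv(opt, file.path(out, "er_opt.csv"), row.names = FALSE)
utils::write.csv(fits, file.path(out, "filter_fits.csv"), row.names = FALSE)

for (cls in c("amat", "izhikevich")) {
  sub <- opt[opt$class == cls, ]
  message(sprintf("%s: %.1f%% of conditions reach Er_opt >= 0.8", cls,
                  100 * mean(!is.na(sub$er_opt) & sub$er_opt >= 0.8)))
  fs <- fits[fits$class == cls, ]
  if (nrow(fs) >= 7) {
    cl <- cluster_models(fs, k = 7, n_init = 100, seed = seed)
    utils::write.csv(cl$groups, file.path(out, paste0("groups_", cls, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cl$counts),
                     file.path(out, paste0("cluster_counts_", cls, ".csv")))
  }
}
message("written: ", out)
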