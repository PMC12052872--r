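#!/usr/bin/env Rscript
# Speed-accuracy tradeoff analyses: conditional accuracy functions (CAF),
# conditional incorrect-activation functions (CIAF), partial-error rates
# and correction likelihood.

library(emgchrono)

tr <- read_trial_table("results/pipeline/trials.tsv")
partials <- read.delim("results/pipeline/partials.tsv")
summ <- read.delim("results/pipeline/summary.tsv")

cat("per-condition rates (mean over participants):\n")
agg <- aggregate(cbind(accuracy, partial_error_rate) ~ sat, summ, mean)
cl <- aggregate(correction_likelihood ~ sat, summ, mean, na.rm = TRUE,
                na.action = na.pass)
agg$correction_likelihood <- cl$correction_likelihood[match(agg$sat,
                                                            cl$sat)]
print(agg, digits = 3, row.names = FALSE)

# pooled conditional functions across participants (per-participant
# functions are in results/pipeline/{caf,ciaf}.tsv)
caf_p <- suppressWarnings(caf(tr, by_participant = FALSE))
ciaf_p <- suppressWarnings(ciaf(tr, partials, by_participant = FALSE))

fmt <- function(cf, s) {
  sub <- cf[cf$sat == s, ]
  out <- tapply(sub$proportion * sub$n_trials, sub$quantile_index, sum) /
    tapply(sub$n_trials, sub$quantile_index, sum)
  paste(sprintf("%.3f", out), collapse = "  ")
}
cat("\nCAF, proportion correct by RT quantile (1..5):\n")
for (s in c("neutral", "accuracy", "speed"))
  cat(sprintf("  %-8s %s\n", s, fmt(caf_p, s)))
cat("CIAF, proportion of incorrect activations by latency quantile:\n")
for (s in c("neutral", "accuracy", "speed"))
  cat(sprintf("  %-8s %s\n", s, fmt(ciaf_p, s)))
cat("(fast impulsive errors surface as the raised first speed bin)\n")

write.table(model_ready(rbind(caf_p, ciaf_p)),
            "results/conditional_functions_pooled.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("written: results/conditional_functions_pooled.tsv\n")
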