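#!/usr/bin/env Rscript
# Stage 2: estimate exponential-phase growth rates.
#
# Fits ln(area) ~ day per plug inside the first-4-days window, keeps one
# randomly chosen plug per SvS plate, and reports how pH shifts control
# growth rates (ANOVA + Tukey HSD on single and SvS controls).

suppressPackageStartupMessages(library(fungalcompete))

plates <- read_plates("results/plates.csv")
fits <- fit_growth_all(plates, window = c(0, 4))
svs_fits <- select_svs_plug(fits[fits$treatment == "SvS", ], seed = 1)

write_growth_fits(fits, "results/growth_fits.csv")
write_growth_fits(svs_fits, "results/svs_fits.csv")

cat(sprintf("fitted %d plug series (skipped %d excluded/unfittable)\n",
            nrow(fits),
            if (is.null(attr(fits, "skipped"))) 0L else
              nrow(attr(fits, "skipped"))))

for (treat in c("single", "SvS")) {
  sub <- if (treat == "SvS") svs_fits else
    fits[fits$treatment == "single", ]
  a <- anova_oneway(sub$rate, sub$ph)
  cat(sprintf("%s controls: pH effect F_%d,%d = %.2f, p = %.3g\n",
              treat, a$df_num, a$df_den, a$f_stat, a$p_value))
  # per-species pH contrasts
  for (sp in sort(unique(sub$focal))) {
    s <- sub[sub$focal == sp, ]
    tk <- tukey_hsd(s$rate, s$ph)
    cat(sprintf("  %-18s pH7 - pH5.6 rate diff %+.3f (Tukey p = %.3g)%s\n",
                sp, tk$mean_diff, tk$adjusted_p,
                if (tk$significant) " *" else ""))
  }
}
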