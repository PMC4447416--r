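#!/usr/bin/env Rscript
# Regenerates the packaged fixtures under inst/extdata from package code.
# Run from the repository root after installing the package:
#   Rscript tools/make_fixtures.R
library(causalmap)

out <- file.path("inst", "extdata")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

mod <- build_insulin_model()
save_ode_model(mod$ode, file.path(out, "insulin_ode.json"))
save_network(mod$network, file.path(out, "insulin_cmap.json"))
writeLines(format_translation_report(translation_report(mod$network)),
           file.path(out, "insulin_translation_report.txt"))

save_condition(insulin_condition("normal"),
               file.path(out, "condition_normal.json"))
save_condition(insulin_condition("t2d"),
               file.path(out, "condition_t2d.json"))

# Example rules file for the CLI: the insulin transient-response screen.
writeLines(jsonlite::toJSON(list(
  schema = "cmap-rules/1",
  rules = list(
    list(kind = "transient_up", observable = c("IRp", "IRip"),
         delta = 0.05, rho = 0.5),
    list(kind = "transient_up", observable = c("IRS1p", "IRS1p307"),
         delta = 0.05, rho = 0.5))),
  auto_unbox = TRUE, pretty = 2, digits = NA),
  file.path(out, "rules_insulin_transient.json"))

# Illustrative (synthetic) rate assignment for the reference integrator:
# fast receptor activation with slower recovery and feedback, chosen so
# the ODE side shows the same qualitative IRp + IRip transient as the
# causal-map pipeline. These are NOT the original publication's values,
# which this model does not reprint.
rates <- c(k1a = 10, k1c = 5, k1basal = 0.05, k1d = 5, k1g = 1,
           k1f = 10, k1r = 0.5,
           k2a = 5, k2b = 1, k2c = 2, k2d = 1, k2f = 1, k2g = 0.5,
           k2basal = 0.05,
           k3a = 2, k3b = 0.5,
           k4a = 2, k4b = 1, k4c = 2, k4e = 2, k4f = 1, k4h = 1,
           k5a1 = 2, k5a2 = 2, k5b = 1, k5c = 2, k5d = 1,
           k6f1 = 2, k6f2 = 2, k6b = 1, km6 = 0.3, n6 = 2,
           k7f = 2, k7b = 1,
           k9f1 = 2, k9b1 = 1, km9 = 0.3, n9 = 2, k9f2 = 2, k9b2 = 1)
writeLines(jsonlite::toJSON(list(
  schema = "cmap-rates/1",
  note = paste("synthetic illustrative rate assignment (not the source",
               "publication's values): fast activation, slower recovery",
               "and feedback, giving a transient IRp+IRip response"),
  values = as.list(rates)),
  auto_unbox = TRUE, pretty = 2, digits = NA),
  file.path(out, "rates_synthetic_transient.json"))

cat("fixtures written to", out, "\n")
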