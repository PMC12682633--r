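#!/usr/bin/env Rscript
# Back-testing: train the APC model on 1990-2010, predict 2011-2021, and
# score the held-out window (MAE, RMSE, CRPS on the log-rate scale, 95%
# interval coverage) along with training-fit criticism (DIC, WAIC, CPO).

library(bapcburden)

stopifnot(file.exists("results/data/burden.csv"))

table <- read_burden_table("results/data/burden.csv")
population <- read_population_grid("results/data/population_both.csv")
grid <- to_lexis_grid(table, population, "incidence", "Synthetica", "both")

report <- backtest(grid, apc_spec(sample_count = 1000, seed = 1L),
                   split_year = 2010)
print(report)

dir.create("results/backtest", recursive = TRUE, showWarnings = FALSE)
validation_report_table(report, "results/backtest/scores.csv")
message("scores under results/backtest/scores.csv")
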